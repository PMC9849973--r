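#' Per-fish condition factors and relative weight
#'
#' Computes, for every fish, the four condition indices used to judge
#' plumpness and habitat well-being:
#' allometric condition `KA = W / L^b`, Fulton's condition
#' `KF = 100 W / L^3`, relative condition `KR = W / (a L^b)`, the standard
#' weight `Ws = a L^b` expected for the length, and the relative weight
#' `WR = 100 W / Ws`. A single full-precision (a, b) pair from the supplied
#' fit feeds KA, KR and Ws, so the identities `WR = 100 KR` and
#' `KA = a KR` hold exactly; `rounded_ab = TRUE` instead uses (a, b) rounded
#' to printed precision (4 and 2 decimals), mimicking hand calculation from a
#' published table.
#'
#' @param sample a [biometric_sample()].
#' @param fit an `lwr_fit` from [fit_lwr()] (conventionally fitted on this
#'   same sample, so that mean KR is ~1).
#' @param rounded_ab use table-precision (a, b) instead of full precision.
#' @return An object of class `condition_profile`: data.frame with columns
#'   `ka`, `kf`, `kr`, `ws`, `wr` and attributes `a`, `b`, `total_length`.
#' @export
condition_profile <- function(sample, fit, rounded_ab = FALSE) {
  stopifnot(inherits(sample, "biometric_sample"))
  a <- fit$a
  b <- fit$b
  if (is.null(a) || a <= 0) stop("fit must supply a > 0")
  if (rounded_ab) {
    a <- round(a, 4)
    b <- round(b, 2)
  }
  l <- sample$total_length
  w <- sample$body_weight
  ws <- a * l^b
  out <- data.frame(
    ka = w / l^b,
    kf = 100 * w / l^3,
    kr = w / ws,
    ws = ws,
    wr = 100 * w / ws
  )
  structure(out, a = a, b = b, total_length = l,
            class = c("condition_profile", "data.frame"))
}

#' Spearman associations of condition indices with total length
#'
#' Spearman rank correlation of each condition index against total length,
#' with a two-sided p-value and a 95% CI obtained through the Fisher
#' z-transform. A constant index vector is flagged rather than correlated.
#'
#' @param profile a [condition_profile()].
#' @param lengths total lengths; defaults to those stored in the profile.
#' @param conf confidence level for the Fisher-transform CI.
#' @return A data.frame with one row per index (`ka`, `kf`, `kr`, `wr`):
#'   `index`, `rs`, `rs_ci_low`, `rs_ci_high`, `p_value`, `flag`.
#' @export
associations_vs_length <- function(profile, lengths = NULL, conf = 0.95) {
  if (is.null(lengths)) lengths <- attr(profile, "total_length")
  n <- length(lengths)
  if (n < 5L) stop("insufficient data: associations require n >= 5")
  one <- function(name) {
    v <- profile[[name]]
    if (max(v) - min(v) <= 1e-10 * max(abs(v)))
      return(data.frame(index = name, rs = NA_real_, rs_ci_low = NA_real_,
                        rs_ci_high = NA_real_, p_value = NA_real_,
                        flag = "undefined-correlation (constant index)"))
    ct <- suppressWarnings(
      stats::cor.test(lengths, v, method = "spearman", exact = FALSE))
    rs <- unname(ct$estimate)
    z <- atanh(min(max(rs, -1 + 1e-12), 1 - 1e-12))
    hw <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
    data.frame(index = name, rs = rs, rs_ci_low = tanh(z - hw),
               rs_ci_high = tanh(z + hw), p_value = ct$p.value, flag = "")
  }
  do.call(rbind, lapply(c("ka", "kf", "kr", "wr"), one))
}

#' Wilcoxon signed-rank test of relative weight against 100
#'
#' Tests whether the population's relative weight WR is centred on 100, the
#' balance point between food availability and predator pressure. A
#' significant departure is read as an imbalanced habitat. Exact signed-rank
#' enumeration is used for n <= 25 (absent ties); the normal approximation
#' with continuity correction otherwise.
#'
#' @param profile a [condition_profile()], or a numeric vector of WR values.
#' @param mu reference relative weight (default 100).
#' @param alpha significance level for the verdict.
#' @return List with `p_value`, `statistic` (V), `mean_wr`, `verdict`
#'   (`"balanced"` / `"imbalanced habitat"`) and `flag`.
#' @export
balance_test <- function(profile, mu = 100, alpha = 0.05) {
  wr <- if (inherits(profile, "condition_profile")) profile$wr
        else as.numeric(profile)
  n <- length(wr)
  if (n < 6L) stop("insufficient data: balance test requires n >= 6")
  if (all(wr == mu))
    return(list(p_value = NA_real_, statistic = NA_real_, mean_wr = mu,
                verdict = "balanced",
                flag = "zero differences: every WR equals the reference"))
  ht <- suppressWarnings(
    stats::wilcox.test(wr, mu = mu, exact = n <= 25, correct = TRUE))
  list(p_value = ht$p.value, statistic = unname(ht$statistic),
       mean_wr = mean(wr),
       verdict = if (ht$p.value < alpha) "imbalanced habitat" else "balanced",
       flag = "")
}
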