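#' Length at first sexual maturity from maximum length
#'
#' Binohlan-Froese empirical estimator
#' `log10(Lm) = -0.1189 + 0.9157 log10(Lmax)`, giving the total length at
#' which 50% of individuals are mature.
#'
#' @param lmax maximum observed total length (cm), > 0; vectorized.
#' @return Lm in cm.
#' @export
size_at_maturity <- function(lmax) {
  stopifnot(all(lmax > 0))
  10^(-0.1189 + 0.9157 * log10(lmax))
}

#' Age at 50% maturity
#'
#' Inverts the growth curve at the maturity length. The printed
#' unit-coefficient form `tm = -(1/1) ln(1 - Lm/Linf)` is the default (it is
#' what reproduces published cross-river tables); pass `k` to use the general
#' form `tm = -(1/K) ln(1 - Lm/Linf)`.
#'
#' @param lm length at maturity (cm), 0 < lm < linf.
#' @param linf asymptotic length (cm).
#' @param k optional growth coefficient (yr^-1) for the general form.
#' @return Age at maturity in years.
#' @export
age_at_maturity <- function(lm, linf, k = NULL) {
  stopifnot(all(linf > 0), all(lm > 0))
  if (any(lm >= linf)) stop("domain error: lm must be < linf")
  core <- -log(1 - lm / linf)
  if (is.null(k)) core else core / k
}

#' Beverton optimum catchable length
#'
#' `Lopt = Linf [3 / (3 + M/K)]`, the length at which the biomass of an
#' unfished cohort peaks and hence the preferred capture size. The default
#' is ratio mode with M/K = 1.5 (the value implicit in published
#' cross-population tables for this estimator, where Lopt = (2/3) Linf);
#' supply `m` and `k` to use a stock-specific ratio instead.
#'
#' @param linf asymptotic length (cm), > 0.
#' @param m natural mortality (yr^-1), optional.
#' @param k growth coefficient (yr^-1), optional.
#' @param mk_ratio M/K ratio used when `m`/`k` are not both given.
#' @return List with `lopt` (cm), `mk_ratio` used and `mode`
#'   (`"ratio"` or `"stock-specific"`).
#' @export
optimum_length <- function(linf, m = NULL, k = NULL, mk_ratio = 1.5) {
  stopifnot(all(linf > 0))
  if (!is.null(m) && !is.null(k)) {
    stopifnot(m > 0, k > 0)
    mk_ratio <- m / k
    mode <- "stock-specific"
  } else {
    stopifnot(mk_ratio > 0)
    mode <- "ratio"
  }
  list(lopt = linf * 3 / (3 + mk_ratio), mk_ratio = mk_ratio, mode = mode)
}

#' Maturity and optimum-length reference points
#'
#' Bundles Lm, tm, Lopt, the +/-10% optimum-length window and the
#' mega-spawner threshold (1.1 Lopt) for a stock, ready for
#' [froese_indicators()].
#'
#' @param lmax maximum observed total length (cm).
#' @param linf asymptotic length; estimated from `lmax` when `NULL`.
#' @param m,k,mk_ratio passed to [optimum_length()].
#' @return An object of class `reference_points`: list with `lmax`, `linf`,
#'   `lm`, `tm`, `lopt`, `lopt_window`, `mega_threshold`, `mk_ratio`,
#'   `mk_mode`.
#' @export
reference_points <- function(lmax, linf = NULL, m = NULL, k = NULL,
                             mk_ratio = 1.5) {
  if (is.null(linf)) linf <- estimate_linf(lmax)
  lm <- size_at_maturity(lmax)
  lo <- optimum_length(linf, m = m, k = k, mk_ratio = mk_ratio)
  structure(list(
    lmax = lmax, linf = linf, lm = lm,
    tm = age_at_maturity(lm, linf),
    lopt = lo$lopt,
    lopt_window = c(0.9, 1.1) * lo$lopt,
    mega_threshold = 1.1 * lo$lopt,
    mk_ratio = lo$mk_ratio, mk_mode = lo$mode
  ), class = "reference_points")
}

#' @export
print.reference_points <- function(x, ...) {
  cat(sprintf(
    "Reference points: Lm = %.2f cm, tm = %.2f yr, Lopt = %.2f cm (M/K = %.2f, %s mode)\n",
    x$lm, x$tm, x$lopt, x$mk_ratio, x$mk_mode))
  cat(sprintf("  optimum window [%.2f, %.2f] cm; mega-spawners > %.2f cm\n",
              x$lopt_window[1], x$lopt_window[2], x$mega_threshold))
  invisible(x)
}

#' Froese catch-sustainability indicators
#'
#' Three percentages over all individuals in the catch: mature fish
#' (L >= Lm; target 100%), fish inside the closed optimum-length window
#' [0.9 Lopt, 1.1 Lopt] (target 100%), and mega-spawners strictly above
#' 1.1 Lopt (target 0%).
#'
#' @param lengths a numeric vector of total lengths, a
#'   [biometric_sample()], or a `length_frequency` (bin midpoints weighted by
#'   counts).
#' @param refpoints a [reference_points()] object.
#' @return List with `pct_mature`, `pct_optimal`, `pct_mega` (each in
#'   [0, 100]) and `n`.
#' @export
froese_indicators <- function(lengths, refpoints) {
  if (inherits(lengths, "length_frequency")) {
    lengths <- rep(lengths$midpoint, lengths$count)
  } else if (inherits(lengths, "biometric_sample")) {
    lengths <- lengths$total_length
  }
  n <- length(lengths)
  if (n == 0L) stop("empty catch")
  win <- refpoints$lopt_window
  list(
    pct_mature = 100 * mean(lengths >= refpoints$lm),
    pct_optimal = 100 * mean(lengths >= win[1] & lengths <= win[2]),
    pct_mega = 100 * mean(lengths > refpoints$mega_threshold),
    n = n
  )
}
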