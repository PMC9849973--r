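# summary.lm warns on noise-free data ("essentially perfect fit"); exact
# power-law or constructed inputs are legitimate here, so that one warning
# is muffled while everything else propagates.
quiet_lm_summary <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Fit a length-weight relationship W = a * L^b
#'
#' Ordinary least squares on the natural-log transformed model
#' `ln W = ln a + b ln L`; `a` is recovered by exponentiation (no smearing
#' correction, matching the conventional naive back-transform). Confidence
#' intervals use Student-t quantiles on the log scale, with the interval for
#' `a` exponentiated. The allometry verdict compares `b` with 3 by t-test
#' (see [test_isometry()]).
#'
#' @param sample a [biometric_sample()].
#' @param length_field,weight_field columns to regress (defaults TL vs BW).
#' @param alpha significance level for the growth-pattern verdict.
#' @param drop_outliers if `TRUE`, points whose absolute studentized residual
#'   on the log scale exceeds `outlier_threshold` are removed and the model
#'   refitted once. Off by default: no principled exclusion rule exists for
#'   these data.
#' @param outlier_threshold studentized-residual cutoff (default 4).
#' @return An object of class `lwr_fit`: list with `a`, `b`, `a_ci95`,
#'   `b_ci95`, `se_b`, `r2`, `n`, `pattern`, `p_isometry`, `t_isometry`,
#'   `n_dropped` and the underlying `lm` fit.
#' @export
fit_lwr <- function(sample, length_field = "total_length",
                    weight_field = "body_weight", alpha = 0.05,
                    drop_outliers = FALSE, outlier_threshold = 4) {
  l <- sample[[length_field]]
  w <- sample[[weight_field]]
  keep <- !is.na(l) & !is.na(w)
  l <- l[keep]; w <- w[keep]
  if (length(l) < 3L) stop("insufficient data: fit_lwr requires n >= 3")
  if (any(l <= 0) || any(w <= 0))
    stop("all lengths and weights must be > 0")
  if (stats::var(log(l)) == 0)
    stop("singular fit: zero length variance")
  df <- data.frame(x = log(l), y = log(w))
  fit <- stats::lm(y ~ x, data = df)
  n_dropped <- 0L
  if (drop_outliers) {
    rs <- stats::rstudent(fit)
    keep2 <- abs(rs) <= outlier_threshold
    n_dropped <- sum(!keep2)
    if (n_dropped > 0L) fit <- stats::lm(y ~ x, data = df[keep2, ])
  }
  co <- quiet_lm_summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  b <- unname(co["x", "Estimate"])
  se_b <- unname(co["x", "Std. Error"])
  n <- length(stats::residuals(fit))
  res <- structure(list(
    a = exp(unname(co["(Intercept)", "Estimate"])),
    b = b,
    a_ci95 = exp(unname(ci["(Intercept)", ])),
    b_ci95 = unname(ci["x", ]),
    se_b = se_b,
    r2 = quiet_lm_summary(fit)$r.squared,
    n = n,
    n_dropped = n_dropped,
    model = fit
  ), class = "lwr_fit")
  iso <- classify_pattern(b, se_b, n, reference = 3, alpha = alpha)
  res$pattern <- iso$verdict
  res$p_isometry <- iso$p_value
  res$t_isometry <- iso$statistic
  res
}

# Shared growth-pattern classifier. An essentially perfect fit (se below
# numerical noise) is classified by direct comparison instead of a t ratio,
# which would be 0/0.
classify_pattern <- function(b, se, n, reference, alpha) {
  if (!is.finite(se) || se < 1e-10) {
    verdict <- if (abs(b - reference) <= 1e-8) "isometric"
    else if (b > reference) "positive_allometric" else "negative_allometric"
    return(list(statistic = NA_real_, df = n - 2, p_value = NA_real_,
                verdict = verdict, reference = reference))
  }
  tstat <- (b - reference) / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  verdict <- if (p < alpha) {
    if (b > reference) "positive_allometric" else "negative_allometric"
  } else "isometric"
  list(statistic = tstat, df = n - 2, p_value = p, verdict = verdict,
       reference = reference)
}

#' @export
print.lwr_fit <- function(x, ...) {
  cat(sprintf("Length-weight relationship  W = %.4g * L^%.3f  (n = %d)\n",
              x$a, x$b, x$n))
  cat(sprintf("  a 95%% CI [%.4g, %.4g]; b 95%% CI [%.3f, %.3f]; r2 = %.3f\n",
              x$a_ci95[1], x$a_ci95[2], x$b_ci95[1], x$b_ci95[2], x$r2))
  cat(sprintf("  growth pattern: %s (p vs b = 3: %.3g)\n",
              x$pattern, x$p_isometry))
  invisible(x)
}

#' Test a regression slope against an isometry reference
#'
#' Two-sided t-test of `b` against the isometric reference value (3 for a
#' length-weight exponent, 1 for a length-length slope), with n - 2 degrees
#' of freedom. The verdict is `positive_allometric` when `b` exceeds the
#' reference significantly, `negative_allometric` when below, `isometric`
#' otherwise; a p-value exactly equal to `alpha` counts as non-significant.
#'
#' @param fit an `lwr_fit` or `llr_fit`, or a list with elements `b` (slope),
#'   `se_b` and `n`.
#' @param reference the isometric value; defaults to 3 for `lwr_fit`, 1 for
#'   `llr_fit`.
#' @param alpha significance level (default 0.05).
#' @return List with `statistic` (t), `df`, `p_value` and `verdict`.
#' @export
test_isometry <- function(fit, reference = NULL, alpha = 0.05) {
  if (is.null(reference))
    reference <- if (inherits(fit, "llr_fit")) 1 else 3
  b <- if (!is.null(fit$b)) fit$b else fit$slope
  se <- if (!is.null(fit$se_b)) fit$se_b else fit$se_slope
  n <- fit$n
  if (is.null(se) || !is.finite(se) || se <= 0)
    stop("degenerate fit: standard error of the slope must be > 0")
  classify_pattern(b, se, n, reference, alpha)
}

#' Fit a length-length relationship TL = a + b * SL
#'
#' Untransformed linear regression of total length on standard length, with
#' the slope tested against the isometric reference 1.
#'
#' @param sample a [biometric_sample()] with standard lengths present.
#' @param alpha significance level for the verdict.
#' @return An object of class `llr_fit`: list with `intercept`, `slope`,
#'   `intercept_ci95`, `slope_ci95`, `se_slope`, `r2`, `n`, `pattern`,
#'   `p_isometry`.
#' @export
fit_llr <- function(sample, alpha = 0.05) {
  sl <- sample$standard_length
  tl <- sample$total_length
  keep <- !is.na(sl)
  if (!all(keep))
    stop("validation error: standard length missing for ",
         sum(!keep), " record(s)")
  if (length(tl) < 3L) stop("insufficient data: fit_llr requires n >= 3")
  fit <- stats::lm(tl ~ sl)
  co <- quiet_lm_summary(fit)$coefficients
  ci <- stats::confint(fit, level = 0.95)
  res <- structure(list(
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope = unname(co["sl", "Estimate"]),
    intercept_ci95 = unname(ci["(Intercept)", ]),
    slope_ci95 = unname(ci["sl", ]),
    se_slope = unname(co["sl", "Std. Error"]),
    r2 = quiet_lm_summary(fit)$r.squared,
    n = length(tl),
    model = fit
  ), class = "llr_fit")
  iso <- classify_pattern(res$slope, res$se_slope, res$n,
                          reference = 1, alpha = alpha)
  res$pattern <- iso$verdict
  res$p_isometry <- iso$p_value
  res
}

# test_isometry needs slope/se under the lwr-style names too
#' @export
`$.llr_fit` <- function(x, name) {
  if (name == "b") return(.subset2(x, "slope"))
  if (name == "se_b") return(.subset2(x, "se_slope"))
  .subset2(x, name)
}

#' Compare length-weight relationships across groups by ANCOVA
#'
#' Fits the full-factorial log-log model `ln W ~ ln L * group`. The p-value
#' for slope equality comes from the interaction term; when slopes are not
#' significantly different at `alpha`, a common-slope model `ln W ~ ln L +
#' group` supplies the p-value for intercept (condition) equality.
#'
#' @param groups a named list of [biometric_sample()] objects (>= 2 groups,
#'   each with n >= 3).
#' @param alpha significance level used to decide whether the common-slope
#'   intercept comparison is meaningful.
#' @return An object of class `ancova_result`: list with `p_slope_equality`,
#'   `p_intercept_equality` (`NA` when slopes differ), `group_labels`,
#'   `alpha`.
#' @export
compare_groups <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop("need at least two groups")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  dat <- do.call(rbind, lapply(names(groups), function(g) {
    s <- groups[[g]]
    if (nrow(s) < 3L) stop("each group needs n >= 3 (group ", g, ")")
    if (stats::var(log(s$total_length)) == 0)
      stop("singular fit: zero length variance in group ", g)
    data.frame(x = log(s$total_length), y = log(s$body_weight), group = g)
  }))
  dat$group <- factor(dat$group)
  full <- stats::lm(y ~ x * group, data = dat)
  av <- stats::anova(full)
  p_slope <- av["x:group", "Pr(>F)"]
  if (!is.finite(p_slope)) p_slope <- 1  # zero interaction SS (F ~ 0)
  p_int <- NA_real_
  if (p_slope >= alpha) {
    common <- stats::lm(y ~ x + group, data = dat)
    p_int <- stats::anova(common)["group", "Pr(>F)"]
  }
  structure(list(p_slope_equality = p_slope, p_intercept_equality = p_int,
                 group_labels = names(groups), alpha = alpha),
            class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA across groups (%s)\n",
              paste(x$group_labels, collapse = ", ")))
  cat(sprintf("  slope equality: p = %.4g\n", x$p_slope_equality))
  if (is.na(x$p_intercept_equality))
    cat("  intercepts not compared (slopes differ)\n")
  else
    cat(sprintf("  intercept equality (common slope): p = %.4g\n",
                x$p_intercept_equality))
  invisible(x)
}

#' Froese's form factor a3.0
#'
#' Rescales the length-weight intercept `a` to the value it would take at
#' b = 3, giving a body-shape descriptor comparable across populations:
#' `a3.0 = 10^(log10 a - s (b - 3))` with `s` the mean slope of the log a
#' versus b regression across LWR studies (-1.358 when no species-specific
#' value exists). Values inside the band 0.0172-0.0193 indicate a short,
#' deep body; smaller values an elongated body; larger values a rounder one.
#'
#' @param a LWR intercept (> 0), in g cm^-b.
#' @param b LWR exponent.
#' @param s slope of log10(a) vs b (default -1.358).
#' @return List with `a3_0`, `shape_band` = `c(0.0172, 0.0193)` and
#'   `body_shape` note.
#' @export
form_factor <- function(a, b, s = -1.358) {
  if (a <= 0) stop("a must be > 0")
  a30 <- a * 10^(-s * (b - 3))
  band <- c(0.0172, 0.0193)
  shape <- if (a30 < band[1]) "elongated"
  else if (a30 <= band[2]) "short and deep"
  else "rounder than short-and-deep"
  list(a3_0 = a30, shape_band = band, body_shape = shape)
}
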