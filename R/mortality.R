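#' Length-converted catch curve
#'
#' Estimates total mortality Z from a length-frequency distribution and
#' growth parameters. Each bin's midpoint length is converted to a relative
#' age `t` by inverting the von Bertalanffy curve, `delta_t` is the time a
#' cohort needs to grow through the bin, and `ln(Nt / delta_t)` is regressed
#' on `t` over the descending limb; `Z = -slope`.
#'
#' The default descending-limb rule uses every bin strictly after the modal
#' bin whose count is at least `min_count` and whose upper edge lies below
#' `linf_fraction * linf` (bins close to the asymptote have unstable age
#' conversions and, under a finite lifespan, truncated counts). Bins with an
#' upper edge at or above `linf` cannot be age-converted and are always
#' excluded, with a note. `limb = c(first, last)` (row indices into the LFD)
#' overrides the automatic rule, mirroring the manual point selection
#' customary for catch-curve plots.
#'
#' @param lfd a `length_frequency` from [bin_lengths()].
#' @param linf asymptotic length (cm).
#' @param k growth coefficient (yr^-1).
#' @param t0 age at zero length (yr); relative ages (t0 = 0) are standard
#'   and sufficient for the slope.
#' @param limb optional integer vector `c(first, last)` of LFD row indices
#'   to use.
#' @param min_count minimum bin count to enter the regression (default 1).
#' @param linf_fraction exclude bins with upper edge >= this fraction of
#'   linf (default 0.95).
#' @return An object of class `catch_curve`: list with `z`, `se_z`,
#'   `intercept`, `r2`, `points` (data.frame `t`, `delta_t`, `count`,
#'   `ln_n_dt`, `used`), `notes`.
#' @export
catch_curve <- function(lfd, linf, k, t0 = 0, limb = NULL,
                        min_count = 1, linf_fraction = 0.95) {
  stopifnot(inherits(lfd, "length_frequency"), linf > 0, k > 0)
  notes <- character()
  convertible <- lfd$upper < linf
  if (any(!convertible))
    notes <- c(notes, sprintf(
      "%d bin(s) with upper edge >= Linf excluded from age conversion",
      sum(!convertible)))
  t_mid <- dt <- rep(NA_real_, nrow(lfd))
  t_mid[convertible] <- relative_age_of_length(
    pmin(lfd$midpoint[convertible], linf * (1 - 1e-12)), linf, k, t0)
  dt[convertible] <- relative_age_of_length(lfd$upper[convertible],
                                            linf, k, t0) -
    relative_age_of_length(lfd$lower[convertible], linf, k, t0)
  if (is.null(limb)) {
    modal <- attr(lfd, "modal_bin")
    used <- seq_len(nrow(lfd)) > modal &
      lfd$count >= min_count &
      lfd$upper < linf_fraction * linf &
      convertible
  } else {
    stopifnot(length(limb) == 2L)
    used <- seq_len(nrow(lfd)) >= limb[1] & seq_len(nrow(lfd)) <= limb[2] &
      convertible & lfd$count > 0
    notes <- c(notes, sprintf("manual limb override rows %d-%d",
                              limb[1], limb[2]))
  }
  if (sum(used) < 3L)
    stop("insufficient data: need >= 3 usable bins on the descending limb")
  y <- ifelse(used, log(lfd$count / dt), NA_real_)
  fit <- stats::lm(y[used] ~ t_mid[used])
  co <- quiet_lm_summary(fit)$coefficients
  structure(list(
    z = -unname(co[2, "Estimate"]),
    se_z = unname(co[2, "Std. Error"]),
    intercept = unname(co[1, "Estimate"]),
    r2 = quiet_lm_summary(fit)$r.squared,
    points = data.frame(t = t_mid, delta_t = dt, count = lfd$count,
                        ln_n_dt = log(lfd$count / dt), used = used),
    notes = notes
  ), class = "catch_curve")
}

#' @export
print.catch_curve <- function(x, ...) {
  cat(sprintf(
    "Length-converted catch curve: Z = %.3f /yr (se %.3f), r2 = %.3f, %d points used\n",
    x$z, x$se_z, x$r2, sum(x$points$used)))
  for (nt in x$notes) cat("  note: ", nt, "\n", sep = "")
  invisible(x)
}

#' Plot a length-converted catch curve
#'
#' Open circles are bins excluded from the regression; solid points entered
#' the fit, with the fitted descending limb drawn through them.
#'
#' @param x a `catch_curve` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.catch_curve <- function(x, ...) {
  p <- x$points[is.finite(x$points$ln_n_dt), ]
  graphics::plot(p$t, p$ln_n_dt, pch = ifelse(p$used, 16, 1),
                 xlab = "Relative age (yr)",
                 ylab = expression(ln(N[t] / Delta * t)), ...)
  graphics::abline(a = x$intercept, b = -x$z)
  invisible(x)
}

#' Natural mortality from longevity
#'
#' `M = -ln(0.01) / tmax`: the mortality rate at which 1% of a cohort
#' survives to the maximum age.
#'
#' @param tmax longevity (yr), > 0.
#' @return M in yr^-1.
#' @export
natural_mortality_from_tmax <- function(tmax) {
  stopifnot(all(tmax > 0))
  -log(0.01) / tmax
}

#' Mortality budget and exploitation rate
#'
#' Partitions total mortality into fishing and natural components,
#' `F = Z - M`, and computes the exploitation rate `E = F/Z`. Under
#' Gulland's heuristic a stock is optimally exploited at E = 0.5; `E < 0.5`
#' reads as under-fished, `E > 0.5` as over-fished. When M exceeds Z the
#' budget is flagged and E is reported as 0 rather than negative.
#'
#' @param z total mortality (yr^-1), > 0.
#' @param m natural mortality (yr^-1), > 0.
#' @param e_optimum exploitation rate treated as optimal (default 0.5).
#' @return An object of class `mortality_budget`: list with `z`, `m`, `f`,
#'   `e`, `verdict`, `flag`.
#' @export
mortality_budget <- function(z, m, e_optimum = 0.5) {
  stopifnot(z > 0, m > 0)
  f <- z - m
  flag <- ""
  if (f < 0) {
    flag <- "M exceeds Z: fishing mortality would be negative; E reported as 0"
    warning(flag)
    e <- 0
  } else {
    e <- f / z
  }
  verdict <- if (e < e_optimum) "under-fished"
  else if (e > e_optimum) "over-fished" else "optimally exploited"
  structure(list(z = z, m = m, f = f, e = e, verdict = verdict, flag = flag),
            class = "mortality_budget")
}

#' @export
print.mortality_budget <- function(x, ...) {
  cat(sprintf(
    "Mortality budget: Z = %.2f, M = %.2f, F = %.2f /yr; E = %.2f (%s)\n",
    x$z, x$m, x$f, x$e, x$verdict))
  if (nzchar(x$flag)) cat("  flag: ", x$flag, "\n", sep = "")
  invisible(x)
}
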