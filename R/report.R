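#' Run the full length-based assessment on a sample
#'
#' Orchestrates the whole workflow on one biometric sample: descriptive
#' statistics and the length-frequency distribution with normality tests;
#' length-weight and length-length regressions with allometry verdicts and
#' the form factor; empirical growth parameters; condition indices with
#' their rank tests; maturity / optimum-length reference points and the
#' Froese indicators; and the catch-curve mortality budget. Every analysis
#' switch in effect is recorded in the returned `settings`.
#'
#' @param sample a [biometric_sample()].
#' @param k growth coefficient (yr^-1); an input, since no length-only
#'   estimator of K exists in this workflow (the route used is recorded).
#' @param bin_width LFD class width (cm).
#' @param alpha significance level for all verdicts.
#' @param mk_ratio M/K ratio for [optimum_length()] ratio mode; set
#'   `use_mk_ratio = FALSE` to use the stock-specific M and K instead.
#' @param use_mk_ratio logical; see above.
#' @param form_slope mean slope of log10(a) vs b for [form_factor()].
#' @param limb optional manual catch-curve limb override (row indices).
#' @return An object of class `biom_report`: a named list of result objects
#'   (see Details) plus `settings`.
#' @export
analyze_sample <- function(sample, k = 0.94, bin_width = 0.5, alpha = 0.05,
                           mk_ratio = 1.5, use_mk_ratio = TRUE,
                           form_slope = -1.358, limb = NULL) {
  stopifnot(inherits(sample, "biometric_sample"))
  has_sl <- !any(is.na(sample$standard_length))
  descr <- rbind(
    cbind(measurement = "total_length_cm",
          descriptive_stats(sample$total_length)),
    if (has_sl) cbind(measurement = "standard_length_cm",
                      descriptive_stats(sample$standard_length)),
    cbind(measurement = "body_weight_g",
          descriptive_stats(sample$body_weight)))
  lfd <- bin_lengths(sample, width = bin_width)
  norm_tl <- normality_test(sample$total_length)
  norm_bw <- normality_test(sample$body_weight)
  lwr <- fit_lwr(sample, alpha = alpha)
  llr <- if (has_sl) fit_llr(sample, alpha = alpha) else NULL
  ff <- form_factor(lwr$a, lwr$b, s = form_slope)
  lmax <- max(sample$total_length)
  growth <- growth_parameters(lmax = lmax, k = k, a = lwr$a, b = lwr$b,
                              k_source = "input")
  cond <- condition_profile(sample, lwr)
  assoc <- associations_vs_length(cond)
  bal <- balance_test(cond, alpha = alpha)
  cc <- catch_curve(lfd, linf = growth$linf, k = k, limb = limb)
  m <- natural_mortality_from_tmax(growth$tmax)
  budget <- mortality_budget(cc$z, m)
  refs <- reference_points(lmax, linf = growth$linf,
                           m = if (use_mk_ratio) NULL else m,
                           k = if (use_mk_ratio) NULL else k,
                           mk_ratio = mk_ratio)
  ind <- froese_indicators(sample, refs)
  structure(list(
    label = attr(sample, "label"),
    descriptives = descr,
    lfd = lfd,
    normality = list(tl = list(W = unname(norm_tl$statistic),
                               p = norm_tl$p.value),
                     bw = list(W = unname(norm_bw$statistic),
                               p = norm_bw$p.value)),
    lwr = lwr, llr = llr, form_factor = ff,
    growth = growth,
    condition = cond, associations = assoc, balance = bal,
    reference_points = refs, indicators = ind,
    catch_curve = cc, mortality = budget,
    settings = list(k = k, k_source = "input", bin_width = bin_width,
                    alpha = alpha, mk_ratio = refs$mk_ratio,
                    mk_mode = refs$mk_mode, form_slope = form_slope,
                    limb = if (is.null(limb)) "automatic"
                           else paste(limb, collapse = ":"))
  ), class = "biom_report")
}

condition_summary_table <- function(report) {
  cond <- report$condition
  rows <- lapply(c("ka", "kf", "kr", "wr"), function(idx)
    cbind(index = idx, descriptive_stats(cond[[idx]])))
  do.call(rbind, rows)
}

report_summary <- function(report) {
  lwr <- report$lwr
  g <- report$growth
  refs <- report$reference_points
  list(
    label = report$label,
    n = report$descriptives$n[1],
    lwr = list(a = lwr$a, b = lwr$b, a_ci95 = lwr$a_ci95,
               b_ci95 = lwr$b_ci95, r2 = lwr$r2, pattern = lwr$pattern,
               p_isometry = lwr$p_isometry),
    llr = if (!is.null(report$llr)) list(
      intercept = report$llr$intercept, slope = report$llr$slope,
      slope_ci95 = report$llr$slope_ci95, r2 = report$llr$r2,
      pattern = report$llr$pattern),
    form_factor = report$form_factor$a3_0,
    body_shape = report$form_factor$body_shape,
    growth = list(linf = g$linf, winf = g$winf, k = g$k, t0 = g$t0,
                  phi_prime = g$phi_prime, tmax = g$tmax),
    normality = report$normality,
    condition = list(mean_wr = report$balance$mean_wr,
                     wilcoxon_p_wr_vs_100 = report$balance$p_value,
                     habitat = report$balance$verdict),
    reference_points = list(lm = refs$lm, tm = refs$tm, lopt = refs$lopt,
                            lopt_window = refs$lopt_window,
                            mk_ratio = refs$mk_ratio, mk_mode = refs$mk_mode),
    indicators = report$indicators[c("pct_mature", "pct_optimal",
                                     "pct_mega")],
    mortality = list(z = report$mortality$z, se_z = report$catch_curve$se_z,
                     catch_curve_r2 = report$catch_curve$r2,
                     m = report$mortality$m, f = report$mortality$f,
                     e = report$mortality$e,
                     verdict = report$mortality$verdict),
    settings = report$settings
  )
}

#' Write a report bundle to disk
#'
#' Emits the assessment as five CSV tables (descriptives, regressions,
#' growth/reference/mortality parameters, condition indices, sustainability
#' indicators), the catch-curve point table, and a single full-precision
#' JSON summary. Output is deterministic: the same report writes
#' byte-identical files.
#'
#' @param report a `biom_report` from [analyze_sample()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "biom_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- function(f) file.path(dir, f)
  wcsv <- function(df, f) {
    utils::write.csv(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     path(f), row.names = FALSE, quote = FALSE)
    path(f)
  }
  lwr <- report$lwr
  reg <- data.frame(
    relationship = "BW = a * TL^b", n = lwr$n, a = lwr$a,
    a_ci_low = lwr$a_ci95[1], a_ci_high = lwr$a_ci95[2], b = lwr$b,
    b_ci_low = lwr$b_ci95[1], b_ci_high = lwr$b_ci95[2], r2 = lwr$r2,
    pattern = lwr$pattern)
  if (!is.null(report$llr)) {
    llr <- report$llr
    reg <- rbind(reg, data.frame(
      relationship = "TL = a + b * SL", n = llr$n, a = llr$intercept,
      a_ci_low = llr$intercept_ci95[1], a_ci_high = llr$intercept_ci95[2],
      b = llr$slope, b_ci_low = llr$slope_ci95[1],
      b_ci_high = llr$slope_ci95[2], r2 = llr$r2, pattern = llr$pattern))
  }
  g <- report$growth
  refs <- report$reference_points
  mort <- report$mortality
  params <- data.frame(
    parameter = c("linf_cm", "winf_g", "k_per_yr", "t0_yr", "phi_prime",
                  "tmax_yr", "lm_cm", "tm_yr", "lopt_cm", "m_per_yr",
                  "z_per_yr", "f_per_yr", "e", "a3_0"),
    value = c(g$linf, g$winf, g$k, g$t0, g$phi_prime, g$tmax, refs$lm,
              refs$tm, refs$lopt, mort$m, mort$z, mort$f, mort$e,
              report$form_factor$a3_0))
  files <- c(
    table1_descriptives = wcsv(report$descriptives, "table1_descriptives.csv"),
    table2_regressions = wcsv(reg, "table2_regressions.csv"),
    table3_parameters = wcsv(params, "table3_parameters.csv"),
    table4_condition = wcsv(cbind_assoc(report), "table4_condition.csv"),
    indicators = wcsv(data.frame(
      indicator = c("pct_mature", "pct_optimal", "pct_mega"),
      value = unlist(report$indicators[c("pct_mature", "pct_optimal",
                                         "pct_mega")]),
      target = c(100, 100, 0)), "indicators.csv"),
    catch_curve = wcsv(report$catch_curve$points, "catch_curve.csv"),
    lfd = wcsv(as.data.frame(report$lfd), "lfd.csv")
  )
  json <- jsonlite::toJSON(report_summary(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
  writeLines(json, path("summary.json"))
  files <- c(files, summary = path("summary.json"))
  invisible(files)
}

cbind_assoc <- function(report) {
  summ <- condition_summary_table(report)
  assoc <- report$associations
  merge(summ, assoc, by = "index", sort = FALSE)
}

#' Comparative reference-point table across populations
#'
#' Applies the empirical estimator chain to published inputs from several
#' populations: for each row (water body) with maximum length `lmax` and,
#' where available, length-weight parameters `a` and `b`, computes the
#' asymptotic length, form factor, length and age at maturity, and optimum
#' catchable length (ratio mode).
#'
#' @param rows a data.frame with columns `label`, `lmax` and optionally
#'   `a`, `b` (use `NA` where a study reports no LWR).
#' @param mk_ratio M/K ratio for the optimum length (default 1.5).
#' @param form_slope mean slope of log10(a) vs b for the form factor.
#' @return A data.frame with columns `label`, `a`, `b`, `lmax`, `linf`,
#'   `a3_0`, `lm`, `tm`, `lopt`.
#' @export
table5_comparative <- function(rows, mk_ratio = 1.5, form_slope = -1.358) {
  stopifnot(all(c("label", "lmax") %in% names(rows)), all(rows$lmax > 0))
  if (is.null(rows$a)) rows$a <- NA_real_
  if (is.null(rows$b)) rows$b <- NA_real_
  linf <- estimate_linf(rows$lmax)
  lm <- size_at_maturity(rows$lmax)
  data.frame(
    label = rows$label, a = rows$a, b = rows$b, lmax = rows$lmax,
    linf = linf,
    a3_0 = ifelse(is.na(rows$a) | is.na(rows$b), NA_real_,
                  mapply(function(a, b) if (is.na(a)) NA_real_ else
                    form_factor(a, b, s = form_slope)$a3_0,
                    rows$a, rows$b)),
    lm = lm,
    tm = age_at_maturity(lm, linf),
    lopt = linf * 3 / (3 + mk_ratio))
}
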