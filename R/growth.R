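#' Asymptotic length from maximum observed length
#'
#' Froese-Binohlan empirical estimator
#' `log10(Linf) = 0.044 + 0.9841 log10(Lmax)`, the standard route to the von
#' Bertalanffy asymptote when only a length sample is available.
#'
#' @param lmax maximum observed total length (cm), > 0.
#' @return Asymptotic length Linf in cm.
#' @export
estimate_linf <- function(lmax) {
  stopifnot(all(lmax > 0))
  10^(0.044 + 0.9841 * log10(lmax))
}

#' Asymptotic weight from the length-weight relationship
#'
#' `Winf = a * Linf^b`, the weight of an average fish grown to the length
#' asymptote.
#'
#' @param a,b length-weight relationship parameters (`a` > 0).
#' @param linf asymptotic length (cm), > 0.
#' @return Asymptotic weight in g.
#' @export
estimate_winf <- function(a, b, linf) {
  stopifnot(a > 0, linf > 0)
  a * linf^b
}

#' Munro-Pauly growth performance index
#'
#' `phi' = log10 K + 2 log10 Linf`, comparable across stocks because faster
#' growth (K) trades off against a smaller asymptote.
#'
#' @param k von Bertalanffy growth coefficient (yr^-1), > 0.
#' @param linf asymptotic length (cm), > 0.
#' @return phi-prime (log10 cm^2 yr^-1 scale).
#' @export
phi_prime <- function(k, linf) {
  stopifnot(k > 0, linf > 0)
  log10(k) + 2 * log10(linf)
}

#' Longevity from the growth coefficient, and its inverse
#'
#' Pauly's rule `tmax = 3/K`: the age at which the von Bertalanffy curve has
#' covered ~95% of the way to the asymptote. `k_from_lifespan()` is the exact
#' inverse.
#'
#' @param k growth coefficient (yr^-1), > 0.
#' @param tmax longevity (yr), > 0.
#' @return Longevity in years, or K in yr^-1.
#' @export
lifespan_from_k <- function(k) {
  stopifnot(all(k > 0))
  3 / k
}

#' @rdname lifespan_from_k
#' @export
k_from_lifespan <- function(tmax) {
  stopifnot(all(tmax > 0))
  3 / tmax
}

#' Age at zero length (Pauly's empirical equation)
#'
#' `log10(-t0) = -0.3922 - 0.2752 log10(Linf) - 1.038 log10(K)`. The result
#' is negative by construction: the curve extrapolates through zero length a
#' fraction of a year before hatching.
#'
#' @param linf asymptotic length (cm), > 0.
#' @param k growth coefficient (yr^-1), > 0.
#' @return t0 in years (always < 0).
#' @export
estimate_t0 <- function(linf, k) {
  stopifnot(linf > 0, k > 0)
  -10^(-0.3922 - 0.2752 * log10(linf) - 1.038 * log10(k))
}

#' Growth coefficient from maturity parameters
#'
#' Beverton's relation linking K to length and age at maturity. The printed
#' form `K = ln(1 + Lm/Linf) tm` is dimensionally a product; the division
#' reading `K = ln(1 + Lm/Linf) / tm` is the one with yr^-1 units and is the
#' default. Set `product = TRUE` for the literal product reading.
#'
#' @param lm length at maturity (cm), 0 < lm < linf.
#' @param linf asymptotic length (cm).
#' @param tm age at maturity (yr), > 0.
#' @param product use the literal product reading.
#' @return K in yr^-1.
#' @export
k_from_maturity <- function(lm, linf, tm, product = FALSE) {
  stopifnot(tm > 0, linf > 0)
  if (any(lm >= linf)) stop("domain error: lm must be < linf")
  core <- log(1 + lm / linf)
  if (product) core * tm else core / tm
}

#' von Bertalanffy length at age
#'
#' `L(t) = Linf [1 - exp(-K (t - t0))]`.
#'
#' @param linf asymptotic length (cm).
#' @param k growth coefficient (yr^-1).
#' @param t0 age at zero length (yr).
#' @param t age (yr), >= t0; vectorized.
#' @return Length in cm (0 at t = t0, -> linf as t -> Inf).
#' @export
vbgf_length_at_age <- function(linf, k, t0 = 0, t) {
  stopifnot(linf > 0, k > 0)
  if (any(t < t0)) stop("t must be >= t0")
  linf * (1 - exp(-k * (t - t0)))
}

#' Relative age at length (inverse von Bertalanffy)
#'
#' `t(L) = t0 - (1/K) ln(1 - L/Linf)`, the inversion used by the
#' length-converted catch curve. With the default `t0 = 0` ages are relative,
#' which is all the catch-curve slope needs.
#'
#' @param l length (cm), 0 <= l < linf; vectorized.
#' @param linf asymptotic length (cm).
#' @param k growth coefficient (yr^-1).
#' @param t0 age at zero length (yr), default 0.
#' @return Relative age in years.
#' @export
relative_age_of_length <- function(l, linf, k, t0 = 0) {
  stopifnot(linf > 0, k > 0)
  if (any(l < 0) || any(l >= linf))
    stop("domain error: lengths must satisfy 0 <= l < linf")
  t0 - log(1 - l / linf) / k
}

#' Assemble the von Bertalanffy growth parameter set
#'
#' Chains the empirical estimators from a maximum observed length, a growth
#' coefficient and the fitted length-weight parameters into the full growth
#' parameter table: Linf, Winf, K, t0, phi-prime and tmax. K is an input
#' (typically taken from the literature or from `k_from_lifespan()`); the
#' route used is recorded in `k_source`.
#'
#' @param lmax maximum observed length (cm); ignored when `linf` is given.
#' @param k growth coefficient (yr^-1).
#' @param a,b length-weight parameters for Winf (optional).
#' @param linf asymptotic length; computed from `lmax` when `NULL`.
#' @param k_source free-text provenance note for K.
#' @return An object of class `growth_parameters`: list with `linf`, `winf`,
#'   `k`, `t0`, `phi_prime`, `tmax`, `lmax`, `k_source`.
#' @export
growth_parameters <- function(lmax = NULL, k, a = NULL, b = NULL,
                              linf = NULL, k_source = "input") {
  if (is.null(linf)) {
    stopifnot(!is.null(lmax))
    linf <- estimate_linf(lmax)
  }
  structure(list(
    linf = linf,
    winf = if (!is.null(a) && !is.null(b)) estimate_winf(a, b, linf)
           else NA_real_,
    k = k,
    t0 = estimate_t0(linf, k),
    phi_prime = phi_prime(k, linf),
    tmax = lifespan_from_k(k),
    lmax = if (is.null(lmax)) NA_real_ else lmax,
    k_source = k_source
  ), class = "growth_parameters")
}

#' @export
print.growth_parameters <- function(x, ...) {
  cat("von Bertalanffy growth parameters\n")
  cat(sprintf("  Linf = %.2f cm   Winf = %.2f g   K = %.2f /yr (%s)\n",
              x$linf, x$winf, x$k, x$k_source))
  cat(sprintf("  t0 = %.4f yr   phi' = %.2f   tmax = %.1f yr\n",
              x$t0, x$phi_prime, x$tmax))
  invisible(x)
}
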