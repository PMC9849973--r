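---
title: "Length-based biometric indices: models, assumptions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-based biometric indices: models, assumptions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishbiom)
```

## The assessment problem

For many small riverine fishes the only data a survey can realistically
collect are per-fish lengths and weights from the commercial catch. This
package implements the standard chain of length-based methods that turns
such a sample into an assessment: population structure, the length–weight
relationship (LWR), empirical von Bertalanffy growth parameters, condition
indices, maturity and optimum-length reference points, and a mortality /
exploitation budget. Each step is a small, well-known estimator; the value
of the package is that the whole chain is implemented coherently, tested,
and validated against a population simulator with known truth.

## Models and estimators

**Length–weight allometry.** Weight follows the power law $W = a L^b$,
fitted by OLS on $\ln W = \ln a + b \ln L$. The exponent is tested against
the isometric value $b = 3$ with a two-sided $t$-test on $n-2$ df
(reference 1 for the TL–SL linear relationship). We deliberately use the
naive back-transform $a = e^{\hat\alpha}$ with no smearing correction,
because that is the convention in the comparative LWR literature the
results feed into; the lognormal retransformation bias this induces in
standard weight $W_s$ is about $e^{\sigma^2/2}-1$ (≈ 1.6 % at the default
residual scale), visible as mean relative weight slightly above 100 on the
fitting sample.

**Empirical growth chain.** With no age data, growth parameters come from
empirical equations (all logs base 10, the convention under which every
published value we cross-check reproduces):

* $\log L_\infty = 0.044 + 0.9841 \log L_{max}$,
* $W_\infty = a L_\infty^b$,
* $\phi' = \log K + 2 \log L_\infty$,
* $t_{max} = 3/K$,
* $\log(-t_0) = -0.3922 - 0.2752 \log L_\infty - 1.038 \log K$,
* $\log L_m = -0.1189 + 0.9157 \log L_{max}$,
* $t_m = -\ln(1 - L_m/L_\infty)$,
* $L_{opt} = L_\infty \frac{3}{3 + M/K}$,
* $M = -\ln(0.01)/t_{max}$.

$K$ is an *input*: the two printed routes to it ($K = 3/t_{max}$ with
$t_{max} = 3/K$) are circular, and the maturity-based relation
$K = \ln(1 + L_m/L_\infty)/t_m$ gives a materially different value
(≈ 0.52 yr⁻¹ at the reference inputs), so `growth_parameters()` records
which route supplied $K$ rather than pretending to estimate it. The
maturity relation is implemented with the dimensionally consistent
division reading; the literal product reading is available behind a flag.
$t_0$ from the empirical equation is negative by construction; the package
reports it as such. For $t_m$ the unit-coefficient form above is the
default because it is the form that reproduces published cross-river
tables; the general $-{(1/K)}\ln(1-L_m/L_\infty)$ variant is available via
the `k` argument.

**Optimum length mode.** `optimum_length()` defaults to ratio mode with
$M/K = 1.5$, i.e. $L_{opt} = \tfrac{2}{3} L_\infty$. Cross-population
tables computed with this estimator are consistent with exactly that
ratio, not with the stock-specific $M/K$ (1.53 at the reference values,
giving 6.02 cm rather than 6.06 cm); both modes are exposed and every
report records which was used.

**Condition indices.** $K_A = W/L^b$, $K_F = 100\,W/L^3$,
$K_R = W/(aL^b)$, $W_s = aL^b$, $W_R = 100\,W/W_s$. One full-precision
$(a, b)$ pair feeds all of them, so $W_R = 100 K_R$ and $K_A = a K_R$ hold
exactly and their rank correlations with length coincide; a `rounded_ab`
switch reproduces the mixed-precision arithmetic of hand-computed tables.
Associations with TL use Spearman's rank correlation (normal-approximation
p-values, Fisher-transform CIs); the $W_R$-vs-100 balance test is a
Wilcoxon signed-rank test, exact for $n \le 25$ and
normal-with-continuity-correction above.

**Mortality.** The length-converted catch curve converts each 0.5-cm bin
midpoint to relative age $t(L) = -\ln(1 - L/L_\infty)/K$, and regresses
$\ln(N_t/\Delta t)$ on $t$; $Z = -$slope. Then $F = Z - M$ and $E = F/Z$,
with $E = 0.5$ the optimal-exploitation heuristic. When $M > Z$ the budget
is flagged rather than returning a negative $F$ silently.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| bin width | 0.5 | cm | resolution of field measurement boards; the class width used throughout the comparative literature |
| bin anchor | 0.0 | cm | left-closed right-open bins anchored at zero match "5.5–6.0" class labels |
| $\alpha$ | 0.05 | – | conventional significance level; ties ($p = \alpha$) are non-significant |
| isometry references | 3 (LWR), 1 (LLR) | – | geometric similarity |
| form-factor slope $s$ | −1.358 | – | mean slope of $\log a$ vs $b$ across LWR studies, used when no species-specific regression exists |
| $M/K$ ratio | 1.5 | – | see optimum-length mode above |
| catch-curve limb | after modal bin, count ≥ 1, upper edge < 0.95 $L_\infty$ | – | see numerical choices |
| outlier drop | off (threshold 4) | – | no principled exclusion rule exists; offered, not imposed |

## The population simulator

`simulate_sample()` draws from the generating model the estimators assume,
so recovery experiments isolate estimator error from model error:

* ages from the steady-state exponential distribution $\propto e^{-Zt}$
  truncated at $t_{max} = 3/K$ (the structure the catch curve assumes;
  truncation keeps lengths below the asymptote);
* individual asymptotes $L_{\infty,i} \sim N(\bar L_\infty,
  cv \cdot \bar L_\infty)$, lengths via the growth curve;
* logistic gear retention $1/(1 + e^{-s_{sel}(L - L_{50})})$, with
  acceptance-resampling to exactly `n_fish`;
* weights $a L^b e^\varepsilon$, $\varepsilon \sim N(0, \sigma)$ with
  $\sigma = 0.18$, chosen so the fitted LWR $r^2$ falls in the 0.90–0.97
  band typical of field samples of this size;
* standard lengths as a noisy fraction (0.813 ± 0.01) of total length.

The default scenario (n = 725, $\bar L_\infty$ = 9.09 cm, $K$ = 0.94 yr⁻¹,
$Z$ = 2.12 yr⁻¹, $a$ = 0.0061, $b$ = 3.33) emulates a heavily
predated small-catfish stock. Its selectivity parameters
($L_{50}$ = 5.0 cm, slope 2.6 cm⁻¹, $cv$ = 0.035) were calibrated once, by
simulation, to reproduce the length structure such surveys report — modal
0.5-cm class at 5.5–6.0 cm, mean TL near 5.8–6.1 cm, catch spanning
roughly 2.6–9 cm — and were then frozen. A genuinely knife-edged gear at
~2.9 cm cannot produce an interior mode at 5.5–6.0 cm under this
steady-state model: with $Z/K \approx 2.26$ the unselected length density
is proportional to $(L_\infty - L)^{Z/K-1}$, which decreases monotonically,
so the modal class sits wherever retention is still ascending. The package
therefore ships a second scenario, `catch_curve_scenario()`, with a sharp
low-$L_{50}$ gear (2.9 cm, slope 10 cm⁻¹) and $cv$ = 0.03, in which
selectivity is complete above the modal class — the regime in which a
catch curve is unbiased — and with $K$ scaled so $Z/K$ stays at the
reference ratio across mortality levels (a descending limb only exists for
$Z/K > 1$).

**What the simulator does not emulate.** No recruitment pulses or seasonal
growth, so the simulated length mode is much flatter than the sharply
peaked distributions fish with short spawning seasons can show in the
field (~17 % of the catch falls in the modal class here, versus close to
half for a strong single cohort), and departures from normality are
correspondingly milder. No sex
structure, no measurement rounding, no dome-shaped selectivity. Passing
recovery tests therefore demonstrates estimator correctness under the
assumed model, not robustness to these field complications. Two
consequences worth knowing: applying the full pipeline to a default-scenario
sample overestimates $Z$ by ~20 % (the gear is still ascending past the
mode, and $L_\infty$ estimated from the sample maximum exceeds the
generating mean asymptote, compressing relative ages), and
`estimate_linf()` applied to the observed maximum recovers the generating
asymptote only to within ~5 % upward bias — both documented behaviours of
these estimators, not defects of the implementation.

## Numerical choices

* Bins are left-closed, right-open, with a small relative guard against
  values sitting one ulp under an exact edge; modal ties resolve to the
  smallest index.
* 95 % CIs on means and regression parameters use Student-t quantiles
  (indistinguishable from z at n = 725, but correct at small n).
* A fit whose slope standard error is below 1e−10 (noise-free data) is
  classified against its isometry reference by direct comparison instead
  of a 0/0 t-ratio.
* Catch-curve bins with upper edge at or above $L_\infty$ cannot be
  age-converted and are excluded with a note; the 0.95 $L_\infty$ cutoff
  additionally drops near-asymptote bins, where $t(L)$ is numerically
  unstable and a finite lifespan truncates counts. The automatic limb is
  every remaining bin strictly after the modal one; a manual
  `limb = c(first, last)` override mirrors the customary hand-selection of
  catch-curve points.
* `form_factor()` computes $a_{3.0} = a \cdot 10^{-s(b-3)}$, which is
  algebraically the published formula but returns exactly `a` at `b = 3`.
* Degenerate inputs fail loudly and specifically: empty samples,
  non-positive measurements (with the offending row), SL > TL, constant
  values passed to the normality test, all-equal relative weights, gears
  that accept fewer than 1 in 10⁴ fish.

## Validation scale

The shipped tests validate the chain at these problem sizes, chosen to
give stable Monte-Carlo summaries while keeping the default suite quick:
LWR coverage and bias over 100 replicated surveys of n = 725; catch-curve
recovery over 50 seeds each at n = 50,000 (median relative error ≈ 1 %,
required < 5 %) and n = 725 (≈ 5 %, required < 15 %); 20-seed stochastic
monotonicity checks for the simulator. The desk-scale estimator chain is
checked against published values for five river populations.

## Known limitations

* $r^2$, correlation coefficients and indicator percentages from any real
  survey depend on raw-data features (outlier handling, measurement
  rounding, recruitment pulses) that neither the estimators nor the
  simulator model; the package reproduces published *estimator outputs*
  from printed inputs, not sample-dependent statistics.
* The empirical equations carry their own (unpropagated) prediction error;
  CIs reported here are conditional on $L_\infty$ and $K$.
* The tmax-based $M$ is a scalar; size-dependent natural mortality is out
  of scope.
* The Shapiro–Wilk wrapper is limited to n ≤ 5000.
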