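---
title: "Rainfall anomalies and short-term mobility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rainfall anomalies and short-term mobility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rainmob)
```

## The scientific problem

Precipitation extremes — droughts and unusually heavy rains — are a suspected
driver of short-term human mobility: being away from one's home community for
more than a month within a year. Quantifying that association from
cross-sectional household surveys linked to gridded precipitation requires
four methodological pieces, each of which this package implements and
validates on synthetic data with known ground truth:

1. an **exposure** that measures how anomalous the year before each interview
   was, relative to the local climate record;
2. a **flexible regression** of the binary mobility outcome on that exposure,
   because the association need not be monotone (drought *and* heavy rain may
   both increase mobility, a U-shape);
3. **marginal standardization** to turn model coefficients into
   population-level risk ratios at policy-relevant exposure levels; and
4. **inference that respects the design**: exposure is assigned at the survey
   cluster (enumeration area, EA) level, so outcomes are correlated within
   clusters.

## The exposure: empirical percentile of 12-month rainfall

For each unique (site, interview date) pair, `build_exposure_table()` sums
daily rainfall over the 365 days before the interview and compares that sum
with the same seasonal window shifted back 1 to 29 whole calendar years. The
current sum is pooled with the 29 historical sums and ranked; the exposure is

$$p = \frac{\mathrm{rank} - 1}{29} \in [0, 1],$$

with tied values receiving midranks. So \(p = 0\) is the driest year on
record, \(p = 1\) the wettest, and the pooled median maps to \(p = 0.5\).
Drought is conventionally the 15th percentile and heavy rain the 85th.

Conventions the package had to fix (the underlying definitions leave them
open), all documented here as deliberate choices:

- **Window**: half-open, 365 days, ending the day *before* the interview; the
  interview day itself is excluded. Historical windows shift the anchor by
  whole calendar years so the seasonal alignment is preserved; a Feb-29
  anchor clamps to Feb-28 in non-leap years.
- **Percentile formula**: pooled 30-value ranking with \((r-1)/29\) and
  midranks. This realizes the 0-to-1 range exactly and sends the pooled
  median to 0.5. Hazen (\((r-0.5)/30\)) and Weibull (\(r/31\)) plotting
  positions are available via the `convention` argument for sensitivity
  analyses. Note the pooled percentile lives on a 30-point lattice; in a
  stationary climate it is uniform *on that lattice*, not continuously
  uniform, which matters when testing distributional properties.
- **Raster linkage**: nearest cell center by great-circle distance (grid
  cells are small relative to typical EA displacement); bilinear
  interpolation over the four surrounding cells is available.
- **Missing rainfall days are never imputed**: the synthetic generator cannot
  produce them and gaps in real data raise an error rather than silently
  biasing a 365-day sum.

## The outcome model

`fit_mobility()` fits, separately by gender, the logistic regression

$$\operatorname{logit} P(\text{mobile}_i = 1) = s(p_i)^\top\beta_s +
x_i^\top\beta_x + \alpha_{c(i)} + \mu_{m(i)},$$

where \(s(p)\) is a restricted cubic spline in the rainfall percentile,
\(x_i\) collects the individual covariates (age; wealth quintile; household
size category; education; literacy; urban residence; marital status),
\(\alpha_c\) are country fixed effects and \(\mu_m\) survey-month indicators.
Because of the country fixed effects the model is a *within* estimator:
respondents are compared with differently-exposed respondents in the same
country.

**Spline basis.** `rcs_basis()` uses the standard restricted (natural)
truncated-power construction, normalized by \((t_k - t_1)^2\): \(k\) knots
give \(k-1\) columns (one linear, \(k-2\) nonlinear), and the fitted function
is exactly linear beyond both boundary knots. Knots sit at conventional
quantiles of the observed exposure (10/50/90 for three knots, 5/35/65/95 for
four, 5/27.5/50/72.5/95 for five); the *number* of knots is chosen by AIC
over \(\{3, 4, 5\}\), with exact ties resolved toward fewer knots. Reference
categories are fixed and documented: poorest wealth quintile, household size
1–2, no education, alphabetically first country code, January (or the
earliest month present).

One deliberate deviation from a strict reading of the source analysis: the
covariate footnote accompanying the stratified results omits the survey-month
indicator and marital status from its control list, while the main model
description includes a survey-month indicator. The pipeline keeps survey
month in *all* models and includes marital status, flagging the discrepancy
here rather than guessing which specification produced which table.

**Estimation.** The MLE is computed by iteratively reweighted least squares
(Newton scoring with step-halving, so the log-likelihood is monotonically
non-decreasing) to a score max-norm below \(10^{-8}\). Complete separation —
every observation classified perfectly, or diverging coefficients — is an
explicit error, never a silent fit; isolated saturated cells (an empty dummy
category in a small stratum) are tolerated as in standard GLM practice, and a
covariate that is constant within a stratum is dropped from that stratum's
design with a record on the fit. Rank-deficient designs are an error that
names the collinear columns.

**Variance.** Standard errors are clustered at the site (EA) level with the
CR1 sandwich: bread = inverse Fisher information, meat = sum of
within-cluster score-sum outer products, scaled by \(G/(G-1)\) for \(G\)
clusters — the small-sample correction used by common statistical-package
defaults; CR0 is available by flag. With singleton clusters this reduces to
HC0 times the finite-cluster factor, which the tests verify against an
independent implementation.

## Marginal risk ratios and effect modification

`marginal_probability()` implements marginal standardization (g-computation):
every respondent's spline (and interaction) columns are re-evaluated at the
counterfactual percentile \(p\), all other covariates are left as observed,
and the fitted probabilities are averaged. The marginal risk ratio is

$$RR(p_1, p_0) = \frac{\bar P(p_1)}{\bar P(p_0)},$$

by default at the drought (0.15 vs 0.50) and heavy-rain (0.85 vs 0.50)
contrasts. Confidence intervals default to the **delta method on
\(\log RR\)** — the analytic gradient of the log ratio propagated through the
cluster-robust covariance — because the source analysis does not state its
interval method and the delta method is deterministic and cheap. A seeded
**cluster bootstrap** (sites resampled with replacement, model refit,
percentile interval) is the built-in cross-check; the tests require the two
to agree closely on a standard scenario.

Effect modification by marital status enters as married × spline interaction
columns; `interaction_test()` is the joint Wald test
\(\beta_{\text{int}}^\top V_{\text{int}}^{-1}\beta_{\text{int}}\) on the
clustered covariance sub-block, \(\chi^2\) with one degree of freedom per
interaction column, declared at \(p < 0.05\). Marital-status-stratified RRs
are computed from this *single* interaction model by standardizing over
married and unmarried respondents separately — keeping the joint test
coherent with the stratum estimates — with plain per-stratum refits available
as a sensitivity flag (`stratified_fits = TRUE`); whether the original
analysis used one interaction model or separate fits is not stated, so the
package makes the internally consistent choice the default. Gender is always
handled as fully separate fits, never a pooled interaction.

## The synthetic data generator

Because the motivating analysis runs on restricted-access microdata joined to
a large raster archive, validation is property-based on synthetic data whose
truth is known. The generator is first-class, tested code.

**Rainfall** (`simulate_rain_grid()`): daily rainfall on a regular lon/lat
grid is a sinusoidal seasonal intensity curve scaled, per cell and year, by a
gamma multiplier with mean 1 and coefficient of variation `interannual_cv`
(drought years are well-defined small multipliers; annual totals are
realistically right-skewed), times optional day-level gamma noise. Expected
annual total per cell is `annual_mean_mm`. Defaults: 900 mm/yr, seasonal
amplitude 0.8, interannual CV 0.25, day-level CV 1 — values in the range of
sub-Saharan rainfall regimes.

**Survey** (`simulate_survey()`): sites uniform over the grid interior,
nested in countries; one interview date per site in the final year (so all
respondents at a site share the exposure, matching EA-level linkage);
covariates drawn from gender-specific distributions calibrated to the
motivating survey population (urban 38%, literacy 53%/67% for women/men,
married 48.5%/44.8%, near-uniform wealth quintiles, right-skewed adult ages
with means 28.5/30.7).

**Outcome** (`simulate_outcome()`): Bernoulli with

$$\operatorname{logit} P = b_0 + \gamma\,u(p) + \delta\,\text{married}\,u(p)
+ x^\top\beta + u_{\text{site}}, \qquad u(p) = 4(p - 0.5)^2,$$

where \(u(p)\) is a U-shaped score (0 at the median, 1 at either extreme),
\(u_{\text{site}} \sim N(0, \sigma_s^2)\) induces within-EA correlation, and
the interaction acts on the quadratic term only — the simplest process that
produces marital-status effect modification. Defaults: \(b_0 =
\operatorname{logit}(0.124)\) calibrates prevalence to the observed 12.4%;
\(\gamma = 0.115\) makes the true drought and heavy-rain RRs ≈ 1.05, the
reported magnitude; \(\sigma_s = 0.3\) on the logit scale (within-EA outcome
correlation is not characterized in the source, so this is a free synthetic
parameter chosen to make clustering consequential — naive intervals visibly
undercover while cluster-robust ones hold level); modest covariate effects
(per-decade age −0.15, urban +0.15, married −0.25, literate +0.05).

`true_marginal_rr()` is the ground-truth oracle: the marginal risk ratio
implied by a generating process, integrating site intercepts out by seeded
Monte Carlo and averaging over the supplied respondents. With
\(\sigma_s = 0\) and no covariates it reduces to the closed-form expit ratio,
which the tests verify to \(10^{-4}\).

All randomness flows from one master seed through named sub-streams
(`substream_seed()`), so each stage is independently reproducible and a fixed
configuration yields a byte-identical report payload.

**What the generator does *not* emulate** — hence what passing tests cannot
show about real data: the spatial covariance of real precipitation products,
real geography, two-stage survey sampling and weights, non-stationary
climate trends (the synthetic climate is stationary, so percentiles are
uniform by construction; observed real-world means near 0.45 reflect drier
recent years, which the generator does not reproduce), measurement error in
cluster displacement, and missing data mechanisms (the generator produces
complete data; missingness is only injected by tests of the complete-case
filter).

## Simulation study sizes and what they established

The package's validation experiments (the `test-acceptance` suite) use the
following desk-scale study conditions, chosen once as a balance between
statistical resolution and a single-CPU run:

- **Parameter recovery**: 400 sites × 100 respondents, \(\sigma_s = 0.3\),
  U-shaped truth with RR ≈ 1.05; 300 replicates; a fixed 4-knot basis
  (isolating estimation from knot-selection noise, whose behaviour is
  validated separately). Mean log-RR bias at both contrasts is required to be
  below 0.01, and delta-method CI coverage within [0.90, 1.00].
- **Null calibration**: 100 replicates at n = 100,000 for the RR centering,
  and 100 replicates with 400 clusters for the size of the joint interaction
  test (acceptance band 1%–12% at the 5% level).
- **Clustering**: 100 replicates of the standard scenario under a null
  exposure effect; naive intervals must undercover (< 92%) while
  cluster-robust intervals stay within [0.90, 1.00].
- **U-shape reproduction**: 4,000 sites × 40 respondents (enough clusters
  that a true RR of 1.05 is reliably detected), 20 replicates; both contrast
  RRs must exceed 1 and the fitted marginal curve must attain its minimum in
  the interior in at least 95% of replicates.

Two small systematic effects are worth knowing about, both quantified during
development and visible in the recovery experiment's tolerances. First, the
plug-in estimator of \(\log RR\) has a finite-cluster (Jensen-type) upward
bias of order a few thousandths at 400 clusters, shrinking as clusters grow.
Second, a restricted cubic spline is linear in its tails and therefore cannot
represent a globally quadratic logit exactly; the residual approximation bias
at the 0.15/0.85 contrasts is again a few thousandths, smallest with 5 knots.
Neither threatens qualitative conclusions at realistic effect sizes, but both
mean the recovery tolerance of 0.01 on the log scale is tight rather than
generous. Data-driven knot selection by AIC adds a further small upward bias
in estimated curvature under weak signal (flexible candidates win exactly
when noise exaggerates curvature), which is why the recovery experiment fixes
the basis and selection behaviour is tested on its own (parsimony under
linear truth; non-monotone fits under strong curvature).

## Known limitations

- Risk differences, survey-weighted standardization, penalized splines,
  mixed-effects models and causal sensitivity analyses are out of scope.
- Contrasts outside the observed exposure support are extrapolations of a
  tail-linear spline; the defaults keep them inside [0.15, 0.85].
- The delta method assumes approximate log-normality of the RR; at very few
  clusters the cluster bootstrap is the safer choice.
- Real-data ingestion stops at plain gridded/tabular formats; parsing survey
  recode files or raster archives is deliberately not implemented.
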