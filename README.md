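# rainmob

Rainfall anomalies and short-term human mobility: exposure construction,
spline logistic modelling, and marginal risk ratios for cluster-sampled
surveys.

## The problem

Household surveys in drought-prone regions ask whether respondents were away
from their home community for more than a month in the past year. Linking
those answers to gridded precipitation makes it possible to ask whether
anomalously dry or wet years move people — but doing it properly requires a
chain of methods that are easy to get subtly wrong:

1. **Exposure.** For each survey cluster (enumeration area, EA) and interview
   date, sum rainfall over the previous 365 days and rank it against the same
   window in the 29 previous years. The exposure is the empirical percentile
   `p = (rank − 1)/29 ∈ [0, 1]` (midranks for ties): 0 ≈ driest year on
   record, 0.5 ≈ the 30-year median, 1 ≈ wettest. Drought is conventionally
   `p = 0.15`, heavy rain `p = 0.85`.
2. **Model.** Logistic regression of mobility on a restricted cubic spline in
   `p` (knot count chosen by AIC), adjusting for age, wealth quintile,
   household size, education, literacy, urban residence, marital status,
   country fixed effects and survey month; fit separately by gender; standard
   errors clustered at the EA level (CR1 sandwich).
3. **Marginal risk ratios.** Marginal standardization (g-computation):
   everyone's exposure is set to a counterfactual percentile, predictions are
   averaged, and contrasts such as `RR = P̄(0.15)/P̄(0.50)` get delta-method
   or cluster-bootstrap intervals on the log scale.
4. **Effect modification.** Married × spline interaction terms with a joint
   Wald test (chi-square, one df per interaction column) at the 5% level, and
   marital-status-stratified RRs from the same interaction model.

Because the motivating analyses run on restricted-access microdata joined to
large raster archives, the package ships a fully parameterized synthetic data
generator — seasonal rainfall grids with interannual anomalies, multi-country
cluster samples with calibrated covariates, and a U-shaped outcome model with
site-level heterogeneity — plus a Monte-Carlo oracle (`true_marginal_rr()`)
for the implied true risk ratios, so every stage is validated against known
ground truth.

## Worked example

```r
library(rainmob)

dgp <- dgp_spec(seed = 42, n_countries = 6, sites_per_country = 80,
                respondents_per_site = 60)      # true drought/heavy RR ~ 1.05
dat <- simulate_study(dgp)

fit <- fit_mobility(dat, gender = "woman", knots = "aic")
fit
#> Rainfall-mobility spline logistic model
#>   stratum: woman
#>   n = 19629 respondents in 480 site clusters
#>   knots (5): 0.061, 0.304, 0.522, 0.767, 0.947
#>   logLik = -7494.84, AIC = 15059.68, CR1 clustered SEs

marginal_rr(fit, 0.15, 0.5)
#> marginal RR (p = 0.15 vs 0.50): 1.088 [0.950, 1.246] (delta, 95%)
marginal_rr(fit, 0.85, 0.5)
#> marginal RR (p = 0.85 vs 0.50): 1.126 [0.979, 1.295] (delta, 95%)
true_marginal_rr(dgp, dat, 0.15, 0.5)
#> [1] 1.049398

fit_i <- fit_mobility(dat, gender = "woman", knots = 3, interaction = TRUE)
interaction_test(fit_i)
#> joint Wald test for effect modification: chi2(2) = 2.840, p = 0.2417
```

Read: at this sample size the estimated drought and heavy-rain risk ratios
(1.09 and 1.13) bracket the generating truth of 1.05 within their
cluster-robust intervals, and the effect-modification test correctly finds no
marital-status interaction (none was generated). `plot(fit)` draws the
marginal probability curve; `stratified_margins(dat)` runs the full
gender × marital-status × contrast battery; `run_pipeline()` executes the
whole chain (rainfall grid → exposure table → fits → margins) from a single
seeded configuration, and `inst/scripts/rainmob.R` wraps it for the shell.

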