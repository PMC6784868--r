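---
title: "Estimating rural and urban BMI trends: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating rural and urban BMI trends: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's statistical account: the hierarchical
model and its assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, the numerical choices that matter for reproducibility, and the
known limitations. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The estimation problem

The quantity of interest is mean BMI (kg/m²) by country, year
(1985–2017 by default), sex, age group and rural/urban place of
residence, together with the urban−rural difference, estimated from
survey summary rows (study × sex × age group × stratum: mean, standard
error, effective sample size, coverage level). Data are sparse and
heterogeneous: many country-years have no survey, some surveys are
subnational or community-based, some report no rural/urban breakdown,
and a small fraction report only the prevalence of BMI categories.

## 2. Model

Fitted separately by sex (geographic and temporal patterns of BMI differ
enough between women and men that sharing parameters would force
unwanted compromises; separate fits also keep each posterior half the
size):

$$\mu_{\text{rural}}(c,t,a) = a_c + b_c (t - t_0) + u_c(t) + \gamma_c(a),
\qquad
\mu_{\text{urban}} = \mu_{\text{rural}} + \delta_{0c} + \delta_{1c}(t - t_0)$$

* **Hierarchical linear terms.** Each of $a_c$, $b_c$, $\delta_{0c}$,
  $\delta_{1c}$ is a sum of a global coefficient and super-region,
  region and country deviations, each level with its own estimated SD.
  Countries with little data are thereby shrunk toward their region,
  regions toward super-regions.
* **RW2 smoothing.** $u_c(t)$ is a second-order random walk on the
  annual grid: a smoothness prior penalizing second differences, so
  departures from the linear trend are locally linear. It is
  re-expressed in the eigenbasis of the second-difference penalty with
  the two null eigenvectors (constant and linear) removed, which
  enforces sum-to-zero and zero-linear-trend constraints exactly and
  makes $u_c$ identifiable against $(a_c, b_c)$.
* **Age pattern.** $\gamma_c(a)$ is a cubic B-spline over age-group
  midpoints with interior knots at 30/45/60 years and boundary knots at
  18/85 (the data rarely support more flexibility than three interior
  knots, and the adult BMI-age curve has a single broad peak). Basis
  columns are centred over the estimation grid so the age pattern is
  approximately orthogonal to the intercept. Global coefficients carry a
  weak prior; country deviations are shrunk with an estimated SD.
* **Urban−rural difference.** $\delta_{0c} + \delta_{1c}(t-t_0)$ is the
  minimal structure that lets the gap vary by country *and* year —
  enough to express narrowing, reversal or widening over three decades.
  A spline gap was considered and rejected: with typical survey density
  the data cannot distinguish it from the linear gap, and the linear
  form keeps the decomposition endpoints stable.

**Observation model.** Row $i$ with reported standard error $se_i$,
coverage level $\ell(i)$ and study $s(i)$:

$$y_i \sim \mathrm{N}\!\left(w_i^\top \mu + \beta_{\ell(i)} + \nu_{s(i)},\;
se_i^2 + \tau_{\ell(i)}^2\right)$$

* $w_i$ maps the observation to estimation cells: a reported 10-year age
  group is the population-weighted combination of the two 5-year groups
  it spans; an unstratified row is the urban-share-weighted combination
  of the urban and rural cells (weights from the population table at the
  observation's country-year). Weights always sum to one.
* $\beta_{\text{subnat}}, \beta_{\text{comm}}$ are fixed effects
  adjusting for systematic offsets of non-national sources (national is
  the reference level and has none).
* $\nu_s \sim \mathrm{N}(0, \phi_{\ell(s)}^2)$ are study random
  effects; the constraint
  $\phi_{\text{nat}} \le \phi_{\text{subnat}} \le \phi_{\text{comm}}$
  (enforced by truncated updates) makes national data more influential
  than non-national data of equal sample size. Study effects apply to
  national studies too, with the smallest SD tier: a national survey is
  still one realization of survey-specific measurement conditions.
* $\tau_{\ell}$ absorbs extra row-level variation beyond the reported
  sampling error, one SD per coverage level (the national tier's is
  typically near zero but is estimated rather than pinned, so any
  unmodelled row noise in national sources is absorbed instead of
  corrupting interval calibration).

**Priors.** All SD hyperparameters get half-Normal priors with
configurable scales (defaults: 1 kg/m² for intercept-type SDs, 0.05 per
year for slope-type SDs, 0.2 for the RW2 innovation SD, 0.5 for age
deviations, 1 for study SDs, 0.5 for τ). Global coefficients get weakly
informative Normal priors, N(25, 10²) kg/m² on the global intercept.
These scales are an order of magnitude wider than plausible adult-BMI
variation at each level; the tests verify they are vague enough for
recovery and calibrated coverage on synthetic data. Exact production
priors from the antecedent literature are not reproduced here; scales
are configurable in `model_config()`.

## 3. Sampler

Conditional on the SD hyperparameters the model is linear-Gaussian, so
the sampler is a block Gibbs scheme:

1. **Joint effect update.** All regression effects θ (≈1,200 parameters
   for the default world) are drawn in one step from their multivariate
   normal full conditional using a sparse Cholesky factorization
   (`Matrix::Cholesky`, permuted, symbolic pattern reused across
   iterations). The precision matrix is block-arrow (per-country blocks
   plus a small global border), so each iteration costs ~35 ms at
   default size.
2. **Scale updates.** Each SD gets a univariate slice-sampling update of
   its half-Normal-prior full conditional; the study-effect SDs are
   truncated to maintain their ordering.
3. **Interweaving.** A rescaling step in the non-centred
   parameterization (θ_block = σ·w) whose conditional for the signed σ
   is Gaussian. This is the standard ancillarity–sufficiency
   interweaving strategy; without it the RW2 SD mixes very slowly on
   sparse data (the funnel), with it all monitored split-R̂ are ≈1.
4. τ updates by slice sampling on the residuals.

Convergence is monitored by split-R̂ and effective sample size on the
global coefficients and all SD hyperparameters; any R̂ > 1.05 flags the
fit (with a warning) rather than failing silently. Draw count defaults
to 5,000 after burn-in; the burn-in default is 500, generous for a
sampler whose effect block is updated jointly.

## 4. Postprocessing conventions

* Credible intervals are the empirical 2.5th/97.5th percentiles with
  linear interpolation between order statistics (quantile type 7) — the
  convention is fixed so results are bit-reproducible.
* The direction probability is the fraction of draws sharing the sign of
  the posterior mean (0.5 with a flag when the mean is exactly zero).
* Age standardization uses the packaged WHO world-standard weights
  restricted to the adult estimation groups and renormalized; any weight
  table with non-negative weights summing to one is accepted, since the
  standard's vintage is a reporting choice, not a model assumption.
* National means use the year-specific urban share, not a fixed base
  year.
* The decomposition reports, per draw, Δrural·(1−share₀),
  Δurban·share₀ and Δshare·(urban₁−rural₁); the three sum to the change
  in the share-weighted mean exactly (an algebraic identity, tested to
  1e−9). Percentages are draw-wise ratios summarized by mean and
  2.5/97.5 percentiles; a *point mode* (ratios of point components,
  integers rounded half away from zero) exists for reproducing published
  tables. Both modes agree after integer rounding on the reference
  table rows. When the total change is below 0.5 kg/m² in magnitude all
  percentages are flagged NR rather than reported, because the small
  denominator makes the ratios unstable.

## 5. The synthetic world

The generator produces ground truth with exactly the structural features
the model assumes, plus the nuisance features the model must be robust
to:

* hierarchical country intercepts/slopes (super-region, region, country
  SDs 0.8/0.5/0.4 kg/m², slope SDs scaled down by 60 per year — chosen
  so that countries span roughly 21–28 kg/m², as adult populations do);
* per-country RW2 deviations (innovation SD 0.03 kg/m²,
  i.e. visible but subtle nonlinearity over 33 years);
* a shared spline age curve with a broad peak near age 57 (amplitude
  ≈4 kg/m² over the adult range) with country-level coefficient noise;
* urban−rural gaps linear in time, drawn at region and country level
  (mean 1.5 kg/m², base SD 0.5, trend mean −0.01/yr, trend SD 0.02/yr),
  so some regions' gaps narrow or reverse while others widen;
* logistic urbanization curves with non-negative slopes (shares never
  decline), random midpoints, populations with a common declining adult
  age profile;
* surveys at Poisson-random country-years (rate 8 per country) with
  coverage sampled 60/25/15% national/subnational/community, systematic
  offsets −0.15/−0.3 kg/m² and extra noise 0.05/0.15/0.25 for
  non-national levels, study effects 0.1/0.2/0.3, 30% of surveys
  unstratified, and within-cell BMI SD 4.0 (women) / 3.5 (men) kg/m² —
  needed to synthesize category prevalences; the within-survey SD used
  by the antecedent conversion regressions is not published, so these
  are field-typical stand-ins;
* 2% of rows stripped to prevalence-only (BMI ≥25, ≥30, <18.5) with
  binomial noise.

Random draws come from sub-streams keyed by (country, purpose), so
enlarging the world leaves existing countries' surfaces unchanged.

**What passing tests do and do not show.** The generator shares the
model's functional forms (linear+RW2 trends, the same spline family,
linear-in-time gaps, Gaussian study effects). Recovery and coverage
results on this world therefore demonstrate correctness of the
implementation and internal calibration of the uncertainty propagation —
not robustness to real-world misspecification (non-Gaussian survey
effects, reclassification of communities from rural to urban, age
misreporting, non-random survey placement). Real-data validation
requires the real database, which is confidential.

**Problem sizes.** The default test world is 3 super-regions × 2
regions × 4 countries (24 countries) × 33 years × one sex with ~8
surveys per country (~2,900 rows). The packaged checks fit it with
1,000–1,500 retained draws, and the five-repetition holdout validation
with 700 retained draws per refit — sizes chosen as the smallest at
which the posterior summaries of interest are stable (doubling the draw
count moves reported quantities by less than their Monte-Carlo error).
Module-level tests use a 8-country, 12-year world.

## 6. Cleaning and ingest conventions

Individual records are kept when age ≥ 18 (ages floored to integer
years), not pregnant, height in [100, 250] cm, weight in [12, 300] kg
and BMI in [10, 80] kg/m² (both the anthropometric and the BMI filters
are applied; bounds are inclusive). Records with unknown rural/urban
status are dropped only in studies that recorded place of residence —
in studies that never did, the whole sample legitimately forms "mixed"
rows. Summary rows use sample-weighted means, the weighted-variance
standard error with effective sample size $(\sum w)^2/\sum w^2$, and an
optional scalar design-effect multiplier; full survey-design
linearization is out of scope because the model consumes only means and
standard errors. Cells with fewer than two records are emitted flagged,
with a pooled-variance fallback SE.

## 7. The prevalence crosswalk

Rows reporting only category prevalences are converted to means by a
regression fitted on paired cells: mean BMI on the logit of each
available prevalence, sex, and a natural-spline age term, with a
study-level random intercept (`lme4::lmer`). Separate models are kept
per metric-availability pattern rather than imputing across metrics.
Conversion draws jointly: prevalence from its sampling distribution
(clamped to [1/(2n), 1−1/(2n)] before the logit, with a warning at the
boundary), coefficients from their estimated covariance, a study effect
and a residual; the converted mean/SE are the draw mean/SD, so all
conversion uncertainty propagates downstream. Converted rows carry a
`converted` flag so summaries can report the converted fraction (~2%
under the default world). Published conversion coefficients are not
re-derived; the functional form is validated by recovery tests instead.

## 8. Cross-validation design

Two designs: withholding all data from ~10% of countries (sampled within
data-rich / average / data-poor strata defined by sex-specific source
counts: ≥8/4–7/1–3 for women, ≥7/3–6/1–2 for men), and withholding ~10%
of sources (per selected country, a random third of its sources or all
its post-2000 sources; countries with no post-2000 data fall back to the
one-third scheme, logged). Stratified sampling rounds the 10% up to at
least one country per non-empty stratum. Each design is repeated five
times.

Errors are posterior-mean prediction minus held-out observed mean,
summarized by median and median absolute error. Interval coverage is
assessed on the *posterior predictive* distribution of the held-out
observation — the held-out value is itself a noisy measurement, so its
sampling SE, the study-effect SD of its coverage level and the extra
residual SD enter the interval; against the mean-only credible interval,
coverage of noisy observations would be systematically understated. The
predictive CDF at the observed value is computed exactly (a mixture of
Normal CDFs over draws) rather than by simulating predictive noise, so
scoring is a deterministic function of the posterior draws.
Errors are computed at the observation's own age-group/stratum mapping
(the comparison scale is not dictated by the estimand; this choice uses
every held-out row without further aggregation).

## 9. Known limitations

* The urban−rural gap is linear in time per country; decade-scale
  non-monotone gap dynamics within a country are absorbed by the
  hierarchy, not modelled.
* Sexes are fitted independently; cross-sex correlation of country
  effects is ignored.
* The sampler is exact Gibbs but single-chain; diagnostics use split-R̂
  within the chain. For publication-grade runs, multiple seeds should be
  compared.
* Countries with zero data in a stratum are determined entirely by the
  hierarchical prior; no covariates (GDP, urbanization) inform the
  extrapolation.
* The synthetic world shares the model's functional forms (see §5), so
  calibration results are internal-validity evidence only.
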