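---
title: "Methods: folding variables, harmonization, uncertainty and model choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: folding variables, harmonization, uncertainty and model choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldbase)
```

## The morphological coordinate system

A cortical hemisphere is summarized by average cortical thickness $T$ (mm),
total pial area $A_T$ (mm²) and exposed hull area $A_E$ (mm²).  Under the
self-similar cortical folding model these are tied by the power law

$$T^{1/2} A_T = k\,A_E^{\alpha}, \qquad \alpha = 5/4 \text{ in theory},$$

so the three usual variables are not independent.  Working in the log basis
$x = (\log_{10} A_T,\ \log_{10} A_E,\ \log_{10} T^2)$, any power-law
combination is a linear functional, and the model suggests rotating to
three nearly independent directions:

* $K = \log_{10} k = x_1 - \tfrac54 x_2 + \tfrac14 x_3$ — a near-invariant
  associated with the viscoelastic/axonal-tension properties of cortical
  matter;
* $I = x_1 + x_2 + x_3$ — the isometric-volume direction (all areas scale
  together);
* $S$ — a shape direction perpendicular to the other two.

Two coefficient sets for $S$ circulate.  The set
$(\tfrac32, -\tfrac34, -\tfrac94)$ appears in print but is **not**
perpendicular to $I$ (dot product $-3/2$), contradicting the construction
of $S$ as the direction orthogonal to both $K$ and $I$.  The unique
orthogonal direction (up to scale) is $(\tfrac32, +\tfrac34, -\tfrac94)$.
`foldbase` defaults to the orthogonal variant and keeps the printed one
behind `s_variant = "printed"`; every output carries the variant tag.  Two
observations support the default.  First, orthogonality is the stated
design goal of the basis.  Second, for a typical adult hemisphere
($T \approx 2.5$ mm, $A_T \approx 10^5$ mm², $A_E \approx 4\times10^4$
mm²) the orthogonal $S$ is $\approx 9.2$, and published uncertainty
percentages for $S$ (a $\sigma_S$ of 0.14 described as about 1.6% of the
control intercept) imply a baseline near $9.0$; the printed coefficients
would give $S \approx 2.3$, far from consistent with those percentages.

Both coefficient matrices are invertible, and `invert_ksi()` implements
the exact inverse; round-trips hold to $10^{-10}$ (tested).  Because the
$K$ coefficient vector annihilates $(1,1,1)$, an additive per-site shift
applied equally to all three log-coordinates (an "isometric"
miscalibration) leaves $K$ and the orthogonal $S$ untouched and moves only
$I$ — one reason $K$ is attractive for multisite work.

The self-similarity exponent is estimated by ordinary least squares of
$y = \log_{10}(A_T\sqrt T)$ on $x = \log_{10} A_E$ (`fit_alpha()`), with a
Student-t 95% interval on the slope.  Each hemisphere row is one point; no
weighting or errors-in-variables correction is attempted, matching
standard practice for this regression.  The identity
$K = y - \tfrac54 x$ makes "constant $K$" equivalent to "exact power law
with $\alpha = 5/4$", which the test suite exploits.

## Harmonization

Heterogeneous scanners, protocols and processing shift each site's
morphometrics by an approximately constant multiplicative factor — an
additive offset in log space.  Per variable $Y \in \{T, A_T, A_E\}$ the
harmonization model is the linear mixed model

$$\log_{10} Y = a\,t_{\mathrm{age}}\ (+\ \mathrm{ROI\ terms})\ +
  u_{\mathrm{sample:ROI}} + \varepsilon,\qquad
  u \sim N(0, \sigma_{\mathrm{Sample}}^2),\quad
  \varepsilon \sim N(0, \sigma_{\mathrm{Natural}}^2),$$

fit by REML through `lme4::lmer()` (REML rather than ML so the variance
components that feed the uncertainty budget are unbiased).  One age slope
is shared by all samples; each (sample, ROI) cell gets a predicted random
intercept $\hat b_{j,\mathrm{ROI}}$ — a BLUP, i.e. a shrinkage estimate
whose shrinkage factor approaches 1 as residual noise vanishes.
`harmonize()` subtracts $\hat b$ on the log scale.  Defaults that matter:

* **Only control rows inform the fit** (`groups_for_fit = "CTL"`); disease
  groups are then shifted with the control-derived offset of their sample,
  so pathology cannot masquerade as a site effect.  A flag allows
  all-group fitting.
* **K, S, I are recomputed from harmonized primaries**, never harmonized
  directly: the basis change is linear in the logs, so it commutes with
  per-record shifts (asserted to $10^{-12}$ in the suite), and this keeps
  a single set of site offsets.
* When more than one ROI is present, `use_roi_interaction = TRUE` adds ROI
  main effects and an Age × ROI interaction, i.e. a per-ROI slope; the
  random intercept is always per (sample, ROI).  With the formula written
  as an interaction the ROI main effect is included as well — with
  heterogeneous per-ROI baselines a slope-only interaction would push ROI
  differences into the residual.
* A $\hat\sigma_{\mathrm{Sample}} = 0$ boundary fit is returned with
  `boundary = TRUE`, never silently: the uncertainty budget downstream
  must know that the between-sample tier was estimated at the edge.
* A single-sample cohort degenerates to OLS with $\hat b \equiv 0$ and is
  flagged; harmonization is then the identity.

`deage()` removes the fitted age trend,
$\mathrm{value}' = \mathrm{value} - \hat a(t - t_{\mathrm{ref}})$ on the
model scale, to express observations at a common reference age.

The true per-sample offsets are identifiable only up to their common
mean, which is absorbed by the fixed intercept; recovery tests therefore
compare predictions against centered true offsets.  The same fact means
the procedure cannot detect a *global* systematic shift common to all
sites — a stated limitation of the approach, not of this implementation.

## Uncertainty budget

Three uncorrelated tiers combine in quadrature:

$$\sigma_X^2 = \sigma_{\mathrm{Natural}}^2 + \sigma_{\mathrm{Random}}^2 +
  \sigma_{\mathrm{Sample}}^2.$$

$\sigma_{\mathrm{Natural}}$ is the mixed model's residual SD (biological
spread), $\sigma_{\mathrm{Sample}}$ the random-intercept SD (systematic
between-site shift), and $\sigma_{\mathrm{Random}}$ comes from
test–retest sets: per subject the sample SD of repeats ($n-1$
denominator), then the unweighted mean across subjects
(`repeated_measures_sd()`).  No bias correction is applied — with $r$
repeats the estimator's expectation is $c_4(r)\,\sigma$, and
$c_4(3) = \sqrt{\pi}/2 \approx 0.8862$, a deliberate fidelity to the
"mean standard deviation" convention; the suite asserts the bias rather
than correcting it.  For $K$, $S$, $I$ each repeat is first mapped through
the basis change and the within-subject SD taken afterwards (propagation
route); a refit route would estimate the same quantity but entangle it
with trend estimation, so propagation is the default.  The optional
percentage column divides $\sigma_X$ by the absolute control fixed
intercept at age 0; the reference age for that intercept is configurable
because conventions differ.

## Trend-model choice by marginal likelihood

Whether one shared slope suffices is decided by Bayesian evidence.  With
data split into $J$ samples, a model $M$ with mean function $\mu(x; A)$
and Gaussian dispersion has marginal likelihood

$$P(M\mid D) = \prod_{j=1}^{J} \int dA_{(j)}\ P(A_{(j)}\mid I)
  \prod_{i=1}^{N_j} \frac{1}{\sigma_{(j)}\sqrt{2\pi}}
  \exp\!\left[-\frac{(y_{i(j)} - \mu(x_{i(j)}; A))^2}
                    {2\sigma_{(j)}^2}\right],$$

with shared parameters integrated outside the product.  Candidates: the
reference scheme `base` ($\mu = a x + b_{(j)}$, per-sample $\sigma_{(j)}$),
`i` (same mean, common $\sigma$), `ii`/`iii` (per-sample slopes with
per-sample/common dispersion), `iv` (shared quadratic
$c x^2 + a x + b_{(j)}$, per-sample $\sigma_{(j)}$).  Posterior model
probabilities assume equal model priors; odds are evidence ratios.  The
integral intrinsically penalizes superfluous parameters (Occam factor),
which the suite verifies analytically: widening an irrelevant uniform
prior tenfold lowers the log evidence by $\ln 10$.

Numerical choices:

* **Priors.** Uninformative but proper: uniform for location parameters
  over data-driven ranges (per-parameter OLS estimate ± 10 standard
  errors), log-uniform for dispersions over
  $[\hat\sigma/10,\ 10\hat\sigma]$.  Ranges are recorded in every result;
  the `expand` argument scales all half-widths for sensitivity analysis,
  and posterior mass exceeding 1% at any range edge triggers a warning.
* **Quadrature.** Nested 1-D Gauss–Legendre rules (`pracma` nodes), made
  cheap by per-sample sufficient statistics: the Gaussian log-likelihood
  at any parameter point is $O(1)$ in the sample size.  Ages are centered
  within each sample internally, which decouples intercepts from slopes
  and keeps each integrand a well-placed, nearly separable peak; reported
  slopes are unaffected.  Dispersions are integrated in $\log\sigma$.
  Location grids are windowed to the region where the likelihood has
  support (±8 conditional SDs, widened for quadratic coupling), with the
  prior density still taken over the full range — mass outside the window
  is below $e^{-32}$.  Defaults: 48 nodes per dimension (32 per shared
  dimension when two are present).  Against the closed-form conjugate
  oracle the 1-D result is exact to $10^{-6}$ and better; the reported
  `error_estimate` compares full and two-thirds node counts and is
  deliberately conservative.
* **Leave-one-out posteriors.** `parameter_posterior()` fixes one target
  parameter on a grid and marginalizes the rest, returning mode and
  central 95% credible interval via midpoint-corrected CDF inversion.  On
  conjugate cases this matches the analytic Gaussian posterior to
  $10^{-3}$; on cohorts the slope posterior agrees with the REML slope
  within one standard error (both tested).

## Trajectories, contrasts and per-decade exponents

`fit_trajectories()` fits per-(variable, group, ROI) least-squares lines
on harmonized data.  Rates for $T$, $A_T$, $A_E$ are reported in natural
units (mm/year, mm²/year) by fitting the back-transformed harmonized
values; the log-scale alternative (slope × ln10 × fitted value) is
available behind `log_scale_rates = TRUE` and agrees to first order.
Percent-per-year divides the slope by the *absolute* fitted value at a
declared reference age (default: the control grand mean age, always
reported) so the rate keeps the slope's sign even where the baseline is
negative, as for $K$.

`compare_slopes()` tests group differences in aging rate through the
Age × Group interaction (Wald t via `emmeans::emtrends`), sign convention
first-listed minus second (default AD − CTL).  Family-wise adjustment is
`none`, `bonferroni` or `tukey`; with two groups Tukey coincides with the
unadjusted test.  The lobe-level variant fits
Age × Group × ROI with a per-(sample, group, ROI) random intercept when
several samples are present, using asymptotic degrees of freedom.
Degenerate cells are skipped with a warning naming the cell, never
imputed.

`alpha_by_decade()` bins ages into decades, fits `fit_alpha()` per bin
and group, and omits bins with fewer than `min_n = 10` observations
(configurable), listing them with their counts.

`baseline_table()` joins trajectory parameters with uncertainty budgets
into a normative band $\hat y(t) \pm \sigma_X$; at the generator's default
noise the ±1σ band covers well above 60% of held-out controls (Gaussian
expectation ≈ 68%, verified by simulation in the suite).

## The synthetic cohort generator

`generate_cohort()` emulates the features of a multisite cross-sectional
compilation that the pipeline must survive: per-sample age windows (nine
default sites — one elderly-heavy, several young-adult, several wide
lifespan), additive per-(sample, ROI) log-scale offsets drawn
$N(0, \sigma_{\mathrm{Sample}})$, a shared log-linear age trend, optional
group-specific trends, and independent natural noise per variable.  Two
modes: `log_linear` draws each primary's log directly;
`ksi_latent` draws $(K, S, I)$ as group-specific linear functions of age
and inverts the basis change, guaranteeing exact control of the scaling
structure (constant noise-free $K$ yields $\alpha = 5/4$ exactly).
`sigma_response` adds noise to the total area only — pure response noise
for scaling-exponent studies, leaving the hull fixed.
`generate_repeats()` produces test–retest sets: 50 subjects × 3 repeats
by default, each repeat adding log-scale noise $\sigma_{\mathrm{Random}}$
around a fixed latent morphology.

Reference study conditions (the generator defaults, chosen once): 9 sites
× 300 hemisphere observations; $\sigma_{\mathrm{Natural}} = 0.1$,
$\sigma_{\mathrm{Random}} = 0.019$, $\sigma_{\mathrm{Sample}} = 0.085$
(log₁₀ units); shared thickness slope $-0.0044$/yr; control $K$ declining
at $-8.6\times10^{-4}$/yr with the AD block flat in $K$; age
distributions uniform within each site's window (truncated normal
available) — the within-site age law is not documented for the real
compilations, and uniform is the neutral declared default.  Unphysical
draws (a hemisphere's noisy $A_T$ falling below $A_E$, well under 1% at
default noise) are discarded by the same lenient validation a real
extraction QC would apply, and counted in the attached report.  Each
input row is one observation; any longitudinal de-duplication is the
caller's responsibility.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: longitudinal within-subject aging (the
design is cross-sectional), non-linear age trends (real thickness
trajectories bend before age 20), heavy-tailed or heteroscedastic
biological noise, correlated site effects across variables beyond the
isometric shift, scanner-specific multiplicative interactions with age,
and any spatial (vertex- or lobe-geometry) structure.  Recovery results
certify the estimation machinery under the stated model, not the model's
adequacy for any particular dataset.

## Data conventions and edge cases

Units are fixed: mm, mm², years.  Hemispheres are separate observations
(an optional averaging pre-step exists but is off).  The ROI vocabulary
is `hemisphere`, `frontal`, `temporal`, `parietal`, `occipital`, with
`lateral` accepted as an input alias of `parietal`.  Lobe areas may
arrive curvature-corrected, so the $A_T \ge A_E$ constraint is enforced
only for whole-hemisphere rows and merely warned for lobes.  CSV I/O is
comma-separated UTF-8 with case-insensitive headers; numeric fields are
written with 15 significant digits so read ∘ write is the identity to
$10^{-9}$ relative.  Validation is strict by default (reject) with a
lenient drop-and-report mode; the report is machine-readable.

Problem sizes used by the test suite — 2,700-row recovery cohorts, 20
replicates for power-style checks, 6 samples × 30 points for evidence
comparisons — were chosen so each check's Monte-Carlo error is several
times smaller than the tolerance it asserts, while the whole suite stays
fast enough to run habitually.

## Orchestration

The package is a library first: `run_pipeline()` executes
simulate → folding coordinates → harmonize → uncertainty → model
selection → trajectories on a declared configuration (YAML via
`read_config()`, defaults via `default_config()`), writing each stage's
artifact plus a manifest with the config echo, seed, package version and
per-file MD5 checksums.  Outputs are timestamp-free, so identical
configurations reproduce byte-identical artifacts.  Boundary fits,
omitted bins and prior-edge warnings surface in the manifest.  A shell
subcommand wrapper would add nothing over `Rscript -e` against these
functions, so none is shipped; `scripts/acceptance.R` is the one script
entry point.

## Known limitations

* The linear lifespan trend is a deliberate simplification; curvature
  before ~20 years is documented in the literature and model `iv` exists
  precisely to let the evidence machinery flag it.
* A global shift common to every site is unidentifiable (absorbed by the
  fixed intercept).
* $\sigma_{\mathrm{Random}}$ aggregates acquisition and processing noise;
  decomposing it by platform, field strength or software version needs
  designed test–retest data the model does not assume.
* Evidence computations assume Gaussian residuals per sample; the
  quadrature backend is exact only relative to that likelihood.
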