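---
title: "Methods: cosinor rhythmometry and circadian group comparison with rhythmkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cosinor rhythmometry and circadian group comparison with rhythmkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmkit)
```

rhythmkit analyses 24-hour rhythms in case-control biomarker studies. This
vignette describes the statistical model at each stage, the tunable
parameters and their defaults, what the synthetic-data generators emulate,
and the numerical and design choices that were genuinely open.

## The cosinor kernel

Every stage rests on the single-component cosinor: for a series
$Y(t_i)$ observed at times $t_i$ (decimal hours), the model is

$$Y(t) = M + A\,\cos\!\big(\omega (t - \varphi)\big) + \varepsilon,
\qquad \omega = 2\pi/\tau,$$

with mesor $M$ (rhythm-adjusted mean), amplitude $A \ge 0$ (half the
peak-to-trough distance) and acrophase $\varphi$ (clock time of the fitted
peak). The period $\tau$ is fixed at 24 h and only the first harmonic is
fitted: the sampling designs supported here (7 draws over 24 h; 6-7
zeitgeber times) cannot resolve period estimation or higher harmonics, which
are deliberately out of scope. The fit is ordinary least squares on the
linearization $Y = M + \beta\cos\omega t + \gamma\sin\omega t$, so
$A = \sqrt{\beta^2 + \gamma^2}$ and $\varphi = \operatorname{atan2}(\gamma,
\beta)/\omega \bmod \tau$. `fit_cosinor()` reports delta-method standard
errors,

$$\widehat{se}^2_A = \frac{\beta^2 v_{\beta\beta} + \gamma^2
v_{\gamma\gamma} + 2\beta\gamma v_{\beta\gamma}}{A^2}, \qquad
\widehat{se}^2_{\varphi} = \frac{\gamma^2 v_{\beta\beta} + \beta^2
v_{\gamma\gamma} - 2\beta\gamma v_{\beta\gamma}}{A^4\,\omega^2},$$

the second being the rotated (tangential) component of
$\operatorname{cov}(\beta, \gamma)$. When $A$ is numerically zero the
acrophase is undefined and its standard error is reported as `NaN` rather
than raising an error; when $A/\widehat{se}_A < 10^{-6}$ the phase
uncertainty is likewise treated as undefined. A 24-h protocol that draws
twice at the same clock time (e.g. 09:00 at the start and end) contributes
two observations at $t$ and $t + 24$; they are equivalent modulo the period
and enter as independent replicates at the same phase. Replicate weighting
is not applied - nothing in the supported designs motivates it.

Rhythm detection uses the zero-amplitude F test,

$$F = \frac{(SS_{total} - SS_{residual})/2}{SS_{residual}/(n-3)}
\sim F_{2,\,n-3} \text{ under } A = 0,$$

which is exact under Gaussian errors at any $n \ge 4$ (one denominator df at
$n = 4$). A perfect fit ($SS_{residual} = 0$) is reported as $p = 0$ with a
`perfect_fit` flag instead of a division error.

Acrophases are circular quantities. `center_acrophase()` maps a phase into
the half-open 24-h window around a chosen centre - pooling acrophases
linearly is only meaningful after such centring, which is why the pooling
stage centres phases before averaging (09:00 is the conventional centre for
morning-peaking markers such as troponin; for other markers the default
centre is the circular mean of the cohort's phases). `circular_diff()`
returns the minimal signed difference in $(-12, 12]$ hours, the convention
used for all acrophase-shift contrasts.

## Two-stage pooling of per-subject rhythms

Group comparison follows the two-stage ("multiple outcomes" meta-analytic)
approach: each subject's cosinor is fitted individually; the triple
$(M_i, A_i, \varphi_i)$ - on the log scale for skewed markers - together
with its delta-method $3\times 3$ covariance $S_i$ forms the stage-1
outcome. Stage 2 fits

$$y_i = X_i \theta + u_i + e_i, \qquad u_i \sim N(0, \Sigma), \quad
e_i \sim N(0, S_i \text{ known}),$$

with a group fixed effect on each outcome (plus confounders when
adjusting), an unstructured $3\times3$ between-subject covariance
$\Sigma$ estimated by REML, and Wald inference. The likelihood is
evaluated with subjects batched by outcome-missingness pattern and
closed-form small-matrix inverses, so a 70-subject fit takes well under a
second; the implementation agrees with `metafor::rma.mv` to at least four
decimals on shared fixtures (see the test suite). If the unstructured fit
fails to converge - e.g. for degenerate, zero-variance cohorts - the
function falls back to independent per-outcome random-effects pooling and
signals a classed warning that the pipeline drivers collect into the run
log.

Design choices that were open here:

* **Stage-2 parameterization.** The source methodology for "multiple
  outcomes mixed model" pooling is cited in the applied literature without
  formulas; we adopt the standard multivariate meta-analytic reading (known
  stage-1 covariances, REML, unstructured $\Sigma$). This is a documented
  substitute, not a verified reproduction of any particular macro.
* **Acrophase pooling scale.** Phases are pooled linearly after centring
  (not via a circular mean), matching the practice of centring "to obtain a
  normal distribution". For acrophase dispersions around 1-2 h the two
  approaches are numerically indistinguishable.
* **Confounders** (sex, age, BMI, kidney function, alcohol consumption)
  enter stage 2 as fixed effects on all three outcomes simultaneously, and
  are mean-centred so the group rows remain interpretable as adjusted group
  means. Subjects with missing covariates are dropped listwise with a
  logged count.
* **Back-transformation.** Log-scale mesors and amplitudes (and their
  contrasts) are exponentiated: a group value reads as a median, a contrast
  as a multiplication factor; a log-scale amplitude factor is relative to
  the mesor. `retransform_log()` exponentiates the point estimate and both
  CI endpoints, preserving order.

## Detection limits, circadian variation, and the non-cosinor analyses

`apply_lod()` implements half-LOD substitution: values strictly below the
detection limit (melatonin: 8 pmol/L) are replaced by the substitute
(4 pmol/L = LOD/2) and flagged. "Below" is read as strict `<`, consistent
with the substitute being exactly half the limit. Substituted series then
enter the cosinor and the variation summaries as ordinary data - formal
censored-likelihood (Tobit) rhythm fitting is out of scope, matching the
substitution convention of the applied analyses this package supports.
Subjects whose samples are *all* below the limit carry no rhythm
information and are excluded by the pipeline with a log entry.

`summarize_variation()` reports the 24-h minimum, maximum and circadian
variation (maximum/minimum, dimensionless, scale-invariant).
`adjusted_regression()` is OLS of an outcome on group plus the confounder
set, with the transform conventions for skewed outcomes: natural log
(contrast back-transforms to a multiplication factor), log after a +1
offset when zeros are present, and a quadratic transform (regression on the
squared outcome, contrast mapped back through the square root at the
confounder means - the retransformed difference is evaluated at the
reference prediction, the one point where such a back-map is well defined).

`firth_logistic()` maximizes the Jeffreys-penalized likelihood
$\ell(b) + \tfrac12 \log\det I(b)$ by modified Newton iteration with
step-halving. The penalty keeps estimates finite under complete separation
- the situation that arises when, say, every control reaches the assay's
detection limit and only a handful of cases do. Wald intervals on the
penalized fit are the default; profile-penalized-likelihood intervals are
available via `ci = "profile"` and are preferable close to separation. On a
saturated 2x2 design the penalized estimate equals the classical
half-cell-corrected log odds ratio, which the test suite verifies to 1e-4.

`classify_dip()` classifies nocturnal dipping from day/night window means:
dipper (fall of at least 10%), riser (nocturnal rise), non-dipper
(in between). The day window defaults to 07:00-23:00; ambulatory studies
differ in windowing convention, so it is configurable. The boundary case of
exactly 10% counts as a dipper ("at least 10% fall").

## Animal panels: delta-Ct rhythms

qPCR expression is analysed on the $\Delta C_t$ = target minus housekeeping
scale. Larger $\Delta C_t$ means lower expression, so the acrophase of a
$\Delta C_t$ rhythm marks the expression *trough*; the package reports this
note on every comparison object. Because animals are sampled terminally,
each contributes a single observation and `fit_group_rhythm()` pools all
replicates of one species/organ/gene/group into a single cosinor (there is
no per-animal fit to pool). Group contrasts in `compare_groups()` are
case minus control with combined standard errors
$se_B = \sqrt{se_1^2 + se_2^2}$ and Welch-Satterthwaite t quantiles (the
group fits have 15-25 residual df, where normal quantiles visibly
undercover). The acrophase contrast is the signed circular difference; its
confidence limits combine *arcsine-bounded* per-group phase uncertainties,
$h_g = \arcsin\!\big(\min(1,\, t^\ast\, \widehat{se}_{\varphi,g}\,
\omega)\big)/\omega$, the form classical cosinor interval practice derives
from the joint $(\beta, \gamma)$ confidence region: it agrees with the
linear delta-method limit when the phase is well determined and saturates
to half the circle as the tangential uncertainty approaches the amplitude.
The CI is capped at 24 h width (with a flag) when the phase is
unconstrained - when either group's zero-amplitude test is non-significant,
or the combined uncertainty exceeds the circle - an honest statement that
the data do not constrain the phase, mirroring the convention of flagging
CI widths beyond 24 h in published rhythm tables. In coverage simulations
at the default panel parameters the plain linear interval undercovers
(about 91-92% for the weakest-amplitude rows) while the arcsine-bounded
form holds the nominal rate. `phase_relation()`
classifies two rhythmic fits as in-phase (offset $\le$ 4 h), anti-phase
($\ge$ 8 h) or intermediate; the thresholds are configurable and sit midway
between the canonical same-phase and 12-h-opposed clock-gene
configurations.

## What the synthetic generators emulate

`generate_hormone_cohort()` draws, per subject, a mesor/amplitude/acrophase
triple from group-level Gaussians and evaluates the cosine at the 7-draw
protocol (09:00, 13:00, ..., 05:00, 09:00). Noise is multiplicative
log-normal for melatonin and troponin (matching their log-scale analysis)
and additive Gaussian for cortisol. Default group sizes are 46 cases vs 24
controls. Default effects follow the magnitudes a heart-failure cohort
shows: melatonin amplitude damped to 0.6 of the control multiplication
factor with mesor ratio 1.1 and a +14 min acrophase shift; cortisol mesor
shifted +56.8 nmol/L with equal amplitudes; troponin with no group effect.
Between-subject SDs default to 1.5 h for acrophase and to values chosen to
give confidence-interval widths of the same order as published cohort
tables; within-subject residual SDs are not reported in such tables, so the
defaults (0.35 on the log scale; 30 nmol/L for cortisol) are calibrated
only to that order-of-magnitude criterion. Cortisol values are floored at
1 nmol/L (an assay lower bound); the floor binds so rarely at the default
parameters that its effect on group contrasts is negligible.

**Melatonin latent-parameter calibration.** The melatonin group parameters
that a substitution-based pipeline estimates are *not* the latent
parameters of the unobserved hormone trajectory: substituting 4 pmol/L for
every value below 8 raises deep control troughs and lowers shallow case
troughs, compressing the two groups' fitted amplitudes differently. The
generator's documented group targets (control median mesor 19.7 pmol/L and
amplitude factor 8.8; case effects mesor x1.11, amplitude x0.6) are
therefore hit *after* the LOD step: the latent defaults in
`default_marker_specs()` were obtained once, with a fixed calibration seed,
by simulation-based inversion - iterate cohort generation and the full
LOD -> log-cosinor -> pooling pipeline, and shift the latent group
parameters until the expected pooled estimates equal the targets. The
methods consequence is worth stating plainly: with ~30-40% of melatonin
samples below the limit, the latent control amplitude factor (~14 on the
natural scale) is substantially larger than the fitted 8.8 (roughly 17), i.e.
substitution attenuates amplitudes, and analyses of substituted data
estimate post-substitution parameters. The calibration's quasi-Newton
details (common-random-number Jacobian across the generation-analysis map)
matter because substitution couples the fitted mesor and amplitude
strongly within each group.

`generate_animal_panel()` draws terminal animals per zeitgeber time (mouse
grid 1, 4, 7.5, 11, 14.5, 18, 21.5, default 4/group/ZT; zebrafish grid 0,
4, 8, 12, 16, 20, default 3 pooled samples/group/ZT) with a flat
housekeeping Ct (mean 20, SD 0.1) and additive Gaussian noise on the Ct
scale (mouse 0.7, zebrafish 0.5) - the conventional qPCR error model. The
default gene tables in `clock_gene_params()` encode per-organ core-clock
rhythms for the two species, with the positive and negative clock limbs in
approximate anti-phase and the diurnal species' rhythms opposed to the
nocturnal one's.

`generate_abpm()` assigns dipping classes by exact largest-remainder
rounding of the requested fractions (default 8/36, 21/36, 7/36), draws a
class-consistent dip fraction (10-25%, 0-10%, or a rise), and recentres the
within-window noise so the day and night means hit their targets exactly -
the round trip through `classify_dip()` is then exact by construction,
which is what makes the generator usable as a classification oracle.

What the generators do **not** emulate: serial within-subject correlation
beyond the cosine (real hormone profiles have pulsatility), non-Gaussian
between-subject heterogeneity, assay drift, irregular or missed draws,
medication timing effects, and any coupling between markers within a
subject. Passing recovery tests on these synthetic cohorts therefore
demonstrates correctness of the estimators under the stated model, not
robustness to those real-data features.

## Numerical choices and degenerate inputs

* REML optimisation: Nelder-Mead on the log-Cholesky parameterization of
  $\Sigma$ (relative tolerance 1e-9, one restart), which keeps $\Sigma$
  positive definite by construction; the GLS fixed effects are profiled
  out in closed form.
* A cosinor fit with collinear harmonic covariates (all samples at one
  clock phase) is an error, as is any series shorter than 4 points.
* Ties in `circular_diff()` at exactly 12 h return +12 (the interval is
  half-open); antisymmetry holds everywhere else.
* Firth iteration uses step-halving on the penalized likelihood and fails
  with diagnostics after 100 steps; a constant outcome or rank-deficient
  design is rejected up front.
* Monte-Carlo problem sizes in the test suite (e.g. 200 synthetic cohorts
  for end-to-end recovery, 5000 replicates for the null size of the rhythm
  test, 200 panel replicates for animal-arm coverage) were chosen so the
  binomial/Monte-Carlo envelopes are tight enough to be informative while
  the whole suite stays comfortably re-runnable on a laptop.

## Worked example

```{r example, eval = FALSE}
cohort <- generate_hormone_cohort(cohort_spec(seed = 17))
fits <- fit_cohort(cohort$measurements, "melatonin", log_scale = TRUE,
                   lod = assay_config(8, 4))
pool_cosinor(subject_estimates(fits, covariates = cohort$covariates))

panel <- compute_delta_ct(generate_animal_panel(animal_spec("mouse", seed = 17)))
hf <- fit_group_rhythm(subset(panel, organ == "kidney" & gene == "Bmal1" &
                                group == "HF"))
sham <- fit_group_rhythm(subset(panel, organ == "kidney" & gene == "Bmal1" &
                                  group == "sham"))
compare_groups(hf, sham)
```

## Known limitations

Single 24-h harmonic only; no period estimation; substitution rather than
censored-likelihood handling of detection limits; linear (post-centring)
rather than fully circular pooling of acrophases; Wald rather than
small-sample inference at stage 2; and the synthetic-data caveats above.
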