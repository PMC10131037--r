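# rhythmkit

Cosinor rhythmometry and circadian group comparison for case-control
biomarker studies.

Clinical studies of 24-hour biology face a recurring analysis problem:
hormones, cardiac markers, blood pressure and clock-gene expression are
sampled a handful of times around the clock, per subject or per terminally
sampled animal, and the question is whether a rhythm exists, what its
parameters are, and whether disease changes them. rhythmkit packages that
pipeline for statisticians and clinical researchers working on such
designs - the motivating use case is a heart-failure case-control study
with 24-h melatonin/cortisol/troponin profiles, ambulatory BP/HR
monitoring, and mouse/zebrafish clock-gene qPCR panels.

## The model

The kernel is the single-component cosinor at fixed period τ = 24 h:

    Y(t) = M + A·cos(ω(t − φ)),   ω = 2π/τ

fitted by least squares through the linearization
`Y = M + β·cos(ωt) + γ·sin(ωt)`, with `A = √(β² + γ²)`,
acrophase `φ = atan2(γ, β)/ω mod 24` (the clock time of the fitted peak),
delta-method standard errors, and the zero-amplitude rhythm-detection test
`F = ((SS_tot − SS_res)/2)/(SS_res/(n − 3)) ~ F(2, n−3)`.

Around it:

* **Two-stage pooling** (`pool_cosinor`): per-subject `(M, A, φ)` triples
  with known covariances are combined in a joint three-outcome
  random-effects model (unstructured between-subject covariance, REML,
  Wald inference), with group contrasts, optional confounder adjustment,
  and log-scale back-transformation to medians / multiplication factors.
* **Variation metrics** (`summarize_variation`, `apply_lod`): 24-h
  maximum/minimum and circadian variation (max/min), with half-LOD
  substitution for left-censored assays.
* **Firth logistic regression** (`firth_logistic`): Jeffreys-penalized
  likelihood, finite under complete separation.
* **Dipping classification** (`classify_dip`, `dip_summary`): dipper
  (≥ 10% nocturnal fall), non-dipper, riser.
* **Animal panels** (`compute_delta_ct`, `fit_group_rhythm`,
  `compare_groups`, `phase_relation`): ΔCt clock-gene rhythms per
  species/organ/gene, case-control contrasts, in-/anti-phase relations.
* **Synthetic data** (`generate_hormone_cohort`, `generate_animal_panel`,
  `generate_abpm`): seeded generators reproducing the sampling designs, so
  every stage is testable without any external data.
* **Pipeline drivers** (`run_human_arm`, `run_animal_arm`): chain the
  stages and write CSV reports plus a run log.

## Worked example

```r
library(rhythmkit)

# a synthetic case-control cohort: 46 cases, 24 controls, 7 draws over 24 h
cohort <- generate_hormone_cohort(cohort_spec(seed = 17))

# melatonin: half-LOD substitution at 8 -> 4 pmol/L, per-subject log cosinor
fits <- fit_cohort(cohort$measurements, "melatonin", log_scale = TRUE,
                   lod = assay_config(lod = 8, substitute = 4))
pool_cosinor(subject_estimates(fits))
```

```
Pooled cosinor comparison: melatonin [unadjusted]
  method: multivariate REML
   group parameter estimate  lower  upper retransformed clock
    case     mesor   23.853 20.910 27.211          TRUE  <NA>
 control     mesor   18.975 15.730 22.890          TRUE  <NA>
    case amplitude    5.443  4.853  6.105          TRUE  <NA>
 control amplitude    7.982  6.733  9.463          TRUE  <NA>
    case acrophase    4.306  3.803  4.809         FALSE 04:18
 control acrophase    3.697  3.004  4.389         FALSE 03:42
  B (case vs control):
 parameter     B  lower upper        p            type
     mesor 1.257  1.000 1.581 0.050400           ratio
 amplitude 0.682  0.555 0.837 0.000256           ratio
 acrophase 0.609 -0.246 1.465 0.163000 time difference
  cosinor significance: case 93.5%, control 100.0%
```

Reading the output: the pooled mesors are medians in pmol/L
(back-transformed from the log scale), the amplitudes are multiplication
factors relative to the mesor, and the case-vs-control B for the amplitude
(0.68 in this particular cohort; the generating damping is 0.6) says the
cases' rhythm swings about two-thirds as wide as the controls' - the
acrophase B is a signed clock difference. The cosinor-significance rows
report the share of subjects whose own series passes the zero-amplitude
test.

The animal arm works the same way on the ΔCt scale (where the acrophase
marks the expression trough):

```r
panel <- compute_delta_ct(generate_animal_panel(animal_spec("mouse", seed = 17)))
kidney <- subset(panel, organ == "kidney" & gene == "Bmal1")
compare_groups(fit_group_rhythm(subset(kidney, group == "HF")),
               fit_group_rhythm(subset(kidney, group == "sham")))
```

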