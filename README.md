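# progspace

Longitudinal clinical cohorts — subjects followed over annual visits on a
large battery of motor, cognitive and sleep instruments — rarely progress as
one homogeneous population. `progspace` is an R package for discovering and
validating *progression subtypes* in such cohorts, built for biostatisticians
and clinical-ML researchers working with case/control panel data
(Parkinson's disease progression cohorts are the motivating application).

## What it does

1. **Progression space.** After direction alignment, percentile clipping,
   longitudinal interpolation, vectorization and min-max normalization, each
   subject is a column of a non-negative matrix `X` (rows = stacked
   (feature, visit) pairs). Rank-3 non-negative matrix factorization
   `X = UV` yields per-subject progression indicators `V`; a latent-space
   adjustment `i_new = C V`, with contribution weights
   `C[s, d] = Σ_{rows r in domain s} U[r, d]` (rows normalized to sum 1),
   maps them onto named motor / cognitive / sleep axes, normalized to
   `[0, 1]`.
2. **Subtyping.** A full-covariance Gaussian mixture is fitted to the cases
   in the 2-D view (motor vs combined cognitive/sleep); the number of
   subtypes is selected by `BIC = −2·loglik + q·ln(n)` over k = 1..6, and
   components are ordered slow → moderate → fast. All fitted decisions
   (flips, bounds, basis, mixture) freeze and transfer to replication
   cohorts via non-negative least squares projection — no refitting.
3. **Early prediction.** A stacked ensemble (random forest + two
   gradient-boosted tree ensembles, combined by a multinomial-logistic
   meta-learner on out-of-fold probabilities) predicts each case's
   long-horizon subtype from early-visit features under stratified nested
   5×5 cross-validation, reporting per-class and macro one-vs-rest AUC,
   feature importance and incremental-horizon curves.
4. **Associations.** A random-intercept linear mixed model tests the
   subtype×time interaction on serum neurofilament light (Nfl); linear and
   logistic regressions test the genetic risk score (GRS, per SD) against
   continuous membership probability and binary subtype membership.
5. **Synthetic cohorts.** `generate_cohort()` simulates cohorts with the
   structure the analysis assumes (three latent subtypes at mixing
   0.45/0.39/0.16 with slow/moderate/fast velocities, mixed feature
   directionality, MCAR missingness, subtype-dependent Nfl slopes and GRS),
   so every stage is testable without access-controlled study data.

## Worked example

```r
library(progspace)

sim  <- generate_cohort(generator_params(), seed = 42)
sim$cohort
#> longitudinal_cohort: 450 subjects ( 300 cases / 150 controls ), 121 features, 6 visits
#>   missing cells: 9817 / 326700

pipe <- subtype_pipeline(sim$cohort, seed = 1)
pipe$space
#> progression_space_model: rank 3 NMF on 720 (feature, visit) rows x 450 subjects
#>   relative reconstruction error: 0.246
#>   explained variance: motor 50.04%, cognitive 23.47%, sleep 26.50%
pipe$model
#> subtype_model: 3 Gaussian components in 2 dimensions (n = 300 )
#>          motor cogsleep
#> slow     0.154    0.186
#> moderate 0.500    0.519
#> fast     0.918    0.887
#> BIC-selected k = 3 over candidates 1, 2, 3, 4, 5, 6

truth <- sim$labels$subtype[match(pipe$assignment$table$subject_id,
                                  sim$labels$subject_id)]
mclust::adjustedRandIndex(truth, pipe$assignment$table$subtype)
#> [1] 1
```

BIC selects three subtypes; the component means sit at increasing positions
along both axes (higher = faster decline on a normalized scale), and the
hard assignments reproduce the generator's hidden labels exactly (adjusted
Rand index 1 at the default separation).

Baseline-only prediction of the 5-year subtype, and the Nfl association:

```r
tab <- filter_and_impute(build_feature_table(sim$cohort, visits = "BL"))
y   <- factor(truth[match(rownames(tab), pipe$assignment$table$subject_id)],
              levels = c("slow", "moderate", "fast"))
nested_cv_evaluate(tab, y, seed = 7)
#> prediction_report: macro AUC 1
#>   slow      AUC 1.000 +/- 0.000
#>   moderate  AUC 1.000 +/- 0.000
#>   fast      AUC 1.000 +/- 0.000

res <- nfl_mixed_model(sim$cohort, sim$labels)
association_term(res, "subtypefast:time")
#> $estimate
#> [1] 2.042013    # fast-vs-slow Nfl slope difference, units/year
#> $se
#> [1] 0.04093947
#> $p
#> [1] 1.437731e-320
```

The interaction estimate recovers the generator's planted slope difference
(2.5 − 0.5 = 2 Nfl units/year, steeper in fast progressors). Synthetic
cohorts at the default settings are cleanly separated, so AUCs here sit at
the ceiling; the test suite also exercises harder regimes (permuted labels,
reduced separation, null effects).

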