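# fissuremap

Non-invasive detection and localization of **outer annular fissures** of the
intervertebral disc from conventional midsagittal T2-weighted MR images.

Fissures reaching the outer third of the annulus fibrosus are a suspected
source of chronic low back pain, yet they are largely invisible on
conventional MRI: the only accepted MR marker, the high-intensity zone
(HIZ), misses roughly a third of them, and the reference standard (CT
discography) is invasive. `fissuremap` implements a texture-based
alternative for researchers in quantitative spine imaging:

1. **Texture features** — an IBSI-style engine computing first-order
   statistics, Geary's C, and GLCM / NGTDM / NGLDM matrix features under
   the standard slice/direction aggregation conventions (`2Davg`, `2Dmrg`,
   `2DDmrg`, `2Dvmrg`, `3Davg`, `3Dmrg`), on a masked disc ROI. A fixed
   22-feature registry collects the features sensitive to tissue near
   outer annular fissures.
2. **Classification** — an averaging ensemble of shallow networks
   (input → 5 tanh units → 2-way softmax; fissure probability
   `p = mean over members of softmax(W2 tanh(W1 x + b1) + b2)[2]`), trained by
   batch gradient descent with momentum and adaptive learning rate, with
   early stopping at the first-best validation loss, evaluated by
   patient-level stratified 10-fold cross-validation.
3. **Occlusion attention mapping** — a vertical slab sweeps the disc one
   column at a time; the drop in the held-out classifier's score when a
   column is hidden is mapped back to that column, normalized, and
   thresholded into a highlighted region whose position is compared with
   the true fissure position.
4. **Diagnostic statistics** — sensitivity, specificity, accuracy,
   likelihood ratios (PLR = sens/(1−spec), NLR = (1−sens)/spec), ROC/AUC,
   and the exact **mid-p McNemar** test
   (`p = 2 P(K ≤ min(b,c)) − P(K = min(b,c))`, `K ~ Bin(b+c, ½)`) for
   paired comparison against the HIZ marker.

A synthetic **disc-phantom generator** reproduces the statistical
structure of a discography-verified study cohort (fissure prevalence,
position mixture, degeneration grades, HIZ rates, a severely-disrupted
phenotype excluded from attention mapping), so the entire pipeline can be
exercised and validated without patient data.

## Worked example

```r
library(fissuremap)

cohort <- generateCohort(phantomConfig(nPatients = 16, seed = 42))
cohort
#> DiscCohort: 48 discs, 16 patients
#>   fissure-positive: 39  HIZ: 25  attention-eligible: 46

se    <- extractCohortFeatures(cohort, featureRegistry("fissure22"))
man   <- cohortManifest(cohort)
folds <- makeFolds(man$patientId, man$fissurePresent, k = 4, seed = 42)
cv    <- runCrossValidation(se, folds, ensembleSize = 10,
                            cfg = trainConfig(maxEpochs = 300, patience = 60),
                            baseSeed = 42, keepModels = TRUE)

confusionTable(cv$result$pred, cv$result$label)
#>             predicted
#> truth        no fissure fissure
#>   no fissure          9       0
#>   fissure             0      39
round(reportMetrics(diagnosticMetrics(
  confusionTable(cv$result$pred, cv$result$label))), 3)
#> sensitivity specificity    accuracy         plr         nlr
#>         100         100         100         Inf           0
rocAuc(cv$result$prob, cv$result$label)$auc
#> [1] 1
```

Every disc was scored by an ensemble that never saw its patient during
training; on this 48-disc phantom cohort the out-of-fold classification
is perfect (the streaks are rendered at high contrast). Localizing the
fissure within a held-out disc:

```r
disc <- cohort[[which(man$discId == "P005_D1")]]
disc
#> DiscPhantom P005_D1 (patient P005 , level L3-L4 )
#>   dims: 48 x 96 x 5  grade: 4
#>   fissure: dorsal  HIZ: TRUE  attention-eligible: TRUE

foldOf <- cv$result$fold[man$discId == "P005_D1"]
map <- computeAttentionMap(discRoi(disc), cv$models[[foldOf]],
                           featureRegistry("fissure22"))
map
#> AttentionMap (drop mode): 82 columns, baseline score 1
#>   peak at column 79

judgeLocalization(map, disc)$verdict
#> [1] "correct"
```

The occlusion profile peaks at column 79 — inside the dorsal (right-hand)
third of the disc where this phantom's fissure lies — and the highlighted
region overlaps the true fissure mask within tolerance, so the judgement
is `correct`. Larger validation runs (201 discs, 50-member ensembles,
10 folds) are exercised by the test suite; the methods vignette
(`vignettes/fissure-detection-methods.Rmd`) documents the model, the
phantom design and every numerical choice.

A command-line front end over the same functions lives in
`inst/cli/fissuremap.R`
(`simulate` / `extract` / `crossval` / `attend` / `evaluate` / `run-all`).

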