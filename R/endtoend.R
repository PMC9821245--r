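#' End-to-end run configuration
#'
#' Bundles the per-stage configurations of the full pipeline: simulate a
#' cohort, extract features, cross-validate the fissure classifier, compare
#' against the bright-zone marker, compute occlusion attention maps for
#' eligible predicted-positive discs and judge their localization.
#'
#' @param phantom a [phantomConfig()]
#' @param nBins discretization levels
#' @param registrySet `"fissure22"` or `"full"` for the main classifier (the
#'   attention classifier always uses the 22-feature set)
#' @param ensembleSize members per cross-validation fold
#' @param k folds
#' @param train a [trainConfig()]
#' @param occlusion an [occlusionConfig()]
#' @param maxAttentionDiscs cap on the number of eligible discs judged
#'   (seeded subset; `Inf` judges all)
#' @param gearyMax,gearySeed Geary's C subsampling controls
#' @param seed master seed for folds and training
#' @return a `RunConfig` (classed list)
#' @export
endToEndConfig <- function(phantom = phantomConfig(), nBins = 32,
    registrySet = c("fissure22", "full"), ensembleSize = 20, k = 10,
    train = trainConfig(), occlusion = occlusionConfig(),
    maxAttentionDiscs = Inf, gearyMax = 3000, gearySeed = 1L, seed = 1L) {
  structure(list(phantom = phantom, nBins = nBins,
    registrySet = match.arg(registrySet), ensembleSize = ensembleSize,
    k = k, train = train, occlusion = occlusion,
    maxAttentionDiscs = maxAttentionDiscs, gearyMax = gearyMax,
    gearySeed = gearySeed, seed = as.integer(seed)), class = "RunConfig")
}

#' Run the full pipeline on a synthetic cohort
#'
#' simulate, extract, cross-validate, compare with the bright-zone marker,
#' map attention on eligible discs, judge localization, and assemble a
#' report. Attention maps are computed with the per-fold 22-feature
#' ensemble that never saw the disc during training. The report carries
#' the seed and a configuration hash; reruns with the same configuration
#' are identical.
#'
#' @param cfg an [endToEndConfig()]
#' @param verbose print stage progress
#' @return a report list (cohort counts, classifier and marker metrics,
#'   the mid-p McNemar comparison, localization judgements and rate,
#'   provenance)
#' @export
runEndToEnd <- function(cfg = endToEndConfig(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  say("simulate: generating cohort")
  cohort <- generateCohort(cfg$phantom)
  manifest <- cohortManifest(cohort)

  say("extract: computing texture features")
  mainRegistry <- featureRegistry(cfg$registrySet)
  reg22 <- featureRegistry("fissure22")
  se <- extractCohortFeatures(cohort, mainRegistry, nBins = cfg$nBins,
                              gearyMax = cfg$gearyMax,
                              gearySeed = cfg$gearySeed)
  se22 <- if (cfg$registrySet == "fissure22") se else
    extractCohortFeatures(cohort, reg22, nBins = cfg$nBins,
                          gearyMax = cfg$gearyMax, gearySeed = cfg$gearySeed)

  say("crossval: ", cfg$k, "-fold patient-level cross-validation")
  folds <- makeFolds(manifest$patientId, manifest$fissurePresent,
                     k = cfg$k, seed = cfg$seed)
  cv <- runCrossValidation(se, folds, ensembleSize = cfg$ensembleSize,
                           cfg = cfg$train, baseSeed = cfg$seed,
                           keepModels = cfg$registrySet == "fissure22")
  cv22 <- if (cfg$registrySet == "fissure22") cv else
    runCrossValidation(se22, folds, ensembleSize = cfg$ensembleSize,
                       cfg = cfg$train, baseSeed = cfg$seed + 500L,
                       keepModels = TRUE)

  annPred <- cv$result$pred
  label <- cv$result$label
  annCt <- confusionTable(annPred, label)
  annDm <- diagnosticMetrics(annCt)
  roc <- rocAuc(cv$result$prob, label)

  hizPred <- hizMarkerPredictions(manifest)
  hizCt <- confusionTable(hizPred, label)
  hizDm <- diagnosticMetrics(hizCt)
  b <- sum(hizPred != label & annPred == label)   # marker wrong, ANN right
  c <- sum(annPred != label & hizPred == label)   # ANN wrong, marker right
  mc <- mcnemarMidP(b, c)

  say("attend: occlusion attention maps")
  eligible <- which(manifest$attentionEligible)
  if (is.finite(cfg$maxAttentionDiscs) &&
      length(eligible) > cfg$maxAttentionDiscs)
    eligible <- withSeed(cfg$seed,
      sort(sample(eligible, cfg$maxAttentionDiscs)))
  pred22 <- cv22$result$pred
  judgements <- vector("list", length(eligible))
  for (i in seq_along(eligible)) {
    di <- eligible[i]
    disc <- cohort[[di]]
    map <- NULL
    if (pred22[di]) {
      ens <- cv22$models[[cv22$result$fold[di]]]
      map <- computeAttentionMap(discRoi(disc), ens, reg22,
        nBins = cfg$nBins, cfg = cfg$occlusion,
        gearyMax = cfg$gearyMax, gearySeed = cfg$gearySeed)
    }
    judgements[[i]] <- judgeLocalization(map, disc,
      tolerancePx = cfg$occlusion$tolerancePx,
      predictedPositive = pred22[di])
  }
  names(judgements) <- manifest$discId[eligible]
  rate <- localizationRate(judgements)

  report <- list(
    cohort = list(nDiscs = nrow(manifest),
      nPatients = length(unique(manifest$patientId)),
      nFissured = sum(manifest$fissurePresent),
      nHiz = sum(manifest$hizFlag),
      nAttentionEligible = sum(manifest$attentionEligible)),
    classifier = list(
      confusion = list(tp = annCt@tp, fp = annCt@fp, fn = annCt@fn,
                       tn = annCt@tn),
      metrics = as.list(reportMetrics(annDm)), auc = roc$auc),
    hizMarker = list(
      confusion = list(tp = hizCt@tp, fp = hizCt@fp, fn = hizCt@fn,
                       tn = hizCt@tn),
      metrics = as.list(reportMetrics(hizDm))),
    comparison = list(b = b, c = c, pMid = mc$pMid),
    attention = list(
      nJudged = rate$nTotal, nCorrect = rate$nCorrect,
      percentCorrect = rate$percent,
      failureModes = table(vapply(judgements, `[[`, "", "failureMode")),
      verdicts = vapply(judgements, `[[`, "", "verdict")),
    provenance = list(seed = cfg$seed,
      configHash = configHash(unclass(cfg)),
      package = as.character(utils::packageVersion("fissuremap"))))
  structure(report, class = "FissureReport",
            cv = cv$result, judgements = judgements)
}

#' Write a pipeline report as JSON
#'
#' Deterministic serialization (no timestamps): two runs with the same
#' configuration produce byte-identical files.
#'
#' @param report a [runEndToEnd()] result
#' @param path output file
#' @return `path`, invisibly
#' @export
writeReport <- function(report, path) {
  rep <- unclass(report)
  rep$attention$failureModes <- as.list(rep$attention$failureModes)
  rep$attention$verdicts <- as.list(rep$attention$verdicts)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
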