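#' Occlusion sweep configuration
#'
#' The occluding slab is a full-height vertical band spanning all slices,
#' `slabWidth` columns wide, moved one column at a time across the disc.
#' Masked voxels under the slab are replaced according to `fillPolicy`
#' (default: the mean of the original, unoccluded ROI, which is neutral and
#' makes repeated occlusion idempotent). With `mapMode = "drop"` the
#' attention value at a column is the classification-score drop relative to
#' the unoccluded disc; `"score"` records the occluded score itself.
#'
#' @param slabWidth slab width in columns (default 5)
#' @param fillPolicy `"roi_mean"`, `"roi_median"` or `"background"` (zero)
#' @param mapMode `"drop"` or `"score"`
#' @param highlightQuantile quantile of in-ROI overlay values above which a
#'   voxel is highlighted (default 0.8)
#' @param tolerancePx localization tolerance in pixels (default 3)
#' @return an `OcclusionConfig` (classed list)
#' @export
occlusionConfig <- function(slabWidth = 5,
    fillPolicy = c("roi_mean", "roi_median", "background"),
    mapMode = c("drop", "score"), highlightQuantile = 0.8,
    tolerancePx = 3) {
  stopifnot2(slabWidth >= 1, "slabWidth must be >= 1")
  structure(list(slabWidth = as.integer(slabWidth),
    fillPolicy = match.arg(fillPolicy), mapMode = match.arg(mapMode),
    highlightQuantile = highlightQuantile,
    tolerancePx = as.integer(tolerancePx)), class = "OcclusionConfig")
}

occlusionFillValue <- function(roi, policy) {
  switch(policy,
    roi_mean = mean(roi@image[roi@mask]),
    roi_median = stats::median(roi@image[roi@mask]),
    background = 0)
}

#' Occlude a column band of a masked image
#'
#' Replaces the masked voxels in columns `center - floor(w/2) ..
#' center + floor(w/2)` (all rows, all slices, clamped to the image) by the
#' fill value; the mask itself is unchanged. The fill value is computed
#' from the original image (pass `fillValue` to reuse one across a sweep).
#'
#' @param roi an [IntensityROI-class]
#' @param center slab center column
#' @param cfg an [occlusionConfig()]
#' @param fillValue optional precomputed fill intensity
#' @return the occluded [IntensityROI-class]
#' @export
occludeColumns <- function(roi, center, cfg = occlusionConfig(),
                           fillValue = NULL) {
  half <- cfg$slabWidth %/% 2
  cols <- max(1, center - half):min(dim(roi@image)[2], center + half)
  sel <- roi@mask
  sel[, -cols, ] <- FALSE
  stopifnot2(any(sel), "slab does not intersect the ROI")
  if (is.null(fillValue)) fillValue <- occlusionFillValue(roi, cfg$fillPolicy)
  img <- roi@image
  img[sel] <- fillValue
  intensityRoi(img, roi@mask, roi@spacing)
}

#' Occlusion attention map for one disc
#'
#' Sweeps the occluding slab one column at a time over every
#' ROI-intersecting column. At each position the feature vector of the
#' occluded disc is extracted, scored by the (22-feature) ensemble, and the
#' score (or the drop relative to the unoccluded score) is mapped back to
#' the slab's center column. The per-column profile is min-max normalized
#' into an overlay on the ROI (negative drops clipped to zero), and voxels
#' whose overlay value reaches the `highlightQuantile` quantile of in-ROI
#' values form the highlighted mask. A flat profile yields an all-zero
#' overlay and an empty highlight.
#'
#' @param roi an [IntensityROI-class]
#' @param ensemble a trained [FissureEnsemble-class] whose feature order
#'   matches `registry`
#' @param registry the [FeatureRegistry-class] the ensemble was trained on
#' @param nBins discretization levels (must match training)
#' @param cfg an [occlusionConfig()]
#' @param gearyMax,gearySeed Geary's C subsampling controls (must match
#'   training)
#' @return an [AttentionMap-class]
#' @export
computeAttentionMap <- function(roi, ensemble, registry, nBins = 32,
    cfg = occlusionConfig(), gearyMax = 3000, gearySeed = 1L) {
  stopifnot2(identical(featureIds(registry), ensemble@featureIds),
             "registry does not match the ensemble's features")
  geom <- buildGeometry(roi@mask, roi@spacing, gearyMax = gearyMax,
                        gearySeed = gearySeed)
  fill <- occlusionFillValue(roi, cfg$fillPolicy)
  roiCols <- which(apply(roi@mask, 2, any))
  pFull <- ensemblePredict(ensemble,
    extractFeatures(roi, registry, nBins, gearyMax, gearySeed, geom))
  scores <- vapply(roiCols, function(cc) {
    occ <- occludeColumns(roi, cc, cfg, fillValue = fill)
    ensemblePredict(ensemble,
      extractFeatures(occ, registry, nBins, gearyMax, gearySeed, geom))
  }, numeric(1))
  # drop mode works on the log-odds scale: probability drops compress to
  # nothing once the ensemble is confident, log-odds drops do not
  lgt <- function(p) stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  columnScores <- if (cfg$mapMode == "drop") lgt(pFull) - lgt(scores)
                  else scores
  names(columnScores) <- roiCols

  v <- columnScores
  if (cfg$mapMode == "drop") v <- pmax(v, 0)
  rng <- max(v) - min(v)
  norm <- if (rng > 0) (v - min(v)) / rng else rep(0, length(v))
  overlay <- array(0, dim(roi@mask))
  for (i in seq_along(roiCols))
    overlay[, roiCols[i], ][roi@mask[, roiCols[i], ]] <- norm[i]
  highlighted <- array(FALSE, dim(roi@mask))
  if (rng > 0) {
    q <- stats::quantile(overlay[roi@mask], cfg$highlightQuantile,
                         names = FALSE)
    highlighted <- overlay >= q & roi@mask & overlay > 0
  }
  new("AttentionMap", columnScores = columnScores, overlay = overlay,
      highlightedMask = highlighted, baselineScore = pFull,
      mode = cfg$mapMode)
}

runsOf <- function(cols) {
  # maximal runs of consecutive integers -> list of vectors
  if (!length(cols)) return(list())
  br <- c(0, which(diff(cols) > 1), length(cols))
  lapply(seq_len(length(br) - 1),
         function(i) cols[(br[i] + 1):br[i + 1]])
}

#' Judge whether an attention map localizes the true fissures
#'
#' A map is correct when every true in-plane (ventral/dorsal) fissure is
#' hit by the highlighted region within `tolerancePx` columns, and no
#' highlighted component lies farther than the tolerance from every
#' fissure. Lateral-only fissures are invisible on midsagittal slices and
#' always judged incorrect (`lateral_fissure`); a disc misclassified by the
#' upstream presence classifier is incorrect (`misclassified`) regardless
#' of its map.
#'
#' @param map an [AttentionMap-class] (may be `NULL` for a disc predicted
#'   negative)
#' @param disc the ground-truth [DiscPhantom-class]
#' @param tolerancePx matching tolerance in columns
#' @param predictedPositive upstream classifier call for this disc
#' @return a `LocalizationJudgement`: list with `verdict`
#'   (`"correct"`/`"incorrect"`), `matchedPositions` and `failureMode`
#' @export
judgeLocalization <- function(map, disc, tolerancePx = 3,
                              predictedPositive = TRUE) {
  stopifnot2(disc@attentionEligible, "disc is not attention-eligible")
  judgement <- function(verdict, matched, mode)
    structure(list(verdict = verdict, matchedPositions = matched,
                   failureMode = mode), class = "LocalizationJudgement")
  if (predictedPositive != disc@fissurePresent)
    return(judgement("incorrect", character(), "misclassified"))
  if (!disc@fissurePresent)
    return(judgement("correct", character(), "none"))
  inPlane <- intersect(disc@fissurePositions, c("ventral", "dorsal"))
  if (!length(inPlane))
    return(judgement("incorrect", character(), "lateral_fissure"))

  hiCols <- which(apply(map@highlightedMask, 2, any))
  roiCols <- which(apply(disc@roiMask, 2, any))
  cx <- mean(range(roiCols))
  fisCols <- which(apply(disc@fissureMask, 2, any))
  posCols <- list(ventral = fisCols[fisCols < cx],
                  dorsal = fisCols[fisCols > cx])

  matched <- character()
  for (p in inPlane) {
    pc <- posCols[[p]]
    if (length(pc) && length(hiCols) &&
        min(vapply(hiCols, function(h) min(abs(h - pc)), numeric(1))) <=
          tolerancePx)
      matched <- c(matched, p)
  }
  extensionOk <- length(hiCols) > 0 &&
    all(vapply(runsOf(hiCols), function(run)
      min(vapply(run, function(h) min(abs(h - fisCols)), numeric(1))) <=
        tolerancePx, logical(1)))

  if (setequal(matched, inPlane) && extensionOk)
    return(judgement("correct", matched, "none"))
  if (length(inPlane) > 1 && length(matched) >= 1)
    return(judgement("incorrect", matched, "missed_inferior_fissure"))
  if (!length(matched) && disc@degenerationGrade >= 5)
    return(judgement("incorrect", matched, "diffuse_degeneration"))
  judgement("incorrect", matched, "extension_mismatch")
}

#' Fraction of correctly localized fissures
#'
#' @param judgements list of [judgeLocalization()] results
#' @return list with `nCorrect`, `nTotal`, `fraction` and `percent`
#'   (integer-rounded, the convention localization rates are reported in)
#' @examples
#' js <- rep(list(structure(list(verdict = "correct"),
#'                class = "LocalizationJudgement")), 3)
#' localizationRate(js)$percent  # 100
#' @export
localizationRate <- function(judgements) {
  stopifnot2(length(judgements) >= 1, "no judgements")
  ok <- vapply(judgements, function(j) j$verdict == "correct", logical(1))
  list(nCorrect = sum(ok), nTotal = length(ok), fraction = mean(ok),
       percent = round(100 * mean(ok)))
}
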