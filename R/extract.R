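#' Extract a feature vector from a masked intensity stack
#'
#' Computes every feature in the registry, in registry order, from one ROI.
#' Matrix features are computed on fixed-bin-number discretized levels;
#' statistics (maximum, range, intensity-volume) on raw intensities. A
#' feature that is undefined on the input (e.g. Geary's C on a constant
#' ROI, or an all-empty matrix) is imputed as 0 with a warning so the
#' classifier input stays dense.
#'
#' @param roi an [IntensityROI-class]
#' @param registry a [FeatureRegistry-class]
#' @param nBins discretization levels (default 32)
#' @param gearyMax,gearySeed exact-pair cap and subsample seed for Geary's C
#' @param geometry optional precomputed geometry (internal; reused across
#'   occlusion positions, valid only while the mask is unchanged)
#' @return named numeric vector, names = [featureIds()] of the registry
#' @examples
#' roi <- intensityRoi(array(rnorm(48 * 96 * 2), c(48, 96, 2)),
#'                     array(TRUE, c(48, 96, 2)))
#' v <- extractFeatures(roi, featureRegistry("fissure22"))
#' length(v)  # 22
#' @export
extractFeatures <- function(roi, registry, nBins = 32, gearyMax = 3000,
                            gearySeed = 1L, geometry = NULL) {
  stopifnot2(is(roi, "IntensityROI"), "roi must be an IntensityROI")
  stopifnot2(length(registry) > 0, "registry is empty")
  if (is.null(geometry))
    geometry <- buildGeometry(roi@mask, roi@spacing, gearyMax = gearyMax,
                              gearySeed = gearySeed)
  d <- discretizeIntensities(roi, nBins)
  lev <- d$levelVec
  xRaw <- roi@image[roi@mask]
  ent <- registry@entries

  counts <- if (any(ent$family == "glcm"))
    glcmDiffCounts(lev, geometry, d$ng) else NULL
  ngtdm2 <- if (any(ent$family == "ngtdm" & ent$mode == "2Dmrg"))
    ngtdmStats(lev, geometry, d$ng, "2d") else NULL
  ngtdm3 <- if (any(ent$family == "ngtdm" & ent$mode == "3D"))
    ngtdmStats(lev, geometry, d$ng, "3d") else NULL
  fo <- if (any(ent$family %in%
                c("statistics", "intensity_volume", "intensity_histogram")))
    firstOrderKernel(xRaw, lev, d$ng) else NULL

  vals <- numeric(nrow(ent))
  for (r in seq_len(nrow(ent))) {
    fam <- ent$family[r]; fea <- ent$feature[r]; mod <- ent$mode[r]
    vals[r] <- switch(fam,
      morphology = gearyFromGeom(xRaw, geometry),
      statistics = unname(fo[fea]),
      intensity_volume = unname(fo["int_at_vol_fraction_90"]),
      intensity_histogram = unname(fo[fea]),
      glcm = glcmAggFromCounts(counts, fea, mod),
      ngtdm = ngtdmComplexityFromStats(
        (if (mod == "2Dmrg") ngtdm2 else ngtdm3)$n_i,
        (if (mod == "2Dmrg") ngtdm2 else ngtdm3)$s_i),
      ngldm = ngldmEnergyKernel(lev, geometry, d$ng),
      stop("unknown feature family: ", fam))
  }
  bad <- !is.finite(vals)
  if (any(bad)) {
    warning("imputed ", sum(bad), " undefined feature value(s) as 0: ",
            paste(ent$featureId[bad], collapse = ", "))
    vals[bad] <- 0
  }
  names(vals) <- ent$featureId
  vals
}

#' Extract features for every disc of a cohort
#'
#' Runs [extractFeatures()] on each disc and assembles the results into a
#' `SummarizedExperiment`: one assay `"features"` (features x discs) and the
#' cohort manifest as column data, so feature values and per-disc labels
#' travel together through cross-validation.
#'
#' @param cohort a [DiscCohort-class]
#' @param registry a [FeatureRegistry-class]
#' @param nBins discretization levels
#' @param gearyMax,gearySeed Geary's C subsampling controls
#' @return a `SummarizedExperiment`
#' @export
extractCohortFeatures <- function(cohort, registry, nBins = 32,
                                  gearyMax = 3000, gearySeed = 1L) {
  mats <- vapply(cohort@discs, function(disc) {
    roi <- discRoi(disc)
    extractFeatures(roi, registry, nBins = nBins, gearyMax = gearyMax,
                    gearySeed = gearySeed)
  }, numeric(length(registry)))
  mats <- matrix(mats, nrow = length(registry),
                 dimnames = list(featureIds(registry),
                                 cohort@manifest$discId))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = mats), colData = cohort@manifest)
}

#' Masked view of a disc phantom
#' @param disc a [DiscPhantom-class]
#' @return the disc's [IntensityROI-class]
#' @export
discRoi <- function(disc) {
  intensityRoi(disc@image, disc@roiMask, disc@spacing)
}

#' Write a cohort feature table as CSV
#'
#' One row per disc; columns are disc/patient identifiers followed by the
#' feature values in registry order.
#'
#' @param se `SummarizedExperiment` from [extractCohortFeatures()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeFeatureTable <- function(se, path) {
  m <- t(SummarizedExperiment::assay(se, "features"))
  cd <- SummarizedExperiment::colData(se)
  df <- data.frame(discId = rownames(m), patientId = cd$patientId,
                   m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
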