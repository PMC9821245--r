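#' Write a cohort to disk
#'
#' One NIfTI file per disc per channel (image, ROI mask, fissure mask),
#' with the manifest as CSV (one row per disc, all labels) and the phantom
#' configuration as a JSON sidecar.
#'
#' @param cohort a [DiscCohort-class]
#' @param dir output directory (created if missing)
#' @return `dir`, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  asNii <- function(x, pd) {
    img <- RNifti::asNifti(x)
    RNifti::pixdim(img) <- pd
    img
  }
  for (disc in cohort@discs) {
    base <- file.path(dir, disc@discId)
    pd <- disc@spacing
    RNifti::writeNifti(asNii(disc@image, pd), paste0(base, "_image.nii.gz"))
    RNifti::writeNifti(asNii(disc@roiMask * 1, pd),
                       paste0(base, "_roi.nii.gz"))
    RNifti::writeNifti(asNii(disc@fissureMask * 1, pd),
                       paste0(base, "_fissure.nii.gz"))
  }
  utils::write.csv(as.data.frame(cohort@manifest),
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(cohort@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a masked image pair from NIfTI files
#'
#' @param imagePath NIfTI intensity image
#' @param maskPath NIfTI binary mask of the same shape
#' @return an [IntensityROI-class]; the voxel spacing is read from the
#'   image header
#' @export
readRoiNifti <- function(imagePath, maskPath) {
  img <- RNifti::readNifti(imagePath)
  msk <- RNifti::readNifti(maskPath)
  sp <- RNifti::pixdim(img)[1:3]
  intensityRoi(array(as.numeric(img), dim(img)),
               array(as.numeric(msk) > 0, dim(msk)), spacing = sp)
}

#' Export an attention map as NIfTI plus CSV
#'
#' Writes the normalized overlay and the highlighted mask as NIfTI volumes
#' and the per-column occlusion scores as CSV.
#'
#' @param map an [AttentionMap-class]
#' @param basePath path prefix; `_overlay.nii.gz`, `_highlight.nii.gz` and
#'   `_columns.csv` are appended
#' @param spacing voxel spacing for the NIfTI headers
#' @return `basePath`, invisibly
#' @export
writeAttentionMap <- function(map, basePath, spacing = c(1, 1, 1)) {
  asNii <- function(x) {
    img <- RNifti::asNifti(x)
    RNifti::pixdim(img) <- spacing
    img
  }
  RNifti::writeNifti(asNii(map@overlay), paste0(basePath, "_overlay.nii.gz"))
  RNifti::writeNifti(asNii(map@highlightedMask * 1),
                     paste0(basePath, "_highlight.nii.gz"))
  utils::write.csv(data.frame(column = as.integer(names(map@columnScores)),
                              score = unname(map@columnScores)),
                   paste0(basePath, "_columns.csv"), row.names = FALSE)
  invisible(basePath)
}
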