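#' @import methods
NULL

#' IntensityROI: a masked intensity stack
#'
#' Couples a real-valued image stack (rows x cols x slices) with a binary
#' region-of-interest mask of identical shape and the physical voxel spacing
#' in millimetres (row, col, slice). All texture features are computed on the
#' voxels inside the mask; voxels outside the mask never influence a feature.
#'
#' @slot image numeric 3D array (rows x cols x slices)
#' @slot mask logical 3D array, same dimensions as `image`
#' @slot spacing numeric length-3, voxel spacing in mm (row, col, slice)
#' @export
setClass("IntensityROI",
  representation(image = "array", mask = "array", spacing = "numeric"))

setValidity("IntensityROI", function(object) {
  msg <- character()
  if (length(dim(object@image)) != 3L) msg <- c(msg, "image must be a 3D array")
  if (!identical(dim(object@image), dim(object@mask)))
    msg <- c(msg, "image and mask dimensions differ")
  if (!any(object@mask)) msg <- c(msg, "mask is empty")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive values (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct an IntensityROI
#'
#' @param image numeric 3D array (rows x cols x slices); a 2D matrix is
#'   promoted to a single-slice stack
#' @param mask logical/0-1 array of the same shape
#' @param spacing voxel spacing in mm (row, col, slice)
#' @return an [IntensityROI-class] object
#' @examples
#' img <- array(rnorm(4 * 6 * 2), c(4, 6, 2))
#' roi <- intensityRoi(img, array(TRUE, dim(img)))
#' @export
intensityRoi <- function(image, mask, spacing = c(1, 1, 1)) {
  if (length(dim(image)) == 2L) image <- array(image, c(dim(image), 1L))
  if (length(dim(mask)) == 2L) mask <- array(mask, c(dim(mask), 1L))
  mask <- array(as.logical(mask), dim(mask))
  new("IntensityROI", image = image, mask = mask, spacing = as.numeric(spacing))
}

#' DiscPhantom: one synthetic intervertebral disc
#'
#' A synthetic midsagittal T2-weighted disc: the image stack, the disc ROI
#' mask, a ground-truth fissure mask, and the per-disc labels the downstream
#' analysis consumes (fissure presence and position, high-intensity-zone
#' surrogate flag, degeneration grade, attention-mapping eligibility and
#' patient grouping). Column index increases ventral (left) to dorsal
#' (right).
#'
#' @slot image numeric array (rows x cols x slices)
#' @slot roiMask logical array, disc region
#' @slot fissureMask logical array, ground-truth fissure voxels (subset of
#'   the ROI); empty for fissure-free and lateral-only discs
#' @slot spacing numeric voxel spacing in mm
#' @slot fissurePresent logical, outer annular fissure present
#' @slot fissurePositions character subset of ventral/dorsal/lateral
#' @slot hizFlag logical, visible bright-zone surrogate
#' @slot degenerationGrade integer 2..5 (Pfirrmann analogue)
#' @slot attentionEligible logical, >50 percent intact outer annulus analogue
#' @slot patientId character patient identifier
#' @slot level character spinal level label
#' @slot discId character unique disc identifier
#' @export
setClass("DiscPhantom",
  representation(image = "array", roiMask = "array", fissureMask = "array",
    spacing = "numeric", fissurePresent = "logical",
    fissurePositions = "character", hizFlag = "logical",
    degenerationGrade = "integer", attentionEligible = "logical",
    patientId = "character", level = "character", discId = "character"))

setValidity("DiscPhantom", function(object) {
  msg <- character()
  if (!identical(dim(object@image), dim(object@roiMask)) ||
      !identical(dim(object@image), dim(object@fissureMask)))
    msg <- c(msg, "image/roiMask/fissureMask dimensions differ")
  if (any(object@fissureMask & !object@roiMask))
    msg <- c(msg, "fissureMask must be a subset of roiMask")
  if (!all(object@fissurePositions %in% c("ventral", "dorsal", "lateral")))
    msg <- c(msg, "fissurePositions must be within ventral/dorsal/lateral")
  inPlane <- any(object@fissurePositions %in% c("ventral", "dorsal"))
  # lateral-only fissures are invisible on midsagittal slices: empty mask
  if (object@fissurePresent && inPlane && !any(object@fissureMask))
    msg <- c(msg, "in-plane fissure labelled but fissureMask empty")
  if (!object@fissurePresent && any(object@fissureMask))
    msg <- c(msg, "fissureMask nonempty but fissurePresent is FALSE")
  if (!(object@degenerationGrade %in% 2:5))
    msg <- c(msg, "degenerationGrade must be in 2..5")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DiscPhantom", function(object) {
  cat("DiscPhantom", object@discId, "(patient", object@patientId,
      ", level", object@level, ")\n")
  cat("  dims:", paste(dim(object@image), collapse = " x "),
      " grade:", object@degenerationGrade, "\n")
  cat("  fissure:", if (object@fissurePresent)
        paste(object@fissurePositions, collapse = "+") else "none",
      " HIZ:", object@hizFlag,
      " attention-eligible:", object@attentionEligible, "\n")
})

#' DiscCohort: a simulated cohort of disc phantoms
#'
#' A list of [DiscPhantom-class] objects with a per-disc manifest
#' (`S4Vectors::DataFrame`, one row per disc recording all labels) and the
#' generating [phantomConfig()].
#'
#' @slot discs list of DiscPhantom
#' @slot manifest DataFrame, one row per disc
#' @slot config list, the phantom configuration used
#' @export
setClass("DiscCohort",
  representation(discs = "list", manifest = "DataFrame", config = "list"))

setValidity("DiscCohort", function(object) {
  if (length(object@discs) != nrow(object@manifest))
    return("manifest rows must match number of discs")
  TRUE
})

setMethod("show", "DiscCohort", function(object) {
  m <- object@manifest
  cat("DiscCohort:", length(object@discs), "discs,",
      length(unique(m$patientId)), "patients\n")
  cat("  fissure-positive:", sum(m$fissurePresent),
      " HIZ:", sum(m$hizFlag),
      " attention-eligible:", sum(m$attentionEligible), "\n")
})

#' @describeIn DiscCohort number of discs
#' @param x a DiscCohort
#' @export
setMethod("length", "DiscCohort", function(x) length(x@discs))

#' @describeIn DiscCohort extract one disc
#' @param i index
#' @export
setMethod("[[", "DiscCohort", function(x, i) x@discs[[i]])

#' FeatureRegistry: ordered catalogue of texture features
#'
#' The registry fixes the identity and order of the features a classifier
#' consumes. Each entry names a feature family (firstorder, morphology,
#' glcm, ngtdm, ngldm), the feature within the family, and the aggregation
#' mode for matrix features.
#'
#' @slot entries data.frame with columns featureId, family, feature, mode
#' @export
setClass("FeatureRegistry", representation(entries = "data.frame"))

setValidity("FeatureRegistry", function(object) {
  need <- c("featureId", "family", "feature", "mode")
  if (!all(need %in% names(object@entries)))
    return("entries must have featureId/family/feature/mode columns")
  if (anyDuplicated(object@entries$featureId)) return("duplicate featureId")
  TRUE
})

setMethod("show", "FeatureRegistry", function(object) {
  cat("FeatureRegistry with", nrow(object@entries), "features\n")
  print(utils::head(object@entries$featureId, 8))
  if (nrow(object@entries) > 8) cat("  ...\n")
})

#' @describeIn FeatureRegistry number of features
#' @param x a FeatureRegistry
#' @export
setMethod("length", "FeatureRegistry", function(x) nrow(x@entries))

#' FissureEnsemble: an ensemble of shallow networks
#'
#' A trained averaging ensemble: each member is a fully connected network
#' with one five-node tanh hidden layer and a two-node softmax output. The
#' ensemble stores the feature standardization parameters estimated on its
#' training data and the feature identity/order it expects.
#'
#' @slot members list of weight sets (W1, b1, W2, b2)
#' @slot center numeric per-feature training means
#' @slot scale numeric per-feature training standard deviations
#' @slot featureIds character, expected feature order
#' @slot config list, the training configuration
#' @export
setClass("FissureEnsemble",
  representation(members = "list", center = "numeric", scale = "numeric",
    featureIds = "character", config = "list"))

setValidity("FissureEnsemble", function(object) {
  if (length(object@members) < 1L) return("ensemble must have >= 1 member")
  nin <- vapply(object@members, function(m) nrow(m$W1), integer(1))
  if (length(unique(nin)) != 1L) return("members disagree on input size")
  if (nin[1] != length(object@featureIds))
    return("member input size must equal number of feature ids")
  TRUE
})

setMethod("show", "FissureEnsemble", function(object) {
  cat("FissureEnsemble:", length(object@members), "members,",
      length(object@featureIds), "input features\n")
})

#' AttentionMap: occlusion attention map for one disc
#'
#' Per-column occlusion scores mapped back onto the disc, the min-max
#' normalized overlay (zero outside the ROI) and the thresholded highlighted
#' mask used for localization judging.
#'
#' @slot columnScores numeric, one score per ROI-intersecting column (names
#'   are column indices)
#' @slot overlay numeric array in [0, 1], zero outside the ROI
#' @slot highlightedMask logical array
#' @slot baselineScore numeric, unoccluded classifier score
#' @slot mode character, "drop" or "score"
#' @export
setClass("AttentionMap",
  representation(columnScores = "numeric", overlay = "array",
    highlightedMask = "array", baselineScore = "numeric", mode = "character"))

setMethod("show", "AttentionMap", function(object) {
  cs <- object@columnScores
  cat("AttentionMap (", object@mode, " mode): ", length(cs), " columns, ",
      "baseline score ", round(object@baselineScore, 3), "\n", sep = "")
  if (length(cs)) cat("  peak at column", names(cs)[which.max(cs)], "\n")
})

#' ConfusionTable: 2x2 classification cross-tabulation
#'
#' Counts of true/false positives and negatives with fissure as the positive
#' class.
#'
#' @slot tp,fp,fn,tn integer counts
#' @export
setClass("ConfusionTable",
  representation(tp = "integer", fp = "integer", fn = "integer",
    tn = "integer"))

setValidity("ConfusionTable", function(object) {
  n <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(n < 0)) return("counts must be non-negative")
  if (sum(n) == 0) return("table is empty")
  TRUE
})

setMethod("show", "ConfusionTable", function(object) {
  m <- matrix(c(object@tn, object@fp, object@fn, object@tp), 2, 2,
    byrow = TRUE,
    dimnames = list(truth = c("no fissure", "fissure"),
                    predicted = c("no fissure", "fissure")))
  print(m)
})
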