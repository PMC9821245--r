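fissure22Entries <- function() {
  e <- rbind(
    c("morph_gearys_c",          "morphology",          "gearys_c", ""),
    c("stat_maximum",            "statistics",          "maximum", ""),
    c("stat_range",              "statistics",          "range", ""),
    c("ivol_int_at_vol_fraction_90", "intensity_volume",
      "int_at_vol_fraction_90", ""),
    c("ih_p10",                  "intensity_histogram", "p10", ""),
    c("ih_mode",                 "intensity_histogram", "mode", ""),
    c("glcm_2Davg_difference_average",  "glcm", "difference_average", "2Davg"),
    c("glcm_2Davg_dissimilarity",       "glcm", "dissimilarity",      "2Davg"),
    c("glcm_2DDmrg_difference_average", "glcm", "difference_average", "2DDmrg"),
    c("glcm_2DDmrg_difference_variance","glcm", "difference_variance","2DDmrg"),
    c("glcm_2DDmrg_contrast",           "glcm", "contrast",           "2DDmrg"),
    c("glcm_2DDmrg_dissimilarity",      "glcm", "dissimilarity",      "2DDmrg"),
    c("glcm_2Dmrg_difference_average",  "glcm", "difference_average", "2Dmrg"),
    c("glcm_2Dvmrg_difference_variance","glcm", "difference_variance","2Dvmrg"),
    c("glcm_2Dvmrg_contrast",           "glcm", "contrast",           "2Dvmrg"),
    c("glcm_2Dvmrg_dissimilarity",      "glcm", "dissimilarity",      "2Dvmrg"),
    c("glcm_3Davg_difference_average",  "glcm", "difference_average", "3Davg"),
    c("glcm_3Davg_difference_variance", "glcm", "difference_variance","3Davg"),
    c("glcm_3Davg_dissimilarity",       "glcm", "dissimilarity",      "3Davg"),
    c("ngtdm_2Dmrg_complexity",         "ngtdm", "complexity",        "2Dmrg"),
    c("ngtdm_3D_complexity",            "ngtdm", "complexity",        "3D"),
    c("ngldm_3Dmrg_dependence_count_energy", "ngldm",
      "dependence_count_energy", "3Dmrg"))
  data.frame(featureId = e[, 1], family = e[, 2], feature = e[, 3],
             mode = e[, 4], stringsAsFactors = FALSE)
}

fullEntries <- function() {
  glcmFeats <- c("difference_average", "difference_variance", "contrast",
                 "dissimilarity")
  glcmModes <- c("2Davg", "2Dmrg", "2DDmrg", "2Dvmrg", "3Davg", "3Dmrg")
  g <- expand.grid(feature = glcmFeats, mode = glcmModes,
                   stringsAsFactors = FALSE)
  glcm <- data.frame(
    featureId = paste0("glcm_", g$mode, "_", g$feature),
    family = "glcm", feature = g$feature, mode = g$mode,
    stringsAsFactors = FALSE)
  fo <- fissure22Entries()[1:6, ]
  ngtdm <- data.frame(
    featureId = c("ngtdm_2Dmrg_complexity", "ngtdm_3D_complexity"),
    family = "ngtdm", feature = "complexity", mode = c("2Dmrg", "3D"),
    stringsAsFactors = FALSE)
  ngldm <- data.frame(
    featureId = "ngldm_3Dmrg_dependence_count_energy",
    family = "ngldm", feature = "dependence_count_energy", mode = "3Dmrg",
    stringsAsFactors = FALSE)
  rbind(fo, glcm, ngtdm, ngldm)
}

#' Texture-feature registry
#'
#' The registry fixes which features are computed and in which order; the
#' order defines the classifier input layout. `"fissure22"` is the 22-feature
#' set sensitive to tissue near outer annular fissures that drives the
#' attention-mapping classifier; `"full"` expands every implemented feature
#' family over all of its aggregation modes and drives the main fissure
#' classifier.
#'
#' @param set `"fissure22"` (22 features) or `"full"` (family x aggregation
#'   expansion)
#' @return a [FeatureRegistry-class]
#' @examples
#' length(featureRegistry("fissure22"))  # 22
#' @export
featureRegistry <- function(set = c("fissure22", "full")) {
  set <- match.arg(set)
  new("FeatureRegistry",
      entries = if (set == "fissure22") fissure22Entries() else fullEntries())
}

#' Feature identifiers of a registry
#' @param registry a [FeatureRegistry-class]
#' @return character vector in registry order
#' @export
featureIds <- function(registry) registry@entries$featureId

#' Serialize a registry to JSON
#' @param registry a [FeatureRegistry-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeRegistry <- function(registry, path) {
  jsonlite::write_json(registry@entries, path, dataframe = "rows")
  invisible(path)
}
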