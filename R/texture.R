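#' Discretize a masked intensity stack to grey levels
#'
#' Fixed-bin-number discretization: masked intensities are mapped to levels
#' `floor(nBins * (x - min) / (max - min)) + 1`, clipped to `nBins`. A
#' constant ROI maps to level 1. Discretization is scanner-scale free: adding
#' a constant to, or rescaling, the image leaves the levels unchanged.
#'
#' @param roi an [IntensityROI-class]
#' @param nBins number of grey levels (>= 2), default 32
#' @return a `DiscretizedROI`: list with `levels` (integer array, `NA`
#'   outside the mask), `levelVec` (levels of masked voxels in mask order),
#'   `ng` (number of levels) and `roi` (the input)
#' @examples
#' roi <- intensityRoi(matrix(0:31, 4, 8), matrix(TRUE, 4, 8))
#' d <- discretizeIntensities(roi, 32)
#' range(d$levelVec)  # 1 .. 32
#' @export
discretizeIntensities <- function(roi, nBins = 32) {
  stopifnot2(is(roi, "IntensityROI"), "roi must be an IntensityROI")
  stopifnot2(nBins >= 2, "nBins must be >= 2")
  x <- roi@image[roi@mask]
  mn <- min(x); mx <- max(x)
  lev <- if (mx > mn)
    pmin(floor(nBins * (x - mn) / (mx - mn)) + 1, nBins)
  else rep(1, length(x))
  arr <- array(NA_integer_, dim(roi@mask))
  arr[roi@mask] <- as.integer(lev)
  structure(list(levels = arr, levelVec = as.integer(lev),
                 ng = as.integer(nBins), roi = roi),
            class = "DiscretizedROI")
}

#' Grey-level co-occurrence matrix for one direction
#'
#' Counts co-occurrences of grey levels at a Chebyshev-distance-1 offset,
#' restricted to voxel pairs that both lie inside the mask, and normalizes to
#' unit sum. With `symmetric = TRUE` (default) each pair is counted in both
#' orders, making the matrix symmetric.
#'
#' @param d a `DiscretizedROI` from [discretizeIntensities()]
#' @param offset integer length-3 (row, col, slice) offset with Chebyshev
#'   norm 1
#' @param symmetric count pairs in both orders
#' @return an Ng x Ng numeric matrix summing to 1; if the direction admits no
#'   valid in-mask pair, a zero matrix with attribute `empty = TRUE`
#' @examples
#' roi <- intensityRoi(matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE),
#'                     matrix(TRUE, 2, 2))
#' d <- discretizeIntensities(roi, 2)
#' glcmMatrix(d, c(0, 1, 0))  # mass 0.5 on (1,1) and (2,2)
#' @export
glcmMatrix <- function(d, offset = c(0, 1, 0), symmetric = TRUE) {
  stopifnot2(length(offset) == 3 && max(abs(offset)) == 1,
             "offset must be a Chebyshev-distance-1 triple")
  mask <- !is.na(d$levels)
  dims <- dim(mask)
  idx <- which(mask)
  pos <- arrayInd(idx, dims)
  id <- array(0L, dims); id[idx] <- seq_along(idx)
  r <- pos[, 1] + offset[1]; c <- pos[, 2] + offset[2]
  s <- pos[, 3] + offset[3]
  ok <- r >= 1 & r <= dims[1] & c >= 1 & c <= dims[2] & s >= 1 & s <= dims[3]
  j <- integer(length(idx)); j[ok] <- id[cbind(r[ok], c[ok], s[ok])]
  keep <- which(j > 0L)
  ng <- d$ng
  lev <- d$levelVec
  P <- matrix(0, ng, ng)
  if (length(keep)) {
    cnt <- tabulate((lev[keep] - 1L) * ng + lev[j[keep]], nbins = ng * ng)
    P <- matrix(cnt, ng, ng, byrow = TRUE)
    if (symmetric) P <- P + t(P)
  }
  tot <- sum(P)
  if (tot == 0) return(structure(P, empty = TRUE))
  structure(P / tot, empty = FALSE)
}

#' Difference features of a co-occurrence matrix
#'
#' With `p(k) = sum over |i-j| = k of P(i, j)`: difference average
#' `DA = sum k p(k)`, difference variance `sum (k - DA)^2 p(k)`, contrast
#' `sum (i-j)^2 P(i,j)` and dissimilarity `sum |i-j| P(i,j)`. For a
#' normalized matrix dissimilarity equals the difference average.
#'
#' @param P normalized co-occurrence matrix (entries sum to 1)
#' @return named list with `difference_average`, `difference_variance`,
#'   `contrast`, `dissimilarity`
#' @export
glcmFeatures <- function(P) {
  if (isTRUE(attr(P, "empty")))
    return(list(difference_average = NA_real_,
                difference_variance = NA_real_,
                contrast = NA_real_, dissimilarity = NA_real_))
  stopifnot2(abs(sum(P) - 1) < 1e-8, "P must be normalized (sum to 1)")
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  k <- abs(i - j)
  pk <- vapply(0:(ng - 1), function(kk) sum(P[k == kk]), numeric(1))
  kk <- 0:(ng - 1)
  da <- sum(kk * pk)
  list(difference_average = da,
       difference_variance = sum((kk - da)^2 * pk),
       contrast = sum(kk^2 * pk),
       dissimilarity = sum(k * P))
}

#' Aggregate a GLCM feature over slices and directions
#'
#' The six aggregation conventions for 2D/3D co-occurrence features:
#' \describe{
#'   \item{2Davg}{feature per slice per in-plane direction, averaged over all}
#'   \item{2Dmrg}{directions merged within each slice, feature per slice,
#'     averaged over slices}
#'   \item{2DDmrg}{matrices merged across slices per direction, feature per
#'     direction, averaged}
#'   \item{2Dvmrg}{all in-plane matrices merged into one, single feature}
#'   \item{3Davg}{feature per 3D direction (13 unique), averaged}
#'   \item{3Dmrg}{all 3D matrices merged, single feature}
#' }
#' Matrices are merged by summing co-occurrence counts; directions or slices
#' contributing no valid pair are excluded from averages.
#'
#' @param d a `DiscretizedROI`
#' @param feature one of `difference_average`, `difference_variance`,
#'   `contrast`, `dissimilarity`
#' @param mode aggregation mode (see above)
#' @return scalar feature value; `NA` if every matrix is empty
#' @export
glcmAggregate <- function(d,
    feature = c("difference_average", "difference_variance", "contrast",
                "dissimilarity"),
    mode = c("2Davg", "2Dmrg", "2DDmrg", "2Dvmrg", "3Davg", "3Dmrg")) {
  feature <- match.arg(feature)
  mode <- match.arg(mode)
  geom <- buildGeometry(!is.na(d$levels), d$roi@spacing)
  counts <- glcmDiffCounts(d$levelVec, geom, d$ng)
  glcmAggFromCounts(counts, feature, mode)
}

#' Neighbourhood grey tone difference complexity
#'
#' For each masked voxel with at least one masked neighbour (Chebyshev
#' distance 1; in-plane 8-neighbourhood for 2D, 26-neighbourhood for 3D),
#' the absolute difference between its level and the mean level of its
#' masked neighbours is accumulated per level (`s_i`), alongside the voxel
#' counts `n_i`. Complexity is
#' `(1/Nvc) * sum over i != j of |i - j| (p_i s_i + p_j s_j) / (p_i + p_j)`
#' over levels with positive probability. In `2Dmrg` mode the per-slice
#' `n_i` and `s_i` are merged (summed) before the feature is computed.
#'
#' @param d a `DiscretizedROI`
#' @param mode `"2Dmrg"` (in-plane neighbourhoods, merged over slices) or
#'   `"3D"`
#' @return scalar complexity; 0 for a uniform ROI
#' @export
ngtdmComplexity <- function(d, mode = c("2Dmrg", "3D")) {
  mode <- match.arg(mode)
  geom <- buildGeometry(!is.na(d$levels), d$roi@spacing)
  st <- ngtdmStats(d$levelVec, geom, d$ng,
                   plane = if (mode == "2Dmrg") "2d" else "3d")
  ngtdmComplexityFromStats(st$n_i, st$s_i)
}

#' Neighbouring grey level dependence count energy
#'
#' With coarseness parameter `alpha = 0` and Chebyshev neighbourhood
#' distance 1, `s(i, j)` counts masked voxels of level `i` with exactly `j`
#' masked neighbours whose level differs by at most `alpha`. The dependence
#' count energy is `sum p(i, j)^2` with `p = s / N`.
#'
#' @param d a `DiscretizedROI`
#' @param alpha coarseness tolerance (default 0: neighbours must match
#'   exactly)
#' @return scalar energy in (0, 1]
#' @export
ngldmDependenceCountEnergy <- function(d, alpha = 0) {
  geom <- buildGeometry(!is.na(d$levels), d$roi@spacing)
  ngldmEnergyKernel(d$levelVec, geom, d$ng, alpha = alpha)
}

#' Geary's C spatial autocorrelation of masked intensities
#'
#' `C = (N - 1) / (2 W) * sum over i != j of w_ij (x_i - x_j)^2 /
#' sum (x_i - xbar)^2` with inverse physical-distance weights
#' `w_ij = 1 / ||pos_i - pos_j||` (millimetres) and `W = sum w_ij`. Values
#' below 1 indicate positive spatial autocorrelation (smooth images); a
#' spatially random arrangement has expectation 1. Beyond `maxVoxels`
#' masked voxels a seeded uniform subsample bounds the O(N^2) pair cost.
#'
#' @param roi an [IntensityROI-class]
#' @param maxVoxels exact-pair cap (default 3000)
#' @param seed subsample seed
#' @return scalar; `NA` (flagged missing) for constant intensities
#' @export
gearysC <- function(roi, maxVoxels = 3000, seed = 1L) {
  stopifnot2(sum(roi@mask) >= 2, "need at least 2 masked voxels")
  geom <- buildGeometry(roi@mask, roi@spacing, gearyMax = maxVoxels,
                        gearySeed = seed)
  gearyFromGeom(roi@image[roi@mask], geom)
}

#' First-order intensity features
#'
#' Maximum and range are computed on the raw masked intensities, the 10th
#' percentile (empirical, inverse-ECDF) and the mode (ties to the lowest
#' level) on the discretized levels, and `int_at_vol_fraction_90` is the
#' smallest observed intensity `g` such that the fraction of masked voxels
#' with intensity `>= g` is at most 0.90.
#'
#' @param roi an [IntensityROI-class]
#' @param d matching `DiscretizedROI` (computed from `roi` if omitted)
#' @param nBins grey levels used when `d` is omitted
#' @return named numeric: `maximum`, `range`, `int_at_vol_fraction_90`,
#'   `p10`, `mode`
#' @export
firstOrderFeatures <- function(roi, d = NULL, nBins = 32) {
  if (is.null(d)) d <- discretizeIntensities(roi, nBins)
  firstOrderKernel(roi@image[roi@mask], d$levelVec, d$ng)
}
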