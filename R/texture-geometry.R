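# Internal neighbourhood geometry for texture-matrix features.
#
# All matrix features (GLCM, NGTDM, NGLDM) and Geary's C depend on the mask
# and voxel spacing only through (a) masked voxel pair lists per direction
# and (b) pairwise inverse-distance weights. These are precomputed once per
# mask and reused across intensity changes, which makes the occlusion sweep
# (many re-extractions under an identical mask) cheap.

# Unique in-plane Chebyshev-distance-1 directions, (row, col, slice).
DIRS2D <- rbind(c(0, 1, 0), c(1, 0, 0), c(1, 1, 0), c(1, -1, 0))

# Unique 3D Chebyshev-distance-1 directions: the 4 in-plane plus all 9 with
# slice offset +1.
DIRS3D <- rbind(DIRS2D,
  as.matrix(expand.grid(dr = -1:1, dc = -1:1, ds = 1))[, c("dr", "dc", "ds")])

buildGeometry <- function(mask, spacing, gearyMax = 3000L, gearySeed = 1L) {
  dims <- dim(mask)
  idx <- which(mask)
  n <- length(idx)
  if (n == 0L) stop("mask is empty", call. = FALSE)
  pos <- arrayInd(idx, dims)
  id <- array(0L, dims)
  id[idx] <- seq_len(n)

  shiftPairs <- function(off) {
    r <- pos[, 1] + off[1]; c <- pos[, 2] + off[2]; s <- pos[, 3] + off[3]
    ok <- r >= 1L & r <= dims[1] & c >= 1L & c <= dims[2] &
          s >= 1L & s <= dims[3]
    j <- integer(n)
    j[ok] <- id[cbind(r[ok], c[ok], s[ok])]
    keep <- which(j > 0L)
    list(i = keep, j = j[keep])
  }

  pairs3d <- lapply(seq_len(nrow(DIRS3D)), function(k) shiftPairs(DIRS3D[k, ]))
  pairs2d <- pairs3d[1:4]

  symCat <- function(plist) {
    i <- unlist(lapply(plist, `[[`, "i"), use.names = FALSE)
    j <- unlist(lapply(plist, `[[`, "j"), use.names = FALSE)
    list(i = c(i, j), j = c(j, i))
  }
  nb2 <- symCat(pairs2d)   # in-plane 8-neighbourhood, directed
  nb3 <- symCat(pairs3d)   # 26-neighbourhood, directed

  m <- min(n, as.integer(gearyMax))
  sub <- if (m < n) withSeed(gearySeed, sort(sample.int(n, m))) else seq_len(n)
  coords <- pos[sub, , drop = FALSE]
  coords <- sweep(coords, 2L, spacing, `*`)
  if (m >= 2L) {
    # dense symmetric inverse-distance weight matrix (zero diagonal): lets
    # sum w_ij (x_i - x_j)^2 be evaluated as 2 (sum x^2 r - x' W x) via one
    # BLAS matrix-vector product per intensity configuration
    sq <- rowSums(coords^2)
    d2 <- -2 * tcrossprod(coords)
    d2 <- d2 + sq                                  # adds sq_i by rows
    d2 <- t(d2) + sq                               # ... and sq_j
    diag(d2) <- Inf                                # no self-pairs
    W <- 1 / sqrt(d2)
    gearyR <- rowSums(W)
    gearyWu <- sum(gearyR) / 2
  } else {
    W <- matrix(0, 0, 0); gearyR <- numeric(0); gearyWu <- 0
  }

  list(dims = dims, n = n, idx = idx, pos = pos, sliceOf = pos[, 3],
       nSlices = dims[3], pairs2d = pairs2d, pairs3d = pairs3d,
       nb2 = nb2, nb3 = nb3,
       gearySub = sub, gearyW = W, gearyR = gearyR, gearyWu = gearyWu)
}

# --- GLCM kernels -----------------------------------------------------------
# The four registry GLCM features (difference average/variance, contrast,
# dissimilarity) are functions of the grey-level difference distribution
# p(k), k = |i - j|, alone, so per-(slice, direction) difference-count
# vectors are a sufficient statistic. Matrix merging = summing counts.

glcmDiffCounts <- function(lev, geom, ng) {
  S <- geom$nSlices
  d2 <- array(0, c(ng, S, 4L))
  for (k in 1:4) {
    p <- geom$pairs2d[[k]]
    if (length(p$i))
      d2[, , k] <- tabulate(abs(lev[p$i] - lev[p$j]) + 1L +
                              (geom$sliceOf[p$i] - 1L) * ng,
                            nbins = ng * S)
  }
  d3 <- matrix(0, ng, nrow(DIRS3D))
  for (k in seq_len(nrow(DIRS3D))) {
    p <- geom$pairs3d[[k]]
    if (length(p$i))
      d3[, k] <- tabulate(abs(lev[p$i] - lev[p$j]) + 1L, nbins = ng)
  }
  list(d2 = d2, d3 = d3)
}

glcmFeatureFromDiff <- function(cnt, feature) {
  tot <- sum(cnt)
  if (tot == 0) return(NA_real_)
  p <- cnt / tot
  k <- seq_along(cnt) - 1
  da <- sum(k * p)
  switch(feature,
    difference_average  = da,
    dissimilarity       = da,
    contrast            = sum(k * k * p),
    difference_variance = sum((k - da)^2 * p),
    stop("unknown GLCM feature: ", feature))
}

glcmAggFromCounts <- function(counts, feature, mode) {
  d2 <- counts$d2; d3 <- counts$d3
  ng <- dim(d2)[1]
  vals <- switch(mode,
    "2Davg" = {
      v <- apply(d2, c(2, 3), glcmFeatureFromDiff, feature = feature)
      as.numeric(v)
    },
    "2Dmrg" = {
      perSlice <- apply(d2, c(1, 2), sum)          # ng x S
      apply(perSlice, 2, glcmFeatureFromDiff, feature = feature)
    },
    "2DDmrg" = {
      perDir <- apply(d2, c(1, 3), sum)            # ng x 4
      apply(perDir, 2, glcmFeatureFromDiff, feature = feature)
    },
    "2Dvmrg" = glcmFeatureFromDiff(apply(d2, 1, sum), feature),
    "3Davg"  = apply(d3, 2, glcmFeatureFromDiff, feature = feature),
    "3Dmrg"  = glcmFeatureFromDiff(rowSums(d3), feature),
    stop("unknown aggregation mode: ", mode))
  vals <- vals[is.finite(vals)]
  if (!length(vals)) NA_real_ else mean(vals)
}

# --- NGTDM ------------------------------------------------------------------

ngtdmStats <- function(lev, geom, ng, plane = c("2d", "3d")) {
  plane <- match.arg(plane)
  nb <- if (plane == "2d") geom$nb2 else geom$nb3
  n <- geom$n
  cnt <- tabulate(nb$i, nbins = n)
  sv <- numeric(n)
  if (length(nb$i)) {
    rs <- rowsum(as.numeric(lev[nb$j]), nb$i)
    sv[as.integer(rownames(rs))] <- rs[, 1]
  }
  has <- cnt > 0L
  dev <- abs(lev[has] - sv[has] / cnt[has])
  li <- lev[has]
  n_i <- tabulate(li, nbins = ng)
  s_i <- numeric(ng)
  if (length(li)) {
    rs2 <- rowsum(dev, li)
    s_i[as.integer(rownames(rs2))] <- rs2[, 1]
  }
  list(n_i = n_i, s_i = s_i)
}

ngtdmComplexityFromStats <- function(n_i, s_i) {
  nvc <- sum(n_i)
  if (nvc == 0) return(NA_real_)
  p <- n_i / nvc
  lv <- which(p > 0)
  tot <- 0
  for (i in lv) for (j in lv) if (i != j)
    tot <- tot + abs(i - j) * (p[i] * s_i[i] + p[j] * s_i[j]) / (p[i] + p[j])
  tot / nvc
}

# --- NGLDM ------------------------------------------------------------------

ngldmEnergyKernel <- function(lev, geom, ng, alpha = 0) {
  nb <- geom$nb3
  dep <- numeric(geom$n)
  if (length(nb$i)) {
    q <- as.numeric(abs(lev[nb$i] - lev[nb$j]) <= alpha)
    rs <- rowsum(q, nb$i)
    dep[as.integer(rownames(rs))] <- rs[, 1]
  }
  maxDep <- 27L                                    # dependence counts 0..26
  s <- tabulate((lev - 1L) * maxDep + dep + 1L, nbins = ng * maxDep)
  p <- s / geom$n
  sum(p * p)
}

# --- Geary's C --------------------------------------------------------------

gearyFromGeom <- function(xRaw, geom) {
  xs <- xRaw[geom$gearySub]
  m <- length(xs)
  if (m < 2L) return(NA_real_)
  ssd <- sum((xs - mean(xs))^2)
  if (ssd == 0) return(NA_real_)
  # sum_{i<j} w_ij (x_i - x_j)^2 = sum_i x_i^2 r_i - x' W x
  au <- sum(xs * xs * geom$gearyR) - sum(xs * as.numeric(geom$gearyW %*% xs))
  (m - 1) * au / (2 * geom$gearyWu * ssd)
}

# --- first order ------------------------------------------------------------

firstOrderKernel <- function(xRaw, lev, ng) {
  n <- length(xRaw)
  mx <- max(xRaw); mn <- min(xRaw)
  # smallest observed intensity g with fraction(x >= g) <= 0.90
  xs <- sort(xRaw)
  r <- rle(xs)
  fracGe <- (n - cumsum(c(0, r$lengths[-length(r$lengths)]))) / n
  k <- which(fracGe <= 0.90)
  ivf90 <- if (length(k)) r$values[k[1]] else mx
  levSorted <- sort(lev)
  p10 <- levSorted[max(1L, ceiling(0.1 * n))]
  tab <- tabulate(lev, nbins = ng)
  modeLev <- which.max(tab)                        # ties break to lowest level
  c(maximum = mx, range = mx - mn,
    int_at_vol_fraction_90 = ivf90,
    p10 = as.numeric(p10), mode = as.numeric(modeLev))
}
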