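# Brute-force oracles: plain voxel-by-voxel loops, written independently of
# the package's vectorized kernels, used to verify every texture feature on
# tiny ROIs.

oracleDirs2d <- list(c(0, 1, 0), c(1, 0, 0), c(1, 1, 0), c(1, -1, 0))
oracleDirs3d <- c(oracleDirs2d, {
  out <- list()
  for (dr in -1:1) for (dc in -1:1) out <- c(out, list(c(dr, dc, 1)))
  out
})

# symmetric co-occurrence counts for one offset over a chosen slice set
oracleGlcmCounts <- function(lev, ng, offset, slices = NULL) {
  dims <- dim(lev)
  if (is.null(slices)) slices <- seq_len(dims[3])
  M <- matrix(0, ng, ng)
  for (s in slices) for (r in seq_len(dims[1])) for (cc in seq_len(dims[2])) {
    a <- lev[r, cc, s]
    if (is.na(a)) next
    r2 <- r + offset[1]; c2 <- cc + offset[2]; s2 <- s + offset[3]
    if (r2 < 1 || r2 > dims[1] || c2 < 1 || c2 > dims[2] ||
        s2 < 1 || s2 > dims[3]) next
    if (!(s2 %in% slices)) next
    b <- lev[r2, c2, s2]
    if (is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

oracleGlcmFeature <- function(M, feature) {
  tot <- sum(M)
  if (tot == 0) return(NA_real_)
  P <- M / tot
  ng <- nrow(P)
  da <- 0; ct <- 0
  for (i in 1:ng) for (j in 1:ng) {
    da <- da + abs(i - j) * P[i, j]
    ct <- ct + (i - j)^2 * P[i, j]
  }
  if (feature %in% c("difference_average", "dissimilarity")) return(da)
  if (feature == "contrast") return(ct)
  dv <- 0
  for (i in 1:ng) for (j in 1:ng)
    dv <- dv + (abs(i - j) - da)^2 * P[i, j]
  dv
}

oracleGlcmAggregate <- function(lev, ng, feature, mode) {
  dims <- dim(lev)
  S <- dims[3]
  avg <- function(vals) {
    vals <- vals[is.finite(vals)]
    if (!length(vals)) NA_real_ else mean(vals)
  }
  if (mode == "2Davg") {
    v <- c()
    for (s in 1:S) for (d in oracleDirs2d)
      v <- c(v, oracleGlcmFeature(oracleGlcmCounts(lev, ng, d, s), feature))
    return(avg(v))
  }
  if (mode == "2Dmrg") {
    v <- c()
    for (s in 1:S) {
      M <- matrix(0, ng, ng)
      for (d in oracleDirs2d) M <- M + oracleGlcmCounts(lev, ng, d, s)
      v <- c(v, oracleGlcmFeature(M, feature))
    }
    return(avg(v))
  }
  if (mode == "2DDmrg") {
    v <- c()
    for (d in oracleDirs2d) {
      M <- matrix(0, ng, ng)
      for (s in 1:S) M <- M + oracleGlcmCounts(lev, ng, d, s)
      v <- c(v, oracleGlcmFeature(M, feature))
    }
    return(avg(v))
  }
  if (mode == "2Dvmrg") {
    M <- matrix(0, ng, ng)
    for (d in oracleDirs2d) for (s in 1:S)
      M <- M + oracleGlcmCounts(lev, ng, d, s)
    return(oracleGlcmFeature(M, feature))
  }
  if (mode == "3Davg") {
    v <- c()
    for (d in oracleDirs3d)
      v <- c(v, oracleGlcmFeature(oracleGlcmCounts(lev, ng, d), feature))
    return(avg(v))
  }
  M <- matrix(0, ng, ng)                           # 3Dmrg
  for (d in oracleDirs3d) M <- M + oracleGlcmCounts(lev, ng, d)
  oracleGlcmFeature(M, feature)
}

oracleNeighbours <- function(dims, r, cc, s, plane) {
  out <- list()
  for (dr in -1:1) for (dc in -1:1) for (ds in (if (plane == "2d") 0 else -1:1)) {
    if (dr == 0 && dc == 0 && ds == 0) next
    r2 <- r + dr; c2 <- cc + dc; s2 <- s + ds
    if (r2 < 1 || r2 > dims[1] || c2 < 1 || c2 > dims[2] ||
        s2 < 1 || s2 > dims[3]) next
    out <- c(out, list(c(r2, c2, s2)))
  }
  out
}

oracleNgtdmComplexity <- function(lev, ng, plane) {
  dims <- dim(lev)
  n_i <- numeric(ng); s_i <- numeric(ng)
  for (s in seq_len(dims[3])) for (r in seq_len(dims[1]))
    for (cc in seq_len(dims[2])) {
      a <- lev[r, cc, s]
      if (is.na(a)) next
      nb <- c()
      for (q in oracleNeighbours(dims, r, cc, s, plane)) {
        b <- lev[q[1], q[2], q[3]]
        if (!is.na(b)) nb <- c(nb, b)
      }
      if (!length(nb)) next
      n_i[a] <- n_i[a] + 1
      s_i[a] <- s_i[a] + abs(a - mean(nb))
    }
  nvc <- sum(n_i)
  if (nvc == 0) return(NA_real_)
  p <- n_i / nvc
  tot <- 0
  for (i in 1:ng) for (j in 1:ng)
    if (i != j && p[i] > 0 && p[j] > 0)
      tot <- tot + abs(i - j) * (p[i] * s_i[i] + p[j] * s_i[j]) / (p[i] + p[j])
  tot / nvc
}

oracleNgldmEnergy <- function(lev, ng, alpha = 0) {
  dims <- dim(lev)
  cells <- list()
  n <- 0
  for (s in seq_len(dims[3])) for (r in seq_len(dims[1]))
    for (cc in seq_len(dims[2])) {
      a <- lev[r, cc, s]
      if (is.na(a)) next
      n <- n + 1
      dep <- 0
      for (q in oracleNeighbours(dims, r, cc, s, "3d")) {
        b <- lev[q[1], q[2], q[3]]
        if (!is.na(b) && abs(a - b) <= alpha) dep <- dep + 1
      }
      key <- paste(a, dep)
      cells[[key]] <- (cells[[key]] %||% 0) + 1
    }
  sum((unlist(cells) / n)^2)
}

oracleGeary <- function(image, mask, spacing) {
  idx <- which(mask, arr.ind = TRUE)
  x <- image[mask]
  n <- length(x)
  num <- 0; W <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    d <- sqrt(sum(((idx[i, ] - idx[j, ]) * spacing)^2))
    w <- 1 / d
    num <- num + w * (x[i] - x[j])^2
    W <- W + w
  }
  den <- sum((x - mean(x))^2)
  if (den == 0) return(NA_real_)
  (n - 1) / (2 * W) * num / den
}

oracleFirstOrder <- function(x, lev, ng) {
  n <- length(x)
  ivf <- NA_real_
  for (g in sort(unique(x))) {
    if (sum(x >= g) / n <= 0.90) { ivf <- g; break }
  }
  if (is.na(ivf)) ivf <- max(x)
  tabs <- sapply(1:ng, function(l) sum(lev == l))
  c(maximum = max(x), range = max(x) - min(x),
    int_at_vol_fraction_90 = ivf,
    p10 = sort(lev)[max(1, ceiling(0.1 * n))],
    mode = which.max(tabs))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random tiny ROI fixture: dims <= 4 x 4 x 2, random mask (>= 3 voxels)
randomTinyRoi <- function(ng = 4) {
  dims <- c(sample(2:4, 1), sample(2:4, 1), sample(1:2, 1))
  repeat {
    mask <- array(runif(prod(dims)) < 0.75, dims)
    if (sum(mask) >= 3) break
  }
  img <- array(sample(0:(ng * 3), prod(dims), replace = TRUE) +
                 runif(prod(dims), 0, 0.1), dims)
  intensityRoi(img, mask, spacing = c(0.7, 0.7, 1.3))
}

# independent fixed-bin discretization (explicit per-voxel loop)
oracleDiscretize <- function(image, mask, ng) {
  x <- image[mask]
  mn <- min(x); mx <- max(x)
  lev <- array(NA_integer_, dim(mask))
  for (i in which(mask)) {
    l <- if (mx > mn) floor(ng * (image[i] - mn) / (mx - mn)) + 1 else 1
    lev[i] <- min(l, ng)
  }
  lev
}

# full 22-feature vector assembled from the loop oracles, in registry order,
# with the same NA -> 0 imputation rule as the extraction engine
oracleFissure22 <- function(roi, ng = 32) {
  lev <- oracleDiscretize(roi@image, roi@mask, ng)
  x <- roi@image[roi@mask]
  fo <- oracleFirstOrder(x, lev[roi@mask], ng)
  glcmSpec <- list(
    c("difference_average", "2Davg"), c("dissimilarity", "2Davg"),
    c("difference_average", "2DDmrg"), c("difference_variance", "2DDmrg"),
    c("contrast", "2DDmrg"), c("dissimilarity", "2DDmrg"),
    c("difference_average", "2Dmrg"),
    c("difference_variance", "2Dvmrg"), c("contrast", "2Dvmrg"),
    c("dissimilarity", "2Dvmrg"),
    c("difference_average", "3Davg"), c("difference_variance", "3Davg"),
    c("dissimilarity", "3Davg"))
  glcmVals <- vapply(glcmSpec, function(s)
    oracleGlcmAggregate(lev, ng, s[1], s[2]), numeric(1))
  v <- c(oracleGeary(roi@image, roi@mask, roi@spacing),
         fo["maximum"], fo["range"], fo["int_at_vol_fraction_90"],
         fo["p10"], fo["mode"], glcmVals,
         oracleNgtdmComplexity(lev, ng, "2d"),
         oracleNgtdmComplexity(lev, ng, "3d"),
         oracleNgldmEnergy(lev, ng))
  v[!is.finite(v)] <- 0
  stats::setNames(as.numeric(v), featureIds(featureRegistry("fissure22")))
}

# outer-annulus region of a rendered disc, reconstructed from the phantom's
# published geometry (centered ellipse, per-slice shrink)
outerRing <- function(d, lo = 0.62, hi = 1) {
  dims <- dim(d@roiMask)
  nr <- dims[1]; nc <- dims[2]; ns <- dims[3]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  aR <- 0.72 * nr / 2; aC <- 0.85 * nc / 2
  mid <- (ns + 1) / 2
  out <- array(FALSE, dims)
  for (s in 1:ns) {
    sh <- 1 - 0.15 * abs(s - mid) / max(mid - 1, 1)
    rr <- sqrt(outer((((1:nr) - cy) / (aR * sh))^2, rep(1, nc)) +
               outer(rep(1, nr), (((1:nc) - cx) / (aC * sh))^2))
    out[, , s] <- d@roiMask[, , s] & rr > lo & rr <= hi
  }
  out
}

# small cohort fixtures used across tests
smallCohort <- function(nPatients = 6, seed = 3, ...) {
  generateCohort(phantomConfig(nPatients = nPatients, seed = seed, ...))
}
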