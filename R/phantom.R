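#' Phantom cohort configuration
#'
#' Defines the statistical structure of a synthetic disc cohort: cohort
#' size, image geometry, the prevalence and spatial mixture of outer
#' annular fissures, the degeneration-grade distribution, fissure streak
#' contrast and noise level. Defaults emulate the reference cohort the
#' analysis is designed for: 43 patients, roughly three lumbar discs each,
#' 94/123 fissure prevalence, position mixture dominated by dorsal fissures,
#' Pfirrmann-style grades 2-5, and a high-intensity-zone surrogate carried
#' by 63 percent of fissured discs.
#'
#' @param nPatients number of patients
#' @param discsPerPatient discs per patient
#' @param imageShape integer (rows, cols, slices); default `c(48, 96, 5)`,
#'   five midsagittal slices
#' @param voxelSpacing mm (row, col, slice); default `c(0.59, 0.59, 4.4)`
#'   mirroring a 300 mm field of view on a 512 matrix and 4.0 mm slices with
#'   0.4 mm gap
#' @param fissurePrevalence probability a disc carries an outer annular
#'   fissure
#' @param ventralFraction,dorsalFraction,bothFraction,lateralFraction
#'   mixture weights over fissure positions among fissured discs (must sum
#'   to 1)
#' @param degenerationGradeProbs named probabilities over grades 2-5
#' @param fissureContrast streak intensity offset in units of `noiseSd`
#' @param noiseSd additive Gaussian noise standard deviation
#' @param disruptedFraction probability a fissured disc shows the severely
#'   disrupted phenotype (diffuse annular brightening, excluded from
#'   attention mapping)
#' @param hizFraction fraction of fissured in-plane discs carrying the
#'   bright-zone flag
#' @param hizFpFraction fraction of fissure-free discs carrying a spurious
#'   bright-zone flag
#' @param seed cohort seed
#' @return a `PhantomConfig` (classed list)
#' @export
phantomConfig <- function(nPatients = 43, discsPerPatient = 3,
    imageShape = c(48, 96, 5), voxelSpacing = c(0.59, 0.59, 4.4),
    fissurePrevalence = 94 / 123,
    ventralFraction = 0.04, dorsalFraction = 0.81, bothFraction = 0.12,
    lateralFraction = 0.03,
    degenerationGradeProbs = c(`2` = 20, `3` = 48, `4` = 51, `5` = 4) / 123,
    fissureContrast = 6, noiseSd = 5, disruptedFraction = 0.2,
    hizFraction = 0.63, hizFpFraction = 0.03, seed = 1L) {
  w <- c(ventralFraction, dorsalFraction, bothFraction, lateralFraction)
  stopifnot2(abs(sum(w) - 1) < 1e-8, "position mixture weights must sum to 1")
  probs <- c(fissurePrevalence, w, disruptedFraction, hizFraction,
             hizFpFraction)
  stopifnot2(all(probs >= 0 & probs <= 1), "probabilities must be in [0,1]")
  stopifnot2(all(imageShape[1:2] >= 8) && imageShape[3] >= 1,
             "degenerate image shape (in-plane dim < 8 or no slices)")
  stopifnot2(abs(sum(degenerationGradeProbs) - 1) < 1e-8,
             "degenerationGradeProbs must sum to 1")
  structure(list(nPatients = as.integer(nPatients),
    discsPerPatient = as.integer(discsPerPatient),
    imageShape = as.integer(imageShape), voxelSpacing = voxelSpacing,
    fissurePrevalence = fissurePrevalence,
    positionWeights = c(ventral = ventralFraction, dorsal = dorsalFraction,
      both = bothFraction, lateral = lateralFraction),
    degenerationGradeProbs = degenerationGradeProbs,
    fissureContrast = fissureContrast, noiseSd = noiseSd,
    disruptedFraction = disruptedFraction, hizFraction = hizFraction,
    hizFpFraction = hizFpFraction, seed = as.integer(seed)),
    class = "PhantomConfig")
}

# nucleus signal by degeneration grade: T2 signal loss with degeneration
nucleusSignal <- c(`2` = 100, `3` = 80, `4` = 55, `5` = 38)
annulusSignal <- 30
# fluid in a fissure is brighter than any nucleus (the classical bright-zone
# criterion: signal approaching CSF); streaks are rendered relative to this
brightReference <- 100
hizVisibilityCutoff <- 3  # minimum streak contrast (noise SDs) for a HIZ

#' Render one synthetic disc
#'
#' Elliptical disc replicated over slices with mild per-slice shrinkage:
#' bright nucleus (signal decreasing with degeneration grade) blending
#' gradually into a darker annulus (a partial-volume analogue: the smooth
#' transition keeps the nucleus boundary out of short-range texture
#' statistics, as in resolution-limited T2-weighted imaging), plus additive
#' Gaussian noise. An in-plane fissure is a thin bright streak running
#' from the nucleus boundary into the outer third of the annulus on the
#' ventral (left) and/or dorsal (right) side, spanning all
#' slices. The severely disrupted phenotype brightens the outer annulus
#' diffusely on both sides with no delimitable streak. Lateral fissures
#' have no in-plane footprint (invisible on midsagittal slices): the
#' fissure mask stays empty.
#'
#' Uses the current RNG stream (seed it, or call via [generateCohort()]).
#'
#' @param grade degeneration grade 2-5
#' @param positions character subset of ventral/dorsal/lateral (empty for a
#'   fissure-free disc)
#' @param disrupted severely disrupted phenotype
#' @param hizFlag bright-zone label
#' @param contrast streak offset in noise-SD units
#' @param noiseSd noise standard deviation
#' @param imageShape (rows, cols, slices)
#' @param spacing voxel spacing mm
#' @param patientId,level,discId identifiers
#' @return a [DiscPhantom-class]
#' @export
renderDisc <- function(grade, positions = character(), disrupted = FALSE,
    hizFlag = FALSE, contrast = 6, noiseSd = 5,
    imageShape = c(48, 96, 5), spacing = c(0.59, 0.59, 4.4),
    patientId = "P1", level = "L4-L5", discId = "P1_D1") {
  stopifnot2(all(positions %in% c("ventral", "dorsal", "lateral")),
             "fissure position must be ventral/dorsal/lateral")
  stopifnot2(grade %in% 2:5, "grade must be in 2..5")
  nr <- imageShape[1]; nc <- imageShape[2]; ns <- imageShape[3]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  aR <- 0.72 * nr / 2; aC <- 0.85 * nc / 2
  mid <- (ns + 1) / 2
  shrink <- 1 - 0.15 * abs(seq_len(ns) - mid) / max(mid - 1, 1)

  img <- array(0, imageShape)
  roi <- array(FALSE, imageShape)
  fis <- array(FALSE, imageShape)
  rowIdx <- matrix(seq_len(nr), nr, nc)
  colIdx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  rowJitter <- round(stats::runif(1, -2, 2))

  inPlane <- intersect(positions, c("ventral", "dorsal"))
  streakOffset <- contrast * max(noiseSd, 1)

  for (s in seq_len(ns)) {
    r2 <- ((rowIdx - cy) / (aR * shrink[s]))^2 +
          ((colIdx - cx) / (aC * shrink[s]))^2
    inside <- r2 <= 1
    rr <- sqrt(r2)
    # gradual nucleus-annulus transition (partial-volume analogue): smooth
    # radial profile keeps the boundary out of distance-1 texture statistics
    nuc <- nucleusSignal[[as.character(grade)]]
    slice <- matrix(0, nr, nc)
    slice[inside] <- annulusSignal + (nuc - annulusSignal) *
      stats::plogis((0.6 - rr[inside]) / 0.06)
    fslice <- matrix(FALSE, nr, nc)
    {
      if (disrupted) {
        # diffuse annular brightening on both sides, no delimitable streak
        diffuse <- inside & rr >= 2 / 3 & rr <= 0.97
        slice[diffuse] <- annulusSignal + 0.6 * streakOffset +
          stats::rnorm(sum(diffuse), 0, 0.3 * streakOffset)
        fslice <- diffuse
      } else {
        for (p in inPlane) {
          side <- if (p == "dorsal") colIdx > cx else colIdx < cx
          band <- abs(rowIdx - (cy + rowJitter)) <= 1
          streak <- inside & side & band & rr >= 0.62 & rr <= 0.95
          fslice <- fslice | streak
        }
        # bright fluid signal above every native tissue class: visible
        # against the local background along the whole fissure path
        slice[fslice] <- brightReference + streakOffset
      }
    }
    img[, , s] <- slice + stats::rnorm(nr * nc, 0, noiseSd)
    roi[, , s] <- inside
    fis[, , s] <- fslice
  }

  fissurePresent <- length(positions) > 0
  new("DiscPhantom", image = img, roiMask = roi, fissureMask = fis,
      spacing = spacing, fissurePresent = fissurePresent,
      fissurePositions = positions, hizFlag = hizFlag,
      degenerationGrade = as.integer(grade),
      attentionEligible = !(fissurePresent && disrupted),
      patientId = patientId, level = level, discId = discId)
}

#' Generate a synthetic disc cohort
#'
#' Draws per-disc labels (fissure presence, position mixture, disrupted
#' phenotype, degeneration grade, bright-zone flag, spinal level and a
#' Dallas-style fissure-extension grade consistent with the presence label)
#' from the configured distributions, renders every disc, and records all
#' labels in a manifest with one row per disc. Patients are disjoint
#' groups; the run is fully deterministic given `config$seed`.
#'
#' @param config a [phantomConfig()]
#' @return a [DiscCohort-class]
#' @examples
#' cohort <- generateCohort(phantomConfig(nPatients = 4, seed = 7))
#' cohort
#' @export
generateCohort <- function(config) {
  stopifnot2(inherits(config, "PhantomConfig"), "config must be a PhantomConfig")
  levels <- c("L1-L2", "L2-L3", "L3-L4", "L4-L5", "L5-S1")
  levelW <- c(2, 15, 40, 40, 26) / 123
  withSeed(config$seed, {
    discs <- list()
    rows <- list()
    dn <- 0L
    for (p in seq_len(config$nPatients)) {
      pid <- sprintf("P%03d", p)
      for (k in seq_len(config$discsPerPatient)) {
        dn <- dn + 1L
        did <- sprintf("%s_D%d", pid, k)
        lvl <- sample(levels, 1, prob = levelW)
        grade <- as.integer(sample(names(config$degenerationGradeProbs), 1,
                                   prob = config$degenerationGradeProbs))
        fissured <- stats::runif(1) < config$fissurePrevalence
        positions <- character()
        disrupted <- FALSE
        hiz <- FALSE
        if (fissured) {
          cat1 <- sample(names(config$positionWeights), 1,
                         prob = config$positionWeights)
          positions <- switch(cat1, ventral = "ventral", dorsal = "dorsal",
                              both = c("ventral", "dorsal"),
                              lateral = "lateral")
          disrupted <- stats::runif(1) < config$disruptedFraction
          visible <- config$fissureContrast >= hizVisibilityCutoff
          hiz <- visible && any(positions %in% c("ventral", "dorsal")) &&
            stats::runif(1) < config$hizFraction
          ddd <- sample(2:3, 1, prob = c(87, 7))
        } else {
          hiz <- stats::runif(1) < config$hizFpFraction
          ddd <- sample(0:1, 1, prob = c(8, 21))
        }
        disc <- renderDisc(grade = grade, positions = positions,
          disrupted = disrupted, hizFlag = hiz,
          contrast = config$fissureContrast, noiseSd = config$noiseSd,
          imageShape = config$imageShape, spacing = config$voxelSpacing,
          patientId = pid, level = lvl, discId = did)
        discs[[dn]] <- disc
        rows[[dn]] <- S4Vectors::DataFrame(discId = did, patientId = pid,
          level = lvl, fissurePresent = disc@fissurePresent,
          fissurePositions = paste(positions, collapse = "+"),
          hizFlag = hiz, degenerationGrade = as.integer(grade),
          dddGrade = as.integer(ddd), disrupted = disrupted,
          attentionEligible = disc@attentionEligible)
      }
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- manifest$discId
    new("DiscCohort", discs = discs, manifest = manifest,
        config = unclass(config))
  })
}

#' Cohort manifest
#' @param cohort a [DiscCohort-class]
#' @return `DataFrame`, one row per disc with all labels
#' @export
cohortManifest <- function(cohort) cohort@manifest
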