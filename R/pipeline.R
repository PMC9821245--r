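#' Dichotomize a Dallas-style fissure-extension grade
#'
#' Grades 2-3 (fissure reaching the outer third of the annulus) are the
#' positive class; grades 0-1 (no fissure, or fissure confined to the inner
#' annulus) are negative.
#'
#' @param grade integer vector with values in 0..3
#' @return logical vector, `TRUE` = outer annular fissure
#' @examples
#' table(dichotomizeDdd(rep(0:3, c(8, 21, 87, 7))))  # 29 FALSE, 94 TRUE
#' @export
dichotomizeDdd <- function(grade) {
  stopifnot2(all(grade %in% 0:3), "grade must be in 0..3")
  grade >= 2
}

#' Patient-level fold assignment with class balancing
#'
#' Assigns whole patients to folds so that no patient's discs are split
#' across folds and fissure-positive discs are spread as evenly as patient
#' granularity allows: patients are shuffled (seeded), ordered by
#' descending positive-disc count, and each is assigned to the fold
#' currently most deficient in positives (ties broken by total disc count,
#' then fold index).
#'
#' @param patientId character vector, one entry per disc
#' @param positive logical vector, one entry per disc
#' @param k number of folds (default 10)
#' @param seed shuffle seed
#' @return a `FoldAssignment`: list with `k`, `assignment` (named integer
#'   vector, fold per patient), `fold` (integer per disc) and `seed`
#' @export
makeFolds <- function(patientId, positive, k = 10, seed = 1L) {
  patients <- unique(patientId)
  stopifnot2(k >= 2, "k must be >= 2 (a single fold leaves no training data)")
  stopifnot2(length(patients) >= k, "more folds than patients")
  stopifnot2(any(positive) && any(!positive), "both classes must be present")
  posBy <- vapply(patients, function(p) sum(positive[patientId == p]),
                  numeric(1))
  totBy <- vapply(patients, function(p) sum(patientId == p), numeric(1))
  ord <- withSeed(seed, sample(seq_along(patients)))
  ord <- ord[order(-posBy[ord])]                  # stable: keeps shuffle ties
  foldPos <- numeric(k); foldTot <- numeric(k)
  assignment <- integer(length(patients))
  names(assignment) <- patients
  for (i in ord) {
    f <- order(foldPos, foldTot, seq_len(k))[1]
    assignment[patients[i]] <- f
    foldPos[f] <- foldPos[f] + posBy[i]
    foldTot[f] <- foldTot[f] + totBy[i]
  }
  structure(list(k = as.integer(k), assignment = assignment,
                 fold = unname(assignment[patientId]), seed = seed),
            class = "FoldAssignment")
}

#' Patient-level k-fold cross-validation of the fissure classifier
#'
#' For each fold a fresh ensemble is trained on the other `k - 1` folds and
#' scores the held-out fold; every disc is predicted exactly once, by a
#' model whose training data exclude its patient. Feature standardization
#' statistics are computed per training split and applied to the held-out
#' discs, so nothing leaks from the validation fold.
#'
#' @param se `SummarizedExperiment` from [extractCohortFeatures()], or a
#'   samples x features matrix (then `labels` and `patientIds` are required)
#' @param folds a [makeFolds()] result
#' @param labels,patientIds per-disc label and patient grouping (taken from
#'   `colData` when `se` is a `SummarizedExperiment`)
#' @param ensembleSize members per fold
#' @param cfg a [trainConfig()]
#' @param baseSeed cross-validation seed; fold `f` trains with seed
#'   `baseSeed + 1000 f`
#' @param earlyStop `"inner"` (default): each fold's ensemble early-stops
#'   on a stratified 20 percent split of its own training data;
#'   `"heldout"`: early stopping is scored on the held-out fold itself
#' @param keepModels retain the per-fold ensembles (needed for attention
#'   mapping on held-out discs)
#' @return a `CVResult`: list with `result` (data.frame: discId, patientId,
#'   fold, prob, pred, label) and, when requested, `models` (per-fold
#'   [FissureEnsemble-class])
#' @export
runCrossValidation <- function(se, folds, labels = NULL, patientIds = NULL,
    ensembleSize = 50, cfg = trainConfig(), baseSeed = 1L,
    earlyStop = c("inner", "heldout"), keepModels = FALSE) {
  earlyStop <- match.arg(earlyStop)
  if (is(se, "SummarizedExperiment")) {
    X <- t(SummarizedExperiment::assay(se, "features"))
    cd <- SummarizedExperiment::colData(se)
    labels <- cd$fissurePresent
    patientIds <- cd$patientId
    discIds <- rownames(cd)
  } else {
    X <- se
    discIds <- rownames(X)
    if (is.null(discIds)) discIds <- sprintf("D%d", seq_len(nrow(X)))
  }
  stopifnot2(length(labels) == nrow(X) && length(patientIds) == nrow(X),
             "labels/patientIds must match the feature table")
  fold <- folds$fold
  stopifnot2(length(fold) == nrow(X), "fold assignment length mismatch")
  stopifnot2(all(tabulate(fold, folds$k) > 0), "fold with zero discs")
  out <- data.frame(discId = discIds, patientId = patientIds,
                    fold = fold, prob = NA_real_, pred = NA,
                    label = as.logical(labels), stringsAsFactors = FALSE)
  models <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    # training rows ordered by disc identity: results depend on which discs
    # are in a fold, never on the order the cohort was supplied in
    tr <- which(fold != f)[order(discIds[fold != f])]
    te <- which(fold == f)
    ens <- if (earlyStop == "heldout")
      trainEnsemble(X[tr, , drop = FALSE], labels[tr], size = ensembleSize,
                    cfg = cfg, valX = X[te, , drop = FALSE],
                    valY = labels[te], baseSeed = baseSeed + 1000L * f)
    else
      trainEnsemble(X[tr, , drop = FALSE], labels[tr], size = ensembleSize,
                    cfg = cfg, baseSeed = baseSeed + 1000L * f)
    out$prob[te] <- ensemblePredict(ens, X[te, , drop = FALSE])
    if (keepModels) models[[f]] <- ens
  }
  out$pred <- classifyProbability(out$prob)
  structure(list(result = out, models = if (keepModels) models, k = folds$k),
            class = "CVResult")
}

#' Bright-zone marker predictions
#'
#' The conventional radiological comparison arm: a disc is called
#' fissure-positive exactly when it carries a ventral or dorsal
#' high-intensity-zone flag. No lateral flag category exists, so lateral-only
#' fissures can never be flagged.
#'
#' @param manifest cohort manifest (`DataFrame`/data.frame with a logical
#'   `hizFlag` column)
#' @return logical vector of predicted classes
#' @export
hizMarkerPredictions <- function(manifest) {
  stopifnot2("hizFlag" %in% colnames(manifest), "manifest lacks hizFlag")
  flag <- manifest$hizFlag
  stopifnot2(!anyNA(flag), "missing hizFlag values")
  as.logical(flag)
}

#' Write cross-validation results as CSV
#' @param cv a `CVResult`
#' @param path output file
#' @return `path`, invisibly
#' @export
writeCvResult <- function(cv, path) {
  utils::write.csv(cv$result, path, row.names = FALSE)
  invisible(path)
}
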