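#' Training configuration for a shallow network
#'
#' Batch gradient descent with momentum and adaptive learning rate: after
#' each epoch the step is kept only if the training loss did not grow by
#' more than `maxPerfInc`; rejected steps are reverted with the learning
#' rate scaled by `lrDec` (and the momentum memory cleared), accepted steps
#' that lowered the loss scale it by `lrInc`. The loss is the cross-entropy
#' of the softmax output against one-hot targets. Weights of the first
#' epoch achieving the minimum early-stop-set loss are returned.
#'
#' @param maxEpochs epoch cap (default 5000)
#' @param lr0 initial learning rate
#' @param momentum momentum coefficient in (0, 1)
#' @param lrInc,lrDec learning-rate scaling on accepted/rejected epochs
#' @param maxPerfInc maximum tolerated loss-growth factor
#' @param standardize z-score features with training-set statistics
#' @param patience epochs without early-stop improvement before halting
#'   (default `Inf`: run to `maxEpochs`)
#' @param seed base seed for weight initialization
#' @return a `TrainConfig` (classed list)
#' @export
trainConfig <- function(maxEpochs = 5000, lr0 = 0.01, momentum = 0.9,
    lrInc = 1.05, lrDec = 0.7, maxPerfInc = 1.04, standardize = TRUE,
    patience = Inf, seed = 1L) {
  stopifnot2(momentum > 0 && momentum < 1, "momentum must be in (0,1)")
  stopifnot2(lrInc > 1 && lrDec < 1 && lrDec > 0,
             "need lrInc > 1 > lrDec > 0")
  structure(list(maxEpochs = maxEpochs, lr0 = lr0, momentum = momentum,
    lrInc = lrInc, lrDec = lrDec, maxPerfInc = maxPerfInc,
    standardize = standardize, patience = patience, seed = as.integer(seed)),
    class = "TrainConfig")
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Forward pass of one shallow network
#'
#' `h = tanh(x W1 + b1)`, `o = softmax(h W2 + b2)`. Column 2 of the output
#' is the fissure-class probability; rows sum to 1.
#'
#' @param x numeric matrix (samples x features) or a single feature vector,
#'   already standardized with the ensemble's stored parameters
#' @param w weight set: list with `W1` (p x 5), `b1`, `W2` (5 x 2), `b2`
#' @return samples x 2 probability matrix
#' @export
forwardNetwork <- function(x, w) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  stopifnot2(ncol(x) == nrow(w$W1), "feature dimension mismatch")
  h <- tanh(sweep(x %*% w$W1, 2, w$b1, `+`))
  softmaxRows(sweep(h %*% w$W2, 2, w$b2, `+`))
}

crossEntropy <- function(P, T) -mean(rowSums(T * log(pmax(P, 1e-12))))

initWeights <- function(p, nHidden = 5L, nOut = 2L) {
  a1 <- 1 / sqrt(p); a2 <- 1 / sqrt(nHidden)
  list(W1 = matrix(stats::runif(p * nHidden, -a1, a1), p, nHidden),
       b1 = stats::runif(nHidden, -a1, a1),
       W2 = matrix(stats::runif(nHidden * nOut, -a2, a2), nHidden, nOut),
       b2 = stats::runif(nOut, -a2, a2))
}

netGrad <- function(X, T, w) {
  n <- nrow(X)
  Z <- sweep(X %*% w$W1, 2, w$b1, `+`)
  H <- tanh(Z)
  P <- softmaxRows(sweep(H %*% w$W2, 2, w$b2, `+`))
  dO <- (P - T) / n
  dH <- dO %*% t(w$W2)
  dZ <- dH * (1 - H * H)
  list(W1 = t(X) %*% dZ, b1 = colSums(dZ),
       W2 = t(H) %*% dO, b2 = colSums(dO),
       loss = crossEntropy(P, T))
}

#' Train one shallow network
#'
#' Batch gradient descent with momentum and adaptive learning rate (see
#' [trainConfig()]). The early-stop set is scored every epoch; the weights
#' of the first epoch achieving the minimum early-stop loss are returned.
#'
#' @param X training matrix (samples x features), already standardized
#' @param y training labels (logical or 0/1; 1 = fissure)
#' @param valX,valY early-stop set
#' @param cfg a [trainConfig()]
#' @param seed weight-initialization seed (default `cfg$seed`)
#' @return weight set with attributes `bestEpoch`, `trainLoss`, `valLoss`
#' @export
trainNetwork <- function(X, y, valX, valY, cfg = trainConfig(), seed = NULL) {
  y <- as.integer(y)
  stopifnot2(length(unique(y)) == 2L, "training set must contain both classes")
  stopifnot2(nrow(X) > 0 && nrow(valX) > 0, "train and early-stop sets must be nonempty")
  T <- cbind(1 - y, y)
  Tv <- cbind(1 - as.integer(valY), as.integer(valY))
  if (is.null(seed)) seed <- cfg$seed
  w <- withSeed(seed, initWeights(ncol(X)))
  v <- lapply(w, function(z) z * 0)
  lr <- cfg$lr0
  g0 <- netGrad(X, T, w)
  prevLoss <- g0$loss
  bestVal <- Inf; bestW <- w; bestEpoch <- 0L; sinceBest <- 0L
  trainTrace <- numeric(0); valTrace <- numeric(0)
  for (epoch in seq_len(cfg$maxEpochs)) {
    g <- netGrad(X, T, w)
    for (nm in c("W1", "b1", "W2", "b2"))
      v[[nm]] <- cfg$momentum * v[[nm]] - lr * g[[nm]]
    wNew <- list(W1 = w$W1 + v$W1, b1 = w$b1 + v$b1,
                 W2 = w$W2 + v$W2, b2 = w$b2 + v$b2)
    newLoss <- crossEntropy(forwardNetwork(X, wNew), T)
    if (newLoss > cfg$maxPerfInc * prevLoss) {
      v <- lapply(v, function(z) z * 0)            # reject: revert + cool
      lr <- lr * cfg$lrDec
    } else {
      if (newLoss < prevLoss) lr <- lr * cfg$lrInc
      w <- wNew
      prevLoss <- newLoss
    }
    valLoss <- crossEntropy(forwardNetwork(valX, w), Tv)
    trainTrace[epoch] <- prevLoss; valTrace[epoch] <- valLoss
    if (valLoss < bestVal) {                       # first best wins ties
      bestVal <- valLoss; bestW <- w; bestEpoch <- epoch; sinceBest <- 0L
    } else sinceBest <- sinceBest + 1L
    if (sinceBest >= cfg$patience) break
  }
  structure(bestW, bestEpoch = bestEpoch, trainLoss = trainTrace,
            valLoss = valTrace)
}

#' Train an averaging ensemble of shallow networks
#'
#' Trains `size` networks that differ only in their initialization seed
#' (`member seed = baseSeed + member index`) and stores them with the
#' feature standardization parameters estimated on the training data. By
#' default a stratified inner 20 percent split of the training data serves
#' as the early-stop set for every member; passing `valX`/`valY` instead
#' scores early stopping on an external set.
#'
#' @param X training matrix (samples x features), raw scale
#' @param y labels (1 = fissure)
#' @param size ensemble size
#' @param cfg a [trainConfig()]
#' @param valX,valY optional external early-stop set (raw scale)
#' @param valFraction inner-split fraction when no external set is given
#' @param baseSeed ensemble seed (default `cfg$seed`)
#' @return a [FissureEnsemble-class]
#' @export
trainEnsemble <- function(X, y, size = 1000, cfg = trainConfig(),
    valX = NULL, valY = NULL, valFraction = 0.2, baseSeed = NULL) {
  y <- as.integer(y)
  if (is.null(baseSeed)) baseSeed <- cfg$seed
  if (cfg$standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[!is.finite(scl) | scl == 0] <- 1
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  Z <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  if (is.null(valX)) {
    idxVal <- withSeed(baseSeed, {
      pos <- which(y == 1L); neg <- which(y == 0L)
      c(sample(pos, max(1L, round(valFraction * length(pos)))),
        sample(neg, max(1L, round(valFraction * length(neg)))))
    })
    Ztr <- Z[-idxVal, , drop = FALSE]; ytr <- y[-idxVal]
    Zv <- Z[idxVal, , drop = FALSE]; yv <- y[idxVal]
  } else {
    Ztr <- Z; ytr <- y
    Zv <- sweep(sweep(valX, 2, ctr), 2, scl, `/`); yv <- as.integer(valY)
  }
  members <- lapply(seq_len(size), function(m)
    trainNetwork(Ztr, ytr, Zv, yv, cfg, seed = baseSeed + m))
  fid <- colnames(X)
  if (is.null(fid)) fid <- sprintf("f%d", seq_len(ncol(X)))
  new("FissureEnsemble", members = members, center = ctr, scale = scl,
      featureIds = fid, config = unclass(cfg))
}

#' Ensemble fissure probability
#'
#' Standardizes the input with the ensemble's stored training statistics
#' and returns the arithmetic mean of the members' fissure-class softmax
#' outputs.
#'
#' @param ensemble a [FissureEnsemble-class]
#' @param x feature vector or samples x features matrix (raw scale, columns
#'   in the ensemble's feature order)
#' @return numeric fissure probability per sample
#' @export
ensemblePredict <- function(ensemble, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1,
                                   dimnames = list(NULL, names(x)))
  stopifnot2(ncol(x) == length(ensemble@featureIds),
             "feature dimension mismatch")
  z <- sweep(sweep(x, 2, ensemble@center), 2, ensemble@scale, `/`)
  probs <- vapply(ensemble@members,
                  function(w) forwardNetwork(z, w)[, 2], numeric(nrow(z)))
  if (nrow(z) == 1L) mean(probs) else rowMeans(matrix(probs, nrow = nrow(z)))
}

#' Dichotomize an ensemble probability
#'
#' Fissure is called when the probability reaches the threshold (boundary
#' assigned positive).
#'
#' @param prob probability in [0, 1]
#' @param threshold decision cut-off (default 0.5)
#' @return logical, `TRUE` = fissure
#' @export
classifyProbability <- function(prob, threshold = 0.5) {
  stopifnot2(all(prob >= 0 & prob <= 1), "prob must be in [0,1]")
  prob >= threshold
}

#' Serialize an ensemble to JSON
#' @param ensemble a [FissureEnsemble-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeEnsemble <- function(ensemble, path) {
  jsonlite::write_json(list(
    members = lapply(ensemble@members, function(w)
      lapply(unclass(w)[c("W1", "b1", "W2", "b2")], unclass)),
    center = ensemble@center, scale = ensemble@scale,
    featureIds = ensemble@featureIds, config = ensemble@config),
    path, digits = NA, auto_unbox = TRUE, matrix = "columnmajor")
  invisible(path)
}

#' Read an ensemble from JSON
#' @param path file written by [writeEnsemble()]
#' @return a [FissureEnsemble-class]
#' @export
readEnsemble <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  members <- lapply(j$members, function(m)
    list(W1 = matrix(num(m$W1), ncol = length(m$W1)),  # columns were written
         b1 = num(m$b1),
         W2 = matrix(num(m$W2), ncol = length(m$W2)),
         b2 = num(m$b2)))
  new("FissureEnsemble", members = members, center = num(j$center),
      scale = num(j$scale),
      featureIds = as.character(unlist(j$featureIds)),
      config = lapply(j$config, function(z) z))
}
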