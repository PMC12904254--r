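#' SPM fitting configuration
#'
#' Hyperparameters of the selection probabilistic model. Defaults follow
#' the reference protocol for this model family: four hidden layers of 100
#' ReLU units, Adam with learning rate 0.001, weight decay 1e-5, dropout
#' 0.1, batch size 10,000.
#'
#' @param hiddenDim units per hidden layer.
#' @param nLayers number of hidden layers (0 gives an additive/linear
#'   model, useful as a capacity baseline).
#' @param learningRate Adam step size.
#' @param batchSize maximal number of sequences processed per gradient
#'   step; when the observed universe fits in one batch (always, at desk
#'   scale) training is full-batch.
#' @param weightDecay L2 penalty on weights.
#' @param dropout per-unit drop probability during training; units are
#'   resampled each epoch and shared across the (full) batch. Inference
#'   is always deterministic.
#' @param maxEpochs,patience,tol optimization bounds: stop after
#'   \code{maxEpochs}, or when the early-stopping metric has not improved
#'   by a relative \code{tol} for \code{patience} epochs.
#' @param valFraction fraction of final-round sequences held out for early
#'   stopping (0 disables; training loss is then the stopping metric).
#' @param pseudocount added to round-0 counts before forming the smoothed
#'   input distribution \eqn{q_0}.
#' @param seed integer seed for initialization, dropout and the validation
#'   split.
#' @return a named list of class \code{"spmConfig"}.
#' @export
spmConfig <- function(hiddenDim = 100L, nLayers = 4L,
                      learningRate = 0.001, batchSize = 10000L,
                      weightDecay = 1e-5, dropout = 0.1,
                      maxEpochs = 500L, patience = 20L, tol = 1e-6,
                      valFraction = 0.1, pseudocount = 0.5, seed = 1L) {
  cfg <- list(hiddenDim = as.integer(hiddenDim),
              nLayers = as.integer(nLayers),
              learningRate = learningRate, batchSize = as.integer(batchSize),
              weightDecay = weightDecay, dropout = dropout,
              maxEpochs = as.integer(maxEpochs),
              patience = as.integer(patience), tol = tol,
              valFraction = valFraction, pseudocount = pseudocount,
              seed = as.integer(seed))
  stopifnot(all(vapply(cfg[c("hiddenDim", "learningRate", "batchSize",
                             "maxEpochs", "patience")],
                       function(v) v > 0, TRUE)))
  stopifnot(cfg$nLayers >= 0L, cfg$dropout >= 0, cfg$dropout < 1)
  class(cfg) <- c("spmConfig", "list")
  cfg
}

#' Fit the selection probabilistic model
#'
#' Maximizes the multi-round multinomial likelihood
#' \deqn{\sum_r \log \mathrm{Mult}(c_r \mid T_r, p_r), \quad
#'   p_r(x) \propto q_{r-1}(x)\, e^{f_{r\theta}(x)},}
#' where \eqn{q_0} is the smoothed empirical round-0 distribution,
#' \eqn{q_r} is the model-propagated distribution, and
#' \eqn{f_{r\theta} = a_r f_\theta + b_r} are affine heads on a shared
#' neural trunk (\eqn{a_r \ge 0} via softplus). The per-round additive
#' gauge is fixed by zero-mean fitness over the observed universe; the
#' invariance of \eqn{p_r} to constant fitness shifts is inherent to the
#' model.
#'
#' @param x a \linkS4class{SelectionExperiment} with at least 2 rounds.
#' @param config an \code{\link{spmConfig}}.
#' @param holdoutFinal optional integer indices (rows of \code{x}) whose
#'   final-round counts are excluded from the training loss (they still
#'   enter the normalizer); used by cross-validation. Overrides the
#'   internal validation split.
#' @param verbose print the loss every 50 epochs.
#' @return a \linkS4class{FitnessModel}.
#' @export
fitSPM <- function(x, config = spmConfig(), holdoutFinal = NULL,
                   verbose = FALSE) {
  stopifnot(is(x, "SelectionExperiment"))
  cts <- selectionCounts(x)
  if (ncol(cts) < 2L)
    stop("selection is unidentifiable from a single round; need >= 2")
  if (any(colSums(cts) == 0))
    stop("every round must contain at least one read")
  if (max(cts) == min(cts))
    warning("all counts identical; fitness will converge to near-flat")
  scheme <- libraryScheme(x)
  n <- nrow(cts)
  if (n > config$batchSize)
    warning(sprintf(paste0(
      "observed universe (%d) exceeds the batch size (%d); ",
      "training proceeds full-batch"), n, config$batchSize))
  rounds <- colnames(cts)
  R <- ncol(cts) - 1L
  q0 <- (cts[, 1L] + config$pseudocount)
  q0 <- q0 / sum(q0)
  logq0 <- log(q0)
  cm <- cts[, -1L, drop = FALSE] * 1.0
  X <- .oneHot(scheme, rownames(cts))

  ## validation entries: final-round counts of held-out sequences
  val <- NULL
  if (!is.null(holdoutFinal)) {
    val <- as.integer(holdoutFinal)
  } else if (config$valFraction > 0) {
    finalSeqs <- which(cts[, R + 1L] > 0L)
    nv <- floor(config$valFraction * length(finalSeqs))
    if (nv >= 1L)
      val <- .withSeed(deriveSeed(config$seed, "spm-val"),
                       sample(finalSeqs, nv))
  }
  cmTrain <- cm
  if (!is.null(val)) cmTrain[val, R] <- 0

  hidden <- if (config$nLayers > 0L)
    rep(config$hiddenDim, config$nLayers) else integer()
  par <- .nnInit(ncol(X), hidden, deriveSeed(config$seed, "spm-init"))
  alpha <- rep(0.5, R)          # softplus(0.5) ~ 0.97: gentle initial slopes
  flat <- c(par$W, par$b, list(alpha))
  adam <- .adamInit(flat)
  nW <- length(par$W)

  valMetric <- function(f, a) {
    if (is.null(val)) return(NA_real_)
    A <- cumsum(a)
    logits <- logq0 + A[R] * f
    logp <- logits - .logSumExp(logits)
    -sum(cm[val, R] * logp[val])
  }

  best <- Inf; bestPar <- par; bestAlpha <- alpha; wait <- 0L
  trace <- numeric(0)
  dropSeed <- deriveSeed(config$seed, "spm-dropout")
  .withSeed(dropSeed, {
    for (epoch in seq_len(config$maxEpochs)) {
      drop <- NULL
      if (config$dropout > 0 && config$nLayers > 0L) {
        keep <- 1 - config$dropout
        drop <- list(units = lapply(seq_len(config$nLayers), function(l)
          which(stats::runif(config$hiddenDim) >= keep)),
          scale = 1 / keep)
      }
      lg <- .spmLossGrad(par, alpha, X, logq0, cmTrain,
                         config$weightDecay, drop)
      trace[epoch] <- lg$loss
      flat <- c(par$W, par$b, list(alpha))
      gflat <- c(lg$grad$W, lg$grad$b, list(lg$galpha))
      st <- .adamStep(adam, flat, gflat, config$learningRate)
      adam <- st$state
      par$W <- st$params[seq_len(nW)]
      par$b <- st$params[nW + seq_len(nW)]
      ## restore matrix shapes lost in the flat update
      for (l in seq_len(nW))
        dim(par$W[[l]]) <- dim(lg$grad$W[[l]])
      par$b <- lapply(par$b, as.numeric)
      alpha <- as.numeric(st$params[[2L * nW + 1L]])

      ## early stopping on the monitored metric (training loss when no
      ## validation split; held-out final-round log-loss otherwise)
      metric <- if (is.null(val)) lg$loss else
        valMetric(.nnForward(par, X)$f, .softplus(alpha))
      if (metric < best * (1 - config$tol)) {
        best <- metric; bestPar <- par; bestAlpha <- alpha; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
      if (verbose && epoch %% 50L == 0L)
        message(sprintf("epoch %d loss %.4f metric %.4f",
                        epoch, lg$loss, metric))
    }
  })
  par <- bestPar; alpha <- bestAlpha

  f <- .nnForward(par, X)$f
  a <- .softplus(alpha)
  mu <- mean(f)
  final <- .spmLossGrad(par, alpha, X, logq0, cm, weightDecay = 0,
                        wantGrad = FALSE)
  names(a) <- rounds[-1L]
  b <- -a * mu
  new("FitnessModel", scheme = scheme, weights = par,
      roundSlopes = a, roundOffsets = b, rounds = rounds,
      logQ0 = stats::setNames(logq0, rownames(cts)),
      config = unclass(config),
      history = list(loss = trace, logLik = -final$loss, trunkMean = mu,
                     nEpochs = length(trace), validation = val))
}

#' @describeIn fitSPM Score sequences with a fitted model: per-round
#'   fitness \eqn{f_r = a_r f_\theta + b_r} for a fitted round label, or
#'   the global (zero-mean gauge) trunk fitness for \code{round="global"}.
#'   Inference is deterministic (no dropout) and extrapolates to any valid
#'   sequence of the scheme, observed in training or not.
#' @param object a \linkS4class{FitnessModel}.
#' @param sequences character vector of concatenated sequences.
#' @param round \code{"global"} or a fitted round label.
#' @export
setMethod("scoreSequences", "FitnessModel",
  function(object, sequences, round = "global") {
    validateSequences(object@scheme, sequences)
    X <- .oneHot(object@scheme, sequences)
    f <- .nnForward(object@weights, X)$f
    if (identical(round, "global"))
      return(f - object@history$trunkMean)
    if (!round %in% names(object@roundSlopes))
      stop("round '", round, "' was not fitted; available: ",
           paste(names(object@roundSlopes), collapse = ", "))
    object@roundSlopes[[round]] * f + object@roundOffsets[[round]]
  })

setMethod("show", "FitnessModel", function(object) {
  cfg <- object@config
  cat("FitnessModel (selection probabilistic model)\n")
  cat(sprintf("  trunk: %d hidden layers x %d units; %d rounds fitted\n",
              cfg$nLayers, cfg$hiddenDim, length(object@roundSlopes)))
  cat(sprintf("  log-likelihood (up to the multinomial constant): %.2f after %d epochs\n",
              object@history$logLik, object@history$nEpochs))
  cat("  round slopes a_r:",
      paste(sprintf("%s=%.3f", names(object@roundSlopes),
                    object@roundSlopes), collapse = ", "), "\n")
})

#' Model-expected read counts for a round
#'
#' Expected counts \eqn{T_r \, p_r(x)} over the sequences of \code{x},
#' where \eqn{p_r} is the model's round-\eqn{r} multinomial probability
#' (softmax of \eqn{\log q_0 + A_r f_\theta} over the observed universe).
#'
#' @param model a \linkS4class{FitnessModel}.
#' @param x the \linkS4class{SelectionExperiment} defining universe and
#'   totals (typically the training data).
#' @param round fitted round label; default the final round.
#' @return named numeric vector summing to the round total.
#' @export
predictCounts <- function(model, x, round = NULL) {
  cts <- selectionCounts(x)
  if (is.null(round)) round <- colnames(cts)[ncol(cts)]
  if (!round %in% names(model@roundSlopes))
    stop("round '", round, "' was not fitted")
  A <- cumsum(model@roundSlopes)[[round]]
  q0 <- (cts[, 1L] + model@config$pseudocount)
  logq0 <- log(q0 / sum(q0))
  f <- .nnForward(model@weights, .oneHot(model@scheme, rownames(cts)))$f
  logits <- logq0 + A * f
  p <- exp(logits - .logSumExp(logits))
  stats::setNames(sum(cts[, round]) * p, rownames(cts))
}

#' Cross-validate SPM hyperparameters
#'
#' Five-fold cross-validation on the final selection round: folds
#' partition the final-round sequences, each fold's counts are dropped
#' from training (all previous rounds are always fully used) and
#' predicted as expected counts, and the configuration with the lowest
#' mean held-out MSE wins.
#'
#' @param x a \linkS4class{SelectionExperiment}.
#' @param grid list of \code{\link{spmConfig}} objects.
#' @param nFolds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return list with \code{best} (the winning config), \code{bestIndex},
#'   and \code{mse} (configs x folds matrix).
#' @export
crossvalidateSPM <- function(x, grid, nFolds = 5L, seed = 1L) {
  if (length(grid) == 0L) stop("hyperparameter grid is empty")
  cts <- selectionCounts(x)
  R <- ncol(cts)
  finalSeqs <- which(cts[, R] > 0L)
  folds <- .withSeed(deriveSeed(seed, "cv-folds"),
                     sample(rep_len(seq_len(nFolds), length(finalSeqs))))
  mse <- matrix(NA_real_, length(grid), nFolds)
  for (ci in seq_along(grid)) {
    cfg <- grid[[ci]]
    cfg$valFraction <- 0      # the CV fold is the holdout
    for (k in seq_len(nFolds)) {
      hold <- finalSeqs[folds == k]
      fit <- fitSPM(x, cfg, holdoutFinal = hold)
      pred <- predictCounts(fit, x, colnames(cts)[R])
      mse[ci, k] <- mean((pred[hold] - cts[hold, R])^2)
    }
  }
  bestIndex <- which.min(rowMeans(mse))
  list(best = grid[[bestIndex]], bestIndex = bestIndex, mse = mse)
}

#' Bootstrap-resample a selection dataset
#'
#' Draws \code{B} replicate datasets; each round of each replicate is a
#' multinomial resample of that round's empirical frequencies at exactly
#' the original read total.
#'
#' @param x a \linkS4class{SelectionExperiment}.
#' @param B number of replicates (reference protocol: 1000).
#' @param seed integer master seed.
#' @return list of \code{B} \linkS4class{SelectionExperiment}s.
#' @export
bootstrapDatasets <- function(x, B = 1000L, seed = 1L) {
  stopifnot(B >= 1L)
  cts <- selectionCounts(x)
  rd <- SummarizedExperiment::rowData(x)
  scheme <- libraryScheme(x)
  lapply(seq_len(B), function(b) {
    .withSeed(deriveSeed(seed, paste0("bootstrap-", b)), {
      newc <- vapply(seq_len(ncol(cts)), function(j) {
        tot <- sum(cts[, j])
        stats::rmultinom(1L, tot, cts[, j] / tot)[, 1L]
      }, integer(nrow(cts)))
      colnames(newc) <- colnames(cts)
      SelectionExperiment(newc, chainA = rd$chain_a, chainB = rd$chain_b,
                          scheme = scheme, rounds = colnames(cts))
    })
  })
}

#' Serialize / restore a fitted model
#'
#' Versioned JSON archive: architecture metadata plus flat parameter
#' arrays (text-only, platform independent).
#'
#' @param model a \linkS4class{FitnessModel}.
#' @param path file path.
#' @export
saveFitnessModel <- function(model, path) {
  obj <- list(
    format = "coevoscape-spm-1",
    scheme = list(chain_a_positions = chainAPositions(model@scheme),
                  chain_b_positions = chainBPositions(model@scheme),
                  alphabet = schemeAlphabet(model@scheme),
                  degenerate_codon = degenerateCodon(model@scheme)),
    config = model@config,
    rounds = model@rounds,
    roundSlopes = as.list(model@roundSlopes),
    roundOffsets = as.list(model@roundOffsets),
    trunkMean = model@history$trunkMean,
    logLik = model@history$logLik,
    logQ0 = as.list(model@logQ0),
    nrowW = vapply(model@weights$W, nrow, 0L),
    ncolW = vapply(model@weights$W, ncol, 0L),
    W = lapply(model@weights$W, as.numeric),
    b = model@weights$b)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveFitnessModel
#' @export
readFitnessModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "coevoscape-spm-1"))
    stop("unrecognized model archive format")
  scheme <- LibraryScheme(
    chainAPositions = obj$scheme$chain_a_positions,
    chainBPositions = obj$scheme$chain_b_positions,
    alphabet = obj$scheme$alphabet,
    degenerateCodon = obj$scheme$degenerate_codon %||% NA_character_)
  W <- lapply(seq_along(obj$W), function(l)
    matrix(obj$W[[l]], obj$nrowW[l], obj$ncolW[l]))
  b <- lapply(obj$b, as.numeric)
  new("FitnessModel", scheme = scheme, weights = list(W = W, b = b),
      roundSlopes = unlist(obj$roundSlopes),
      roundOffsets = unlist(obj$roundOffsets),
      rounds = obj$rounds,
      logQ0 = unlist(obj$logQ0),
      config = obj$config,
      history = list(loss = numeric(), logLik = obj$logLik,
                     trunkMean = obj$trunkMean,
                     nEpochs = NA_integer_, validation = NULL))
}
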