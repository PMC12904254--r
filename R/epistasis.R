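## Chain label of a set of concatenated-position indices.
.chainClass <- function(scheme, positions) {
  nA <- length(chainAPositions(scheme))
  inA <- positions <= nA
  if (all(inA)) "intra_A" else if (all(!inA)) "intra_B" else "inter"
}

.asFitnessFunction <- function(fn) {
  if (is.function(fn)) return(fn)
  if (is(fn, "FitnessModel") || is(fn, "TrueLandscape"))
    return(function(s) scoreSequences(fn, s))
  stop("fitness must be a function, FitnessModel or TrueLandscape")
}

#' Functional-ANOVA decomposition of a fitness function
#'
#' Decomposes any sequence-to-fitness function into zero-mean effect
#' sizes under the uniform reference distribution over the alphabet (the
#' orthogonal contrast system underlying the Walsh-Hadamard view of a
#' landscape): \eqn{\beta_0} is the grand mean,
#' \eqn{\beta_i(a) = E[f \mid x_i = a] - \beta_0},
#' \eqn{\beta_{ij}(a,b) = E[f \mid x_i = a, x_j = b] - \beta_i(a) -
#' \beta_j(b) - \beta_0}, with analogous Moebius subtraction at order 3.
#' The importance of a term is the difference between the maximum and
#' minimum effect size over its letter configurations — the maximal
#' dynamic range attributable to those positions.
#'
#' Conditional means are exact (full enumeration) when the space has at
#' most \code{exhaustiveLimit} sequences, else Monte-Carlo estimates from
#' \code{mcSamples} uniform draws.
#'
#' @param fitness a function mapping character sequences to numeric, or a
#'   \linkS4class{FitnessModel} / \linkS4class{TrueLandscape} (scored
#'   globally).
#' @param scheme the \linkS4class{LibraryScheme}.
#' @param maxOrder highest interaction order (1-3; default 2).
#' @param exhaustiveLimit enumeration cap (default 1e6 sequences).
#' @param mcSamples Monte-Carlo sample size above the cap.
#' @param seed seed for Monte-Carlo sampling.
#' @return an \linkS4class{EpistasisReport}.
#' @examples
#' sch <- LibraryScheme(1, 2, alphabet = c("A", "B"))
#' xor <- function(s) as.numeric(substr(s, 1, 1) == substr(s, 2, 2))
#' rep2 <- decomposeFitness(xor, sch, maxOrder = 2)
#' epistasisTerms(rep2)   # pairwise importance 1, no main effects
#' @export
decomposeFitness <- function(fitness, scheme, maxOrder = 2L,
                             exhaustiveLimit = 1e6, mcSamples = 1e5,
                             seed = 1L) {
  fn <- .asFitnessFunction(fitness)
  p <- totalPositions(scheme)
  q <- length(schemeAlphabet(scheme))
  ab <- schemeAlphabet(scheme)
  maxOrder <- as.integer(maxOrder)
  if (maxOrder < 1L) stop("maxOrder must be >= 1")
  if (maxOrder > p) stop("maxOrder exceeds the number of positions")
  if (maxOrder > 3L) stop("orders above 3 are not supported")
  nSpace <- q^p
  exhaustive <- nSpace <= exhaustiveLimit
  if (exhaustive) {
    idx <- seq_len(nSpace)
    L <- .indexToLetterIdx(scheme, idx)
    F <- fn(.indexToSeq(scheme, idx))
  } else {
    L <- .withSeed(deriveSeed(seed, "epistasis-mc"),
                   matrix(sample.int(q, mcSamples * p, replace = TRUE),
                          mcSamples, p))
    seqs <- apply(L, 1L, function(r) paste(ab[r], collapse = ""))
    F <- fn(seqs)
  }
  stopifnot(length(F) == nrow(L), all(is.finite(F)))
  b0 <- mean(F)

  groupMeans <- function(g, nlev) {
    s <- rowsum(F, g)
    cnt <- rowsum(rep(1, length(g)), g)
    m <- rep(NA_real_, nlev)
    m[as.integer(rownames(s))] <- s / cnt
    m
  }

  beta1 <- vector("list", p)
  for (i in seq_len(p))
    beta1[[i]] <- groupMeans(L[, i], q) - b0

  beta2 <- list()
  if (maxOrder >= 2L) {
    for (pair in utils::combn(p, 2L, simplify = FALSE)) {
      i <- pair[1L]; j <- pair[2L]
      g <- (L[, i] - 1L) * q + L[, j]
      m <- matrix(groupMeans(g, q * q), q, q, byrow = TRUE)
      beta2[[paste(i, j)]] <- m - outer(beta1[[i]], rep(1, q)) -
        outer(rep(1, q), beta1[[j]]) - b0
    }
  }

  beta3 <- list()
  if (maxOrder >= 3L) {
    for (tri in utils::combn(p, 3L, simplify = FALSE)) {
      i <- tri[1L]; j <- tri[2L]; k <- tri[3L]
      g <- ((L[, i] - 1L) * q + (L[, j] - 1L)) * q + L[, k]
      m <- array(groupMeans(g, q^3), c(q, q, q))
      ## groupMeans index runs k fastest, then j, then i
      m <- aperm(array(m, c(q, q, q)), c(3L, 2L, 1L))
      arr <- array(0, c(q, q, q))
      for (a in seq_len(q)) for (bb in seq_len(q)) for (cc in seq_len(q))
        arr[a, bb, cc] <- m[a, bb, cc] -
          beta2[[paste(i, j)]][a, bb] - beta2[[paste(i, k)]][a, cc] -
          beta2[[paste(j, k)]][bb, cc] -
          beta1[[i]][a] - beta1[[j]][bb] - beta1[[k]][cc] - b0
      beta3[[paste(i, j, k)]] <- arr
    }
  }

  effects <- list(); terms <- list()
  addTerm <- function(posv, confLetters, vals) {
    term <- paste(posv, collapse = ",")
    cls <- .chainClass(scheme, posv)
    effects[[length(effects) + 1L]] <<- data.frame(
      term = term, order = length(posv), chain_class = cls,
      config = confLetters, effect = vals)
    terms[[length(terms) + 1L]] <<- data.frame(
      term = term, order = length(posv), chain_class = cls,
      importance = max(vals) - min(vals))
  }
  for (i in seq_len(p))
    addTerm(i, ab, beta1[[i]])
  if (maxOrder >= 2L)
    for (key in names(beta2)) {
      ij <- as.integer(strsplit(key, " ")[[1]])
      cfg <- as.matrix(expand.grid(a = ab, b = ab,
                                   stringsAsFactors = FALSE))
      addTerm(ij, paste(cfg[, 1L], cfg[, 2L], sep = ","),
              beta2[[key]][cbind(match(cfg[, 1L], ab),
                                 match(cfg[, 2L], ab))])
    }
  if (maxOrder >= 3L)
    for (key in names(beta3)) {
      ijk <- as.integer(strsplit(key, " ")[[1]])
      cfg <- as.matrix(expand.grid(a = ab, b = ab, c = ab,
                                   stringsAsFactors = FALSE))
      addTerm(ijk, paste(cfg[, 1L], cfg[, 2L], cfg[, 3L], sep = ","),
              beta3[[key]][cbind(match(cfg[, 1L], ab),
                                 match(cfg[, 2L], ab),
                                 match(cfg[, 3L], ab))])
    }

  new("EpistasisReport", scheme = scheme, intercept = b0,
      effects = do.call(rbind, effects), terms = do.call(rbind, terms),
      maxOrder = maxOrder,
      estimator = list(mode = if (exhaustive) "exhaustive" else
                         "monte-carlo",
                       nEvaluated = nrow(L), seed = as.integer(seed)))
}

#' @describeIn EpistasisReport-class Table of term importances.
#' @param report an \code{EpistasisReport}.
#' @export
epistasisTerms <- function(report) report@terms

#' @describeIn EpistasisReport-class Long table of effect sizes.
#' @export
epistasisEffects <- function(report) report@effects

setMethod("show", "EpistasisReport", function(object) {
  cat("EpistasisReport:", nrow(object@terms), "terms up to order",
      object@maxOrder, sprintf("(%s)\n", object@estimator$mode))
  byo <- tapply(object@terms$importance, object@terms$order, mean)
  cat("  mean importance by order:",
      paste(sprintf("%s: %.4g", names(byo), byo), collapse = ", "), "\n")
})

#' Effect size of a term at a particular variant
#'
#' Looks up the decomposition's effect size for the letter configuration
#' that \code{variant} carries at the term's positions — the quantity used
#' to rank interactions along an individual coevolutionary path.
#'
#' @param report an \linkS4class{EpistasisReport}.
#' @param positions integer vector of concatenated-position indices
#'   identifying the term.
#' @param variant a concatenated sequence.
#' @return numeric effect size.
#' @export
effectSizeAt <- function(report, positions, variant) {
  term <- paste(sort(as.integer(positions)), collapse = ",")
  eff <- report@effects
  sub <- eff[eff$term == term, ]
  if (nrow(sub) == 0L)
    stop("term {", term, "} is not in the report")
  letters <- strsplit(variant, "")[[1]][sort(as.integer(positions))]
  cfg <- paste(letters, collapse = ",")
  hit <- sub$effect[sub$config == cfg]
  if (length(hit) == 0L)
    stop("configuration ", cfg, " not found for term {", term, "}")
  hit
}

#' Reconstruct fitness from a decomposition
#'
#' Sums the intercept and every term's effect size at the variant's
#' configuration. In exhaustive mode with \code{maxOrder} equal to the
#' number of positions this reproduces the fitness function exactly.
#'
#' @param report an \linkS4class{EpistasisReport}.
#' @param sequences character vector.
#' @return numeric vector.
#' @export
reconstructFitness <- function(report, sequences) {
  eff <- report@effects
  termPos <- strsplit(unique(eff$term), ",")
  vapply(sequences, function(s) {
    letters <- strsplit(s, "")[[1]]
    tot <- report@intercept
    for (tp in termPos) {
      posv <- as.integer(tp)
      cfg <- paste(letters[posv], collapse = ",")
      term <- paste(posv, collapse = ",")
      tot <- tot + eff$effect[eff$term == term & eff$config == cfg]
    }
    tot
  }, 0, USE.NAMES = FALSE)
}

#' @describeIn EpistasisReport-class Ratio of average inter-chain to
#'   average intra-chain importance per term at the given order (REI).
#'   Returns \code{NA} with a warning when either side has no terms or
#'   when both averages are numerically zero (e.g. an additive
#'   landscape, where the ratio is 0/0).
#' @param eps importances below this are treated as numerically zero.
#' @export
setMethod("rei", "EpistasisReport",
  function(object, order = 2L, eps = 1e-9) {
    t <- object@terms[object@terms$order == order, ]
    inter <- t$importance[t$chain_class == "inter"]
    intra <- t$importance[t$chain_class != "inter"]
    if (length(inter) == 0L || length(intra) == 0L) {
      warning("REI undefined: need terms on both sides at order ", order)
      return(NA_real_)
    }
    den <- mean(intra)
    if (den < eps) {
      warning("REI undefined at order ", order,
              ": zero intra-chain importance")
      return(NA_real_)
    }
    mean(inter) / den
  })

#' Epistasis decomposition of an external score table
#'
#' Applies the identical functional-ANOVA decomposition to externally
#' supplied sequence scores (for example a structure-conditioned scorer),
#' so epistasis summaries are comparable across scorers. The table must
#' cover the full enumerated space of the scheme.
#'
#' @param scores data.frame with columns \code{sequence} and \code{score}.
#' @param scheme the \linkS4class{LibraryScheme}.
#' @param maxOrder highest interaction order.
#' @return an \linkS4class{EpistasisReport}.
#' @export
epistasisFromScores <- function(scores, scheme, maxOrder = 2L) {
  stopifnot(all(c("sequence", "score") %in% colnames(scores)))
  validateSequences(scheme, scores$sequence)
  full <- enumerateSequences(scheme)
  missing <- setdiff(full, scores$sequence)
  if (length(missing) > 0L)
    stop(sprintf(
      "score table misses %d of %d sequences (e.g. %s)",
      length(missing), length(full),
      paste(head(missing, 3L), collapse = ", ")))
  lut <- stats::setNames(scores$score, scores$sequence)
  decomposeFitness(function(s) unname(lut[s]), scheme,
                   maxOrder = maxOrder,
                   exhaustiveLimit = length(full))
}

#' Export an epistasis report as TSV tables
#'
#' @param report an \linkS4class{EpistasisReport}.
#' @param termsPath,effectsPath output paths (either may be NULL).
#' @export
writeEpistasisTSV <- function(report, termsPath = NULL,
                              effectsPath = NULL) {
  if (!is.null(termsPath))
    utils::write.table(report@terms, termsPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(effectsPath))
    utils::write.table(report@effects, effectsPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
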