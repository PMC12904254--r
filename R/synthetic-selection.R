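## Seed hygiene: every stochastic entry point takes an integer seed and
## leaves the caller's RNG state untouched.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-stage seed derivation from a master seed (kept < 2^31).
deriveSeed <- function(master, stage) {
  h <- sum(utf8ToInt(as.character(stage)) *
             (seq_len(nchar(as.character(stage))) + 31))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483587 + 1)
}

#' Draw a ground-truth fitness landscape
#'
#' Samples additive (position x letter) effects and a sparse set of
#' pairwise (position pair x letter pair) effects, with a configurable
#' split between inter-chain and intra-chain pairwise terms. All effects
#' are Gaussian with the given scales; a landscape with both scales zero is
#' flat.
#'
#' @param scheme a \linkS4class{LibraryScheme}.
#' @param additiveScale sd of additive effects (>= 0).
#' @param pairwiseScale sd of pairwise effects (>= 0; 0 gives a purely
#'   additive landscape with an empty pairwise table).
#' @param pairFraction fraction of all position pairs that receive
#'   pairwise terms.
#' @param interFraction fraction of the drawn pairwise terms that must be
#'   inter-chain (subject to availability).
#' @param intercept baseline fitness.
#' @param seed integer seed; the draw is reproducible.
#' @return a \linkS4class{TrueLandscape}.
#' @export
sampleLandscape <- function(scheme, additiveScale = 1, pairwiseScale = 0.5,
                            pairFraction = 0.3, interFraction = 0.5,
                            intercept = 0, seed = 1L) {
  stopifnot(additiveScale >= 0, pairwiseScale >= 0)
  ab <- schemeAlphabet(scheme)
  if (length(ab) == 0L) stop("scheme alphabet is empty")
  p <- totalPositions(scheme)
  q <- length(ab)
  nA <- length(chainAPositions(scheme))
  .withSeed(seed, {
    addm <- matrix(if (additiveScale > 0)
      stats::rnorm(p * q, 0, additiveScale) else 0, p, q,
      dimnames = list(NULL, ab))
    pw <- data.frame(pos_i = integer(), pos_j = integer(),
                     letter_i = character(), letter_j = character(),
                     value = numeric())
    if (pairwiseScale > 0 && p >= 2L) {
      pairs <- t(utils::combn(p, 2L))
      inter <- pairs[, 1L] <= nA & pairs[, 2L] > nA
      nPick <- max(1L, round(pairFraction * nrow(pairs)))
      nInter <- min(round(interFraction * nPick), sum(inter))
      nIntra <- min(nPick - nInter, sum(!inter))
      pick <- c(sample(which(inter), nInter),
                sample(which(!inter), nIntra))
      for (k in pick) {
        g <- expand.grid(letter_i = ab, letter_j = ab,
                         stringsAsFactors = FALSE)
        pw <- rbind(pw, data.frame(
          pos_i = pairs[k, 1L], pos_j = pairs[k, 2L],
          letter_i = g$letter_i, letter_j = g$letter_j,
          value = stats::rnorm(nrow(g), 0, pairwiseScale)))
      }
    }
    new("TrueLandscape", scheme = scheme, intercept = intercept,
        additive = addm, pairwise = pw, seed = as.integer(seed))
  })
}

#' @describeIn sampleLandscape Evaluate the true fitness of sequences
#'   (the \code{round} argument is ignored: the truth is round-free).
#' @param object a \linkS4class{TrueLandscape}.
#' @param sequences character vector of concatenated sequences.
#' @param round ignored.
#' @export
setMethod("scoreSequences", "TrueLandscape",
  function(object, sequences, round = "global") {
    sch <- object@scheme
    li <- .seqToLetterIdx(sch, sequences)
    f <- rep(object@intercept, length(sequences))
    for (j in seq_len(ncol(li)))
      f <- f + object@additive[j, li[, j]]
    pw <- object@pairwise
    if (nrow(pw) > 0L) {
      ab <- schemeAlphabet(sch)
      for (key in unique(paste(pw$pos_i, pw$pos_j))) {
        sub <- pw[paste(pw$pos_i, pw$pos_j) == key, ]
        M <- matrix(0, length(ab), length(ab),
                    dimnames = list(ab, ab))
        M[cbind(sub$letter_i, sub$letter_j)] <- sub$value
        i <- sub$pos_i[1L]; j <- sub$pos_j[1L]
        f <- f + M[cbind(li[, i], li[, j])]
      }
    }
    unname(f)
  })

#' Write a true landscape as a long-format TSV
#'
#' Columns \code{term} (intercept/additive/pairwise), \code{positions}
#' (comma-joined concatenated-position indices), \code{letters}
#' (comma-joined), \code{value}. Companion output of the simulator for
#' parameter-recovery studies.
#'
#' @param landscape a \linkS4class{TrueLandscape}.
#' @param path output file.
#' @export
writeLandscapeTSV <- function(landscape, path) {
  ab <- colnames(landscape@additive)
  add <- expand.grid(pos = seq_len(nrow(landscape@additive)), letter = ab,
                     stringsAsFactors = FALSE)
  rows <- rbind(
    data.frame(term = "intercept", positions = "", letters = "",
               value = landscape@intercept),
    data.frame(term = "additive", positions = as.character(add$pos),
               letters = add$letter,
               value = landscape@additive[cbind(add$pos,
                                                match(add$letter, ab))]),
    if (nrow(landscape@pairwise) > 0L)
      with(landscape@pairwise, data.frame(
        term = "pairwise", positions = paste(pos_i, pos_j, sep = ","),
        letters = paste(letter_i, letter_j, sep = ","), value = value)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate a multi-round library-on-library selection
#'
#' Forward-simulates the generative process the selection probabilistic
#' model inverts: starting from an initial sequence distribution, each
#' round multiplies frequencies by a logistic selection factor
#' \eqn{s_r(x) = \mathrm{logit}^{-1}(\sigma_r (f^*(x) - o_r))} and
#' renormalizes, and observed read counts are a multinomial sample of the
#' stated depth from the current (latent) frequencies. Round 0 counts are
#' drawn from the initial distribution itself.
#'
#' @param landscape a \linkS4class{TrueLandscape} (or any object with a
#'   \code{scoreSequences} method and a \code{scheme} slot).
#' @param nRounds number of selection rounds (>= 1) after round 0.
#' @param depth reads sampled per round.
#' @param stringency selection slope, scalar or one value per round.
#' @param offset selection midpoint on the fitness scale; default centres
#'   it at the universe mean fitness.
#' @param initial \code{"uniform"} or \code{"dirichlet"} start
#'   frequencies.
#' @param alpha Dirichlet concentration when \code{initial="dirichlet"}.
#' @param universe explicit character vector of sequences, or \code{NULL}
#'   to enumerate the scheme's full space.
#' @param seed integer seed.
#' @param dropUnobserved drop sequences never read in any round (default
#'   TRUE, mimicking real NGS tables).
#' @return a \linkS4class{SelectionExperiment} with rounds
#'   \code{R0..R<nRounds>}.
#' @export
simulateSelection <- function(landscape, nRounds = 5L, depth = 1e5,
                              stringency = 1, offset = NULL,
                              initial = c("uniform", "dirichlet"),
                              alpha = 1, universe = NULL, seed = 1L,
                              dropUnobserved = TRUE) {
  stopifnot(nRounds >= 1L, depth >= 1)
  initial <- match.arg(initial)
  scheme <- landscape@scheme
  if (is.null(universe))
    universe <- enumerateSequences(scheme)
  if (length(universe) == 0L) stop("universe is empty")
  f <- scoreSequences(landscape, universe)
  if (is.null(offset)) offset <- mean(f)
  stringency <- rep_len(stringency, nRounds)
  offset <- rep_len(offset, nRounds)
  .withSeed(seed, {
    q0 <- if (initial == "uniform") rep(1 / length(universe),
                                        length(universe))
          else {
            g <- stats::rgamma(length(universe), shape = alpha)
            g / sum(g)
          }
    if (all(q0 == 0)) stop("initial distribution has zero mass")
    cts <- matrix(0L, length(universe), nRounds + 1L)
    cts[, 1L] <- stats::rmultinom(1L, depth, q0)[, 1L]
    q <- q0
    for (r in seq_len(nRounds)) {
      s <- stats::plogis(stringency[r] * (f - offset[r]))
      q <- q * s
      tot <- sum(q)
      if (tot == 0) stop("selection annihilated all probability mass")
      q <- q / tot
      cts[, r + 1L] <- stats::rmultinom(1L, depth, q)[, 1L]
    }
    keep <- if (dropUnobserved) rowSums(cts) > 0L else
      rep(TRUE, length(universe))
    nA <- length(chainAPositions(scheme))
    SelectionExperiment(
      cts[keep, , drop = FALSE],
      chainA = substr(universe[keep], 1L, nA),
      chainB = substr(universe[keep], nA + 1L, nchar(universe[keep])),
      scheme = scheme,
      rounds = paste0("R", 0:nRounds))
  })
}
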