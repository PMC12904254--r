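## Vectorized greedy adaptive walks over the enumerated sequence space.
## States are 1-based space indices; neighbor indices are obtained by
## digit arithmetic, so a whole cohort of walks advances per iteration.

.precomputeFitness <- function(fn, scheme, limit) {
  n <- .spaceSize(scheme)
  if (n > limit)
    stop(sprintf(paste0(
      "sequence space has %.3g states; raise enumerationLimit or ",
      "supply a reduced scheme"), n))
  F <- fn(.indexToSeq(scheme, seq_len(n)))
  if (!all(is.finite(F))) stop("fitness must be finite over the space")
  F
}

## One cohort of walks from integer start states; returns the path matrix
## (walks x steps, NA-padded) and terminal indices.
.walkCohort <- function(F, scheme, starts) {
  q <- length(schemeAlphabet(scheme))
  p <- totalPositions(scheme)
  pow <- q^(seq_len(p) - 1L)
  nW <- length(starts)
  cur <- starts
  active <- seq_len(nW)
  paths <- list(starts)
  term <- integer(nW)
  while (length(active) > 0L) {
    ca <- cur[active]
    dig <- .indexToLetterIdx(scheme, ca)
    nb <- matrix(0L, length(active), p * (q - 1L))
    col <- 0L
    for (j in seq_len(p)) {
      dj <- dig[, j]
      for (l in seq_len(q - 1L)) {
        ## the l-th other letter at position j
        lj <- ifelse(l < dj, l, l + 1L)
        col <- col + 1L
        nb[, col] <- ca + (lj - dj) * pow[j]
      }
    }
    better <- matrix(F[nb] > F[ca], nrow(nb), ncol(nb))
    hasMove <- rowSums(better) > 0L
    ## uniform choice among improving moves via random keys
    nxt <- rep(NA_integer_, length(active))
    if (any(hasMove)) {
      keys <- matrix(stats::runif(length(better)), nrow(better))
      keys[!better] <- -1
      pick <- max.col(keys, ties.method = "first")
      nxt[hasMove] <- nb[cbind(which(hasMove), pick[hasMove])]
    }
    term[active[!hasMove]] <- cur[active[!hasMove]]
    cur[active[hasMove]] <- nxt[hasMove]
    active <- active[hasMove]
    step <- rep(NA_integer_, nW)
    step[active] <- cur[active]
    if (length(active) > 0L) paths[[length(paths) + 1L]] <- step
  }
  pm <- do.call(cbind, paths)
  storage.mode(pm) <- "integer"
  list(paths = pm, terminals = as.integer(term))
}

#' Simulate greedy stochastic adaptive walks
#'
#' Each walk starts at a random sequence (or a supplied start), and at
#' every step enumerates all single-position substitutions with strictly
#' higher fitness, picks one uniformly at random, and stops when none
#' remain — a terminal is therefore always a strict local optimum. Ties in
#' fitness are not improving moves.
#'
#' @param fitness function / \linkS4class{FitnessModel} /
#'   \linkS4class{TrueLandscape}; evaluated once over the whole enumerated
#'   space and memoized.
#' @param scheme the \linkS4class{LibraryScheme}.
#' @param nTrajectories number of walks (reference protocol: 1e7;
#'   desk-scale analyses use 1e4-1e5).
#' @param seed integer seed; results are bit-identical across runs.
#' @param start \code{NULL} for uniform-random starts, or a character
#'   vector of start sequences recycled over the walks.
#' @param storePaths keep the full path matrix (needed for seed-sequence
#'   analysis; memory scales with walks x path length).
#' @param chunkSize walks advanced per vectorized cohort.
#' @param enumerationLimit refuse larger sequence spaces.
#' @return a \linkS4class{TrajectoryEnsemble}.
#' @export
simulateTrajectories <- function(fitness, scheme, nTrajectories = 1e7,
                                 seed = 1L, start = NULL,
                                 storePaths = FALSE, chunkSize = 2e5,
                                 enumerationLimit = 5^9) {
  stopifnot(nTrajectories >= 1)
  fn <- .asFitnessFunction(fitness)
  F <- .precomputeFitness(fn, scheme, enumerationLimit)
  n <- length(F)
  nT <- as.integer(nTrajectories)
  startIdx <- if (!is.null(start)) .seqToIndex(scheme, start) else NULL
  .withSeed(seed, {
    termCount <- integer(n)
    visitCount <- integer(n)
    allPaths <- list(); allTerm <- integer(0)
    done <- 0L
    while (done < nT) {
      m <- min(as.integer(chunkSize), nT - done)
      starts <- if (is.null(startIdx)) sample.int(n, m, replace = TRUE)
        else rep_len(startIdx, nT)[done + seq_len(m)]
      cohort <- .walkCohort(F, scheme, starts)
      tc <- tabulate(cohort$terminals, n)
      termCount <- termCount + tc
      ## visits: unique states per walk
      pm <- cohort$paths
      walkId <- rep(seq_len(nrow(pm)), ncol(pm))
      flat <- as.vector(pm)
      keep <- !is.na(flat)
      key <- (as.numeric(walkId[keep]) - 1) * n + flat[keep]
      states <- as.integer((unique(key) - 1) %% n + 1)
      visitCount <- visitCount + tabulate(states, n)
      if (storePaths) {
        allPaths[[length(allPaths) + 1L]] <- pm
        allTerm <- c(allTerm, cohort$terminals)
      }
      done <- done + m
    }
    paths <- if (storePaths) {
      maxc <- max(vapply(allPaths, ncol, 0L))
      do.call(rbind, lapply(allPaths, function(m0)
        cbind(m0, matrix(NA_integer_, nrow(m0), maxc - ncol(m0)))))
    } else matrix(NA_integer_, 0L, 0L)
    nz <- which(termCount > 0L)
    vz <- which(visitCount > 0L)
    new("TrajectoryEnsemble", scheme = scheme, nTrajectories = nT,
        terminalCounts = stats::setNames(termCount[nz],
                                         .indexToSeq(scheme, nz)),
        visitCounts = stats::setNames(visitCount[vz],
                                      .indexToSeq(scheme, vz)),
        paths = paths, terminals = if (storePaths) allTerm else integer(),
        fitness = F, seed = as.integer(seed))
  })
}

#' @describeIn TrajectoryEnsemble-class Fraction of walks terminating at
#'   each sequence (0 for non-terminals).
#' @export
setMethod("accessibility", "TrajectoryEnsemble",
  function(object, sequences = NULL) {
    acc <- object@terminalCounts / object@nTrajectories
    if (is.null(sequences)) return(acc)
    out <- stats::setNames(rep(0, length(sequences)), sequences)
    hit <- intersect(sequences, names(acc))
    out[hit] <- acc[hit]
    out
  })

setMethod("show", "TrajectoryEnsemble", function(object) {
  cat("TrajectoryEnsemble:", object@nTrajectories, "walks,",
      length(object@terminalCounts), "distinct terminals\n")
  top <- sort(accessibility(object), decreasing = TRUE)
  top <- head(top, 3L)
  cat("  most accessible:",
      paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
})

#' Export an ensemble summary TSV
#'
#' Columns \code{sequence}, \code{terminal_count}, \code{visit_count},
#' \code{accessibility}, one row per visited sequence.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param path output file.
#' @export
writeEnsembleTSV <- function(ensemble, path) {
  seqs <- names(ensemble@visitCounts)
  tc <- rep(0L, length(seqs)); names(tc) <- seqs
  hit <- intersect(seqs, names(ensemble@terminalCounts))
  tc[hit] <- ensemble@terminalCounts[hit]
  df <- data.frame(sequence = seqs, terminal_count = unname(tc),
                   visit_count = unname(ensemble@visitCounts),
                   accessibility = unname(tc) / ensemble@nTrajectories)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
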