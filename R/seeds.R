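## Tally of (visited state, terminal) trajectory counts from a stored
## path matrix. Returns a function(stateIdx, terminalIdx) -> count and a
## per-state through-traffic lookup.
.pathTally <- function(ensemble) {
  pm <- ensemble@paths
  if (nrow(pm) == 0L)
    stop("ensemble was simulated without storePaths = TRUE")
  n <- length(ensemble@fitness)
  walkId <- rep(seq_len(nrow(pm)), ncol(pm))
  flat <- as.vector(pm)
  keep <- !is.na(flat)
  key <- (as.numeric(walkId[keep]) - 1) * n + flat[keep]
  uk <- unique(key)
  state <- as.integer((uk - 1) %% n + 1)
  walk <- as.integer((uk - 1) %/% n + 1)
  term <- ensemble@terminals[walk]
  list(state = state, terminal = term)
}

.countThrough <- function(tally, stateIdx, terminalIdx = NULL) {
  hit <- tally$state == stateIdx
  if (is.null(terminalIdx)) sum(hit)
  else sum(hit & tally$terminal == terminalIdx)
}

#' Exclusivity of a sequence for a well
#'
#' Fraction of the trajectories passing through \code{sequence} that end
#' at \code{well}. Returns \code{NA} (with a warning) when the sequence
#' is never visited.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble} simulated with
#'   \code{storePaths = TRUE}.
#' @param sequence,well concatenated sequences.
#' @return a fraction in [0, 1], or NA.
#' @export
exclusivity <- function(ensemble, sequence, well) {
  tally <- .pathTally(ensemble)
  s <- .seqToIndex(ensemble@scheme, sequence)
  w <- .seqToIndex(ensemble@scheme, well)
  through <- .countThrough(tally, s)
  if (through == 0L) {
    warning("sequence was never visited; exclusivity undefined")
    return(NA_real_)
  }
  .countThrough(tally, s, w) / through
}

#' Contribution of a sequence to a well
#'
#' Fraction of all trajectories ending at \code{well} that pass through
#' \code{sequence}. The well representative itself has contribution 1.
#'
#' @inheritParams exclusivity
#' @return a fraction in [0, 1], or NA when the well receives no
#'   trajectories.
#' @export
contribution <- function(ensemble, sequence, well) {
  tally <- .pathTally(ensemble)
  s <- .seqToIndex(ensemble@scheme, sequence)
  w <- .seqToIndex(ensemble@scheme, well)
  into <- sum(tally$terminal == w & tally$state == w)
  if (into == 0L) {
    warning("well receives no trajectories; contribution undefined")
    return(NA_real_)
  }
  .countThrough(tally, s, w) / into
}

#' Fitness band of weak binders anchored on read counts
#'
#' The weak-binder band is defined by the data: its bounds are the mean
#' global fitness of sequences whose final-round read count equals the
#' two anchor counts (defaults 5 and 20). When no sequence has exactly an
#' anchor count, the nearest observed count is used.
#'
#' @param x a \linkS4class{SelectionExperiment}.
#' @param model a \linkS4class{FitnessModel}.
#' @param anchorCounts two read-count anchors.
#' @param round final round label (default last).
#' @return numeric band \code{c(lo, hi)}, sorted.
#' @export
fitnessBand <- function(x, model, anchorCounts = c(5L, 20L),
                        round = NULL) {
  cts <- selectionCounts(x)
  if (is.null(round)) round <- colnames(cts)[ncol(cts)]
  k <- cts[, round]
  obs <- sort(unique(k[k > 0L]))
  if (length(obs) == 0L) stop("final round is empty")
  bounds <- vapply(anchorCounts, function(a) {
    use <- obs[which.min(abs(obs - a))]
    mean(scoreSequences(model, rownames(cts)[k == use]))
  }, 0)
  sort(bounds)
}

#' Identify seed sequences of coevolutionary trajectories
#'
#' A seed is a weak binder (fitness inside \code{band}) whose
#' through-traffic funnels into one target well: exclusivity at least
#' \code{minExclusivity}, contribution at least \code{minContribution},
#' and at least \code{minDistance} substitutions away from the well
#' representative. The target well of a candidate is the well receiving
#' the most trajectories through it ("most likely well"); the column
#' \code{exclusivity_well_differs} flags candidates whose globally most
#' frequent terminal is not among the targets.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble} with stored paths.
#' @param band numeric \code{c(lo, hi)} fitness band (see
#'   \code{\link{fitnessBand}}).
#' @param targetWells character vector of well representatives to
#'   consider.
#' @param minExclusivity,minContribution,minDistance selection thresholds
#'   (reference protocol: 0.9, 0.01, 3).
#' @return data.frame: \code{sequence}, \code{fitness},
#'   \code{target_well}, \code{exclusivity}, \code{contribution},
#'   \code{distance}, \code{exclusivity_well_differs}.
#' @export
findSeeds <- function(ensemble, band, targetWells,
                      minExclusivity = 0.9, minContribution = 0.01,
                      minDistance = 3L) {
  if (length(band) != 2L || band[1] > band[2])
    stop("band must be c(lo, hi)")
  scheme <- ensemble@scheme
  tally <- .pathTally(ensemble)
  F <- ensemble@fitness
  widx <- .seqToIndex(scheme, targetWells)
  visited <- sort(unique(tally$state))
  cand <- visited[F[visited] >= band[1] & F[visited] <= band[2]]
  rows <- list()
  for (s in cand) {
    hit <- tally$state == s
    through <- sum(hit)
    if (through == 0L) next
    termTab <- table(tally$terminal[hit])
    ## counts into each target well
    wCounts <- vapply(widx, function(w)
      if (as.character(w) %in% names(termTab))
        as.integer(termTab[[as.character(w)]]) else 0L, 0L)
    if (all(wCounts == 0L)) next
    best <- which.max(wCounts)
    w <- widx[best]
    excl <- wCounts[best] / through
    into <- ensemble@terminalCounts[[.indexToSeq(scheme, w)]]
    contr <- wCounts[best] / into
    dist <- hammingDistance(.indexToSeq(scheme, s),
                            targetWells[best])
    globalBest <- as.integer(names(termTab)[which.max(termTab)])
    if (excl >= minExclusivity && contr >= minContribution &&
        dist >= minDistance)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = .indexToSeq(scheme, s), fitness = F[s],
        target_well = targetWells[best], exclusivity = excl,
        contribution = contr, distance = dist,
        exclusivity_well_differs = globalBest != w)
  }
  if (length(rows) == 0L)
    return(data.frame(sequence = character(), fitness = numeric(),
                      target_well = character(), exclusivity = numeric(),
                      contribution = numeric(), distance = integer(),
                      exclusivity_well_differs = logical()))
  do.call(rbind, rows)
}

#' Extract coevolutionary paths from a seed to a target
#'
#' Re-simulates a dedicated walk ensemble started at the seed (exact for
#' the seed's downstream behaviour, far cheaper than storing a global
#' path archive), keeps the walks that terminate at the target, and
#' tabulates the distinct monotone single-substitution paths with their
#' multiplicities. Low-weight paths are aggregated: the largest set of
#' least-visited paths whose collective weight stays below
#' \code{minorThreshold} is reported only as \code{minor_fraction}.
#'
#' @param fitness fitness function / model used for the walks.
#' @param scheme the \linkS4class{LibraryScheme}.
#' @param seedSequence,target concatenated sequences.
#' @param nTrajectories walks to simulate from the seed.
#' @param minorThreshold collective weight below which paths are folded
#'   into the minor fraction (reference protocol: 0.15).
#' @param seed RNG seed.
#' @return list with \code{paths} (data.frame \code{path},
#'   \code{multiplicity}, \code{fraction}; steps joined by \code{"->"}),
#'   \code{minor_fraction}, \code{n_minor_paths},
#'   \code{n_seed_to_target}, \code{n_trajectories}.
#' @export
extractPaths <- function(fitness, scheme, seedSequence, target,
                         nTrajectories = 1e4, minorThreshold = 0.15,
                         seed = 1L) {
  ens <- simulateTrajectories(fitness, scheme, nTrajectories,
                              seed = seed, start = seedSequence,
                              storePaths = TRUE)
  tIdx <- .seqToIndex(scheme, target)
  sel <- which(ens@terminals == tIdx)
  empty <- list(paths = data.frame(path = character(),
                                   multiplicity = integer(),
                                   fraction = numeric()),
                minor_fraction = 0, n_minor_paths = 0L,
                n_seed_to_target = length(sel),
                n_trajectories = as.integer(nTrajectories))
  if (length(sel) == 0L) return(empty)
  pm <- ens@paths[sel, , drop = FALSE]
  strs <- apply(pm, 1L, function(r) {
    r <- r[!is.na(r)]
    paste(.indexToSeq(scheme, r), collapse = "->")
  })
  tab <- sort(table(strs), decreasing = TRUE)
  frac <- as.numeric(tab) / length(sel)
  csTail <- rev(cumsum(rev(frac)))
  minor <- csTail < minorThreshold
  list(paths = data.frame(path = names(tab)[!minor],
                          multiplicity = as.integer(tab)[!minor],
                          fraction = frac[!minor], row.names = NULL),
       minor_fraction = sum(frac[minor]),
       n_minor_paths = sum(minor),
       n_seed_to_target = length(sel),
       n_trajectories = as.integer(nTrajectories))
}

#' Export a seed table
#'
#' @param seeds output of \code{\link{findSeeds}}.
#' @param path output TSV.
#' @export
writeSeedsTSV <- function(seeds, path) {
  utils::write.table(seeds, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
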