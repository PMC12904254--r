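#' Identify the top energy wells of a landscape
#'
#' Ranks the terminals of an adaptive-walk ensemble by accessibility and
#' keeps the top \code{k} as wells. Energy is negative fitness; relative
#' energy subtracts the energy of the strongest binder (the minimum-energy
#' terminal found), so the strongest binder sits at relative energy 0.
#'
#' @param ensemble a \linkS4class{TrajectoryEnsemble}.
#' @param fitness the fitness used for the walks (function or model).
#' @param k number of wells (reference protocol: 20).
#' @return a \linkS4class{LandscapeGeometry} (depths NA until
#'   \code{\link{wellDepth}}).
#' @export
findWells <- function(ensemble, fitness, k = 20L) {
  fn <- .asFitnessFunction(fitness)
  acc <- sort(accessibility(ensemble), decreasing = TRUE)
  if (length(acc) < k) {
    warning(sprintf("only %d terminals found; returning all (k = %d)",
                    length(acc), k))
  }
  top <- head(acc, k)
  energy <- -fn(names(top))
  eAll <- -fn(names(acc))
  wells <- data.frame(representative = names(top),
                      energy = energy,
                      relative_energy = energy - min(eAll),
                      accessibility = unname(top),
                      depth = NA_real_,
                      row.names = NULL)
  new("LandscapeGeometry", wells = wells,
      barriers = matrix(numeric(), 0L, 0L), k = as.integer(k))
}

## Materialize the single-mutation move graph of the enumerated space with
## uphill-energy edge weights w(u -> v) = max(0, E(v) - E(u)).
.moveGraph <- function(F, scheme) {
  q <- length(schemeAlphabet(scheme))
  p <- totalPositions(scheme)
  n <- length(F)
  pow <- q^(seq_len(p) - 1L)
  idx <- seq_len(n)
  dig <- .indexToLetterIdx(scheme, idx)
  from <- integer(0); to <- integer(0)
  for (j in seq_len(p)) {
    dj <- dig[, j]
    for (l in seq_len(q - 1L)) {
      lj <- ifelse(l < dj, l, l + 1L)
      from <- c(from, idx)
      to <- c(to, idx + (lj - dj) * pow[j])
    }
  }
  E <- -F
  w <- pmax(0, E[to] - E[from])
  g <- igraph::make_empty_graph(n, directed = TRUE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  g
}

#' Energy-well depths via minimal cumulative uphill barriers
#'
#' The depth of a well is the minimal cumulative uphill energy a
#' trajectory must climb to reach any other well representative: on the
#' single-mutation graph with edge weight \eqn{\max(0, E(v) - E(u))}
#' ("cumulative" barrier: positive increments along the path are summed),
#' depth(i) is the Dijkstra shortest-path cost from representative i to
#' the nearest other representative. With a single well the depth is
#' \code{Inf}.
#'
#' @param geometry a \linkS4class{LandscapeGeometry}.
#' @param fitness the fitness function / model used for the walks.
#' @param scheme the \linkS4class{LibraryScheme}.
#' @param barrier \code{"cumulative"} (default) sums uphill increments;
#'   \code{"max"} uses the largest single uphill step (sensitivity
#'   analysis only; minimized via a minimax relaxation).
#' @return the geometry with \code{depth} filled and the representative
#'   barrier matrix attached.
#' @export
wellDepth <- function(geometry, fitness, scheme,
                      barrier = c("cumulative", "max")) {
  barrier <- match.arg(barrier)
  fn <- .asFitnessFunction(fitness)
  reps <- geometry@wells$representative
  if (length(reps) < 2L) {
    geometry@wells$depth <- Inf
    geometry@barriers <- matrix(0, length(reps), length(reps),
                                dimnames = list(reps, reps))
    return(geometry)
  }
  F <- .precomputeFitness(fn, scheme, limit = 5^9)
  ridx <- .seqToIndex(scheme, reps)
  if (barrier == "cumulative") {
    g <- .moveGraph(F, scheme)
    D <- igraph::distances(g, v = ridx, to = ridx, mode = "out",
                           algorithm = "dijkstra")
  } else {
    D <- .minimaxBarriers(F, scheme, ridx)
  }
  dimnames(D) <- list(reps, reps)
  diag(D) <- 0
  off <- D; diag(off) <- Inf
  geometry@wells$depth <- apply(off, 1L, min)
  geometry@barriers <- D
  geometry
}

## Minimax (largest-single-step) barrier between representatives, by
## iterative relaxation of the bottleneck shortest path.
.minimaxBarriers <- function(F, scheme, ridx) {
  q <- length(schemeAlphabet(scheme)); p <- totalPositions(scheme)
  n <- length(F); pow <- q^(seq_len(p) - 1L)
  dig <- .indexToLetterIdx(scheme, seq_len(n))
  E <- -F
  D <- matrix(Inf, length(ridx), n)
  for (s in seq_along(ridx)) {
    d <- rep(Inf, n); d[ridx[s]] <- 0
    repeat {
      dOld <- d
      for (j in seq_len(p)) for (l in seq_len(q - 1L)) {
        lj <- ifelse(l < dig[, j], l, l + 1L)
        to <- seq_len(n) + (lj - dig[, j]) * pow[j]
        cand <- pmax(d, pmax(0, E[to] - E))
        imp <- cand < d[to]
        d[to[imp]] <- cand[imp]
      }
      if (identical(d, dOld)) break
    }
    D[s, ] <- d
  }
  D[, ridx, drop = FALSE]
}

setMethod("show", "LandscapeGeometry", function(object) {
  cat("LandscapeGeometry:", nrow(object@wells), "wells (k =", object@k,
      ")\n")
  print(utils::head(object@wells, 5L), row.names = FALSE)
})

#' One-sided bootstrap comparison of landscape geometries
#'
#' Tests, by Mann-Whitney U, whether a geometry statistic of the first
#' (e.g. natural) interface exceeds \code{factor} times the statistic of
#' the second (synthetic) interface across bootstrap replicates:
#' depth of the most accessible well against \code{factorDepth} x the
#' deepest of the top wells, and top accessibility against
#' \code{factorAccess} x the top accessibility. Samples are unpaired.
#'
#' @param natural,synthetic data.frames of per-replicate statistics with
#'   columns \code{depth} and \code{accessibility}.
#' @param factorDepth,factorAccess fold-change hypotheses (reference
#'   protocol: 3 and 5).
#' @return named numeric: one-sided p-values \code{p_depth},
#'   \code{p_accessibility}.
#' @export
compareGeometries <- function(natural, synthetic, factorDepth = 3,
                              factorAccess = 5) {
  stopifnot(nrow(natural) > 0L, nrow(synthetic) > 0L)
  pd <- stats::wilcox.test(natural$depth,
                           factorDepth * synthetic$depth,
                           alternative = "greater", exact = FALSE)$p.value
  pa <- stats::wilcox.test(natural$accessibility,
                           factorAccess * synthetic$accessibility,
                           alternative = "greater", exact = FALSE)$p.value
  c(p_depth = pd, p_accessibility = pa)
}

#' Per-replicate geometry statistics for the bootstrap test
#'
#' Runs the bootstrap-geometry pipeline (resample reads, refit the SPM,
#' re-simulate walks, find wells and depths) and returns one row of
#' summary statistics per replicate: the depth of the most accessible
#' well, the maximal depth among the top wells, and the top
#' accessibility.
#'
#' @param x a \linkS4class{SelectionExperiment}.
#' @param B bootstrap replicates.
#' @param nTrajectories walks per replicate.
#' @param k wells per replicate.
#' @param config an \code{\link{spmConfig}} for the refits.
#' @param seed master seed; replicate seeds are derived deterministically.
#' @return data.frame with columns \code{depth_top},
#'   \code{depth_deepest}, \code{accessibility}.
#' @export
bootstrapGeometry <- function(x, B = 20L, nTrajectories = 1e4, k = 20L,
                              config = spmConfig(), seed = 1L) {
  boots <- bootstrapDatasets(x, B, seed = deriveSeed(seed, "geom-boot"))
  scheme <- libraryScheme(x)
  out <- lapply(seq_along(boots), function(b) {
    cfg <- config
    cfg$seed <- deriveSeed(seed, paste0("geom-fit-", b))
    fit <- fitSPM(boots[[b]], cfg)
    ens <- simulateTrajectories(fit, scheme, nTrajectories,
                                seed = deriveSeed(seed,
                                                  paste0("geom-walk-", b)))
    geo <- suppressWarnings(findWells(ens, fit, k))
    geo <- wellDepth(geo, fit, scheme)
    data.frame(depth_top = geo@wells$depth[1L],
               depth_deepest = max(geo@wells$depth),
               accessibility = geo@wells$accessibility[1L])
  })
  do.call(rbind, out)
}

#' Convert a dissociation-constant ratio to an energy gap
#'
#' \deqn{\Delta\Delta G = R T \ln(K_{D,2} / K_{D,1})} with
#' \eqn{R = 1.987 \times 10^{-3}} kcal/(mol K); the default temperature
#' is 298 K. Both constants must be in the same (molar) units.
#'
#' @param kd1 stronger-binding (smaller) dissociation constant, molar.
#' @param kd2 weaker-binding dissociation constant, molar.
#' @param temperature kelvin.
#' @return energy gap in kcal/mol.
#' @examples
#' energyGapFromKd(0.4e-6, 8.8e-6)    # ~1.8 kcal/mol
#' energyGapFromKd(2.4e-9, 6.7e-6)    # ~4.7 kcal/mol
#' @export
energyGapFromKd <- function(kd1, kd2, temperature = 298) {
  if (any(kd1 <= 0) || any(kd2 <= 0))
    stop("dissociation constants must be positive")
  R <- 1.987e-3
  R * temperature * log(kd2 / kd1)
}

#' Export geometry tables
#'
#' @param geometry a \linkS4class{LandscapeGeometry}.
#' @param wellsPath,barriersPath output TSV paths (either may be NULL).
#' @export
writeGeometryTSV <- function(geometry, wellsPath = NULL,
                             barriersPath = NULL) {
  if (!is.null(wellsPath))
    utils::write.table(geometry@wells, wellsPath, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(barriersPath) && length(geometry@barriers) > 0L)
    utils::write.table(geometry@barriers, barriersPath, sep = "\t",
                       quote = FALSE, row.names = TRUE,
                       col.names = NA)
  invisible(NULL)
}
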