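#' Hypergeometric pair-enrichment test
#'
#' For every chain-A/chain-B pair observed in a round, tests whether the
#' pair co-occurs more often than expected if partners were drawn
#' independently: with total population size \eqn{M}, marginal counts
#' \eqn{n} (chain A) and \eqn{N} (chain B) and pair count \eqn{k}, the
#' p-value is the one-sided hypergeometric survival probability
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Hypergeom}(M, n, N)}.
#'
#' @param x a \linkS4class{SelectionExperiment}.
#' @param round round label; default the final round.
#' @return data.frame with one row per observed pair: \code{chain_a},
#'   \code{chain_b}, \code{k}, \code{n}, \code{N}, \code{M},
#'   \code{p_value}, plus a \code{"summary"} attribute reporting the
#'   number of pairs and of unique concatenated sequences.
#' @export
pairEnrichment <- function(x, round = NULL) {
  cts <- selectionCounts(x)
  if (is.null(round)) round <- colnames(cts)[ncol(cts)]
  if (!round %in% colnames(cts)) stop("unknown round: ", round)
  k <- cts[, round]
  keep <- k > 0L
  rd <- SummarizedExperiment::rowData(x)
  a <- rd$chain_a[keep]; b <- rd$chain_b[keep]; k <- k[keep]
  M <- sum(k)
  if (M == 0L) stop("round ", round, " has no reads")
  n <- as.vector(rowsum(k, a)[a, 1L])
  N <- as.vector(rowsum(k, b)[b, 1L])
  p <- stats::phyper(k - 1L, m = n, n = M - n, k = N, lower.tail = FALSE)
  out <- data.frame(chain_a = a, chain_b = b, k = as.integer(k),
                    n = n, N = N, M = M, p_value = p,
                    row.names = NULL)
  attr(out, "summary") <- c(n_pairs = nrow(out),
                            n_unique_sequences =
                              length(unique(paste0(a, b))))
  out
}

#' Filter enriched pairs
#'
#' Retains pairs with p-value strictly below \code{pMax} and pair count at
#' least \code{minCount} (defaults p < 0.05, k >= 20). Optionally applies
#' Benjamini-Hochberg correction before thresholding (off by default; the
#' filter is conventionally run on raw p-values).
#'
#' @param records output of \code{\link{pairEnrichment}}.
#' @param pMax strict upper p-value bound.
#' @param minCount inclusive lower pair-count bound.
#' @param adjust \code{"none"} (default) or \code{"BH"}.
#' @return the retained subset, with a logical \code{retained} column
#'   added to the input for export.
#' @export
filterEnriched <- function(records, pMax = 0.05, minCount = 20L,
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- if (adjust == "BH") stats::p.adjust(records$p_value, "BH")
       else records$p_value
  keep <- p < pMax & records$k >= minCount
  records$retained <- keep
  records[keep, , drop = FALSE]
}

.hammingMatrix <- function(sequences) {
  n <- length(sequences)
  if (n == 0L) return(matrix(0L, 0L, 0L))
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must have equal length")
  m <- matrix(unlist(strsplit(sequences, "")), nrow = n, byrow = TRUE)
  d <- matrix(0L, n, n, dimnames = list(sequences, sequences))
  for (j in seq_len(L)) {
    d <- d + outer(m[, j], m[, j], "!=")
  }
  d
}

#' Build a sequence similarity network
#'
#' Nodes are unique concatenated sequences; an undirected edge joins two
#' sequences whose Hamming distance is strictly below \code{threshold}
#' (all library sequences have fixed length, so substitutions are the only
#' meaningful edits; threshold 3 connects sequences differing at <= 2
#' positions).
#'
#' @param sequences character vector (duplicates collapsed).
#' @param threshold strict edit-distance bound (default 3).
#' @return an \code{igraph} graph with a \code{hamming} edge attribute.
#' @export
buildSSN <- function(sequences, threshold = 3L) {
  sequences <- unique(sequences)
  d <- .hammingMatrix(sequences)
  adj <- d < threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  if (igraph::ecount(g) > 0L)
    igraph::E(g)$hamming <- d[igraph::as_edgelist(g, names = FALSE)]
  g
}

#' Detect communities and build the community map
#'
#' Clusters an SSN by greedy (multilevel) modularity optimization with a
#' fixed seed, or the Leiden algorithm, then contracts each community to
#' a single node; community-map edge weights count inter-community
#' edges.
#'
#' @param graph an \code{igraph} graph from \code{\link{buildSSN}}.
#' @param method \code{"modularity"} (default; Louvain multilevel) or
#'   \code{"leiden"}.
#' @param seed seed fixing the refinement order.
#' @return list with \code{membership} (named integer), \code{sizes},
#'   \code{communityMap} (weighted \code{igraph} graph), \code{method}.
#' @export
detectCommunities <- function(graph, method = c("modularity", "leiden"),
                              seed = 1L) {
  method <- match.arg(method)
  memb <- .withSeed(seed, {
    if (method == "modularity") {
      as.integer(igraph::membership(igraph::cluster_louvain(graph)))
    } else {
      as.integer(igraph::membership(
        igraph::cluster_leiden(graph, objective_function = "modularity")))
    }
  })
  names(memb) <- igraph::V(graph)$name
  cmap <- igraph::simplify(
    igraph::contract(graph, memb),
    remove.loops = TRUE, remove.multiple = TRUE,
    edge.attr.comb = list("ignore"))
  ## inter-community edge counts as weights
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) > 0L) {
    cc <- cbind(memb[el[, 1L]], memb[el[, 2L]])
    cc <- cc[cc[, 1L] != cc[, 2L], , drop = FALSE]
    if (nrow(cc) > 0L) {
      key <- paste(pmin(cc[, 1L], cc[, 2L]), pmax(cc[, 1L], cc[, 2L]))
      w <- table(key)
      elc <- igraph::as_edgelist(cmap, names = FALSE)
      ckey <- paste(pmin(elc[, 1L], elc[, 2L]), pmax(elc[, 1L], elc[, 2L]))
      igraph::E(cmap)$weight <- as.integer(w[ckey])
    }
  }
  list(membership = memb,
       sizes = as.integer(table(memb)),
       communityMap = cmap,
       method = method)
}

#' Cluster-by-cluster pairing matrix
#'
#' Cross-tabulates enriched chain-A/chain-B pairs by the community labels
#' of their chains (the data behind a chord/Circos rendering, which this
#' package does not draw).
#'
#' @param pairs data.frame with \code{chain_a}, \code{chain_b} (e.g.
#'   output of \code{\link{filterEnriched}}).
#' @param clustersA,clustersB named vectors mapping chain sequences to
#'   cluster labels.
#' @return integer matrix, chain-A clusters x chain-B clusters; the grand
#'   total equals \code{nrow(pairs)}.
#' @export
pairingMatrix <- function(pairs, clustersA, clustersB) {
  la <- clustersA[pairs$chain_a]
  lb <- clustersB[pairs$chain_b]
  if (anyNA(la) || anyNA(lb))
    stop("unlabeled pair(s) at row(s) ",
         paste(head(which(is.na(la) | is.na(lb)), 5L), collapse = ","))
  ua <- sort(unique(unname(clustersA)))
  ub <- sort(unique(unname(clustersB)))
  m <- matrix(0L, length(ua), length(ub), dimnames = list(ua, ub))
  if (nrow(pairs) > 0L) {
    t0 <- table(factor(la, levels = ua), factor(lb, levels = ub))
    m[] <- as.integer(t0)
  }
  m
}

#' Export SSN edge list and community table
#'
#' @param graph SSN graph.
#' @param communities output of \code{\link{detectCommunities}}.
#' @param edgePath,communityPath output TSV paths (either may be NULL).
#' @export
writeSSN <- function(graph, communities = NULL, edgePath = NULL,
                     communityPath = NULL) {
  if (!is.null(edgePath)) {
    el <- igraph::as_edgelist(graph)
    df <- data.frame(from = el[, 1L], to = el[, 2L],
                     hamming = if (igraph::ecount(graph) > 0L)
                       igraph::E(graph)$hamming else integer())
    utils::write.table(df, edgePath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(communityPath) && !is.null(communities)) {
    df <- data.frame(sequence = names(communities$membership),
                     community = unname(communities$membership))
    utils::write.table(df, communityPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(NULL)
}
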