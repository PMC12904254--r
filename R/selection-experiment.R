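#' Construct a SelectionExperiment
#'
#' @param counts integer matrix, sequences x rounds (column order = temporal
#'   order of the selection rounds).
#' @param chainA,chainB character vectors of per-chain library sequences,
#'   one per row of \code{counts}.
#' @param scheme the \linkS4class{LibraryScheme}.
#' @param rounds optional round labels; defaults to \code{colnames(counts)}
#'   or \code{R0..Rn}.
#' @return a \linkS4class{SelectionExperiment}.
#' @rdname SelectionExperiment
#' @export
SelectionExperiment <- function(counts, chainA, chainB, scheme,
                                rounds = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(rounds))
    rounds <- colnames(counts)
  if (is.null(rounds))
    rounds <- paste0("R", seq_len(ncol(counts)) - 1L)
  colnames(counts) <- rounds
  concat <- paste0(chainA, chainB)
  validateSequences(scheme, concat)
  if (anyDuplicated(concat)) {
    agg <- rowsum(counts, group = concat, reorder = FALSE)
    keep <- match(rownames(agg), concat)
    chainA <- chainA[keep]; chainB <- chainB[keep]
    counts <- agg
    concat <- rownames(agg)
  }
  rownames(counts) <- concat
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(chain_a = chainA, chain_b = chainB,
                                   row.names = concat))
  S4Vectors::metadata(se)$scheme <- scheme
  new("SelectionExperiment", se)
}

#' @rdname SelectionExperiment
#' @export
setMethod("libraryScheme", "SelectionExperiment",
  function(x) S4Vectors::metadata(x)$scheme)

#' @rdname SelectionExperiment
#' @export
setMethod("roundTotals", "SelectionExperiment", function(x)
  colSums(SummarizedExperiment::assay(x, "counts")))

#' @rdname SelectionExperiment
#' @param x a \code{SelectionExperiment}.
#' @export
roundLabels <- function(x) colnames(x)

#' @rdname SelectionExperiment
#' @export
selectionCounts <- function(x) SummarizedExperiment::assay(x, "counts")

setMethod("show", "SelectionExperiment", function(object) {
  cat("SelectionExperiment:", nrow(object), "unique sequence pairs,",
      ncol(object), "rounds\n")
  tot <- roundTotals(object)
  cat("  rounds:", paste(sprintf("%s (%d reads)", names(tot), tot),
                         collapse = ", "), "\n")
})

#' Read / write per-round paired-sequence count tables
#'
#' Plain TSV with header \code{round  chain_a  chain_b  count}; lines
#' starting with \code{#} are ignored; duplicate (round, pair) rows are
#' summed. Round order is the order of first appearance in the file.
#'
#' @param path TSV file path.
#' @param scheme the \linkS4class{LibraryScheme} the sequences must obey.
#' @return \code{readCountsTSV} returns a
#'   \linkS4class{SelectionExperiment}.
#' @export
readCountsTSV <- function(path, scheme) {
  df <- utils::read.delim(path, header = TRUE, comment.char = "#",
                          colClasses = c("character", "character",
                                         "character", "numeric"))
  need <- c("round", "chain_a", "chain_b", "count")
  if (!all(need %in% colnames(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0))
    stop("negative count at row(s) ",
         paste(head(which(df$count < 0), 5L), collapse = ","))
  concat <- paste0(df$chain_a, df$chain_b)
  ok <- tryCatch({ validateSequences(scheme, concat); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok)) stop("invalid sequence in count table: ",
                        conditionMessage(ok))
  rounds <- unique(df$round)
  pairs <- unique(concat)
  cts <- matrix(0L, length(pairs), length(rounds),
                dimnames = list(pairs, rounds))
  ij <- cbind(match(concat, pairs), match(df$round, rounds))
  for (k in seq_len(nrow(df)))
    cts[ij[k, 1L], ij[k, 2L]] <- cts[ij[k, 1L], ij[k, 2L]] +
      as.integer(df$count[k])
  nA <- length(chainAPositions(scheme))
  SelectionExperiment(cts,
                      chainA = substr(pairs, 1L, nA),
                      chainB = substr(pairs, nA + 1L, nchar(pairs)),
                      scheme = scheme, rounds = rounds)
}

#' @rdname readCountsTSV
#' @param x a \linkS4class{SelectionExperiment} to write.
#' @export
writeCountsTSV <- function(x, path) {
  cts <- selectionCounts(x)
  rd <- SummarizedExperiment::rowData(x)
  rows <- do.call(rbind, lapply(seq_len(ncol(cts)), function(j) {
    nz <- which(cts[, j] > 0L)
    data.frame(round = colnames(cts)[j],
               chain_a = rd$chain_a[nz], chain_b = rd$chain_b[nz],
               count = cts[nz, j])
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
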