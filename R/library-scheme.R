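#' @describeIn LibraryScheme-class Constructor.
#'
#' When \code{degenerateCodon} is given and \code{alphabet} is not, the
#' alphabet is taken from the codon's translation set (stop codons
#' excluded). Supplying both cross-checks one against the other.
#'
#' @param chainAPositions,chainBPositions integer vectors of randomized
#'   residue numbers (1-based structure numbering).
#' @param alphabet optional character vector of single-letter amino acids.
#' @param degenerateCodon optional three-letter IUPAC codon string.
#' @export
LibraryScheme <- function(chainAPositions, chainBPositions,
                          alphabet = NULL, degenerateCodon = NA_character_) {
  if (!is.na(degenerateCodon) && is.null(alphabet))
    alphabet <- expandDegenerateCodon(degenerateCodon)$aminoAcids
  if (is.null(alphabet))
    stop("supply an alphabet or a degenerate codon")
  new("LibraryScheme",
      chainAPositions = as.integer(sort(chainAPositions)),
      chainBPositions = as.integer(sort(chainBPositions)),
      alphabet = sort(unique(as.character(alphabet))),
      degenerateCodon = as.character(degenerateCodon))
}

#' @rdname LibraryScheme-class
#' @export
setMethod("chainAPositions", "LibraryScheme", function(x) x@chainAPositions)
#' @rdname LibraryScheme-class
#' @export
setMethod("chainBPositions", "LibraryScheme", function(x) x@chainBPositions)
#' @rdname LibraryScheme-class
#' @export
setMethod("schemeAlphabet", "LibraryScheme", function(x) x@alphabet)
#' @rdname LibraryScheme-class
#' @export
setMethod("degenerateCodon", "LibraryScheme", function(x) x@degenerateCodon)
#' @rdname LibraryScheme-class
#' @export
setMethod("totalPositions", "LibraryScheme",
  function(x) length(x@chainAPositions) + length(x@chainBPositions))

setMethod("show", "LibraryScheme", function(object) {
  cat("LibraryScheme:",
      length(object@chainAPositions), "+", length(object@chainBPositions),
      "randomized positions,", length(object@alphabet), "letters\n")
  cat("  chain A:", paste(object@chainAPositions, collapse = ", "), "\n")
  cat("  chain B:", paste(object@chainBPositions, collapse = ", "), "\n")
  cat("  alphabet: {", paste(object@alphabet, collapse = ","), "}",
      if (!is.na(object@degenerateCodon))
        paste0(" from codon ", object@degenerateCodon), "\n", sep = "")
})

#' Expand an IUPAC degenerate codon
#'
#' Enumerates the DNA codons encoded by a three-letter IUPAC degenerate
#' codon and translates them with the standard genetic code. Stop codons
#' are reported separately, never silently dropped.
#'
#' @param code three-character IUPAC string, e.g. \code{"DTS"}.
#' @return list with \code{codons}, \code{aminoAcids}, \code{stopCodons},
#'   \code{codonCount}, \code{aaCount}.
#' @examples
#' expandDegenerateCodon("DTS")$aminoAcids   # F, I, L, M, V
#' @export
expandDegenerateCodon <- function(code) {
  code <- toupper(as.character(code))
  if (length(code) != 1L || is.na(code) || nchar(code) != 3L)
    stop("degenerate codon must be a single 3-letter string")
  sym <- strsplit(code, "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  if (!all(sym %in% names(map)))
    stop(sprintf("non-IUPAC symbol in codon '%s'", code))
  parts <- lapply(sym, function(s) strsplit(map[[s]], "")[[1]])
  codons <- sort(apply(expand.grid(parts[[1]], parts[[2]], parts[[3]],
                                   stringsAsFactors = FALSE,
                                   KEEP.OUT.ATTRS = FALSE)[, 1:3],
                       1L, paste, collapse = ""))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stops <- codons[aa == "*"]
  aas <- sort(unique(aa[aa != "*"]))
  list(codons = codons, aminoAcids = aas, stopCodons = stops,
       codonCount = length(codons), aaCount = length(aas))
}

#' Theoretical diversity of a library scheme
#'
#' Nucleotide diversity is the number of distinct DNA sequences the
#' degenerate codon can produce over all randomized positions
#' (\code{codonCount^totalPositions}); protein diversity is
#' \code{aaCount^totalPositions}, counting stop-free translations only.
#'
#' @param scheme a \linkS4class{LibraryScheme} with a degenerate codon.
#' @return list with \code{nucleotide} and \code{protein} diversities.
#' @examples
#' sch <- LibraryScheme(c(8, 11, 14, 15, 45), c(29, 30, 33, 43, 44, 47),
#'                      degenerateCodon = "DTS")
#' theoreticalDiversity(sch)   # 6^11 = 362,797,056 and 5^11
#' @export
theoreticalDiversity <- function(scheme) {
  stopifnot(is(scheme, "LibraryScheme"))
  code <- degenerateCodon(scheme)
  if (is.na(code)) stop("scheme has no degenerate codon")
  exp <- expandDegenerateCodon(code)
  p <- totalPositions(scheme)
  list(nucleotide = exp$codonCount^p, protein = exp$aaCount^p)
}

#' Validate concatenated library sequences against a scheme
#'
#' @param scheme a \linkS4class{LibraryScheme}.
#' @param sequences character vector of concatenated sequences.
#' @return invisibly \code{TRUE}; stops with the offending entries
#'   otherwise.
#' @export
validateSequences <- function(scheme, sequences) {
  p <- totalPositions(scheme)
  bad <- nchar(sequences) != p
  if (any(bad))
    stop(sprintf("sequence(s) %s have length != %d",
                 paste(head(which(bad), 5L), collapse = ","), p))
  ok <- grepl(sprintf("^[%s]+$", paste(schemeAlphabet(scheme), collapse = "")),
              sequences)
  if (!all(ok))
    stop(sprintf("sequence(s) at index %s contain letters outside {%s}",
                 paste(head(which(!ok), 5L), collapse = ","),
                 paste(schemeAlphabet(scheme), collapse = ",")))
  invisible(TRUE)
}

## -- integer encoding of the enumerated sequence space --------------------
## A sequence is a vector of letter indices l_1..l_p in 1..q; its 1-based
## space index is 1 + sum (l_i - 1) q^(i-1). All landscape-wide machinery
## (walks, Dijkstra, exhaustive ANOVA) works on these indices.

.spaceSize <- function(scheme) {
  length(schemeAlphabet(scheme))^totalPositions(scheme)
}

.seqToLetterIdx <- function(scheme, sequences) {
  ab <- schemeAlphabet(scheme)
  m <- matrix(match(unlist(strsplit(sequences, "")), ab),
              ncol = totalPositions(scheme), byrow = TRUE)
  if (anyNA(m)) stop("sequence letters outside the scheme alphabet")
  m
}

.seqToIndex <- function(scheme, sequences) {
  q <- length(schemeAlphabet(scheme))
  m <- .seqToLetterIdx(scheme, sequences)
  as.integer(1 + (m - 1L) %*% q^(seq_len(ncol(m)) - 1L))
}

.indexToLetterIdx <- function(scheme, idx) {
  q <- length(schemeAlphabet(scheme))
  p <- totalPositions(scheme)
  m <- matrix(0L, length(idx), p)
  r <- idx - 1L
  for (j in seq_len(p)) {
    m[, j] <- r %% q + 1L
    r <- r %/% q
  }
  m
}

.indexToSeq <- function(scheme, idx) {
  ab <- schemeAlphabet(scheme)
  m <- .indexToLetterIdx(scheme, idx)
  apply(m, 1L, function(r) paste(ab[r], collapse = ""))
}

#' Enumerate the full combinatorial sequence space of a scheme
#'
#' @param scheme a \linkS4class{LibraryScheme}.
#' @param limit refuse to enumerate more than this many sequences.
#' @return character vector of all \code{alphabet^positions} concatenated
#'   sequences, in index order.
#' @export
enumerateSequences <- function(scheme, limit = 1e6) {
  n <- .spaceSize(scheme)
  if (n > limit)
    stop(sprintf("space has %.3g sequences, above limit %.3g", n, limit))
  .indexToSeq(scheme, seq_len(n))
}

#' Hamming distance between equal-length sequences
#'
#' @param a,b character vectors (recycled) of equal-length strings.
#' @return integer vector of per-pair mismatch counts.
#' @export
hammingDistance <- function(a, b) {
  if (any(nchar(a) != nchar(b)))
    stop("sequences must have equal length")
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

#' Read / write a scheme as a key-value config file
#'
#' Plain-text format, one \code{key = value} per line: keys
#' \code{chain_a_positions}, \code{chain_b_positions} (comma-separated),
#' \code{degenerate_codon}, \code{alphabet} (optional override).
#'
#' @param path file path.
#' @return \code{readScheme} returns a \linkS4class{LibraryScheme}.
#' @examples
#' cfg <- system.file("extdata", "z_library_scheme.cfg",
#'                    package = "coevoscape")
#' readScheme(cfg)
#' @export
readScheme <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  kv <- strsplit(ln, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
  nums <- function(s) as.integer(strsplit(s, ",")[[1]])
  ab <- get("alphabet")
  LibraryScheme(
    chainAPositions = nums(get("chain_a_positions")),
    chainBPositions = nums(get("chain_b_positions")),
    alphabet = if (is.na(ab)) NULL else strsplit(gsub("[ ,]", "", ab), "")[[1]],
    degenerateCodon = get("degenerate_codon"))
}

#' @rdname readScheme
#' @param scheme a \linkS4class{LibraryScheme} to write.
#' @export
writeScheme <- function(scheme, path) {
  lines <- c(
    paste("chain_a_positions =",
          paste(chainAPositions(scheme), collapse = ",")),
    paste("chain_b_positions =",
          paste(chainBPositions(scheme), collapse = ",")),
    if (!is.na(degenerateCodon(scheme)))
      paste("degenerate_codon =", degenerateCodon(scheme)),
    paste("alphabet =", paste(schemeAlphabet(scheme), collapse = "")))
  writeLines(lines, path)
  invisible(path)
}
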