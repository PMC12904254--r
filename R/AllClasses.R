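#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Library scheme for a two-chain combinatorial protein library
#'
#' A \code{LibraryScheme} records which residue positions of each chain are
#' randomized, the amino-acid alphabet used at those positions, and the
#' degenerate codon that encodes the alphabet at the DNA level. Sequences
#' handled by the package are the concatenation of the chain-A library
#' letters (ascending residue order) followed by the chain-B letters.
#'
#' @slot chainAPositions integer vector of randomized residue numbers on
#'   chain A (1-based, structure numbering), strictly increasing.
#' @slot chainBPositions integer vector for chain B, same conventions.
#' @slot alphabet character vector of single-letter amino acids allowed at
#'   every randomized position.
#' @slot degenerateCodon three-letter IUPAC code encoding the alphabet, or
#'   \code{NA} when the scheme was declared directly from an alphabet.
#'
#' @examples
#' zScheme <- LibraryScheme(chainAPositions = c(8, 11, 14, 15, 45),
#'                          chainBPositions = c(29, 30, 33, 43, 44, 47),
#'                          degenerateCodon = "DTS")
#' totalPositions(zScheme)
#' @export
setClass("LibraryScheme",
  representation(chainAPositions = "integer",
                 chainBPositions = "integer",
                 alphabet = "character",
                 degenerateCodon = "character"))

setValidity("LibraryScheme", function(object) {
  msg <- NULL
  a <- object@chainAPositions; b <- object@chainBPositions
  if (length(a) == 0L || length(b) == 0L)
    msg <- c(msg, "both chains must have at least one randomized position")
  if (is.unsorted(a, strictly = TRUE) || is.unsorted(b, strictly = TRUE))
    msg <- c(msg, "position lists must be strictly increasing")
  if (length(object@alphabet) == 0L)
    msg <- c(msg, "alphabet is empty")
  if (anyDuplicated(object@alphabet))
    msg <- c(msg, "alphabet letters must be unique")
  if (any(nchar(object@alphabet) != 1L))
    msg <- c(msg, "alphabet entries must be single letters")
  code <- object@degenerateCodon
  if (!is.na(code)) {
    exp <- tryCatch(expandDegenerateCodon(code), error = function(e) NULL)
    if (is.null(exp)) {
      msg <- c(msg, sprintf("invalid degenerate codon '%s'", code))
    } else if (!setequal(exp$aminoAcids, object@alphabet)) {
      msg <- c(msg, sprintf(
        "alphabet {%s} does not match the translation set {%s} of codon %s",
        paste(sort(object@alphabet), collapse = ","),
        paste(sort(exp$aminoAcids), collapse = ","), code))
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Multi-round selection read counts
#'
#' \code{SelectionExperiment} extends
#' \linkS4class{SummarizedExperiment}: rows are unique chain-A/chain-B
#' sequence pairs, columns are selection rounds in temporal order, and the
#' single \code{"counts"} assay holds the read counts. \code{rowData} carries
#' the per-chain and concatenated sequences; the \code{LibraryScheme} lives
#' in \code{metadata(x)$scheme}.
#'
#' @export
setClass("SelectionExperiment", contains = "SummarizedExperiment")

setValidity("SelectionExperiment", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("chain_a", "chain_b") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain chain_a and chain_b")
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0) || any(cts != round(cts)))
    msg <- c(msg, "counts must be non-negative integers")
  sch <- S4Vectors::metadata(object)$scheme
  if (is.null(sch) || !is(sch, "LibraryScheme"))
    msg <- c(msg, "metadata(x)$scheme must be a LibraryScheme")
  if (is.null(msg)) TRUE else msg
})

#' Ground-truth fitness landscape for simulation studies
#'
#' An explicitly parametrized sequence-to-fitness function with additive
#' (per position, per letter) and sparse pairwise (per position pair, per
#' letter pair) terms. Used by the synthetic-selection simulator so that
#' inference can be benchmarked against a known truth.
#'
#' @slot scheme the \linkS4class{LibraryScheme}.
#' @slot intercept numeric baseline fitness.
#' @slot additive numeric matrix, positions x alphabet.
#' @slot pairwise data.frame with columns \code{pos_i}, \code{pos_j}
#'   (concatenated-position indices), \code{letter_i}, \code{letter_j},
#'   \code{value}.
#' @slot seed integer seed the landscape was drawn with.
#' @export
setClass("TrueLandscape",
  representation(scheme = "LibraryScheme", intercept = "numeric",
                 additive = "matrix", pairwise = "data.frame",
                 seed = "integer"))

#' Fitted selection probabilistic model
#'
#' Holds the trained neural trunk \eqn{f_\theta} (fully connected ReLU
#' layers), the per-round affine heads \eqn{f_r = a_r f_\theta + b_r} with
#' \eqn{a_r \ge 0}, and training metadata. Create with \code{\link{fitSPM}};
#' evaluate with \code{\link{scoreSequences}}.
#'
#' @slot scheme the \linkS4class{LibraryScheme} the model was trained under.
#' @slot weights list of layer weight matrices and bias vectors.
#' @slot roundSlopes named numeric \eqn{a_r} per fitted round (>= 0).
#' @slot roundOffsets named numeric \eqn{b_r} fixing the zero-mean gauge.
#' @slot rounds character vector of all round labels (first = input round).
#' @slot logQ0 named numeric, smoothed log frequencies of the input round.
#' @slot config list, the \code{\link{spmConfig}} used.
#' @slot history list with the loss trace, final log-likelihood and the
#'   trunk mean used for the gauge.
#' @export
setClass("FitnessModel",
  representation(scheme = "LibraryScheme", weights = "list",
                 roundSlopes = "numeric", roundOffsets = "numeric",
                 rounds = "character", logQ0 = "numeric",
                 config = "list", history = "list"))

setValidity("FitnessModel", function(object) {
  if (any(object@roundSlopes < 0))
    "round slopes a_r must be non-negative" else TRUE
})

#' Ensemble of simulated adaptive walks
#'
#' Result of \code{\link{simulateTrajectories}}: greedy stochastic uphill
#' walks on a fitness landscape. Terminal counts define per-sequence
#' accessibility; optional full path storage supports seed-sequence
#' analysis.
#'
#' @slot scheme the \linkS4class{LibraryScheme}.
#' @slot nTrajectories integer, number of walks.
#' @slot terminalCounts named integer, walks ending at each terminal.
#' @slot visitCounts named integer, walks visiting each sequence at least
#'   once (terminal included).
#' @slot paths integer matrix (walks x steps) of 1-based sequence-space
#'   indices padded with NA, or a 0x0 matrix when path storage is off.
#' @slot terminals integer vector, per-walk terminal index (empty when path
#'   storage is off).
#' @slot fitness numeric vector of fitness over the enumerated space.
#' @slot seed integer seed.
#' @export
setClass("TrajectoryEnsemble",
  representation(scheme = "LibraryScheme", nTrajectories = "integer",
                 terminalCounts = "integer", visitCounts = "integer",
                 paths = "matrix", terminals = "integer",
                 fitness = "numeric", seed = "integer"))

setValidity("TrajectoryEnsemble", function(object) {
  if (sum(object@terminalCounts) != object@nTrajectories)
    "terminal counts must sum to the number of trajectories" else TRUE
})

#' Epistasis decomposition of a fitness function
#'
#' Functional-ANOVA decomposition under the uniform reference distribution:
#' zero-mean effect sizes per term (set of positions) and letter
#' configuration, plus the max-minus-min importance of every term and its
#' intra-/inter-chain label.
#'
#' @slot scheme the \linkS4class{LibraryScheme}.
#' @slot intercept numeric, the grand mean \eqn{\beta_0}.
#' @slot effects data.frame: \code{term}, \code{order}, \code{chain_class},
#'   \code{config} (letter configuration), \code{effect}.
#' @slot terms data.frame: \code{term}, \code{order}, \code{chain_class},
#'   \code{importance}.
#' @slot maxOrder integer.
#' @slot estimator list describing exhaustive vs Monte-Carlo estimation.
#' @export
setClass("EpistasisReport",
  representation(scheme = "LibraryScheme", intercept = "numeric",
                 effects = "data.frame", terms = "data.frame",
                 maxOrder = "integer", estimator = "list"))

#' Energy-well geometry of a fitness landscape
#'
#' Top-k wells (terminals of an adaptive-walk ensemble ranked by
#' accessibility) with energies, relative energies, accessibilities and,
#' after \code{\link{wellDepth}}, escape depths and the pairwise barrier
#' matrix.
#'
#' @slot wells data.frame: \code{representative}, \code{energy},
#'   \code{relative_energy}, \code{accessibility}, \code{depth}.
#' @slot barriers numeric matrix of minimal cumulative uphill barriers
#'   between representatives (0x0 until \code{wellDepth} is run).
#' @slot k integer, requested number of wells.
#' @export
setClass("LandscapeGeometry",
  representation(wells = "data.frame", barriers = "matrix", k = "integer"))
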