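#' @rdname LibraryScheme-class
#' @param x a \code{LibraryScheme} (or object carrying one).
#' @export
setGeneric("chainAPositions", function(x) standardGeneric("chainAPositions"))

#' @rdname LibraryScheme-class
#' @export
setGeneric("chainBPositions", function(x) standardGeneric("chainBPositions"))

#' @rdname LibraryScheme-class
#' @export
setGeneric("schemeAlphabet", function(x) standardGeneric("schemeAlphabet"))

#' @rdname LibraryScheme-class
#' @export
setGeneric("degenerateCodon", function(x) standardGeneric("degenerateCodon"))

#' @rdname LibraryScheme-class
#' @export
setGeneric("totalPositions", function(x) standardGeneric("totalPositions"))

#' @rdname SelectionExperiment
#' @export
setGeneric("libraryScheme", function(x) standardGeneric("libraryScheme"))

#' @rdname SelectionExperiment
#' @export
setGeneric("roundTotals", function(x) standardGeneric("roundTotals"))

#' Evaluate a fitness model or landscape on sequences
#'
#' @param object a \linkS4class{FitnessModel} or \linkS4class{TrueLandscape}.
#' @param sequences character vector of concatenated library sequences.
#' @param round round label, or \code{"global"} for the shared trunk
#'   fitness (models only).
#' @return numeric vector of fitness values.
#' @export
setGeneric("scoreSequences",
  function(object, sequences, round = "global")
    standardGeneric("scoreSequences"))

#' @rdname TrajectoryEnsemble-class
#' @param object a \code{TrajectoryEnsemble}.
#' @param sequences optional character vector; default reports all
#'   terminals.
#' @export
setGeneric("accessibility",
  function(object, sequences = NULL) standardGeneric("accessibility"))

#' @rdname EpistasisReport-class
#' @param object an \code{EpistasisReport}.
#' @param order interaction order (2 = pairwise).
#' @param ... method-specific arguments.
#' @export
setGeneric("rei",
  function(object, order = 2L, ...) standardGeneric("rei"))
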