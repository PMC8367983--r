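#' @rdname OligoCutoffs-class
#' @param x an object with per-bin cutoffs.
#' @export
setGeneric("binCutoffs", function(x) standardGeneric("binCutoffs"))

#' @rdname PolyATailExperiment-class
#' @param x a \code{PolyATailExperiment}.
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname PolyATailExperiment-class
#' @export
setGeneric("tailMeans", function(x) standardGeneric("tailMeans"))
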