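#' @rdname ShiftLibrary-accessors
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' @rdname ShiftLibrary-accessors
#' @export
setGeneric("carbonShifts", function(x, ...) standardGeneric("carbonShifts"))

#' @rdname ShiftLibrary-accessors
#' @export
setGeneric("protonShifts", function(x, ...) standardGeneric("protonShifts"))

#' @rdname ShiftLibrary-accessors
#' @export
setGeneric("solventLabel", function(x) standardGeneric("solventLabel"))

#' @rdname ShiftLibrary-accessors
#' @export
setGeneric("nMolecules", function(x) standardGeneric("nMolecules"))

#' @rdname countIndex
#' @export
setGeneric("countIndex", function(x) standardGeneric("countIndex"))

#' @rdname nucleusCounts
#' @export
setGeneric("nucleusCounts", function(x) standardGeneric("nucleusCounts"))

#' @rdname summarizeLibrary
#' @export
setGeneric("summarizeLibrary", function(x) standardGeneric("summarizeLibrary"))
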