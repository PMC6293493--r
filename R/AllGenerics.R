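#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))

#' @rdname ExpressionMatrix-accessors
#' @export
setGeneric("exprUnit<-", function(x, value) standardGeneric("exprUnit<-"))

#' @rdname zeroPositions
#' @export
setGeneric("zeroPositions", function(x) standardGeneric("zeroPositions"))

#' @rdname MissingPositionSet-accessors
#' @export
setGeneric("missingPositions", function(x) standardGeneric("missingPositions"))
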