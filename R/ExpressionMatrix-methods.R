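#' Accessors for ExpressionMatrix
#'
#' \code{geneIds}/\code{cellIds} return the identifier axes;
#' \code{exprValues} the genes x cells value matrix (sparse or dense,
#' as stored); \code{exprUnit} the unit tag.
#'
#' @param x an \code{ExpressionMatrix}.
#' @param value replacement unit tag.
#' @return Identifier vectors, the value matrix, or the unit string.
#' @name ExpressionMatrix-accessors
NULL

#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("cellIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "expr"))

#' @rdname ExpressionMatrix-accessors
#' @export
setMethod("exprUnit", "ExpressionMatrix",
          function(x) S4Vectors::metadata(x)$unit)

#' @rdname ExpressionMatrix-accessors
#' @export
setReplaceMethod("exprUnit", "ExpressionMatrix", function(x, value) {
  stopifnot(value %in% .VALID_UNITS)
  S4Vectors::metadata(x)$unit <- value
  x
})

#' Enumerate zero-valued elements without densifying
#'
#' Returns the (gene, cell) index pairs of all exactly-zero elements of
#' the matrix. For sparse storage the complement of the nonzero pattern
#' is enumerated column-wise, so no dense copy of the matrix is made.
#'
#' @param x an \code{ExpressionMatrix}.
#' @return Integer matrix with columns \code{gene}, \code{cell}, ordered
#'   by cell then gene.
#' @name zeroPositions
#' @export
setMethod("zeroPositions", "ExpressionMatrix", function(x) {
  v <- exprValues(x)
  if (methods::is(v, "sparseMatrix")) {
    vc <- methods::as(v, "CsparseMatrix")
    m <- nrow(vc)
    res <- vector("list", ncol(vc))
    for (j in seq_len(ncol(vc))) {
      if (vc@p[j + 1L] > vc@p[j]) {
        idx <- (vc@p[j] + 1L):vc@p[j + 1L]
        nz <- (vc@i[idx] + 1L)[vc@x[idx] != 0]
      } else nz <- integer()
      zr <- setdiff(seq_len(m), nz)
      res[[j]] <- cbind(gene = zr, cell = rep.int(j, length(zr)))
    }
    out <- do.call(rbind, res)
  } else {
    w <- which(v == 0, arr.ind = TRUE)
    out <- w[order(w[, 2], w[, 1]), , drop = FALSE]
    dimnames(out) <- NULL
    colnames(out) <- c("gene", "cell")
  }
  out
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells [unit: %s]\n",
              nrow(object), ncol(object), exprUnit(object)))
  v <- exprValues(object)
  nz <- if (methods::is(v, "sparseMatrix")) length(v@x[v@x != 0])
        else sum(v != 0)
  cat(sprintf("  zero fraction: %.3f\n", 1 - nz / prod(dim(object))))
})

#' @rdname MissingPositionSet-accessors
#' @export
setMethod("missingPositions", "MissingPositionSet",
          function(x) x@positions)

#' Accessors for MissingPositionSet
#'
#' @param x a \code{MissingPositionSet}.
#' @return \code{missingPositions} returns the integer (gene, cell)
#'   position matrix.
#' @name MissingPositionSet-accessors
NULL

setMethod("show", "MissingPositionSet", function(object) {
  cat(sprintf(
    "MissingPositionSet: %d positions [detectors: %s; eta = %.3f]\n",
    nrow(object@positions), paste(object@provenance, collapse = "+"),
    object@eta))
})

setMethod("show", "MissingProbabilityMatrix", function(object) {
  cat(sprintf(
    "MissingProbabilityMatrix[%s]: %d x %d, %d elements scored\n",
    object@source, nrow(object@scores), ncol(object@scores),
    sum(!is.na(object@scores))))
})

setMethod("show", "LinearModel", function(object) {
  cat(sprintf("LinearModel: %s (C = %g", object@objective, object@C))
  if (grepl("^svr", object@objective))
    cat(sprintf(", epsilon = %g, p = %d", object@epsilon, object@p))
  cat(sprintf(")\n  %d weights, bias %.4g, final objective %.6g\n",
              length(object@weights), object@bias,
              object@solverInfo$objective))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf(
    "SyntheticDataset: %d genes x %d cells, %d dropout positions (seed %d)\n",
    nrow(object@truth), ncol(object@truth),
    nrow(object@mask), object@config$seed))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
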