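#' Read an expression matrix from MTX or delimited text
#'
#' Two on-disk layouts are supported. \code{format = "mtx"}: a Matrix
#' Market coordinate file (1-based indices) plus two sidecar text files
#' of row and column names, located as \code{<stem>_rows.txt} /
#' \code{<stem>_cols.txt} next to the matrix unless given explicitly.
#' \code{format = "delimited"}: TSV/CSV (autodetected from the
#' extension, \code{.csv} means comma) with a header row of cell names
#' and gene identifiers in the first column.
#'
#' @param path matrix file path.
#' @param format \code{"mtx"} or \code{"delimited"}; default guessed
#'   from the extension.
#' @param orientation \code{"genes_in_rows"} (default) or
#'   \code{"cells_in_rows"}; the returned matrix is always genes x cells.
#' @param unit unit tag to attach (\code{"counts"}, \code{"umi"},
#'   \code{"rpkm"}, \code{"unknown"}).
#' @param rowNames,colNames sidecar name files for MTX input.
#' @return An [ExpressionMatrix-class] in genes x cells orientation.
#' @export
readExpressionMatrix <- function(path,
                                 format = c("auto", "mtx", "delimited"),
                                 orientation = c("genes_in_rows",
                                                 "cells_in_rows"),
                                 unit = "unknown",
                                 rowNames = NULL, colNames = NULL) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
              else "delimited"
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(rowNames)) rowNames <- paste0(stem, "_rows.txt")
    if (is.null(colNames)) colNames <- paste0(stem, "_cols.txt")
    for (f in c(rowNames, colNames))
      if (!file.exists(f)) stop("MTX sidecar name file not found: ", f)
    v <- tryCatch(Matrix::readMM(path), error = function(e)
      stop("malformed MTX file '", path, "': ", conditionMessage(e)))
    if (methods::is(v, "nMatrix"))  # pattern matrix (e.g. no entries)
      v <- methods::as(v, "dMatrix")
    v <- methods::as(v, "CsparseMatrix")
    rn <- readLines(rowNames)
    cn <- readLines(colNames)
    if (length(rn) != nrow(v) || length(cn) != ncol(v))
      stop("sidecar name files do not match declared MTX dimensions")
    dimnames(v) <- list(rn, cn)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                        check.names = FALSE, stringsAsFactors = FALSE,
                        comment.char = ""),
      error = function(e)
        stop("malformed delimited file '", path, "': ",
             conditionMessage(e)))
    ids <- as.character(df[[1L]])
    v <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric value in '", path, "' near data line ",
           ((bad - 1L) %% nrow(v)) + 1L)
    }
    rownames(v) <- ids
  }
  if (orientation == "cells_in_rows") v <- Matrix::t(v)
  if (anyDuplicated(rownames(v)))
    stop("duplicate gene identifiers in ", path)
  if (anyDuplicated(colnames(v)))
    stop("duplicate cell identifiers in ", path)
  ExpressionMatrix(v, unit = unit)
}

#' Write an expression matrix to MTX or delimited text
#'
#' MTX output writes the Matrix Market coordinate file plus
#' \code{<stem>_rows.txt} and \code{<stem>_cols.txt} sidecars, so that
#' [readExpressionMatrix()] round-trips. Delimited output preserves
#' gene and cell order.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output file path.
#' @param format \code{"mtx"} or \code{"delimited"} (default from the
#'   extension).
#' @return Invisibly, \code{path}.
#' @export
writeExpressionMatrix <- function(x, path,
                                  format = c("auto", "mtx", "delimited")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx"
              else "delimited"
  v <- exprValues(x)
  if (format == "mtx") {
    sp <- methods::as(Matrix::Matrix(v, sparse = TRUE), "CsparseMatrix")
    sp <- Matrix::drop0(sp)
    Matrix::writeMM(sp, path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    writeLines(geneIds(x), paste0(stem, "_rows.txt"))
    writeLines(cellIds(x), paste0(stem, "_cols.txt"))
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    dv <- as.matrix(v)
    df <- data.frame(gene_id = geneIds(x), dv, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("gene_id", cellIds(x))
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read or write a gene list
#'
#' Plain text, one identifier per line; \code{'#'} starts a comment.
#'
#' @param path file path.
#' @return \code{readGeneList}: character vector of unique identifiers.
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  x <- x[nzchar(x)]
  if (!length(x)) stop("gene list '", path, "' is empty")
  if (anyDuplicated(x)) stop("gene list '", path, "' has duplicate ids")
  x
}

#' @rdname readGeneList
#' @param ids character vector of gene identifiers.
#' @export
writeGeneList <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' RPKM normalization
#'
#' Converts raw read counts to reads per kilobase of transcript per
#' million mapped reads:
#' \deqn{rpkm_{ij} = 10^9 \, c_{ij} / (L_i \, N_j)}
#' with \eqn{L_i} the gene length in bases and \eqn{N_j} the cell's
#' total count. Zeros map to zeros, so the zero pattern is preserved
#' exactly.
#'
#' @param x an [ExpressionMatrix-class] with unit \code{"counts"}.
#' @param geneLengths named numeric vector, gene id -> length in bases.
#' @return An \code{ExpressionMatrix} with unit \code{"rpkm"}.
#' @export
rpkmNormalize <- function(x, geneLengths) {
  if (exprUnit(x) != "counts")
    stop("rpkmNormalize expects unit 'counts', got '", exprUnit(x), "'")
  missing <- setdiff(geneIds(x), names(geneLengths))
  if (length(missing))
    stop("missing gene lengths for: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)",
                                           length(missing) - 10))
  len <- geneLengths[geneIds(x)]
  if (any(len <= 0)) stop("non-positive gene length supplied")
  v <- exprValues(x)
  tot <- Matrix::colSums(v)
  if (any(tot <= 0))
    stop("cell with zero total count: ",
         paste(cellIds(x)[tot <= 0], collapse = ", "))
  if (methods::is(v, "sparseMatrix")) {
    out <- methods::as(v, "CsparseMatrix")
    j <- rep.int(seq_len(ncol(out)), diff(out@p))
    out@x <- out@x * 1e9 / (len[out@i + 1L] * tot[j])
  } else {
    out <- v * 1e9 / outer(len, tot)
  }
  ExpressionMatrix(out, unit = "rpkm", geneIds = geneIds(x),
                   cellIds = cellIds(x))
}
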