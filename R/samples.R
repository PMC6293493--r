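#' Split matrix genes into richly and non-richly expressed sets
#'
#' The richly expressed set is the intersection of a user-supplied
#' list (typically housekeeping genes) with the matrix genes, kept in
#' matrix order; the remaining genes form the non-richly expressed
#' (test) set. List identifiers absent from the matrix are reported.
#'
#' @param x an [ExpressionMatrix-class].
#' @param richlyList character vector of richly-expressed gene ids.
#' @return List with components \code{richly}, \code{nonRichly}
#'   (character vectors in matrix order) and \code{unmatched} (list ids
#'   not present in the matrix).
#' @export
partitionGenes <- function(x, richlyList) {
  g <- geneIds(x)
  richly <- g[g %in% richlyList]
  if (!length(richly))
    stop("no richly-expressed list identifier occurs in the matrix; ",
         "check that the gene identifier namespaces match")
  unmatched <- setdiff(richlyList, g)
  if (length(unmatched))
    message(length(unmatched),
            " richly-list identifier(s) absent from the matrix")
  nonRichly <- setdiff(g, richly)
  if (!length(nonRichly))
    warning("richly list covers every matrix gene; no test set exists")
  list(richly = richly, nonRichly = nonRichly, unmatched = unmatched)
}

#' Number of element-wise samples / features for a gene set
#'
#' Computed from the dimensions alone (no materialization): a gene set
#' of size m over n cells yields m * n samples of n - 1 features each.
#'
#' @param x an [ExpressionMatrix-class].
#' @param genes character vector of gene ids (subset of the matrix).
#' @return Integer-valued numeric count.
#' @export
sampleCount <- function(x, genes) {
  stopifnot(all(genes %in% geneIds(x)))
  length(genes) * as.numeric(ncol(x))
}

#' @rdname sampleCount
#' @export
featureCount <- function(x) {
  if (ncol(x) < 2) stop("need at least 2 cells to form features")
  ncol(x) - 1L
}

.deletionIndex <- function(n) {
  # I[j, ] = (1:n)[-j]: cell order with the sample's own cell deleted
  t(vapply(seq_len(n), function(j) seq_len(n)[-j], integer(n - 1L)))
}

.sampleBlockFor <- function(v, rows, labelMode, I = NULL) {
  n <- ncol(v)
  if (is.null(I)) I <- .deletionIndex(n)
  nb <- length(rows)
  feat <- matrix(0, nb * n, n - 1L)
  lab <- numeric(nb * n)
  ei <- matrix(0L, nb * n, 2L, dimnames = list(NULL, c("gene", "cell")))
  for (k in seq_len(nb)) {
    val <- as.numeric(v[rows[k], ])
    idx <- ((k - 1L) * n + 1L):(k * n)
    feat[idx, ] <- matrix(val[I], n, n - 1L)
    lab[idx] <- if (labelMode == "sign") ifelse(val > 0, 1, -1) else val
    ei[idx, 1L] <- rows[k]
    ei[idx, 2L] <- seq_len(n)
  }
  list(features = feat, labels = lab, elementIndex = ei)
}

#' Build element-wise samples from a gene set
#'
#' Each matrix element (g, c) of the given gene set becomes one
#' sample whose features are gene g's values at every cell except c,
#' in matrix cell order with the sample's own cell deleted (n - 1
#' features). With \code{labelMode = "sign"} the label is +1 if the
#' element is positive and -1 if it is zero; with \code{"value"} it is
#' the element's own expression value. Samples are ordered gene-major
#' (all cells of the first gene, then the second, ...).
#'
#' @param x an [ExpressionMatrix-class] with at least 2 cells.
#' @param genes gene ids to build samples for.
#' @param labelMode \code{"sign"} or \code{"value"}.
#' @param role \code{"train"} or \code{"test"} (bookkeeping tag).
#' @return A [SampleSet-class].
#' @seealso [sampleBlockApply()] for block-wise streaming over large
#'   gene sets.
#' @export
buildSamples <- function(x, genes, labelMode = c("sign", "value"),
                         role = "train") {
  labelMode <- match.arg(labelMode)
  stopifnot(all(genes %in% geneIds(x)))
  if (ncol(x) < 2) stop("need at least 2 cells to form features")
  v <- exprValues(x)
  rows <- match(genes, geneIds(x))
  b <- .sampleBlockFor(v, rows, labelMode)
  methods::new("SampleSet", elementIndex = b$elementIndex,
               features = b$features, labels = b$labels,
               labelMode = labelMode, role = role)
}

#' Apply a function over blocks of element-wise samples
#'
#' Streams the sample construction of [buildSamples()] in gene blocks
#' so that at most \code{blockSize} genes' samples (blockSize * n
#' rows) are resident at a time; block boundaries are deterministic
#' (gene order, fixed size). Used for test sets too large to
#' materialize.
#'
#' @inheritParams buildSamples
#' @param FUN function taking a \code{SampleSet} block, called once
#'   per block; its results are returned as a list.
#' @param blockSize genes per block.
#' @return List of \code{FUN} results, one per block.
#' @export
sampleBlockApply <- function(x, genes, FUN,
                             labelMode = c("sign", "value"),
                             blockSize = 200L, role = "test") {
  labelMode <- match.arg(labelMode)
  stopifnot(all(genes %in% geneIds(x)), blockSize >= 1)
  if (ncol(x) < 2) stop("need at least 2 cells to form features")
  v <- exprValues(x)
  rows <- match(genes, geneIds(x))
  starts <- seq(1L, length(rows), by = blockSize)
  lapply(starts, function(s) {
    blk <- rows[s:min(s + blockSize - 1L, length(rows))]
    b <- .sampleBlockFor(v, blk, labelMode)
    FUN(methods::new("SampleSet", elementIndex = b$elementIndex,
                     features = b$features, labels = b$labels,
                     labelMode = labelMode, role = role))
  })
}
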