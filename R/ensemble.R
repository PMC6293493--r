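# Ensemble refinement: the classifier's positive rate over zero test
# elements defines the threshold eta; each probability-matrix detector
# contributes its top eta fraction of available zero elements; the
# detectors' candidate sets are intersected; values at the surviving
# positions are imputed with the SVR model.

#' Classifier scores over zero elements
#'
#' Evaluates the trained classifier on every element of the given
#' genes and converts decision values at zero-valued elements into
#' [0, 1] scores: the logistic transform for logistic regression, or a
#' min-max rescaling over the zero set for the SVM.
#'
#' @param model a classifier [LinearModel-class].
#' @param x an [ExpressionMatrix-class].
#' @param genes gene ids to score (the test set).
#' @return A [MissingProbabilityMatrix-class] with source \code{"llc"}.
#' @export
llcMissingProbabilities <- function(model, x, genes) {
  dec <- matrixDecisionValues(model, x, genes)
  v <- exprValues(x)
  rows <- match(genes, geneIds(x))
  zero <- as.matrix(v[rows, , drop = FALSE] == 0)
  scores <- matrix(NA_real_, nrow(x), ncol(x),
                   dimnames = list(geneIds(x), cellIds(x)))
  dz <- dec[zero]
  sz <- if (model@objective == "lr_l2") {
    stats::plogis(dz)
  } else {
    rng <- range(dz)
    if (rng[1] == rng[2]) rep(0.5, length(dz))
    else (dz - rng[1]) / (rng[2] - rng[1])
  }
  sub <- which(zero, arr.ind = TRUE)
  scores[cbind(rows[sub[, 1]], sub[, 2])] <- sz
  methods::new("MissingProbabilityMatrix", source = "llc",
               scores = scores)
}

#' Candidate positions called missing by the classifier
#'
#' The classifier's own candidate set: zero-valued elements of the
#' test genes with a strictly positive decision value.
#'
#' @inheritParams llcMissingProbabilities
#' @return A [MissingPositionSet-class] (provenance \code{"llc"}); its
#'   \code{eta} slot records the positive fraction over zero elements.
#' @export
llcCandidates <- function(model, x, genes) {
  dec <- matrixDecisionValues(model, x, genes)
  v <- exprValues(x)
  rows <- match(genes, geneIds(x))
  zero <- as.matrix(v[rows, , drop = FALSE] == 0)
  if (!any(zero)) stop("test genes contain no zero elements")
  hit <- zero & dec > 0
  sub <- which(hit, arr.ind = TRUE)
  pos <- cbind(gene = rows[sub[, 1]], cell = as.integer(sub[, 2]))
  pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
  methods::new("MissingPositionSet", positions = pos,
               geneIds = geneIds(x), cellIds = cellIds(x),
               provenance = "llc", eta = sum(hit) / sum(zero))
}

#' Missing-rate threshold eta from classifier output
#'
#' eta is the rate of positive classification over the zero elements
#' of the test set: the number of zero elements the classifier calls
#' missing divided by the number of zero elements.
#'
#' @inheritParams llcMissingProbabilities
#' @return eta in [0, 1].
#' @export
computeEta <- function(model, x, genes) {
  v <- exprValues(x)
  rows <- match(genes, geneIds(x))
  zero <- as.matrix(v[rows, , drop = FALSE] == 0)
  if (!any(zero)) stop("test genes contain no zero elements")
  dec <- matrixDecisionValues(model, x, genes)
  sum(dec[zero] > 0) / sum(zero)
}

#' @rdname computeEta
#' @param labels vector of predicted labels (+1/-1) over all
#'   zero-valued test elements.
#' @export
computeEtaFromLabels <- function(labels) {
  if (!length(labels)) stop("empty zero-element label set")
  sum(labels > 0) / length(labels)
}

#' Top-eta candidate positions of a detector
#'
#' Selects the \eqn{\lceil \eta D \rceil} highest-scoring available
#' elements, where D is the number of elements the detector scored.
#' Ties are broken by (gene index, cell index) ascending for
#' determinism.
#'
#' @param prob a [MissingProbabilityMatrix-class].
#' @param eta fraction in [0, 1].
#' @return A [MissingPositionSet-class].
#' @export
topCandidates <- function(prob, eta) {
  stopifnot(eta >= 0, eta <= 1)
  s <- prob@scores
  avail <- which(!is.na(s), arr.ind = TRUE)
  D <- nrow(avail)
  k <- ceiling(eta * D)
  if (k > 0) {
    sc <- s[avail]
    ord <- order(-sc, avail[, 1], avail[, 2])[seq_len(k)]
    pos <- avail[ord, , drop = FALSE]
    pos <- pos[order(pos[, 1], pos[, 2]), , drop = FALSE]
  } else {
    pos <- matrix(integer(), 0, 2)
  }
  dimnames(pos) <- list(NULL, c("gene", "cell"))
  methods::new("MissingPositionSet", positions = pos,
               geneIds = rownames(s), cellIds = colnames(s),
               provenance = prob@source, eta = eta)
}

#' Intersect detectors' missing-position sets
#'
#' Strict set intersection of two or three candidate sets over the
#' same matrix; the provenance records all contributors.
#'
#' @param ... two or three [MissingPositionSet-class] objects (or one
#'   list of them).
#' @return A [MissingPositionSet-class].
#' @export
intersectMissing <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !methods::is(sets[[1]], "MissingPositionSet"))
    sets <- sets[[1]]
  if (length(sets) < 2)
    stop("need at least 2 candidate sets to intersect")
  ng <- length(sets[[1]]@geneIds)
  key <- function(s) s@positions[, 1] + (s@positions[, 2] - 1) * ng
  common <- Reduce(intersect, lapply(sets, key))
  common <- sort(common)
  pos <- cbind(gene = as.integer((common - 1) %% ng + 1),
               cell = as.integer((common - 1) %/% ng + 1))
  methods::new("MissingPositionSet", positions = pos,
               geneIds = sets[[1]]@geneIds, cellIds = sets[[1]]@cellIds,
               provenance = unlist(lapply(sets, methods::slot,
                                          "provenance")),
               eta = sets[[1]]@eta)
}

#' Missing rate of a position set
#'
#' Number of missing positions divided by the total number of matrix
#' elements (the full genes x cells matrix is the denominator).
#'
#' @param set a [MissingPositionSet-class].
#' @return Fraction in [0, 1].
#' @export
missingRate <- function(set) {
  nrow(set@positions) /
    (length(set@geneIds) * length(set@cellIds))
}

#' Impute values at refined missing positions with the SVR model
#'
#' Every missing position must be zero-valued in the input (corruption
#' guard). The imputed value is the SVR prediction on the element's
#' feature vector (the gene's values at all other cells), clamped at
#' zero; all other elements are returned unchanged. The imputation
#' report (gene, cell, imputed value) is stored in
#' \code{metadata(result)$imputationReport}.
#'
#' @param x an [ExpressionMatrix-class].
#' @param missing a [MissingPositionSet-class].
#' @param model a trained SVR [LinearModel-class] in the same unit as
#'   the matrix.
#' @return A new \code{ExpressionMatrix} with imputed values.
#' @export
imputeExpression <- function(x, missing, model) {
  pos <- missing@positions
  v <- exprValues(x)
  if (nrow(pos)) {
    if (any(v[pos] != 0))
      stop("missing position with nonzero observed value: ",
           "refusing to overwrite data")
    genes <- geneIds(x)[sort(unique(pos[, 1]))]
    dec <- matrixDecisionValues(model, x, genes)
    pred <- pmax(0, dec[cbind(match(geneIds(x)[pos[, 1]], genes),
                              pos[, 2])])
    v <- as(v, "matrix")
    v[pos] <- pred
  } else pred <- numeric()
  out <- ExpressionMatrix(v, unit = exprUnit(x),
                          geneIds = geneIds(x), cellIds = cellIds(x))
  S4Vectors::metadata(out)$imputationReport <- data.frame(
    gene_id = geneIds(x)[pos[, 1]], cell_id = cellIds(x)[pos[, 2]],
    imputed_value = pred, stringsAsFactors = FALSE)
  out
}
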