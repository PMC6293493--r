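#' @import methods
#' @importFrom Matrix Matrix readMM writeMM t colSums rowSums
#' @importFrom S4Vectors metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#' @importFrom stats dnbinom dpois rnbinom rpois runif rnorm plogis qlogis
#'   glm binomial coef optim optimize setNames sd
#' @importFrom utils read.table write.table head
NULL

.VALID_UNITS <- c("counts", "umi", "rpkm", "unknown")

#' Genes-by-cells expression matrix
#'
#' An \code{ExpressionMatrix} is a thin extension of
#' \linkS4class{SummarizedExperiment} holding one assay named
#' \code{"expr"}: a genes (rows) by cells (columns) matrix of
#' non-negative expression values (counts, UMIs or RPKM), with unique
#' gene and cell identifiers as dimnames and a unit tag in
#' \code{metadata(x)$unit}. The unit tag is metadata only: no operation
#' renormalizes silently.
#'
#' @slot .
#'   Inherits all slots from \code{SummarizedExperiment}.
#' @seealso [readExpressionMatrix()], [rpkmNormalize()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'expr' is required")
  v <- SummarizedExperiment::assay(object, "expr")
  gid <- rownames(object)
  cid <- colnames(object)
  if (is.null(gid) || is.null(cid))
    msg <- c(msg, "gene and cell identifiers (dimnames) are required")
  if (!is.null(gid) && anyDuplicated(gid))
    msg <- c(msg, "duplicate gene identifiers")
  if (!is.null(cid) && anyDuplicated(cid))
    msg <- c(msg, "duplicate cell identifiers")
  x <- if (methods::is(v, "nMatrix")) numeric()
       else if (methods::is(v, "sparseMatrix")) v@x else v
  if (anyNA(x)) msg <- c(msg, "values contain NA/NaN")
  else if (length(x) && min(x) < 0) msg <- c(msg, "negative expression values")
  unit <- S4Vectors::metadata(object)$unit
  if (is.null(unit) || !unit %in% .VALID_UNITS)
    msg <- c(msg, sprintf("unit must be one of %s",
                          paste(.VALID_UNITS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values genes x cells matrix (base or \pkg{Matrix} sparse) of
#'   non-negative values; must carry unique row (gene) and column
#'   (cell) names, or they can be supplied via \code{geneIds}/\code{cellIds}.
#' @param unit expression unit tag, one of \code{"counts"}, \code{"umi"},
#'   \code{"rpkm"}, \code{"unknown"}.
#' @param geneIds,cellIds optional identifier vectors overriding the
#'   dimnames of \code{values}.
#' @return An \code{ExpressionMatrix}.
#' @examples
#' m <- matrix(rpois(12, 3), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' em <- ExpressionMatrix(m, unit = "counts")
#' dim(em)
#' @export
ExpressionMatrix <- function(values, unit = "unknown",
                             geneIds = NULL, cellIds = NULL) {
  if (!is.null(geneIds)) rownames(values) <- geneIds
  if (!is.null(cellIds)) colnames(values) <- cellIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = values), metadata = list(unit = unit))
  methods::new("ExpressionMatrix", se)
}

#' Element-wise sample set for classification or regression
#'
#' One sample per (gene, cell) matrix element. The features of the
#' sample at element (g, c) are gene g's expression values at all cells
#' except c, in matrix cell order with the sample's own cell deleted,
#' so every sample has n - 1 features for n cells. Labels are either
#' the sign of the element (+1 if > 0, else -1) or the element's own
#' expression value.
#'
#' @slot elementIndex integer matrix, one row per sample, columns
#'   \code{gene} and \code{cell} (1-based row/column of the source matrix).
#' @slot features numeric matrix, samples x (n - 1).
#' @slot labels numeric vector, \{-1, +1\} for \code{labelMode = "sign"},
#'   non-negative reals for \code{"value"}.
#' @slot labelMode \code{"sign"} or \code{"value"}.
#' @slot role \code{"train"} or \code{"test"}.
#' @export
setClass("SampleSet",
  representation(elementIndex = "matrix", features = "matrix",
                 labels = "numeric", labelMode = "character",
                 role = "character"))

setValidity("SampleSet", function(object) {
  msg <- character()
  ns <- nrow(object@features)
  if (nrow(object@elementIndex) != ns || length(object@labels) != ns)
    msg <- c(msg, "elementIndex, features and labels must agree in length")
  if (!object@labelMode %in% c("sign", "value"))
    msg <- c(msg, "labelMode must be 'sign' or 'value'")
  if (object@labelMode == "sign" && ns &&
      !all(object@labels %in% c(-1, 1)))
    msg <- c(msg, "sign labels must be -1/+1")
  if (length(msg)) msg else TRUE
})

#' Fitted linear model (classifier or support vector regressor)
#'
#' @slot weights numeric weight vector (feature space, excluding bias).
#' @slot bias numeric scalar bias term (0 when trained without bias).
#' @slot objective one of \code{"lr_l2"}, \code{"svm_l2_l2loss"},
#'   \code{"svr_l1loss"}, \code{"svr_l2loss"}.
#' @slot C positive penalty parameter.
#' @slot epsilon SVR sensitivity (>= 0); 0 for classifiers.
#' @slot p SVR loss exponent, 1 or 2; NA for classifiers.
#' @slot solverInfo list with \code{iterations}, \code{objective}
#'   (final value), \code{tol}, \code{converged}, \code{formulation}.
#' @export
setClass("LinearModel",
  representation(weights = "numeric", bias = "numeric",
                 objective = "character", C = "numeric",
                 epsilon = "numeric", p = "numeric",
                 solverInfo = "list"))

setValidity("LinearModel", function(object) {
  msg <- character()
  if (!object@objective %in%
      c("lr_l2", "svm_l2_l2loss", "svr_l1loss", "svr_l2loss"))
    msg <- c(msg, "unknown objective")
  if (object@C <= 0) msg <- c(msg, "C must be > 0")
  if (object@epsilon < 0) msg <- c(msg, "epsilon must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Per-element missing-probability matrix from one detector
#'
#' Scores in [0, 1], defined only at zero-valued elements of the
#' observed matrix; \code{NA} marks elements where the detector has no
#' coverage (availability mask).
#'
#' @slot source detector tag: \code{"llc"}, \code{"zim"} or \code{"fnc"}.
#' @slot scores numeric genes x cells matrix with \code{NA} at
#'   unavailable elements; dimnames are the gene/cell identifiers.
#' @export
setClass("MissingProbabilityMatrix",
  representation(source = "character", scores = "matrix"))

setValidity("MissingProbabilityMatrix", function(object) {
  msg <- character()
  if (!object@source %in% c("llc", "zim", "fnc"))
    msg <- c(msg, "source must be llc, zim or fnc")
  x <- object@scores[!is.na(object@scores)]
  if (length(x) && (min(x) < 0 || max(x) > 1))
    msg <- c(msg, "scores must lie in [0, 1]")
  if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
    msg <- c(msg, "scores must carry gene/cell dimnames")
  if (length(msg)) msg else TRUE
})

#' Refined set of (gene, cell) positions declared missing
#'
#' @slot positions integer matrix with columns \code{gene}, \code{cell}
#'   (1-based indices into the observed matrix).
#' @slot geneIds,cellIds identifier axes of the matrix the positions
#'   refer to.
#' @slot provenance character vector of contributing detectors.
#' @slot eta threshold fraction used to pick candidates.
#' @export
setClass("MissingPositionSet",
  representation(positions = "matrix", geneIds = "character",
                 cellIds = "character", provenance = "character",
                 eta = "numeric"))

setValidity("MissingPositionSet", function(object) {
  msg <- character()
  p <- object@positions
  if (ncol(p) != 2) msg <- c(msg, "positions must have two columns")
  if (nrow(p)) {
    if (min(p) < 1 || max(p[, 1]) > length(object@geneIds) ||
        max(p[, 2]) > length(object@cellIds))
      msg <- c(msg, "positions out of matrix range")
  }
  if (length(msg)) msg else TRUE
})

#' Seeded synthetic dataset with ground-truth dropout mask
#'
#' @slot truth true (pre-dropout) \code{ExpressionMatrix}.
#' @slot observed observed matrix after per-cell dropout and Poisson
#'   background.
#' @slot mask integer matrix (\code{gene}, \code{cell}) of positions
#'   zeroed by dropout; every mask position has positive truth.
#' @slot housekeeping identifiers of the near-ubiquitously detected
#'   gene subset.
#' @slot groups named character vector: cell id -> subpopulation label.
#' @slot ordering cell identifiers in trajectory order.
#' @slot config the generating configuration (list, including seed).
#' @export
setClass("SyntheticDataset",
  representation(truth = "ExpressionMatrix", observed = "ExpressionMatrix",
                 mask = "matrix", housekeeping = "character",
                 groups = "character", ordering = "character",
                 config = "list"))
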