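# False-negative-curve detector. Each cell gets a logistic detection
# curve F_c(mu) fitted on housekeeping genes: the response is the
# detection indicator (observed value > 0), the covariate is
# log(mu*), where mu* is the gene's expected expression conditioned
# on detection (mean of its nonzero values). The missing probability
# of a zero element is then 1 - F_c(mu*_g).

#' Expected expression conditioned on detection
#'
#' For every requested gene, mu* is the mean of the gene's nonzero
#' values across all cells. Genes with no nonzero observation have no
#' defined mu* and are returned as NA with a warning.
#'
#' @param x an [ExpressionMatrix-class].
#' @param genes gene ids (default: all matrix genes).
#' @return Named numeric vector of mu* values (NA where undefined).
#' @export
expectedExpression <- function(x, genes = geneIds(x)) {
  rows <- match(genes, geneIds(x))
  stopifnot(!anyNA(rows))
  v <- exprValues(x)
  sums <- Matrix::rowSums(v)[rows]
  nnz <- Matrix::rowSums(v > 0)[rows]
  mu <- ifelse(nnz > 0, sums / nnz, NA_real_)
  if (anyNA(mu))
    warning(sum(is.na(mu)), " all-zero gene(s) excluded: mu* undefined")
  setNames(as.numeric(mu), genes)
}

#' Fit per-cell detection-efficiency curves
#'
#' For each cell, logistic regression of the housekeeping detection
#' indicator on log(mu*). Cells where all usable housekeeping genes
#' are detected (or none are), or with fewer than 5 usable genes, or
#' where the fit separates perfectly, get a degenerate constant curve:
#' detection probability equal to the observed detection rate clipped
#' to [0.01, 0.99] (slope 0).
#'
#' @param x an [ExpressionMatrix-class].
#' @param housekeeping housekeeping gene ids present in the matrix.
#' @param muStar named mu* vector from [expectedExpression()]; computed
#'   from the housekeeping genes if missing.
#' @return data.frame with one row per cell: \code{cell},
#'   \code{intercept}, \code{slope}, \code{nPoints}, \code{degenerate}.
#' @export
fitDetectionCurves <- function(x, housekeeping, muStar = NULL) {
  hk <- intersect(housekeeping, geneIds(x))
  if (!length(hk)) stop("no housekeeping gene occurs in the matrix")
  if (is.null(muStar)) muStar <- expectedExpression(x, hk)
  usable <- hk[!is.na(muStar[hk]) & muStar[hk] > 0]
  v <- exprValues(x)
  rows <- match(usable, geneIds(x))
  lmu <- log(muStar[usable])
  res <- data.frame(cell = cellIds(x), intercept = NA_real_,
                    slope = NA_real_, nPoints = length(usable),
                    degenerate = FALSE, stringsAsFactors = FALSE)
  degen <- function(rate) {
    p <- min(max(rate, 0.01), 0.99)
    c(stats::qlogis(p), 0)
  }
  for (j in seq_len(ncol(x))) {
    d <- as.numeric(v[rows, j] > 0)
    if (length(usable) < 5L) {
      warning("cell '", cellIds(x)[j], "': fewer than 5 usable ",
              "housekeeping genes; degenerate curve")
      ab <- degen(mean(d)); res$degenerate[j] <- TRUE
    } else if (all(d == 1) || all(d == 0)) {
      ab <- degen(mean(d)); res$degenerate[j] <- TRUE
    } else {
      fit <- NULL
      separated <- FALSE
      withCallingHandlers(
        fit <- stats::glm(d ~ lmu, family = stats::binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w)))
            separated <<- TRUE
          invokeRestart("muffleWarning")
        })
      if (separated || !fit$converged) {
        ab <- degen(mean(d)); res$degenerate[j] <- TRUE
      } else ab <- as.numeric(stats::coef(fit))
    }
    res$intercept[j] <- ab[1]
    res$slope[j] <- ab[2]
  }
  res
}

#' Missing probabilities from false-negative curves
#'
#' For every zero-valued element (g, c) whose mu* is defined, the
#' missing probability is \eqn{1 - logistic(a_c + b_c \log \mu^*_g)};
#' nonzero elements and genes with undefined mu* are unavailable (NA).
#' mu* must be computed over the target genes (typically all genes),
#' not just the housekeeping set used to fit the curves.
#'
#' @param x an [ExpressionMatrix-class].
#' @param curves per-cell curve data.frame from [fitDetectionCurves()].
#' @param muStar named mu* vector covering the target genes.
#' @return A [MissingProbabilityMatrix-class] with source \code{"fnc"}.
#' @export
fncMissingProbabilities <- function(x, curves, muStar) {
  stopifnot(nrow(curves) == ncol(x))
  genes <- intersect(names(muStar)[!is.na(muStar) & muStar > 0],
                     geneIds(x))
  rows <- match(genes, geneIds(x))
  lmu <- log(muStar[genes])
  v <- exprValues(x)
  scores <- matrix(NA_real_, nrow(x), ncol(x),
                   dimnames = list(geneIds(x), cellIds(x)))
  for (j in seq_len(ncol(x))) {
    pm <- 1 - stats::plogis(curves$intercept[j] + curves$slope[j] * lmu)
    zero <- as.numeric(v[rows, j]) == 0
    scores[rows[zero], j] <- pm[zero]
  }
  methods::new("MissingProbabilityMatrix", source = "fnc",
               scores = scores)
}
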