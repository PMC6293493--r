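#' Mean-smoothing baseline along a cell ordering
#'
#' The comparison method: at each supplied missing position (g, c),
#' the value is replaced by the mean of gene g's expression in the up
#' to \code{gamma} preceding and up to \code{gamma} following cells
#' along the given trajectory ordering (the window is truncated at the
#' trajectory ends, so its effective size lies in [gamma, 2 gamma]).
#' Window values include zeros of neighboring cells unless
#' \code{excludeZeros} is set. All other elements are unchanged.
#'
#' @param x an [ExpressionMatrix-class].
#' @param ordering character vector of cell ids: a permutation of the
#'   matrix cells in trajectory order.
#' @param positions a [MissingPositionSet-class], or \code{"all"} to
#'   smooth every zero element.
#' @param gamma window half-width in cells (default 3).
#' @param excludeZeros drop zero-valued neighbors from the window mean
#'   (an empty window imputes 0).
#' @return A new \code{ExpressionMatrix}.
#' @export
meanSmoothImpute <- function(x, ordering, positions, gamma = 3L,
                             excludeZeros = FALSE) {
  stopifnot(gamma >= 1)
  cid <- cellIds(x)
  if (!setequal(ordering, cid) || length(ordering) != length(cid))
    stop("ordering must be a permutation of the matrix cells; ",
         "absent cell(s): ",
         paste(utils::head(setdiff(cid, ordering), 5), collapse = ", "))
  if (identical(positions, "all")) {
    pos <- zeroPositions(x)
  } else {
    pos <- positions@positions
  }
  v <- as.matrix(exprValues(x))
  rank <- match(cid, ordering)        # cell column -> trajectory position
  colOfRank <- match(ordering, cid)   # trajectory position -> cell column
  n <- length(cid)
  out <- v
  for (k in seq_len(nrow(pos))) {
    g <- pos[k, 1]; cc <- pos[k, 2]
    r <- rank[cc]
    win <- setdiff(max(1, r - gamma):min(n, r + gamma), r)
    vals <- v[g, colOfRank[win]]
    if (excludeZeros) vals <- vals[vals > 0]
    out[g, cc] <- if (length(vals)) mean(vals) else 0
  }
  ExpressionMatrix(out, unit = exprUnit(x), geneIds = geneIds(x),
                   cellIds = cid)
}
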