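# Zero-inflated mixture detector. For a pair of cells, each gene's
# counts (r_i, r_j) are modeled as a three-component mixture:
#   dropout in c_i : r_i ~ Poisson(lambda0), r_j ~ NB
#   amplified      : r_i ~ NB, r_j ~ NB
#   dropout in c_j : r_i ~ NB, r_j ~ Poisson(lambda0)
# NB means come from a pair-level expected magnitude (the mean of the
# pair's library-size-normalized positive counts, i.e. the counterpart
# cell's scaled count when one side is zero) with a single shared
# dispersion. The mixing weights are a softmax in the covariate
# m = log(r_i + 1) + log(r_j + 1) (pseudocount 1 since zero counts are
# the object of interest), fitted by EM.

.softmaxPi <- function(coef, m) {
  # coef = (a1, b1, a3, b3); class 2 (amplified) is the reference
  e1 <- coef[1] + coef[2] * m
  e3 <- coef[3] + coef[4] * m
  mx <- pmax(e1, 0, e3)
  z1 <- exp(e1 - mx); z2 <- exp(-mx); z3 <- exp(e3 - mx)
  tot <- z1 + z2 + z3
  cbind(z1 / tot, z2 / tot, z3 / tot)
}

.logSoftmaxPi <- function(coef, m) {
  e1 <- coef[1] + coef[2] * m
  e3 <- coef[3] + coef[4] * m
  mx <- pmax(e1, 0, e3)
  lse <- mx + log(exp(e1 - mx) + exp(-mx) + exp(e3 - mx))
  cbind(e1 - lse, -lse, e3 - lse)
}

.rowLogSumExp <- function(L) {
  mx <- pmax(L[, 1], L[, 2], L[, 3])
  mx + log(exp(L[, 1] - mx) + exp(L[, 2] - mx) + exp(L[, 3] - mx))
}

#' Fit the zero-inflated mixture to one cell pair
#'
#' Runs EM until the relative log-likelihood change drops below
#' \code{tol} or \code{maxIter} is reached. The M-step updates the
#' mixing softmax (weighted multinomial logistic regression on the
#' mixing covariate) and, periodically, the shared NB dispersion by
#' exact coordinate maximization; both updates are guarded to never
#' decrease the expected complete-data log-likelihood, so the
#' log-likelihood trace is monotone non-decreasing.
#'
#' @param x an [ExpressionMatrix-class] with count-like unit.
#' @param cellI,cellJ cell ids or 1-based column indices.
#' @param lambda0 Poisson background rate of the dropout component
#'   (default 0.1).
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter maximum EM iterations.
#' @return A \code{"PairMixtureFit"} list: \code{cellI}, \code{cellJ},
#'   \code{genes} (row indices of evaluated genes, those expressed in
#'   at least one of the two cells), \code{geneIds},
#'   \code{posteriors} (genes x 3, columns \code{dropout_i},
#'   \code{amplified}, \code{dropout_j}, rows summing to 1),
#'   \code{mixingCoef}, \code{theta}, \code{lambda0},
#'   \code{loglikTrace}.
#' @export
fitPairMixture <- function(x, cellI, cellJ, lambda0 = 0.1,
                           tol = 1e-6, maxIter = 100L) {
  v <- exprValues(x)
  ci <- if (is.character(cellI)) match(cellI, cellIds(x)) else cellI
  cj <- if (is.character(cellJ)) match(cellJ, cellIds(x)) else cellJ
  stopifnot(!is.na(ci), !is.na(cj), ci != cj)
  riAll <- as.numeric(v[, ci])
  rjAll <- as.numeric(v[, cj])
  if (any(riAll != round(riAll)) || any(rjAll != round(rjAll))) {
    warning("non-integer counts rounded for the mixture fit")
    riAll <- round(riAll); rjAll <- round(rjAll)
  }
  if (all(riAll == 0))
    stop("degenerate pair: cell '", cellIds(x)[ci], "' has no nonzero gene")
  if (all(rjAll == 0))
    stop("degenerate pair: cell '", cellIds(x)[cj], "' has no nonzero gene")
  keep <- which(riAll + rjAll > 0)
  ri <- riAll[keep]; rj <- rjAll[keep]
  si <- sum(riAll); sj <- sum(rjAll)
  g <- sqrt(si * sj)
  fi <- si / g; fj <- sj / g
  den <- (ri > 0) + (rj > 0)
  e <- (ri / fi + rj / fj) / den  # normalized positive-count mean
  mui <- pmax(e * fi, 1e-8)
  muj <- pmax(e * fj, 1e-8)
  m <- log(ri + 1) + log(rj + 1)
  ldPi <- stats::dpois(ri, lambda0, log = TRUE)
  ldPj <- stats::dpois(rj, lambda0, log = TRUE)
  nbLogLik <- function(theta)
    cbind(i = stats::dnbinom(ri, size = theta, mu = mui, log = TRUE),
          j = stats::dnbinom(rj, size = theta, mu = muj, log = TRUE))
  compLog <- function(nb)
    cbind(ldPi + nb[, "j"], nb[, "i"] + nb[, "j"], nb[, "i"] + ldPj)
  qTheta <- function(theta, gam, idx = TRUE) {
    nbi <- stats::dnbinom(ri[idx], size = theta, mu = mui[idx], log = TRUE)
    nbj <- stats::dnbinom(rj[idx], size = theta, mu = muj[idx], log = TRUE)
    g <- gam[idx, , drop = FALSE]
    sum(g[, 1] * nbj + g[, 2] * (nbi + nbj) + g[, 3] * nbi)
  }
  # dispersion is located on a deterministic gene subsample, then the
  # candidate is accepted only if it improves the full-data Q (keeps
  # the EM trace monotone)
  thetaSub <- if (length(ri) > 600)
    seq(1L, length(ri), by = ceiling(length(ri) / 600)) else TRUE
  maxQTheta <- function(gam, cur) {
    op <- stats::optimize(function(lt) -qTheta(exp(lt), gam, thetaSub),
                          interval = c(log(0.02), log(500)), tol = 1e-2)
    cand <- exp(op$minimum)
    if (qTheta(cand, gam) >= qTheta(cur, gam)) cand else cur
  }
  qMix <- function(coef, gam) sum(gam * .logSoftmaxPi(coef, m))
  qMixGrad <- function(coef, gam) {
    pi <- .softmaxPi(coef, m)
    d1 <- gam[, 1] - pi[, 1]
    d3 <- gam[, 3] - pi[, 3]
    c(sum(d1), sum(d1 * m), sum(d3), sum(d3 * m))
  }
  maxQMix <- function(gam, cur) {
    op <- stats::optim(cur, function(cf) -qMix(cf, gam),
                       function(cf) -qMixGrad(cf, gam),
                       method = "BFGS", control = list(maxit = 8))
    if (qMix(op$par, gam) >= qMix(cur, gam)) op$par else cur
  }
  # initialization: hard assignment, count < 1 goes to its dropout side
  gam <- matrix(0, length(ri), 3)
  cls <- ifelse(ri < 1, 1L, ifelse(rj < 1, 3L, 2L))
  gam[cbind(seq_along(cls), cls)] <- 1
  theta <- maxQTheta(gam, 2)
  coef <- maxQMix(gam, c(0, 0, 0, 0))
  ll <- -Inf
  trace <- numeric()
  for (iter in seq_len(maxIter)) {
    L <- compLog(nbLogLik(theta)) + .logSoftmaxPi(coef, m)
    lse <- .rowLogSumExp(L)
    gam <- exp(L - lse)
    newLL <- sum(lse)
    trace <- c(trace, newLL)
    if (is.finite(ll) && abs(newLL - ll) <= tol * (abs(newLL) + 1)) break
    ll <- newLL
    coef <- maxQMix(gam, coef)
    if (iter <= 3L || iter %% 5L == 0L) theta <- maxQTheta(gam, theta)
  }
  colnames(gam) <- c("dropout_i", "amplified", "dropout_j")
  structure(list(cellI = ci, cellJ = cj, genes = keep,
                 geneIds = geneIds(x)[keep], posteriors = gam,
                 mixingCoef = coef, theta = theta, lambda0 = lambda0,
                 loglikTrace = trace),
            class = "PairMixtureFit")
}

#' Select genes assigned to the amplified component
#'
#' A gene is retained when its posterior argmax is the amplified
#' component in at least \code{threshold} of the pair fits where it was
#' evaluable.
#'
#' @param fits list of \code{"PairMixtureFit"} objects from one
#'   subpopulation.
#' @param threshold minimum amplified fraction (default 0.2).
#' @return Character vector of amplified gene ids.
#' @export
selectAmplifiedGenes <- function(fits, threshold = 0.2) {
  stopifnot(length(fits) >= 1)
  allIds <- unique(unlist(lapply(fits, `[[`, "geneIds")))
  evaluable <- setNames(numeric(length(allIds)), allIds)
  amplified <- evaluable
  for (f in fits) {
    isAmp <- max.col(f$posteriors, ties.method = "first") == 2L
    evaluable[f$geneIds] <- evaluable[f$geneIds] + 1
    amplified[f$geneIds] <- amplified[f$geneIds] + isAmp
  }
  names(evaluable)[amplified / evaluable >= threshold]
}

#' Per-element dropout probabilities from the zero-inflated mixture
#'
#' Fits the pair mixture within each subpopulation over all cell
#' pairs, or a seeded random sample of \code{pairBudget} pairs when
#' the full set is larger. The dropout probability of a zero element
#' (g, c) is the mean, over all fitted pairs involving c, of the
#' posterior of the dropout-in-c component for gene g, restricted to
#' genes in the subpopulation's amplified set; other elements are
#' unavailable (NA).
#'
#' @inheritParams fitPairMixture
#' @param groups named character vector (cell id -> subpopulation
#'   label) covering every cell, or NULL to treat all cells as one
#'   group.
#' @param threshold amplified-set fraction passed to
#'   [selectAmplifiedGenes()].
#' @param pairBudget maximum pairs fitted per subpopulation
#'   (\code{Inf} enumerates all pairs).
#' @param seed seed for pair subsampling.
#' @param force fit even if the unit is \code{"rpkm"} (the mixture
#'   assumes count-like data).
#' @return List with \code{probability} (a
#'   [MissingProbabilityMatrix-class], source \code{"zim"}),
#'   \code{amplifiedGenes} (per-group list), \code{nPairs} (per-group
#'   fitted pair counts).
#' @export
zimMissingProbabilities <- function(x, groups = NULL, lambda0 = 0.1,
                                    threshold = 0.2, pairBudget = 100L,
                                    seed = 1L, force = FALSE,
                                    tol = 1e-6, maxIter = 100L) {
  if (exprUnit(x) == "rpkm" && !force)
    stop("the zero-inflated mixture requires count-like data ",
         "(unit is 'rpkm'); use force = TRUE to override")
  cid <- cellIds(x)
  if (is.null(groups)) {
    groups <- setNames(rep("all", length(cid)), cid)
  } else {
    missing <- setdiff(cid, names(groups))
    if (length(missing))
      stop("no subpopulation label for cell(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
  }
  v <- exprValues(x)
  scores <- matrix(NA_real_, nrow(x), ncol(x),
                   dimnames = list(geneIds(x), cid))
  sumP <- matrix(0, nrow(x), ncol(x))
  cntP <- matrix(0, nrow(x), ncol(x))
  ampGenes <- list(); nPairs <- list()
  set.seed(seed)
  for (grp in unique(groups[cid])) {
    cells <- which(groups[cid] == grp)
    if (length(cells) < 2)
      stop("subpopulation '", grp, "' has fewer than 2 cells")
    prs <- utils::combn(cells, 2)
    if (ncol(prs) > pairBudget)
      prs <- prs[, sample.int(ncol(prs), pairBudget), drop = FALSE]
    fits <- vector("list", ncol(prs))
    for (k in seq_len(ncol(prs))) {
      f <- fitPairMixture(x, prs[1, k], prs[2, k], lambda0 = lambda0,
                          tol = tol, maxIter = maxIter)
      fits[[k]] <- f
      sumP[cbind(f$genes, f$cellI)] <-
        sumP[cbind(f$genes, f$cellI)] + f$posteriors[, "dropout_i"]
      cntP[cbind(f$genes, f$cellI)] <- cntP[cbind(f$genes, f$cellI)] + 1
      sumP[cbind(f$genes, f$cellJ)] <-
        sumP[cbind(f$genes, f$cellJ)] + f$posteriors[, "dropout_j"]
      cntP[cbind(f$genes, f$cellJ)] <- cntP[cbind(f$genes, f$cellJ)] + 1
    }
    ampGenes[[grp]] <- selectAmplifiedGenes(fits, threshold)
    nPairs[[grp]] <- ncol(prs)
    ampRows <- match(ampGenes[[grp]], geneIds(x))
    for (cc in cells) {
      zeroRows <- ampRows[v[ampRows, cc] == 0]
      zeroRows <- zeroRows[cntP[zeroRows, cc] > 0]
      scores[zeroRows, cc] <- sumP[zeroRows, cc] / cntP[zeroRows, cc]
    }
  }
  prob <- methods::new("MissingProbabilityMatrix", source = "zim",
                       scores = pmin(pmax(scores, 0), 1))
  list(probability = prob, amplifiedGenes = ampGenes, nPairs = nPairs)
}
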