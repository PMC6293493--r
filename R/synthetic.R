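# Seeded synthetic genes x cells datasets with a ground-truth dropout
# mask. True expression is negative binomial with gene-specific
# log-uniform means (plus group-specific shifts for a subset of
# genes); each element is then observed through a per-cell logistic
# detection-efficiency model increasing in log true expression;
# dropped entries are replaced by a low-magnitude Poisson background.
# Housekeeping genes are drawn from the top of the mean range and get
# a detection-efficiency offset, making them near-ubiquitously
# detected.

#' Synthetic dataset configuration
#'
#' Defaults describe the study conditions used throughout the test
#' suite: 2,000 genes by 300 cells in 3 subpopulations with roughly
#' 30\% of elements dropped out.
#'
#' @param nGenes,nCells,nHousekeeping dimensions; housekeeping genes
#'   are a subset of the genes.
#' @param nbMeanLogRange range of gene mean log-expression (natural
#'   log); means are log-uniform.
#' @param nbDispersion shared NB dispersion (size) of true expression.
#' @param dropoutIntercept,dropoutSlope per-cell logistic
#'   detection-efficiency parameters on log true expression
#'   (detection probability = plogis(intercept + slope * log x));
#'   cells get individual intercepts jittered by \code{cellInterceptSd}.
#' @param cellInterceptSd SD of per-cell intercept jitter.
#' @param hkDetectOffset extra detection-efficiency logit offset for
#'   housekeeping genes (near-ubiquitous detection by construction).
#' @param lambda0 Poisson background rate at dropped-out entries.
#' @param groupCount number of cell subpopulations.
#' @param groupEffectSd SD of group-specific log-mean shifts applied
#'   to \code{deGeneFraction} of the non-housekeeping genes.
#' @param deGeneFraction fraction of non-housekeeping genes with
#'   group-specific expression.
#' @param seed integer seed; every draw derives from it.
#' @return Validated config list.
#' @export
syntheticConfig <- function(nGenes = 2000L, nCells = 300L,
                            nHousekeeping = 100L,
                            nbMeanLogRange = c(log(2), log(200)),
                            nbDispersion = 2,
                            dropoutIntercept = -0.87,
                            dropoutSlope = 0.6,
                            cellInterceptSd = 0.3,
                            hkDetectOffset = 1.5,
                            lambda0 = 0.1,
                            groupCount = 3L,
                            groupEffectSd = 0.7,
                            deGeneFraction = 0.3,
                            seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), nCells = as.integer(nCells),
              nHousekeeping = as.integer(nHousekeeping),
              nbMeanLogRange = nbMeanLogRange,
              nbDispersion = nbDispersion,
              dropoutIntercept = dropoutIntercept,
              dropoutSlope = dropoutSlope,
              cellInterceptSd = cellInterceptSd,
              hkDetectOffset = hkDetectOffset, lambda0 = lambda0,
              groupCount = as.integer(groupCount),
              groupEffectSd = groupEffectSd,
              deGeneFraction = deGeneFraction, seed = as.integer(seed))
  with(cfg, {
    if (nGenes < 2 || nCells < 2) stop("need at least 2 genes and 2 cells")
    if (nHousekeeping >= nGenes)
      stop("nHousekeeping must be smaller than nGenes")
    if (nHousekeeping < 1 || groupCount < 1) stop("counts must be positive")
    if (nCells < 2 * groupCount)
      stop("need at least 2 cells per subpopulation")
    if (nbDispersion <= 0 || lambda0 < 0) stop("invalid expression law")
    if (length(nbMeanLogRange) != 2 ||
        nbMeanLogRange[2] <= nbMeanLogRange[1])
      stop("nbMeanLogRange must be an increasing range")
  })
  cfg
}

#' Generate a synthetic dataset with known dropout mask
#'
#' Fully reproducible per seed; per-stage sub-seeds are derived from
#' the main seed so the stages' draws are independent streams.
#'
#' @param config list from [syntheticConfig()].
#' @return A [SyntheticDataset-class].
#' @export
generateSyntheticData <- function(config = syntheticConfig()) {
  cfg <- do.call(syntheticConfig,
                 config[intersect(names(config),
                                  names(formals(syntheticConfig)))])
  set.seed(cfg$seed)
  stageSeeds <- sample.int(.Machine$integer.max - 1L, 4L)

  # stage 1: gene means, housekeeping set, groups, ordering
  set.seed(stageSeeds[1])
  gid <- sprintf("gene%04d", seq_len(cfg$nGenes))
  cid <- sprintf("cell%03d", seq_len(cfg$nCells))
  lo <- cfg$nbMeanLogRange[1]; hi <- cfg$nbMeanLogRange[2]
  logMean <- stats::runif(cfg$nGenes, lo, hi)
  hkIdx <- sort(sample.int(cfg$nGenes, cfg$nHousekeeping))
  logMean[hkIdx] <- stats::runif(cfg$nHousekeeping,
                                 hi - 0.25 * (hi - lo), hi)
  grp <- sort(rep_len(seq_len(cfg$groupCount), cfg$nCells))
  grpNames <- paste0("group", grp)
  deIdx <- setdiff(seq_len(cfg$nGenes), hkIdx)
  deIdx <- sort(sample(deIdx, round(length(deIdx) * cfg$deGeneFraction)))
  shift <- matrix(0, cfg$nGenes, cfg$groupCount)
  shift[deIdx, ] <- stats::rnorm(length(deIdx) * cfg$groupCount,
                                 0, cfg$groupEffectSd)
  cellInt <- cfg$dropoutIntercept +
    stats::rnorm(cfg$nCells, 0, cfg$cellInterceptSd)
  ordering <- cid[order(grp, stats::runif(cfg$nCells))]

  # stage 2: true expression
  set.seed(stageSeeds[2])
  mu <- exp(outer(logMean, rep(1, cfg$nCells)) +
              shift[, grp, drop = FALSE])
  truth <- matrix(stats::rnbinom(length(mu), size = cfg$nbDispersion,
                                 mu = mu),
                  cfg$nGenes, cfg$nCells, dimnames = list(gid, cid))

  # stage 3: per-cell detection efficiency
  set.seed(stageSeeds[3])
  isHK <- seq_len(cfg$nGenes) %in% hkIdx
  logit <- matrix(rep(cellInt, each = cfg$nGenes), cfg$nGenes) +
    cfg$dropoutSlope * log(pmax(truth, 1)) +
    cfg$hkDetectOffset * isHK
  pdet <- stats::plogis(logit)
  drop <- truth > 0 & matrix(stats::runif(length(truth)),
                             cfg$nGenes) > pdet

  # stage 4: Poisson background at dropped entries
  set.seed(stageSeeds[4])
  observed <- truth
  observed[drop] <- stats::rpois(sum(drop), cfg$lambda0)
  mask <- which(drop, arr.ind = TRUE)
  mask <- mask[order(mask[, 1], mask[, 2]), , drop = FALSE]
  dimnames(mask) <- list(NULL, c("gene", "cell"))

  methods::new("SyntheticDataset",
               truth = ExpressionMatrix(truth, unit = "counts"),
               observed = ExpressionMatrix(observed, unit = "counts"),
               mask = mask, housekeeping = gid[hkIdx],
               groups = setNames(grpNames, cid), ordering = ordering,
               config = c(cfg, list(
                 expectedDropoutFraction =
                   sum((1 - pdet)[truth > 0]) / length(truth))))
}

#' Realized and expected dropout fractions of a synthetic dataset
#'
#' The expected fraction integrates the per-element logistic
#' detection efficiency over the drawn true expression values; the
#' realized fraction is the mask size over all matrix elements.
#'
#' @param ds a [SyntheticDataset-class].
#' @return Named numeric: \code{realized}, \code{expected}.
#' @export
dropoutFraction <- function(ds) {
  c(realized = nrow(ds@mask) /
      (nrow(ds@truth) * ncol(ds@truth)),
    expected = ds@config$expectedDropoutFraction)
}

#' Write a synthetic dataset's files
#'
#' Writes \code{truth.mtx}, \code{observed.mtx} (with name sidecars),
#' \code{mask.tsv}, \code{housekeeping.txt}, \code{groups.tsv} and
#' \code{ordering.txt} under the given prefix.
#'
#' @param ds a [SyntheticDataset-class].
#' @param prefix output directory (created if needed).
#' @return Invisibly, the output paths.
#' @export
writeSyntheticDataset <- function(ds, prefix) {
  dir.create(prefix, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(prefix, f)
  writeExpressionMatrix(ds@truth, p("truth.mtx"))
  writeExpressionMatrix(ds@observed, p("observed.mtx"))
  utils::write.table(
    data.frame(gene_id = geneIds(ds@truth)[ds@mask[, 1]],
               cell_id = cellIds(ds@truth)[ds@mask[, 2]]),
    p("mask.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeGeneList(ds@housekeeping, p("housekeeping.txt"))
  utils::write.table(
    data.frame(cell_id = names(ds@groups), group = unname(ds@groups)),
    p("groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(ds@ordering, p("ordering.txt"))
  invisible(p(c("truth.mtx", "observed.mtx", "mask.tsv",
                "housekeeping.txt", "groups.tsv", "ordering.txt")))
}
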