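# End-to-end driver: partition genes -> element-wise samples ->
# (cross-validated) linear classifier -> eta -> FNC (+ ZIM on count
# data) -> top-eta candidates -> strict intersection -> SVR
# imputation.

#' Pipeline configuration and dataset presets
#'
#' All tunable parameters of the pipeline with their defaults. The
#' presets bundle the settings reported for the two published dataset
#' scales: \code{"cml"} (FDR-filtered CML stem cells, RPKM-like data
#' without raw counts, so the ZIM detector is skipped and eta = 0.35
#' was used) and \code{"mouseCortex"} (UMI counts; eta = 0.397).
#'
#' @param objective classifier objective (\code{"lr_l2"} or
#'   \code{"svm_l2_l2loss"}).
#' @param C classifier penalty.
#' @param folds cross-validation folds (logged sanity check).
#' @param cv run cross-validation before training.
#' @param tol,maxIter solver controls.
#' @param svrP,svrFormulation,svrC,svrEpsilon SVR loss exponent,
#'   formulation, penalty and sensitivity.
#' @param lambda0 ZIM Poisson background rate.
#' @param amplifiedThreshold ZIM amplified-set fraction.
#' @param pairBudget ZIM pairs per subpopulation.
#' @param detectors \code{"auto"} (ZIM when the unit is count-like),
#'   \code{"fnc"} (classifier + FNC only) or \code{"zim+fnc"}.
#' @param etaOverride use this eta for the ZIM/FNC rankings instead of
#'   the classifier-derived value (NULL = derive).
#' @param lenient per-element intersection over covering detectors
#'   only, instead of strict intersection.
#' @param gamma baseline smoother half-window.
#' @param seed seed for fold assignment and ZIM pair subsampling.
#' @return Named list of resolved parameters.
#' @export
pipelineConfig <- function(objective = "lr_l2", C = 1, folds = 5L,
                           cv = TRUE, tol = 1e-4, maxIter = 1000L,
                           svrP = 2, svrFormulation = "primal",
                           svrC = 1, svrEpsilon = 0.1, lambda0 = 0.1,
                           amplifiedThreshold = 0.2, pairBudget = 100L,
                           detectors = "auto", etaOverride = NULL,
                           lenient = FALSE, gamma = 3L, seed = 1L) {
  list(objective = objective, C = C, folds = as.integer(folds), cv = cv,
       tol = tol, maxIter = as.integer(maxIter), svrP = svrP,
       svrFormulation = svrFormulation, svrC = svrC,
       svrEpsilon = svrEpsilon, lambda0 = lambda0,
       amplifiedThreshold = amplifiedThreshold,
       pairBudget = pairBudget, detectors = detectors,
       etaOverride = etaOverride, lenient = lenient,
       gamma = as.integer(gamma), seed = as.integer(seed))
}

#' @rdname pipelineConfig
#' @export
pipelinePresets <- function() {
  list(
    cml = pipelineConfig(objective = "svm_l2_l2loss", C = 2,
                         svrP = 2, svrFormulation = "primal",
                         svrC = 0.125, detectors = "fnc",
                         etaOverride = 0.35),
    mouseCortex = pipelineConfig(objective = "lr_l2", C = 104.858,
                                 svrP = 2, svrFormulation = "primal",
                                 svrC = 4, detectors = "zim+fnc",
                                 etaOverride = 0.397))
}

#' Read a pipeline configuration file
#'
#' Plain \code{key = value} lines; \code{'#'} starts a comment. Keys
#' must be [pipelineConfig()] parameters; values are coerced to the
#' default's type.
#'
#' @param path config file path.
#' @return Resolved config list.
#' @export
readPipelineConfig <- function(path) {
  ln <- sub("#.*$", "", readLines(path))
  ln <- trimws(ln[grepl("=", ln)])
  kv <- strsplit(ln, "\\s*=\\s*")
  args <- list()
  defaults <- formals(pipelineConfig)
  for (p in kv) {
    key <- p[1]
    if (!key %in% names(defaults))
      stop("unknown config key '", key, "' in ", path)
    val <- p[2]
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (val %in% c("TRUE", "FALSE")) as.logical(val)
                   else if (!is.na(num)) num else val
  }
  do.call(pipelineConfig, args)
}

.lenientIntersect <- function(llcSet, sets, probs, x, testGenes) {
  ng <- length(llcSet@geneIds)
  key <- function(pos) pos[, 1] + (pos[, 2] - 1) * ng
  cand <- lapply(c(list(llcSet), sets), function(s) key(s@positions))
  avail <- lapply(probs, function(p) key(which(!is.na(p@scores),
                                               arr.ind = TRUE)))
  keep <- cand[[1]]  # llc covers all zero test elements
  for (i in seq_along(sets)) {
    covered <- keep %in% avail[[i]]
    keep <- keep[!covered | keep %in% cand[[i + 1]]]
  }
  keep <- sort(keep)
  pos <- cbind(gene = as.integer((keep - 1) %% ng + 1),
               cell = as.integer((keep - 1) %/% ng + 1))
  methods::new("MissingPositionSet", positions = pos,
               geneIds = llcSet@geneIds, cellIds = llcSet@cellIds,
               provenance = c("llc", vapply(sets, methods::slot,
                                            character(1), "provenance")),
               eta = llcSet@eta)
}

#' Run the full detection-and-imputation pipeline
#'
#' Executes: gene partition, element-wise sample construction,
#' (optional) stratified cross-validation, classifier training,
#' prediction over the test set's zero elements, eta computation,
#' false-negative curves, the zero-inflated mixture (count data
#' only), top-eta candidate selection, intersection, SVR training and
#' imputation. Progress and the resolved configuration are logged via
#' \code{message()}.
#'
#' @param x observed [ExpressionMatrix-class].
#' @param housekeeping richly-expressed (housekeeping) gene ids.
#' @param groups named cell -> subpopulation vector (NULL = one group).
#' @param config list from [pipelineConfig()].
#' @param verbose log progress.
#' @return List with \code{imputed} (ExpressionMatrix),
#'   \code{missing} (final [MissingPositionSet-class]), \code{eta},
#'   \code{missingRate}, \code{cv}, \code{classifier}, \code{svr},
#'   \code{detectorSets}, \code{probabilities}, \code{report}
#'   (data.frame gene_id, cell_id, llc_score, zim_prob, fnc_prob,
#'   imputed_value), \code{config}.
#' @export
runPipeline <- function(x, housekeeping, groups = NULL,
                        config = pipelineConfig(), verbose = TRUE) {
  log <- function(...) if (verbose) message("[pipeline] ", ...)
  log("resolved config: ",
      paste(names(config), vapply(config, function(v)
        paste(format(v), collapse = ","), character(1)),
        sep = "=", collapse = " "))
  part <- partitionGenes(x, housekeeping)
  log(length(part$richly), " richly / ", length(part$nonRichly),
      " non-richly expressed genes")
  train <- buildSamples(x, part$richly, "sign")
  cvReport <- NULL
  if (isTRUE(config$cv)) {
    cvReport <- crossValidate(train, config$objective, C = config$C,
                              k = config$folds, seed = config$seed,
                              tol = config$tol,
                              maxIter = config$maxIter)
    log(sprintf("%d-fold CV accuracy: %.3f", config$folds,
                cvReport$meanAccuracy))
  }
  clf <- trainClassifier(train, config$objective, C = config$C,
                         tol = config$tol, maxIter = config$maxIter)
  eta <- config$etaOverride
  if (is.null(eta)) eta <- computeEta(clf, x, part$nonRichly)
  log(sprintf("missing rate threshold eta = %.4f", eta))
  llcSet <- llcCandidates(clf, x, part$nonRichly)
  llcProb <- llcMissingProbabilities(clf, x, part$nonRichly)
  muStar <- suppressWarnings(expectedExpression(x))
  curves <- fitDetectionCurves(x, part$richly, muStar)
  fncProb <- fncMissingProbabilities(x, curves, muStar)
  fncSet <- topCandidates(fncProb, eta)
  useZim <- switch(config$detectors,
                   auto = exprUnit(x) %in% c("counts", "umi"),
                   fnc = FALSE,
                   `zim+fnc` = TRUE,
                   stop("unknown detectors setting: ", config$detectors))
  zimProb <- NULL; zimSet <- NULL; zimRes <- NULL
  if (useZim) {
    zimRes <- zimMissingProbabilities(
      x, groups, lambda0 = config$lambda0,
      threshold = config$amplifiedThreshold,
      pairBudget = config$pairBudget, seed = config$seed)
    zimProb <- zimRes$probability
    zimSet <- topCandidates(zimProb, eta)
  } else {
    log("ZIM detector skipped (no count data); ",
        "intersection over classifier + FNC only")
  }
  sets <- c(list(llc = llcSet),
            if (useZim) list(zim = zimSet), list(fnc = fncSet))
  log("candidate counts: ",
      paste(names(sets), vapply(sets, function(s) nrow(s@positions),
                                numeric(1)), sep = "=", collapse = " "))
  final <- if (isTRUE(config$lenient)) {
    .lenientIntersect(llcSet, sets[-1],
                      c(if (useZim) list(zimProb), list(fncProb)),
                      x, part$nonRichly)
  } else intersectMissing(sets)
  final@eta <- eta
  log("intersection size: ", nrow(final@positions),
      sprintf(" (missing rate %.4f)", missingRate(final)))
  svrTrain <- buildSamples(x, part$richly, "value")
  svr <- trainSVR(svrTrain, p = config$svrP,
                  formulation = config$svrFormulation,
                  C = config$svrC, epsilon = config$svrEpsilon,
                  tol = config$tol, maxIter = config$maxIter)
  imputed <- imputeExpression(x, final, svr)
  rep <- S4Vectors::metadata(imputed)$imputationReport
  pos <- final@positions
  rep$llc_score <- llcProb@scores[pos]
  rep$zim_prob <- if (useZim) zimProb@scores[pos] else NA_real_
  rep$fnc_prob <- fncProb@scores[pos]
  rep <- rep[, c("gene_id", "cell_id", "llc_score", "zim_prob",
                 "fnc_prob", "imputed_value")]
  list(imputed = imputed, missing = final, eta = eta,
       missingRate = missingRate(final), cv = cvReport,
       classifier = clf, svr = svr, detectorSets = sets,
       probabilities = c(list(llc = llcProb),
                         if (useZim) list(zim = zimProb),
                         list(fnc = fncProb)),
       amplifiedGenes = if (useZim) zimRes$amplifiedGenes,
       report = rep, config = config)
}

#' Score an imputed matrix against synthetic ground truth
#'
#' Position metrics compare a called missing-position set with the
#' true dropout mask (precision, recall, F1); value metrics are the
#' RMSE between imputed and true values at the mask positions,
#' together with the RMSE of leaving those positions at zero.
#'
#' @param imputed imputed [ExpressionMatrix-class].
#' @param truth true [ExpressionMatrix-class].
#' @param mask integer (gene, cell) matrix of true dropout positions.
#' @param missing optional [MissingPositionSet-class] of called
#'   positions for the precision/recall metrics.
#' @return Named list: \code{rmse}, \code{rmseZero}, and (with
#'   \code{missing}) \code{precision}, \code{recall}, \code{f1}.
#' @export
evaluateImputation <- function(imputed, truth, mask, missing = NULL) {
  tv <- as.matrix(exprValues(truth))
  iv <- as.matrix(exprValues(imputed))
  out <- list(
    rmse = sqrt(mean((iv[mask] - tv[mask])^2)),
    rmseZero = sqrt(mean(tv[mask]^2)))
  if (!is.null(missing)) {
    ng <- nrow(tv)
    mk <- mask[, 1] + (mask[, 2] - 1) * ng
    pk <- missing@positions[, 1] + (missing@positions[, 2] - 1) * ng
    tp <- sum(pk %in% mk)
    out$precision <- if (length(pk)) tp / length(pk) else NA_real_
    out$recall <- tp / length(mk)
    out$f1 <- if (!is.na(out$precision) && (out$precision + out$recall) > 0)
      2 * out$precision * out$recall / (out$precision + out$recall)
      else NA_real_
  }
  out
}

#' Precision of a candidate set against the true dropout mask
#'
#' @param set a [MissingPositionSet-class].
#' @param mask integer (gene, cell) matrix of true dropout positions.
#' @return Fraction of the set's positions that are true dropouts.
#' @export
positionPrecision <- function(set, mask) {
  ng <- length(set@geneIds)
  mk <- mask[, 1] + (mask[, 2] - 1) * ng
  pk <- set@positions[, 1] + (set@positions[, 2] - 1) * ng
  if (!length(pk)) return(NA_real_)
  sum(pk %in% mk) / length(pk)
}
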