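mpm <- function(scores, source = "fnc") {
  new("MissingProbabilityMatrix", source = source, scores = scores)
}
mps <- function(pos, gid, cid, prov = "llc", eta = 0.5) {
  new("MissingPositionSet",
      positions = cbind(gene = pos[, 1], cell = pos[, 2]),
      geneIds = gid, cellIds = cid, provenance = prov, eta = eta)
}

test_that("eta is the positive rate over zero test elements", {
  expect_equal(computeEtaFromLabels(c(rep(1, 35), rep(-1, 65))), 0.35)
  expect_equal(computeEtaFromLabels(rep(-1, 10)), 0)
  expect_error(computeEtaFromLabels(numeric()), "empty")
})

test_that("top candidates take the ceiling(eta * D) best with ordered ties", {
  s <- matrix(NA_real_, 2, 5,
              dimnames = list(c("g1", "g2"), paste0("c", 1:5)))
  s[1, ] <- c(0.9, 0.1, 0.5, 0.7, 0.3)
  s[2, ] <- c(0.8, NA, 0.2, 0.6, 0.4)
  top <- topCandidates(mpm(s), 0.3)  # D = 9, k = 3
  expect_equal(nrow(top@positions), 3)
  expect_setequal(s[top@positions], c(0.9, 0.8, 0.7))
  all9 <- topCandidates(mpm(s), 1)
  expect_equal(nrow(all9@positions), 9)
  # equal scores: first ceil(eta D) in (gene, cell) ascending order
  tie <- matrix(0.5, 2, 3, dimnames = list(c("g1", "g2"), paste0("c", 1:3)))
  t2 <- topCandidates(mpm(tie), 0.5)  # k = 3 of 6
  expect_equal(unname(t2@positions),
               cbind(c(1L, 1L, 1L), c(1L, 2L, 3L)), ignore_attr = TRUE)
  expect_equal(nrow(topCandidates(mpm(tie), 0)@positions), 0)
})

test_that("intersection is strict set intersection with provenance", {
  gid <- paste0("g", 1:5); cid <- paste0("c", 1:5)
  A <- mps(cbind(1:3, 1), gid, cid, "llc")       # a, b, c
  B <- mps(cbind(2:4, 1), gid, cid, "zim")       # b, c, d
  C <- mps(cbind(3:5, 1), gid, cid, "fnc")       # c, d, e
  out <- intersectMissing(A, B, C)
  expect_equal(unname(out@positions), cbind(3L, 1L), ignore_attr = TRUE)
  expect_setequal(out@provenance, c("llc", "zim", "fnc"))
  expect_equal(missingRate(out), 1 / 25)
  # idempotence and the pairwise upper bound
  expect_equal(intersectMissing(A, A)@positions, A@positions)
  pairMin <- min(nrow(intersectMissing(A, B)@positions),
                 nrow(intersectMissing(A, C)@positions),
                 nrow(intersectMissing(B, C)@positions))
  expect_lte(nrow(out@positions), pairMin)
  expect_error(intersectMissing(A), "at least 2")
})

test_that("imputation writes only at missing positions, clamped at zero", {
  em <- toyMatrix(4, 5, seed = 31)
  v <- as.matrix(exprValues(em))
  v[2, 3] <- 0; v[4, 1] <- 0
  em <- ExpressionMatrix(v, unit = "counts", geneIds = geneIds(em),
                         cellIds = cellIds(em))
  svr <- new(Class = "LinearModel", weights = rep(0.25, 4), bias = 0.5,
             objective = "svr_l2loss", C = 1, epsilon = 0.1, p = 2,
             solverInfo = list())
  miss <- mps(rbind(c(2, 3), c(4, 1)), geneIds(em), cellIds(em))
  out <- imputeExpression(em, miss, svr)
  ov <- as.matrix(exprValues(out))
  expect_equal(ov[2, 3], 0.25 * sum(v[2, -3]) + 0.5)
  expect_equal(ov[4, 1], 0.25 * sum(v[4, -1]) + 0.5)
  # untouched elsewhere, bit-equal
  ov[2, 3] <- v[2, 3]; ov[4, 1] <- v[4, 1]
  expect_identical(ov, v)
  rep <- S4Vectors::metadata(out)$imputationReport
  expect_equal(nrow(rep), 2)

  # empty set is the identity
  none <- mps(matrix(integer(), 0, 2), geneIds(em), cellIds(em))
  same <- imputeExpression(em, none, svr)
  expect_identical(as.matrix(exprValues(same)), v)

  # negative raw prediction stores 0
  neg <- new(Class = "LinearModel", weights = rep(-1, 4), bias = -1,
             objective = "svr_l2loss", C = 1, epsilon = 0.1, p = 2,
             solverInfo = list())
  out2 <- imputeExpression(em, miss, neg)
  expect_equal(as.matrix(exprValues(out2))[2, 3], 0)

  # corruption guard: nonzero position refuses
  bad <- mps(rbind(c(1, 1)), geneIds(em), cellIds(em))
  expect_error(imputeExpression(em, bad, svr), "nonzero")
})

test_that("classifier scores lie in [0, 1] and only cover zero elements", {
  ds <- generateSyntheticData(syntheticConfig(
    nGenes = 200, nCells = 30, nHousekeeping = 20, seed = 12))
  x <- ds@observed
  part <- partitionGenes(x, ds@housekeeping)
  train <- buildSamples(x, part$richly, "sign")
  for (obj in c("lr_l2", "svm_l2_l2loss")) {
    clf <- trainClassifier(train, obj, C = 1)
    p <- llcMissingProbabilities(clf, x, part$nonRichly)
    v <- as.matrix(exprValues(x))
    expect_true(all(is.na(p@scores[v > 0])))
    ok <- p@scores[!is.na(p@scores)]
    expect_true(all(ok >= 0 & ok <= 1))
    # candidate set consistent with eta
    eta <- computeEta(clf, x, part$nonRichly)
    cand <- llcCandidates(clf, x, part$nonRichly)
    nz <- sum(v[match(part$nonRichly, geneIds(x)), ] == 0)
    expect_equal(nrow(cand@positions) / nz, eta)
  }
})
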