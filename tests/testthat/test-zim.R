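# two-cell fixture: gene counts chosen to exercise all three
# components (zero vs high -> dropout; balanced positive -> amplified)
pairFixture <- function(seed = 42, G = 400, dropFrac = 0.3, mu = 50,
                        size = 2, lambda0 = 0.1) {
  set.seed(seed)
  lab <- sample(1:3, G, replace = TRUE,
                prob = c(dropFrac, 1 - 2 * dropFrac, dropFrac))
  ri <- ifelse(lab == 1, rpois(G, lambda0), rnbinom(G, size = size, mu = mu))
  rj <- ifelse(lab == 3, rpois(G, lambda0), rnbinom(G, size = size, mu = mu))
  em <- ExpressionMatrix(cbind(ci = ri, cj = rj),
                         unit = "counts",
                         geneIds = sprintf("g%04d", seq_len(G)))
  list(em = em, lab = lab)
}

test_that("component posteriors follow the evidence at extreme counts", {
  fx <- pairFixture(seed = 1)
  v <- as.matrix(exprValues(fx$em))
  v[1, ] <- c(0, 120)   # dropout in cell i
  v[2, ] <- c(40, 45)   # amplified
  v[3, ] <- c(130, 0)   # dropout in cell j
  em <- ExpressionMatrix(v, unit = "counts")
  f <- fitPairMixture(em, "ci", "cj")
  post <- f$posteriors[match(1:3, f$genes), ]
  expect_gt(post[1, "dropout_i"], 0.5)
  expect_equal(which.max(post[2, ]), c(amplified = 2L))
  expect_gt(post[3, "dropout_j"], 0.5)
  # rows sum to one
  expect_equal(rowSums(f$posteriors), rep(1, nrow(f$posteriors)),
               tolerance = 1e-8)
})

test_that("EM log-likelihood is monotone and converges", {
  for (sd in 1:3) {
    fx <- pairFixture(seed = sd)
    f <- fitPairMixture(fx$em, 1, 2)
    tr <- f$loglikTrace
    expect_true(all(diff(tr) >= -1e-6 * (abs(tr[-1]) + 1)))
  }
})

test_that("mixture recovers generating component fractions", {
  fx <- pairFixture(seed = 7, G = 2000)
  f <- fitPairMixture(fx$em, 1, 2, lambda0 = 0.1)
  hard <- max.col(f$posteriors, ties.method = "first")
  truthFrac <- mean(fx$lab[f$genes] == 1)
  expect_lt(abs(mean(hard == 1) - truthFrac), 0.05)
  truthFracJ <- mean(fx$lab[f$genes] == 3)
  expect_lt(abs(mean(hard == 3) - truthFracJ), 0.05)
})

test_that("with tiny lambda0 and all-positive counts, dropout vanishes", {
  set.seed(9)
  v <- cbind(ci = rnbinom(200, size = 2, mu = 30) + 1,
             cj = rnbinom(200, size = 2, mu = 30) + 1)
  em <- ExpressionMatrix(v, unit = "counts",
                         geneIds = sprintf("g%03d", 1:200))
  f <- fitPairMixture(em, 1, 2, lambda0 = 1e-8)
  expect_lt(max(f$posteriors[, c("dropout_i", "dropout_j")]), 1e-6)
})

test_that("degenerate pairs and non-integer input are handled", {
  v <- cbind(c1 = c(0, 0), c2 = c(3, 1))
  em <- ExpressionMatrix(v, unit = "counts", geneIds = c("a", "b"))
  expect_error(fitPairMixture(em, 1, 2), "c1")
  v2 <- cbind(c1 = c(1.5, 2), c2 = c(3, 1))
  em2 <- ExpressionMatrix(v2, unit = "counts", geneIds = c("a", "b"))
  expect_warning(fitPairMixture(em2, 1, 2), "rounded")
})

test_that("amplified-set selection applies the evaluable-fraction rule", {
  fakeFit <- function(ampGenes, genes = paste0("g", 1:4)) {
    post <- matrix(0, length(genes), 3,
                   dimnames = list(NULL, c("dropout_i", "amplified",
                                           "dropout_j")))
    post[, 1] <- 1
    post[match(ampGenes, genes), ] <- rep(c(0, 1, 0), each = length(ampGenes))
    structure(list(geneIds = genes, posteriors = post),
              class = "PairMixtureFit")
  }
  fits <- c(replicate(3, fakeFit("g1"), simplify = FALSE),
            replicate(7, fakeFit(character()), simplify = FALSE))
  fits2 <- c(replicate(1, fakeFit("g2"), simplify = FALSE),
             replicate(9, fakeFit(character()), simplify = FALSE))
  expect_true("g1" %in% selectAmplifiedGenes(fits, 0.2))    # 3/10
  expect_false("g2" %in% selectAmplifiedGenes(fits2, 0.2))  # 1/10
  expect_setequal(selectAmplifiedGenes(fits, 0), paste0("g", 1:4))
})

test_that("zim probability matrix covers only zero elements of amplified genes", {
  ds <- generateSyntheticData(syntheticConfig(
    nGenes = 250, nCells = 30, nHousekeeping = 25, groupCount = 2,
    seed = 4))
  res <- zimMissingProbabilities(ds@observed, ds@groups,
                                 pairBudget = 15, seed = 4)
  s <- res$probability@scores
  v <- as.matrix(exprValues(ds@observed))
  expect_true(all(is.na(s[v > 0])))
  ok <- s[!is.na(s)]
  expect_true(all(ok >= 0 & ok <= 1))
  # two cells in one group -> exactly one pair
  small <- ExpressionMatrix(
    cbind(c1 = c(5, 0, 2), c2 = c(4, 3, 0)), unit = "counts",
    geneIds = c("a", "b", "c"))
  one <- zimMissingProbabilities(small, pairBudget = 10)
  expect_equal(one$nPairs$all, 1)
})

test_that("zim separates dropout zeros from biological zeros on synthetic data", {
  ds <- generateSyntheticData(syntheticConfig(
    nGenes = 300, nCells = 36, nHousekeeping = 30, groupCount = 2,
    seed = 6))
  res <- zimMissingProbabilities(ds@observed, ds@groups,
                                 pairBudget = 30, seed = 6)
  s <- res$probability@scores
  tv <- as.matrix(exprValues(ds@truth))
  ov <- as.matrix(exprValues(ds@observed))
  dropZero <- ov == 0 & tv > 0
  bioZero <- ov == 0 & tv == 0
  expect_gt(mean(s[dropZero], na.rm = TRUE),
            mean(s[bioZero], na.rm = TRUE))
})

test_that("rpkm data is refused without force and lambda0 defaults to 0.1", {
  em <- toyMatrix(3, 4, unit = "rpkm")
  expect_error(zimMissingProbabilities(em), "rpkm")
  fx <- pairFixture(seed = 11, G = 100)
  f <- fitPairMixture(fx$em, 1, 2)
  expect_equal(f$lambda0, 0.1)
})
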