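test_that("separable toy data is fit to training accuracy 1 by both objectives", {
  X <- matrix(c(-1, 1), 2, 1)
  y <- c(-1, 1)
  s <- makeSampleSet(X, y)
  for (obj in c("lr_l2", "svm_l2_l2loss")) {
    mod <- trainClassifier(s, obj, C = 1, tol = 1e-8)
    expect_equal(predictClassifier(mod, s)$label, y)
  }
})

test_that("solvers match an independent convex minimizer on small toys", {
  set.seed(101)
  X <- matrix(rnorm(40), 20, 2)
  y <- sign(X[, 1] + 0.5 * rnorm(20))
  s <- makeSampleSet(X, y)
  for (obj in c("lr_l2", "svm_l2_l2loss")) {
    mod <- trainClassifier(s, obj, C = 1, tol = 1e-10, maxIter = 5000)
    ours <- objectiveValue(mod, s)
    oracle <- oracleMinimize(X, y, obj, C = 1)$value
    expect_lt(abs(ours - oracle) / oracle, 1e-6)
  }
  # held-out predictions agree with the oracle's weights on separable data
  Xh <- matrix(c(-2, -1.5, 1.5, 2), 4, 1)
  sh <- makeSampleSet(Xh, c(-1, -1, 1, 1))
  st <- makeSampleSet(matrix(c(-1, 1), 2, 1), c(-1, 1))
  mod <- trainClassifier(st, "lr_l2", C = 1, tol = 1e-10)
  wo <- oracleMinimize(matrix(c(-1, 1), 2, 1), c(-1, 1), "lr_l2", C = 1)$par
  oraclePred <- ifelse(cbind(Xh, 1) %*% wo > 0, 1, -1)
  expect_equal(predictClassifier(mod, sh)$label, as.numeric(oraclePred))
})

test_that("flipping all labels negates the weights (bias-free LR)", {
  set.seed(7)
  X <- matrix(rnorm(30), 15, 2)
  y <- sign(rnorm(15))
  m1 <- trainClassifier(makeSampleSet(X, y), "lr_l2", C = 2,
                        tol = 1e-10, bias = FALSE)
  m2 <- trainClassifier(makeSampleSet(X, -y), "lr_l2", C = 2,
                        tol = 1e-10, bias = FALSE)
  expect_equal(m1@weights, -m2@weights, tolerance = 1e-4)
})

test_that("decision values and the sign(0) = -1 tie rule", {
  mod <- new(Class = "LinearModel", weights = c(1, 0), bias = 0,
             objective = "lr_l2", C = 1, epsilon = 0, p = NA_real_,
             solverInfo = list(objective = NA_real_))
  s <- makeSampleSet(matrix(c(3, -5, 0, 7), 2, 2, byrow = TRUE), c(1, 1))
  pr <- predictClassifier(mod, s)
  expect_equal(pr$decision, c(3, 0))
  expect_equal(pr$label, c(1, -1))  # exact zero is "not missing"
  expect_error(predictClassifier(mod, makeSampleSet(matrix(1, 1, 3), 1)),
               "mismatch")
})

test_that("cross-validation is stratified, seeded and calibrated", {
  set.seed(3)
  X <- matrix(rnorm(400), 200, 2)
  X[, 1] <- X[, 1] + rep(c(-3, 3), each = 100)
  y <- rep(c(-1, 1), each = 100)
  s <- makeSampleSet(X, y)
  cv <- crossValidate(s, "lr_l2", C = 1, k = 4, seed = 9)
  expect_equal(cv$meanAccuracy, 1)
  expect_equal(cv$meanAccuracy, mean(cv$perFoldAccuracy))
  # same seed -> identical folds and report
  cv2 <- crossValidate(s, "lr_l2", C = 1, k = 4, seed = 9)
  expect_identical(cv$foldAssignment, cv2$foldAssignment)
  expect_identical(cv$perFoldAccuracy, cv2$perFoldAccuracy)
  # shuffled labels on balanced data: accuracy near the binomial null
  set.seed(5)
  yr <- sample(y)
  cvr <- crossValidate(makeSampleSet(X, yr), "lr_l2", C = 1, k = 5,
                       seed = 2)
  expect_lt(abs(cvr$meanAccuracy - 0.5), 3 * sqrt(0.25 / 200))
  expect_error(crossValidate(makeSampleSet(X[1:6, ], c(-1, 1, 1, 1, 1, 1)),
                             "lr_l2", k = 5), "minority")
})

test_that("SVR recovers noiseless linear data and the OLS limit", {
  x <- seq(-2, 2, length.out = 10)
  s <- makeSampleSet(matrix(x), 2 * x, labelMode = "value")
  for (form in c("primal", "dual")) {
    mod <- trainSVR(s, p = 2, formulation = form, C = 1e6, epsilon = 0,
                    tol = 1e-12, maxIter = 5000)
    expect_lt(abs(mod@weights - 2), 1e-3)
    expect_lt(max(abs(predictSVR(mod, s) - 2 * x)), 1e-3)
  }
  # large C, p = 2, eps = 0 approaches the least-squares closed form
  set.seed(21)
  xr <- rnorm(10); yr <- 1.5 * xr + rnorm(10, sd = 0.2)
  A <- cbind(xr, 1)
  wls <- solve(crossprod(A), crossprod(A, yr))
  mod <- trainSVR(makeSampleSet(matrix(xr), yr, "value"), p = 2,
                  C = 1e6, epsilon = 0, tol = 1e-12, maxIter = 5000)
  expect_lt(abs(mod@weights - wls[1]), 1e-3)
  expect_lt(abs(mod@bias - wls[2]), 1e-3)
})

test_that("SVR objective matches the independent minimizer; p = 1 needs the dual", {
  set.seed(31)
  X <- matrix(rnorm(30), 15, 2)
  y <- X %*% c(1, -2) + rnorm(15, sd = 0.3)
  s <- makeSampleSet(X, as.numeric(y), "value")
  mod <- trainSVR(s, p = 2, formulation = "primal", C = 3,
                  epsilon = 0.1, tol = 1e-10, maxIter = 5000)
  oracle <- oracleMinimize(X, as.numeric(y), "svr_l2loss", C = 3,
                           epsilon = 0.1)$value
  expect_lt(abs(objectiveValue(mod, s) - oracle) / oracle, 1e-6)
  expect_error(trainSVR(s, p = 1, formulation = "primal"),
               "unsupported variant")
  expect_error(trainSVR(s, p = 3), "p must be 1 or 2")
  modL1 <- trainSVR(s, p = 1, formulation = "dual", C = 3,
                    epsilon = 0.1, tol = 1e-10, maxIter = 5000)
  oracleL1 <- oracleMinimize(X, as.numeric(y), "svr_l1loss", C = 3,
                             epsilon = 0.1)$value
  expect_lt(abs(objectiveValue(modL1, s) - oracleL1) /
              abs(oracleL1), 1e-4)
})

test_that("label translation shifts the bias when regularization is negligible", {
  set.seed(41)
  x <- rnorm(12)
  y <- 0.8 * x + rnorm(12, sd = 0.1)
  s1 <- makeSampleSet(matrix(x), y, "value")
  s2 <- makeSampleSet(matrix(x), y + 10, "value")
  m1 <- trainSVR(s1, p = 2, C = 1e4, epsilon = 0, tol = 1e-10,
                 maxIter = 5000)
  m2 <- trainSVR(s2, p = 2, C = 1e4, epsilon = 0, tol = 1e-10,
                 maxIter = 5000)
  expect_equal(m1@weights, m2@weights, tolerance = 1e-3)
  expect_equal(m2@bias - m1@bias, 10, tolerance = 1e-3)
})

test_that("strong duality holds on small instances", {
  set.seed(51)
  X <- matrix(rnorm(40), 20, 2)
  y <- sign(X[, 1] + rnorm(20))
  s <- makeSampleSet(X, y)
  tol <- 1e-9
  svm <- trainClassifier(s, "svm_l2_l2loss", formulation = "dual",
                         C = 2, tol = tol, maxIter = 20000)
  gap <- svm@solverInfo$objective + svm@solverInfo$dualObjective
  expect_lt(abs(gap), 10 * sqrt(tol))
  ys <- as.numeric(X %*% c(1, 1) + rnorm(20, sd = 0.2))
  sv <- makeSampleSet(X, ys, "value")
  for (p in c(1, 2)) {
    svr <- trainSVR(sv, p = p, formulation = "dual", C = 2,
                    epsilon = 0.1, tol = tol, maxIter = 20000)
    gap <- svr@solverInfo$objective + svr@solverInfo$dualObjective
    expect_lt(abs(gap), 10 * sqrt(tol))
  }
  # primal and dual p = 2 solutions agree in objective
  svrP <- trainSVR(sv, p = 2, formulation = "primal", C = 2,
                   epsilon = 0.1, tol = 1e-10, maxIter = 5000)
  svrD <- trainSVR(sv, p = 2, formulation = "dual", C = 2,
                   epsilon = 0.1, tol = tol, maxIter = 20000)
  expect_lt(abs(svrP@solverInfo$objective - svrD@solverInfo$objective) /
              svrP@solverInfo$objective, 1e-4)
})

test_that("optimizers never end worse than the zero vector and C is monotone", {
  set.seed(61)
  X <- matrix(rnorm(60), 30, 2)
  y <- sign(X[, 2] + rnorm(30))
  yv <- as.numeric(X %*% c(2, 1) + rnorm(30, sd = 0.5))
  zero <- function(obj, eps) new(Class = "LinearModel",
    weights = c(0, 0), bias = 0, objective = obj, C = 1,
    epsilon = eps, p = NA_real_, solverInfo = list())
  cases <- list(
    list(obj = "lr_l2", s = makeSampleSet(X, y)),
    list(obj = "svm_l2_l2loss", s = makeSampleSet(X, y)),
    list(obj = "svr_l2loss", s = makeSampleSet(X, yv, "value")))
  lossTerm <- c()
  for (cs in cases) {
    if (cs$obj == "svr_l2loss")
      mod <- trainSVR(cs$s, p = 2, C = 1, epsilon = 0.1, tol = 1e-8)
    else mod <- trainClassifier(cs$s, cs$obj, C = 1, tol = 1e-8)
    expect_lte(objectiveValue(mod, cs$s),
               objectiveValue(zero(cs$obj, 0.1), cs$s))
  }
  # doubling C never increases the total training-loss term
  s <- makeSampleSet(X, y)
  loss <- vapply(c(0.5, 1, 2, 4), function(C) {
    mod <- trainClassifier(s, "lr_l2", C = C, tol = 1e-10)
    (objectiveValue(mod, s) -
       0.5 * (sum(mod@weights^2) + mod@bias^2)) / C
  }, numeric(1))
  expect_true(all(diff(loss) <= 1e-8))
})

test_that("whole-matrix decision values equal the materialized prediction", {
  em <- toyMatrix(6, 5, seed = 71)
  v <- as.matrix(exprValues(em))
  v[cbind(c(1, 3, 5), c(2, 4, 1))] <- 0  # ensure both classes exist
  em <- ExpressionMatrix(v, unit = "counts")
  s <- buildSamples(em, geneIds(em), "sign")
  mod <- trainClassifier(s, "lr_l2", C = 1, tol = 1e-8)
  dec <- matrixDecisionValues(mod, em, geneIds(em), blockSize = 2L)
  ref <- predictClassifier(mod, s)$decision
  expect_equal(as.numeric(t(dec)), ref, tolerance = 1e-12)
})

test_that("model serialization round-trips", {
  set.seed(81)
  s <- makeSampleSet(matrix(rnorm(20), 10, 2), sign(rnorm(10)))
  mod <- trainClassifier(s, "svm_l2_l2loss", C = 0.5, tol = 1e-8)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLinearModel(mod, f)
  back <- readLinearModel(f)
  expect_equal(back@weights, mod@weights, tolerance = 1e-12)
  expect_equal(back@bias, mod@bias, tolerance = 1e-12)
  expect_identical(back@objective, mod@objective)
  expect_equal(back@C, mod@C)
})
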