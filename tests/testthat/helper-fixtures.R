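# Shared fixtures: small matrices built in code, and independent
# oracle implementations of the regularized objectives used to check
# the package's solvers.

toyMatrix <- function(m = 3, n = 4, seed = 1, unit = "counts",
                      sparse = FALSE) {
  set.seed(seed)
  v <- matrix(rpois(m * n, 3), m, n,
              dimnames = list(sprintf("g%d", seq_len(m)),
                              sprintf("c%d", seq_len(n))))
  if (sparse) v <- Matrix::Matrix(v, sparse = TRUE)
  ExpressionMatrix(v, unit = unit)
}

makeSampleSet <- function(X, y, labelMode = "sign") {
  new("SampleSet",
      elementIndex = cbind(gene = seq_len(nrow(X)),
                           cell = rep(1L, nrow(X))),
      features = X, labels = y, labelMode = labelMode, role = "train")
}

# independent objective implementations (oracle side); bias handled as
# an augmented, regularized constant feature, matching the package's
# stated convention
oracleObjective <- function(wfull, X, y, objective, C, epsilon = 0,
                            bias = TRUE) {
  Xa <- if (bias) cbind(X, 1) else X
  m <- drop(Xa %*% wfull)
  loss <- switch(objective,
    lr_l2 = log1p(exp(-y * m)),
    svm_l2_l2loss = pmax(0, 1 - y * m)^2,
    svr_l2loss = pmax(0, abs(y - m) - epsilon)^2,
    svr_l1loss = pmax(0, abs(y - m) - epsilon))
  0.5 * sum(wfull^2) + C * sum(loss)
}

# generic convex minimizer run on the same objective (independent of
# the package's solver path)
oracleMinimize <- function(X, y, objective, C, epsilon = 0, bias = TRUE) {
  d <- ncol(X) + as.integer(bias)
  optim(numeric(d), oracleObjective, X = X, y = y,
        objective = objective, C = C, epsilon = epsilon, bias = bias,
        method = "BFGS",
        control = list(maxit = 5000, reltol = 1e-14))
}
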