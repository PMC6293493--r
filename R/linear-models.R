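# Large linear models: L2-regularized logistic regression, L2-loss SVM,
# and epsilon-insensitive support vector regression with linear kernel.
# Primal problems are smooth and solved with L-BFGS-B; duals with
# coordinate descent. The bias is handled liblinear-style as an
# augmented constant feature (and is therefore regularized).

.lossGrad <- function(objective, m, y, epsilon = 0) {
  switch(objective,
    lr_l2 = {
      t <- y * m
      loss <- ifelse(t > 0, log1p(exp(-t)), -t + log1p(exp(t)))
      list(loss = loss, dm = -y * stats::plogis(-t))
    },
    svm_l2_l2loss = {
      h <- pmax(0, 1 - y * m)
      list(loss = h^2, dm = -2 * y * h)
    },
    svr_l2loss = {
      r <- m - y
      h <- pmax(0, abs(r) - epsilon)
      list(loss = h^2, dm = 2 * sign(r) * h)
    },
    svr_l1loss = {
      r <- m - y
      h <- pmax(0, abs(r) - epsilon)
      list(loss = h, dm = sign(r) * (h > 0))
    },
    stop("unknown objective: ", objective))
}

#' Evaluate a model's regularized objective on a sample set
#'
#' Computes \eqn{\frac12 w^T w + C \sum_i loss(w, s_i, y_i)} for the
#' model's stated objective: logistic loss, squared hinge, or the
#' epsilon-insensitive loss to the power p. The bias enters the
#' regularizer as an augmented constant feature (liblinear
#' convention).
#'
#' @param model a [LinearModel-class].
#' @param samples a [SampleSet-class] with matching feature length.
#' @return The objective value (numeric scalar).
#' @export
objectiveValue <- function(model, samples) {
  X <- samples@features
  y <- samples@labels
  m <- drop(X %*% model@weights) + model@bias
  lg <- .lossGrad(model@objective, m, y, model@epsilon)
  0.5 * (sum(model@weights^2) + model@bias^2) + model@C * sum(lg$loss)
}

.solvePrimal <- function(X, y, objective, C, epsilon, tol, maxIter, bias) {
  d <- ncol(X)
  Xa <- if (bias) cbind(X, 1) else X
  fn <- function(w) {
    m <- drop(Xa %*% w)
    0.5 * sum(w^2) + C * sum(.lossGrad(objective, m, y, epsilon)$loss)
  }
  gr <- function(w) {
    m <- drop(Xa %*% w)
    w + C * drop(crossprod(Xa, .lossGrad(objective, m, y, epsilon)$dm))
  }
  res <- stats::optim(numeric(ncol(Xa)), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxIter,
                                     factr = max(10, tol * 1e13)))
  if (res$convergence != 0)
    warning("primal solver did not converge (code ", res$convergence,
            "): ", res$message)
  list(weights = res$par[seq_len(d)],
       bias = if (bias) res$par[d + 1L] else 0,
       objective = res$value,
       iterations = res$counts[["function"]],
       converged = res$convergence == 0)
}

# Dual coordinate descent for L2-regularized L2-loss SVM:
#   min_a 1/2 a' (Q + I/(2C)) a - e'a,  a >= 0, Q_ij = y_i y_j x_i'x_j
.dcdSVM <- function(X, y, C, tol, maxIter) {
  l <- nrow(X)
  sq <- rowSums(X^2) + 1 / (2 * C)
  alpha <- numeric(l)
  w <- numeric(ncol(X))
  obj <- Inf
  for (epoch in seq_len(maxIter)) {
    maxPG <- 0
    for (i in sample.int(l)) {
      G <- y[i] * sum(w * X[i, ]) - 1 + alpha[i] / (2 * C)
      PG <- if (alpha[i] == 0) min(G, 0) else G
      maxPG <- max(maxPG, abs(PG))
      if (abs(PG) > 1e-12) {
        a0 <- alpha[i]
        alpha[i] <- max(0, alpha[i] - G / sq[i])
        w <- w + (alpha[i] - a0) * y[i] * X[i, ]
      }
    }
    newObj <- 0.5 * sum(w^2) + sum(alpha^2) / (4 * C) - sum(alpha)
    if (is.finite(obj) && abs(obj - newObj) <= tol * max(1, abs(newObj)) &&
        maxPG < 0.1 * sqrt(tol))
      { obj <- newObj; break }
    obj <- newObj
  }
  list(w = w, alpha = alpha, dualObjective = obj, epochs = epoch)
}

# Dual coordinate descent for L2-regularized SVR (liblinear beta form):
#   min_b 1/2 b'(Q + lambda I) b - y'b + eps ||b||_1,  |b_i| <= U
# with lambda = 0, U = C for p = 1; lambda = 1/(2C), U = Inf for p = 2.
.dcdSVR <- function(X, y, C, epsilon, p, tol, maxIter) {
  l <- nrow(X)
  lambda <- if (p == 2) 1 / (2 * C) else 0
  U <- if (p == 2) Inf else C
  H <- rowSums(X^2) + lambda
  beta <- numeric(l)
  w <- numeric(ncol(X))
  obj <- Inf
  for (epoch in seq_len(maxIter)) {
    maxViol <- 0
    for (i in sample.int(l)) {
      G <- sum(w * X[i, ]) - y[i] + lambda * beta[i]
      Gp <- G + epsilon
      Gn <- G - epsilon
      viol <- 0
      if (beta[i] == 0) {
        if (Gp < 0) viol <- -Gp else if (Gn > 0) viol <- Gn
      } else if (beta[i] > 0) viol <- abs(Gp) else viol <- abs(Gn)
      maxViol <- max(maxViol, viol)
      d <- if (Gp < H[i] * beta[i]) -Gp / H[i]
           else if (Gn > H[i] * beta[i]) -Gn / H[i]
           else -beta[i]
      b0 <- beta[i]
      beta[i] <- min(max(beta[i] + d, -U), U)
      if (beta[i] != b0) w <- w + (beta[i] - b0) * X[i, ]
    }
    newObj <- 0.5 * sum(w^2) + 0.5 * lambda * sum(beta^2) -
      sum(y * beta) + epsilon * sum(abs(beta))
    if (is.finite(obj) && abs(obj - newObj) <= tol * max(1, abs(newObj)) &&
        maxViol < 0.1 * sqrt(tol))
      { obj <- newObj; break }
    obj <- newObj
  }
  list(w = w, beta = beta, dualObjective = obj, epochs = epoch)
}

#' Train a large linear classifier
#'
#' Minimizes the L2-regularized objective
#' \deqn{\min_w \frac12 w^T w + C \sum_i \xi(w; s_i, y_i)}
#' with logistic loss (\code{"lr_l2"}) or squared hinge loss
#' (\code{"svm_l2_l2loss"}) over element-wise samples with sign
#' labels. Deterministic given the sample order and seed.
#'
#' @param samples a [SampleSet-class] with \code{labelMode = "sign"}
#'   containing both classes.
#' @param objective \code{"lr_l2"} or \code{"svm_l2_l2loss"}.
#' @param C positive penalty parameter.
#' @param tol relative objective tolerance (default 1e-4).
#' @param maxIter iteration cap; non-convergence warns rather than fails.
#' @param bias include a (regularized, augmented) bias term.
#' @param seed integer seed for the dual solver's coordinate order.
#' @param formulation \code{"primal"} (default) or \code{"dual"}
#'   (coordinate descent; SVM only).
#' @return A [LinearModel-class].
#' @export
trainClassifier <- function(samples,
                            objective = c("lr_l2", "svm_l2_l2loss"),
                            C = 1, tol = 1e-4, maxIter = 1000L,
                            bias = TRUE, seed = 1L,
                            formulation = c("primal", "dual")) {
  objective <- match.arg(objective)
  formulation <- match.arg(formulation)
  stopifnot(samples@labelMode == "sign", C > 0, tol > 0)
  X <- samples@features
  y <- samples@labels
  if (!all(is.finite(X))) stop("non-finite feature value in samples")
  if (length(unique(y)) < 2)
    stop("training samples contain a single class")
  if (formulation == "dual") {
    if (objective != "svm_l2_l2loss")
      stop("dual formulation implemented for svm_l2_l2loss only")
    Xa <- if (bias) cbind(X, 1) else X
    set.seed(seed)
    fit <- .dcdSVM(Xa, y, C, tol, maxIter)
    d <- ncol(X)
    w <- fit$w[seq_len(d)]
    b <- if (bias) fit$w[d + 1L] else 0
    m <- drop(Xa %*% fit$w)
    pobj <- 0.5 * sum(fit$w^2) +
      C * sum(.lossGrad(objective, m, y)$loss)
    info <- list(iterations = fit$epochs, objective = pobj,
                 dualObjective = fit$dualObjective, tol = tol,
                 converged = fit$epochs < maxIter,
                 formulation = "dual")
  } else {
    fit <- .solvePrimal(X, y, objective, C, 0, tol, maxIter, bias)
    w <- fit$weights; b <- fit$bias
    info <- list(iterations = fit$iterations, objective = fit$objective,
                 tol = tol, converged = fit$converged,
                 formulation = "primal")
  }
  methods::new(Class = "LinearModel", weights = w, bias = b,
               objective = objective, C = C, epsilon = 0,
               p = NA_real_, solverInfo = info)
}

#' Predict class labels and decision values
#'
#' Decision value \eqn{w^T s + b}; label is +1 for a strictly positive
#' decision and -1 otherwise (an exactly-zero decision is conservatively
#' "not missing").
#'
#' @param model a classifier [LinearModel-class].
#' @param samples a [SampleSet-class] with matching feature length.
#' @return data.frame with columns \code{decision} and \code{label}.
#' @export
predictClassifier <- function(model, samples) {
  X <- samples@features
  if (ncol(X) != length(model@weights))
    stop("feature dimension mismatch: model has ", length(model@weights),
         ", samples have ", ncol(X))
  d <- drop(X %*% model@weights) + model@bias
  data.frame(decision = d, label = ifelse(d > 0, 1, -1))
}

#' Stratified k-fold cross-validation of a linear classifier
#'
#' Folds are stratified by class and assigned from a seeded shuffle, so
#' the same seed reproduces the same report. Accuracy is the fraction
#' of correct sign predictions on each held-out fold.
#'
#' @inheritParams trainClassifier
#' @param k number of folds (>= 2; must not exceed the minority class size).
#' @param seed integer seed controlling fold assignment.
#' @return List with \code{k}, \code{perFoldAccuracy}, \code{meanAccuracy},
#'   \code{seed}, \code{foldAssignment}.
#' @export
crossValidate <- function(samples, objective = c("lr_l2", "svm_l2_l2loss"),
                          C = 1, k = 5L, seed = 1L, tol = 1e-4,
                          maxIter = 1000L, bias = TRUE) {
  objective <- match.arg(objective)
  stopifnot(samples@labelMode == "sign", k >= 2)
  y <- samples@labels
  minority <- min(table(y))
  if (k > minority)
    stop("k = ", k, " exceeds the minority class size (", minority, ")")
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  acc <- vapply(seq_len(k), function(f) {
    tr <- fold != f
    sub <- methods::new("SampleSet",
                        elementIndex = samples@elementIndex[tr, , drop = FALSE],
                        features = samples@features[tr, , drop = FALSE],
                        labels = y[tr], labelMode = "sign", role = "train")
    mod <- trainClassifier(sub, objective, C = C, tol = tol,
                           maxIter = maxIter, bias = bias)
    ho <- methods::new("SampleSet",
                       elementIndex = samples@elementIndex[!tr, , drop = FALSE],
                       features = samples@features[!tr, , drop = FALSE],
                       labels = y[!tr], labelMode = "sign", role = "test")
    mean(predictClassifier(mod, ho)$label == y[!tr])
  }, numeric(1))
  list(k = k, perFoldAccuracy = acc, meanAccuracy = mean(acc),
       seed = seed, foldAssignment = fold)
}

#' Train a linear support vector regressor
#'
#' Minimizes \eqn{\frac12 w^T w + C \sum_i \max(0, |y_i - w^T x_i| -
#' \epsilon)^p} with \eqn{p \in \{1, 2\}}. Three variants are
#' available, mirroring the standard solver families for this problem:
#' the dual problem for p = 1, and the primal or dual problem for
#' p = 2 (the smooth primal is the default). The p = 1 primal is not
#' smooth and is not offered.
#'
#' @param samples a [SampleSet-class] with \code{labelMode = "value"}.
#' @param p loss exponent: 1 (absolute) or 2 (squared).
#' @param formulation \code{"primal"} (p = 2 only) or \code{"dual"}.
#' @param C positive penalty parameter.
#' @param epsilon insensitivity zone half-width (>= 0).
#' @param tol relative objective tolerance.
#' @param maxIter iteration cap.
#' @param bias include an augmented bias term.
#' @param seed seed for the dual solver's coordinate order.
#' @return A [LinearModel-class].
#' @export
trainSVR <- function(samples, p = 2, formulation = c("primal", "dual"),
                     C = 1, epsilon = 0.1, tol = 1e-4, maxIter = 1000L,
                     bias = TRUE, seed = 1L) {
  formulation <- match.arg(formulation)
  stopifnot(samples@labelMode == "value", C > 0, epsilon >= 0)
  if (!p %in% c(1, 2)) stop("p must be 1 or 2")
  if (p == 1 && formulation == "primal")
    stop("unsupported variant: the p = 1 primal is not smooth; ",
         "use formulation = 'dual'")
  X <- samples@features
  y <- samples@labels
  if (nrow(X) < 2) stop("need at least 2 samples")
  objective <- if (p == 1) "svr_l1loss" else "svr_l2loss"
  if (formulation == "primal") {
    fit <- .solvePrimal(X, y, objective, C, epsilon, tol, maxIter, bias)
    w <- fit$weights; b <- fit$bias
    info <- list(iterations = fit$iterations, objective = fit$objective,
                 tol = tol, converged = fit$converged,
                 formulation = "primal")
  } else {
    Xa <- if (bias) cbind(X, 1) else X
    set.seed(seed)
    fit <- .dcdSVR(Xa, y, C, epsilon, p, tol, maxIter)
    d <- ncol(X)
    w <- fit$w[seq_len(d)]
    b <- if (bias) fit$w[d + 1L] else 0
    m <- drop(Xa %*% fit$w)
    pobj <- 0.5 * sum(fit$w^2) +
      C * sum(.lossGrad(objective, m, y, epsilon)$loss)
    info <- list(iterations = fit$epochs, objective = pobj,
                 dualObjective = fit$dualObjective, tol = tol,
                 converged = fit$epochs < maxIter, formulation = "dual")
  }
  methods::new(Class = "LinearModel", weights = w, bias = b,
               objective = objective, C = C, epsilon = epsilon,
               p = as.numeric(p), solverInfo = info)
}

#' Predict with a linear support vector regressor
#'
#' @param model an SVR [LinearModel-class].
#' @param samples a [SampleSet-class] with matching feature length.
#' @return Numeric vector of predictions \eqn{w^T s + b}.
#' @export
predictSVR <- function(model, samples) {
  X <- samples@features
  if (ncol(X) != length(model@weights))
    stop("feature dimension mismatch: model has ", length(model@weights),
         ", samples have ", ncol(X))
  drop(X %*% model@weights) + model@bias
}

#' Decision values over whole-matrix element samples
#'
#' Evaluates a fitted linear model on the element-wise samples of the
#' given genes without materializing their feature matrices: for gene
#' g and cell j the decision is \eqn{\sum_{c<j} w_c v_c + \sum_{c>j}
#' w_{c-1} v_c + b} (the deleted-own-cell feature layout), computed
#' with two running sums in O(n) per gene.
#'
#' @param model a [LinearModel-class] trained on n - 1 features.
#' @param x an [ExpressionMatrix-class] with n cells.
#' @param genes gene ids to evaluate (default: all).
#' @param blockSize genes per dense block.
#' @return Numeric matrix (length(genes) x n) of decision values with
#'   gene/cell dimnames.
#' @export
matrixDecisionValues <- function(model, x, genes = geneIds(x),
                                 blockSize = 1000L) {
  n <- ncol(x)
  w <- model@weights
  if (length(w) != n - 1L)
    stop("model has ", length(w), " weights; matrix needs ", n - 1L)
  v <- exprValues(x)
  rows <- match(genes, geneIds(x))
  stopifnot(!anyNA(rows))
  out <- matrix(NA_real_, length(genes), n,
                dimnames = list(genes, cellIds(x)))
  starts <- seq(1L, length(rows), by = blockSize)
  for (s in starts) {
    blk <- s:min(s + blockSize - 1L, length(rows))
    V <- as.matrix(v[rows[blk], , drop = FALSE])
    A1 <- sweep(V[, -n, drop = FALSE], 2L, w, `*`)
    A2 <- sweep(V[, -1L, drop = FALSE], 2L, w, `*`)
    pref <- cbind(0, t(apply(A1, 1L, cumsum)))
    suf <- cbind(t(apply(A2[, rev(seq_len(n - 1L)), drop = FALSE],
                         1L, cumsum))[, rev(seq_len(n - 1L)), drop = FALSE],
                 0)
    out[blk, ] <- pref + suf + model@bias
  }
  out
}

#' Write / read a linear model as a small text file
#'
#' Self-describing plain-text serialization (objective tag, C, epsilon,
#' p, bias, weight vector at full precision).
#'
#' @param model a [LinearModel-class].
#' @param path file path.
#' @return \code{writeLinearModel}: invisibly, \code{path};
#'   \code{readLinearModel}: the restored model.
#' @export
writeLinearModel <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("scDropImpute-linear-model 1",
               paste("objective", model@objective),
               paste("C", format(model@C, digits = 17)),
               paste("epsilon", format(model@epsilon, digits = 17)),
               paste("p", model@p),
               paste("bias", format(model@bias, digits = 17)),
               paste("weights", length(model@weights)),
               format(model@weights, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname writeLinearModel
#' @export
readLinearModel <- function(path) {
  ln <- readLines(path)
  if (!startsWith(ln[1], "scDropImpute-linear-model"))
    stop("not a linear model file: ", path)
  field <- function(key) {
    hit <- grep(paste0("^", key, " "), ln, value = TRUE)[1]
    strsplit(hit, " ", fixed = TRUE)[[1]][2]
  }
  numField <- function(key) {
    val <- field(key)
    if (val %in% c("NA", "NaN")) NA_real_ else as.numeric(val)
  }
  nw <- as.integer(field("weights"))
  wStart <- grep("^weights ", ln)[1] + 1L
  methods::new(Class = "LinearModel",
               weights = as.numeric(ln[wStart:(wStart + nw - 1L)]),
               bias = numField("bias"),
               objective = field("objective"),
               C = numField("C"),
               epsilon = numField("epsilon"),
               p = numField("p"),
               solverInfo = list(objective = NA_real_, restored = TRUE))
}
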