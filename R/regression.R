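#' Default regularisation grid
#'
#' @param n number of grid points, log-spaced over `[1e-4, 1e4]`.
#' @return Ascending numeric vector of lambda values.
#' @export
default_lambda_grid <- function(n = 50L) 10^seq(-4, 4, length.out = n)

#' Matrix product as a MapReduce program
#'
#' Computes `C = A %*% B` via the cellwise decomposition
#' `c[i,k] = A[i,] . B[,k]`: the input multiset holds one pair per output
#' cell carrying the row of A and column of B, the mapper emits one partial
#' dot product per fixed block of the shared dimension, and the reducer sums
#' the (canonically ordered) partials per cell. The block structure is
#' independent of the worker count, so results are bit-identical across P.
#'
#' @param A,B conformable numeric matrices (a plain vector is treated as a
#'   one-column matrix).
#' @param engine an [engine_config()].
#' @param block_size shared-dimension block length handled by one mapper
#'   emission.
#' @return The product matrix, `nrow(A)` x `ncol(B)`.
#' @export
mr_multiply <- function(A, B, engine = engine_config(), block_size = 2048L) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  if (ncol(A) != nrow(B)) {
    stop_("non-conformable arguments: A is ", nrow(A), "x", ncol(A),
          ", B is ", nrow(B), "x", ncol(B))
  }
  shared <- ncol(A)
  n_blocks <- max(1L, ceiling(shared / block_size))
  blocks <- split(seq_len(shared), ceiling(seq_len(shared) * n_blocks / shared))
  nr <- nrow(A)
  nc <- ncol(B)
  input <- vector("list", nr * nc)
  idx <- 1L
  for (k in seq_len(nc)) {
    bk <- B[, k]
    for (i in seq_len(nr)) {
      input[[idx]] <- kv(c(i, k), list(a = A[i, ], b = bk))
      idx <- idx + 1L
    }
  }
  prog <- mr_program(mr_round(
    mapper = function(pair) {
      a <- pair$value$a
      b <- pair$value$b
      lapply(blocks, function(jj) kv(pair$key, sum(a[jj] * b[jj])))
    },
    reducer = function(key, values) {
      list(kv(key, sum(unlist(values, use.names = FALSE))))
    }
  ))
  out <- execute_program(prog, input, engine)
  C <- matrix(0, nr, nc)
  for (p in out) C[p$key[1L], p$key[2L]] <- p$value
  C
}

as_design <- function(X) {
  if (inherits(X, "score_matrix")) return(X$values)
  as.matrix(X)
}

check_alignment <- function(Xm, Y) {
  if (length(Y) != nrow(Xm)) {
    stop_("X has ", nrow(Xm), " genes but Y has ", length(Y))
  }
  if (!is.null(names(Y)) && !is.null(rownames(Xm)) &&
      !identical(names(Y), rownames(Xm))) {
    stop_("gene ordering of X and Y differs")
  }
}

new_fit <- function(beta, lambda, Xm, Y, n_pred, penalize_bias = NA,
                    cv_table = NULL, cv_seed = NULL) {
  yhat <- drop(Xm %*% beta)
  residuals <- Y - yhat
  structure(list(
    beta = stats::setNames(drop(beta), colnames(Xm)),
    lambda = lambda,
    penalize_bias = penalize_bias,
    yhat = stats::setNames(yhat, rownames(Xm)),
    residuals = stats::setNames(residuals, rownames(Xm)),
    adj_r2 = adjusted_r2(Y, yhat, n_pred),
    n_predictors = n_pred,
    feature_names = colnames(Xm),
    cv_table = cv_table,
    cv_seed = cv_seed
  ), class = "epi_fit")
}

#' @export
print.epi_fit <- function(x, ...) {
  cat("Expression model fit:", length(x$beta), "coefficients, lambda =",
      format(x$lambda, digits = 4), "\n")
  cat("  adj. R2 =", format(x$adj_r2, digits = 4), "over",
      length(x$yhat), "genes\n")
  invisible(x)
}

#' Ordinary least squares expression model
#'
#' Fits `Y = X beta + eps` by the normal equations. The two large products,
#' `X'X` and `X'Y`, are computed through [mr_multiply()]; the final N x N
#' system is solved single-node with a stable linear solve (the
#' communication overhead of the distributed path cannot be amortised over
#' an N x N matrix).
#'
#' @param X a [score_matrix()] (or plain design matrix) with M rows >> N
#'   columns.
#' @param Y numeric expression vector aligned to X's gene order.
#' @param engine an [engine_config()].
#' @return An object of class `epi_fit` with elements `beta`, `lambda` (0),
#'   `yhat`, `residuals`, `adj_r2`, `cv_table` (NULL).
#' @export
fit_ols <- function(X, Y, engine = engine_config()) {
  Xm <- as_design(X)
  check_alignment(Xm, Y)
  if (nrow(Xm) <= ncol(Xm)) stop_("need more genes than predictors (M > N)")
  A <- mr_multiply(t(Xm), Xm, engine)
  Bv <- mr_multiply(t(Xm), matrix(Y, ncol = 1L), engine)
  if (rcond(A) < 1e-12) {
    stop_("X'X is singular or ill-conditioned; consider L2 regularisation ",
          "(fit_ridge) or dropping collinear features")
  }
  beta <- solve(A, Bv)
  n_pred <- if (inherits(X, "score_matrix")) n_predictors_of(X) else ncol(Xm)
  new_fit(beta, 0, Xm, unname(Y), n_pred)
}

ridge_penalty_diag <- function(X, p, penalize_bias) {
  d <- rep(1, p)
  if (!penalize_bias && inherits(X, "score_matrix") && X$has_bias) d[p] <- 0
  d
}

#' L2-regularised (ridge) expression model
#'
#' Solves `argmin ||Y - X beta||^2 + lambda ||beta||^2` by the closed form
#' `beta = (X'X + lambda D)^{-1} X'Y`, with `D = I_N` by default (every
#' coefficient penalised, including the unity bias term) or with a zero at
#' the bias position when `penalize_bias = FALSE`. `method = "augmented"`
#' instead stacks `sqrt(lambda) D` rows under X and zeros under Y and runs
#' the OLS route on the augmented system; the two routes agree to numerical
#' precision and `lambda = 0` reduces exactly to [fit_ols()].
#'
#' @inheritParams fit_ols
#' @param lambda non-negative regularisation strength.
#' @param penalize_bias include the bias coefficient in the penalty.
#' @param method `"normal"` (closed form) or `"augmented"` (data
#'   augmentation).
#' @return An object of class `epi_fit`.
#' @export
fit_ridge <- function(X, Y, lambda, penalize_bias = TRUE,
                      method = c("normal", "augmented"),
                      engine = engine_config()) {
  method <- match.arg(method)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop_("`lambda` must be a single non-negative number")
  }
  Xm <- as_design(X)
  check_alignment(Xm, Y)
  p <- ncol(Xm)
  d <- ridge_penalty_diag(X, p, penalize_bias)
  n_pred <- if (inherits(X, "score_matrix")) n_predictors_of(X) else p
  if (method == "augmented") {
    Xa <- rbind(Xm, sqrt(lambda) * diag(d, p))
    Ya <- c(unname(Y), rep(0, p))
    A <- mr_multiply(t(Xa), Xa, engine)
    Bv <- mr_multiply(t(Xa), matrix(Ya, ncol = 1L), engine)
  } else {
    A <- mr_multiply(t(Xm), Xm, engine) + lambda * diag(d, p)
    Bv <- mr_multiply(t(Xm), matrix(Y, ncol = 1L), engine)
  }
  if (rcond(A) < 1e-14) stop_("penalised system is singular; increase lambda")
  beta <- solve(A, Bv)
  new_fit(beta, lambda, Xm, unname(Y), n_pred, penalize_bias = penalize_bias)
}

#' Select lambda by the 10-fold one-standard-error rule
#'
#' Genes are permuted (seeded) into k near-equal folds. For each fold the
#' training products `X'X` and `X'Y` are formed once through
#' [mr_multiply()] (they do not depend on lambda) and the ridge system is
#' solved per grid value; the CV error is the per-fold mean squared
#' prediction error on the held-out genes. The selected lambda is the
#' largest grid value whose mean CV error is within one standard error
#' (the SE of the k fold errors at the minimising lambda) of the minimum.
#'
#' @inheritParams fit_ridge
#' @param grid non-empty ascending vector of non-negative lambda values.
#' @param k_folds number of CV folds.
#' @param seed integer seed fixing the fold permutation.
#' @return `list(lambda =, cv_table =)` where `cv_table` has one row per
#'   grid value with columns `lambda`, `mean_cv`, `se`.
#' @export
select_lambda <- function(X, Y, grid = default_lambda_grid(), k_folds = 10L,
                          seed = 0L, penalize_bias = TRUE,
                          engine = engine_config()) {
  Xm <- as_design(X)
  check_alignment(Xm, Y)
  M <- nrow(Xm)
  if (length(grid) == 0L || any(grid < 0)) {
    stop_("`grid` must be a non-empty vector of non-negative values")
  }
  if (is.unsorted(grid)) stop_("`grid` must be sorted ascending")
  if (k_folds > M) stop_("k_folds (", k_folds, ") exceeds number of genes (", M, ")")
  p <- ncol(Xm)
  d <- ridge_penalty_diag(X, p, penalize_bias)
  folds <- make_folds(M, k_folds, seed)
  Y <- unname(Y)
  errs <- matrix(NA_real_, k_folds, length(grid))
  for (f in seq_len(k_folds)) {
    test <- folds == f
    Xtr <- Xm[!test, , drop = FALSE]
    Ytr <- Y[!test]
    A <- mr_multiply(t(Xtr), Xtr, engine)
    Bv <- mr_multiply(t(Xtr), matrix(Ytr, ncol = 1L), engine)
    Xte <- Xm[test, , drop = FALSE]
    Yte <- Y[test]
    for (g in seq_along(grid)) {
      beta <- solve(A + grid[g] * diag(d, p), Bv)
      errs[f, g] <- mean((Yte - drop(Xte %*% beta))^2)
    }
  }
  mean_cv <- colMeans(errs)
  se <- apply(errs, 2L, stats::sd) / sqrt(k_folds)
  i_min <- which.min(mean_cv)
  threshold <- mean_cv[i_min] + se[i_min]
  lambda <- max(grid[mean_cv <= threshold])
  list(lambda = lambda,
       cv_table = data.frame(lambda = grid, mean_cv = mean_cv, se = se),
       seed = seed, k_folds = k_folds)
}

make_folds <- function(n, k, seed) {
  with_local_seed(seed, {
    fold <- integer(n)
    fold[sample.int(n)] <- rep(seq_len(k), length.out = n)
    fold
  })
}

#' Fit an expression model with automatic or fixed lambda
#'
#' Convenience wrapper: `lambda = "auto"` runs [select_lambda()] and fits
#' the ridge model at the selected value (recording the CV table in the
#' fit); a numeric lambda fits directly.
#'
#' @inheritParams select_lambda
#' @param lambda `"auto"` or a single non-negative number.
#' @return An object of class `epi_fit`.
#' @export
fit_expression_model <- function(X, Y, lambda = "auto",
                                 grid = default_lambda_grid(), k_folds = 10L,
                                 seed = 0L, penalize_bias = TRUE,
                                 engine = engine_config()) {
  if (identical(lambda, "auto")) {
    sel <- select_lambda(X, Y, grid = grid, k_folds = k_folds, seed = seed,
                         penalize_bias = penalize_bias, engine = engine)
    fit <- fit_ridge(X, Y, sel$lambda, penalize_bias = penalize_bias,
                     engine = engine)
    fit$cv_table <- sel$cv_table
    fit$cv_seed <- seed
    return(fit)
  }
  fit_ridge(X, Y, lambda, penalize_bias = penalize_bias, engine = engine)
}

#' Predict expression from a fitted model
#'
#' One matrix--vector product, `yhat = X beta`.
#'
#' @param object an `epi_fit`.
#' @param newdata a [score_matrix()] or design matrix with the fit's
#'   predictor count.
#' @param ... unused.
#' @return Numeric vector of predictions (named by gene when available).
#' @export
predict.epi_fit <- function(object, newdata, ...) {
  Xm <- as_design(newdata)
  if (ncol(Xm) != length(object$beta)) {
    stop_("newdata has ", ncol(Xm), " columns but the model has ",
          length(object$beta), " coefficients")
  }
  drop(Xm %*% object$beta)
}

#' Adjusted coefficient of determination
#'
#' `R2 = 1 - SSE/SST` and
#' `adj R2 = 1 - (1 - R2) (M - 1) / (M - p - 1)`, penalising goodness of fit
#' for the number of free predictors p (the bias term is not counted as a
#' predictor).
#'
#' @param y observed values (length M, non-constant).
#' @param yhat predictions, same length.
#' @param n_predictors number of predictors p, with `M > p + 1`.
#' @return Adjusted R-squared (<= 1; can be negative).
#' @export
adjusted_r2 <- function(y, yhat, n_predictors) {
  if (length(y) != length(yhat)) stop_("y and yhat differ in length")
  M <- length(y)
  if (M <= n_predictors + 1L) stop_("need M > n_predictors + 1")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop_("Y has zero variance; adjusted R2 undefined")
  r2 <- 1 - sum((y - yhat)^2) / sst
  1 - (1 - r2) * (M - 1) / (M - n_predictors - 1)
}
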