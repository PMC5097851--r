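test_that("mr_multiply matches the naive triple-loop product", {
  expect_equal(mr_multiply(matrix(c(1, 3, 2, 4), 2), matrix(c(5, 7, 6, 8), 2)),
               matrix(c(19, 43, 22, 50), 2))

  A <- with_local_seed(1, matrix(rnorm(12), 4))
  expect_equal(mr_multiply(A, diag(3)), A)

  for (seed in 1:25) {
    dims <- with_local_seed(seed, sample.int(9, 3) + 1L)
    A <- with_local_seed(seed + 100, matrix(rnorm(dims[1] * dims[2]), dims[1]))
    B <- with_local_seed(seed + 200, matrix(rnorm(dims[2] * dims[3]), dims[2]))
    got <- mr_multiply(A, B)
    want <- naive_multiply(A, B)
    expect_equal(got, want, tolerance = 1e-10)
  }

  expect_error(mr_multiply(matrix(0, 2, 3), matrix(0, 2, 3)),
               "non-conformable.*2x3.*2x3")
})

test_that("mr_multiply is identical across worker counts and block sizes", {
  A <- with_local_seed(5, matrix(rnorm(7 * 30), 7))
  B <- with_local_seed(6, matrix(rnorm(30 * 5), 30))
  c1 <- mr_multiply(A, B, engine_config(1), block_size = 8L)
  c4 <- mr_multiply(A, B, engine_config(4), block_size = 8L)
  expect_identical(c1, c4)
})

test_that("OLS recovers exact linear relationships and the intercept-only mean", {
  X <- rand_design(100, 3, seed = 2)
  beta <- c(1.5, -2, 0.25, 3)
  Y <- stats::setNames(drop(X$values %*% beta), rownames(X$values))
  fit <- fit_ols(X, Y)
  expect_equal(unname(fit$beta), beta, tolerance = 1e-9)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)

  bias_only <- assemble_score_matrix(list(), add_bias = TRUE,
                                     gene_ids = rownames(X$values))
  Y2 <- Y + with_local_seed(3, rnorm(100))
  fit2 <- fit_ols(bias_only, Y2)
  expect_equal(unname(fit2$beta), mean(Y2))
})

test_that("OLS agrees with a dense normal-equation oracle and satisfies the normal equations", {
  for (seed in 1:10) {
    X <- rand_design(80, 4, seed = seed)
    Y <- with_local_seed(seed + 50,
                         drop(X$values %*% rnorm(5)) + rnorm(80, 0, 0.5))
    names(Y) <- rownames(X$values)
    fit <- fit_ols(X, Y)
    Xm <- X$values
    want <- solve(crossprod(Xm), crossprod(Xm, Y))
    expect_equal(unname(fit$beta), unname(drop(want)), tolerance = 1e-8)
    resid_norm <- sqrt(sum((crossprod(Xm) %*% fit$beta - crossprod(Xm, Y))^2))
    expect_lte(resid_norm, 1e-6 * sqrt(sum(crossprod(Xm, Y)^2)))
    expect_equal(fit$residuals, Y - fit$yhat)
  }
})

test_that("singular designs are rejected with advice to regularise", {
  v <- cbind(f1 = rep(1, 30), f2 = rep(2, 30), bias = 1)
  rownames(v) <- sprintf("g%02d", 1:30)
  X <- score_matrix(v, has_bias = TRUE)
  Y <- stats::setNames(rnorm(30), rownames(v))
  expect_error(fit_ols(X, Y), "regularisation")
})

test_that("ridge at lambda 0 equals OLS and the augmented route equals the closed form", {
  for (seed in 1:50) {
    M <- 40L
    X <- rand_design(M, 3, seed = seed)
    Y <- with_local_seed(seed + 500,
                         drop(X$values %*% rnorm(4)) + rnorm(M, 0, 0.7))
    names(Y) <- rownames(X$values)
    lam <- with_local_seed(seed + 900, 10^runif(1, -3, 2))

    ols <- fit_ols(X, Y)
    r0 <- fit_ridge(X, Y, 0)
    expect_equal(r0$beta, ols$beta)

    closed <- fit_ridge(X, Y, lam)
    aug <- fit_ridge(X, Y, lam, method = "augmented")
    expect_equal(closed$beta, aug$beta, tolerance = 1e-8)

    # with the bias excluded from the penalty too
    closed_nb <- fit_ridge(X, Y, lam, penalize_bias = FALSE)
    aug_nb <- fit_ridge(X, Y, lam, penalize_bias = FALSE,
                        method = "augmented")
    expect_equal(closed_nb$beta, aug_nb$beta, tolerance = 1e-8)
  }
})

test_that("penalised coefficients shrink towards zero as lambda grows", {
  X <- rand_design(60, 4, seed = 77)
  Y <- with_local_seed(78, drop(X$values %*% c(1, -1, 2, 0.5, 3)) + rnorm(60))
  names(Y) <- rownames(X$values)
  norms <- vapply(c(0, 0.1, 1, 10, 100, 1e4, 1e6), function(lam) {
    sqrt(sum(fit_ridge(X, Y, lam)$beta^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
  huge <- fit_ridge(X, Y, 1e10)
  expect_lt(max(abs(huge$beta)), 1e-4)
  expect_error(fit_ridge(X, Y, -1), "non-negative")
})

test_that("the 1-SE rule picks the largest lambda within one SE of the CV minimum", {
  X <- rand_design(120, 4, seed = 31)
  Y <- with_local_seed(32, drop(X$values %*% c(1, -0.5, 0.8, -1, 2)) +
                         rnorm(120, 0, 0.8))
  names(Y) <- rownames(X$values)
  grid <- default_lambda_grid(20)
  sel <- select_lambda(X, Y, grid = grid, k_folds = 10, seed = 4)
  tab <- sel$cv_table
  i_min <- which.min(tab$mean_cv)
  thr <- tab$mean_cv[i_min] + tab$se[i_min]
  expect_lte(tab$mean_cv[tab$lambda == sel$lambda], thr)
  expect_equal(sel$lambda, max(grid[tab$mean_cv <= thr]))
  # no larger grid value satisfies the bound
  larger <- grid[grid > sel$lambda]
  if (length(larger)) {
    expect_true(all(tab$mean_cv[tab$lambda %in% larger] > thr))
  }
})

test_that("CV fold errors are reproduced by an independent refit of each fold", {
  X <- rand_design(60, 3, seed = 41)
  Y <- with_local_seed(42, drop(X$values %*% c(1, 2, -1, 0.5)) + rnorm(60, 0, 0.6))
  names(Y) <- rownames(X$values)
  grid <- c(0.01, 1, 100)
  sel <- select_lambda(X, Y, grid = grid, k_folds = 5, seed = 9)
  folds <- epimapred:::make_folds(60, 5, seed = 9)
  oracle <- vapply(grid, function(lam) {
    mean(vapply(1:5, function(f) {
      tr <- folds != f
      Xtr <- X$values[tr, , drop = FALSE]
      fit <- fit_ridge(score_matrix(Xtr, has_bias = TRUE), unname(Y)[tr], lam)
      mean((unname(Y)[!tr] - drop(X$values[!tr, , drop = FALSE] %*% fit$beta))^2)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(sel$cv_table$mean_cv, oracle, tolerance = 1e-10)
})

test_that("degenerate lambda grids behave deterministically", {
  X <- rand_design(40, 2, seed = 51)
  Y <- with_local_seed(52, drop(X$values %*% c(1, -1, 2)) + rnorm(40, 0, 0.5))
  names(Y) <- rownames(X$values)
  one <- select_lambda(X, Y, grid = 3.7, k_folds = 5, seed = 1)
  expect_equal(one$lambda, 3.7)
  dup <- select_lambda(X, Y, grid = c(2, 2, 2), k_folds = 5, seed = 1)
  expect_equal(dup$lambda, 2)
  expect_error(select_lambda(X, Y, k_folds = 50, seed = 1), "exceeds")
  expect_error(select_lambda(X, Y, grid = numeric(0)), "non-empty")
})

test_that("predictions are the matrix-vector product X beta", {
  X <- rand_design(30, 3, seed = 61)
  Y <- with_local_seed(62, drop(X$values %*% c(1, 0, -1, 2)) + rnorm(30, 0, 0.3))
  names(Y) <- rownames(X$values)
  fit <- fit_ridge(X, Y, 0.5)
  expect_equal(predict(fit, X), drop(X$values %*% fit$beta))
  fit$beta[] <- 0
  expect_equal(unname(predict(fit, X)), rep(0, 30))
  expect_error(predict(fit, X$values[, 1:2]), "coefficients")
})

test_that("adjusted R2 follows the Wherry formula", {
  y <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(adjusted_r2(y, y, 2), 1)
  # predicting the mean: R2 = 0, adj R2 = 1 - (M-1)/(M-p-1) < 0
  const <- rep(mean(y), 8)
  expect_equal(adjusted_r2(y, const, 2), 1 - 7 / 5)
  # adj R2 <= R2 whenever p >= 1
  yhat <- y + c(0.1, -0.2, 0.3, 0, -0.1, 0.2, -0.3, 0.1)
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_lte(adjusted_r2(y, yhat, 3), r2)
  expect_error(adjusted_r2(rep(1, 8), yhat, 2), "zero variance")
  expect_error(adjusted_r2(y, y, 7), "n_predictors")
})

test_that("ridge can beat OLS in CV error on noisy data (existence of a useful lambda)", {
  # many weak predictors + noise: the regime where shrinkage pays
  M <- 80L
  X <- rand_design(M, 12, seed = 71)
  beta <- c(with_local_seed(72, rnorm(12, 0, 0.15)), 1)
  Y <- stats::setNames(drop(X$values %*% beta), rownames(X$values)) +
    with_local_seed(73, rnorm(M, 0, 1.5))
  grid <- c(0, default_lambda_grid(15))
  sel <- select_lambda(X, Y, grid = sort(grid), k_folds = 10, seed = 5)
  tab <- sel$cv_table
  cv0 <- tab$mean_cv[tab$lambda == 0]
  expect_true(any(tab$mean_cv[tab$lambda > 0] <= cv0 + tab$se[tab$lambda == 0]))
})

test_that("coefficients are recovered within 3 SEs on simulated data", {
  M <- 2000L
  X <- rand_design(M, 4, seed = 81)
  beta_true <- c(1, -0.8, 0.5, -0.3, 2)
  Y <- simulate_expression(X, beta_true, noise_sigma = 0.7, seed = 82)
  fit <- fit_ols(X, Y)
  sigma2_hat <- sum(fit$residuals^2) / (M - 5)
  se <- sqrt(diag(solve(crossprod(X$values))) * sigma2_hat)
  expect_true(all(abs(fit$beta - beta_true) <= 3 * se))
})
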