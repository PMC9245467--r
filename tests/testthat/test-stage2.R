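test_that("block update reduces to OLS at lambda 0 and to zero at lambda_max", {
  set.seed(1)
  X <- matrix(rnorm(20 * 3), 20, 3)
  r <- rnorm(20) + X %*% c(1, 0, -0.5)
  b0 <- sgl_block_update(X, r, 0)
  expect_equal(b0, as.vector(qr.coef(qr(X), r)), tolerance = 1e-7)
  z <- as.vector(crossprod(X, r)) / 20
  lam_max <- max(abs(z)) + sqrt(sum(z^2))   # above any possible entry point
  expect_equal(sgl_block_update(X, r, lam_max), rep(0, 3))
})

test_that("block update matches the proximal-gradient oracle objective", {
  # dedicated one-block ISTA oracle on the identical blockwise objective
  ista_block <- function(X, r, lam, iters = 100000) {
    n <- nrow(X)
    A <- crossprod(X) / n
    c0 <- as.vector(crossprod(X, r)) / n
    step <- 1 / max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
    b <- numeric(ncol(X))
    for (it in seq_len(iters)) {
      nb <- prox_sgl_vec(b - step * (A %*% b - c0), step, lam)
      if (max(abs(nb - b)) < 1e-13) { b <- nb; break }
      b <- nb
    }
    b
  }
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 3), 20, 3)
    r <- rnorm(20) + X %*% rnorm(3)
    lam <- 0.2
    b <- sgl_block_update(X, r, lam)
    oracle <- ista_block(X, r, lam)
    obj <- function(bb) sum((r - X %*% bb)^2) / 40 +
      lam * (sqrt(sum(bb^2)) + sum(abs(bb)))
    expect_equal(obj(b), obj(oracle), tolerance = 1e-5)
  }
})

test_that("pure environmental model gives the closed-form OLS alpha", {
  set.seed(2)
  n <- 50; q <- 2
  E <- matrix(rnorm(n * q), n, q)
  Y <- E %*% c(1.5, -2) + rnorm(n)
  des <- manual_design(Y, E, matrix(0, n, 1), matrix(0, n, 1),
                       matrix(0, n, 1))
  f <- fit_ige(des, lambda = 0.5, standardize = FALSE)
  expect_equal(f$alpha_hat, as.vector(solve(crossprod(E), crossprod(E, Y))),
               tolerance = 1e-6)
  expect_equal(f$b1_hat, matrix(0, 1, q + 1))
  expect_equal(f$gamma_hat, 0)
})

test_that("a penalty above the path maximum leaves only alpha nonzero", {
  pb <- random_stage2_problem(3)
  f <- fit_ige(pb$design, lambda = 1e4, standardize = FALSE)
  expect_true(all(f$b1_hat == 0) && all(f$b2_hat == 0) &&
                all(f$gamma_hat == 0))
  # alpha equals OLS of Y on E alone
  expect_equal(f$alpha_hat,
               as.vector(solve(crossprod(pb$design$E),
                               crossprod(pb$design$E, pb$Y))),
               tolerance = 1e-5)
})

test_that("alternating solver reaches the joint convex minimum", {
  for (seed in 1:6) {
    pb <- random_stage2_problem(seed)
    lam <- 0.3
    f <- fit_ige(pb$design, lambda = lam, tol = 1e-7, max_iter = 2000,
                 standardize = FALSE)
    beta <- c(f$alpha_hat, as.vector(t(f$b1_hat)), as.vector(t(f$b2_hat)),
              f$gamma_hat)
    obj_cd <- ige_objective(pb$X, pb$Y, beta, pb$q, pb$L, pb$p_g, pb$p_r, lam)
    oracle <- ista_ige(pb$X, pb$Y, pb$q, pb$L, pb$p_g, pb$p_r, lam)
    expect_equal(obj_cd, oracle$objective, tolerance = 1e-4)
    expect_equal(f$objective, obj_cd, tolerance = 1e-6)
  }
})

test_that("descent is monotone across outer sweeps", {
  pb <- random_stage2_problem(9)
  lam_seq <- c(0.8, 0.4, 0.2, 0.1, 0.05)
  pf <- fit_path(pb$design, lam_seq, standardize = FALSE)
  # objective at every lambda is optimal, hence no larger than a cold
  # restart stopped after one sweep
  for (i in seq_along(lam_seq)) {
    one <- suppressWarnings(fit_ige(pb$design, lam_seq[i], max_iter = 1,
                                    standardize = FALSE))
    expect_lte(pf$objective[i], one$objective + 1e-8)
  }
})

test_that("path sparsity grows as the penalty falls and warm starts are exact",
{
  pb <- random_stage2_problem(4)
  grid <- c(2, 1, 0.5, 0.25, 0.1, 0.05, 0.01)
  pf <- fit_path(pb$design, grid, tol = 1e-7, standardize = FALSE)
  df <- path_df(pf)
  expect_true(all(diff(df) >= 0))        # nonzeros non-increasing in lambda
  # warm-started fits match cold restarts at each grid point
  for (i in seq_along(grid)) {
    cold <- fit_ige(pb$design, grid[i], tol = 1e-7, max_iter = 2000,
                    standardize = FALSE)
    expect_lte(pf$objective[i], cold$objective + 1e-6)
  }
  # single-value grid equals a single fit
  pf1 <- fit_path(pb$design, 0.5, tol = 1e-7, standardize = FALSE)
  f1 <- fit_ige(pb$design, 0.5, tol = 1e-7, standardize = FALSE)
  expect_equal(pf1$beta[, 1],
               c(f1$alpha_hat, as.vector(t(f1$b1_hat)),
                 as.vector(t(f1$b2_hat)), f1$gamma_hat),
               tolerance = 1e-8)
})

test_that("the zero endpoint returns a dense minimum-norm fit", {
  pb <- random_stage2_problem(5, n = 30, L = 2, p_g = 8, p_r = 8, q = 2)
  pf <- fit_path(pb$design, c(0.5, 0), standardize = FALSE)
  b0 <- pf$beta[, 2]
  expect_gt(mean(b0 != 0), 0.95)         # generically dense
  # it solves the normal equations on the design
  n <- nrow(pb$X)
  expect_lt(max(abs(crossprod(pb$X, pb$Y - pb$X %*% b0) / n)), 1e-8)
})

test_that("bi-level selection zeroes whole blocks and single slots", {
  set.seed(6)
  n <- 200; q <- 1
  E <- matrix(rnorm(n), n, 1)
  GV <- cbind(rnorm(n), rnorm(n))
  # block 1: strong main effect only; block 2: silent
  Y <- 2 * GV[, 1] + rnorm(n, sd = 0.3)
  des <- manual_design(Y, E, GV, matrix(rnorm(n), n, 1),
                       matrix(rnorm(n), n, 1))
  f <- fit_ige(des, lambda = 0.3, standardize = FALSE)
  expect_true(all(f$b1_hat[2, ] == 0))             # whole block out
  expect_true(f$b1_hat[1, 1] != 0)                 # main slot in
  expect_true(any(f$b1_hat[1, ] == 0))             # within-block sparsity
})

test_that("environmental main effects are never penalized", {
  pb <- random_stage2_problem(7)
  for (lam in c(0.1, 1, 10, 1e4)) {
    f <- fit_ige(pb$design, lam, standardize = FALSE)
    expect_true(all(abs(f$alpha_hat) > 0))
  }
})

test_that("cross-validation prefers heavy shrinkage on pure noise", {
  # noise outcome: the best penalty should sit in the upper half of the
  # grid on average over seeds
  grid <- seq(0.02, 1, length.out = 10)
  wins <- 0
  for (seed in 1:10) {
    cfg <- sim_config(n = 60, p_g = 10, p_r = 10, q = 2, L_true = 2,
                      support_size = 2, n_causal_genes = 0,
                      effects_per_gene = 0, n_causal_regulators = 0,
                      seed = seed)
    sim <- simulate_dataset(cfg)
    sim$dataset$Y <- rnorm(60)
    cv <- cross_validate(sim$dataset, L = 2, lambda_grid = grid, folds = 3,
                         seed = seed, refit_stage1 = FALSE,
                         lambda_svd = 0.01, lambda = 0.05)
    if (cv$best_lambda >= stats::median(grid)) wins <- wins + 1
  }
  expect_gte(wins, 6)
})

test_that("leave-one-out cross-validation matches an explicit loop", {
  cfg <- sim_config(n = 20, p_g = 4, p_r = 4, q = 1, L_true = 1,
                    support_size = 2, n_causal_genes = 2,
                    effects_per_gene = 1, n_causal_regulators = 2, seed = 8)
  sim <- simulate_dataset(cfg)
  grid <- c(0.5, 0.1)
  cv <- cross_validate(sim$dataset, L = 1, lambda_grid = grid, folds = 20,
                       seed = 3, refit_stage1 = FALSE, lambda_svd = 0.01,
                       lambda = 0.05)
  # explicit LOO with the same fold assignment and pipeline pieces
  set.seed(3)
  foldid <- sample(rep_len(1:20, 20))
  s1 <- fit_stage1(sim$dataset$G, sim$dataset$R, L = 1, lambda_svd = 0.01,
                   lambda = 0.05)
  errs <- matrix(NA_real_, 20, length(grid))
  for (f in 1:20) {
    tr <- foldid != f
    train <- structure(list(Y = sim$dataset$Y[tr],
                            E = sim$dataset$E[tr, , drop = FALSE],
                            G = sim$dataset$G[tr, , drop = FALSE],
                            R = sim$dataset$R[tr, , drop = FALSE],
                            regulator_blocks = sim$dataset$regulator_blocks),
                       class = "omics_dataset")
    des_tr <- decompose_dataset(train, s1, center = FALSE)
    X_tr <- cbind(des_tr$E, des_tr$X1, des_tr$X2, des_tr$R_resid)
    mu <- colMeans(X_tr); ybar <- mean(train$Y)
    sx <- apply(sweep(X_tr, 2, mu), 2, sd); sx[sx < 1e-12] <- 1
    sy <- sd(train$Y - ybar)
    ws <- local({
      Xs <- sweep(sweep(X_tr, 2, mu), 2, sx, "/")
      yc <- (train$Y - ybar) / sy
      list(X = Xs, Y = yc, n = nrow(Xs), q = ncol(des_tr$E),
           L = ncol(des_tr$GV), p_g = ncol(des_tr$G_resid),
           p_r = ncol(des_tr$R_resid), Gram = crossprod(Xs) / nrow(Xs),
           covYX = as.vector(crossprod(Xs, yc)) / nrow(Xs),
           yty = sum(yc^2) / nrow(Xs), sx = sx, sy = sy)
    })
    pf <- fit_path(ws, grid)
    X_te <- igesel:::heldout_design(sim$dataset, !tr, s1, des_tr)
    pred <- sweep(X_te, 2, mu) %*% pf$beta + ybar
    errs[f, ] <- colMeans((sim$dataset$Y[!tr] - pred)^2)
  }
  expect_equal(cv$cv_errors, colMeans(errs), tolerance = 1e-8)
})
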