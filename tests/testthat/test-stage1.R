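test_that("full shrinkage zeroes the transition matrix, intercepts keep means", {
  set.seed(1)
  R <- matrix(rnorm(40 * 6), 40, 6)
  G <- matrix(rnorm(40 * 4), 40, 4) + 3
  fit <- fit_gene_lasso(G, R, lambda = 1e6)
  expect_equal(fit$Theta_hat, matrix(0, 6, 4), ignore_attr = TRUE)
  expect_equal(fit$intercepts, colMeans(G), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("orthonormal design reduces the per-gene LASSO to soft-thresholding",
{
  # R with R'R/n = I and centered columns (the intercept is fit, so the
  # orthonormal basis must be orthogonal to the ones vector)
  set.seed(2)
  n <- 60
  M <- scale(matrix(rnorm(n * 5), n, 5), scale = FALSE)
  Q <- qr.Q(qr(M)) * sqrt(n)
  theta <- c(1.2, -0.8, 0, 0.4, 0)
  g <- as.vector(Q %*% theta) + rnorm(n, sd = 0.1)
  lam <- 0.3
  fit <- fit_gene_lasso(matrix(g), Q, lambda = lam)
  z <- as.vector(crossprod(Q, g - mean(g))) / n
  oracle <- sign(z) * pmax(abs(z) - lam, 0)
  expect_equal(as.vector(fit$Theta_hat), oracle, tolerance = 1e-4)
})

test_that("near-unpenalized fit recovers a noiseless transition matrix", {
  set.seed(3)
  R <- matrix(rnorm(50 * 10), 50, 10)
  Theta <- matrix(0, 10, 10)
  Theta[cbind(sample(10), sample(10))] <- runif(10, 1, 2)
  G <- R %*% Theta
  fit <- fit_gene_lasso(G, R, lambda = 1e-6)
  expect_lt(max(abs(fit$Theta_hat - Theta)), 1e-3)
})

test_that("constant gene columns are zeroed with a warning", {
  set.seed(4)
  R <- matrix(rnorm(30 * 4), 30, 4)
  G <- cbind(rnorm(30), rep(2, 30))
  expect_warning(fit <- fit_gene_lasso(G, R, lambda = 0.1), "constant")
  expect_equal(fit$Theta_hat[, 2], rep(0, 4), ignore_attr = TRUE)
  expect_equal(fit$intercepts[2], 2)
})

test_that("sparse svd recovers an exact rank-1 matrix at lambda 0", {
  u0 <- c(0, 0.6, 0, 0.8, 0)
  v0 <- c(1, 0, 0, 2, 0, 2) / 3
  M <- 3 * tcrossprod(u0, v0)
  f <- sparse_svd_rank1(M, lambda = 0)
  expect_equal(f$d, 3, tolerance = 1e-6)
  expect_equal(abs(f$u), abs(u0), tolerance = 1e-6)
  expect_equal(abs(f$v), abs(v0), tolerance = 1e-6)
  expect_equal(f$d * tcrossprod(f$u, f$v), M, tolerance = 1e-6)
  # sign convention: largest-magnitude entry of v positive
  expect_gt(f$v[which.max(abs(f$v))], 0)
})

test_that("sparse svd returns the zero triplet on a zero matrix", {
  f <- sparse_svd_rank1(matrix(0, 3, 4), lambda = 0.1)
  expect_equal(f$d, 0)
  expect_equal(f$u, numeric(3))
  expect_equal(f$v, numeric(4))
})

test_that("penalized rank-1 svd matches a grid oracle on its subproblems", {
  # the u-subproblem at fixed unit v minimizes
  # (1/2n)||M - u v'||_F^2 + lambda |u|_1 over the scaled vector u;
  # solve it by independent per-coordinate grid search and compare
  set.seed(5)
  M <- matrix(rnorm(16), 4, 4) + 2 * tcrossprod(c(1, 0, 0, 1), c(0, 1, 1, 0))
  n <- 1; lambda <- 0.1
  f <- sparse_svd_rank1(M, lambda = lambda, n = n)
  expect_true(f$converged)
  # at convergence, u-step fixed point: scaled u equals soft(Mv, n*lambda)
  us <- as.vector(M %*% f$v)
  grid_opt <- vapply(seq_along(us), function(i) {
    cand <- seq(-abs(us[i]) - 1, abs(us[i]) + 1, length.out = 40001)
    obj <- (cand^2 - 2 * cand * us[i]) / (2 * n) + lambda * abs(cand)
    cand[which.min(obj)]
  }, double(1))
  du <- f$d * f$u
  expect_equal(du / sqrt(sum(du^2)) * sqrt(sum(grid_opt^2)), grid_opt,
               tolerance = 1e-3)
  # objective at the fitted triplet is no worse than nearby perturbations
  obj <- function(d, u, v) sum((M - d * tcrossprod(u, v))^2) / (2 * n) +
    lambda * sum(abs(d * u)) + lambda * sum(abs(d * v))
  f0 <- obj(f$d, f$u, f$v)
  set.seed(6)
  for (i in 1:25) {
    up <- f$u + rnorm(4, sd = 0.01); up <- up / sqrt(sum(up^2))
    vp <- f$v + rnorm(4, sd = 0.01); vp <- vp / sqrt(sum(vp^2))
    expect_gte(obj(f$d, up, vp), f0 - 1e-4)
  }
})

test_that("recursive extraction recovers disjoint rank-1 components", {
  supports_u <- list(1:2, 4:5, 7:8)
  supports_v <- list(c(1, 3), c(5, 6), c(8, 10))
  U <- unit_sparse_loadings(10, supports_u, list(c(1, 2), c(2, 1), c(1, 1)))
  V <- unit_sparse_loadings(10, supports_v, list(c(2, 1), c(1, 1), c(1, 2)))
  d <- c(5, 3, 2)
  Theta <- U %*% diag(d) %*% t(V)
  fit <- extract_lrms(Theta, L = 3, lambda_svd = 0)
  expect_equal(fit$d, d, tolerance = 1e-6)
  sv <- svd(Theta)
  expect_equal(fit$d, sv$d[1:3], tolerance = 1e-6)
  for (l in 1:3) {
    expect_equal(abs(fit$U[, l]), abs(U[, l]), tolerance = 1e-6)
    expect_equal(abs(fit$V[, l]), abs(V[, l]), tolerance = 1e-6)
  }
  # complete decomposition leaves a negligible residual
  expect_lt(sqrt(sum(fit$residual^2)), 1e-6)
  # deflation telescopes exactly
  approx <- Reduce(`+`, lapply(1:3, function(l)
    fit$d[l] * tcrossprod(fit$U[, l], fit$V[, l])))
  expect_equal(Theta - approx, fit$residual, tolerance = 1e-12)
})

test_that("L = 1 extraction equals a single rank-1 call", {
  set.seed(7)
  M <- matrix(rnorm(30), 5, 6)
  one <- sparse_svd_rank1(M, lambda = 0.05, n = 2)
  fit <- extract_lrms(M, L = 1, lambda_svd = 0.05, n = 2)
  expect_equal(fit$d, one$d)
  expect_equal(fit$U[, 1], one$u)
  expect_equal(fit$V[, 1], one$v)
})

test_that("unpenalized full-rank extraction reproduces the dense SVD", {
  set.seed(8)
  M <- matrix(rnorm(42), 6, 7)
  fit <- extract_lrms(M, L = 6, lambda_svd = 0)
  sv <- svd(M)
  expect_equal(fit$d, sv$d[1:6], tolerance = 1e-6)
  expect_lt(sqrt(sum(fit$residual^2)), 1e-5)
  expect_true(all(diff(fit$d) <= 1e-8))
})

test_that("the Gram-based lasso engine agrees with glmnet", {
  set.seed(11)
  n <- 80
  R <- matrix(rnorm(n * 12), n, 12)
  Theta <- matrix(0, 12, 3)
  Theta[1:3, 1] <- c(1.5, -1, 0.8); Theta[5:6, 2] <- c(2, 1)
  G <- R %*% Theta + matrix(rnorm(n * 3), n, 3) + 2
  for (lam in c(0.05, 0.2, 0.6)) {
    a <- fit_gene_lasso(G, R, lambda = lam, engine = "gram")
    b <- fit_gene_lasso(G, R, lambda = lam, engine = "glmnet")
    expect_equal(a$Theta_hat, b$Theta_hat, tolerance = 1e-4)
    expect_equal(a$intercepts, b$intercepts, tolerance = 1e-4)
  }
  # cross-validated engines pick near-identical transition matrices on
  # a well-separated signal
  a <- fit_gene_lasso(G, R, seed = 4, engine = "gram")
  b <- fit_gene_lasso(G, R, seed = 4, engine = "glmnet")
  expect_gte(mean((a$Theta_hat != 0) == (b$Theta_hat != 0)), 0.9)
  expect_lt(max(abs(a$Theta_hat - b$Theta_hat)), 0.15)
  expect_true(all(a$Theta_hat[Theta != 0] != 0))
})

test_that("stage 1 recovers generating loading supports on simulated data", {
  cfg <- sim_config(n = 400, p_g = 60, p_r = 60, q = 2, L_true = 6,
                    support_size = 4, n_causal_genes = 10,
                    effects_per_gene = 2, n_causal_regulators = 10,
                    signal = "strong", seed = 17)
  sim <- simulate_dataset(cfg)
  s1 <- fit_stage1(sim$dataset$G, sim$dataset$R, L = 6, lambda_svd = "bic",
                   seed = 17)
  est <- rowSums(abs(s1$V) > 1e-12) > 0
  true <- rowSums(sim$truth$V_true != 0) > 0
  expect_gte(sum(est & true) / sum(true), 0.8)
})
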