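# Independent solvers used as oracles. The package's Stage-2 fitter is
# blockwise coordinate/proximal descent on Gram matrices; the oracle here
# is plain proximal gradient (ISTA) on the explicit design — a different
# algorithm converging to the same global minimum of the convex objective.

# prox of step * lambda * (||b||_2 + ||b||_1) — soft-threshold then
# group shrinkage
prox_sgl_vec <- function(x, step, lambda) {
  u <- sign(x) * pmax(abs(x) - step * lambda, 0)
  nr <- sqrt(sum(u^2))
  if (nr <= step * lambda) return(numeric(length(x)))
  u * (1 - step * lambda / nr)
}

# Full G×E objective on explicit matrices:
# (1/2n)||Y - Xb||^2 + lambda * [sum_blocks (||b||_2 + ||b||_1) + ||gamma||_1]
ige_objective <- function(X, Y, beta, q, L, p_g, p_r, lambda) {
  n <- nrow(X); m <- q + 1
  obj <- sum((Y - X %*% beta)^2) / (2 * n)
  for (b in seq_len(L + p_g)) {
    idx <- q + (b - 1) * m + seq_len(m)
    obj <- obj + lambda * (sqrt(sum(beta[idx]^2)) + sum(abs(beta[idx])))
  }
  gidx <- q + (L + p_g) * m + seq_len(p_r)
  obj + lambda * sum(abs(beta[gidx]))
}

ista_ige <- function(X, Y, q, L, p_g, p_r, lambda, iters = 50000,
                     tol = 1e-12) {
  n <- nrow(X); m <- q + 1; D <- ncol(X)
  A <- crossprod(X) / n
  c0 <- as.vector(crossprod(X, Y)) / n
  step <- 1 / max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  beta <- numeric(D)
  gidx <- q + (L + p_g) * m + seq_len(p_r)
  for (it in seq_len(iters)) {
    grad <- A %*% beta - c0
    z <- beta - step * as.vector(grad)
    nb <- z
    for (b in seq_len(L + p_g)) {
      idx <- q + (b - 1) * m + seq_len(m)
      nb[idx] <- prox_sgl_vec(z[idx], step, lambda)
    }
    if (p_r > 0) {
      nb[gidx] <- sign(z[gidx]) * pmax(abs(z[gidx]) - step * lambda, 0)
    }
    if (max(abs(nb - beta)) < tol) { beta <- nb; break }
    beta <- nb
  }
  list(beta = beta,
       objective = ige_objective(X, Y, beta, q, L, p_g, p_r, lambda))
}

# Build a decomposed_design directly from explicit blocks (bypassing
# Stage 1) so Stage-2 behavior can be tested in isolation.
manual_design <- function(Y, E, GV, G_resid, R_resid) {
  des <- build_design(GV, G_resid, E, center = FALSE)
  structure(list(GV = as.matrix(GV), RU = as.matrix(GV),
                 G_resid = as.matrix(G_resid), R_resid = as.matrix(R_resid),
                 X1 = des$X1, X2 = des$X2, map1 = des$map1, map2 = des$map2,
                 E = as.matrix(E), Y = Y,
                 G = as.matrix(G_resid), R = as.matrix(R_resid)),
            class = "decomposed_design")
}

# Random small Stage-2 problem with known block structure.
random_stage2_problem <- function(seed, n = 60, L = 2, p_g = 4, p_r = 4,
                                  q = 2) {
  set.seed(seed)
  E <- matrix(rnorm(n * q), n, q)
  GV <- matrix(rnorm(n * L), n, L)
  G_resid <- matrix(rnorm(n * p_g), n, p_g)
  R_resid <- matrix(rnorm(n * p_r), n, p_r)
  Y <- rnorm(n) + GV[, 1] * 0.8 + G_resid[, 1] * 0.5 + R_resid[, 2] * 0.6 +
    E[, 1] * 0.7
  des <- manual_design(Y, E, GV, G_resid, R_resid)
  X <- cbind(des$E, des$X1, des$X2, des$R_resid)
  list(design = des, X = X, Y = Y, q = q, L = L, p_g = p_g, p_r = p_r)
}
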