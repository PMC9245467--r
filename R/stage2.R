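#' Default penalty grid for the G×E path
#'
#' 100 equally spaced penalty values on \[0, 3\] (the benchmark grid), in
#' descending order for warm-started path fitting. The exact 0 endpoint
#' is kept: path fitters treat it as the unpenalized (minimum-norm)
#' least-squares fit, whose coefficients are generically all nonzero, so
#' every selection ROC curve is anchored at the select-everything
#' corner. `spacing = "log"` gives a glmnet-style geometric grid over
#' the same range (99 values from `to` down to `to * min_ratio`, plus 0)
#' for analyses that need to resolve the weak-signal tail of the path.
#'
#' @param from Lower endpoint (only 0 is treated specially).
#' @param to Upper endpoint.
#' @param length Total number of grid values.
#' @param spacing `"linear"` (default) or `"log"`.
#' @param min_ratio Smallest positive value as a fraction of `to` under
#'   log spacing.
#' @return Descending numeric vector.
#' @export
default_lambda_grid <- function(from = 0, to = 3, length = 100,
                                spacing = c("linear", "log"),
                                min_ratio = 1e-4) {
  spacing <- match.arg(spacing)
  if (spacing == "linear") {
    return(sort(unique(seq(from, to, length.out = length)),
                decreasing = TRUE))
  }
  lo <- if (from > 0) from else to * min_ratio
  npos <- if (from > 0) length else length - 1
  pos <- 10^seq(log10(to), log10(lo), length.out = npos)
  if (from > 0) pos else c(pos, 0)
}

# Precompute the stacked design [E | X1 | X2 | R_resid] and its Gram
# quantities once per dataset; every path fit reuses them. With
# `standardize = TRUE` (the default) the penalized problem is solved on
# unit-variance columns and a unit-variance response, which puts the
# shared penalty grid on the correlation scale; coefficients are
# back-transformed to the original units afterwards.
ige_workspace <- function(design, standardize = TRUE) {
  stopifnot(inherits(design, "decomposed_design"))
  X <- cbind(design$E, design$X1, design$X2, design$R_resid)
  n <- nrow(X)
  Y <- design$Y
  if (standardize) {
    sx <- apply(X, 2, stats::sd)
    sx[!is.finite(sx) | sx < 1e-12] <- 1
    sy <- stats::sd(Y)
    if (!is.finite(sy) || sy < 1e-12) sy <- 1
    X <- sweep(X, 2, sx, "/")
    Y <- Y / sy
  } else {
    sx <- rep(1, ncol(X))
    sy <- 1
  }
  list(
    X = X, Y = Y, n = n,
    q = ncol(design$E), L = ncol(design$GV),
    p_g = ncol(design$G_resid), p_r = ncol(design$R_resid),
    Gram = crossprod(X) / n,
    covYX = as.vector(crossprod(X, Y)) / n,
    yty = sum(Y^2) / n,
    sx = sx, sy = sy,
    design = design
  )
}

# Back-transform a standardized-space coefficient vector to original units.
unscale_beta <- function(beta, ws) beta * ws$sy / ws$sx

split_beta <- function(beta, ws) {
  q <- ws$q; L <- ws$L; m <- q + 1
  idx <- q
  b1 <- matrix(beta[idx + seq_len(L * m)], nrow = L, byrow = TRUE)
  idx <- idx + L * m
  b2 <- matrix(beta[idx + seq_len(ws$p_g * m)], nrow = ws$p_g, byrow = TRUE)
  idx <- idx + ws$p_g * m
  list(alpha = beta[seq_len(q)], b1 = b1, b2 = b2,
       gamma = beta[idx + seq_len(ws$p_r)])
}

#' Fit the penalized G×E model at a single penalty value
#'
#' Minimizes
#' `(1/2n)||Y - E a - X1 b1 - X2 b2 - R~ g||^2 +
#'  lambda sum_l (||b1l||_2 + ||b1l||_1) +
#'  lambda sum_j (||b2j||_2 + ||b2j||_1) + lambda ||g||_1`
#' by alternating a closed-form unpenalized update of the environmental
#' coefficients with blockwise sparse-group updates for the regulated and
#' residual expression blocks and coordinate-wise LASSO updates for the
#' residual regulators, starting from all-zero penalized coefficients.
#' A single `lambda` drives all three penalty terms. The problem is
#' convex, and every update decreases the objective.
#'
#' With `standardize = TRUE` the penalized problem is posed on
#' unit-variance design columns and response (so `lambda` lives on the
#' correlation scale shared by the default grid); reported coefficients
#' and the objective are back-transformed / interpreted accordingly.
#'
#' @param design A `decomposed_design` from [decompose_dataset()] (or a
#'   workspace built internally by [fit_path()]).
#' @param lambda Penalty value.
#' @param tol Convergence tolerance on the maximum coefficient change.
#' @param max_iter Maximum outer sweeps.
#' @param standardize Solve on unit-variance columns and response.
#' @return Object of class `gxe_fit`: `alpha_hat` (length `q`), `b1_hat`
#'   (`L` x `(q+1)`, main-effect column first), `b2_hat`
#'   (`p_g` x `(q+1)`), `gamma_hat` (length `p_r`), `lambda`, `n_iter`,
#'   `converged`, `objective` (on the fitting scale).
#' @export
fit_ige <- function(design, lambda, tol = 1e-5, max_iter = 500L,
                    standardize = TRUE) {
  ws <- if (inherits(design, "decomposed_design"))
    ige_workspace(design, standardize) else design
  D <- ncol(ws$X)
  res <- ige_sgl_path_cpp(ws$Gram, ws$covYX, ws$yty, ws$q, ws$L, ws$p_g,
                          ws$p_r, lambda, tol, as.integer(max_iter),
                          numeric(D))
  if (!res$converged[1]) {
    warning("fit_ige did not converge in ", max_iter, " sweeps")
  }
  parts <- split_beta(unscale_beta(res$beta[, 1], ws), ws)
  structure(list(
    alpha_hat = parts$alpha, b1_hat = parts$b1, b2_hat = parts$b2,
    gamma_hat = parts$gamma,
    lambda = lambda, n_iter = res$iterations[1],
    converged = as.logical(res$converged[1]),
    objective = res$objective[1]
  ), class = "gxe_fit")
}

#' Fit the full penalty path of the G×E model
#'
#' Fits every value of `lambda_grid` in descending order with warm starts.
#'
#' @inheritParams fit_ige
#' @param lambda_grid Penalty values; defaults to [default_lambda_grid()].
#' @return Object of class `path_fit`: `lambda_grid` (descending), `beta`
#'   (coefficient matrix in original units, one column per penalty),
#'   per-fit `iterations`, `converged` and `objective` (fitting scale),
#'   and block-layout bookkeeping.
#' @export
fit_path <- function(design, lambda_grid = default_lambda_grid(),
                     tol = 1e-5, max_iter = 500L, standardize = TRUE) {
  ws <- if (inherits(design, "decomposed_design"))
    ige_workspace(design, standardize) else design
  stopifnot(length(lambda_grid) >= 1)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  D <- ncol(ws$X)
  pos <- lambda_grid[lambda_grid > 0]
  res <- ige_sgl_path_cpp(ws$Gram, ws$covYX, ws$yty, ws$q, ws$L, ws$p_g,
                          ws$p_r, if (length(pos)) pos else 0.0, tol,
                          as.integer(max_iter), numeric(D))
  beta <- res$beta[, seq_along(pos), drop = FALSE]
  iters <- res$iterations[seq_along(pos)]
  conv <- res$converged[seq_along(pos)]
  objs <- res$objective[seq_along(pos)]
  if (any(lambda_grid == 0)) {
    # unpenalized endpoint: minimum-norm least squares (dense solution)
    b0 <- min_norm_ls(ws)
    beta <- cbind(beta, b0)
    iters <- c(iters, 0L)
    conv <- c(conv, TRUE)
    objs <- c(objs, 0.5 * ws$yty - sum(b0 * ws$covYX) +
                0.5 * sum(b0 * (ws$Gram %*% b0)))
  }
  structure(list(
    lambda_grid = lambda_grid,
    beta = beta * (ws$sy / ws$sx),
    iterations = as.integer(iters),
    converged = as.logical(conv),
    objective = as.vector(objs),
    q = ws$q, L = ws$L, p_g = ws$p_g, p_r = ws$p_r,
    ws = ws
  ), class = "path_fit")
}

#' Extract the fit at one grid position of a path
#'
#' @param path A `path_fit`.
#' @param i Grid index (1 = largest penalty).
#' @return A `gxe_fit` (see [fit_ige()]).
#' @export
path_fit_at <- function(path, i) {
  parts <- split_beta(path$beta[, i], path)
  structure(list(
    alpha_hat = parts$alpha, b1_hat = parts$b1, b2_hat = parts$b2,
    gamma_hat = parts$gamma,
    lambda = path$lambda_grid[i], n_iter = path$iterations[i],
    converged = path$converged[i], objective = path$objective[i]
  ), class = "gxe_fit")
}

#' Single sparse-group-LASSO block update
#'
#' Minimizes `(1/2n)||r - X b||^2 + lambda ||b||_2 + lambda ||b||_1` for
#' one coefficient block given the partial residual `r`, exactly as used
#' inside [fit_ige()]: the block is zeroed when
#' `||soft(X'r/n, lambda)||_2 <= lambda`, otherwise solved by proximal
#' descent on the blockwise objective.
#'
#' @param X Block design (`n` x `(q+1)` columns).
#' @param r Partial residual with the block's contribution removed.
#' @param lambda Penalty.
#' @return Length-`ncol(X)` coefficient vector.
#' @export
sgl_block_update <- function(X, r, lambda) {
  as.vector(sgl_block_update_cpp(as.matrix(X), as.numeric(r), lambda))
}

#' Number of nonzero penalized coefficients along a path
#' @param path A `path_fit`.
#' @return Integer vector over the grid.
#' @export
path_df <- function(path) {
  pen <- path$beta[-seq_len(path$q), , drop = FALSE]
  colSums(pen != 0)
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat("gxe_fit: lambda =", signif(x$lambda, 4),
      "| nonzero b1 slots:", sum(x$b1_hat != 0),
      "| nonzero b2 slots:", sum(x$b2_hat != 0),
      "| nonzero gamma:", sum(x$gamma_hat != 0),
      "|", x$n_iter, "sweeps",
      if (!x$converged) "(not converged)" else "", "\n")
  invisible(x)
}

#' @export
print.path_fit <- function(x, ...) {
  cat("path_fit:", length(x$lambda_grid), "penalty values in [",
      signif(min(x$lambda_grid), 3), ",", signif(max(x$lambda_grid), 3),
      "]; df range", paste(range(path_df(x)), collapse = "-"), "\n")
  invisible(x)
}

# Minimum-norm least squares on the workspace Gram (the unpenalized
# path endpoint when the design is wider than the sample).
min_norm_ls <- function(ws) {
  ev <- eigen(ws$Gram, symmetric = TRUE)
  keep <- ev$values > max(ev$values, 0) * 1e-10
  if (!any(keep)) return(numeric(ncol(ws$Gram)))
  as.vector(ev$vectors[, keep, drop = FALSE] %*%
              ((crossprod(ev$vectors[, keep, drop = FALSE], ws$covYX)) /
                 ev$values[keep]))
}

#' Five-fold cross-validation for the G×E penalty
#'
#' Assigns folds by a seeded permutation of the rows and scores each
#' penalty by mean held-out squared prediction error. By default Stage 1
#' (the per-gene LASSO, sparse SVD and the projections) is refit on each
#' training fold and held-out rows are projected with the training-fold
#' loadings; `refit_stage1 = FALSE` reuses one full-data decomposition
#' and only refits Stage 2 per fold.
#'
#' Predictions add the training-fold outcome mean, matching the centered
#' design columns.
#'
#' @param dataset An `omics_dataset`.
#' @param L Number of LRMs for Stage 1.
#' @param lambda_grid Stage-2 penalty grid.
#' @param folds Number of folds.
#' @param seed Seed for the fold permutation.
#' @param refit_stage1 Refit Stage 1 within each training fold.
#' @param lambda_svd Sparse-SVD penalty (or `"bic"`).
#' @param tol,max_iter Stage-2 convergence controls.
#' @param standardize Solve Stage 2 on unit-variance columns/response
#'   (training-fold scales).
#' @param ... Passed to [fit_stage1()].
#' @return List with `best_lambda`, `cv_errors` (per grid value,
#'   descending grid), `lambda_grid`, `foldid`.
#' @export
cross_validate <- function(dataset, L, lambda_grid = default_lambda_grid(),
                           folds = 5, seed = 1L, refit_stage1 = TRUE,
                           lambda_svd = "bic", tol = 1e-5,
                           max_iter = 500L, standardize = TRUE, ...) {
  n <- length(dataset$Y)
  stopifnot(n >= folds, folds >= 2)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), n))
  errs <- matrix(NA_real_, folds, length(lambda_grid))

  full_fit <- NULL
  if (!refit_stage1) full_fit <- fit_stage1(dataset$G, dataset$R, L = L,
                                            lambda_svd = lambda_svd, ...)
  for (f in seq_len(folds)) {
    tr <- foldid != f
    te <- !tr
    train <- structure(list(Y = dataset$Y[tr],
                            E = dataset$E[tr, , drop = FALSE],
                            G = dataset$G[tr, , drop = FALSE],
                            R = dataset$R[tr, , drop = FALSE],
                            regulator_blocks = dataset$regulator_blocks),
                       class = "omics_dataset")
    s1 <- if (refit_stage1) {
      fit_stage1(train$G, train$R, L = L, lambda_svd = lambda_svd, ...)
    } else full_fit
    des_tr <- decompose_dataset(train, s1, center = FALSE)
    X_tr <- cbind(des_tr$E, des_tr$X1, des_tr$X2, des_tr$R_resid)
    mu <- colMeans(X_tr)
    X_tr <- sweep(X_tr, 2, mu)
    ybar <- mean(train$Y)
    yc <- train$Y - ybar
    if (standardize) {
      sx <- apply(X_tr, 2, stats::sd)
      sx[!is.finite(sx) | sx < 1e-12] <- 1
      sy <- stats::sd(yc); if (!is.finite(sy) || sy < 1e-12) sy <- 1
      X_tr <- sweep(X_tr, 2, sx, "/")
      yc <- yc / sy
    } else {
      sx <- rep(1, ncol(X_tr)); sy <- 1
    }
    ws <- list(X = X_tr, Y = yc, n = nrow(X_tr),
               q = ncol(des_tr$E), L = ncol(des_tr$GV),
               p_g = ncol(des_tr$G_resid), p_r = ncol(des_tr$R_resid),
               Gram = crossprod(X_tr) / nrow(X_tr),
               covYX = as.vector(crossprod(X_tr, yc)) / nrow(X_tr),
               yty = sum(yc^2) / nrow(X_tr),
               sx = sx, sy = sy)
    pf <- fit_path(ws, lambda_grid, tol = tol, max_iter = max_iter)
    X_te <- heldout_design(dataset, te, s1, des_tr)
    X_te <- sweep(X_te, 2, mu)
    pred <- X_te %*% pf$beta + ybar
    errs[f, ] <- colMeans((dataset$Y[te] - pred)^2)
  }
  cv <- colMeans(errs)
  list(best_lambda = lambda_grid[which.min(cv)], cv_errors = cv,
       lambda_grid = lambda_grid, foldid = foldid)
}

# Held-out design rows from a training-fold Stage-1 fit: scores use the
# training loadings, residuals use the training projection coefficients.
heldout_design <- function(dataset, te, s1, des_tr) {
  G_te <- dataset$G[te, , drop = FALSE]
  R_te <- dataset$R[te, , drop = FALSE]
  E_te <- dataset$E[te, , drop = FALSE]
  GV_te <- G_te %*% s1$V
  RU_te <- R_te %*% s1$U
  mv <- loading_memberships(s1$V)
  mu_ <- loading_memberships(s1$U)
  cg <- residual_coefs(des_tr$G, des_tr$GV, mv)
  cr <- residual_coefs(des_tr$R, des_tr$RU, mu_)
  G_res <- apply_residuals(G_te, GV_te, mv, cg)
  R_res <- apply_residuals(R_te, RU_te, mu_, cr)
  des <- build_design(GV_te, G_res, E_te, center = FALSE)
  cbind(E_te, des$X1, des$X2, R_res)
}
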