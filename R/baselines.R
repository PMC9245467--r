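# Design for the one-stage (parallel-integration) G×E model:
# [E | G | G×E interactions | R], gene block ordered main effect first
# then interactions in environment order, matching the truth layout.
model1_design <- function(dataset, include_R = TRUE) {
  G <- as.matrix(dataset$G); E <- as.matrix(dataset$E)
  R <- as.matrix(dataset$R)
  n <- nrow(G); q <- ncol(E); p_g <- ncol(G)
  GX <- matrix(0, n, p_g * (q + 1))
  comp <- integer(p_g * (q + 1)); slot <- integer(p_g * (q + 1))
  col <- 0L
  for (j in seq_len(p_g)) {
    col <- col + 1L
    GX[, col] <- G[, j]; comp[col] <- j; slot[col] <- 0L
    for (k in seq_len(q)) {
      col <- col + 1L
      GX[, col] <- G[, j] * E[, k]; comp[col] <- j; slot[col] <- k
    }
  }
  X <- if (include_R) cbind(E, GX, R) else cbind(E, GX)
  pf <- c(rep(0, q), rep(1, ncol(X) - q))   # E unpenalized
  list(X = X, penalty_factor = pf, q = q, p_g = p_g,
       p_r = if (include_R) ncol(R) else 0L, comp = comp, slot = slot)
}

# Shared-grid LASSO path. The penalized problem is solved on
# unit-variance predictors and response (the scale the shared penalty
# grid is designed for); coefficients are returned in original units.
glmnet_path <- function(X, Y, penalty_factor, lambda_grid,
                        standardize = TRUE) {
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  pos <- lambda_grid[lambda_grid > 0]
  sy <- if (standardize) stats::sd(Y) else 1
  if (!is.finite(sy) || sy < 1e-12) sy <- 1
  beta <- matrix(0, ncol(X), 0)
  if (length(pos)) {
    fit <- glmnet::glmnet(X, Y / sy, family = "gaussian", lambda = pos,
                          standardize = standardize,
                          penalty.factor = penalty_factor)
    beta <- as.matrix(fit$beta) * sy
    # glmnet may drop trailing (smallest) lambdas on early exit; pad by
    # carrying the last fitted column forward
    if (ncol(beta) < length(pos)) {
      pad <- matrix(beta[, ncol(beta)], nrow(beta),
                    length(pos) - ncol(beta))
      beta <- cbind(beta, pad)
    }
  }
  if (any(lambda_grid == 0)) {
    # unpenalized endpoint: minimum-norm least squares after centering
    # (the intercept's job); generically dense, anchoring ROC curves at
    # the select-everything corner
    Xc <- scale(X, center = TRUE, scale = FALSE)
    yc <- Y - mean(Y)
    sv <- svd(Xc)
    keep <- sv$d > max(sv$d) * 1e-10
    b0 <- sv$v[, keep, drop = FALSE] %*%
      (crossprod(sv$u[, keep, drop = FALSE], yc) / sv$d[keep])
    beta <- cbind(beta, as.vector(b0))
  }
  list(beta = beta, lambda_grid = lambda_grid)
}

unpack_baseline <- function(beta_col, d) {
  q <- d$q
  ge <- matrix(0, d$p_g, q + 1)
  gx <- beta_col[q + seq_along(d$comp)]
  ge[cbind(d$comp, d$slot + 1L)] <- gx
  gamma <- if (d$p_r > 0) beta_col[q + length(d$comp) + seq_len(d$p_r)]
           else numeric(0)
  list(alpha_hat = beta_col[seq_len(q)], gene_effect_hat = ge,
       gamma_hat = gamma)
}

#' Joint LASSO baseline (J-LASSO)
#'
#' One LASSO on the pooled design `[E | G | G×E | R]` — gene expressions,
#' their environmental interactions and regulators penalized jointly with
#' a single penalty, environmental main effects unpenalized. This is the
#' parallel-integration comparator: regulators enter as exchangeable
#' predictors with no regulatory structure.
#'
#' @param dataset An `omics_dataset`.
#' @param lambda Single penalty value.
#' @return Object of class `baseline_fit` with `method`, `alpha_hat`,
#'   `gene_effect_hat` (`p_g` x `(q+1)`), `gamma_hat`, `lambda`.
#' @export
fit_j_lasso <- function(dataset, lambda) {
  p <- fit_j_lasso_path(dataset, lambda)
  f <- baseline_fit_at(p, 1L)
  f$lambda <- lambda
  f
}

#' J-LASSO along a penalty grid
#'
#' @inheritParams fit_j_lasso
#' @param lambda_grid Penalty values (shared with the integrative fit for
#'   like-for-like ROC comparison).
#' @param standardize Solve on unit-variance predictors and response.
#' @return Object of class `baseline_path` holding per-penalty
#'   coefficients (original units).
#' @export
fit_j_lasso_path <- function(dataset, lambda_grid = default_lambda_grid(),
                             standardize = TRUE) {
  d <- model1_design(dataset, include_R = TRUE)
  gp <- glmnet_path(d$X, dataset$Y, d$penalty_factor, lambda_grid,
                    standardize)
  structure(list(method = "j_lasso", design = d, beta = gp$beta,
                 lambda_grid = gp$lambda_grid),
            class = "baseline_path")
}

#' Separate LASSO baseline (S-LASSO)
#'
#' Two independent LASSO fits: (a) the outcome on `[E | G | G×E]` for the
#' gene side and (b) the outcome on `[E | R]` for the regulator side,
#' with environmental main effects unpenalized in both. Coefficients are
#' concatenated for evaluation.
#'
#' @inheritParams fit_j_lasso
#' @param lambda_genes,lambda_regulators Penalties for the two fits
#'   (independent by default).
#' @return A `baseline_fit` (`alpha_hat` taken from the gene-side fit).
#' @export
fit_s_lasso <- function(dataset, lambda_genes, lambda_regulators = lambda_genes) {
  p <- fit_s_lasso_path(dataset, sort(unique(c(lambda_genes, lambda_regulators)),
                                      decreasing = TRUE))
  ig <- match(lambda_genes, p$lambda_grid)
  ir <- match(lambda_regulators, p$lambda_grid)
  g <- unpack_baseline(p$beta_genes[, ig], p$design_genes)
  qd <- p$design_reg$q
  reg_rows <- qd + seq_len(p$design_reg$p_r)
  structure(list(method = "s_lasso", alpha_hat = g$alpha_hat,
                 gene_effect_hat = g$gene_effect_hat,
                 gamma_hat = p$beta_reg[reg_rows, ir],
                 lambda = c(genes = lambda_genes,
                            regulators = lambda_regulators)),
            class = "baseline_fit")
}

#' S-LASSO along a penalty grid
#'
#' Both component fits traverse the same grid; at each grid value the
#' evaluation combines the gene-side and regulator-side selections.
#'
#' @inheritParams fit_j_lasso_path
#' @return Object of class `baseline_path` (`method = "s_lasso"`).
#' @export
fit_s_lasso_path <- function(dataset, lambda_grid = default_lambda_grid(),
                             standardize = TRUE) {
  dg <- model1_design(dataset, include_R = FALSE)
  R <- as.matrix(dataset$R); E <- as.matrix(dataset$E)
  XR <- cbind(E, R)
  pfR <- c(rep(0, ncol(E)), rep(1, ncol(R)))
  gg <- glmnet_path(dg$X, dataset$Y, dg$penalty_factor, lambda_grid,
                    standardize)
  gr <- glmnet_path(XR, dataset$Y, pfR, lambda_grid, standardize)
  structure(list(method = "s_lasso",
                 design_genes = dg,
                 design_reg = list(q = ncol(E), p_r = ncol(R)),
                 beta_genes = gg$beta, beta_reg = gr$beta,
                 lambda_grid = gg$lambda_grid),
            class = "baseline_path")
}

#' Extract a single-penalty baseline fit from a baseline path
#'
#' @param path A `baseline_path`.
#' @param i Grid index.
#' @return A `baseline_fit`.
#' @export
baseline_fit_at <- function(path, i) {
  if (path$method == "j_lasso") {
    u <- unpack_baseline(path$beta[, i], path$design)
    structure(c(list(method = "j_lasso"), u,
                list(lambda = path$lambda_grid[i])),
              class = "baseline_fit")
  } else {
    g <- unpack_baseline(path$beta_genes[, i], path$design_genes)
    reg_rows <- path$design_reg$q + seq_len(path$design_reg$p_r)
    structure(list(method = "s_lasso", alpha_hat = g$alpha_hat,
                   gene_effect_hat = g$gene_effect_hat,
                   gamma_hat = path$beta_reg[reg_rows, i],
                   lambda = path$lambda_grid[i]),
              class = "baseline_fit")
  }
}
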