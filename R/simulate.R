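#' Simulation configuration for integrative G×E data
#'
#' Bundles the parameters of the benchmark data-generating design: `n`
#' subjects, `p_g` gene expressions regulated through a rank-`L_true` sparse
#' transition matrix by `p_r` regulators (a methylation block stacked on a
#' copy-number block), `q` environmental factors, and a linear outcome with
#' environmental main effects, gene main effects, G×E interactions and
#' direct regulator effects.
#'
#' The defaults reproduce the benchmarked design: `p_g = p_r = 200`,
#' `q = 4`, `L_true = 20` regulatory models with 5 nonzero loading entries
#' each, 30 causal genes carrying 4 nonzero effect slots (main effect or
#' interaction) apiece, and 30 causal regulators.
#'
#' @param n Sample size.
#' @param p_g Number of gene expressions.
#' @param p_r Number of regulators (methylation + copy number stacked).
#' @param q Number of environmental factors.
#' @param L_true Number of generating linear regulatory models (LRMs).
#' @param support_size Nonzero entries per loading vector.
#' @param cov_kind Regulator covariance: `"ar1"` (correlation 0.25^|i-j|),
#'   `"banded"` (0.33 at lag one, 0 beyond) or `"custom"`.
#' @param custom_cov Positive-definite `p_r` x `p_r` matrix when
#'   `cov_kind = "custom"`.
#' @param signal `"weak"` (gene effects Uniform(0.25, 0.5)) or `"strong"`
#'   (Uniform(0.5, 1)).
#' @param n_causal_genes Genes with nonzero outcome effects.
#' @param effects_per_gene Nonzero slots (of the `q + 1` main/interaction
#'   slots) per causal gene.
#' @param n_causal_regulators Regulators with nonzero direct effects.
#' @param regulator_split Optional `c(p_r1, p_r2)` block sizes for the
#'   methylation and copy-number blocks; defaults to an even split.
#' @param disjoint Require disjoint loading supports across LRMs (the
#'   construction that realizes orthogonal loading columns); always
#'   recommended and the default.
#' @param normalize_loadings Optionally rescale every loading column to
#'   unit Euclidean norm after drawing its nonzero entries (the singular
#'   vector convention; the uniform draws then only shape the
#'   within-support pattern). The benchmark design keeps the raw draws
#'   (`FALSE`), so transition-matrix entries are products of two
#'   Uniform(2, 4) values.
#' @param seed Integer seed driving every random draw.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n = 500, p_g = 200, p_r = 200, q = 4,
                       L_true = 20, support_size = 5,
                       cov_kind = c("ar1", "banded", "custom"),
                       custom_cov = NULL,
                       signal = c("weak", "strong"),
                       n_causal_genes = 30, effects_per_gene = 4,
                       n_causal_regulators = 30,
                       regulator_split = NULL,
                       disjoint = TRUE, normalize_loadings = FALSE,
                       seed = 1L) {
  cov_kind <- match.arg(cov_kind)
  signal <- match.arg(signal)
  stopifnot(n >= 1, p_g >= 1, p_r >= 1, q >= 0,
            L_true >= 0, support_size >= 1,
            n_causal_genes >= 0, n_causal_genes <= p_g,
            effects_per_gene >= 0, effects_per_gene <= q + 1,
            n_causal_regulators >= 0, n_causal_regulators <= p_r)
  if (disjoint && L_true * support_size > min(p_g, p_r)) {
    stop("disjoint loading supports need L_true * support_size <= min(p_g, p_r)")
  }
  if (cov_kind == "custom") {
    if (is.null(custom_cov)) stop("cov_kind = 'custom' requires custom_cov")
    custom_cov <- as.matrix(custom_cov)
    if (nrow(custom_cov) != p_r || ncol(custom_cov) != p_r) {
      stop("custom_cov must be p_r x p_r")
    }
    if (max(abs(custom_cov - t(custom_cov))) > 1e-8) {
      stop("custom_cov must be symmetric")
    }
    ev <- eigen(custom_cov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
      stop("custom_cov is not positive definite (min eigenvalue ",
           format(min(ev)), ")")
    }
  }
  if (is.null(regulator_split)) {
    regulator_split <- c(ceiling(p_r / 2), p_r - ceiling(p_r / 2))
  }
  stopifnot(length(regulator_split) == 2, sum(regulator_split) == p_r)
  structure(list(
    n = as.integer(n), p_g = as.integer(p_g), p_r = as.integer(p_r),
    q = as.integer(q), L_true = as.integer(L_true),
    support_size = as.integer(support_size),
    cov_kind = cov_kind, custom_cov = custom_cov, signal = signal,
    n_causal_genes = as.integer(n_causal_genes),
    effects_per_gene = as.integer(effects_per_gene),
    n_causal_regulators = as.integer(n_causal_regulators),
    regulator_split = as.integer(regulator_split),
    disjoint = isTRUE(disjoint),
    normalize_loadings = isTRUE(normalize_loadings),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Regulator covariance matrix of a simulation design
#'
#' AR-1 uses correlation `0.25^|i-j|`; the banded structure has
#' correlation 0.33 between adjacent regulators and 0 beyond lag one.
#'
#' @param config A [sim_config()].
#' @return A `p_r` x `p_r` covariance (correlation) matrix.
#' @export
build_covariance <- function(config) {
  p <- config$p_r
  switch(config$cov_kind,
    ar1 = 0.25^abs(outer(seq_len(p), seq_len(p), "-")),
    banded = {
      S <- diag(p)
      if (p > 1) {
        idx <- cbind(seq_len(p - 1), seq_len(p - 1) + 1L)
        S[idx] <- 0.33
        S[idx[, 2:1, drop = FALSE]] <- 0.33
      }
      S
    },
    custom = config$custom_cov
  )
}

#' Simulate sparse orthogonal loading matrices and the transition matrix
#'
#' Each of the `L_true` loading columns of `U` (regulators) and `V` (genes)
#' receives `support_size` nonzero entries drawn from Uniform(2, 4) on
#' randomly assigned positions; supports are disjoint across columns within
#' each matrix, which makes the columns exactly orthogonal and keeps the
#' rank-1 components non-overlapping. The transition matrix is
#' `Theta = sum_l u_l v_l'`.
#'
#' Uses the current RNG state; [simulate_dataset()] seeds it.
#'
#' @param config A [sim_config()].
#' @return List with `U_true` (`p_r` x `L_true`), `V_true` (`p_g` x
#'   `L_true`) and `Theta_true` (`p_r` x `p_g`).
#' @export
simulate_loadings <- function(config) {
  L <- config$L_true
  s <- config$support_size
  U <- matrix(0, config$p_r, L)
  V <- matrix(0, config$p_g, L)
  if (L > 0) {
    pick <- function(p) {
      if (config$disjoint) {
        idx <- sample.int(p, L * s)
        matrix(idx, nrow = s)           # column l = support of loading l
      } else {
        vapply(seq_len(L), function(l) sample.int(p, s), integer(s))
      }
    }
    su <- pick(config$p_r)
    sv <- pick(config$p_g)
    for (l in seq_len(L)) {
      U[su[, l], l] <- stats::runif(s, 2, 4)
      V[sv[, l], l] <- stats::runif(s, 2, 4)
    }
    if (config$normalize_loadings) {
      U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
      V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
    }
  }
  list(U_true = U, V_true = V, Theta_true = U %*% t(V))
}

# Sample n rows from N(0, Sigma) via the Cholesky factor.
rmvn_rows <- function(n, Sigma) {
  p <- nrow(Sigma)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Z %*% chol(Sigma)
}

#' Simulate an integrative G×E dataset with ground truth
#'
#' Draws regulators `R` with rows iid N(0, Sigma), expressions
#' `G = R Theta + eps` with noise rows sharing the regulator covariance,
#' environments `E` with rows iid N(0, AR-1(0.5)), and the outcome
#' `Y = E alpha + sum_j beta_j G_j + sum_jk eta_jk G_j E_k + R gamma + N(0,1)`.
#' Causal gene coefficients are Uniform(0.25, 0.5) (weak) or
#' Uniform(0.5, 1) (strong), regulator effects Uniform(1, 2), and
#' environmental main effects Uniform(2, 3), all positive.
#'
#' All randomness flows from `config$seed` in a fixed draw order
#' (loadings, R, noise, E, causal-gene slots, gene effect values, gamma,
#' alpha, outcome error), so identical configs give identical datasets.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (class `omics_dataset`: `Y`, `E`, `G`, `R`,
#'   `regulator_blocks`, column names) and `truth` (class `ground_truth`:
#'   `alpha`, `gene_effects` (`p_g` x `(q+1)`; column 1 = main effect),
#'   `gamma`, `U_true`, `V_true`, `Theta_true`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n; q <- config$q
  p_g <- config$p_g; p_r <- config$p_r

  load <- simulate_loadings(config)
  Sigma <- build_covariance(config)
  cS <- chol(Sigma)

  R <- matrix(stats::rnorm(n * p_r), n, p_r) %*% cS
  eps <- matrix(stats::rnorm(n * p_g), n, p_g)
  if (identical(dim(Sigma), dim(diag(p_g)))) {
    eps <- eps %*% cS                    # same covariance structure as R
  } else {
    # non-square case (p_r != p_g): reuse the same family on p_g features
    cfg_g <- config
    cfg_g$p_r <- p_g
    if (config$cov_kind == "custom")
      stop("custom covariance requires p_g == p_r for the noise structure")
    eps <- eps %*% chol(build_covariance(cfg_g))
  }
  G <- R %*% load$Theta_true + eps

  E <- if (q > 0) {
    SigE <- 0.5^abs(outer(seq_len(q), seq_len(q), "-"))
    rmvn_rows(n, SigE)
  } else matrix(0, n, 0)

  # outcome coefficients
  gene_effects <- matrix(0, p_g, q + 1)
  if (config$n_causal_genes > 0 && config$effects_per_gene > 0) {
    causal_genes <- sort(sample.int(p_g, config$n_causal_genes))
    lo <- if (config$signal == "weak") 0.25 else 0.5
    hi <- if (config$signal == "weak") 0.5 else 1
    for (j in causal_genes) {
      slots <- sample.int(q + 1, config$effects_per_gene)
      gene_effects[j, slots] <- stats::runif(config$effects_per_gene, lo, hi)
    }
  }
  gamma <- numeric(p_r)
  if (config$n_causal_regulators > 0) {
    causal_reg <- sort(sample.int(p_r, config$n_causal_regulators))
    gamma[causal_reg] <- stats::runif(config$n_causal_regulators, 1, 2)
  }
  alpha <- if (q > 0) stats::runif(q, 2, 3) else numeric(0)

  Y <- as.vector(G %*% gene_effects[, 1])
  if (q > 0) {
    Y <- Y + as.vector(E %*% alpha)
    for (k in seq_len(q)) {
      Y <- Y + as.vector((G * E[, k]) %*% gene_effects[, k + 1])
    }
  }
  Y <- Y + as.vector(R %*% gamma) + stats::rnorm(n)

  colnames(G) <- paste0("gene_", seq_len(p_g))
  reg_names <- c(
    if (config$regulator_split[1] > 0)
      paste0("meth_", seq_len(config$regulator_split[1])),
    if (config$regulator_split[2] > 0)
      paste0("cna_", seq_len(config$regulator_split[2]))
  )
  colnames(R) <- reg_names
  if (q > 0) colnames(E) <- paste0("env_", seq_len(q))

  dataset <- structure(list(
    Y = Y, E = E, G = G, R = R,
    regulator_blocks = config$regulator_split
  ), class = "omics_dataset")
  truth <- structure(list(
    alpha = alpha, gene_effects = gene_effects, gamma = gamma,
    U_true = load$U_true, V_true = load$V_true,
    Theta_true = load$Theta_true
  ), class = "ground_truth")
  list(dataset = dataset, truth = truth, config = config)
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("omics_dataset:", length(x$Y), "subjects,",
      ncol(x$G), "gene expressions,",
      ncol(x$R), "regulators (", x$regulator_blocks[1], "+",
      x$regulator_blocks[2], "),", ncol(x$E), "environmental factors\n")
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: n =", x$n, ", p_g =", x$p_g, ", p_r =", x$p_r,
      ", q =", x$q, ", L_true =", x$L_true,
      ", cov =", x$cov_kind, ", signal =", x$signal,
      ", seed =", x$seed, "\n")
  invisible(x)
}
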