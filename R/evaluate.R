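#' True-regulator indicator for ROC evaluation
#'
#' `"pathway"` (the default used by the benchmark's regulator family)
#' marks a regulator positive when it participates in the outcome model
#' through either route: a nonzero direct effect (`gamma`) or membership
#' in the support of any generating regulatory-model loading (a column
#' of `U_true`), i.e. the regulators whose signal reaches the expression
#' layer the integrative model is built around. `"direct"` restricts
#' positives to the nonzero `gamma` entries.
#'
#' @param truth A `ground_truth`.
#' @param type `"pathway"` or `"direct"`.
#' @return Logical vector of length `p_r`.
#' @export
regulator_truth <- function(truth, type = c("pathway", "direct")) {
  type <- match.arg(type)
  direct <- truth$gamma != 0
  if (type == "direct") return(direct)
  direct | rowSums(truth$U_true != 0) > 0
}

#' Gene- and regulator-level selection calls from an integrative fit
#'
#' Maps the LRM-level coefficients back to the native feature space:
#' gene slot `(j, k)` is called selected iff the residual-expression
#' coefficient `b2[j, k]` is nonzero OR some LRM `l` carrying gene `j`
#' (`v_lj != 0`) has a nonzero `b1[l, k]`; regulator `t` is called iff
#' its residual coefficient `gamma_t` is nonzero OR some LRM carrying it
#' (`u_lt != 0`) is selected at all (any nonzero slot of `b1[l, ]`).
#'
#' @param fit A `gxe_fit`.
#' @param reg_fit The `regulatory_fit` behind the decomposition.
#' @return Object of class `selection_call`: `gene_calls`
#'   (`p_g` x `(q+1)` 0/1 matrix, main-effect column first),
#'   `regulator_calls` (0/1 vector), `lambda`.
#' @export
call_selection_ige <- function(fit, reg_fit) {
  V_ind <- abs(reg_fit$V) > 1e-12
  U_ind <- abs(reg_fit$U) > 1e-12
  b1_nz <- fit$b1_hat != 0
  gene <- (fit$b2_hat != 0) | (V_ind %*% b1_nz > 0)
  lrm_active <- rowSums(b1_nz) > 0
  reg <- (fit$gamma_hat != 0) | (U_ind %*% lrm_active > 0)
  structure(list(gene_calls = gene * 1L,
                 regulator_calls = as.integer(reg),
                 lambda = fit$lambda),
            class = "selection_call")
}

#' Selection calls from a baseline fit
#'
#' Baseline coefficients live directly in the native feature space, so
#' calls are the coefficient supports.
#'
#' @param fit A `baseline_fit`.
#' @return A `selection_call`.
#' @export
call_selection_baseline <- function(fit) {
  structure(list(gene_calls = (fit$gene_effect_hat != 0) * 1L,
                 regulator_calls = as.integer(fit$gamma_hat != 0),
                 lambda = fit$lambda),
            class = "selection_call")
}

# Selection calls at every grid point of a path, as a list.
path_selection_calls <- function(path, reg_fit = NULL) {
  if (inherits(path, "path_fit")) {
    stopifnot(inherits(reg_fit, "regulatory_fit"))
    lapply(seq_along(path$lambda_grid), function(i) {
      call_selection_ige(path_fit_at(path, i), reg_fit)
    })
  } else if (inherits(path, "baseline_path")) {
    lapply(seq_along(path$lambda_grid), function(i) {
      call_selection_baseline(baseline_fit_at(path, i))
    })
  } else stop("unsupported path object")
}

#' ROC curve and partial AUC over a regularization path
#'
#' At each penalty the selection calls are scored against the simulation
#' truth for one evaluation family: `"gene_gxe"` compares all
#' `p_g (q+1)` gene main-effect and interaction slots against the
#' nonzero pattern of the true gene effects; `"regulators"` compares the
#' `p_r` regulator calls against the regulators that touch the outcome
#' model at all — those carrying a direct (residual) effect or
#' participating in a generating regulatory model (see
#' [regulator_truth()]); `"regulators_direct"` restricts the positives
#' to the direct-effect support only. Points are sorted by
#' false-positive rate, tied rates keep the maximal true-positive rate,
#' `(0, 0)` is prepended, and the partial AUC is the trapezoidal area
#' over the range of false-positive rates the path actually attains (no
#' extrapolation beyond the largest attained rate).
#'
#' @param path A `path_fit` or `baseline_path`.
#' @param truth A `ground_truth` from [simulate_dataset()].
#' @param family `"gene_gxe"`, `"regulators"` or `"regulators_direct"`.
#' @param reg_fit The `regulatory_fit` (required for `path_fit` input).
#' @return Object of class `roc_result`: `family`, `fpr`, `tpr` (the
#'   cleaned curve including the origin), `pauc`, `n_lambda`.
#' @export
roc_from_path <- function(path, truth,
                          family = c("gene_gxe", "regulators",
                                     "regulators_direct"),
                          reg_fit = NULL) {
  family <- match.arg(family)
  calls <- path_selection_calls(path, reg_fit)
  truth_vec <- switch(family,
    gene_gxe = as.vector(truth$gene_effects != 0),
    regulators = regulator_truth(truth, "pathway"),
    regulators_direct = regulator_truth(truth, "direct")
  )
  if (!any(truth_vec)) stop("truth has no positives for family ", family)
  if (all(truth_vec)) stop("truth has no negatives for family ", family)
  rates <- vapply(calls, function(cl) {
    sel <- if (family == "gene_gxe") as.vector(cl$gene_calls != 0)
           else cl$regulator_calls != 0
    c(fpr = sum(sel & !truth_vec) / sum(!truth_vec),
      tpr = sum(sel & truth_vec) / sum(truth_vec))
  }, double(2))
  roc_points(rates["fpr", ], rates["tpr", ], family, length(calls))
}

# Sort by FPR, keep max TPR per tied FPR, prepend the origin, integrate.
roc_points <- function(fpr, tpr, family, n_lambda) {
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  tpr <- cummax(tpr)
  keep <- !duplicated(fpr, fromLast = TRUE)
  fpr <- fpr[keep]; tpr <- tpr[keep]
  if (length(fpr) == 0 || fpr[1] > 0 || tpr[1] > 0) {
    fpr <- c(0, fpr); tpr <- c(0, tpr)
  }
  pauc <- if (length(fpr) > 1) {
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  } else 0
  structure(list(family = family, fpr = fpr, tpr = tpr,
                 pauc = pauc, n_lambda = n_lambda),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result [", x$family, "]: ", length(x$fpr), " points, FPR range [",
      signif(min(x$fpr), 3), ", ", signif(max(x$fpr), 3),
      "], PAUC = ", round(x$pauc, 4), "\n", sep = "")
  invisible(x)
}

#' Run one simulation replicate of the selection benchmark
#'
#' Simulates a dataset, runs the requested methods over a shared penalty
#' grid, and returns the PAUC of each method for both evaluation
#' families. The integrative method fits Stage 1 (per-gene LASSO with
#' `L = config$L_true` LRMs), decomposes, and traverses the Stage-2 path;
#' baselines traverse the same grid.
#'
#' @param config A [sim_config()] (its `seed` drives the replicate).
#' @param methods Subset of `c("ige", "j_lasso", "s_lasso")`.
#' @param lambda_grid Shared penalty grid.
#' @param L LRMs to extract (defaults to the generating number).
#' @param lambda_svd Sparse-SVD penalty or `"bic"`.
#' @param stage1_nlambda Per-gene candidate path length in Stage 1.
#' @return Data frame with columns `method`, `family`, `pauc`.
#' @export
run_replicate <- function(config, methods = c("ige", "j_lasso", "s_lasso"),
                          lambda_grid = default_lambda_grid(),
                          L = config$L_true, lambda_svd = "bic",
                          stage1_nlambda = 50) {
  sim <- simulate_dataset(config)
  out <- list()
  if ("ige" %in% methods) {
    s1 <- fit_stage1(sim$dataset$G, sim$dataset$R, L = L,
                     lambda_svd = lambda_svd, nlambda = stage1_nlambda,
                     seed = config$seed)
    des <- decompose_dataset(sim$dataset, s1)
    pf <- fit_path(des, lambda_grid)
    out[["ige"]] <- c(
      gene_gxe = roc_from_path(pf, sim$truth, "gene_gxe", s1)$pauc,
      regulators = roc_from_path(pf, sim$truth, "regulators", s1)$pauc)
  }
  if ("j_lasso" %in% methods) {
    jp <- fit_j_lasso_path(sim$dataset, lambda_grid)
    out[["j_lasso"]] <- c(
      gene_gxe = roc_from_path(jp, sim$truth, "gene_gxe")$pauc,
      regulators = roc_from_path(jp, sim$truth, "regulators")$pauc)
  }
  if ("s_lasso" %in% methods) {
    sp <- fit_s_lasso_path(sim$dataset, lambda_grid)
    out[["s_lasso"]] <- c(
      gene_gxe = roc_from_path(sp, sim$truth, "gene_gxe")$pauc,
      regulators = roc_from_path(sp, sim$truth, "regulators")$pauc)
  }
  do.call(rbind, lapply(names(out), function(m) {
    data.frame(method = m, family = names(out[[m]]), pauc = unname(out[[m]]),
               row.names = NULL)
  }))
}

#' Aggregate PAUCs over simulation replicates
#'
#' Runs [run_replicate()] for each seed and tabulates the mean and
#' standard deviation of the PAUC per scenario, method and family — the
#' layout of the benchmark summary tables.
#'
#' @param config Base [sim_config()]; each replicate reuses it with one
#'   of `seeds`.
#' @param methods Methods to benchmark.
#' @param seeds Integer vector, one per replicate.
#' @param ... Passed to [run_replicate()].
#' @return Data frame with `cov_kind`, `signal`, `n`, `method`, `family`,
#'   `mean_pauc`, `sd_pauc`, `n_replicates`, plus a `"replicates"`
#'   attribute holding the per-replicate values.
#' @export
replicate_summary <- function(config, methods = c("ige", "j_lasso", "s_lasso"),
                              seeds = 1:10, ...) {
  stopifnot(length(seeds) >= 2)
  reps <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    r <- run_replicate(cfg, methods = methods, ...)
    r$seed <- s
    r
  })
  all <- do.call(rbind, reps)
  agg <- stats::aggregate(pauc ~ method + family, data = all,
                          FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
  out <- data.frame(cov_kind = config$cov_kind, signal = config$signal,
                    n = config$n,
                    method = agg$method, family = agg$family,
                    mean_pauc = agg$pauc[, "mean"], sd_pauc = agg$pauc[, "sd"],
                    n_replicates = length(seeds))
  attr(out, "replicates") <- all
  out
}
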