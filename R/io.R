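#' Write a dataset (and optional ground truth) to a directory
#'
#' One tab-delimited file per matrix (`Y.tsv`, `E.tsv`, `G.tsv`,
#' `R.tsv`), each with a header row of feature names and no row-name
#' column, plus a JSON `manifest.json` carrying the simulation config,
#' seed, regulator block sizes, package version and — when supplied —
#' the ground-truth coefficients (sparse loadings as index/value maps).
#'
#' @param dataset An `omics_dataset`.
#' @param dir Output directory (created if missing).
#' @param truth Optional `ground_truth`.
#' @param config Optional `sim_config`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir, truth = NULL, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(M, file, names) {
    M <- as.matrix(M)
    colnames(M) <- names
    utils::write.table(M, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(dataset$Y, "Y.tsv", "Y")
  wr(dataset$E, "E.tsv", colnames(dataset$E))
  wr(dataset$G, "G.tsv", colnames(dataset$G))
  wr(dataset$R, "R.tsv", colnames(dataset$R))
  sparse_cols <- function(M) {
    lapply(seq_len(ncol(M)), function(l) {
      nz <- which(M[, l] != 0)
      list(index = nz, value = unname(M[nz, l]))
    })
  }
  manifest <- list(
    package = "igesel",
    version = as.character(utils::packageVersion("igesel")),
    regulator_blocks = dataset$regulator_blocks,
    config = if (!is.null(config)) unclass(config),
    truth = if (!is.null(truth)) list(
      alpha = truth$alpha,
      gene_effects = truth$gene_effects,
      gamma = truth$gamma,
      U_true = sparse_cols(truth$U_true),
      V_true = sparse_cols(truth$V_true)
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

read_tsv_matrix <- function(file) {
  M <- utils::read.table(file, header = TRUE, sep = "\t",
                         check.names = FALSE)
  M <- as.matrix(M)
  if (!is.numeric(M)) stop("non-numeric values in ", file)
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    stop("missing value in ", basename(file), " at row ", bad[1],
         ", column '", colnames(M)[bad[2]], "'")
  }
  M
}

#' Read a dataset written by [write_dataset()]
#'
#' Validates completeness and row alignment; regulator block sizes come
#' from the manifest when present, else are inferred from the `meth_` /
#' `cna_` column-name prefixes, else default to an even split.
#'
#' @param dir Directory holding `Y.tsv`, `E.tsv`, `G.tsv`, `R.tsv` (and
#'   optionally `manifest.json`).
#' @return List with `dataset` (an `omics_dataset`), and `truth` /
#'   `config` when the manifest carries them.
#' @export
read_dataset <- function(dir) {
  Y <- read_tsv_matrix(file.path(dir, "Y.tsv"))[, 1]
  E <- read_tsv_matrix(file.path(dir, "E.tsv"))
  G <- read_tsv_matrix(file.path(dir, "G.tsv"))
  R <- read_tsv_matrix(file.path(dir, "R.tsv"))
  n <- length(Y)
  for (nm in c("E", "G", "R")) {
    if (nrow(get(nm)) != n) {
      stop("row count of ", nm, ".tsv (", nrow(get(nm)),
           ") does not match Y.tsv (", n, ")")
    }
  }
  manifest_path <- file.path(dir, "manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  }
  blocks <- if (!is.null(manifest$regulator_blocks)) {
    as.integer(manifest$regulator_blocks)
  } else {
    nm <- colnames(R)
    n_meth <- sum(startsWith(nm, "meth_"))
    n_cna <- sum(startsWith(nm, "cna_"))
    if (n_meth + n_cna == ncol(R)) c(n_meth, n_cna)
    else c(ceiling(ncol(R) / 2), ncol(R) - ceiling(ncol(R) / 2))
  }
  dataset <- structure(list(Y = Y, E = E, G = G, R = R,
                            regulator_blocks = blocks),
                       class = "omics_dataset")
  truth <- NULL
  if (!is.null(manifest$truth)) {
    t <- manifest$truth
    dense <- function(sc, p) {
      M <- matrix(0, p, length(sc$index))
      for (l in seq_along(sc$index)) {
        M[unlist(sc$index[[l]]), l] <- unlist(sc$value[[l]])
      }
      M
    }
    truth <- structure(list(
      alpha = as.numeric(t$alpha),
      gene_effects = as.matrix(t$gene_effects),
      gamma = as.numeric(t$gamma),
      U_true = dense(t$U_true, ncol(R)),
      V_true = dense(t$V_true, ncol(G))
    ), class = "ground_truth")
    truth$Theta_true <- truth$U_true %*% t(truth$V_true)
  }
  cfg <- NULL
  if (!is.null(manifest$config)) {
    mc <- manifest$config
    cfg <- sim_config(n = mc$n, p_g = mc$p_g, p_r = mc$p_r, q = mc$q,
                      L_true = mc$L_true, support_size = mc$support_size,
                      cov_kind = mc$cov_kind, signal = mc$signal,
                      n_causal_genes = mc$n_causal_genes,
                      effects_per_gene = mc$effects_per_gene,
                      n_causal_regulators = mc$n_causal_regulators,
                      regulator_split = mc$regulator_split,
                      disjoint = mc$disjoint, seed = mc$seed)
  }
  list(dataset = dataset, truth = truth, config = cfg)
}

#' Write Stage-1 results (transition matrix and LRMs)
#'
#' `Theta_hat.tsv` holds the dense transition matrix; `lrms.json` the
#' per-LRM singular value and sparse loadings as index/value maps.
#'
#' @param fit A `regulatory_fit`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_stage1 <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(fit$Theta_hat, file.path(dir, "Theta_hat.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lrms <- lapply(fit$lrms, function(l) {
    nu <- which(l$u != 0); nv <- which(l$v != 0)
    list(d = l$d,
         u = list(index = nu, value = unname(l$u[nu])),
         v = list(index = nv, value = unname(l$v[nv])))
  })
  jsonlite::write_json(list(L = fit$L, lambda_svd = fit$lambda_svd,
                            intercepts = fit$intercepts, lrms = lrms),
                       file.path(dir, "lrms.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write Stage-2 coefficient tables
#'
#' `alpha.tsv`, `b1.tsv` (LRM by effect slot), `b2.tsv` (gene by effect
#' slot) and `gamma.tsv`, tab-delimited.
#'
#' @param fit A `gxe_fit`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_stage2 <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  q <- length(fit$alpha_hat)
  slots <- c("main", if (q > 0) paste0("env_", seq_len(q)))
  wr <- function(x, file) {
    utils::write.table(x, file.path(dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wr(data.frame(env = seq_len(q), alpha = fit$alpha_hat), "alpha.tsv")
  b1 <- as.data.frame(fit$b1_hat); names(b1) <- slots
  wr(cbind(lrm = seq_len(nrow(b1)), b1), "b1.tsv")
  b2 <- as.data.frame(fit$b2_hat); names(b2) <- slots
  wr(cbind(gene = seq_len(nrow(b2)), b2), "b2.tsv")
  wr(data.frame(regulator = seq_along(fit$gamma_hat),
                gamma = fit$gamma_hat), "gamma.tsv")
  invisible(dir)
}
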