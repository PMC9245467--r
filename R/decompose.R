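#' Regulated expression and regulator components
#'
#' Projects expressions and regulators onto the LRM loading directions:
#' `GV[, l] = G v_l` is the regulated-expression score of LRM `l`, and
#' `RU[, l] = R u_l` the matching regulator score.
#'
#' @param G `n` x `p_g` expression matrix.
#' @param R `n` x `p_r` regulator matrix.
#' @param fit A `regulatory_fit` from [extract_lrms()] / [fit_stage1()].
#' @return List with `GV` and `RU`, each `n` x `L`.
#' @export
regulated_components <- function(G, R, fit) {
  stopifnot(inherits(fit, "regulatory_fit"),
            ncol(G) == nrow(fit$V), ncol(R) == nrow(fit$U))
  list(GV = as.matrix(G) %*% fit$V, RU = as.matrix(R) %*% fit$U)
}

# Residualize the columns of M against the score columns listed in
# `memberships` (list over features: integer vector of component indices).
project_out <- function(M, scores, memberships, tol_label) {
  M <- as.matrix(M)
  out <- M
  for (j in seq_len(ncol(M))) {
    S <- memberships[[j]]
    if (length(S) == 0) next
    Z <- scores[, S, drop = FALSE]
    qrz <- qr(Z)
    if (qrz$rank < ncol(Z)) {
      warning("rank-deficient score block for ", tol_label, " ", j,
              "; using pseudo-inverse projection")
    }
    out[, j] <- M[, j] - qr.fitted(qrz, M[, j])
  }
  out
}

#' Residual expressions orthogonal to their regulated components
#'
#' For each gene `j`, let `S_j = {l : v_lj != 0}` be the LRMs containing
#' that gene. The residual is the perpendicular projection
#' `G~_j = (I - P_{S_j}) G_j`, with `P_{S_j}` the orthogonal projector
#' onto the span of the regulated scores `{GV_l : l in S_j}`. Genes not
#' carried by any LRM pass through unchanged. Membership uses
#' `|v_lj| > 1e-12` (loadings are exactly zero after soft-thresholding).
#'
#' @param G Expression matrix.
#' @param GV Regulated scores from [regulated_components()].
#' @param fit The `regulatory_fit` supplying the loadings.
#' @return `n` x `p_g` residual matrix.
#' @export
residualize <- function(G, GV, fit) {
  memberships <- lapply(seq_len(nrow(fit$V)), function(j) {
    which(abs(fit$V[j, ]) > 1e-12)
  })
  project_out(G, GV, memberships, "gene")
}

#' Residual regulators orthogonal to their regulated components
#'
#' Same perpendicular projection as [residualize()], on the regulator
#' side: regulator `t` is residualized against `{RU_l : l in T_t}` with
#' `T_t = {l : u_lt != 0}`.
#'
#' @param R Regulator matrix.
#' @param RU Regulator scores from [regulated_components()].
#' @param fit The `regulatory_fit`.
#' @return `n` x `p_r` residual matrix.
#' @export
residualize_regulators <- function(R, RU, fit) {
  memberships <- lapply(seq_len(nrow(fit$U)), function(t) {
    which(abs(fit$U[t, ]) > 1e-12)
  })
  project_out(R, RU, memberships, "regulator")
}

#' Interaction design blocks for the G×E model
#'
#' Builds `X1` (one block of `q + 1` columns per LRM: the regulated score
#' and its products with each environmental factor) and `X2` (one block
#' per gene from the residual expressions, likewise). Within a block the
#' main-effect column comes first, then interactions in environment-column
#' order.
#'
#' @param GV Regulated scores (`n` x `L`).
#' @param G_resid Residual expressions (`n` x `p_g`).
#' @param E Environmental factors (`n` x `q`).
#' @param center Center the factors before forming products and re-center
#'   the product columns (keeps the unpenalized environmental update
#'   well-conditioned).
#' @return List with `X1`, `X2` and `map1`, `map2` — data frames mapping
#'   each design column to its (component, effect slot) pair; slot 0 is
#'   the main effect, slot `k` the interaction with `E_k`.
#' @export
build_design <- function(GV, G_resid, E, center = TRUE) {
  GV <- as.matrix(GV); G_resid <- as.matrix(G_resid); E <- as.matrix(E)
  n <- nrow(G_resid)
  stopifnot(nrow(E) == n, nrow(GV) == n || ncol(GV) == 0)
  q <- ncol(E)
  if (center && n > 1) {
    GV <- scale(GV, center = TRUE, scale = FALSE)
    G_resid <- scale(G_resid, center = TRUE, scale = FALSE)
    E <- scale(E, center = TRUE, scale = FALSE)
  }
  expand <- function(M, label) {
    p <- ncol(M)
    if (p == 0) {
      return(list(X = matrix(0, n, 0),
                  map = data.frame(component = integer(0), slot = integer(0))))
    }
    X <- matrix(0, n, p * (q + 1))
    comp <- integer(p * (q + 1)); slot <- integer(p * (q + 1))
    col <- 0L
    for (j in seq_len(p)) {
      col <- col + 1L
      X[, col] <- M[, j]; comp[col] <- j; slot[col] <- 0L
      for (k in seq_len(q)) {
        col <- col + 1L
        x <- M[, j] * E[, k]
        if (center && n > 1) x <- x - mean(x)
        X[, col] <- x; comp[col] <- j; slot[col] <- k
      }
    }
    colnames(X) <- paste0(label, comp, ifelse(slot == 0, "",
                                              paste0(".e", slot)))
    list(X = X, map = data.frame(component = comp, slot = slot))
  }
  b1 <- expand(GV, "lrm")
  b2 <- expand(G_resid, "res")
  list(X1 = b1$X, X2 = b2$X, map1 = b1$map, map2 = b2$map)
}

# Least-squares coefficients of each feature column on its score block;
# used to carry a training-fold projection onto held-out rows.
residual_coefs <- function(M, scores, memberships) {
  M <- as.matrix(M)
  lapply(seq_len(ncol(M)), function(j) {
    S <- memberships[[j]]
    if (length(S) == 0) return(numeric(0))
    co <- qr.coef(qr(scores[, S, drop = FALSE]), M[, j])
    co[is.na(co)] <- 0
    co
  })
}

apply_residuals <- function(M, scores, memberships, coefs) {
  M <- as.matrix(M)
  out <- M
  for (j in seq_len(ncol(M))) {
    S <- memberships[[j]]
    if (length(S) == 0) next
    out[, j] <- M[, j] - scores[, S, drop = FALSE] %*% coefs[[j]]
  }
  out
}

loading_memberships <- function(load_mat) {
  lapply(seq_len(nrow(load_mat)), function(i) {
    which(abs(load_mat[i, ]) > 1e-12)
  })
}

#' Decompose a dataset into the Stage-2 design
#'
#' Chains [regulated_components()], the two residualizations and
#' [build_design()], returning everything Stage 2 needs.
#'
#' @param dataset An `omics_dataset`.
#' @param fit A `regulatory_fit`.
#' @param center Passed to [build_design()]; residual regulators are
#'   centered under the same flag.
#' @return Object of class `decomposed_design` with `GV`, `RU`,
#'   `G_resid`, `R_resid`, `X1`, `X2`, `map1`, `map2`, `E`, `Y`.
#' @export
decompose_dataset <- function(dataset, fit, center = TRUE) {
  comp <- regulated_components(dataset$G, dataset$R, fit)
  G_resid <- residualize(dataset$G, comp$GV, fit)
  R_resid <- residualize_regulators(dataset$R, comp$RU, fit)
  des <- build_design(comp$GV, G_resid, dataset$E, center = center)
  E <- as.matrix(dataset$E)
  if (center && nrow(E) > 1) {
    E <- scale(E, center = TRUE, scale = FALSE)
    R_resid <- scale(R_resid, center = TRUE, scale = FALSE)
  }
  structure(list(
    GV = comp$GV, RU = comp$RU, G_resid = G_resid, R_resid = R_resid,
    X1 = des$X1, X2 = des$X2, map1 = des$map1, map2 = des$map2,
    E = E, Y = dataset$Y,
    G = as.matrix(dataset$G), R = as.matrix(dataset$R)
  ), class = "decomposed_design")
}
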