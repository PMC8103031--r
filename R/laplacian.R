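#' Affinity/penalty graphs over labeled samples and their Laplacians
#'
#' Builds two weighted graphs on the labeled samples from a side feature
#' matrix (for example copy-number values): the affinity graph `W_a` connects
#' same-group pairs and the penalty graph `W_p` connects different-group
#' pairs. Edge weights are pairwise Pearson correlations between the samples'
#' feature columns; an edge belongs to exactly one of the two graphs. The
#' Laplacians `L = D - W` of the two graphs enter the fit as
#' `beta * (tr[V_L L_a V_L'] - tr[V_L L_p V_L'])`, pulling same-group samples
#' together and pushing different-group samples apart in latent space.
#'
#' Negative correlations are clipped to zero by default (`mode = "clip"`) so
#' that the multiplicative updates stay non-negative; `mode = "abs"` uses the
#' absolute correlation instead. Samples with zero feature variance get all
#' their correlations set to 0 with a warning.
#'
#' @param side_matrix numeric matrix, features x labeled samples; columns must
#'   align with `labels`.
#' @param labels group identifier per labeled sample (length = ncol).
#' @param mode `"clip"` (default) or `"abs"` treatment of negative
#'   correlations.
#' @return object of class `laplacian_pair` with elements `W_a`, `W_p`,
#'   `D_a`, `D_p`, `L_a`, `L_p`, and `sample_order`.
#' @export
build_laplacians <- function(side_matrix, labels, mode = c("clip", "abs")) {
  mode <- match.arg(mode)
  side_matrix <- as.matrix(side_matrix)
  nl <- ncol(side_matrix)
  if (nl < 2) stop("need at least 2 labeled samples")
  if (length(labels) != nl)
    stop("labels must have one entry per side_matrix column")

  sds <- apply(side_matrix, 2, stats::sd)
  degenerate <- which(sds == 0 | !is.finite(sds))
  r <- suppressWarnings(stats::cor(side_matrix))
  if (length(degenerate) > 0) {
    warning("zero-variance labeled sample(s) in side matrix; correlations set to 0: ",
            paste(colnames(side_matrix)[degenerate], collapse = ", "))
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  r[!is.finite(r)] <- 0
  w <- if (mode == "clip") pmax(r, 0) else abs(r)
  diag(w) <- 0

  same <- outer(labels, labels, "==")
  W_a <- w * same
  W_p <- w * !same
  ids <- colnames(side_matrix)
  if (is.null(ids)) ids <- sprintf("sample%03d", seq_len(nl))
  dimnames(W_a) <- dimnames(W_p) <- list(ids, ids)

  D_a <- diag(rowSums(W_a), nl)
  D_p <- diag(rowSums(W_p), nl)
  structure(
    list(W_a = W_a, W_p = W_p, D_a = D_a, D_p = D_p,
         L_a = D_a - W_a, L_p = D_p - W_p, sample_order = ids),
    class = "laplacian_pair")
}

#' @export
print.laplacian_pair <- function(x, ...) {
  cat("laplacian_pair over", length(x$sample_order), "labeled samples;",
      sum(x$W_a > 0) / 2, "affinity edges,", sum(x$W_p > 0) / 2,
      "penalty edges\n")
  invisible(x)
}

#' Graph-Laplacian smoothness of the labeled sample factors
#'
#' Evaluates `tr[V_L L_a V_L']` and `tr[V_L L_p V_L']` for a `k x N_L` latent
#' matrix over the labeled samples. Each trace equals
#' `0.5 * sum_ij W_ij * ||v_i - v_j||^2` over the corresponding graph, i.e. a
#' weighted sum of squared latent distances.
#'
#' @param V_L `k x N_L` matrix of labeled-sample latent loadings, columns in
#'   `pair$sample_order` order.
#' @param pair a [build_laplacians()] result.
#' @return named numeric vector `c(affinity = ..., penalty = ...)`.
#' @export
laplacian_penalty <- function(V_L, pair) {
  V_L <- as.matrix(V_L)
  if (ncol(V_L) != length(pair$sample_order))
    stop("V_L must have one column per labeled sample")
  c(affinity = sum((V_L %*% pair$L_a) * V_L),
    penalty  = sum((V_L %*% pair$L_p) * V_L))
}
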