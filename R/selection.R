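#' Recommend the factor count k by consensus clustering over restarts
#'
#' For every candidate `k`, fits the joint tri-factorization from `restarts`
#' different random initializations, assigns each sample to its argmax factor,
#' and accumulates the sample-by-sample co-assignment frequency (consensus)
#' matrix. Rank stability is scored by the cophenetic correlation between the
#' consensus dissimilarity `1 - C` and the cophenetic distances of its
#' average-linkage dendrogram; the `k` with the highest correlation is
#' recommended. Ranks whose correlation lies within `1e-6` of the maximum are
#' treated as equally stable and the largest of them is returned: on clean
#' data the best rank-`k` approximation below the true rank is essentially
#' unique, so restart stability persists up to the true rank and breaks only
#' above it, and the largest equally-stable rank is the one carrying the full
#' group structure. A perfectly stable rank yields a 0/1 block consensus
#' matrix and correlation 1.
#'
#' @param stack an [omics_stack()]
#' @param params a [jtf_params()]; `params$k` is ignored in favor of
#'   `k_range`, and `params$seed` seeds the restart seeds
#' @param k_range integer vector of candidate factor counts
#' @param restarts number of random restarts per candidate (>= 2)
#' @param laplacians optional [build_laplacians()] pair forwarded to the fits
#' @return object of class `consensus_result`: list with `k_candidates`,
#'   `consensus_matrices`, `cophenetic`, `recommended_k`, `failed_fits`
#' @export
consensus_select_k <- function(stack, params, k_range = 2:8, restarts = 20,
                               laplacians = NULL) {
  stopifnot(restarts >= 2, length(k_range) >= 1)
  k_range <- sort(unique(as.integer(k_range)))
  n <- n_samples(stack)
  set.seed(params$seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, restarts)

  consensus <- list()
  coph <- numeric(length(k_range))
  failed <- integer(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    co <- matrix(0, n, n)
    used <- 0
    for (r in seq_len(restarts)) {
      pr <- params
      pr$k <- as.integer(k)
      pr$seed <- restart_seeds[r]
      fit <- tryCatch(
        suppressWarnings(jtf_fit(stack, pr, laplacians)),
        error = function(e) {
          message("fit failed for k = ", k, ", restart ", r, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(fit)) next
      # remove the per-factor scale ambiguity (U_f c, V_f / c) before
      # comparing factors within a sample column
      Vn <- fit$V / pmax(sqrt(rowSums(fit$V^2)), .Machine$double.eps)
      assign <- apply(Vn, 2, which.max)
      co <- co + outer(assign, assign, "==")
      used <- used + 1
    }
    failed[i] <- restarts - used
    if (used == 0) stop("all restarts failed for k = ", k)
    C <- co / used
    diag(C) <- 1
    dimnames(C) <- list(stack$sample_ids, stack$sample_ids)
    consensus[[i]] <- C
    d <- stats::as.dist(1 - C)
    if (stats::sd(d) == 0) {
      # degenerate consensus (all samples always together or always apart)
      coph[i] <- -1
    } else {
      h <- stats::hclust(d, method = "average")
      coph[i] <- suppressWarnings(stats::cor(d, stats::cophenetic(h)))
      if (!is.finite(coph[i])) coph[i] <- -1
    }
  }
  names(consensus) <- names(coph) <- as.character(k_range)
  best <- max(k_range[coph >= max(coph) - 1e-6])
  structure(
    list(k_candidates = as.integer(k_range),
         consensus_matrices = consensus,
         cophenetic = coph,
         recommended_k = as.integer(best),
         failed_fits = stats::setNames(failed, as.character(k_range))),
    class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("consensus_result over k in {",
      paste(x$k_candidates, collapse = ", "), "}\n")
  print(round(x$cophenetic, 4))
  cat("recommended k:", x$recommended_k, "\n")
  invisible(x)
}
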