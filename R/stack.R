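#' Assemble a multi-omics stack
#'
#' Bundles `P` non-negative molecule-by-sample matrices that share one sample
#' set (columns in identical order) together with an optional partial labeling
#' of the samples. The stack is the input object for [jtf_fit()] and friends.
#'
#' @param matrices list of non-negative numeric matrices, each `m_p x n` with
#'   molecules in rows and samples in columns. Rownames are used as molecule
#'   identifiers (generated if absent); all matrices must agree on `n`.
#' @param sample_ids character vector of length `n` naming the shared samples.
#'   Defaults to the colnames of the first matrix.
#' @param labels named character vector mapping sample id to group for the
#'   labeled subset, or `NULL` for a fully unlabeled stack.
#' @return An object of class `omics_stack`: a list with elements `matrices`,
#'   `molecule_ids`, `sample_ids`, `labeled_index` (positions of labeled
#'   samples, increasing), and `labels` (group per labeled sample, in
#'   `labeled_index` order).
#' @examples
#' X1 <- matrix(runif(20), 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' X2 <- matrix(runif(15), 3, 5, dimnames = list(paste0("m", 1:3), paste0("s", 1:5)))
#' st <- omics_stack(list(X1, X2), labels = c(s1 = "A", s2 = "B"))
#' @export
omics_stack <- function(matrices, sample_ids = NULL, labels = NULL) {
  stopifnot(is.list(matrices), length(matrices) >= 1)
  matrices <- lapply(matrices, function(x) {
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  })
  n <- ncol(matrices[[1]])
  for (p in seq_along(matrices)) {
    if (ncol(matrices[[p]]) != n)
      stop("all omics matrices must have the same number of sample columns")
    if (anyNA(matrices[[p]]) || any(!is.finite(matrices[[p]])))
      stop("omic ", p, " contains missing or non-finite values")
    if (any(matrices[[p]] < 0)) {
      bad <- which(matrices[[p]] < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("omic %d has a negative entry at row %d, column %d",
                   p, bad[1], bad[2]))
    }
    if (is.null(rownames(matrices[[p]])))
      rownames(matrices[[p]]) <- sprintf("om%d_%04d", p, seq_len(nrow(matrices[[p]])))
  }
  if (is.null(sample_ids)) sample_ids <- colnames(matrices[[1]])
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%03d", seq_len(n))
  stopifnot(length(sample_ids) == n, !anyDuplicated(sample_ids))
  for (p in seq_along(matrices)) colnames(matrices[[p]]) <- sample_ids

  labeled_index <- integer(0)
  label_vec <- character(0)
  if (!is.null(labels) && length(labels) > 0) {
    labels <- labels[!is.na(labels)]
    unknown <- setdiff(names(labels), sample_ids)
    if (length(unknown) > 0) {
      warning("ignoring labels for unknown sample ids: ",
              paste(unknown, collapse = ", "))
      labels <- labels[setdiff(names(labels), unknown)]
    }
    labeled_index <- sort(match(names(labels), sample_ids))
    label_vec <- as.character(labels[sample_ids[labeled_index]])
    if (length(unique(label_vec)) < 2)
      warning("fewer than 2 distinct groups among labeled samples")
  }

  structure(
    list(matrices = matrices,
         molecule_ids = lapply(matrices, rownames),
         sample_ids = sample_ids,
         labeled_index = labeled_index,
         labels = label_vec),
    class = "omics_stack")
}

#' @export
print.omics_stack <- function(x, ...) {
  cat("omics_stack:", length(x$matrices), "omic(s),",
      length(x$sample_ids), "samples (",
      length(x$labeled_index), "labeled )\n")
  for (p in seq_along(x$matrices))
    cat(sprintf("  omic %d: %d molecules\n", p, nrow(x$matrices[[p]])))
  invisible(x)
}

#' Number of samples / omics in a stack
#' @param stack an `omics_stack`
#' @return integer count
#' @keywords internal
n_samples <- function(stack) length(stack$sample_ids)

#' @rdname n_samples
#' @keywords internal
n_omics <- function(stack) length(stack$matrices)

#' Positions of unlabeled samples
#' @param stack an `omics_stack`
#' @return integer vector of column positions without a label
#' @keywords internal
unlabeled_index <- function(stack) {
  setdiff(seq_along(stack$sample_ids), stack$labeled_index)
}

#' Hyperparameters for the joint tri-factorization
#'
#' @param k number of latent factors; should usually equal the number of
#'   sample groups.
#' @param beta weight of the labeled-sample graph-Laplacian term (affinity
#'   minus penalty); `0` disables semi-supervision.
#' @param omega weight of the squared-norm penalty on the omic weight vector;
#'   larger values keep the weights closer to uniform. Must be positive.
#' @param max_iter maximum number of full update sweeps.
#' @param tol stopping threshold on the relative objective change
#'   `|O_t - O_{t-1}| / max(1, O_{t-1})`.
#' @param seed integer seed for the random initialization.
#' @return a list of class `jtf_params`
#' @export
jtf_params <- function(k = 4, beta = 10, omega = 1e5, max_iter = 500,
                       tol = 1e-6, seed = 1) {
  stopifnot(k >= 1, k == round(k), beta >= 0, omega > 0,
            max_iter >= 1, tol > 0)
  structure(list(k = as.integer(k), beta = beta, omega = omega,
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "jtf_params")
}

check_params_stack <- function(stack, params) {
  k <- params$k
  if (k > n_samples(stack))
    stop("k = ", k, " exceeds the number of samples")
  for (p in seq_along(stack$matrices))
    if (k > nrow(stack$matrices[[p]]))
      stop("k = ", k, " exceeds the number of molecules in omic ", p)
  invisible(TRUE)
}
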