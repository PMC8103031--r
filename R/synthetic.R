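# Planted-truth generator: low-rank block-structured multi-omics matrices
# with partial labels, a group-correlated side feature matrix, and an
# interaction network whose edges concentrate inside planted modules.

#' Simulate a planted multi-omics dataset
#'
#' Builds `P` matrices `X^(p) = max(0, U^(p) S^(p) V + noise)` with planted
#' block structure: the molecules of each omic split into `k` blocks loading
#' highly on "their" factor, `S^(p)` is diagonally dominant, and the samples
#' split into `k` groups whose columns of `V` load highly on the matching
#' factor (high/low contrast 0.8-1.2 vs 0-0.2). Gaussian noise with standard
#' deviation `noise_sd * mean(signal)` is added and the result clipped at
#' zero, giving mild zero-inflation as in real expression matrices. A
#' stratified fraction of samples per group is labeled. Alongside the stack
#' the generator emits a side feature matrix over the labeled samples whose
#' within-group correlations exceed between-group correlations, and an
#' interaction network whose edge probability is higher inside planted
#' molecule blocks than across them. Everything is determined by `seed`.
#'
#' @param P number of omics
#' @param m integer vector of molecule counts per omic (recycled to `P`)
#' @param n number of samples
#' @param k number of planted groups/factors
#' @param noise_sd noise level relative to the mean signal entry (0 = exact
#'   low-rank data)
#' @param labeled_fraction fraction of each group's samples that carry a
#'   label (at least one per group)
#' @param contrast length-2 vector `c(high, low)` block weight contrast
#' @param coupling upper bound of the uniform off-diagonal entries of the
#'   planted scale matrices `S^(p)`; `0` plants fully decoupled
#'   (well-separated) factors
#' @param n_side_features rows of the side feature matrix
#' @param edge_prob_within,edge_prob_between network edge probabilities
#'   inside / across planted modules
#' @param seed integer seed
#' @return list with `stack` ([omics_stack()]), `side_matrix` (features x
#'   labeled samples), `network` (`igraph`), and `truth` (class
#'   `synthetic_truth`: `U`, `S`, `V`, `labels` per sample, `blocks` per
#'   omic, plus the generator settings)
#' @export
simulate_multiomics <- function(P = 2, m = c(300, 80), n = 120, k = 4,
                                noise_sd = 0.1, labeled_fraction = 0.25,
                                contrast = c(0.8, 0.2), coupling = 0.1,
                                n_side_features = 40,
                                edge_prob_within = 0.25,
                                edge_prob_between = 0.02,
                                seed = 1) {
  m <- rep_len(as.integer(m), P)
  stopifnot(k >= 1, n >= k, all(m >= k), noise_sd >= 0,
            labeled_fraction > 0, labeled_fraction <= 1)
  set.seed(seed)
  hi <- function(nv) stats::runif(nv, contrast[1], contrast[1] + 0.4)
  lo <- function(nv) stats::runif(nv, 0, contrast[2])

  # group-structured V: consecutive sample blocks, one group per factor
  group_of <- sort(rep(seq_len(k), length.out = n))
  group_names <- sprintf("G%d", seq_len(k))
  sample_ids <- sprintf("s%03d", seq_len(n))
  V <- matrix(lo(k * n), k, n, dimnames = list(NULL, sample_ids))
  for (g in seq_len(k)) V[g, group_of == g] <- hi(sum(group_of == g))

  U <- vector("list", P); S <- vector("list", P); X <- vector("list", P)
  blocks <- vector("list", P)
  for (p in seq_len(P)) {
    block <- sort(rep(seq_len(k), length.out = m[p]))
    blocks[[p]] <- block
    ids <- sprintf("om%d_%04d", p, seq_len(m[p]))
    Up <- matrix(lo(m[p] * k), m[p], k, dimnames = list(ids, NULL))
    for (g in seq_len(k)) Up[block == g, g] <- hi(sum(block == g))
    Sp <- matrix(stats::runif(k * k, 0, coupling), k, k)
    diag(Sp) <- stats::runif(k, contrast[1], contrast[1] + 0.4)
    signal <- Up %*% Sp %*% V
    noise <- if (noise_sd > 0)
      matrix(stats::rnorm(m[p] * n, 0, noise_sd * mean(signal)), m[p], n)
    else 0
    U[[p]] <- Up; S[[p]] <- Sp
    X[[p]] <- pmax(signal + noise, 0)
  }

  # stratified partial labels, at least one per group
  labeled <- unlist(lapply(seq_len(k), function(g) {
    idx <- which(group_of == g)
    sample(idx, max(1L, round(labeled_fraction * length(idx))))
  }))
  labeled <- sort(labeled)
  labels <- stats::setNames(group_names[group_of[labeled]],
                            sample_ids[labeled])
  stack <- omics_stack(X, sample_ids = sample_ids, labels = labels)

  # side features: one feature block per group, high where group matches
  fblock <- rep(seq_len(k), length.out = n_side_features)
  side <- matrix(lo(n_side_features * length(labeled)),
                 n_side_features, length(labeled),
                 dimnames = list(sprintf("feat%03d", seq_len(n_side_features)),
                                 sample_ids[labeled]))
  for (g in seq_len(k)) {
    cols <- which(group_of[labeled] == g)
    side[fblock == g, cols] <- hi(sum(fblock == g) * length(cols))
  }
  side <- side + matrix(stats::rnorm(length(side), 0, 0.05),
                        nrow(side), ncol(side))

  # network: denser inside planted modules (pooled across omics) than across
  all_ids <- unlist(lapply(seq_len(P), function(p) rownames(U[[p]])))
  all_blocks <- unlist(blocks)
  same <- outer(all_blocks, all_blocks, "==")
  upper <- upper.tri(same)
  prob <- ifelse(same[upper], edge_prob_within, edge_prob_between)
  hit <- stats::runif(length(prob)) < prob
  idx <- which(upper, arr.ind = TRUE)[hit, , drop = FALSE]
  edges <- data.frame(from = all_ids[idx[, 1]], to = all_ids[idx[, 2]],
                      weight = round(stats::runif(nrow(idx), 0.5, 1), 3))
  network <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = all_ids))

  truth <- structure(
    list(U = U, S = S, V = V,
         labels = stats::setNames(group_names[group_of], sample_ids),
         blocks = blocks, group_names = group_names,
         noise_sd = noise_sd, labeled_fraction = labeled_fraction,
         seed = seed),
    class = "synthetic_truth")
  list(stack = stack, side_matrix = side, network = network, truth = truth)
}

#' Corrupt one omic of a stack
#'
#' Replaces omic `p` by a structure-free matrix with the same marginal value
#' distribution: `"shuffle"` permutes all entries, `"noise"` resamples them
#' with replacement. Used as a negative control — the fitted omic weight of a
#' corrupted matrix should fall below that of an intact one.
#'
#' @param stack an [omics_stack()]
#' @param p omic index to corrupt
#' @param mode `"shuffle"` or `"noise"`
#' @param seed integer seed (deterministic corruption)
#' @return the modified `omics_stack`
#' @export
corrupt_omic <- function(stack, p, mode = c("shuffle", "noise"), seed = 1) {
  mode <- match.arg(mode)
  stopifnot(p >= 1, p <= n_omics(stack))
  set.seed(seed)
  X <- stack$matrices[[p]]
  vals <- if (mode == "shuffle") sample(X) else sample(X, length(X),
                                                       replace = TRUE)
  stack$matrices[[p]] <- matrix(vals, nrow(X), ncol(X),
                                dimnames = dimnames(X))
  stack
}

#' Agreement between predicted and true group labels
#'
#' @param predicted,truth character vectors (aligned, or both named by
#'   sample id)
#' @return fraction of matching entries
#' @export
label_accuracy <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth)))
    truth <- truth[names(predicted)]
  stopifnot(length(predicted) == length(truth))
  mean(predicted == truth)
}
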