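# Shared fixtures and independent oracles.

# Exact low-rank stack X^(p) = U^(p) S^(p) V with strictly positive factors;
# optionally labels the first `labeled` samples in two alternating groups.
exact_fixture <- function(P = 2, m = c(6, 5), n = 5, k = 2, labeled = 0,
                          seed = 1) {
  set.seed(seed)
  m <- rep_len(m, P)
  U <- lapply(m, function(mp) matrix(runif(mp * k, 0.5, 1.5), mp, k))
  S <- lapply(seq_len(P), function(p) matrix(runif(k * k, 0.5, 1.5), k, k))
  V <- matrix(runif(k * n, 0.5, 1.5), k, n)
  X <- lapply(seq_len(P), function(p) U[[p]] %*% S[[p]] %*% V)
  ids <- sprintf("s%02d", seq_len(n))
  labels <- NULL
  if (labeled > 0)
    labels <- setNames(rep(c("A", "B"), length.out = labeled), ids[seq_len(labeled)])
  stack <- omics_stack(X, sample_ids = ids, labels = labels)
  state <- structure(
    list(U = U, S = S, V = V, pi = rep(1 / P, P),
         objective_trace = numeric(0), converged = NA, iterations = 0L),
    class = "jtf_state")
  list(stack = stack, state = state)
}

# Random noisy stack (no planted structure) for descent/invariant checks.
noisy_fixture <- function(P = 2, m = c(7, 5), n = 6, k = 2, labeled = 4,
                          seed = 1) {
  set.seed(seed)
  m <- rep_len(m, P)
  X <- lapply(m, function(mp) matrix(runif(mp * n, 0, 2), mp, n))
  ids <- sprintf("s%02d", seq_len(n))
  labels <- NULL
  if (labeled > 0)
    labels <- setNames(rep(c("A", "B"), length.out = labeled),
                       ids[seq_len(labeled)])
  omics_stack(X, sample_ids = ids, labels = labels)
}

# Independent objective oracle: explicit elementwise sums, no linear algebra.
naive_objective <- function(stack, state, params, pair = NULL) {
  total <- 0
  for (p in seq_along(stack$matrices)) {
    X <- stack$matrices[[p]]
    R <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
      fit_ij <- 0
      for (a in seq_len(params$k)) for (b in seq_len(params$k))
        fit_ij <- fit_ij + state$U[[p]][i, a] * state$S[[p]][a, b] *
          state$V[b, j]
      R <- R + (X[i, j] - fit_ij)^2
    }
    total <- total + state$pi[p] * R
  }
  if (!is.null(pair) && params$beta > 0) {
    VL <- state$V[, stack$labeled_index, drop = FALSE]
    acc <- 0
    nl <- ncol(VL)
    for (i in seq_len(nl)) for (j in seq_len(nl)) {
      d2 <- sum((VL[, i] - VL[, j])^2)
      acc <- acc + 0.5 * (pair$W_a[i, j] - pair$W_p[i, j]) * d2
    }
    total <- total + params$beta * acc
  }
  unname(total + params$omega * sum(state$pi^2))
}

# Independent simplex-QP oracle: enumerate every support subset, solve the
# equality-constrained quadratic in closed form, keep the feasible minimum.
pi_oracle <- function(cvec, omega) {
  P <- length(cvec)
  best <- NULL
  best_val <- Inf
  for (mask in seq_len(2^P - 1)) {
    act <- which(bitwAnd(mask, 2^(seq_len(P) - 1)) > 0)
    lam <- (2 * omega + sum(cvec[act])) / length(act)
    cand <- numeric(P)
    cand[act] <- (lam - cvec[act]) / (2 * omega)
    if (any(cand[act] < -1e-12)) next
    cand <- pmax(cand, 0)
    cand <- cand / sum(cand)
    val <- sum(cand * cvec) + omega * sum(cand^2)
    if (val < best_val) {
      best_val <- val
      best <- cand
    }
  }
  best
}

# Per-omic weighted squared reconstruction residual.
recon_term <- function(stack, state, p) {
  R <- stack$matrices[[p]] - state$U[[p]] %*% state$S[[p]] %*% state$V
  state$pi[p] * sum(R * R)
}

max_rel_change <- function(a, b) max(abs(a - b) / pmax(abs(a), 1e-300))
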