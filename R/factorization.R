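# Core optimizer: weighted joint non-negative matrix tri-factorization with
# graph-Laplacian semi-supervision on the labeled sample columns.
#
# Each omic X^(p) (m_p x n) is factorized as X^(p) ~ U^(p) S^(p) V with a
# common sample factor V (k x n). The objective is
#   sum_p pi_p ||X^(p) - U^(p) S^(p) V||_F^2
#     + beta * ( tr[V_L L_a V_L'] - tr[V_L L_p V_L'] )
#     + omega * ||pi||^2
# with pi on the probability simplex. U, S, V are optimized by multiplicative
# updates; pi by a closed-form simplex-constrained quadratic program.

.jtf_eps <- 1e-12  # denominator guard; leaves exact fixed points intact

#' Random positive initialization of the factor state
#'
#' Draws every factor entry from a strictly positive uniform distribution,
#' scaled so that the reconstruction `U S V` matches the data mean in
#' expectation, and sets the omic weights to the uniform simplex vector
#' `(1/P, ..., 1/P)`. Strictly positive entries keep the multiplicative
#' updates from freezing at zero.
#'
#' @param stack an [omics_stack()]
#' @param params a [jtf_params()]; `params$seed` makes the draw reproducible
#' @param laplacians optional [build_laplacians()] pair used to include the
#'   Laplacian term in the recorded initial objective
#' @return object of class `jtf_state` with elements `U` (list of `m_p x k`),
#'   `S` (list of `k x k`), `V` (`k x n`), `pi`, `objective_trace`,
#'   `converged`, `iterations`.
#' @export
jtf_init <- function(stack, params, laplacians = NULL) {
  check_params_stack(stack, params)
  P <- n_omics(stack)
  n <- n_samples(stack)
  k <- params$k
  set.seed(params$seed)
  runif_pos <- function(nr, nc) matrix(1 - stats::runif(nr * nc), nr, nc)

  # with i.i.d. U(0,1] entries scaled by a, E[(USV)_ij] = k^2 (a/2)^3;
  # choose a per omic so the initial reconstruction is on the data's scale
  U <- vector("list", P); S <- vector("list", P)
  scales <- vapply(stack$matrices, mean, numeric(1))
  a <- 2 * (pmax(scales, .Machine$double.eps) / k^2)^(1 / 3)
  for (p in seq_len(P)) {
    U[[p]] <- runif_pos(nrow(stack$matrices[[p]]), k) * a[p]
    rownames(U[[p]]) <- stack$molecule_ids[[p]]
    S[[p]] <- runif_pos(k, k) * a[p]
  }
  V <- runif_pos(k, n) * mean(a)
  colnames(V) <- stack$sample_ids

  state <- structure(
    list(U = U, S = S, V = V, pi = rep(1 / P, P),
         objective_trace = numeric(0), converged = NA, iterations = 0L),
    class = "jtf_state")
  state$objective_trace <- jtf_objective(stack, state, params, laplacians)
  state
}

#' @export
print.jtf_state <- function(x, ...) {
  cat("jtf_state: k =", nrow(x$V), ", P =", length(x$U),
      ", iterations =", x$iterations, "\n")
  cat("  pi:", paste(signif(x$pi, 4), collapse = " "), "\n")
  if (length(x$objective_trace) > 0)
    cat("  objective:", signif(utils::tail(x$objective_trace, 1), 8),
        if (isTRUE(x$converged)) "(converged)" else "", "\n")
  invisible(x)
}

#' Evaluate the joint tri-factorization objective
#'
#' @inheritParams jtf_init
#' @param state a `jtf_state`
#' @param breakdown if `TRUE`, return the three summands
#'   (`reconstruction`, `laplacian`, `weight_penalty`) alongside `total`.
#' @return the objective value, or a named list when `breakdown = TRUE`.
#' @export
jtf_objective <- function(stack, state, params, laplacians = NULL,
                          breakdown = FALSE) {
  recon <- 0
  for (p in seq_len(n_omics(stack))) {
    R <- stack$matrices[[p]] - state$U[[p]] %*% state$S[[p]] %*% state$V
    recon <- recon + state$pi[p] * sum(R * R)
  }
  lap <- 0
  if (!is.null(laplacians) && params$beta > 0 &&
      length(stack$labeled_index) > 0) {
    tr <- laplacian_penalty(state$V[, stack$labeled_index, drop = FALSE],
                            laplacians)
    lap <- params$beta * (tr[["affinity"]] - tr[["penalty"]])
  }
  wt <- params$omega * sum(state$pi^2)
  total <- recon + lap + wt
  if (!is.finite(total)) stop("non-finite objective value")
  if (breakdown)
    list(reconstruction = recon, laplacian = lap, weight_penalty = wt,
         total = total)
  else total
}

#' Multiplicative update of one molecular factor U
#'
#' `U <- U * (X V' S') / (U S V V' S')` elementwise, for omic `p`; all other
#' factors are left untouched. Non-negativity is preserved and exact
#' factorizations are fixed points.
#'
#' @inheritParams jtf_objective
#' @param p omic index
#' @return the updated `jtf_state`
#' @export
jtf_update_u <- function(stack, state, p) {
  SV <- state$S[[p]] %*% state$V
  num <- stack$matrices[[p]] %*% t(SV)
  den <- state$U[[p]] %*% tcrossprod(SV)
  state$U[[p]] <- state$U[[p]] * num / (den + .jtf_eps)
  state
}

#' Multiplicative update of one scale matrix S
#'
#' `S <- S * (U' X V') / (U' U S V V')` elementwise for omic `p`.
#'
#' @inheritParams jtf_update_u
#' @return the updated `jtf_state`
#' @export
jtf_update_s <- function(stack, state, p) {
  U <- state$U[[p]]; V <- state$V
  num <- crossprod(U, stack$matrices[[p]]) %*% t(V)
  den <- crossprod(U) %*% state$S[[p]] %*% tcrossprod(V)
  state$S[[p]] <- state$S[[p]] * num / (den + .jtf_eps)
  state
}

#' Multiplicative update of the labeled sample factors V_L
#'
#' With `beta > 0` the update mixes the weighted reconstruction pull with the
#' graph terms: the affinity adjacency (plus the penalty graph's degrees)
#' appears in the numerator and the penalty adjacency (plus the affinity
#' degrees) in the denominator, so same-group neighbors attract and
#' different-group neighbors repel. With `beta = 0` (or no labels) it reduces
#' to the plain weighted tri-factorization update on the labeled columns.
#'
#' @inheritParams jtf_objective
#' @return the updated `jtf_state`
#' @export
jtf_update_vl <- function(stack, state, params, laplacians = NULL) {
  lab <- stack$labeled_index
  if (length(lab) == 0) return(state)
  VL <- state$V[, lab, drop = FALSE]
  num <- matrix(0, nrow(VL), ncol(VL))
  den <- matrix(0, nrow(VL), ncol(VL))
  for (p in seq_len(n_omics(stack))) {
    StUt <- crossprod(state$S[[p]], t(state$U[[p]]))   # k x m_p
    num <- num + state$pi[p] *
      (StUt %*% stack$matrices[[p]][, lab, drop = FALSE])
    G <- StUt %*% state$U[[p]] %*% state$S[[p]]        # S'U'US, k x k
    den <- den + state$pi[p] * (G %*% VL)
  }
  if (!is.null(laplacians) && params$beta > 0) {
    num <- num + params$beta * VL %*% (laplacians$D_p + laplacians$W_a)
    den <- den + params$beta * VL %*% (laplacians$D_a + laplacians$W_p)
  }
  state$V[, lab] <- VL * num / (den + .jtf_eps)
  state
}

#' Multiplicative update of the unlabeled sample factors V_UL
#'
#' Plain weighted tri-factorization update on the unlabeled columns; a no-op
#' when every sample is labeled.
#'
#' @inheritParams jtf_objective
#' @return the updated `jtf_state`
#' @export
jtf_update_vul <- function(stack, state, params) {
  ul <- unlabeled_index(stack)
  if (length(ul) == 0) return(state)
  VU <- state$V[, ul, drop = FALSE]
  num <- matrix(0, nrow(VU), ncol(VU))
  den <- matrix(0, nrow(VU), ncol(VU))
  for (p in seq_len(n_omics(stack))) {
    StUt <- crossprod(state$S[[p]], t(state$U[[p]]))
    num <- num + state$pi[p] *
      (StUt %*% stack$matrices[[p]][, ul, drop = FALSE])
    G <- StUt %*% state$U[[p]] %*% state$S[[p]]
    den <- den + state$pi[p] * (G %*% VU)
  }
  state$V[, ul] <- VU * num / (den + .jtf_eps)
  state
}

#' Closed-form omic weight update on the probability simplex
#'
#' Minimizes `sum_p pi_p c_p + omega * sum_p pi_p^2` over the probability
#' simplex, where `c_p` is omic `p`'s (unweighted) squared Frobenius
#' residual. The KKT conditions give the water-filling solution
#' `pi_p = max(0, (lambda - c_p) / (2 omega))` with `lambda` chosen so the
#' weights sum to one: omics with smaller residuals receive (weakly) larger
#' weights, and sufficiently noisy omics can be driven to exactly zero.
#'
#' @param residuals length-`P` vector of non-negative squared residuals
#' @param omega positive scalar penalty on `||pi||^2`
#' @return length-`P` simplex vector
#' @examples
#' jtf_update_pi(c(0, 1), omega = 1)  # c(0.75, 0.25)
#' jtf_update_pi(c(0, 2), omega = 1)  # boundary solution c(1, 0)
#' @export
jtf_update_pi <- function(residuals, omega) {
  if (omega <= 0)
    stop("omega must be positive; the simplex objective is degenerate otherwise")
  if (any(residuals < 0) || anyNA(residuals))
    stop("residuals must be non-negative")
  P <- length(residuals)
  ord <- order(residuals)
  c_sorted <- residuals[ord]
  # largest active set r such that lambda = (2*omega + sum_{i<=r} c_i)/r
  # keeps pi_(r) = (lambda - c_(r))/(2*omega) >= 0
  csum <- cumsum(c_sorted)
  r_seq <- seq_len(P)
  lambda_r <- (2 * omega + csum) / r_seq
  feasible <- lambda_r >= c_sorted
  r <- max(r_seq[feasible])
  lambda <- lambda_r[r]
  pi <- numeric(P)
  pi[ord[seq_len(r)]] <- (lambda - c_sorted[seq_len(r)]) / (2 * omega)
  pi / sum(pi)  # renormalize away rounding in the simplex constraint
}

#' Fit the joint tri-factorization
#'
#' Runs full update sweeps — `U` then `S` for every omic, then the labeled
#' and unlabeled sample factors, then the omic weights — until the relative
#' objective change drops below `params$tol` or `params$max_iter` sweeps have
#' run. Non-convergence produces a warning and `converged = FALSE`, never an
#' error.
#'
#' @inheritParams jtf_init
#' @param state optional warm-start `jtf_state`; defaults to [jtf_init()].
#' @param verbose print the objective every 25 sweeps.
#' @return the fitted `jtf_state`, with `objective_trace` holding the
#'   objective after initialization and after every sweep.
#' @examples
#' sim <- simulate_multiomics(m = c(40, 30), n = 24, k = 2, seed = 1)
#' fit <- jtf_fit(sim$stack, jtf_params(k = 2, beta = 0, seed = 1))
#' @export
jtf_fit <- function(stack, params, laplacians = NULL, state = NULL,
                    verbose = FALSE) {
  check_params_stack(stack, params)
  if (!is.null(laplacians) && length(stack$labeled_index) > 0 &&
      length(laplacians$sample_order) != length(stack$labeled_index))
    stop("laplacians were built over a different labeled sample set")
  if (is.null(state)) state <- jtf_init(stack, params, laplacians)
  P <- n_omics(stack)
  obj_prev <- utils::tail(state$objective_trace, 1)
  converged <- FALSE

  for (iter in seq_len(params$max_iter)) {
    for (p in seq_len(P)) {
      state <- jtf_update_u(stack, state, p)
      state <- jtf_update_s(stack, state, p)
    }
    state <- jtf_update_vl(stack, state, params, laplacians)
    state <- jtf_update_vul(stack, state, params)
    resid <- vapply(seq_len(P), function(p) {
      R <- stack$matrices[[p]] - state$U[[p]] %*% state$S[[p]] %*% state$V
      sum(R * R)
    }, numeric(1))
    state$pi <- jtf_update_pi(resid, params$omega)

    obj <- jtf_objective(stack, state, params, laplacians)
    state$objective_trace <- c(state$objective_trace, obj)
    state$iterations <- iter
    if (verbose && iter %% 25 == 0)
      message(sprintf("sweep %4d  objective %.8g", iter, obj))
    if (abs(obj - obj_prev) / max(1, abs(obj_prev)) < params$tol) {
      converged <- TRUE
      break
    }
    obj_prev <- obj
  }
  if (!converged)
    warning("objective change did not fall below tol within max_iter sweeps")
  state$converged <- converged
  state
}
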