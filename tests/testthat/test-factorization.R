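test_that("initialization is reproducible, positive, and starts pi uniform", {
  fx <- noisy_fixture(P = 2, seed = 3)
  pr <- jtf_params(k = 2, beta = 0, seed = 42)
  st1 <- jtf_init(fx, pr)
  st2 <- jtf_init(fx, pr)
  expect_identical(st1, st2)
  expect_equal(st1$pi, c(0.5, 0.5))
  expect_true(all(vapply(st1$U, function(u) all(u > 0), logical(1))))
  expect_true(all(st1$V > 0))
  expect_length(st1$objective_trace, 1)
  expect_true(is.finite(st1$objective_trace))

  st3 <- jtf_init(fx, jtf_params(k = 2, beta = 0, seed = 43))
  expect_false(identical(st1$V, st3$V))

  # three omics -> uniform thirds
  fx3 <- noisy_fixture(P = 3, m = c(5, 4, 6), seed = 1)
  expect_equal(jtf_init(fx3, jtf_params(k = 2, beta = 0, seed = 1))$pi,
               rep(1 / 3, 3))

  # degenerate 1x1 case stays scalar and positive
  tiny <- omics_stack(list(matrix(2, 1, 1)), sample_ids = "s1")
  stt <- jtf_init(tiny, jtf_params(k = 1, beta = 0, seed = 9))
  expect_true(stt$U[[1]] > 0 && stt$S[[1]] > 0 && stt$V > 0)

  expect_error(jtf_init(fx, jtf_params(k = 50, beta = 0)), "exceeds")
})

test_that("objective matches an elementwise oracle and its closed cases", {
  pr <- jtf_params(k = 2, beta = 0, omega = 2, seed = 1)

  # exact factorization, beta = 0: only the weight penalty survives
  fx <- exact_fixture(seed = 5)
  expect_equal(jtf_objective(fx$stack, fx$state, pr),
               pr$omega * sum(fx$state$pi^2))

  # all-zero V: residual is the weighted data norm
  z <- fx$state
  z$V[] <- 0
  expect_equal(jtf_objective(fx$stack, z, pr),
               sum(vapply(seq_along(fx$stack$matrices), function(p)
                 z$pi[p] * sum(fx$stack$matrices[[p]]^2), numeric(1))) +
               pr$omega * sum(z$pi^2))

  # random instance vs the naive triple-loop oracle, with Laplacian term
  st <- noisy_fixture(P = 2, m = c(6, 5), n = 5, labeled = 4, seed = 11)
  set.seed(2)
  side <- matrix(runif(12), 3, 4,
                 dimnames = list(NULL, st$sample_ids[st$labeled_index]))
  pair <- build_laplacians(side, st$labels)
  state <- jtf_init(st, jtf_params(k = 2, beta = 3, omega = 2, seed = 7))
  prb <- jtf_params(k = 2, beta = 3, omega = 2, seed = 7)
  expect_equal(jtf_objective(st, state, prb, pair),
               naive_objective(st, state, prb, pair), tolerance = 1e-10)

  bd <- jtf_objective(st, state, prb, pair, breakdown = TRUE)
  expect_equal(bd$reconstruction + bd$laplacian + bd$weight_penalty,
               bd$total)
})

test_that("multiplicative updates keep exact factorizations fixed", {
  for (seed in 1:5) {
    fx <- exact_fixture(P = 2, m = c(6, 8), n = 6, k = 2, labeled = 4,
                        seed = seed)
    pr <- jtf_params(k = 2, beta = 0, seed = seed)
    st <- fx$state
    for (p in 1:2) {
      expect_lt(max_rel_change(jtf_update_u(fx$stack, st, p)$U[[p]],
                               st$U[[p]]), 1e-10)
      expect_lt(max_rel_change(jtf_update_s(fx$stack, st, p)$S[[p]],
                               st$S[[p]]), 1e-10)
    }
    expect_lt(max_rel_change(jtf_update_vl(fx$stack, st, pr)$V, st$V), 1e-10)
    expect_lt(max_rel_change(jtf_update_vul(fx$stack, st, pr)$V, st$V), 1e-10)
  }
})

test_that("U update drives factors to zero on all-zero data", {
  fx <- exact_fixture(seed = 2)
  fx$stack$matrices[[1]][] <- 0
  st <- fx$state
  for (i in 1:50) st <- jtf_update_u(fx$stack, st, 1)
  expect_true(all(st$U[[1]] < 1e-8))
  expect_true(all(st$U[[1]] >= 0))
})

test_that("k = 1 scale update equals the closed-form ratio of inner products", {
  set.seed(4)
  X <- matrix(runif(12, 0.1, 1), 3, 4)
  u <- matrix(runif(3, 0.1, 1), 3, 1)
  v <- matrix(runif(4, 0.1, 1), 1, 4)
  s0 <- matrix(0.7, 1, 1)
  stack <- omics_stack(list(X))
  state <- structure(list(U = list(u), S = list(s0), V = v, pi = 1,
                          objective_trace = numeric(0), converged = NA,
                          iterations = 0L), class = "jtf_state")
  got <- jtf_update_s(stack, state, 1)$S[[1]][1, 1]
  expected <- 0.7 * sum(outer(c(u), c(v)) * X) /
    (sum(u^2) * 0.7 * sum(v^2))
  expect_equal(got, expected, tolerance = 1e-9)
})

test_that("each factor update weakly decreases its reconstruction term", {
  for (seed in 1:10) {
    st <- noisy_fixture(P = 2, m = c(5, 4), n = 4, labeled = 0, seed = seed)
    state <- jtf_init(st, jtf_params(k = 2, beta = 0, seed = seed + 100))
    for (p in 1:2) {
      before <- recon_term(st, state, p)
      state_u <- jtf_update_u(st, state, p)
      expect_lte(recon_term(st, state_u, p), before * (1 + 1e-12))
      after_u <- recon_term(st, state_u, p)
      state_s <- jtf_update_s(st, state_u, p)
      expect_lte(recon_term(st, state_s, p), after_u * (1 + 1e-12))
      state <- state_s
    }
  }
})

test_that("the labeled update at beta = 0 matches the unlabeled update rule", {
  st <- noisy_fixture(P = 2, m = c(6, 5), n = 6, labeled = 4, seed = 9)
  pr <- jtf_params(k = 2, beta = 0, seed = 8)
  state <- jtf_init(st, pr)
  vl <- jtf_update_vl(st, state, pr)

  # same data with no labels: the plain update applies to every column and
  # is column-separable, so the labeled columns must agree exactly
  st_free <- omics_stack(st$matrices, sample_ids = st$sample_ids)
  state_free <- state
  vul <- jtf_update_vul(st_free, state_free, pr)
  lab <- st$labeled_index
  expect_equal(vl$V[, lab], vul$V[, lab], tolerance = 1e-14)
})

test_that("the unlabeled update is a no-op when every sample is labeled", {
  st <- noisy_fixture(n = 4, labeled = 4, seed = 2)
  state <- jtf_init(st, jtf_params(k = 2, beta = 0, seed = 3))
  expect_identical(jtf_update_vul(st, state, jtf_params(k = 2, beta = 0))$V,
                   state$V)
})

test_that("the omic-weight step solves the simplex quadratic exactly", {
  expect_equal(jtf_update_pi(c(0, 1), 1), c(0.75, 0.25))
  expect_equal(jtf_update_pi(c(0, 2), 1), c(1, 0))
  expect_equal(jtf_update_pi(rep(3.7, 4), 5), rep(0.25, 4))
  expect_error(jtf_update_pi(c(1, 2), 0), "positive")
  expect_error(jtf_update_pi(c(-1, 2), 1), "non-negative")

  # lower residual => weakly higher weight
  set.seed(14)
  for (i in 1:20) {
    cvec <- runif(sample(2:5, 1), 0, 10)
    pi <- jtf_update_pi(cvec, runif(1, 0.5, 5))
    expect_equal(sum(pi), 1, tolerance = 1e-9)
    expect_true(all(pi >= 0))
    expect_true(all(diff(pi[order(cvec)]) <= 1e-12))
  }
})

test_that("fit recovers noiseless planted data and flags non-convergence", {
  sim <- simulate_multiomics(P = 2, m = c(40, 30), n = 24, k = 2,
                             noise_sd = 0, labeled_fraction = 0.25, seed = 21)
  pr <- jtf_params(k = 2, beta = 0, omega = 1, max_iter = 5000, tol = 1e-12,
                   seed = 5)
  fit <- suppressWarnings(jtf_fit(sim$stack, pr))
  rel_err <- vapply(1:2, function(p) {
    R <- sim$stack$matrices[[p]] - fit$U[[p]] %*% fit$S[[p]] %*% fit$V
    sqrt(sum(R^2) / sum(sim$stack$matrices[[p]]^2))
  }, numeric(1))
  expect_true(all(rel_err < 1e-3))

  # single omic: the weight simplex collapses to 1
  st1 <- omics_stack(sim$stack$matrices[1], sample_ids = sim$stack$sample_ids)
  fit1 <- suppressWarnings(jtf_fit(st1, jtf_params(k = 2, beta = 0,
                                                   max_iter = 50, seed = 1)))
  expect_equal(fit1$pi, 1)

  expect_warning(
    out <- jtf_fit(sim$stack, jtf_params(k = 2, beta = 0, max_iter = 2,
                                         tol = 1e-12, seed = 1)),
    "did not fall below")
  expect_false(out$converged)
})

test_that("factor entries stay non-negative and pi on the simplex while fitting", {
  st <- noisy_fixture(P = 2, m = c(8, 6), n = 7, labeled = 4, seed = 33)
  set.seed(6)
  side <- matrix(runif(12), 3, 4,
                 dimnames = list(NULL, st$sample_ids[st$labeled_index]))
  pair <- build_laplacians(side, st$labels)
  pr <- jtf_params(k = 2, beta = 5, omega = 10, max_iter = 30, seed = 2)
  state <- jtf_init(st, pr, pair)
  for (it in 1:30) {
    for (p in 1:2) {
      state <- jtf_update_u(st, state, p)
      state <- jtf_update_s(st, state, p)
    }
    state <- jtf_update_vl(st, state, pr, pair)
    state <- jtf_update_vul(st, state, pr)
    resid <- vapply(1:2, function(p) recon_term(st, state, p) / state$pi[p],
                    numeric(1))
    state$pi <- jtf_update_pi(resid, pr$omega)
    expect_true(all(state$V >= 0))
    expect_true(all(vapply(state$U, function(u) all(u >= 0), logical(1))))
    expect_true(all(vapply(state$S, function(s) all(s >= 0), logical(1))))
    expect_equal(sum(state$pi), 1, tolerance = 1e-9)
  }
})
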