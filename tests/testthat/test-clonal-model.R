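test_that("generator matrix has absorbing boundaries and zero row sums", {
  Q2 <- clone_generator(clone_params(2, 1))
  expect_equal(dim(Q2), c(3, 3))
  expect_equal(Q2[1, ], c(`0` = 0, `1` = 0, `2` = 0))
  expect_equal(Q2[3, ], c(`0` = 0, `1` = 0, `2` = 0))
  expect_equal(Q2[2, 2], -2) # exit rate 2 lambda out of the only interior state

  Q5 <- clone_generator(clone_params(5, 0.02))
  expect_equal(unname(rowSums(Q5)), rep(0, 6))
  expect_equal(-Q5[4, 4], 0.04) # rate out of state 3
  expect_error(clone_params(1, 0.02), "integer >= 2")
  expect_error(clone_params(5, 0), "positive")
})

test_that("spectral transition matrix matches the matrix-exponential oracle", {
  for (case in list(list(N = 5, lam = 0.02, t = 100),
                    list(N = 3, lam = 0.5, t = 2),
                    list(N = 12, lam = 0.1, t = 40))) {
    p <- clone_params(case$N, case$lam)
    expect_lt(max(abs(pyloclone:::clone_transition_matrix(p, case$t) -
                        expm_transition(p, case$t))), 1e-10)
  }
})

test_that("long-time absorption matches the linear-system fixation oracle", {
  p <- clone_params(5, 0.02)
  h <- fixation_linear_system(5)
  t_limit <- 20 / p$lambda * p$N^2
  P <- pyloclone:::clone_transition_matrix(p, t_limit)
  expect_equal(h[3], 0.4) # i = 2, N = 5
  for (i in 0:5) {
    expect_lt(abs(P[i + 1, 6] - h[i + 1]), 1e-6)
    expect_lt(abs(P[i + 1, 1] - (1 - h[i + 1])), 1e-6)
    expect_lt(sum(P[i + 1, 2:5]), 1e-6) # interior mass gone
  }
})

test_that("clone pmf is a normalized martingale started at its initial state", {
  p <- clone_params(8, 0.3)
  for (i in c(0, 3, 8)) {
    d0 <- clone_pmf(p, i, 0)
    expect_equal(d0$prob[d0$size == i], 1)
    for (tt in c(1, 10, 1000, 1e4)) {
      d <- clone_pmf(p, i, tt)
      expect_lt(abs(sum(d$prob) - 1), 1e-10)
      expect_lt(abs(sum(d$size * d$prob) - i), 1e-8) # neutral drift mean
      expect_true(all(d$prob >= 0 & d$prob <= 1))
    }
  }
})

test_that("absorbing starts stay absorbed", {
  p <- clone_params(5, 0.02)
  for (tt in c(0, 5, 500)) {
    expect_equal(clone_pmf(p, 0, tt)$prob, c(1, 0, 0, 0, 0, 0))
    expect_equal(clone_pmf(p, 5, tt)$prob, c(0, 0, 0, 0, 0, 1))
  }
})

test_that("mixture pmf is linear in F and reduces to the degenerate case", {
  p <- clone_params(5, 0.02)
  t <- 60
  deg <- clone_pmf_mixed(p, init_degenerate(1, 5), t)
  expect_equal(deg$prob, clone_pmf(p, 1, t)$prob, tolerance = 1e-12)

  F1 <- init_truncated_poisson(2.3, 5)
  F2 <- init_binomial(0.4, 5)
  mix <- 0.3 * F1$probs + 0.7 * F2$probs
  lhs <- pyloclone:::clone_pmf_vec(p, mix, t)
  rhs <- 0.3 * pyloclone:::clone_pmf_vec(p, F1, t) +
    0.7 * pyloclone:::clone_pmf_vec(p, F2, t)
  expect_equal(lhs, rhs, tolerance = 1e-12)

  # uniform initial distribution: half the mass ends extinct by symmetry
  unif <- rep(1 / 6, 6)
  late <- pyloclone:::clone_pmf_vec(p, unif, 20 / p$lambda * 25)
  expect_lt(abs(late[1] - 0.5), 1e-6)
})

test_that("mixed pmf agrees with Monte-Carlo simulation of the chain", {
  p <- clone_params(5, 0.02)
  F <- init_truncated_poisson(2.3, 5)
  n_rep <- 3e5
  emp <- mc_clone_pmf(p, F$probs, 120, n_rep, seed = 202)
  expect_within_3sigma(emp, pyloclone:::clone_pmf_vec(p, F, 120), n_rep)
})

test_that("extinction probability is the lambda-free absorption limit", {
  expect_equal(extinction_probability(5, init_degenerate(5, 5)), 0)
  expect_equal(extinction_probability(5, init_degenerate(0, 5)), 1)

  F <- init_truncated_poisson(2.3, 5)
  pi0 <- extinction_probability(5, F)
  limit <- pyloclone:::clone_pmf_vec(clone_params(5, 1), F, 1e4)[1]
  expect_lt(abs(pi0 - limit), 1e-6)
  # bit-identical for any lambda: the limit does not involve the rate
  expect_identical(pi0, extinction_probability(5, F))
})

test_that("truncated Poisson reassigns exactly the tail mass to N", {
  F <- init_truncated_poisson(2.3, 5)
  expect_equal(F$probs[1], exp(-2.3))
  brute <- c(dpois(0:4, 2.3), sum(dpois(5:200, 2.3)))
  expect_equal(F$probs, brute, tolerance = 1e-14)
  expect_equal(sum(F$probs), 1, tolerance = 1e-12)

  tiny <- init_truncated_poisson(1e-10, 5)
  expect_gt(tiny$probs[1], 1 - 1e-9) # alpha -> 0 limit is degenerate at 0
  expect_error(init_truncated_poisson(0, 5), "positive")
})

test_that("alpha estimators invert the Poisson zero class", {
  expect_equal(estimate_alpha(1 / exp(1)), 1)
  expect_equal(estimate_alpha(exp(-2.3)), 2.3)
  expect_equal(estimate_alpha(0.5), log(2))
  expect_error(estimate_alpha(0), "between 0 and 1")
  expect_error(estimate_alpha(1), "between 0 and 1")
  expect_equal(estimate_alpha_mean(c(2, 3, 4)), 3)
})

test_that("initial distributions validate their support", {
  expect_error(clone_pmf(clone_params(5, 0.02), 6, 1), "0..N")
  expect_error(pyloclone:::as_init_probs(init_truncated_poisson(2, 4), 5),
               "defined on")
  expect_error(pyloclone:::as_init_probs(c(0.5, 0.6), 1), "sum to 1")
  emp <- init_empirical(c(0, 1, 7, 2), 5) # counts above N binned into N
  expect_equal(emp$probs[6], 0.25)
})
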