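test_that("multinomial log-likelihood matches the binomial closed form", {
  counts <- c(30, 70)
  p <- 0.62
  expect_equal(multinomial_loglik(counts, c(1 - p, p)),
               dbinom(70, 100, p, log = TRUE) - lchoose(100, 70))
  ll <- multinomial_loglik(c(0, 5, 1), c(0.5, 0.5, 0))
  expect_identical(unclass(ll)[1], -Inf)
  expect_equal(attr(ll, "zero_prob_bins"), 2L)
  # pooling above the support vs strict support
  expect_equal(multinomial_loglik(c(1, 1, 3), c(0.25, 0.75)),
               1 * log(0.25) + 4 * log(0.75))
  expect_identical(unclass(multinomial_loglik(c(1, 1, 3), c(0.25, 0.75),
                                              pool_above = FALSE))[1], -Inf)
})

test_that("Metropolis recovers a known Gaussian target deterministically", {
  lp <- function(th) dnorm(th, 2, 0.5, log = TRUE)
  post <- metropolis(lp, c(x = 0), n_iter = 15000, seed = 5)
  s <- tidy(post)
  expect_lt(abs(s$estimate - 2), 0.03)
  expect_lt(abs(s$std.error - 0.5), 0.03)
  expect_lt(max(post$rhat), 1.05)
  expect_gt(min(post$ess), 200)
  expect_gt(post$accept_rate, 0.1)
  expect_lt(post$accept_rate, 0.6)

  again <- metropolis(lp, c(x = 0), n_iter = 15000, seed = 5)
  expect_identical(post$draws, again$draws)
  other <- metropolis(lp, c(x = 0), n_iter = 15000, seed = 6)
  expect_false(identical(post$draws$x, other$draws$x))
  expect_lt(abs(tidy(other)$estimate - 2), 0.03) # same target, either seed

  expect_error(metropolis(function(th) -Inf, c(x = 0), n_iter = 100),
               "not finite")
})

test_that("grid profile and MCMC agree on the replacement-rate mode", {
  # per-gland rows whose histogram is proportional to the exact model pmf
  p <- clone_params(5, 0.02)
  init <- init_degenerate(1, 5)
  rows <- purrr::map_dfr(c(0, 40, 100, 200), function(tt) {
    pmf <- pyloclone:::clone_pmf_vec(p, init, tt)
    counts <- round(4000 * pmf)
    tibble::tibble(time_days = tt, n_labelled_lgr5pos = rep(0:5, counts))
  })
  fit <- fit_clonal_lambda(rows, N = 5, init = init, n_iter = 8000, seed = 31)
  s <- tidy(fit)
  expect_lt(abs(s$estimate - 0.02), 0.001)
  prof_mode <- fit$profile$lambda[which.max(fit$profile$loglik)]
  expect_lt(abs(prof_mode - s$estimate), 0.002)
})

test_that("birth-death fit recovers rates from its own exact probabilities", {
  h <- bd_exact_histogram(0.1, 0.05, times = c(2, 4, 6, 8, 10))
  fit <- fit_birth_death(h, n_iter = 12000, seed = 41)
  s <- tidy(fit)
  expect_lt(abs(s$estimate[s$term == "mu"] - 0.1) / 0.1, 0.02)
  expect_lt(abs(s$estimate[s$term == "delta"] - 0.05) / 0.05, 0.05)

  # critical input: the mu - delta interval covers zero
  hc <- purrr::map_dfr(c(5, 15, 30), function(tt) {
    p <- pyloclone:::bd_pmf_vec(0.064, 0.064, tt, k_max = 60)
    p1 <- p[-1] / (1 - p[1])
    tibble::tibble(time_days = tt, k = seq_along(p1), n = 2e4 * p1)
  })
  fitc <- fit_birth_death(hc, n_iter = 12000, seed = 42)
  d <- tidy(fitc)
  diff_row <- d[d$term == "mu_minus_delta", ]
  expect_gt(diff_row$conf.high, 0)
  expect_lt(diff_row$conf.low, 0)
  expect_true(glance(fitc)$diff_ci_covers_zero)

  # the equal-rate refit then pins the common rate
  fite <- fit_birth_death(hc, equal_rates = TRUE, n_iter = 12000, seed = 43)
  expect_lt(abs(tidy(fite)$estimate - 0.064) / 0.064, 0.02)
})

test_that("clone-count decline restores identification near the critical point", {
  # critical cohort: conditional frequencies alone leave a soft (mu, delta)
  # ridge; adding the observed-clone-count decline pins both rates
  cm <- lineage_fixture("clone-matrix", seed = 7001)
  fit <- fit_birth_death(cm, extinction_from_counts = TRUE, n_iter = 10000,
                         seed = 7002)
  s <- tidy(fit)
  expect_lt(abs(s$estimate[s$term == "mu"] - 0.064), 0.012)
  expect_lt(abs(s$estimate[s$term == "delta"] - 0.064), 0.012)
  d <- s[s$term == "mu_minus_delta", ]
  expect_lt(d$conf.low, 0.01)
  expect_gt(d$conf.high, -0.01)
  expect_error(
    fit_birth_death(cm, extinction_from_counts = TRUE,
                    condition_on_labelled = FALSE),
    "conditional")
})

test_that("extinction-probability fit inverts N exactly on noise-free input", {
  pi0 <- extinction_probability(5, init_truncated_poisson(2.3, 5))
  d <- tibble::tibble(time_days = c(200, 300, 400), n_glands = 1000L,
                      n_unresolved = round(1000 * pi0))
  fit <- fit_extinction_N(d, alpha = 2.3)
  expect_equal(fit$N_mode, 5L)
  expect_lt(abs(fit$N_mean - 5), 0.05)
})

test_that("eta fit recovers the progeny growth rate from noise-free means", {
  m <- compartment_means(0.064, 0.064, 0.39, t = c(0, 2, 4, 6, 8))
  d <- tibble::tibble(time_days = m$time, mean_lgr5pos = m$lgr5pos,
                      mean_lgr5neg = m$lgr5neg)
  fit <- fit_compartment_eta(d, 0.064, 0.064, n_iter = 10000, seed = 51)
  s <- tidy(fit)
  expect_lt(abs(s$estimate[s$term == "eta"] - 0.39) / 0.39, 0.02)
})

test_that("Poisson goodness of fit is calibrated and detects non-Poisson data", {
  set.seed(61)
  pvals <- replicate(200, poisson_gof(rpois(300, 4.4))$p_value)
  expect_gt(mean(pvals > 0.05), 0.9)

  d <- poisson_gof(rep(3L, 400))
  expect_lt(d$p_value, 1e-10)
  expect_equal(d$alpha_hat, 3)
  expect_error(poisson_gof(rpois(10, 2)), "at least 30")

  set.seed(62)
  expect_lt(abs(poisson_gof(rpois(5000, 4.4))$alpha_hat - 4.4), 0.1)
})
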