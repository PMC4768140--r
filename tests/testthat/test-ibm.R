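test_that("effective occupancy and the Lgr5+ pool are conserved", {
  d <- ibm_simulate_cohort(ibm_config(), 50, c(0, 30, 90, 200), label_fixed(1),
                           seed = 7)
  expect_true(all(d$n_total_lgr5pos == 7))
  expect_true(all(d$clone_size_effective <= 5))
  expect_true(all(d$clone_size_effective >= 0))
  expect_equal(nrow(d), 50 * 4)

  wide <- ibm_simulate_cohort(ibm_config(diff_boundary = 14), 30,
                              c(0, 10, 40), label_fixed(1, "lgr5"), seed = 8)
  expect_true(all(wide$n_total_lgr5pos >= 7 & wide$n_total_lgr5pos <= 14))
})

test_that("no replacement freezes the basal clone", {
  d <- ibm_simulate_cohort(ibm_config(p_replace = 0), 40,
                           c(0, 50, 150, 400), label_fixed(2), seed = 11)
  per_gland <- tapply(d$clone_size_effective, d$gland_id,
                      function(x) length(unique(x)))
  expect_true(all(per_gland == 1))
  expect_true(all(d$clone_size_effective == 2))
})

test_that("labels are inherited, never created", {
  d <- ibm_simulate_cohort(ibm_config(), 30, c(0, 100, 300), label_fixed(0),
                           seed = 3)
  expect_true(all(d$n_labelled_lgr5pos == 0))
  expect_true(all(d$n_labelled_lgr5neg == 0))
  expect_true(all(d$clone_size_effective == 0))
})

test_that("day-0 clone size equals the number of initially labelled cells", {
  d <- ibm_simulate_cohort(ibm_config(), 60, 0, label_fixed(3), seed = 5)
  expect_true(all(d$clone_size_effective == 3))
  expect_true(all(d$n_labelled_lgr5pos == 3))
})

test_that("identical seeds reproduce the cohort exactly", {
  a <- ibm_simulate_cohort(ibm_config(), 20, c(0, 60, 120), label_fixed(1),
                           seed = 99)
  b <- ibm_simulate_cohort(ibm_config(), 20, c(0, 60, 120), label_fixed(1),
                           seed = 99)
  expect_identical(a, b)
  c <- ibm_simulate_cohort(ibm_config(), 20, c(0, 60, 120), label_fixed(1),
                           seed = 100)
  expect_false(identical(b$clone_size_effective, c$clone_size_effective))
})

test_that("neutral drift: clone-size mean is conserved and fixation nears i/N", {
  # fast replacement so absorption is all but complete within the run
  cfg <- ibm_config(p_replace = 1)
  d <- ibm_simulate_cohort(cfg, 400, c(0, 30, 600), label_fixed(1), seed = 17)
  m30 <- mean(d$clone_size_effective[d$time_days == 30])
  se <- sd(d$clone_size_effective[d$time_days == 30]) / sqrt(400)
  expect_lt(abs(m30 - 1), 4 * se + 0.05) # martingale mean ~ i = 1
  end <- d$clone_size_effective[d$time_days == 600]
  expect_gt(mean(end %in% c(0, 5)), 0.95) # absorbed
  fixed <- mean(end == 5)
  expect_lt(abs(fixed - 0.2), 3 * sqrt(0.2 * 0.8 / 400) + 0.02)
})

test_that("both scenarios run and fitted lambda increases with P", {
  times <- c(0, 40, 90, 150)
  lam_hat <- sapply(c(0.15, 0.6), function(P) {
    d <- ibm_simulate_cohort(ibm_config(p_replace = P, scenario = "1D"), 300,
                             times, label_fixed(1), seed = 23)
    hists <- pyloclone:::clone_hists(d, 5, "clone_size_effective")
    grid <- exp(seq(log(0.004), log(0.15), length.out = 80))
    prof <- sapply(grid, function(lam) {
      pars <- clone_params(5, lam)
      sum(sapply(names(hists), function(tt) {
        multinomial_loglik(hists[[tt]],
                           pyloclone:::clone_pmf_vec(pars, init_degenerate(1, 5),
                                                     as.numeric(tt)))
      }))
    })
    grid[which.max(prof)]
  })
  expect_gt(lam_hat[2], lam_hat[1])
})

test_that("growth rate follows the ln2 / cycle-mean rule", {
  expect_equal(ibm_growth_rate(ibm_config()), log(2) / 11)
  expect_lt(abs(ibm_growth_rate(ibm_config()) - 0.063), 1e-3)
  expect_equal(ibm_growth_rate(ibm_config(cycle_mean = log(2))), 1)
  expect_lt(abs(ibm_growth_rate(ibm_config(cycle_mean = 10.7)) - 0.0648), 1e-4)
})

test_that("configuration is validated", {
  expect_error(ibm_config(p_replace = 1.2))
  expect_error(ibm_config(n_effective = 9, n_lgr5 = 7))
  expect_error(ibm_config(diff_boundary = 5))
  expect_error(ibm_simulate_cohort(ibm_config(), 5, numeric(0)), "at least one")
  expect_error(ibm_simulate_cohort(ibm_config(), 5, c(10, 0)), "nondecreasing")
  expect_error(
    ibm_simulate_cohort(ibm_config(), 2, 0,
                        list(kind = "mystery", where = "lgr5")),
    "labelling rule")
})
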