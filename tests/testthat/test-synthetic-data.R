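test_that("day-0 labelling histogram matches the Poisson scheme", {
  d <- generate_experiment(experiment_design(
    2e4, 0, scheme_poisson(3.7), "markov", clone_params(12, 0.02), seed = 71))
  counts <- d$n_labelled_lgr5pos
  n <- length(counts)
  for (k in 0:8) { # truncation at N = 12 barely touches these bins
    expect_within_3sigma(mean(counts == k), dpois(k, 3.7), n)
  }
})

test_that("four independent colours superpose to a single Poisson total", {
  alphas <- c(1.0, 0.5, 0.4, 0.4)
  d <- generate_experiment(experiment_design(
    2e4, 0, scheme_four_colour(alphas), "markov", clone_params(12, 0.02),
    seed = 72))
  counts <- d$n_labelled_lgr5pos
  expect_lt(abs(mean(counts) - sum(alphas)), 0.05)
  expect_lt(abs(var(counts) / mean(counts) - 1), 0.05) # Poisson dispersion
})

test_that("generators emit the lineage schema with a ground-truth sidecar", {
  for (des in list(
    experiment_design(8, c(0, 20, 40), scheme_poisson(2.3), "markov",
                      clone_params(5, 0.02), seed = 73),
    experiment_design(8, c(0, 10), scheme_poisson(1), "birthdeath",
                      list(mu = 0.064, delta = 0.064), seed = 74),
    experiment_design(8, c(0, 10), scheme_poisson(1), "ibm",
                      ibm_config(), seed = 75))) {
    d <- generate_experiment(des)
    expect_true(all(c("gland_id", "site", "time_days", "n_labelled_lgr5pos",
                      "n_labelled_lgr5neg", "n_total_lgr5pos") %in% names(d)))
    gt <- attr(d, "ground_truth")
    expect_identical(gt$generator, des$generator)
    expect_identical(gt$seed, des$seed)
    expect_equal(nrow(d), 8 * length(des$times))
  }
})

test_that("an induction-only design yields a single snapshot", {
  d <- generate_experiment(experiment_design(
    25, 0, scheme_poisson(2.3), "markov", clone_params(5, 0.02), seed = 76))
  expect_equal(unique(d$time_days), 0)
  expect_equal(nrow(d), 25)
})

test_that("birth-death generator starts every clone at one labelled cell", {
  d <- generate_experiment(experiment_design(
    300, c(0, 15), scheme_poisson(1), "birthdeath",
    list(mu = 0.064, delta = 0.064), seed = 77))
  expect_true(all(d$n_labelled_lgr5pos[d$time_days == 0] == 1))
  # critical process: mean conserved
  m <- mean(d$n_labelled_lgr5pos[d$time_days == 15])
  expect_lt(abs(m - 1), 0.2)
})

test_that("fixtures are deterministic and shaped like their targets", {
  et <- lineage_fixture("extinction-table")
  expect_identical(et, lineage_fixture("extinction-table"))
  pi0 <- extinction_probability(5, init_truncated_poisson(2.3, 5))
  expect_true(all(abs(et$n_unresolved / et$n_glands - pi0) < 0.1))

  cm <- lineage_fixture("clone-matrix")
  day0 <- cm[cm$time_days == 0, ]
  expect_equal(day0$k, 1) # one labelled cell per clone at induction
  expect_true(all(cm$k >= 1))

  mm <- lineage_fixture("mean-matrix")
  expect_equal(nrow(mm), 5)
  expect_true(all(abs(mm$mean_lgr5pos - 1) < 0.2)) # steady Lgr5+ mean
  expect_true(all(diff(mm$mean_lgr5neg) > 0)) # growing progeny

  td <- lineage_fixture("tdtomato")
  expect_setequal(unique(td$site), c("greater", "lesser"))
  expect_equal(sort(unique(td$time_days)), c(0, 5, 12, 42, 59))
  # neutral drift: mean labelled count per gland is conserved over time
  for (s in c("greater", "lesser")) {
    sub <- td[td$site == s, ]
    m <- tapply(pmin(sub$n_labelled_lgr5pos, 5), sub$time_days, mean)
    expect_lt(max(abs(m - m[1])), 0.25)
  }
})

test_that("round-trip refit recovers a fixture's generating lambda", {
  td <- lineage_fixture("tdtomato")
  gt <- attr(td, "ground_truth")
  sub <- td[td$site == "lesser", ]
  fit <- fit_clonal_lambda(sub, N = gt$N, n_iter = 8000, seed = 81)
  s <- tidy(fit)
  expect_gt(gt$lambda[["lesser"]], s$conf.low)
  expect_lt(gt$lambda[["lesser"]], s$conf.high)
})
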