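# Bayesian fits of the clone-expansion, birth-death and compartment models
# to longitudinal lineage-tracing count tables. All fits use flat priors on
# a box whose upper end is 10x a coarse pilot (grid/moment) estimate, and
# random-walk Metropolis ([metropolis()]) for posterior draws.

new_pyloclone_fit <- function(subclass, posterior, data, extra = list()) {
  structure(c(list(posterior = posterior, data = data), extra),
            class = c(subclass, "pyloclone_fit"))
}

#' @export
print.pyloclone_fit <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.pyloclone_fit <- function(x, ...) tidy(x$posterior)

#' @export
glance.pyloclone_fit <- function(x, ...) glance(x$posterior)

# ---------------------------------------------------------------------------
# clone replacement rate lambda, N fixed

#' Fit the clone replacement rate lambda
#'
#' Fits the neutral-drift clone-expansion model to per-time histograms of
#' clone sizes with `N` fixed, by a multinomial likelihood over sizes `0..N`
#' (observed counts above `N` are binned into `N`) and a flat prior on
#' `lambda`. All glands are used, including those with no labelled cells,
#' which carry the extinction signal.
#'
#' @param data A tibble of per-gland records with columns `time_days` and
#'   the clone-size column named by `value_col`.
#' @param N Number of effective cells (fixed).
#' @param init Initial clone-size distribution; by default the empirical
#'   distribution of the earliest sampling time.
#' @param value_col Column holding the per-gland labelled-cell count.
#' @param n_iter,n_chains,seed MCMC settings (see [metropolis()]).
#' @param lambda_max Upper end of the flat prior; defaults to 10x the grid
#'   profile-likelihood mode.
#' @return A `clonal_fit` object; see [tidy.pyloclone_fit()].
#' @export
fit_clonal_lambda <- function(data, N = 5, init = NULL,
                              value_col = "n_labelled_lgr5pos",
                              n_iter = 50000, n_chains = 2L, seed = 1L,
                              lambda_max = NULL) {
  N <- check_N(N)
  hists <- clone_hists(data, N, value_col)
  t0 <- min(as.numeric(names(hists)))
  if (is.null(init)) {
    sizes <- pmin(data[[value_col]][data$time_days == t0], N)
    init <- init_empirical(sizes, N)
  }
  loglik <- function(lam) {
    if (lam <= 0) return(-Inf)
    pars <- clone_params(N, lam)
    sum(vapply(names(hists), function(tt) {
      multinomial_loglik(hists[[tt]], clone_pmf_vec(pars, init, as.numeric(tt)))
    }, numeric(1)))
  }
  grid <- exp(seq(log(1e-4), log(1), length.out = 120))
  prof <- vapply(grid, loglik, numeric(1))
  lam_hat <- grid[which.max(prof)]
  if (is.null(lambda_max)) lambda_max <- max(0.1, 10 * lam_hat)
  post <- metropolis(function(th) loglik(th[1]),
                     c(lambda = lam_hat), n_iter = n_iter, n_chains = n_chains,
                     scales = lam_hat / 4, lower = 0, upper = lambda_max,
                     seed = seed)
  new_pyloclone_fit("clonal_fit", post, data,
                    list(N = N, init = init, value_col = value_col,
                         profile = tibble::tibble(lambda = grid, loglik = prof)))
}

clone_hists <- function(data, N, value_col) {
  stopifnot("time_days" %in% names(data), value_col %in% names(data))
  d <- data
  d$.size <- pmin(d[[value_col]], N)
  times <- sort(unique(d$time_days))
  lapply(stats::setNames(times, times), function(tt) {
    tabulate(d$.size[d$time_days == tt] + 1L, nbins = N + 1L)
  })
}

#' Fit N and lambda jointly by enumeration over N
#'
#' Enumerates the integer number of effective cells over `N_range`, fitting
#' `lambda` freely for each `N`. The posterior probability of each `N`
#' (uniform prior over `N_range`, flat prior on `lambda`) is computed by
#' trapezoidal integration of the likelihood over `lambda`, and the
#' replacement rate is then refit conditional on the modal `N`.
#'
#' The value column must be the clone size on the effective-position scale
#' (e.g. `clone_size_effective` from the IBM): all candidate models are
#' compared on this common outcome space, so a candidate `N` smaller than
#' the largest observed clone size has zero likelihood. Observations are
#' never re-binned per candidate, which would make coarser state spaces
#' spuriously likely.
#'
#' @inheritParams fit_clonal_lambda
#' @param N_range Candidate values of `N`.
#' @return A `clonal_N_fit` object with elements `N_posterior` (tibble over
#'   `N_range`), `N_mode`, and `lambda_fit` (the [fit_clonal_lambda()] fit
#'   at the modal `N`).
#' @export
fit_clonal_N <- function(data, N_range = 2:12,
                         value_col = "clone_size_effective",
                         n_iter = 50000, n_chains = 2L, seed = 1L) {
  stopifnot(all(N_range >= 2))
  lam_grid <- exp(seq(log(1e-4), log(1), length.out = 160))
  max_obs <- max(data[[value_col]])
  times <- sort(unique(data$time_days))
  raw_hists <- lapply(stats::setNames(times, times), function(tt) {
    tabulate(data[[value_col]][data$time_days == tt] + 1L,
             nbins = max_obs + 1L)
  })
  log_ev <- vapply(N_range, function(N) {
    if (N < max_obs) return(-Inf)
    sizes0 <- data[[value_col]][data$time_days == min(data$time_days)]
    init <- init_empirical(sizes0, N)
    prof <- vapply(lam_grid, function(lam) {
      pars <- clone_params(N, lam)
      sum(vapply(names(raw_hists), function(tt) {
        multinomial_loglik(raw_hists[[tt]],
                           clone_pmf_vec(pars, init, as.numeric(tt)),
                           pool_above = FALSE)
      }, numeric(1)))
    }, numeric(1))
    m <- max(prof)
    if (!is.finite(m)) return(-Inf)
    # evidence under a flat prior on lambda over the grid span
    dl <- diff(lam_grid)
    w <- exp(prof - m)
    m + log(sum(dl * (w[-1] + w[-length(w)]) / 2)) - log(max(lam_grid))
  }, numeric(1))
  pN <- exp(log_ev - max(log_ev))
  pN <- pN / sum(pN)
  N_mode <- N_range[which.max(pN)]
  lam_fit <- fit_clonal_lambda(data, N = N_mode, value_col = value_col,
                               n_iter = n_iter, n_chains = n_chains, seed = seed)
  structure(list(N_posterior = tibble::tibble(N = N_range, prob = pN,
                                              log_evidence = log_ev),
                 N_mode = N_mode, lambda_fit = lam_fit, data = data),
            class = c("clonal_N_fit", "pyloclone_fit"))
}

#' @export
tidy.clonal_N_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(term = "N", estimate = x$N_mode,
                   std.error = sqrt(sum(x$N_posterior$prob *
                                          (x$N_posterior$N - sum(x$N_posterior$prob * x$N_posterior$N))^2)),
                   conf.low = NA_real_, median = NA_real_, conf.high = NA_real_,
                   rhat = NA_real_, ess = NA_real_),
    tidy(x$lambda_fit)
  )
}

#' @export
glance.clonal_N_fit <- function(x, ...) {
  dplyr::mutate(glance(x$lambda_fit), N_mode = x$N_mode,
                N_prob = max(x$N_posterior$prob))
}

# ---------------------------------------------------------------------------
# effective cell number N from the limiting extinction probability

#' Fit N from late-time extinction fractions
#'
#' Fits the limiting extinction probability
#' `Pi0(N) = sum_i F(i) (1 - i/N)` to observed late-time fractions of glands
#' that still contain unlabelled Lgr5+ cells, with a binomial observation
#' model per sampling time and truncated-Poisson(`alpha`) initial clone
#' sizes. `N` is treated as an integer and enumerated.
#'
#' @param data A tibble with columns `time_days`, `n_unresolved` (glands
#'   with unlabelled Lgr5+ cells, i.e. not monoclonal for the label) and
#'   `n_glands` (glands analysed). Use times at which the process has
#'   reached its limiting behaviour.
#' @param alpha Poisson labelling intensity at induction (cells).
#' @param N_range Candidate integer values of `N`.
#' @return An `extinction_fit` object with `N_posterior`, `N_mode` and
#'   `N_mean`.
#' @examples
#' d <- tibble::tibble(time_days = c(180, 360, 540),
#'                     n_unresolved = c(275, 270, 272), n_glands = c(500, 500, 500))
#' fit_extinction_N(d, alpha = 2.3)
#' @export
fit_extinction_N <- function(data, alpha, N_range = 2:12) {
  stopifnot(all(c("time_days", "n_unresolved", "n_glands") %in% names(data)),
            all(data$n_unresolved <= data$n_glands))
  ll <- vapply(N_range, function(N) {
    p0 <- extinction_probability(N, init_truncated_poisson(alpha, N))
    sum(stats::dbinom(data$n_unresolved, data$n_glands, p0, log = TRUE))
  }, numeric(1))
  pN <- exp(ll - max(ll)); pN <- pN / sum(pN)
  post <- tibble::tibble(N = N_range, prob = pN, loglik = ll)
  structure(list(N_posterior = post, N_mode = N_range[which.max(pN)],
                 N_mean = sum(N_range * pN),
                 N_sd = sqrt(sum(pN * (N_range - sum(N_range * pN))^2)),
                 alpha = alpha, data = data),
            class = c("extinction_fit", "pyloclone_fit"))
}

#' @export
tidy.extinction_fit <- function(x, ...) {
  tibble::tibble(term = "N", estimate = x$N_mean, std.error = x$N_sd,
                 conf.low = NA_real_, median = NA_real_, conf.high = NA_real_,
                 rhat = NA_real_, ess = NA_real_)
}

#' @export
glance.extinction_fit <- function(x, ...) {
  tibble::tibble(N_mode = x$N_mode, N_mean = x$N_mean, N_sd = x$N_sd,
                 alpha = x$alpha, n_times = nrow(x$data))
}

# ---------------------------------------------------------------------------
# birth-death rates mu, delta

# accept raw per-gland rows or a prebuilt (time_days, k, n) histogram
bd_hist_table <- function(data, value_col) {
  if (all(c("k", "n") %in% names(data))) {
    return(data[c("time_days", "k", "n")])
  }
  stopifnot(value_col %in% names(data))
  d <- dplyr::count(data, .data$time_days, k = .data[[value_col]], name = "n")
  d$n <- as.numeric(d$n)
  d
}

#' Fit birth-death proliferation and differentiation rates
#'
#' Fits the linear birth-death model for the labelled Lgr5+ count per gland
#' (initially one labelled cell) to per-time count histograms from labelled
#' glands. The likelihood is multinomial over counts `k >= 1`, conditioning
#' on the clone being observable (`k >= 1`) at each time, since glands whose
#' clone has gone extinct cannot be distinguished from never-labelled glands
#' in cross-sectional samples. With `equal_rates = TRUE` the critical model
#' `mu = delta` is fitted for the single common rate.
#'
#' @param data Either per-gland rows (`time_days` plus `value_col`) or a
#'   histogram tibble with columns `time_days`, `k`, `n` (counts may be
#'   fractional, e.g. probability-weighted frequencies).
#' @param equal_rates Fit the critical `mu = delta` model.
#' @param value_col Column with the labelled Lgr5+ count per gland.
#' @param k_cap Histogram cap; counts above are pooled.
#' @param condition_on_labelled Condition the likelihood on the clone being
#'   observable (`k >= 1`) at each time, dropping zero-count glands. This
#'   is the right observation model for cross-sectional tissue samples,
#'   where an extinct clone cannot be told apart from a never-labelled
#'   gland. Set `FALSE` for simulated cohorts followed from induction, in
#'   which zero counts are genuine extinction observations that identify
#'   the rates much more sharply.
#' @param extinction_from_counts Use the decline of the absolute number of
#'   observed clones over time as extinction information, in addition to
#'   the conditional clone-size frequencies. Assumes each sampling time is
#'   a batch with the same number of initiated clones, read off the
#'   earliest (day-0) column where no extinction has yet occurred, so that
#'   the observed count at time `t` is Binomial(initiated, `1 - P_0(t)`).
#'   Near the critical point `mu = delta` the conditional frequencies alone
#'   identify the two rates only weakly; this term restores identification
#'   from data already in the clone matrix.
#' @inheritParams fit_clonal_lambda
#' @return A `bd_fit` object. `tidy()` reports `mu` and `delta` (or the
#'   common `rate`) plus the derived difference `mu - delta`.
#' @export
fit_birth_death <- function(data, equal_rates = FALSE,
                            value_col = "n_labelled_lgr5pos", k_cap = 60L,
                            condition_on_labelled = TRUE,
                            extinction_from_counts = FALSE,
                            n_iter = 50000, n_chains = 2L, seed = 1L) {
  h <- bd_hist_table(data, value_col)
  if (condition_on_labelled) h <- h[h$k >= 1, ]
  times <- sort(unique(h$time_days))
  counts <- lapply(stats::setNames(times, times), function(tt) {
    sub <- h[h$time_days == tt, ]
    out <- numeric(max(sub$k) + 1L)
    out[sub$k + 1L] <- sub$n
    out
  })
  n_obs <- vapply(counts, sum, numeric(1))
  if (extinction_from_counts && !condition_on_labelled) {
    stop("`extinction_from_counts` applies to conditional (k >= 1) fits only.",
         call. = FALSE)
  }
  n_init <- n_obs[[1L]] # earliest batch: no extinction yet
  cond_ll <- function(mu, delta) {
    ll <- sum(vapply(names(counts), function(tt) {
      t <- as.numeric(tt)
      p <- bd_pmf_vec(mu, delta, t, k_max = k_cap)
      if (condition_on_labelled) {
        multinomial_loglik(counts[[tt]][-1L], p[-1L] / (1 - p[1L]))
      } else {
        multinomial_loglik(counts[[tt]], p)
      }
    }, numeric(1)))
    if (extinction_from_counts) {
      surv <- vapply(as.numeric(names(counts)[-1L]), function(t) {
        1 - bd_pmf_vec(mu, delta, t, k_max = k_cap)[1L]
      }, numeric(1))
      m <- n_obs[-1L]
      if (any(surv <= 0 | surv >= 1)) {
        surv <- pmin(pmax(surv, 1e-12), 1 - 1e-12)
      }
      ll <- ll + sum(m * log(surv) + pmax(n_init - m, 0) * log(1 - surv))
    }
    ll
  }
  pilot <- pilot_bd_rates(h)
  if (equal_rates) {
    loglik <- function(th) cond_ll(th[1], th[1])
    init <- c(rate = max(pilot["mu"], 1e-3))
    upper <- 10 * init
  } else {
    loglik <- function(th) cond_ll(th[1], th[2])
    init <- c(mu = max(pilot["mu"], 1e-3), delta = max(pilot["delta"], 1e-3))
    upper <- 10 * pmax(init, 0.05)
  }
  post <- metropolis(loglik, init, n_iter = n_iter, n_chains = n_chains,
                     scales = pmax(init / 5, 5e-4), lower = 0, upper = upper,
                     seed = seed)
  new_pyloclone_fit("bd_fit", post, h,
                    list(equal_rates = equal_rates, k_cap = k_cap,
                         condition_on_labelled = condition_on_labelled,
                         extinction_from_counts = extinction_from_counts))
}

# moment pilot: conditional mean of k given k>=1 is m(t)/(1-P0(t)); use the
# growth of the raw conditional mean for mu - delta and a mild default split
pilot_bd_rates <- function(h) {
  means <- dplyr::summarise(dplyr::group_by(h, .data$time_days),
                            m = sum(.data$k * .data$n) / sum(.data$n))
  means <- means[order(means$time_days), ]
  if (nrow(means) >= 2 && max(means$time_days) > 0) {
    slope <- stats::coef(stats::lm(log(pmax(m, 1e-6)) ~ time_days, data = means))[2]
  } else {
    slope <- 0
  }
  # conditional means grow with rate >= mu - delta; centre the pilot at a
  # homeostatic guess and let the flat prior cover 10x
  mu <- max(0.05, slope + 0.05)
  c(mu = mu, delta = max(0.02, mu - slope))
}

#' @export
tidy.bd_fit <- function(x, ...) {
  out <- tidy(x$posterior)
  if (!x$equal_rates) {
    d <- x$posterior$draws$mu - x$posterior$draws$delta
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "mu_minus_delta", estimate = mean(d), std.error = stats::sd(d),
      conf.low = stats::quantile(d, 0.025, names = FALSE),
      median = stats::median(d),
      conf.high = stats::quantile(d, 0.975, names = FALSE),
      rhat = NA_real_, ess = NA_real_))
  }
  out
}

#' @export
glance.bd_fit <- function(x, ...) {
  g <- glance(x$posterior)
  if (!x$equal_rates) {
    d <- x$posterior$draws$mu - x$posterior$draws$delta
    g$diff_ci_covers_zero <- stats::quantile(d, 0.025) <= 0 &&
      stats::quantile(d, 0.975) >= 0
  }
  g
}

# ---------------------------------------------------------------------------
# progeny growth rate eta

#' Fit the Lgr5- progeny growth rate eta
#'
#' Fits the two-compartment mean model ([compartment_means()]) to observed
#' mean labelled Lgr5+ and Lgr5- counts per gland over time, with `mu` and
#' `delta` fixed (to the rates estimated from the same experiment) and a
#' Gaussian observation model whose standard deviation is estimated jointly.
#'
#' @param data A tibble with columns `time_days`, `mean_lgr5pos`,
#'   `mean_lgr5neg`.
#' @param mu,delta Fixed Lgr5+ rates (per day).
#' @param lplus0,lminus0 Initial labelled cells per gland.
#' @inheritParams fit_clonal_lambda
#' @return A `compartment_fit` object; `tidy()` reports `eta` and `sigma`.
#' @export
fit_compartment_eta <- function(data, mu, delta, lplus0 = 1, lminus0 = 0,
                                n_iter = 50000, n_chains = 2L, seed = 1L) {
  stopifnot(all(c("time_days", "mean_lgr5pos", "mean_lgr5neg") %in% names(data)))
  obs <- c(data$mean_lgr5pos, data$mean_lgr5neg)
  loglik <- function(th) {
    eta <- th[1]; sigma <- th[2]
    if (eta < 0 || sigma <= 0) return(-Inf)
    m <- compartment_means(mu, delta, eta, data$time_days, lplus0, lminus0)
    sum(stats::dnorm(obs, c(m$lgr5pos, m$lgr5neg), sigma, log = TRUE))
  }
  # pilot: log-linear growth of the Lgr5- series
  pos <- data$mean_lgr5neg > 0 & data$time_days > 0
  eta0 <- if (sum(pos) >= 2) {
    max(0.05, stats::coef(stats::lm(log(data$mean_lgr5neg[pos]) ~ data$time_days[pos]))[2])
  } else 0.2
  init <- c(eta = eta0, sigma = max(0.05, stats::sd(obs) / 4))
  post <- metropolis(loglik, init, n_iter = n_iter, n_chains = n_chains,
                     scales = c(eta0 / 5, init[2] / 5),
                     lower = c(0, 1e-4), upper = c(10 * eta0, 10 * init[2]),
                     seed = seed)
  new_pyloclone_fit("compartment_fit", post, data,
                    list(mu = mu, delta = delta, lplus0 = lplus0,
                         lminus0 = lminus0))
}

# ---------------------------------------------------------------------------
# Poisson goodness of fit of the initial labelling

#' Chi-square goodness of fit of Poisson initial labelling
#'
#' Tests whether day-0 labelled-cell counts per gland follow a Poisson
#' distribution, as expected if tamoxifen induces recombination events at
#' random. The Poisson mean is estimated by the sample mean; expected bins
#' below `min_expected` are pooled from the top; degrees of freedom are
#' `bins - 2` (one for normalization, one for the estimated mean).
#'
#' @param counts Labelled-cell counts per gland at day 0 (>= 30 glands).
#' @param min_expected Minimum expected count per bin before pooling.
#' @return A tibble with `alpha_hat`, `statistic`, `df`, `p_value`,
#'   `n_bins`.
#' @export
poisson_gof <- function(counts, min_expected = 5) {
  stopifnot(is.numeric(counts), all(counts >= 0), all(counts == round(counts)))
  if (length(counts) < 30) {
    stop("need at least 30 glands for the goodness-of-fit test.", call. = FALSE)
  }
  n <- length(counts)
  alpha_hat <- mean(counts)
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  expd <- n * c(stats::dpois(0:(kmax - 1L), alpha_hat),
                stats::ppois(kmax - 1L, alpha_hat, lower.tail = FALSE))
  # pool sparse bins from the top down
  while (length(expd) > 2L && expd[length(expd)] < min_expected) {
    k <- length(expd)
    expd[k - 1L] <- expd[k - 1L] + expd[k]; expd <- expd[-k]
    obs[k - 1L] <- obs[k - 1L] + obs[k]; obs <- obs[-k]
  }
  # pool any remaining sparse low bins into their neighbour
  while (any(expd < min_expected) && length(expd) > 2L) {
    k <- which(expd < min_expected)[1L]
    j <- if (k == 1L) 2L else k - 1L
    expd[j] <- expd[j] + expd[k]; obs[j] <- obs[j] + obs[k]
    expd <- expd[-k]; obs <- obs[-k]
  }
  stat <- sum((obs - expd)^2 / expd)
  df <- max(1L, length(expd) - 2L)
  tibble::tibble(alpha_hat = alpha_hat, statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 n_bins = length(expd))
}
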