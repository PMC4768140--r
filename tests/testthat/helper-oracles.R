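# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: matrix exponentials for the spectral clone
# pmf, direct stochastic simulation for the analytic pmfs, and a linear
# absorption system for fixation probabilities.

# transition matrix by matrix exponential of the generator (oracle for the
# spectral solution)
expm_transition <- function(params, t) {
  as.matrix(Matrix::expm(clone_generator(params) * t))
}

# fixation probabilities h_i = P(absorb at N | start i) from the linear
# system h_i = (h_{i-1} + h_{i+1})/2, h_0 = 0, h_N = 1
fixation_linear_system <- function(N) {
  A <- diag(N - 1)
  b <- numeric(N - 1)
  for (i in seq_len(N - 1)) {
    if (i > 1) A[i, i - 1] <- -0.5
    if (i < N - 1) A[i, i + 1] <- -0.5
    if (i == N - 1) b[i] <- 0.5
  }
  c(0, solve(A, b), 1)
}

# Monte-Carlo pmf of the clone-size walk: vectorized jump-chain simulation
mc_clone_pmf <- function(params, init_probs, t, n_rep, seed) {
  set.seed(seed)
  N <- params$N
  s <- sample(0:N, n_rep, replace = TRUE, prob = init_probs)
  tcur <- numeric(n_rep)
  repeat {
    active <- which(s > 0 & s < N & tcur < t)
    if (length(active) == 0) break
    tcur[active] <- tcur[active] + stats::rexp(length(active), 2 * params$lambda)
    jump <- active[tcur[active] < t]
    s[jump] <- s[jump] + ifelse(stats::runif(length(jump)) < 0.5, -1L, 1L)
  }
  tabulate(s + 1L, nbins = N + 1L) / n_rep
}

# Monte-Carlo pmf of the linear birth-death process from one cell
gillespie_bd_pmf <- function(mu, delta, t, n_rep, seed, k_bins = 50) {
  set.seed(seed)
  k <- rep(1L, n_rep)
  tcur <- numeric(n_rep)
  repeat {
    active <- which(k > 0 & tcur < t)
    if (length(active) == 0) break
    tcur[active] <- tcur[active] + stats::rexp(length(active),
                                               k[active] * (mu + delta))
    jump <- active[tcur[active] < t]
    up <- stats::runif(length(jump)) < mu / (mu + delta)
    k[jump] <- k[jump] + ifelse(up, 1L, -1L)
  }
  tabulate(pmin(k, k_bins) + 1L, nbins = k_bins + 1L) / n_rep
}

# per-gland rows whose histogram equals w x the exact birth-death pmf,
# conditioned on k >= 1 (noise-free fit input)
bd_exact_histogram <- function(mu, delta, times, weight = 1e5, k_max = 60) {
  purrr::map_dfr(times, function(tt) {
    p <- pyloclone:::bd_pmf_vec(mu, delta, tt, k_max = k_max)
    p1 <- p[-1] / (1 - p[1])
    tibble::tibble(time_days = tt, k = seq_along(p1), n = weight * p1)
  })
}

# binomial three-sigma band check for a vector of empirical frequencies
expect_within_3sigma <- function(emp, expected, n) {
  se <- sqrt(pmax(expected * (1 - expected), 1e-12) / n)
  expect_true(all(abs(emp - expected) <= 3 * se + 1e-9),
              label = paste0("all bins within 3 sigma (max dev ",
                             signif(max(abs(emp - expected) / pmax(se, 1e-12)), 3),
                             " sigma)"))
}
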