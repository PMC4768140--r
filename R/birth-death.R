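#' Linear birth-death model of the labelled Lgr5+ population
#'
#' Number of labelled Lgr5+ cells per gland starting from a single labelled
#' cell, with symmetric division at rate `mu` per cell per day and
#' differentiation (loss of Lgr5) at rate `delta`. For `mu != delta` the
#' classical solution is
#' `P_0(t) = delta (e^{(mu-delta)t} - 1) / (mu e^{(mu-delta)t} - delta)` and
#' `P_k(t) = (1 - P_0)(1 - beta) beta^{k-1}` with
#' `beta = mu (e^{(mu-delta)t} - 1) / (mu e^{(mu-delta)t} - delta)`; the mean
#' is `e^{(mu-delta)t}`. The critical case `mu == delta` has its own form,
#' [bd_pmf_equal()].
#'
#' @param mu Proliferation rate (per day, >= 0).
#' @param delta Differentiation rate (per day, >= 0). Must differ from `mu`;
#'   use [bd_pmf_equal()] at equality.
#' @param t Vector of times (days, >= 0).
#' @param k_max Truncation cap for the count support. By default grown
#'   automatically until the untruncated tail mass is below `1e-8`.
#' @return A tibble with columns `time`, `k` (0..k_max) and `prob`.
#' @examples
#' bd_pmf(0.1, 0.05, t = c(0, 10, 20))
#' @export
bd_pmf <- function(mu, delta, t, k_max = NULL) {
  check_rate(mu, "mu"); check_rate(delta, "delta")
  if (mu == delta) {
    stop("mu == delta is the critical case: use bd_pmf_equal().", call. = FALSE)
  }
  purrr::map_dfr(t, function(tt) {
    p <- bd_pmf_vec(mu, delta, tt, k_max)
    tibble::tibble(time = tt, k = seq_along(p) - 1L, prob = p)
  })
}

check_rate <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop("`", name, "` must be a single nonnegative rate (per day).", call. = FALSE)
  }
}

# internal: pmf over 0..k_max as a numeric vector; handles mu == delta too
bd_pmf_vec <- function(mu, delta, t, k_max = NULL) {
  stopifnot(t >= 0)
  if (is.null(k_max)) {
    k_max <- max(50, ceiling(50 * exp((mu - delta) * t)))
  }
  if (t == 0) {
    p <- numeric(k_max + 1L)
    p[2L] <- 1
    return(p)
  }
  if (mu == delta) {
    if (mu == 0) { # frozen population
      p <- numeric(k_max + 1L)
      p[2L] <- 1
      return(p)
    }
    mt <- mu * t
    k <- seq_len(k_max)
    p <- c(mt / (1 + mt), mt^(k - 1) / (1 + mt)^(k + 1))
  } else {
    w <- exp((mu - delta) * t)
    denom <- mu * w - delta
    p0 <- delta * (w - 1) / denom
    beta <- mu * (w - 1) / denom
    k <- seq_len(k_max)
    if (mu == 0) { # pure death
      p <- c(1 - exp(-delta * t), exp(-delta * t), numeric(k_max - 1L))
    } else {
      p <- c(p0, (1 - p0) * (1 - beta) * beta^(k - 1))
    }
  }
  tail_mass <- 1 - sum(p)
  if (tail_mass > 1e-8) {
    return(bd_pmf_vec(mu, delta, t, k_max = 2L * k_max))
  }
  p
}

#' @rdname bd_pmf
#' @export
bd_pmf_equal <- function(mu, t, k_max = NULL) {
  check_rate(mu, "mu")
  purrr::map_dfr(t, function(tt) {
    p <- bd_pmf_vec(mu, mu, tt, k_max)
    tibble::tibble(time = tt, k = seq_along(p) - 1L, prob = p)
  })
}

#' Birth-death time-scale diagnostics
#'
#' Doubling time and ultimate extinction probability implied by birth-death
#' rates. For a growing population (`mu > delta`) the doubling time is
#' `ln 2 / (mu - delta)` and a clone eventually dies out with probability
#' `delta/mu`; a critical or shrinking population (`mu <= delta`) never
#' doubles (reported as `Inf` with `grows = FALSE`) and dies out with
#' probability 1. For a single net growth rate (e.g. the Lgr5- progeny rate
#' `eta`) pass it as `mu` with `delta = 0`.
#'
#' @inheritParams bd_pmf
#' @return A tibble with columns `mu`, `delta`, `net_rate`, `doubling_time`
#'   (days), `grows` and `extinction_prob`.
#' @examples
#' bd_time_scales(0.39, 0)   # Lgr5- progeny: doubling time ~ 1.8 days
#' bd_time_scales(0.1, 0.05)
#' @export
bd_time_scales <- function(mu, delta) {
  check_rate(mu, "mu"); check_rate(delta, "delta")
  net <- mu - delta
  grows <- net > 0
  tibble::tibble(
    mu = mu, delta = delta, net_rate = net,
    doubling_time = if (grows) log(2) / net else Inf,
    grows = grows,
    extinction_prob = if (mu == 0) 1 else min(1, delta / mu)
  )
}
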