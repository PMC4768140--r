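#' Random-walk Metropolis sampler
#'
#' Plain symmetric Gaussian random-walk Metropolis with per-parameter
#' proposal scales, box support, and scale adaptation during burn-in only
#' (scales are frozen afterwards, preserving detailed balance for the
#' retained draws). Two or more chains are run from jittered starts;
#' split-chain R-hat and a monotone-autocorrelation effective sample size
#' are reported per parameter.
#'
#' @param log_post Function of a parameter vector returning the
#'   log-posterior (may return `-Inf` outside the support).
#' @param init Named numeric vector of initial values; must have finite
#'   log-posterior.
#' @param n_iter Iterations per chain.
#' @param burn Fraction of each chain discarded as burn-in (also the
#'   adaptation window).
#' @param scales Initial proposal standard deviations (recycled).
#' @param lower,upper Box support; proposals outside are rejected via the
#'   prior.
#' @param n_chains Number of chains.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param target_accept Acceptance rate targeted during adaptation.
#' @return An object of class `pyloclone_posterior` with elements `draws`
#'   (tibble of retained draws, with `.chain` and `.lp`), `accept_rate`,
#'   `rhat`, `ess`, `scales`, `seed`.
#' @examples
#' post <- metropolis(function(th) dnorm(th, 2, 1, log = TRUE),
#'                    c(x = 0), n_iter = 2000, seed = 1)
#' summary(post)
#' @export
metropolis <- function(log_post, init, n_iter = 50000, burn = 0.2,
                       scales = NULL, lower = -Inf, upper = Inf,
                       n_chains = 2L, seed = 1L, target_accept = 0.3) {
  stopifnot(is.function(log_post), n_iter > 10, burn > 0, burn < 1)
  d <- length(init)
  if (is.null(names(init))) names(init) <- paste0("par", seq_len(d))
  lp0 <- log_post(init)
  if (!is.finite(lp0)) stop("log-posterior not finite at `init`.", call. = FALSE)
  if (is.null(scales)) scales <- pmax(abs(init), 1e-3) * 0.1
  scales <- rep_len(scales, d)
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  n_burn <- floor(burn * n_iter)

  chains <- vector("list", n_chains)
  acc_rates <- numeric(n_chains)
  final_scales <- matrix(NA_real_, n_chains, d)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + ch - 1L)
    th <- init
    if (ch > 1L) { # jittered overdispersed starts inside the support
      for (tries in 1:50) {
        cand <- pmin(pmax(init + stats::rnorm(d, 0, 2 * scales), lower), upper)
        if (is.finite(log_post(cand))) { th <- cand; break }
      }
    }
    lp <- log_post(th)
    sc <- scales
    draws <- matrix(NA_real_, n_iter, d)
    lps <- numeric(n_iter)
    n_acc <- 0L; win_acc <- 0L; win_n <- 0L
    for (it in seq_len(n_iter)) {
      prop <- th + stats::rnorm(d, 0, sc)
      lp_prop <- if (any(prop < lower | prop > upper)) -Inf else log_post(prop)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        th <- prop; lp <- lp_prop
        n_acc <- n_acc + 1L; win_acc <- win_acc + 1L
      }
      win_n <- win_n + 1L
      if (it <= n_burn && win_n == 50L) { # adapt every 50 iters during burn-in
        rate <- win_acc / win_n
        sc <- sc * exp(rate - target_accept)
        win_acc <- 0L; win_n <- 0L
      }
      draws[it, ] <- th
      lps[it] <- lp
    }
    keep <- (n_burn + 1L):n_iter
    chains[[ch]] <- list(draws = draws[keep, , drop = FALSE], lp = lps[keep])
    acc_rates[ch] <- n_acc / n_iter
    final_scales[ch, ] <- sc
  }

  kept <- do.call(rbind, lapply(chains, `[[`, "draws"))
  colnames(kept) <- names(init)
  draws_tbl <- tibble::as_tibble(kept)
  draws_tbl$.chain <- rep(seq_len(n_chains), each = n_iter - n_burn)
  draws_tbl$.lp <- unlist(lapply(chains, `[[`, "lp"))

  rhat <- vapply(seq_len(d), function(j) {
    split_rhat(lapply(chains, function(c) c$draws[, j]))
  }, numeric(1))
  ess <- vapply(seq_len(d), function(j) {
    sum(vapply(chains, function(c) ess_acf(c$draws[, j]), numeric(1)))
  }, numeric(1))
  names(rhat) <- names(ess) <- names(init)

  mean_acc <- mean(acc_rates)
  if (mean_acc < 0.1 || mean_acc > 0.6) {
    warning("Metropolis acceptance rate ", round(mean_acc, 3),
            " outside [0.1, 0.6] after adaptation.", call. = FALSE)
  }
  structure(list(draws = draws_tbl, accept_rate = mean_acc, rhat = rhat,
                 ess = ess, scales = colMeans(final_scales), seed = seed,
                 n_iter = n_iter, burn = burn, n_chains = n_chains),
            class = "pyloclone_posterior")
}

# split-chain potential scale reduction factor
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[(n + 1L):(2L * n)])
  }), recursive = FALSE)
  m <- length(halves); n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size from initial-monotone positive autocorrelations
ess_acf <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  acf_vals <- stats::acf(x, lag.max = min(n - 1L, 500L), plot = FALSE)$acf[-1L]
  s <- 0
  for (k in seq_along(acf_vals)) {
    if (acf_vals[k] < 0.05) break
    s <- s + acf_vals[k]
  }
  n / (1 + 2 * s)
}

#' @export
print.pyloclone_posterior <- function(x, ...) {
  cat("Random-walk Metropolis posterior:", x$n_chains, "chains x",
      x$n_iter, "iterations (", round(100 * x$burn), "% burn-in )\n", sep = " ")
  cat("acceptance rate", round(x$accept_rate, 3), "\n")
  print(summary(x))
  invisible(x)
}

#' @export
summary.pyloclone_posterior <- function(object, ...) {
  tidy.pyloclone_posterior(object)
}

#' Tidy a posterior into per-parameter summaries
#'
#' @param x A `pyloclone_posterior` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter: posterior mean, sd,
#'   2.5/50/97.5 percentiles, split R-hat and effective sample size.
#' @export
tidy.pyloclone_posterior <- function(x, ...) {
  pars <- setdiff(names(x$draws), c(".chain", ".lp"))
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(
      term = p, estimate = mean(v), std.error = stats::sd(v),
      conf.low = stats::quantile(v, 0.025, names = FALSE),
      median = stats::median(v),
      conf.high = stats::quantile(v, 0.975, names = FALSE),
      rhat = x$rhat[[p]], ess = x$ess[[p]]
    )
  })
}

#' @export
glance.pyloclone_posterior <- function(x, ...) {
  tibble::tibble(n_chains = x$n_chains, n_iter = x$n_iter,
                 accept_rate = x$accept_rate, max_rhat = max(x$rhat),
                 min_ess = min(x$ess), seed = x$seed)
}

#' Trace and density plot of a posterior
#'
#' @param object A `pyloclone_posterior` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pyloclone_posterior <- function(object, ...) {
  pars <- setdiff(names(object$draws), c(".chain", ".lp"))
  d <- object$draws
  d$.iter <- stats::ave(seq_len(nrow(d)), d$.chain, FUN = seq_along)
  long <- tidyr::pivot_longer(d, dplyr::all_of(pars),
                              names_to = "term", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$.iter, .data$value,
                                     colour = factor(.data$.chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration (post burn-in)", y = NULL, colour = "chain") +
    ggplot2::theme_minimal()
}
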