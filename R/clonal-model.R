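#' Neutral-drift clone-size model at the gland base
#'
#' The base of a pyloric gland is modelled as `N` equipotent effective
#' stem-cell positions. A labelled clone of size `S(t)` (number of effective
#' positions carrying the label) performs a continuous-time random walk:
#' it gains one cell at rate `lambda` and loses one cell at rate `lambda`
#' (neighbour replacement), until it is absorbed at extinction (`S = 0`) or
#' monoclonal fixation (`S = N`).
#'
#' @param N Integer, number of effective clone-producing cells (>= 2).
#' @param lambda Clone replacement rate in cells/day (> 0).
#' @return A list of class `clone_params` with elements `N` and `lambda`.
#' @examples
#' clone_params(5, 0.02)
#' @export
clone_params <- function(N, lambda) {
  N <- check_N(N)
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) || lambda <= 0) {
    stop("`lambda` must be a single positive rate (cells/day).", call. = FALSE)
  }
  structure(list(N = N, lambda = lambda), class = "clone_params")
}

check_N <- function(N) {
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N != round(N) || N < 2) {
    stop("`N` must be a single integer >= 2.", call. = FALSE)
  }
  as.integer(N)
}

#' @export
print.clone_params <- function(x, ...) {
  cat("Neutral-drift clone expansion: N =", x$N,
      "effective cells, lambda =", x$lambda, "cells/day\n")
  invisible(x)
}

#' Generator matrix of the clone-size chain
#'
#' Builds the `(N+1) x (N+1)` rate matrix of the clone-size random walk over
#' states `0..N`. Interior states move up and down at rate `lambda`; states
#' 0 and N are absorbing (all-zero rows).
#'
#' @param params A [clone_params()] object.
#' @return A numeric matrix with dimnames `0..N`; every row sums to zero.
#' @export
clone_generator <- function(params) {
  stopifnot(inherits(params, "clone_params"))
  N <- params$N
  lam <- params$lambda
  Q <- matrix(0, N + 1L, N + 1L, dimnames = list(0:N, 0:N))
  for (s in seq_len(N - 1L)) { # interior states 1..N-1, row index s+1
    Q[s + 1L, s] <- lam
    Q[s + 1L, s + 2L] <- lam
    Q[s + 1L, s + 1L] <- -2 * lam
  }
  Q
}

# Transition matrix P_ij(t) = P{S(t)=j | S(0)=i} by the spectral solution of
# the tridiagonal interior block. The interior block is symmetric with known
# eigensystem: eigenvectors v_k(s) = sqrt(2/N) sin(k pi s / N) and
# eigenvalues a_k = -2 lambda (1 - cos(k pi / N)), k = 1..N-1. Absorption
# probabilities follow from integrating the probability flux
# dP_i0/dt = lambda P_i1 and dP_iN/dt = lambda P_i,N-1.
clone_transition_matrix <- function(params, t) {
  stopifnot(inherits(params, "clone_params"), is.numeric(t), length(t) == 1L, t >= 0)
  N <- params$N
  lam <- params$lambda
  k <- seq_len(N - 1L)
  a <- -2 * lam * (1 - cos(k * pi / N))
  V <- sqrt(2 / N) * sin(outer(seq_len(N - 1L), k) * pi / N) # V[s, k] = v_k(s)
  expat <- exp(a * t)
  P <- matrix(0, N + 1L, N + 1L, dimnames = list(0:N, 0:N))
  P[1L, 1L] <- 1
  P[N + 1L, N + 1L] <- 1
  # interior-to-interior block: V diag(e^{a t}) V'
  P[2:N, 2:N] <- V %*% (expat * t(V))
  # flux integrals; a < 0 strictly so (e^{a t} - 1)/a is well defined
  g <- (expat - 1) / a
  P[2:N, 1L] <- lam * as.vector(V %*% (g * V[1L, ]))
  P[2:N, N + 1L] <- lam * as.vector(V %*% (g * V[N - 1L, ]))
  # guard against tiny negative round-off
  P[P < 0 & P > -1e-12] <- 0
  P
}

#' Transient clone-size distribution
#'
#' Probability mass function of the clone size `S(t)` under neutral drift,
#' starting from a fixed initial size `i` ([clone_pmf()]) or from an initial
#' clone-size distribution `F(i)` over `0..N` ([clone_pmf_mixed()]), in which
#' case the pmf is the mixture `sum_i F(i) P_ij(t)`.
#'
#' @param params A [clone_params()] object.
#' @param i Initial clone size, integer in `0..N`.
#' @param t Vector of times since Cre induction (days, >= 0).
#' @return A tibble with columns `time`, `size` (0..N) and `prob`.
#' @examples
#' p <- clone_params(5, 0.02)
#' clone_pmf(p, i = 1, t = c(0, 60, 300))
#' @export
clone_pmf <- function(params, i, t) {
  stopifnot(inherits(params, "clone_params"))
  if (!is.numeric(i) || length(i) != 1L || i != round(i) || i < 0 || i > params$N) {
    stop("`i` must be an integer in 0..N.", call. = FALSE)
  }
  F <- init_degenerate(as.integer(i), params$N)
  clone_pmf_mixed(params, F, t)
}

#' @rdname clone_pmf
#' @param init An initial clone-size distribution created by
#'   [init_truncated_poisson()], [init_degenerate()], [init_binomial()] or
#'   [init_empirical()].
#' @export
clone_pmf_mixed <- function(params, init, t) {
  stopifnot(inherits(params, "clone_params"), is.numeric(t), all(t >= 0))
  F <- as_init_probs(init, params$N)
  purrr::map_dfr(t, function(tt) {
    pj <- as.vector(F %*% clone_transition_matrix(params, tt))
    tibble::tibble(time = tt, size = 0:params$N, prob = pj)
  })
}

# internal: pmf over 0..N as a bare numeric vector at a single time
clone_pmf_vec <- function(params, init, t) {
  F <- as_init_probs(init, params$N)
  as.vector(F %*% clone_transition_matrix(params, t))
}

#' Limiting probability of clone extinction
#'
#' In the limit the clone-size walk is absorbed at 0 (extinction) or `N`
#' (monoclonal fixation). Starting from `S(0) = i` the fixation probability
#' is `i/N`, so with initial distribution `F` the extinction probability is
#' `sum_i F(i) (1 - i/N)`. It does not depend on the replacement rate
#' `lambda`, which is what makes it useful for estimating `N` on its own.
#'
#' @param N Integer number of effective cells.
#' @param init Initial clone-size distribution (see [clone_pmf_mixed()]).
#' @return A single probability.
#' @examples
#' extinction_probability(5, init_truncated_poisson(2.3, 5))
#' @export
extinction_probability <- function(N, init) {
  N <- check_N(N)
  F <- as_init_probs(init, N)
  sum(F * (1 - (0:N) / N))
}

#' Initial clone-size distributions
#'
#' Distributions of the number of labelled effective cells per gland at Cre
#' induction, with support `0..N`:
#' * `init_truncated_poisson()`: Poisson(`alpha`) with the tail mass above
#'   `N` reassigned to `N` (a gland cannot carry more than `N` effective
#'   labelled cells);
#' * `init_binomial()`: Binomial(`N`, `p`), each effective cell labelled
#'   independently;
#' * `init_degenerate()`: all mass at a fixed size `i`;
#' * `init_empirical()`: the observed day-0 size frequencies, counts above
#'   `N` binned into `N`.
#'
#' @param alpha Poisson mean (labelled cells per gland, > 0).
#' @param N Integer number of effective cells.
#' @return An object of class `clone_init`: a probability vector over `0..N`.
#' @examples
#' init_truncated_poisson(2.3, 5)
#' init_empirical(c(0, 1, 1, 3, 0, 7), 5)
#' @export
init_truncated_poisson <- function(alpha, N) {
  N <- check_N(N)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive number.", call. = FALSE)
  }
  probs <- stats::dpois(0:N, alpha)
  probs[N + 1L] <- probs[N + 1L] + stats::ppois(N, alpha, lower.tail = FALSE)
  new_clone_init(probs, N, kind = "poisson-truncated", alpha = alpha)
}

#' @rdname init_truncated_poisson
#' @param p Per-cell labelling probability in `[0, 1]`.
#' @export
init_binomial <- function(p, N) {
  N <- check_N(N)
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  new_clone_init(stats::dbinom(0:N, N, p), N, kind = "binomial")
}

#' @rdname init_truncated_poisson
#' @param i Fixed initial clone size in `0..N`.
#' @export
init_degenerate <- function(i, N) {
  N <- check_N(N)
  stopifnot(i == round(i), i >= 0, i <= N)
  probs <- numeric(N + 1L)
  probs[i + 1L] <- 1
  new_clone_init(probs, N, kind = "degenerate")
}

#' @rdname init_truncated_poisson
#' @param sizes Vector of observed initial clone sizes (counts of labelled
#'   cells per gland at day 0); values above `N` are binned into `N`.
#' @export
init_empirical <- function(sizes, N) {
  N <- check_N(N)
  stopifnot(is.numeric(sizes), length(sizes) > 0, all(sizes >= 0), all(sizes == round(sizes)))
  sizes <- pmin(sizes, N)
  probs <- tabulate(sizes + 1L, nbins = N + 1L) / length(sizes)
  new_clone_init(probs, N, kind = "empirical")
}

new_clone_init <- function(probs, N, kind, alpha = NULL) {
  stopifnot(length(probs) == N + 1L, all(probs >= 0), abs(sum(probs) - 1) < 1e-12)
  structure(list(kind = kind, N = N, probs = probs, alpha = alpha),
            class = "clone_init")
}

#' @export
print.clone_init <- function(x, ...) {
  cat("Initial clone-size distribution (", x$kind, ") on 0..", x$N, ":\n", sep = "")
  print(round(stats::setNames(x$probs, 0:x$N), 4))
  invisible(x)
}

as_init_probs <- function(init, N) {
  if (inherits(init, "clone_init")) {
    if (init$N != N) stop("initial distribution defined on 0..", init$N,
                          " but the model has N = ", N, ".", call. = FALSE)
    return(init$probs)
  }
  if (is.numeric(init)) {
    if (length(init) != N + 1L) {
      stop("numeric initial distribution must have length N + 1 (support 0..N).",
           call. = FALSE)
    }
    if (any(init < 0) || abs(sum(init) - 1) > 1e-12) {
      stop("initial distribution must be nonnegative and sum to 1.", call. = FALSE)
    }
    return(init)
  }
  stop("`init` must be a clone_init object or a probability vector over 0..N.",
       call. = FALSE)
}

#' Estimate the labelling intensity alpha
#'
#' Under Poisson(`alpha`) labelling the fraction of glands with no labelled
#' cell at induction is `exp(-alpha)`, so `alpha = -log(p_zero)`.
#' `estimate_alpha_mean()` is the alternative moment estimator, the mean
#' labelled-cell count per gland; the two agree when labelling is Poisson.
#'
#' @param p_zero Observed fraction of glands with zero labelled cells,
#'   strictly between 0 and 1.
#' @return Estimated `alpha` in cells.
#' @examples
#' estimate_alpha(exp(-2.3))
#' @export
estimate_alpha <- function(p_zero) {
  if (!is.numeric(p_zero) || length(p_zero) != 1L || p_zero <= 0 || p_zero >= 1) {
    stop("`p_zero` must lie strictly between 0 and 1.", call. = FALSE)
  }
  -log(p_zero)
}

#' @rdname estimate_alpha
#' @param counts Labelled-cell counts per gland at day 0.
#' @export
estimate_alpha_mean <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) > 0, all(counts >= 0))
  mean(counts)
}
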