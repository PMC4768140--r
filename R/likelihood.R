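# Observation-model building blocks shared by the fit_* functions.

#' Multinomial log-likelihood of binned counts against model probabilities
#'
#' Computes `sum(count * log(prob))` over bins after pooling observations
#' above the model cap into the top bin. A zero-probability bin carrying a
#' nonzero count yields `-Inf` (with the offending bin reported as an
#' attribute) rather than an error, so samplers can reject such parameter
#' values.
#'
#' @param counts Nonnegative counts (or probability-weighted pseudo-counts)
#'   per observed value `0, 1, 2, ...`.
#' @param probs Model probabilities for values `0..length(probs)-1`; counts
#'   beyond the support are pooled into the last bin when
#'   `pool_above = TRUE`.
#' @param pool_above Pool observations above the model support into the top
#'   bin (the preprocessing rule for fitting rates with the state space
#'   fixed). With `FALSE`, observations outside the support make the
#'   likelihood `-Inf`, as required when models with different state spaces
#'   compete on the same data.
#' @return The log-likelihood (a single number, possibly `-Inf`).
#' @export
multinomial_loglik <- function(counts, probs, pool_above = TRUE) {
  stopifnot(is.numeric(counts), is.numeric(probs), all(counts >= 0))
  nb <- length(probs)
  if (length(counts) > nb) {
    extra <- sum(counts[nb:length(counts)])
    if (!pool_above && sum(counts[(nb + 1L):length(counts)]) > 0) {
      ll <- -Inf
      attr(ll, "zero_prob_bins") <- which(counts > 0) - 1L
      return(ll)
    }
    counts <- c(counts[seq_len(nb - 1L)], extra)
  } else if (length(counts) < nb) {
    counts <- c(counts, numeric(nb - length(counts)))
  }
  used <- counts > 0
  if (any(probs[used] <= 0)) {
    ll <- -Inf
    attr(ll, "zero_prob_bins") <- which(used & probs <= 0) - 1L
    return(ll)
  }
  sum(counts[used] * log(probs[used]))
}

# histogram of a count column per time: named list time -> counts over 0..max
count_histograms <- function(data, value_col, time_col = "time_days") {
  stopifnot(value_col %in% names(data), time_col %in% names(data))
  times <- sort(unique(data[[time_col]]))
  lapply(stats::setNames(times, times), function(tt) {
    v <- data[[value_col]][data[[time_col]] == tt]
    tabulate(v + 1L, nbins = max(v) + 1L)
  })
}

# flat prior on a box; returns a log-prior function
log_prior_box <- function(lower, upper) {
  force(lower); force(upper)
  function(theta) {
    if (any(theta < lower | theta > upper)) -Inf else 0
  }
}
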