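# ggplot2 views of data and fitted models.

#' Observed clone-size frequencies over time
#'
#' Relative frequency of each labelled-cell count per gland at each
#' sampling time, as plotted when judging clone-expansion fits.
#'
#' @param data Per-gland records with `time_days` and the count column.
#' @param value_col Count column name.
#' @param cap Bin counts above `cap` into `cap`.
#' @return A ggplot object.
#' @export
plot_clone_frequencies <- function(data, value_col = "n_labelled_lgr5pos",
                                   cap = 5L) {
  d <- dplyr::count(data, .data$time_days,
                    size = pmin(.data[[value_col]], cap))
  d <- dplyr::mutate(dplyr::group_by(d, .data$time_days),
                     freq = .data$n / sum(.data$n))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_days, .data$freq,
                                  colour = factor(.data$size))) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "days post induction", y = "relative frequency",
                  colour = "labelled cells") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.clonal_fit <- function(object, ...) {
  N <- object$N
  lam <- tidy(object$posterior)$estimate[1]
  pars <- clone_params(N, lam)
  times <- sort(unique(object$data$time_days))
  fitted <- purrr::map_dfr(times, function(tt) {
    tibble::tibble(time_days = tt, size = 0:N,
                   freq = clone_pmf_vec(pars, object$init, tt))
  })
  obs <- dplyr::count(object$data, .data$time_days,
                      size = pmin(.data[[object$value_col]], N))
  obs <- dplyr::mutate(dplyr::group_by(obs, .data$time_days),
                       freq = .data$n / sum(.data$n))
  ggplot2::ggplot(mapping = ggplot2::aes(.data$time_days, .data$freq,
                                         colour = factor(.data$size))) +
    ggplot2::geom_line(data = fitted) +
    ggplot2::geom_point(data = obs) +
    ggplot2::labs(x = "days post induction", y = "probability / frequency",
                  colour = "clone size",
                  title = sprintf("neutral drift fit: N = %d, lambda = %.3f /day",
                                  N, lam)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.bd_fit <- function(object, ...) {
  est <- tidy(object$posterior)
  if (object$equal_rates) {
    mu <- est$estimate[est$term == "rate"]; delta <- mu
  } else {
    mu <- est$estimate[est$term == "mu"]
    delta <- est$estimate[est$term == "delta"]
  }
  times <- sort(unique(object$data$time_days))
  kmax <- min(max(object$data$k), 8L)
  fitted <- purrr::map_dfr(times, function(tt) {
    p <- bd_pmf_vec(mu, delta, tt, k_max = object$k_cap)
    p1 <- p[-1L] / (1 - p[1L])
    tibble::tibble(time_days = tt, k = pmin(seq_along(p1), kmax),
                   freq = p1) |>
      dplyr::summarise(freq = sum(.data$freq), .by = c("time_days", "k"))
  })
  obs <- dplyr::mutate(object$data, k = pmin(.data$k, kmax))
  obs <- dplyr::summarise(obs, n = sum(.data$n), .by = c("time_days", "k"))
  obs <- dplyr::mutate(dplyr::group_by(obs, .data$time_days),
                       freq = .data$n / sum(.data$n))
  ggplot2::ggplot(mapping = ggplot2::aes(.data$time_days, .data$freq,
                                         colour = factor(.data$k))) +
    ggplot2::geom_line(data = fitted) +
    ggplot2::geom_point(data = obs) +
    ggplot2::labs(x = "days post induction", y = "probability / frequency",
                  colour = "labelled Lgr5+ cells",
                  title = sprintf("birth-death fit: mu = %.3f, delta = %.3f /day",
                                  mu, delta)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.compartment_fit <- function(object, ...) {
  eta <- tidy(object$posterior)$estimate[1]
  tt <- seq(min(object$data$time_days), max(object$data$time_days),
            length.out = 100)
  m <- compartment_means(object$mu, object$delta, eta, tt,
                         object$lplus0, object$lminus0)
  fitted <- tidyr::pivot_longer(m, c("lgr5pos", "lgr5neg", "total"),
                                names_to = "population", values_to = "cells")
  obs <- tidyr::pivot_longer(
    dplyr::mutate(object$data,
                  total = .data$mean_lgr5pos + .data$mean_lgr5neg),
    c("mean_lgr5pos", "mean_lgr5neg", "total"),
    names_to = "population", values_to = "cells")
  obs$population <- sub("^mean_", "", obs$population)
  ggplot2::ggplot(mapping = ggplot2::aes(colour = .data$population)) +
    ggplot2::geom_line(data = fitted,
                       ggplot2::aes(.data$time, .data$cells)) +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(.data$time_days, .data$cells)) +
    ggplot2::labs(x = "days post induction", y = "labelled cells per gland",
                  title = sprintf("compartment fit: eta = %.3f /day", eta)) +
    ggplot2::theme_minimal()
}
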