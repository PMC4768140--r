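#' Two-compartment mean dynamics of labelled Lgr5+ and Lgr5- cells
#'
#' Deterministic mean model coupling the labelled Lgr5+ population (net
#' growth `mu - delta`) to its differentiated Lgr5- progeny, which receives
#' the differentiation flux and grows at its own specific rate `eta`:
#' \deqn{dL^+/dt = (\mu - \delta) L^+,\qquad dL^-/dt = \delta L^+ + \eta L^-.}
#' The explicit solution is
#' `L+(t) = L0+ e^{(mu-delta)t}` and
#' `L-(t) = L0- e^{eta t} + delta L0+ (e^{(mu-delta)t} - e^{eta t}) / (mu - delta - eta)`,
#' with the resonant case `eta == mu - delta` handled by its limit
#' `delta L0+ t e^{eta t}` (no near-cancellation).
#'
#' @param mu,delta Lgr5+ proliferation and differentiation rates (per day).
#' @param eta Specific growth rate of labelled Lgr5- cells (per day, >= 0).
#' @param t Vector of times (days, >= 0).
#' @param lplus0,lminus0 Initial labelled Lgr5+ / Lgr5- cells per gland.
#' @return A tibble with columns `time`, `lgr5pos`, `lgr5neg`, `total`.
#' @examples
#' compartment_means(0.064, 0.064, 0.39, t = 0:8)
#' @export
compartment_means <- function(mu, delta, eta, t, lplus0 = 1, lminus0 = 0) {
  check_rate(mu, "mu"); check_rate(delta, "delta"); check_rate(eta, "eta")
  stopifnot(is.numeric(t), all(t >= 0), lplus0 >= 0, lminus0 >= 0)
  net <- mu - delta
  lp <- lplus0 * exp(net * t)
  # resonance threshold: relative, so parameter grids touching eta == net are stable
  if (abs(net - eta) < 1e-10 * max(1, abs(net), abs(eta))) {
    lm <- lminus0 * exp(eta * t) + delta * lplus0 * t * exp(eta * t)
  } else {
    lm <- lminus0 * exp(eta * t) +
      delta * lplus0 * (exp(net * t) - exp(eta * t)) / (net - eta)
  }
  tibble::tibble(time = t, lgr5pos = lp, lgr5neg = lm, total = lp + lm)
}
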