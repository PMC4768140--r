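# Synthetic lineage-tracing experiments. These generators emulate the
# statistical structure of in-vivo pyloric-gland tracing cohorts (Poisson
# labelling at induction, neutral-drift or birth-death clone dynamics,
# cross-sectional sampling) so that every fitting routine can be exercised
# and calibrated without animal data. All outputs carry a `ground_truth`
# attribute recording the generating parameters and seed.

#' Design of a synthetic lineage-tracing experiment
#'
#' @param n_glands Glands per sampling time (longitudinal generators follow
#'   the same glands across times).
#' @param times Sampling times (days since Cre induction), nondecreasing.
#' @param scheme Labelling scheme: `scheme_poisson(alpha)` for single-colour
#'   Poisson labelling or `scheme_four_colour(alphas)` for four independent
#'   superposed Poisson labels.
#' @param generator `"markov"` (neutral-drift clone-size chain),
#'   `"birthdeath"` (labelled Lgr5+ counts), or `"ibm"`.
#' @param params Generating parameters: for `"markov"` a [clone_params()];
#'   for `"birthdeath"` a list with `mu`, `delta`; for `"ibm"` an
#'   [ibm_config()].
#' @param sampling `"cross-sectional"` (the default; each sampling time is
#'   an independent set of glands, as in destructive tissue collection) or
#'   `"longitudinal"` (the same glands followed over time, as in intravital
#'   imaging or simulation studies).
#' @param seed Integer seed.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(n_glands, times, scheme, generator, params,
                              sampling = c("cross-sectional", "longitudinal"),
                              seed = 1L) {
  generator <- match.arg(generator, c("markov", "birthdeath", "ibm"))
  sampling <- match.arg(sampling)
  stopifnot(n_glands >= 1, length(times) >= 1, !is.unsorted(times))
  structure(list(n_glands = as.integer(n_glands), times = times,
                 scheme = scheme, generator = generator, params = params,
                 sampling = sampling, seed = as.integer(seed)),
            class = "experiment_design")
}

#' @rdname experiment_design
#' @param alpha,alphas Poisson labelling intensities (cells per gland).
#' @export
scheme_poisson <- function(alpha) {
  stopifnot(alpha > 0)
  list(kind = "poisson", alpha = alpha)
}

#' @rdname experiment_design
#' @export
scheme_four_colour <- function(alphas) {
  stopifnot(length(alphas) == 4, all(alphas > 0))
  list(kind = "four_colour", alphas = alphas)
}

#' Generate a synthetic lineage-tracing dataset
#'
#' Draws initial labelled-cell counts per gland from the labelling scheme,
#' evolves them with the selected generator, and returns per-gland
#' longitudinal records in the package's lineage-table schema, with the
#' generating parameters in the `ground_truth` attribute (tests and refits
#' must take truth from the sidecar, never from the data).
#'
#' @param design An [experiment_design()] object.
#' @return A tibble with columns `gland_id`, `site`, `time_days`,
#'   `n_labelled_lgr5pos`, `n_labelled_lgr5neg`, `n_total_lgr5pos`, plus a
#'   `ground_truth` attribute.
#' @export
generate_experiment <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  out <- switch(design$generator,
    markov = generate_markov(design),
    birthdeath = generate_birthdeath(design),
    ibm = generate_ibm(design)
  )
  attr(out, "ground_truth") <- list(generator = design$generator,
                                    params = design$params,
                                    scheme = design$scheme,
                                    seed = design$seed)
  out
}

draw_initial_counts <- function(scheme, n) {
  switch(scheme$kind,
    poisson = stats::rpois(n, scheme$alpha),
    four_colour = stats::rpois(n, sum(scheme$alphas)),
    stop("unknown scheme kind: ", scheme$kind, call. = FALSE)
  )
}

# realistic gland-to-gland Lgr5+ totals (discretized normal, truncated >= 1);
# cosmetic only, not used by any model
draw_lgr5_totals <- function(n, mean = 6.9, sd = 2.2) {
  pmax(1L, as.integer(round(stats::rnorm(n, mean, sd))))
}

generate_markov <- function(design) {
  pars <- design$params
  stopifnot(inherits(pars, "clone_params"))
  N <- pars$N
  n <- design$n_glands
  if (identical(design$sampling, "cross-sectional")) {
    # independent glands per sampling time, each evolved from induction
    out <- purrr::map_dfr(seq_along(design$times), function(j) {
      tt <- design$times[j]
      s <- pmin(draw_initial_counts(design$scheme, n), N)
      if (tt > 0) {
        P <- clone_transition_matrix(pars, tt)
        s <- vapply(s, function(i) {
          sample.int(N + 1L, 1L, prob = P[i + 1L, ]) - 1L
        }, integer(1))
      }
      totals <- draw_lgr5_totals(n)
      tibble::tibble(
        gland_id = (j - 1L) * n + seq_len(n), site = "synthetic",
        time_days = tt, n_labelled_lgr5pos = s,
        n_labelled_lgr5neg = NA_integer_,
        n_total_lgr5pos = pmax(totals, s))
    })
    return(out)
  }
  times <- design$times
  s <- pmin(draw_initial_counts(design$scheme, n), N)
  states <- matrix(0L, n, length(times))
  tprev <- 0
  cur <- s
  for (j in seq_along(times)) {
    dt <- times[j] - tprev
    if (dt > 0) {
      P <- clone_transition_matrix(pars, dt)
      cur <- vapply(cur, function(i) {
        sample.int(N + 1L, 1L, prob = P[i + 1L, ]) - 1L
      }, integer(1))
    }
    states[, j] <- cur
    tprev <- times[j]
  }
  totals <- draw_lgr5_totals(n)
  tibble::tibble(
    gland_id = rep(seq_len(n), each = length(times)),
    site = "synthetic",
    time_days = rep(times, n),
    n_labelled_lgr5pos = as.integer(t(states)),
    n_labelled_lgr5neg = NA_integer_,
    n_total_lgr5pos = rep(pmax(totals, apply(states, 1, max)), each = length(times))
  )
}

# exact Gillespie paths of the linear birth-death process from one labelled
# cell, recorded at the sampling times
bd_gillespie_paths <- function(mu, delta, n, times) {
  counts <- matrix(0L, n, length(times))
  for (g in seq_len(n)) {
    k <- 1L; tnow <- 0
    j <- 1L
    while (j <= length(times)) {
      rate <- k * (mu + delta)
      tnext <- if (rate > 0) tnow + stats::rexp(1, rate) else Inf
      while (j <= length(times) && times[j] < tnext) {
        counts[g, j] <- k
        j <- j + 1L
      }
      if (j > length(times)) break
      tnow <- tnext
      k <- if (stats::runif(1) < mu / (mu + delta)) k + 1L else k - 1L
    }
  }
  counts
}

generate_birthdeath <- function(design) {
  mu <- design$params$mu; delta <- design$params$delta
  n <- design$n_glands
  if (identical(design$sampling, "cross-sectional")) {
    out <- purrr::map_dfr(seq_along(design$times), function(j) {
      tt <- design$times[j]
      k <- as.integer(bd_gillespie_paths(mu, delta, n, tt))
      tibble::tibble(
        gland_id = (j - 1L) * n + seq_len(n), site = "synthetic",
        time_days = tt, n_labelled_lgr5pos = k,
        n_labelled_lgr5neg = NA_integer_, n_total_lgr5pos = NA_integer_)
    })
    return(out)
  }
  counts <- bd_gillespie_paths(mu, delta, n, design$times)
  tibble::tibble(
    gland_id = rep(seq_len(n), each = length(design$times)),
    site = "synthetic",
    time_days = rep(design$times, n),
    n_labelled_lgr5pos = as.integer(t(counts)),
    n_labelled_lgr5neg = NA_integer_,
    n_total_lgr5pos = NA_integer_
  )
}

generate_ibm <- function(design) {
  cfg <- design$params
  stopifnot(inherits(cfg, "ibm_config"))
  rule <- if (design$scheme$kind == "poisson") {
    label_poisson(design$scheme$alpha)
  } else {
    label_poisson(sum(design$scheme$alphas))
  }
  if (identical(design$sampling, "cross-sectional")) {
    d <- purrr::map_dfr(seq_along(design$times), function(j) {
      dj <- ibm_simulate_cohort(cfg, design$n_glands, design$times[j], rule,
                                seed = design$seed + j - 1L)
      dj$gland_id <- dj$gland_id + (j - 1L) * design$n_glands
      dj
    })
  } else {
    d <- ibm_simulate_cohort(cfg, design$n_glands, design$times, rule,
                             seed = design$seed)
  }
  tibble::tibble(
    gland_id = d$gland_id, site = "synthetic", time_days = d$time_days,
    n_labelled_lgr5pos = d$n_labelled_lgr5pos,
    n_labelled_lgr5neg = d$n_labelled_lgr5neg,
    n_total_lgr5pos = d$n_total_lgr5pos
  )
}

#' Deterministic desk-scale fixtures shaped like the published datasets
#'
#' Seeded synthetic stand-ins with the structure of the lineage-tracing
#' datasets the models were originally fitted to, generated at the
#' published parameter values (`N = 5`, `lambda = 0.02`/day,
#' `mu = delta = 0.064`/day, `eta = 0.39`/day, `alpha = 2.3`):
#' * `"extinction-table"`: late-time percentages of glands retaining
#'   unlabelled Lgr5+ cells (limiting behaviour; three sampling times);
#' * `"clone-matrix"`: cross-sectional clone-size counts (labelled Lgr5+
#'   cells per clone) from a four-colour short-term experiment, one labelled
#'   cell per clone at day 0, evolved by the critical birth-death process;
#' * `"mean-matrix"`: mean labelled Lgr5+ and Lgr5- cells per gland over the
#'   first days, from the compartment model with observation noise;
#' * `"tdtomato"`: longitudinal neutral-drift clone-size records on two
#'   sites (greater/lesser curvature analogues) at days 0, 5, 12, 42, 59.
#'
#' @param name Fixture name.
#' @param seed Integer seed (fixtures are deterministic given the seed).
#' @return A tibble whose schema depends on the fixture (see each fit's
#'   expected input), with a `ground_truth` attribute.
#' @export
lineage_fixture <- function(name = c("extinction-table", "clone-matrix",
                                     "mean-matrix", "tdtomato"),
                            seed = 20160226L) {
  name <- match.arg(name)
  set.seed(seed)
  out <- switch(name,
    "extinction-table" = {
      p0 <- extinction_probability(5, init_truncated_poisson(2.3, 5))
      n <- c(512L, 488L, 503L)
      tibble::tibble(
        time_days = c(180, 360, 540),
        n_glands = n,
        n_unresolved = stats::rbinom(3, n, p0)
      )
    },
    "clone-matrix" = {
      # cross-sectional four-colour cohort; only observable clones (k >= 1)
      d <- generate_experiment(experiment_design(
        n_glands = 800, times = c(0, 7, 14, 21, 30),
        scheme = scheme_four_colour(rep(0.25, 4)),
        generator = "birthdeath", params = list(mu = 0.064, delta = 0.064),
        seed = seed))
      h <- dplyr::count(d[d$n_labelled_lgr5pos >= 1, ],
                        .data$time_days, k = .data$n_labelled_lgr5pos,
                        name = "n")
      h$n <- as.numeric(h$n)
      h
    },
    "mean-matrix" = {
      m <- compartment_means(0.064, 0.064, 0.39, t = c(0, 2, 4, 6, 8))
      tibble::tibble(
        time_days = m$time,
        mean_lgr5pos = pmax(0, m$lgr5pos + stats::rnorm(5, 0, 0.05)),
        mean_lgr5neg = pmax(0, m$lgr5neg + c(0, stats::rnorm(4, 0, 0.08)))
      )
    },
    "tdtomato" = {
      # gland numbers emulate 737 / 477 glands spread over five collections
      sites <- list(greater = list(n = 147L, alpha = 4.4, lambda = 0.017),
                    lesser = list(n = 95L, alpha = 3.7, lambda = 0.020))
      purrr::imap_dfr(sites, function(s, nm) {
        d <- generate_experiment(experiment_design(
          n_glands = s$n, times = c(0, 5, 12, 42, 59),
          scheme = scheme_poisson(s$alpha), generator = "markov",
          params = clone_params(5, s$lambda), seed = seed + s$n))
        d$site <- nm
        d
      })
    }
  )
  attr(out, "ground_truth") <- list(
    fixture = name, seed = seed, N = 5, lambda = c(greater = 0.017, lesser = 0.020),
    mu = 0.064, delta = 0.064, eta = 0.39, alpha = 2.3)
  out
}
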