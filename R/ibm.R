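#' Configuration of the individual-based gland model
#'
#' Event-driven simulator of the base of a pyloric gland. Seven Lgr5+ cells
#' occupy a single upward stack of positions `0..n_lgr5-1`; the bottom
#' `n_effective` positions form the ring of effective clone-producing cells.
#' Cells divide with gamma-distributed cycle times. When an effective cell
#' divides, with probability `p_replace` the new cell displaces another
#' effective cell (a ring neighbour in scenario `"1D"`, any other effective
#' cell in `"2D"`); the displaced cell in turn either moves upward
#' (probability `1 - p_replace`) or displaces another effective cell, so the
#' displacement cascade recurses until one cell is exported upward. Exactly
#' one cell leaves the effective compartment per division event. Cells
#' pushed to positions at or above `diff_boundary` lose Lgr5 permanently.
#' Labels are heritable and are never created or destroyed.
#'
#' @param n_effective Number of effective clone-producing basal positions.
#' @param n_lgr5 Number of Lgr5+ cells at the base at the start.
#' @param cycle_mean Mean cell-cycle duration (days).
#' @param cycle_shape Gamma shape of the cycle-time distribution
#'   (dimensionless; the default gives a cycle CV of about 0.35).
#' @param p_replace Probability `P` that a newly generated effective cell
#'   replaces another effective cell rather than moving upward. The default
#'   is calibrated so that, with the default cycle, the basal replacement
#'   dynamics correspond to a clone replacement rate of about 0.02
#'   cells/day (see the package vignette).
#' @param scenario `"1D"` (ring neighbours) or `"2D"` (any effective cell).
#' @param diff_boundary Position index at and above which cells lose Lgr5.
#'   Defaults to `n_lgr5`, keeping the Lgr5+ pool at its initial size; set
#'   to 14 to reproduce the uncoupled-differentiation experiment in which
#'   cells do not differentiate within the first 14 positions.
#' @return A list of class `ibm_config`.
#' @examples
#' ibm_config()
#' ibm_config(diff_boundary = 14)
#' @export
ibm_config <- function(n_effective = 5L, n_lgr5 = 7L, cycle_mean = 11,
                       cycle_shape = 8, p_replace = 0.25, scenario = c("2D", "1D"),
                       diff_boundary = n_lgr5) {
  scenario <- match.arg(scenario)
  stopifnot(n_effective >= 2, n_lgr5 >= n_effective, cycle_mean > 0,
            cycle_shape > 0, p_replace >= 0, p_replace <= 1,
            diff_boundary >= n_lgr5)
  structure(list(n_effective = as.integer(n_effective),
                 n_lgr5 = as.integer(n_lgr5),
                 cycle_mean = cycle_mean, cycle_shape = cycle_shape,
                 p_replace = p_replace, scenario = scenario,
                 diff_boundary = as.integer(diff_boundary)),
            class = "ibm_config")
}

#' @export
print.ibm_config <- function(x, ...) {
  cat("IBM gland config:", x$n_lgr5, "Lgr5+ cells,", x$n_effective,
      "effective;", "cycle", x$cycle_mean, "d (gamma shape", x$cycle_shape,
      ");", "P =", x$p_replace, x$scenario,
      "; differentiation above position", x$diff_boundary - 1L, "\n")
  invisible(x)
}

#' Specific growth rate implied by the cell cycle
#'
#' Binary fission with mean cycle `T` doubles a population every `T` days,
#' so the specific (exponential) growth rate is `ln 2 / T`; an 11-day cycle
#' gives 0.063 per day.
#'
#' @param config An [ibm_config()] object.
#' @return Growth rate per day.
#' @export
ibm_growth_rate <- function(config) {
  stopifnot(inherits(config, "ibm_config"))
  log(2) / config$cycle_mean
}

#' Initial labelling rules for the IBM
#'
#' `label_fixed(k)` labels `k` cells at random positions (among the
#' effective ring by default, matching clonal-expansion experiments where
#' the clone size at induction is the count of labelled effective cells);
#' `label_poisson(alpha)` labels a Poisson(`alpha`) number of Lgr5+ cells at
#' random positions, capped at the number of Lgr5+ cells.
#'
#' @param k Number of cells to label.
#' @param where `"effective"` or `"lgr5"`.
#' @param alpha Poisson mean of the number of labelled cells.
#' @return A labelling rule understood by [ibm_simulate_cohort()].
#' @export
label_fixed <- function(k, where = c("effective", "lgr5")) {
  where <- match.arg(where)
  stopifnot(k >= 0, k == round(k))
  list(kind = "fixed", k = as.integer(k), where = where)
}

#' @rdname label_fixed
#' @export
label_poisson <- function(alpha, where = c("lgr5", "effective")) {
  where <- match.arg(where)
  stopifnot(alpha > 0)
  list(kind = "poisson", alpha = alpha, where = where)
}

draw_initial_labels <- function(rule, config) {
  pool <- if (identical(rule$where, "effective")) config$n_effective else config$n_lgr5
  k <- switch(rule$kind,
    fixed = rule$k,
    poisson = min(stats::rpois(1L, rule$alpha), pool),
    stop("unknown labelling rule kind: ", rule$kind, call. = FALSE)
  )
  if (k > pool) stop("cannot label ", k, " cells among ", pool, ".", call. = FALSE)
  sample.int(pool, k)
}

# fresh cycle draw and stationary residual draw (length-biased cycle x U)
draw_cycle <- function(n, config) {
  stats::rgamma(n, shape = config$cycle_shape,
                rate = config$cycle_shape / config$cycle_mean)
}
draw_residual <- function(n, config) {
  stats::runif(n) * stats::rgamma(n, shape = config$cycle_shape + 1,
                                  rate = config$cycle_shape / config$cycle_mean)
}

# Simulate one gland; returns a matrix with one row per sampling time:
# columns lgr5pos_lab, lgr5neg_lab, clone_eff, lgr5pos_total.
sim_gland_core <- function(config, sampling_times, label_positions) {
  ne <- config$n_effective
  cap <- config$diff_boundary
  P <- config$p_replace
  two_d <- identical(config$scenario, "2D")
  n_occ <- config$n_lgr5
  lab <- integer(cap)
  lab[label_positions] <- 1L
  tdiv <- rep(Inf, cap)
  tdiv[seq_len(n_occ)] <- draw_residual(n_occ, config)
  exported <- 0L

  ns <- length(sampling_times)
  out <- matrix(0L, ns, 4L)
  si <- 1L

  # push a cell (plab, ptd) into stack slot q (1-based), shifting cells above
  # upward; the top cell leaves the Lgr5+ zone if the stack is at capacity
  repeat {
    j <- which.min(tdiv[seq_len(n_occ)])
    tnow <- tdiv[j]
    while (si <= ns && sampling_times[si] <= tnow) {
      occ <- seq_len(n_occ)
      out[si, ] <- c(sum(lab[occ] > 0L), exported,
                     sum(lab[seq_len(ne)] > 0L), n_occ)
      si <- si + 1L
    }
    if (si > ns) break

    tdiv[j] <- tnow + draw_cycle(1L, config) # mother redraws her clock
    push_lab <- NA_integer_; push_td <- NA_real_; push_q <- NA_integer_
    if (j <= ne) {
      if (stats::runif(1L) < P) {
        # displacement cascade within the effective ring
        inc_lab <- lab[j]
        inc_td <- tnow + draw_cycle(1L, config)
        from <- j
        replaced <- logical(ne)
        nrep <- 0L
        repeat {
          target <- if (two_d) {
            tg <- sample.int(ne - 1L, 1L)
            if (tg >= from) tg + 1L else tg
          } else {
            if (stats::runif(1L) < 0.5) from %% ne + 1L else (from - 2L) %% ne + 1L
          }
          disp_lab <- lab[target]; disp_td <- tdiv[target]
          lab[target] <- inc_lab; tdiv[target] <- inc_td
          if (!replaced[target]) { replaced[target] <- TRUE; nrep <- nrep + 1L }
          if (nrep < ne && stats::runif(1L) < P) {
            inc_lab <- disp_lab; inc_td <- disp_td; from <- target
          } else {
            push_lab <- disp_lab; push_td <- disp_td; push_q <- ne + 1L
            break
          }
        }
      } else {
        push_lab <- lab[j]; push_td <- tnow + draw_cycle(1L, config); push_q <- ne + 1L
      }
    } else {
      push_lab <- lab[j]; push_td <- tnow + draw_cycle(1L, config); push_q <- j + 1L
    }
    # insert the pushed cell, shifting the stack upward; whoever crosses the
    # differentiation boundary loses Lgr5 and leaves the tracked zone
    if (push_q > cap) { # division in the top ring of a full zone
      if (push_lab > 0L) exported <- exported + 1L
    } else if (n_occ == cap) {
      if (lab[cap] > 0L) exported <- exported + 1L
      idx <- if (push_q <= cap - 1L) (cap - 1L):push_q else integer(0)
      for (q in idx) { lab[q + 1L] <- lab[q]; tdiv[q + 1L] <- tdiv[q] }
      lab[push_q] <- push_lab; tdiv[push_q] <- push_td
    } else {
      idx <- if (push_q <= n_occ) n_occ:push_q else integer(0)
      for (q in idx) { lab[q + 1L] <- lab[q]; tdiv[q + 1L] <- tdiv[q] }
      n_occ <- n_occ + 1L
      lab[push_q] <- push_lab; tdiv[push_q] <- push_td
    }
  }
  out
}

#' Simulate a cohort of glands with the individual-based model
#'
#' Runs independent glands and records, at each sampling time, the number of
#' labelled Lgr5+ cells, the number of labelled cells that have left the
#' Lgr5+ zone (labelled Lgr5- cells, counted as exported cells without
#' further proliferation), the clone size among effective positions, and the
#' total Lgr5+ count.
#'
#' @param config An [ibm_config()] object.
#' @param n_glands Number of independent glands.
#' @param sampling_times Sorted vector of sampling times (days).
#' @param init_label A labelling rule from [label_fixed()] or
#'   [label_poisson()].
#' @param seed Master seed; per-gland streams are derived from it.
#' @return A tibble with columns `gland_id`, `time_days`,
#'   `n_labelled_lgr5pos`, `n_labelled_lgr5neg`, `clone_size_effective`,
#'   `n_total_lgr5pos`.
#' @examples
#' ibm_simulate_cohort(ibm_config(), 5, c(0, 30, 60), label_fixed(1), seed = 1)
#' @export
ibm_simulate_cohort <- function(config, n_glands, sampling_times,
                                init_label = label_fixed(1), seed = 1L) {
  stopifnot(inherits(config, "ibm_config"), n_glands >= 1)
  if (length(sampling_times) == 0) {
    stop("`sampling_times` must contain at least one time.", call. = FALSE)
  }
  if (is.unsorted(sampling_times)) {
    stop("`sampling_times` must be nondecreasing.", call. = FALSE)
  }
  set.seed(seed)
  gland_seeds <- sample.int(.Machine$integer.max, n_glands)
  ns <- length(sampling_times)
  res <- matrix(0L, n_glands * ns, 4L)
  for (g in seq_len(n_glands)) {
    set.seed(gland_seeds[g])
    pos <- draw_initial_labels(init_label, config)
    res[((g - 1L) * ns + 1L):(g * ns), ] <- sim_gland_core(config, sampling_times, pos)
  }
  tibble::tibble(
    gland_id = rep(seq_len(n_glands), each = ns),
    time_days = rep(sampling_times, n_glands),
    n_labelled_lgr5pos = res[, 1L],
    n_labelled_lgr5neg = res[, 2L],
    clone_size_effective = res[, 3L],
    n_total_lgr5pos = res[, 4L]
  )
}

#' @rdname ibm_simulate_cohort
#' @export
ibm_simulate_gland <- function(config, sampling_times,
                               init_label = label_fixed(1), seed = 1L) {
  ibm_simulate_cohort(config, 1L, sampling_times, init_label, seed)
}
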