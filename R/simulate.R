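#' Simulate the growth of a cell population as a lineage tree
#'
#' Event-driven birth process: each founder starts at age 0 at time 0 with a
#' cycle length drawn from the marginal Gamma(a, b). When a cell's cycle
#' elapses it is replaced by two daughters whose cycle lengths come from
#' [sample_daughter_pair()] (correlated sisters, independent of the mother).
#' Cells whose division would fall after `t_end` are censored alive.
#'
#' @param params A [cycle_params()] object.
#' @param t_end Simulation horizon (hours, > 0).
#' @param n_founders Number of independent founder cells at time 0.
#' @param seed Optional integer seed.
#' @param cap Maximum number of cells recorded before the simulation aborts
#'   with an error; guards against runaway parameter choices.
#' @param tau_min Minimum admissible daughter cycle length, see
#'   [sample_daughter_pair()].
#' @return A lineage table: data frame with columns `cell_id`, `parent_id`,
#'   `sister_id` (`NA` for founders), `birth_h`, `cycle_h` and `division_h`
#'   (`NA` for cells still alive at `t_end`).
#' @examples
#' lin <- simulate_population(cycle_params(3, 0.405, 1), t_end = 48, seed = 1)
#' nrow(lin)
#' @export
simulate_population <- function(params, t_end, n_founders = 1L, seed = NULL,
                                cap = 2e6, tau_min = 0.5) {
  p <- as_cycle_params(params)
  stopifnot(t_end > 0, n_founders >= 1)
  if (!is.null(seed)) set.seed(seed)
  s <- p$sigma / sqrt(2)

  birth <- list(rep(0, n_founders))
  cycle <- list(rgamma(n_founders, p$shape, p$rate))
  parent <- list(rep(NA_integer_, n_founders))
  sister <- list(rep(NA_integer_, n_founders))
  n_total <- n_founders

  ## frontier: cells that will divide before t_end
  div0 <- birth[[1]] + cycle[[1]]
  live <- div0 <= t_end
  f_div <- div0[live]
  f_id <- seq_len(n_founders)[live]

  while (length(f_div)) {
    k <- length(f_div)
    tau1 <- rgamma(k, p$shape, p$rate)
    tau2 <- tau1 + rlaplace(k, s)
    bad <- which(tau2 <= tau_min)
    while (length(bad)) {
      tau2[bad] <- tau1[bad] + rlaplace(length(bad), s)
      bad <- bad[tau2[bad] <= tau_min]
    }
    ids <- n_total + seq_len(2 * k)
    n_total <- n_total + 2 * k
    if (n_total > cap) stop("population cap exceeded")
    nb <- rep(f_div, each = 2)
    nc <- as.vector(rbind(tau1, tau2))
    birth[[length(birth) + 1L]] <- nb
    cycle[[length(cycle) + 1L]] <- nc
    parent[[length(parent) + 1L]] <- rep(f_id, each = 2)
    odd <- seq(1L, 2L * k, by = 2L)
    sis <- integer(2 * k)
    sis[odd] <- ids[odd + 1L]
    sis[odd + 1L] <- ids[odd]
    sister[[length(sister) + 1L]] <- sis
    nd <- nb + nc
    keep <- nd <= t_end
    f_div <- nd[keep]
    f_id <- ids[keep]
  }

  birth <- unlist(birth); cycle <- unlist(cycle)
  division <- birth + cycle
  division[division > t_end] <- NA_real_
  data.frame(cell_id = seq_len(n_total),
             parent_id = unlist(parent),
             sister_id = unlist(sister),
             birth_h = birth,
             cycle_h = cycle,
             division_h = division)
}

#' Extract the live population at the end of a simulation
#'
#' Cells censored alive at `t_end` with their age (hours since their last
#' division, i.e. their birth) and the already-scheduled time remaining to
#' their next division.
#'
#' @param lineage A lineage table from [simulate_population()].
#' @param t_end The horizon the table was simulated to.
#' @return Data frame with columns `cell_id`, `hours_since_division` and
#'   `hours_to_next_division`.
#' @export
population_at_time <- function(lineage, t_end) {
  alive <- is.na(lineage$division_h) |
    (lineage$birth_h <= t_end & lineage$birth_h + lineage$cycle_h > t_end)
  lin <- lineage[alive & lineage$birth_h <= t_end, , drop = FALSE]
  data.frame(cell_id = lin$cell_id,
             hours_since_division = t_end - lin$birth_h,
             hours_to_next_division = lin$birth_h + lin$cycle_h - t_end)
}

#' Hourly division counts and per-capita division fractions
#'
#' For each hourly window `[h, h+1)` counts the division events and divides
#' by the number of cells alive at the window start `h` (a cell is alive on
#' `[birth, division)`; censored cells remain alive through `t_end`). With
#' this denominator the steady-state fraction equals `exp(r) - 1`, where `r`
#' is the Euler-Lotka growth rate, making the series checkable analytically.
#'
#' @param lineage A lineage table from [simulate_population()] or an
#'   observed table with the same columns.
#' @param t_end Horizon in hours; windows run from 0 to `ceiling(t_end)`.
#' @return Data frame of class `"division_series"` with columns
#'   `window_start_h`, `divisions`, `cells_at_start` and `fraction`.
#' @export
hourly_division_fraction <- function(lineage, t_end) {
  stopifnot(t_end > 0)
  n_win <- as.integer(ceiling(t_end))
  h <- seq_len(n_win) - 1
  div <- lineage$division_h[!is.na(lineage$division_h)]
  div <- div[div <= t_end]
  divisions <- tabulate(floor(div) + 1L, nbins = n_win)
  n_born <- findInterval(h, sort(lineage$birth_h))
  n_divided <- findInterval(h, sort(div))
  cells <- n_born - n_divided
  out <- data.frame(window_start_h = h,
                    divisions = divisions,
                    cells_at_start = cells,
                    fraction = divisions / cells)
  class(out) <- c("division_series", "data.frame")
  out
}

#' Replicate population simulations and average the division-fraction series
#'
#' Runs `n_reps` independent simulations from a single founder, computes the
#' hourly division-fraction series of each, and averages across replicates.
#' Per-replicate seeds are drawn from a stream seeded by `seed`, so the
#' whole batch is reproducible from one master seed.
#'
#' @param params A [cycle_params()] object.
#' @param t_end Horizon (hours).
#' @param n_reps Number of replicate populations.
#' @param seed Master seed for the batch.
#' @param window Window (hours) over which per-replicate steady means are
#'   also returned, counted back from `t_end`.
#' @param ... Passed on to [simulate_population()].
#' @return List with `mean_series` (a `division_series` data frame of the
#'   across-replicate mean fraction), `fraction_matrix` (hours x replicates),
#'   and `rep_window_mean` (per-replicate mean fraction over the final
#'   `window` hours).
#' @export
replicate_division_series <- function(params, t_end, n_reps, seed = NULL,
                                      window = 24, ...) {
  if (!is.null(seed)) set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  n_win <- as.integer(ceiling(t_end))
  M <- matrix(NA_real_, n_win, n_reps)
  for (i in seq_len(n_reps)) {
    lin <- simulate_population(params, t_end, seed = rep_seeds[i], ...)
    M[, i] <- hourly_division_fraction(lin, t_end)$fraction
  }
  win_rows <- seq.int(n_win - window + 1L, n_win)
  mean_series <- data.frame(window_start_h = seq_len(n_win) - 1,
                            fraction = rowMeans(M))
  class(mean_series) <- c("division_series", "data.frame")
  list(mean_series = mean_series,
       fraction_matrix = M,
       rep_window_mean = colMeans(M[win_rows, , drop = FALSE]))
}

#' De-synchronization time of a division-fraction series
#'
#' The steady value is the mean of the series over its final
#' `steady_window` hours. The de-synchronization (convergence) time is the
#' first hour `h` from which every subsequent value stays within
#' `rel_tol` (relative to the steady value) of it.
#'
#' @param series Numeric vector of hourly division fractions (first element
#'   is the window starting at hour 0), or a `division_series` data frame.
#' @param steady_window Number of final hours defining the steady value.
#' @param rel_tol Relative tolerance of the convergence band.
#' @return Convergence time in hours (0 for a constant series).
#' @export
desynchronization_time <- function(series, steady_window = 24, rel_tol = 0.10) {
  if (is.data.frame(series)) series <- series$fraction
  n <- length(series)
  if (n < steady_window)
    stop("series shorter than the steady-state window")
  steady <- mean(tail(series, steady_window))
  ok <- abs(series - steady) <= rel_tol * abs(steady)
  if (!ok[n]) stop("no convergence: series ends outside the tolerance band")
  last_bad <- max(which(!ok), 0L)
  as.numeric(last_bad)  # hours are 0-based: window index == its start hour
}
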