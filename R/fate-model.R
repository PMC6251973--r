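## Hourly fate-bin labels: ages 0-1, ..., 10-11, and one open 11+ bin.
fate_bin_labels <- function() c(as.character(0:10), "11+")

## Decay bins used for the exponential stage of the fit (first six points)
## and checkpoint bins used for the plateau stage.
decay_bin_labels <- function() as.character(0:5)
checkpoint_bin_labels <- function() c(as.character(7:10), "11+")

fate_bin <- function(hours_since_division) {
  factor(ifelse(hours_since_division >= 11, "11+",
                as.character(floor(hours_since_division))),
         levels = fate_bin_labels())
}

#' Parameters of the stalk-fate propensity model
#'
#' The propensity of a cell to adopt the stalk fate is a function of its
#' position in the cell cycle: directly after mitosis it starts at `chi`
#' and decays exponentially with rate `lambda`; once the cell passes a
#' checkpoint `alpha` hours before its next mitosis the propensity jumps to
#' its plateau and stays there until division.
#'
#' @param chi Starting stalk propensity at mitosis (dimensionless, >= 0;
#'   values above 1 are clamped to 1 when used as a probability).
#' @param lambda Exponential decay rate of the propensity (1/hour, >= 0).
#' @param alpha Checkpoint delay before the next mitosis (hours, >= 0).
#' @return An object of class `"fate_params"`.
#' @export
fate_params <- function(chi, lambda, alpha) {
  stopifnot(is.numeric(chi), length(chi) == 1L, is.finite(chi),
            is.numeric(lambda), length(lambda) == 1L, is.finite(lambda),
            is.numeric(alpha), length(alpha) == 1L, is.finite(alpha))
  if (chi < 0) stop("'chi' must be non-negative")
  if (lambda < 0) stop("'lambda' must be non-negative")
  if (alpha < 0) stop("'alpha' must be non-negative")
  structure(list(chi = chi, lambda = lambda, alpha = alpha),
            class = "fate_params")
}

#' @export
print.fate_params <- function(x, ...) {
  cat("Stalk-fate propensity model\n")
  cat(sprintf("  chi = %.4g, lambda = %.4g /h, checkpoint alpha = %.4g h (%.0f min)\n",
              x$chi, x$lambda, x$alpha, x$alpha * 60))
  invisible(x)
}

as_fate_params <- function(x) {
  if (inherits(x, "fate_params")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(fate_params(x[1], x[2], x[3]))
  stop("expected a 'fate_params' object")
}

#' Stalk-fate propensity of a cell at induction
#'
#' Outside the checkpoint (`hours_to_next_division > alpha`) the propensity
#' is `min(chi * exp(-lambda * hours_since_division), 1)`. Within the
#' checkpoint it sits at its plateau. The plateau is `min(chi, 1)` by
#' default; `checkpoint = "unit"` selects the variant in which passing the
#' checkpoint saturates the propensity at 1 regardless of `chi`.
#'
#' @param hours_since_division Time since the cell's last mitosis (hours,
#'   vectorised).
#' @param hours_to_next_division Time until the cell's next scheduled
#'   mitosis (hours, vectorised).
#' @param params A [fate_params()] object.
#' @param checkpoint Plateau convention, `"plateau"` (`min(chi, 1)`,
#'   default) or `"unit"` (always 1).
#' @return Vector of probabilities in \[0, 1\].
#' @examples
#' gp <- fate_params(chi = 1, lambda = 0.412, alpha = 0.4)
#' stalk_propensity(1, 5, gp)   # exp(-0.412)
#' @export
stalk_propensity <- function(hours_since_division, hours_to_next_division,
                             params, checkpoint = c("plateau", "unit")) {
  p <- as_fate_params(params)
  checkpoint <- match.arg(checkpoint)
  stopifnot(all(hours_since_division >= 0),
            all(hours_to_next_division >= 0))
  plateau <- if (checkpoint == "unit") 1 else min(p$chi, 1)
  decay <- pmin(p$chi * exp(-p$lambda * hours_since_division), 1)
  ifelse(hours_to_next_division <= p$alpha, plateau, decay)
}

#' Draw stalk/spore fates for a population at induction
#'
#' Each cell independently becomes a stalk cell with probability given by
#' [stalk_propensity()], otherwise a spore cell.
#'
#' @param population Data frame with columns `hours_since_division` and
#'   `hours_to_next_division` (one row per cell).
#' @param params A [fate_params()] object.
#' @param seed Optional integer seed.
#' @param ... Passed on to [stalk_propensity()].
#' @return The input data frame with added columns `propensity` and `fate`
#'   (`"stalk"` or `"spore"`).
#' @export
assign_fates <- function(population, params, seed = NULL, ...) {
  stopifnot(nrow(population) >= 1L,
            all(c("hours_since_division", "hours_to_next_division") %in%
                  names(population)))
  if (!is.null(seed)) set.seed(seed)
  pr <- stalk_propensity(population$hours_since_division,
                         population$hours_to_next_division, params, ...)
  population$propensity <- pr
  population$fate <- ifelse(rbinom(nrow(population), 1L, pr) == 1L,
                            "stalk", "spore")
  population
}

#' Bin induction records into hourly fate-fraction curves
#'
#' Cells are binned by the integer hour of `hours_since_division`
#' (0-1, 1-2, ..., 10-11), with everything at 11 hours or more pooled into
#' an open `11+` bin. Fractions in empty bins are reported as `NA`, never 0.
#'
#' @param records Data frame with columns `hours_since_division` and `fate`
#'   (values `"stalk"`/`"spore"`).
#' @return Data frame of class `"fate_bin_curve"` with columns `bin_label`,
#'   `n_cells`, `frac_stalk`, `frac_spore`.
#' @export
bin_fate_curve <- function(records) {
  stopifnot(nrow(records) >= 1L,
            all(c("hours_since_division", "fate") %in% names(records)))
  if (!all(records$fate %in% c("stalk", "spore")))
    stop("'fate' must be 'stalk' or 'spore'")
  bl <- fate_bin(records$hours_since_division)
  n <- as.vector(table(bl))
  fs <- as.vector(tapply(records$fate == "stalk", bl, mean))
  out <- data.frame(bin_label = fate_bin_labels(),
                    n_cells = n,
                    frac_stalk = fs,
                    frac_spore = 1 - fs)
  class(out) <- c("fate_bin_curve", "data.frame")
  out
}

#' Model-predicted hourly fate curve (noise-free)
#'
#' Expected stalk fraction per hourly bin for a given population of cell
#' ages and times-to-next-division. With `idealized = FALSE` (default) the
#' prediction is the exact mean propensity of the bin's cells. With
#' `idealized = TRUE` the prediction follows the structure of the fitting
#' procedure: bins 0-5 use the pure exponential decay (no checkpoint term)
#' and the checkpoint mixture applies only to bins 7-11+; this is the
#' idealised curve on which the qualitative parameter effects (raising
#' `alpha` affects only late bins) hold exactly.
#'
#' @param population Data frame with `hours_since_division` and
#'   `hours_to_next_division`.
#' @param params A [fate_params()] object.
#' @param idealized Apply the checkpoint term only to the late bins.
#' @return A `fate_bin_curve` data frame of expected fractions.
#' @export
predicted_fate_curve <- function(population, params, idealized = FALSE) {
  p <- as_fate_params(params)
  bl <- fate_bin(population$hours_since_division)
  decay <- pmin(p$chi * exp(-p$lambda * population$hours_since_division), 1)
  full <- stalk_propensity(population$hours_since_division,
                           population$hours_to_next_division, p)
  pr <- if (idealized) {
    ifelse(bl %in% checkpoint_bin_labels(), full, decay)
  } else full
  n <- as.vector(table(bl))
  fs <- as.vector(tapply(pr, bl, mean))
  out <- data.frame(bin_label = fate_bin_labels(),
                    n_cells = n,
                    frac_stalk = fs,
                    frac_spore = 1 - fs)
  class(out) <- c("fate_bin_curve", "data.frame")
  out
}

#' Simulate a fate-induction experiment on a de-synchronized population
#'
#' Grows a population with [simulate_population()] for `growth_hours` (long
#' enough for the cell-cycle positions to reach their steady-state
#' distribution), freezes it at the induction time (no further divisions),
#' computes each cell's age and scheduled time to next division, draws
#' fates from the propensity model and bins them hourly.
#'
#' @param cycle A [cycle_params()] object.
#' @param fate A [fate_params()] object.
#' @param growth_hours Growth period before induction (hours).
#' @param n_founders Founder cells at time 0 (increase to enlarge the
#'   population at induction).
#' @param seed Optional integer seed.
#' @param ... Passed on to [simulate_population()].
#' @return List with `records` (one row per cell: ages, time to next
#'   division, propensity, fate) and `curve` (the hourly [bin_fate_curve()]).
#' @export
simulate_induction_experiment <- function(cycle, fate, growth_hours = 96,
                                          n_founders = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lin <- simulate_population(cycle, growth_hours, n_founders = n_founders, ...)
  pop <- population_at_time(lin, growth_hours)
  records <- assign_fates(pop, fate)
  list(records = records, curve = bin_fate_curve(records))
}
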