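#' Generate synthetic tracked-lineage tables
#'
#' Emulates manual cell tracking: sister-pair cycle lengths drawn from the
#' joint Gamma-Laplace model, and mother-daughter dyads whose cycle lengths
#' are independent draws from the marginal distribution (the model couples
#' sisters only).
#'
#' @param params A [cycle_params()] object (the generating truth).
#' @param n_pairs Number of sister pairs (and of mother-daughter dyads).
#' @param seed Integer seed; the output is a pure function of
#'   `(params, n_pairs, seed)`.
#' @param tau_min Positivity guard on cycle lengths; tracked cells always
#'   have positive cycles, so the default matches the population
#'   simulator's guarded law rather than the raw Gamma-Laplace law.
#' @return List with `pairs` (`pair_id`, `tau1_h`, `tau2_h`), `dyads`
#'   (`dyad_id`, `mother_h`, `daughter_h`) and `truth` (the generating
#'   parameters and seed).
#' @export
gen_lineage_data <- function(params, n_pairs, seed = 1L, tau_min = 0.5) {
  p <- as_cycle_params(params)
  stopifnot(n_pairs >= 2)
  set.seed(seed)
  sp <- sample_daughter_pair(p, n = n_pairs, tau_min = tau_min)
  ## mother and daughter cycles are independent; each is one member of an
  ## independent sister pair, so both carry the marginal distribution
  mo <- sample_daughter_pair(p, n = n_pairs, tau_min = tau_min)
  da <- sample_daughter_pair(p, n = n_pairs, tau_min = tau_min)
  pick <- function(sp_) ifelse(runif(n_pairs) < 0.5, sp_$tau1, sp_$tau2)
  list(pairs = data.frame(pair_id = seq_len(n_pairs),
                          tau1_h = sp$tau1, tau2_h = sp$tau2),
       dyads = data.frame(dyad_id = seq_len(n_pairs),
                          mother_h = pick(mo), daughter_h = pick(da)),
       truth = list(params = p, seed = seed))
}

#' Sample cell-cycle positions of an asynchronous population
#'
#' Ages and scheduled times-to-next-division of cells in a de-synchronized,
#' exponentially growing population. `method = "population"` (default)
#' simulates lineage trees with [simulate_population()] until at least `n`
#' cells are alive at the horizon and samples `n` of them - slow but exact.
#' `method = "analytic"` samples from the steady-state joint density of
#' (age, cycle length), proportional to `exp(-r * age) f(tau)` on
#' `0 < age < tau`: cycle lengths are drawn from the sister mixture `f`,
#' size-biased by acceptance probability `1 - exp(-r * tau)` (longer cycles
#' keep cells in the population longer), and ages from the truncated
#' exponential on `(0, tau)` by inversion; `r` is the Laplace-corrected
#' Euler-Lotka rate. The two methods agree up to Monte Carlo error once the
#' simulated population has de-synchronized.
#'
#' @param params A [cycle_params()] object.
#' @param n Number of cells to return.
#' @param seed Optional integer seed.
#' @param method `"population"` or `"analytic"`.
#' @param growth_hours Growth horizon for `method = "population"`.
#' @return Data frame with `hours_since_division` and
#'   `hours_to_next_division`.
#' @export
sample_async_population <- function(params, n, seed = NULL,
                                    method = c("population", "analytic"),
                                    growth_hours = 96) {
  p <- as_cycle_params(params)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (method == "population") {
    pops <- list()
    total <- 0
    while (total < n) {
      lin <- simulate_population(p, growth_hours)
      pop <- population_at_time(lin, growth_hours)
      pops[[length(pops) + 1L]] <- pop
      total <- total + nrow(pop)
    }
    pop <- do.call(rbind, pops)
    pop <- pop[sample.int(nrow(pop), n), c("hours_since_division",
                                           "hours_to_next_division")]
    rownames(pop) <- NULL
    return(pop)
  }
  r <- euler_lotka_rate(p, laplace = p$sigma > 0)
  age <- tau <- numeric(0)
  while (length(age) < n) {
    k <- max(2L * (n - length(age)), 100L)
    ## cycle lengths follow the simulator's guarded law (tau_min = 0.5)
    sp <- sample_daughter_pair(p, n = ceiling(k / 2), tau_min = 0.5)
    tau_c <- ifelse(runif(nrow(sp)) < 0.5, sp$tau1, sp$tau2)
    w <- 1 - exp(-r * tau_c)
    tau_c <- tau_c[runif(length(tau_c)) < w]
    x <- -log(1 - runif(length(tau_c)) * (1 - exp(-r * tau_c))) / r
    age <- c(age, x); tau <- c(tau, tau_c)
  }
  data.frame(hours_since_division = age[seq_len(n)],
             hours_to_next_division = (tau - age)[seq_len(n)])
}

#' Generate a synthetic fate-induction experiment table
#'
#' Emulates tracking cells through growth and differentiation: cell-cycle
#' positions are sampled from an asynchronous population
#' ([sample_async_population()]) and binary stalk/spore fates drawn from
#' the propensity model ([assign_fates()]).
#'
#' @param cycle A [cycle_params()] object.
#' @param fate A [fate_params()] object (the generating truth).
#' @param n_cells Number of tracked cells.
#' @param seed Integer seed.
#' @param method Age sampler, see [sample_async_population()].
#' @param growth_hours Growth horizon for the population sampler.
#' @return List with `records` (induction table: `cell_id`,
#'   `hours_since_division`, `hours_to_next_division`, `fate`) and `truth`.
#' @export
gen_induction_data <- function(cycle, fate, n_cells, seed = 1L,
                               method = c("population", "analytic"),
                               growth_hours = 96) {
  stopifnot(n_cells >= 1)
  fp <- as_fate_params(fate)
  set.seed(seed)
  pop <- sample_async_population(cycle, n_cells, method = method,
                                 growth_hours = growth_hours)
  rec <- assign_fates(pop, fp)
  rec <- data.frame(cell_id = seq_len(n_cells),
                    hours_since_division = rec$hours_since_division,
                    hours_to_next_division = rec$hours_to_next_division,
                    fate = rec$fate)
  list(records = rec,
       truth = list(cycle = as_cycle_params(cycle), fate = fp, seed = seed))
}

#' Generate a synthetic hourly time-course expression matrix
#'
#' Emulates a cell-cycle time course after synchronization release: peaked
#' genes carry a Gaussian bump (height `bump_height` times baseline,
#' standard deviation `bump_sd` hours) centred on an assigned timepoint;
#' flat genes are baseline only; low-count genes sit below the default
#' binning filter. Counts are negative binomial around the noise-free
#' profile with `Var = mu + dispersion * mu^2`.
#'
#' @param n_peaked,n_flat,n_lowcount Gene counts per class.
#' @param timepoints Hourly timepoint labels (hours after release).
#' @param baseline Baseline normalised count of peaked and flat genes.
#' @param bump_height Peak height as a multiple of `baseline`.
#' @param bump_sd Bump standard deviation (hours).
#' @param dispersion Negative-binomial dispersion.
#' @param lowcount_mean Mean count of low-count genes (below the default
#'   `min_mean_count` filter of [detect_peak_bins()]).
#' @param seed Integer seed.
#' @return List with `matrix` (genes x timepoints) and `truth` (data frame
#'   of gene classes and planted peak bins, plus the generator settings).
#' @export
gen_timecourse_matrix <- function(n_peaked = 200L, n_flat = 200L,
                                  n_lowcount = 50L, timepoints = 0:10,
                                  baseline = 100, bump_height = 5,
                                  bump_sd = 0.5, dispersion = 0.1,
                                  lowcount_mean = 2, seed = 1L) {
  stopifnot(n_peaked >= 0, n_flat >= 0, n_lowcount >= 0,
            n_peaked + n_flat + n_lowcount > 0)
  set.seed(seed)
  tp <- as.numeric(timepoints)
  n_t <- length(tp)
  ids <- c(if (n_peaked) sprintf("peak_%04d", seq_len(n_peaked)),
           if (n_flat) sprintf("flat_%04d", seq_len(n_flat)),
           if (n_lowcount) sprintf("low_%04d", seq_len(n_lowcount)))
  class_v <- rep(c("peaked", "flat", "lowcount"),
                 c(n_peaked, n_flat, n_lowcount))
  peak_at <- rep(NA_real_, length(ids))
  if (n_peaked)
    peak_at[seq_len(n_peaked)] <- sample(tp, n_peaked, replace = TRUE)

  mu <- matrix(rep(c(rep(baseline, n_peaked + n_flat),
                     rep(lowcount_mean, n_lowcount)), n_t),
               ncol = n_t)
  if (n_peaked) {
    bump <- outer(peak_at[seq_len(n_peaked)], tp,
                  function(ctr, t) exp(-0.5 * ((t - ctr) / bump_sd)^2))
    mu[seq_len(n_peaked), ] <- mu[seq_len(n_peaked), ] +
      bump_height * baseline * bump
  }
  size <- 1 / dispersion
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu), size = size),
                   nrow = nrow(mu),
                   dimnames = list(ids, as.character(tp)))
  truth <- data.frame(gene_id = ids, class = class_v,
                      peak_bin = ifelse(is.na(peak_at), NA_character_,
                                        as.character(peak_at)))
  list(matrix = counts,
       truth = list(genes = truth, baseline = baseline,
                    bump_height = bump_height, bump_sd = bump_sd,
                    dispersion = dispersion, seed = seed))
}
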