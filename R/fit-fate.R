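#' Least-squares fit of the exponential decay stage
#'
#' Fits `frac_stalk(h) ~ chi * exp(-lambda * m_h)` over the first six
#' hourly bins (0-5) at the bin midpoints `m_h = h + 0.5`, by nonlinear
#' least squares on the fraction scale (default) or by a linear fit on the
#' log scale.
#'
#' @param curve A [bin_fate_curve()] data frame.
#' @param log_scale Fit `log(frac)` linearly instead of nonlinear least
#'   squares on the natural scale.
#' @return List with `chi`, `lambda`, `rss` (residual sum of squares on the
#'   fraction scale) and `fitted` (the six fitted values).
#' @export
fit_decay <- function(curve, log_scale = FALSE) {
  rows <- match(decay_bin_labels(), curve$bin_label)
  y <- curve$frac_stalk[rows]
  n <- curve$n_cells[rows]
  if (anyNA(y) || any(n == 0))
    stop("insufficient bins: all of bins 0-5 must be non-empty")
  fit_decay_points(y, 0:5 + 0.5, log_scale = log_scale)
}

## Core decay fit on arbitrary (fraction, midpoint) points.
fit_decay_points <- function(y, mids, log_scale = FALSE) {
  if (diff(range(y)) < 1e-10) {
    ## flat curve: lambda sits at its zero boundary, chi at the level
    return(list(chi = mean(y), lambda = 0, rss = sum((y - mean(y))^2),
                fitted = rep(mean(y), length(y))))
  }
  sl <- lm(log(pmax(y, 1e-8)) ~ mids)
  chi0 <- unname(exp(coef(sl)[1]))
  lam0 <- unname(max(-coef(sl)[2], 1e-6))
  if (log_scale) {
    chi <- chi0; lam <- unname(max(-coef(sl)[2], 0))
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ chi * exp(-lam * mids),
                        start = list(chi = chi0, lam = lam0),
                        lower = c(0, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) stop("fit failed: ", conditionMessage(e)))
    chi <- coef(fit)[["chi"]]; lam <- coef(fit)[["lam"]]
  }
  fitted <- chi * exp(-lam * mids)
  list(chi = chi, lambda = lam, rss = sum((y - fitted)^2), fitted = fitted)
}

#' Grid least-squares fit of the checkpoint delay
#'
#' All cells past the checkpoint are assumed to sit at the plateau
#' propensity `min(chi, 1)`. For every candidate `alpha` on a grid, the
#' predicted stalk fraction of a late bin (hours 7-11+) is
#' `p * min(chi, 1) + (1 - p) * d`, where `p` is the empirical proportion of
#' the bin's cells within `alpha` hours of their next division and `d` is
#' the bin's mean decay propensity. The returned `alpha` minimises the
#' squared error over the late bins. Because `p` only changes when `alpha`
#' crosses an observed time-to-division, the objective is piecewise
#' constant; the midpoint of the minimising plateau is reported.
#'
#' @param curve A [bin_fate_curve()] data frame with observed fractions.
#' @param chi,lambda Decay parameters (e.g. from [fit_decay()]).
#' @param population Data frame with `hours_since_division` and
#'   `hours_to_next_division` for the cells behind the curve.
#' @param grid_max Upper end of the `alpha` search grid (hours).
#' @param grid_step Grid resolution (hours); default one minute.
#' @return List with `alpha` (hours), `rss`, `grid` and `sse` (the objective
#'   over the grid).
#' @export
fit_alpha <- function(curve, chi, lambda, population,
                      grid_max = 4, grid_step = 1 / 60) {
  late <- checkpoint_bin_labels()
  if (anyNA(population$hours_to_next_division))
    stop("'population' must have known hours_to_next_division")
  bl <- fate_bin(population$hours_since_division)
  grid <- seq(0, grid_max, by = grid_step)
  sse <- numeric(length(grid))
  used <- 0L
  plateau <- min(chi, 1)
  for (h in late) {
    row <- match(h, curve$bin_label)
    yh <- curve$frac_stalk[row]
    idx <- which(bl == h)
    if (is.na(yh) || !length(idx)) next
    used <- used + 1L
    d <- mean(pmin(chi * exp(-lambda * population$hours_since_division[idx]), 1))
    p <- findInterval(grid, sort(population$hours_to_next_division[idx])) /
      length(idx)
    sse <- sse + (yh - (p * plateau + (1 - p) * d))^2
  }
  if (used == 0L) stop("insufficient bins: no non-empty late bin (7-11+)")
  mn <- min(sse)
  plate <- range(grid[sse <= mn + 1e-12])
  list(alpha = mean(plate), rss = mn, grid = grid, sse = sse)
}

#' Fit the full stalk-propensity model to an hourly fate curve
#'
#' Two-stage fit with iterative refinement. Stage one fits the exponential
#' decay (`chi`, `lambda`) to bins 0-5 ([fit_decay()]); stage two fits the
#' checkpoint delay `alpha` to bins 7-11+ ([fit_alpha()]). Because some
#' cells in the early bins are themselves within `alpha` of their next
#' division, their plateau propensity contaminates the decay points; after
#' each pass the early-bin fractions are therefore corrected by removing
#' the estimated checkpoint mixture component,
#' `y_corrected = (y - p * min(chi, 1)) / (1 - p)`, and both stages are
#' re-run. A few iterations suffice; `n_iter = 1` with
#' `correct_early = FALSE` reproduces the plain one-pass composition.
#'
#' @param curve A [bin_fate_curve()] data frame.
#' @param population Data frame with `hours_since_division` and
#'   `hours_to_next_division` for the cell population behind the curve.
#' @param n_iter Number of refinement passes.
#' @param correct_early Correct early-bin fractions for checkpoint
#'   contamination between passes.
#' @param log_scale Passed to [fit_decay()].
#' @param ... Passed to [fit_alpha()].
#' @return A [fate_params()] object with a `diagnostics` attribute (list
#'   with per-stage residual sums of squares and the iteration trace).
#' @export
fit_fate_model <- function(curve, population, n_iter = 4L,
                           correct_early = TRUE, log_scale = FALSE, ...) {
  rows <- match(decay_bin_labels(), curve$bin_label)
  y <- curve$frac_stalk[rows]
  if (anyNA(y) || any(curve$n_cells[rows] == 0))
    stop("insufficient bins: all of bins 0-5 must be non-empty")
  bl <- fate_bin(population$hours_since_division)
  mids <- 0:5 + 0.5
  chi <- 1; alpha <- 0
  trace <- vector("list", n_iter)
  dec <- NULL; alp <- NULL
  for (it in seq_len(n_iter)) {
    yc <- y
    if (correct_early && alpha > 0) {
      p <- vapply(decay_bin_labels(), function(h) {
        idx <- bl == h
        mean(population$hours_to_next_division[idx] <= alpha)
      }, numeric(1))
      p <- pmin(p, 0.99)  # keep the correction defined in degenerate bins
      yc <- pmin(pmax((y - p * min(chi, 1)) / (1 - p), 0), 1)
    }
    dec <- fit_decay_points(yc, mids, log_scale = log_scale)
    chi <- dec$chi
    alp <- fit_alpha(curve, chi, dec$lambda, population, ...)
    alpha <- alp$alpha
    trace[[it]] <- c(chi = chi, lambda = dec$lambda, alpha = alpha)
    if (!correct_early) break
  }
  out <- fate_params(chi = chi, lambda = dec$lambda, alpha = alpha)
  attr(out, "diagnostics") <- list(rss_decay = dec$rss, rss_alpha = alp$rss,
                                   trace = do.call(rbind, trace))
  out
}

#' Bootstrap confidence intervals for the fate-model fit
#'
#' Nonparametric bootstrap over induction records: cells are resampled with
#' replacement, the curve is rebuilt and [fit_fate_model()] re-run. The
#' returned percentile intervals quantify the sampling uncertainty of
#' `chi`, `lambda` and `alpha` at the observed sample size.
#'
#' @param records Induction records (one row per cell) with
#'   `hours_since_division`, `hours_to_next_division` and `fate`.
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level of the percentile interval.
#' @param seed Optional integer seed.
#' @param ... Passed to [fit_fate_model()].
#' @return List with `estimate` (the fit on the full records), `ci`
#'   (2 x 3 matrix of interval bounds), and `replicates` (n_boot x 3 matrix;
#'   rows from resamples where the fit failed are `NA`).
#' @export
bootstrap_fate_fit <- function(records, n_boot = 99L, level = 0.95,
                               seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  est <- fit_fate_model(bin_fate_curve(records), records, ...)
  n <- nrow(records)
  reps <- matrix(NA_real_, n_boot, 3,
                 dimnames = list(NULL, c("chi", "lambda", "alpha")))
  for (b in seq_len(n_boot)) {
    rb <- records[sample.int(n, replace = TRUE), , drop = FALSE]
    fit <- tryCatch(fit_fate_model(bin_fate_curve(rb), rb, ...),
                    error = function(e) NULL)
    if (!is.null(fit)) reps[b, ] <- c(fit$chi, fit$lambda, fit$alpha)
  }
  a <- (1 - level) / 2
  ci <- apply(reps, 2, quantile, probs = c(a, 1 - a), na.rm = TRUE)
  list(estimate = est, ci = ci, replicates = reps)
}
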