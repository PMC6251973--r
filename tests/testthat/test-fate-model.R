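test_that("stalk propensity follows the piecewise decay-plateau law", {
  gp <- fate_gplus()
  # at mitosis, outside the checkpoint, chi = 1: propensity 1
  expect_equal(stalk_propensity(0, 5, gp), 1)
  # one hour after division: exp(-0.412)
  expect_equal(stalk_propensity(1, 5, gp), 0.66232428, tolerance = 1e-7)
  # inside the checkpoint the plateau is min(chi, 1)
  ge <- fate_gefe()
  expect_equal(stalk_propensity(6, 0.2, ge), 0.813)
  # ... or saturates at 1 under the literal-equation variant
  expect_equal(stalk_propensity(6, 0.2, ge, checkpoint = "unit"), 1)

  # bounded in [0, 1], non-increasing in age outside the checkpoint, and
  # the checkpoint jump is non-negative for chi <= 1
  set.seed(5)
  for (i in 1:20) {
    p <- fate_params(runif(1, 0, 2), runif(1, 0, 1), runif(1, 0, 3))
    ages <- sort(runif(50, 0, 12))
    pr <- stalk_propensity(ages, rep(10, 50), p)
    expect_true(all(pr >= 0 & pr <= 1))
    expect_true(all(diff(pr) <= 1e-12))
    if (p$chi <= 1) {
      jump <- stalk_propensity(5, p$alpha, p) - stalk_propensity(5, p$alpha + 1e-9, p)
      expect_gte(jump, -1e-12)
    }
  }
})

test_that("fate assignment is Bernoulli in the propensity", {
  pop <- data.frame(hours_since_division = rep(2, 1e5),
                    hours_to_next_division = rep(5, 1e5))
  rec <- assign_fates(pop, fate_gplus(), seed = 9)
  p <- exp(-0.824)
  se <- sqrt(p * (1 - p) / 1e5)
  expect_lt(abs(mean(rec$fate == "stalk") - p), 3 * se)

  # degenerate propensities
  rec0 <- assign_fates(pop[1:100, ], fate_params(0, 0.4, 0.4), seed = 1)
  expect_true(all(rec0$fate == "spore"))
  rec1 <- assign_fates(pop[1:100, ], fate_params(1, 0, 0.4), seed = 1)
  expect_true(all(rec1$fate == "stalk"))
})

test_that("expected stalk fraction equals mean propensity (total expectation)", {
  cp <- canonical_cycle()
  pop <- sample_async_population(cp, 5e4, seed = 33, method = "analytic")
  rec <- assign_fates(pop, fate_gplus())
  p_bar <- mean(rec$propensity)
  se <- sqrt(sum(rec$propensity * (1 - rec$propensity))) / nrow(rec)
  expect_lt(abs(mean(rec$fate == "stalk") - p_bar), 3 * se)
})

test_that("hourly fate binning pools ages and flags empty bins as missing", {
  rec <- data.frame(hours_since_division = 0.5, fate = "stalk")
  curve <- bin_fate_curve(rec)
  expect_equal(curve$frac_stalk[curve$bin_label == "0"], 1)
  expect_equal(curve$n_cells[curve$bin_label == "0"], 1)
  expect_true(all(is.na(curve$frac_stalk[curve$bin_label != "0"])))
  expect_true(all(curve$n_cells[curve$bin_label != "0"] == 0))

  rec2 <- data.frame(hours_since_division = c(0.2, 0.7, 11.5, 14),
                     fate = c("stalk", "spore", "stalk", "stalk"))
  curve2 <- bin_fate_curve(rec2)
  expect_equal(curve2$frac_stalk[curve2$bin_label == "0"], 0.5)
  expect_equal(curve2$n_cells[curve2$bin_label == "11+"], 2)
  expect_equal(curve2$frac_stalk[curve2$bin_label == "11+"], 1)
  expect_equal(sum(curve2$n_cells), nrow(rec2))
  ok <- !is.na(curve2$frac_stalk)
  expect_equal(curve2$frac_stalk[ok] + curve2$frac_spore[ok], rep(1, sum(ok)))
})

test_that("decay fitting recovers its own model and handles edge cases", {
  mids <- 0:5 + 0.5
  curve <- data.frame(bin_label = fate_bin_labels_for_test(),
                      n_cells = c(rep(100, 6), rep(0, 6)),
                      frac_stalk = c(1 * exp(-0.412 * mids), rep(NA, 6)))
  fit <- fit_decay(curve)
  expect_equal(fit$chi, 1, tolerance = 1e-6)
  expect_equal(fit$lambda, 0.412, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)

  # flat curve: lambda at the zero boundary, chi at the level
  flat <- curve
  flat$frac_stalk <- c(rep(0.5, 6), rep(NA, 6))
  ffit <- fit_decay(flat)
  expect_equal(ffit$chi, 0.5, tolerance = 1e-4)
  expect_lt(ffit$lambda, 1e-4)

  # log-scale fit agrees on noiseless data
  lfit <- fit_decay(curve, log_scale = TRUE)
  expect_equal(lfit$lambda, 0.412, tolerance = 1e-6)

  # any empty early bin is an error
  bad <- curve
  bad$n_cells[3] <- 0
  expect_error(fit_decay(bad), "insufficient bins")
})

test_that("checkpoint fitting locates alpha from late-bin plateau occupancy", {
  cp <- canonical_cycle()
  pop <- sample_async_population(cp, 4e4, seed = 55, method = "analytic")

  # truth alpha = 0: pure decay late bins put the fit at the zero boundary
  curve0 <- predicted_fate_curve(pop, fate_params(1, 0.412, 0))
  a0 <- fit_alpha(curve0, 1, 0.412, pop)
  expect_lt(a0$alpha, 0.05)

  # recovery of a planted checkpoint from stochastic fates
  rec <- assign_fates(pop, fate_gplus(), seed = 56)
  af <- fit_alpha(bin_fate_curve(rec), 1, 0.412, rec)
  expect_lt(abs(af$alpha - 0.4), 2 / 60 + 1e-9)

  # longer checkpoint under a longer-G2 cycle
  long_cp <- cycle_params(6, 0.55, 1)  # mean cycle ~10.9 h
  pop_l <- sample_async_population(long_cp, 4e4, seed = 57, method = "analytic")
  rec_l <- assign_fates(pop_l, fate_gminus(), seed = 58)
  af_l <- fit_alpha(bin_fate_curve(rec_l), 1, 0.439, rec_l)
  expect_lt(abs(af_l$alpha - 2.1), 0.1)
})

test_that("the full fit recovers generating parameters across replicates", {
  cp <- canonical_cycle()
  truth <- fate_gplus()
  set.seed(61)
  errs <- t(replicate(20, {
    pop <- sample_async_population(cp, 1e4, method = "analytic")
    rec <- assign_fates(pop, truth)
    fit <- fit_fate_model(bin_fate_curve(rec), rec)
    c(lam = abs(fit$lambda - truth$lambda) / truth$lambda,
      chi = abs(fit$chi - truth$chi))
  }))
  expect_lt(median(errs[, "lam"]), 0.10)
  expect_lt(median(errs[, "chi"]), 0.05)
})

test_that("fitting is deterministic and the bootstrap brackets the estimate", {
  cp <- canonical_cycle()
  g <- gen_induction_data(cp, fate_gplus(), 5000, seed = 71,
                          method = "analytic")
  f1 <- fit_fate_model(bin_fate_curve(g$records), g$records)
  f2 <- fit_fate_model(bin_fate_curve(g$records), g$records)
  expect_identical(c(f1$chi, f1$lambda, f1$alpha),
                   c(f2$chi, f2$lambda, f2$alpha))

  bf <- bootstrap_fate_fit(g$records, n_boot = 20, seed = 72, n_iter = 3)
  expect_true(all(bf$ci[1, ] <= c(bf$estimate$chi, bf$estimate$lambda,
                                  bf$estimate$alpha) + 1e-9))
  expect_true(all(bf$ci[2, ] >= c(bf$estimate$chi, bf$estimate$lambda,
                                  bf$estimate$alpha) - 1e-9))
})

test_that("simulated induction experiments have the modelled curve shape", {
  cp <- canonical_cycle()
  sim <- simulate_induction_experiment(cp, fate_gplus(), growth_hours = 96,
                                       seed = 81)
  expect_equal(sum(sim$curve$n_cells), nrow(sim$records))

  # monotone decline over the decay bins, then a late rise
  early <- sim$curve$frac_stalk[match(as.character(0:5), sim$curve$bin_label)]
  expect_true(all(diff(early) < 0))
  late_mean <- mean(sim$curve$frac_stalk[match(c("9", "10", "11+"),
                                               sim$curve$bin_label)])
  expect_gt(late_mean, early[6] * 0.5)

  # chi = 0 makes every cell a spore
  sim0 <- simulate_induction_experiment(cp, fate_params(0, 0.4, 0.4),
                                        growth_hours = 48, seed = 82)
  ok <- !is.na(sim0$curve$frac_spore)
  expect_true(all(sim0$curve$frac_spore[ok] == 1))
})

test_that("parameter effects move predicted curves in the expected directions", {
  cp <- canonical_cycle()
  pop <- sample_async_population(cp, 2e4, seed = 91, method = "analytic")
  base <- predicted_fate_curve(pop, fate_gplus(), idealized = TRUE)
  early_idx <- match(as.character(0:5), base$bin_label)
  late_idx <- match(c("7", "8", "9", "10", "11+"), base$bin_label)

  # raising alpha: late bins rise, decay bins untouched
  up <- predicted_fate_curve(pop, fate_params(1, 0.412, 2.1), idealized = TRUE)
  expect_equal(up$frac_stalk[early_idx], base$frac_stalk[early_idx])
  expect_true(all(up$frac_stalk[late_idx] > base$frac_stalk[late_idx]))

  # lowering chi: every bin falls
  dn <- predicted_fate_curve(pop, fate_params(0.813, 0.412, 0.4),
                             idealized = TRUE)
  expect_true(all(dn$frac_stalk < base$frac_stalk))
})
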