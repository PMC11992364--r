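# Binning, joint two-channel fitting, normalization, sink prediction and
# the orientation test.

test_that("binning produces the expected bin structure and statistics", {
  tab <- simulate_experiment(seed = 1)
  bp <- bin_cells(tab, "gfp")
  # ~6,700 cells over 5,400 um in 100-um bins, one trimmed: 53 bins
  expect_true(nrow(bp) %in% 52:54)
  expect_true(all(bp$count >= 1))
  expect_true(all(bp$sem >= 0))
  expect_true(all(diff(bp$bin_center) == 100))

  # cells inside the trimmed left margin do not contribute: with cells at
  # 50/150/250 and a 100-um trim, the first cell is dropped and its bin
  # disappears entirely
  one <- generate_cells(population_config(n_receivers = 3, n_emitters = 0), 2)
  one$x_um <- c(50, 150, 250)
  one$gfp_au <- c(9, 2, 3)
  bt <- bin_cells(one, "gfp", width = 100)
  expect_equal(bt$bin_center, c(150, 250))
  expect_equal(bt$mean, c(2, 3))

  # single cell per bin: mean is the value, SEM 0 by convention
  one$x_um <- c(150, 250, 350)
  one$gfp_au <- c(1, 2, 3)
  b1 <- bin_cells(one, "gfp", width = 100, trim_left = 0)
  expect_equal(b1$mean, c(1, 2, 3))
  expect_equal(b1$sem, c(0, 0, 0))
  expect_error(bin_cells(one, "length"), "no receiver cells")
})

test_that("noiseless bin means match the model at bin centers within binning bias", {
  tab <- simulate_experiment(seed = 7, noise = noise_config(0, 0))
  bp <- bin_cells(tab, "gfp")
  model <- observed_response(bp$bin_center, fixture_shape(), fixture_resp_g())
  expect_lt(max(abs(bp$mean - model) / model), 0.005)
})

test_that("joint fit on exact model bins recovers the generating parameters", {
  prof <- exact_profiles()
  fit <- joint_fit(prof$gfp, prof$len, weighting = "none")
  expect_equal(fit$lambda, 735, tolerance = 1e-4)
  expect_equal(fit$C, 1.45, tolerance = 1e-4)
  expect_identical(fit$n_m, 3L)
  expect_equal(fit$A_g, 1, tolerance = 1e-4)
  expect_equal(fit$b_g, 0.1, tolerance = 1e-3)
  expect_equal(fit$A_m, 25, tolerance = 1e-4)
  expect_equal(fit$b_m, 5, tolerance = 1e-3)
  expect_equal(length(fit$sse_by_n), 7)
  expect_equal(unname(fit$sse_total), unname(min(fit$sse_by_n)))
  expect_false(fit$diagnostics$lambda_at_bound)
  # exact recovery holds for other generating Hill coefficients
  prof5 <- exact_profiles(resp_m = response_params(5, 25, 5))
  fit5 <- joint_fit(prof5$gfp, prof5$len, weighting = "none")
  expect_identical(fit5$n_m, 5L)
  expect_equal(fit5$lambda, 735, tolerance = 1e-4)
})

test_that("a flat morphology channel makes the Hill-coefficient choice degenerate", {
  prof <- exact_profiles()
  flat <- binned_profile(prof$len$bin_center,
                         rep(5, nrow(prof$len)), sem = 1, count = 100L,
                         width = 100, channel = "length")
  fit <- joint_fit(prof$gfp, flat, weighting = "none")
  expect_true(fit$diagnostics$n_degenerate)
  # parsimony tie-break: smallest n wins
  expect_identical(fit$n_m, 1L)
})

test_that("the joint fit genuinely couples both channels through lambda and C", {
  tab <- simulate_experiment(seed = 2)
  gp <- bin_cells(tab, "gfp")
  f_ok <- joint_fit(gp, bin_cells(tab, "length"), weighting = "sem")
  shuf <- tab
  rec <- shuf$identity == "receiver"
  set.seed(7)
  shuf$length_um[rec] <- sample(shuf$length_um[rec])
  f_sh <- joint_fit(gp, bin_cells(shuf, "length"), weighting = "sem")
  expect_gt(abs(f_sh$lambda - 735), abs(f_ok$lambda - 735))
})

test_that("normalization maps fitted profiles onto the common response scale", {
  tab <- simulate_experiment(seed = 3)
  gp <- bin_cells(tab, "gfp")
  mp <- bin_cells(tab, "length")
  fit <- joint_fit(gp, mp, weighting = "sem")
  ng <- normalize_profile(gp, response_params(1, fit$A_g, fit$b_g))
  nm <- normalize_profile(mp, response_params(fit$n_m, fit$A_m, fit$b_m))
  # normalized bins sit on the fitted dimensionless Hill response
  sh <- gradient_shape(fit$lambda, fit$C)
  lit <- ng$bin_center < -2000
  expect_equal(mean(ng$mean[lit]),
               mean(hill_response(concentration(ng$bin_center[lit], sh, "source"), 1L)),
               tolerance = 0.05)
  litm <- nm$bin_center < -2000
  expect_equal(mean(nm$mean[litm]),
               mean(hill_response(concentration(nm$bin_center[litm], sh, "source"),
                                  fit$n_m)),
               tolerance = 0.05)
  # normalize then denormalize is the identity
  back <- nm
  back$mean <- back$mean * fit$A_m + fit$b_m
  back$sem <- back$sem * fit$A_m
  expect_equal(back$mean, mp$mean, tolerance = 1e-12)
  expect_error(normalize_profile(gp, structure(list(n = 1L, A = -1, b = 0),
                                               class = "response_params")),
               "A")
})

test_that("sink prediction uses the source fit with zero free parameters", {
  prof <- exact_profiles()
  fit <- joint_fit(prof$gfp, prof$len, weighting = "none")
  x <- seq(-2500, 2500, by = 50)
  pred <- predict_sink_response(fit, x)
  # exactly the baseline over the whole sink domain
  expect_true(all(pred$length_um[x > 0] == fit$b_m))
  expect_true(all(pred$c[x > 0] == 0))
  # on the diffusion side: the source-fit response composed with 2f - 1
  sh <- gradient_shape(fit$lambda, fit$C)
  manual <- fit$A_m * hill_response(
    fit$C * (2 * source_profile(x[x < 0], fit$lambda) - 1), fit$n_m) + fit$b_m
  expect_equal(pred$length_um[x < 0], manual, tolerance = 1e-12)
  # rises toward the same plateau as the source fit far into the light domain
  far <- predict_sink_response(fit, -1e6)
  expect_equal(far$length_um,
               fit$A_m * hill_response(fit$C, fit$n_m) + fit$b_m,
               tolerance = 1e-3)
  # prediction is a pure function of the fit: repeated calls identical
  expect_identical(pred, predict_sink_response(fit, x))
})

test_that("recovery experiment is unbiased without noise and tracks sample size", {
  rec0 <- recovery_experiment(n_seeds = 2, seed0 = 5,
                              noise = noise_config(0, 0),
                              pop = small_pop(4000), weighting = "none")
  expect_equal(rec0$summary$bias[rec0$summary$parameter == "lambda"], 0,
               tolerance = 735 * 0.02)
  expect_identical(rec0$n_m_modal, 3L)
  expect_equal(rec0$n_failed, 0)

  big <- recovery_experiment(n_seeds = 4, seed0 = 11, pop = small_pop(6000),
                             noise = noise_config(0.3, 1.5))
  small_ <- recovery_experiment(n_seeds = 4, seed0 = 11, pop = small_pop(700),
                                noise = noise_config(0.3, 1.5))
  rmse <- function(r) r$summary$rmse[r$summary$parameter == "lambda"]
  expect_gt(rmse(small_), rmse(big))
  expect_error(recovery_experiment(n_seeds = 1), "n_seeds")
})

test_that("orientation enrichment: calibrated null and positive control", {
  tab <- simulate_experiment(seed = 4)
  res <- orientation_enrichment(tab)
  expect_gt(res$p_value, 0.01)
  expect_gte(res$n, 20)
  # null calibration across seeds
  pvals <- vapply(1:20, function(s) {
    t2 <- simulate_experiment(seed = 500 + s, pop = small_pop(2500))
    orientation_enrichment(t2)$p_value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
  # aligned cells are detected
  aligned <- tab
  rec <- aligned$identity == "receiver"
  set.seed(1)
  aligned$orientation_deg[rec] <- runif(sum(rec), 0, 10)
  expect_lt(orientation_enrichment(aligned)$p_value, 1e-6)
  # cutoff excluding everything errors
  expect_error(orientation_enrichment(tab, area_cutoff = 1e9), "fewer than 20")
})
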