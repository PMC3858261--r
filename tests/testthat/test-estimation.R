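truth <- mesc_parameters()

test_that("the objective is zero at the generating truth and well-scaled", {
  data <- generate_dataset(truth, noise = quiet_noise(), seed = 1)
  expect_lt(fit_objective(truth, data, rtol = 1e-8, atol = 1e-10), 1e-6)

  # a single observation one scale-unit off contributes exactly 1
  traj <- simulate_culture(horizon = 48, times = c(0, 24))
  model_xv <- traj$x_u[traj$time_h == 24] + traj$x_d[traj$time_h == 24]
  one <- tibble::tibble(time_h = 24, variable = "x_v",
                        value = model_xv + 500, sd = 500)
  expect_equal(fit_objective(truth, one), 1, tolerance = 1e-4)

  # order invariance
  data2 <- data[sample.int(nrow(data)), ]
  expect_equal(fit_objective(truth, data), fit_objective(truth, data2))

  expect_error(fit_objective(truth, dplyr::mutate(one, variable = "oxygen")),
               "no model observable")
})

test_that("an empty free set returns the supplied parameters untouched", {
  data <- generate_dataset(truth, noise = quiet_noise(), seed = 2)
  fit <- fit_parameters(data, free = character(0))
  expect_s3_class(fit, "mesc_fit")
  expect_equal(fit$parameters$value, truth$value)
  expect_lt(fit$objective, 1e-6)
  expect_equal(nrow(fit$multistart), 0)
})

test_that("noise-free yield parameters are recovered to under 1%", {
  data <- generate_dataset(truth, noise = quiet_noise(), seed = 3)
  start <- set_parameter_values(truth, Y_LACGLC = 1.750 * 3,
                                Y_AMMGLN = 0.814 / 3)
  fit <- fit_parameters(data, free = c("Y_LACGLC", "Y_AMMGLN"),
                        start = start, n_starts = 0)
  est <- param_values(fit$parameters)
  expect_lt(abs(est[["Y_LACGLC"]] - 1.750) / 1.750, 0.01)
  expect_lt(abs(est[["Y_AMMGLN"]] - 0.814) / 0.814, 0.01)
  # fitted values respect bounds; objective beats every multistart endpoint
  tab <- fit$parameters
  expect_true(all(tab$lower <= tab$value & tab$value <= tab$upper))
})

test_that("multistart is deterministic given the seed", {
  data <- generate_dataset(truth, noise = assay_noise_model(replicates = 1),
                           seed = 4)
  f1 <- fit_parameters(data, free = c("Y_LACGLC", "GLC_MIN"),
                       n_starts = 3, seed = 99)
  f2 <- fit_parameters(data, free = c("Y_LACGLC", "GLC_MIN"),
                       n_starts = 3, seed = 99)
  expect_identical(f1$multistart, f2$multistart)
  expect_identical(f1$parameters$value, f2$parameters$value)
  expect_lte(f1$objective, min(f1$multistart$objective))
  f3 <- fit_parameters(data, free = c("Y_LACGLC", "GLC_MIN"),
                       n_starts = 3, seed = 100)
  expect_false(identical(f3$multistart$objective, f1$multistart$objective))
})

test_that("tidy and glance expose fit results in broom form", {
  data <- generate_dataset(truth, noise = quiet_noise(), seed = 5)
  fit <- fit_parameters(data, free = "Y_LACGLC", n_starts = 0)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "unit", "free", "std.error"))
  expect_equal(nrow(td), 29)
  expect_equal(sum(td$free), 1)
  gl <- glance(fit)
  expect_equal(gl$n_free, 1)
  expect_gte(gl$n_obs, nrow(data) - 1)
})

test_that("the two-stage refit frees exactly the significant subset", {
  batch_data <- generate_dataset(truth, noise = quiet_noise(), seed = 6)
  batch_fit <- fit_parameters(batch_data, free = character(0))

  perf_truth <- mesc_parameters("table1_with_table2_perfusion")
  perf_data <- generate_dataset(perf_truth, reactor_perfusion(),
                                noise = quiet_noise(), seed = 7)

  # empty significant set: batch estimates pass through unchanged
  pass <- refit_significant(batch_fit, perf_data, significant = character(0))
  expect_equal(pass$parameters$value, batch_fit$parameters$value)

  refit <- refit_significant(batch_fit, perf_data,
                             significant = significant_parameters(),
                             n_starts = 0)
  expect_length(refit$free, 6)
  expect_equal(sum(refit$parameters$free), 6)
  frozen <- setdiff(truth$name, significant_parameters())
  expect_equal(
    refit$parameters$value[match(frozen, refit$parameters$name)],
    batch_fit$parameters$value[match(frozen, batch_fit$parameters$name)]
  )
})

test_that("the perfusion refit recovers the truth from a nearby start", {
  # From the batch estimates the 6-parameter perfusion landscape is a
  # narrow correlated valley (mu_max_U and Kglc_U trade off almost
  # perfectly), so value recovery is tested from a perturbed
  # neighbourhood of the truth, as when iterating the workflow.
  perf_truth <- mesc_parameters("table1_with_table2_perfusion")
  perf_data <- generate_dataset(perf_truth, reactor_perfusion(),
                                noise = quiet_noise(), seed = 8)
  tv <- param_values(perf_truth)
  start <- set_parameter_values(
    perf_truth,
    Y_LACGLC = tv[["Y_LACGLC"]] * 1.6, Y_AMMGLN = tv[["Y_AMMGLN"]] / 1.6,
    K_GLN_MAX = tv[["K_GLN_MAX"]] * 1.5, mud_max_U = tv[["mud_max_U"]] / 1.5
  )
  refit <- refit_significant(start, perf_data,
                             reactor = reactor_perfusion(), n_starts = 0)
  est <- param_values(refit$parameters)
  expect_lt(abs(est[["Y_LACGLC"]] - 1.357) / 1.357, 0.15)
  expect_lt(abs(est[["Y_AMMGLN"]] - 1.769) / 1.769, 0.15)
  expect_lt(abs(est[["K_GLN_MAX"]] - 3.916e-8) / 3.916e-8, 0.15)
})

test_that("recovery bias shrinks as measurement noise goes to zero", {
  lvl <- function(cv) assay_noise_model(cell_count_cv = cv, nutrient_cv = cv,
                                        nutrient_sd_floor = 0.01 * cv / 0.02,
                                        qpcr_cv = cv, replicates = 2)
  bias_at <- function(cv, n_repeats) {
    rec <- recovery_experiment(truth, free = "Y_LACGLC",
                               noise = lvl(cv), n_repeats = n_repeats,
                               seed = 10, n_starts = 0)
    abs(rec$rel_bias)
  }
  expect_lt(bias_at(0, 1), 0.01)
  expect_lt(bias_at(0.02, 3), 0.05)
  expect_lt(bias_at(0.05, 3), 0.10)
})
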