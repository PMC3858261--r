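test_that("reduced model reproduces closed-form exponential growth", {
  v <- exponential_growth_params()
  tt <- seq(0, 48, 4)
  traj <- simulate_culture(initial_state(), v, reactor_batch(),
                           horizon = 48, times = tt)
  x_v <- traj$x_u + traj$x_d
  expect_rel_equal(x_v, 2e4 * exp(0.2 * tt), 1e-6)
  # glucose untouched: no uptake configured
  expect_rel_equal(traj$glc, rep(25, length(tt)), 1e-8)
})

test_that("cell-free perfusion relaxes to the inlet as closed-form washout", {
  r <- reactor_perfusion()
  d <- dilution_rate(r)
  v <- param_values(mesc_parameters())
  tt <- seq(0, 96, 8)
  traj <- simulate_culture(initial_state(x_v = 0, glc = 5, gln = 1, lac = 10,
                                         amm = 2),
                           v, r, horizon = 96, times = tt)
  expect_rel_equal(traj$glc, 25 + (5 - 25) * exp(-d * tt), 1e-6)
  expect_rel_equal(traj$lac, 10 * exp(-d * tt), 1e-6)
  expect_rel_equal(traj$amm, 2 * exp(-d * tt), 1e-6)
  # glutamine adds abiotic decay to the washout
  kd <- v[["K_D_GLN"]]
  gln_ss <- d * 4 / (d + kd)
  expect_rel_equal(traj$gln, gln_ss + (1 - gln_ss) * exp(-(d + kd) * tt), 1e-6)
})

test_that("trajectories are nonnegative and tolerance-stable", {
  for (r in list(reactor_batch(), reactor_fed_batch(), reactor_perfusion())) {
    params <- if (r$mode == "perfusion") {
      mesc_parameters("table1_with_table2_perfusion")
    } else {
      mesc_parameters()
    }
    traj <- simulate_culture(params = params, reactor = r, horizon = 192)
    expect_gte(min(as.matrix(traj[-1])), -1e-9)
  }
  t1 <- simulate_culture(horizon = 96, times = seq(0, 96, 12))
  t2 <- simulate_culture(horizon = 96, times = seq(0, 96, 12),
                         rtol = 5e-9, atol = 5e-11)
  rel <- abs(as.matrix(t1[-1]) - as.matrix(t2[-1])) /
    pmax(abs(as.matrix(t2[-1])), 1e-6)
  expect_lt(max(rel), 1e-5)
})

test_that("compiled and R right-hand sides integrate to the same trajectory", {
  tt <- seq(0, 72, 12)
  tc <- simulate_culture(horizon = 72, times = tt, engine = "compiled")
  tr <- simulate_culture(horizon = 72, times = tt, engine = "r")
  rel <- abs(as.matrix(tc[-1]) - as.matrix(tr[-1])) /
    pmax(abs(as.matrix(tr[-1])), 1e-6)
  expect_lt(max(rel), 1e-5)
})

test_that("switch events match sign changes of the Rex1 switching expression", {
  traj <- simulate_culture(horizon = 192)
  switches <- attr(traj, "switches")
  s <- sign(traj$rex1 - 1)
  s <- s[s != 0]  # the t = 0 state sits exactly on the switching surface
  sign_changes <- sum(diff(s) != 0)
  expect_equal(length(switches), sign_changes)
  expect_true(all(switches > 0 & switches < 192))
})

test_that("finite differences of the trajectory agree with the RHS", {
  dt <- 0.25
  tt <- seq(24, 48, dt)  # smooth span, away from the early switch
  traj <- simulate_culture(horizon = 48, times = tt)
  traj <- traj[traj$time_h %in% tt, ]  # drop the implicit t = 0 row
  m <- as.matrix(traj[-1])
  p <- mesc_parameters()
  r <- reactor_batch()
  for (i in seq(2, nrow(m) - 1, by = 8)) {
    fd <- (m[i + 1, ] - m[i - 1, ]) / (2 * dt)
    rhs <- culture_rhs(pmax(m[i, ], 0), p, r)
    scale <- pmax(abs(rhs), max(abs(fd)) * 1e-3 + 1e-9)
    expect_lt(max(abs(fd - rhs) / scale), 5 * dt^2)
  }
})

test_that("medium exchange resets solutes and retains cells", {
  r <- reactor_fed_batch()
  st <- initial_state(x_v = 5e4, glc = 3, gln = 0.5, lac = 20, amm = 5)
  ex <- apply_medium_exchange(st, r)
  expect_equal(ex$lac, 0)
  expect_equal(ex$amm, 0)
  expect_equal(ex$glc, 25)
  expect_equal(ex$gln, 4)
  expect_equal(ex[c("x_u", "x_d", "rex1", "fgf5", "dppa3")],
               st[c("x_u", "x_d", "rex1", "fgf5", "dppa3")])
  expect_equal(apply_medium_exchange(ex, r), ex)  # idempotent on solutes
  expect_error(apply_medium_exchange(st, reactor_batch()), "fed_batch")
})

test_that("fed-batch integration applies exchanges on schedule", {
  traj <- simulate_culture(reactor = reactor_fed_batch(), horizon = 72)
  # shortly after each daily exchange glucose is back near the inlet level
  expect_gt(traj$glc[traj$time_h == 25], traj$glc[traj$time_h == 24])
  expect_gt(traj$glc[traj$time_h == 25], traj$glc[traj$time_h == 23])
  # lactate drops across the exchange
  expect_lt(traj$lac[traj$time_h == 25], traj$lac[traj$time_h == 24])
})

test_that("trajectory summaries report growth, composition and crossings", {
  mu <- 0.03
  tt <- seq(0, 96, 2)
  expgrow <- tibble::tibble(
    time_h = tt, x_u = 1e4 * exp(mu * tt), x_d = 0, glc = 25, gln = 4,
    lac = 0.2 * tt, amm = 0.05 * tt, rex1 = 1, fgf5 = 1, dppa3 = 1
  )
  s <- summarize_trajectory(expgrow)
  expect_equal(s$mu_max_realized, mu, tolerance = 1e-6)
  expect_equal(s$doubling_time_h, log(2) / mu, tolerance = 1e-6)
  expect_equal(s$t_lac_cross_h, 16 / 0.2)
  expect_equal(s$t_amm_cross_h, 4 / 0.05)
  expect_equal(s$final_frac_d, 0)
  expect_equal(s$fold_expansion, exp(mu * 96), tolerance = 1e-6)

  decay <- dplyr::mutate(expgrow, x_u = 1e4 * exp(-mu * time_h),
                         lac = 0, amm = 0)
  sd <- summarize_trajectory(decay)
  expect_lte(sd$mu_max_realized, 0)
  expect_equal(sd$t_peak_h, 0)
  expect_true(is.na(sd$t_lac_cross_h))
  expect_true(is.na(sd$doubling_time_h))
})

test_that("simulation inputs are validated", {
  expect_error(simulate_culture(horizon = 48, times = c(0, 60)),
               "within")
  expect_error(simulate_culture(initial = initial_state(lac = -1)),
               ">= 0")
  long <- trajectory_long(simulate_culture(horizon = 24, times = seq(0, 24, 6)))
  expect_named(long, c("time_h", "variable", "value"))
  expect_true("x_v" %in% long$variable)
})
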