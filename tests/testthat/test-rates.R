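p <- mesc_parameters()
v <- param_values(p)

test_that("growth rate is Monod in glucose", {
  expect_equal(specific_growth_rate(0, "U", p), 0)
  expect_equal(specific_growth_rate(v[["Kglc_U"]], "U", p),
               v[["mu_max_U"]] / 2)
  expect_equal(specific_growth_rate(25, "U", p), 0.928 * 25 / 26)
  expect_equal(specific_growth_rate(v[["Kglc_D"]], "D", p),
               v[["mu_max_D"]] / 2)
  glc <- seq(0, 40, 2)
  mu <- specific_growth_rate(glc, "U", p)
  expect_true(all(diff(mu) >= 0))
  expect_true(all(mu <= v[["mu_max_U"]]))
  expect_error(specific_growth_rate(-1, "U", p), ">= 0")
})

test_that("death rate saturates in lactate", {
  expect_equal(specific_death_rate(v[["Kdlac_U"]], "U", p),
               v[["mud_max_U"]] / 2)
  expect_equal(specific_death_rate(1e9, "D", p), v[["mud_max_D"]],
               tolerance = 1e-6)
  # direct scalar evaluation at the batch day-2 lactate level
  expect_equal(specific_death_rate(16, "U", p), 0.517 * 16 / 16.212)
  lac <- seq(0, 40, 2)
  expect_true(all(diff(specific_death_rate(lac, "U", p)) >= 0))
  expect_error(specific_death_rate(-0.1, "U", p), ">= 0")
})

test_that("transfer direction follows Rex1 relative to its reference", {
  expect_identical(transfer_direction(0.3), 1L)   # stressed: naive -> primed
  expect_identical(transfer_direction(2.0), 0L)   # unstressed: primed -> naive
  expect_identical(transfer_direction(1.0), 0L)   # tie takes unstressed branch
  expect_identical(transfer_direction(1.0, reference = 1.5), 1L)
})

test_that("transfer flux is gated, scaled by K_Diff, and conservative", {
  expect_equal(transfer_rate(1, 100, 50, p), 0)      # fixed point at reference
  v0 <- v; v0["K_Diff"] <- 0
  expect_equal(transfer_rate(0.3, 100, 50, v0), 0)
  # stressed branch drains the naive pool
  expect_equal(transfer_rate(0.3, 1, 1, p), 0.721 * 0.7)
  # unstressed branch drains the primed pool (negative net naive->primed)
  expect_equal(transfer_rate(2, 1, 1, p), -0.721 * 1)
  # flux enters the two cell balances with opposite signs
  st <- initial_state(rex1 = 0.3)
  d <- culture_rhs(st, transfer_only_params(), reactor_batch())
  expect_equal(d[["x_u"]] + d[["x_d"]], 0)
})

test_that("glucose uptake respects the consumption threshold", {
  r <- reactor_batch()
  expect_equal(glucose_uptake(25, 0, p, r), 0)
  expect_equal(glucose_uptake(v[["GLC_MIN"]], 1e5, p, r), 0)
  expect_equal(glucose_uptake(v[["GLC_MIN"]] / 2, 1e5, p, r), 0)
  # continuity at the threshold
  expect_lt(glucose_uptake(v[["GLC_MIN"]] + 1e-9, 1e5, p, r), 1e-8)
  # half-saturation one Monod constant above the threshold
  expect_equal(glucose_uptake(v[["GLC_MIN"]] + v[["Kx_GLC"]], 1e5, p, r),
               0.5 * v[["K_GLC_MAX"]] * 1e5 * r$n_bead)
  expect_true(glucose_uptake(25, 1e5, p, r) > 0)
})

test_that("glutamine consumption separates cellular uptake from abiotic decay", {
  r <- reactor_batch()
  cellfree <- glutamine_uptake_and_decay(4, 0, p, r)
  expect_equal(cellfree$uptake, 0)
  expect_equal(cellfree$decay, v[["K_D_GLN"]] * 4)
  none <- glutamine_uptake_and_decay(0, 1e5, p, r)
  expect_equal(none$uptake + none$decay, 0)
  half <- glutamine_uptake_and_decay(v[["Kx_GLN"]], 1e5, p, r)
  expect_equal(half$uptake, 0.5 * v[["K_GLN_MAX"]] * 1e5 * r$n_bead)
})

test_that("product formation is yield-coupled to nutrient uptake", {
  expect_equal(lactate_production(0, 10, p), 0)
  expect_equal(lactate_production(1, 10, p), 1.750)
  expect_equal(lactate_production(2, 10, p), 2 * lactate_production(1, 10, p))
  expect_equal(ammonia_production(0, 2, p), 0)
  expect_equal(ammonia_production(1, 2, p), 0.814)
  perf <- mesc_parameters("table1_with_table2_perfusion")
  expect_equal(ammonia_production(1, 2, perf), 1.769)
  expect_equal(lactate_production(1, 2, perf), 1.357)
})

test_that("gene dynamics have the stated limits and steady states", {
  # basal production off -> pure exponential decay
  v0 <- v; v0["b_REX1"] <- 0
  expect_equal(gene_rhs_rex(2, 10, v0), -v[["a_REX"]] * 2)
  v0 <- v; v0["b_DPPA"] <- 0
  expect_equal(gene_rhs_dppa(1.5, 3, v0), -v[["alpha_DPPA"]] * 1.5)
  v0 <- v; v0["b_FGF"] <- 0
  expect_equal(gene_rhs_fgf(1, 30, v0), -0.306 * 1)

  # half-inhibition one Hill constant above the stress threshold
  prod_at <- function(lac) gene_rhs_rex(0, lac, p)
  expect_equal(prod_at(v[["LAC_MIN"]] + v[["K_LAC_REX"]]), prod_at(0) / 2)
  dppa_prod <- function(amm) gene_rhs_dppa(0, amm, p)
  expect_equal(dppa_prod(v[["AMM_MIN"]] + v[["K_AMM_DPPA"]]), dppa_prod(0) / 2)

  # stress-free steady states solve production = degradation
  expect_equal(gene_rhs_rex(1.848 / 1.465, 0, p), 0)
  expect_equal(gene_rhs_dppa(10 / 6.549, 0, p), 0)

  # production monotone nonincreasing in the stress metabolite
  lac <- seq(0, 40, 1)
  expect_true(all(diff(vapply(lac, prod_at, numeric(1))) <= 0))

  # Fgf5: no lactate stress means no production, only decay
  expect_equal(gene_rhs_fgf(1, 0, p), -v[["alpha_FGF"]])
  expect_equal(gene_rhs_fgf(0, 0, p), 0)
  # self-regulation factor is half-maximal at K_FGF
  act <- function(fgf, lac) gene_rhs_fgf(fgf, lac, p) + v[["alpha_FGF"]] * fgf
  s <- 30 - v[["LAC_MIN"]]
  expect_equal(act(v[["K_FGF"]], 30),
               v[["b_FGF"]] * s / (v[["K_LAC_FGF"]] + s) / 2)
  # production positively correlated with lactate stress
  expect_gt(act(1, 30), act(1, 10))
})

test_that("full RHS equals the sum of its term operations", {
  set.seed(42)
  reactors <- list(reactor_batch(), reactor_perfusion())
  for (r in reactors) {
    for (i in 1:10) {
      st <- c(x_u = runif(1, 0, 1e5), x_d = runif(1, 0, 1e5),
              glc = runif(1, 0, 30), gln = runif(1, 0, 5),
              lac = runif(1, 0, 40), amm = runif(1, 0, 6),
              rex1 = runif(1, 0, 2), fgf5 = runif(1, 0, 5),
              dppa3 = runif(1, 0, 2))
      d <- culture_rhs(st, p, r)
      x_v <- st[["x_u"]] + st[["x_d"]]
      flux <- transfer_rate(st[["rex1"]], st[["x_u"]], st[["x_d"]], p)
      q_glc <- glucose_uptake(st[["glc"]], x_v, p, r)
      gln_t <- glutamine_uptake_and_decay(st[["gln"]], x_v, p, r)
      dil <- dilution_rate(r)
      expect_equal(d[["x_u"]],
                   (specific_growth_rate(st[["glc"]], "U", p) -
                      specific_death_rate(st[["lac"]], "U", p)) * st[["x_u"]] - flux)
      expect_equal(d[["x_d"]],
                   (specific_growth_rate(st[["glc"]], "D", p) -
                      specific_death_rate(st[["lac"]], "D", p)) * st[["x_d"]] + flux)
      expect_equal(d[["glc"]], -q_glc + dil * (r$inlet[["GLC"]] - st[["glc"]]))
      expect_equal(d[["gln"]], -gln_t$uptake - gln_t$decay +
                     dil * (r$inlet[["GLN"]] - st[["gln"]]))
      expect_equal(d[["lac"]], lactate_production(q_glc, st[["lac"]], p) +
                     dil * (0 - st[["lac"]]))
      expect_equal(d[["amm"]], ammonia_production(gln_t$uptake, st[["amm"]], p) +
                     dil * (0 - st[["amm"]]))
      expect_equal(d[["rex1"]], gene_rhs_rex(st[["rex1"]], st[["lac"]], p))
      expect_equal(d[["fgf5"]], gene_rhs_fgf(st[["fgf5"]], st[["lac"]], p))
      expect_equal(d[["dppa3"]], gene_rhs_dppa(st[["dppa3"]], st[["amm"]], p))
    }
  }
})

test_that("abiotic vessels behave as pure chemistry", {
  st <- initial_state(x_v = 0)
  d <- culture_rhs(st, p, reactor_batch())
  expect_equal(unname(d[c("x_u", "x_d", "glc", "lac", "amm")]), rep(0, 5))
  expect_equal(d[["gln"]], -v[["K_D_GLN"]] * 4)
})

test_that("reactor configs enforce mode-specific requirements", {
  expect_error(reactor_perfusion(feed_rate = 0), "feed_rate")
  expect_error(reactor_fed_batch(exchange_interval = -1), "exchange_interval")
  expect_error(new_reactor <- reactor_batch(volume = 0), "volume")
  expect_equal(dilution_rate(reactor_perfusion()), 2.29 / 60)
  expect_equal(dilution_rate(reactor_batch()), 0)
  expect_equal(unname(reactor_perfusion()$inlet[c("LAC", "AMM")]), c(0, 0))
})
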