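# Pointwise kinetic rate laws of the two-population mESC bioprocess model.
#
# Growth of each pool is Monod in glucose; death saturates in lactate.
# The two pools exchange cells through a Rex1-gated transfer flux: when
# relative Rex1 expression falls below its day-0 reference the flux runs
# naive -> primed, above it primed -> naive. Nutrient uptake is Monod with
# a hard glucose threshold (uptake stops at GLC_MIN, continuously);
# lactate/ammonia production is yield-coupled to the corresponding uptake;
# glutamine additionally decays abiotically. Gene expression follows
# basal-production/first-order-degradation dynamics in which metabolite
# stress -- concentration in excess of a critical level -- inhibits Rex1
# (lactate) and Dppa3 (ammonia) through cooperative Hill terms and
# activates Fgf5 (lactate) through a saturating term with Monod-type
# self-regulation.

# Hill exponent of the inhibitory stress terms (lactate -> Rex1,
# ammonia -> Dppa3). Cooperative inhibition reproduces the sharp
# naive -> primed transition the model is known for; see the methods
# vignette for the audit that fixed this value.
.stress_hill_n <- 2

.check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("`", what, "` must be finite and >= 0", call. = FALSE)
  }
}

#' Specific growth rate
#'
#' Monod growth on glucose for the naive (`"U"`) or primed (`"D"`) pool:
#' `mu_i = mu_max_i * GLC / (Kglc_i + GLC)`.
#'
#' @param glc Glucose concentration (mM); vectorized.
#' @param pop `"U"` (naive) or `"D"` (primed).
#' @param params Parameter tibble or named vector (see [mesc_parameters()]).
#' @return Specific growth rate (1/h).
#' @examples
#' p <- mesc_parameters()
#' specific_growth_rate(25, "U", p)
#' @export
specific_growth_rate <- function(glc, pop = c("U", "D"), params) {
  pop <- match.arg(pop)
  .check_nonneg(glc, "glc")
  v <- param_values(params)
  mu_max <- if (pop == "U") v[["mu_max_U"]] else v[["mu_max_D"]]
  k <- if (pop == "U") v[["Kglc_U"]] else v[["Kglc_D"]]
  mu_max * glc / (k + glc)
}

#' Specific death rate
#'
#' Lactate-driven death, saturating at the maximum specific death rate:
#' `mud_i = mud_max_i * LAC / (Kdlac_i + LAC)`.
#'
#' @param lac Lactate concentration (mM); vectorized.
#' @inheritParams specific_growth_rate
#' @return Specific death rate (1/h).
#' @export
specific_death_rate <- function(lac, pop = c("U", "D"), params) {
  pop <- match.arg(pop)
  .check_nonneg(lac, "lac")
  v <- param_values(params)
  mud_max <- if (pop == "U") v[["mud_max_U"]] else v[["mud_max_D"]]
  k <- if (pop == "U") v[["Kdlac_U"]] else v[["Kdlac_D"]]
  mud_max * lac / (k + lac)
}

#' Direction of inter-population transfer
#'
#' Binary indicator of the transfer direction between the naive and primed
#' pools, set by relative Rex1 expression: 1 (naive to primed) when Rex1 is
#' below the reference level, 0 (primed to naive) at or above it. The
#' reference is the day-0 normalized expression, 1 by construction of the
#' fold-change scale; at exactly the reference the unstressed branch is
#' taken.
#'
#' @param rex Relative Rex1 expression (fold); vectorized.
#' @param reference Reference expression level.
#' @return Integer 0/1.
#' @export
transfer_direction <- function(rex, reference = 1) {
  .check_nonneg(rex, "rex")
  as.integer(rex < reference)
}

#' Inter-population transfer flux
#'
#' Net cell flux from the naive to the primed pool (cells/bead/h). The
#' first-order transfer coefficient scales with the deviation of Rex1 from
#' its reference, `K_Diff * |1 - REX|`, and acts on the donor pool selected
#' by [transfer_direction()]: on `x_u` under stress (Rex1 suppressed), on
#' `x_d` otherwise (returned with negative sign). Entering the two cell
#' balances with opposite signs, the flux conserves total viable cells.
#'
#' @param rex Relative Rex1 expression (fold).
#' @param x_u,x_d Naive and primed cell densities (cells/bead).
#' @inheritParams specific_growth_rate
#' @param reference Rex1 reference level (see [transfer_direction()]).
#' @return Signed flux, positive naive -> primed (cells/bead/h).
#' @export
transfer_rate <- function(rex, x_u, x_d, params, reference = 1) {
  .check_nonneg(c(rex, x_u, x_d), "rex, x_u, x_d")
  v <- param_values(params)
  d_t <- transfer_direction(rex, reference)
  r <- v[["K_Diff"]] * abs(reference - rex)
  r * (d_t * x_u - (1 - d_t) * x_d)
}

#' Metabolite stress above a critical level
#'
#' Concentration in excess of a threshold, floored at zero:
#' `max(conc - threshold, 0)`. This is the stress signal driving the gene
#' expression dynamics and the glucose-uptake cutoff; the flux it feeds is
#' continuous at the threshold.
#'
#' @param conc Concentration (mM); vectorized.
#' @param threshold Critical level (mM).
#' @return Excess concentration (mM).
#' @export
metabolite_stress <- function(conc, threshold) {
  pmax(conc - threshold, 0)
}

# Per-cell uptake laws (mM per cell per hour).
per_cell_glucose_uptake <- function(glc, v) {
  s <- metabolite_stress(glc, v[["GLC_MIN"]])
  v[["K_GLC_MAX"]] * s / (v[["Kx_GLC"]] + s)
}

per_cell_glutamine_uptake <- function(gln, v) {
  v[["K_GLN_MAX"]] * gln / (v[["Kx_GLN"]] + gln)
}

#' Vessel-level glucose uptake
#'
#' Total glucose consumption rate in vessel concentration terms. Per-cell
#' uptake is Monod in the glucose excess over the threshold `GLC_MIN`
#' (below which consumption ceases, matching the observed sharp drop in
#' glucose use despite abundant glucose), multiplied by the viable cell
#' density and the bead count.
#'
#' @param glc Glucose concentration (mM).
#' @param x_v Total viable cell density (cells/bead).
#' @inheritParams specific_growth_rate
#' @param reactor A `reactor_config` supplying the bead count.
#' @return Uptake rate (mM/h), nonnegative.
#' @export
glucose_uptake <- function(glc, x_v, params, reactor) {
  .check_nonneg(c(glc, x_v), "glc, x_v")
  validate_reactor(reactor)
  v <- param_values(params)
  per_cell_glucose_uptake(glc, v) * x_v * reactor$n_bead
}

#' Vessel-level glutamine consumption
#'
#' Cellular uptake (Monod in glutamine) plus spontaneous first-order
#' abiotic degradation at rate `K_D_GLN`, which proceeds even in a
#' cell-free vessel.
#'
#' @param gln Glutamine concentration (mM).
#' @inheritParams glucose_uptake
#' @return A list with components `uptake` (cellular, mM/h) and `decay`
#'   (abiotic, mM/h); their sum is the total removal rate.
#' @export
glutamine_uptake_and_decay <- function(gln, x_v, params, reactor) {
  .check_nonneg(c(gln, x_v), "gln, x_v")
  validate_reactor(reactor)
  v <- param_values(params)
  list(
    uptake = per_cell_glutamine_uptake(gln, v) * x_v * reactor$n_bead,
    decay = v[["K_D_GLN"]] * gln
  )
}

#' Yield-coupled lactate production
#'
#' Lactate is produced stoichiometrically from glucose uptake,
#' `Q_LAC = Y_LACGLC * Q_GLC`. The `lac` argument is part of the interface
#' for symmetry with the other rate laws; the lactate critical level
#' `LAC_MIN` acts on the gene-expression stress signal, not on production
#' (see [metabolite_stress()]).
#'
#' @param glc_uptake Vessel-level glucose uptake (mM/h).
#' @param lac Lactate concentration (mM), unused by the coupled law.
#' @inheritParams specific_growth_rate
#' @return Production rate (mM/h).
#' @export
lactate_production <- function(glc_uptake, lac = 0, params) {
  .check_nonneg(glc_uptake, "glc_uptake")
  v <- param_values(params)
  v[["Y_LACGLC"]] * glc_uptake
}

#' Yield-coupled ammonia production
#'
#' `Q_AMM = Y_AMMGLN * Q_GLN`, where `Q_GLN` is the *cellular* glutamine
#' uptake; abiotic glutamine decay does not produce ammonia in the model.
#'
#' @param gln_uptake Vessel-level cellular glutamine uptake (mM/h).
#' @param amm Ammonia concentration (mM), unused by the coupled law.
#' @inheritParams specific_growth_rate
#' @return Production rate (mM/h).
#' @export
ammonia_production <- function(gln_uptake, amm = 0, params) {
  .check_nonneg(gln_uptake, "gln_uptake")
  v <- param_values(params)
  v[["Y_AMMGLN"]] * gln_uptake
}

#' Gene expression dynamics
#'
#' Time derivatives of the day-0-normalized expression of the three
#' modeled genes.
#'
#' Rex1 (naive marker): basal production inhibited by lactate stress
#' through a cooperative Hill term, first-order degradation:
#' `dREX/dt = b_REX1 / (1 + (s_lac/K_LAC_REX)^2) - a_REX * REX`,
#' with `s_lac = max(LAC - LAC_MIN, 0)`.
#'
#' Dppa3 (naive marker): same form driven by ammonia stress with constants
#' `b_DPPA`, `K_AMM_DPPA`, `alpha_DPPA` and `s_amm = max(AMM - AMM_MIN, 0)`.
#'
#' Fgf5 (primed marker): production activated by lactate stress
#' (`s_lac / (K_LAC_FGF + s_lac)`) with Monod-type self-regulation of the
#' transcript (`FGF / (K_FGF + FGF)`, the two isoforms promoting their own
#' expression), degraded at `alpha_FGF`:
#' `dFGF/dt = b_FGF * s_lac/(K_LAC_FGF + s_lac) * FGF/(K_FGF + FGF)
#'  - alpha_FGF * FGF`.
#'
#' @param rex,fgf,dppa Relative expression (fold).
#' @param lac,amm Metabolite concentrations (mM).
#' @inheritParams specific_growth_rate
#' @return Time derivative of the expression level (1/h).
#' @export
gene_rhs_rex <- function(rex, lac, params) {
  .check_nonneg(c(rex, lac), "rex, lac")
  v <- param_values(params)
  s <- metabolite_stress(lac, v[["LAC_MIN"]])
  v[["b_REX1"]] / (1 + (s / v[["K_LAC_REX"]])^.stress_hill_n) -
    v[["a_REX"]] * rex
}

#' @rdname gene_rhs_rex
#' @export
gene_rhs_fgf <- function(fgf, lac, params) {
  .check_nonneg(c(fgf, lac), "fgf, lac")
  v <- param_values(params)
  s <- metabolite_stress(lac, v[["LAC_MIN"]])
  v[["b_FGF"]] * (s / (v[["K_LAC_FGF"]] + s)) * (fgf / (v[["K_FGF"]] + fgf)) -
    v[["alpha_FGF"]] * fgf
}

#' @rdname gene_rhs_rex
#' @export
gene_rhs_dppa <- function(dppa, amm, params) {
  .check_nonneg(c(dppa, amm), "dppa, amm")
  v <- param_values(params)
  s <- metabolite_stress(amm, v[["AMM_MIN"]])
  v[["b_DPPA"]] / (1 + (s / v[["K_AMM_DPPA"]])^.stress_hill_n) -
    v[["alpha_DPPA"]] * dppa
}

#' Full model right-hand side
#'
#' Assembles the individual rate laws into the time derivative of the full
#' nine-component culture state for a given reactor configuration. Cell
#' balances combine population-specific growth and death with the signed
#' transfer flux; solute balances combine cellular uptake/production
#' (averaged over total viable cells and scaled by bead count), abiotic
#' glutamine decay and, in perfusion mode only, a dilution term
#' `D * (inlet - conc)` applied to the four solutes -- never to cells or
#' gene states, since beads are retained in the vessel.
#'
#' This reference implementation in R mirrors the compiled right-hand side
#' used by the solver and is intended for direct evaluation and testing.
#'
#' @param state Named state vector or one-row tibble (see
#'   [initial_state()]).
#' @inheritParams specific_growth_rate
#' @param reactor A `reactor_config`.
#' @return Named numeric vector of time derivatives (per hour).
#' @examples
#' culture_rhs(initial_state(), mesc_parameters(), reactor_batch())
#' @export
culture_rhs <- function(state, params, reactor) {
  y <- as_state_vector(state)
  v <- param_values(params)
  validate_reactor(reactor)

  x_u <- y[["x_u"]]; x_d <- y[["x_d"]]; x_v <- x_u + x_d
  glc <- y[["glc"]]; gln <- y[["gln"]]
  lac <- y[["lac"]]; amm <- y[["amm"]]

  flux <- transfer_rate(y[["rex1"]], x_u, x_d, v)
  q_glc <- glucose_uptake(glc, x_v, v, reactor)
  gln_terms <- glutamine_uptake_and_decay(gln, x_v, v, reactor)
  d <- dilution_rate(reactor)
  inlet <- reactor$inlet

  c(
    x_u = specific_growth_rate(glc, "U", v) * x_u -
      specific_death_rate(lac, "U", v) * x_u - flux,
    x_d = specific_growth_rate(glc, "D", v) * x_d -
      specific_death_rate(lac, "D", v) * x_d + flux,
    glc = -q_glc + d * (inlet[["GLC"]] - glc),
    gln = -gln_terms$uptake - gln_terms$decay + d * (inlet[["GLN"]] - gln),
    lac = lactate_production(q_glc, lac, v) + d * (inlet[["LAC"]] - lac),
    amm = ammonia_production(gln_terms$uptake, amm, v) + d * (inlet[["AMM"]] - amm),
    rex1 = gene_rhs_rex(y[["rex1"]], lac, v),
    fgf5 = gene_rhs_fgf(y[["fgf5"]], lac, v),
    dppa3 = gene_rhs_dppa(y[["dppa3"]], amm, v)
  )
}
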