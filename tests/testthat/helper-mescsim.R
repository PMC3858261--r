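# Shared fixtures, built in code.

# Noise-free assay configuration: generated datasets equal model output.
quiet_noise <- function(replicates = 1) {
  assay_noise_model(cell_count_cv = 0, nutrient_cv = 0,
                    nutrient_sd_floor = 0, qpcr_cv = 0,
                    replicates = replicates)
}

# Parameter vector with growth, death and solute dynamics switched off,
# leaving only Rex1-gated transfer between the two pools (plus gene
# dynamics). Built as a named vector so zeros bypass the strict-positivity
# check applied to shipped tables.
transfer_only_params <- function() {
  v <- param_values(mesc_parameters())
  v[c("mu_max_U", "mu_max_D", "mud_max_U", "mud_max_D",
      "K_GLC_MAX", "K_GLN_MAX", "K_D_GLN")] <- 0
  v
}

# Pure exponential growth: no death, no transfer, no solute consumption,
# and a vanishing glucose Monod constant so mu is effectively frozen at
# mu_max while glucose stays constant.
exponential_growth_params <- function() {
  v <- transfer_only_params()
  v[c("Kglc_U", "Kglc_D")] <- 1e-12
  v["K_Diff"] <- 0
  v["mu_max_U"] <- 0.2
  v["mu_max_D"] <- 0.2
  v
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
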