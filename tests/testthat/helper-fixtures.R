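# shared fixtures, all generated in code

fixture_life_table <- make_life_table()

fixture_ms <- function(seed = 42, ...) {
  ce_model_set(econ = make_econ_tables(seed), life_table = fixture_life_table,
               ...)
}

# near-zero mortality inputs: Weibull rates at the numerical floor, point
# death probabilities zeroed, background hazard negligible
immortal_life_table <- make_life_table(makeham_c = 0, gompertz_b = 1e-300,
                                       gompertz_g = 0.085)

immortal_params <- function() {
  p <- default_parameter_table()
  p$lambda[p$kind == "weibull"] <- 1e-12
  p$value[p$name == "cart_df_death"] <- 0
  p
}

# a parameter set under which the intervention arm is a genuine tradeoff
# (more effective and more costly), used to exercise ICER/DSA machinery
# on a well-defined frontier: a hypothetical gentler event hazard for the
# intervention's event-free survival
tradeoff_params <- function() {
  p <- default_parameter_table()
  p$lambda[p$name == "efs_irchop"] <- 0.10
  p$k[p$name == "efs_irchop"] <- 0.884
  p
}

tradeoff_ms <- function(seed = 42, ...) {
  ce_model_set(params = tradeoff_params(), econ = make_econ_tables(seed),
               life_table = fixture_life_table, ...)
}

# per-strategy totals printed in the source cost-effectiveness analysis,
# used as calibration targets
published_totals <- tibble::tibble(
  strategy = c("RCHOP", "I-RCHOP"),
  ly = c(17.59, 20.13),
  qaly = c(14.245, 15.479),
  cost = c(32520.82, 74606.41)
)

published_icer <- 34111.45
published_wtp <- 1e5
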