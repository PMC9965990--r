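# Shared fixtures: a session-level cache so expensive simulations are run
# once and reused across test files, plus cheap solver settings for
# property checks where high accuracy is not needed.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache))
    assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# fast solver settings for comparative/property tests
FAST <- list(rtol = 1e-6, atol = 1e-9)

ktz_sim <- function(dose, prandial = "fasted", t_end = 24, grid = 0.1,
                    n_doses = 1, interval = 24, form = "tablet",
                    scenario = "P_M1_M2", rtol = 1e-8, atol = 1e-10) {
  key <- sprintf("ktz_%g_%s_%g_%g_%d_%g_%s_%s_%g", dose, prandial, t_end,
                 grid, n_doses, interval, form, scenario, rtol)
  cached(key, {
    reg <- regimen("ketoconazole", dose, n_doses, interval,
                   formulation = formulation(form),
                   prandial_state = prandial)
    mod <- pbpk_model(build_reference_individual(),
                      ketoconazole_compounds(), reg, scenario = scenario)
    simulate_model(mod, t_end, grid = grid, rtol = rtol, atol = atol)
  })
}

# an inert, impermeant, weakly filtered tracer used for the analytic
# one-compartment reduction and conservation checks
inert_compound <- function(gfr_fraction = 0.01) {
  compound("inert", MW = 300,
           solubility = list(list(pH = 6.5, mg_per_L = 1000)),
           logP = -8, fu = 1, GFR_fraction = gfr_fraction,
           partition_method = "Berezhkovskiy",
           permeability_method = "PKSimStandard")
}

# victim AUC_last over a window after the victim dose, under a given
# inhibition scenario with a ketoconazole solution perpetrator
victim_auc <- function(victim_name, gap, scenario, window = 12,
                       perp_dose = 400, victim_dose = 5) {
  key <- sprintf("vauc_%s_%g_%s_%g", victim_name, gap, scenario, window)
  cached(key, {
    vic <- load_victim(victim_name)
    perp_start <- max(0, -gap)
    vic_time <- perp_start + gap
    cmps <- c(stats::setNames(list(vic), vic$name),
              ketoconazole_compounds())
    doses <- c(regimen("ketoconazole", perp_dose, 1, start = perp_start),
               regimen(vic$name, victim_dose, 1, start = vic_time))
    mod <- pbpk_model(build_reference_individual(), cmps, doses,
                      scenario = scenario)
    res <- simulate_model(mod, vic_time + window, grid = 0.25,
                          rtol = FAST$rtol, atol = FAST$atol)
    keep <- res$times >= vic_time
    auc_last(res$times[keep], res$plasma[keep, vic$name])
  })
}
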