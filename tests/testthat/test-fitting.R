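# Fitting tests use oral-solution designs (no solid-particle states), which
# keeps each objective evaluation to a fraction of a second.

fit_studies <- function(doses = c(200, 400), cv = 0, seed = 11,
                        kcat_aadac = 0.87) {
  cmps <- ketoconazole_compounds()
  for (k in seq_along(cmps$ketoconazole$processes))
    if (cmps$ketoconazole$processes[[k]]$protein == "AADAC")
      cmps$ketoconazole$processes[[k]]$k_cat <- kcat_aadac
  out <- list()
  for (i in seq_along(doses)) {
    st <- synthetic_study(paste0("fs", i),
                          regimen("ketoconazole", doses[i], 1,
                                  formulation = formulation("solution")),
                          sampling_times = c(0.5, 1, 2, 3, 5, 8, 12, 24),
                          n_subjects = 12)
    profs <- generate_observed_profiles(
      st, error_model(cv = cv, loq = 0, seed = seed + i),
      compounds = cmps, rtol = 1e-6, atol = 1e-9)
    out <- c(out, profs)
  }
  out
}

test_that("noiseless Levenberg-Marquardt recovery is exact to 1%", {
  observed <- cached("fit_obs_cv0", fit_studies(cv = 0))
  free <- data.frame(compound = "ketoconazole", protein = "AADAC",
                     param = "k_cat", lower = 0.1, upper = 5, start = 1.4,
                     stringsAsFactors = FALSE)
  fit <- cached("fit_lm_cv0", fit_parameters(
    free, observed, method = "LevenbergMarquardt", rtol = 1e-6,
    atol = 1e-9, maxiter = 15))
  expect_equal(unname(fit$estimates), 0.87, tolerance = 0.01)
  # final objective does not exceed the starting objective
  expect_lte(fit$objective, fit$trace[1])
})

test_that("Monte-Carlo search is reproducible for a fixed seed", {
  observed <- cached("fit_obs_cv0", fit_studies(cv = 0))
  free <- data.frame(compound = "ketoconazole", protein = "AADAC",
                     param = "k_cat", lower = 0.2, upper = 3, start = 1,
                     stringsAsFactors = FALSE)
  run <- function() suppressWarnings(
    fit_parameters(free, observed, method = "MonteCarlo", seed = 5,
                   n_mc = 4, rtol = 1e-6, atol = 1e-9, maxiter = 3))
  f1 <- run(); f2 <- run()
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$objective, f2$objective)
})

test_that("a parameter with no pathway to the output has zero sensitivity", {
  # M2's clearance cannot touch ketoconazole exposure when M2's inhibition
  # is inactive (scenario P)
  s <- local_sensitivity(
    list(compound = "m2", protein = "FMO3", param = "CL_spec"),
    doses = regimen("ketoconazole", 200, 1,
                    formulation = formulation("solution")),
    output_compound = "ketoconazole", t_end = 12, scenario = "P")
  expect_equal(s, 0, tolerance = 1e-6)
})

test_that("lipophilicity and binding dominate the sensitivity ranking", {
  doses <- regimen("ketoconazole", 200, 1,
                   formulation = formulation("solution"))
  pars <- data.frame(
    compound = "ketoconazole",
    protein = c(NA, NA, "UGT1A4"),
    param = c("fu", "logP", "k_cat"),
    stringsAsFactors = FALSE)
  ranked <- cached("sens_rank", sensitivity_analysis(
    pars, doses = doses, t_end = 24))
  s <- stats::setNames(abs(ranked$sensitivity), ranked$param)
  expect_gt(s[["fu"]], s[["k_cat"]])
  expect_gt(s[["logP"]], s[["k_cat"]])
})

test_that("sensitivity coefficients are step-size stable", {
  doses <- regimen("ketoconazole", 200, 1,
                   formulation = formulation("solution"))
  par <- list(compound = "ketoconazole", protein = NA, param = "fu")
  s10 <- local_sensitivity(par, doses, t_end = 24,
                           relative_perturbation = 0.1)
  s05 <- local_sensitivity(par, doses, t_end = 24,
                           relative_perturbation = 0.05)
  expect_equal(s10, s05, tolerance = 0.1)
})
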