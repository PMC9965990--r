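test_that("zero-dose simulations stay identically zero", {
  mod <- pbpk_model(build_reference_individual(),
                    ketoconazole_compounds(), doses = list())
  res <- simulate_model(mod, 1, grid = 0.25)
  expect_true(all(res$states == 0))
  expect_true(all(res$plasma == 0))
})

test_that("a tablet dose deposits dose/MW micromol of solid in the stomach", {
  reg <- regimen("ketoconazole", 200, 1,
                 formulation = formulation("tablet"))
  mod <- pbpk_model(build_reference_individual(),
                    ketoconazole_compounds(), reg)
  st <- mod$cs$ketoconazole
  expect_equal(sum(mod$y0[st$sol[1, ]]), 200 * 1000 / 531.43,
               tolerance = 1e-12)
  # solutions go straight to the dissolved stomach state
  mod2 <- pbpk_model(build_reference_individual(),
                     ketoconazole_compounds(),
                     regimen("ketoconazole", 200, 1,
                             formulation = formulation("solution")))
  expect_equal(mod2$y0[[mod2$cs$ketoconazole$dis[1]]], 200 * 1000 / 531.43)
})

test_that("model assembly rejects dangling products and missing pools", {
  ind <- build_reference_individual()
  bad <- load_compound("ketoconazole")
  bad$processes[[1]]$product <- "phantom"
  expect_error(pbpk_model(ind, list(ketoconazole = bad)), "phantom")
  ind2 <- ind
  ind2$pools <- ind2$pools[ind2$pools$protein != "AADAC", ]
  expect_error(pbpk_model(ind2, ketoconazole_compounds()), "AADAC")
})

test_that("distribution-only dynamics conserve an intravenous bolus", {
  cmp <- inert_compound()
  mod <- pbpk_model(build_reference_individual(),
                    list(inert = cmp), doses = list())
  res <- simulate_model(mod, 6, grid = 0.5,
                        initial_amounts = list(inert = c(ven = 10)))
  totals <- rowSums(res$states)
  # only the (tiny) renal route removes mass; conservation to 0.2%
  expect_lt(max(abs(totals - 10)) / 10, 0.002)
  # redistribution happened: venous amount fell below the initial bolus
  expect_lt(res$states[nrow(res$states), mod$cs$inert$ven], 10)
})

test_that("the engine matches the one-compartment analytic reduction", {
  ind <- build_reference_individual()
  cmp <- inert_compound(gfr_fraction = 0.01)
  mod <- pbpk_model(ind, list(inert = cmp), doses = list())
  res <- simulate_model(mod, 48, grid = 1,
                        initial_amounts = list(inert = c(ven = 10)))
  # analytic oracle: well-mixed extracellular pool, renal clearance
  # corrected for the kidney perfusion bottleneck
  org <- ind$organs
  v_ec <- org$volume * (org$f_plasma + org$f_interstitial)
  v_tot <- sum(v_ec[!org$name %in% c("venous blood", "arterial blood")]) +
    org$volume[org$name == "venous blood"] +
    org$volume[org$name == "arterial blood"]
  cl <- 0.01 * ind$gfr / 1000                          # L/min
  qk <- org$blood_flow[org$name == "kidney"]
  k_pred <- cl * qk / (qk + cl) / v_tot                # 1/min
  keep <- res$times >= 12
  cc <- res$plasma[keep, "inert"]
  k_sim <- -stats::coef(stats::lm(log(cc) ~ tt,
                                  data.frame(tt = res$times[keep] * 60,
                                             cc = cc)))[["tt"]]
  expect_equal(k_sim, k_pred, tolerance = 1e-3)
})

test_that("solver refinement leaves exposure unchanged", {
  a <- ktz_sim(200, t_end = 24, rtol = 1e-6, grid = 0.25)
  b <- ktz_sim(200, t_end = 24, rtol = 5e-7, grid = 0.25)
  auc_a <- auc_last(a$times, a$plasma[, "ketoconazole"])
  auc_b <- auc_last(b$times, b$plasma[, "ketoconazole"])
  expect_equal(auc_a / auc_b, 1, tolerance = 1e-3)
})

test_that("M2 never reaches plasma and accumulates in liver cells", {
  res <- ktz_sim(400, t_end = 24)
  expect_true(all(res$plasma[, "m2"] == 0))
  expect_gt(max(res$liver_ic[, "m2"]), 0)
})

test_that("metabolite inhibition barely changes parent exposure", {
  res_p <- ktz_sim(400, t_end = 24, scenario = "P")
  res_full <- ktz_sim(400, t_end = 24, scenario = "P_M1_M2")
  auc_p <- auc_last(res_p$times, res_p$plasma[, "ketoconazole"])
  auc_f <- auc_last(res_full$times, res_full$plasma[, "ketoconazole"])
  expect_lt(abs(auc_f / auc_p - 1), 0.10)
})

test_that("urinary excretion of unchanged drug stays in the low percent range", {
  res <- ktz_sim(200, t_end = 24)
  ur <- res$ledger[["ketoconazole.urine"]] /
    res$dose_total[["ketoconazole"]] * 100
  expect_gt(ur, 0.2)
  expect_lt(ur, 6)
})
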