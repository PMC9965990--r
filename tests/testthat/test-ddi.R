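test_that("an inhibition-free network leaves the victim untouched", {
  # perpetrator present but all inhibition entries inactive: DDI ratios 1
  vic <- load_victim("midazolam")
  perp <- regimen("ketoconazole", 400, 1)
  vreg <- regimen("midazolam", 5, 1, start = 1)
  scen <- ddi_scenario(vic, "P", perp, vreg)
  rep <- run_ddi_study(scen, scenarios = "none", window = 12, grid = 0.25,
                       rtol = FAST$rtol, atol = FAST$atol)
  expect_equal(rep$arms$none$ratios$AUC_last$ratio, 1, tolerance = 1e-4)
  expect_equal(rep$arms$none$ratios$C_max$ratio, 1, tolerance = 1e-4)
  # reference and effect arms share the victim regimen bit-for-bit
  expect_identical(rep$regimen_hash, ketopbpk:::.regimen_hash(vreg))
})

test_that("inhibition is monotone across perpetrator scenarios and gaps", {
  scen_order <- c("P", "P_M1", "P_M1_M2")
  tol <- 1 + 1e-6  # numerical slack on non-strict monotonicity
  for (v in c("midazolam", "alprazolam", "alfentanil", "triazolam",
              "digoxin")) {
    for (gap in c(0, 8)) {
      aucs <- vapply(scen_order, function(sc) victim_auc(v, gap, sc),
                     numeric(1))
      ref <- victim_auc(v, gap, "none")
      expect_true(all(diff(aucs) >= -ref * 1e-6),
                  label = sprintf("%s gap %g: AUC non-decreasing P -> P+M1 -> P+M1+M2", v, gap))
      expect_true(all(aucs * tol >= ref),
                  label = sprintf("%s gap %g: DDI AUC ratios >= 1", v, gap))
    }
  }
  for (gap in c(1, 12)) {
    aucs <- vapply(scen_order, function(sc)
      victim_auc("midazolam", gap, sc), numeric(1))
    expect_true(all(diff(aucs) >= -aucs[1] * 1e-6))
  }
})

test_that("metabolites matter more as the dosing gap grows", {
  # relative advantage of the full parent+metabolite network over the
  # parent alone widens between concomitant dosing and a long gap
  adv <- function(gap) {
    ref <- victim_auc("midazolam", gap, "none")
    (victim_auc("midazolam", gap, "P_M1_M2") -
       victim_auc("midazolam", gap, "P")) / ref
  }
  expect_gte(adv(12), adv(0) - 1e-9)
})

test_that("zeroing M2 inhibition reproduces the P+M1 scenario", {
  vic <- load_victim("midazolam")
  cmps <- c(list(midazolam = vic), ketoconazole_compounds())
  doses <- c(regimen("ketoconazole", 400, 1),
             regimen("midazolam", 5, 1, start = 2))
  ind <- build_reference_individual()
  m_a <- pbpk_model(ind, cmps, doses, scenario = "P_M1")
  m_b <- pbpk_model(ind, cmps, doses, scenario = "P_M1_M2",
                    k_i_override = list(m2 = list("CYP3A4" = 1e15,
                                                  "P-gp" = 1e15)))
  r_a <- simulate_model(m_a, 14, grid = 0.5, rtol = FAST$rtol,
                        atol = FAST$atol)
  r_b <- simulate_model(m_b, 14, grid = 0.5, rtol = FAST$rtol,
                        atol = FAST$atol)
  auc_a <- auc_last(r_a$times, r_a$plasma[, "midazolam"])
  auc_b <- auc_last(r_b$times, r_b$plasma[, "midazolam"])
  expect_equal(auc_a, auc_b, tolerance = 1e-6)
})

test_that("scenario sweeps are tabulated, deterministic and order-free", {
  empty <- scenario_sweep("midazolam", gaps = numeric(0))
  expect_equal(nrow(empty), 0)
  tw <- cached("sweep_mid_0", scenario_sweep(
    "midazolam", gaps = 0, scenarios = c("P", "P_M1_M2"), window = 8,
    grid = 0.5, rtol = FAST$rtol, atol = FAST$atol))
  tw2 <- scenario_sweep(
    "midazolam", gaps = 0, scenarios = c("P_M1_M2", "P"), window = 8,
    grid = 0.5, rtol = FAST$rtol, atol = FAST$atol)
  expect_equal(tw$auc_ratio[tw$scenario == "P"],
               tw2$auc_ratio[tw2$scenario == "P"])
  expect_equal(tw$auc_ratio[tw$scenario == "P_M1_M2"],
               tw2$auc_ratio[tw2$scenario == "P_M1_M2"])
  expect_true(all(tw$auc_ratio >= 1 - 1e-6))
})
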