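test_that("shipped parameter sets load with the published constants", {
  ktz <- load_compound("ketoconazole")
  m1 <- load_compound("m1")
  m2 <- load_compound("m2")
  expect_equal(ktz$fu, 0.01)          # 1.00 % fraction unbound
  ki <- function(cmp, target) {
    for (i in cmp$inhibitions)
      if (i$target_protein == target) return(i$K_i)
    NA_real_
  }
  expect_equal(ki(ktz, "CYP3A4"), 0.008)
  expect_equal(ki(ktz, "P-gp"), 0.035)
  expect_equal(ki(m1, "CYP3A4"), 0.022)
  expect_equal(ki(m1, "P-gp"), 0.119)
  # M2 inhibition constants are surrogated from M1
  expect_equal(ki(m2, "CYP3A4"), ki(m1, "CYP3A4"))
  expect_equal(ki(m2, "P-gp"), ki(m1, "P-gp"))
  expect_true(m2$plasma_restricted)
  # K_M surrogacy: the autoinhibition K_i doubles as the K_M
  km <- function(cmp, protein) {
    for (p in cmp$processes) if (p$protein == protein) return(p$K_M)
    NA_real_
  }
  expect_equal(km(ktz, "CYP3A4"), ki(ktz, "CYP3A4"))
  expect_equal(km(ktz, "P-gp"), ki(ktz, "P-gp"))
  expect_equal(km(ktz, "AADAC"), 1.88)
})

test_that("violating the K_M = K_i surrogacy is rejected at load time", {
  x <- yaml::read_yaml(system.file("extdata", "compounds",
                                   "ketoconazole.yaml",
                                   package = "ketopbpk"))
  x$processes[[2]]$K_M <- 0.5  # CYP3A4 K_M decoupled from K_i
  expect_error(ketopbpk:::.compound_from_list(x), "surrogacy")
})

test_that("ionized fractions follow Henderson-Hasselbalch", {
  one_base <- compound("b", MW = 300, pKa = list(list(value = 6.51,
                                                      type = "base")),
                       solubility = list(list(pH = 7, mg_per_L = 10)),
                       logP = 1, fu = 0.5)
  fr <- ionized_fractions(one_base, 6.51)
  expect_equal(fr[["cationic"]], 0.5, tolerance = 1e-12)
  ktz <- load_compound("ketoconazole")
  expect_gte(ionized_fractions(ktz, 10)[["neutral"]], 0.99)
  for (ph in c(1, 3.3, 7.4, 12))
    expect_equal(sum(ionized_fractions(ktz, ph)), 1, tolerance = 1e-12)
  expect_error(ionized_fractions(ktz, 15), "pH")
})

test_that("solubility interpolates log-linearly and extrapolates flat", {
  ktz <- load_compound("ketoconazole")
  expect_equal(solubility_at_ph(ktz, 7), 5.40)
  expect_equal(solubility_at_ph(ktz, 1.2), 2.03e4)
  # midpoint of a log-linear segment is the geometric mean of its ends
  expect_equal(solubility_at_ph(ktz, 7.25), sqrt(5.40 * 6.00),
               tolerance = 1e-10)
  s725 <- solubility_at_ph(ktz, 7.25)
  expect_true(s725 > 5.40 && s725 < 6.00)
  expect_equal(solubility_at_ph(ktz, 0.5), 2.03e4)   # below table
  expect_equal(solubility_at_ph(ktz, 9), 6.00)       # above table
})

test_that("partition methods behave in limiting cases and differ", {
  ind <- build_reference_individual()
  water_organ <- ind$organs[ind$organs$name == "muscle", , drop = FALSE]
  water_organ$f_water <- 1
  water_organ$f_neutral_lipid <- 0
  water_organ$f_phospholipid <- 0
  neutral <- compound("n", MW = 300, logP = 0, fu = 1,
                      solubility = list(list(pH = 7, mg_per_L = 10)))
  expect_equal(partition_coefficient(neutral, water_organ), 1,
               tolerance = 0.06)
  # Kp non-decreasing in logP in a lipid-containing organ
  kps <- vapply(seq(-1, 5, by = 0.5), function(lp) {
    cmp <- compound("n", MW = 300, logP = lp, fu = 1,
                    solubility = list(list(pH = 7, mg_per_L = 10)))
    partition_coefficient(cmp, "liver", individual = ind)
  }, numeric(1))
  expect_true(all(diff(kps) >= 0))
  # the three methods give distinct values for an ionizable compound
  ktz <- load_compound("ketoconazole")
  v <- vapply(c("Berezhkovskiy", "RodgersRowland",
                "SchmittChargeDependent"), function(m)
    partition_coefficient(ktz, "liver", method = m, individual = ind),
    numeric(1))
  expect_gt(min(v), 0)
  expect_equal(length(unique(round(v, 8))), 3)
})

test_that("cellular permeability is monotone in logP and MW", {
  perm <- function(lp, mw)
    cellular_permeability(compound("x", MW = mw, logP = lp, fu = 1,
      solubility = list(list(pH = 7, mg_per_L = 1))))
  ps <- vapply(seq(0, 4, 0.5), perm, numeric(1), mw = 400)
  expect_true(all(diff(ps) > 0))
  ps_mw <- vapply(c(200, 300, 450, 600), function(mw) perm(2, mw),
                  numeric(1))
  expect_true(all(diff(ps_mw) < 0))
  expect_identical(perm(2.5, 500), perm(2.5, 500))
  # the charge-dependent variant penalizes ionized compounds
  m1 <- load_compound("m1")
  expect_lt(cellular_permeability(m1),
            cellular_permeability(m1, method = "PKSimStandard"))
})
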