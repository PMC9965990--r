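make_small_study <- function(id = "s1", dose = 200) {
  synthetic_study(id, regimen("ketoconazole", dose, 1,
                              formulation = formulation("solution")),
                  sampling_times = c(0.5, 1, 2, 4, 8, 12),
                  n_subjects = 12)
}

test_that("noise-free generation reproduces the truth simulation exactly", {
  st <- make_small_study()
  profs <- cached("synth_cv0", generate_observed_profiles(
    st, error_model(cv = 0, loq = 0), rtol = FAST$rtol, atol = FAST$atol))
  ktz <- profs$ketoconazole
  expect_equal(ktz$conc, attr(ktz, "truth"), tolerance = 1e-12)
  expect_equal(ktz$times, st$sampling_times)
  expect_equal(attr(ktz, "n_censored"), 0)
})

test_that("generation is reproducible for a fixed seed and censors at LOQ", {
  st <- make_small_study()
  em <- error_model(cv = 0.2, loq = 1, seed = 7)
  a <- generate_observed_profiles(st, em, rtol = FAST$rtol,
                                  atol = FAST$atol)
  b <- generate_observed_profiles(st, em, rtol = FAST$rtol,
                                  atol = FAST$atol)
  expect_identical(a$ketoconazole$conc, b$ketoconazole$conc)
  expect_identical(a$m1$conc, b$m1$conc)
  # raising the LOQ never increases the number of retained points
  hi <- generate_observed_profiles(st, error_model(cv = 0.2, loq = 50,
                                                   seed = 7),
                                   rtol = FAST$rtol, atol = FAST$atol)
  expect_lte(length(hi$ketoconazole$times), length(a$ketoconazole$times))
  expect_lte(length(hi$m1$times), length(a$m1$times))
  # M1 runs close to its LOQ, so censoring engages there
  expect_gt(attr(hi$m1, "n_censored"), 0)
})

test_that("M2 is never a measurable compound", {
  expect_error(synthetic_study("bad", regimen("ketoconazole", 200, 1),
                               c(1, 2), compounds = c("ketoconazole",
                                                      "m2")),
               "plasma")
})

test_that("mean-of-n noise keeps profile-level MRD small", {
  st <- make_small_study()
  base <- cached("synth_cv0", generate_observed_profiles(
    st, error_model(cv = 0, loq = 0), rtol = FAST$rtol, atol = FAST$atol))
  truth <- base$ketoconazole$conc
  # apply the error model repeatedly to the fixed truth (no re-simulation)
  mrds <- vapply(1:50, function(s) {
    set.seed(s)
    noisy <- ketopbpk:::.apply_noise(truth, error_model(cv = 0.2),
                                     n_subjects = 12)
    mrd(truth, noisy)
  }, numeric(1))
  expect_lt(mean(mrds), 1.3)
})

test_that("study tables mask prandial states recoverably", {
  tab0 <- generate_study_table(40, missing_state_fraction = 0, seed = 3)
  expect_false(any(tab0$declared_state == "unknown"))
  tab <- generate_study_table(40, missing_state_fraction = 0.5, seed = 3)
  expect_identical(tab, generate_study_table(40, 0.5, seed = 3))
  expect_gt(sum(tab$declared_state == "unknown"), 0)
  # the deterministic rules recover every study whose metadata fires them
  resolved <- mapply(resolve_prandial_state, tab$observed_tmax,
                     tab$doses_per_day, tab$dose,
                     ifelse(tab$declared_state == "unknown", "unknown",
                            tab$declared_state))
  rule_fed <- tab$observed_tmax > 2 | tab$doses_per_day > 1 |
    tab$dose >= 800
  unk <- tab$declared_state == "unknown"
  expect_true(all(resolved[unk & rule_fed] == "fed"))
  expect_true(all(resolved[unk & !rule_fed] == "fasted"))
  expect_true(all(resolved[!unk] == tab$declared_state[!unk]))
})

test_that("paired DDI datasets reproduce the truth ratio and design", {
  vic <- load_victim("midazolam")
  scen <- ddi_scenario(vic, "P_M1_M2",
                       regimen("ketoconazole", 400, 1),
                       regimen("midazolam", 5, 1, start = 1))
  ds <- cached("ddi_ds_cv0", generate_ddi_dataset(
    scen, error_model(cv = 0, loq = 0),
    sampling_times = c(0.5, 1, 2, 4, 8, 12),
    rtol = FAST$rtol, atol = FAST$atol))
  # noise-free: recomputed ratio equals the truth ratio to machine precision
  rr <- auc_last(ds$effect$times, ds$effect$conc) /
    auc_last(ds$reference$times, ds$reference$conc)
  expect_equal(rr, ds$truth_ratio, tolerance = 1e-12)
  expect_gt(ds$truth_ratio, 1)
  # the reference arm carries no perpetrator doses
  expect_false(any(vapply(ds$reference$regimen, `[[`, character(1),
                          "compound") == "ketoconazole"))
  # noisy ratios stay inside the Guest band of the truth in >= 90% of seeds
  inside <- vapply(1:100, function(s) {
    set.seed(s)
    em <- error_model(cv = 0.2)
    eff <- ketopbpk:::.apply_noise(attr(ds$effect, "truth"), em, 12)
    ref <- ketopbpk:::.apply_noise(attr(ds$reference, "truth"), em, 12)
    r <- auc_last(ds$effect$times, eff) / auc_last(ds$reference$times, ref)
    gl <- guest_limits(ds$truth_ratio)
    r >= gl[["lower"]] && r <= gl[["upper"]]
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})
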