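test_that("trapezoidal AUC is exact on piecewise-linear profiles", {
  expect_equal(auc_last(c(0, 10), c(1, 1)), 10)
  expect_equal(auc_last(c(0, 1, 2), c(0, 2, 0)), 2)
  # collinear midpoint leaves the integral unchanged
  expect_equal(auc_last(c(0, 0.5, 1, 2), c(0, 1, 2, 0)),
               auc_last(c(0, 1, 2), c(0, 2, 0)))
  expect_error(auc_last(1, 5), "two points")
  expect_error(auc_last(c(0, 0), c(1, 1)), "increasing")
})

test_that("Cmax/Tmax honor first-occurrence tie-break and flag degeneracy", {
  expect_equal(unname(cmax_tmax(c(0, 1, 2), c(0, 5, 3))), c(5, 1))
  tie <- cmax_tmax(c(0, 1, 2, 3), c(0, 4, 4, 1))
  expect_equal(unname(tie["tmax"]), 1)
  z <- cmax_tmax(c(0, 1), c(0, 0))
  expect_equal(unname(z), c(0, 0), ignore_attr = TRUE)
  expect_true(isTRUE(attr(z, "degenerate")))
})

test_that("terminal half-life recovers exponential decay", {
  tt <- seq(0, 48, by = 2)
  cc <- 100 * exp(-0.1 * tt)
  expect_equal(terminal_half_life(tt, cc), log(2) / 0.1, tolerance = 1e-8)
  # proportional noise: recovery within 10%
  set.seed(42)
  noisy <- cc * exp(rnorm(length(cc), 0, 0.05))
  expect_equal(terminal_half_life(tt, noisy, n_terminal = 10),
               log(2) / 0.1, tolerance = 0.1)
  expect_warning(th <- terminal_half_life(c(0, 1, 2, 3, 4),
                                          c(5, 4, 0, 0, 0)), "terminal")
  expect_true(is.na(th))
})

test_that("MRD and GMFE identities, examples and invariances hold", {
  expect_equal(mrd(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(mrd(10, 100), 10)
  expect_equal(mrd(c(10, 100), c(100, 10)), 10)
  expect_equal(gmfe(c(5, 7), c(5, 7)), 1)
  expect_equal(gmfe(c(100, 100), c(200, 50)), 2)
  expect_equal(gmfe(100, 137), 1.37)
  o <- c(3, 8, 20); p <- c(4, 6, 30)
  # scale invariance and prediction/observation symmetry
  expect_equal(mrd(o, p), mrd(10 * o, 10 * p))
  expect_equal(mrd(o, p), mrd(p, o))
  expect_equal(gmfe(o, p), gmfe(10 * o, 10 * p))
  expect_equal(gmfe(o, p), gmfe(p, o))
  expect_error(mrd(c(1, 0), c(1, 1)), "index 2")
  expect_error(gmfe(numeric(0), numeric(0)), "empty")
})

test_that("Guest limits reproduce the published band geometry", {
  expect_equal(guest_limits(1), c(lower = 0.8, upper = 1.25))
  # large ratios approach the two-fold criterion
  gl <- guest_limits(1e6)
  expect_equal(gl[["upper"]] / 1e6, 2, tolerance = 1e-5)
  # reciprocal symmetry of the band
  r <- 1.7
  gl_r <- guest_limits(r); gl_inv <- guest_limits(1 / r)
  expect_equal(gl_r[["lower"]], 1 / gl_inv[["upper"]], tolerance = 1e-12)
  expect_equal(gl_r[["upper"]], 1 / gl_inv[["lower"]], tolerance = 1e-12)
  # band nested in the two-fold band and containing the observed ratio
  for (r in c(0.3, 0.8, 1, 1.9, 5)) {
    gl <- guest_limits(r)
    expect_gte(gl[["lower"]], r / 2 - 1e-12)
    expect_lte(gl[["upper"]], r * 2 + 1e-12)
    expect_true(r >= gl[["lower"]] && r <= gl[["upper"]])
  }
})

test_that("two-fold criterion is boundary-inclusive", {
  expect_true(within_twofold(2, 1))
  expect_false(within_twofold(2.01, 1))
  expect_true(within_twofold(1, 1))
  expect_true(within_twofold(0.5, 1))
})

test_that("interaction ratios are plain quotients with validation", {
  r <- interaction_ratio(150, 100)
  expect_equal(r$ratio, 1.5)
  expect_equal(interaction_ratio(7, 7)$ratio, 1)
  expect_error(interaction_ratio(5, 0), "positive")
})
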