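test_that("fed-state assumption rules fire as specified", {
  # rule (i): Tmax delayed beyond two hours
  expect_equal(resolve_prandial_state(4, 1, 200, "unknown"), "fed")
  # rule (ii): multiple doses per day
  expect_equal(resolve_prandial_state(NA, 2, 200, "unknown"), "fed")
  # rule (iii): single tablet doses of 800 mg or more
  expect_equal(resolve_prandial_state(NA, 1, 800, "unknown"), "fed")
  # no rule fires
  expect_equal(resolve_prandial_state(1.5, 1, 200, "unknown"), "fasted")
  # declared states pass through regardless of the rules
  expect_equal(resolve_prandial_state(4, 2, 800, "fasted"), "fasted")
  expect_equal(resolve_prandial_state(1, 1, 100, "fed"), "fed")
})

test_that("GI tract defaults encode the prandial parametrization", {
  fa <- default_gi_tract("fasted")
  fe <- default_gi_tract("fed")
  expect_equal(fa$GET, 15)
  expect_equal(fe$GET, 45)
  expect_true(all(fa$segments$pH >= 1 & fa$segments$pH <= 8.5))
  expect_true(all(fa$segments$transit > 0))
  # only the stomach differs between prandial states
  expect_equal(fa$segments[-1, ], fe$segments[-1, ])
})

test_that("formulations discretize the particle distribution correctly", {
  tab <- formulation("tablet")
  expect_equal(sum(tab$particle_bins$mass_fraction), 1, tolerance = 1e-12)
  expect_true(all(tab$particle_bins$radius > 0))
  sol <- formulation("solution")
  expect_true(all(sol$particle_bins$radius < 0.002))
  expect_error(formulation("tablet", median_radius = -5), "positive")
})

test_that("dissolution rate follows Noyes-Whitney with no precipitation", {
  # saturation: zero driving force
  expect_equal(dissolution_rate(10, 100, 50, 50, MW = 531.43), 0)
  # supersaturation never precipitates (rate clipped at zero)
  expect_equal(dissolution_rate(10, 100, 50, 500, MW = 531.43), 0)
  # no solid left -> no flux
  expect_equal(dissolution_rate(0, 100, 50, 0, MW = 531.43), 0)
  # halving the radius (at fixed mass) increases the specific surface
  r_small <- dissolution_rate(10, 50, 50, 0, MW = 531.43)
  r_big <- dissolution_rate(10, 100, 50, 0, MW = 531.43)
  expect_gt(r_small, r_big)
  # linear in the solubility gap
  expect_equal(dissolution_rate(10, 100, 40, 0, MW = 531.43),
               2 * dissolution_rate(10, 100, 20, 0, MW = 531.43))
})

test_that("dose events validate and regimens expand", {
  expect_error(dose_event("ketoconazole", -1), "dose")
  expect_error(dose_event("ketoconazole", 100, time = -1), "time")
  reg <- regimen("ketoconazole", 200, n_doses = 3, interval = 12)
  expect_length(reg, 3)
  expect_equal(vapply(reg, `[[`, numeric(1), "time"), c(0, 12, 24))
})
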