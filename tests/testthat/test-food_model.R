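# Food groups, presets, energy gate and dose-response change-HRs.

test_that("the three diet presets reproduce the published intake list", {
  tw <- preset_diet("TW")$intake
  fa <- preset_diet("FA")$intake
  od <- preset_diet("OD")$intake

  expected_tw <- c(
    whole_grains = 50, vegetables = 250, fruits = 200, nuts = 0, legumes = 0,
    fish = 50, eggs = 50, milk_dairy = 300, refined_grains = 150,
    red_meat = 100, processed_meat = 50, white_meat = 75, ssb = 500,
    added_oils = 25
  )
  expected_od <- c(
    whole_grains = 225, vegetables = 400, fruits = 400, nuts = 25,
    legumes = 200, fish = 200, eggs = 25, milk_dairy = 200,
    refined_grains = 50, red_meat = 0, processed_meat = 0, white_meat = 50,
    ssb = 0, added_oils = 25
  )
  expect_equal(tw[names(expected_tw)], expected_tw)
  expect_equal(od[names(expected_od)], expected_od)
  # FA is the per-group TW-OD midpoint for every group (fish 125 g).
  expect_equal(fa, (tw + od) / 2)
  expect_equal(fa[["whole_grains"]], 137.5)
  expect_equal(fa[["fish"]], 125)
  expect_error(preset_diet("mediterranean"), "TW, FA, OD")
})

test_that("presets round-trip through JSON serialization unchanged", {
  for (nm in c("TW", "FA", "OD")) {
    p <- preset_diet(nm)
    path <- withr::local_tempfile(fileext = ".json")
    write_diet_profile(p, path)
    back <- read_diet_profile(path)
    expect_equal(back$intake, p$intake)
    expect_equal(back$label, p$label)
  }
})

test_that("diet profiles enforce full coverage and non-negative intakes", {
  good <- preset_diet("TW")$intake
  expect_error(diet_profile(good[-1]), "missing")
  expect_error(diet_profile(c(good, junk_food = 10)), "unknown")
  bad <- good; bad[["fish"]] <- -1
  expect_error(diet_profile(bad), ">= 0")
})

test_that("total energy is the intake-weighted density sum and matches the published preset totals", {
  zero <- diet_profile(setNames(rep(0, 14), food_groups()), "zero")
  expect_identical(total_energy(zero), 0)

  one <- zero
  one$intake[["fish"]] <- 100
  dens <- setNames(rep(0, 14), food_groups()); dens[["fish"]] <- 10
  expect_equal(total_energy(one, dens), 1000)

  # Calibrated density table reproduces the published 8,085/7,850/7,615 kJ/day.
  expect_equal(total_energy(preset_diet("TW")), 8085, tolerance = 1 / 8085)
  expect_equal(total_energy(preset_diet("FA")), 7850, tolerance = 1 / 7850)
  expect_equal(total_energy(preset_diet("OD")), 7615, tolerance = 1 / 7615)

  expect_error(total_energy(preset_diet("TW"), dens[-1]), "missing")
})

test_that("energy gate rejects strictly below 4,000 and above 16,000 kJ/day", {
  diet_with_energy <- function(kj) {
    x <- setNames(rep(0, 14), food_groups())
    x[["ssb"]] <- kj / default_energy_densities()[["ssb"]]
    diet_profile(x, sprintf("%g kJ", kj))
  }
  expect_identical(check_energy_gate(diet_with_energy(3999)), "reject_low")
  expect_identical(check_energy_gate(diet_with_energy(16001)), "reject_high")
  expect_identical(check_energy_gate(diet_with_energy(4000)), "pass")
  expect_identical(check_energy_gate(diet_with_energy(16000)), "pass")
  expect_identical(check_energy_gate(preset_diet("TW")), "pass")
})

test_that("energy gate is monotone under scaling all intakes", {
  verdict_rank <- c(reject_low = 1, pass = 2, reject_high = 3)
  base <- preset_diet("TW")
  scales <- c(0.1, 0.4, 0.5, 1, 1.9, 2, 3)
  verdicts <- vapply(scales, function(s) {
    check_energy_gate(diet_profile(base$intake * s, "scaled"))
  }, character(1))
  expect_true(all(diff(verdict_rank[verdicts]) >= 0))
})

test_that("change-HR uses linear interpolation and plateau extrapolation", {
  cv <- dose_response_curve("nuts", dose = c(0, 100), hr = c(1, 0.8))
  expect_equal(hazard_ratio_for_change(cv, 50, 50),
               c(hr = 1, hr_lo = 1, hr_hi = 1))
  expect_equal(hazard_ratio_for_change(cv, 0, 50)[["hr"]], 0.9)
  expect_equal(hazard_ratio_for_change(cv, 0, 250)[["hr"]], 0.8)
  expect_error(hazard_ratio_for_change(cv, -1, 50), ">= 0")

  neutral <- dose_response_curve("white_meat", 0, 1, neutral = TRUE)
  expect_equal(hazard_ratio_for_change(neutral, 0, 500),
               c(hr = 1, hr_lo = 1, hr_hi = 1))
})

test_that("change-HR satisfies ratio symmetry and collinear-point invariance", {
  cv <- dose_response_curve("legumes", dose = c(0, 50, 200),
                            hr = c(1, 0.95, 0.84),
                            ci_lo = c(1, 0.90, 0.76),
                            ci_hi = c(1, 1.00, 0.92))
  doses <- c(0, 10, 50, 125, 200, 400)
  for (a in doses) for (b in doses) {
    fwd <- hazard_ratio_for_change(cv, a, b)
    bwd <- hazard_ratio_for_change(cv, b, a)
    expect_equal(fwd[["hr"]] * bwd[["hr"]], 1, tolerance = 1e-12)
    expect_equal(fwd[["hr_lo"]] * bwd[["hr_lo"]], 1, tolerance = 1e-12)
    expect_equal(fwd[["hr_hi"]] * bwd[["hr_hi"]], 1, tolerance = 1e-12)
  }

  # A redundant point collinear with its neighbours (dose 25, midway on the
  # 0->50 segment of every band) must not change any change-HR.
  with_collinear <- dose_response_curve(
    "legumes", dose = c(0, 25, 50, 200),
    hr = c(1, 0.975, 0.95, 0.84),
    ci_lo = c(1, 0.95, 0.90, 0.76),
    ci_hi = c(1, 1.00, 1.00, 0.92)
  )
  for (a in doses) for (b in doses) {
    expect_equal(hazard_ratio_for_change(with_collinear, a, b)[["hr"]],
                 hazard_ratio_for_change(cv, a, b)[["hr"]], tolerance = 1e-12)
  }
})

test_that("curve validation enforces ordering and band containment", {
  expect_error(dose_response_curve("nuts", c(0, 0), c(1, 0.8)),
               "strictly increasing")
  expect_error(dose_response_curve("nuts", c(0, 100), c(1, 0.8),
                                   ci_lo = c(1, 0.85), ci_hi = c(1, 0.9)),
               "ci_lo <= hr <= ci_hi")
  expect_error(dose_response_curve("chocolate", c(0, 10), c(1, 1)),
               "unknown food group")
  expect_error(dose_response_curve("nuts", c(0, 100), c(1, -0.2)), "positive")
})

test_that("curve sets round-trip through the CSV table format", {
  cs <- make_curveset()
  pts <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".csv")
  write_hr_table(cs, pts, meta)
  back <- read_hr_table(pts, meta)
  expect_setequal(names(back), food_groups())
  for (g in food_groups()) {
    expect_equal(back[[g]]$points, cs[[g]]$points, ignore_attr = TRUE)
    expect_identical(back[[g]]$neutral, cs[[g]]$neutral)
    expect_equal(back[[g]]$nutrigrade, cs[[g]]$nutrigrade)
  }
})
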