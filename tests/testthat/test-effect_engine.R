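# Scenario -> hazard trajectory -> life-expectancy gains.

test_that("ramp fraction is linear with saturation", {
  expect_equal(ramp_fraction(2, 10), 0.2)
  expect_equal(ramp_fraction(0, 10), 0)
  expect_equal(ramp_fraction(37, 10), 1)
  expect_equal(ramp_fraction(c(1, 5, 10, 20), 10), c(0.1, 0.5, 1, 1))
  expect_error(ramp_fraction(-1, 10), ">= 0")
  expect_error(ramp_fraction(1, 0), "> 0")
})

test_that("combined HR is the product of per-group change HRs", {
  cs <- toy_curves()
  d <- toy_diets()
  # nuts 0 -> 100 contributes 0.8; red_meat 100 -> 0 contributes 1/1.25 = 0.8
  expect_equal(combined_hr(cs, d$baseline, d$target), 0.8 * 0.8,
               tolerance = 1e-12)
  # identical diets: empty change
  expect_equal(combined_hr(cs, d$baseline, d$baseline), 1)
  # neutral groups contribute exactly 1
  all_neutral <- curve_set(lapply(food_groups(), function(g)
    dose_response_curve(g, 0, 1, neutral = TRUE)))
  expect_equal(combined_hr(all_neutral, preset_diet("TW"), preset_diet("OD")), 1)
  # missing curve for a requested group
  expect_error(combined_hr(curve_set(cs[1:13]), d$baseline, d$target),
               "no dose-response curve")
})

test_that("hazard trajectory samples the ramp at year midpoints", {
  traj <- hazard_trajectory(0.8, change_age = 20, T_full = 10, max_age = 60)
  expect_equal(traj[["20"]], 1 + 0.05 * (0.8 - 1))  # t = 0.5 -> f = 0.05
  expect_equal(traj[["25"]], 1 + 0.55 * (0.8 - 1))
  expect_equal(traj[["40"]], 0.8)                   # post-saturation
  expect_equal(unname(hazard_trajectory(1, 20, 10, 60)), rep(1, 41))
  expect_error(hazard_trajectory(0, 20, 10, 60), "> 0")
})

test_that("null change yields exactly zero gain", {
  sc <- diet_change_scenario(preset_diet("TW"), preset_diet("TW"), 30)
  res <- gain_in_le(sc, make_schedule(), make_curveset())
  expect_identical(res$gain, 0)
  expect_equal(res$hr_full, 1)
})

test_that("gain matches an independent brute-force life table for an instant effect", {
  # Constant-rate schedule, hr_full = 0.8 applied immediately (T ~ 0): the
  # gain must equal the difference of two independently computed life tables.
  sched <- const_schedule(0.01, 20L, 110L)
  d <- toy_diets()
  cs <- toy_curves()
  sc <- diet_change_scenario(d$baseline, d$target, 20,
                             time_to_full_effect = 1e-9)
  res <- gain_in_le(sc, sched, cs)

  hr <- 0.64  # 0.8 * 0.8, verified above
  le0 <- brute_force_le(sched$rate, sched$age, 20)
  le1 <- brute_force_le(sched$rate * hr, sched$age, 20)
  expect_equal(res$gain, le1 - le0, tolerance = 1e-9)
  expect_equal(res$le_baseline, le0, tolerance = 1e-12)
})

test_that("longer time to full effect never increases a protective gain", {
  sched <- make_schedule()
  base <- preset_diet("TW"); target <- preset_diet("OD")
  cs <- make_curveset()
  for (age in c(20, 50, 80)) {
    gains <- vapply(c(5, 10, 30, 50), function(T_full) {
      sc <- diet_change_scenario(base, target, age, T_full)
      gain_in_le(sc, sched, cs)$gain
    }, numeric(1))
    expect_true(all(diff(gains) < 0))
  }
})

test_that("gains shrink with the age at change on a senescent schedule", {
  sched <- make_schedule()
  cs <- make_curveset()
  gains <- vapply(seq(20, 80, by = 10), function(a) {
    sc <- diet_change_scenario(preset_diet("TW"), preset_diet("OD"), a)
    gain_in_le(sc, sched, cs)$gain
  }, numeric(1))
  expect_true(all(diff(gains) < 0))
})

test_that("per-group gains isolate one group against the baseline", {
  sched <- make_schedule()
  cs <- make_curveset()

  same <- diet_change_scenario(preset_diet("TW"), preset_diet("TW"), 40)
  expect_true(all(per_group_gains(same, sched, cs) == 0))

  # changing a single group: its per-group gain IS the total gain
  d <- toy_diets()
  one <- d$baseline
  one$intake[["nuts"]] <- 100
  sc1 <- diet_change_scenario(d$baseline, diet_profile(one$intake, "one"), 40)
  pg <- per_group_gains(sc1, sched, toy_curves())
  expect_equal(pg[["nuts"]], gain_in_le(sc1, sched, toy_curves())$gain)
  expect_true(all(pg[setdiff(food_groups(), "nuts")] == 0))

  # neutral groups report exactly zero in a full change
  full <- diet_change_scenario(preset_diet("TW"), preset_diet("OD"), 40)
  pg_full <- per_group_gains(full, sched, cs)
  expect_identical(pg_full[["white_meat"]], 0)
  expect_identical(pg_full[["added_oils"]], 0)

  # near-additivity: per-group gains sum close to (but not exactly) the total
  total <- gain_in_le(full, sched, cs)$gain
  expect_false(isTRUE(all.equal(sum(pg_full), total)))
  expect_lt(abs(sum(pg_full) - total) / total, 0.10)
})

test_that("reciprocal swap scales post-saturation rates reciprocally", {
  sched <- const_schedule(0.01, 20L, 110L)
  d <- toy_diets()
  cs <- toy_curves()
  fwd <- diet_change_scenario(d$baseline, d$target, 20, 10)
  bwd <- diet_change_scenario(d$target, d$baseline, 20, 10)
  hr_f <- combined_hr(cs, d$baseline, d$target)
  hr_b <- combined_hr(cs, d$target, d$baseline)
  expect_equal(hr_f * hr_b, 1, tolerance = 1e-12)
  mod_f <- apply_hazard_trajectory(sched, 20,
                                   hazard_trajectory(hr_f, 20, 10, 110))
  mod_b <- apply_hazard_trajectory(sched, 20,
                                   hazard_trajectory(hr_b, 20, 10, 110))
  sat <- sched$age >= 30  # ramp saturated
  expect_equal(mod_f$rate[sat] * mod_b$rate[sat] / sched$rate[sat]^2,
               rep(1, sum(sat)), tolerance = 1e-12)
})

test_that("the energy gate blocks gain computations with a named refusal", {
  x <- setNames(rep(0, 14), food_groups())
  starve <- diet_profile(x, "starvation")
  sc <- diet_change_scenario(preset_diet("TW"), starve, 40)
  expect_error(
    gain_in_le(sc, make_schedule(), make_curveset(),
               densities = default_energy_densities()),
    class = "dietspan_energy_gate"
  )
  expect_error(
    gain_in_le(sc, make_schedule(), make_curveset(),
               densities = default_energy_densities()),
    "estimates not reported"
  )
  # without densities the gate is not applied
  expect_no_error(gain_in_le(sc, make_schedule(), make_curveset()))
})
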