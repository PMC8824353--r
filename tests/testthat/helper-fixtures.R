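# Shared fixtures, built in code at test time.

# Constant-rate schedule over ages `from:to`.
const_schedule <- function(m, from = 0L, to = 110L, sex = "female") {
  mortality_schedule(from:to, rep(m, to - from + 1L), sex = sex)
}

# Schedule with a chosen constant annual death probability q (inverts the
# q = m / (1 + 0.5 m) conversion).
const_q_schedule <- function(q, from = 0L, to = 110L) {
  const_schedule(q / (1 - 0.5 * q), from, to)
}

# A two-group toy curve set: one protective, one harmful, rest neutral.
toy_curves <- function(halfwidth = 0.05) {
  protective <- dose_response_curve(
    "nuts", dose = c(0, 100), hr = c(1, 0.8),
    ci_lo = c(1, 0.8 - halfwidth), ci_hi = c(1, 0.8 + halfwidth),
    nutrigrade = 7
  )
  harmful <- dose_response_curve(
    "red_meat", dose = c(0, 100), hr = c(1, 1.25),
    ci_lo = c(1, 1.25 - halfwidth), ci_hi = c(1, 1.25 + halfwidth),
    nutrigrade = 6.5
  )
  rest <- lapply(setdiff(food_groups(), c("nuts", "red_meat")),
                 function(g) dose_response_curve(g, 0, 1, neutral = TRUE))
  curve_set(c(list(protective, harmful), rest))
}

# Diet pair that changes only the toy groups: nuts 0 -> 100 (protective),
# red_meat 100 -> 0 (protective direction on a harmful curve).
toy_diets <- function() {
  base <- preset_diet("TW")$intake
  base["nuts"] <- 0; base["red_meat"] <- 100
  target <- base
  target["nuts"] <- 100; target["red_meat"] <- 0
  list(baseline = diet_profile(base, "toy_base"),
       target = diet_profile(target, "toy_target"))
}

# Independent brute-force period life table, written against the documented
# conventions (q = m/(1+0.5m) capped at 1, half-year death credit, l/m
# terminal interval). Deliberately a plain loop, separate from the package's
# vectorised implementation.
brute_force_le <- function(rates, ages, at) {
  stopifnot(length(rates) == length(ages))
  i0 <- match(at, ages)
  l <- 1
  total <- 0
  for (i in i0:length(ages)) {
    if (i == length(ages)) {
      total <- total + l / rates[i]
    } else {
      q <- min(rates[i] / (1 + 0.5 * rates[i]), 1)
      total <- total + l * (1 - q) + l * q * 0.5
      l <- l * (1 - q)
    }
  }
  total
}
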