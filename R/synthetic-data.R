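# Synthetic fixtures: Gompertz-Makeham mortality schedules, a default
# dose-response curve set, and a brute-force cohort simulation oracle.
# Everything here is generated, clearly-labelled stand-in data: it emulates
# the structure of public mortality extracts and meta-analytic hazard-ratio
# tables without reproducing either.

#' Gompertz-Makeham hazard parameters
#'
#' Adult all-cause mortality is well described by the Gompertz-Makeham
#' hazard `h(x) = c + a exp(b x)`: a constant background rate plus an
#' exponentially age-increasing senescent term.
#'
#' @param makeham Background hazard `c` per year, >= 0.
#' @param gompertz_a Senescent scale `a`, > 0.
#' @param gompertz_b Senescent shape `b` per year of age, > 0.
#' @param max_age Closure age of generated schedules.
#' @return Object of class `gompertz_makeham_params`.
#' @export
gompertz_makeham_params <- function(makeham = 5e-4, gompertz_a = 3e-5,
                                    gompertz_b = 0.095, max_age = 110L) {
  stopifnot(makeham >= 0, gompertz_a > 0, gompertz_b > 0, max_age >= 1)
  structure(list(makeham = makeham, gompertz_a = gompertz_a,
                 gompertz_b = gompertz_b, max_age = as.integer(max_age)),
            class = "gompertz_makeham_params")
}

#' Generate a synthetic single-year mortality schedule
#'
#' Rates `m_x = c + a exp(b x)` for ages 0 through `params$max_age`. The
#' default parameters are chosen so that remaining life expectancy at age 20
#' falls in the realistic adult range (roughly 58-63 years); the schedule is
#' synthetic, not an extract of any published life table.
#'
#' @param params A [gompertz_makeham_params()].
#' @param sex,region Labels attached to the schedule.
#' @return A [mortality_schedule()].
#' @export
make_schedule <- function(params = gompertz_makeham_params(),
                          sex = c("female", "male"), region = "synthetic") {
  stopifnot(inherits(params, "gompertz_makeham_params"))
  sex <- match.arg(sex)
  ages <- 0:params$max_age
  m <- params$makeham + params$gompertz_a * exp(params$gompertz_b * ages)
  if (any(!is.finite(m))) stop("hazard overflows at high ages; reduce b or max_age",
                               call. = FALSE)
  mortality_schedule(ages, m, sex = sex, region = region)
}

#' Default synthetic dose-response effects
#'
#' Plateau hazard ratios and confidence half-widths for each food group,
#' emulating the structure of meta-analytic dose-response tables: protective
#' groups (HR < 1) plateau at the optimized-diet intake, harmful groups
#' (HR > 1) rise to their plateau at the typical-diet intake, and white meat
#' and added oils are neutral. The magnitudes are plausible for this
#' literature but are synthetic placeholders, NOT transcribed meta-analytic
#' estimates.
#'
#' @return data.frame with columns `group`, `plateau_dose`, `hr`, `halfwidth`.
#' @export
default_curve_effects <- function() {
  data.frame(
    group = c("whole_grains", "vegetables", "fruits", "nuts", "legumes",
              "fish", "eggs", "milk_dairy", "refined_grains", "red_meat",
              "processed_meat", "ssb"),
    plateau_dose = c(225, 400, 400, 25, 200, 200, 50, 300, 150, 100, 50, 500),
    hr = c(0.78, 0.85, 0.85, 0.85, 0.84, 0.88, 1.05, 1.04, 1.06, 1.12, 1.12, 1.10),
    halfwidth = c(0.06, 0.06, 0.06, 0.04, 0.08, 0.05, 0.05, 0.05, 0.05,
                  0.04, 0.04, 0.05),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic curve set
#'
#' Piecewise-linear curves from `(dose 0, HR 1)` to
#' `(plateau_dose, plateau HR)` with symmetric confidence bands that widen
#' linearly from zero at dose 0 to `halfwidth` at the plateau. White meat and
#' added oils are always included as neutral curves. NutriGrade scores are
#' attached from [default_nutrigrade_scores()].
#'
#' @param effects data.frame as [default_curve_effects()]; one row per
#'   non-neutral group with `group`, `plateau_dose`, `hr` (> 0), `halfwidth`
#'   (>= 0).
#' @param seed Unused (generation is deterministic); accepted so fixture
#'   builders can pass a common seed argument everywhere.
#' @return A [curve_set()] covering all 14 food groups.
#' @export
make_curveset <- function(effects = default_curve_effects(), seed = NULL) {
  stopifnot(all(c("group", "plateau_dose", "hr", "halfwidth") %in% names(effects)),
            all(effects$hr > 0), all(effects$halfwidth >= 0))
  scores <- default_nutrigrade_scores()
  curves <- lapply(seq_len(nrow(effects)), function(i) {
    g <- effects$group[i]
    hw <- effects$halfwidth[i]
    hr <- c(1, effects$hr[i])
    dose_response_curve(
      g, dose = c(0, effects$plateau_dose[i]), hr = hr,
      ci_lo = hr - c(0, hw), ci_hi = hr + c(0, hw),
      nutrigrade = if (g %in% names(scores)) scores[[g]] else NA_real_
    )
  })
  for (g in setdiff(food_groups(), effects$group)) {
    curves <- c(curves, list(dose_response_curve(
      g, 0, 1, neutral = TRUE,
      nutrigrade = if (g %in% names(scores)) scores[[g]] else NA_real_
    )))
  }
  curve_set(curves)
}

#' Brute-force cohort simulation oracle
#'
#' Independently estimates remaining life expectancy by simulating `n`
#' individual lifetimes year by year: each year an individual alive at age
#' `a` dies with probability `q_a = m_a / (1 + 0.5 m_a)` (after applying the
#' hazard-multiplier trajectory, if any), earning half a year's credit in the
#' death year and a full year otherwise; survivors to the closure age draw an
#' exponential tail at the terminal rate. The sample mean should agree with
#' [life_expectancy()] within Monte-Carlo error, which is this package's
#' strongest correctness check on the analytic life table.
#'
#' @param schedule A [mortality_schedule()].
#' @param start_age Age from which lifetimes are simulated.
#' @param trajectory Optional hazard multipliers as accepted by
#'   [apply_hazard_trajectory()] (applied from `start_age`).
#' @param n Number of simulated individuals.
#' @param seed Integer seed.
#' @return List with `mean` (years), `se` (standard error of the mean), `n`.
#' @export
cohort_oracle <- function(schedule, start_age, trajectory = NULL,
                          n = 200000, seed = 1) {
  stopifnot(inherits(schedule, "mortality_schedule"), n >= 1)
  if (!is.null(trajectory)) {
    schedule <- apply_hazard_trajectory(schedule, start_age, trajectory)
  }
  m <- .schedule_tail(schedule, start_age)
  k <- length(m)
  q <- pmin(m / (1 + 0.5 * m), 1)
  .with_seed(seed, {
    years <- numeric(n)
    alive <- rep(TRUE, n)
    if (k > 1) {
      for (i in seq_len(k - 1)) {
        if (!any(alive)) break
        idx <- which(alive)
        dies <- stats::runif(length(idx)) < q[i]
        years[idx[dies]] <- years[idx[dies]] + 0.5
        years[idx[!dies]] <- years[idx[!dies]] + 1
        alive[idx[dies]] <- FALSE
      }
    }
    if (any(alive)) {
      years[alive] <- years[alive] + stats::rexp(sum(alive), rate = m[k])
    }
    list(mean = mean(years),
         se = stats::sd(years) / sqrt(n),
         n = n)
  })
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits, in `dir`, the same plain-text formats the package's readers
#' consume: `rates.csv` (age-grouped 5-year bands derived from a synthetic
#' Gompertz-Makeham schedule), `hr_points.csv` + `hr_meta.csv` (the default
#' synthetic curve set), and `densities.csv` (the calibrated energy-density
#' table). Guarantees format round-trips without shipping any real extract.
#'
#' @param dir Output directory (created if missing).
#' @param params A [gompertz_makeham_params()] for the rates file.
#' @param sex,region Labels for the rates file.
#' @return Invisibly, the paths written.
#' @export
write_fixtures <- function(dir, params = gompertz_makeham_params(),
                           sex = "female", region = "synthetic") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sched <- make_schedule(params, sex = sex, region = region)
  # 5-year bands 0,5,...,95 plus an open 95+ band; band rate = mean of the
  # schedule's single-year rates so expansion round-trips the band values.
  starts <- seq(0L, 95L, by = 5L)
  ends <- c(starts[-1], NA)
  band_rate <- vapply(seq_along(starts), function(i) {
    lo <- starts[i]
    hi <- if (is.na(ends[i])) params$max_age else ends[i] - 1L
    mean(sched$rate[sched$age >= lo & sched$age <= hi])
  }, numeric(1))
  rates_path <- file.path(dir, "rates.csv")
  utils::write.csv(
    data.frame(sex = sex, region = region, age_start = starts,
               age_end = ends, rate = band_rate),
    rates_path, row.names = FALSE, quote = FALSE
  )
  hr_points <- file.path(dir, "hr_points.csv")
  hr_meta <- file.path(dir, "hr_meta.csv")
  write_hr_table(make_curveset(), hr_points, hr_meta)
  dens_path <- file.path(dir, "densities.csv")
  write_energy_densities(default_energy_densities(), dens_path)
  invisible(c(rates = rates_path, hr_points = hr_points, hr_meta = hr_meta,
              densities = dens_path))
}
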