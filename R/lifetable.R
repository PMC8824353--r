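# Period life-table engine: age-grouped rates, single-year expansion,
# remaining life expectancy, and hazard modification.

#' Construct age-grouped mortality rates
#'
#' All-cause mortality rates for one sex and region in contiguous age bands,
#' e.g. the 5-year bands of public burden-of-disease extracts. `age_end` is
#' exclusive; the final band must be open-ended (`age_end = NA`) and its rate
#' must be positive so remaining life expectancy is finite.
#'
#' @param age_start,age_end Integer band bounds in years; `age_end[i]` must
#'   equal `age_start[i + 1]`; last `age_end` is `NA` (open).
#' @param rate Deaths per person-year in each band, >= 0 (> 0 for the open band).
#' @param sex `"female"` or `"male"`.
#' @param region Free-text region label.
#' @return Object of class `age_grouped_rates`.
#' @export
age_grouped_rates <- function(age_start, age_end, rate,
                              sex = c("female", "male"), region = "unspecified") {
  sex <- match.arg(sex)
  n <- length(age_start)
  stopifnot(n >= 1, length(age_end) == n, length(rate) == n)
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("band rates must be finite and >= 0", call. = FALSE)
  }
  if (!is.na(age_end[n])) {
    stop("final band must be open-ended (age_end = NA)", call. = FALSE)
  }
  if (rate[n] <= 0) {
    stop("open-ended band must have rate > 0 (life expectancy diverges otherwise)",
         call. = FALSE)
  }
  if (n > 1) {
    closed_end <- age_end[-n]
    if (any(is.na(closed_end))) {
      stop("only the final band may be open-ended", call. = FALSE)
    }
    gap <- which(closed_end != age_start[-1])
    if (length(gap)) {
      stop(sprintf(
        "age bands must be contiguous: band [%d, %s) is followed by band starting at %d",
        age_start[gap[1]], closed_end[gap[1]], age_start[gap[1] + 1]
      ), call. = FALSE)
    }
    if (any(closed_end <= age_start[-n])) {
      stop("each closed band must satisfy age_end > age_start", call. = FALSE)
    }
  }
  structure(
    list(sex = sex, region = region,
         bands = data.frame(age_start = as.integer(age_start),
                            age_end = as.integer(age_end),
                            rate = as.numeric(rate))),
    class = "age_grouped_rates"
  )
}

#' Construct a single-year mortality schedule
#'
#' @param age Integer vector of consecutive single-year ages.
#' @param rate Mortality rate (deaths per person-year) at each age; all >= 0
#'   and the terminal rate > 0.
#' @inheritParams age_grouped_rates
#' @return Object of class `mortality_schedule` with fields `sex`, `region`,
#'   `age`, `rate`, `max_age`.
#' @export
mortality_schedule <- function(age, rate, sex = c("female", "male"),
                               region = "unspecified") {
  sex <- match.arg(sex)
  age <- as.integer(age)
  stopifnot(length(age) >= 1, length(rate) == length(age))
  if (length(age) > 1 && any(diff(age) != 1L)) {
    stop("ages must be consecutive single years", call. = FALSE)
  }
  if (any(!is.finite(rate)) || any(rate < 0)) {
    stop("rates must be finite and >= 0", call. = FALSE)
  }
  if (rate[length(rate)] <= 0) {
    stop("terminal-age rate must be > 0", call. = FALSE)
  }
  structure(list(sex = sex, region = region, age = age,
                 rate = as.numeric(rate), max_age = age[length(age)]),
            class = "mortality_schedule")
}

#' @export
print.mortality_schedule <- function(x, ...) {
  cat(sprintf("Mortality schedule: %s, %s, ages %d-%d\n",
              x$sex, x$region, x$age[1], x$max_age))
  invisible(x)
}

#' Expand age-grouped rates to single-year rates
#'
#' Each single-year age receives its band's rate unchanged (piecewise-constant
#' expansion); ages in the open-ended band up to `max_age` receive the open
#' band's rate. Averaging the expanded rates over any band therefore recovers
#' the band rate exactly.
#'
#' @param grouped An [age_grouped_rates()] object.
#' @param max_age Closure age of the resulting schedule (default 110); must be
#'   at or beyond the start of the open band.
#' @return A [mortality_schedule()].
#' @export
expand_to_single_year <- function(grouped, max_age = 110L) {
  stopifnot(inherits(grouped, "age_grouped_rates"))
  b <- grouped$bands
  n <- nrow(b)
  if (max_age < b$age_start[n]) {
    stop("max_age must be at or beyond the start of the open-ended band",
         call. = FALSE)
  }
  ages <- b$age_start[1]:max_age
  idx <- findInterval(ages, b$age_start)
  mortality_schedule(ages, b$rate[idx], sex = grouped$sex, region = grouped$region)
}

.schedule_tail <- function(schedule, age) {
  if (age < schedule$age[1] || age > schedule$max_age) {
    stop(sprintf("age %d outside schedule range [%d, %d]",
                 age, schedule$age[1], schedule$max_age), call. = FALSE)
  }
  schedule$rate[match(age, schedule$age):length(schedule$age)]
}

#' Remaining life expectancy
#'
#' Standard period life table, conditional on survival to `age`. Annual death
#' probabilities are `q = m / (1 + 0.5 m)` (deaths uniform within the year),
#' capped at 1; each lived year credits `l (1 - 0.5 q)` person-years
#' (survivors a full year, decedents half a year); the open interval at the
#' closure age contributes `l / m` person-years (exponential tail at the
#' terminal rate).
#'
#' @param schedule A [mortality_schedule()].
#' @param age Integer age at which remaining life expectancy is evaluated.
#' @return Remaining life expectancy in years.
#' @export
#' @examples
#' sched <- mortality_schedule(0:110, rep(0.0105263, 111))
#' life_expectancy(sched, 0)  # constant hazard: (1 - 0.5 q) / q
life_expectancy <- function(schedule, age) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  m <- .schedule_tail(schedule, age)
  n <- length(m)
  if (n == 1) return(1 / m[1])  # only the open terminal interval remains
  q <- pmin(m[-n] / (1 + 0.5 * m[-n]), 1)
  l <- c(1, cumprod(1 - q))            # survivorship at each year start
  person_years <- l[-n] * (1 - 0.5 * q)
  terminal <- l[n] / m[n]
  sum(person_years) + terminal
}

#' Apply a hazard-multiplier trajectory to a schedule
#'
#' Returns a new schedule whose rates are unchanged below `start_age` and
#' multiplied by `multiplier(a)` for every age `a >= start_age`; the input is
#' not modified. This is how a sustained diet change enters the life table:
#' mortality after the change age is scaled by the (ramped) hazard ratio.
#'
#' @param schedule A [mortality_schedule()].
#' @param start_age Age from which the multipliers apply.
#' @param multiplier Either a single positive number, a function of age, or a
#'   numeric vector named by age (as produced by [hazard_trajectory()])
#'   covering every age from `start_age` to the closure age.
#' @return A new [mortality_schedule()].
#' @export
apply_hazard_trajectory <- function(schedule, start_age, multiplier) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  ages <- start_age:schedule$max_age
  mult <- if (is.function(multiplier)) {
    vapply(ages, multiplier, numeric(1))
  } else if (length(multiplier) == 1) {
    rep(as.numeric(multiplier), length(ages))
  } else {
    if (is.null(names(multiplier)) ||
        !all(as.character(ages) %in% names(multiplier))) {
      stop("multiplier vector must be named by age and cover every age from ",
           start_age, " to ", schedule$max_age, call. = FALSE)
    }
    as.numeric(multiplier[as.character(ages)])
  }
  if (any(!is.finite(mult)) || any(mult <= 0)) {
    stop("hazard multipliers must be finite and > 0", call. = FALSE)
  }
  idx <- match(ages, schedule$age)
  if (anyNA(idx)) {
    stop("start_age outside schedule range", call. = FALSE)
  }
  out <- schedule
  out$rate[idx] <- out$rate[idx] * mult
  out
}

#' Read age-grouped rates from CSV
#'
#' Expected columns: `sex`, `region`, `age_start`, `age_end` (empty or `NA`
#' for the open-ended band), `rate`.
#'
#' @param path CSV file path.
#' @return An [age_grouped_rates()] object.
#' @export
read_rates_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sex", "region", "age_start", "age_end", "rate") %in% names(d)))
  d <- d[order(d$age_start), , drop = FALSE]
  age_grouped_rates(d$age_start, suppressWarnings(as.integer(d$age_end)), d$rate,
                    sex = unique(d$sex), region = unique(d$region)[1])
}

#' Read a burden-of-disease results-tool export
#'
#' Tolerant reader for the common results-tool CSV layout with columns
#' `location`, `sex`, `age` (e.g. `"20 to 24"`, `"95 plus"`, `"95+"`) and
#' `val` (the rate). Rows are filtered to one location and sex and mapped
#' onto [age_grouped_rates()].
#'
#' @param path CSV file path.
#' @param location Location name to keep.
#' @param sex `"female"` or `"male"` (case-insensitive match on the file).
#' @param rate_scale Divisor applied to `val` (use `1e5` if rates are per
#'   100,000 person-years; default 1 for plain rates).
#' @return An [age_grouped_rates()] object.
#' @export
read_gbd_csv <- function(path, location, sex = c("female", "male"),
                         rate_scale = 1) {
  sex <- match.arg(sex)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("location", "sex", "age", "val") %in% names(d)))
  d <- d[d$location == location & tolower(d$sex) == sex, , drop = FALSE]
  if (nrow(d) == 0) {
    stop("no rows for location '", location, "' and sex '", sex, "'",
         call. = FALSE)
  }
  parse_age <- function(s) {
    s <- trimws(s)
    if (grepl("plus$", s) || grepl("\\+$", s)) {
      c(as.integer(sub("[^0-9].*$", "", s)), NA_integer_)
    } else if (grepl("to", s)) {
      parts <- as.integer(strsplit(s, "\\s*to\\s*")[[1]])
      c(parts[1], parts[2] + 1L)  # "20 to 24" covers ages 20-24 inclusive
    } else if (grepl("^<", s)) {
      c(0L, as.integer(sub("^<\\s*([0-9]+).*$", "\\1", s)))
    } else {
      a <- as.integer(sub("[^0-9].*$", "", s))
      c(a, a + 1L)
    }
  }
  bounds <- t(vapply(d$age, parse_age, integer(2)))
  ord <- order(bounds[, 1])
  age_grouped_rates(bounds[ord, 1], bounds[ord, 2], d$val[ord] / rate_scale,
                    sex = sex, region = location)
}

#' Write a single-year schedule to CSV
#'
#' Columns `age`, `rate`, for inspection and plotting.
#'
#' @param schedule A [mortality_schedule()].
#' @param path Output CSV path.
#' @export
write_schedule_csv <- function(schedule, path) {
  stopifnot(inherits(schedule, "mortality_schedule"))
  utils::write.csv(data.frame(age = schedule$age, rate = schedule$rate),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
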