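# Food groups, diet profiles, presets, energy densities and the energy gate.

.FOOD_GROUPS <- c(
  "whole_grains", "vegetables", "fruits", "nuts", "legumes", "fish",
  "eggs", "milk_dairy", "refined_grains", "red_meat", "processed_meat",
  "white_meat", "ssb", "added_oils"
)

#' The 14 modelled food groups
#'
#' Canonical identifiers, in canonical order, of the food groups the model
#' covers: whole grains, vegetables, fruits, nuts, legumes, fish, eggs,
#' milk/dairy, refined grains, red meat, processed meat, white meat,
#' sugar-sweetened beverages (`ssb`) and added plant oils.
#'
#' @return Character vector of length 14.
#' @export
#' @examples
#' food_groups()
food_groups <- function() .FOOD_GROUPS

.check_groups <- function(x, what) {
  nm <- names(x)
  missing <- setdiff(.FOOD_GROUPS, nm)
  extra <- setdiff(nm, .FOOD_GROUPS)
  if (length(missing) || length(extra)) {
    stop(sprintf(
      "%s must cover each of the 14 food groups exactly once (missing: %s; unknown: %s)",
      what,
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"
    ), call. = FALSE)
  }
  if (anyDuplicated(nm)) stop(what, " has duplicated food groups", call. = FALSE)
  invisible(x)
}

#' Construct a diet profile
#'
#' A diet profile is a complete intake vector, in grams per day, over the 14
#' food groups.
#'
#' @param intake Named numeric vector, one non-negative value (g/day) per food
#'   group; names must be exactly [food_groups()].
#' @param label Short text label for the profile.
#' @return An object of class `diet_profile`: a list with elements `label` and
#'   `intake` (named numeric in canonical group order).
#' @seealso [preset_diet()] for the built-in diet patterns.
#' @export
diet_profile <- function(intake, label = "custom") {
  .check_groups(intake, "diet intake")
  intake <- intake[.FOOD_GROUPS]
  if (!is.numeric(intake) || any(!is.finite(intake)) || any(intake < 0)) {
    stop("all intakes must be finite and >= 0 g/day", call. = FALSE)
  }
  structure(list(label = as.character(label)[1], intake = intake),
            class = "diet_profile")
}

#' @export
print.diet_profile <- function(x, ...) {
  cat(sprintf("Diet profile '%s' (g/day)\n", x$label))
  print(round(x$intake, 2))
  invisible(x)
}

# Preset intakes (g/day). FA is the per-group arithmetic midpoint of TW and
# OD by construction; the printed FA values all satisfy it (fish FA = 125 g).
.preset_intakes <- local({
  tw <- c(
    whole_grains = 50, vegetables = 250, fruits = 200, nuts = 0,
    legumes = 0, fish = 50, eggs = 50, milk_dairy = 300,
    refined_grains = 150, red_meat = 100, processed_meat = 50,
    white_meat = 75, ssb = 500, added_oils = 25
  )
  od <- c(
    whole_grains = 225, vegetables = 400, fruits = 400, nuts = 25,
    legumes = 200, fish = 200, eggs = 25, milk_dairy = 200,
    refined_grains = 50, red_meat = 0, processed_meat = 0,
    white_meat = 50, ssb = 0, added_oils = 25
  )
  list(TW = tw, FA = (tw + od) / 2, OD = od)
})

#' Built-in diet presets
#'
#' Returns one of the three published diet patterns: `"TW"`, the typical
#' Western diet used as baseline; `"OD"`, the optimized diet with each intake
#' set where the mortality dose-response plateaus; `"FA"`, the feasibility
#' approach diet, the per-group midpoint between TW and OD.
#'
#' @param name One of `"TW"`, `"FA"`, `"OD"`.
#' @return A [diet_profile()].
#' @export
#' @examples
#' preset_diet("TW")$intake[["whole_grains"]]  # 50 g/day
#' preset_diet("OD")$intake[["red_meat"]]      # 0 g/day
preset_diet <- function(name) {
  if (!(is.character(name) && length(name) == 1 && name %in% names(.preset_intakes))) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; valid presets are: TW, FA, OD", call. = FALSE)
  }
  diet_profile(.preset_intakes[[name]], label = name)
}

#' Default energy-density table (kJ/g)
#'
#' Per-group energy densities used by the energy-feasibility gate. Values are
#' typical food-composition figures for the as-consumed (fresh/cooked) weight
#' basis of each group, calibrated so that the preset diets reproduce the
#' published totals of 8,085 (TW), 7,850 (FA) and 7,615 (OD) kJ/day. The
#' table is a stand-in for a full food-composition database, not an extract
#' of one.
#'
#' @return Named numeric vector, kJ per gram, one entry per food group.
#' @export
default_energy_densities <- function() {
  c(
    whole_grains = 4.70, vegetables = 1.00, fruits = 2.20, nuts = 25.00,
    legumes = 4.00, fish = 6.31, eggs = 6.00, milk_dairy = 2.50,
    refined_grains = 13.30, red_meat = 8.50, processed_meat = 12.00,
    white_meat = 7.00, ssb = 1.80, added_oils = 37.00
  )
}

#' Total energy content of a diet
#'
#' @param diet A [diet_profile()].
#' @param densities Named numeric vector of energy densities in kJ/g covering
#'   all 14 groups; defaults to [default_energy_densities()].
#' @return Total energy in kJ/day.
#' @export
#' @examples
#' total_energy(preset_diet("TW"))  # ~8085 kJ/day
total_energy <- function(diet, densities = default_energy_densities()) {
  stopifnot(inherits(diet, "diet_profile"))
  .check_groups(densities, "energy-density table")
  if (any(!is.finite(densities)) || any(densities < 0)) {
    stop("energy densities must be finite and >= 0 kJ/g", call. = FALSE)
  }
  sum(diet$intake * densities[names(diet$intake)])
}

#' Energy-feasibility gate
#'
#' The model refuses to report estimates for diets that are implausibly low
#' or high in energy: below 4,000 kJ/day or above 16,000 kJ/day. The bounds
#' themselves pass (the refusal is strict: "below"/"above").
#'
#' @inheritParams total_energy
#' @param lower,upper Gate bounds in kJ/day.
#' @return `"pass"`, `"reject_low"` or `"reject_high"`.
#' @export
check_energy_gate <- function(diet, densities = default_energy_densities(),
                              lower = 4000, upper = 16000) {
  e <- total_energy(diet, densities)
  if (e < lower) "reject_low" else if (e > upper) "reject_high" else "pass"
}

# Signal a gate refusal as a classed condition so callers (and the CLI) can
# distinguish it from programming errors.
.stop_energy_gate <- function(diet, verdict, densities) {
  msg <- sprintf(
    "estimates not reported: diet '%s' (%.0f kJ/day) is %s the energy-feasibility gate (4,000-16,000 kJ/day)",
    diet$label, total_energy(diet, densities),
    if (verdict == "reject_low") "below" else "above"
  )
  stop(structure(
    class = c("dietspan_energy_gate", "dietspan_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Read or write a diet profile as JSON
#'
#' The serialized form is a JSON object with a `label` and one key per food
#' group giving intake in g/day; presets round-trip unchanged.
#'
#' @param path File path.
#' @param diet A [diet_profile()].
#' @return `read_diet_profile()` returns a [diet_profile()];
#'   `write_diet_profile()` returns `path` invisibly.
#' @export
read_diet_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  label <- if (!is.null(x$label)) x$label else "custom"
  x$label <- NULL
  diet_profile(unlist(x), label = label)
}

#' @rdname read_diet_profile
#' @export
write_diet_profile <- function(diet, path) {
  stopifnot(inherits(diet, "diet_profile"))
  out <- c(list(label = diet$label), as.list(diet$intake))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read or write an energy-density table (CSV)
#'
#' CSV layout: columns `group`, `kj_per_g`.
#'
#' @param path File path.
#' @param densities Named numeric vector of kJ/g values.
#' @export
read_energy_densities <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "kj_per_g") %in% names(d)))
  dens <- stats::setNames(as.numeric(d$kj_per_g), d$group)
  .check_groups(dens, "energy-density table")
  dens[.FOOD_GROUPS]
}

#' @rdname read_energy_densities
#' @export
write_energy_densities <- function(densities, path) {
  .check_groups(densities, "energy-density table")
  utils::write.csv(
    data.frame(group = names(densities), kj_per_g = as.numeric(densities)),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
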