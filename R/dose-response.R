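# Dose-response hazard-ratio curves and the change-HR evaluation.

#' Construct a dose-response hazard-ratio curve
#'
#' One food group's all-cause-mortality hazard ratio as a function of daily
#' intake, tabulated at increasing doses with 95% confidence bands, plus its
#' NutriGrade evidence score. Curves are treated as relative: only ratios
#' `HR(to)/HR(from)` are ever used, so the reference dose at which the source
#' meta-analysis anchored HR = 1 is irrelevant.
#'
#' @param group A food-group identifier (see [food_groups()]).
#' @param dose Strictly increasing numeric vector of intakes (g/day), >= 0.
#' @param hr Central hazard ratios at each dose (> 0).
#' @param ci_lo,ci_hi Lower/upper 95% confidence bands; must satisfy
#'   `ci_lo <= hr <= ci_hi` pointwise. Default to `hr` (degenerate bands).
#' @param nutrigrade NutriGrade evidence score in \[0, 10\], or `NA`.
#' @param neutral Logical; `TRUE` for groups modelled as having no mortality
#'   effect (the curve is then forced to HR = 1 everywhere).
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(group, dose, hr, ci_lo = hr, ci_hi = hr,
                                nutrigrade = NA_real_, neutral = FALSE) {
  if (!(is.character(group) && length(group) == 1 && group %in% food_groups())) {
    stop("unknown food group '", paste(group, collapse = ","), "'", call. = FALSE)
  }
  if (isTRUE(neutral)) {
    dose <- c(0, 1); hr <- c(1, 1); ci_lo <- hr; ci_hi <- hr
  }
  n <- length(dose)
  stopifnot(n >= 1, length(hr) == n, length(ci_lo) == n, length(ci_hi) == n)
  if (any(dose < 0)) stop("doses must be >= 0 g/day", call. = FALSE)
  if (n > 1 && any(diff(dose) <= 0)) {
    stop("doses must be strictly increasing", call. = FALSE)
  }
  if (any(hr <= 0) || any(ci_lo <= 0) || any(ci_hi <= 0)) {
    stop("hazard ratios and bands must be positive", call. = FALSE)
  }
  if (any(ci_lo > hr + 1e-12) || any(ci_hi < hr - 1e-12)) {
    stop("confidence bands must satisfy ci_lo <= hr <= ci_hi at every dose",
         call. = FALSE)
  }
  if (!is.na(nutrigrade) && (nutrigrade < 0 || nutrigrade > 10)) {
    stop("NutriGrade score must lie in [0, 10]", call. = FALSE)
  }
  structure(
    list(group = group,
         points = data.frame(dose = as.numeric(dose), hr = as.numeric(hr),
                             ci_lo = as.numeric(ci_lo), ci_hi = as.numeric(ci_hi)),
         nutrigrade = as.numeric(nutrigrade),
         neutral = isTRUE(neutral)),
    class = "dose_response_curve"
  )
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("Dose-response curve: %s%s (NutriGrade %s)\n", x$group,
              if (x$neutral) " [neutral]" else "",
              ifelse(is.na(x$nutrigrade), "NA", format(x$nutrigrade))))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Bundle curves into a curve set
#'
#' @param curves A list of [dose_response_curve()] objects.
#' @return A named list of curves (class `curve_set`), keyed by food group.
#' @export
curve_set <- function(curves) {
  stopifnot(is.list(curves),
            all(vapply(curves, inherits, logical(1), "dose_response_curve")))
  names(curves) <- vapply(curves, `[[`, character(1), "group")
  if (anyDuplicated(names(curves))) {
    stop("duplicate curve for group(s): ",
         paste(unique(names(curves)[duplicated(names(curves))]), collapse = ", "),
         call. = FALSE)
  }
  structure(curves, class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("Curve set over %d food groups: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

# Evaluate one band of a curve at arbitrary doses: linear interpolation
# between tabulated points, flat (plateau) extrapolation beyond the ends.
.eval_band <- function(points, band, at) {
  if (nrow(points) == 1) return(rep(points[[band]], length(at)))
  stats::approx(points$dose, points[[band]], xout = at, rule = 2)$y
}

#' Hazard ratio for an intake change
#'
#' Evaluates the hazard ratio associated with changing one food group's
#' intake from `from_dose` to `to_dose` g/day, as the ratio
#' `HR(to_dose) / HR(from_dose)` on the central curve and on each confidence
#' band. `HR(d)` is obtained by linear interpolation between tabulated points
#' and plateaus (flat extrapolation) beyond the first and last tabulated
#' dose, mirroring the convention that intakes past the plateau confer no
#' further benefit or harm. Neutral curves return exactly `(1, 1, 1)`.
#'
#' @param curve A [dose_response_curve()].
#' @param from_dose,to_dose Intakes in g/day, >= 0.
#' @return Named numeric vector `c(hr, hr_lo, hr_hi)`.
#' @export
#' @examples
#' cv <- dose_response_curve("nuts", dose = c(0, 100), hr = c(1, 0.8))
#' hazard_ratio_for_change(cv, 0, 50)   # hr = 0.90
#' hazard_ratio_for_change(cv, 0, 250)  # hr = 0.80 (plateau beyond 100 g)
hazard_ratio_for_change <- function(curve, from_dose, to_dose) {
  stopifnot(inherits(curve, "dose_response_curve"),
            is.numeric(from_dose), is.numeric(to_dose),
            length(from_dose) == 1, length(to_dose) == 1)
  if (from_dose < 0 || to_dose < 0) stop("doses must be >= 0", call. = FALSE)
  if (curve$neutral) return(c(hr = 1, hr_lo = 1, hr_hi = 1))
  at <- c(from_dose, to_dose)
  ctr <- .eval_band(curve$points, "hr", at)
  lo <- .eval_band(curve$points, "ci_lo", at)
  hi <- .eval_band(curve$points, "ci_hi", at)
  c(hr = ctr[2] / ctr[1], hr_lo = lo[2] / lo[1], hr_hi = hi[2] / hi[1])
}

# Replace a curve's central ordinates by the uniform blend
# lo + u * (hi - lo), pointwise with one deviate u for the whole curve.
# Used by the uncertainty draws; bands collapse onto the blend.
.blend_curve <- function(curve, u) {
  if (curve$neutral) return(curve)
  p <- curve$points
  drawn <- p$ci_lo + u * (p$ci_hi - p$ci_lo)
  curve$points <- data.frame(dose = p$dose, hr = drawn, ci_lo = drawn, ci_hi = drawn)
  curve
}

#' Read a curve set from CSV files
#'
#' Two delimited files describe a curve set: a points file with columns
#' `group, dose_g, hr, ci_lo, ci_hi` (one row per tabulated point), and a
#' metadata file with columns `group, nutrigrade, neutral`. Neutral groups
#' need no rows in the points file.
#'
#' @param points_path,meta_path CSV file paths.
#' @return A [curve_set()].
#' @export
read_hr_table <- function(points_path, meta_path) {
  pts <- utils::read.csv(points_path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "dose_g", "hr", "ci_lo", "ci_hi") %in% names(pts)))
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "nutrigrade", "neutral") %in% names(meta)))
  curves <- lapply(seq_len(nrow(meta)), function(i) {
    g <- meta$group[i]
    neutral <- as.logical(meta$neutral[i])
    if (neutral) {
      dose_response_curve(g, 0, 1, nutrigrade = meta$nutrigrade[i], neutral = TRUE)
    } else {
      sub <- pts[pts$group == g, , drop = FALSE]
      if (nrow(sub) == 0) {
        stop("no dose-response points for non-neutral group '", g, "'",
             call. = FALSE)
      }
      sub <- sub[order(sub$dose_g), , drop = FALSE]
      dose_response_curve(g, sub$dose_g, sub$hr, sub$ci_lo, sub$ci_hi,
                          nutrigrade = meta$nutrigrade[i])
    }
  })
  curve_set(curves)
}

#' Write a curve set to CSV files
#'
#' Inverse of [read_hr_table()].
#'
#' @param curves A [curve_set()].
#' @inheritParams read_hr_table
#' @export
write_hr_table <- function(curves, points_path, meta_path) {
  stopifnot(inherits(curves, "curve_set"))
  pts <- do.call(rbind, lapply(curves, function(cv) {
    if (cv$neutral) return(NULL)
    data.frame(group = cv$group, dose_g = cv$points$dose, hr = cv$points$hr,
               ci_lo = cv$points$ci_lo, ci_hi = cv$points$ci_hi)
  }))
  meta <- data.frame(
    group = names(curves),
    nutrigrade = vapply(curves, `[[`, numeric(1), "nutrigrade"),
    neutral = vapply(curves, `[[`, logical(1), "neutral")
  )
  utils::write.csv(pts, points_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(points_path, meta_path))
}
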