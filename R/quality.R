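# NutriGrade evidence-quality bookkeeping.

#' NutriGrade category of a score
#'
#' Published category bounds: very low \[0, 3.99\], low \[4, 5.99\],
#' moderate \[6, 7.99\], high \[8, 10\]. A boundary score belongs to the
#' upper class (8 is "high").
#'
#' @param score Numeric score(s) in \[0, 10\].
#' @return Character vector: `"very_low"`, `"low"`, `"moderate"` or `"high"`.
#' @export
#' @examples
#' nutrigrade_category(c(0, 5.99, 8))
nutrigrade_category <- function(score) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 10)) {
    stop("NutriGrade scores must lie in [0, 10]", call. = FALSE)
  }
  as.character(cut(score, breaks = c(-Inf, 4, 6, 8, Inf), right = FALSE,
                   labels = c("very_low", "low", "moderate", "high")))
}

#' Contribution-weighted overall NutriGrade score
#'
#' Mean of the per-group NutriGrade scores weighted by each group's absolute
#' contribution to the life-expectancy change:
#' `sum(score_g * |dLE_g|) / sum(|dLE_g|)`. Groups with zero contribution
#' (including neutral groups) carry zero weight; groups with `NA` scores are
#' excluded from both sums (they can carry no evidence grade).
#'
#' @param scores Named numeric vector of NutriGrade scores by food group
#'   (`NA` allowed for ungraded groups).
#' @param contributions Named numeric vector of per-group LE contributions in
#'   years (signs are ignored), as from [per_group_gains()].
#' @return The weighted overall score.
#' @export
#' @examples
#' weighted_nutrigrade(c(a = 8, b = 4), c(a = 1, b = 3))  # 5
weighted_nutrigrade <- function(scores, contributions) {
  common <- intersect(names(scores), names(contributions))
  if (length(common) == 0) stop("no shared groups between scores and contributions",
                                call. = FALSE)
  s <- scores[common]
  w <- abs(contributions[common])
  keep <- !is.na(s)
  s <- s[keep]; w <- w[keep]
  if (sum(w) == 0) {
    stop("all contributions are zero: weighted score undefined", call. = FALSE)
  }
  sum(s * w) / sum(w)
}

#' Published NutriGrade scores for the 14 food groups
#'
#' Evidence-quality scores reported for the underlying meta-analyses: high
#' for whole grains (8); moderate for fish (7.75), processed meat (7.5),
#' nuts (7), red meat (6.5), legumes (6) and dairy (6); low for vegetables
#' (5.8), fruits (5.8), sugar-sweetened beverages (5.5) and refined grains
#' (5); very low for eggs (3.8) and white meat (2). Added oils carry no
#' published score (`NA`) and are modelled as neutral.
#'
#' @return Named numeric vector of scores by food group.
#' @export
default_nutrigrade_scores <- function() {
  c(
    whole_grains = 8, vegetables = 5.8, fruits = 5.8, nuts = 7,
    legumes = 6, fish = 7.75, eggs = 3.8, milk_dairy = 6,
    refined_grains = 5, red_meat = 6.5, processed_meat = 7.5,
    white_meat = 2, ssb = 5.5, added_oils = NA_real_
  )
}
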