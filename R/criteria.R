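# Criterion applications: the common currency every evaluator returns.

default_strengths <- c(PVS = "very_strong", PS = "strong", PM = "moderate",
                       PP = "supporting", BA = "standalone", BS = "strong",
                       BP = "supporting")

#' Build a criterion application
#'
#' @param code ACMG/AMP code string, e.g. `"PS2"`.
#' @param direction `"pathogenic"` or `"benign"`.
#' @param strength Assigned strength (`standalone`, `very_strong`, `strong`,
#'   `moderate`, `supporting`, `not_applicable`).
#' @param points Pre-binning point tally where a point system exists, else `NA`.
#' @param rationale Human-readable audit string.
#' @return One-row tibble with columns `code`, `direction`, `strength`,
#'   `points`, `label`, `rationale`.
#' @export
criterion <- function(code, direction, strength, points = NA_real_, rationale = "") {
  chk_enum(direction, c("pathogenic", "benign"), "direction")
  chk_enum(strength, strength_levels, "strength")
  tibble(code = code, direction = direction, strength = strength,
         points = as.numeric(points), label = vcep_label(code, strength),
         rationale = rationale)
}

empty_criteria <- function() {
  tibble(code = character(), direction = character(), strength = character(),
         points = numeric(), label = character(), rationale = character())
}

camel <- function(x) {
  gsub("(^|_)([a-z])", "\\U\\2", x, perl = TRUE)
}

#' Render a criterion code in expert-panel notation
#'
#' A code applied at its default letter strength renders bare (`PS2`); a
#' strength-modified application carries a suffix (`PS2_VeryStrong`,
#' `PM2_Supporting`).
#'
#' @param code ACMG/AMP code string.
#' @param strength Assigned strength.
#' @return Character label.
#' @export
vcep_label <- function(code, strength) {
  if (length(code) > 1 || length(strength) > 1) {
    return(mapply(vcep_label, code, strength, USE.NAMES = FALSE))
  }
  if (strength == "not_applicable") return(paste0(code, " (not applicable)"))
  prefix <- sub("[0-9].*$", "", code)
  def <- unname(default_strengths[prefix])
  if (!is.na(def) && identical(def, strength)) return(code)
  paste0(code, "_", camel(strength))
}

strength_rank <- function(strength) {
  # higher = stronger evidence; not_applicable ranks lowest
  match(strength, rev(strength_levels)) - 1L
}

# Inclusive pathogenic point binning: the first (largest) threshold at or
# below the tally wins; below the smallest threshold -> not_applicable.
bin_points <- function(total, bins) {
  bins <- sort(bins, decreasing = TRUE)
  for (nm in names(bins)) {
    if (total >= bins[[nm]]) return(nm)
  }
  "not_applicable"
}

# Benign tallies are negative; thresholds inclusive at the printed value.
bin_points_benign <- function(total, bins) {
  bins <- sort(bins)
  for (nm in names(bins)) {
    if (total <= bins[[nm]]) return(nm)
  }
  "not_applicable"
}

tally_attr <- function(out, contributions) {
  attr(out, "tally") <- contributions
  out
}

#' Point contributions behind a scored criterion
#'
#' The case-observation scorers record every per-observation contribution;
#' this accessor returns them as a tibble (`observation`, `points`, `reason`).
#'
#' @param x A criterion tibble returned by one of the point-based scorers.
#' @return Tibble of contributions (zero rows when nothing contributed).
#' @export
point_tally <- function(x) {
  attr(x, "tally") %||% tibble(observation = integer(), points = numeric(),
                               reason = character())
}
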