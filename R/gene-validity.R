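# Case-level point rules for gene-disease validity curation (SOP v9 style):
# genetic and experimental evidence points with caps and strength bins.

validity_defaults <- list(
  de_novo_missense = 0.5,       # recommended default for a de novo missense case
  de_novo_missense_gof = 1.5,   # de novo missense with GoF functional support (max)
  missense_gof = 1.0,           # missense with GoF functional support, not de novo
  other_case = 0.5,             # SOP default for other case-level evidence
  genetic_cap = 12,
  experimental_cap = 6,
  strong_min = 12,
  moderate_min = 7
)

#' Score gene-disease validity evidence
#'
#' Case entries are awarded points by class: a de novo missense case scores
#' the recommended default 0.5 points; functional data supporting a
#' gain-of-function mechanism raise a missense case to 1 point, or to the
#' 1.5-point maximum when the variant is also de novo. An explicit
#' `points_override` (within the 0-1.5 case bounds) wins over the class
#' default. Genetic points are capped at 12 and experimental points at 6;
#' the capped total is binned into Limited (0.1-6), Moderate (7-11) and
#' Strong (12-18), with Strong upgraded to Definitive when the relationship
#' has been replicated over time.
#'
#' @param evidence List with elements `cases` (tibble: `variant_class` in
#'   `de_novo_missense`/`other_case`, `has_gof_functional` logical,
#'   `points_override` numeric or `NA`) and `experimental` (tibble:
#'   `category`, `points`).
#' @param replicated_over_time Has the relationship been replicated over
#'   time (upgrades Strong to Definitive)?
#' @return One-row tibble (`genetic_points`, `experimental_points`,
#'   `total_points`, `classification`).
#' @export
score_validity <- function(evidence, replicated_over_time = FALSE) {
  cases <- as_tibble(evidence$cases %||%
                       tibble(variant_class = character(),
                              has_gof_functional = logical(),
                              points_override = numeric()))
  experimental <- as_tibble(evidence$experimental %||%
                              tibble(category = character(), points = numeric()))
  if (nrow(cases) > 0) {
    chk_enum(cases$variant_class, c("de_novo_missense", "other_case"), "variant_class")
    if (!"points_override" %in% names(cases)) cases$points_override <- NA_real_
    if (!"has_gof_functional" %in% names(cases)) cases$has_gof_functional <- FALSE
    bad <- !is.na(cases$points_override) &
      (cases$points_override < 0 | cases$points_override > 1.5)
    if (any(bad)) abort("points_override must lie within [0, 1.5]")
    pts <- case_when(
      !is.na(cases$points_override) ~ cases$points_override,
      cases$variant_class == "de_novo_missense" & cases$has_gof_functional ~
        validity_defaults$de_novo_missense_gof,
      cases$variant_class == "de_novo_missense" ~ validity_defaults$de_novo_missense,
      cases$has_gof_functional ~ validity_defaults$missense_gof,
      .default = validity_defaults$other_case
    )
  } else {
    pts <- numeric()
  }
  genetic <- min(sum(pts), validity_defaults$genetic_cap)
  exppts <- min(sum(experimental$points), validity_defaults$experimental_cap)
  total <- genetic + exppts
  classification <- if (total >= validity_defaults$strong_min) {
    if (isTRUE(replicated_over_time)) "Definitive" else "Strong"
  } else if (total >= validity_defaults$moderate_min) {
    "Moderate"
  } else {
    if (total <= 0) warning("no scorable validity evidence; classification is Limited by default")
    "Limited"
  }
  tibble(genetic_points = genetic, experimental_points = exppts,
         total_points = total, classification = classification)
}

#' Read a gene-validity evidence table from TSV
#'
#' @param path TSV with columns `entry_type` (`case`/`experimental`),
#'   `variant_class`, `has_gof_functional`, `points_override`, `category`,
#'   `points`.
#' @return A validity-evidence list suitable for [score_validity()].
#' @export
read_validity_table <- function(path) {
  tb <- readr::read_tsv(path, na = ".", show_col_types = FALSE)
  chk_enum(tb$entry_type, c("case", "experimental"), "entry_type")
  cases <- tb |>
    filter(.data$entry_type == "case") |>
    transmute(variant_class = .data$variant_class,
              has_gof_functional = as.logical(.data$has_gof_functional %||% FALSE),
              points_override = as.numeric(.data$points_override))
  experimental <- tb |>
    filter(.data$entry_type == "experimental") |>
    transmute(category = .data$category, points = as.numeric(.data$points))
  list(cases = cases, experimental = experimental)
}
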