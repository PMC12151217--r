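# broom-style accessors and plotting for classification results.

#' Tidy a classification result
#'
#' @param x A `ras_classification`.
#' @param ... Unused.
#' @return Tibble of criterion applications (`code`, `direction`,
#'   `strength`, `points`, `label`, `rationale`, `applied`).
#' @exportS3Method generics::tidy
#' @export
tidy.ras_classification <- function(x, ...) {
  x$criteria |>
    mutate(applied = .data$strength != "not_applicable")
}

#' One-row summary of a classification result
#'
#' @param x A `ras_classification`.
#' @param ... Unused.
#' @return One-row tibble with the tier, route, capping flag and applied
#'   criterion counts by direction.
#' @exportS3Method generics::glance
#' @export
glance.ras_classification <- function(x, ...) {
  applied <- filter(x$criteria, .data$strength != "not_applicable")
  tibble(
    gene = x$identity$gene %||% NA_character_,
    hgvs_c = x$identity$hgvs_c %||% NA_character_,
    tier = x$tier,
    mechanism_route = x$mechanism_route,
    capped_by_validity = x$capped_by_validity,
    n_applied = nrow(applied),
    n_pathogenic = sum(applied$direction == "pathogenic"),
    n_benign = sum(applied$direction == "benign")
  )
}

#' Plot the criterion ledger of a classification
#'
#' A lollipop-style chart of applied criteria ordered by evidence strength,
#' pathogenic criteria to the right, benign to the left.
#'
#' @param object A `ras_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.ras_classification <- function(object, ...) {
  strength_weight <- c(standalone = 4, very_strong = 4, strong = 3,
                       moderate = 2, supporting = 1)
  dat <- object$criteria |>
    filter(.data$strength != "not_applicable") |>
    mutate(weight = strength_weight[.data$strength] *
             ifelse(.data$direction == "pathogenic", 1, -1),
           label = factor(.data$label, levels = .data$label[order(.data$weight)]))
  if (nrow(dat) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no applied criteria") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$weight, y = .data$label,
                                    colour = .data$direction)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$weight,
                                       yend = .data$label)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::scale_colour_manual(values = c(pathogenic = "#b2182b",
                                            benign = "#2166ac")) +
    ggplot2::labs(x = "evidence weight (benign ← 0 → pathogenic)",
                  y = NULL,
                  title = paste0(object$identity$gene %||% "", " ",
                                 object$identity$hgvs_c %||% "",
                                 " — ", object$tier)) +
    ggplot2::theme_minimal()
}

#' Tier summary plot for a batch of classifications
#'
#' @param results Tibble from [classify_bundles()].
#' @return A ggplot bar chart of classification tiers.
#' @export
plot_tier_summary <- function(results) {
  dat <- results |>
    count(tier = factor(.data$tier, levels = c("B", "LB", "VUS", "LP", "P")))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$tier, y = .data$n)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "classification tier", y = "variants") +
    ggplot2::theme_minimal()
}
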