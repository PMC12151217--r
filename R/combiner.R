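# Combination of criterion applications into a five-tier classification via
# the classic ACMG/AMP combining rubric, followed by gene-validity capping
# and the LZTR1 undetermined-route VUS override.

#' Census of applied criteria by direction and strength
#'
#' Strength-modified codes count at their modified strength, not their
#' default letter; not-applicable entries are excluded.
#'
#' @param criteria Criterion tibble (rows from the evaluators and/or
#'   passthrough criteria).
#' @return One-row tibble with counts `vs`, `s`, `m`, `su` (pathogenic) and
#'   `ba`, `bs`, `bp` (benign).
#' @export
census <- function(criteria) {
  criteria <- as_tibble(criteria %||% empty_criteria()) |>
    filter(.data$strength != "not_applicable")
  path <- filter(criteria, .data$direction == "pathogenic")
  ben <- filter(criteria, .data$direction == "benign")
  tibble(
    vs = sum(path$strength == "very_strong"),
    s = sum(path$strength == "strong"),
    m = sum(path$strength == "moderate"),
    su = sum(path$strength == "supporting"),
    ba = sum(ben$strength == "standalone"),
    bs = sum(ben$strength == "strong"),
    bp = sum(ben$strength %in% c("supporting", "moderate"))
  )
}

#' Map strength censuses to classification tiers (vectorised)
#'
#' Applies the combining rubric to a data frame of censuses. Pathogenic:
#' one very strong plus (>=1 strong, >=2 moderate, 1 moderate + 1
#' supporting, or >=2 supporting); >=2 strong; or 1 strong plus (>=3
#' moderate, 2 moderate + 2 supporting, or 1 moderate + 4 supporting).
#' Likely pathogenic: 1 very strong + 1 moderate; 1 strong + 1-2 moderate;
#' 1 strong + >=2 supporting; >=3 moderate; 2 moderate + >=2 supporting; or
#' 1 moderate + >=4 supporting. Benign: a stand-alone criterion or >=2
#' strong benign. Likely benign: 1 strong benign + 1 supporting benign, or
#' >=2 supporting benign. A census satisfying both a pathogenic and a benign
#' tier is conflicting and resolves to VUS, as does one satisfying neither.
#'
#' @param censuses Data frame with columns `vs`, `s`, `m`, `su`, `ba`, `bs`,
#'   `bp`.
#' @return Character vector of tiers (`P`, `LP`, `VUS`, `LB`, `B`).
#' @export
tier_from_census <- function(censuses) {
  with(censuses, {
    path_p <- (vs >= 1 & (s >= 1 | m >= 2 | (m >= 1 & su >= 1) | su >= 2)) |
      (s >= 2) |
      (s >= 1 & (m >= 3 | (m >= 2 & su >= 2) | (m >= 1 & su >= 4)))
    path_lp <- (vs >= 1 & m >= 1) |
      (s >= 1 & m >= 1) |
      (s >= 1 & su >= 2) |
      (m >= 3) |
      (m >= 2 & su >= 2) |
      (m >= 1 & su >= 4)
    ben_b <- (ba >= 1) | (bs >= 2)
    ben_lb <- (bs >= 1 & bp >= 1) | (bp >= 2)
    path_tier <- ifelse(path_p, "P", ifelse(path_lp, "LP", "none"))
    ben_tier <- ifelse(ben_b, "B", ifelse(ben_lb, "LB", "none"))
    ifelse(path_tier != "none" & ben_tier != "none", "VUS",
           ifelse(path_tier != "none", path_tier,
                  ifelse(ben_tier != "none", ben_tier, "VUS")))
  })
}

route_validity_tier <- function(profile, route) {
  v <- profile$validity
  key <- if (identical(route, "AR")) "AR" else "AD"
  v[[key]] %||% v[[1]] %||% "Definitive"
}

#' Combine criterion applications into a classification
#'
#' Applies the combining rubric to the applied criteria, then two
#' post-rubric rules: for genes whose disease relationship is only Moderate
#' validity, a Pathogenic outcome is capped at Likely Pathogenic; and an
#' undetermined LZTR1 mechanism route forces VUS regardless of accumulated
#' evidence.
#'
#' @param criteria Criterion tibble (engine-evaluated plus passthrough).
#' @param profile Gene profile.
#' @param route `"AD"`, `"AR"` or `"undetermined"` (or a `ras_mechanism`
#'   row).
#' @param identity Optional [variant_identity()] carried into the result.
#' @return An object of class `ras_classification`.
#' @export
combine_criteria <- function(criteria, profile, route = "AD", identity = NULL) {
  if (inherits(route, "ras_mechanism") || is.data.frame(route)) route <- route$route[[1]]
  criteria <- as_tibble(criteria)
  cen <- census(criteria)
  tier <- tier_from_census(cen)
  notes <- character()
  applied <- filter(criteria, .data$strength != "not_applicable")
  if (tier == "VUS" && nrow(applied) > 0) {
    both <- tier_from_census(mutate(cen, ba = 0, bs = 0, bp = 0)) %in% c("P", "LP") &&
      tier_from_census(mutate(cen, vs = 0, s = 0, m = 0, su = 0)) %in% c("B", "LB")
    if (both) notes <- c(notes, "conflicting pathogenic and benign evidence")
  }
  capped <- FALSE
  if (tier == "P" && identical(route_validity_tier(profile, route), "Moderate")) {
    tier <- "LP"
    capped <- TRUE
    notes <- c(notes, paste0("capped at LP: ", profile$gene,
                             " gene-disease validity is Moderate"))
  }
  if (identical(route, "undetermined")) {
    if (tier != "VUS") {
      notes <- c(notes, paste0("mechanism route undetermined: classification forced ",
                               "to VUS (was ", tier, ")"))
    } else {
      notes <- c(notes, "mechanism route undetermined: variant remains VUS")
    }
    tier <- "VUS"
  }
  dj <- criteria |>
    filter(.data$strength != "not_applicable",
           .data$code %in% c("PS4", "BP5", "BP2"))
  if (all(c("PS4") %in% dj$code) && any(dj$code %in% c("BP5", "BP2"))) {
    notes <- c(notes, "audit: proband(s) contributed to both PS4 and BP5/BP2 tallies")
  }
  structure(list(identity = identity, tier = tier, criteria = criteria,
                 census = cen, mechanism_route = route,
                 capped_by_validity = capped, notes = notes),
            class = "ras_classification")
}

#' @export
print.ras_classification <- function(x, ...) {
  id <- x$identity
  hdr <- if (!is.null(id)) paste0(id$gene, " ", id$hgvs_c,
                                  if (!is.na(id$hgvs_p)) paste0(" ", id$hgvs_p)) else "variant"
  applied <- filter(x$criteria, .data$strength != "not_applicable")
  cat("<ras_classification> ", hdr, "\n", sep = "")
  cat("  tier: ", x$tier,
      if (x$capped_by_validity) " (capped by gene validity)",
      "  route: ", x$mechanism_route, "\n", sep = "")
  cat("  applied: ", if (nrow(applied) == 0) "none" else
    paste(applied$label, collapse = ", "), "\n", sep = "")
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

#' Classify one variant from its evidence bundle
#'
#' Runs the full engine: bundle validation, LZTR1 mechanism routing where
#' relevant, every criterion evaluator applicable to the route, passthrough
#' merging and rubric combination.
#'
#' The dominant-route criteria are the case-observation codes (PS2/PM6,
#' PS4) and missense constraint (PP2); the recessive LZTR1 route replaces
#' them with PVS1 and PM3. Frequency, computational, functional,
#' protein-length, hotspot/domain, precedent and benign criteria are
#' evaluated on every route. When the route is undetermined neither
#' route-specific set is scored and the outcome is forced to VUS.
#'
#' @param bundle An [evidence_bundle()].
#' @param kb Knowledge base from [load_knowledge_base()].
#' @param case_table Optional case-count table for PM5.
#' @param known_pathogenic Optional known-pathogenic index for PS1.
#' @param transcript_meta Optional exon table for LZTR1 PVS1; defaults to
#'   the knowledge base's packaged transcript.
#' @return An object of class `ras_classification`.
#' @export
classify_variant <- function(bundle, kb = load_knowledge_base(),
                             case_table = NULL, known_pathogenic = NULL,
                             transcript_meta = NULL) {
  violations <- validate_bundle(bundle, kb)
  if (length(violations) > 0) {
    abort(paste0("invalid evidence bundle:\n  - ",
                 paste(violations, collapse = "\n  - ")))
  }
  id <- bundle$identity
  profile <- kb_profile(kb, id$gene)

  if (id$gene == "LZTR1") {
    mech <- route_lztr1(bundle, kb)
  } else {
    mech <- tibble(route = "AD", basis = "inheritance_pattern",
                   note = "single-mechanism gene")
  }
  route <- mech$route[[1]]

  splice_label <- {
    sp <- bundle$computational$splice_predictions
    if (length(sp) > 0) as.character(sp[[1]]) else NULL
  }

  crits <- list()
  if (route == "AD") {
    crits <- c(crits, list(
      score_de_novo(bundle$probands),
      score_ps4(bundle$probands),
      evaluate_pp2(profile, id)
    ))
  }
  if (route == "AR" && profile$pvs1_applicable) {
    tm <- transcript_meta %||% kb$transcripts[[id$gene]]
    crits <- c(crits, list(evaluate_pvs1(id, tm)))
  }
  if (route == "AR" && profile$pm3_applicable) {
    crits <- c(crits, list(evaluate_pm3(bundle$trans_observations, id)))
  }
  mechanism_for_freq <- if (route == "AR") "AR" else "AD"
  verdict <- evaluate_frequency(bundle$population, profile, mechanism_for_freq)
  crits <- c(crits, list(
    frequency_criterion(verdict),
    evaluate_computational(bundle$computational),
    evaluate_ps3(bundle$functional, profile),
    evaluate_pm4_bp3(id),
    evaluate_pm1_pm5(id, profile, case_table = case_table, kb = kb),
    evaluate_ps1(id, profile, known_pathogenic, kb = kb,
                 splice_impact = splice_label),
    score_bs2(bundle$family)
  ))
  if (route != "AR") {
    # on the recessive route an in-trans pathogenic partner is PM3 support,
    # not benign evidence, so the BP5/BP2 scorer is dominant-route only
    crits <- c(crits, list(score_bp5_bp2(bundle$probands,
                                         bundle$trans_observations,
                                         gene = id$gene)))
  }
  criteria <- bind_rows(crits)
  criteria <- bind_rows(criteria, bundle$passthrough_criteria)

  res <- combine_criteria(criteria, profile, route, identity = id)
  res$notes <- c(mech$note[[1]][nzchar(mech$note[[1]])], res$notes)
  res$frequency_verdict <- verdict
  res
}

#' Classify a list of evidence bundles
#'
#' @param bundles List of [evidence_bundle()] objects.
#' @inheritParams classify_variant
#' @return Tibble with one row per variant (`gene`, `hgvs_c`, `hgvs_p`,
#'   `tier`, `mechanism_route`, `capped_by_validity`, `applied` codes,
#'   `result` list-column of full `ras_classification` objects), in input
#'   order.
#' @export
classify_bundles <- function(bundles, kb = load_knowledge_base(),
                             case_table = NULL, known_pathogenic = NULL,
                             transcript_meta = NULL) {
  results <- map(bundles, classify_variant, kb = kb, case_table = case_table,
                 known_pathogenic = known_pathogenic,
                 transcript_meta = transcript_meta)
  list_rbind(map(results, function(r) {
    applied <- filter(r$criteria, .data$strength != "not_applicable")
    tibble(gene = r$identity$gene, hgvs_c = r$identity$hgvs_c,
           hgvs_p = r$identity$hgvs_p, tier = r$tier,
           mechanism_route = r$mechanism_route,
           capped_by_validity = r$capped_by_validity,
           applied = paste(applied$label, collapse = ","),
           result = list(r))
  }))
}
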