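# Deterministic threshold evaluators: population frequency, computational
# predictions, gene constraint, functional assays, protein-length and
# structural criteria.

#' Filtering allele frequency (one-sided binomial lower bound)
#'
#' The lower bound of the one-sided confidence interval of the allele
#' frequency given an observed allele count and total allele number --
#' the exact (Clopper-Pearson style) binomial lower limit, the method behind
#' the widely used allele-frequency web calculator. Zero observed alleles
#' give a filtering frequency of zero.
#'
#' @param allele_count Observed allele count(s), nonnegative.
#' @param allele_number Total allele number(s), positive.
#' @param confidence One-sided confidence level (default 0.95).
#' @return Numeric vector of filtering allele frequencies.
#' @export
filtering_allele_frequency <- function(allele_count, allele_number, confidence = 0.95) {
  if (any(allele_number <= 0)) abort("allele_number must be positive")
  if (any(allele_count < 0) || any(allele_count > allele_number)) {
    abort("allele_count must lie in [0, allele_number]")
  }
  ifelse(allele_count == 0, 0,
         qbeta(1 - confidence, allele_count, allele_number - allele_count + 1))
}

#' Evaluate population-frequency criteria (BA1 / BS1 / PM2_Supporting)
#'
#' Uses the supplied Grpmax filtering allele frequency, or derives one as the
#' maximum exact-binomial lower bound across non-bottlenecked subpopulations.
#' Thresholds (inclusive for BA1/BS1, exclusive for the PM2 rarity bound) are
#' per-gene knowledge-base data; the recessive LZTR1 route uses the stricter
#' heterozygote-adjusted rarity bound. PM2 is only ever emitted at
#' supporting strength.
#'
#' @param population A [population_data()].
#' @param profile Gene profile from [kb_profile()].
#' @param mechanism `"AD"` or `"AR"` -- selects the applicable PM2 bound.
#' @return One-row tibble (`code`, `faf_used`, `population`) of class
#'   `ras_frequency_verdict`; `code` is `BA1`, `BS1`, `PM2_Supporting` or
#'   `none`.
#' @export
evaluate_frequency <- function(population, profile, mechanism = c("AD", "AR")) {
  mechanism <- match.arg(mechanism)
  faf <- NA_real_
  pop_label <- NA_character_
  if (!is.na(population$grpmax_faf)) {
    faf <- population$grpmax_faf
    pop_label <- "Grpmax"
  } else if (nrow(population$subpopulations) > 0) {
    sp <- filter(population$subpopulations, !.data$bottlenecked)
    if (nrow(sp) > 0) {
      fafs <- filtering_allele_frequency(sp$allele_count, sp$allele_number)
      faf <- max(fafs)
      pop_label <- sp$population[which.max(fafs)]
    }
  }
  pm2 <- if (mechanism == "AR") profile$pm2_threshold_ar else profile$pm2_threshold
  code <- if (is.na(faf)) {
    "none"
  } else if (faf >= profile$ba1_threshold) {
    "BA1"
  } else if (faf >= profile$bs1_threshold) {
    "BS1"
  } else if (faf < pm2) {
    "PM2_Supporting"
  } else {
    "none"
  }
  out <- tibble(code = code, faf_used = faf, population = pop_label)
  class(out) <- c("ras_frequency_verdict", class(out))
  out
}

frequency_criterion <- function(verdict) {
  faf_txt <- if (is.na(verdict$faf_used)) "no frequency data" else
    paste0("Grpmax FAF ", signif(verdict$faf_used, 4),
           if (!is.na(verdict$population)) paste0(" (", verdict$population, ")"))
  switch(verdict$code,
    BA1 = criterion("BA1", "benign", "standalone", rationale = faf_txt),
    BS1 = criterion("BS1", "benign", "strong", rationale = faf_txt),
    PM2_Supporting = criterion("PM2", "pathogenic", "supporting", rationale = faf_txt),
    criterion("PM2", "pathogenic", "not_applicable",
              rationale = paste0(faf_txt, "; no frequency criterion met"))
  )
}

#' Evaluate computational predictions (PP3 / BP4)
#'
#' REVEL at or above 0.7 applies PP3 at supporting strength (never higher);
#' REVEL at or below 0.3 applies BP4. Scores strictly between the thresholds,
#' or a missing score, apply neither. Mutually exclusive by construction.
#'
#' @param computational A [computational_evidence()].
#' @return One-row criterion tibble.
#' @export
evaluate_computational <- function(computational) {
  revel <- computational$revel
  if (is.na(revel)) {
    return(criterion("PP3", "pathogenic", "not_applicable", rationale = "no REVEL score"))
  }
  if (revel >= 0.7) {
    criterion("PP3", "pathogenic", "supporting",
              rationale = paste0("REVEL ", revel, " >= 0.7"))
  } else if (revel <= 0.3) {
    criterion("BP4", "benign", "supporting",
              rationale = paste0("REVEL ", revel, " <= 0.3"))
  } else {
    criterion("PP3", "pathogenic", "not_applicable",
              rationale = paste0("REVEL ", revel, " between thresholds"))
  }
}

#' Evaluate missense constraint (PP2)
#'
#' Applicable only to missense variants in the genes with significant
#' missense constraint (gnomAD missense z-score >= 3.09): BRAF, MAP2K1,
#' PTPN11 and PPP1CB, encoded as the profile's `pp2_applicable` mask.
#'
#' @param profile Gene profile.
#' @param identity A [variant_identity()].
#' @return One-row criterion tibble.
#' @export
evaluate_pp2 <- function(profile, identity) {
  if (identity$consequence == "missense" && profile$pp2_applicable) {
    criterion("PP2", "pathogenic", "supporting",
              rationale = paste0(profile$gene, " is missense-constrained (z >= 3.09)"))
  } else {
    criterion("PP2", "pathogenic", "not_applicable",
              rationale = if (identity$consequence != "missense") "not a missense variant"
                          else paste0("PP2 not applicable to ", profile$gene))
  }
}

#' Evaluate functional assay evidence (PS3; BS3 never applies)
#'
#' Counts distinct approved assays (by assay id -- replicates of one assay
#' count once) with the expected abnormal result: two or more apply
#' PS3_Moderate (the cap), exactly one applies PS3_Supporting. Normal
#' results never generate benign evidence because well-established
#' pathogenic variants can score wild type under some conditions, so BS3 is
#' not applicable. Genes with an empty assay registry (PPP1CB) always return
#' not-applicable.
#'
#' @param functional A [functional_evidence()].
#' @param profile Gene profile.
#' @return One-row criterion tibble.
#' @export
evaluate_ps3 <- function(functional, profile) {
  reg <- profile$approved_assays$id
  if (length(reg) == 0) {
    return(criterion("PS3", "pathogenic", "not_applicable",
                     rationale = paste0("no approved functional assays for ", profile$gene)))
  }
  ab <- functional$assays |>
    filter(.data$result == "abnormal_expected", .data$assay_id %in% reg)
  n_ab <- n_distinct(ab$assay_id)
  unapproved <- setdiff(unique(functional$assays$assay_id), reg)
  note <- if (length(unapproved) > 0) {
    paste0("; unapproved assay(s) ignored: ", paste(unapproved, collapse = ", "))
  } else ""
  if (n_ab >= 2) {
    criterion("PS3", "pathogenic", "moderate",
              rationale = paste0(n_ab, " distinct approved assays abnormal (capped at Moderate)", note))
  } else if (n_ab == 1) {
    criterion("PS3", "pathogenic", "supporting",
              rationale = paste0("1 approved assay abnormal", note))
  } else {
    criterion("PS3", "pathogenic", "not_applicable",
              rationale = paste0("no abnormal results in approved assays", note))
  }
}

#' Evaluate protein-length change (PM4; BP3 never applies)
#'
#' In-frame indels and stop-loss variants earn PM4 at moderate strength: no
#' benign repetitive region exists in any covered gene's coding sequence, so
#' every in-frame length change is treated as occurring in a non-repeat
#' region, and BP3 is never emitted.
#'
#' @param identity A [variant_identity()].
#' @return One-row criterion tibble.
#' @export
evaluate_pm4_bp3 <- function(identity) {
  if (identity$consequence %in% c("inframe_indel", "stop_loss")) {
    criterion("PM4", "pathogenic", "moderate",
              rationale = paste0(identity$consequence,
                                 " in a non-repeat coding region"))
  } else {
    criterion("PM4", "pathogenic", "not_applicable",
              rationale = "no protein-length change")
  }
}

#' Evaluate hotspot and functional-domain criteria (PM1, PM5/PM5_Strong)
#'
#' For a missense variant: PM1 applies when the residue lies in a predefined
#' functional domain; PM5_Strong applies when the residue (or an analogous
#' paralog residue, when a knowledge base with alignments is supplied) is a
#' recurrence hotspot; baseline PM5 at moderate strength applies when a
#' different P/LP missense change is known at the residue. PM1 and PM5 may
#' be used together, but PM1 and PM5_Strong may not: when both qualify,
#' PM5_Strong is downgraded to moderate PM5 alongside PM1. Splice-affecting
#' variants never receive PM5.
#'
#' When the profile carries a precomputed hotspot list it wins; otherwise
#' hotspots are detected from `case_table` via
#' [detect_pm5_strong_hotspots()].
#'
#' @param identity A [variant_identity()].
#' @param profile Gene profile.
#' @param case_table Optional case-count table (see
#'   [read_case_count_table()]); backs runtime hotspot detection and the
#'   moderate PM5 rule.
#' @param kb Optional `ras_kb`; enables analogous-residue hotspot/PM5 checks
#'   through the paralog alignment.
#' @return Criterion tibble with zero, one or two rows (PM1 and/or PM5).
#' @export
evaluate_pm1_pm5 <- function(identity, profile, case_table = NULL, kb = NULL) {
  if (identity$consequence %in% c("canonical_splice", "splice_region")) {
    return(criterion("PM5", "pathogenic", "not_applicable",
                     rationale = "PM5 is not applicable to variants that alter splicing"))
  }
  if (identity$consequence != "missense" || is.na(identity$residue_position)) {
    return(empty_criteria())
  }
  pos <- identity$residue_position
  gene <- identity$gene

  domain <- in_pm1_domain(profile, pos)

  hotspots <- profile$pm5_strong_hotspots
  if (length(hotspots) == 0 && !is.null(case_table)) {
    hotspots <- detect_pm5_strong_hotspots(case_table) |>
      filter(.data$gene == !!gene) |>
      pull(.data$residue_position)
  }
  candidates <- tibble(gene = gene, residue_position = pos)
  if (!is.null(kb) && !identical(profile$paralog_family, "none") &&
      profile$paralog_family %in% names(kb$alignments)) {
    mapped <- tryCatch(map_analogous_residue(kb, gene, pos), error = function(e) NULL)
    if (!is.null(mapped)) candidates <- distinct(bind_rows(candidates, mapped))
  }
  is_hotspot <- pos %in% hotspots
  hotspot_via <- if (is_hotspot) paste0(gene, " residue ", pos) else NA_character_
  if (!is_hotspot && !is.null(kb) && nrow(candidates) > 1) {
    for (i in seq_len(nrow(candidates))) {
      g2 <- candidates$gene[i]; p2 <- candidates$residue_position[i]
      if (g2 == gene) next
      hs2 <- if (g2 %in% names(kb$genes)) kb$genes[[g2]]$pm5_strong_hotspots else integer()
      if (p2 %in% hs2) {
        is_hotspot <- TRUE
        hotspot_via <- paste0("analogous residue ", g2, " ", p2)
        break
      }
    }
  }

  pm5_moderate <- FALSE
  if (!is.null(case_table)) {
    hits <- as_tibble(case_table) |>
      inner_join(candidates, by = c("gene", "residue_position")) |>
      filter(.data$classification %in% c("P", "LP"),
             is.na(identity$alt_aa) | .data$alt_aa != identity$alt_aa)
    pm5_moderate <- nrow(hits) > 0
  }

  out <- empty_criteria()
  if (!is.na(domain)) {
    out <- bind_rows(out, criterion("PM1", "pathogenic", "moderate",
                                    rationale = paste0("residue ", pos, " in ",
                                                       domain, " domain")))
  }
  if (is_hotspot && is.na(domain)) {
    out <- bind_rows(out, criterion("PM5", "pathogenic", "strong",
                                    rationale = paste0("recurrence hotspot: ", hotspot_via)))
  } else if (is_hotspot && !is.na(domain)) {
    out <- bind_rows(out, criterion("PM5", "pathogenic", "moderate",
                                    rationale = paste0("hotspot (", hotspot_via,
                                                       ") downgraded: PM5_Strong cannot combine with PM1")))
  } else if (pm5_moderate) {
    out <- bind_rows(out, criterion("PM5", "pathogenic", "moderate",
                                    rationale = paste0("different P/LP missense known at residue ", pos)))
  }
  out
}

#' Evaluate same-change precedent (PS1), including paralogous residues
#'
#' PS1 applies when the identical amino-acid change has been classified
#' pathogenic in the same gene, or at the analogous aligned residue of a
#' paralog family member. For splice variants, PS1 requires a known
#' pathogenic splice variant at the same (or analogous) position *and* an
#' identical predicted splice impact -- in-frame versus out-of-frame
#' predictions must agree, since an in-frame event may act through gain of
#' function.
#'
#' @param identity A [variant_identity()].
#' @param profile Gene profile.
#' @param known_pathogenic Known-pathogenic index tibble (see
#'   [read_known_pathogenic()]).
#' @param kb Optional `ras_kb` for analogous-residue mapping.
#' @param splice_impact Predicted splice-impact label for the variant being
#'   classified (required to match splice precedents).
#' @param position Position to match against the index; defaults to the
#'   identity's residue position. Splice variants (which carry no residue
#'   fields) must pass the affected position explicitly.
#' @return One-row criterion tibble.
#' @export
evaluate_ps1 <- function(identity, profile, known_pathogenic, kb = NULL,
                         splice_impact = NULL, position = NULL) {
  if (is.null(known_pathogenic) || nrow(known_pathogenic) == 0) {
    return(criterion("PS1", "pathogenic", "not_applicable",
                     rationale = "no known-pathogenic index supplied"))
  }
  gene <- identity$gene
  is_splice <- identity$consequence %in% c("canonical_splice", "splice_region")
  position <- position %||% identity$residue_position

  candidate_positions <- function(pos) {
    cand <- tibble(gene = gene, position = pos)
    if (!is.null(kb) && !identical(profile$paralog_family, "none") &&
        profile$paralog_family %in% names(kb$alignments)) {
      mapped <- tryCatch(map_analogous_residue(kb, gene, pos), error = function(e) NULL)
      if (!is.null(mapped)) {
        cand <- distinct(bind_rows(cand, rename(mapped, position = "residue_position")))
      }
    }
    cand
  }

  if (!is_splice) {
    if (identity$consequence != "missense" || is.na(position)) {
      return(criterion("PS1", "pathogenic", "not_applicable",
                       rationale = "PS1 precedent matching requires a missense or splice variant"))
    }
    cand <- candidate_positions(position)
    hits <- known_pathogenic |>
      filter(.data$type == "missense", .data$classification == "P") |>
      inner_join(cand, by = c("gene", "position")) |>
      filter(.data$alt_aa == identity$alt_aa)
    if (nrow(hits) > 0) {
      via <- paste0(hits$gene[1], " position ", hits$position[1])
      return(criterion("PS1", "pathogenic", "strong",
                       rationale = paste0("identical change classified P at ", via)))
    }
    return(criterion("PS1", "pathogenic", "not_applicable",
                     rationale = "no pathogenic precedent for this change"))
  }

  # splice branch
  if (is.null(splice_impact) || is.null(position) || is.na(position)) {
    return(criterion("PS1", "pathogenic", "not_applicable",
                     rationale = "splice PS1 requires a position and a predicted splice impact"))
  }
  cand <- candidate_positions(position)
  hits <- known_pathogenic |>
    filter(.data$type == "splice", .data$classification == "P") |>
    inner_join(cand, by = c("gene", "position")) |>
    filter(.data$splice_impact == !!splice_impact)
  if (nrow(hits) > 0) {
    criterion("PS1", "pathogenic", "strong",
              rationale = paste0("pathogenic splice precedent with matching predicted impact ('",
                                 splice_impact, "')"))
  } else {
    criterion("PS1", "pathogenic", "not_applicable",
              rationale = "no splice precedent with the same predicted impact")
  }
}
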