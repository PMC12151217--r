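# Point-based scorers for the four case-observation criterion groups.
# Tariffs and strength bins follow the expert-panel point tables; threshold
# comparisons are inclusive at the printed bin values, and fractional totals
# between bins fall to the lower strength.

de_novo_tariff <- function(de_novo, phenotype) {
  case_when(
    de_novo == "confirmed" & phenotype == "consistent" ~ 2,
    de_novo == "confirmed" & phenotype == "limited" ~ 1,
    de_novo == "assumed" & phenotype == "consistent" ~ 1,
    de_novo == "assumed" & phenotype == "limited" ~ 0.5,
    .default = 0
  )
}

de_novo_bins <- c(very_strong = 4, strong = 2, moderate = 1, supporting = 0.5)
ps4_bins <- c(strong = 5, moderate = 3, supporting = 1)
bs2_bins <- c(strong = -3, supporting = -1)
bp_bins <- c(strong = -3, supporting = -1)

#' Score de novo occurrences (PS2/PM6)
#'
#' Each de novo proband contributes points by phenotypic consistency and
#' parentage status: confirmed parentage scores 2 (consistent phenotype) or
#' 1 (limited); assumed parentage scores 1 or 0.5. Phenotypes not consistent
#' with a RASopathy contribute nothing. The combined tally is binned
#' (0.5 Supporting / 1 Moderate / 2 Strong / 4 VeryStrong, inclusive) and a
#' single code is emitted: PS2 when parentage is confirmed for any
#' contributing proband, otherwise PM6.
#'
#' @param probands Tibble of [proband_observation()] rows.
#' @return One-row criterion tibble; per-proband contributions are available
#'   via [point_tally()].
#' @export
score_de_novo <- function(probands) {
  probands <- as_tibble(probands)
  if (nrow(probands) == 0) {
    out <- criterion("PM6", "pathogenic", "not_applicable", 0,
                     "no de novo probands")
    return(tally_attr(out, NULL))
  }
  pts <- de_novo_tariff(probands$de_novo, probands$phenotype_category)
  contrib <- tibble(observation = seq_len(nrow(probands)), points = pts,
                    reason = paste0(probands$de_novo, " de novo, ",
                                    probands$phenotype_category, " phenotype")) |>
    filter(.data$points != 0 | probands$de_novo %in% c("confirmed", "assumed"))
  total <- sum(pts)
  code <- if (any(probands$de_novo == "confirmed" & pts > 0)) "PS2" else "PM6"
  strength <- bin_points(total, de_novo_bins)
  out <- criterion(code, "pathogenic", strength, total,
                   paste0("de novo point total ", total, " across ",
                          sum(pts > 0), " contributing proband(s)"))
  tally_attr(out, contrib)
}

#' Score proband counts for a dominant disorder (PS4)
#'
#' Per proband: 1 point for a well-phenotyped RASopathy case, 0.5 for
#' limited phenotypic information (prenatal cases with a qualifying feature,
#' panel orders without clinical information, limited exome/genome cases),
#' 0 for no information or isolated nonspecific features, and -1 for a well
#' phenotyped case consistent with a non-RASopathy disorder. The tally is
#' binned 1/3/5 (Supporting/Moderate/Strong). A negative tally never yields
#' benign evidence here; alternate-diagnosis cases are handled by
#' [score_bp5_bp2()].
#'
#' @inheritParams score_de_novo
#' @return One-row criterion tibble.
#' @export
score_ps4 <- function(probands) {
  probands <- as_tibble(probands)
  if (nrow(probands) == 0) {
    out <- criterion("PS4", "pathogenic", "not_applicable", 0, "no probands")
    return(tally_attr(out, NULL))
  }
  pts <- case_when(
    probands$phenotype_category == "consistent" ~ 1,
    probands$phenotype_category == "limited" ~ 0.5,
    probands$phenotype_category == "inconsistent_alt_disorder" ~ -1,
    .default = 0
  )
  total <- sum(pts)
  strength <- bin_points(total, ps4_bins)
  out <- criterion("PS4", "pathogenic", strength, total,
                   paste0("proband phenotype point total ", total, " across ",
                          nrow(probands), " proband(s)"))
  tally_attr(out, tibble(observation = seq_along(pts), points = pts,
                         reason = probands$phenotype_category))
}

#' Score healthy carriers (BS2)
#'
#' Per individual: -3 for a healthy, clinically assessed homozygote, -1 for
#' a healthy assessed heterozygote, -0.25 when the only information is
#' "unaffected", 0 when no clinical information exists. Binned at -1
#' (Supporting) and -3 (Strong); no moderate bin exists for BS2.
#'
#' @param family Tibble of [family_observation()] rows.
#' @return One-row criterion tibble.
#' @export
score_bs2 <- function(family) {
  family <- as_tibble(family)
  if (nrow(family) == 0) {
    out <- criterion("BS2", "benign", "not_applicable", 0, "no family observations")
    return(tally_attr(out, NULL))
  }
  pts <- case_when(
    family$health_status == "healthy_assessed" & family$zygosity == "hom" ~ -3,
    family$health_status == "healthy_assessed" ~ -1,
    family$health_status == "unaffected_unassessed" ~ -0.25,
    .default = 0
  )
  total <- sum(pts)
  strength <- bin_points_benign(total, bs2_bins)
  out <- criterion("BS2", "benign", strength, total,
                   paste0("healthy-carrier point total ", total, " across ",
                          nrow(family), " individual(s)"))
  tally_attr(out, tibble(observation = seq_along(pts), points = pts,
                         reason = paste0(family$health_status, " ", family$zygosity)))
}

#' Score alternate molecular cause observations (BP5/BP2 merged)
#'
#' One point of -1 per qualifying observation: a proband whose phenotype is
#' inconsistent with a RASopathy *and* in whom a causative variant was
#' identified; a molecular cause found in a different RASopathy gene
#' (double heterozygote); or a molecular cause in trans or in cis with the
#' variant being classified. An inconsistent phenotype with no causative
#' variant contributes nothing. Points are additive between the BP5-type and
#' BP2-type clauses but only one code is emitted: BP2 when any phase-based
#' (in trans / in cis) observation contributed, else BP5. Binned at -1
#' (Supporting) and -3 (Strong).
#'
#' @inheritParams score_de_novo
#' @param trans_observations Tibble of [trans_observation()] rows.
#' @param gene Gene of the variant being classified; used to recognise the
#'   different-gene clause. `NULL` disables that clause.
#' @return One-row criterion tibble.
#' @export
score_bp5_bp2 <- function(probands, trans_observations = NULL, gene = NULL) {
  probands <- as_tibble(probands %||% empty_probands())
  trans_observations <- as_tibble(trans_observations %||% empty_trans())

  p_pts <- if (nrow(probands) > 0) {
    ifelse(probands$phenotype_category == "inconsistent_alt_disorder" &
             probands$alt_cause_identified, -1, 0)
  } else numeric()

  if (nrow(trans_observations) > 0) {
    plp <- trans_observations$partner_classification %in% c("P", "LP")
    phase_based <- trans_observations$phase %in% c("confirmed_trans", "cis")
    diff_gene <- if (is.null(gene)) rep(FALSE, nrow(trans_observations)) else
      trans_observations$partner_gene != gene
    t_pts <- ifelse(plp & (phase_based | diff_gene), -1, 0)
    any_phase <- any(t_pts < 0 & phase_based)
  } else {
    t_pts <- numeric()
    any_phase <- FALSE
  }

  total <- sum(p_pts) + sum(t_pts)
  code <- if (any_phase) "BP2" else "BP5"
  strength <- bin_points_benign(total, bp_bins)
  out <- criterion(code, "benign", strength, total,
                   paste0("alternate-cause point total ", total,
                          if (any_phase) " (includes phase-based observation(s))" else ""))
  tally_attr(out, tibble(
    observation = seq_len(length(p_pts) + length(t_pts)),
    points = c(p_pts, t_pts),
    reason = c(rep("proband alternate diagnosis", length(p_pts)),
               rep("trans/cis or different-gene partner", length(t_pts)))
  ))
}
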