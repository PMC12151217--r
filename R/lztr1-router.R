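# LZTR1 is the one covered gene with two disease mechanisms: dominant
# (typically dominant-negative missense) and recessive (loss-of-function /
# hypomorphic). The router decides which criteria set applies; the PVS1 and
# PM3 evaluators implement the recessive-specific codes.

pm3_bins <- c(very_strong = 4, strong = 2, moderate = 1, supporting = 0.5)

#' Decide the LZTR1 mechanism route (AD vs AR)
#'
#' Implements the dual-mechanism decision tree, in order: (1) case-level
#' inheritance pattern (a biallelic affected proband routes AR; a confirmed
#' de novo heterozygous proband with a consistent phenotype routes AD;
#' conflicting signals leave the route undetermined); (2) presumed
#' loss-of-function consequence (nonsense, frameshift, or canonical splice
#' predicted out-of-frame) routes AR; (3) functional data route via the
#' knowledge-base assay-to-mechanism map; (4) otherwise the route is
#' undetermined and the engine forces a VUS outcome.
#'
#' @param bundle An LZTR1 [evidence_bundle()].
#' @param kb Knowledge base (supplies the assay-to-mechanism map).
#' @return One-row tibble (`route`, `basis`, `note`) of class
#'   `ras_mechanism`; `route` is `AD`, `AR` or `undetermined`.
#' @export
route_lztr1 <- function(bundle, kb = NULL) {
  id <- bundle$identity
  if (id$gene != "LZTR1") abort("route_lztr1() applies only to LZTR1 bundles")

  decision <- function(route, basis, note = "") {
    out <- tibble(route = route, basis = basis, note = note)
    class(out) <- c("ras_mechanism", class(out))
    out
  }

  pb <- bundle$probands
  biallelic <- nrow(pb) > 0 && any(pb$zygosity %in% c("hom", "compound_het_confirmed_trans"))
  ad_pattern <- nrow(pb) > 0 && any(pb$de_novo == "confirmed" & pb$zygosity == "het" &
                                      pb$phenotype_category == "consistent")
  if (biallelic && ad_pattern) {
    return(decision("undetermined", "none",
                    "conflicting case-level inheritance signals (biallelic and de novo het)"))
  }
  if (biallelic) return(decision("AR", "inheritance_pattern", "biallelic affected proband(s)"))
  if (ad_pattern) return(decision("AD", "inheritance_pattern",
                                  "confirmed de novo heterozygous consistent proband"))

  lof <- id$consequence %in% c("nonsense", "frameshift") ||
    (id$consequence == "canonical_splice" &&
       identical(id$splice_frame, "out_of_frame"))
  if (lof) return(decision("AR", "presumed_lof",
                           paste0("presumed loss-of-function consequence (",
                                  id$consequence, ")")))

  if (!is.null(kb) && nrow(bundle$functional$assays) > 0) {
    reg <- kb_profile(kb, "LZTR1")$approved_assays
    ab <- bundle$functional$assays |>
      filter(.data$result == "abnormal_expected") |>
      inner_join(reg, by = c(assay_id = "id"))
    mechs <- unique(ab$mechanism)
    if (length(mechs) == 1) {
      return(decision(mechs, "functional_data",
                      paste0("abnormal results in ", mechs, "-supporting assay(s)")))
    }
    if (length(mechs) > 1) {
      return(decision("undetermined", "none", "functional data support both mechanisms"))
    }
  }
  decision("undetermined", "none",
           "no inheritance pattern, presumed-LoF consequence or informative functional data")
}

#' Evaluate loss-of-function (PVS1) for recessive LZTR1
#'
#' Applies the generic loss-of-function decision framework: a premature stop
#' predicted to trigger nonsense-mediated decay (more than 50 nt upstream of
#' the last exon-exon junction, computed from the transcript exon table)
#' earns PVS1 at very strong; an NMD-escaping truncation, an unplaceable
#' stop, or a canonical splice variant predicted out-of-frame earns PVS1
#' reduced one level (Strong); an in-frame splice outcome is not applicable
#' under PVS1 because a truncated in-frame product may act through gain of
#' function. Strengths are marked provisional pending panel-curated
#' exon-level calls.
#'
#' @param identity An LZTR1 [variant_identity()] (uses `cds_stop_pos` and
#'   `splice_frame`).
#' @param transcript_meta Exon table with a `cds_width` column (nucleotides
#'   of CDS per exon, in order); `NULL` falls back on the packaged synthetic
#'   default via the knowledge base caller.
#' @return One-row criterion tibble.
#' @export
evaluate_pvs1 <- function(identity, transcript_meta = NULL) {
  if (identity$gene != "LZTR1") abort("PVS1 is applicable only to LZTR1")
  prov <- " [provisional strength pending curated exon-level rules]"
  cons <- identity$consequence
  if (cons %in% c("nonsense", "frameshift")) {
    if (!is.null(transcript_meta) && !is.na(identity$cds_stop_pos)) {
      w <- transcript_meta$cds_width
      last_junction <- sum(w) - w[length(w)]
      nmd <- identity$cds_stop_pos < (last_junction - 50)
      if (nmd) {
        return(criterion("PVS1", "pathogenic", "very_strong",
                         rationale = paste0("premature stop at CDS ", identity$cds_stop_pos,
                                            ", >50 nt upstream of the last junction (",
                                            last_junction, "): NMD predicted", prov)))
      }
      return(criterion("PVS1", "pathogenic", "strong",
                       rationale = paste0("premature stop at CDS ", identity$cds_stop_pos,
                                          " predicted to escape NMD: strength reduced one level", prov)))
    }
    return(criterion("PVS1", "pathogenic", "strong",
                     rationale = paste0("truncating variant, stop position unknown: ",
                                        "conservative one-level reduction", prov)))
  }
  if (cons == "canonical_splice") {
    if (identical(identity$splice_frame, "out_of_frame")) {
      return(criterion("PVS1", "pathogenic", "strong",
                       rationale = paste0("canonical splice, predicted out-of-frame", prov)))
    }
    if (identical(identity$splice_frame, "in_frame")) {
      return(criterion("PVS1", "pathogenic", "not_applicable",
                       rationale = "in-frame splice outcome: possible gain-of-function product"))
    }
    return(criterion("PVS1", "pathogenic", "not_applicable",
                     rationale = "canonical splice with no frame prediction"))
  }
  criterion("PVS1", "pathogenic", "not_applicable",
            rationale = paste0("consequence '", cons, "' is not loss-of-function"))
}

#' Evaluate in-trans observations for recessive disease (PM3)
#'
#' Per observation: 1 point for a confirmed in-trans P/LP partner, 0.5 for a
#' suspected-trans or phase-unknown P/LP partner, and 0.5 for homozygosity
#' (the partner is the same variant). Points are halved for probands with
#' limited phenotypic information. The tally is binned 0.5/1/2/4
#' (Supporting/Moderate/Strong/VeryStrong). Partners in cis contribute
#' nothing here.
#'
#' @param trans_observations Tibble of [trans_observation()] rows.
#' @param identity Optional [variant_identity()]; when supplied, a partner
#'   with the same gene and coding change is recognised as homozygosity.
#' @return One-row criterion tibble.
#' @export
evaluate_pm3 <- function(trans_observations, identity = NULL) {
  tr <- as_tibble(trans_observations %||% empty_trans())
  if (nrow(tr) == 0) {
    out <- criterion("PM3", "pathogenic", "not_applicable", 0, "no in-trans observations")
    return(tally_attr(out, NULL))
  }
  same_variant <- if (!is.null(identity)) {
    tr$partner_gene == identity$gene &
      !is.na(tr$partner_hgvs_c) & tr$partner_hgvs_c == identity$hgvs_c
  } else rep(FALSE, nrow(tr))
  plp <- tr$partner_classification %in% c("P", "LP")
  base <- case_when(
    same_variant ~ 0.5,
    plp & tr$phase == "confirmed_trans" ~ 1,
    plp & tr$phase %in% c("suspected_trans", "unknown") ~ 0.5,
    .default = 0
  )
  pts <- ifelse(tr$proband_phenotype == "limited", base / 2, base)
  total <- sum(pts)
  strength <- bin_points(total, pm3_bins)
  out <- criterion("PM3", "pathogenic", strength, total,
                   paste0("in-trans point total ", total, " across ",
                          nrow(tr), " observation(s)"))
  tally_attr(out, tibble(observation = seq_along(pts), points = pts,
                         reason = ifelse(same_variant, "homozygote",
                                         paste0(tr$phase, " ", tr$partner_classification,
                                                " partner, ", tr$proband_phenotype,
                                                " phenotype"))))
}
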