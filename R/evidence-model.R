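# Domain types for variant evidence. Enums are closed: unknown strings are
# hard errors at construction/parse time, never silently coerced.

#' Genes covered by the RASopathy specifications
#'
#' The sixteen Ras/MAPK-pathway genes the rules engine knows about. NF1 and
#' SPRED1 are deliberately absent (their specifications are maintained by a
#' different expert panel).
#'
#' @export
ras_genes <- function() {
  c("PTPN11", "BRAF", "RAF1", "SOS1", "SOS2", "KRAS", "HRAS", "NRAS",
    "MRAS", "RIT1", "RRAS2", "MAP2K1", "MAP2K2", "SHOC2", "LZTR1", "PPP1CB")
}

consequence_levels <- c("missense", "nonsense", "frameshift", "canonical_splice",
                        "splice_region", "inframe_indel", "stop_loss",
                        "synonymous", "other")
residue_consequences <- c("missense", "inframe_indel", "stop_loss")
phenotype_levels <- c("consistent", "limited", "nonspecific_or_none",
                      "inconsistent_alt_disorder")
de_novo_levels <- c("confirmed", "assumed", "inherited", "unknown")
context_levels <- c("clinical", "prenatal", "panel_no_info", "exome_genome")
prenatal_feature_levels <- c("HCM", "increased_NT", "cystic_hygroma",
                             "pleural_effusion", "hydrops")
zygosity_levels <- c("het", "hom", "compound_het_confirmed_trans",
                     "compound_het_unknown_phase")
family_health_levels <- c("healthy_assessed", "unaffected_unassessed",
                          "no_info_or_nonspecific")
assay_result_levels <- c("abnormal_expected", "normal", "ambiguous")
phase_levels <- c("confirmed_trans", "suspected_trans", "cis", "unknown")
partner_class_levels <- c("P", "LP", "other")
strength_levels <- c("standalone", "very_strong", "strong", "moderate",
                     "supporting", "not_applicable")
splice_frame_levels <- c("in_frame", "out_of_frame")

# codes the engine itself evaluates; passthrough criteria must not collide
engine_codes <- c("PVS1", "PS1", "PS2", "PM6", "PS3", "PS4", "PM1", "PM2",
                  "PM3", "PM4", "PM5", "PP2", "PP3",
                  "BA1", "BS1", "BS2", "BS3", "BP2", "BP3", "BP4", "BP5")

chk_enum <- function(x, levels, field, null_ok = FALSE) {
  if (is.null(x) || (length(x) == 1 && is.na(x))) {
    if (null_ok) return(invisible(NULL))
    abort(paste0("`", field, "` is required"))
  }
  bad <- setdiff(as.character(x), levels)
  if (length(bad) > 0) {
    abort(paste0("`", field, "` has unknown value(s): ",
                 paste(bad, collapse = ", "),
                 " (allowed: ", paste(levels, collapse = ", "), ")"))
  }
  invisible(NULL)
}

#' Variant identity
#'
#' Describes the variant being classified. `residue_position`, `ref_aa` and
#' `alt_aa` are required exactly when the consequence pins a specific residue
#' (missense, in-frame indel anchor, stop-loss). `cds_stop_pos` (CDS
#' coordinate of a premature stop) and `splice_frame` (predicted reading-frame
#' outcome of a splice event) are optional annotations consumed by the LZTR1
#' loss-of-function logic.
#'
#' @param gene Gene symbol, one of [ras_genes()].
#' @param transcript Transcript accession, e.g. `"NM_002834.5"`.
#' @param hgvs_c Coding-level HGVS description.
#' @param hgvs_p Protein-level HGVS description, or `NULL`.
#' @param consequence One of `missense`, `nonsense`, `frameshift`,
#'   `canonical_splice`, `splice_region`, `inframe_indel`, `stop_loss`,
#'   `synonymous`, `other`.
#' @param residue_position 1-based protein residue, or `NULL`.
#' @param ref_aa,alt_aa One-letter amino-acid codes, or `NULL`.
#' @param cds_stop_pos Optional CDS nucleotide position of the premature stop
#'   introduced by a nonsense/frameshift variant.
#' @param splice_frame Optional `"in_frame"` or `"out_of_frame"` prediction
#'   for splice-affecting variants.
#' @return An object of class `ras_identity`.
#' @export
variant_identity <- function(gene, transcript = NA_character_, hgvs_c = NA_character_,
                             hgvs_p = NULL, consequence, residue_position = NULL,
                             ref_aa = NULL, alt_aa = NULL, cds_stop_pos = NULL,
                             splice_frame = NULL) {
  chk_enum(gene, ras_genes(), "gene")
  chk_enum(consequence, consequence_levels, "consequence")
  if (!is.null(splice_frame)) chk_enum(splice_frame, splice_frame_levels, "splice_frame")
  out <- list(
    gene = gene, transcript = transcript, hgvs_c = hgvs_c,
    hgvs_p = hgvs_p %||% NA_character_, consequence = consequence,
    residue_position = if (is.null(residue_position)) NA_integer_ else as.integer(residue_position),
    ref_aa = ref_aa %||% NA_character_, alt_aa = alt_aa %||% NA_character_,
    cds_stop_pos = if (is.null(cds_stop_pos)) NA_integer_ else as.integer(cds_stop_pos),
    splice_frame = splice_frame %||% NA_character_
  )
  structure(out, class = "ras_identity")
}

#' One proband (case) observation
#'
#' @param phenotype_category `consistent`, `limited`, `nonspecific_or_none`
#'   or `inconsistent_alt_disorder` -- assigned by the referring clinician,
#'   never inferred by the engine.
#' @param de_novo `confirmed`, `assumed`, `inherited` or `unknown`.
#' @param context Test context: `clinical`, `prenatal`, `panel_no_info`,
#'   `exome_genome`.
#' @param prenatal_features Character vector drawn from `HCM`,
#'   `increased_NT`, `cystic_hygroma`, `pleural_effusion`, `hydrops`.
#' @param alt_cause_identified Was a causative variant for an alternate
#'   diagnosis identified in this proband?
#' @param zygosity `het`, `hom`, `compound_het_confirmed_trans`,
#'   `compound_het_unknown_phase`.
#' @return A one-row tibble; bind rows to build a proband table.
#' @export
proband_observation <- function(phenotype_category, de_novo = "unknown",
                                context = "clinical",
                                prenatal_features = character(),
                                alt_cause_identified = FALSE,
                                zygosity = "het") {
  chk_enum(phenotype_category, phenotype_levels, "phenotype_category")
  chk_enum(de_novo, de_novo_levels, "de_novo")
  chk_enum(context, context_levels, "context")
  if (length(prenatal_features) > 0) {
    chk_enum(prenatal_features, prenatal_feature_levels, "prenatal_features")
  }
  chk_enum(zygosity, zygosity_levels, "zygosity")
  tibble(phenotype_category = phenotype_category, de_novo = de_novo,
         context = context, prenatal_features = list(prenatal_features),
         alt_cause_identified = isTRUE(alt_cause_identified),
         zygosity = zygosity)
}

#' One family-member observation (for BS2)
#'
#' @param relationship Free-text relationship, e.g. `"father"`.
#' @param zygosity `het` or `hom`.
#' @param health_status `healthy_assessed` (clinically assessed for a
#'   RASopathy and healthy), `unaffected_unassessed` (reported unaffected,
#'   no assessment) or `no_info_or_nonspecific`.
#' @return A one-row tibble.
#' @export
family_observation <- function(relationship = "relative", zygosity = "het",
                               health_status) {
  chk_enum(zygosity, c("het", "hom"), "zygosity")
  chk_enum(health_status, family_health_levels, "health_status")
  tibble(relationship = relationship, zygosity = zygosity,
         health_status = health_status)
}

#' One in-trans/in-cis partner observation
#'
#' Used by the LZTR1 recessive PM3 scorer and by BP2/BP5.
#'
#' @param partner_gene Gene symbol of the partner variant.
#' @param partner_hgvs_c Coding HGVS of the partner variant (equal to the
#'   classified variant's `hgvs_c` for a homozygote).
#' @param partner_classification `P`, `LP` or `other`.
#' @param phase `confirmed_trans`, `suspected_trans`, `cis` or `unknown`.
#' @param proband_phenotype `consistent` or `limited`.
#' @return A one-row tibble.
#' @export
trans_observation <- function(partner_gene, partner_hgvs_c = NA_character_,
                              partner_classification, phase = "unknown",
                              proband_phenotype = "consistent") {
  chk_enum(partner_gene, ras_genes(), "partner_gene")
  chk_enum(partner_classification, partner_class_levels, "partner_classification")
  chk_enum(phase, phase_levels, "phase")
  chk_enum(proband_phenotype, c("consistent", "limited"), "proband_phenotype")
  tibble(partner_gene = partner_gene, partner_hgvs_c = partner_hgvs_c,
         partner_classification = partner_classification, phase = phase,
         proband_phenotype = proband_phenotype)
}

#' Population frequency data
#'
#' Either a precomputed group-maximum filtering allele frequency (Grpmax FAF)
#' or raw per-population allele counts from which the engine derives one via
#' the exact binomial confidence bound (see
#' [filtering_allele_frequency()]). Populations flagged `bottlenecked` are
#' excluded from the Grpmax maximum, mirroring expert-panel practice for
#' noncontinental founder populations.
#'
#' @param grpmax_faf Fraction in `[0, 1]`, or `NULL`.
#' @param subpopulations Tibble with columns `population`, `allele_count`,
#'   `allele_number` and optionally `bottlenecked` (logical, default `FALSE`).
#' @return An object of class `ras_population`.
#' @export
population_data <- function(grpmax_faf = NULL, subpopulations = NULL) {
  if (is.null(subpopulations)) {
    subpopulations <- tibble(population = character(),
                             allele_count = integer(),
                             allele_number = integer(),
                             bottlenecked = logical())
  } else {
    subpopulations <- as_tibble(subpopulations)
    if (!"bottlenecked" %in% names(subpopulations)) {
      subpopulations$bottlenecked <- FALSE
    }
    subpopulations <- subpopulations |>
      mutate(allele_count = as.integer(.data$allele_count),
             allele_number = as.integer(.data$allele_number),
             bottlenecked = as.logical(.data$bottlenecked))
  }
  structure(list(grpmax_faf = grpmax_faf %||% NA_real_,
                 subpopulations = subpopulations),
            class = "ras_population")
}

#' Functional assay evidence
#'
#' @param assays Tibble with columns `assay_id` (key into the knowledge-base
#'   assay registry for the variant's gene) and `result`
#'   (`abnormal_expected`, `normal`, `ambiguous`).
#' @return An object of class `ras_functional`.
#' @export
functional_evidence <- function(assays = NULL) {
  if (is.null(assays)) {
    assays <- tibble(assay_id = character(), result = character())
  } else {
    assays <- as_tibble(assays)
    chk_enum(assays$result, assay_result_levels, "result")
  }
  structure(list(assays = assays), class = "ras_functional")
}

#' Computational (in-silico) evidence
#'
#' @param revel REVEL ensemble missense score in `[0, 1]`, or `NULL`.
#' @param splice_predictions Optional named list mapping tool id to a
#'   predicted splice-impact label; consumed only by PS1 splice matching.
#' @return An object of class `ras_computational`.
#' @export
computational_evidence <- function(revel = NULL, splice_predictions = NULL) {
  structure(list(revel = revel %||% NA_real_,
                 splice_predictions = splice_predictions %||% list()),
            class = "ras_computational")
}

#' Pre-evaluated (passthrough) criterion
#'
#' Criteria outside the engine's scope (e.g. segregation codes PP1/BS4) are
#' supplied already evaluated and merged verbatim at combination time.
#'
#' @param code ACMG/AMP code string, must not collide with an
#'   engine-evaluated code.
#' @param direction `"pathogenic"` or `"benign"`.
#' @param strength One of `standalone`, `very_strong`, `strong`, `moderate`,
#'   `supporting`, `not_applicable`.
#' @param rationale Free-text audit string.
#' @return A one-row criterion tibble.
#' @export
passthrough_criterion <- function(code, direction, strength, rationale = "supplied pre-evaluated") {
  chk_enum(direction, c("pathogenic", "benign"), "direction")
  chk_enum(strength, strength_levels, "strength")
  criterion(code, direction, strength, points = NA_real_, rationale = rationale)
}

empty_probands <- function() {
  tibble(phenotype_category = character(), de_novo = character(),
         context = character(), prenatal_features = list(),
         alt_cause_identified = logical(), zygosity = character())
}
empty_family <- function() {
  tibble(relationship = character(), zygosity = character(),
         health_status = character())
}
empty_trans <- function() {
  tibble(partner_gene = character(), partner_hgvs_c = character(),
         partner_classification = character(), phase = character(),
         proband_phenotype = character())
}

#' Assemble an evidence bundle for one variant
#'
#' The bundle is the engine's unit of input: one variant identity plus every
#' piece of structured evidence known for it.
#'
#' @param identity A [variant_identity()].
#' @param probands Tibble of [proband_observation()] rows (or `NULL`).
#' @param family Tibble of [family_observation()] rows (or `NULL`).
#' @param population A [population_data()] (or `NULL`).
#' @param functional A [functional_evidence()] (or `NULL`).
#' @param computational A [computational_evidence()] (or `NULL`).
#' @param trans_observations Tibble of [trans_observation()] rows (or `NULL`).
#' @param passthrough_criteria Tibble of [passthrough_criterion()] rows
#'   (or `NULL`).
#' @return An object of class `ras_bundle`.
#' @export
evidence_bundle <- function(identity, probands = NULL, family = NULL,
                            population = NULL, functional = NULL,
                            computational = NULL, trans_observations = NULL,
                            passthrough_criteria = NULL) {
  stopifnot(inherits(identity, "ras_identity"))
  structure(list(
    identity = identity,
    probands = if (is.null(probands)) empty_probands() else as_tibble(probands),
    family = if (is.null(family)) empty_family() else as_tibble(family),
    population = population %||% population_data(),
    functional = functional %||% functional_evidence(),
    computational = computational %||% computational_evidence(),
    trans_observations = if (is.null(trans_observations)) empty_trans() else as_tibble(trans_observations),
    passthrough_criteria = if (is.null(passthrough_criteria)) empty_criteria() else as_tibble(passthrough_criteria)
  ), class = "ras_bundle")
}

#' @export
print.ras_bundle <- function(x, ...) {
  id <- x$identity
  cat("<ras_bundle> ", id$gene, " ", id$hgvs_c,
      if (!is.na(id$hgvs_p)) paste0(" ", id$hgvs_p), "\n", sep = "")
  cat("  consequence: ", id$consequence,
      "; probands: ", nrow(x$probands),
      "; family: ", nrow(x$family),
      "; trans: ", nrow(x$trans_observations), "\n", sep = "")
  invisible(x)
}

#' Validate an evidence bundle
#'
#' Checks every cross-field invariant and returns a character vector of
#' violations (empty when the bundle is well formed). Pure: never raises and
#' never mutates.
#'
#' @param bundle A [evidence_bundle()].
#' @param kb Optional knowledge base; when supplied, gene membership and
#'   assay-registry references are also checked.
#' @return Character vector of violation descriptions naming the offending
#'   fields; `character(0)` when valid.
#' @export
validate_bundle <- function(bundle, kb = NULL) {
  v <- character()
  id <- bundle$identity
  if (!id$gene %in% ras_genes()) {
    v <- c(v, paste0("identity.gene: '", id$gene, "' is not a supported RASopathy gene"))
  }
  if (!is.null(kb) && !id$gene %in% names(kb$genes)) {
    v <- c(v, paste0("identity.gene: '", id$gene, "' absent from knowledge base"))
  }
  needs_residue <- id$consequence %in% residue_consequences
  has_residue <- !is.na(id$residue_position) && !is.na(id$ref_aa) && !is.na(id$alt_aa)
  if (needs_residue && !has_residue) {
    v <- c(v, paste0("identity.residue_position/ref_aa/alt_aa: required for consequence '",
                     id$consequence, "'"))
  }
  if (!needs_residue && (!is.na(id$residue_position) || !is.na(id$ref_aa) || !is.na(id$alt_aa))) {
    v <- c(v, paste0("identity.residue_position/ref_aa/alt_aa: must be null for consequence '",
                     id$consequence, "'"))
  }
  if (!is.na(id$residue_position) && id$residue_position < 1) {
    v <- c(v, "identity.residue_position: must be a positive integer")
  }
  pb <- bundle$probands
  if (nrow(pb) > 0) {
    for (i in seq_len(nrow(pb))) {
      if (pb$context[i] == "prenatal") {
        if (!pb$phenotype_category[i] %in% c("limited", "nonspecific_or_none")) {
          v <- c(v, paste0("probands[", i, "].phenotype_category: prenatal cases are ",
                           "restricted to the limited (or no-information) phenotype category"))
        }
        if (pb$phenotype_category[i] == "limited" &&
            length(pb$prenatal_features[[i]]) == 0) {
          v <- c(v, paste0("probands[", i, "].prenatal_features: a limited prenatal case ",
                           "must display at least one qualifying feature"))
        }
      }
    }
  }
  sp <- bundle$population$subpopulations
  if (nrow(sp) > 0) {
    bad <- which(sp$allele_count > sp$allele_number | sp$allele_count < 0 |
                   sp$allele_number <= 0)
    for (i in bad) {
      v <- c(v, paste0("population.subpopulations[", i, "]: allele_count must be in ",
                       "[0, allele_number] with allele_number > 0"))
    }
  }
  gf <- bundle$population$grpmax_faf
  if (!is.na(gf) && (gf < 0 || gf > 1)) {
    v <- c(v, "population.grpmax_faf: must lie in [0, 1]")
  }
  rv <- bundle$computational$revel
  if (!is.na(rv) && (rv < 0 || rv > 1)) {
    v <- c(v, "computational.revel: must lie in [0, 1]")
  }
  if (!is.null(kb) && id$gene %in% names(kb$genes)) {
    reg <- kb$genes[[id$gene]]$approved_assays$id
    unknown <- setdiff(bundle$functional$assays$assay_id, reg)
    if (length(unknown) > 0) {
      v <- c(v, paste0("functional.assays.assay_id: not in the ", id$gene,
                       " assay registry: ", paste(unknown, collapse = ", ")))
    }
  }
  pc <- bundle$passthrough_criteria
  if (nrow(pc) > 0) {
    clash <- intersect(pc$code, engine_codes)
    if (length(clash) > 0) {
      v <- c(v, paste0("passthrough_criteria.code: collides with engine-evaluated code(s): ",
                       paste(clash, collapse = ", ")))
    }
  }
  v
}
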