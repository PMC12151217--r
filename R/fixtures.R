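# Seeded synthetic-evidence generator. Every scenario constructs a bundle
# together with the classification it is *designed* to receive; the
# expectation is computed from rule tables re-transcribed here as plain
# scalar lookups, deliberately duplicating (never importing) the engine's
# implementations so that divergence between the two is detectable.

fx_pp2_genes <- c("PTPN11", "BRAF", "MAP2K1", "PPP1CB")

# independent transcription of the de novo strength table
fx_bin_de_novo <- function(total) {
  if (total >= 4) "very_strong"
  else if (total >= 2) "strong"
  else if (total >= 1) "moderate"
  else if (total >= 0.5) "supporting"
  else "not_applicable"
}
fx_bin_ps4 <- function(total) {
  if (total >= 5) "strong"
  else if (total >= 3) "moderate"
  else if (total >= 1) "supporting"
  else "not_applicable"
}
fx_bin_bs2 <- function(total) {
  if (total <= -3) "strong" else if (total <= -1) "supporting" else "not_applicable"
}
fx_bin_bp <- fx_bin_bs2

# independent transcription of the combining rubric (scalar)
fx_tier <- function(codes) {
  n_of <- function(dir, str) sum(codes$direction == dir & codes$strength == str)
  vs <- n_of("pathogenic", "very_strong"); s <- n_of("pathogenic", "strong")
  m <- n_of("pathogenic", "moderate"); su <- n_of("pathogenic", "supporting")
  ba <- n_of("benign", "standalone"); bs <- n_of("benign", "strong")
  bp <- n_of("benign", "supporting")
  p <- FALSE; lp <- FALSE
  if (vs >= 1) {
    if (s >= 1 || m >= 2 || (m >= 1 && su >= 1) || su >= 2) p <- TRUE
    if (m >= 1) lp <- TRUE
  }
  if (s >= 2) p <- TRUE
  if (s >= 1) {
    if (m >= 3 || (m >= 2 && su >= 2) || (m >= 1 && su >= 4)) p <- TRUE
    if (m >= 1 || su >= 2) lp <- TRUE
  }
  if (m >= 3 || (m >= 2 && su >= 2) || (m >= 1 && su >= 4)) lp <- TRUE
  b <- ba >= 1 || bs >= 2
  lb <- (bs >= 1 && bp >= 1) || bp >= 2
  path <- if (p) "P" else if (lp) "LP" else "none"
  ben <- if (b) "B" else if (lb) "LB" else "none"
  if (path != "none" && ben != "none") return("VUS")
  if (path != "none") return(path)
  if (ben != "none") return(ben)
  "VUS"
}

fx_code <- function(code, strength) tibble(code = code, strength = strength)

fx_scenarios <- c("de_novo_strong", "prenatal_limited", "benign_frequency",
                  "lztr1_ar_biallelic", "hotspot_missense", "conflicting",
                  "alt_diagnosis")

fx_build <- function(scenario, idx) {
  hc <- paste0("c.", 100 + idx, "A>G")
  expected <- NULL

  if (scenario == "de_novo_strong") {
    gene <- sample(c("PTPN11", "BRAF", "SOS1"), 1)
    nc <- sample(1:3, 1); na <- sample(0:2, 1)
    probands <- bind_rows(
      map(seq_len(nc), ~proband_observation("consistent", de_novo = "confirmed")),
      map(seq_len(na), ~proband_observation("consistent", de_novo = "assumed"))
    )
    bundle <- evidence_bundle(
      variant_identity(gene, hgvs_c = hc, consequence = "missense",
                       residue_position = 130, ref_aa = "A", alt_aa = "V"),
      probands = probands,
      population = population_data(grpmax_faf = 0),
      computational = computational_evidence(revel = round(runif(1, 0.72, 0.95), 2))
    )
    dn <- 2 * nc + 1 * na
    ps4 <- nc + na
    codes <- bind_rows(
      fx_code("PS2", fx_bin_de_novo(dn)),
      fx_code("PS4", fx_bin_ps4(ps4)),
      fx_code("PP3", "supporting"),
      fx_code("PM2", "supporting"),
      if (gene %in% fx_pp2_genes) fx_code("PP2", "supporting")
    )
  } else if (scenario == "prenatal_limited") {
    n <- sample(1:2, 1)
    probands <- bind_rows(map(seq_len(n), ~proband_observation(
      "limited", de_novo = "assumed", context = "prenatal",
      prenatal_features = sample(prenatal_feature_levels, 1))))
    bundle <- evidence_bundle(
      variant_identity("PTPN11", hgvs_c = hc, consequence = "missense",
                       residue_position = 130, ref_aa = "G", alt_aa = "S"),
      probands = probands,
      population = population_data(grpmax_faf = 0),
      computational = computational_evidence(revel = 0.5)
    )
    codes <- bind_rows(
      fx_code("PM6", fx_bin_de_novo(0.5 * n)),
      if (fx_bin_ps4(0.5 * n) != "not_applicable") fx_code("PS4", fx_bin_ps4(0.5 * n)),
      fx_code("PM2", "supporting"),
      fx_code("PP2", "supporting")
    )
  } else if (scenario == "benign_frequency") {
    sub <- sample(c("ba1", "bs1_family", "bs1_revel"), 1)
    faf <- if (sub == "ba1") round(runif(1, 5e-4, 2e-3), 6) else
      round(runif(1, 2.6e-4, 4.9e-4), 6)
    family <- if (sub == "bs1_family") {
      bind_rows(map(1:3, ~family_observation(health_status = "healthy_assessed",
                                             zygosity = "het")))
    } else NULL
    revel <- if (sub == "bs1_revel") 0.1 else NULL
    bundle <- evidence_bundle(
      variant_identity("SHOC2", hgvs_c = hc, consequence = "missense",
                       residue_position = 100, ref_aa = "L", alt_aa = "F"),
      family = family,
      population = population_data(grpmax_faf = faf),
      computational = computational_evidence(revel = revel)
    )
    codes <- switch(sub,
      ba1 = fx_code("BA1", "standalone"),
      bs1_family = bind_rows(fx_code("BS1", "strong"), fx_code("BS2", "strong")),
      bs1_revel = bind_rows(fx_code("BS1", "strong"), fx_code("BP4", "supporting"))
    )
  } else if (scenario == "lztr1_ar_biallelic") {
    stop_pos <- sample(100:2000, 1)
    bundle <- evidence_bundle(
      variant_identity("LZTR1", hgvs_c = hc, consequence = "frameshift",
                       cds_stop_pos = stop_pos),
      probands = proband_observation("consistent", zygosity = "hom"),
      population = population_data(grpmax_faf = 1e-6),
      trans_observations = trans_observation("LZTR1", partner_hgvs_c = hc,
                                             partner_classification = "other",
                                             phase = "confirmed_trans")
    )
    codes <- bind_rows(
      fx_code("PVS1", "very_strong"),   # stop always NMD-range for this template
      fx_code("PM3", "supporting"),     # homozygote tariff 0.5
      fx_code("PM2", "supporting")
    )
  } else if (scenario == "hotspot_missense") {
    k <- sample(3:6, 1)
    probands <- bind_rows(map(seq_len(k), ~proband_observation("consistent")))
    bundle <- evidence_bundle(
      variant_identity("PTPN11", hgvs_c = hc, consequence = "missense",
                       residue_position = 308, ref_aa = "N", alt_aa = "C"),
      probands = probands,
      population = population_data(grpmax_faf = 0),
      computational = computational_evidence(revel = 0.8)
    )
    codes <- bind_rows(
      fx_code("PM5", "strong"),         # hotspot residue outside any domain
      fx_code("PS4", fx_bin_ps4(k)),
      fx_code("PP3", "supporting"),
      fx_code("PM2", "supporting"),
      fx_code("PP2", "supporting")
    )
  } else if (scenario == "conflicting") {
    probands <- bind_rows(map(1:2, ~proband_observation("consistent", de_novo = "confirmed")))
    bundle <- evidence_bundle(
      variant_identity("KRAS", hgvs_c = hc, consequence = "missense",
                       residue_position = 13, ref_aa = "G", alt_aa = "D"),
      probands = probands,
      population = population_data(grpmax_faf = 6e-4),
      computational = computational_evidence(revel = 0.9)
    )
    codes <- bind_rows(
      fx_code("PS2", "very_strong"),    # 2 confirmed consistent = 4 points
      fx_code("PS4", "supporting"),
      fx_code("PM1", "moderate"),       # P-loop residue
      fx_code("PM5", "moderate"),       # hotspot downgraded next to PM1
      fx_code("PP3", "supporting"),
      fx_code("BA1", "standalone")
    )
  } else if (scenario == "alt_diagnosis") {
    n <- sample(1:3, 1)
    probands <- bind_rows(map(seq_len(n), ~proband_observation(
      "inconsistent_alt_disorder", context = "exome_genome",
      alt_cause_identified = TRUE)))
    bundle <- evidence_bundle(
      variant_identity("RAF1", hgvs_c = hc, consequence = "missense",
                       residue_position = 50, ref_aa = "T", alt_aa = "M"),
      probands = probands,
      population = population_data(grpmax_faf = 1e-4),
      computational = computational_evidence(revel = 0.1)
    )
    codes <- bind_rows(
      fx_code("BP5", fx_bin_bp(-n)),
      fx_code("BP4", "supporting")
    )
  } else {
    abort(paste0("unknown scenario: ", scenario))
  }

  codes <- filter(codes, .data$strength != "not_applicable")
  dir_of <- function(code) if (grepl("^B", code)) "benign" else "pathogenic"
  codes$direction <- vapply(codes$code, dir_of, character(1))
  expected <- fx_tier(codes)
  list(bundle = bundle,
       expectation = tibble(scenario = scenario,
                            gene = bundle$identity$gene,
                            hgvs_c = bundle$identity$hgvs_c,
                            expected_tier = expected,
                            expected_codes = list(select(codes, "code", "strength"))))
}

#' Generate synthetic evidence bundles with known expected classifications
#'
#' Draws scenarios from a weighted mix and builds, for each variant, an
#' evidence bundle plus the classification it was designed to receive. The
#' expectations are computed from independently transcribed rule tables
#' (not by running the engine), so the output doubles as a golden oracle
#' for regression testing. Generation is fully reproducible from the seed.
#'
#' @param seed Integer seed for the single internal generator.
#' @param n_variants Number of bundles to generate.
#' @param scenarios Named nonnegative weights over the scenario mix
#'   (`de_novo_strong`, `prenatal_limited`, `benign_frequency`,
#'   `lztr1_ar_biallelic`, `hotspot_missense`, `conflicting`,
#'   `alt_diagnosis`).
#' @return List with `bundles` (list of [evidence_bundle()]) and
#'   `expectations` (tibble: `scenario`, `gene`, `hgvs_c`, `expected_tier`,
#'   `expected_codes` list-column).
#' @export
generate_fixtures <- function(seed, n_variants = 100,
                              scenarios = setNames(rep(1, length(fx_scenarios)),
                                                   fx_scenarios)) {
  bad <- setdiff(names(scenarios), fx_scenarios)
  if (length(bad) > 0) abort(paste0("unknown scenario name(s): ", paste(bad, collapse = ", ")))
  if (any(scenarios < 0) || sum(scenarios) <= 0) {
    abort("scenario weights must be nonnegative with positive sum")
  }
  withr::local_seed(as.integer(seed))
  picks <- sample(names(scenarios), n_variants, replace = TRUE,
                  prob = scenarios / sum(scenarios))
  built <- map2(picks, seq_len(n_variants), fx_build)
  list(bundles = map(built, "bundle"),
       expectations = list_rbind(map(built, "expectation")))
}
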