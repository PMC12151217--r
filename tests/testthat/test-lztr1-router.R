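lztr1_bundle <- function(consequence = "missense", biallelic = FALSE,
                         ad_proband = FALSE, functional = NULL,
                         splice_frame = NULL, cds_stop_pos = NULL) {
  probands <- NULL
  if (biallelic) probands <- dplyr::bind_rows(probands,
    proband_observation("consistent", zygosity = "hom"))
  if (ad_proband) probands <- dplyr::bind_rows(probands,
    proband_observation("consistent", de_novo = "confirmed", zygosity = "het"))
  residue <- if (consequence %in% c("missense", "inframe_indel", "stop_loss"))
    list(pos = 100, ref = "A", alt = "V") else list(pos = NULL, ref = NULL, alt = NULL)
  fun <- if (!is.null(functional)) functional_evidence(tibble::tibble(
    assay_id = functional, result = "abnormal_expected"))
  evidence_bundle(
    variant_identity("LZTR1", hgvs_c = "c.1A>G", consequence = consequence,
                     residue_position = residue$pos, ref_aa = residue$ref,
                     alt_aa = residue$alt, splice_frame = splice_frame,
                     cds_stop_pos = cds_stop_pos),
    probands = probands, functional = fun,
    population = population_data(grpmax_faf = 1e-6)
  )
}

test_that("the mechanism router reproduces the hand-transcribed branch table", {
  cases <- list(
    list(b = lztr1_bundle(biallelic = TRUE), route = "AR", basis = "inheritance_pattern"),
    list(b = lztr1_bundle(ad_proband = TRUE), route = "AD", basis = "inheritance_pattern"),
    list(b = lztr1_bundle(biallelic = TRUE, ad_proband = TRUE),
         route = "undetermined", basis = "none"),
    list(b = lztr1_bundle("nonsense"), route = "AR", basis = "presumed_lof"),
    list(b = lztr1_bundle("frameshift"), route = "AR", basis = "presumed_lof"),
    list(b = lztr1_bundle("canonical_splice", splice_frame = "out_of_frame"),
         route = "AR", basis = "presumed_lof"),
    list(b = lztr1_bundle("canonical_splice", splice_frame = "in_frame"),
         route = "undetermined", basis = "none"),
    list(b = lztr1_bundle(functional = "p_erk"), route = "AD", basis = "functional_data"),
    list(b = lztr1_bundle(functional = "protein_stability"), route = "AR",
         basis = "functional_data"),
    list(b = lztr1_bundle(functional = c("p_erk", "protein_stability")),
         route = "undetermined", basis = "none"),
    list(b = lztr1_bundle(), route = "undetermined", basis = "none"),
    # case-level data take precedence over consequence
    list(b = lztr1_bundle("frameshift", ad_proband = TRUE), route = "AD",
         basis = "inheritance_pattern"),
    list(b = lztr1_bundle("nonsense", biallelic = TRUE), route = "AR",
         basis = "inheritance_pattern")
  )
  for (i in seq_along(cases)) {
    d <- route_lztr1(cases[[i]]$b, test_kb)
    expect_equal(d$route, cases[[i]]$route, info = paste("case", i))
    expect_equal(d$basis, cases[[i]]$basis, info = paste("case", i))
  }
  # routing is total and deterministic over fixture bundles
  fx <- generate_fixtures(5, 60, scenarios = c(lztr1_ar_biallelic = 1))
  for (b in fx$bundles) {
    d1 <- route_lztr1(b, test_kb)
    expect_true(d1$route %in% c("AD", "AR", "undetermined"))
    expect_identical(d1, route_lztr1(b, test_kb))
  }
  expect_error(route_lztr1(evidence_bundle(
    variant_identity("KRAS", consequence = "synonymous")), test_kb), "LZTR1")
})

test_that("an undetermined route forces VUS no matter the accumulated evidence", {
  b <- lztr1_bundle(functional = c("p_erk", "protein_stability"))
  b$computational <- computational_evidence(revel = 0.95)
  b$passthrough_criteria <- dplyr::bind_rows(
    passthrough_criterion("PP1", "pathogenic", "strong"),
    passthrough_criterion("PP4", "pathogenic", "moderate"))
  res <- classify_variant(b, test_kb)
  expect_equal(res$mechanism_route, "undetermined")
  expect_equal(res$tier, "VUS")
  expect_true(any(grepl("undetermined", res$notes)))
})

test_that("PVS1 applies the NMD 50-nt rule on the transcript exon table", {
  tm <- tibble::tibble(exon = 1:4, cds_width = c(100L, 100L, 100L, 100L))
  fs <- function(stop) variant_identity("LZTR1", consequence = "frameshift",
                                        cds_stop_pos = stop)
  # last exon-exon junction sits at CDS 300
  expect_equal(evaluate_pvs1(fs(200), tm)$strength, "very_strong")  # 200 < 250
  expect_equal(evaluate_pvs1(fs(260), tm)$strength, "strong")       # NMD escape
  expect_equal(evaluate_pvs1(fs(350), tm)$strength, "strong")       # last exon
  # canonical splice outcomes
  spl <- function(frame) variant_identity("LZTR1", consequence = "canonical_splice",
                                          splice_frame = frame)
  expect_equal(evaluate_pvs1(spl("out_of_frame"), tm)$strength, "strong")
  expect_equal(evaluate_pvs1(spl("in_frame"), tm)$strength, "not_applicable")
  mis <- variant_identity("LZTR1", consequence = "missense",
                          residue_position = 10, ref_aa = "A", alt_aa = "V")
  expect_equal(evaluate_pvs1(mis, tm)$strength, "not_applicable")
  expect_error(evaluate_pvs1(variant_identity("KRAS", consequence = "nonsense"), tm),
               "LZTR1")
})

test_that("PM3 follows the in-trans point table with limited-phenotype halving", {
  ob <- function(phase, cls = "P", pheno = "consistent")
    trans_observation("LZTR1", "c.999del", cls, phase = phase,
                      proband_phenotype = pheno)
  expect_equal(evaluate_pm3(ob("confirmed_trans"))$points, 1)
  expect_equal(evaluate_pm3(ob("confirmed_trans"))$strength, "moderate")
  lim <- evaluate_pm3(ob("confirmed_trans", pheno = "limited"))
  expect_equal(lim$points, 0.5)
  expect_equal(lim$label, "PM3_Supporting")
  expect_equal(evaluate_pm3(ob("suspected_trans"))$points, 0.5)
  expect_equal(evaluate_pm3(ob("cis"))$strength, "not_applicable")
  four <- dplyr::bind_rows(purrr::map(1:4, ~ob("confirmed_trans")))
  expect_equal(evaluate_pm3(four)$strength, "very_strong")
  # homozygosity (partner is the same variant) earns the 0.5 tariff
  id <- variant_identity("LZTR1", hgvs_c = "c.1A>G", consequence = "missense",
                         residue_position = 1, ref_aa = "M", alt_aa = "V")
  hom <- trans_observation("LZTR1", "c.1A>G", "other", phase = "confirmed_trans")
  expect_equal(evaluate_pm3(hom, id)$points, 0.5)
  # point sweep against the transcribed bin table
  for (n in 1:8) {
    obs <- dplyr::bind_rows(purrr::map(seq_len(n), ~ob("suspected_trans")))
    expect_equal(evaluate_pm3(obs)$strength, oracle_bin_pm3(0.5 * n))
  }
})

test_that("recessive-route results never mix PVS1/PM3 with dominant case codes", {
  fx <- generate_fixtures(17, 80)
  res <- classify_bundles(fx$bundles, test_kb)
  for (r in res$result) {
    applied <- r$criteria$code[r$criteria$strength != "not_applicable"]
    if (any(applied %in% c("PVS1", "PM3"))) {
      expect_false(any(applied %in% c("PS2", "PM6", "PS4")))
    }
  }
})
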