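test_that("filtering allele frequency matches the exact CDF root-finding oracle", {
  expect_equal(filtering_allele_frequency(0, 5000), 0)
  faf <- filtering_allele_frequency(1000, 10000)
  expect_lt(faf, 0.1)
  expect_gt(faf, 0.09)
  withr::local_seed(3)
  for (i in 1:200) {
    an <- sample(50:500000, 1)
    ac <- sample(1:min(an, 2000), 1)
    expect_equal(filtering_allele_frequency(ac, an), oracle_faf(ac, an),
                 tolerance = 1e-6, info = paste(ac, an))
  }
  # scaled monotonicity: more data at the same frequency tightens upward
  expect_lt(filtering_allele_frequency(5, 10000),
            filtering_allele_frequency(50, 100000))
  expect_error(filtering_allele_frequency(-1, 10), "allele_count")
  expect_error(filtering_allele_frequency(1, 0), "allele_number")
})

test_that("frequency verdicts honour the BA1/BS1/PM2 threshold lattice", {
  prof <- kb_profile(test_kb, "PTPN11")
  verdict <- function(faf, profile = prof, mech = "AD") {
    evaluate_frequency(population_data(grpmax_faf = faf), profile, mech)$code
  }
  expect_equal(verdict(5e-4), "BA1")          # inclusive at the boundary
  expect_equal(verdict(3e-4), "BS1")
  expect_equal(verdict(2.5e-4), "BS1")        # inclusive
  expect_equal(verdict(1e-4), "none")         # between PM2 and BS1
  expect_equal(verdict(1e-5), "none")
  expect_equal(verdict(2e-6), "PM2_Supporting")
  expect_equal(verdict(0), "PM2_Supporting")
  # recessive LZTR1 uses the heterozygote-adjusted rarity bound
  lztr1 <- kb_profile(test_kb, "LZTR1")
  expect_equal(verdict(2e-5, lztr1, "AR"), "PM2_Supporting")
  expect_equal(verdict(2.5e-5, lztr1, "AR"), "none")  # bound is exclusive
  # increasing FAF never moves the verdict toward rarity (monotone ordering)
  code_rank <- c(PM2_Supporting = 0, none = 1, BS1 = 2, BA1 = 3)
  for (profile in list(prof, lztr1)) {
    fafs <- sort(c(0, 10^seq(-7, -2.5, length.out = 40)))
    ranks <- code_rank[vapply(fafs, verdict, character(1), profile = profile)]
    expect_true(all(diff(ranks) >= 0))
  }
})

test_that("Grpmax FAF is derived from subpopulations, excluding bottlenecked ones", {
  sub <- tibble::tibble(population = c("nfe", "afr", "amish"),
                        allele_count = c(30L, 4L, 50L),
                        allele_number = c(100000L, 80000L, 1000L),
                        bottlenecked = c(FALSE, FALSE, TRUE))
  v <- evaluate_frequency(population_data(subpopulations = sub),
                          kb_profile(test_kb, "PTPN11"))
  expect_equal(v$population, "nfe")
  expect_equal(v$faf_used, filtering_allele_frequency(30, 100000))
  # no data at all -> no verdict, audited as a note
  v2 <- evaluate_frequency(population_data(), kb_profile(test_kb, "PTPN11"))
  expect_equal(v2$code, "none")
  expect_true(is.na(v2$faf_used))
})

test_that("REVEL thresholds are inclusive and mutually exclusive", {
  ev <- function(r) evaluate_computational(computational_evidence(revel = r))
  expect_equal(ev(0.7)$label, "PP3")
  expect_equal(ev(0.7)$strength, "supporting")    # never above supporting
  expect_equal(ev(0.3)$label, "BP4")
  expect_equal(ev(0.5)$strength, "not_applicable")
  expect_equal(ev(NULL)$strength, "not_applicable")
  for (r in seq(0, 1, by = 0.01)) {
    cr <- ev(r)
    expect_false(cr$code == "PP3" && cr$strength != "not_applicable" && r < 0.7)
    expect_false(cr$code == "BP4" && cr$strength != "not_applicable" && r > 0.3)
  }
})

test_that("PP2 applies only to missense variants in constrained genes", {
  mis <- function(g) variant_identity(g, consequence = "missense",
                                      residue_position = 50, ref_aa = "A", alt_aa = "V")
  expect_equal(evaluate_pp2(kb_profile(test_kb, "PTPN11"), mis("PTPN11"))$strength,
               "supporting")
  expect_equal(evaluate_pp2(kb_profile(test_kb, "SOS1"), mis("SOS1"))$strength,
               "not_applicable")
  non <- variant_identity("PTPN11", consequence = "nonsense")
  expect_equal(evaluate_pp2(kb_profile(test_kb, "PTPN11"), non)$strength,
               "not_applicable")
})

test_that("PS3 counts distinct approved assays and is capped at moderate", {
  prof <- kb_profile(test_kb, "KRAS")
  fa <- function(...) functional_evidence(tibble::tibble(
    assay_id = c(...), result = "abnormal_expected"))
  expect_equal(evaluate_ps3(fa("p_erk", "p_mek"), prof)$strength, "moderate")
  expect_equal(evaluate_ps3(fa("p_erk", "p_mek", "gtp_hydrolysis"), prof)$strength,
               "moderate")
  one <- functional_evidence(tibble::tibble(
    assay_id = c("p_erk", "p_mek"), result = c("abnormal_expected", "normal")))
  expect_equal(evaluate_ps3(one, prof)$strength, "supporting")
  # replicates of one assay count once
  expect_equal(evaluate_ps3(fa("p_erk", "p_erk"), prof)$strength, "supporting")
  # PPP1CB has no approved assays
  rep <- functional_evidence(tibble::tibble(assay_id = "p_erk",
                                            result = "abnormal_expected"))
  ppp <- evaluate_ps3(rep, kb_profile(test_kb, "PPP1CB"))
  expect_equal(ppp$strength, "not_applicable")
  expect_match(ppp$rationale, "no approved")
})

test_that("PM4 applies to in-frame length changes and stop-loss only", {
  dup <- variant_identity("RRAS2", hgvs_c = "c.70_78dup",
                          hgvs_p = "p.(Gly24_Gly26dup)",
                          consequence = "inframe_indel", residue_position = 24,
                          ref_aa = "G", alt_aa = "G")
  expect_equal(evaluate_pm4_bp3(dup)$label, "PM4")
  sl <- variant_identity("HRAS", consequence = "stop_loss",
                         residue_position = 190, ref_aa = "*", alt_aa = "Q")
  expect_equal(evaluate_pm4_bp3(sl)$strength, "moderate")
  mis <- variant_identity("HRAS", consequence = "missense",
                          residue_position = 12, ref_aa = "G", alt_aa = "V")
  expect_equal(evaluate_pm4_bp3(mis)$strength, "not_applicable")
})

test_that("PM1/PM5 interplay follows the hotspot-vs-domain resolution rules", {
  mis <- function(g, pos, alt = "C") variant_identity(
    g, consequence = "missense", residue_position = pos, ref_aa = "X", alt_aa = alt)
  # hotspot inside a domain: PM1 + PM5 downgraded to moderate, never PM1 + PM5_Strong
  both <- evaluate_pm1_pm5(mis("KRAS", 61), kb_profile(test_kb, "KRAS"), kb = test_kb)
  expect_setequal(both$code, c("PM1", "PM5"))
  expect_equal(both$strength[both$code == "PM5"], "moderate")
  # hotspot outside any domain: PM5_Strong alone
  hs <- evaluate_pm1_pm5(mis("PTPN11", 308), kb_profile(test_kb, "PTPN11"), kb = test_kb)
  expect_equal(hs$label, "PM5_Strong")
  # domain with a known different P/LP change: PM1 + moderate PM5 in conjunction
  ct <- tibble::tibble(gene = "KRAS", residue_position = 35L, alt_aa = "D",
                       classification = "P", proband_count = 2L,
                       benign_variation_present = FALSE)
  conj <- evaluate_pm1_pm5(mis("KRAS", 35, alt = "G"), kb_profile(test_kb, "KRAS"),
                           case_table = ct, kb = test_kb)
  expect_setequal(conj$label, c("PM1", "PM5"))
  # analogous-residue hotspot through the family alignment
  ana <- evaluate_pm1_pm5(mis("KRAS", 117), kb_profile(test_kb, "KRAS"), kb = test_kb)
  expect_equal(ana$label, "PM5_Strong")
  expect_match(ana$rationale, "HRAS")
  # splice variants never receive PM5, even at a hotspot codon
  spl <- variant_identity("KRAS", consequence = "canonical_splice")
  out <- evaluate_pm1_pm5(spl, kb_profile(test_kb, "KRAS"), kb = test_kb)
  expect_true(all(out$strength == "not_applicable"))
})

test_that("PS1 matches identical changes directly and through paralogy", {
  # paralogous precedent: MRAS Thr68Ile <-> HRAS Thr58Ile (P)
  mras <- variant_identity("MRAS", hgvs_c = "c.203C>T", hgvs_p = "p.(Thr68Ile)",
                           consequence = "missense", residue_position = 68,
                           ref_aa = "T", alt_aa = "I")
  cr <- evaluate_ps1(mras, kb_profile(test_kb, "MRAS"), test_known, kb = test_kb)
  expect_equal(cr$label, "PS1")
  expect_match(cr$rationale, "HRAS")
  # identity precedent in the same gene
  same <- variant_identity("PTPN11", consequence = "missense",
                           residue_position = 308, ref_aa = "N", alt_aa = "D")
  expect_equal(evaluate_ps1(same, kb_profile(test_kb, "PTPN11"), test_known,
                            kb = test_kb)$strength, "strong")
  # a different substitution at the same residue is not PS1
  diff <- variant_identity("PTPN11", consequence = "missense",
                           residue_position = 308, ref_aa = "N", alt_aa = "K")
  expect_equal(evaluate_ps1(diff, kb_profile(test_kb, "PTPN11"), test_known,
                            kb = test_kb)$strength, "not_applicable")
  # splice precedent requires the same predicted impact
  spl <- variant_identity("BRAF", consequence = "canonical_splice")
  hit <- evaluate_ps1(spl, kb_profile(test_kb, "BRAF"), test_known, kb = test_kb,
                      splice_impact = "exon12_skip_out_of_frame", position = 487)
  expect_equal(hit$strength, "strong")
  miss <- evaluate_ps1(spl, kb_profile(test_kb, "BRAF"), test_known, kb = test_kb,
                       splice_impact = "exon12_skip_in_frame", position = 487)
  expect_equal(miss$strength, "not_applicable")
})

test_that("BS3 and BP3 never appear in any engine output", {
  fx <- generate_fixtures(99, 150)
  res <- classify_bundles(fx$bundles, test_kb)
  codes <- unlist(purrr::map(res$result, function(r) r$criteria$code))
  expect_false(any(codes %in% c("BS3", "BP3")))
  ps3 <- unlist(purrr::map(res$result, function(r)
    r$criteria$strength[r$criteria$code == "PS3"]))
  expect_true(all(ps3 %in% c("moderate", "supporting", "not_applicable")))
})
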