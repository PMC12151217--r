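consistent_conf <- function(n) dplyr::bind_rows(purrr::map(seq_len(n), ~
  proband_observation("consistent", de_novo = "confirmed")))
consistent_asm <- function(n) dplyr::bind_rows(purrr::map(seq_len(n), ~
  proband_observation("consistent", de_novo = "assumed")))

test_that("the worked de novo example scores 4 points and PS2_VeryStrong", {
  cr <- score_de_novo(dplyr::bind_rows(consistent_conf(1), consistent_asm(2)))
  expect_equal(cr$points, 4)
  expect_equal(cr$code, "PS2")
  expect_equal(cr$strength, "very_strong")
  expect_equal(cr$label, "PS2_VeryStrong")
})

test_that("de novo scoring emits PM6 when no parentage is confirmed", {
  cr <- score_de_novo(proband_observation("limited", de_novo = "assumed",
                                          context = "prenatal",
                                          prenatal_features = "cystic_hygroma"))
  expect_equal(cr$points, 0.5)
  expect_equal(cr$label, "PM6_Supporting")
  expect_equal(score_de_novo(empty_probands_tbl())$strength, "not_applicable")
})


test_that("de novo tariffs match exhaustive enumeration of category x parentage", {
  for (dn in c("confirmed", "assumed", "inherited", "unknown")) {
    for (cat in c("consistent", "limited", "nonspecific_or_none",
                  "inconsistent_alt_disorder")) {
      cr <- score_de_novo(proband_observation(cat, de_novo = dn))
      want <- if (dn == "confirmed" && cat == "consistent") 2
      else if (dn == "confirmed" && cat == "limited") 1
      else if (dn == "assumed" && cat == "consistent") 1
      else if (dn == "assumed" && cat == "limited") 0.5
      else 0
      expect_equal(cr$points, want, info = paste(dn, cat))
      expect_equal(cr$strength, oracle_bin_de_novo(want), info = paste(dn, cat))
    }
  }
})

test_that("PS4 worked examples and tariffs", {
  five <- dplyr::bind_rows(purrr::map(1:5, ~proband_observation("consistent")))
  expect_equal(score_ps4(five)$label, "PS4")
  expect_equal(score_ps4(five)$strength, "strong")
  mixed <- dplyr::bind_rows(
    proband_observation("consistent"), proband_observation("consistent"),
    proband_observation("inconsistent_alt_disorder", context = "exome_genome",
                        alt_cause_identified = TRUE))
  cr <- score_ps4(mixed)
  expect_equal(cr$points, 1)                       # 1 + 1 - 1
  expect_equal(cr$strength, "supporting")
  expect_equal(score_ps4(empty_probands_tbl())$strength, "not_applicable")
  # a negative total is never benign evidence here
  neg <- score_ps4(proband_observation("inconsistent_alt_disorder",
                                       alt_cause_identified = TRUE))
  expect_equal(neg$strength, "not_applicable")
  expect_equal(neg$direction, "pathogenic")
})

test_that("BS2 tariffs and bins", {
  hom <- score_bs2(family_observation(zygosity = "hom",
                                      health_status = "healthy_assessed"))
  expect_equal(hom$points, -3)
  expect_equal(hom$strength, "strong")
  parents <- dplyr::bind_rows(purrr::map(1:4, ~
    family_observation(health_status = "unaffected_unassessed")))
  cr <- score_bs2(parents)
  expect_equal(cr$points, -1)                      # 4 x -0.25
  expect_equal(cr$label, "BS2_Supporting")
  noinfo <- score_bs2(family_observation(health_status = "no_info_or_nonspecific"))
  expect_equal(noinfo$strength, "not_applicable")
})

test_that("BP5/BP2 merge: tariffs, zero rule and code selection", {
  cdls <- proband_observation("inconsistent_alt_disorder", context = "exome_genome",
                              alt_cause_identified = TRUE)
  cr <- score_bp5_bp2(cdls)
  expect_equal(cr$points, -1)
  expect_equal(cr$label, "BP5")
  expect_equal(cr$strength, "supporting")
  # inconsistent phenotype but no causative variant -> nothing
  none <- score_bp5_bp2(proband_observation("inconsistent_alt_disorder",
                                            alt_cause_identified = FALSE))
  expect_equal(none$points, 0)
  expect_equal(none$strength, "not_applicable")
  # three independent alternate-cause cases -> Strong
  three <- dplyr::bind_rows(purrr::map(1:3, ~cdls))
  expect_equal(score_bp5_bp2(three)$points, -3)
  expect_equal(score_bp5_bp2(three)$strength, "strong")
  # a phase-based partner switches the emitted code to BP2
  tr <- trans_observation("KRAS", "c.1A>G", "P", phase = "confirmed_trans")
  cr2 <- score_bp5_bp2(cdls, tr, gene = "KRAS")
  expect_equal(cr2$code, "BP2")
  expect_equal(cr2$points, -2)
  # a different-gene pathogenic partner without phase counts but stays BP5
  tr2 <- trans_observation("RAF1", "c.2A>G", "LP", phase = "unknown")
  cr3 <- score_bp5_bp2(cdls, tr2, gene = "KRAS")
  expect_equal(cr3$code, "BP5")
  expect_equal(cr3$points, -2)
  # same-gene suspected-trans partner does not qualify
  tr3 <- trans_observation("KRAS", "c.3A>G", "P", phase = "suspected_trans")
  expect_equal(score_bp5_bp2(empty_probands_tbl(), tr3, gene = "KRAS")$points, 0)
})

test_that("bin boundaries are inclusive and sweeps match the transcribed tables", {
  grid <- seq(-6, 6, by = 0.25)
  for (t in grid) {
    expect_equal(rasrules:::bin_points(t, rasrules:::de_novo_bins),
                 oracle_bin_de_novo(t), info = paste("de novo", t))
    expect_equal(rasrules:::bin_points(t, rasrules:::ps4_bins),
                 oracle_bin_ps4(t), info = paste("ps4", t))
    expect_equal(rasrules:::bin_points_benign(t, rasrules:::bs2_bins),
                 oracle_bin_bs2(t), info = paste("bs2", t))
    expect_equal(rasrules:::bin_points_benign(t, rasrules:::bp_bins),
                 oracle_bin_bp(t), info = paste("bp", t))
  }
  # exact-threshold spot checks
  expect_equal(score_de_novo(consistent_conf(1))$strength, "strong")     # exactly 2
  expect_equal(score_bs2(dplyr::bind_rows(purrr::map(1:3, ~
    family_observation(health_status = "healthy_assessed"))))$strength, "strong")  # exactly -3
})

test_that("adding nonnegative observations never lowers case-scorer strength", {
  withr::local_seed(11)
  cats <- c("consistent", "limited", "nonspecific_or_none")
  for (i in 1:50) {
    n <- sample(0:4, 1)
    base <- if (n == 0) empty_probands_tbl() else
      dplyr::bind_rows(purrr::map(seq_len(n), ~proband_observation(
        sample(cats, 1), de_novo = sample(c("confirmed", "assumed", "unknown"), 1))))
    before <- score_de_novo(base)
    extra <- proband_observation(sample(cats, 1),
                                 de_novo = sample(c("confirmed", "assumed"), 1))
    after <- score_de_novo(dplyr::bind_rows(base, extra))
    expect_gte(strength_order[after$strength], strength_order[before$strength])
    # a zero-point observation changes nothing
    zero <- proband_observation("nonspecific_or_none", de_novo = "unknown")
    expect_equal(score_de_novo(dplyr::bind_rows(base, zero))$strength,
                 before$strength)
    expect_gte(strength_order[score_ps4(dplyr::bind_rows(base, extra))$strength],
               strength_order[score_ps4(base)$strength])
  }
})

test_that("exactly one code per group is emitted and tallies sum their contributions", {
  probands <- dplyr::bind_rows(consistent_conf(2), consistent_asm(1))
  cr <- score_de_novo(probands)
  expect_true(cr$code %in% c("PS2", "PM6"))
  expect_equal(nrow(cr), 1)
  expect_equal(sum(point_tally(cr)$points), cr$points)
  cr2 <- score_bp5_bp2(proband_observation("inconsistent_alt_disorder",
                                           alt_cause_identified = TRUE))
  expect_equal(sum(point_tally(cr2)$points), cr2$points)
})
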