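# Independent oracles, transcribed separately from both the engine and the
# fixture module, used to cross-check every table-driven component.

# strength tables as printed: total -> strength (inclusive at the boundary)
oracle_bin_de_novo <- function(total) {
  if (total >= 4) "very_strong" else if (total >= 2) "strong"
  else if (total >= 1) "moderate" else if (total >= 0.5) "supporting"
  else "not_applicable"
}
oracle_bin_ps4 <- function(total) {
  if (total >= 5) "strong" else if (total >= 3) "moderate"
  else if (total >= 1) "supporting" else "not_applicable"
}
oracle_bin_bs2 <- function(total) {
  if (total <= -3) "strong" else if (total <= -1) "supporting" else "not_applicable"
}
oracle_bin_bp <- oracle_bin_bs2
oracle_bin_pm3 <- function(total) {
  if (total >= 4) "very_strong" else if (total >= 2) "strong"
  else if (total >= 1) "moderate" else if (total >= 0.5) "supporting"
  else "not_applicable"
}

# brute-force triple-filter hotspot detector (row-by-row loops, no dplyr)
oracle_hotspots <- function(tb) {
  out <- list()
  keys <- unique(paste(tb$gene, tb$residue_position))
  for (k in keys) {
    parts <- strsplit(k, " ")[[1]]
    rows <- tb[tb$gene == parts[1] & tb$residue_position == as.integer(parts[2]), ]
    plp <- rows[rows$classification %in% c("P", "LP"), ]
    distinct_changes <- length(unique(plp$alt_aa))
    total_probands <- sum(plp$proband_count)
    benign <- any(rows$benign_variation_present) ||
      any(rows$classification %in% c("B", "LB"))
    if (distinct_changes >= 2 && total_probands >= 5 && !benign) {
      out[[length(out) + 1]] <- data.frame(gene = parts[1],
                                           residue_position = as.integer(parts[2]))
    }
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(), residue_position = integer()))
  }
  do.call(rbind, out)
}

# exact binomial lower confidence bound by root-finding on the CDF
oracle_faf <- function(ac, an, confidence = 0.95) {
  if (ac == 0) return(0)
  f <- function(p) stats::pbinom(ac - 1, an, p) - confidence
  stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
}

# scalar combining-rubric oracle, written as explicit rule rows
oracle_tier <- function(vs, s, m, su, ba, bs, bp) {
  p <- (vs >= 1 && (s >= 1 || m >= 2 || (m >= 1 && su >= 1) || su >= 2)) ||
    s >= 2 ||
    (s >= 1 && (m >= 3 || (m >= 2 && su >= 2) || (m >= 1 && su >= 4)))
  lp <- (vs >= 1 && m >= 1) || (s >= 1 && m >= 1) || (s >= 1 && su >= 2) ||
    m >= 3 || (m >= 2 && su >= 2) || (m >= 1 && su >= 4)
  b <- ba >= 1 || bs >= 2
  lb <- (bs >= 1 && bp >= 1) || bp >= 2
  path <- if (p) "P" else if (lp) "LP" else "none"
  ben <- if (b) "B" else if (lb) "LB" else "none"
  if (path != "none" && ben != "none") return("VUS")
  if (path != "none") return(path)
  if (ben != "none") return(ben)
  "VUS"
}

strength_order <- c(not_applicable = 0, supporting = 1, moderate = 2,
                    strong = 3, very_strong = 4, standalone = 4)
tier_order <- c(B = 1, LB = 2, VUS = 3, LP = 4, P = 5)

# shared test objects
test_kb <- load_knowledge_base()
test_known <- read_known_pathogenic(
  system.file("extdata", "known_pathogenic_synthetic.tsv", package = "rasrules"))

random_case_table <- function(n_residues = 8, genes = c("PTPN11", "KRAS")) {
  rows <- list()
  for (i in seq_len(n_residues)) {
    g <- sample(genes, 1)
    pos <- sample(1:20, 1)
    n_changes <- sample(1:3, 1)
    for (j in seq_len(n_changes)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = g, residue_position = pos,
        alt_aa = sample(c("A", "C", "D", "E", "F"), 1),
        classification = sample(c("P", "LP", "B", "LB", "VUS"), 1,
                                prob = c(0.35, 0.25, 0.1, 0.1, 0.2)),
        proband_count = sample(0:5, 1),
        benign_variation_present = runif(1) < 0.15
      )
    }
  }
  dplyr::bind_rows(rows)
}

empty_probands_tbl <- function() proband_observation("consistent")[0, ]
empty_criteria_tbl <- function() criterion("PS2", "pathogenic", "supporting")[0, ]
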