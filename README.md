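# rasrules

Point-based ACMG/AMP variant classification for the RASopathy genes.

RASopathies (Noonan syndrome and related Ras/MAPK-pathway disorders) are
classified clinically from sequence variants in sixteen genes (PTPN11, BRAF,
RAF1, SOS1/2, the RAS-family genes, MAP2K1/2, SHOC2, LZTR1, PPP1CB).
Diagnostic laboratories and ClinGen expert-panel curators score each variant
against the ACMG/AMP evidence codes (PVS1, PS1–4, PM1–6, PP1–5, BA1, BS1–4,
BP1–7), with disease-specific tariffs and thresholds, and combine the applied
codes into one of five tiers: Pathogenic (P), Likely Pathogenic (LP), VUS,
Likely Benign (LB), Benign (B). Doing this by hand is slow and inconsistent;
`rasrules` implements the updated RASopathy specifications as a deterministic,
auditable rules engine.

What the engine implements:

- **Point-based case scoring.** De novo observations (PS2/PM6): a confirmed
  de novo proband with a consistent phenotype scores 2 points, limited 1;
  assumed de novo scores 1 / 0.5; totals bin at 0.5 / 1 / 2 / 4 points into
  Supporting / Moderate / Strong / VeryStrong. Case counting (PS4): +1 per
  well-phenotyped proband, +0.5 limited, −1 for a well-phenotyped
  non-RASopathy case, binned at 1 / 3 / 5. Healthy carriers (BS2): −3 per
  healthy assessed homozygote, −1 per heterozygote, −0.25 per
  unaffected-unassessed relative, binned at −1 / −3. Alternate molecular
  cause (BP5/BP2, merged): −1 per qualifying observation, binned at −1 / −3.
- **Threshold criteria.** Grpmax filtering allele frequency (FAF), computed
  where needed as the exact one-sided 95% binomial lower confidence bound
  from allele counts: BA1 at FAF ≥ 5×10⁻⁴, BS1 at ≥ 2.5×10⁻⁴,
  PM2_Supporting below a per-gene rarity bound (2.5×10⁻⁵ for recessive
  LZTR1). REVEL ≥ 0.7 → PP3, ≤ 0.3 → BP4 (supporting only). PP2 restricted
  to the missense-constrained genes. PS3 capped at Moderate (≥2 distinct
  approved abnormal assays; 1 → Supporting); BS3 and BP3 never apply.
  PM4 for in-frame indels and stop-loss.
- **Hotspots, domains and paralogy.** PM5_Strong for predefined recurrence
  hotspots (≥2 distinct P/LP substitutions over ≥5 probands, no benign
  variation — also detectable at runtime from a case-count table); PM1 for
  predefined functional domains; PM1+PM5 may combine but PM1+PM5_Strong may
  not. PS1 and PM5 match through family alignments (e.g. MRAS Thr68 ↔ HRAS
  Thr58).
- **LZTR1 dual mechanism.** A decision tree routes LZTR1 variants to the
  dominant or recessive criteria set (case-level inheritance pattern →
  presumed loss of function → functional data → otherwise VUS), with
  recessive-only PVS1 (NMD 50-nt rule) and PM3 (in-trans point table).
- **Combination.** The classic ACMG/AMP combining rubric, then gene-validity
  capping (Moderate-validity genes such as MRAS cannot exceed LP) and the
  undetermined-route VUS override.
- **Gene validity scoring.** The case-level point rules used in recurations
  (de novo missense 0.5; +GoF functional 1.5; caps 12 genetic / 6
  experimental; Limited/Moderate/Strong/Definitive bins).

A seeded synthetic-evidence generator (`generate_fixtures()`) produces
bundles with independently derived expected classifications for testing.

## Worked example

A PTPN11 missense variant at the Asn308 hotspot with one parentage-confirmed
and two assumed de novo probands, absent from population databases, REVEL
0.88, and two abnormal approved functional assays:

```r
library(rasrules)
kb <- load_knowledge_base()
bundle <- read_bundles(system.file("extdata", "example_bundle.json",
                                   package = "rasrules"))[[1]]
res <- classify_variant(bundle, kb)
res
#> <ras_classification> PTPN11 c.922A>G p.(Asn308Asp)
#>   tier: P  route: AD
#>   applied: PS2_VeryStrong, PS4_Moderate, PP2, PM2_Supporting, PP3, PS3_Moderate, PM5_Strong
#>   note: single-mechanism gene
```

Reading the ledger: the three de novo probands tally 2+1+1 = 4 points →
PS2_VeryStrong; the same probands give PS4 3 points → Moderate; absence from
gnomAD gives PM2_Supporting; REVEL 0.88 ≥ 0.7 gives PP3; PTPN11 is
missense-constrained, so PP2 applies; two distinct abnormal assays give the
capped PS3_Moderate; and residue 308 is a predefined hotspot outside any
PM1 domain, so PM5_Strong applies. One VeryStrong plus one Strong satisfies
the Pathogenic rubric row, so the tier is P. `tidy(res)` returns the full
criterion table (including the codes that did *not* apply, with reasons),
`glance(res)` a one-row summary, and `autoplot(res)` a weight chart.

Batch use: `classify_bundles()` takes a list of bundles and returns a tibble
(one row per variant, `result` list-column with the full objects). A thin
CLI wraps the same functions:

```sh
exec/rasrules classify --evidence bundles.json --out results.json
exec/rasrules hotspots --case-table cases.tsv --out hotspots.tsv
exec/rasrules validity --evidence validity.tsv --out validity.json --replicated
exec/rasrules fixtures --seed 1 --n 100 --out bundles.json --expectations exp.tsv
```

The packaged knowledge base (`inst/extdata/rasopathy_kb.yaml`) holds every
gene-specific constant — applicable-criteria masks, frequency thresholds,
provisional PM1 domain coordinates and PM5_Strong hotspot lists, assay
registries, and paths to the (synthetic, offset-preserving) paralog-family
alignments. It is plain YAML and meant to be edited as curated data evolve.

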