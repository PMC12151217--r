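---
title: "Methods: point-based ACMG/AMP classification of RASopathy variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: point-based ACMG/AMP classification of RASopathy variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rasrules)
library(dplyr)
```

## The model

`rasrules` is a deterministic rules engine, not a statistical model: given a
structured evidence bundle for one variant in a RASopathy gene, it applies
each ACMG/AMP criterion under the RASopathy-specific tariffs and thresholds,
and combines the applied codes categorically. Its assumptions are therefore
the framework's assumptions:

- **Evidence is pre-structured.** Phenotype categories (`consistent`,
  `limited`, `nonspecific_or_none`, `inconsistent_alt_disorder`) are
  assigned upstream by a clinician experienced in RASopathies; the engine
  never infers them from free text. Likewise consequence annotations, REVEL
  scores, splice-impact predictions and assay results are inputs.
- **Independence of criterion groups.** A proband may legitimately
  contribute to both the de novo tally (PS2/PM6) and the case-count tally
  (PS4); these are scored independently, and an alternate-diagnosis proband
  counted at −1 under PS4 also remains eligible for the BP5 tally. The
  combiner's audit notes flag the co-application rather than silently
  suppressing it, because the tariff tables assign both deductions for the
  same scenario and nothing forbids the pairing.
- **Categorical combination.** The final tier comes from the classic
  combining rubric, not a Bayesian point sum. One consequence worth knowing:
  a single VeryStrong criterion with no Moderate and fewer than two
  Supporting criteria remains VUS. We did not adopt later extensions (e.g.
  VeryStrong + Supporting → LP) because the specifications cite the original
  rubric only.

## Point systems and their bins

The four case-observation groups use additive per-observation tariffs with
inclusive strength bins:

| group | tariff (per observation) | bins |
|---|---|---|
| PS2/PM6 | confirmed de novo: 2 (consistent) / 1 (limited); assumed: 1 / 0.5; not consistent: 0 | ≥0.5 Su, ≥1 M, ≥2 S, ≥4 VS |
| PS4 | consistent 1; limited 0.5; no info 0; non-RASopathy −1 | ≥1 Su, ≥3 M, ≥5 S |
| BS2 | healthy assessed hom −3 / het −1; unaffected-only −0.25; no info 0 | ≤−1 Su, ≤−3 S (no Moderate bin) |
| BP5/BP2 | −1 per qualifying alternate-cause observation | ≤−1 Su, ≤−3 S (no Moderate bin) |

Numerical choices:

- **Inclusive thresholds.** A tally landing exactly on a bin boundary takes
  that bin (the published worked de novo example lands exactly on 4 points
  and is VeryStrong). Fractional totals between bins fall to the lower
  strength; there is no interpolation.
- **One code per group.** PS2 is emitted when parentage is confirmed for any
  contributing proband, else PM6; BP2 is emitted when any phase-based
  (in-trans/in-cis) observation contributed, else BP5.
- **Prenatal cases** are restricted to the limited category and must carry at
  least one qualifying feature (HCM, increased nuchal translucency, cystic
  hygroma, pleural effusion, hydrops); this is a validation invariant, not a
  scoring rule.
- The tariff tables define −0.25 for an "unaffected heterozygote" without
  assessment. An unaffected-unassessed *homozygote* is not defined; we score
  it at the same −0.25 rather than inventing a larger deduction.
- For BP5/BP2 we count an in-trans/in-cis pathogenic partner only when phase
  is known (`confirmed_trans` or `cis`); a suspected-trans same-gene partner
  contributes nothing (cautious reading of "identified in trans or cis").
  A P/LP partner in a *different* RASopathy gene counts regardless of phase
  (the double-heterozygote clause). On the recessive LZTR1 route the
  BP5/BP2 scorer is disabled entirely: there an in-trans pathogenic partner
  is PM3 support, not benign evidence.

## Thresholds

- **Frequency.** BA1 at Grpmax FAF ≥ 5×10⁻⁴ and BS1 at ≥ 2.5×10⁻⁴
  (inclusive, as printed). PM2 is only ever Supporting, with an *exclusive*
  rarity bound (`<`): 2.5×10⁻⁵ for LZTR1 and a retained default of
  2.5×10⁻⁶ for the other genes. The non-LZTR1 bound is a configurable
  knowledge-base value because the updated specifications restate the bound
  only for LZTR1.
- **FAF from counts.** When only per-population allele counts are available,
  the Grpmax FAF is the maximum over non-bottlenecked populations of the
  exact one-sided 95% binomial lower confidence bound
  (`qbeta(0.05, AC, AN − AC + 1)`; zero for AC = 0) — the Clopper–Pearson
  style limit behind the widely used allele-frequency calculator. We attach
  the bottleneck flag per population (rather than one flag for the whole
  record) because founder populations are excluded individually from the
  Grpmax maximum. The test suite checks the closed form against an
  independent root-finding oracle on the binomial CDF to 1×10⁻⁶.
- **REVEL.** PP3 at ≥ 0.7 and BP4 at ≤ 0.3, both inclusive, both capped at
  Supporting; scores strictly between apply neither.
- **PS3** counts *distinct approved assays* by assay id (replicates count
  once): ≥2 abnormal → Moderate (the cap), exactly 1 → Supporting. BS3 is
  never emitted — validated pathogenic variants can score wild type under
  some conditions — and PPP1CB has an empty assay registry, so PS3 can never
  apply there. BP3 is never emitted either: no benign repetitive region
  exists in these coding sequences, so PM4 covers every in-frame length
  change and stop-loss.

## Hotspots, domains, paralogy

A PM5_Strong hotspot is a residue with ≥2 distinct P/LP substitutions,
summing to ≥5 probands, with no benign variation at the residue. The
knowledge base ships a precomputed list per gene; when a gene's list is
empty and a case-count table is supplied, the same rule is applied at
runtime (`detect_pm5_strong_hotspots()`). A precomputed list wins over
runtime detection because the published list is explicitly non-exhaustive
and curator-maintained.

Tie-breaks: PM1 (predefined domain) and moderate PM5 may apply together;
PM1 and PM5_Strong may not — when a hotspot lies inside a domain the engine
emits PM1 plus PM5 downgraded to Moderate, with the downgrade recorded in
the rationale. PM5 (any strength) is never applied to splice-affecting
variants. Both PM5 and PS1 may match through the paralog-family alignment
(same alignment column in another family member); PS1 additionally requires
the identical alternate amino acid, and for splice variants an identical
predicted splice-impact label (in-frame versus out-of-frame outcomes must
agree, since an in-frame product may act through gain of function).

The shipped alignments are **synthetic**: their column structure encodes the
published residue correspondences (MRAS +10 relative to HRAS, so Thr68 ↔
Thr58; RRAS2 +11; RIT1 +19; RAF1 ↔ BRAF +108; MAP2K1 ↔ MAP2K2 +4) with
placeholder conserved content. Only the column structure is consumed.
Likewise the PM1 domain coordinates (RAS-family P-Loop/SW1/SW2/SAK, with
SAK absent from MRAS/RIT1/RRAS2) and the hotspot lists are provisional
curated defaults, flagged replaceable in the YAML; classification
correctness intentionally depends on this editable data, not on hard-coded
constants.

## LZTR1 routing

LZTR1 is the one covered gene with two disease mechanisms. The router walks
the decision tree in order: (1) case-level inheritance pattern — one
biallelic affected proband suffices for AR, one confirmed de novo
heterozygous consistent proband for AD, and if both signals are present the
route is undetermined with an audit note (the tree gives no precedence);
(2) presumed loss of function (nonsense, frameshift, canonical splice
predicted out-of-frame) → AR; (3) functional data, mapped to a mechanism by
knowledge-base data (`p_erk`/`p_mek` → AD, `protein_stability`/
`subcellular_localization` → AR) because the specifications list the assays
but not their decision values; (4) otherwise undetermined, and the engine
forces VUS regardless of accumulated criteria.

On the AR route, PVS1 uses the generic loss-of-function framework at the
granularity available: a premature stop more than 50 nt upstream of the
last exon–exon junction (computed from the transcript exon table; a
synthetic 21-exon default ships with the package) is NMD-predicted →
VeryStrong; NMD-escaping or unplaceable truncations and out-of-frame
canonical splice variants → Strong (one-level reduction); in-frame splice
outcomes → not applicable. Every PVS1 rationale carries a "provisional"
marker because the panel's exon-level dispensability calls are not encoded
here. PM3 scores 1 point per confirmed-trans P/LP partner, 0.5 for
suspected/unknown phase and for homozygosity, halved for limited-phenotype
probands, binned 0.5/1/2/4. The AR route replaces the dominant
case-observation codes (PS2/PM6, PS4, PP2) rather than adding to them.

## The synthetic-evidence generator

`generate_fixtures()` draws bundles from seven scenario templates
(strong de novo series, prenatal limited cases, high-frequency benign
variants, biallelic recessive LZTR1 truncations, hotspot missense series,
deliberately conflicting evidence, alternate-diagnosis exome cases). Each
template randomises realistic quantities — 1–3 confirmed plus 0–2 assumed
de novo probands, FAFs drawn inside the relevant threshold interval, REVEL
in the decisive range for the scenario — under one seeded generator, and
pairs every bundle with the classification computed from rule tables
*re-transcribed inside the generator* (scalar lookups, deliberately not the
engine's vectorised code), so any divergence between the two
transcriptions is detectable. The suite checks engine/oracle agreement on
1,025 bundles across five seeds, alongside an exhaustive census
enumeration, bin-boundary sweeps on a 0.25-point grid, a 1,000-table
hotspot brute-force comparison and a 200-pair FAF oracle check; these
problem sizes keep the default run around four minutes on one core.

What the generator does **not** emulate: real genomic coordinates or
sequence context (HGVS strings are schematic), correlated evidence (e.g.
REVEL tracking hotspot status), curation noise such as conflicting ClinVar
assertions, and the long tail of partially specified real-world bundles.
Passing the fixture suite therefore demonstrates that the engine implements
the rule tables faithfully — not that the rules themselves, or the
provisional domain/hotspot defaults, match any particular external cohort.

## Degenerate inputs and determinism

Empty observation tables yield `not_applicable` with a zero tally, never an
error; a bundle with no frequency data yields no frequency criterion and an
audit note. Unknown enum strings are hard parse errors at construction
(clinical-safety choice: silently coerced evidence is worse than a refused
file). Validation (`validate_bundle()`) is pure and returns violations
rather than raising, so a batch can be fully checked before any
classification runs; the CLI refuses the whole file on the first invalid
bundle. All outputs, including rationale strings, are deterministic
functions of the inputs; result files are byte-identical across runs.

## Known limitations

- PM1 domains, hotspot lists and the paralog alignments are provisional
  stand-ins pending panel-curated data (see above).
- No HGVS validation or normalisation, no phenotype-ontology mapping, no
  splice-impact prediction: these are upstream responsibilities.
- Segregation (PP1/BS4) and the other unchanged criteria enter only as
  pre-evaluated passthrough codes.
- The gene-validity scorer implements the case-level point rules and SOP
  bins (Limited 0.1–6, Moderate 7–11, Strong/Definitive 12–18; caps 12
  genetic / 6 experimental) as configuration; earlier SOP versions' default
  points are out of scope.
- NF1 and SPRED1 are excluded by design; somatic evidence is not modelled.
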