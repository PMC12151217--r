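# Per-gene knowledge base: applicable-criteria masks, functional domains,
# hotspot lists, frequency thresholds, assay registries and paralog
# alignments. All of it is versioned *data* (YAML + aligned FASTA), not code:
# the shipped defaults are curated and replaceable.

#' Load the gene knowledge base
#'
#' Reads a YAML (or JSON) knowledge-base document plus the paralog-family
#' alignments and transcript tables it references, validates the structural
#' constraints the specifications impose (PVS1/PM3 restricted to LZTR1, PP2
#' restricted to the four missense-constrained genes, no approved assays for
#' PPP1CB, non-overlapping domains), and returns a `ras_kb` object.
#'
#' With no arguments the packaged default knowledge base is loaded. Its
#' domain coordinates, hotspot residues and alignments are provisional
#' curated defaults (the alignments are synthetic: their column structure
#' encodes published residue correspondences, not real sequence content) and
#' are intended to be replaced with panel-curated data.
#'
#' @param path Path to a knowledge-base YAML/JSON file, or `NULL` for the
#'   packaged default.
#' @return An object of class `ras_kb` with elements `genes` (named list of
#'   gene profiles), `alignments` (named list of paralog-family column maps)
#'   and `transcripts` (named list of exon tables).
#' @export
load_knowledge_base <- function(path = NULL) {
  path <- path %||% system.file("extdata", "rasopathy_kb.yaml", package = "rasrules")
  if (!file.exists(path)) abort(paste0("knowledge base not found: ", path))
  raw <- yaml::read_yaml(path)
  base_dir <- dirname(path)
  defaults <- raw$defaults %||% list()

  genes <- lapply(names(raw$genes), function(g) {
    spec <- raw$genes[[g]]
    thr <- spec$thresholds %||% list()
    domains <- if (length(spec$pm1_domains) == 0) {
      tibble(domain = character(), start = integer(), end = integer())
    } else {
      list_rbind(map(spec$pm1_domains, function(d) {
        tibble(domain = d$name, start = as.integer(d$start), end = as.integer(d$end))
      }))
    }
    assays <- if (length(spec$approved_assays) == 0) {
      tibble(id = character(), mechanism = character())
    } else {
      list_rbind(map(spec$approved_assays, function(a) {
        tibble(id = a$id, mechanism = a$mechanism %||% "AD")
      }))
    }
    list(
      gene = g,
      validity = spec$validity %||% list(AD = "Definitive"),
      inheritance_modes = unlist(spec$inheritance_modes %||% list("AD")),
      pp2_applicable = isTRUE(spec$pp2_applicable),
      pvs1_applicable = isTRUE(spec$pvs1_applicable),
      pm3_applicable = isTRUE(spec$pm3_applicable),
      pm1_domains = domains,
      pm5_strong_hotspots = as.integer(unlist(spec$pm5_strong_hotspots %||% list())),
      ba1_threshold = as.numeric(thr$ba1 %||% defaults$ba1 %||% 5e-4),
      bs1_threshold = as.numeric(thr$bs1 %||% defaults$bs1 %||% 2.5e-4),
      pm2_threshold = as.numeric(thr$pm2 %||% defaults$pm2 %||% 2.5e-6),
      pm2_threshold_ar = as.numeric(thr$pm2_ar %||% thr$pm2 %||% defaults$pm2 %||% 2.5e-6),
      approved_assays = assays,
      paralog_family = spec$paralog_family %||% "none"
    )
  })
  names(genes) <- names(raw$genes)

  alignments <- list()
  for (fam in names(raw$alignments %||% list())) {
    afile <- file.path(base_dir, raw$alignments[[fam]])
    alignments[[fam]] <- read_paralog_alignment(afile, family = fam)
  }
  transcripts <- list()
  for (g in names(raw$transcripts %||% list())) {
    tfile <- file.path(base_dir, raw$transcripts[[g]])
    transcripts[[g]] <- readr::read_tsv(tfile, show_col_types = FALSE)
  }

  kb <- structure(list(genes = genes, alignments = alignments,
                       transcripts = transcripts, source = path),
                  class = "ras_kb")
  validate_kb(kb)
  kb
}

validate_kb <- function(kb) {
  for (g in names(kb$genes)) {
    p <- kb$genes[[g]]
    if ((p$pvs1_applicable || p$pm3_applicable) && g != "LZTR1") {
      abort(paste0("knowledge base: PVS1/PM3 are applicable only to LZTR1 (offending gene: ", g, ")"))
    }
    if (p$pp2_applicable && !g %in% c("BRAF", "MAP2K1", "PTPN11", "PPP1CB")) {
      abort(paste0("knowledge base: PP2 restricted to BRAF/MAP2K1/PTPN11/PPP1CB (offending gene: ", g, ")"))
    }
    if (g == "PPP1CB" && nrow(p$approved_assays) > 0) {
      abort("knowledge base: PPP1CB has no approved functional assays")
    }
    if (g %in% c("MRAS", "RIT1", "RRAS2") && "SAK" %in% p$pm1_domains$domain) {
      abort(paste0("knowledge base: ", g, " lacks the SAK domain"))
    }
    d <- p$pm1_domains
    if (nrow(d) > 1) {
      d <- arrange(d, .data$start)
      if (any(d$start[-1] <= d$end[-nrow(d)])) {
        abort(paste0("knowledge base: overlapping PM1 domains for ", g))
      }
    }
  }
  invisible(kb)
}

#' @export
print.ras_kb <- function(x, ...) {
  cat("<ras_kb> ", length(x$genes), " genes; families: ",
      paste(names(x$alignments), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fetch one gene profile from a knowledge base
#'
#' Fails loudly when the gene is absent -- classification must never proceed
#' against a missing profile.
#'
#' @param kb A `ras_kb`.
#' @param gene Gene symbol.
#' @return The gene profile (a named list).
#' @export
kb_profile <- function(kb, gene) {
  if (!gene %in% names(kb$genes)) {
    abort(paste0("gene '", gene, "' is not in the knowledge base"))
  }
  kb$genes[[gene]]
}

#' Read an aligned FASTA paralog alignment
#'
#' Builds the residue-to-column map once at load. The map is bijective per
#' gene over non-gap positions.
#'
#' @param path Aligned FASTA file; records named by gene symbol.
#' @param family Family label to attach.
#' @return An object of class `ras_alignment` with elements `family`,
#'   `sequences` (named character vector of aligned rows) and `colmap`
#'   (named list: residue index -> alignment column).
#' @export
read_paralog_alignment <- function(path, family = "unknown") {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  aligned <- vapply(seqs, function(s) toupper(as.character(s)[1]), character(1))
  widths <- nchar(aligned)
  if (length(unique(widths)) != 1) {
    abort(paste0("alignment rows have unequal widths in ", path))
  }
  colmap <- lapply(aligned, function(s) {
    chars <- strsplit(s, "")[[1]]
    which(chars != "-")   # residue i sits in column colmap[i]
  })
  structure(list(family = family, sequences = aligned, colmap = colmap),
            class = "ras_alignment")
}

#' Map a residue to its analogous positions in paralogous genes
#'
#' Returns, for every family member (including the source gene itself, which
#' maps to identity), the residue occupying the same alignment column as the
#' source residue. Genes with a gap at that column contribute no row.
#'
#' @param alignment A `ras_alignment` (or a `ras_kb`, in which case the
#'   family containing `gene` is looked up).
#' @param gene Source gene symbol.
#' @param position Source residue position (1-based).
#' @return Tibble with columns `gene`, `residue_position`.
#' @export
map_analogous_residue <- function(alignment, gene, position) {
  if (inherits(alignment, "ras_kb")) {
    fam <- kb_profile(alignment, gene)$paralog_family
    if (identical(fam, "none") || !fam %in% names(alignment$alignments)) {
      abort(paste0("gene '", gene, "' is not in an aligned paralog family"))
    }
    alignment <- alignment$alignments[[fam]]
  }
  if (!gene %in% names(alignment$colmap)) {
    abort(paste0("gene '", gene, "' is not in the ", alignment$family, " alignment"))
  }
  cm <- alignment$colmap[[gene]]
  if (position < 1 || position > length(cm)) {
    abort(paste0("position ", position, " out of range for ", gene,
                 " (length ", length(cm), ")"))
  }
  col <- cm[position]
  list_rbind(map(names(alignment$colmap), function(g) {
    hit <- match(col, alignment$colmap[[g]])
    if (is.na(hit)) return(NULL)
    tibble(gene = g, residue_position = as.integer(hit))
  }))
}

#' Detect strong-level recurrence hotspots from a case-count table
#'
#' A residue qualifies as a PM5_Strong hotspot when (a) at least two distinct
#' pathogenic/likely-pathogenic substitutions have been reported there, (b)
#' those P/LP substitutions account for at least five probands in total, and
#' (c) no benign variation is present at the residue.
#'
#' @param case_table Tibble with columns `gene`, `residue_position`,
#'   `alt_aa`, `classification` (`P`, `LP`, `B`, `LB`, `VUS`),
#'   `proband_count` and `benign_variation_present`.
#' @return Tibble with columns `gene`, `residue_position`, one row per
#'   detected hotspot.
#' @export
detect_pm5_strong_hotspots <- function(case_table) {
  case_table <- as_tibble(case_table)
  if (nrow(case_table) == 0) {
    return(tibble(gene = character(), residue_position = integer()))
  }
  case_table |>
    group_by(.data$gene, .data$residue_position) |>
    summarise(
      n_plp = n_distinct(.data$alt_aa[.data$classification %in% c("P", "LP")]),
      plp_probands = sum(.data$proband_count[.data$classification %in% c("P", "LP")]),
      any_benign = any(.data$benign_variation_present) ||
        any(.data$classification %in% c("B", "LB")),
      .groups = "drop"
    ) |>
    filter(.data$n_plp >= 2, .data$plp_probands >= 5, !.data$any_benign) |>
    transmute(gene = .data$gene,
              residue_position = as.integer(.data$residue_position))
}

#' Locate a residue within a gene's predefined functional domains
#'
#' Genes for which no well-defined functional domain exists (SOS1, SOS2,
#' LZTR1, PPP1CB) always return `NA`: PM1 cannot be used for them.
#'
#' @param profile A gene profile from [kb_profile()].
#' @param position Residue position (1-based).
#' @return Domain name, or `NA_character_` when the residue lies in no
#'   domain.
#' @export
in_pm1_domain <- function(profile, position) {
  d <- profile$pm1_domains
  if (nrow(d) == 0 || is.na(position)) return(NA_character_)
  hit <- d |> filter(.data$start <= position, position <= .data$end)
  if (nrow(hit) == 0) NA_character_ else hit$domain[[1]]
}

#' Read a case-count table from TSV
#'
#' @param path TSV with columns `gene`, `residue_position`, `alt_aa`,
#'   `classification`, `proband_count`, `benign_variation_present`.
#' @return Tibble.
#' @export
read_case_count_table <- function(path) {
  tb <- readr::read_tsv(path, na = ".", show_col_types = FALSE)
  required <- c("gene", "residue_position", "alt_aa", "classification",
                "proband_count", "benign_variation_present")
  missing <- setdiff(required, names(tb))
  if (length(missing) > 0) {
    abort(paste0("case-count table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  chk_enum(tb$classification, c("P", "LP", "B", "LB", "VUS"), "classification")
  if (any(tb$proband_count < 0)) abort("proband_count must be nonnegative")
  tb |>
    mutate(residue_position = as.integer(.data$residue_position),
           proband_count = as.integer(.data$proband_count),
           benign_variation_present = as.logical(.data$benign_variation_present))
}

#' Read a known-pathogenic variant index from TSV
#'
#' The index backs PS1 (identical change in the same gene or at an analogous
#' paralog residue) and the moderate PM5 rule. Splice entries carry the
#' predicted splice-impact label that PS1 splice matching must reproduce.
#'
#' @param path TSV with columns `gene`, `type` (`missense`/`splice`),
#'   `position`, `alt_aa`, `splice_impact`, `classification`.
#' @return Tibble.
#' @export
read_known_pathogenic <- function(path) {
  tb <- readr::read_tsv(path, na = ".", show_col_types = FALSE)
  required <- c("gene", "type", "position", "alt_aa", "splice_impact", "classification")
  missing <- setdiff(required, names(tb))
  if (length(missing) > 0) {
    abort(paste0("known-pathogenic index is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  mutate(tb, position = as.integer(.data$position))
}
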