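# File interfaces: evidence bundles as JSON (one object per variant) or TSV
# (one row per observation keyed by variant id), classification reports as
# JSON (full ledger) or TSV (summary). TSV dialect: tab-separated, UTF-8,
# header row, '.' for nulls; numeric fields accept the typographic minus on
# input and are always emitted with the ASCII hyphen.

na_null <- function(x) if (length(x) == 0 || (length(x) == 1 && is.na(x))) NULL else x

bundle_to_list <- function(bundle) {
  id <- bundle$identity
  list(
    identity = compact(list(
      gene = id$gene, transcript = na_null(id$transcript),
      hgvs_c = na_null(id$hgvs_c), hgvs_p = na_null(id$hgvs_p),
      consequence = id$consequence,
      residue_position = na_null(id$residue_position),
      ref_aa = na_null(id$ref_aa), alt_aa = na_null(id$alt_aa),
      cds_stop_pos = na_null(id$cds_stop_pos),
      splice_frame = na_null(id$splice_frame)
    )),
    probands = if (nrow(bundle$probands) == 0) list() else
      map(seq_len(nrow(bundle$probands)), function(i) {
        p <- bundle$probands[i, ]
        list(phenotype_category = p$phenotype_category, de_novo = p$de_novo,
             context = p$context,
             prenatal_features = as.list(p$prenatal_features[[1]]),
             alt_cause_identified = p$alt_cause_identified,
             zygosity = p$zygosity)
      }),
    family = if (nrow(bundle$family) == 0) list() else
      map(seq_len(nrow(bundle$family)), function(i) as.list(bundle$family[i, ])),
    population = list(
      grpmax_faf = na_null(bundle$population$grpmax_faf),
      subpopulations = if (nrow(bundle$population$subpopulations) == 0) list() else
        map(seq_len(nrow(bundle$population$subpopulations)),
            function(i) as.list(bundle$population$subpopulations[i, ]))
    ),
    functional = list(assays = if (nrow(bundle$functional$assays) == 0) list() else
      map(seq_len(nrow(bundle$functional$assays)),
          function(i) as.list(bundle$functional$assays[i, ]))),
    computational = list(
      revel = na_null(bundle$computational$revel),
      splice_predictions = bundle$computational$splice_predictions
    ),
    trans_observations = if (nrow(bundle$trans_observations) == 0) list() else
      map(seq_len(nrow(bundle$trans_observations)),
          function(i) as.list(bundle$trans_observations[i, ])),
    passthrough_criteria = if (nrow(bundle$passthrough_criteria) == 0) list() else
      map(seq_len(nrow(bundle$passthrough_criteria)), function(i) {
        p <- bundle$passthrough_criteria[i, ]
        list(code = p$code, direction = p$direction, strength = p$strength,
             rationale = p$rationale)
      })
  )
}

bundle_from_list <- function(x) {
  idf <- x$identity
  identity <- variant_identity(
    gene = idf$gene, transcript = idf$transcript %||% NA_character_,
    hgvs_c = idf$hgvs_c %||% NA_character_, hgvs_p = idf$hgvs_p,
    consequence = idf$consequence, residue_position = idf$residue_position,
    ref_aa = idf$ref_aa, alt_aa = idf$alt_aa, cds_stop_pos = idf$cds_stop_pos,
    splice_frame = idf$splice_frame
  )
  probands <- if (length(x$probands) == 0) NULL else
    list_rbind(map(x$probands, function(p) {
      proband_observation(p$phenotype_category, p$de_novo %||% "unknown",
                          p$context %||% "clinical",
                          unlist(p$prenatal_features) %||% character(),
                          isTRUE(p$alt_cause_identified), p$zygosity %||% "het")
    }))
  family <- if (length(x$family) == 0) NULL else
    list_rbind(map(x$family, function(f) {
      family_observation(f$relationship %||% "relative", f$zygosity %||% "het",
                         f$health_status)
    }))
  sub <- if (length(x$population$subpopulations) == 0) NULL else
    list_rbind(map(x$population$subpopulations, function(s) {
      tibble(population = s$population, allele_count = as.integer(s$allele_count),
             allele_number = as.integer(s$allele_number),
             bottlenecked = isTRUE(s$bottlenecked))
    }))
  population <- population_data(grpmax_faf = x$population$grpmax_faf,
                                subpopulations = sub)
  assays <- if (length(x$functional$assays) == 0) NULL else
    list_rbind(map(x$functional$assays, function(a) {
      chk_enum(a$result, assay_result_levels, "result")
      tibble(assay_id = a$assay_id, result = a$result)
    }))
  computational <- computational_evidence(
    revel = x$computational$revel,
    splice_predictions = x$computational$splice_predictions
  )
  trans <- if (length(x$trans_observations) == 0) NULL else
    list_rbind(map(x$trans_observations, function(t) {
      trans_observation(t$partner_gene, t$partner_hgvs_c %||% NA_character_,
                        t$partner_classification, t$phase %||% "unknown",
                        t$proband_phenotype %||% "consistent")
    }))
  passthrough <- if (length(x$passthrough_criteria) == 0) NULL else
    list_rbind(map(x$passthrough_criteria, function(p) {
      passthrough_criterion(p$code, p$direction, p$strength,
                            p$rationale %||% "supplied pre-evaluated")
    }))
  evidence_bundle(identity, probands, family, population,
                  functional_evidence(assays), computational, trans, passthrough)
}

#' Write evidence bundles to JSON
#'
#' @param bundles List of [evidence_bundle()] objects (or a single bundle).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bundles <- function(bundles, path) {
  if (inherits(bundles, "ras_bundle")) bundles <- list(bundles)
  jsonlite::write_json(map(unname(bundles), bundle_to_list), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read evidence bundles from JSON or TSV
#'
#' JSON files hold one bundle object or an array of them. TSV files hold one
#' row per observation, keyed by `variant_id` with a `record` discriminator
#' (`identity`, `proband`, `family`, `subpopulation`, `assay`,
#' `computational`, `trans`, `passthrough`); `.` marks nulls, and numeric
#' fields accept the typographic minus sign. Unknown enum values are hard
#' parse errors.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"json"` or `"tsv"`.
#' @return List of [evidence_bundle()] objects, in file order.
#' @export
read_bundles <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "tsv" else "json"
  }
  if (format == "json") {
    raw <- jsonlite::read_json(path)
    if (!is.null(raw$identity)) raw <- list(raw)  # single object
    return(map(raw, bundle_from_list))
  }
  read_bundles_tsv(path)
}

fix_minus <- function(x) gsub("−", "-", x)
tsv_num <- function(x) if (is.null(x) || is.na(x)) NULL else as.numeric(fix_minus(x))
tsv_int <- function(x) if (is.null(x) || is.na(x)) NULL else as.integer(fix_minus(x))
tsv_chr <- function(x) if (is.null(x) || is.na(x)) NULL else x
tsv_lgl <- function(x) if (is.null(x) || is.na(x)) FALSE else as.logical(x)
tsv_or <- function(x, default) if (is.null(x) || is.na(x)) default else x

read_bundles_tsv <- function(path) {
  tb <- readr::read_tsv(path, na = ".", col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE)
  for (col in c("variant_id", "record")) {
    if (!col %in% names(tb)) abort(paste0("bundle TSV is missing the '", col, "' column"))
  }
  getf <- function(row, field) if (field %in% names(tb)) row[[field]] else NA_character_
  ids <- unique(tb$variant_id)
  map(ids, function(vid) {
    rows <- filter(tb, .data$variant_id == vid)
    idr <- filter(rows, .data$record == "identity")
    if (nrow(idr) != 1) {
      abort(paste0("variant '", vid, "': expected exactly one identity row, found ",
                   nrow(idr)))
    }
    identity <- variant_identity(
      gene = getf(idr, "gene"), transcript = tsv_or(getf(idr, "transcript"), NA_character_),
      hgvs_c = tsv_or(getf(idr, "hgvs_c"), NA_character_), hgvs_p = tsv_chr(getf(idr, "hgvs_p")),
      consequence = getf(idr, "consequence"),
      residue_position = tsv_int(getf(idr, "residue_position")),
      ref_aa = tsv_chr(getf(idr, "ref_aa")), alt_aa = tsv_chr(getf(idr, "alt_aa")),
      cds_stop_pos = tsv_int(getf(idr, "cds_stop_pos")),
      splice_frame = tsv_chr(getf(idr, "splice_frame"))
    )
    sub_rows <- filter(rows, .data$record == "subpopulation")
    sub <- if (nrow(sub_rows) == 0) NULL else
      list_rbind(map(seq_len(nrow(sub_rows)), function(i) {
        r <- sub_rows[i, ]
        tibble(population = getf(r, "population"),
               allele_count = tsv_int(getf(r, "allele_count")),
               allele_number = tsv_int(getf(r, "allele_number")),
               bottlenecked = tsv_lgl(getf(r, "bottlenecked")))
      }))
    comp_row <- filter(rows, .data$record == "computational")
    computational <- if (nrow(comp_row) == 0) NULL else
      computational_evidence(revel = tsv_num(getf(comp_row[1, ], "revel")))
    build_rows <- function(rec, f) {
      rr <- filter(rows, .data$record == !!rec)
      if (nrow(rr) == 0) return(NULL)
      list_rbind(map(seq_len(nrow(rr)), function(i) f(rr[i, ])))
    }
    probands <- build_rows("proband", function(r) {
      feats <- getf(r, "prenatal_features")
      proband_observation(
        getf(r, "phenotype_category"), tsv_or(getf(r, "de_novo"), "unknown"),
        tsv_or(getf(r, "context"), "clinical"),
        if (is.na(feats)) character() else strsplit(feats, ",")[[1]],
        tsv_lgl(getf(r, "alt_cause_identified")), tsv_or(getf(r, "zygosity"), "het"))
    })
    family <- build_rows("family", function(r) {
      family_observation(tsv_or(getf(r, "relationship"), "relative"),
                         tsv_or(getf(r, "zygosity"), "het"), getf(r, "health_status"))
    })
    assays <- build_rows("assay", function(r) {
      chk_enum(getf(r, "result"), assay_result_levels, "result")
      tibble(assay_id = getf(r, "assay_id"), result = getf(r, "result"))
    })
    trans <- build_rows("trans", function(r) {
      trans_observation(getf(r, "partner_gene"),
                        tsv_or(getf(r, "partner_hgvs_c"), NA_character_),
                        getf(r, "partner_classification"),
                        tsv_or(getf(r, "phase"), "unknown"),
                        tsv_or(getf(r, "proband_phenotype"), "consistent"))
    })
    passthrough <- build_rows("passthrough", function(r) {
      passthrough_criterion(getf(r, "code"), getf(r, "direction"), getf(r, "strength"))
    })
    grpmax <- {
      popr <- filter(rows, .data$record == "population")
      if (nrow(popr) == 0) NULL else tsv_num(getf(popr[1, ], "grpmax_faf"))
    }
    evidence_bundle(identity, probands, family,
                    population_data(grpmax_faf = grpmax, subpopulations = sub),
                    functional_evidence(assays), computational, trans, passthrough)
  })
}

#' Write classification results
#'
#' JSON output carries the full per-variant criterion ledger and audit
#' notes; TSV output is a one-row-per-variant summary. Output is
#' byte-identical across runs for identical inputs.
#'
#' @param results Tibble from [classify_bundles()].
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(select(results, -"result"), path)
    return(invisible(path))
  }
  payload <- map(results$result, function(r) {
    list(
      identity = compact(list(gene = r$identity$gene,
                              transcript = na_null(r$identity$transcript),
                              hgvs_c = na_null(r$identity$hgvs_c),
                              hgvs_p = na_null(r$identity$hgvs_p))),
      tier = r$tier,
      mechanism_route = r$mechanism_route,
      capped_by_validity = r$capped_by_validity,
      criteria = map(seq_len(nrow(r$criteria)), function(i) {
        cr <- r$criteria[i, ]
        compact(list(code = cr$code, direction = cr$direction,
                     strength = cr$strength, points = na_null(cr$points),
                     label = cr$label, rationale = cr$rationale))
      }),
      notes = as.list(r$notes)
    )
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

command_status <- function(expr) {
  tryCatch({ expr; 0L }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
}

#' Classify evidence bundles from the command line
#'
#' Reads bundles, validates every one (any violation aborts with a nonzero
#' status naming the offending fields), classifies them in input order, logs
#' every criterion decision with its rationale to stderr, and writes the
#' result file.
#'
#' @param evidence_path Bundle JSON/TSV file.
#' @param output_path Result file to write.
#' @param kb_path Knowledge-base YAML, or `NULL` for the packaged default.
#' @param output_format `"json"` or `"tsv"`.
#' @param case_table_path,known_pathogenic_path Optional TSV side inputs.
#' @param quiet Suppress the per-criterion log.
#' @return Integer exit status, invisibly (0 on success).
#' @export
classify_command <- function(evidence_path, output_path, kb_path = NULL,
                             output_format = c("json", "tsv"),
                             case_table_path = NULL,
                             known_pathogenic_path = NULL, quiet = FALSE) {
  output_format <- match.arg(output_format)
  status <- command_status({
    kb <- load_knowledge_base(kb_path)
    bundles <- read_bundles(evidence_path)
    violations <- character()
    for (i in seq_along(bundles)) {
      v <- validate_bundle(bundles[[i]], kb)
      if (length(v) > 0) violations <- c(violations, paste0("bundle ", i, ": ", v))
    }
    if (length(violations) > 0) {
      abort(paste0("validation failed:\n  ", paste(violations, collapse = "\n  ")))
    }
    case_table <- if (!is.null(case_table_path)) read_case_count_table(case_table_path)
    known <- if (!is.null(known_pathogenic_path)) read_known_pathogenic(known_pathogenic_path)
    results <- classify_bundles(bundles, kb, case_table = case_table,
                                known_pathogenic = known)
    if (!quiet) {
      for (r in results$result) {
        message(r$identity$gene, " ", r$identity$hgvs_c, " -> ", r$tier)
        for (i in seq_len(nrow(r$criteria))) {
          message("  ", r$criteria$label[i], ": ", r$criteria$rationale[i])
        }
      }
    }
    write_results(results, output_path, output_format)
  })
  invisible(status)
}

#' Detect hotspots from a case-count table (command wrapper)
#'
#' @param case_table_path Case-count TSV.
#' @param output_path Output TSV of detected (gene, residue) hotspots.
#' @return Integer exit status, invisibly.
#' @export
hotspots_command <- function(case_table_path, output_path) {
  invisible(command_status({
    tb <- read_case_count_table(case_table_path)
    readr::write_tsv(detect_pm5_strong_hotspots(tb), output_path)
  }))
}

#' Score gene-validity evidence (command wrapper)
#'
#' @param evidence_table_path Validity-evidence TSV.
#' @param output_path Output JSON.
#' @param replicated_over_time Replication flag passed to [score_validity()].
#' @return Integer exit status, invisibly.
#' @export
validity_command <- function(evidence_table_path, output_path,
                             replicated_over_time = FALSE) {
  invisible(command_status({
    ev <- read_validity_table(evidence_table_path)
    res <- withCallingHandlers(
      score_validity(ev, replicated_over_time),
      warning = function(w) {
        message("warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    jsonlite::write_json(as.list(res), output_path, auto_unbox = TRUE, digits = NA)
  }))
}

#' Generate fixture bundles and expectations (command wrapper)
#'
#' @param seed Integer seed.
#' @param n_variants Number of bundles.
#' @param bundles_path Output bundles JSON.
#' @param expectations_path Output expectations TSV.
#' @return Integer exit status, invisibly.
#' @export
fixtures_command <- function(seed, n_variants, bundles_path, expectations_path) {
  invisible(command_status({
    fx <- generate_fixtures(seed, n_variants)
    write_bundles(fx$bundles, bundles_path)
    flat <- fx$expectations |>
      mutate(expected_codes = map_chr(.data$expected_codes, function(tb) {
        paste(paste0(tb$code, ":", tb$strength), collapse = ",")
      }))
    readr::write_tsv(flat, expectations_path)
  }))
}
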