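#' @title Table readers/writers, configuration and the integration pipeline
#'
#' @description All tabular artifacts are tab-separated UTF-8. Study tables
#' carry one quantification per row with full provenance metadata; the atlas
#' output carries normalized molar concentrations with the same provenance.
#' The pipeline configuration exposes every physical constant with its
#' default, since the built-in values (200 g/L, 200 pg, 1.04 g/mL, 80%
#' water, the volume fractions) are assumptions a user may wish to replace
#' with tissue-specific numbers.
#'
#' @name io_cli
NULL

STUDY_COLUMNS <- c("gene", "value", "value_type", "study_id", "species",
                   "brain_region", "cell_type", "location", "condition",
                   "age")
VALUE_TYPES <- c("LFQ", "iBAQ", "TMT", "SILAC", "M", "mM", "uM", "nM",
                 "mol_per_g_protein")

#' Read a per-study quantification table
#'
#' Tab-separated with required columns `gene` (and/or `accession`), `value`,
#' `value_type`, `study_id`, `species`, `brain_region`, `cell_type`,
#' `location`, `condition`, `age`. Values must be numeric; unknown value
#' types are rejected; blank metadata fields become `"unknown"`.
#'
#' @param path file path
#' @return data.frame of typed measurement records
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- STUDY_COLUMNS
  if (!("gene" %in% names(tab)) && "accession" %in% names(tab))
    required <- setdiff(required, "gene")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("missing column ", paste(missing, collapse = ", "))
  value <- suppressWarnings(as.numeric(tab$value))
  bad <- which(is.na(value) & nzchar(tab$value))
  if (length(bad))
    stop(sprintf("non-numeric value '%s' at row %d", tab$value[bad[1L]],
                 bad[1L]))
  tab$value <- value
  unknown_vt <- setdiff(unique(tab$value_type), VALUE_TYPES)
  if (length(unknown_vt))
    stop("unknown value_type '", unknown_vt[1L], "'")
  for (col in setdiff(names(tab), c("value"))) {
    blank <- is.na(tab[[col]]) | !nzchar(trimws(tab[[col]]))
    tab[[col]][blank] <- "unknown"
  }
  tab
}

#' Write the atlas of concentration entries
#'
#' Tab-separated, one row per entry, stable column order, concentrations in
#' uM serialized with 15 significant digits so a read-back loses no
#' precision beyond 1e-9 relative.
#'
#' @param entries non-empty data.frame of concentration entries
#' @param path output path
#' @export
write_atlas <- function(entries, path) {
  if (!is.data.frame(entries) || nrow(entries) == 0L)
    stop("no entries to write")
  num <- vapply(entries, is.numeric, logical(1))
  out <- entries
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15,
                                                   format = "g"))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an atlas written by [write_atlas()]
#'
#' @param path file path
#' @return data.frame of concentration entries
#' @export
read_atlas <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Collects every constant and path the pipeline uses, all defaulted to the
#' package's built-in values, and validates them (positive constants, volume
#' fractions summing to 1).
#'
#' @param studies_dir directory of study tables (`*.tsv`)
#' @param fasta FASTA file of protein sequences
#' @param housekeeping path to a one-symbol-per-line housekeeping gene list
#' @param synonym_table path to the offline synonym table
#' @param out_atlas,out_report output paths (optional; `NULL` keeps results
#'   in memory)
#' @param params an [estimation_params()]
#' @param digest a [digest_spec()]
#' @param metabolite_constants a [conversion_constants()]
#' @param fractions volume fractions for [tissue_composition()]
#' @param organelle_only_studies study ids excluded from the reference pool
#' @param alpha significance level
#' @param seed integer seed for the stochastic validation steps
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(studies_dir, fasta, housekeeping, synonym_table,
                            out_atlas = NULL, out_report = NULL,
                            params = estimation_params(),
                            digest = digest_spec(),
                            metabolite_constants = conversion_constants(),
                            fractions = c(extracellular = 0.19,
                                          vasculature = 0.03,
                                          neuron_soma = 0.10,
                                          neurites = 0.60, glia = 0.08),
                            organelle_only_studies = character(),
                            alpha = 0.05, seed = 1L) {
  tissue_composition(fractions)  # validates the fractions
  stopifnot(inherits(params, "estimation_params"),
            inherits(digest, "digest_spec"),
            inherits(metabolite_constants, "conversion_constants"))
  structure(
    list(studies_dir = studies_dir, fasta = fasta,
         housekeeping = housekeeping, synonym_table = synonym_table,
         out_atlas = out_atlas, out_report = out_report, params = params,
         digest = digest, metabolite_constants = metabolite_constants,
         fractions = fractions,
         organelle_only_studies = organelle_only_studies,
         alpha = alpha, seed = as.integer(seed)),
    class = "pipeline_config")
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full protein integration pipeline
#'
#' Stages, in order: ingest study tables; nomenclature alignment (synonym
#' graph over co-listed names plus the offline synonym table); per-study
#' concentration estimation (total-protein-mass conversion for MS signal
#' types, direct unit conversion for reported concentrations); reference
#' median over housekeeping proteins; per-study normalization; validation
#' report (variability scores before/after normalization, per-study
#' correlation table, median-equality battery when three or more studies are
#' present). Per-stage record counts are logged to stderr. Records are
#' sorted by study and gene before processing, so outputs do not depend on
#' file enumeration order.
#'
#' @param config a [pipeline_config()]
#' @return list with `atlas` (normalized concentration entries),
#'   `reference_median_uM`, `report` (named list of stage summaries)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- sort(list.files(config$studies_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
  if (length(paths) == 0L) stop("stage ingest: no study tables in ",
                                config$studies_dir)
  records <- do.call(rbind, lapply(paths, read_study_table))
  records <- records[order(records$study_id, records$gene), , drop = FALSE]
  log_stage("ingest", "%d records from %d studies", nrow(records),
            length(unique(records$study_id)))

  syn_tab <- read_synonym_table(config$synonym_table)
  entries_names <- strsplit(records$gene, "[|;]")
  graph <- build_synonym_graph(entries_names, syn_tab$gene_names)
  records$canonical_gene <- canonical_labels(
    graph, vapply(entries_names, `[`, character(1), 1L))
  log_stage("nomenclature", "%d names in %d components",
            length(graph$canonical_map), length(graph$components))

  seqs <- read_fasta_proteins(config$fasta)
  seq_gene <- canonical_labels(graph, names(seqs))
  mol_weight <- stats::setNames(
    vapply(seqs, molecular_weight, numeric(1)), seq_gene)
  peptides <- stats::setNames(
    vapply(seqs, count_theoretical_peptides, numeric(1),
           spec = config$digest), seq_gene)

  ms_types <- c("LFQ", "iBAQ", "TMT", "SILAC")
  out <- list()
  dropped_no_seq <- 0L
  dropped_zero_pep <- 0L
  for (study in split(records, records$study_id)) {
    sid <- study$study_id[1L]
    est <- list()
    for (vt in unique(study$value_type)) {
      part <- study[study$value_type == vt, , drop = FALSE]
      if (vt %in% ms_types) {
        known <- part$canonical_gene %in% names(mol_weight)
        dropped_no_seq <- dropped_no_seq + sum(!known)
        part <- part[known, , drop = FALSE]
        if (nrow(part) == 0L) next
        det <- if (vt == "iBAQ") rep(1, nrow(part)) else
          unname(peptides[part$canonical_gene])
        usable <- det > 0
        dropped_zero_pep <- dropped_zero_pep + sum(!usable)
        part <- part[usable, , drop = FALSE]
        if (nrow(part) == 0L) next
        inputs <- data.frame(gene = part$canonical_gene,
                             signal = part$value,
                             detectability = det[usable],
                             mol_weight = unname(
                               mol_weight[part$canonical_gene]))
        res <- estimate_study(inputs, config$params)
        part <- part[inputs$signal > 0 & !is.na(inputs$signal), ,
                     drop = FALSE]
        part$copy_number <- res$table$copy_number
        part$concentration_uM <- res$table$concentration_uM
      } else {
        part$copy_number <- NA_real_
        part$concentration_uM <- convert_reported_units(part$value, vt,
                                                        config$params)
      }
      est[[vt]] <- part
    }
    if (length(est)) out[[sid]] <- do.call(rbind, est)
  }
  entries <- do.call(rbind, out)
  rownames(entries) <- NULL
  log_stage("estimate", "%d entries (%d without sequence, %d with zero peptides dropped)",
            nrow(entries), dropped_no_seq, dropped_zero_pep)

  housekeeping <- canonical_labels(graph,
                                   readLines(config$housekeeping))
  ref_median <- compute_reference_median(
    entries, housekeeping,
    organelle_only_studies = config$organelle_only_studies)
  log_stage("reference", "housekeeping reference median %.4g uM", ref_median)

  atlas <- normalize_to_reference(entries, housekeeping, ref_median)
  atlas <- atlas[order(atlas$study_id, atlas$canonical_gene), , drop = FALSE]
  rownames(atlas) <- NULL
  log_stage("normalize", "%d normalized entries across %d studies",
            nrow(atlas), length(unique(atlas$study_id)))

  report <- list(
    n_records = nrow(records),
    n_entries = nrow(atlas),
    n_studies = length(unique(atlas$study_id)),
    reference_median_uM = ref_median,
    dropped_no_sequence = dropped_no_seq,
    dropped_zero_peptides = dropped_zero_pep)

  vs <- tapply(atlas$concentration_uM, atlas$canonical_gene,
               variability_score)
  report$median_variability_score <- stats::median(vs, na.rm = TRUE)
  if (report$n_studies >= 2L) {
    ct <- correlation_tables(atlas, "study_id")
    report$median_pairwise_r <- stats::median(
      ct$r[upper.tri(ct$r)], na.rm = TRUE)
  }
  if (report$n_studies >= 3L) {
    grp <- lapply(split(atlas$concentration_uM, atlas$study_id), log)
    grp <- grp[vapply(grp, length, 1L) >= 2L]
    if (length(grp) >= 3L) {
      meb <- median_equality_battery(grp, alpha = config$alpha)
      report$kw_statistic <- meb$kw_statistic
      report$kw_p <- meb$kw_p
    }
  }
  log_stage("validate", "median variability score %.4g",
            report$median_variability_score)

  if (!is.null(config$out_atlas)) write_atlas(atlas, config$out_atlas)
  if (!is.null(config$out_report))
    jsonlite::write_json(report, config$out_report, auto_unbox = TRUE,
                         digits = NA)
  list(atlas = atlas, reference_median_uM = ref_median, report = report)
}
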