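# Orchestration: the three end-to-end analyses (a-priori stratification,
# temporal ITH, spatial ITH) with config, stage logging and reproducible
# run manifests.

#' Pipeline run configuration
#'
#' Collects the thresholds every analysis shares. Defaults are the
#' pipeline's standard operating point: candidates need `dscore > 0.7`;
#' cohort-level prescription additionally requires `gscore > 0.6`;
#' temporal selection uses VAF < 1% at baseline and >= 10% at relapse;
#' CNV support needs `|z| > 2`.
#'
#' @param dscore_min,gscore_min Prescription thresholds.
#' @param low_vaf,rise_min Temporal-selection thresholds.
#' @param z_min CNV expression-support threshold.
#' @param drug_class Named list of drug classes (class label -> canonical
#'   drug names).
#' @param seed Integer seed recorded in manifests.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dscore_min = 0.7, gscore_min = 0.6,
                       low_vaf = 0.01, rise_min = 0.10, z_min = 2,
                       drug_class = list(), seed = 1L) {
  ct_assert(dscore_min >= -1 && dscore_min <= 1, "dscore_min outside [-1, 1]")
  ct_assert(gscore_min >= 0 && gscore_min <= 1, "gscore_min outside [0, 1]")
  ct_assert(low_vaf > 0 && low_vaf < rise_min && rise_min < 1,
            "need 0 < low_vaf < rise_min < 1")
  ct_assert(z_min > 0, "z_min must be positive")
  structure(list(dscore_min = dscore_min, gscore_min = gscore_min,
                 low_vaf = low_vaf, rise_min = rise_min, z_min = z_min,
                 drug_class = drug_class, seed = as.integer(seed)),
            class = "run_config")
}

# Run manifest: config values + digests of any input files + versions.
run_manifest <- function(cfg, inputs = character()) {
  digests <- if (length(inputs)) {
    existing <- inputs[file.exists(inputs)]
    as.list(tools::md5sum(existing))
  } else list()
  list(
    package = "clonotherapy",
    version = as.character(utils::packageVersion("clonotherapy")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config = cfg[c("dscore_min", "gscore_min", "low_vaf", "rise_min", "z_min")],
    input_md5 = digests
  )
}

write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' A-priori stratification analysis
#'
#' Per patient, classifies response to the administered drug class from
#' the molecular profile ([classify_response()]), compares overall
#' survival between the responder and non-responder strata
#' ([stratified_os_analysis()]), and proposes alternative therapies
#' outside the class for every non-responder
#' ([alternative_therapies()]).
#'
#' @param cfg A [run_config()] whose `drug_class` holds the administered
#'   class under `class_label`.
#' @param profiles Named list: patient id -> mutated gene symbols.
#' @param survival_records Tibble with `patient_id`, `time_days`, `event`.
#' @param kb An `evidence_kb`.
#' @param class_label Name of the drug class in `cfg$drug_class`.
#' @param out_dir Optional output directory; when given, writes
#'   `labels.tsv`, `alternatives.tsv`, `stratification.json`,
#'   `km_plot.pdf` and `manifest.json`.
#' @param inputs Optional character vector of input file paths to digest
#'   into the manifest.
#' @return List of class `stratification_report`: `labels`, `os`,
#'   `alternatives`, `alternative_rate`, `manifest`.
#' @export
run_stratification <- function(cfg, profiles, survival_records, kb,
                               class_label = names(cfg$drug_class)[1],
                               out_dir = NULL, inputs = character()) {
  stopifnot(inherits(cfg, "run_config"))
  ct_assert(length(profiles) > 0 && !is.null(names(profiles)),
            "profiles must be a non-empty named list")
  drug_class <- cfg$drug_class[[class_label]]
  ct_assert(length(drug_class) > 0,
            "stage classify: drug class '", class_label,
            "' is empty or missing from cfg$drug_class")

  message("stage classify: ", length(profiles), " profiles against ",
          length(drug_class), " class drugs")
  cls <- lapply(profiles, classify_response, drug_class = drug_class, kb = kb)
  labels <- tibble::tibble(
    patient_id = names(profiles),
    label = vapply(cls, `[[`, "", "label"),
    reason = vapply(cls, `[[`, "", "reason")
  )
  ct_assert(any(labels$label == "non_responder"),
            "stage stratify: cohort has zero non-responders; ",
            "no two-group comparison is possible")
  ct_assert(any(labels$label == "responder"),
            "stage stratify: cohort has zero responders; ",
            "no two-group comparison is possible")

  os <- stratified_os_analysis(labels[c("patient_id", "label")],
                               survival_records)
  message("stage stratify: log-rank p = ", format(os$p_value, digits = 3))

  nr_ids <- labels$patient_id[labels$label == "non_responder"]
  alts <- lapply(setNames(nr_ids, nr_ids), function(pid)
    alternative_therapies(profiles[[pid]], drug_class, kb,
                          dscore_min = cfg$dscore_min,
                          gscore_min = cfg$gscore_min))
  alt_rate <- mean(vapply(alts, nrow, 1L) > 0)
  message("stage alternatives: proposals for ",
          round(100 * alt_rate, 1), "% of non-responders")

  report <- structure(list(
    labels = labels, os = os, alternatives = alts,
    alternative_rate = alt_rate,
    manifest = run_manifest(cfg, inputs)
  ), class = "stratification_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(labels, file.path(out_dir, "labels.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    alt_tbl <- dplyr::bind_rows(lapply(names(alts), function(pid) {
      a <- alts[[pid]]
      if (nrow(a) == 0) return(NULL)
      tibble::tibble(patient_id = pid, drug = a$drug,
                     drug_status = a$drug_status,
                     best_dscore = a$best_dscore, best_gscore = a$best_gscore)
    }))
    write.table(alt_tbl, file.path(out_dir, "alternatives.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_report_json(list(
      group_sizes = as.list(report$os$group_sizes),
      medians = as.list(report$os$medians),
      logrank_statistic = report$os$statistic,
      p_value = report$os$p_value,
      alternative_rate = alt_rate
    ), file.path(out_dir, "stratification.json"))
    write_report_json(report$manifest, file.path(out_dir, "manifest.json"))
    p <- plot_km(report$os)
    ggplot2::ggsave(file.path(out_dir, "km_plot.pdf"), p,
                    width = 6, height = 4)
  }
  report
}

#' Temporal-ITH prescription analysis
#'
#' Selects genes under positive temporal selection (pre-existing at low
#' VAF, expanded at relapse, plus relapse-specific gains) and prescribes
#' drugs on the selected profile.
#'
#' @param cfg A [run_config()].
#' @param vaf_table Tibble `gene` / `timepoint` / `vaf` (see
#'   [read_vaf_table()]).
#' @param kb An `evidence_kb`.
#' @param t0,t1 Baseline and relapse timepoint labels.
#' @param out_dir,inputs As in [run_stratification()].
#' @return List of class `temporal_report`: `selection` (from
#'   [select_temporal_genes()]), `prescription` (ranked records, each
#'   flagged pre-existing vs relapse-specific via its supporting genes),
#'   `druggable_genes`, `manifest`.
#' @export
run_temporal <- function(cfg, vaf_table, kb, t0, t1,
                         out_dir = NULL, inputs = character()) {
  stopifnot(inherits(cfg, "run_config"))
  vaf_table <- tibble::as_tibble(vaf_table)
  if (nrow(vaf_table) > 0)
    ct_assert(length(unique(vaf_table$timepoint)) >= 2,
              "stage select: need at least two timepoints")
  sel <- select_temporal_genes(vaf_table, t0, t1,
                               low_vaf = cfg$low_vaf, rise_min = cfg$rise_min)
  message("stage select: ", length(sel$genes), " genes (",
          length(sel$pre_existing), " pre-existing, ",
          length(sel$relapse_specific), " relapse-specific)")
  rx <- if (length(sel$genes))
    prescribe_profile(sel$genes, kb, dscore_min = cfg$dscore_min,
                      gscore_min = 0)
  else prescribe_profile(character(), kb)
  if (nrow(rx) > 0) {
    rx$origin <- vapply(rx$supporting_genes, function(g) {
      pre <- any(g %in% sel$pre_existing)
      rel <- any(g %in% sel$relapse_specific)
      if (pre && rel) "both" else if (rel) "relapse_specific" else "pre_existing"
    }, "")
  }
  report <- structure(list(
    selection = sel,
    prescription = rx,
    druggable_genes = if (length(sel$genes))
      druggable_genes(sel$genes, kb) else character(),
    manifest = run_manifest(cfg, inputs)
  ), class = "temporal_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(list(
      selected_genes = sel$genes,
      pre_existing = sel$pre_existing,
      relapse_specific = sel$relapse_specific,
      druggable_genes = report$druggable_genes,
      drugs = if (nrow(rx)) rx$drug else character()
    ), file.path(out_dir, "temporal.json"))
    write_prescription_tsv(rx, file.path(out_dir, "prescription.tsv"))
    write_report_json(report$manifest, file.path(out_dir, "manifest.json"))
  }
  report
}

#' Spatial-ITH prescription analysis
#'
#' For every sample of the architecture: bulk-vs-ITH comparison, per-clone
#' druggability, and a trunk-plus-specific regimen; the per-sample
#' regimens are unioned into a cross-sample drug set.
#'
#' @param cfg A [run_config()].
#' @param arch A `clonal_architecture` with >= 1 sample.
#' @param kb An `evidence_kb`.
#' @param strategy Regimen strategy, see [propose_regimen()].
#' @param out_dir,inputs As in [run_stratification()].
#' @return List of class `spatial_report`: per-sample `comparisons`,
#'   `druggability` tibble, `regimen` (whole-architecture proposal),
#'   `combined_drugs`, `manifest`.
#' @export
run_spatial <- function(cfg, arch, kb,
                        strategy = "trunk_plus_specific",
                        out_dir = NULL, inputs = character()) {
  stopifnot(inherits(cfg, "run_config"), inherits(arch, "clonal_architecture"))
  ct_assert(length(sample_ids(arch)) >= 1, "architecture has no samples")

  comparisons <- lapply(setNames(sample_ids(arch), sample_ids(arch)),
                        function(sid) {
    cmp <- bulk_vs_ith(arch, sid, kb, dscore_min = cfg$dscore_min,
                       gscore_min = 0)
    message("stage compare[", sid, "]: bulk ", cmp$bulk_gene_count,
            " vs ITH ", cmp$ith_gene_count, " genes")
    cmp
  })
  druggability <- dplyr::bind_rows(lapply(sample_ids(arch), function(sid) {
    p <- arch$samples[[sid]]
    present <- names(p)[p > 0]
    tibble::tibble(
      sample_id = sid, clone_id = present,
      prevalence = unname(p[present]),
      druggability = vapply(present, function(cid)
        clone_druggability(arch, sid, cid, kb), 1.0, USE.NAMES = FALSE)
    )
  }))
  regimen <- propose_regimen(arch, kb, dscore_min = cfg$dscore_min,
                             gscore_min = 0, strategy = strategy)
  message("stage regimen: ", length(regimen$drugs), " drug(s), ",
          length(regimen$uncovered_clones), " uncovered clone(s)")

  report <- structure(list(
    comparisons = comparisons,
    druggability = druggability,
    regimen = regimen,
    combined_drugs = sort(unique(regimen$drugs)),
    manifest = run_manifest(cfg, inputs)
  ), class = "spatial_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(list(
      samples = lapply(comparisons, function(cmp) list(
        bulk_clone = cmp$bulk_clone,
        bulk_gene_count = cmp$bulk_gene_count,
        ith_gene_count = cmp$ith_gene_count,
        bulk_druggable = length(cmp$bulk_druggable_genes),
        ith_druggable = length(cmp$ith_druggable_genes),
        bulk_drugs = if (nrow(cmp$bulk_drugs)) cmp$bulk_drugs$drug else character(),
        ith_drugs = if (nrow(cmp$ith_drugs)) cmp$ith_drugs$drug else character()
      )),
      regimen = list(
        drugs = regimen$drugs,
        trunk_drug = regimen$trunk_drug,
        covered_clones = regimen$covered_clones,
        uncovered_clones = regimen$uncovered_clones,
        coverage_by_sample = as.list(regimen$coverage_by_sample)
      )
    ), file.path(out_dir, "spatial.json"))
    write.table(druggability, file.path(out_dir, "druggability.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_report_json(report$manifest, file.path(out_dir, "manifest.json"))
  }
  report
}

#' Write a ranked prescription table as TSV
#'
#' Columns: `drug`, `status`, `response`, `best_gscore`, `best_dscore`,
#' `supporting_genes` (comma-joined), `associations` (gene:class pairs).
#'
#' @param rx Prescription tibble from [prescribe_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prescription_tsv <- function(rx, path) {
  flat <- tibble::tibble(
    drug = rx$drug, status = rx$drug_status, response = rx$response,
    best_gscore = rx$best_gscore, best_dscore = rx$best_dscore,
    supporting_genes = vapply(rx$supporting_genes, paste, "", collapse = ","),
    associations = vapply(rx$associations, function(a)
      paste(names(a), a, sep = ":", collapse = ","), "")
  )
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
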