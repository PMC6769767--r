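# Core prescription operators: per-profile and per-clone drug ranking,
# druggability metrics, bulk-vs-ITH comparison, and the a-priori
# responder/non-responder classification.

#' Prescribe drugs for a mutated-gene profile
#'
#' Queries the knowledge base for the profile's genes and ranks candidate
#' drugs ([rank_candidates()]): resistance-vetoed, sensitivity-supported,
#' `dscore > dscore_min`, `gscore > gscore_min`, sorted by DScore then
#' GScore descending. Supporting genes are aggregated per drug.
#'
#' @param genes Character vector of mutated gene symbols.
#' @param kb An `evidence_kb`.
#' @param dscore_min,gscore_min Strict score thresholds (defaults 0.7
#'   and 0).
#' @param require_sensitivity Keep only sensitivity-supported drugs
#'   (default `TRUE`).
#' @return Ranked tibble of prescription records (zero rows when no
#'   candidate passes).
#' @export
prescribe_profile <- function(genes, kb, dscore_min = 0.7, gscore_min = 0,
                              require_sensitivity = TRUE) {
  genes <- normalize_genes(genes)
  if (length(genes) == 0) {
    return(rank_candidates(tibble::tibble(), dscore_min, gscore_min))
  }
  rank_candidates(query_genes(kb, genes),
                  dscore_min = dscore_min, gscore_min = gscore_min,
                  require_sensitivity = require_sensitivity)
}

#' Druggable subset of a gene set
#'
#' Default convention: a gene is druggable when the knowledge base holds
#' at least one entry for it, of any association class or response.
#' `strict = TRUE` switches to the prescription-grade convention:
#' sensitivity entries with `dscore > dscore_min` only.
#'
#' @param genes Character vector of gene symbols.
#' @param kb An `evidence_kb`.
#' @param strict Use the strict convention (default `FALSE`).
#' @param dscore_min DScore threshold for `strict` mode.
#' @return Character vector of druggable genes (sorted).
#' @export
druggable_genes <- function(genes, kb, strict = FALSE, dscore_min = 0.7) {
  genes <- normalize_genes(genes)
  if (length(genes) == 0) return(character())
  e <- kb$entries[kb$entries$gene %in% genes, , drop = FALSE]
  if (strict)
    e <- e[e$response == "sensitivity" & e$dscore > dscore_min, , drop = FALSE]
  sort(unique(e$gene))
}

#' Druggability of a clone within a sample
#'
#' Fraction of the sample's targetable genes carried by the clone:
#' `|druggable(complement(clone))| / |druggable(region union)|`. Returns 0
#' (with a warning) when the region has no druggable gene at all.
#'
#' @param arch A `clonal_architecture`.
#' @param sample_id Sample the clone is evaluated in.
#' @param clone_id Clone id (must have prevalence > 0 in the sample).
#' @param kb An `evidence_kb`.
#' @param strict,dscore_min Druggability convention, see
#'   [druggable_genes()].
#' @return A fraction in `[0, 1]`.
#' @export
clone_druggability <- function(arch, sample_id, clone_id, kb,
                               strict = FALSE, dscore_min = 0.7) {
  ct_assert(sample_id %in% sample_ids(arch), "unknown sample id: ", sample_id)
  p <- arch$samples[[sample_id]]
  ct_assert(clone_id %in% names(p)[p > 0],
            "clone ", clone_id, " is not present in sample ", sample_id)
  denom <- druggable_genes(region_union_genes(arch, sample_id), kb,
                           strict = strict, dscore_min = dscore_min)
  if (length(denom) == 0) {
    warning("sample ", sample_id, " has no druggable gene; druggability is 0",
            call. = FALSE)
    return(0)
  }
  num <- druggable_genes(full_complement(arch, clone_id), kb,
                         strict = strict, dscore_min = dscore_min)
  length(num) / length(denom)
}

#' Compare bulk and ITH-aware prescription for a sample
#'
#' The bulk side emulates standard single-sample sequencing by assuming
#' only the predominant clone is detected; the ITH side uses the union of
#' all clones present in the sample. Both sides are prescribed with
#' [prescribe_profile()].
#'
#' @inheritParams clone_druggability
#' @param dscore_min,gscore_min Prescription thresholds.
#' @return Object of class `bulk_ith_comparison`: sample id, bulk/ITH gene
#'   counts, druggable gene sets and ranked drug tibbles.
#' @export
bulk_vs_ith <- function(arch, sample_id, kb, dscore_min = 0.7, gscore_min = 0) {
  bulk_clone <- predominant_clone(arch, sample_id)
  bulk_genes <- full_complement(arch, bulk_clone)
  ith_genes <- region_union_genes(arch, sample_id)
  out <- list(
    sample_id = sample_id,
    bulk_clone = bulk_clone,
    bulk_gene_count = length(bulk_genes),
    ith_gene_count = length(ith_genes),
    bulk_druggable_genes = druggable_genes(bulk_genes, kb),
    ith_druggable_genes = druggable_genes(ith_genes, kb),
    bulk_drugs = prescribe_profile(bulk_genes, kb, dscore_min, gscore_min),
    ith_drugs = prescribe_profile(ith_genes, kb, dscore_min, gscore_min)
  )
  structure(out, class = "bulk_ith_comparison")
}

#' @export
print.bulk_ith_comparison <- function(x, ...) {
  cat("<bulk_ith_comparison> sample ", x$sample_id,
      " (bulk = clone ", x$bulk_clone, ")\n",
      "  genes:      bulk ", x$bulk_gene_count, " | ITH ", x$ith_gene_count, "\n",
      "  druggable:  bulk ", length(x$bulk_druggable_genes),
      " | ITH ", length(x$ith_druggable_genes), "\n",
      "  candidates: bulk ", nrow(x$bulk_drugs),
      " | ITH ", nrow(x$ith_drugs), "\n", sep = "")
  invisible(x)
}

#' A-priori responder classification against a drug class
#'
#' Restricts the knowledge base to the patient's mutated genes crossed
#' with the administered drug class and applies the three-way rule:
#' any resistance association -> `non_responder` (`resistance_present`);
#' otherwise any sensitivity association -> `responder`
#' (`sensitivity_only`); otherwise `non_responder` (`no_evidence`).
#'
#' @param genes Patient's mutated gene symbols.
#' @param drug_class Canonical drug names making up the administered class
#'   (e.g. all EGFR inhibitors); must be non-empty.
#' @param kb An `evidence_kb`.
#' @return List with `label` (`responder`/`non_responder`) and `reason`
#'   (`sensitivity_only`/`resistance_present`/`no_evidence`).
#' @export
classify_response <- function(genes, drug_class, kb) {
  drug_class <- unique(normalize_drugs(drug_class))
  drug_class <- drug_class[nzchar(drug_class)]
  ct_assert(length(drug_class) > 0, "drug_class must be non-empty")
  genes <- normalize_genes(genes)
  e <- kb$entries[kb$entries$gene %in% genes & kb$entries$drug %in% drug_class, ,
                  drop = FALSE]
  if (any(e$response == "resistance")) {
    list(label = "non_responder", reason = "resistance_present")
  } else if (any(e$response == "sensitivity")) {
    list(label = "responder", reason = "sensitivity_only")
  } else {
    list(label = "non_responder", reason = "no_evidence")
  }
}

#' Alternative therapies outside an excluded drug class
#'
#' Re-runs [prescribe_profile()] with the drugs of `excluded_class`
#' removed from candidacy — the proposal step for patients classified as
#' non-responders to their administered class. Records keep `drug_status`
#' so approved vs clinical-trial proportions can be summarized.
#'
#' @inheritParams prescribe_profile
#' @param excluded_class Canonical drug names to exclude (may be empty, in
#'   which case the result equals [prescribe_profile()]).
#' @return Ranked tibble of prescription records.
#' @export
alternative_therapies <- function(genes, excluded_class, kb,
                                  dscore_min = 0.7, gscore_min = 0) {
  rx <- prescribe_profile(genes, kb, dscore_min, gscore_min)
  excluded_class <- normalize_drugs(excluded_class)
  rx[!rx$drug %in% excluded_class, , drop = FALSE]
}
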