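# Gene-drug evidence knowledge base: data model, reader/validator and the
# query/ranking engine used by every prescription operation.

KB_COLUMNS <- c("gene", "drug", "gscore", "dscore", "response",
                "association", "drug_status", "indications")

RESPONSE_LEVELS    <- c("sensitivity", "resistance")
ASSOCIATION_LEVELS <- c("direct_target", "biomarker", "pathway_member")
STATUS_LEVELS      <- c("approved", "clinical_trials", "experimental")

#' Construct an evidence knowledge base
#'
#' An `evidence_kb` holds gene-drug associations, each scored by a gene
#' relevance score (GScore, in `[0, 1]`) and a drug suitability score
#' (DScore, in `[-1, 1]`; positive values support sensitivity, negative
#' resistance). Associations are classed as `direct_target` (the drug binds
#' the gene product), `biomarker` (the gene's status predicts response) or
#' `pathway_member` (a druggable gene downstream of the altered one).
#'
#' @param entries Data frame with columns `gene`, `drug`, `gscore`,
#'   `dscore`, `response`, `association`, `drug_status` and `indications`
#'   (comma-joined cancer-type labels, `"."` for none).
#' @return An object of class `evidence_kb` wrapping a validated tibble.
#' @seealso [load_kb()] to read the TSV representation, [query_genes()],
#'   [rank_candidates()].
#' @export
evidence_kb <- function(entries) {
  entries <- tibble::as_tibble(entries)
  missing <- setdiff(KB_COLUMNS, names(entries))
  ct_assert(length(missing) == 0,
            "knowledge base is missing columns: ", paste(missing, collapse = ", "))
  entries <- entries[KB_COLUMNS]
  entries$gene <- toupper(trimws(as.character(entries$gene)))
  entries$drug <- normalize_drugs(entries$drug)
  entries$gscore <- as.numeric(entries$gscore)
  entries$dscore <- as.numeric(entries$dscore)
  entries$indications <- as.character(entries$indications)
  entries$indications[is.na(entries$indications) | entries$indications == ""] <- "."

  bad_gene <- which(!nzchar(entries$gene) | is.na(entries$gene))
  ct_assert(length(bad_gene) == 0, "empty gene symbol at row(s) ",
            paste(head(bad_gene, 5), collapse = ", "))
  bad_drug <- which(!nzchar(entries$drug) | is.na(entries$drug))
  ct_assert(length(bad_drug) == 0, "empty drug name at row(s) ",
            paste(head(bad_drug, 5), collapse = ", "))

  bad_g <- which(is.na(entries$gscore) | entries$gscore < 0 | entries$gscore > 1)
  ct_assert(length(bad_g) == 0, "gscore outside [0, 1] (or non-numeric) at row(s) ",
            paste(head(bad_g, 5), collapse = ", "))
  bad_d <- which(is.na(entries$dscore) | entries$dscore < -1 | entries$dscore > 1)
  ct_assert(length(bad_d) == 0, "dscore outside [-1, 1] (or non-numeric) at row(s) ",
            paste(head(bad_d, 5), collapse = ", "))

  check_enum <- function(x, levels, what) {
    bad <- which(!x %in% levels)
    ct_assert(length(bad) == 0, "unknown ", what, " token '",
              x[bad[1]], "' at row ", bad[1],
              " (expected one of: ", paste(levels, collapse = ", "), ")")
  }
  check_enum(entries$response, RESPONSE_LEVELS, "response")
  check_enum(entries$association, ASSOCIATION_LEVELS, "association")
  check_enum(entries$drug_status, STATUS_LEVELS, "drug_status")

  key <- paste(entries$gene, entries$drug, entries$association, sep = "\r")
  dup <- which(duplicated(key))
  ct_assert(length(dup) == 0,
            "duplicate (gene, drug, association) entries at row(s) ",
            paste(head(dup, 5), collapse = ", "))

  structure(list(entries = entries), class = "evidence_kb")
}

#' @export
print.evidence_kb <- function(x, ...) {
  cat("<evidence_kb> ", nrow(x$entries), " entries | ",
      length(unique(x$entries$gene)), " genes | ",
      length(unique(x$entries$drug)), " drugs\n", sep = "")
  invisible(x)
}

#' Read a knowledge base from TSV
#'
#' The file is a UTF-8 TSV with the eight-column header described in
#' [evidence_kb()]. Every row is validated: scores out of range, unknown
#' enum tokens and duplicate (gene, drug, association) triples are rejected
#' with the offending row named.
#'
#' @param path Path to the TSV file.
#' @return An `evidence_kb`.
#' @export
load_kb <- function(path) {
  ct_assert(file.exists(path), "knowledge base file not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE,
                   colClasses = "character", check.names = FALSE,
                   quote = "", comment.char = "")
  suppressWarnings({
    df$gscore <- as.numeric(df$gscore)
    df$dscore <- as.numeric(df$dscore)
  })
  evidence_kb(df)
}

#' Write a knowledge base to TSV
#'
#' @param kb An `evidence_kb`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kb <- function(kb, path) {
  stopifnot(inherits(kb, "evidence_kb"))
  write.table(kb$entries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Query knowledge-base entries by gene set
#'
#' Returns every entry whose (normalized) gene symbol is in `genes`,
#' deterministically ordered by gene then drug.
#'
#' @param kb An `evidence_kb`.
#' @param genes Character vector of gene symbols (normalized internally;
#'   must be non-empty after normalization).
#' @return Tibble of matching entries (possibly zero rows).
#' @export
query_genes <- function(kb, genes) {
  stopifnot(inherits(kb, "evidence_kb"))
  genes <- normalize_genes(genes)
  ct_assert(length(genes) > 0, "query gene set is empty after normalization")
  hit <- kb$entries[kb$entries$gene %in% genes, , drop = FALSE]
  hit[order(hit$gene, hit$drug), , drop = FALSE]
}

#' Rank candidate drugs from evidence entries
#'
#' Groups entries by drug and applies the prescription rule: a drug is
#' vetoed outright if *any* entry for it (within the queried profile)
#' reports resistance; survivors are kept when the best supporting entry
#' has `dscore > dscore_min` and `gscore > gscore_min` (strict
#' inequalities), then sorted by DScore descending, GScore descending and
#' drug name ascending.
#'
#' @param entries Tibble of evidence entries as returned by
#'   [query_genes()].
#' @param dscore_min DScore threshold, default 0.7 (candidates must exceed
#'   it).
#' @param gscore_min GScore threshold, default 0 (cohort-level analyses use
#'   0.6).
#' @param require_sensitivity Keep only sensitivity-supported drugs
#'   (default `TRUE`; resistance entries always veto regardless).
#' @return Tibble with one row per surviving drug: `drug`, `drug_status`,
#'   `response`, `best_gscore`, `best_dscore`, `n_genes`,
#'   `supporting_genes` and `associations` (list-columns).
#' @export
rank_candidates <- function(entries, dscore_min = 0.7, gscore_min = 0,
                            require_sensitivity = TRUE) {
  ct_assert(dscore_min >= -1 && dscore_min <= 1, "dscore_min outside [-1, 1]")
  ct_assert(gscore_min >= 0 && gscore_min <= 1, "gscore_min outside [0, 1]")
  entries <- tibble::as_tibble(entries)
  empty <- tibble::tibble(
    drug = character(), drug_status = character(), response = character(),
    best_gscore = numeric(), best_dscore = numeric(), n_genes = integer(),
    supporting_genes = list(), associations = list()
  )
  if (nrow(entries) == 0) return(empty)

  # Resistance veto is drug-level across the whole queried profile.
  vetoed <- unique(entries$drug[entries$response == "resistance"])
  ok <- entries[!entries$drug %in% vetoed, , drop = FALSE]
  if (require_sensitivity) ok <- ok[ok$response == "sensitivity", , drop = FALSE]
  if (nrow(ok) == 0) return(empty)

  recs <- lapply(split(ok, ok$drug), function(d) {
    best <- d[order(-d$dscore, -d$gscore), , drop = FALSE][1, ]
    tibble::tibble(
      drug = best$drug,
      drug_status = best$drug_status,
      response = best$response,
      best_gscore = best$gscore,
      best_dscore = best$dscore,
      n_genes = length(unique(d$gene)),
      supporting_genes = list(sort(unique(d$gene))),
      associations = list(setNames(d$association, d$gene))
    )
  })
  out <- dplyr::bind_rows(recs)
  out <- out[out$best_dscore > dscore_min & out$best_gscore > gscore_min, ,
             drop = FALSE]
  out[order(-out$best_dscore, -out$best_gscore, out$drug), , drop = FALSE]
}
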