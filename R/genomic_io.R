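# Readers and filters turning raw genomic inputs (VCF, CNV calls,
# drug-name tables) into per-patient altered-gene sets.

#' Genes of PASS-filtered somatic variants in a VCF
#'
#' Reads a VCF 4.x file and returns the gene symbols annotated on records
#' whose FILTER field is exactly `PASS` — the variants with the strongest
#' evidence of being somatic. All other records are dropped and their
#' count reported via `message()`. Multi-gene annotations are split on
#' commas and every symbol emitted.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param gene_field INFO key holding the gene symbol(s), default `"GENE"`.
#' @return Character vector of normalized gene symbols (sorted, unique).
#' @export
read_vcf_pass_genes <- function(path, gene_field = "GENE") {
  ct_assert(file.exists(path), "VCF not found: ", path)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) ct_stop("failed to parse VCF ", path,
                                              ": ", conditionMessage(e)))
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0) {
    message("0 of 0 records PASS")
    return(character())
  }
  is_pass <- !is.na(fix[, "FILTER"]) & fix[, "FILTER"] == "PASS"
  message(sum(!is_pass), " of ", nrow(fix), " records dropped (non-PASS)")
  if (!any(is_pass)) return(character())
  info <- fix[is_pass, "INFO"]
  genes <- vapply(info, function(x) {
    m <- regmatches(x, regexec(paste0("(?:^|;)", gene_field, "=([^;]*)"), x))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }, "", USE.NAMES = FALSE)
  n_missing <- sum(is.na(genes) | genes == "")
  if (n_missing > 0)
    warning(n_missing, " PASS record(s) lack a ", gene_field,
            " annotation and were skipped", call. = FALSE)
  genes <- genes[!is.na(genes) & genes != ""]
  sort(normalize_genes(unlist(strsplit(genes, ",", fixed = TRUE))))
}

#' Read CNV calls with expression support
#'
#' TSV with columns `gene`, `direction` (`gain`/`loss`) and `expr_z`
#' (per-gene expression z-score).
#'
#' @param path TSV path.
#' @return Tibble of CNV calls.
#' @export
read_cnv_calls <- function(path) {
  ct_assert(file.exists(path), "CNV table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
  ct_assert(all(c("gene", "direction", "expr_z") %in% names(df)),
            "CNV table needs columns gene, direction, expr_z")
  out <- tibble::tibble(
    gene = toupper(trimws(df$gene)),
    direction = tolower(trimws(df$direction)),
    expr_z = as.numeric(df$expr_z)
  )
  ct_assert(all(out$direction %in% c("gain", "loss")),
            "direction must be 'gain' or 'loss' for every call")
  out
}

#' Filter CNV calls by expression-change support
#'
#' Keeps a gene when its copy-number change is supported by a concordant
#' expression change: gains require `expr_z > z_min`, losses require
#' `expr_z < -z_min` (strict, so `|z| = z_min` exactly is dropped). With
#' `concordant = FALSE` only the magnitude rule `|z| > z_min` applies.
#'
#' @param calls Tibble of CNV calls (see [read_cnv_calls()]).
#' @param z_min Positive z-score threshold, default 2.
#' @param concordant Require sign concordance between the copy-number
#'   direction and the expression change (default `TRUE`).
#' @return Character vector of gene symbols kept (sorted, unique).
#' @export
cnv_expression_filter <- function(calls, z_min = 2, concordant = TRUE) {
  ct_assert(is.numeric(z_min) && z_min > 0, "z_min must be positive")
  calls <- tibble::as_tibble(calls)
  if (nrow(calls) == 0) return(character())
  keep <- if (concordant) {
    (calls$direction == "gain" & calls$expr_z > z_min) |
      (calls$direction == "loss" & calls$expr_z < -z_min)
  } else {
    abs(calls$expr_z) > z_min
  }
  sort(unique(calls$gene[keep]))
}

#' Read a drug-name alias table
#'
#' Two-column TSV (`alias`, `canonical`) mapping nomenclature variants to
#' canonical drug names. Canonical names always map to themselves.
#'
#' @param path TSV path.
#' @return Named character vector: lowercase alias -> canonical name.
#' @export
read_drug_aliases <- function(path) {
  ct_assert(file.exists(path), "alias table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
  ct_assert(all(c("alias", "canonical") %in% names(df)),
            "alias table needs columns alias, canonical")
  canonical <- normalize_drugs(df$canonical)
  map <- setNames(canonical, normalize_drugs(df$alias))
  # canonical names are aliases of themselves
  self <- setNames(unique(canonical), unique(canonical))
  c(map, self[!names(self) %in% names(map)])
}

#' Standardize drug nomenclature
#'
#' Case-insensitive alias resolution against an alias table; names without
#' an alias entry pass through (case-normalized) with a warning.
#'
#' @param names Character vector of drug names as reported.
#' @param aliases Alias map from [read_drug_aliases()] (or any named
#'   character vector alias -> canonical).
#' @return Character vector of canonical names, same length as `names`.
#' @export
normalize_drug_names <- function(names, aliases) {
  key <- normalize_drugs(names)
  hit <- key %in% names(aliases)
  if (any(!hit))
    warning("no alias entry for: ",
            paste(unique(key[!hit]), collapse = ", "), call. = FALSE)
  ifelse(hit, unname(aliases[key]), key)
}
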