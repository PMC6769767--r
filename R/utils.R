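#' @importFrom stats median pchisq rbinom rexp rgamma runif setNames
#' @importFrom utils read.delim write.table head
NULL

# Signal a validation error (input violates a documented contract).
# Carries its own condition class so callers (and the CLI) can map
# validation failures to a distinct exit code.
ct_stop <- function(..., call. = FALSE) {
  msg <- paste0(...)
  cnd <- structure(
    class = c("clonotherapy_validation_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cnd)
}

ct_assert <- function(ok, ...) {
  if (!isTRUE(ok)) ct_stop(...)
  invisible(TRUE)
}

#' Normalize gene symbols
#'
#' Uppercases and whitespace-trims HGNC-style symbols; drops empty strings
#' and duplicates (order of first appearance is kept).
#'
#' @param genes Character vector of gene symbols.
#' @return Character vector of normalized, unique symbols.
#' @export
normalize_genes <- function(genes) {
  if (is.null(genes)) return(character())
  g <- toupper(trimws(as.character(genes)))
  unique(g[nzchar(g) & !is.na(g)])
}

#' Normalize drug names to canonical case
#'
#' Lowercases and whitespace-trims drug names. Alias resolution is a
#' separate step ([normalize_drug_names()]).
#'
#' @param drugs Character vector of drug names.
#' @return Character vector of the same length, case-normalized.
#' @export
normalize_drugs <- function(drugs) {
  tolower(trimws(as.character(drugs)))
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. Each generator derives its own sub-seed from the master seed
# so adding one generator never perturbs another's stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded sub-seed from a master seed and a stream label.
sub_seed <- function(seed, stream) {
  offs <- sum(utf8ToInt(stream))
  as.integer((as.numeric(seed) * 131L + offs) %% 2147483629)
}
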