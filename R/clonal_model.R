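# Clonal architecture model: phylogeny of clones with per-clone novel
# mutation sets and per-sample (region/timepoint) clone prevalences, plus
# the set/graph computations the prescription analyses are built on.

PREVALENCE_TOL <- 1e-6

#' Construct a clonal architecture
#'
#' A clonal architecture is a rooted tree of clones. Each clone carries the
#' set of genes *newly* mutated on its branch (`novel_genes`); a clone's
#' full mutation complement is the union of novel sets along the root-to-
#' clone path. Samples (tumour regions or timepoints) record the prevalence
#' of each clone present; prevalences must sum to 1 (tolerance 1e-6 —
#' inputs failing it are rejected, not renormalized).
#'
#' @param clones Data frame with columns `id`, `parent` (`NA` for the
#'   single root) and `novel_genes` (list-column of character vectors).
#' @param samples Named list: sample id -> named numeric vector of clone
#'   prevalences in `[0, 1]`.
#' @return An object of class `clonal_architecture`.
#' @export
clonal_architecture <- function(clones, samples = list()) {
  clones <- tibble::as_tibble(clones)
  ct_assert(all(c("id", "parent", "novel_genes") %in% names(clones)),
            "clones need columns id, parent, novel_genes")
  clones$id <- as.character(clones$id)
  clones$parent <- as.character(clones$parent)
  ct_assert(!anyDuplicated(clones$id), "duplicate clone ids")
  roots <- which(is.na(clones$parent) | clones$parent == "")
  ct_assert(length(roots) == 1, "architecture must have exactly one root clone (found ",
            length(roots), ")")
  clones$parent[roots] <- NA_character_
  unknown_parent <- setdiff(stats::na.omit(clones$parent), clones$id)
  ct_assert(length(unknown_parent) == 0, "parent references unknown clone(s): ",
            paste(unknown_parent, collapse = ", "))
  clones$novel_genes <- lapply(clones$novel_genes, normalize_genes)

  # cycle check: every clone must reach the root in <= n steps
  parent_of <- setNames(clones$parent, clones$id)
  n <- nrow(clones)
  for (id in clones$id) {
    cur <- id; steps <- 0L
    while (!is.na(cur)) {
      cur <- parent_of[[cur]]
      steps <- steps + 1L
      ct_assert(steps <= n, "parent links contain a cycle involving clone ", id)
    }
  }

  ct_assert(is.list(samples), "samples must be a named list")
  if (length(samples) > 0) {
    ct_assert(!is.null(names(samples)) && all(nzchar(names(samples))),
              "every sample needs a name")
    sample_names <- names(samples)
    samples <- lapply(sample_names, function(sid) {
      p <- samples[[sid]]
      ct_assert(is.numeric(p) && !is.null(names(p)),
                "sample ", sid, ": prevalence must be a named numeric vector")
      bad <- setdiff(names(p), clones$id)
      ct_assert(length(bad) == 0, "sample ", sid,
                " references undeclared clone(s): ", paste(bad, collapse = ", "))
      ct_assert(all(p >= 0 & p <= 1), "sample ", sid,
                ": prevalences must lie in [0, 1]")
      ct_assert(abs(sum(p) - 1) <= PREVALENCE_TOL, "sample ", sid,
                ": prevalences sum to ", format(sum(p), digits = 10),
                ", expected 1 within 1e-6")
      p
    })
    names(samples) <- sample_names
  }
  structure(list(clones = clones, samples = samples),
            class = "clonal_architecture")
}

#' @export
print.clonal_architecture <- function(x, ...) {
  cat("<clonal_architecture> ", nrow(x$clones), " clones, ",
      length(x$samples), " samples\n", sep = "")
  cat("  clones: ", paste(x$clones$id, collapse = ", "), "\n", sep = "")
  if (length(x$samples))
    cat("  samples: ", paste(names(x$samples), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname clonal_architecture
#' @param arch A `clonal_architecture`.
#' @export
clone_ids <- function(arch) arch$clones$id

#' @rdname clonal_architecture
#' @export
sample_ids <- function(arch) names(arch$samples)

#' Read / write a clonal architecture as JSON
#'
#' The JSON schema is
#' `{"clones": [{"id", "parent", "novel_genes": [...]}],
#'   "samples": [{"id", "prevalence": {"C1": 0.12, ...}}]}`.
#' Files may alternatively store each clone's *full* mutation complement
#' (`format = "complement"`); these are converted to novel sets by
#' subtracting the parent's complement.
#'
#' @param path JSON file path.
#' @param format `"novel"` (default) or `"complement"`.
#' @return A `clonal_architecture`.
#' @export
read_architecture <- function(path, format = c("novel", "complement")) {
  format <- match.arg(format)
  ct_assert(file.exists(path), "architecture file not found: ", path)
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  ct_assert(!is.null(j$clones), "architecture JSON lacks a 'clones' field")
  clones <- tibble::tibble(
    id = vapply(j$clones, function(c) as.character(c$id), ""),
    parent = vapply(j$clones, function(c)
      if (length(c$parent) != 1) NA_character_ else as.character(c$parent),
      ""),
    novel_genes = lapply(j$clones, function(c)
      as.character(unlist(c$novel_genes)))
  )
  if (format == "complement") {
    comp <- setNames(clones$novel_genes, clones$id)
    parent_of <- setNames(clones$parent, clones$id)
    clones$novel_genes <- lapply(clones$id, function(id) {
      p <- parent_of[[id]]
      if (is.na(p)) comp[[id]] else setdiff(comp[[id]], comp[[p]])
    })
  }
  samples <- list()
  for (s in j$samples) {
    samples[[as.character(s$id)]] <-
      unlist(lapply(s$prevalence, as.numeric))
  }
  clonal_architecture(clones, samples)
}

#' @rdname read_architecture
#' @param arch A `clonal_architecture`.
#' @export
write_architecture <- function(arch, path) {
  stopifnot(inherits(arch, "clonal_architecture"))
  j <- list(
    clones = lapply(seq_len(nrow(arch$clones)), function(i) {
      cl <- list(id = arch$clones$id[i],
                 novel_genes = as.list(arch$clones$novel_genes[[i]]))
      if (!is.na(arch$clones$parent[i])) cl$parent <- arch$clones$parent[i]
      cl
    }),
    samples = lapply(names(arch$samples), function(sid) list(
      id = sid, prevalence = as.list(arch$samples[[sid]])
    ))
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Full mutation complement of a clone
#'
#' Union of `novel_genes` along the root-to-clone path: every mutation a
#' cell of this clone carries, inherited plus private.
#'
#' @param arch A `clonal_architecture`.
#' @param clone_id Clone id.
#' @return Character vector of gene symbols (sorted).
#' @export
full_complement <- function(arch, clone_id) {
  stopifnot(inherits(arch, "clonal_architecture"))
  ct_assert(clone_id %in% arch$clones$id, "unknown clone id: ", clone_id)
  novel <- setNames(arch$clones$novel_genes, arch$clones$id)
  parent_of <- setNames(arch$clones$parent, arch$clones$id)
  genes <- character()
  cur <- clone_id
  while (!is.na(cur)) {
    genes <- c(genes, novel[[cur]])
    cur <- parent_of[[cur]]
  }
  sort(unique(genes))
}

#' Trunk (clonal) mutations
#'
#' Genes present in every clone's full complement — the alterations shared
#' by all tumour cell populations, the targets for therapies intended to
#' hit the whole tumour.
#'
#' @inheritParams full_complement
#' @return Character vector of gene symbols (sorted).
#' @export
trunk_genes <- function(arch) {
  stopifnot(inherits(arch, "clonal_architecture"))
  comps <- lapply(arch$clones$id, full_complement, arch = arch)
  sort(Reduce(intersect, comps))
}

#' Union of mutated genes revealed by ITH analysis of a sample
#'
#' Union of the full complements of every clone with prevalence > 0 in the
#' sample — what multi-region / clonal dissection sees, as opposed to the
#' bulk (predominant-clone) approximation.
#'
#' @inheritParams full_complement
#' @param sample_id Sample id.
#' @return Character vector of gene symbols (sorted).
#' @export
region_union_genes <- function(arch, sample_id) {
  stopifnot(inherits(arch, "clonal_architecture"))
  ct_assert(sample_id %in% names(arch$samples), "unknown sample id: ", sample_id)
  p <- arch$samples[[sample_id]]
  present <- names(p)[p > 0]
  sort(unique(unlist(lapply(present, full_complement, arch = arch))))
}

#' Predominant clone of a sample
#'
#' The clone with maximum prevalence — the one a standard single-sample
#' bulk analysis is assumed to detect. Exact ties resolve to the
#' lexicographically smallest id, with a warning.
#'
#' @inheritParams region_union_genes
#' @return A clone id.
#' @export
predominant_clone <- function(arch, sample_id) {
  stopifnot(inherits(arch, "clonal_architecture"))
  ct_assert(sample_id %in% names(arch$samples), "unknown sample id: ", sample_id)
  p <- arch$samples[[sample_id]]
  p <- p[p > 0]
  ct_assert(length(p) > 0, "sample ", sample_id, " has no clone with prevalence > 0")
  top <- names(p)[p == max(p)]
  if (length(top) > 1) {
    top <- sort(top)
    warning("sample ", sample_id, ": prevalence tie between ",
            paste(top, collapse = ", "), "; taking ", top[1], call. = FALSE)
  }
  top[1]
}

#' Read a temporal VAF table
#'
#' TSV with columns `gene`, `timepoint`, `vaf`; one row per gene per
#' timepoint at which the variant was detected (absence = not detected).
#'
#' @param path TSV path.
#' @return Tibble with normalized gene symbols.
#' @export
read_vaf_table <- function(path) {
  ct_assert(file.exists(path), "VAF table not found: ", path)
  df <- read.delim(path, sep = "\t", header = TRUE, colClasses = "character")
  ct_assert(all(c("gene", "timepoint", "vaf") %in% names(df)),
            "VAF table needs columns gene, timepoint, vaf")
  out <- tibble::tibble(
    gene = toupper(trimws(df$gene)),
    timepoint = trimws(df$timepoint),
    vaf = as.numeric(df$vaf)
  )
  ct_assert(all(!is.na(out$vaf) & out$vaf >= 0 & out$vaf <= 1),
            "VAFs must be fractions in [0, 1]")
  out
}

#' Select genes under positive temporal selection
#'
#' Implements the temporal-ITH rule: flag genes that were *pre-existing*
#' at low VAF before treatment (`vaf(t0) < low_vaf`) and expanded at
#' relapse (`vaf(t1) >= rise_min`), plus genes absent at `t0` that appear
#' at `t1` with `vaf(t1) >= rise_min` (*relapse-specific*). These mark the
#' clone positively selected by therapy and are the input profile for
#' relapse-anticipating prescription.
#'
#' @param profiles Tibble with columns `gene`, `timepoint`, `vaf` (see
#'   [read_vaf_table()]); a gene absent at a timepoint simply has no row.
#' @param t0,t1 Timepoint labels (e.g. diagnosis and relapse).
#' @param low_vaf Low-VAF ceiling at `t0`, default 0.01 (i.e. < 1%).
#' @param rise_min Minimum VAF at `t1`, default 0.10.
#' @return List with `genes` (all selected, sorted), `pre_existing` and
#'   `relapse_specific` subsets.
#' @export
select_temporal_genes <- function(profiles, t0, t1,
                                  low_vaf = 0.01, rise_min = 0.10) {
  profiles <- tibble::as_tibble(profiles)
  ct_assert(low_vaf > 0 && low_vaf < 1, "low_vaf must lie in (0, 1)")
  ct_assert(rise_min > 0 && rise_min < 1, "rise_min must lie in (0, 1)")
  ct_assert(low_vaf < rise_min, "low_vaf must be smaller than rise_min")
  tps <- unique(profiles$timepoint)
  if (nrow(profiles) > 0) {
    ct_assert(t0 %in% tps, "unknown timepoint: ", t0)
    ct_assert(t1 %in% tps, "unknown timepoint: ", t1)
  }
  v0 <- setNames(profiles$vaf[profiles$timepoint == t0],
                 profiles$gene[profiles$timepoint == t0])
  v1 <- setNames(profiles$vaf[profiles$timepoint == t1],
                 profiles$gene[profiles$timepoint == t1])
  genes1 <- names(v1)[v1 >= rise_min]
  pre  <- genes1[genes1 %in% names(v0) & v0[genes1] < low_vaf]
  rel  <- genes1[!genes1 %in% names(v0)]
  list(genes = sort(unique(c(pre, rel))),
       pre_existing = sort(unique(pre)),
       relapse_specific = sort(unique(rel)))
}

#' Partition somatic events between two tumour samples
#'
#' Standard set bookkeeping between, e.g., a primary and a relapse genome:
#' shared events, primary-specific and relapse-specific counts. The three
#' counts always sum to the union size.
#'
#' @param primary,relapse Character vectors of event identifiers.
#' @return Named list `shared`, `primary_specific`, `relapse_specific`,
#'   `total` (union size), all integer counts.
#' @export
partition_events <- function(primary, relapse) {
  primary <- unique(as.character(primary))
  relapse <- unique(as.character(relapse))
  shared <- length(intersect(primary, relapse))
  list(
    shared = shared,
    primary_specific = length(primary) - shared,
    relapse_specific = length(relapse) - shared,
    total = length(union(primary, relapse))
  )
}
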