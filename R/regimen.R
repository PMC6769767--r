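# Combination-regimen design: pick drugs covering the trunk and each
# subclone population, compute prevalence-mass therapeutic coverage, and
# flag clones no passing candidate can reach.

#' Does a drug cover a clone?
#'
#' A prescription record covers a clone when at least one of its
#' supporting genes lies in the clone's full mutation complement (the
#' record itself already encodes sensitivity support passing the
#' prescription thresholds). Trunk-supported drugs therefore cover every
#' clone.
#'
#' @param record One-row prescription record (a row of the tibble returned
#'   by [prescribe_profile()]).
#' @param arch A `clonal_architecture`.
#' @param clone_id Clone id.
#' @return `TRUE` or `FALSE`.
#' @export
drug_covers_clone <- function(record, arch, clone_id) {
  record <- tibble::as_tibble(record)
  ct_assert(nrow(record) == 1, "record must be a single prescription row")
  genes <- record$supporting_genes[[1]]
  length(intersect(genes, full_complement(arch, clone_id))) > 0
}

#' Therapeutic coverage of a drug set in a sample
#'
#' Sum of prevalences of the clones covered by at least one drug in the
#' set — the fraction of the sampled tumour cell mass that carries a
#' targeted alteration.
#'
#' @param drugs Tibble of prescription records (zero or more rows).
#' @param arch A `clonal_architecture`.
#' @param sample_id Sample id.
#' @return A fraction in `[0, 1]`.
#' @export
therapeutic_coverage <- function(drugs, arch, sample_id) {
  ct_assert(sample_id %in% sample_ids(arch), "unknown sample id: ", sample_id)
  p <- arch$samples[[sample_id]]
  p <- p[p > 0]
  if (length(p) == 0 || nrow(drugs) == 0) return(0)
  covered <- vapply(names(p), function(cid) {
    any(vapply(seq_len(nrow(drugs)), function(i)
      drug_covers_clone(drugs[i, ], arch, cid), TRUE))
  }, TRUE)
  sum(p[covered])
}

# Clone-specific gene set: mutations of the clone beyond the trunk.
clone_specific_genes <- function(arch, clone_id) {
  setdiff(full_complement(arch, clone_id), trunk_genes(arch))
}

#' Propose a combination regimen over a clonal architecture
#'
#' Three strategies:
#' \describe{
#'   \item{`trunk_plus_specific` (default)}{The clonotherapy procedure:
#'     take the top-ranked candidate on the trunk genes (targeting the
#'     whole tumour), then give every clone with clone-specific mutations
#'     (complement minus trunk) its own top-ranked candidate on those
#'     genes. Clones whose specific mutations admit no candidate passing
#'     the thresholds are reported `uncovered` — they are reached only at
#'     the trunk level, not individually.}
#'   \item{`greedy_cover`}{Candidates are all passing drugs on the
#'     region-union profile; repeatedly add the drug covering the largest
#'     remaining prevalence mass (summed over samples), ties broken by
#'     DScore descending then drug name.}
#'   \item{`exact_cover`}{Minimum-cardinality drug set covering every
#'     coverable clone, by exhaustive subset search; refused beyond 20
#'     candidate drugs.}
#' }
#'
#' @param arch A `clonal_architecture` (with at least one clone; samples
#'   are required for coverage fractions and the greedy strategy).
#' @param kb An `evidence_kb`.
#' @param dscore_min,gscore_min Prescription thresholds (defaults 0.7, 0).
#' @param strategy One of `"trunk_plus_specific"`, `"greedy_cover"`,
#'   `"exact_cover"`.
#' @return Object of class `regimen_proposal`: `drugs` (ordered character
#'   vector), `records` (their prescription rows), `covered_clones`
#'   (drug -> clone ids), `uncovered_clones`, `coverage_by_sample`, and
#'   `trunk_drug` (for the default strategy).
#' @export
propose_regimen <- function(arch, kb, dscore_min = 0.7, gscore_min = 0,
                            strategy = c("trunk_plus_specific",
                                         "greedy_cover", "exact_cover")) {
  strategy <- match.arg(strategy)
  ct_assert(nrow(arch$clones) >= 1, "architecture has no clones")

  all_union <- sort(unique(unlist(
    lapply(clone_ids(arch), full_complement, arch = arch))))
  candidates <- prescribe_profile(all_union, kb, dscore_min, gscore_min)

  proposal <- switch(
    strategy,
    trunk_plus_specific = regimen_trunk_plus_specific(arch, kb, dscore_min,
                                                      gscore_min),
    greedy_cover = regimen_greedy(arch, candidates),
    exact_cover = regimen_exact(arch, candidates)
  )

  proposal$strategy <- strategy
  proposal$coverage_by_sample <- setNames(
    vapply(sample_ids(arch), function(sid)
      therapeutic_coverage(proposal$records, arch, sid), 1.0),
    sample_ids(arch))
  structure(proposal, class = "regimen_proposal")
}

regimen_trunk_plus_specific <- function(arch, kb, dscore_min, gscore_min) {
  trunk <- trunk_genes(arch)
  trunk_rx <- if (length(trunk))
    prescribe_profile(trunk, kb, dscore_min, gscore_min)
  else prescribe_profile(character(), kb, dscore_min, gscore_min)
  trunk_drug <- if (nrow(trunk_rx)) trunk_rx$drug[1] else NA_character_

  records <- if (nrow(trunk_rx)) trunk_rx[1, ] else trunk_rx[0, ]
  covered <- list()
  if (!is.na(trunk_drug)) covered[[trunk_drug]] <- character()
  uncovered <- character()

  for (cid in clone_ids(arch)) {
    specific <- clone_specific_genes(arch, cid)
    if (length(specific) == 0) {
      # clone is the clonal population itself: reached by the trunk drug
      if (!is.na(trunk_drug))
        covered[[trunk_drug]] <- sort(unique(c(covered[[trunk_drug]], cid)))
      else uncovered <- c(uncovered, cid)
      next
    }
    rx <- prescribe_profile(specific, kb, dscore_min, gscore_min)
    if (nrow(rx) == 0) {
      uncovered <- c(uncovered, cid)
    } else {
      d <- rx$drug[1]
      if (!d %in% records$drug) records <- dplyr::bind_rows(records, rx[1, ])
      covered[[d]] <- sort(unique(c(covered[[d]], cid)))
    }
  }
  list(drugs = records$drug, records = records, trunk_drug = trunk_drug,
       covered_clones = covered, uncovered_clones = sort(unique(uncovered)))
}

# clones each candidate drug can cover (full-complement membership)
candidate_cover_sets <- function(arch, candidates) {
  lapply(seq_len(nrow(candidates)), function(i) {
    cids <- clone_ids(arch)
    cids[vapply(cids, function(cid)
      drug_covers_clone(candidates[i, ], arch, cid), TRUE)]
  })
}

# prevalence mass of a clone summed over all samples (for greedy ties,
# clones absent from every sample count 0)
clone_mass <- function(arch) {
  mass <- setNames(numeric(length(clone_ids(arch))), clone_ids(arch))
  for (p in arch$samples) mass[names(p)] <- mass[names(p)] + p
  mass
}

regimen_greedy <- function(arch, candidates) {
  cover <- candidate_cover_sets(arch, candidates)
  mass <- clone_mass(arch)
  coverable <- sort(unique(unlist(cover)))
  remaining <- coverable
  picked <- integer()
  while (length(remaining) > 0) {
    gain <- vapply(seq_along(cover), function(i)
      sum(mass[intersect(cover[[i]], remaining)]), 1.0)
    gain[picked] <- -Inf
    best <- max(gain)
    if (!is.finite(best) || best <= 0) {
      # remaining clones have zero mass; still cover them by count
      gain <- vapply(seq_along(cover), function(i)
        length(intersect(cover[[i]], remaining)), 1.0)
      gain[picked] <- -Inf
      best <- max(gain)
      if (best <= 0) break
    }
    tie <- which(gain == best)
    tie <- tie[order(-candidates$best_dscore[tie], candidates$drug[tie])]
    i <- tie[1]
    picked <- c(picked, i)
    remaining <- setdiff(remaining, cover[[i]])
  }
  records <- candidates[picked, , drop = FALSE]
  covered <- setNames(cover[picked], candidates$drug[picked])
  list(drugs = records$drug, records = records, trunk_drug = NA_character_,
       covered_clones = covered,
       uncovered_clones = sort(setdiff(clone_ids(arch), unlist(covered))))
}

regimen_exact <- function(arch, candidates) {
  n <- nrow(candidates)
  ct_assert(n <= 20,
            "exact_cover is limited to 20 candidate drugs (got ", n,
            "); use strategy = 'greedy_cover' for larger instances")
  cover <- candidate_cover_sets(arch, candidates)
  coverable <- sort(unique(unlist(cover)))
  best_idx <- integer()
  if (length(coverable) > 0 && n > 0) {
    found <- FALSE
    for (k in seq_len(n)) {
      combos <- utils::combn(n, k, simplify = FALSE)
      for (cb in combos) {
        if (setequal(intersect(unlist(cover[cb]), coverable), coverable)) {
          best_idx <- cb
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }
  records <- candidates[best_idx, , drop = FALSE]
  covered <- setNames(cover[best_idx], candidates$drug[best_idx])
  list(drugs = records$drug, records = records, trunk_drug = NA_character_,
       covered_clones = covered,
       uncovered_clones = sort(setdiff(clone_ids(arch), unlist(covered))))
}

#' @export
print.regimen_proposal <- function(x, ...) {
  cat("<regimen_proposal> strategy = ", x$strategy, "\n", sep = "")
  if (!is.na(x$trunk_drug))
    cat("  trunk drug: ", x$trunk_drug, "\n", sep = "")
  for (d in names(x$covered_clones)) {
    cl <- x$covered_clones[[d]]
    cat("  ", d, " -> ", if (length(cl)) paste(cl, collapse = ", ")
        else "(trunk only)", "\n", sep = "")
  }
  if (length(x$uncovered_clones))
    cat("  uncovered: ", paste(x$uncovered_clones, collapse = ", "), "\n",
        sep = "")
  for (s in names(x$coverage_by_sample))
    cat("  coverage[", s, "] = ",
        format(x$coverage_by_sample[[s]], digits = 4), "\n", sep = "")
  invisible(x)
}
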