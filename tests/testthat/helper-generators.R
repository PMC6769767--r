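# Shared fixture builders: small random knowledge bases, architectures and
# survival cohorts, built in code under explicit seeds.

kb_entry <- function(gene, drug, gscore = 0.5, dscore = 0.8,
                     response = "sensitivity", association = "direct_target",
                     drug_status = "approved", indications = ".") {
  tibble::tibble(gene = gene, drug = drug, gscore = gscore, dscore = dscore,
                 response = response, association = association,
                 drug_status = drug_status, indications = indications)
}

make_kb <- function(...) evidence_kb(dplyr::bind_rows(...))

# random but always-valid KB over genes G1..Gn
rand_kb_entries <- function(n_entries, n_genes = 12, n_drugs = 8,
                            p_resistance = 0.2) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  drugs <- sprintf("drug%02d", seq_len(n_drugs))
  assoc <- c("direct_target", "biomarker", "pathway_member")
  repeat {
    e <- tibble::tibble(
      gene = sample(genes, n_entries, replace = TRUE),
      drug = sample(drugs, n_entries, replace = TRUE),
      gscore = round(runif(n_entries), 3),
      dscore = round(runif(n_entries, -1, 1), 3),
      response = ifelse(runif(n_entries) < p_resistance,
                        "resistance", "sensitivity"),
      association = sample(assoc, n_entries, replace = TRUE),
      drug_status = sample(c("approved", "clinical_trials", "experimental"),
                           n_entries, replace = TRUE),
      indications = "."
    )
    if (!anyDuplicated(e[c("gene", "drug", "association")])) return(e)
  }
}

rand_kb <- function(n_entries, ...) evidence_kb(rand_kb_entries(n_entries, ...))

# random rooted clone tree with one or more samples
rand_arch <- function(n_clones = 5, n_samples = 2, genes_per_clone = 3,
                      gene_pool = sprintf("G%02d", 1:12)) {
  ids <- paste0("K", seq_len(n_clones))
  parent <- c(NA_character_,
              if (n_clones > 1)
                vapply(2:n_clones, function(i) ids[sample.int(i - 1, 1)], ""))
  novel <- lapply(seq_len(n_clones), function(i)
    sample(gene_pool, sample.int(genes_per_clone, 1)))
  samples <- list()
  for (s in seq_len(n_samples)) {
    k <- sample.int(n_clones, 1)
    present <- sort(sample(ids, k))
    w <- runif(k)
    samples[[paste0("S", s)]] <- setNames(w / sum(w), present)
  }
  clonal_architecture(
    tibble::tibble(id = ids, parent = parent, novel_genes = novel),
    samples
  )
}

# independent path-walk complement oracle (explicit ancestor walk on the
# raw clone table, not via package internals)
oracle_complement <- function(arch, clone_id) {
  tbl <- arch$clones
  genes <- character()
  cur <- clone_id
  repeat {
    i <- match(cur, tbl$id)
    genes <- union(genes, tbl$novel_genes[[i]])
    if (is.na(tbl$parent[i])) break
    cur <- tbl$parent[i]
  }
  sort(genes)
}

# brute-force filter-then-sort ranking oracle
oracle_rank <- function(entries, dscore_min = 0.7, gscore_min = 0) {
  out <- list()
  for (d in unique(entries$drug)) {
    e <- entries[entries$drug == d, ]
    if (any(e$response == "resistance")) next
    e <- e[e$response == "sensitivity", ]
    if (nrow(e) == 0) next
    best <- e[e$dscore == max(e$dscore), ]
    best <- best[which.max(best$gscore), ]
    if (best$dscore > dscore_min && best$gscore > gscore_min)
      out[[d]] <- c(dscore = best$dscore, gscore = best$gscore)
  }
  if (length(out) == 0)
    return(tibble::tibble(drug = character(), best_dscore = numeric(),
                          best_gscore = numeric()))
  tbl <- tibble::tibble(
    drug = names(out),
    best_dscore = unname(vapply(out, `[[`, 1.0, "dscore")),
    best_gscore = unname(vapply(out, `[[`, 1.0, "gscore"))
  )
  tbl[order(-tbl$best_dscore, -tbl$best_gscore, tbl$drug), ]
}

# exponential survival cohort with a known hazard ratio
sim_surv_cohort <- function(n_a, n_b, hr = 1, base_hazard = 1 / 100,
                            censor_prob = 0) {
  t_a <- rexp(n_a, rate = base_hazard * hr)
  t_b <- rexp(n_b, rate = base_hazard)
  cens_a <- runif(n_a) < censor_prob
  cens_b <- runif(n_b) < censor_prob
  list(
    time_a = ifelse(cens_a, runif(n_a, 0, t_a), t_a),
    event_a = as.integer(!cens_a),
    time_b = ifelse(cens_b, runif(n_b, 0, t_b), t_b),
    event_b = as.integer(!cens_b)
  )
}

# minimal VCF writer for parser tests
write_test_vcf <- function(path, records) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(gene, filter = "PASS", pos = 100, chrom = "1") {
  paste(chrom, pos, ".", "A", "T", ".", filter,
        paste0("GENE=", gene), sep = "\t")
}
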