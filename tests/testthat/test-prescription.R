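test_that("prescribe_profile composes query, veto, filter and sort", {
  kb <- make_kb(
    kb_entry("DDR2", "dasatinib", gscore = 0.64, dscore = 0.95,
             drug_status = "clinical_trials"),
    kb_entry("TP53", "paclitaxel", gscore = 0.63, dscore = 0.94,
             association = "biomarker"),
    kb_entry("TS1", "pemetrexed", gscore = 0.79, dscore = 0.84,
             association = "biomarker")
  )
  rx <- prescribe_profile(c("DDR2", "TP53", "TS1"), kb)
  expect_equal(rx$drug, c("dasatinib", "paclitaxel", "pemetrexed"))
  expect_equal(rx$best_dscore, c(0.95, 0.94, 0.84))

  # resistance-only profile yields an empty ranking
  kb2 <- make_kb(kb_entry("KRAS", "cetuximab", dscore = -0.8,
                          response = "resistance"))
  expect_equal(nrow(prescribe_profile("KRAS", kb2)), 0L)
  expect_equal(nrow(prescribe_profile(character(), kb)), 0L)

  set.seed(31)
  for (rep in 1:10) {
    kb <- rand_kb(40)
    genes <- sample(sprintf("G%02d", 1:12), 6)
    got <- prescribe_profile(genes, kb, dscore_min = 0.3)
    want <- oracle_rank(kb$entries[kb$entries$gene %in% genes, ],
                        dscore_min = 0.3)
    expect_equal(got$drug, want$drug)
    expect_equal(got$best_dscore, want$best_dscore)
  }
})

test_that("clone druggability is the share of the region's targetable genes", {
  arch <- clonal_architecture(
    tibble::tibble(id = c("A", "B"), parent = c(NA, "A"),
                   novel_genes = list(c("X1", "X2"), "Y1")),
    list(s = c(A = 0.4, B = 0.6))
  )
  kb <- make_kb(kb_entry(c("X1", "Y1"), c("d1", "d2")))
  expect_equal(clone_druggability(arch, "s", "B", kb), 1.0)  # B carries all
  expect_equal(clone_druggability(arch, "s", "A", kb), 0.5)

  kb_empty <- make_kb(kb_entry("ZZ", "d3"))
  expect_warning(frac <- clone_druggability(arch, "s", "A", kb_empty),
                 "no druggable gene")
  expect_equal(frac, 0)
  expect_error(clone_druggability(arch, "s", "Q", kb), "not present",
               class = "clonotherapy_validation_error")

  set.seed(32)
  for (rep in 1:10) {
    a <- rand_arch(n_clones = 5, n_samples = 1)
    kb <- rand_kb(30)
    sid <- sample_ids(a)[1]
    p <- a$samples[[sid]]
    denom <- druggable_genes(region_union_genes(a, sid), kb)
    for (cid in names(p)[p > 0]) {
      want <- if (length(denom) == 0) 0 else
        length(druggable_genes(full_complement(a, cid), kb)) / length(denom)
      got <- suppressWarnings(clone_druggability(a, sid, cid, kb))
      expect_equal(got, want)
      expect_lte(got, 1)
    }
  }
})

test_that("bulk_vs_ith: bulk is the predominant clone, ITH the union", {
  # single-clone sample: bulk equals ITH exactly
  arch <- clonal_architecture(
    tibble::tibble(id = "A", parent = NA_character_,
                   novel_genes = list(c("X1", "X2"))),
    list(s = c(A = 1.0)))
  kb <- make_kb(kb_entry("X1", "d1"))
  cmp <- bulk_vs_ith(arch, "s", kb)
  expect_equal(cmp$bulk_gene_count, cmp$ith_gene_count)
  expect_equal(cmp$bulk_druggable_genes, cmp$ith_druggable_genes)
  expect_equal(cmp$bulk_drugs, cmp$ith_drugs)

  set.seed(33)
  for (rep in 1:10) {
    a <- rand_arch(n_clones = 6, n_samples = 1)
    kb <- rand_kb(40)
    sid <- sample_ids(a)[1]
    cmp <- bulk_vs_ith(a, sid, kb)
    expect_equal(cmp$bulk_gene_count,
                 length(full_complement(a, predominant_clone(a, sid))))
    expect_equal(cmp$ith_gene_count, length(region_union_genes(a, sid)))
    expect_lte(cmp$bulk_gene_count, cmp$ith_gene_count)
  }
})

test_that("bulk druggable genes and drugs are subsets of the ITH side", {
  set.seed(34)
  for (rep in 1:30) {
    a <- rand_arch(n_clones = sample(2:7, 1), n_samples = 1)
    # gene-level inclusion holds regardless of resistance entries
    kb <- rand_kb(40)
    cmp <- bulk_vs_ith(a, sample_ids(a)[1], kb, dscore_min = 0.2)
    expect_true(all(cmp$bulk_druggable_genes %in% cmp$ith_druggable_genes))
    # drug-level inclusion holds on sensitivity-only evidence; with
    # resistance entries the wider ITH profile can veto a bulk candidate
    kb_s <- rand_kb(40, p_resistance = 0)
    cmp_s <- bulk_vs_ith(a, sample_ids(a)[1], kb_s, dscore_min = 0.2)
    expect_true(all(cmp_s$bulk_drugs$drug %in% cmp_s$ith_drugs$drug))
  }
})

test_that("ITH-vetoed bulk candidates are the only drug-level exceptions", {
  # when a bulk candidate is missing from the ITH ranking, the cause must
  # be a resistance entry on an ITH-only gene for that drug
  set.seed(37)
  for (rep in 1:20) {
    a <- rand_arch(n_clones = sample(2:7, 1), n_samples = 1)
    kb <- rand_kb(40, p_resistance = 0.3)
    sid <- sample_ids(a)[1]
    cmp <- bulk_vs_ith(a, sid, kb, dscore_min = 0.2)
    missing <- setdiff(cmp$bulk_drugs$drug, cmp$ith_drugs$drug)
    for (d in missing) {
      e <- kb$entries[kb$entries$drug == d &
                        kb$entries$gene %in% region_union_genes(a, sid), ]
      expect_true(any(e$response == "resistance"))
    }
  }
})

test_that("classify_response follows the three-way molecular-evidence rule", {
  kb <- make_kb(
    kb_entry("EGFR", "erlotinib", dscore = 0.9),
    kb_entry("KRAS", "erlotinib", dscore = -0.9, response = "resistance",
             association = "biomarker"),
    kb_entry("BRAF", "vemurafenib", dscore = 0.8)
  )
  cls <- c("erlotinib", "gefitinib")
  expect_equal(classify_response("EGFR", cls, kb),
               list(label = "responder", reason = "sensitivity_only"))
  # resistance present wins even with a sensitivity mutation on board
  expect_equal(classify_response(c("EGFR", "KRAS"), cls, kb),
               list(label = "non_responder", reason = "resistance_present"))
  # evidence for another class's drug does not count
  expect_equal(classify_response("BRAF", cls, kb),
               list(label = "non_responder", reason = "no_evidence"))
  expect_error(classify_response("EGFR", character(), kb), "non-empty",
               class = "clonotherapy_validation_error")
})

test_that("classification matches a predicate oracle and partitions cases", {
  set.seed(35)
  kb <- rand_kb(60, n_genes = 15, n_drugs = 10, p_resistance = 0.3)
  drug_class <- sprintf("drug%02d", 1:3)
  reasons <- character(500)
  for (i in 1:500) {
    genes <- sample(sprintf("G%02d", 1:15), sample.int(6, 1))
    got <- classify_response(genes, drug_class, kb)
    e <- kb$entries[kb$entries$gene %in% genes &
                      kb$entries$drug %in% drug_class, ]
    want <- if (any(e$response == "resistance")) {
      list(label = "non_responder", reason = "resistance_present")
    } else if (any(e$response == "sensitivity")) {
      list(label = "responder", reason = "sensitivity_only")
    } else list(label = "non_responder", reason = "no_evidence")
    expect_equal(got, want)
    expect_equal(got$label == "responder", got$reason == "sensitivity_only")
    reasons[i] <- got$reason
  }
  expect_true(all(reasons %in% c("sensitivity_only", "resistance_present",
                                 "no_evidence")))
})

test_that("alternative therapies drop the excluded class and nothing else", {
  kb <- make_kb(
    kb_entry("EGFR", "erlotinib", dscore = 0.9),
    kb_entry("EGFR", "osimertinib", dscore = 0.85),
    kb_entry("TP53", "paclitaxel", dscore = 0.8, association = "biomarker")
  )
  egfri <- c("erlotinib", "osimertinib")
  alt <- alternative_therapies(c("EGFR", "TP53"), egfri, kb)
  expect_equal(alt$drug, "paclitaxel")
  # excluding nothing reproduces prescribe_profile
  expect_equal(alternative_therapies(c("EGFR", "TP53"), character(), kb),
               prescribe_profile(c("EGFR", "TP53"), kb))
  # profile whose only candidates are in the excluded class
  expect_equal(nrow(alternative_therapies("EGFR", egfri, kb)), 0L)

  set.seed(36)
  for (rep in 1:10) {
    kb <- rand_kb(40)
    genes <- sample(sprintf("G%02d", 1:12), 5)
    excl <- sample(sprintf("drug%02d", 1:8), 3)
    got <- alternative_therapies(genes, excl, kb, dscore_min = 0.2)
    want <- prescribe_profile(genes, kb, dscore_min = 0.2)
    want <- want[!want$drug %in% excl, ]
    expect_equal(got, want)
  }
})
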