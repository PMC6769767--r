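simple_arch <- function() {
  clonal_architecture(
    tibble::tibble(
      id = c("A", "B", "C"),
      parent = c(NA, "A", "B"),
      novel_genes = list("X1", "Y1", c("Z1", "Z2"))
    ),
    list(s1 = c(A = 0.5, B = 0.5), s2 = c(C = 1.0))
  )
}

test_that("architecture validation rejects malformed inputs", {
  tbl <- tibble::tibble(id = c("A", "B"), parent = c(NA, "A"),
                        novel_genes = list("X", "Y"))
  expect_s3_class(clonal_architecture(tbl), "clonal_architecture")

  two_roots <- tibble::tibble(id = c("A", "B"), parent = c(NA, NA),
                              novel_genes = list("X", "Y"))
  expect_error(clonal_architecture(two_roots), "exactly one root",
               class = "clonotherapy_validation_error")

  cyc <- tibble::tibble(id = c("R", "A", "B"), parent = c(NA, "B", "A"),
                        novel_genes = list("X", "Y", "Z"))
  expect_error(clonal_architecture(cyc), "cycle",
               class = "clonotherapy_validation_error")

  expect_error(clonal_architecture(tbl, list(s1 = c(A = 0.5, B = 0.6))),
               "sum to", class = "clonotherapy_validation_error")
  expect_error(clonal_architecture(tbl, list(s1 = c(Q = 1.0))),
               "undeclared", class = "clonotherapy_validation_error")
  # prevalences within tolerance are accepted, not renormalized
  a <- clonal_architecture(tbl, list(s1 = c(A = 0.5, B = 0.5 + 1e-8)))
  expect_equal(sum(a$samples$s1), 1, tolerance = 1e-7)
})

test_that("full_complement unions novel genes along the root path", {
  a <- simple_arch()
  expect_equal(full_complement(a, "A"), "X1")
  expect_equal(full_complement(a, "B"), c("X1", "Y1"))
  expect_equal(full_complement(a, "C"), c("X1", "Y1", "Z1", "Z2"))
  expect_error(full_complement(a, "nope"), "unknown clone",
               class = "clonotherapy_validation_error")
})

test_that("complements match the ancestor-walk oracle on random trees", {
  set.seed(21)
  for (rep in 1:15) {
    a <- rand_arch(n_clones = 8, gene_pool = sprintf("G%02d", 1:40))
    for (cid in clone_ids(a))
      expect_equal(full_complement(a, cid), oracle_complement(a, cid))
    # monotone along any root->leaf path: child superset of parent
    for (i in seq_len(nrow(a$clones))) {
      p <- a$clones$parent[i]
      if (!is.na(p))
        expect_true(all(full_complement(a, p) %in%
                          full_complement(a, a$clones$id[i])))
    }
  }
})

test_that("trunk genes are the intersection of all complements", {
  a <- simple_arch()
  expect_equal(trunk_genes(a), "X1")
  single <- clonal_architecture(
    tibble::tibble(id = "A", parent = NA_character_,
                   novel_genes = list(c("X", "Y"))))
  expect_equal(trunk_genes(single), c("X", "Y"))

  set.seed(22)
  for (rep in 1:10) {
    a <- rand_arch(n_clones = 6)
    want <- Reduce(intersect,
                   lapply(clone_ids(a), oracle_complement, arch = a))
    expect_equal(trunk_genes(a), sort(want))
    for (cid in clone_ids(a))
      expect_true(all(trunk_genes(a) %in% full_complement(a, cid)))
  }
})

test_that("region union and predominant clone follow sample prevalences", {
  a <- simple_arch()
  expect_equal(region_union_genes(a, "s2"), c("X1", "Y1", "Z1", "Z2"))
  expect_equal(predominant_clone(a, "s2"), "C")
  expect_warning(predominant_clone(a, "s1"), "tie")
  expect_error(region_union_genes(a, "nope"), "unknown sample",
               class = "clonotherapy_validation_error")

  set.seed(23)
  for (rep in 1:10) {
    a <- rand_arch(n_clones = 6, n_samples = 2)
    for (sid in sample_ids(a)) {
      p <- a$samples[[sid]]
      want <- sort(unique(unlist(lapply(names(p)[p > 0], oracle_complement,
                                        arch = a))))
      expect_equal(region_union_genes(a, sid), want)
      expect_equal(predominant_clone(a, sid),
                   names(p)[which.max(p)])
      # ITH never reveals fewer genes than the bulk approximation
      expect_true(all(full_complement(a, predominant_clone(a, sid)) %in%
                        region_union_genes(a, sid)))
    }
  }
})

test_that("architecture JSON round-trips, also from complement format", {
  a <- simple_arch()
  path <- withr::local_tempfile(fileext = ".json")
  write_architecture(a, path)
  b <- read_architecture(path)
  expect_equal(b$clones$id, a$clones$id)
  for (cid in clone_ids(a))
    expect_equal(full_complement(b, cid), full_complement(a, cid))
  expect_equal(b$samples, a$samples)

  # complement-format file: each clone lists its full mutation load
  j <- list(
    clones = list(
      list(id = "A", novel_genes = list("X1")),
      list(id = "B", parent = "A", novel_genes = list("X1", "Y1"))
    ),
    samples = list(list(id = "s1", prevalence = list(A = 0.3, B = 0.7)))
  )
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  cc <- read_architecture(path, format = "complement")
  expect_equal(cc$clones$novel_genes[[2]], "Y1")
  expect_equal(full_complement(cc, "B"), c("X1", "Y1"))
})

test_that("temporal selection applies the low-VAF / expansion rule", {
  profiles <- tibble::tibble(
    gene = c("A", "A", "B", "B", "C", "D"),
    timepoint = c("t0", "t1", "t0", "t1", "t1", "t0"),
    vaf = c(0.005, 0.35, 0.40, 0.40, 0.20, 0.008)
  )
  sel <- select_temporal_genes(profiles, "t0", "t1")
  expect_equal(sel$pre_existing, "A")     # low at t0, expanded at t1
  expect_equal(sel$relapse_specific, "C") # absent at t0
  expect_equal(sel$genes, c("A", "C"))    # B high at both; D vanished

  expect_error(select_temporal_genes(profiles, "t0", "t1", low_vaf = 0.2,
                                     rise_min = 0.1),
               "smaller", class = "clonotherapy_validation_error")
  expect_error(select_temporal_genes(profiles, "tX", "t1"),
               "unknown timepoint", class = "clonotherapy_validation_error")
})

test_that("temporal selection equals a predicate-scan oracle", {
  set.seed(24)
  genes <- sprintf("G%03d", 1:100)
  rows <- list()
  for (g in genes) {
    if (runif(1) < 0.8)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = g, timepoint = "t0", vaf = round(runif(1, 0, 0.5), 4))
    if (runif(1) < 0.8)
      rows[[length(rows) + 1]] <- tibble::tibble(
        gene = g, timepoint = "t1", vaf = round(runif(1, 0, 0.5), 4))
  }
  profiles <- dplyr::bind_rows(rows)
  sel <- select_temporal_genes(profiles, "t0", "t1",
                               low_vaf = 0.05, rise_min = 0.2)
  want <- character()
  for (g in genes) {
    v0 <- profiles$vaf[profiles$gene == g & profiles$timepoint == "t0"]
    v1 <- profiles$vaf[profiles$gene == g & profiles$timepoint == "t1"]
    if (length(v1) == 1 && v1 >= 0.2 && (length(v0) == 0 || v0 < 0.05))
      want <- c(want, g)
  }
  expect_equal(sel$genes, sort(want))
  expect_equal(sort(c(sel$pre_existing, sel$relapse_specific)), sort(want))
})

test_that("partition_events conserves the union cardinality", {
  expect_equal(partition_events(c("a", "b"), c("c", "d", "e")),
               list(shared = 0L, primary_specific = 2L,
                    relapse_specific = 3L, total = 5L))
  expect_equal(partition_events(letters[1:5], letters[1:5]),
               list(shared = 5L, primary_specific = 0L,
                    relapse_specific = 0L, total = 5L))
  set.seed(25)
  for (rep in 1:10) {
    p <- sample(letters, sample(5:20, 1))
    r <- sample(letters, sample(5:20, 1))
    pe <- partition_events(p, r)
    expect_equal(pe$shared + pe$primary_specific + pe$relapse_specific,
                 pe$total)
    expect_equal(pe$total, length(union(p, r)))
  }
})
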