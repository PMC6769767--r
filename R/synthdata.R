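# Seeded generators for every input the pipeline consumes (architectures,
# knowledge bases, cohorts), plus the transcribed worked-case fixtures, so
# all stages are testable offline.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Identical
#' configs (including `seed`) produce identical outputs; each generator
#' draws from its own sub-stream of the master seed, so adding one
#' generator never perturbs another.
#'
#' @param seed Master integer seed.
#' @param n_clones Number of clones in generated architectures.
#' @param n_trunk_genes Novel genes on the root (trunk) clone.
#' @param clone_gene_rate Mean novel genes per non-root clone (Poisson,
#'   floored at 1).
#' @param dirichlet_alpha Concentration of per-sample clone prevalences.
#' @param n_samples Samples (regions) per architecture.
#' @param gene_universe Size of the synthetic gene name pool.
#' @param druggable_fraction Fraction of the universe with >= 1 KB entry.
#' @param sensitivity_prob Probability a KB entry reports sensitivity
#'   (otherwise resistance).
#' @param gscore_range,dscore_range Uniform bounds for generated scores.
#' @param cohort List: `n_patients`, `responder_fraction`, `hazard_ratio`
#'   (responder hazard = `baseline_hazard * hazard_ratio`; values < 1 mean
#'   protection), `baseline_hazard` (events/day), `censor_prob`
#'   (independent uniform censoring).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_clones = 5L,
                       n_trunk_genes = 20L,
                       clone_gene_rate = 5,
                       dirichlet_alpha = 1,
                       n_samples = 2L,
                       gene_universe = 400L,
                       druggable_fraction = 0.3,
                       sensitivity_prob = 0.8,
                       gscore_range = c(0.1, 1),
                       dscore_range = c(0.1, 1),
                       cohort = list()) {
  cohort_defaults <- list(n_patients = 150L, responder_fraction = 0.5,
                          hazard_ratio = 0.5, baseline_hazard = 1 / 365,
                          censor_prob = 0.2)
  cohort <- utils::modifyList(cohort_defaults, cohort)
  cfg <- list(seed = as.integer(seed), n_clones = as.integer(n_clones),
              n_trunk_genes = as.integer(n_trunk_genes),
              clone_gene_rate = clone_gene_rate,
              dirichlet_alpha = dirichlet_alpha,
              n_samples = as.integer(n_samples),
              gene_universe = as.integer(gene_universe),
              druggable_fraction = druggable_fraction,
              sensitivity_prob = sensitivity_prob,
              gscore_range = gscore_range, dscore_range = dscore_range,
              cohort = cohort)
  ct_assert(cfg$n_clones >= 1, "n_clones must be >= 1")
  probs <- c(cfg$druggable_fraction, cfg$sensitivity_prob,
             cohort$responder_fraction, cohort$censor_prob)
  ct_assert(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  ct_assert(cohort$hazard_ratio > 0, "hazard_ratio must be positive")
  structure(cfg, class = "sim_config")
}

gene_pool <- function(cfg) sprintf("G%04d", seq_len(cfg$gene_universe))

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Generate a random clonal architecture
#'
#' Builds a random rooted tree (uniform parent choice among existing
#' clones), draws novel gene sets without replacement from the gene
#' universe, and assigns each sample Dirichlet prevalences over a random
#' non-empty subset of clones (summing to 1 exactly).
#'
#' @param cfg A [sim_config()].
#' @return A `clonal_architecture`.
#' @export
gen_architecture <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seed(cfg$seed, "architecture"), {
    pool <- gene_pool(cfg)
    n_novel <- c(cfg$n_trunk_genes,
                 if (cfg$n_clones > 1)
                   pmax(1L, stats::rpois(cfg$n_clones - 1L, cfg$clone_gene_rate)))
    ct_assert(sum(n_novel) <= length(pool),
              "gene universe too small for requested novel gene counts")
    pool <- sample(pool)  # shuffle, then carve disjoint novel sets
    offsets <- cumsum(c(0, n_novel))
    ids <- paste0("C", seq_len(cfg$n_clones))
    clones <- tibble::tibble(
      id = ids,
      parent = c(NA_character_,
                 if (cfg$n_clones > 1)
                   vapply(2:cfg$n_clones,
                          function(i) ids[sample.int(i - 1L, 1L)], "")),
      novel_genes = lapply(seq_len(cfg$n_clones), function(i)
        pool[(offsets[i] + 1):offsets[i + 1]])
    )
    samples <- list()
    for (s in seq_len(cfg$n_samples)) {
      k <- sample.int(cfg$n_clones, 1L)
      present <- sort(sample(ids, k))
      prev <- rdirichlet1(rep(cfg$dirichlet_alpha, k))
      prev <- prev / sum(prev)
      samples[[paste0("R", s)]] <- setNames(prev, present)
    }
    clonal_architecture(clones, samples)
  })
}

#' Generate a synthetic evidence knowledge base
#'
#' A stand-in for a curated gene-drug database: each druggable gene (a
#' `druggable_fraction` share of the universe) receives 1-3 entries with
#' scores drawn uniformly from the configured bounds, sensitivity response
#' with probability `sensitivity_prob` (else resistance), and association
#' class / drug status uniform over their enums.
#'
#' @param cfg A [sim_config()].
#' @return An `evidence_kb` (possibly empty).
#' @export
gen_kb <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seed(cfg$seed, "kb"), {
    pool <- gene_pool(cfg)
    druggable <- pool[runif(length(pool)) < cfg$druggable_fraction]
    k <- if (length(druggable)) sample.int(3L, length(druggable),
                                           replace = TRUE) else integer()
    gene <- rep(druggable, times = k)
    j <- sequence(k)
    n <- length(gene)
    entries <- tibble::tibble(
      gene = gene,
      drug = sprintf("drug_%s_%d", tolower(gene), j),
      gscore = runif(n, cfg$gscore_range[1], cfg$gscore_range[2]),
      dscore = runif(n, cfg$dscore_range[1], cfg$dscore_range[2]),
      response = ifelse(runif(n) < cfg$sensitivity_prob,
                        "sensitivity", "resistance"),
      association = sample(ASSOCIATION_LEVELS, n, replace = TRUE),
      drug_status = sample(STATUS_LEVELS, n, replace = TRUE),
      indications = rep(".", n)
    )
    evidence_kb(entries)
  })
}

#' Generate a synthetic two-arm cohort with known ground truth
#'
#' Emulates the a-priori stratification design: responders carry a
#' sensitivity-associated gene for the administered drug class and no
#' resistance gene; non-responders carry either a class resistance gene or
#' a no-evidence profile (50/50). Survival times are exponential with
#' hazard `baseline_hazard * hazard_ratio` for responders and
#' `baseline_hazard` for non-responders; censoring is independent and
#' uniform on `(0, T)` with probability `censor_prob`. By construction,
#' [classify_response()] on the generated profiles recovers the
#' generating label for every patient.
#'
#' @param cfg A [sim_config()].
#' @return List: `labels` (patient_id, label, reason), `survival`
#'   (patient_id, time_days, event), `profiles` (named list of gene
#'   vectors), plus the class `kb` and `drug_class` needed to classify.
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seed(cfg$seed, "cohort"), {
    co <- cfg$cohort
    n <- co$n_patients
    # Fixed, small class knowledge base: two class drugs, one sensitivity
    # gene, one resistance gene, plus neutral background genes.
    drug_class <- c("classdrug_a", "classdrug_b")
    kb <- evidence_kb(tibble::tibble(
      gene = c("SENSG1", "SENSG2", "RESG1"),
      drug = c("classdrug_a", "classdrug_b", "classdrug_a"),
      gscore = c(0.9, 0.8, 0.85),
      dscore = c(0.9, 0.8, -0.8),
      response = c("sensitivity", "sensitivity", "resistance"),
      association = c("direct_target", "biomarker", "biomarker"),
      drug_status = c("approved", "approved", "approved"),
      indications = "."
    ))
    background <- sprintf("BG%03d", 1:50)

    ids <- sprintf("P%04d", seq_len(n))
    is_resp <- runif(n) < co$responder_fraction
    profiles <- vector("list", n)
    reason <- character(n)
    for (i in seq_len(n)) {
      bg <- sample(background, sample.int(5L, 1L))
      if (is_resp[i]) {
        profiles[[i]] <- c(sample(c("SENSG1", "SENSG2"), 1L), bg)
        reason[i] <- "sensitivity_only"
      } else if (runif(1) < 0.5) {
        # resistance present trumps any sensitivity gene
        extra <- if (runif(1) < 0.5) "SENSG1" else character()
        profiles[[i]] <- c("RESG1", extra, bg)
        reason[i] <- "resistance_present"
      } else {
        profiles[[i]] <- bg
        reason[i] <- "no_evidence"
      }
    }
    names(profiles) <- ids

    hazard <- ifelse(is_resp, co$baseline_hazard * co$hazard_ratio,
                     co$baseline_hazard)
    t_event <- rexp(n, rate = hazard)
    censored <- runif(n) < co$censor_prob
    time <- ifelse(censored, runif(n, 0, t_event), t_event)
    list(
      labels = tibble::tibble(
        patient_id = ids,
        label = ifelse(is_resp, "responder", "non_responder"),
        reason = reason
      ),
      survival = tibble::tibble(
        patient_id = ids,
        time_days = time,
        event = as.integer(!censored)
      ),
      profiles = profiles,
      kb = kb,
      drug_class = drug_class
    )
  })
}

fixture_path <- function(file) {
  p <- system.file("extdata", "fixtures", file, package = "clonotherapy")
  ct_assert(nzchar(p), "fixture file not installed: ", file)
  p
}

#' Transcribed worked-case fixtures
#'
#' Three cases transcribed from published clonal-evolution studies, used
#' throughout the package's examples and tests:
#' \describe{
#'   \item{`UPN933124`}{An AML patient sequenced at diagnosis and relapse:
#'     temporal VAF profiles (18 genes at VAF < 1% at diagnosis expanding
#'     to 30-40% at relapse, plus 2 relapse-specific genes), the 413-event
#'     partition (330 shared / 5 primary-specific / 78 relapse-specific)
#'     and a matching evidence KB in which 10 of the 20 selected genes are
#'     druggable.}
#'   \item{`CRUK0056`}{A multi-region NSCLC case: four clones (trunk of
#'     116 genes; 11 genes shared by C2 and C3 including TP53; CAMK4
#'     private to C2; 3 non-druggable genes private to C4) over three
#'     regions (R2: C3 12% / C4 88%).}
#'   \item{`CRUK0016`}{A two-region NSCLC case: 507 trunk mutations
#'     including DDR2 (dasatinib, GScore 0.64 / DScore 0.95; paclitaxel
#'     0.63 / 0.94; pemetrexed 0.79 / 0.84), sorafenib and axitinib
#'     (DScore > 0.9) on genes private to C8 and C12, and no candidate
#'     above DScore 0.70 for C4's private mutations.}
#' }
#' Gene names beyond the published ones (and all prevalences or scores the
#' source figures do not print) are synthetic placeholders; analyses on
#' these fixtures should rely only on published cardinalities and scores.
#'
#' @return Named list of fixtures: per case, the relevant
#'   `clonal_architecture` / VAF table / event sets plus an `evidence_kb`.
#' @export
case_fixtures <- function() {
  events <- read.delim(fixture_path("upn933124_events.tsv"), sep = "\t",
                       colClasses = "character")
  list(
    UPN933124 = list(
      vaf_profiles = read_vaf_table(fixture_path("upn933124_vaf.tsv")),
      primary_events = events$event_id[events$category %in%
                                         c("shared", "primary_specific")],
      relapse_events = events$event_id[events$category %in%
                                         c("shared", "relapse_specific")],
      kb = load_kb(fixture_path("upn933124_kb.tsv")),
      timepoints = c(t0 = "diagnosis", t1 = "relapse")
    ),
    CRUK0056 = list(
      arch = read_architecture(fixture_path("cruk0056_arch.json")),
      kb = load_kb(fixture_path("cruk0056_kb.tsv"))
    ),
    CRUK0016 = list(
      arch = read_architecture(fixture_path("cruk0016_arch.json")),
      kb = load_kb(fixture_path("cruk0016_kb.tsv"))
    )
  )
}
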