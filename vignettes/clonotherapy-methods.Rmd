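---
title: "Methods: ITH-aware in silico drug prescription"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ITH-aware in silico drug prescription}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonotherapy)
```

## The problem

Standard in silico drug prescription matches a patient's mutated genes
against a curated gene–drug evidence base and returns a ranked list of
candidate therapies. Clinical sequencing, however, is almost always *bulk*
sequencing: it effectively reports the mutations of the most prevalent
tumour cell population, while minority subclones — including pre-existing
drug-resistant ones — remain invisible. This package implements a
prescription pipeline that treats intra-tumour heterogeneity (ITH) as a
first-class input: drugs are ranked per clone, bulk and ITH-aware views
are compared, combination regimens are designed to cover the clonal trunk
plus each subclone ("clonotherapy"), and cohorts are stratified a priori
into responders and non-responders whose overall survival is compared.

## Evidence model and ranking rule

Each knowledge-base entry links a gene to a drug with two scores and three
annotations:

* **GScore** in $[0, 1]$: evidence for the gene's clinical and biological
  relevance in cancer;
* **DScore** in $[-1, 1]$: drug suitability; positive values support
  sensitivity, negative values resistance;
* a **response** direction (sensitivity / resistance), an **association
  class** (direct target, biomarker, or downstream pathway member) and a
  **drug status** (approved, clinical trials, experimental).

Both scores are *inputs*: computing them from primary evidence sources is
out of scope here. Ranking a mutated-gene profile proceeds in three steps:

1. **Resistance veto.** If any entry linking a profile gene to a drug
   reports resistance, that drug is excluded outright, regardless of how
   strong its sensitivity entries are. The veto is drug-level across the
   whole profile; it mirrors the requirement that a prescribable patient
   harbour *no* resistance mutation for the drug.
2. **Thresholds.** Surviving drugs are kept when their best supporting
   entry has DScore strictly above `dscore_min` (default 0.7) and GScore
   strictly above `gscore_min` (0 for per-clone work, 0.6 for
   cohort-level prescription). Strict inequalities are deliberate: a drug
   at DScore exactly 0.7 does not pass.
3. **Ordering.** Candidates sort by DScore descending, then GScore
   descending, then drug name ascending. No combining formula of the two
   scores is assumed; the lexicographic order is the least-assumptive
   reading of "higher DScores on genes with GScores closer to 1", and the
   name tie-break makes the output totally ordered and stable.

The association class is carried as annotation and does not weight the
ranking; there is no published basis for down-weighting pathway members
relative to direct targets, so the package does not invent one.

A consequence worth knowing: the resistance veto makes drug lists
**non-monotone in the profile**. Adding genes (for instance, moving from
the bulk profile to the richer ITH profile) can *remove* a drug, because a
newly visible gene may carry a resistance entry for it. Druggable *gene*
sets are monotone; candidate *drug* sets are not. This is a feature of the
model, not a defect — a subclonal resistance mutation is precisely the
information bulk sequencing misses — and the test suite asserts drug-list
monotonicity only on sensitivity-only knowledge bases.

## Clonal architecture

A clonal architecture is a rooted tree of clones; each clone stores only
the genes *newly* mutated on its branch, and its full mutation complement
is the union of novel sets along the root-to-clone path. Storing novel
sets and deriving complements (rather than the reverse) avoids redundancy
and matches the Venn-diagram semantics of multi-region studies; a loader
flag (`format = "complement"`) converts files that store full complements.
Derived quantities:

* **trunk genes** — intersection of all complements: alterations carried
  by every tumour cell, the targets for whole-tumour therapy;
* **region union** — union of complements of clones present in a sample:
  what ITH-aware analysis sees;
* **predominant clone** — the maximum-prevalence clone of a sample: what
  bulk sequencing is assumed to see. Exact prevalence ties resolve to the
  lexicographically smallest clone id, with a warning.

Per-sample prevalences must sum to 1 within $10^{-6}$; inputs failing
this are rejected rather than renormalized, because a silently rescaled
prevalence vector usually signals an upstream bookkeeping error. Variant
allele frequency (VAF) and clone prevalence are kept as distinct notions
throughout — no ploidy/purity conversion between them is attempted.

## Temporal selection

For a diagnosis/relapse pair, the pipeline flags genes under positive
selection: *pre-existing* genes detected at VAF below `low_vaf` (default
0.01, i.e. < 1%) at baseline that reach VAF at least `rise_min` at
relapse, plus *relapse-specific* genes absent at baseline that appear at
or above `rise_min`. The relapse threshold defaults to 0.10 — expanded
relapse clones are typically reported at 30–40% VAF, so 0.10 is a
permissive default that still excludes noise-level calls; both thresholds
are per gene profile and configurable. Prescribing on the selected genes
suggests therapies that could have been given at diagnosis to anticipate
the relapse clone.

## Bulk vs ITH, druggability and regimens

`bulk_vs_ith()` contrasts the predominant-clone profile with the region
union, at the gene level, the druggable-gene level and the ranked-drug
level. "Druggable" defaults to *has at least one knowledge-base entry of
any class*; a strict mode (sensitivity entries above the DScore threshold
only) is available because published druggable-gene counts do not always
state their convention.

`clone_druggability()` is the fraction of a region's druggable genes
carried by one clone — 1.0 for a clone whose complement contains every
targetable gene of the region, 0 (with a warning) when the region has no
druggable gene at all.

`propose_regimen()` formalizes combination design. The default
`trunk_plus_specific` strategy follows the clonotherapy idea directly:
one top-ranked candidate on the trunk genes targets every tumour cell;
then each clone's *clone-specific* genes (complement minus trunk) get
their own top-ranked candidate. A clone whose specific genes admit no
candidate above the DScore threshold is reported **uncovered** — it is
still reached at the trunk level, but cannot be hit individually. This
definition is deliberate: since trunk genes belong to every complement, a
trunk drug trivially "covers" all clones, and a coverage notion based on
full complements could never flag a clone as uncoverable; the
clone-specific reading is the one under which reporting an uncoverable
subclone is meaningful. Two alternative strategies are provided:
`greedy_cover` (largest remaining prevalence mass first) and
`exact_cover` (minimum-cardinality cover by exhaustive search, refused
above 20 candidate drugs since the search is exponential).

**Therapeutic coverage** of a drug set in a sample is the summed
prevalence of clones covered by at least one drug (full-complement
membership). The source studies show coverage only as plots, never as a
number; the prevalence-mass definition is this package's formalization
and is flagged as such.

## Responder stratification and survival

`classify_response()` applies a three-way rule to a patient profile
restricted to an administered drug class (an explicit drug list — class
membership such as "EGFR inhibitors" is configuration, not inference):
resistance evidence present → non-responder (`resistance_present`);
otherwise sensitivity evidence present → responder (`sensitivity_only`);
otherwise non-responder (`no_evidence`). The three reasons are mutually
exclusive and exhaustive by construction.

Survival comparison is implemented from first principles so the
stratification analysis is self-contained and testable:

* **Kaplan–Meier**: $S(t) = \prod_{t_i \le t} (1 - d_i / n_i)$ over
  distinct event times, right-continuous, $S(0) = 1$; subjects censored
  at an event time count as at risk at that time; medians are the
  smallest time with $S(t) \le 0.5$.
* **Log-rank**: at each distinct event time, observed minus expected
  events in group A under the hypergeometric model;
  $\chi^2 = (\sum O - E)^2 / \sum V$ with the standard tied-event
  variance, referred to $\chi^2_1$, two-sided. No multiplicity
  correction is applied (the design is a single comparison).

Cox proportional-hazards modelling is deliberately not implemented: the
stratified comparison is the analysis of record here, and no Cox
coefficients are part of the worked results this package reproduces. The
test suite cross-checks both estimators against the independent
`survival` package (`survfit`, `survdiff`) and verifies Monte-Carlo
calibration: type-I error within $[0.035, 0.065]$ at $\alpha = 0.05$ over
2000 null cohorts of $n = 50 + 50$, and power $\ge 0.8$ at hazard ratio
0.5 with $n = 75 + 75$ and 20% uniform censoring over 500 replicates.
These problem sizes make the full suite run in well under a minute while
keeping the binomial noise on the estimated rates small relative to the
asserted bands.

## Genomic input conventions

* VCF records contribute genes only when FILTER is exactly `PASS`
  (dropped-record counts are logged); multi-gene annotations split on
  commas; coordinates are 1-based per the VCF standard and irrelevant
  downstream (gene sets are coordinate-free). Genome-build liftover is
  not implemented; inputs are assumed on one build.
* CNV calls are kept when the expression z-score supports the change
  *with concordant sign*: gains need $z >$ `z_min`, losses need
  $z < -$`z_min` (default 2, strict). The magnitude rule alone
  (`concordant = FALSE`) is available, but sign concordance is the
  default because an amplification with *under*-expression does not
  support the call; the z-filter is applied to CNV support only, not to
  mutation genes.
* Drug nomenclature is standardized through a user-supplied alias table
  (case-insensitive; canonical names map to themselves; unknown names
  pass through with a warning).

## Synthetic data and the worked-case fixtures

The generators (`gen_architecture`, `gen_kb`, `gen_cohort`) are pure
functions of a `sim_config`: every generator draws from its own
sub-stream of the master seed, so outputs are byte-identical across runs
and adding a generator never perturbs another. Architectures use a
uniform random tree, disjoint novel gene sets and Dirichlet prevalences;
knowledge bases draw 1–3 entries per druggable gene with uniform scores;
cohorts encode the responder label directly in the molecular profile
(sensitivity gene and no resistance gene for responders; a resistance
gene or a no-evidence profile, 50/50, for non-responders) with
exponential survival — responder hazard equals
`baseline_hazard * hazard_ratio`, so `hazard_ratio` 0.5 means protection
— and independent uniform censoring. Label recovery by
`classify_response()` is exact by construction, which is asserted rather
than assumed.

What the generators deliberately do **not** emulate: mutational
signatures, read-level noise, VAF measurement error, clonal-deconvolution
uncertainty, or correlated censoring. Passing tests on synthetic cohorts
therefore validate the *pipeline logic and statistics*, not performance
on real sequencing data.

The three packaged fixtures transcribe published worked cases: an AML
diagnosis/relapse genome pair (413 somatic events split 330 shared / 5
primary-specific / 78 relapse-specific; 18 low-VAF pre-existing genes
plus ETV6 and TMEM117 relapse-specific; 10 of the 20 druggable) and two
multi-region NSCLC cases (one with a 116-gene trunk and a region where
ITH reveals 130 genes against 119 for the 88%-prevalence predominant
clone; one with a 507-gene trunk whose top candidate is dasatinib at
DScore 0.95, subclone-specific sorafenib and axitinib above 0.9, and one
subclone with no candidate above 0.7). Gene names and values the source
figures do not print — most gene symbols, one case's clone prevalences,
per-clone private gene counts, and the non-printed drug scores — are
synthetic placeholders fixed once in the fixture files; fixture-based
tests assert only published cardinalities and scores. The second NSCLC
case names three subclones plus a set of mutations shared by all of
them; the fixture represents that shared set as an explicit ancestral
root clone, the standard tree representation, with prevalence 0 in the
sampled regions.

## Numerical and degenerate-input choices

* Prevalence sum tolerance $10^{-6}$ (reject, never renormalize).
* Score thresholds are strict (`>`), at every boundary.
* Empty prescriptions, empty alternative-therapy lists and zero-druggable
  regions are ordinary, non-error outcomes (empty tibble / 0 with a
  warning); validation failures (malformed scores, unknown clones,
  non-tree architectures, a single-stratum cohort) raise a typed
  condition (`clonotherapy_validation_error`) that the command-line
  wrapper maps to exit code 2.
* `exact_cover` refuses instances above 20 candidate drugs instead of
  silently running an exponential search.

## Known limitations

Clonal architectures are taken as given — no deconvolution from raw VAFs
and no phylogeny reconstruction. Scores are consumed, not computed, so
results inherit whatever biases the upstream evidence base carries.
Drug–drug interactions, dosing and scheduling are out of model: a regimen
here is a drug *set*. Cancer-type indications are carried as annotation
only, not used as a hard filter. Cohort-scale published results that
depend on external patient repositories are reproduced structurally on
synthetic cohorts, not numerically.
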