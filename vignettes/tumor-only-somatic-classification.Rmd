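---
title: "Tumor-only somatic alteration classification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor-only somatic alteration classification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tosomatic)
```

## The problem

When a tumor is sequenced without a matched normal from the same patient,
every call set is a mixture of somatic alterations and the patient's own
germline variation — and germline variants outnumber somatic ones by more
than an order of magnitude. Standard hard filters (drop anything seen in a
population database) remove most germline variants but plateau well short of
the accuracy needed for downstream genomic analyses. `tosomatic` implements
a supervised alternative: where a subset of the cohort *does* have matched
normals, the matched somatic calls provide ground-truth labels on the
corresponding tumor-only call sets, and a random-forest classifier trained
on those labels transfers to the samples that have no normal.

The package covers four connected analyses:

1. **Small variants** (SNVs and indels): ground-truth labeling, a 20-feature
   random forest, and a cohort classification step.
2. **Structural variants**: consensus merging of three callers' breakpoint
   calls, a 19-feature random forest per caller, and a vote-based
   integration into a final somatic SV set.
3. **Copy number**: post-processing of tumor-only segment calls
   (artifact-region exclusion, negative-value handling) and a concordance
   benchmark against matched calls.
4. **Cohort QC**: sex validation across genome coverage, expression and
   methylation intensity, and concordance of purity estimates from three
   sources.

All of it is exercised end to end on a bundled synthetic-cohort generator
with known truth, so the full pipeline is testable without controlled
patient data.

## Small-variant model

A tumor-only call is represented by 20 numeric features in three blocks:

* **Databases (4)** — presence and allele frequency in a population
  database (gnomAD-like), presence and occurrence count in a cancer
  mutation catalogue (COSMIC-like), matched by literal
  (chrom, pos, ref, alt) identity. Germline variants are common in the
  population database and rare in the catalogue; somatic variants the
  reverse.
* **Location / impact / context (6)** — region class at the site
  (CDS = 3 > UTR = 2 > intron = 1 > intergenic = 0), an impact proxy
  derived from region and variant class only (a frameshift-like indel in
  CDS outranks a coding SNV; no external effect predictor is consulted),
  the 96-channel pyrimidine-strand trinucleotide substitution context,
  repeat and conserved-element flags, and the homopolymer run length.
* **Caller metrics (10)** — allele fraction, total and alt read depth,
  median base and mapping quality, strand balance, caller confidence
  score, filter status, multi-allelic flag, and the SNV indicator.

The allele fraction carries the core biological signal: a clonal,
copy-neutral somatic variant sits near purity/2, while germline
heterozygotes sit at 0.5 and homozygotes at 1.0 regardless of purity.

Two models are trained: an SNV model on the 20 features, and an indel model
on 19 (the SNV indicator removed), following the upstream protocol of
separating the variant classes. Training uses 1:1 class balancing by
down-sampling the majority class, a stratified 75/25 train/test split, and
a probability forest with mtry 8, 1000 trees and minimal node size 5 — the
grid-search optimum for this problem; the stock settings (4/400/1) are also
in the default search grid. Classification is at somatic probability 0.5;
no threshold tuning is performed, matching how the upstream evaluation is
reported.

Missing caller annotations are recorded as sentinel −1 rather than imputed:
trees split on the sentinel directly, which avoids a second, separately
fitted imputation model.

## Structural-variant model

SVs are oriented breakpoint pairs normalized so that the lower breakpoint
(under the natural chromosome order chr1..chr22, chrX, chrY, unknown
contigs last) comes first. Three caller dialects are read: paired BND
records with bracket notation, symbolic ALTs with `END`/`SVLEN`, and
symbolic ALTs with `CHR2`/`CT` connection types.

Consensus merging clusters two calls when both breakpoints lie within a
maximum distance (default 1000 bp, the common consensus-merging
convention), with type and strand matching required by default; events are
the transitive closure of that relation, computed by union-find and
verified in the tests against an all-pairs graph-components oracle. The
representative call is the member with the highest caller quality.

Each caller gets its own 19-feature random forest (database block,
panel-of-normals counts around both breakpoints within ±200 bp,
region/conservation at both breakpoints, and caller metrics including
`log_length` = ln(1+length), 0 for translocations). The PON window of
±200 bp is this package's explicit choice — it is recorded in the model
manifest and configurable, since upstream documentation does not pin it.
Integration is deliberately conservative: an event is somatic iff the
somatic votes are unanimous among its supporting callers, or at least two
callers vote somatic. The vote rule is a package design decision,
documented and replayed row-by-row in the tests.

## Copy-number post-processing

Upstream allele-specific copy-number callers fitted without a matched
normal produce two known artifact classes: focal spurious peaks near
telomeres and centromeres, and negative copy-number estimates where the
model penalizes rather than truncates. Post-processing applies, in order:

1. removal of any segment overlapping (by one or more bp) a curated
   artifact interval — whole-segment removal, no trimming;
2. rounding of slightly negative values (−0.5, 0) to 0;
3. removal of segments with any value below −0.5, which indicate read-depth
   noise too high to trust.

Exclusion runs first so the removal log attributes each segment to a single
reason; both orders are equivalent for the shipped generator since
injections never coincide. Genome state fractions are length-weighted over
the covered segment length and classify each segment by rounded total copy
number against the absolute diploid state 2 (not against sample ploidy).
The benchmark pairs each tumor-only callset with its matched counterpart
and reports Pearson correlations for purity, ploidy, segment count, the
three state fractions, and pooled gene-level major/minor copy numbers.
Identical paired vectors report r = 1 even when degenerate (a cohort
uniformly at ploidy 2 is perfect concordance, not undefined).

## Cohort QC

Sex is called per modality: normalized Y coverage at or above 0.25 is male,
below 0.10 female, the band between is ambiguous and flags a candidate
somatic Y loss (thresholds are package choices — upstream assessments were
visual — placed to separate XY at ~0.5 from XX at ~0 with a wide buffer);
methylation calls female when the Y−X log2 median intensity difference is
below −2, with the boundary value itself classed male (strict inequality,
documented); expression uses a deterministic two-means split of the
Y-expression sums with the class-mean midpoint as boundary, abstaining when
the two means are closer than 3 vst units (a single-sex cohort has no
trustworthy split). Consensus is the majority of non-ambiguous modality
calls. Purity estimates from pathology, genome and transcriptome are
compared pairwise by Pearson correlation with Benjamini–Hochberg adjustment
over the three tests, excluding samples pairwise where an estimate is
missing.

## The synthetic cohort

The generator defines the package's reference study conditions:

| parameter | default | rationale |
|---|---|---|
| samples | 20 | cohort large enough for stable held-out metrics, small enough for desk-scale runs |
| purity | uniform 0.2–0.9 | the realistic clinical range; drives somatic AF |
| germline / somatic small variants per sample | 5000 / 500 | ~10:1 imbalance typical of tumor-only calls at cohort scale |
| depth | Poisson 60× matched / 30× tumor-only | common WGS depths |
| population-db membership | 0.95 germline / 0.01 somatic | high but imperfect database coverage |
| cancer-catalogue membership | 0.10 somatic / 0.001 germline | catalogue enrichment |
| SVs per type per sample | 15 germline / 8 somatic (DEL, DUP, INV, TRA) | germline SV excess |
| germline / somatic SV length | lognormal ~2 kb / ~50 kb | short common polymorphisms vs. larger rearrangements; a designed class signal |
| PON | clusters at 90% of germline SV breakpoints + 2/Mbp background | panel-of-normals support concentrates on germline events |
| caller dropout / jitter | 10–20% per caller, 30 bp sd | imperfect caller sensitivity and breakpoint precision |
| CN noise / injections | value sd 0.05; negative and artifact-peak injections per sample | the two artifact classes post-processing must handle |

Allele fractions are observed through binomial read sampling at the true
fraction (germline 0.5/1.0, somatic purity/2 for clonal copy-neutral
variants), so class supports overlap at high purity and the classification
problem is non-trivial. The `separable_params()` scenario replaces this
with exact fractions and perfectly separating databases, a limit in which
held-out accuracy must be exactly 1 — a correctness check on the whole
training path rather than a realism claim.

The genome is a 190 Mbp miniature (three 50 Mbp autosomes, 30 Mbp X,
10 Mbp Y) so that brute-force oracles — per-bp state tallies, all-pairs
overlap scans, O(n²) cluster closure — run in seconds. Copy-number segment
boundaries include the artifact-zone edges, as real callers break segments
at assembly gaps. One male tumor receives a somatic Y loss (intermediate Y
coverage with male evidence elsewhere): it must surface as the cohort's
only Y-loss candidate.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: read-level errors and mapping artifacts,
mutational-signature structure (contexts are uniform), population linkage
and shared germline variation between patients, subclonal architecture,
and realistic inter-caller correlation structure beyond independent jitter
and dropout. Held-out accuracies on the synthetic cohort (~0.98) are
accordingly higher than what the same protocol reaches on real tumors
(~0.93); the synthetic cohort validates the machinery and its contracts,
not the field performance.

## Numerical and reproducibility choices

* Every random-forest fit is single-threaded with a fixed seed; identical
  seeds give identical predictions. Simulator sub-generators draw from
  independent streams derived by scrambling the master seed, so adjacent
  seeds share no output.
* Interval logic is 0-based half-open everywhere internally; positions are
  1-based only inside VCF files. Point-variant records keep their VCF
  `pos` because every consumer (database keys, VCF round trips) speaks VCF
  coordinates; interval queries at a variant use the window
  `[pos−1, pos)`.
* Grid-search ties break toward the cheaper, more regularized model (fewer
  trees, larger node size, smaller mtry).
* Gene-level copy-number ties (equal overlap) break toward the lower total
  copy number, preferring the more conservative state.
* Segment state assignment uses `round()`; copy-number values exactly at
  .5 are vanishingly rare in practice and the convention is deterministic.

## Worked example

```{r example, eval = FALSE}
cohort <- simulate_cohort(simulation_params(n_samples = 6, seed = 42),
                          dir = "cohort")

snv <- run_snv_pipeline(cohort, use_files = TRUE, seed = 42)
snv$reports$snv            # held-out confusion counts and metrics
head(names(snv$importances$snv), 3)

svp <- run_sv_pipeline(cohort, seed = 42)
sapply(svp$models, function(m) m$report$accuracy)

cnb <- run_cn_benchmark(cohort)
round(cnb$report$r, 3)

qc <- run_cohort_qc(cohort)
table(qc$sex$consensus == cohort$meta$sex)
```

## Known limitations

* The concrete identities of some upstream features are not published;
  the 4 + 6 + 10 block composition here is this package's documented
  realization of the three described feature classes, and the impact
  feature is a region-based proxy.
* The shipped artifact-region list is a synthetic stand-in for a curated
  list (its filename says so); users benchmarking real genomes must supply
  their own.
* Sample-identity matching across omics (SNP-panel genotype concordance)
  is out of scope; the simulator simply emits per-patient-consistent
  evidence.
* The SV integration rule and PON window are package choices where the
  upstream pipeline does not publish values; both are configurable and
  logged.
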