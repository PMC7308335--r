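---
title: "Methods: TCRβ repertoire architecture and cryptic RSS/RUNX1 enrichment"
author: "vdjrss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TCRβ repertoire architecture and cryptic RSS/RUNX1 enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdjrss)
library(dplyr)
```

## Scope and model

`vdjrss` implements two connected analyses around V(D)J recombination.

The **repertoire arm** turns paired-end TCRβ amplicon reads into an annotated
clonotype table. A rearranged TCRβ gene is modelled as

```
V[1 .. len(V) − tV] · N1 · D[d5 + 1 .. len(D) − d3] · N2 · J[tJ + 1 .. len(J)]
```

where `tV`, `d5`, `d3`, `tJ` are exonucleolytic truncations and N1/N2 are
non-templated insertions. The CDR3 is delimited by the conserved V-cysteine
codon and J-phenylalanine codon, both included. A clonotype is a unique
(V, J, CDR3 nucleotide sequence) with a read count; the pipeline applies,
in order: quality-weighted read joining, V/J assignment, clustering,
merging of 1-bp neighbours that are at least 20-fold less frequent than a
related clonotype, and a 0.001% frequency cutoff. Each surviving clonotype is
decomposed into the architecture above, with a D segment called only when a
contiguous exact germline D match of ≥ 5 nt exists in the junction.

The **motif arm** scores cryptic recombination signal sequences. Position
weight matrices are built from seed sequences with pseudocount 0.01; the
similarity of a window is the information-weighted normalised score

$$ s(w) = \frac{\sum_i c_i f_i(w_i)}{\sum_i c_i \max_b f_i(b)}, \qquad
   c_i = 2 + \sum_b f_i(b)\log_2 f_i(b), $$

which is 1 exactly at the per-position consensus. Eight composite RSS models
pair two heptamer and two nonamer matrices with spacer classes 12 ± 1 and
23 ± 1 bp. Deletion borders are analysed as 67-bp end regions (60 bp inside
the deletion plus 7 bp beyond the border); heptamer hits are expanded by
± 7 nt, overlapping windows merged, and a window counts as RUNX1-positive
when a RUNX1 hit (similarity ≥ 0.8) overlaps a *contributing heptamer hit*
by ≥ 4 nt. Enrichment against a background genome scanned with identical
rules is summarised by fold (observed/expected), a continuity-corrected
Z-score and an exact binomial tail.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `clonotype_frequency_cutoff` | 1e-5 (0.001%) | rows strictly below are removed; no renormalisation |
| `merge_fold_threshold` | 20 | minimum recipient/donor count ratio for 1-bp merging |
| `min_d_match` | 5 nt | minimum contiguous germline D match to call a D |
| `similarity_threshold_*` | 0.8 | matrix similarity floors (RUNX1, heptamer, nonamer) |
| `window_flank` | 7 nt | heptamer window expansion (matches the 11-nt RUNX1 site and 4-nt overlap rule) |
| `min_runx1_heptamer_overlap` | 4 nt | RUNX1–heptamer overlap demanded for positivity |
| `spacer_classes` | 12±1, 23±1 bp | RSS module spacer ranges |
| `partial_spacer_classes` | {12}, 19–25 bp | spacers accepted for the partial-heptamer category |
| `region_inner_span` | 60 bp | deletion-end bases inside the deletion |

Joining and assignment defaults (`join_min_overlap` 10, `join_max_mismatch_frac`
0.25, `assign_min_ident` 0.9 over ≥ 15 nt) are deliberately permissive: they
tolerate the ~0.2% substitution error rate typical of the assay while leaving
V/J discrimination to the match-count score.

## Design choices on genuinely open points

* **Cutoff boundary.** A clonotype at exactly 0.001% is retained; only
  strictly smaller frequencies are removed. This is the conservative reading
  of a "cutoff" and is configurable.
* **Merge scope and order.** "Differed by 1 bp" is read as one substitution
  (same V, J, equal CDR3 length, Hamming distance 1); indel neighbours are
  not merged. Donors are processed in ascending abundance, the recipient is
  the most abundant qualifying neighbour, and eligibility is recomputed as
  counts grow, so the outcome is deterministic and the total read count is
  conserved exactly.
* **Merge/cutoff order.** Merging runs before the frequency cutoff by
  default (`cutoff_before_merge = FALSE` switches this): error-derived
  1-bp neighbours are artefacts of their abundant parent and should be
  reabsorbed before any row is discarded.
* **D-assignment ties.** Equal best matches prefer the longer match, then
  the D earlier in genomic order (D1), then the leftmost junction placement,
  and set `d_ambiguous`.
* **Functionality** is defined as in-frame (CDR3 length divisible by 3) and
  stop-free in the reading frame anchored at the V cysteine codon. Germline
  V and J bodies are assumed stop-free; this is the minimal testable
  definition.
* **Truncation inference.** The matched V prefix/J suffix is maximal, so an
  N base that coincidentally equals the next germline base is absorbed into
  the segment. Inferred truncations are therefore never larger than the
  generative ones; with uniform N bases roughly 7/16 of clonotypes shift by
  at least one base on one side. The reconstruction identity (kept V + N1 +
  kept D + N2 + kept J equals the CDR3) holds in all cases and is
  property-tested.
* **Similarity formula.** Commercial matrix-scan suites behind the usual
  "matrix similarity 0.8" convention ship proprietary matrices; the canonical
  information-weighted normalised score above is used, with a replaceable
  11-column RUNX1 matrix built around the TGTGG core, and heptamer/nonamer
  matrices seeded from the canonical CACAGTG/ACAAAAACC RSS families. All
  matrices can be swapped for user files (`read_pwm()`).
* **Z-score variance.** The enrichment Z uses a 0.5 continuity correction
  with a binomial SD by default. Reported ChIP-peak enrichment conventions
  (an expected count with an SD equal to its square root) correspond to a Poisson SD
  (√7.6 ≈ 2.76), available as `variance = "poisson"`; a seeded resampling
  estimator is provided as an alternative for backgrounds whose variance
  model is unknown. Analytic and resampling estimates agree within 0.3 Z and
  a factor 2 in tail probability for expected counts ≥ 5 (property-tested).
* **Distances** from a RUNX1 hit to the deletion border are unsigned (first
  plus-strand base to the border coordinate), with a signed variant also
  reported (negative outside the deleted span of the 5′ region convention).
* **Partial-heptamer spacer.** For the partial category (GTG/CAC flank plus
  a spaced nonamer) the spacer is measured between the outer edge of the
  flanking trinucleotide and the near edge of the nonamer hit, on the same
  strand as the RUNX1 hit.
* **Backgrounds** are recomputed by scanning the provided genome at call
  time rather than cached to disk: at package scale a scan costs seconds,
  and recomputation keeps results a pure function of the inputs.
* **Interval convention** is 0-based half-open (BED) everywhere.

## What the simulators emulate

`simulate_repertoire()` draws geometric truncations, Poisson N lengths with
uniform bases, uniform V/J choice, Bernoulli(p) D2 choice and Zipf clone
sizes. These canonical laws match the first moments that repertoire studies
report; they do not reproduce position-specific nuclease preferences,
GC-biased N addition, allelic exclusion or PCR amplification bias. The
optional `p_functional` knob rejection-samples junctions toward a target
functional fraction, emulating the selection pressure that shifts the
functional/non-functional ratio in vivo; it is off by default.
`simulate_reads()` produces 2 × 150 bp pairs whose amplicon is the full
rearrangement (the germline V head and J tail double as primer landing
sites), multinomial read counts, and substitution-only errors — no indels,
so the closed-loop identity test (error rate 0, cutoff 0 recovers the truth
set exactly) stays exact while the 1-bp merge rule is still exercised by
error-bearing runs.

`simulate_genome()` plants consensus-sequence templates (full RSS,
RUNX1-overlapping heptamer within an RSS module, lone heptamer) into an
i.i.d. background at a given GC, guaranteeing above-threshold hits
irrespective of similarity fine detail. `simulate_deletion_cohort()` places
non-overlapping deletions and plants RUNX1 site classes at controlled border
distances. Passing tests on these synthetic data demonstrate the scanning,
counting and statistical machinery; they do not certify motif calls on real
genomes, whose repeat structure and base composition differ.

## Problem sizes and numerical notes

The test and acceptance runs use desk-scale problem sizes chosen so the full
suite completes in a few minutes on one CPU: repertoires of 500–2000
clonotypes and 1500–3000 read pairs, genomes of 40–60 kb, cohorts of 30–56
deletions, and 100–1000 statistical replicates. The parameter-recovery study
simulates two 10-sample cohorts (2000 vs 500 clonotypes per sample) carrying
the knockout-scale effect folds (richness 4.0, functional ratio 2.9,
N length 1.2, D 5′ truncation 1.2, D1/D2 ratio 2.5) and recovers each fold
from per-sample medians within 20% relative error. Two small systematic
effects are worth knowing: conditioning on a visible D (kept ≥ 5 nt) censors
the deepest truncations, compressing the recovered truncation fold from 1.20
toward ≈ 1.16; and for clonotypes whose kept D falls below 5 nt the whole
junction is reported as N1, slightly inflating mean N length in both cohorts.
Both effects apply to real data processed by the same rules.

Exact tails (binomial, Poisson, hypergeometric) are computed in log space;
the Mann-Whitney test switches from exact enumeration to the tie- and
continuity-corrected normal approximation above 12 pooled observations or in
the presence of ties, and the mode is reported. Raw p-values are reported unadjusted; a Benjamini–Hochberg column is added
for convenience and clearly labelled.

## Known limitations

* V-allele disambiguation, somatic hypermutation and UMI handling are out of
  scope (the assay modelled uses none).
* The packaged germline registry is a toy locus for tests and examples; real
  IMGT-derived references are supplied by the user in the same TSV format.
* Genome-wide background counts on a real reference genome are supported as
  user input but are not a test dependency.
* Diversity indices beyond richness (Shannon, clonality) are not computed.

## A worked pass through both arms

```{r pipeline, eval = FALSE}
reg <- load_germline_registry()
p <- sim_params(n_clonotypes = 50, read_depth = 3000, seed = 1)
truth <- simulate_repertoire(p)
reads <- simulate_reads(truth, p)
clonotypes <- profile_repertoire(reads, reg)
summarize_repertoire(clonotypes, sample_name = "demo")

g <- simulate_genome(genome_sim_params(
  length = 40000, n_planted_rss = 60, n_planted_runx1_overlap = 12, seed = 2
))
bg <- scan_background_genome(g$genome)
coh <- simulate_deletion_cohort(
  g$genome, 30, enriched_fraction = 0.5, distance_law = 10, seed = 3
)
regions <- build_deletion_end_regions(coh$deletions, coh$genome)
enr <- deletion_border_enrichment(regions, bg)
tidy(enr$rss_modules)
```
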