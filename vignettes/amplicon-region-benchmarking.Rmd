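---
title: "Benchmarking 16S regions, classifiers and reference databases for species-level vaginal microbiota profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking 16S regions, classifiers and reference databases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplibench)
library(dplyr)
```

## The problem

Vaginal microbiota studies hinge on species-level distinctions: within one
genus, *Lactobacillus crispatus* is protective while *L. iners* is associated
with adverse outcomes, so genus-level profiles are not actionable. Yet most
amplicon studies sequence a short hypervariable region of the 16S rRNA gene
(V1–V3, V3–V4, V4, ...), and species-level resolution depends jointly on

1. **which region** is amplified (regions differ in how well they separate
   closely related species),
2. **which classifier** assigns taxonomy (alignment top-hit consensus versus
   k-mer naive Bayes), and
3. **which reference database** is used (Greengenes2, SILVA and RDP each
   resolve different species well).

amplibench packages that three-way benchmark: in-silico PCR over a built-in
panel of published primer sets, two self-contained classifiers, per-species
accuracy scoring, and a *combination rule* that delegates each species call
to whichever database classifies that species most accurately for the chosen
region. The combination is the interesting scientific object: because
database strengths are complementary, the combined pipeline dominates every
single database.

## The primer panel and in-silico PCR

`builtin_panel()` carries eight primer sets: full-length 27F/1492R plus
seven partial regions (V1–V2, V1–V3, V3–V4, V4, V4–V6, V5–V7, V7–V9). The
V1–V2 and V1–V3 sets use a 27F mixture — fourfold 27F-A plus onefold 27F-B —
because no single oligo covers both sequence variants of the 27F site (the
two variants are incompatible at one position). In-silico site detection
takes the union over forward primers; the 4:1 weights only steer which
primer label the read simulator records.

`amplify()` scans both strands, allowing up to `max_mismatch` mismatches per
primer (default 1) but none within the 3'-terminal `clamp` bases (default
4), since 3' mismatches abort extension. Each forward site pairs with the
nearest downstream reverse site (shortest product, the polymerase-realistic
choice); `all_products = TRUE` overrides. Products are primer-inclusive and
bounded to 50–5000 bp by default. Coordinates are 1-based inclusive on the
plus strand, the R/Bioconductor convention. The published description of
mismatch handling in the original SeqKit-based workflow is not quantified;
our default (1 mismatch, 4-base clamp) is a documented choice of this
toolkit, not a claim about any other tool's settings.

Degenerate matching follows IUPAC expansion, with one conservative rule: a
template `N` matches nothing except a primer `N`, because an unknown
template base should not be credited as a binding site.

## Classifiers

Both classifiers are hermetic (no external binaries), standing in for the
usual QIIME2 arms.

**Naive Bayes (`train_nb()` / `classify_nb()`).** A multinomial model over
overlapping k-mers, one class per distinct training lineage, Laplace
smoothing `alpha`. Defaults k = 8, alpha = 0.001, confidence threshold 0.7,
100 bootstrap k-mer subsamples of 1/8 of the query's k-mers — the
conventions of the RDP-style classifier family. Counts are plus-strand only;
queries are orientation-normalized first (forward versus reverse complement
by shared k-mer types with the training vocabulary). Confidence per rank is
bootstrap agreement with the point prediction; the lineage is truncated
below the first rank failing the threshold. Ties break lexicographically on
the full lineage string, which makes predictions independent of
training-record order and of the random seed.

**Top-hit consensus (`classify_tophit()`).** Candidates are ranked by shared
k-mers, globally aligned (match +1, mismatch −1, gap open −5, gap extend
−2), and hits within `top_margin` (default 0.005) of the best identity —
capped at `max_accepts` — vote rank-wise; a rank is assigned at ≥ 51%
agreement. The margin matters: without it, a generous `max_accepts` drags
distant (~89% identity) inter-species hits into the vote and species rank
never reaches consensus. With `max_accepts = 1` the classifier reduces to
nearest-neighbor assignment.

## The combination rule

`score_accuracy()` computes per-species accuracy for every
(region, method, database) pipeline; a prediction truncated above species
counts as a miss, as does a missing prediction. `build_lookup()` maps each
species to its argmax-accuracy database, breaking exact ties by a priority
list (default RDP, SILVA, Greengenes2; configurable) and flagging species no
database gets right. At inference time, `combine_classifications()` accepts
a database's species call only when that database is the designated
authority for the species it called; among several accepted candidates the
highest stored (species, database) accuracy wins, and with none the fallback
database's call is returned, flagged. The published work reports the
accuracies of the combined pipeline but not an explicit inference-time
conflict rule; this authority-based rule is our documented interpretation,
and the fallback defaults to the best single pipeline for the region.

One caveat we verified rather than assumed: the rule does not *guarantee*
that combined per-species accuracy is at least the best single database for
every species (a database that is the authority for its own wrong call can
win a tie-break), so the dominance claim is tested at the level it holds —
mean accuracy across species, over many simulated worlds.

## Community-level comparison and validation

`profile_from_classifications()` builds species-level relative-abundance
profiles with an explicit `unclassified` key so mass is conserved.
`dissimilarity()` offers the four distances used for partial-versus-full
comparison — Bray-Curtis, Euclidean, abundance-weighted Jaccard
(2B/(1+B)), and quantitative Kulczynski — delegated to `vegan::vegdist`,
whose definitions these are; `pcoa()` is classical metric scaling
(`stats::cmdscale`) with no negative-eigenvalue correction and a
deterministic sign convention (each axis's largest-magnitude coordinate is
positive). `sti_positivity()` calls a pathogen present at relative abundance
≥ 0.1% (inclusive), and `confusion_metrics()` implements the seven
concordance formulas — sensitivity, specificity, precision, recall, F1,
accuracy and Cohen's kappa = (accuracy − Pe)/(1 − Pe) with
Pe = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN))/total² — with NaN sentinels and a
warning for zero denominators.

## What the synthetic worlds emulate — and what they do not

`make_reference_world()` builds ~1.5 kb block-structured sequences:
conserved blocks carrying every panel primer site at realistic spacings
(V1–V3 span ≈ 515 bp, V4 ≈ 296 bp), alternating with nine variable blocks
mutated off a shared backbone at 10% per base. The defaults — 20 species
drawn from a vaginal species pool headed by the key Lactobacillus quartet,
2 sister pairs, 3 records per species with 0.5% record noise, 15% defect
subsets — are the package's standing study conditions and are not tuned per
analysis.

Three constructions make the worlds scientifically useful:

* **Sister pairs** differ only in the V1 block, so V1-containing regions
  separate them and the others cannot — the key-Lactobacillus phenomenon,
  and the reason 223 bp forward reads over V1–V3 retain species resolution
  (the discriminating block sits inside the prefix).
* **Complementary database defects**: Greengenes2 mislabels a species
  subset, SILVA omits one, RDP truncates one at genus; the subsets are
  disjoint, so every species has a competent database and no database is
  best for all — the precondition for combination uplift.
* **Primer-site sharing**: overlapping primer sets share physical sites
  exactly as on the real gene (338F is revcomp(338R) plus one base; 533F
  extends 515F; 1115F coincides with revcomp(1100R)). Primer dropout
  therefore scrambles a physical site, and regions sharing it drop
  together — which is also why dropout-prone regions underestimate specific
  taxa while full-length profiles do not.

The generator does **not** mimic real 16S base composition, phylogenetic
covariance between regions, chimeras, length variation, or platform error
profiles (errors are iid substitutions). Passing tests therefore demonstrate
the correctness and the qualitative behavior of the machinery — not
quantitative accuracy on any real database release, which depends on
database snapshots outside desk scale.

## Numerical choices and edge cases

* Tie-breaks are lexicographic everywhere (class labels, consensus taxa,
  database priority), so no result depends on storage order or RNG state.
* `alpha = 0` is allowed in the NB model; absent k-mers then score −Inf,
  and bootstrap resamples clamp −Inf · 0 to 0 rather than NaN.
* Records shorter than 200 bp are dropped by `deduplicate()`; duplicate
  detection is exact string equality after upper-casing, first occurrence
  kept, and the filter is idempotent.
* The annotation filter defaults to OR-discard (a hit failing either the
  1e-10 e-value or the 99% identity threshold is discarded); the literal
  "and" reading is available via `logic = "and"`. The vague-name blacklist
  (`sp.`, `uncultured`, bracketed genera, ...) is configurable because no
  authoritative list exists.
* Dissimilarities error on an all-zero profile (undefined denominators);
  PCoA validates symmetry and the zero diagonal and reports negative
  eigenvalues unchanged (Cailliez-style corrections are deliberately out of
  scope).
* All randomness flows from explicit seeds; worlds, read sets and
  classification runs regenerate byte-identically.

## Problem sizes used by the test suite

The shipped checks run at deliberately modest scale, chosen as
representative rather than exhaustive: 200 random 2 kb templates against a
brute-force IUPAC-expansion oracle; ≤ 5-class k = 4 toys against brute-force
log-likelihoods; 1,000 random confusion matrices against an independent
implementation; 20-seed world batteries for the combination-uplift claim
and 10 seeds for truncation robustness; 1,000-read zero-error mocks for
composition recovery in every region. The same quantities are recomputed
from scratch by `scripts/acceptance.R`.

## Known limitations

* The combination rule is an interpretation; other merge rules (e.g.
  confidence-weighted voting) are plausible and not implemented.
* Held-out evaluation (building the lookup on one amplicon set and scoring
  on another) is supported by calling `build_lookup()` and
  `combine_classifications()` on different query sets, but the default
  `run_evaluation()` scores on the lookup-building set, as the original
  design does — dominance there is partly by construction.
* `classify_tophit()` computes identity over the full global alignment;
  for amplicon-versus-full-gene comparisons this behaves glocally because
  end gaps fall outside the counted aligned region, but extreme length
  mismatches can still depress identity.
* No attempt is made to reproduce version-specific defaults of external
  classifiers; agreement with them is qualitative.
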