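---
title: "Methods: MPSS tag-count profiling, exact-test differential expression, and signature-based gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MPSS tag-count profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and the analysis problem

Massively parallel signature sequencing (MPSS) counts transcripts by
sequencing a fixed-length tag — a 21 bp *signature* beginning at a DpnII
restriction site (GATC) near the 3' end of each cDNA. A library is a list
of distinct signatures with integer counts; abundance is the count divided
by the library total, scaled to tags per million (TPM). The design this
package targets is a four-library comparison of a dinoflagellate
(*Alexandrium tamarense*) grown nutrient-replete (F, the control),
nitrogen-limited (N), phosphorus-limited (P), and with its bacterial
community present (xenic, X). Dinoflagellate genomes carry very large gene
families, and because family members differ by only a few substitutions in
the 3' UTR, their signatures differ by a correspondingly small number of
mismatches — which makes tag mismatch structure usable for family
inference, and family-level expression coherence testable.

The pipeline has five analysis stages, each exposed as plain functions:

1. **Signature QC and normalization** (`filter_deterministic`,
   `filter_homopolymer`, `normalize_tpm`, `filter_min_abundance`).
2. **Differential expression** per signature and library pair by two-sided
   Fisher's exact test with BH false-discovery-rate control
   (`run_pairwise_de`), plus condition-exclusive calls (`find_exclusive`).
3. **Signature-to-unigene mapping** by an exhaustive DpnII-anchored scan
   with mismatch validation (`match_signatures`, `transfer_annotations`).
4. **Gene-family inference** from pairwise signature Hamming distances:
   threshold calibration on an annotated subset, then single-linkage
   clustering (`mismatch_distributions`, `calibrate_threshold`,
   `cluster_families`).
5. **Within-family co-regulation scoring** across the four conditions
   (`family_correlation`, `coregulation_screen`).

`run_pipeline()` composes the stages; `generate_dataset()` provides
ground-truthed synthetic libraries so that every stage is testable.

## QC and normalization

Signatures containing any character other than A/C/G/T are removed
(ambiguity codes mark unreliable base calls), as are signatures containing
a single-nucleotide run longer than 7 nt (likely synthesis/sequencing
artifacts; a run of exactly 7 is kept — the rule is a strict inequality).
TPM is count / library-total x 10^6, with the total taken over the
signatures that survive the two sequence filters; the abundance filter
(keep signatures reaching at least 4 TPM in at least one library) is
applied *after* normalization and does not change the denominator. The
sequence filters are deterministic, so applying them before normalization
gives every downstream value a reproducible denominator; this ordering is
one consistent reading of how the filters are usually stated, and both
filters commute with each other in any case.

`summarize_libraries()` reports, per library, the expressed ("unique"),
exclusively expressed ("specific") and shared ("common") signature counts
plus abundance bins (>= 10, 100, 1000 TPM by default). "Expressed" means
TPM > 0 on the retained set — the bin thresholds use >=, treating the
operational footnote-style definition ("at least") as authoritative over
the cosmetic ">" column labels such tables usually carry.

## Differential expression

For a signature with integerized TPM `a` in a treatment and `c` in the
control, the test statistic is the two-sided Fisher exact p-value of

    [ a, 10^6 - a ]
    [ c, 10^6 - c ]

i.e. signature versus rest-of-library for two libraries whose totals are
fixed at the TPM scale. Choices worth stating:

* **TPM-scale tables.** Published per-signature examples print TPM values
  directly beside their p-values, implying tables on the TPM scale with
  totals of 10^6. TPM values are integerized by rounding half away from
  zero (base R's `round` is round-half-even, which is not what a reader of
  a printed table expects). Note the caveat: a Fisher table at scale 10^6
  is calibrated when the physical library depth is at or above that scale
  (true both in the motivating study, ~3x10^6 reads, and in the
  generator's default 10^6). If TPM were computed from much shallower
  libraries and rescaled, the table would overstate the evidence.
* **Two-sided by minimum likelihood.** The p-value sums hypergeometric
  point probabilities not exceeding the observed table's, with a 1e-7
  relative tie tolerance — the convention of mainstream exact-test
  implementations. Equal counts return exactly 1. The computation is done
  in log space because deeply significant TPM pairs underflow double
  precision (observed examples reach p ~ 1e-230); p-values are floored at
  the smallest positive normal double.
* **BH per comparison.** The BH step-up adjustment is applied within each
  treatment-vs-control family of tests, not globally across the three
  comparisons — "a consistent threshold between all pairwise comparisons"
  reads most naturally as per-comparison adjustment. Classification uses
  the adjusted p-value against the stringent threshold 1e-10 (with 0.05 as
  the permissive companion threshold).
* **Fold changes.** `log2_fold_change` is undefined (NA) when either side
  is zero: presence/absence is reported through the exclusivity path, not
  as an infinite ratio. Reported magnitudes are positive with a direction
  flag, matching how such tables are printed.

Condition-exclusive signatures — nonzero TPM in exactly one library of the
retained matrix — are reported separately because they are the strongest
form of condition-specific transcription.

## Mapping signatures to unigenes

A valid hit requires (i) an exact GATC anchor at the hit site, and (ii) at
most 3 mismatches between the signature and the unigene window over the
full tag length, substitutions only. Rather than approximating this with a
relaxed heuristic alignment search and post-filtering, the matcher scans
every GATC site on both strands of every unigene — exact, deterministic,
and cheap for fixed-length tags (one Hamming-matrix call against the
precomputed site windows). Hits are ranked by identity; ties break by
unigene id and then by the 3'-most offset, since MPSS tags derive from the
3'-most DpnII site of a transcript. The rank-1 hit donates its unigene's
annotation to the signature; unmatched signatures are "unknown".

One documented ambiguity: the tag literature describes both "21 bp
signatures" and "20/20 matching nucleotides" for perfect hits. The
compared-region length here is the full configured `signature_length`
(default 21); the length is configuration, not a constant, precisely so
either reading can be reproduced.

## Gene families from signature distances

On an annotated subset (signatures with family labels, e.g. from KEGG
orthology of their matched unigenes), all pairwise Hamming distances are
split into within-family and between-family distributions. For each
candidate threshold `t`, a 2x2 table (pairs <= t vs > t, within vs
between) gets a one-sided Fisher exact p-value for enrichment of
within-family pairs at small distances. The chosen threshold is the
*largest significant `t` that minimizes total misclassification*
(within-pairs above `t` plus between-pairs at or below `t`). The
selection rule and the full per-`t` table are both exposed because the
rule by which a published cutoff (five mismatches, in the motivating
study) was chosen is rarely stated; under a regime where families cohere
within five mismatches and unrelated signatures sit just above it, this
rule selects five.

Families are then the connected components of the graph joining signature
pairs at distance <= t — single linkage, because "maximum number of
pairwise mismatches" used as a clustering rule reads most naturally as a
distance cutoff, and transitive chaining is the biologically conservative
choice for duplicated-gene lineages. Family ids are deterministic
(lexicographically smallest member), so assignments are invariant to input
order. The all-pairs distance matrix is computed by a small C++ kernel;
at the package's desk scale (a few thousand retained signatures) this is
well under a second, and the quadratic cost is the honest algorithm — no
approximate bucketing is silently substituted.

## Co-regulation within families

For a family with members' TPM profiles over the four conditions, the
score is the mean of all pairwise Pearson correlations, squared
(`r_squared`); for the two-member families that dominate such tables this
reduces to the familiar pairwise r^2. Two p-like quantities are reported:

* `p_convention = 1 - r_squared`. In the published table this package
  mirrors, every printed p-value equals 1 - r^2 at the printed precision;
  that is a reporting convention, not a test, and it is labelled as such.
* `perm_p`: a seeded permutation p-value — condition labels shuffled
  independently per member, counting permutations whose mean pairwise r
  reaches the observed value, with the +1 correction so p stays in (0, 1].

With only four conditions the permutation null is discrete (24 relative
orderings per member pair), so permutation p-values cannot go below about
1/24 for a pair and the nominal 5% level is reached only approximately
from below. This fragility is inherent to n = 4 profiles and is the
reason both quantities are reported rather than either being presented as
a significance test. Profiles are raw TPM by default, matching how such
family heatmaps are usually drawn; `log_tpm = TRUE` scores log2(TPM + 1)
instead. Constant (zero-variance) profiles have no defined correlation and
are excluded with a warning.

## The synthetic-data generator

`generate_dataset()` emulates the statistical structure the analysis
assumes, with ground truth for every planted property:

```{r}
library(mpssr)
cfg <- simulation_config(seed = 1)
ds <- generate_dataset(cfg)
```

* **Scale.** Defaults: 2,000 genes, four libraries of 10^6 reads. This is
  a deliberate desk-scale rendition of a full MPSS experiment (tens of
  thousands of retained signatures from ~3x10^6 reads): per-signature
  counts land in the same TPM regime as the published worked examples, so
  power and calibration behave comparably while a full dataset generates
  in seconds.
* **Baselines.** Log-normal (meanlog log 125, sdlog 1.6), floored at 10
  TPM and capped at 15,000 TPM. The log-normal reproduces a heavy-tailed
  abundance spectrum (tens of signatures above 1,000 TPM); the floor keeps
  every planted gene reliably above the 4 TPM retention threshold in all
  libraries (so exclusivity ground truth is unambiguous), and the cap
  keeps any one transcript from dominating a library. The true underlying
  abundance law of the organism is unknown; the log-normal is a modelling
  stand-in, not a claim.
* **Family geometry.** Family sizes are geometric (mean 2.5). Each family
  has a centroid tail and a private set of 5 variable positions; members
  differ from the centroid at 1-2 of those positions, so within-family
  pairwise distances are at most 4-5 mismatches by construction. Between
  families, every realized signature is rejection-sampled to lie at
  Hamming distance >= 8 from all other families' signatures (largest
  families are placed first, while the space is empty). At 2,000+ tags of
  tail length 17 this packing is close to the combinatorial limit — the
  greedy sampler is the reason the generator can guarantee the
  within/between gap exactly rather than approximately. Signatures never
  mutate their GATC anchor and never contain a second GATC.
* **Fold changes.** Per treatment, a configurable fraction of genes
  (default 10%) receives a planted log2 fold change, sign symmetric,
  magnitude uniform on [0.5, 3.5] — the span of the published per-signature
  examples. DE genes are drawn from baselines in [40, 5000] TPM, the
  abundance regime of those examples (all printed pairs involve >= 31
  TPM); this also keeps a strongly down-regulated gene from sampling zero
  and masquerading as condition-exclusive.
* **Exclusive genes.** Defaults F = 18, N = 2, P = 12, X = 487 (the
  motivating study's counts). Exclusive genes have expected TPM exactly 0
  outside their condition and a baseline floored at 50 TPM inside it, so
  exactly the configured numbers are recoverable.
* **Compositional closure (ballast).** Tag counting is compositional: a
  fixed read depth means that planting extra mass in one library (487
  exclusives in X, asymmetric fold changes) deflates every other
  signature's expected TPM there, which would silently distort all planted
  null ratios. A small set of balancing transcripts (default 20, labelled
  `role = "ballast"` in the ground truth) absorbs the per-condition
  intensity imbalance so that planted expected-TPM ratios equal the
  planted fold changes exactly. Ballast transcripts are ordinary clean
  signatures with unigenes; they are simply excluded from planted-DE
  bookkeeping.
* **Artifacts.** Ambiguous-base signatures (default 100), homopolymer
  signatures (default 50) and sub-threshold background signatures
  (default 3,000) are injected. Background tags carry expected counts of
  0.01-0.06 reads per library — stray singleton-level noise. This is
  deliberately *lighter* than a real MPSS run, where discarded signatures
  outnumber retained ones roughly 6:1: background tags with realistic
  per-tag means (0.5-3 reads) would occasionally sample >= 4 reads in one
  library and zero elsewhere, mimicking condition-exclusive transcripts at
  a rate of ~10^-3 per tag and contaminating exclusivity ground truth.
  The generator therefore exercises the QC filters without quantitatively
  matching the raw-to-retained ratio; tests that pass on it say nothing
  about that ratio in real data.
* **Sampling.** Each library is one multinomial of `library_depth` reads
  over all signatures (fixed sequencing depth, realistic count
  covariance). Everything derives from `config$seed`; the same seed gives
  byte-identical datasets. Expected TPM recorded in the ground truth is
  the planted intensity rescaled by the clean-signature mass — exactly
  what the QC + normalization pipeline estimates in expectation.

What the generator does **not** emulate: sequencing errors inside tags
(beyond whole-tag artifacts), bead/hybridization chemistry, EST assembly
noise in the unigenes, the raw:retained signature ratio, and any real
phylogenetic structure within families beyond the mismatch geometry.

## Numerical and degenerate-input policy

* Exact-test ties: relative tolerance 1e-7; p floored at the smallest
  normal double; equal counts short-circuit to p = 1.
* TPM integerization: round half away from zero.
* Empty inputs: filters and summaries pass empty tables through; an empty
  unigene set or a missing control library is an error naming the problem.
* A library with zero total counts is an error naming the library.
* Calibration with no significant threshold fails with a diagnostic
  rather than guessing; the pipeline then falls back to the configured
  threshold with a warning.
* All signature comparisons require equal lengths; length mismatches are
  errors, never silent truncation.

## Problem sizes used in the shipped checks

The package's own test suite regenerates data rather than shipping it:
power and null checks use ten datasets each at the default scale (2,000
genes, 10^6 reads); structural checks (mapping recovery, family
recovery, calibration) use 150-400 gene configurations, which preserve
the mismatch geometry and TPM regime while running in seconds. The
reported sensitivity of the stringent DE call (adjusted p < 1e-10) on
planted |log2FC| >= 2 at >= 500 TPM baselines is essentially complete,
and the same threshold produces no calls under the null configuration —
consistent with how conservative an exact test at this depth is.

## Known limitations

* Fisher on TPM-scale integers treats the TPM total as the observation
  count; with physical depths below the TPM scale the test is
  anticonservative (not the regime here, but worth knowing before reusing
  the functions on shallow libraries).
* The permutation co-regulation p is nearly vacuous for two-member
  families over four conditions (minimum ~0.04); it is reported for
  honesty, not power.
* Single-linkage families chain: one intermediate signature merges two
  otherwise-distant families. That is the documented behaviour of the
  distance-cutoff reading, not a bug; complete-linkage variants can be
  built from the exposed distance matrices if needed.
* The `1 - r^2` "p-value" is a published reporting convention mirrored for
  comparability; it has no sampling-theory justification.
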