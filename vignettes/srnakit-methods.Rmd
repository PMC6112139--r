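---
title: "srnakit: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnakit: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical models and algorithmic choices
behind srnakit: what each stage assumes, which tunable parameters matter
and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and where the design was genuinely
open and a choice had to be made.

## 1. Pre-alignment

Reads are 3'-adapter trimmed by a suffix-anchored scan: the leftmost
position where the adapter prefix aligns to the rest of the read with
overlap ≥ `adapter_min_overlap` (default 8 nt) and mismatch rate ≤
`adapter_max_mismatch_rate` (default 0.1) is the cut point. Reads with
no adapter hit are kept unchanged by default (`require_adapter = FALSE`):
small RNA libraries routinely contain reads read through or already
trimmed upstream, and discarding them is an opt-in. After trimming,
reads are rejected outside a 16–40 nt window (spanning mature miRNAs,
isomiRs and tRNA-fragment-length species), with mean phred < 20, or
containing `N`. The quality filter is a mean-phred threshold — a simple,
monotone summary chosen because nothing finer is contractually required.

Surviving reads collapse into unique sequences with exact per-sample
counts, sorted by total count then sequence, so collapsed output is
invariant to stream order. All later stages work on unique reads; counts
are carried, never re-estimated.

## 2. Cascade annotation

Libraries are searched in a fixed order: spike-ins (optional), mature
miRNAs (exact full-length equality), then exact substring containment in
hairpins, mature tRNAs, precursor tRNAs, snoRNAs, rRNAs, other ncRNAs
and mRNAs, and finally an isomiR-tolerant mature-miRNA pass. Running the
tolerant pass *last* is deliberate: a 1-mismatch miRNA match must not
steal reads that are exact matches to another RNA class. Each read is
assigned at most once.

The isomiR tolerance is ≤1 internal mismatch, ≤3 soft-clipped 3' bases,
5' offset in [−2, +2], minimum aligned core 14 nt. These are declared,
logged defaults (`annotate_config()`), not published constants. Ties
within the pass go to the lexicographically first target with an
`ambiguous` flag — deterministic and auditable; fractional counting was
rejected because downstream editing and isomiR analyses need integer
read-to-target attributions.

Library curation before alignment: mature tRNAs get `CCA` appended
(the post-transcriptional tail present in reads but absent from genomic
reference sets); SNP variants of mature miRNAs are added as
`<id>.SNP<n>` entries whose counts are attributed to the parent (they
are alleles, not isomiRs — for the same reason an exact match to a
variant entry counts as *canonical*); near-identical matures (Hamming
distance ≤1 over the shared prefix, transitive closure) are merged into
`a/b`-named entries, the conventional way cross-mapping pairs like
miR-192-5p/miR-215-5p are reported. The merge distance is configurable
because "similar" has no single published definition; 1 mismatch
reproduces the classic example pair.

The canonical-ratio filter marks miRNAs where exact full-length reads
are less than `threshold` (default 0.1, range limited to [0, 0.5]) of
all assigned reads; such rows are zeroed in the primary table but kept
in a diagnostics attribute. RPM is computed per sample over unfiltered
miRNAs, so RPM columns sum to 1e6; spike-ins never enter the
denominator.

## 3. IsomiR GFF3

Variant tags are emitted in fixed order (`iso_5p`, `iso_3p`,
`iso_add3p`, `iso_snp`), with `iso_5p:+n` meaning the read starts n nt
*upstream* of the canonical 5' end (one convention, tested; no mirroring
option). Templated-versus-non-templated 3' classification is decided
against the precursor: the maximal suffix of the read disagreeing with
the precursor is the non-templated tail, whatever the annotate stage
soft-clipped.

The CIGAR dialect is run-length `nM` with substituted positions written
as the read's base letter (`13MA8M`). Non-templated additions are *not*
inside the precursor span: coordinates are clamped to the templated
part and the tail is declared by `iso_add3p` and carried in the `Read`
attribute. The design goal was a round-trippable record: for every Pass
record, `reconstruct_isomir()` applied to the precursor slice must
reproduce the read byte-for-byte, and the test suite enforces this for
every synthetic isomiR.

## 4. A-to-I editing

Editing is tallied per (miRNA, A-position) from the aligned cores of
assigned reads; 3' soft-clips never contribute. Reads that matched a
*precursor* exactly also contribute coverage at the mature positions
they overlap. This matters: a read with a templated 3' extension is an
exact precursor substring and is annotated at the hairpin stage, while
its edited twin (one mismatch) can only be caught by the tolerant
mature pass. Tallying only mature-assigned reads would therefore deplete
the denominator of exactly the unedited reads and bias fractions upward
— a bias the recovery tests caught (CI coverage 69/100 before the fix,
≈99/100 after).

The four exclusion criteria are independent set operations (blacklisted
family/SNP positions; repeat-element miRNAs; canonical RPM < 1 in every
sample, where canonical RPM = RPM × canonical ratio; and the
A→G-switched mature sequence, trimmed of its last two 3' bases, matching
more than one genomic locus exactly on either strand). Order of
application cannot change the result, and the tests verify this.

Significance: the upstream description names no test, so srnakit
declares one — a one-sided binomial test of the G count against a
configurable sequencing error rate (default 0.001), BH-corrected across
all tested site/sample pairs, with a hard ≥1% fraction floor in at least
one sample. This is a stand-in and is flagged as such; both pooled and
per-sample fractions are reported so users can re-test externally.

## 5. Read clusters and the stable range

Unannotated reads are placed on the genome by exact match (both
strands), with one extension: reads with no full-length hit are retried
with up to 3 soft-clipped 3' bases, and the *full* read span is
recorded. Strict exact-only placement would exclude every read carrying
a non-templated tail, which makes the tail-composition features
(`tail_plus{1,2,3}_A_percentage`) identically zero and removes the very
signal that distinguishes miRNA clusters. The soft-clip plays the role
that an aligner's mismatch tolerance plays in pipelines built on bowtie.
Reads at more than 20 loci are discarded as repetitive (an operational
stand-in for repeat-element exclusion; configurable).

Placements within 10 nt on the same chromosome and strand merge
transitively into clusters; minus-strand clusters are represented in
transcript orientation. The stable range is computed by per-position
majority vote: covering reads vote their base, non-covering cluster
members vote an explicit "absent" symbol, all weighted by read counts,
and the stable range is the longest contiguous run where the major
symbol is a real base with probability ≥ 0.8 (leftmost run on ties).
Counting "absent" as a symbol means ragged ends destabilize flanks —
which is precisely what separates a tight miRNA 5' end from a loose
fragment end. Count-weighting (rather than weighting each distinct
sequence once) was chosen because abundance is the evidence the
statistic is meant to summarize.

## 6. Folding and structural features

The default folding engine maximizes base pairs (Watson–Crick plus G:T
wobble, minimum hairpin loop 3 nt) by dynamic programming and reports a
pseudo-MFE of −(pairs) − 0.5·(stacked adjacencies). It is *not* a
thermodynamic model; it is deterministic, dependency-free, and exact for
its own objective (the test suite checks it against exhaustive
enumeration on all short sequences). A thermodynamic folder can be
plugged in via the `engine` argument of `fold()`; every
structure-derived feature is computed from the dot-bracket string alone,
so the feature definitions are engine-independent.

Two windows are folded per cluster — stable range + (10 up, 70 down)
and (70 up, 10 down) — modelling the range as the 5p or 3p arm; the
lower pseudo-MFE wins, ties prefer the 5p model (arbitrary but
deterministic and documented). Structure statistics come from a
loop/stem decomposition of the dot-bracket: hairpin loops (unpaired run
directly enclosed by a pair), interior loops *including bulges*
(unpaired gap between consecutive pair blocks on a single branch — the
inclusive definition keeps the count monotone under small bulges),
stem length (pairs along the deepest root-to-hairpin path), pairs
overlapping the stable range, and the distance from the stable range to
the main terminal loop (the hairpin under the deepest stem). The arm
type is `loop` when the stable range sits inside that terminal loop.

Compositional features are count-weighted fractions over reads covering
each flank position (−3..−1, +1..+6 relative to the stable range):
genomic-template agreement, A/T/C/G composition, and non-templated-A
fractions at +1..+3 (zero by definition where the genome base is A).
Positions with no covering read yield 0 plus a companion `covered_*`
indicator rather than NA, so downstream matrices have no missing values
and the classifier can learn from "nobody extends past the 3' end" as a
signal in its own right.

## 7. Classifier

Feature ranking is mRMR in the MID (difference) form: equal-frequency
10-bin discretization, mutual information relevance minus mean mutual
information redundancy against the already-ranked set, ties broken by
feature name. The variant and estimator are unstated upstream; MID with
equal-frequency bins is the common default and is deterministic.

Forward stepwise selection evaluates the top-k ranked features for
k = 1..K on ten random 4:1 train/validation splits and picks the
smallest k within `selection_epsilon` (default 0.005) of the best mean
validation MCC. Each k is evaluated with fixed SVM defaults (C = 1,
γ = 1/k) rather than a nested grid search: nesting would multiply
compute ~500-fold, and the selection only needs relative comparisons
across k. The final model *is* grid-searched: 10-fold cross-validation
over C, γ ∈ {1e-4, 1e-3, 0.01, 0.1, 1, 10, 100, 1000}, maximizing MCC
(not accuracy), then refitting on all training data. Standardization to
zero mean/unit variance is fitted on training data only.

The SVM itself is an SMO-trained C-SVM with RBF kernel implemented in
C++ (deterministic working-set selection, precomputed kernel matrix),
because no kernel-SVM package is available in the target environment and
the classifier is part of the method rather than infrastructure. It is
sized for desk-scale n (hundreds of clusters); the decision threshold is
0 (SVM convention). Missing feature values at prediction time are
imputed as 0, matching the training-side convention of
zero-plus-indicator.

Quality scores are `1 − rank/N` over decision values, ties sharing mean
ranks, so the best of N candidates scores (N−1)/N and the worst 0.

## 8. The synthetic world

The generator plants hairpin loci (22 nt arm + 14 nt loop + perturbed
reverse-complement arm, ~10% of 3' arm positions wobbled) in random
background, plus negative loci: tRNA-like (CCA-capped), snoRNA-like,
short fragments, and one duplicated locus to exercise multimapping
logic. miRNA loci emit reads with tight 5' starts (92% exact), ragged
3' ends (±2 nt), non-templated A/U tails (lengths 0–3 with probabilities
0.55/0.25/0.15/0.05, 70% A) and optional planted A→G edits — never in
the last two 3' bases, so the criterion-4 trimming logic is exercised
independently. Negative loci emit fragments around a random processing
hotspot with ±4 nt jitter on *both* ends. A note on that choice: reads
spread uniformly over a whole negative locus never reach the 0.8
majority threshold, so every negative cluster would be rejected as
having no stable range and no negative training class would exist; real
tRNA/snoRNA fragments do pile up near cleavage sites, so the hotspot
model is both necessary and the more realistic description. The
generator is deterministic under its seed.

What a green test does establish: the implementation computes its own
contracts exactly (oracle agreement), the pipeline recovers planted
compositions, editing fractions and cluster labels, and the classifier
separates the two planted populations. What it does not establish:
performance on real libraries — real data have sequence-dependent error
profiles, expression spanning six orders of magnitude, degradation
products, and miRNAs whose isomiR spectra are biological rather than
parametric. Numbers obtained on the synthetic world are statements about
internal consistency, not external benchmarks.

## 9. Degenerate inputs and numerical conventions

Empty FASTA libraries warn and produce empty libraries; empty read sets
produce empty (but structurally complete) outputs everywhere. A sample
with zero miRNA-mapped reads gets zero RPM with a warning rather than
NaN. MCC returns 0 when any denominator factor is zero. Clusters with no
position above the stability threshold are rejected with a reason code,
as are candidates failing the ≥10 reads / ≥3 distinct sequences filter
(boundaries inclusive). Fold windows truncated at chromosome bounds warn
and shift coordinates consistently. All randomized procedures (splits,
folds, simulations) derive from explicit integer seeds recorded in run
manifests, and byte-identical outputs across repeated runs are part of
the test suite.

## 10. Known limitations

The folding engine's pseudo-MFE is on its own scale; models trained with
the default engine should not score features folded by a thermodynamic
engine (and vice versa). Merging of similar miRNAs uses a single
mismatch threshold rather than curated family knowledge. The editing
significance test is a declared stand-in. 5' isomiR
templated/non-templated subclassification beyond the offset sign is not
attempted. Paired-end reads, UMIs and 5' adapters are out of scope.
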