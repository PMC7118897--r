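---
title: "cancerSig: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cancerSig: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cancerSig)
```

# Overview

`cancerSig` turns somatic variant calls of three mutation modes — single
nucleotide variants (SNV), structural variants (SV) and microsatellite
instability (MSI) — into one weighted per-tumor feature profile, deciphers
shared mutational signatures across a cohort by non-negative matrix
factorization (NMF), refits per-sample exposures and renders decomposition
reports. This vignette explains the model, the fixed conventions the
implementation had to choose where the field leaves room, and what the
synthetic-data tests do and do not demonstrate.

# Feature catalogs

## SNV: 96 trinucleotide classes

Substitutions are folded onto the pyrimidine strand: a `G>T` call is the
same biological event as `C>A` read from the other strand, so the 12
ordered base pairs collapse to 6 substitution classes. Each class is
subclassified by the reference bases immediately 5′ and 3′ of the variant,
giving 6 × 4 × 4 = 96 classes with ids like `G[T>C]G`. When the reference
base is a purine, the *whole context* is reverse-complemented — the flanks
swap and complement — so a variant and its reverse-complement
representation always land in the same class. The flanking bases are read
from the reference genome, never from the VCF.

Acceptance rules for VCF records are deliberately explicit, and every
rejected record is tallied by reason (`skippedRecords()`), so that
accepted + skipped always reconciles with the input count:

- only single-base REF and ALT; multi-allelic records are decomposed and
  each single-base ALT is counted independently;
- FILTER must be `PASS` or `.` by default (somatic callers rely on FILTER
  to mark rejected candidates); `passOnly = FALSE` overrides;
- the reference base at the position must equal the VCF REF — a cheap
  guard against genome-build mixups;
- records at contig edges or with an N flank are skipped, because their
  context is undefined.

A missing contig is a hard error rather than a skip: it almost always
means the wrong reference was supplied.

## SV: 4 classes × 8 size bins

`SVTYPE` maps DEL/DUP (including `DUP:TANDEM`)/INV/TRA-or-BND onto
deletion, duplication, inversion, translocation. Sizes mean different
things per class: for deletion/duplication/inversion the size is the
nucleotides lost or gained (`END − POS`); for a translocation it is the
distance between the old and new position — a 100 bp segment moved from
20 Mb to 25 Mb on one chromosome is a 5 Mb event, and a move to another
chromosome has infinite size.

Size bins are half-open and lower-inclusive, `[100, 1K), [1K, 10K), …,
[100M, 1000M)`, so every size ≥ 100 bp maps to exactly one bin; events
below 100 bp are below the catalog and are skipped with a tally. The
whole-chromosome bin collects infinite-size events, plus intra-chromosomal
events at least as long as their contig when the VCF header declares
contig lengths. The `END − POS` convention (no +1) keeps round event
lengths in their intuitive bins (a 15,000 bp duplication is a
`10K-100K` event).

Breakend (BND) records describe one junction twice, as a mate pair; only
the mate whose (chromosome, position) sorts first is counted, the other is
tallied as `bnd_mate`, so one rearrangement is one event. The line parser
is a pluggable hook (`parser` argument of `profileSV()`), mirroring how SV
caller dialects differ in practice.

## MSI: 18 repeat-unit classes

A microsatellite motif is the same repeat whether you rotate it (`AGC` vs
`GCA`) or read it from the other strand (`GT` vs `AC`). The canonical
class of a 1–3 bp unit is therefore the lexicographically smallest string
among all cyclic rotations of the unit and of its reverse complement;
units that are repetitions of a shorter unit (`CC`, `AAA`) reduce to the
shorter unit's class first. Exhaustive enumeration of all 84 units of
length 1–3 yields exactly 16 classes — this enumeration is a test. Units
of declared length 4 or 5 are counted pattern-free as `unit4`/`unit5`;
the declared length wins even for internally periodic motifs such as
`ACAC`, because pattern checking is defined only below 4 bp.

The loci counted are the unstable (somatic) loci reported by the upstream
MSI caller, not all scanned microsatellites. Per-sample locus totals are
not normalized by the number of scanned sites; within-group normalization
at the merge stage makes cohort columns comparable regardless.

# Merging and group weights

For each sample, each group's counts are normalized to fractions and
scaled by the group weight (default SNV:SV:MSI = 7:2:1, adjustable via a
small key-value config validated to sum to 1). Every merged column then
sums to 1 and every group block to its weight. This per-group cap is the
central design choice of the combined profile: mutation burden differs by
orders of magnitude between modes and between tumors (hypermutators can
carry 100–1000× the substitutions), and an uncapped concatenation would
let one mode drown out the others in the factorization. The cost is that
relative burden *between* groups is not represented in the matrix; burden
is reported separately (`tmb()`, `svb()`).

Two degenerate cases needed decisions:

- *single-group analyses* (SNV-only, SV-only) are expressed as degenerate
  weights (`SNV = 1, SV = 0, MSI = 0`), not separate code paths;
- *empty groups*: when a sample has a zero-count or missing group, the
  default policy is to abort (it usually indicates an upstream problem);
  the `zero-fill` policy instead zeroes that block and re-normalizes the
  remaining groups so the column still sums to 1 — columns must stay
  stochastic for the factorization. The re-normalization is a choice, not
  a necessity; it is flagged here because a deflated column sum would be
  the other defensible convention.

# Deciphering

## Factorization

The merged matrix is factorized as `M ≈ P E`, minimizing the Frobenius
error with the classic multiplicative updates; the objective is
non-increasing per iteration (a property test), iteration stops on a
relative objective change below `tol` (default 1e-9 for final fits) or at
`maxIter`. P's columns are rescaled to sum to 1 after fitting, with the
compensating scale absorbed into E, so P columns are probability
distributions over feature classes. Initialization is uniform random;
every random draw derives its seed deterministically from one master seed,
so results are bitwise reproducible. Final fits use multiple random
restarts (default 5), keeping the lowest-error solution.

## Choosing the number of signatures

For each candidate k the data are bootstrap-resampled: within each
sample and group block, event counts are redrawn from a multinomial with
that sample's original per-group event total (stored by `mergeProfiles()`
in the matrix metadata; a configurable default total is used for matrices
read from files). Each resample is refactorized, and the pooled k ×
bootstrap signatures are partitioned into k clusters under a
one-per-replicate constraint: every bootstrap contributes exactly one
signature to each cluster, matched greedily by cosine similarity to
running cluster centroids. Stability is the mean silhouette width on
cosine distance; the mean relative reconstruction error is reported
alongside.

The one-per-replicate matching matters. A free clustering of the pooled
signatures (e.g. k-medoids) can keep silhouettes deceptively high past the
true rank by making unbalanced clusters; under the matched partition, a
spurious extra cluster is forced to collect one inconsistent signature per
replicate and its silhouette collapses. On a planted 3-signature cohort
the stability profile drops from ≈ 0.99 at k = 3 to ≈ 0.55 at k = 4.

The *suggested* k is the largest k with stability ≥ 0.8. This rule
(floor and maximization) is this package's policy — the underlying
framework leaves the decision to inspection — and the full per-k
diagnostics are always returned precisely so users can override it. At
k = 1, where a silhouette is undefined, stability is reported as the mean
cosine similarity of the pooled signatures to their centroid. When no k
passes the floor, the suggestion is `NA` and the final factorization falls
back to the most stable k, clearly flagged in `selectedK()`.

## Exposure refitting

Per-sample exposures against a fixed P — the deciphered one or an external
COSMIC/WTSI-format table — are obtained by non-negative least squares
(`min ‖m − P e‖₂, e ≥ 0`, Lawson–Hanson via `pracma::lsqnonneg`). Tests
check the refit against an exhaustive grid search on the exposure simplex
at 1e-3 resolution. Reports always refit rather than reusing the E from
the factorization: this makes visualization work identically for
deciphered and externally supplied signatures, at the cost that a sample's
reported exposures can differ slightly from its column of E.

# Reporting

Each sample's report is a 4-page PDF: exposure pie chart, observed
profile, reconstructed profile (`P e`), and prediction error
(observed − reconstructed, conserved exactly by construction). Since a
PDF is a poor testing surface, a machine-readable annex with the same
numbers is written next to it, and the cohort-level
`normalized_weights.txt` holds each sample's signature percentages (rows
sum to 100). Percentages are written at full precision (10 significant
digits) — rounding to a few decimals would break the row-sum and
round-trip guarantees that the tests enforce, and precision matters near
the 30% association boundary.

The association rule is strictly greater than 30%: a sample at exactly
30%, or at 26%, is not associated. Tumor mutation burden divides the SNV
profile total by 30 (an exome-scale Mbp heuristic; the denominator is an
argument for whole-genome use) and rejects fraction-normalized profiles.
SV burden is the raw SV event total.

# Synthetic data: what it shows and what it does not

All tests run on generated data: a random miniature reference genome (with
optional recorded N injection), SNV VCFs planted at loci that realize
requested trinucleotide contexts, SV VCFs with SVTYPE/END/CHR2 or BND mate
pairs, MSIsensor-style locus tables, and planted-signature cohorts (true
P₀ with group blocks respecting the 7:2:1 weights and pairwise cosine
similarity < 0.3; exposures from a flat Dirichlet; per-sample counts drawn
multinomially with totals of 5000 SNV, 200 SV and 100 MSI events,
loosely echoing a tumor-cohort scale). Fixtures always pass through the
public file formats so the real parsers are exercised, and ground truth is
recorded at generation time.

Recovery tests use a cohort of 60 samples with 3 planted signatures
(bootstrap depth 30, k scanned over 2–5); the suite runs in well under a
minute. What passing shows: the pipeline is internally consistent, the
factorization recovers well-separated planted structure (cosine ≥ 0.95
after matching), and the stability statistic identifies the planted rank.
What it does not show: performance on real tumors, where signatures are
correlated (cosine similarities well above 0.3), exposure distributions
are skewed, counts are contaminated by calling artifacts, and the true
number of processes is not well defined. The generator also does not
simulate reads or variant calling — the workflow explicitly delegates
those to upstream tools.

# Known limitations

- Clustered vs non-clustered SVs are not distinguished, so
  rearrangement-cluster phenomena are invisible to the SV profile.
- Rare but pathogenic events (whole-chromosome losses) are underweighted
  by the fraction representation within their group.
- The MSI profile counts unstable loci only; repeat-length distributions
  are not modeled.
- Intra-chromosomal events reaching the whole-chromosome bin depend on
  contig lengths being declared in the VCF header.
- NMF is a local optimizer; restarts mitigate but do not eliminate
  initialization sensitivity. All defaults favor reproducibility
  (deterministic seed derivation) over search breadth.
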