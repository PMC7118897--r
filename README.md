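# cancerSig

Integrated SNV + SV + MSI mutational signature profiling and deciphering
for tumor cohorts.

## The problem

Somatic mutations accumulate in tumors as the combined footprint of
multiple DNA damage and repair processes. Each process leaves a
recognizable pattern — a *mutational signature* — over classes of mutation
events. Most signature tools look only at single-base substitutions;
`cancerSig` builds a *combined* per-tumor profile from three mutation
modes and deciphers shared signatures across a cohort:

- **SNV**: 96 trinucleotide-context substitution classes (6
  pyrimidine-reference substitution types × 4 possible 5′ bases × 4
  possible 3′ bases, COSMIC-style ids such as `G[T>C]G`), with flanking
  bases read from the reference genome;
- **SV**: 32 structural-variant classes (deletion, duplication, inversion,
  translocation × 8 log10 size bins from 100 bp–1 kb up to whole
  chromosome). A translocation's size is the distance between its
  breakpoints — infinite, hence whole-chromosome, when they sit on
  different chromosomes;
- **MSI**: 18 microsatellite repeat-unit classes — the 16 canonical 1–3 bp
  repeat patterns (equivalence classes under cyclic rotation and reverse
  complementation) plus pattern-free 4 bp and 5 bp classes — counted over
  unstable loci from an MSIsensor-style somatic-site table.

Per sample, each group's counts are normalized to fractions and scaled by
group weights (default SNV:SV:MSI = 7:2:1), so no hypermutated mode can
overpower the rest: the SNV block of every merged column always sums to
70% under the default weights.

## The model

The merged features × samples matrix **M** (columns summing to 1) is
factorized by non-negative matrix factorization as

    M ≈ P × E

where **P** (features × k) holds the signature probability profiles
(columns sum to 1) and **E** (k × samples) the per-sample exposures. The
factorization minimizes the Frobenius reconstruction error with
multiplicative updates. The number of signatures k is selected by a
bootstrap-stability procedure: per-sample multinomial resampling of event
counts, refactorization of each resample, one-per-replicate matched
clustering of the pooled signatures, and the mean cosine silhouette as the
stability statistic. The suggested k is the largest k with stability
≥ 0.8; per-k diagnostics are always reported so the user can override.

Per-sample exposures are refit against the fixed **P** (deciphered, or an
external COSMIC/WTSI-format table) by non-negative least squares, and a
sample is *associated* with a signature when its exposure fraction exceeds
30% (strictly).

## Worked example

```r
library(cancerSig)

## the 96-class SNV encoding: a T>C variant with 5' G and 3' G flanks
trinucleotideClass("T", "C", "G", "G")
#> [1] "G[T>C]G"

## tumor mutation burden: substitutions / 30 (exome-scale heuristic)
p <- FeatureProfile("tumor1", "SNV", c(`G[T>C]G` = 1500, `A[C>T]A` = 540))
tmb(p)
#> [1] 68

## a synthetic 30-sample cohort with 3 planted signatures
cohort <- makePlantedCohort(k = 3, nSamples = 30, seed = 42)
res <- decipherSignatures(cohort$merged, kRange = 2:4,
                          bootstrapIterations = 20, seed = 42)
res
#> DecipherResult: 146 features, 30 samples
#>   selected k = 3
#>  k stability reconError
#>  2 0.9970176  0.3249155
#>  3 0.9938621  0.1806174
#>  4 0.5519718  0.1715783

## refit one sample's exposures against the deciphered signatures
fit <- refitExposures(signatures(res), featureValues(cohort$merged)[, "S001"])
round(fit$fractions, 3)
#> Signature.A Signature.B Signature.C
#>       0.465       0.327       0.208
associatedSignatures(fit$fractions)   # strictly > 30%
#> [1] "Signature.A" "Signature.B"
```

The stability column reads as: 2 and 3 signatures are reproducible across
bootstrap resamples (silhouette ≈ 1), a 4th signature is not (0.55), so 3
is suggested — the planted number.

## Command line

A `cancersig` Rscript (installed under `exec/` in the package library)
mirrors the workflow stages:

```sh
cancersig feature snv   --vcf tumor.vcf --ref genome.fa --sample T1 --output t1_snv.tsv
cancersig feature sv    --vcf tumor_sv.vcf --sample T1 --output t1_sv.tsv
cancersig feature msi   --raw-msisensor-report t1.msi --sample T1 --output t1_msi.tsv
cancersig feature merge --profiles t1_snv.tsv,t1_sv.tsv,t1_msi.tsv --output merged.tsv
cancersig signature decipher  --mutation-profiles merged.tsv --out-prefix run
cancersig signature visualize --mutation-profiles merged.tsv \
    --signatures run.signatures.tsv --output-dir reports/
```

`visualize` writes a 4-page PDF per sample (exposure pie chart, observed
profile, reconstructed profile, prediction error), a machine-readable
per-sample annex, and the cohort table `normalized_weights.txt` (one row
per sample, signature percentages summing to 100).

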