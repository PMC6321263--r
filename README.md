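# promusage

Alternative promoter usage quantification from spliced RNA-seq alignments.

Many genes are transcribed from several alternative promoters, each producing
an isoform with its own first exon. Because the first exons differ while
downstream exons are shared, the reads falling on each isoform's *unique*
first-exon bases identify which promoter fired. `promusage` turns that
observation into a pipeline for bulk RNA-seq: derive isoform-discriminating
first-exon regions from a gene model, count supporting reads from spliced
alignments, normalize to reads per million (RPM), compute per-sample promoter
usage proportions, and compare usage between sample groups. The motivating
use case is the pig *PPARγ* locus, whose three promoter-driven isoforms show
breed- and age-specific usage in subcutaneous adipose tissue; the package is
generic over any multi-promoter gene.

The headline statistic is the usage proportion of promoter *i* in sample *s*:

```
usage_i(s) = n_i(s) / Σ_j n_j(s)
```

where `n_i(s)` is the number of units (reads or fragments) whose aligned
bases (CIGAR `M`/`=`/`X` operations) overlap promoter *i*'s unique first-exon
region by at least a configurable minimum. Group differences are tested per
promoter with a two-sided Welch *t*-test on the per-sample proportions.

Around this core the package also implements the surrounding expression
stage — median-of-ratios size factors, FPKM/TPM, an expressed-gene filter
(normalized count > 3 in at least one sample), fold-change + Welch
differential-expression calls with DEG set algebra — and hypergeometric term
enrichment with Benjamini–Hochberg correction and richness factors
(`k/K`: selected genes in a term over all background genes in it).

A synthetic-data module generates every input with machine-readable truth:
a three-promoter gene model (GTF), coordinate-sorted spliced alignments
drawn from known isoform mixtures (SAM, 150-nt paired ends), negative
binomial count matrices with planted fold-changes, and annotation maps with
a planted enriched term. Everything is therefore testable end to end without
external data.

## Worked example

Simulate the default two-group study — an obese-breed group (`Min`) and a
lean-breed group (`DL`), three replicates each, 50,000 fragments per sample —
then quantify and compare promoter usage:

```r
library(promusage)

cfg    <- sim_config(reads_per_sample = 50000L)
model  <- simulate_gene_model(cfg)
fes    <- derive_first_exons(model)
fes
#> FirstExonSet for gene SIMG1 on chrS +
#>   P1: 1001-1600 (600 bp; transcripts: SIMG1.t1)
#>   P2: 3001-3600 (600 bp; transcripts: SIMG1.t2)
#>   P3: 5001-5600 (600 bp; transcripts: SIMG1.t3)

policy <- alignment_policy(count_unit = "fragment")
counts <- list(); groups <- character(0)
for (g in c("Min", "DL")) for (r in 1:3) {
  sid <- sprintf("%s_%d", g, r)
  sam <- tempfile(fileext = ".sam")
  simulate_alignments(model, cfg$mixtures[[g]], cfg$reads_per_sample, cfg,
                      sample_id = sid, path = sam)
  counts[[sid]] <- count_first_exon_reads(sam, fes, policy, sample_id = sid)
  groups[sid] <- g
}
counts[["Min_1"]]
#> FirstExonCounts Min_1 (gene SIMG1): P1=3129, P2=1468, P3=4680; library 50000

tab <- usage_proportions(counts, groups)
aggregate(proportion ~ group_id + promoter_id, tab, mean)
#>   group_id promoter_id proportion
#> 1       DL          P1  0.1861864
#> 2      Min          P1  0.3376322
#> 3       DL          P2  0.3118178
#> 4      Min          P2  0.1616599
#> 5       DL          P3  0.5019958
#> 6      Min          P3  0.5007079

compare_usage(tab, "Min", "DL", "P1")
#> UsageComparison P1: Min (mean 0.3376, n=3) vs DL (mean 0.1862, n=3)
#>   Welch t = 149.9, p = 1.419e-08
```

The estimated group means recover the configured mixtures (first promoter
~34% of transcripts in the obese group versus ~19% in the lean group; second
promoter the reverse contrast), and the Welch test flags the usage shift at
the first promoter while the third — equally used in both groups — is not
significant.

The whole chain, including the expression and enrichment side on a simulated
count matrix, runs as one command:

```r
run_pipeline("all", output_dir = "promusage_out", seed = 7)
```

or from a shell via the thin wrapper:

```sh
Rscript inst/cli/promusage-cli.R all --seed 7 --output-dir promusage_out
```

Outputs are plain TSV/BED/GTF/SAM; reruns with the same seed are
byte-identical.

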