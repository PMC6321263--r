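---
title: "Quantifying alternative promoter usage from spliced alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alternative promoter usage from spliced alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promusage)
```

## The problem and the model

A gene with several alternative promoters produces transcript isoforms that
differ in their first exon and share the downstream exon structure. Standard
gene-level expression cannot see which promoter fired: total output may stay
flat while the promoter mix shifts. The observable that does discriminate
promoters is read coverage on the bases of each first exon that belong to
*only* that isoform. `promusage` estimates promoter activity from exactly
those bases.

For gene $g$ with promoters $i = 1..P$, sample $s$, let $n_i(s)$ be the
number of sequenced units whose aligned bases overlap promoter $i$'s unique
first-exon region. The two quantities reported are the RPM-normalized count
$\mathrm{rpm}_i(s) = n_i(s) \cdot 10^6 / N(s)$, with $N(s)$ the number of
mapped units in the library, and the usage proportion

$$\hat{u}_i(s) = \frac{n_i(s)}{\sum_j n_j(s)},$$

the fraction of the gene's promoter-assignable signal attributable to
promoter $i$. Usage is compared between groups per promoter with a
two-sided Welch $t$-test on the per-sample proportions.

### Assumptions

* The gene model is trusted: first exons and their genomic extents come from
  the annotation, not from assembly.
* A read overlapping an isoform-unique base originates from that isoform.
  This holds exactly when the unique regions are computed against all
  annotated isoforms of the gene and alignments are correct.
* Proportions are computed per sample and then averaged/tested across
  samples, treating the biological replicate as the experimental unit.

### What usage proportions estimate

First-exon read proportions estimate *read mass*, not molar transcript
proportions: an isoform with a longer unique first-exon region attracts
proportionally more reads. With unique lengths $u_i$ and transcript lengths
$L_i$, the expected read share of isoform $i$ under molar mixture $m$ is
approximately $m_i u_i / \sum_j m_j u_j$ for equal $L$. The simulator
records both truths ([expected_read_shares()]), and [mixture_for_shares()]
inverts the relation exactly for a given geometry; the estimator is
validated against the read-mass truth. When all first exons have equal
length — the default simulated geometry — the two notions coincide.

## Deriving unique first-exon regions

`derive_first_exons()` takes each distinct first exon and subtracts every
base overlapped by any exon of any other isoform of the gene (interval
arithmetic via IRanges). Isoforms with byte-identical first exons collapse
to one promoter; promoters are labelled `P1, P2, ...` in 5'→3'
transcription order. Whether to count on whole first exons or only their
isoform-unique portions is a genuine design choice — coverage alone cannot
attribute shared bases — and this package trims to unique portions so that
every counted unit is promoter-informative by construction.

Residual fragments shorter than `min_unique_length` (default 25 bases) are
dropped: a 150-nt read overlapping a shorter anchor is mostly evidence
about neighbouring exons. A promoter whose entire unique residue falls
below the floor is excluded with a warning — its activity is unobservable
by this method, and silently merging it into another promoter would bias
proportions. Fewer than two usable promoters is an error since usage is
then undefined.

## Counting policy

A unit is assigned to the promoter whose regions its aligned reference
bases (CIGAR `M`/`=`/`X`; `N`, `D`, `S`, `I` contribute none) overlap by at
least `min_overlap` bases, subject to MAPQ ≥ `min_mapq`, primary
non-supplementary records, and strand compatibility. Defaults
(`min_overlap = 10`, `min_mapq = 20`, unstranded, duplicates included,
unit = read) are conventional RNA-seq choices; every one is configurable.
A unit bridging two promoters' regions — possible only via splicing or long
fragments — goes to the larger overlap, with exact ties discarded and
tallied. In fragment mode a pair counts once if either mate qualifies;
mates voting for different promoters are discarded as ambiguous rather than
double-counted.

The RPM denominator is the whole-file count of mapped, primary,
non-supplementary, MAPQ-passing units, matching the plain reading of
"reads per million reads". The alternative denominator (total first-exon
reads) is exactly what `usage_proportions()` computes, so both conventions
are available.

## Group comparison

The Welch (unequal-variance) $t$-test is used because group variances of
proportions have no reason to be equal, and at $n = 3$ per group the Welch
correction is the safer default. No transform is applied by default; an
arcsine-square-root option exists for proportions near the boundary. When
both groups are constant and equal the statistic degenerates and $p = 1$ is
returned. Raw p-values are reported across the handful of promoters of a
gene — with three tests, multiplicity correction would be cosmetic, and
cross-promoter tests are not independent anyway (proportions sum to one).

The package exposes explicit two-group comparisons; composite groupings
(one condition versus the pool of all others) are expressed through the
sample table by labelling the pooled samples as one group.

## Expression stage

* **Size factors** are DESeq2-style median-of-ratios:
  $s_j = \mathrm{median}_g\, c_{gj} / (\prod_k c_{gk})^{1/K}$ over genes
  with nonzero counts in all samples. Only this normalization is
  implemented, not the negative-binomial GLM.
* **FPKM/TPM** follow their standard definitions;
  $\mathrm{TPM} = \mathrm{FPKM}$ renormalized per column to $10^6$, an
  identity the tests enforce at $10^{-10}$ relative tolerance.
* **Expressed filter**: a gene is expressed if its size-factor-normalized
  count exceeds 3 in at least one sample (threshold configurable).
* **DEG criterion**: $|\log_2 \mathrm{FC}| > 1$ on pseudocounted group
  means of normalized counts and $p < 0.05$ from a two-sided Welch test on
  $\log_2(\text{normalized} + 1)$. This is a deliberately simple,
  clearly-labelled test — not a reimplementation of a shrinkage-based NB
  model — chosen so the criterion is self-contained and auditable.
  The pseudocount of 1 (configurable) bounds fold-changes of low-count
  genes; it shrinks a nominal mean ratio of 8/2 from $\log_2 = 2$ to
  $\log_2(9/3) \approx 1.585$, which the DEG threshold accounts for.
* **Set algebra**: shared-DEG percentages are reported against both the
  union and the summed sizes of the two lists, because "percent shared" is
  used with both denominators in the literature and the two differ
  materially.

## Enrichment

Over-representation only: $p = P(X \ge k)$ for
$X \sim \mathrm{Hypergeom}(N, K, n)$, computed through the numerically
stable distribution-function routine (`phyper` upper tail, never
$1 - \mathrm{CDF}$), with Benjamini–Hochberg correction across tested terms
(those with $K \ge$ `min_term_size`, default 5 — smaller terms produce
unstable p-values and are conventionally floored). The richness factor
$k/K$ is reported per term. Terms are tested independently: no ontology
graph propagation is performed, so annotations should be pre-propagated if
parent-term inheritance is wanted. The background defaults to the distinct
annotated genes but should be passed explicitly as the assayed universe
when available.

## The synthetic-data generator

`sim_config()` encodes the emulated study: one gene with three isoforms,
equal 600-bp first exons spaced 1,400 bp apart, three shared downstream
exons (1,000/900/1,000 bp), 150-nt paired-end fragments
(mean 300, sd 30), three biological replicates per group, and group
mixtures `Min = (0.3403, 0.1615, 0.4982)` versus
`DL = (0.1869, 0.3111, 0.5020)` — an obese-breed group dominated by the
first promoter against a lean-breed group preferring the second, with the
third promoter (the major isoform in both) balanced. Fragment lengths are
drawn from a *discretized* truncated normal so that expected read shares
are computable exactly rather than by Monte Carlo.

Reads are emitted as already-aligned, coordinate-sorted SAM — the
pipeline's scope begins at alignments, and skipping the sequence/aligner
step keeps tests hermetic and fast. The truth table labels each fragment
with its isoform and with the promoter whose unique region it overlaps
(≥ 1 base), so counting with `min_overlap = 1` in fragment mode must
recover truth *exactly*, which the tests assert on both strands.

What the generator does not emulate: sequencing errors and base qualities,
PCR duplicates, GC and positional bias, multi-gene loci, intron retention,
and misalignment. Passing tests therefore demonstrate correctness of the
counting and inference machinery under clean alignments, not robustness to
aligner artifacts. An optional uniform 0–5-base soft-clip exercises CIGAR
handling only.

For properties that need thousands of replicates (type-I error calibration,
convergence rates), `simulate_usage_counts()` draws first-exon counts
directly from the truth shares via a multinomial — the exact sampling
distribution of truth-recovered counts — avoiding thousands of SAM
round-trips without changing the distribution being tested.

Count matrices are negative binomial with log-normal gene means
(meanlog $= \log 100$, sdlog $= 1$), dispersion 0.05 by default (typical
for laboratory bulk RNA-seq replicates), and a planted fraction of genes
with symmetric-random-signed fold-changes; dispersion 0 falls back to
Poisson. Annotation simulations plant one term whose gene membership is
drawn preferentially from the selected pool so that its enrichment rank is
a known truth.

## Numerical and reproducibility choices

* Coordinates are 1-based inclusive internally (GTF convention); BED export
  converts to 0-based half-open at the boundary.
* Proportions must sum to 1 within $10^{-9}$ per sample; zero-total samples
  are flagged `NA` and excluded from tests with a warning rather than
  silently dropped.
* Degenerate Welch inputs (zero variance in both groups) return $p = 1$ on
  equal means and the smallest representable positive $p$ on unequal means,
  keeping $p \in (0, 1]$.
* Each simulated sample derives its RNG stream deterministically from
  (seed, sample id), so per-sample outputs are reproducible independently
  of generation order; identical seeds give byte-identical SAM/TSV files.
* Problem sizes used by the test-suite calibration runs — $10^5$ fragments
  per sample for proportion recovery, 2,000 null replicates for test
  calibration, 5,000 genes for DEG recovery, 100 replicates for enrichment
  ranking — were chosen to make the Monte Carlo error small relative to the
  property margins being checked.

## Known limitations

* Promoters whose first exon is entirely contained in other isoforms'
  exons are unobservable and excluded; genes where this leaves fewer than
  two promoters cannot be analysed by this method.
* Usage proportions are read-mass proportions; converting to molar
  proportions requires the length correction described above and is left
  to the caller for real annotations.
* The differential-expression test is a two-sample Welch test on
  log-normalized counts: adequate for planted-effect recovery at moderate
  depth, but without dispersion shrinkage it loses power for low-count
  genes at small $n$ relative to NB-GLM methods.
* No multi-gene disambiguation: counting trusts the `FirstExonSet` of one
  gene at a time; overlapping loci must be resolved in the annotation step.
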