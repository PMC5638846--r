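---
title: "Calling focal single-copy gains from targeted sequencing: methods and design"
author: "focalGain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling focal single-copy gains from targeted sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

## The problem

A single extra copy of a gene — a focal tandem duplication of, say, 100 kb on
one parental haplotype — is among the hardest somatic copy-number events to
detect. The coverage step is only 1.5x at full tumour purity and shrinks
towards 1x as normal cells dilute the signal; SNP arrays and genome-wide
segmentation tools routinely miss it. The motivating case is duplication of
the brachyury (*T*) locus in chordoma, a notochordal cancer in which both
germline and somatic gains of this transcription factor drive disease.
Targeted capture of the gene footprint plus flanking intergenic sequence
gives deep coverage of exactly the region of interest, and `focalGain`
implements a caller for such data that fuses three evidence sources:

1. **Binned coverage.** Fragment 5' ends are counted in bins and normalized
   as `n5prime / (bin length x total reads) x 3e9`, so a diploid bin has
   expectation 1 and a clonal single-copy gain 1.5. Each bin carries an
   exact Poisson 95% CI and the mean mapping score of its fragments.
2. **B-allele frequencies (BAF).** At a heterozygous SNP inside a
   duplication, the allele on the gained haplotype is covered by 2 of 3
   copies: its expected BAF moves from 1/2 to
   $\mathrm{BAF}(\rho) = \frac{2\rho + (1-\rho)}{3\rho + 2(1-\rho)}$,
   reaching 2/3 at purity $\rho = 1$.
3. **Haplotype blocks.** Statistically phased blocks tell us which alleles
   co-occur on one parental chromosome, letting the per-SNP BAFs be
   organised into two haplotype series that separate into distinct bands
   when a gain is present — far more power than unphased BAF dispersion.

## The purity mixture model

Everything rests on one assumption: the sample is a two-component mixture of
tumour cells (fraction $\rho$, locally carrying $c_A$ and $c_B$ copies of the
two parental haplotypes) and diploid normal cells (one copy of each). The
expected relative coverage is $(\rho(c_A + c_B) + 2(1-\rho))/2$ and the
expected BAF of an allele with $c_{allele}$ tumour copies out of $c_{tot}$ is

$$\mathrm{BAF} = \frac{\rho\, c_{allele} + (1-\rho)}{\rho\, c_{tot} + 2(1-\rho)}.$$

`expectedBaf()` is this closed form; the simulator and the tests lean on it
as the analytic reference.

## Evidence channels and the decision rule

**Coverage ratio** (`coverageRatio`): mean normalized coverage over target
bins divided by the mean over flanking bins. Because all bins share one
normalization, the ratio reduces to a ratio of Poisson totals; its 95% CI is
obtained by conditioning on the summed count (an exact binomial interval on
the target share, mapped to the odds scale and corrected for unequal total
bin lengths). Bins with mean mapping score below `mapqFloor` (default 20)
are excluded first — low-mappability bins carry misplaced fragments in both
directions and would bias the ratio.

**Phased-BAF split** (`bafSplitStatistic`): at each phased SNP the
haplotype-A series is `baf` if the alt allele is on A and `1 - baf`
otherwise, so the A and B series sum to 1 exactly. Each block contributes
the mean A-minus-B difference of its SNPs. Population-based phasing cannot
guarantee orientation *between* blocks (switch errors), so block
contributions are aggregated by SNP-count-weighted *magnitude*, and the
reported split carries the sign of the weighted majority orientation — a
clonal gain yields |split| near 1/3, and relabelling A and B exactly negates
the statistic. The p-value permutes the haplotype-of-alt labels among the
SNPs *within* each block: under no gain the BAFs are exchangeable against
the labels, while whole-block label flips would leave the magnitude
statistic untouched and carry no information. Blocks whose labels are all
identical are unchanged by this permutation, which can only make the test
conservative. The add-one correction $(1 + \#\{perm \ge obs\})/(n_{perms}+1)$
keeps p strictly positive.

**Fusion** (`callGain`): a sample is *informative* only when its
heterozygous-SNP count over the assayed footprint strictly exceeds the
threshold (default `> 40`); with no or few het SNPs the allelic channel is
blind and no verdict should be attempted. For informative samples, the
default AND rule calls a gain when the coverage-ratio point estimate exceeds
1 *and* the BAF-split permutation p is at or below `alpha`. The per-channel
`alpha` defaults to 0.01: the assay is intended to be specific rather than
maximally sensitive, and with the AND rule this puts the theoretical
false-positive rate near $0.5 \times 0.01$ per locus. An OR variant
(`requireBothChannels = FALSE`) is available for sensitivity-first use; it
then demands the coverage CI exclude 1 rather than the bare point estimate.
Evidence is computed once and stored in the `GainCall`, so
`cohortInformativeness()` can re-gate a cohort across candidate thresholds
(0, 20, 40, 60, ...) without re-running the channels; informative counts are
monotonically non-increasing in the threshold by construction.

```{r example}
library(focalGain)
cfg <- SimulationConfig(purity = 0.8, seed = 42L)
s <- simulateSample(cfg)
snps <- phaseBafs(selectHetSnps(hetSnps(s)), haploBlocks(s))
callGain(coverageBins(s), snps, cfg@dupInterval, CallerConfig(), seed = 1)
```

## The synthetic-data generator

`simulateSample()` emulates exactly the statistical structure the caller
assumes: Poisson bin counts with mean proportional to the purity-mixed local
copy number, Poisson SNP depths scaled the same way, Binomial alt counts at
the model BAF, SNP positions uniform over the locus, alt alleles assigned to
a random haplotype, blocks of on average `snpsPerBlock` consecutive SNPs,
and phase flips between adjacent blocks at `switchErrorRate`. Defaults are a
200 kb targeted locus around the *T* gene with a central 100 kb duplication
(real events at this locus span roughly 70–136 kb), 100 expected fragment
starts per 1 kb bin, 60 het SNPs at 100x, a 1% switch-error rate, and purity
0.6; purities are varied over 0.2–1.0 in the validation grids since tumour
purity varies widely between specimens and is not estimable from the
targeted data themselves.

What the generator does **not** model: GC and capture-efficiency bias,
overdispersion beyond Poisson/Binomial, mapping artefacts, subclonal
duplications, and read-level detail (no BAM simulation). Passing the
simulation-based tests therefore demonstrates that the method is correct
under its own model assumptions and has the claimed operating
characteristics there — not that real capture data meet those assumptions.
The mapping-score floor and the exact CIs are the two guards that transfer
to real data; bias correction would have to happen upstream.

## Driver rules and cohort statistics

`isTruncating()` encodes the loss-of-function consequence set (nonsense,
essential splice, start lost, frameshift indel — in-frame indels excluded).
Point drivers: truncating events in recessive cancer genes; curated-hotspot
mutations in oncogenes. Copy-number drivers: amplification of an oncogene
at >= 5 copies (diploid sample) or >= 9 (tetraploid) in a segment strictly
under 1 Mb; homozygous deletion of a recessive gene under the same focality
rule, relaxed for bona fide recessive genes that present with both focal and
larger deletions. Segment length is `end - start` in half-open coordinates,
and both inequalities are deliberately strict/exact — the boundary sweep in
the test suite pins copies 4 vs 5, 8 vs 9, and 999,999 vs 1,000,000 bp. The
shipped role table covers the genes recurrent in chordoma (T, PIK3CA,
PIK3R1, PTEN, ARID1A, PBRM1, SETD2, CDKN2A, LYST); roles and hotspot lists
are inputs, not inferences.

`fisherExactOneSided()` computes the exact hypergeometric tail
$P(X \ge a)$ by log-space summation of `lchoose` terms, which stays accurate
for cohorts of thousands (the headline comparison is 5/67 tumours vs
13/4947). One-sided orientation is the point: the question is enrichment in
the first cohort. Hypermutators (>= 100 coding substitutions per exome,
inclusive) are excluded before cohort comparisons, since a single
high-burden tumour can mimic gene-level enrichment. The indel-pattern
permutation test resamples class labels (frameshift vs in-frame) from a
user-supplied background to ask whether in-frame indels are depleted; the
background is an explicit input because no canonical choice exists, and the
test's closed-form limit $(1-q)^n$ for an all-frameshift observation is
used as its oracle. The locus-mutability comparison runs one-sided Fisher
tests per class (substitutions, indels) and applies Benjamini–Hochberg
across them — BH is the standard choice when the two tests are positively
dependent at most.

## Numerical and design choices

- **Bin size** defaults to 1 kb: fine enough to resolve a 100 kb event into
  ~100 points, coarse enough that Poisson CIs stay tight at 100x.
- **Garwood (chi-square) exact Poisson CI**, lower bound 0 at count 0; the
  CI is rescaled by the same normalization as the coverage itself.
- **Het-SNP selection** defaults: depth >= 15 and, when a matched normal is
  available, normal BAF in (0.3, 0.7) at the same depth — bounds genotyping
  error at the cost of a few true het sites.
- **Ties** (BAF exactly 0.5) contribute zero to the split statistic in
  either label state; no tie-breaking is needed.
- **Strict inequalities** everywhere the rule text is strict: informativeness
  `> 40`, focality `< 1 Mb`, hypermutator `>= 100`.
- **Seeding**: every stochastic routine takes an explicit seed; identical
  inputs and seed give identical output, including permutation p-values.
- **Validation problem sizes**: the test suite runs the caller's parameter
  recovery on 50 duplicated + 50 diploid loci at purity >= 0.4, 60 het SNPs,
  80x, and measures monotone sensitivity along purity {0.12, 0.2, 0.45},
  depth {15, 35, 120} and SNP-count {42, 60, 140} axes with 30 replicates
  per cell and 199 permutations per call; null calibrations use 500
  replicates. The axis cells were chosen from the model's power
  considerations so that each axis spans weak to saturated sensitivity —
  flat-at-1 grids could not exhibit a trend, and cells inside the steep part
  of the power curve make the monotonicity property measurable.

## Limitations

- The gain/no-gain verdict is deliberately not an integer copy-number or
  purity estimate; targeted data over one locus cannot separate the two.
- Breakpoint structure (tandem vs complex duplication) is out of reach
  without genome-wide mate-pair evidence.
- The caller assumes the flanking bins are copy-neutral; a gain spanning the
  entire capture design would defeat the internal normalization.
- Cohort-level prevalence estimates from real tumour series depend on
  patient-level data access; the package validates operating characteristics
  on synthetic cohorts instead.
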