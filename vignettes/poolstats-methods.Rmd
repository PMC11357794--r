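---
title: "Pool-seq diversity and differentiation estimators: models and methods"
author: "poolstats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-seq diversity and differentiation estimators: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolstats)
```

# The statistical problem

Pool sequencing (Pool-seq) estimates population allele frequencies by
sequencing a single library made from the pooled DNA of many individuals.
Two nested sampling processes separate the observed base counts from the
population parameters of interest:

1. **Pool sampling** — a pool of $p$ haploid genome copies is drawn from
   the population.  Throughout this package $p$ counts *haploid genomes*,
   i.e. individuals times ploidy: 50 diploid individuals give $p = 100$.
2. **Read sampling** — at each site, $n$ reads are drawn (with
   replacement, the standard Pool-seq assumption) from the pool.

Naive plug-in estimators of nucleotide diversity or $F_{ST}$ computed from
read frequencies are biased by both stages.  The estimators below correct
for both, as a function of $p$, $n$, and the minimum allele count $b$ —
the smallest per-allele read count accepted as real signal rather than
sequencing error.

# Diversity estimators

For one sample at one site with depth $n = n_A + n_C + n_G + n_T$ and base
frequencies $f_a = n_a / n$, the read-sampling-corrected heterozygosity is

$$\hat h \;=\; \frac{n}{n-1}\Bigl(1 - \sum_a f_a^2\Bigr),$$

computed over all four bases, so multiallelic sites need no special
handling.  The per-site estimators divide observable numerators by
denominators that integrate the neutral $1/k$ frequency weights over both
sampling stages:

$$D_W(n,p,b) = \sum_{m=b}^{n-b}\; \sum_{k=1}^{p-1} \frac{1}{k}
   \binom{n}{m}\Bigl(\frac{k}{p}\Bigr)^m\Bigl(1-\frac{k}{p}\Bigr)^{n-m},$$

$$D_\pi(n,p,b) = \sum_{m=b}^{n-b} \frac{2m(n-m)}{n(n-1)}
   \sum_{k=1}^{p-1} \frac{1}{k}
   \binom{n}{m}\Bigl(\frac{k}{p}\Bigr)^m\Bigl(1-\frac{k}{p}\Bigr)^{n-m}.$$

A site contributes $\hat h / D_\pi(n, p, b)$ to the $\theta_\pi$ window
sum, and $1 / D_W(n, p, b)$ to the $\theta_W$ sum when its minor allele
count lies in $[b, n-b]$ (a *detectable* SNP).  Invariant sites contribute
zero to the numerators but are counted by the averaging denominators.
These have the classical limits $D_\pi(n, p, 1) \to 1$ and
$D_W(n, p, 1) \to H_{n-1} = \sum_{i=1}^{n-1} 1/i$ as $p \to \infty$, i.e.
with an effectively infinite pool only the read-sampling (Watterson)
correction remains; both limits are verified by the test suite at
$p = 10^6$ to $10^{-3}$.

When $b > n - b$ no read configuration can reveal a minor allele; the
denominators are zero and the site is flagged uninformative rather than
dividing by zero.

## Tajima's D

The default output is the *unnormalized numerator*
$(\hat\theta_\pi - \hat\theta_W)$ averaged per site.  Pool-seq data do not
support a well-behaved normalized Tajima's $D$: the variance of the
numerator depends on the two-stage noise in a way that no published
normalization captures reliably, and every output row therefore carries a
`tajimas_d_caution` flag.  An opt-in normalization
(`tajimasDDenominator = "pool-size"`) divides by the classical Tajima
(1989) standard deviation $\sqrt{e_1 S + e_2 S(S-1)}$ evaluated at sample
size $p$ with $S$ the window's SNP count.  This treats the pool's $p$
haploid copies as if they were individually sequenced and ignores
read-depth noise entirely; it is provided for comparability with
individual-sequencing conventions, not as a calibrated test statistic.
This design — numerator by default, a clearly-labelled classical
normalization as the only alternative — is a deliberate choice: we found
no pool-specific variance formula we were prepared to stand behind.

# Differentiation estimators

For a pair of pools with per-site frequencies $f_{1,a}, f_{2,a}$, depths
$n_1, n_2 \ge 2$, and pool sizes $p_1, p_2 \ge 2$:

$$\hat\pi_{within} = \tfrac12(\hat h_1 + \hat h_2), \qquad
  \hat h_i = \frac{n_i}{n_i - 1}\,\frac{p_i}{p_i - 1}
  \Bigl(1 - \sum_a f_{i,a}^2\Bigr),$$

$$\hat\pi_{between} = 1 - \sum_a f_{1,a} f_{2,a}, \qquad
  \hat\pi_{total} = \tfrac12(\hat\pi_{within} + \hat\pi_{between}).$$

$\hat h_i$ is unbiased for the population heterozygosity under the
two-stage model; $\hat\pi_{between}$ needs no correction because the two
pools are sampled independently.  Window $F_{ST}$ is always a **ratio of
window sums**, never a mean of per-site ratios (per-site ratios are
undefined at low variation and noisy everywhere):

$$F_{ST}^{Nei} = 1 - \frac{\sum \pi_{within}}{\sum \pi_{total}}, \qquad
  F_{ST}^{Hudson} = 1 - \frac{\sum \pi_{within}}{\sum \pi_{between}}.$$

Negative estimates are reported as-is; clamping at zero would
re-introduce bias.  A window without variation reports `NA`.

Two PoPoolation2-era estimators are included as comparison baselines and
restricted to biallelic sites: the "Kofler" form,
$(\pi_t - \pi_w)/\pi_t$ with Bessel-style corrections using
$n_{\mathrm{eff}} = \min(\text{depth}, \text{pool size})$, and the
"Karlsson" (Karlsson et al. 2007) ratio of sums.  Both are biased upward
at low read depth and small pool size because they do not correct the
pool-sampling stage; the test suite demonstrates this by Monte-Carlo at
zero true differentiation ($p = 10$, depth 10), where both baselines sit
several standard errors above zero while the Hudson and Nei estimators do
not.

Because the ratio of sums is itself a ratio estimator, it carries a small
$O(1/S)$ Jensen bias for windows holding $S$ SNPs.  Windows should
contain enough SNPs for the ratio to stabilise; the validation runs use
2000-site windows (roughly 50+ SNPs at $\theta = 0.01$), and single-SNP
windows should be interpreted with this in mind.

# Data flow

Every input is normalized into one uniform per-position container, a
`PoolSeq` object (a `RangedSummarizedExperiment` whose assays are the six
tallies `A`, `C`, `G`, `T`, `N`, `DEL` plus the per-sample filter state).
`N` and `DEL` are parsed and stored but excluded from read depth and all
statistics; an optional deletion-fraction guard can filter samples with
excessive `DEL` evidence.

Parsers: sync (both the 6-field and the 4-field dialect, header lines,
missing markers `.:.:.:.:.:.` and `-`), samtools (m)pileup (full base
string grammar with `^X`, `$`, indels, `*`, `>`/`<`, and a minimum base
quality with configurable ASCII offset, default 33), and simple
allele-count/frequency tables (frequencies are scaled into pseudo-counts
at a configurable depth $n_0$, supporting haplotype-corrected frequency
inputs where the pool-size correction still applies but the read-depth
correction matters less).  All text inputs may be gzipped.  Multiple
files are merged positionally by union or intersection, with absent
samples filled as missing; reference-base conflicts resolve with priority
reference genome > first non-N input, and error otherwise.  Chromosome
order across files is lexicographic unless an explicit order is given —
a deterministic choice.

The filter cascade runs in a fixed order: region filters (which *remove*
positions) → masks (which *flag* positions but keep them, so window
denominators can count them) → per-sample numerical filters (rare-base
zeroing below `minCount`, then depth bounds on the recomputed depth) →
SNP classification → optional depth subsampling.  Classification merges
counts over passed samples: one nonzero base is invariant, two make a
biallelic SNP, three or more a multiallelic SNP.  Design choices where
conventions differ: the minor-allele-frequency threshold is evaluated on
counts merged across samples (per-sample evaluation would couple the
filter to sample order and depth imbalance), and the biallelic
restriction is applied before the MAF demotion.  Rare-base zeroing, not
site removal, is the `minCount` semantic, matching the role $b$ plays
inside the estimator denominators.  Tie-breaks when inferring ref/alt
from counts use the fixed base order A < C < G < T, so outputs are
deterministic; ref bases provided by the input file are kept.

Windows come in six types (fixed-width intervals, optionally sliding; a
fixed SNP count; user regions, possibly overlapping; single SNPs; whole
chromosomes; whole genome), all anchored on 1-based inclusive
coordinates with interval windows starting at position 1 of each
chromosome.  Without chromosome lengths, trailing empty windows are not
emitted; with lengths they are, so that genome-wide per-base-pair
averages are possible.  Region windows report the region bounds (not the
covered positions) as their coordinates.  Six averaging policies convert
window sums to per-base-pair values: window size, available loci, valid
loci (the recommended default; mask-aware), SNP count, no averaging, or
a user mask.  They always satisfy
$\mathrm{snp} \le \mathrm{valid} \le \mathrm{available} \le
\mathrm{window\ size}$; a zero denominator reports `NA`.

# The synthetic-data generator

`simulateSite()` implements exactly the two-stage model the estimators
correct for: $k \sim \mathrm{Binomial}(p, f)$ pool copies, then
$m \sim \mathrm{Binomial}(n, k/p)$ reads (a without-replacement
hypergeometric option exists for sensitivity checks), with optional
substitution-only sequencing errors flipping each read to a uniform
different base.

`simulateNeutralDataset()` draws, per site, a segregating indicator with
probability $\theta H_{P-1}$ and a derived population frequency from the
neutral SFS discretized on a large ancestral panel of $P$ copies
(weights $1/k$ on the grid $k/P$, default $P = 10^6$).  The panel must be
much larger than the pool: the pool is *sampled from* the population, and
it is that Binomial$(p, f)$ stage that turns the $1/f$ population
spectrum into the $1/k$ pool-count spectrum the estimator denominators
integrate over.  Discretizing the SFS on the pool itself and then
resampling the pool would apply pool sampling twice and depress
$\theta_W$ recovery by $\approx 4.5\%$ at $p = 100$, $n = 50$ (exact
computation); with the panel the estimators are unbiased up to
$O(1/P)$.  `simulatePairDataset()` adds an island model: population
frequencies are drawn around the ancestral frequency from a
Balding–Nichols Beta distribution with the target $F_{ST}$ as its
parameter — the simplest model with an exact $F_{ST}$ interpretation —
and the truth table carries the latent per-site diversity components so
realized window $F_{ST}$ can be computed independently of the estimators.

What the generator deliberately does **not** emulate: linkage (sites are
independent, so window statistics have no autocorrelation), demography or
selection, mapping and duplicate-read artifacts, base-quality error
structure (errors are uniform), and indels.  Passing recovery tests
therefore demonstrates correctness of the *sampling-noise corrections*,
not robustness to alignment artifacts in real data.

# Numerical choices

* Binomial terms are evaluated through `dbinom()` (log-gamma space), so
  depths in the thousands do not overflow; denominators are cached by
  $(n, p, b)$, and the cache equals a direct brute-force double sum to
  $10^{-10}$ relative error over $n, p \in [2, 60]$, $b \in [1, 3]$
  (tested).
* $D_W$ decreases strictly in $b$; uninformative $(n, b)$ combinations
  return zero with a flag.
* Depth subsampling offers a multivariate hypergeometric draw, a
  multinomial draw, and deterministic proportional rescaling with
  largest-remainder rounding (ties broken by base order); all three
  preserve expected allele frequencies, and `N`/`DEL` are rescaled by the
  same depth ratio.  All stochastic steps take explicit seeds.
* Frequency-to-count conversion rounds half away from zero.
* Validation problem sizes (chosen once as realistic study conditions):
  $10^5$ sites at $\theta = 0.01$, $p = 100$, depth 50 for $\theta$
  recovery within 5%; $2 \times 10^4$ sites for $F_{ST}$ recovery at
  $F_{ST} = 0.2$, $p = 50$, depth 50 and for the bias demonstration at
  $F_{ST} = 0$, $p = 10$, depth 10; $10^5$ replicates per cell of the
  $p, n \in \{5, 10, 50\} \times f \in \{0.1, 0.3, 0.5\}$ unbiasedness
  grid, with 3-standard-error acceptance bands throughout.

# Known limitations

* The engine is in-memory and vectorized rather than streaming; datasets
  must fit in RAM as six integer matrices (a million sites times tens of
  samples is unproblematic, whole-genome resequencing at scale is not the
  target).
* SAM/BAM/CRAM and VCF are not read directly; convert upstream (e.g.
  `samtools mpileup`).  VCF-derived data lose the invariant/missing
  distinction, which masks exist to repair.
* Tajima's D is reported with the caution flag for the statistical
  reasons above.
* $F_{ST}$ is pairwise only; multi-population decompositions and
  f-statistics are out of scope.
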