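# poolstats

Population genetic statistics for pooled sequencing (Pool-seq) data in R.

Pool-seq estimates genome-wide allele frequencies by sequencing one
library made from the pooled DNA of many individuals — the workhorse
design of Evolve-and-Resequence experiments, population monitoring, and
pooled genome scans.  Two nested sampling stages separate the observed
base counts from the population: a pool of *p* haploid genome copies is
drawn from the population, then *n* reads are drawn from the pool at each
site.  Plug-in estimators of diversity and differentiation computed from
read frequencies are biased by both stages.

`poolstats` implements bias-corrected estimators of

- nucleotide diversity **θ<sub>π</sub>** and **Watterson's θ**, via the
  pool-corrected per-site denominators
  D<sub>π</sub>(n, p, b) and D<sub>W</sub>(n, p, b) =
  Σ<sub>m=b</sub><sup>n−b</sup> Σ<sub>k=1</sub><sup>p−1</sup> (1/k)
  Binom(m; n, k/p), where *b* is the minimum allele count treated as real
  signal;
- **Tajima's D** (unnormalized numerator by default, with an explicit
  caution flag — see the methods vignette for why);
- pairwise **F<sub>ST</sub>** from unbiased π<sub>within</sub>,
  π<sub>between</sub>, π<sub>total</sub> components, as windowed ratios of
  sums: Nei (1 − π<sub>w</sub>/π<sub>t</sub>) and Hudson
  (1 − π<sub>w</sub>/π<sub>b</sub>), plus the PoPoolation2-era "Kofler"
  and "Karlsson" estimators as comparison baselines (biased upward at low
  depth and small pools — reproduced by the test suite);

together with the surrounding machinery: sync (PoPoolation2) and
samtools (m)pileup parsers, allele-frequency tables, positional
union/intersection merging of multiple files, a region/mask/numerical
filter cascade, six window types, six window-averaging policies, and a
two-stage binomial Pool-seq simulator with truth tables for validation.

Data live in a `PoolSeq` object extending Bioconductor's
`RangedSummarizedExperiment` (assays = per-base count matrices), so the
usual subsetting and range machinery applies.

## Worked example

Simulate two populations at true F<sub>ST</sub> = 0.2 (θ = 0.01, pools of
100 haploid genomes, depth 40), then compute windowed statistics:

```r
library(poolstats)

sim <- simulatePairDataset(nSites = 5000, theta = 0.01, fst = 0.2,
                           poolSizes = 100, depth = 40, seed = 1)
x <- classifySites(sim$data)
x
#> PoolSeq object: 5000 positions, 2 samples
#>   chromosomes: sim1
#>   pool sizes: 100, 100
#>   min allele count (b): 1
#>   site classes: MISSING=0, INVARIANT=4832, SNP_BIALLELIC=168, SNP_MULTIALLELIC=0

win <- makeWindows(x, "interval", width = 1000, stride = 1000)
div <- windowDiversity(x, win)   # default policy: valid-loci averaging
div[div$sample == "pop1", c("start", "end", "snps", "theta_pi", "theta_w")]
#>  start  end snps theta_pi theta_w
#>      1 1000   26  0.00509 0.00468
#>   1001 2000   44  0.00882 0.00813
#>   2001 3000   27  0.00539 0.00468
#>   3001 4000   38  0.00757 0.00764
#>   4001 5000   33  0.00782 0.00616

windowFst(x, win, method = "hudson")[, c("start", "end", "fst")]
#>  start  end   fst
#>      1 1000 0.181
#>   1001 2000 0.167
#>   2001 3000 0.208
#>   3001 4000 0.161
#>   4001 5000 0.189
```

Per-window θ̂<sub>π</sub> and θ̂<sub>W</sub> scatter around the generating
θ = 0.01 (they are per-site averages over *all* valid loci, SNPs and
invariants alike), and the Hudson F<sub>ST</sub> estimates scatter around
the simulated 0.2.

Real data enter the same way through `readSync()`, `readMpileup()`, or
`readFrequencyTable()`, followed by `applyFilters()` /
`classifySites()`.  A command line front end wrapping the same functions
is installed at `inst/cli/poolstats`:

```sh
poolstats diversity --input pools.sync.gz --pool-sizes 100,100 \
    --window-type interval --window-interval-width 10000 \
    --window-average-policy valid-loci --out diversity.tsv
poolstats fst --input pools.sync.gz --pool-sizes 100,100 --method hudson \
    --out fst.tsv
```

See `vignettes/poolstats-methods.Rmd` for the estimator derivations'
assumptions, parameter semantics (in particular: pool size counts
*haploid genome copies*), averaging-policy guidance, and the simulator's
scope.

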