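## Two-stage Pool-seq sampling simulator.
##
## Pool-seq allele counts arise from two nested binomial sampling stages:
## a pool of p haploid genome copies is drawn from the population (derived
## copies k ~ Binomial(p, f)), then n reads are drawn with replacement from
## the pool (derived reads m ~ Binomial(n, k/p)).  Optionally each read is
## flipped to a uniformly chosen different base with probability e
## (substitution-only sequencing error).  This is exactly the noise model
## the estimators correct for, so simulated data with known truth validates
## every statistical module without external data.

## split nflip errors uniformly over the three other bases (vectorized)
splitThreeWays <- function(nflip) {
  x1 <- stats::rbinom(length(nflip), nflip, 1 / 3)
  x2 <- stats::rbinom(length(nflip), nflip - x1, 1 / 2)
  cbind(x1, x2, nflip - x1 - x2)
}

#' Simulate Pool-seq base counts at independent sites
#'
#' Vectorized two-stage sampling for one pooled sample: derived-allele pool
#' copies `k ~ Binomial(p, freq)`, then derived read counts
#' `m ~ Binomial(depth, k/p)` (reads drawn with replacement from the pool;
#' set `readsWithoutReplacement = TRUE` for a hypergeometric sensitivity
#' check).  Sequencing errors flip each read to a uniform different base
#' with probability `error`.
#'
#' @param freq vector of population derived-allele frequencies, one per
#'   site.
#' @param p pool size (haploid genome copies, >= 2).
#' @param depth read depth per site (scalar or vector).
#' @param error per-read-base substitution error rate in \[0, 1\].
#' @param refBase,altBase bases carrying the ancestral and derived counts.
#' @param readsWithoutReplacement draw reads without replacement from the
#'   pool's p copies (requires `depth <= p`).
#' @return list with `counts` (sites x 4 integer matrix, columns A/C/G/T)
#'   and `truth` (data.frame with `freq`, `poolCount` k, `derivedReads` m).
#' @export
simulateSite <- function(freq, p, depth, error = 0, refBase = "A",
                         altBase = "C", readsWithoutReplacement = FALSE) {
  stopifnot(p >= 2, all(freq >= 0 & freq <= 1), error >= 0, error <= 1,
            refBase %in% BASES, altBase %in% BASES, refBase != altBase)
  nsite <- length(freq)
  depth <- rep_len(as.integer(depth), nsite)
  k <- stats::rbinom(nsite, p, freq)
  m <- if (readsWithoutReplacement) {
    if (any(depth > p)) stop("without-replacement reads need depth <= p")
    stats::rhyper(nsite, k, p - k, depth)
  } else {
    stats::rbinom(nsite, depth, k / p)
  }
  counts <- matrix(0L, nsite, 4L, dimnames = list(NULL, BASES))
  counts[, refBase] <- depth - m
  counts[, altBase] <- m
  if (error > 0) {
    for (b in BASES) {
      src <- counts[, b]
      nflip <- stats::rbinom(nsite, src, error)
      dest <- setdiff(BASES, b)
      add <- splitThreeWays(nflip)
      counts[, b] <- counts[, b] - nflip
      for (d in seq_len(3)) {
        counts[, dest[d]] <- counts[, dest[d]] + add[, d]
      }
    }
  }
  list(counts = counts,
       truth = data.frame(freq = freq, poolCount = k, derivedReads = m))
}

## Neutral site frequency spectrum, discretized on a large ancestral panel
## of `panelSize` haploid copies: a site segregates with probability
## theta * H_{panelSize-1}, and segregating sites carry derived frequency
## k/panelSize with weight 1/k, k = 1..panelSize-1.  The panel must be much
## larger than the pool: the pool of p copies is subsequently *sampled*
## from the population (Binomial(p, f) in simulateSite()), and it is that
## sampling stage which turns the 1/f population spectrum into the 1/k
## pool-count spectrum the estimator denominators integrate over.
## Discretizing the SFS on the pool itself would apply the pool-sampling
## stage twice and bias theta recovery downward.
sampleNeutralFreqs <- function(nSites, theta, panelSize = 1e6L) {
  k <- seq_len(panelSize - 1L)
  hp <- sum(1 / k)
  pSeg <- theta * hp
  if (pSeg > 1) {
    stop("theta * H_{panelSize-1} = ", signif(pSeg, 3),
         " > 1: too many segregating sites for per-site simulation")
  }
  seg <- stats::runif(nSites) < pSeg
  f <- numeric(nSites)
  f[seg] <- sample(k, sum(seg), replace = TRUE, prob = 1 / k) / panelSize
  f
}

#' Simulate a neutral Pool-seq dataset with truth table
#'
#' Sites are independent.  Each site segregates with probability
#' `theta * H_{panelSize-1}`; segregating sites carry a derived population
#' frequency drawn from the neutral SFS (weights 1/k on the frequency grid
#' `k/panelSize`, k = 1..panelSize-1, a large ancestral panel).  Counts
#' then follow the two-stage sampling of [simulateSite()]: pool copies
#' `Binomial(p, f)`, reads `Binomial(depth, k/p)`.  Under this model the
#' windowed Pool-seq estimators of theta-pi and Watterson's theta are
#' unbiased for `theta` (up to O(1/panelSize)).  All randomness flows from
#' `seed`.
#'
#' @param nSites number of sites (positions 1..nSites on one chromosome).
#' @param theta per-site scaled mutation rate.
#' @param poolSize pool size p (haploid genome copies).
#' @param depth mean read depth; fixed, or Poisson-distributed per site
#'   when `depthModel = "poisson"`.
#' @param errorRate per-read substitution error rate.
#' @param depthModel `"fixed"` or `"poisson"`.
#' @param chrom chromosome name.
#' @param seed integer seed (`NULL` leaves the RNG state alone).
#' @param panelSize size of the ancestral panel the SFS is discretized on;
#'   must be much larger than `poolSize`.
#' @return list with `data` (a [PoolSeq-class], ref = A, alt = C),
#'   `truth` (per-site data.frame), and `theta`.
#' @export
simulateNeutralDataset <- function(nSites, theta, poolSize, depth,
                                   errorRate = 0,
                                   depthModel = c("fixed", "poisson"),
                                   chrom = "sim1", seed = NULL,
                                   panelSize = 1e6L) {
  depthModel <- match.arg(depthModel)
  if (!is.null(seed)) set.seed(seed)
  f <- sampleNeutralFreqs(nSites, theta, panelSize)
  d <- if (depthModel == "poisson") {
    stats::rpois(nSites, depth)
  } else {
    rep_len(as.integer(depth), nSites)
  }
  sim <- simulateSite(f, poolSize, d, errorRate)
  ps <- PoolSeq(
    counts = list(A = sim$counts[, "A", drop = FALSE],
                  C = sim$counts[, "C", drop = FALSE],
                  G = sim$counts[, "G", drop = FALSE],
                  T = sim$counts[, "T", drop = FALSE]),
    chrom = rep(chrom, nSites), pos = seq_len(nSites),
    ref = rep("A", nSites), alt = rep("C", nSites),
    poolSizes = poolSize
  )
  truth <- cbind(data.frame(chrom = chrom, pos = seq_len(nSites),
                            depth = d), sim$truth)
  list(data = ps, truth = truth, theta = theta)
}

#' Simulate a two-population Pool-seq dataset with known FST
#'
#' Per site, an ancestral frequency is drawn from the neutral SFS as in
#' [simulateNeutralDataset()]; each population's frequency is then drawn
#' from a Balding-Nichols distribution
#' `Beta(f (1-FST)/FST, (1-f) (1-FST)/FST)` around the ancestral f
#' (`fst = 0` makes both populations share f exactly).  Both pools are
#' sampled through the two-stage model.  The truth table carries the
#' latent per-site diversity components (`hWithin`, `hBetween`, `hTotal`)
#' from which realized window FST can be computed.
#'
#' @param nSites,theta,depth,errorRate,depthModel,chrom,seed as in
#'   [simulateNeutralDataset()].
#' @param fst target FST in \[0, 1).
#' @param poolSizes pool sizes of the two populations (recycled to 2).
#' @param panelSize ancestral panel size for the SFS discretization.
#' @return list with `data` (2-sample [PoolSeq-class]), `truth`, and
#'   `fst`.
#' @export
simulatePairDataset <- function(nSites, theta, fst, poolSizes, depth,
                                errorRate = 0,
                                depthModel = c("fixed", "poisson"),
                                chrom = "sim1", seed = NULL,
                                panelSize = 1e6L) {
  depthModel <- match.arg(depthModel)
  stopifnot(fst >= 0, fst < 1)
  if (!is.null(seed)) set.seed(seed)
  poolSizes <- rep_len(as.integer(poolSizes), 2L)
  f0 <- sampleNeutralFreqs(nSites, theta, panelSize)
  seg <- f0 > 0 & f0 < 1
  drawPop <- function() {
    f <- f0
    if (fst > 0 && any(seg)) {
      shape <- (1 - fst) / fst
      f[seg] <- stats::rbeta(sum(seg), f0[seg] * shape,
                             (1 - f0[seg]) * shape)
    }
    f
  }
  f1 <- drawPop()
  f2 <- drawPop()
  d <- function() {
    if (depthModel == "poisson") stats::rpois(nSites, depth)
    else rep_len(as.integer(depth), nSites)
  }
  d1 <- d(); d2 <- d()
  s1 <- simulateSite(f1, poolSizes[1], d1, errorRate)
  s2 <- simulateSite(f2, poolSizes[2], d2, errorRate)
  asList <- function(cc1, cc2) {
    lapply(stats::setNames(BASES, BASES), function(b) {
      cbind(cc1[, b], cc2[, b])
    })
  }
  ps <- PoolSeq(
    counts = asList(s1$counts, s2$counts),
    chrom = rep(chrom, nSites), pos = seq_len(nSites),
    ref = rep("A", nSites), alt = rep("C", nSites),
    poolSizes = poolSizes, sampleNames = c("pop1", "pop2")
  )
  hW <- (2 * f1 * (1 - f1) + 2 * f2 * (1 - f2)) / 2
  hB <- f1 * (1 - f2) + f2 * (1 - f1)
  truth <- data.frame(
    chrom = chrom, pos = seq_len(nSites), ancestralFreq = f0,
    freq1 = f1, freq2 = f2, depth1 = d1, depth2 = d2,
    hWithin = hW, hBetween = hB, hTotal = (hW + hB) / 2
  )
  list(data = ps, truth = truth, fst = fst)
}
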