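## Pool-seq diversity estimators.
##
## Pool-seq allele counts carry two levels of sampling noise: p haploid
## genome copies are pooled from the population, then n reads are sampled
## (with replacement) from the pool.  The per-site estimators divide an
## observable numerator by a denominator that integrates the neutral 1/k
## frequency weights over both sampling stages:
##
##   D_W(n, p, b)  = sum_{m=b}^{n-b}                         sum_{k=1}^{p-1} (1/k) Binom(m; n, k/p)
##   D_pi(n, p, b) = sum_{m=b}^{n-b} [2m(n-m) / (n(n-1))] *  sum_{k=1}^{p-1} (1/k) Binom(m; n, k/p)
##
## where b is the minimum allele count treated as real signal.  As p -> inf,
## D_pi(n, p, 1) -> 1 and D_W(n, p, 1) -> H_{n-1} (the classical Watterson
## harmonic denominator).  Binomial terms are evaluated through dbinom(),
## i.e. in log-gamma space, so large n does not overflow.

.denomCache <- new.env(parent = emptyenv())

## inner sum over pool allele copies, for all m = b..n-b at once
poolInnerSums <- function(n, p, b) {
  m <- seq.int(b, n - b)
  k <- seq_len(p - 1L)
  vapply(m, function(mm) sum(stats::dbinom(mm, n, k / p) / k), numeric(1))
}

computeDenominators <- function(n, p, b) {
  if (b > n - b) {
    ## no read configuration can show the minor allele: uninformative site
    return(list(dpi = 0, dw = 0, informative = FALSE))
  }
  m <- seq.int(b, n - b)
  inner <- poolInnerSums(n, p, b)
  list(
    dpi = sum(2 * m * (n - m) / (n * (n - 1)) * inner),
    dw = sum(inner),
    informative = TRUE
  )
}

denominatorsFor <- function(n, p, b) {
  key <- paste(n, p, b, sep = "_")
  hit <- .denomCache[[key]]
  if (is.null(hit)) {
    hit <- computeDenominators(n, p, b)
    assign(key, hit, envir = .denomCache)
  }
  hit
}

#' Pool-corrected estimator denominators
#'
#' `thetaPiDenominator()` and `thetaWDenominator()` return the per-site
#' denominators that make the Pool-seq heterozygosity and segregating-site
#' numerators unbiased for the population-scaled mutation rate theta, given
#' pool size `p` (haploid genome copies), read depth `n`, and minimum
#' allele count `b`.  Results are cached by `(n, p, b)`.  When `b > n - b`
#' no read configuration can reveal a minor allele; both denominators are 0
#' and the site is flagged uninformative (attribute `informative`).
#'
#' @param n read depth (>= 2).
#' @param p pool size in haploid genome copies (>= 2).
#' @param b minimum allele count (>= 1).
#' @return positive number (0 with `attr(, "informative") = FALSE` for
#'   uninformative combinations).
#' @examples
#' thetaPiDenominator(n = 2, p = 2, b = 1)  # 0.5
#' thetaWDenominator(n = 10, p = 1e6, b = 1)  # ~ sum(1/(1:9))
#' @export
thetaPiDenominator <- function(n, p, b = 1L) {
  stopifnot(n >= 2, p >= 2, b >= 1)
  d <- denominatorsFor(as.integer(n), as.integer(p), as.integer(b))
  structure(d$dpi, informative = d$informative)
}

#' @rdname thetaPiDenominator
#' @export
thetaWDenominator <- function(n, p, b = 1L) {
  stopifnot(n >= 2, p >= 2, b >= 1)
  d <- denominatorsFor(as.integer(n), as.integer(p), as.integer(b))
  structure(d$dw, informative = d$informative)
}

## vectorized cache lookup over a depth vector (single p, b)
denominatorVectors <- function(nvec, p, b) {
  dpi <- numeric(length(nvec))
  dw <- numeric(length(nvec))
  usable <- !is.na(nvec) & nvec >= 2
  for (n in unique(nvec[usable])) {
    d <- denominatorsFor(as.integer(n), as.integer(p), as.integer(b))
    i <- usable & nvec == n
    dpi[i] <- d$dpi
    dw[i] <- d$dw
  }
  list(dpi = dpi, dw = dw)
}

#' Per-site heterozygosity
#'
#' The read-sampling-corrected heterozygosity
#' `(n/(n-1)) (1 - sum_a f_a^2)` over the four base frequencies
#' f_a = count_a / n.  All four base tallies enter the sum, so multiallelic
#' sites are handled naturally.  Sites with depth below 2 are `NA`.
#'
#' @param x A [PoolSeq-class] object (returns a sites x samples matrix) or
#'   a named tally vector (returns a scalar).
#' @return matrix or scalar of heterozygosities in \[0, 2\].
#' @export
setGeneric("siteHeterozygosity",
           function(x) standardGeneric("siteHeterozygosity"))

#' @rdname siteHeterozygosity
#' @export
setMethod("siteHeterozygosity", "PoolSeq", function(x) {
  n <- readDepth(x)
  sq <- assay(x, "A")^2 + assay(x, "C")^2 + assay(x, "G")^2 +
    assay(x, "T")^2
  h <- ifelse(n >= 2, n / (n - 1) * (1 - sq / n^2), NA_real_)
  h
})

#' @rdname siteHeterozygosity
#' @export
setMethod("siteHeterozygosity", "numeric", function(x) {
  stopifnot(all(BASES %in% names(x)))
  n <- sum(x[BASES])
  if (n < 2) return(NA_real_)
  n / (n - 1) * (1 - sum((x[BASES] / n)^2))
})

## classical Tajima (1989) constants for sample size nchrom
tajimaConstants <- function(nchrom) {
  n <- nchrom
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Windowed diversity estimates
#'
#' Computes, per window and per sample, the Pool-seq estimators of
#' nucleotide diversity (theta-pi), Watterson's theta, and Tajima's D.  Per
#' PASSED site, theta-pi adds `siteHeterozygosity / D_pi(n, p, b)` and
#' theta-W adds `1 / D_W(n, p, b)` when the sample's minor allele count
#' lies in `[b, n - b]` (so the site is a detectable SNP for that sample);
#' invariant sites contribute zero to the numerators but are still counted
#' by the averaging denominators.  Sums are divided by the
#' [windowDenominator()] of the chosen policy.
#'
#' Tajima's D is reported as the unnormalized numerator
#' `(theta_pi_sum - theta_w_sum) / denominator` by default.  Pool-seq data
#' does not support a well-behaved normalized Tajima's D, so every row
#' carries `tajimas_d_caution = TRUE`; interpret magnitudes with care.  The
#' opt-in `tajimasDDenominator = "pool-size"` divides instead by the
#' classical Tajima (1989) standard deviation `sqrt(e1 S + e2 S (S - 1))`
#' evaluated at sample size p (the pool's haploid count) with S the
#' sample's SNP count in the window — a normalization that ignores
#' read-depth noise entirely and is provided for comparability only.
#'
#' @param x A filtered, classified [PoolSeq-class] object with pool sizes
#'   set.
#' @param windows A `PoolWindows` object from [makeWindows()].
#' @param policy averaging policy, see [windowDenominator()].
#' @param mask optional mask [GenomicRanges::GRanges] forwarded to
#'   [windowTallies()].
#' @param tajimasDDenominator `"none"` (numerator only, default) or
#'   `"pool-size"`.
#' @return A long-format data.frame: one row per window x sample with
#'   columns `chrom`, `start`, `end`, `sample`, the window tallies, the
#'   denominator, `theta_pi_sum`, `theta_w_sum`, `theta_pi`, `theta_w`,
#'   `snps_sample`, `tajimas_d`, `tajimas_d_caution`.
#' @export
windowDiversity <- function(x, windows, policy = "valid-loci", mask = NULL,
                            tajimasDDenominator = c("none", "pool-size")) {
  stopifnot(is(x, "PoolSeq"), is(windows, "PoolWindows"))
  tajimasDDenominator <- match.arg(tajimasDDenominator)
  tal <- windowTallies(x, windows, mask)
  denom <- windowDenominator(tal, policy)
  b <- minCount(x)
  h <- siteHeterozygosity(x)
  depth <- readDepth(x)
  maxBase <- pmax(assay(x, "A"), assay(x, "C"), assay(x, "G"), assay(x, "T"))
  okSite <- sitePassedVector(x)
  okSample <- sampleStatus(x) == SAMPLE_STATUS[["PASSED"]]
  hts <- windows@hits
  nw <- nrow(tal)
  out <- vector("list", ncol(x))
  for (j in seq_len(ncol(x))) {
    p <- poolSizes(x)[j]
    if (is.na(p) || p < 2) {
      stop("pool size missing or < 2 for sample ", colnames(x)[j])
    }
    n <- depth[, j]
    use <- okSite & okSample[, j] & n >= 2
    dns <- denominatorVectors(ifelse(use, n, NA), p, b)
    minor <- n - maxBase[, j]
    snpInd <- as.numeric(use & minor >= b & minor <= n - b)
    piContrib <- ifelse(use & dns$dpi > 0, h[, j] / dns$dpi, 0)
    wContrib <- ifelse(use & dns$dw > 0, snpInd / dns$dw, 0)
    sumBy <- function(v) {
      s <- numeric(nw)
      if (nrow(hts)) {
        r <- rowsum(v[hts$site], hts$window)
        s[as.integer(rownames(r))] <- r[, 1]
      }
      s
    }
    piSum <- sumBy(piContrib)
    wSum <- sumBy(wContrib)
    sSnp <- sumBy(snpInd)
    td <- if (tajimasDDenominator == "none") {
      (piSum - wSum) / denom
    } else {
      k <- tajimaConstants(p)
      v <- k$e1 * sSnp + k$e2 * sSnp * (sSnp - 1)
      ifelse(v > 0, (piSum - wSum) / sqrt(v), NA_real_)
    }
    out[[j]] <- data.frame(
      tal,
      sample = rep(colnames(x)[j], nw),
      denominator = denom,
      theta_pi_sum = piSum,
      theta_w_sum = wSum,
      theta_pi = piSum / denom,
      theta_w = wSum / denom,
      snps_sample = sSnp,
      tajimas_d = td,
      tajimas_d_caution = rep(TRUE, nw)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
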