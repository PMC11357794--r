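## Pairwise FST from unbiased pi-within / pi-between / pi-total.
##
## For a pair of pools with base frequencies f1, f2 (from n1, n2 reads) and
## pool sizes p1, p2:
##
##   pi_within  = (h1 + h2) / 2,  h_i = (n_i/(n_i-1)) (p_i/(p_i-1)) (1 - sum_a f_ia^2)
##   pi_between = 1 - sum_a f_1a f_2a
##   pi_total   = (pi_within + pi_between) / 2
##
## h_i is unbiased for the population heterozygosity under reads-sampled-
## with-replacement-from-pool and pool-sampled-from-population; pi_between
## needs no correction because the two pools are independent.  Window FST
## is a ratio of window sums (never a mean of per-site ratios):
##
##   FST_Nei    = 1 - pi_within_sum / pi_total_sum
##   FST_Hudson = 1 - pi_within_sum / pi_between_sum
##
## The PoPoolation2 "Kofler" and "Karlsson" estimators are included as
## comparison baselines; both are biased upward at low read depth and
## small pool size, which the unbiased estimators above avoid.

## per-site pieces, vectorized over sites (freqs as 4-column matrices)
freqMatrix <- function(x, j) {
  n <- readDepth(x)[, j]
  f <- cbind(assay(x, "A")[, j], assay(x, "C")[, j],
             assay(x, "G")[, j], assay(x, "T")[, j])
  list(f = f / ifelse(n > 0, n, NA_real_), n = n)
}

#' Per-site pairwise diversity components for two pools
#'
#' `sitePiWithin()`, `sitePiBetween()`, and `sitePiTotal()` compute the
#' unbiased per-site diversity components for a pair of pooled samples from
#' their base tallies (named vectors over A/C/G/T at one site).  See
#' [windowFst()] for the windowed ratio-of-sums estimators built on them.
#'
#' @param c1,c2 named tally vectors (A/C/G/T at least).
#' @param p1,p2 pool sizes (haploid genome copies, >= 2).
#' @return numeric scalar (`NA` when depths/pool sizes are insufficient:
#'   within needs both depths >= 2, between needs both >= 1).
#' @examples
#' sitePiWithin(c(A = 5, C = 5, G = 0, T = 0),
#'              c(A = 5, C = 5, G = 0, T = 0), 10, 10)
#' @export
sitePiWithin <- function(c1, c2, p1, p2) {
  n1 <- sum(c1[BASES]); n2 <- sum(c2[BASES])
  if (n1 < 2 || n2 < 2 || p1 < 2 || p2 < 2) return(NA_real_)
  h1 <- n1 / (n1 - 1) * p1 / (p1 - 1) * (1 - sum((c1[BASES] / n1)^2))
  h2 <- n2 / (n2 - 1) * p2 / (p2 - 1) * (1 - sum((c2[BASES] / n2)^2))
  (h1 + h2) / 2
}

#' @rdname sitePiWithin
#' @export
sitePiBetween <- function(c1, c2) {
  n1 <- sum(c1[BASES]); n2 <- sum(c2[BASES])
  if (n1 < 1 || n2 < 1) return(NA_real_)
  1 - sum((c1[BASES] / n1) * (c2[BASES] / n2))
}

#' @rdname sitePiWithin
#' @param piWithinSite,piBetweenSite per-site values.
#' @export
sitePiTotal <- function(piWithinSite, piBetweenSite) {
  (piWithinSite + piBetweenSite) / 2
}

## all per-site components for one sample pair, vectorized
pairSiteComponents <- function(x, j1, j2) {
  a <- freqMatrix(x, j1)
  bq <- freqMatrix(x, j2)
  p1 <- poolSizes(x)[j1]
  p2 <- poolSizes(x)[j2]
  ok <- sitePassedVector(x) &
    sampleStatus(x)[, j1] == 0L & sampleStatus(x)[, j2] == 0L &
    a$n >= 2 & bq$n >= 2
  h1 <- a$n / (a$n - 1) * p1 / (p1 - 1) * (1 - rowSums(a$f^2))
  h2 <- bq$n / (bq$n - 1) * p2 / (p2 - 1) * (1 - rowSums(bq$f^2))
  w <- (h1 + h2) / 2
  btw <- 1 - rowSums(a$f * bq$f)
  list(ok = ok, within = ifelse(ok, w, 0), between = ifelse(ok, btw, 0),
       total = ifelse(ok, (w + btw) / 2, 0),
       f1 = a$f, f2 = bq$f, n1 = a$n, n2 = bq$n, p1 = p1, p2 = p2)
}

## PoPoolation2-style per-site pieces for the Kofler and Karlsson baselines
## (biallelic sites of the pair only)
pairBaselineComponents <- function(comp) {
  tot <- comp$f1 * comp$n1 + comp$f2 * comp$n2
  nAll <- rowSums(tot > 0, na.rm = TRUE)
  bi <- comp$ok & nAll == 2
  ## index of the highest- and second-highest-count base of the pair
  i1 <- max.col(replace(tot, is.na(tot), -1), ties.method = "first")
  tot2 <- tot
  tot2[cbind(seq_len(nrow(tot)), i1)] <- -1
  i2 <- max.col(replace(tot2, is.na(tot2), -1), ties.method = "first")
  rows <- seq_len(nrow(tot))
  fa1 <- comp$f1[cbind(rows, i2)]     # minor-allele freq in pool 1
  fa2 <- comp$f2[cbind(rows, i2)]
  ne1 <- pmin(comp$n1, comp$p1)
  ne2 <- pmin(comp$n2, comp$p2)
  ## Kofler: Bessel-style correction with n_eff = min(depth, pool size)
  piw1 <- ne1 / (ne1 - 1) * 2 * fa1 * (1 - fa1)
  piw2 <- ne2 / (ne2 - 1) * 2 * fa2 * (1 - fa2)
  fbar <- (fa1 + fa2) / 2
  net <- pmin(ne1, ne2)
  pit <- net / (net - 1) * 2 * fbar * (1 - fbar)
  ## Karlsson: sample-allele-count based numerator/denominator
  a1 <- fa1 * comp$n1
  a2 <- fa2 * comp$n2
  h1 <- a1 * (comp$n1 - a1) / (comp$n1 * (comp$n1 - 1))
  h2 <- a2 * (comp$n2 - a2) / (comp$n2 * (comp$n2 - 1))
  kN <- (fa1 - fa2)^2 - h1 / comp$n1 - h2 / comp$n2
  kD <- kN + h1 + h2
  zero <- function(v) ifelse(bi & is.finite(v), v, 0)
  list(bi = bi,
       koflerWithin = zero((piw1 + piw2) / 2), koflerTotal = zero(pit),
       karlssonNum = zero(kN), karlssonDen = zero(kD))
}

#' Window FST ratios from component sums
#'
#' `fstNei()` and `fstHudson()` turn window sums of the per-site diversity
#' components into the two FST variants, as ratios of sums:
#' `1 - piWithinSum / piTotalSum` (Nei) and
#' `1 - piWithinSum / piBetweenSum` (Hudson).  A zero denominator (no
#' variation in the window) yields `NA`.  Negative values are reported
#' as-is; unbiased estimators scatter below zero under weak
#' differentiation and clamping would re-introduce bias.
#'
#' @param piWithinSum,piTotalSum,piBetweenSum window sums.
#' @return numeric (vectorized).
#' @export
fstNei <- function(piWithinSum, piTotalSum) {
  ifelse(piTotalSum > 0, 1 - piWithinSum / piTotalSum, NA_real_)
}

#' @rdname fstNei
#' @export
fstHudson <- function(piWithinSum, piBetweenSum) {
  ifelse(piBetweenSum > 0, 1 - piWithinSum / piBetweenSum, NA_real_)
}

#' Pairwise windowed FST
#'
#' Computes FST for every requested sample pair per window, by summing
#' per-site diversity components over the window and forming the ratio of
#' sums.  Methods: `"hudson"` and `"nei"` (unbiased pi-components, all
#' sites with both depths >= 2, multiallelic sites included through the
#' full four-base sums), plus the PoPoolation2 comparison baselines
#' `"kofler"` ((pi_total - pi_within)/pi_total with n_eff = min(depth,
#' pool size) corrections) and `"karlsson"` (the Karlsson et al. 2007
#' ratio of sums), both restricted to biallelic sites of the pair.  The
#' baselines are biased upward at low read depth and small pool size and
#' are included for comparison only.
#'
#' @param x A filtered, classified [PoolSeq-class] object (>= 2 samples,
#'   pool sizes set).
#' @param windows A `PoolWindows` object.
#' @param method one of `"hudson"`, `"nei"`, `"kofler"`, `"karlsson"`.
#' @param pairs optional 2-column matrix/data.frame of sample names or
#'   indices; default all pairs.
#' @param keepComponents include the window component sums in the output.
#' @return long-format data.frame: one row per window x pair with `chrom`,
#'   `start`, `end`, `sample1`, `sample2`, `fst`, and (with
#'   `keepComponents`) `pi_within_sum`, `pi_between_sum`, `pi_total_sum`.
#' @export
windowFst <- function(x, windows, method = c("hudson", "nei", "kofler",
                                             "karlsson"),
                      pairs = NULL, keepComponents = TRUE) {
  stopifnot(is(x, "PoolSeq"), is(windows, "PoolWindows"))
  method <- match.arg(method)
  if (ncol(x) < 2) stop("FST needs at least 2 samples")
  if (is.null(pairs)) {
    pairs <- t(utils::combn(seq_len(ncol(x)), 2L))
  } else {
    pairs <- as.matrix(pairs)
    if (is.character(pairs)) {
      pairs <- matrix(match(pairs, colnames(x)), ncol = 2L)
    }
  }
  info <- windows@info
  hts <- windows@hits
  nw <- nrow(info)
  sumBy <- function(v) {
    s <- numeric(nw)
    if (nrow(hts)) {
      r <- rowsum(v[hts$site], hts$window)
      s[as.integer(rownames(r))] <- r[, 1]
    }
    s
  }
  out <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    j1 <- pairs[r, 1L]
    j2 <- pairs[r, 2L]
    comp <- pairSiteComponents(x, j1, j2)
    if (method %in% c("hudson", "nei")) {
      wS <- sumBy(comp$within)
      bS <- sumBy(comp$between)
      tS <- sumBy(comp$total)
      fst <- if (method == "hudson") fstHudson(wS, bS) else fstNei(wS, tS)
    } else {
      base <- pairBaselineComponents(comp)
      if (method == "kofler") {
        wS <- sumBy(base$koflerWithin)
        tS <- sumBy(base$koflerTotal)
        bS <- NA_real_
        fst <- ifelse(tS > 0, (tS - wS) / tS, NA_real_)
      } else {
        nS <- sumBy(base$karlssonNum)
        dS <- sumBy(base$karlssonDen)
        fst <- ifelse(dS > 0, nS / dS, NA_real_)
        wS <- nS; tS <- dS; bS <- NA_real_
      }
    }
    df <- data.frame(
      chrom = info$chrom, start = info$start, end = info$end,
      sample1 = rep(colnames(x)[j1], nw),
      sample2 = rep(colnames(x)[j2], nw),
      method = rep(method, nw), fst = fst
    )
    if (keepComponents && method %in% c("hudson", "nei")) {
      df$pi_within_sum <- wS
      df$pi_between_sum <- bS
      df$pi_total_sum <- tS
    }
    out[[r]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
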