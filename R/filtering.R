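#' Region filter: keep only positions inside (or outside) regions
#'
#' Region filters completely remove positions from the data, unlike masks
#' ([applyMask()]) which flag them but keep them in the stream.  Removed
#' positions therefore do not count toward any downstream tally.
#'
#' @param x A [PoolSeq-class] object.
#' @param regions A [GenomicRanges::GRanges] (see [readRegions()]).
#' @param invert keep positions *outside* all regions instead.
#' @return The subset [PoolSeq-class]; an empty region list with
#'   `invert = FALSE` removes everything.
#' @export
filterRegions <- function(x, regions, invert = FALSE) {
  stopifnot(is(x, "PoolSeq"), is(regions, "GRanges"))
  inside <- IRanges::overlapsAny(rowRanges(x), regions, ignore.strand = TRUE)
  x[if (invert) !inside else inside, ]
}

#' Apply a position mask
#'
#' Positions not covered by the mask are flagged `FILTERED(masked)` but stay
#' in the stream, so window averaging denominators can still count them.
#' With `samples = NULL` the mask is global and sets the site-level status;
#' otherwise only the named/indexed samples' `sampleStatus` entries are
#' flagged.  A chromosome absent from the mask is entirely invalid.
#'
#' @param x A [PoolSeq-class] object.
#' @param mask [GenomicRanges::GRanges] of VALID positions ([readMask()]).
#' @param samples `NULL` for a global mask, else sample names or indices.
#' @return `x` with filter states updated.
#' @export
applyMask <- function(x, mask, samples = NULL) {
  stopifnot(is(x, "PoolSeq"), is(mask, "GRanges"))
  valid <- IRanges::overlapsAny(rowRanges(x), mask, ignore.strand = TRUE)
  if (is.null(samples)) {
    st <- siteStatus(x)
    st[!valid & st == SITE_STATUS[["PASSED"]]] <- SITE_STATUS[["masked"]]
    siteStatus(x) <- st
  } else {
    if (is.character(samples)) samples <- match(samples, colnames(x))
    ss <- sampleStatus(x)
    for (j in samples) {
      upd <- !valid & ss[, j] == SAMPLE_STATUS[["PASSED"]]
      ss[upd, j] <- SAMPLE_STATUS[["masked"]]
    }
    sampleStatus(x) <- ss
  }
  x
}

#' Numerical per-sample quality filters
#'
#' Applies, in order: (1) rare-base masking — any base tally strictly below
#' `minCount` is zeroed (the site is kept; this mirrors the role the minimum
#' allele count b plays inside the estimator denominators); (2) depth
#' filters on the recomputed depth — a sample is flagged `low_depth` /
#' `high_depth` when its depth falls outside `[minReadDepth, maxReadDepth]`
#' (0 disables either bound); (3) an optional deletion guard — a sample is
#' flagged `high_deletion` when DEL/(depth+DEL) exceeds
#' `maxDeletionFraction`.  Already-filtered samples are left untouched.
#'
#' @param x A [PoolSeq-class] object.
#' @param minCount minimum per-allele count; defaults to `minCount(x)`.
#' @param minReadDepth,maxReadDepth depth bounds (0 = off).
#' @param maxDeletionFraction proportion in \[0,1\], `NA` = off.
#' @return `x` with counts zeroed and filter states updated.
#' @export
applyNumericFilters <- function(x, minCount = NULL, minReadDepth = 0L,
                                maxReadDepth = 0L,
                                maxDeletionFraction = NA_real_) {
  stopifnot(is(x, "PoolSeq"))
  if (is.null(minCount)) minCount <- minCount(x)
  if (minReadDepth > 0L && maxReadDepth > 0L &&
      minReadDepth > maxReadDepth) {
    stop("minReadDepth > maxReadDepth")
  }
  if (minCount > 1L) {
    for (b in BASES) {
      m <- assay(x, b)
      m[m > 0L & m < minCount] <- 0L
      assay(x, b) <- m
    }
  }
  depth <- readDepth(x)
  ss <- sampleStatus(x)
  ok <- ss == SAMPLE_STATUS[["PASSED"]]
  if (minReadDepth > 0L) {
    flag <- ok & depth < minReadDepth
    ss[flag] <- SAMPLE_STATUS[["low_depth"]]
    ok <- ok & !flag
  }
  if (maxReadDepth > 0L) {
    flag <- ok & depth > maxReadDepth
    ss[flag] <- SAMPLE_STATUS[["high_depth"]]
    ok <- ok & !flag
  }
  if (!is.na(maxDeletionFraction)) {
    del <- assay(x, "DEL")
    frac <- ifelse(depth + del > 0, del / (depth + del), 0)
    flag <- ok & frac > maxDeletionFraction
    ss[flag] <- SAMPLE_STATUS[["high_deletion"]]
  }
  sampleStatus(x) <- ss
  x
}

#' Classify sites as missing, invariant, or SNPs
#'
#' Counts are merged over PASSED samples; a site with exactly one base with
#' nonzero count is invariant, two nonzero counts make a biallelic SNP,
#' three or more a multiallelic SNP, and zero nonzero counts mean missing.
#' A SNP whose minor-allele frequency (on the merged counts) is below
#' `minAlleleFrequency` is demoted to invariant; the biallelic restriction
#' is evaluated before this demotion.  `onlySNPs` / `onlyBiallelic` update
#' the site filter status accordingly.
#'
#' @param x A [PoolSeq-class] object (numeric filters already applied).
#' @param minAlleleFrequency proportion in \[0,1\].
#' @param onlySNPs flag non-SNP sites as filtered.
#' @param onlyBiallelic flag non-biallelic sites as filtered (implies
#'   `onlySNPs`).
#' @return `x` with `siteClass` and `siteStatus` filled in.
#' @export
classifySites <- function(x, minAlleleFrequency = 0, onlySNPs = FALSE,
                          onlyBiallelic = FALSE) {
  stopifnot(is(x, "PoolSeq"))
  if (onlyBiallelic) onlySNPs <- TRUE
  ok <- sampleStatus(x) == SAMPLE_STATUS[["PASSED"]]
  tot <- vapply(BASES, function(b) rowSums(assay(x, b) * ok),
                numeric(nrow(x)))
  if (nrow(x) == 1L) tot <- matrix(tot, nrow = 1L)
  nAlleles <- rowSums(tot > 0)
  cls <- rep("MISSING", nrow(x))
  cls[nAlleles == 1L] <- "INVARIANT"
  cls[nAlleles == 2L] <- "SNP_BIALLELIC"
  cls[nAlleles >= 3L] <- "SNP_MULTIALLELIC"
  demoted <- rep(FALSE, nrow(x))
  if (minAlleleFrequency > 0) {
    depth <- rowSums(tot)
    minor <- ifelse(depth > 0, 1 - apply(tot, 1L, max) / depth, 0)
    demoted <- nAlleles >= 2L & minor < minAlleleFrequency
    cls[demoted] <- "INVARIANT"
  }
  mcols(rowRanges(x))$siteClass <- cls
  if (onlySNPs) {
    st <- siteStatus(x)
    upd <- st == SITE_STATUS[["PASSED"]]
    st[upd & cls == "MISSING"] <- SITE_STATUS[["no_data"]]
    st[upd & demoted] <- SITE_STATUS[["low_allele_frequency"]]
    st[upd & cls == "INVARIANT" & !demoted] <- SITE_STATUS[["not_snp"]]
    if (onlyBiallelic) {
      st[upd & cls == "SNP_MULTIALLELIC"] <- SITE_STATUS[["not_biallelic"]]
    }
    siteStatus(x) <- st
  }
  x
}

## multivariate hypergeometric draw: k reads without replacement from counts
rmvhyper1 <- function(counts, k) {
  out <- integer(length(counts))
  left <- sum(counts)
  for (i in seq_along(counts)) {
    if (k <= 0L) break
    if (i == length(counts)) {
      out[i] <- k
      break
    }
    out[i] <- stats::rhyper(1L, counts[i], left - counts[i], k)
    left <- left - counts[i]
    k <- k - out[i]
  }
  out
}

## largest-remainder proportional scaling to sum exactly k (ties broken by
## position order, i.e. the fixed base order)
scaleLargestRemainder <- function(counts, k) {
  tot <- sum(counts)
  if (tot == 0L) return(integer(length(counts)))
  exact <- counts * k / tot
  out <- floor(exact)
  rem <- k - sum(out)
  if (rem > 0L) {
    ord <- order(exact - out, decreasing = TRUE)
    out[ord[seq_len(rem)]] <- out[ord[seq_len(rem)]] + 1L
  }
  as.integer(out)
}

#' Limit excessive read depths by subsampling or rescaling
#'
#' Per site and sample: when the read depth (A+C+G+T) exceeds `maxDepth`,
#' the four base tallies are reduced to sum exactly `maxDepth` by one of
#' three methods: a multivariate hypergeometric draw
#' (`"subsample-without-replacement"`), a multinomial draw with
#' probabilities proportional to the counts
#' (`"subsample-with-replacement"`), or deterministic proportional scaling
#' with largest-remainder rounding (`"rescale"`).  All three preserve the
#' expected allele frequencies.  `N` and `DEL` tallies are rescaled
#' deterministically by the same depth ratio.  Sites at or below `maxDepth`
#' pass through unchanged.
#'
#' @param x A [PoolSeq-class] object.
#' @param maxDepth target maximum depth (>= 1).
#' @param method one of the three methods above.
#' @param seed optional integer seed for the stochastic methods.
#' @return `x` with reduced counts.
#' @export
subsampleCounts <- function(x, maxDepth,
                            method = c("subsample-without-replacement",
                                       "subsample-with-replacement",
                                       "rescale"),
                            seed = NULL) {
  stopifnot(is(x, "PoolSeq"))
  method <- match.arg(method)
  if (maxDepth < 1L) stop("maxDepth must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  depth <- readDepth(x)
  over <- which(depth > maxDepth, arr.ind = TRUE)
  if (length(over) == 0L) return(x)
  cnts <- lapply(BASES, function(b) assay(x, b))
  names(cnts) <- BASES
  nmat <- assay(x, "N")
  dmat <- assay(x, "DEL")
  for (r in seq_len(nrow(over))) {
    i <- over[r, 1L]
    j <- over[r, 2L]
    v <- vapply(BASES, function(b) cnts[[b]][i, j], integer(1))
    d <- sum(v)
    nv <- switch(method,
      "subsample-without-replacement" = rmvhyper1(v, as.integer(maxDepth)),
      "subsample-with-replacement" =
        as.integer(stats::rmultinom(1L, maxDepth, v / d)),
      "rescale" = scaleLargestRemainder(v, as.integer(maxDepth))
    )
    for (b in seq_along(BASES)) cnts[[BASES[b]]][i, j] <- nv[b]
    nmat[i, j] <- as.integer(roundHalfAway(nmat[i, j] * maxDepth / d))
    dmat[i, j] <- as.integer(roundHalfAway(dmat[i, j] * maxDepth / d))
  }
  for (b in BASES) assay(x, b) <- cnts[[b]]
  assay(x, "N") <- nmat
  assay(x, "DEL") <- dmat
  x
}

#' Apply the full filter cascade
#'
#' Runs the fixed-order cascade region filter -> masks -> numerical filters
#' -> SNP classification -> depth subsampling, and records conservation
#' tallies in `metadata(x)$filterLog`: positions `read`, `regionRemoved`,
#' `emitted` (= read - regionRemoved), `sitePassed`, `siteFiltered`
#' (= emitted - sitePassed), and `snps`.
#'
#' @param x A [PoolSeq-class] object.
#' @param regions,invertRegions see [filterRegions()]; `NULL` skips.
#' @param mask global mask, `NULL` skips ([applyMask()]).
#' @param sampleMasks named list of per-sample masks, `NULL` skips.
#' @param minCount,minReadDepth,maxReadDepth,maxDeletionFraction see
#'   [applyNumericFilters()].
#' @param minAlleleFrequency,onlySNPs,onlyBiallelic see [classifySites()].
#' @param maxDepth,subsampleMethod,seed see [subsampleCounts()]; `NA`
#'   `maxDepth` skips.
#' @return The filtered [PoolSeq-class] with `metadata(x)$filterLog` set.
#' @export
applyFilters <- function(x, regions = NULL, invertRegions = FALSE,
                         mask = NULL, sampleMasks = NULL,
                         minCount = NULL, minReadDepth = 0L,
                         maxReadDepth = 0L,
                         maxDeletionFraction = NA_real_,
                         minAlleleFrequency = 0, onlySNPs = FALSE,
                         onlyBiallelic = FALSE, maxDepth = NA_integer_,
                         subsampleMethod = "subsample-without-replacement",
                         seed = NULL) {
  nRead <- nrow(x)
  if (!is.null(regions)) x <- filterRegions(x, regions, invertRegions)
  nEmitted <- nrow(x)
  if (!is.null(mask)) x <- applyMask(x, mask)
  if (!is.null(sampleMasks)) {
    for (nm in names(sampleMasks)) {
      x <- applyMask(x, sampleMasks[[nm]], samples = nm)
    }
  }
  x <- applyNumericFilters(x, minCount, minReadDepth, maxReadDepth,
                           maxDeletionFraction)
  x <- classifySites(x, minAlleleFrequency, onlySNPs, onlyBiallelic)
  if (!is.na(maxDepth)) x <- subsampleCounts(x, maxDepth, subsampleMethod,
                                             seed = seed)
  passed <- sitePassedVector(x)
  metadata(x)$filterLog <- list(
    read = nRead,
    regionRemoved = nRead - nEmitted,
    emitted = nEmitted,
    sitePassed = sum(passed),
    siteFiltered = nEmitted - sum(passed),
    snps = sum(passed & siteClass(x) %in%
                 c("SNP_BIALLELIC", "SNP_MULTIALLELIC"))
  )
  x
}

## a site counts as "valid"/PASSED when its site-level status is PASSED and
## at least one sample passed with data (class not MISSING when classified)
sitePassedVector <- function(x) {
  ok <- siteStatus(x) == SITE_STATUS[["PASSED"]]
  anySample <- rowSums(sampleStatus(x) == SAMPLE_STATUS[["PASSED"]]) > 0
  cls <- siteClass(x)
  hasData <- if (all(is.na(cls))) {
    rowSums(readDepth(x) * (sampleStatus(x) == 0L)) > 0
  } else {
    !is.na(cls) & cls != "MISSING"
  }
  ok & anySample & hasData
}
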