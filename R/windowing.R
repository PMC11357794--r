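#' @title Genomic windows over a PoolSeq object
#' @description
#' `makeWindows()` assembles the positions of a filtered [PoolSeq-class]
#' object into one of six window types: fixed-width intervals (optionally
#' sliding, with a stride smaller than the width), a fixed number of SNPs
#' per window, user-defined (possibly nested or overlapping) regions,
#' single SNPs, whole chromosomes, or the whole genome.  Interval windows
#' are anchored at position 1 of each chromosome and use 1-based inclusive
#' bounds.  Without chromosome lengths, windows end at the last observed
#' position and trailing empty windows are not emitted; with lengths, the
#' full tiling (including empty windows) is produced so that per-base-pair
#' averages over the whole genome are possible.
#'
#' @param x A [PoolSeq-class] object, sorted by (chromosome, position), with
#'   [classifySites()] already applied when SNP-based windows are requested.
#' @param type one of `"interval"`, `"snp_count"`, `"regions"`,
#'   `"single_snp"`, `"chromosome"`, `"genome"`.
#' @param width,stride interval window width and stride in bases
#'   (`1 <= stride <= width`; `stride < width` gives overlapping sliding
#'   windows).
#' @param count number of SNPs per window for `type = "snp_count"`.
#' @param regions [GenomicRanges::GRanges] for `type = "regions"`; a
#'   position inside several overlapping regions enters each of their
#'   windows.
#' @param chromosomeLengths optional named integer vector.
#' @return A `PoolWindows` object: window bounds plus the assignment of
#'   site indices to windows.
#' @export
makeWindows <- function(x, type = c("interval", "snp_count", "regions",
                                    "single_snp", "chromosome", "genome"),
                        width = NULL, stride = width, count = NULL,
                        regions = NULL, chromosomeLengths = NULL) {
  type <- match.arg(type)
  stopifnot(is(x, "PoolSeq"))
  chrom <- chromosomes(x)
  pos <- positions(x)
  if (!isPositionSorted(chrom, pos)) {
    stop("makeWindows() requires input sorted by (chromosome, position)")
  }
  chrs <- unique(chrom)
  chrEnd <- function(chr) {
    if (!is.null(chromosomeLengths) && chr %in% names(chromosomeLengths)) {
      as.integer(chromosomeLengths[[chr]])
    } else if (any(chrom == chr)) {
      max(pos[chrom == chr])
    } else {
      NA_integer_
    }
  }
  snp <- !is.na(siteClass(x)) &
    siteClass(x) %in% c("SNP_BIALLELIC", "SNP_MULTIALLELIC") &
    siteStatus(x) == SITE_STATUS[["PASSED"]]

  if (type == "interval") {
    stopifnot(!is.null(width), width >= 1)
    if (is.null(stride)) stride <- width
    if (stride < 1 || stride > width) stop("need 1 <= stride <= width")
    info <- do.call(rbind, lapply(chrs, function(chr) {
      L <- chrEnd(chr)
      starts <- seq.int(1L, L, by = as.integer(stride))
      data.frame(chrom = chr, start = starts,
                 end = pmin(starts + as.integer(width) - 1L, L))
    }))
  } else if (type == "snp_count") {
    stopifnot(!is.null(count), count >= 1)
    info <- do.call(rbind, lapply(chrs, function(chr) {
      sp <- pos[chrom == chr & snp]
      if (length(sp) == 0L) return(NULL)
      grp <- ceiling(seq_along(sp) / count)
      data.frame(chrom = chr,
                 start = tapply(sp, grp, min),
                 end = tapply(sp, grp, max))
    }))
    if (is.null(info)) info <- data.frame(chrom = character(),
                                          start = integer(), end = integer())
  } else if (type == "regions") {
    stopifnot(is(regions, "GRanges"))
    info <- data.frame(chrom = as.character(seqnames(regions)),
                       start = start(regions), end = end(regions))
  } else if (type == "single_snp") {
    info <- data.frame(chrom = chrom[snp], start = pos[snp], end = pos[snp])
  } else if (type == "chromosome") {
    info <- data.frame(chrom = chrs, start = 1L,
                       end = vapply(chrs, chrEnd, integer(1)))
  } else { # genome
    total <- sum(vapply(chrs, chrEnd, integer(1)))
    info <- data.frame(chrom = "genome", start = 1L,
                       end = if (length(chrs)) total else 1L)
  }
  if (is.null(info)) {
    info <- data.frame(chrom = character(), start = integer(),
                       end = integer())
  }
  rownames(info) <- NULL

  if (type == "genome") {
    hits <- data.frame(window = rep(1L, nrow(x)), site = seq_len(nrow(x)))
  } else if (nrow(info) == 0L) {
    hits <- data.frame(window = integer(), site = integer())
  } else {
    wgr <- GRanges(info$chrom, IRanges(info$start, info$end))
    ov <- GenomicRanges::findOverlaps(rowRanges(x), wgr,
                                      ignore.strand = TRUE)
    hits <- data.frame(window = S4Vectors::subjectHits(ov),
                       site = S4Vectors::queryHits(ov))
  }
  new("PoolWindows", info = info, hits = hits, type = type)
}

#' @rdname makeWindows
#' @export
setClass("PoolWindows", representation(
  info = "data.frame", hits = "data.frame", type = "character"
))

setMethod("show", "PoolWindows", function(object) {
  cat("PoolWindows:", nrow(object@info), "windows of type",
      object@type, "\n")
  invisible(NULL)
})

#' Per-window bookkeeping tallies
#'
#' For each window: `windowSize` (last - first + 1 bases), `withData`
#' (positions present in the stream within bounds), `passed` (positions
#' that passed all filters: invariants and SNPs; restricted to mask-valid
#' positions when a mask is given), `snps` (passed SNP positions), and
#' `maskValid` (positions in bounds marked valid by the mask; equals
#' `windowSize` without a mask).  These tallies always satisfy
#' `snps <= passed <= withData <= windowSize`.
#'
#' @param x A [PoolSeq-class] object.
#' @param windows A `PoolWindows` object from [makeWindows()].
#' @param mask optional [GenomicRanges::GRanges] of valid positions.
#' @return A data.frame, one row per window.
#' @export
windowTallies <- function(x, windows, mask = NULL) {
  stopifnot(is(x, "PoolSeq"), is(windows, "PoolWindows"))
  info <- windows@info
  nw <- nrow(info)
  h <- windows@hits
  passedV <- sitePassedVector(x)
  snpV <- passedV & !is.na(siteClass(x)) &
    siteClass(x) %in% c("SNP_BIALLELIC", "SNP_MULTIALLELIC")
  if (!is.null(mask)) {
    maskOK <- IRanges::overlapsAny(rowRanges(x), mask, ignore.strand = TRUE)
    passedV <- passedV & maskOK
    snpV <- snpV & maskOK
  }
  tally <- function(v) {
    out <- numeric(nw)
    if (nrow(h)) {
      s <- rowsum(as.numeric(v[h$site]), h$window)
      out[as.integer(rownames(s))] <- s[, 1]
    }
    as.integer(out)
  }
  size <- info$end - info$start + 1L
  maskValid <- if (is.null(mask)) {
    size
  } else if (windows@type == "genome") {
    rep(sum(width(GenomicRanges::reduce(mask))), nw)
  } else {
    wgr <- GRanges(info$chrom, IRanges(info$start, info$end))
    vapply(seq_len(nw), function(i) {
      sum(width(GenomicRanges::intersect(wgr[i], mask,
                                         ignore.strand = TRUE)))
    }, numeric(1))
  }
  data.frame(
    chrom = info$chrom, start = info$start, end = info$end,
    windowSize = size,
    withData = tally(rep(TRUE, nrow(x))),
    passed = tally(passedV),
    snps = tally(snpV),
    maskValid = as.integer(maskValid)
  )
}

#' Window averaging denominators
#'
#' Converts per-window sums into per-base-pair averages under one of six
#' policies: `"window-size"` (last - first + 1; likely an underestimate of
#' the per-site value when data is sparse), `"available-loci"` (positions
#' with data), `"valid-loci"` (positions that passed all filters, the
#' recommended default; takes the mask into account when one was given to
#' [windowTallies()]), `"snp-count"` (SNPs only; likely an overestimate),
#' `"sum"` (no averaging, denominator 1), or `"mask"` (mask-valid positions
#' in bounds, for externally defined denominators).  A zero denominator
#' yields `NA` (the window statistic is reported as not available, never a
#' division by zero).
#'
#' @param tallies data.frame from [windowTallies()].
#' @param policy one of the six policies.
#' @return numeric vector of denominators (`NA` where zero).
#' @export
windowDenominator <- function(tallies,
                              policy = c("valid-loci", "window-size",
                                         "available-loci", "snp-count",
                                         "sum", "mask")) {
  policy <- match.arg(policy)
  d <- switch(policy,
    "window-size" = tallies$windowSize,
    "available-loci" = tallies$withData,
    "valid-loci" = tallies$passed,
    "snp-count" = tallies$snps,
    "sum" = rep(1, nrow(tallies)),
    "mask" = tallies$maskValid
  )
  d <- as.numeric(d)
  d[d <= 0] <- NA_real_
  d
}
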