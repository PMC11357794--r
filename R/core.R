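#' Merge per-sample base tallies
#'
#' Element-wise sum of a list of tally vectors, the elementary operation
#' behind sample grouping (e.g. combining sequencing runs of the same pool
#' into one artificial pool).  Inputs flagged as filtered contribute zero;
#' the merged tally is PASSED iff at least one input is PASSED.
#'
#' @param countsList non-empty list of named numeric vectors with names among
#'   `A`, `C`, `G`, `T`, `N`, `DEL` (missing tallies count as zero).
#' @param passed logical vector, one per input (default all `TRUE`).
#' @return list with `counts` (named vector over all six tallies) and
#'   `passed` (logical scalar).
#' @examples
#' mergeCounts(list(c(A = 2), c(A = 3, C = 1)))$counts
#' @export
mergeCounts <- function(countsList, passed = NULL) {
  if (!is.list(countsList) || length(countsList) == 0L) {
    stop("mergeCounts() needs a non-empty list of tally vectors ",
         "(invalid sample grouping)")
  }
  if (is.null(passed)) passed <- rep(TRUE, length(countsList))
  stopifnot(length(passed) == length(countsList))
  out <- stats::setNames(numeric(length(TALLIES)), TALLIES)
  for (i in seq_along(countsList)) {
    if (!passed[i]) next
    v <- countsList[[i]]
    stopifnot(all(names(v) %in% TALLIES))
    out[names(v)] <- out[names(v)] + v
  }
  list(counts = out, passed = any(passed))
}

#' Group samples of a PoolSeq object by merging their counts
#'
#' @param x A [PoolSeq-class] object.
#' @param groups factor or vector of length `ncol(x)` assigning each sample to
#'   a group; group order follows first appearance.
#' @return A [PoolSeq-class] with one column per group.  Filtered entries
#'   (non-zero `sampleStatus`) contribute zero counts; a merged entry is
#'   PASSED iff at least one member passed.  Pool sizes add up across
#'   members (`NA` if any member's is `NA`).
#' @export
mergeSamples <- function(x, groups) {
  stopifnot(is(x, "PoolSeq"), length(groups) == ncol(x))
  if (length(groups) == 0L) stop("cannot merge zero samples")
  groups <- factor(groups, levels = unique(as.character(groups)))
  ok <- sampleStatus(x) == 0L
  grpidx <- split(seq_len(ncol(x)), groups)
  merge1 <- function(m) {
    vapply(grpidx, function(j) {
      mm <- m[, j, drop = FALSE] * ok[, j, drop = FALSE]
      as.integer(rowSums(mm))
    }, integer(nrow(x)))
  }
  counts <- lapply(TALLIES, function(b) {
    v <- merge1(assay(x, b))
    if (nrow(x) == 1L) v <- matrix(v, nrow = 1L)
    v
  })
  names(counts) <- TALLIES
  anyok <- vapply(grpidx, function(j) {
    rowSums(ok[, j, drop = FALSE]) > 0
  }, logical(nrow(x)))
  if (nrow(x) == 1L) anyok <- matrix(anyok, nrow = 1L)
  status <- ifelse(anyok, SAMPLE_STATUS[["PASSED"]], SAMPLE_STATUS[["missing"]])
  ps <- vapply(grpidx, function(j) {
    v <- poolSizes(x)[j]
    if (any(is.na(v))) NA_integer_ else as.integer(sum(v))
  }, integer(1))
  out <- PoolSeq(
    counts = counts, chrom = chromosomes(x), pos = positions(x),
    ref = refBase(x), alt = altBase(x), poolSizes = ps,
    minCount = minCount(x), sampleNames = levels(groups),
    sampleStatus = status
  )
  siteStatus(out) <- siteStatus(x)
  out
}

## Reference genome lookup: accepts a FASTA path or a DNAStringSet; names are
## truncated at the first whitespace to match chromosome names.
loadReference <- function(reference) {
  if (is.character(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  stopifnot(is(reference, "DNAStringSet"))
  names(reference) <- sub("\\s.*$", "", names(reference))
  reference
}

referenceBases <- function(reference, chrom, pos) {
  out <- rep(NA_character_, length(chrom))
  for (chr in unique(chrom)) {
    if (!chr %in% names(reference)) next
    i <- which(chrom == chr)
    s <- as.character(reference[[chr]])
    p <- pos[i]
    inside <- p >= 1 & p <= nchar(s)
    out[i][inside] <- toupper(substring(s, p[inside], p[inside]))
  }
  out
}

#' Infer reference and alternative bases from counts
#'
#' Fills the per-site `ref`/`alt` bases of a [PoolSeq-class] object.  Counts
#' are first merged across all PASSED samples.  Without a reference genome,
#' `ref` is the most common base and `alt` the second most common; ties are
#' broken deterministically by the fixed base order A < C < G < T.  With a
#' reference genome, `ref` is taken from it (when it is one of A/C/G/T) and
#' `alt` is the highest-count base different from `ref`.  `alt` is `N` when
#' no second (or no non-ref) base is observed.  A warning is raised when the
#' reference base disagrees with every observed count; the counts are kept.
#'
#' A ref base already present on the object (e.g. parsed from a sync or
#' pileup file) is kept by default; only positions whose ref is `N` are
#' inferred.  Set `keepExisting = FALSE` to re-infer everything from the
#' counts.
#'
#' @param x A [PoolSeq-class] object.
#' @param reference optional FASTA path or [Biostrings::DNAStringSet].
#' @param keepExisting keep file-provided ref bases (default).
#' @return `x` with `refBase`/`altBase` filled in.
#' @export
inferRefAlt <- function(x, reference = NULL, keepExisting = TRUE) {
  stopifnot(is(x, "PoolSeq"))
  if (nrow(x) == 0L) return(x)
  ok <- sampleStatus(x) == 0L
  tot <- vapply(BASES, function(b) {
    rowSums(assay(x, b) * ok)
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) tot <- matrix(tot, nrow = 1L, dimnames = list(NULL, BASES))
  ## ties.method = "first" on columns ordered A,C,G,T implements the
  ## alphabetical tie-break
  i1 <- max.col(tot, ties.method = "first")
  ref <- BASES[i1]
  fromRef <- rep(FALSE, length(ref))
  if (keepExisting) {
    ref0 <- refBase(x)
    keep <- !is.na(ref0) & ref0 %in% BASES
    ref[keep] <- ref0[keep]
    fromRef <- keep
  }
  if (!is.null(reference)) {
    reference <- loadReference(reference)
    rb <- referenceBases(reference, chromosomes(x), positions(x))
    use <- !is.na(rb) & rb %in% BASES
    ref[use] <- rb[use]
    fromRef <- use
    totref <- tot[cbind(seq_len(nrow(tot)), match(ref, BASES))]
    bad <- use & totref == 0 & rowSums(tot) > 0
    if (any(bad)) {
      warning(sum(bad), " position(s) where the reference base is absent ",
              "from all observed counts; counts retained")
    }
  }
  tot2 <- tot
  tot2[cbind(seq_len(nrow(tot2)), match(ref, BASES))] <- -1
  i2 <- max.col(tot2, ties.method = "first")
  alt <- BASES[i2]
  alt[tot2[cbind(seq_len(nrow(tot2)), i2)] <= 0] <- "N"
  ## no data at all: ref unknown unless the reference genome provided it
  nodata <- rowSums(tot) == 0
  ref[nodata & !fromRef] <- "N"
  refBase(x) <- ref
  altBase(x) <- alt
  x
}
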