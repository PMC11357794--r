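## sync format (PoPoolation2): tab-separated chrom, pos, ref, then one field
## per sample with colon-separated counts in on-disk order A:T:C:G:N:DEL.
## Note the on-disk order differs from the internal A/C/G/T slot order.
SYNC_ORDER <- c("A", "T", "C", "G", "N", "DEL")

## open any text input, transparently gunzipping
textConnectionFor <- function(path) gzfile(path, open = "rt")

#' Read a sync file
#'
#' Parses the PoPoolation2 sync allele-count format: one line per genomic
#' position with tab-separated chromosome, 1-based position, reference base,
#' and one `A:T:C:G:N:DEL` count field per sample.  Both the 6-field and the
#' older 4-field (`A:T:C:G`) sample dialect are accepted (missing `N`/`DEL`
#' read as zero), an optional header line starting with `#` is skipped, and
#' gzip compression is transparent.  A sample field of `.:.:.:.:.:.` or `-`
#' denotes missing data and yields all-zero counts flagged as
#' `FILTERED(missing)`.
#'
#' @param path file path (optionally gzipped).
#' @param poolSizes,minCount,sampleNames passed to [PoolSeq()].
#' @return A [PoolSeq-class] object; `alt` is left as `N` (use
#'   [inferRefAlt()]).
#' @export
readSync <- function(path, poolSizes = NA_integer_, minCount = 1L,
                     sampleNames = NULL) {
  con <- textConnectionFor(path)
  on.exit(close(con))
  lines <- readLines(con)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(PoolSeq(
      counts = list(A = matrix(integer(), 0, 1), C = matrix(integer(), 0, 1),
                    G = matrix(integer(), 0, 1), T = matrix(integer(), 0, 1)),
      chrom = character(), pos = integer(), poolSizes = poolSizes,
      minCount = minCount, sampleNames = sampleNames
    ))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 4L) || length(unique(nf)) != 1L) {
    bad <- lineno[which(nf < 4L | nf != nf[1])[1]]
    stop("sync parse error at line ", bad, ": inconsistent column count")
  }
  m <- matrix(unlist(parts), nrow = length(lines), byrow = TRUE)
  chrom <- m[, 1]
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos) || any(pos < 1L)) {
    bad <- lineno[which(is.na(pos) | pos < 1L)[1]]
    stop("sync parse error at line ", bad, ": invalid position")
  }
  ref <- toupper(m[, 3])
  nsmp <- nf[1] - 3L
  nsite <- length(lines)
  counts <- lapply(TALLIES, function(b) matrix(0L, nsite, nsmp))
  names(counts) <- TALLIES
  status <- matrix(SAMPLE_STATUS[["PASSED"]], nsite, nsmp)
  for (j in seq_len(nsmp)) {
    f <- m[, 3L + j]
    miss <- f == "-" | f == ".:.:.:.:.:." | f == ".:.:.:."
    status[miss, j] <- SAMPLE_STATUS[["missing"]]
    sp <- strsplit(f[!miss], ":", fixed = TRUE)
    ln <- lengths(sp)
    if (any(ln != 4L & ln != 6L)) {
      bad <- lineno[!miss][which(ln != 4L & ln != 6L)[1]]
      stop("sync parse error at line ", bad,
           ": sample field must have 4 or 6 counts")
    }
    toks <- suppressWarnings(
      vapply(sp, function(v) as.integer(v[seq_len(6)]), integer(6))
    )
    ## 4-field dialect: N and DEL absent -> zero
    toks[is.na(toks) & row(toks) >= 5] <- 0L
    if (anyNA(toks)) {
      bad <- lineno[!miss][which(colSums(is.na(toks)) > 0)[1]]
      stop("sync parse error at line ", bad, ": non-integer count")
    }
    for (k in seq_along(SYNC_ORDER)) {
      counts[[SYNC_ORDER[k]]][!miss, j] <- toks[k, ]
    }
  }
  PoolSeq(
    counts = counts, chrom = chrom, pos = pos, ref = ref,
    poolSizes = poolSizes, minCount = minCount,
    sampleNames = sampleNames, sampleStatus = status
  )
}

## TRUE iff positions are sorted by (chromosome block, position) with no
## chromosome appearing in two separate blocks
isPositionSorted <- function(chrom, pos) {
  if (length(chrom) <= 1L) return(TRUE)
  r <- rle(chrom)
  if (anyDuplicated(r$values)) return(FALSE)
  all(vapply(split(pos, factor(chrom, levels = r$values)),
             function(p) !is.unsorted(p, strictly = FALSE), logical(1)))
}

#' Write a PoolSeq object in sync format
#'
#' Inverse of [readSync()]: `readSync()` of the written output reproduces the
#' counts exactly.  Missing samples (`FILTERED(missing)` with zero depth) are
#' written as `.:.:.:.:.:.`.
#'
#' @param x A [PoolSeq-class] object, sorted by (chromosome, position).
#' @param path output file; `NULL` returns the lines invisibly instead.
#' @return character vector of lines, invisibly.
#' @export
writeSync <- function(x, path = NULL) {
  stopifnot(is(x, "PoolSeq"))
  if (!isPositionSorted(chromosomes(x), positions(x))) {
    stop("writeSync() requires input sorted by (chromosome, position)")
  }
  if (nrow(x) == 0L) {
    lines <- character()
  } else {
    cnts <- baseCounts(x)
    miss <- sampleStatus(x) == SAMPLE_STATUS[["missing"]] & readDepth(x) == 0L
    fields <- matrix("", nrow(x), ncol(x))
    for (j in seq_len(ncol(x))) {
      fields[, j] <- paste(
        cnts$A[, j], cnts$T[, j], cnts$C[, j], cnts$G[, j],
        cnts$N[, j], cnts$DEL[, j], sep = ":"
      )
    }
    fields[miss] <- ".:.:.:.:.:."
    ref <- refBase(x)
    ref[is.na(ref)] <- "N"
    lines <- paste(
      chromosomes(x), positions(x), ref,
      apply(fields, 1L, paste, collapse = "\t"),
      sep = "\t"
    )
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
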