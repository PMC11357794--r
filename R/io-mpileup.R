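## samtools (m)pileup parsing.  Each sample contributes a (depth, bases,
## qualities) column triplet; the base-string grammar is expanded by a small
## state machine below.

## Decode one pileup base string + quality string into the six tallies.
## Returns an integer vector over TALLIES, or stops with a descriptive error.
parseBaseString <- function(bases, quals, ref, minBaseQuality = 0L,
                            qualityOffset = 33L) {
  counts <- stats::setNames(integer(length(TALLIES)), TALLIES)
  if (bases == "*" && (quals == "*" || quals == "")) return(counts)
  bs <- strsplit(bases, "", fixed = TRUE)[[1]]
  qs <- strsplit(quals, "", fixed = TRUE)[[1]]
  ref <- toupper(ref)
  i <- 1L
  q <- 1L
  n <- length(bs)
  while (i <= n) {
    ch <- bs[i]
    if (ch == "^") {
      i <- i + 2L            # caret + mapping-quality char, no base consumed
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && bs[j] >= "0" && bs[j] <= "9") j <- j + 1L
      if (j == i + 1L) stop("malformed indel (no length digits)")
      len <- as.integer(paste(bs[(i + 1L):(j - 1L)], collapse = ""))
      if (j + len - 1L > n) stop("malformed indel (sequence truncated)")
      i <- j + len           # indel sequence consumed, no quality char
    } else {
      if (q > length(qs)) {
        stop("base/quality string length mismatch")
      }
      qv <- utf8ToInt(qs[q]) - qualityOffset
      q <- q + 1L
      if (qv >= minBaseQuality) {
        up <- toupper(ch)
        slot <- if (ch == "." || ch == ",") {
          if (ref %in% BASES) ref else "N"
        } else if (up %in% BASES) {
          up
        } else if (ch == "*") {
          "DEL"
        } else {
          "N"                # n/N, reference skips > <, anything else
        }
        counts[slot] <- counts[slot] + 1L
      }
      i <- i + 1L
    }
  }
  if (q - 1L != length(qs)) stop("base/quality string length mismatch")
  counts
}

#' Read a samtools (m)pileup file
#'
#' Parses the pileup text format: tab-separated chromosome, 1-based position,
#' reference base, then per sample a read depth, a base string, and a quality
#' string.  The base-string grammar is fully expanded: `.`/`,` map to the
#' reference base, letters map case-insensitively to their base, `*`
#' increments the deletion tally, `>`/`<` and `n`/`N` increment the `N`
#' tally, `^X` (read start) and `$` (read end) markers are skipped, and
#' `+N[seq]`/`-N[seq]` indel annotations are consumed without affecting the
#' counts.  A base is only counted when its quality character decodes to at
#' least `minBaseQuality` (quality = ASCII code minus `qualityOffset`;
#' offset 33 is the Sanger/Illumina-1.8 encoding).
#'
#' @param path file path (optionally gzipped).
#' @param minBaseQuality minimum decoded base quality; 0 keeps everything.
#' @param qualityOffset ASCII offset of the quality encoding (default 33).
#' @param poolSizes,minCount,sampleNames passed to [PoolSeq()].
#' @return A [PoolSeq-class] object.
#' @export
readMpileup <- function(path, minBaseQuality = 0L, qualityOffset = 33L,
                        poolSizes = NA_integer_, minCount = 1L,
                        sampleNames = NULL) {
  con <- textConnectionFor(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  nsite <- length(lines)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (nsite > 0 && (any(nf < 6L) || any((nf - 3L) %% 3L != 0L) ||
                    length(unique(nf)) != 1L)) {
    bad <- which(nf < 6L | (nf - 3L) %% 3L != 0L | nf != nf[1])[1]
    stop("pileup parse error at line ", bad, ": malformed column layout")
  }
  nsmp <- if (nsite > 0) (nf[1] - 3L) %/% 3L else 1L
  counts <- lapply(TALLIES, function(b) matrix(0L, nsite, nsmp))
  names(counts) <- TALLIES
  chrom <- character(nsite)
  pos <- integer(nsite)
  ref <- character(nsite)
  for (i in seq_len(nsite)) {
    p <- parts[[i]]
    chrom[i] <- p[1]
    pos[i] <- suppressWarnings(as.integer(p[2]))
    if (is.na(pos[i]) || pos[i] < 1L) {
      stop("pileup parse error at line ", i, ": invalid position")
    }
    ref[i] <- toupper(p[3])
    for (j in seq_len(nsmp)) {
      cc <- tryCatch(
        parseBaseString(p[3L + 3L * j - 1L], p[3L + 3L * j], ref[i],
                        minBaseQuality, qualityOffset),
        error = function(e) {
          stop("pileup parse error at line ", i, ": ", conditionMessage(e),
               call. = FALSE)
        }
      )
      for (b in TALLIES) counts[[b]][i, j] <- cc[[b]]
    }
  }
  PoolSeq(
    counts = counts, chrom = chrom, pos = pos, ref = ref,
    poolSizes = poolSizes, minCount = minCount, sampleNames = sampleNames
  )
}
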