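#' Read a region list (BED, GFF/GTF, or simple text)
#'
#' All formats are converted to the internal 1-based inclusive convention
#' ([GenomicRanges::GRanges]): BED input is 0-based half-open, GFF/GTF is
#' already 1-based inclusive, and the text format accepts one region per
#' line as `chrom`, `chrom:pos`, or `chrom:start-end` (1-based inclusive;
#' a bare `chrom` spans the whole chromosome).  BED and GFF/GTF parsing is
#' delegated to [rtracklayer::import()].
#'
#' @param path file path (optionally gzipped).
#' @param format `"auto"` (by file extension), `"bed"`, `"gff"` (also GTF),
#'   or `"text"`.
#' @return A [GenomicRanges::GRanges] of 1-based inclusive intervals;
#'   `metadata(x)$source` records the input format.  Intervals may overlap.
#' @export
readRegions <- function(path, format = c("auto", "bed", "gff", "text")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    ext <- tolower(sub("^.*\\.", "", base))
    format <- switch(ext,
      bed = "bed",
      gff = , gff2 = , gff3 = , gtf = "gff",
      "text"
    )
  }
  gr <- switch(format,
    bed = {
      g <- rtracklayer::import(path, format = "BED")
      mcols(g) <- NULL
      g
    },
    gff = {
      g <- rtracklayer::import(path, format = ifelse(
        grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE), "GTF", "GFF"))
      mcols(g) <- NULL
      g
    },
    text = {
      con <- textConnectionFor(path)
      on.exit(close(con))
      lines <- trimws(readLines(con))
      lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
      parseTextRegion(lines)
    }
  )
  if (any(start(gr) > end(gr))) {
    stop("region with start > end after coordinate conversion")
  }
  if (any(start(gr) < 1L)) stop("region start < 1")
  metadata(gr)$source <- format
  gr
}

## "chrom", "chrom:pos", "chrom:start-end" -> GRanges (whole chromosome is
## encoded as 1..2^31-2)
parseTextRegion <- function(lines) {
  if (length(lines) == 0L) return(GRanges())
  chrom <- sub(":.*$", "", lines)
  rest <- ifelse(grepl(":", lines, fixed = TRUE),
                 sub("^[^:]*:", "", lines), "")
  from <- integer(length(lines))
  to <- integer(length(lines))
  whole <- rest == ""
  from[whole] <- 1L
  to[whole] <- .Machine$integer.max - 1L
  single <- !whole & !grepl("-", rest, fixed = TRUE)
  from[single] <- as.integer(rest[single])
  to[single] <- from[single]
  span <- !whole & !single
  from[span] <- as.integer(sub("-.*$", "", rest[span]))
  to[span] <- as.integer(sub("^.*-", "", rest[span]))
  if (anyNA(from) || anyNA(to)) stop("malformed text region line")
  if (any(from > to)) stop("region with start > end after coordinate conversion")
  GRanges(chrom, IRanges(from, to))
}

#' Read a position mask
#'
#' A mask marks each genomic position as valid or invalid; positions not
#' covered by the mask file are invalid, and a chromosome absent from the
#' mask is entirely invalid.  The file lists the VALID intervals in any
#' format [readRegions()] accepts.  Masks differ from region filters in that
#' masked positions stay in the stream (flagged `FILTERED(masked)`) so that
#' window averaging denominators can still count them.
#'
#' @inheritParams readRegions
#' @return A [GenomicRanges::GRanges] of valid positions.
#' @export
readMask <- function(path, format = c("auto", "bed", "gff", "text")) {
  readRegions(path, format)
}
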