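## round half away from zero (base round() rounds half to even)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Read a simple per-sample allele table
#'
#' Reads a header-bearing delimited table with columns `chrom`, `pos`,
#' `ref`, `alt`, and per-sample columns of either ref/alt read counts
#' (`<sample>.ref` / `<sample>.alt`) or alt-allele frequencies in \[0, 1\]
#' (`<sample>.freq`); `_` is accepted in place of `.` in the suffix.
#' Frequencies f are converted to pseudo-counts at a configurable scaling
#' depth n0: ref = round((1-f) n0), alt = round(f n0), rounding half away
#' from zero.  This supports haplotype-corrected frequency inputs, where the
#' read-depth correction matters less but the pool-size correction still
#' applies.  Counts are passed through unchanged.
#'
#' @param path file path (optionally gzipped).
#' @param scalingDepth pseudo-count depth n0 for frequency columns.
#' @param sep field separator (default tab).
#' @param poolSizes,minCount passed to [PoolSeq()].
#' @return A [PoolSeq-class] object with counts on the ref/alt bases.
#' @export
readFrequencyTable <- function(path, scalingDepth = 100L, sep = "\t",
                               poolSizes = NA_integer_, minCount = 1L) {
  con <- textConnectionFor(path)
  on.exit(close(con))
  ## everything as character first: a lone "T" allele must never become
  ## the logical TRUE
  tab <- utils::read.table(con, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE)
  for (col in setdiff(names(tab), c("chrom", "ref", "alt"))) {
    tab[[col]] <- as.numeric(tab[[col]])
  }
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(tab))) {
    stop("frequency table must have columns: ", paste(req, collapse = ", "))
  }
  cols <- setdiff(names(tab), req)
  suffix <- sub("^.*[._]", "", cols)
  sample <- sub("[._][^._]*$", "", cols)
  if (!all(suffix %in% c("freq", "ref", "alt"))) {
    stop("per-sample columns must end in .freq, .ref, or .alt")
  }
  samples <- unique(sample)
  nsite <- nrow(tab)
  counts <- lapply(TALLIES, function(b) matrix(0L, nsite, length(samples)))
  names(counts) <- TALLIES
  ref <- toupper(tab$ref)
  alt <- toupper(tab$alt)
  if (!all(ref %in% c(BASES, "N")) || !all(alt %in% c(BASES, "N"))) {
    stop("ref/alt must be one of A, C, G, T, N")
  }
  setBase <- function(mat, base, j, vals) {
    for (b in BASES) {
      k <- base == b
      if (any(k)) mat[[b]][k, j] <- as.integer(vals[k])
    }
    mat
  }
  for (j in seq_along(samples)) {
    mycols <- cols[sample == samples[j]]
    mysuf <- suffix[sample == samples[j]]
    if ("freq" %in% mysuf) {
      f <- tab[[mycols[mysuf == "freq"][1]]]
      if (any(f < 0 | f > 1, na.rm = TRUE)) {
        stop("allele frequency outside [0, 1] for sample ", samples[j])
      }
      refN <- roundHalfAway((1 - f) * scalingDepth)
      altN <- roundHalfAway(f * scalingDepth)
    } else {
      if (!all(c("ref", "alt") %in% mysuf)) {
        stop("sample ", samples[j], " needs both .ref and .alt count columns")
      }
      refN <- tab[[mycols[mysuf == "ref"][1]]]
      altN <- tab[[mycols[mysuf == "alt"][1]]]
    }
    counts <- setBase(counts, ref, j, refN)
    ## alt counts add on top in the degenerate ref == alt case
    for (b in BASES) {
      k <- alt == b
      if (any(k)) {
        counts[[b]][k, j] <- counts[[b]][k, j] + as.integer(altN[k])
      }
    }
  }
  PoolSeq(
    counts = counts, chrom = as.character(tab$chrom),
    pos = as.integer(tab$pos), ref = ref, alt = alt,
    poolSizes = poolSizes, minCount = minCount, sampleNames = samples
  )
}
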