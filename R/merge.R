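#' Merge multiple PoolSeq inputs positionally
#'
#' Combines several [PoolSeq-class] objects (typically parsed from separate
#' files) into one, as if they were a single input with the sample columns
#' concatenated.  Positions are taken as either the union or the
#' intersection of the inputs' position sets.  In union mode, samples absent
#' at a position are filled with all-zero counts flagged
#' `FILTERED(missing)`.  Reference-base conflicts are resolved with priority
#' reference genome > first non-N input; conflicting non-N reference bases
#' without a reference genome are an error naming the position.
#'
#' @param objects list of [PoolSeq-class] objects, each sorted by
#'   (chromosome, position).
#' @param mode `"union"` or `"intersection"`.
#' @param reference optional FASTA path or [Biostrings::DNAStringSet] used to
#'   resolve reference-base conflicts.
#' @param chromosomeOrder optional character vector fixing the output
#'   chromosome order; defaults to lexicographic.
#' @return A merged, sorted [PoolSeq-class] object.
#' @export
mergePoolSeq <- function(objects, mode = c("union", "intersection"),
                         reference = NULL, chromosomeOrder = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.list(objects), length(objects) >= 1L,
            all(vapply(objects, is, logical(1), "PoolSeq")))
  for (i in seq_along(objects)) {
    o <- objects[[i]]
    if (!isPositionSorted(chromosomes(o), positions(o))) {
      stop("input ", i, " is not sorted by (chromosome, position)")
    }
  }
  keys <- lapply(objects, function(o) paste(chromosomes(o), positions(o)))
  if (mode == "intersection") {
    allkeys <- unique(keys[[1]])
    for (k in keys[-1]) allkeys <- allkeys[allkeys %in% k]
  } else {
    allkeys <- unique(unlist(keys))
  }
  chrom <- sub(" .*$", "", allkeys)
  pos <- as.integer(sub("^.* ", "", allkeys))
  chrOrder <- if (is.null(chromosomeOrder)) {
    sort(unique(chrom))
  } else {
    c(chromosomeOrder, setdiff(unique(chrom), chromosomeOrder))
  }
  ord <- order(match(chrom, chrOrder), pos)
  chrom <- chrom[ord]
  pos <- pos[ord]
  allkeys <- allkeys[ord]
  nsite <- length(allkeys)
  nsmp <- sum(vapply(objects, ncol, integer(1)))
  counts <- lapply(TALLIES, function(b) matrix(0L, nsite, nsmp))
  names(counts) <- TALLIES
  status <- matrix(SAMPLE_STATUS[["missing"]], nsite, nsmp)
  ref <- rep("N", nsite)
  refSource <- rep(NA_integer_, nsite)
  off <- 0L
  for (i in seq_along(objects)) {
    o <- objects[[i]]
    hit <- match(keys[[i]], allkeys)
    inres <- !is.na(hit)
    rows <- hit[inres]
    jj <- off + seq_len(ncol(o))
    for (b in TALLIES) {
      counts[[b]][rows, jj] <- assay(o, b)[inres, , drop = FALSE]
    }
    status[rows, jj] <- sampleStatus(o)[inres, , drop = FALSE]
    oref <- refBase(o)[inres]
    isbase <- oref %in% BASES
    newref <- is.na(refSource[rows]) & isbase
    conflict <- !is.na(refSource[rows]) & isbase & ref[rows] != oref
    if (any(conflict) && is.null(reference)) {
      w <- which(conflict)[1]
      stop("conflicting reference bases at ", chrom[rows][w], ":",
           pos[rows][w], " (provide a reference genome to resolve)")
    }
    ref[rows][newref] <- oref[newref]
    refSource[rows][newref] <- i
    off <- off + ncol(o)
  }
  if (!is.null(reference)) {
    reference <- loadReference(reference)
    rb <- referenceBases(reference, chrom, pos)
    use <- !is.na(rb) & rb %in% BASES
    ref[use] <- rb[use]
  }
  ps <- unlist(lapply(objects, poolSizes))
  nm <- unlist(lapply(objects, colnames))
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  PoolSeq(
    counts = counts, chrom = chrom, pos = pos, ref = ref,
    poolSizes = ps, minCount = minCount(objects[[1]]),
    sampleNames = nm, sampleStatus = status
  )
}
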