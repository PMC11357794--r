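#' @rdname PoolSeq-accessors
#' @name PoolSeq-accessors
#' @title Accessors for PoolSeq objects
#'
#' @description
#' `baseCounts(x, base)` returns one of the six integer tally matrices
#' (sites x samples).  `readDepth(x)` returns the matrix of read depths
#' n = A + C + G + T; `N` and `DEL` tallies never count toward depth or any
#' statistic.  `poolSizes(x)` and `minCount(x)` access the pool profile:
#' the per-sample number of haploid genome copies p and the minimum allele
#' count b used inside the estimator denominators.  `refBase`/`altBase`
#' access the per-site reference and alternative base; `sampleStatus` and
#' `siteStatus` the filter states (see [filterCodes()]); `siteClass` the
#' classification produced by [classifySites()].
#'
#' @param x A [PoolSeq-class] object.
#' @param base One of `"A"`, `"C"`, `"G"`, `"T"`, `"N"`, `"DEL"`.
#' @param value Replacement value.
NULL

#' @rdname PoolSeq-accessors
#' @export
baseCounts <- function(x, base = NULL) {
  if (is.null(base)) {
    cnts <- lapply(TALLIES, function(b) assay(x, b))
    names(cnts) <- TALLIES
    return(cnts)
  }
  base <- match.arg(base, TALLIES)
  assay(x, base)
}

#' @rdname PoolSeq-accessors
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))

#' @rdname PoolSeq-accessors
#' @export
setMethod("readDepth", "PoolSeq", function(x) {
  assay(x, "A") + assay(x, "C") + assay(x, "G") + assay(x, "T")
})

#' @rdname PoolSeq-accessors
#' @export
setMethod("readDepth", "numeric", function(x) {
  ## named tally vector for a single sample at a single site
  stopifnot(all(BASES %in% names(x)))
  sum(x[BASES])
})

#' @rdname PoolSeq-accessors
#' @export
poolSizes <- function(x) colData(x)$poolSize

#' @rdname PoolSeq-accessors
#' @export
`poolSizes<-` <- function(x, value) {
  colData(x)$poolSize <- as.integer(rep_len(value, ncol(x)))
  x
}

#' @rdname PoolSeq-accessors
#' @export
minCount <- function(x) x@minCount

#' @rdname PoolSeq-accessors
#' @export
`minCount<-` <- function(x, value) {
  x@minCount <- as.integer(value)
  validObject(x)
  x
}

#' @rdname PoolSeq-accessors
#' @export
refBase <- function(x) mcols(rowRanges(x))$ref

#' @rdname PoolSeq-accessors
#' @export
`refBase<-` <- function(x, value) {
  mcols(rowRanges(x))$ref <- as.character(value)
  x
}

#' @rdname PoolSeq-accessors
#' @export
altBase <- function(x) mcols(rowRanges(x))$alt

#' @rdname PoolSeq-accessors
#' @export
`altBase<-` <- function(x, value) {
  mcols(rowRanges(x))$alt <- as.character(value)
  x
}

#' @rdname PoolSeq-accessors
#' @export
sampleStatus <- function(x) assay(x, "sampleStatus")

#' @rdname PoolSeq-accessors
#' @export
`sampleStatus<-` <- function(x, value) {
  storage.mode(value) <- "integer"
  assay(x, "sampleStatus") <- value
  x
}

#' @rdname PoolSeq-accessors
#' @export
siteStatus <- function(x) mcols(rowRanges(x))$siteStatus

#' @rdname PoolSeq-accessors
#' @export
`siteStatus<-` <- function(x, value) {
  mcols(rowRanges(x))$siteStatus <- as.integer(value)
  x
}

#' @rdname PoolSeq-accessors
#' @export
siteClass <- function(x) mcols(rowRanges(x))$siteClass

#' @rdname PoolSeq-accessors
#' @export
chromosomes <- function(x) as.character(seqnames(rowRanges(x)))

#' @rdname PoolSeq-accessors
#' @export
positions <- function(x) start(rowRanges(x))
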