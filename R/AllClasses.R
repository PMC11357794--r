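#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end
#' @importFrom IRanges IRanges width
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowRanges
#'   colData assay<- rowRanges<- colData<- assayNames
NULL

## Names of the six per-base tally assays, in canonical order.
BASES <- c("A", "C", "G", "T")
TALLIES <- c("A", "C", "G", "T", "N", "DEL")

## Per-sample filter status codes stored in the "sampleStatus" assay and the
## site-level codes stored in rowData$siteStatus.  0 always means PASSED.
SAMPLE_STATUS <- c(
  PASSED        = 0L,
  missing       = 1L,
  masked        = 2L,
  low_depth     = 3L,
  high_depth    = 4L,
  high_deletion = 5L
)

SITE_STATUS <- c(
  PASSED               = 0L,
  masked               = 1L,
  not_snp              = 2L,
  not_biallelic        = 3L,
  low_allele_frequency = 4L,
  no_data              = 5L
)

## Site classification after filtering.
SITE_CLASSES <- c("MISSING", "INVARIANT", "SNP_BIALLELIC", "SNP_MULTIALLELIC")

#' PoolSeq: per-position base counts for pooled sequencing samples
#'
#' `PoolSeq` extends [SummarizedExperiment::RangedSummarizedExperiment].  Rows
#' are genomic positions (width-1 ranges, 1-based), columns are pooled samples.
#' Six integer assays named `A`, `C`, `G`, `T`, `N`, `DEL` hold the read tallies
#' per base, plus the count of ambiguous reads (`N`) and of reads supporting a
#' deletion (`DEL`).  `N` and `DEL` are carried along but excluded from read
#' depth and from all statistics.  A seventh integer assay `sampleStatus` holds
#' the per-sample filter state (0 = passed; see [filterCodes()]).
#'
#' Row metadata columns: `ref` and `alt` (one of A/C/G/T/N), `siteStatus`
#' (site-level filter state), `siteClass` (one of MISSING, INVARIANT,
#' SNP_BIALLELIC, SNP_MULTIALLELIC, or NA before [classifySites()] has run).
#' Column metadata: `poolSize`, the number p of haploid genome copies in each
#' pool.  Note that p counts haploid genomes, i.e. individuals times ploidy:
#' a pool of 50 diploid individuals has `poolSize = 100`.  The estimator
#' denominators sum over k = 1..p-1 allele copies in the pool, so p must be
#' at least 2 wherever a pool-corrected estimator is evaluated.
#'
#' @slot minCount integer scalar b, the minimum allele count used inside the
#'   estimator denominators (and by [applyNumericFilters()] when zeroing rare
#'   bases).
#'
#' @seealso [PoolSeq()] for construction, [readSync()], [readMpileup()],
#'   [readFrequencyTable()] for parsing files, [simulateNeutralDataset()] for
#'   simulation.
#' @export
setClass("PoolSeq",
  contains = "RangedSummarizedExperiment",
  slots = c(minCount = "integer")
)

setValidity("PoolSeq", function(object) {
  msgs <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c(TALLIES, "sampleStatus")
  if (!all(need %in% an)) {
    msgs <- c(msgs, paste0(
      "missing assays: ", paste(setdiff(need, an), collapse = ", ")
    ))
  } else {
    for (b in TALLIES) {
      m <- assay(object, b)
      if (any(m < 0, na.rm = TRUE)) {
        msgs <- c(msgs, paste0("negative counts in assay ", b))
      }
    }
  }
  rd <- mcols(rowRanges(object))
  for (col in c("ref", "alt", "siteStatus")) {
    if (!col %in% colnames(rd)) msgs <- c(msgs, paste0("missing rowData$", col))
  }
  if (!"poolSize" %in% colnames(colData(object))) {
    msgs <- c(msgs, "missing colData$poolSize")
  }
  if (length(object@minCount) != 1L || is.na(object@minCount) ||
      object@minCount < 1L) {
    msgs <- c(msgs, "minCount must be a single integer >= 1")
  }
  if (nrow(object) > 0 && any(start(rowRanges(object)) < 1L)) {
    msgs <- c(msgs, "positions must be >= 1 (1-based coordinates)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a PoolSeq object
#'
#' @param counts named list of six integer matrices (`A`, `C`, `G`, `T`, `N`,
#'   `DEL`), each sites x samples.  `N` and `DEL` may be omitted (treated as
#'   zero).
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt bases per site (A/C/G/T/N).  Default `"N"`; use
#'   [inferRefAlt()] to fill them in from the counts.
#' @param poolSizes integer vector p per sample (haploid genome copies),
#'   recycled; `NA` allowed until an estimator needs it.
#' @param minCount integer scalar b >= 1 used in estimator denominators.
#' @param sampleNames optional character vector of sample names.
#' @param sampleStatus optional integer matrix of per-sample filter codes
#'   (default all 0 = passed).
#'
#' @return A [PoolSeq-class] object.
#' @examples
#' ps <- PoolSeq(
#'   counts = list(A = matrix(6L), C = matrix(2L), G = matrix(0L),
#'                 T = matrix(0L)),
#'   chrom = "Chr1", pos = 123L, poolSizes = 100L
#' )
#' readDepth(ps)
#' @export
PoolSeq <- function(counts, chrom, pos, ref = NULL, alt = NULL,
                    poolSizes = NA_integer_, minCount = 1L,
                    sampleNames = NULL, sampleStatus = NULL) {
  stopifnot(is.list(counts), all(c("A", "C", "G", "T") %in% names(counts)))
  amat <- as.matrix(counts[["A"]])
  nsite <- nrow(amat)
  nsmp <- ncol(amat)
  full <- lapply(TALLIES, function(b) {
    m <- counts[[b]]
    if (is.null(m)) m <- matrix(0L, nsite, nsmp)
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    dimnames(m) <- NULL
    m
  })
  names(full) <- TALLIES
  if (is.null(sampleStatus)) sampleStatus <- matrix(0L, nsite, nsmp)
  storage.mode(sampleStatus) <- "integer"
  if (is.null(sampleNames)) sampleNames <- paste0("S", seq_len(nsmp))
  if (is.null(ref)) ref <- rep("N", nsite)
  if (is.null(alt)) alt <- rep("N", nsite)
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L))
  mcols(gr) <- DataFrame(
    ref = as.character(ref), alt = as.character(alt),
    siteStatus = rep(SITE_STATUS[["PASSED"]], nsite),
    siteClass = rep(NA_character_, nsite)
  )
  se <- SummarizedExperiment(
    assays = c(full, list(sampleStatus = sampleStatus)),
    rowRanges = gr,
    colData = DataFrame(
      poolSize = as.integer(rep_len(poolSizes, nsmp)),
      row.names = sampleNames
    )
  )
  new("PoolSeq", se, minCount = as.integer(minCount))
}

#' Filter status code tables
#'
#' Returns the named integer codes used in the `sampleStatus` assay and the
#' `siteStatus` row metadata column of a [PoolSeq-class] object.  0 always
#' means PASSED.
#'
#' @return A list with elements `sample` and `site`, each a named integer
#'   vector.
#' @export
filterCodes <- function() {
  list(sample = SAMPLE_STATUS, site = SITE_STATUS)
}

setMethod("show", "PoolSeq", function(object) {
  cat("PoolSeq object:", nrow(object), "positions,", ncol(object), "samples\n")
  if (nrow(object) > 0) {
    chr <- unique(as.character(seqnames(rowRanges(object))))
    cat("  chromosomes:", paste(utils::head(chr, 5), collapse = ", "),
        if (length(chr) > 5) "..." else "", "\n")
  }
  cat("  pool sizes:",
      paste(utils::head(colData(object)$poolSize, 8), collapse = ", "),
      if (ncol(object) > 8) "..." else "", "\n")
  cat("  min allele count (b):", object@minCount, "\n")
  sc <- mcols(rowRanges(object))$siteClass
  if (nrow(object) > 0 && !all(is.na(sc))) {
    tab <- table(factor(sc, levels = SITE_CLASSES))
    cat("  site classes:",
        paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
  }
  invisible(NULL)
})
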