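## Orchestration: config-driven runs tying parsers, filters, windows, and
## estimators together.  A RunConfig is a plain named list; every CLI flag
## of the poolstats script maps onto one of its fields, and a YAML file
## with the same field names round-trips through readRunConfig().

#' Read a run configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [runDiversity()] / [runFst()] /
#' [runSyncConvert()]; a config file and the equivalent flags produce
#' identical results.
#'
#' @param path YAML file.
#' @return named list (RunConfig).
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading config files requires the yaml package")
  }
  yaml::read_yaml(path)
}

## defaults for every RunConfig field
defaultConfig <- function() {
  list(
    input = list(paths = character(), format = "sync",
                 minBaseQuality = 0L, qualityOffset = 33L,
                 scalingDepth = 100L, multiFileMode = "union",
                 reference = NULL, chromosomeOrder = NULL),
    poolSizes = NA_integer_,
    minCount = 1L,
    sampleGroups = NULL,
    filters = list(regions = NULL, invertRegions = FALSE, mask = NULL,
                   sampleMasks = NULL, minReadDepth = 0L, maxReadDepth = 0L,
                   maxDeletionFraction = NA_real_, minAlleleFrequency = 0,
                   onlySNPs = FALSE, onlyBiallelic = FALSE,
                   maxDepth = NA_integer_,
                   subsampleMethod = "subsample-without-replacement"),
    window = list(type = "interval", width = 1000L, stride = NULL,
                  count = 100L, regions = NULL, chromosomeLengths = NULL),
    policy = "valid-loci",
    windowMask = NULL,
    tajimasDDenominator = "none",
    fstMethod = "hudson",
    fstPairs = NULL,
    output = NULL,
    naString = "nan",
    seed = NULL,
    verbose = TRUE
  )
}

mergeConfig <- function(config) {
  def <- defaultConfig()
  for (nm in names(config)) {
    if (is.list(def[[nm]]) && is.list(config[[nm]])) {
      for (sub in names(config[[nm]])) def[[nm]][[sub]] <- config[[nm]][[sub]]
    } else {
      def[[nm]] <- config[[nm]]
    }
  }
  def
}

runLog <- function(verbose, ...) {
  if (verbose) message(...)
}

asRegions <- function(spec) {
  if (is.null(spec) || is(spec, "GRanges")) return(spec)
  readRegions(spec)
}

## parse + merge + group + ref/alt inference + filter cascade
prepareData <- function(cfg) {
  inp <- cfg$input
  if (length(inp$paths) == 0L) stop("config needs at least one input path")
  readOne <- function(path) {
    switch(inp$format,
      sync = readSync(path, minCount = cfg$minCount),
      mpileup = readMpileup(path, minBaseQuality = inp$minBaseQuality,
                            qualityOffset = inp$qualityOffset,
                            minCount = cfg$minCount),
      table = readFrequencyTable(path, scalingDepth = inp$scalingDepth,
                                 minCount = cfg$minCount),
      stop("unknown input format: ", inp$format)
    )
  }
  objs <- lapply(inp$paths, readOne)
  x <- if (length(objs) == 1L) {
    objs[[1]]
  } else {
    mergePoolSeq(objs, mode = inp$multiFileMode,
                 reference = inp$reference,
                 chromosomeOrder = inp$chromosomeOrder)
  }
  if (!is.null(cfg$sampleGroups)) x <- mergeSamples(x, cfg$sampleGroups)
  poolSizes(x) <- rep_len(cfg$poolSizes, ncol(x))
  minCount(x) <- cfg$minCount
  x <- inferRefAlt(x, reference = inp$reference)
  fl <- cfg$filters
  x <- applyFilters(
    x,
    regions = asRegions(fl$regions), invertRegions = isTRUE(fl$invertRegions),
    mask = asRegions(fl$mask),
    sampleMasks = if (is.null(fl$sampleMasks)) NULL else
      lapply(fl$sampleMasks, asRegions),
    minCount = cfg$minCount, minReadDepth = fl$minReadDepth,
    maxReadDepth = fl$maxReadDepth,
    maxDeletionFraction = fl$maxDeletionFraction,
    minAlleleFrequency = fl$minAlleleFrequency,
    onlySNPs = isTRUE(fl$onlySNPs), onlyBiallelic = isTRUE(fl$onlyBiallelic),
    maxDepth = fl$maxDepth, subsampleMethod = fl$subsampleMethod,
    seed = cfg$seed
  )
  lg <- metadata(x)$filterLog
  runLog(cfg$verbose, "positions read: ", lg$read,
         "; removed by region filter: ", lg$regionRemoved,
         "; emitted: ", lg$emitted)
  runLog(cfg$verbose, "sites passed: ", lg$sitePassed,
         "; filtered: ", lg$siteFiltered, "; SNPs: ", lg$snps)
  x
}

windowsFor <- function(x, cfg) {
  w <- cfg$window
  makeWindows(
    x, type = w$type, width = w$width,
    stride = if (is.null(w$stride)) w$width else w$stride,
    count = w$count, regions = asRegions(w$regions),
    chromosomeLengths = w$chromosomeLengths
  )
}

writeResultTable <- function(df, cfg) {
  if (!is.null(cfg$output)) {
    utils::write.table(df, cfg$output, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = cfg$naString)
    runLog(cfg$verbose, "wrote ", nrow(df), " rows to ", cfg$output)
  }
  df
}

#' Run a windowed diversity analysis from a configuration
#'
#' Parses the configured inputs, applies the filter cascade, assembles
#' windows, and computes per-window theta-pi, Watterson's theta, and
#' Tajima's D per sample ([windowDiversity()]).  The run is deterministic
#' for a fixed `seed`.  With `output` set, a tab-separated table (header
#' row; `NA` rendered as `naString`) is written.
#'
#' @param config named list (see [readRunConfig()]); unspecified fields
#'   take defaults.
#' @return the result data.frame, invisibly.
#' @export
runDiversity <- function(config) {
  cfg <- mergeConfig(config)
  x <- prepareData(cfg)
  win <- windowsFor(x, cfg)
  res <- windowDiversity(x, win, policy = cfg$policy,
                         mask = asRegions(cfg$windowMask),
                         tajimasDDenominator = cfg$tajimasDDenominator)
  if (nrow(res) == 0L) runLog(cfg$verbose, "warning: no windows produced")
  invisible(writeResultTable(res, cfg))
}

#' Run a pairwise FST analysis from a configuration
#'
#' As [runDiversity()], but computes windowed pairwise FST
#' ([windowFst()]) with the configured `fstMethod` over all sample pairs
#' (or `fstPairs`).
#'
#' @inheritParams runDiversity
#' @return the result data.frame, invisibly.
#' @export
runFst <- function(config) {
  cfg <- mergeConfig(config)
  x <- prepareData(cfg)
  if (ncol(x) < 2) stop("FST needs at least 2 samples")
  win <- windowsFor(x, cfg)
  res <- windowFst(x, win, method = cfg$fstMethod, pairs = cfg$fstPairs)
  invisible(writeResultTable(res, cfg))
}

#' Convert any supported input to sync format
#'
#' Parses the configured inputs, applies the filter cascade, and writes the
#' post-filter stream in sync format ([writeSync()]).
#'
#' @inheritParams runDiversity
#' @return the sync lines, invisibly.
#' @export
runSyncConvert <- function(config) {
  cfg <- mergeConfig(config)
  x <- prepareData(cfg)
  lines <- writeSync(x, path = cfg$output)
  if (!is.null(cfg$output)) {
    runLog(cfg$verbose, "wrote ", length(lines), " sync lines to ",
           cfg$output)
  }
  invisible(lines)
}
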