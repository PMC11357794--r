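codes <- filterCodes()

test_that("region filters remove positions; masks only flag them", {
  x <- makePool(rep(list(list(c(A = 5))), 10), pos = 1:10)
  reg <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(5, 7))
  expect_equal(positions(filterRegions(x, reg)), 5:7)
  expect_equal(positions(filterRegions(x, reg, invert = TRUE)),
               c(1:4, 8:10))
  none <- GenomicRanges::GRanges()
  expect_equal(nrow(filterRegions(x, none)), 0L)

  m <- applyMask(x, reg)  # global mask: valid only at 5..7
  expect_equal(nrow(m), 10L)  # positions stay in the stream
  expect_equal(siteStatus(m)[4], codes$site[["masked"]])
  expect_equal(siteStatus(m)[5], codes$site[["PASSED"]])
})

test_that("per-sample masks flag only the targeted sample", {
  x <- makePool(list(list(c(A = 5), c(C = 5))), pos = 5L)
  mask <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(100, 200))
  m <- applyMask(x, mask, samples = 2)
  expect_equal(unname(sampleStatus(m)[1, ]),
               unname(c(codes$sample[["PASSED"]], codes$sample[["masked"]])))
  expect_equal(siteStatus(m)[1], codes$site[["PASSED"]])
  ## valid position: unchanged
  ok <- applyMask(x, GenomicRanges::GRanges("Chr1", IRanges::IRanges(5, 5)))
  expect_equal(siteStatus(ok)[1], codes$site[["PASSED"]])
})

test_that("numeric filters zero rare bases then gate on recomputed depth", {
  x <- makePool(list(list(c(A = 9, C = 1))))
  f <- applyNumericFilters(x, minCount = 2)
  expect_equal(unname(baseCounts(f, "C")[1, 1]), 0L)
  expect_equal(unname(readDepth(f)[1, 1]), 9L)
  f2 <- applyNumericFilters(x, minCount = 2, minReadDepth = 10)
  expect_equal(unname(sampleStatus(f2)[1, 1]), codes$sample[["low_depth"]])
  ## minCount = 0/1 is the identity on counts
  id <- applyNumericFilters(x, minCount = 1)
  expect_equal(baseCounts(id, "A"), baseCounts(x, "A"))
  hi <- applyNumericFilters(makePool(list(list(c(A = 50)))),
                            maxReadDepth = 20)
  expect_equal(unname(sampleStatus(hi)[1, 1]), codes$sample[["high_depth"]])
  del <- applyNumericFilters(makePool(list(list(c(A = 5, DEL = 5)))),
                             maxDeletionFraction = 0.3)
  expect_equal(unname(sampleStatus(del)[1, 1]),
               codes$sample[["high_deletion"]])
})

test_that("site classification follows the nonzero-base-count rule", {
  x <- makePool(list(
    list(c(A = 5, C = 3)),        # biallelic
    list(c(A = 5)),               # invariant
    list(c(A = 99, C = 1)),       # demoted under MAF filter
    list(c(A = 2, C = 2, G = 2)), # multiallelic
    list(c())                     # missing
  ))
  cl <- siteClass(classifySites(x))
  expect_equal(cl, c("SNP_BIALLELIC", "INVARIANT", "SNP_BIALLELIC",
                     "SNP_MULTIALLELIC", "MISSING"))
  clm <- siteClass(classifySites(x, minAlleleFrequency = 0.05))
  expect_equal(clm[3], "INVARIANT")
  ## only-SNP / biallelic restrictions set site status
  st <- siteStatus(classifySites(x, minAlleleFrequency = 0.05,
                                 onlyBiallelic = TRUE))
  expect_equal(unname(st), unname(c(
    codes$site[["PASSED"]], codes$site[["not_snp"]],
    codes$site[["low_allele_frequency"]], codes$site[["not_biallelic"]],
    codes$site[["no_data"]])))
})

test_that("classification ignores sample order and all-zero samples", {
  set.seed(5)
  for (rep in 1:10) {
    smp <- lapply(1:3, function(i) {
      v <- rpois(4, 1)
      names(v) <- c("A", "C", "G", "T")
      v
    })
    a <- siteClass(classifySites(makePool(list(smp))))
    b <- siteClass(classifySites(makePool(list(smp[c(2, 3, 1)]))))
    c0 <- siteClass(classifySites(makePool(list(c(smp, list(c()))))))
    expect_equal(a, b)
    expect_equal(a, c0)
  }
})

test_that("depth subsampling caps depth and preserves frequencies", {
  x <- makePool(list(list(c(A = 30, C = 10))))
  r <- subsampleCounts(x, 20, "rescale")
  expect_equal(unname(baseCounts(r, "A")[1, 1]), 15L)
  expect_equal(unname(baseCounts(r, "C")[1, 1]), 5L)
  ## below threshold: identity under any method
  low <- makePool(list(list(c(A = 5))))
  for (m in c("subsample-without-replacement", "subsample-with-replacement",
              "rescale")) {
    expect_equal(unname(baseCounts(subsampleCounts(low, 10, m, seed = 1),
                                   "A")[1, 1]), 5L)
  }
  ## depth never exceeds the cap
  set.seed(9)
  for (m in c("subsample-without-replacement", "subsample-with-replacement")) {
    for (rep in 1:20) {
      v <- rpois(4, 20) + 1L
      names(v) <- c("A", "C", "G", "T")
      s <- subsampleCounts(makePool(list(list(v))), 15, m)
      expect_equal(unname(readDepth(s)[1, 1]), 15L)
    }
  }
})

test_that("hypergeometric subsampling matches its expectation", {
  ## E[A] after drawing 20 of 40 reads from (A=30, C=10) is 15
  nrep <- 20000
  x <- makePool(rep(list(list(c(A = 30, C = 10))), nrep), pos = seq_len(nrep))
  s <- subsampleCounts(x, 20, "subsample-without-replacement", seed = 13)
  a <- baseCounts(s, "A")[, 1]
  se <- stats::sd(a) / sqrt(nrep)
  expect_lt(abs(mean(a) - 15), 3 * se)
})

test_that("the filter cascade is idempotent and logs conservation tallies", {
  set.seed(21)
  sites <- lapply(1:50, function(i) {
    v <- rpois(4, 3)
    names(v) <- c("A", "C", "G", "T")
    list(v)
  })
  x <- makePool(sites, pos = 1:50)
  reg <- GenomicRanges::GRanges("Chr1", IRanges::IRanges(10, 40))
  run <- function(obj) {
    applyFilters(obj, regions = reg, minCount = 2, minReadDepth = 3)
  }
  once <- run(x)
  twice <- run(once)
  expect_equal(baseCounts(once, "A"), baseCounts(twice, "A"))
  expect_equal(siteClass(once), siteClass(twice))
  ## subsampling reaches a fixed point: capped depth passes through untouched
  sub1 <- subsampleCounts(once, 8, "rescale")
  sub2 <- subsampleCounts(sub1, 8, "rescale")
  expect_equal(baseCounts(sub1, "A"), baseCounts(sub2, "A"))
  lg <- S4Vectors::metadata(once)$filterLog
  expect_equal(lg$read, lg$regionRemoved + lg$emitted)
  expect_equal(lg$emitted, lg$sitePassed + lg$siteFiltered)
  expect_lte(lg$snps, lg$sitePassed)
})
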