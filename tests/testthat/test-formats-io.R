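test_that("sync parsing maps the on-disk A:T:C:G:N:DEL order to slots", {
  p <- writeTempLines(c(
    "Chr1\t123\tA\t6:0:2:0:0:0",
    "Chr1\t124\tN\t0:0:0:0:0:0",
    "Chr1\t125\tA\t1:2:3:4:5:6"
  ), ".sync")
  x <- readSync(p)
  expect_equal(chromosomes(x), rep("Chr1", 3))
  expect_equal(positions(x), 123:125)
  expect_equal(refBase(x), c("A", "N", "A"))
  expect_equal(unname(baseCounts(x, "A")[, 1]), c(6L, 0L, 1L))
  expect_equal(unname(baseCounts(x, "C")[, 1]), c(2L, 0L, 3L))
  expect_equal(unname(baseCounts(x, "G")[, 1]), c(0L, 0L, 4L))
  expect_equal(unname(baseCounts(x, "T")[, 1]), c(0L, 0L, 2L))
  expect_equal(unname(baseCounts(x, "N")[, 1]), c(0L, 0L, 5L))
  expect_equal(unname(baseCounts(x, "DEL")[, 1]), c(0L, 0L, 6L))
  expect_equal(as.vector(readDepth(x)), c(8L, 0L, 10L))
})

test_that("sync dialects: header line, 4-field columns, missing samples", {
  p <- writeTempLines(c(
    "#chr\tpos\tref\ts1\ts2",
    "Chr1\t1\tA\t6:0:2:0\t.:.:.:.:.:.",
    "Chr1\t2\tC\t-\t0:1:0:0:0:0"
  ), ".sync")
  x <- readSync(p)
  expect_equal(nrow(x), 2L)
  expect_equal(unname(baseCounts(x, "N")[1, 1]), 0L)
  miss <- sampleStatus(x) == filterCodes()$sample[["missing"]]
  expect_equal(as.vector(miss), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("sync write/parse round-trips byte-identically", {
  lines <- c(
    "Chr1\t123\tA\t6:0:2:0:0:0\t.:.:.:.:.:.",
    "Chr1\t124\tN\t0:0:0:0:0:0\t1:1:1:1:0:0",
    "Chr2\t5\tG\t1:2:3:4:5:6\t9:8:7:6:5:4"
  )
  p <- writeTempLines(lines, ".sync")
  x <- readSync(p)
  expect_identical(as.character(writeSync(x)), lines)
  ## empty stream round-trips to empty output
  empty <- readSync(writeTempLines(character(), ".sync"))
  expect_length(writeSync(empty), 0L)
})

test_that("sync parse errors carry line numbers; writer rejects unsorted", {
  bad1 <- writeTempLines(c("Chr1\t1\tA\t1:0:0:0:0:0", "Chr1\t2\tA"), ".sync")
  expect_error(readSync(bad1), "line 2")
  bad2 <- writeTempLines("Chr1\t0\tA\t1:0:0:0:0:0", ".sync")
  expect_error(readSync(bad2), "position")
  bad3 <- writeTempLines("Chr1\t3\tA\t1:x:0:0:0:0", ".sync")
  expect_error(readSync(bad3), "line 1")
  x <- makePool(list(list(c(A = 1)), list(c(A = 2))), pos = c(5L, 3L))
  expect_error(writeSync(x), "sorted")
})

test_that("gzipped sync input is read transparently", {
  path <- tempfile(fileext = ".sync.gz")
  con <- gzfile(path, "wt")
  writeLines("Chr1\t9\tT\t0:7:0:0:0:0", con)
  close(con)
  x <- readSync(path)
  expect_equal(unname(baseCounts(x, "T")[1, 1]), 7L)
})

test_that("pileup grammar: ref dots, case, quality threshold, indels", {
  p <- writeTempLines("Chr1\t10\tA\t5\t..,TT\tIII!!", ".pileup")
  x <- readMpileup(p)
  expect_equal(unname(baseCounts(x, "A")[1, 1]), 3L)
  expect_equal(unname(baseCounts(x, "T")[1, 1]), 2L)
  ## '!' decodes to 0 under offset 33: both T columns drop at min qual 20
  xq <- readMpileup(p, minBaseQuality = 20)
  expect_equal(unname(baseCounts(xq, "A")[1, 1]), 3L)
  expect_equal(unname(baseCounts(xq, "T")[1, 1]), 0L)
  ## indel annotations are consumed without affecting counts
  pi <- writeTempLines("Chr1\t11\tG\t3\t.+2AT,.\tJJJ", ".pileup")
  xi <- readMpileup(pi)
  expect_equal(unname(baseCounts(xi, "G")[1, 1]), 3L)
  ## read start/end markers, deletion placeholder, reference skip
  pm <- writeTempLines("Chr1\t12\tC\t4\t^I.$,*>\tJJJJ", ".pileup")
  xm <- readMpileup(pm)
  expect_equal(unname(baseCounts(xm, "C")[1, 1]), 2L)
  expect_equal(unname(baseCounts(xm, "DEL")[1, 1]), 1L)
  expect_equal(unname(baseCounts(xm, "N")[1, 1]), 1L)
})

test_that("pileup parser errors on malformed input with line numbers", {
  bad1 <- writeTempLines(c("Chr1\t1\tA\t1\t.\tI",
                           "Chr1\t2\tA\t2\t..\tI"), ".pileup")
  expect_error(readMpileup(bad1), "line 2.*mismatch")
  bad2 <- writeTempLines("Chr1\t1\tA\t1\t.+\tI", ".pileup")
  expect_error(readMpileup(bad2), "indel")
})

test_that("pileup parser agrees with a naive reference decoder", {
  set.seed(42)
  nlines <- 1000
  refs <- sample(c("A", "C", "G", "T", "N"), nlines, replace = TRUE)
  cols <- lapply(refs, randomPileupColumn)
  minq <- 15L
  p <- writeTempLines(vapply(seq_len(nlines), function(i) {
    paste("Chr1", i, refs[i], "0", cols[[i]]$bases, cols[[i]]$quals,
          sep = "\t")
  }, character(1)), ".pileup")
  x <- readMpileup(p, minBaseQuality = minq)
  tal <- c("A", "C", "G", "T", "N", "DEL")
  got <- vapply(tal, function(b) baseCounts(x, b)[, 1], integer(nlines))
  want <- t(vapply(seq_len(nlines), function(i) {
    naivePileupDecode(cols[[i]]$bases, cols[[i]]$quals, refs[i], minq)
  }, integer(6)))
  dimnames(want) <- dimnames(got)
  expect_identical(got, want)
})

test_that("frequency tables convert frequencies to scaled pseudo-counts", {
  p <- writeTempLines(c(
    "chrom\tpos\tref\talt\ts1.freq",
    "Chr1\t1\tA\tC\t0.25",
    "Chr1\t2\tA\tC\t0",
    "Chr1\t3\tA\tC\t0.333"
  ), ".tsv")
  x <- readFrequencyTable(p, scalingDepth = 100)
  expect_equal(unname(baseCounts(x, "A")[1:2, 1]), c(75L, 100L))
  expect_equal(unname(baseCounts(x, "C")[1:2, 1]), c(25L, 0L))
  y <- readFrequencyTable(p, scalingDepth = 10)
  expect_equal(unname(baseCounts(y, "A")[2, 1]), 10L)
  ## rounding half away from zero at n0 = 3: 0.333*3 = 0.999 -> 1
  z <- readFrequencyTable(p, scalingDepth = 3)
  expect_equal(unname(baseCounts(z, "A")[3, 1]), 2L)
  expect_equal(unname(baseCounts(z, "C")[3, 1]), 1L)
})

test_that("count tables pass through; malformed tables error", {
  p <- writeTempLines(c(
    "chrom\tpos\tref\talt\ts1.ref\ts1.alt",
    "Chr1\t1\tG\tT\t12\t3"
  ), ".tsv")
  x <- readFrequencyTable(p)
  expect_equal(unname(baseCounts(x, "G")[1, 1]), 12L)
  expect_equal(unname(baseCounts(x, "T")[1, 1]), 3L)
  bad <- writeTempLines(c(
    "chrom\tpos\tref\talt\ts1.freq", "Chr1\t1\tA\tC\t1.5"), ".tsv")
  expect_error(readFrequencyTable(bad), "\\[0, 1\\]")
  nocol <- writeTempLines(c("chrom\tpos\ts1.freq", "Chr1\t1\t0.5"), ".tsv")
  expect_error(readFrequencyTable(nocol), "columns")
})

test_that("region formats converge on 1-based inclusive coordinates", {
  bed <- readRegions(writeTempLines("chr1\t99\t200", ".bed"))
  expect_equal(GenomicRanges::start(bed), 100L)
  expect_equal(GenomicRanges::end(bed), 200L)
  gff <- readRegions(writeTempLines(
    "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=g1", ".gff3"))
  expect_equal(GenomicRanges::start(gff), 100L)
  expect_equal(GenomicRanges::end(gff), 200L)
  txt <- readRegions(writeTempLines(
    c("chr2:5", "chr3:10-20", "chr4"), ".txt"))
  expect_equal(GenomicRanges::start(txt)[1:2], c(5L, 10L))
  expect_equal(GenomicRanges::end(txt)[1:2], c(5L, 20L))
  expect_gt(GenomicRanges::end(txt)[3], 1e9)  # bare chrom spans everything
  expect_error(readRegions(writeTempLines("chr1:20-10", ".txt")),
               "start > end")
})

test_that("stream merging honors union and intersection of positions", {
  s1 <- writeTempLines(c("Chr1\t1\tA\t2:0:0:0:0:0",
                         "Chr1\t2\tA\t3:0:0:0:0:0"), ".sync")
  s2 <- writeTempLines(c("Chr1\t2\tA\t0:0:4:0:0:0",
                         "Chr1\t3\tA\t0:5:0:0:0:0"), ".sync")
  a <- readSync(s1)
  b <- readSync(s2)
  u <- mergePoolSeq(list(a, b), mode = "union")
  expect_equal(positions(u), 1:3)
  expect_equal(ncol(u), 2L)
  expect_equal(unname(sampleStatus(u)[1, 2]), filterCodes()$sample[["missing"]])
  expect_equal(unname(baseCounts(u, "C")[2, 2]), 4L)
  i <- mergePoolSeq(list(a, b), mode = "intersection")
  expect_equal(positions(i), 2L)
  ## single stream is the identity in either mode
  one <- mergePoolSeq(list(a), mode = "union")
  expect_equal(positions(one), positions(a))
  expect_equal(baseCounts(one, "A"), baseCounts(a, "A"))
})

test_that("merged output is sorted and |union| >= |intersection|", {
  set.seed(3)
  for (rep in 1:10) {
    mk <- function() {
      pos <- sort(sample(1:30, sample(3:10, 1)))
      lines <- paste0("Chr1\t", pos, "\tA\t1:0:0:0:0:0")
      readSync(writeTempLines(lines, ".sync"))
    }
    a <- mk(); b <- mk()
    u <- mergePoolSeq(list(a, b), "union")
    i <- mergePoolSeq(list(a, b), "intersection")
    expect_false(is.unsorted(positions(u)))
    expect_gte(nrow(u), nrow(i))
    same <- setequal(positions(a), positions(b))
    expect_equal(nrow(u) == nrow(i), same)
  }
})

test_that("ref conflicts across files error unless a reference resolves", {
  s1 <- readSync(writeTempLines("Chr1\t3\tA\t2:0:0:0:0:0", ".sync"))
  s2 <- readSync(writeTempLines("Chr1\t3\tC\t0:0:4:0:0:0", ".sync"))
  expect_error(mergePoolSeq(list(s1, s2)), "Chr1:3")
  fa <- writeTempLines(c(">Chr1", "GGGGG"), ".fa")
  m <- mergePoolSeq(list(s1, s2), reference = fa)
  expect_equal(refBase(m), "G")
})
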