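test_that("per-site pi components match hand values", {
  c55 <- c(A = 5, C = 5, G = 0, T = 0)
  expect_equal(sitePiWithin(c55, c55, 10, 10), (10 / 9)^2 * 0.5)
  mono <- c(A = 8, C = 0, G = 0, T = 0)
  expect_equal(sitePiWithin(mono, mono, 10, 10), 0)
  expect_true(is.na(sitePiWithin(c(A = 1, C = 0, G = 0, T = 0), c55, 10, 10)))
  ## fixed difference and matched intermediate frequencies
  allA <- c(A = 6, C = 0, G = 0, T = 0)
  allC <- c(A = 0, C = 6, G = 0, T = 0)
  expect_equal(sitePiBetween(allA, allC), 1.0)
  expect_equal(sitePiBetween(c55, c55), 0.5)
  expect_equal(sitePiTotal(0, 1), 0.5)
  expect_equal(sitePiTotal(0.4, 0.4), 0.4)
})

test_that("pi-total equals the within/between average identically", {
  set.seed(17)
  for (rep in 1:20) {
    f1 <- c(A = rpois(1, 5) + 1, C = rpois(1, 3), G = rpois(1, 1), T = 0)
    f2 <- c(A = rpois(1, 2) + 1, C = rpois(1, 4) + 1, G = 0, T = rpois(1, 1))
    w <- sitePiWithin(f1, f2, 10, 12)
    b <- sitePiBetween(f1, f2)
    expect_equal(sitePiTotal(w, b), (w + b) / 2)
  }
})

test_that("window FST is 1 at fixed differences and NA without variation", {
  x <- classifySites(makePool(list(
    list(c(A = 20), c(C = 20)),
    list(c(A = 20), c(C = 20))
  ), pos = 1:2, poolSizes = 50))
  w <- makeWindows(x, "genome")
  expect_equal(windowFst(x, w, "hudson")$fst, 1.0)
  expect_equal(windowFst(x, w, "nei")$fst, 1.0)
  ## identical monomorphic pools: no variation anywhere -> not available
  mono <- classifySites(makePool(list(list(c(A = 20), c(A = 20))),
                                 poolSizes = 50))
  wm <- makeWindows(mono, "genome")
  for (m in c("hudson", "nei", "kofler", "karlsson")) {
    expect_true(is.na(windowFst(mono, wm, m)$fst))
  }
})

test_that("window component sums keep pi_total = (pi_w + pi_b)/2 exactly", {
  sim <- simulatePairDataset(nSites = 2000, theta = 0.01, fst = 0.1,
                             poolSizes = 20, depth = 20, seed = 3)
  x <- classifySites(sim$data)
  w <- makeWindows(x, "interval", width = 250, stride = 250)
  h <- windowFst(x, w, "hudson")
  expect_equal(h$pi_total_sum, (h$pi_within_sum + h$pi_between_sum) / 2,
               tolerance = 1e-12)
  ## Hudson >= Nei wherever both are defined with pi_b >= pi_t > 0
  n <- windowFst(x, w, "nei")
  ok <- !is.na(h$fst) & !is.na(n$fst) &
    h$pi_between_sum >= h$pi_total_sum & h$pi_total_sum > 0
  expect_true(all(h$fst[ok] >= n$fst[ok]))
})

test_that("FST estimates are symmetric under swapping the samples", {
  sim <- simulatePairDataset(nSites = 1000, theta = 0.01, fst = 0.2,
                             poolSizes = c(20, 30), depth = 20, seed = 19)
  x <- classifySites(sim$data)
  w <- makeWindows(x, "interval", width = 250, stride = 250)
  for (m in c("hudson", "nei", "kofler", "karlsson")) {
    ab <- windowFst(x, w, m, pairs = cbind(1, 2))$fst
    ba <- windowFst(x, w, m, pairs = cbind(2, 1))$fst
    expect_equal(ab, ba, tolerance = 1e-12)
  }
})

test_that("pi estimators are unbiased under two-stage sampling", {
  ## true freq 0.3 in both pools, p = 10, n = 10: E pi_within = 0.42,
  ## and with independent pools E pi_between = 0.42 as well
  nrep <- 30000
  set.seed(23)
  s1 <- simulateSite(rep(0.3, nrep), p = 10, depth = 10)
  s2 <- simulateSite(rep(0.3, nrep), p = 10, depth = 10)
  x <- PoolSeq(
    counts = lapply(setNames(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
                    function(b) cbind(s1$counts[, b], s2$counts[, b])),
    chrom = rep("c", nrep), pos = seq_len(nrep), poolSizes = 10
  )
  x <- classifySites(x)
  w <- makeWindows(x, "interval", width = 1000, stride = 1000)
  h <- windowFst(x, w, "hudson")
  mw <- h$pi_within_sum / 1000
  mb <- h$pi_between_sum / 1000
  zw <- (mean(mw) - 0.42) / (sd(mw) / sqrt(length(mw)))
  zb <- (mean(mb) - 0.42) / (sd(mb) / sqrt(length(mb)))
  expect_lt(abs(zw), 3)
  expect_lt(abs(zb), 3)
})

test_that("pi-between matches its expectation for distinct frequencies", {
  ## freqs 0.3 and 0.6: E pi_between = 1 - (0.3*0.6 + 0.7*0.4) = 0.54
  nrep <- 30000
  set.seed(29)
  s1 <- simulateSite(rep(0.3, nrep), p = 10, depth = 10)
  s2 <- simulateSite(rep(0.6, nrep), p = 10, depth = 10)
  x <- PoolSeq(
    counts = lapply(setNames(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
                    function(b) cbind(s1$counts[, b], s2$counts[, b])),
    chrom = rep("c", nrep), pos = seq_len(nrep), poolSizes = 10
  )
  x <- classifySites(x)
  w <- makeWindows(x, "interval", width = 1000, stride = 1000)
  h <- windowFst(x, w, "hudson")
  mb <- h$pi_between_sum / 1000
  zb <- (mean(mb) - 0.54) / (sd(mb) / sqrt(length(mb)))
  expect_lt(abs(zb), 3)
})

test_that("Kofler and Karlsson are biased upward where Hudson/Nei are not", {
  sim <- simulatePairDataset(nSites = 2e4, theta = 0.01, fst = 0,
                             poolSizes = 10, depth = 10, seed = 8)
  x <- classifySites(sim$data)
  w <- makeWindows(x, "interval", width = 2000, stride = 2000)
  z <- sapply(c("hudson", "nei", "kofler", "karlsson"), function(m) {
    f <- windowFst(x, w, m)$fst
    mean(f, na.rm = TRUE) / (sd(f, na.rm = TRUE) / sqrt(sum(!is.na(f))))
  })
  expect_gt(z[["kofler"]], 3)
  expect_gt(z[["karlsson"]], 3)
  expect_lt(z[["hudson"]], 3)
  expect_lt(z[["nei"]], 3)
})

test_that("Hudson and Nei recover the realized FST of an island model", {
  sim <- simulatePairDataset(nSites = 2e4, theta = 0.01, fst = 0.2,
                             poolSizes = 50, depth = 50, seed = 7)
  x <- classifySites(sim$data)
  W <- 2000
  w <- makeWindows(x, "interval", width = W, stride = W)
  tr <- sim$truth
  wid <- ceiling(tr$pos / W)
  hw <- tapply(tr$hWithin, wid, sum)
  hb <- tapply(tr$hBetween, wid, sum)
  ht <- tapply(tr$hTotal, wid, sum)
  dH <- windowFst(x, w, "hudson")$fst - (1 - hw / hb)
  dN <- windowFst(x, w, "nei")$fst - (1 - hw / ht)
  expect_lt(abs(mean(dH)) / (sd(dH) / sqrt(length(dH))), 3)
  expect_lt(abs(mean(dN)) / (sd(dN) / sqrt(length(dN))), 3)
})
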