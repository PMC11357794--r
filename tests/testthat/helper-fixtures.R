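## Shared test fixtures: tiny PoolSeq builders, on-the-fly sync/pileup text,
## and independent reference implementations used as oracles.

## Build a PoolSeq from a compact per-site spec: a list of sample count
## lists, e.g. sites = list(list(c(A = 6, C = 2), c(T = 4))) for one site
## with two samples.
makePool <- function(sites, chrom = "Chr1", pos = seq_along(sites),
                     ref = NULL, poolSizes = 10L, minCount = 1L) {
  nsmp <- length(sites[[1]])
  tal <- c("A", "C", "G", "T", "N", "DEL")
  counts <- lapply(tal, function(b) {
    m <- matrix(0L, length(sites), nsmp)
    for (i in seq_along(sites)) {
      for (j in seq_len(nsmp)) {
        v <- sites[[i]][[j]]
        if (b %in% names(v)) m[i, j] <- as.integer(v[[b]])
      }
    }
    m
  })
  names(counts) <- tal
  PoolSeq(counts = counts, chrom = rep(chrom, length(sites)), pos = pos,
          ref = ref, poolSizes = poolSizes, minCount = minCount)
}

writeTempLines <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

## ---- independent oracles ---------------------------------------------

## brute-force estimator denominators: explicit double loops over the
## closed-form binomial pmf (no dbinom, no caching)
bruteDenominators <- function(n, p, b) {
  dpi <- 0
  dw <- 0
  if (b > n - b) return(list(dpi = 0, dw = 0))
  for (m in b:(n - b)) {
    k <- 1:(p - 1)
    inner <- sum(choose(n, m) * (k / p)^m * (1 - k / p)^(n - m) / k)
    dw <- dw + inner
    dpi <- dpi + 2 * m * (n - m) / (n * (n - 1)) * inner
  }
  list(dpi = dpi, dw = dw)
}

## naive character-consuming pileup decoder, deliberately written with a
## different mechanism (front-stripping regexes) than the package parser
naivePileupDecode <- function(bases, quals, ref, minq = 0L, offset = 33L) {
  counts <- stats::setNames(integer(6), c("A", "C", "G", "T", "N", "DEL"))
  if (bases == "*" && (quals == "*" || quals == "")) return(counts)
  qi <- 0L
  ref <- toupper(ref)
  while (nchar(bases) > 0L) {
    if (startsWith(bases, "^")) {
      bases <- substr(bases, 3L, nchar(bases))
    } else if (startsWith(bases, "$")) {
      bases <- substr(bases, 2L, nchar(bases))
    } else if (grepl("^[+-][0-9]+", bases)) {
      tok <- regmatches(bases, regexpr("^[+-][0-9]+", bases))
      len <- as.integer(substr(tok, 2L, nchar(tok)))
      bases <- substr(bases, nchar(tok) + len + 1L, nchar(bases))
    } else {
      ch <- substr(bases, 1L, 1L)
      bases <- substr(bases, 2L, nchar(bases))
      qi <- qi + 1L
      qv <- utf8ToInt(substr(quals, qi, qi)) - offset
      if (qv >= minq) {
        slot <- if (ch %in% c(".", ",")) {
          if (ref %in% c("A", "C", "G", "T")) ref else "N"
        } else if (toupper(ch) %in% c("A", "C", "G", "T")) {
          toupper(ch)
        } else if (ch == "*") {
          "DEL"
        } else {
          "N"
        }
        counts[slot] <- counts[slot] + 1L
      }
    }
  }
  counts
}

## random well-formed pileup sample column (bases + quality strings)
randomPileupColumn <- function(ref) {
  nread <- sample(0:8, 1)
  if (nread == 0) return(list(bases = "*", quals = "*"))
  bases <- character(0)
  quals <- character(0)
  alphabet <- c(".", ",", "A", "C", "G", "T", "a", "c", "g", "t",
                "N", "n", "*", ">", "<")
  for (r in seq_len(nread)) {
    tok <- sample(alphabet, 1)
    if (runif(1) < 0.15) tok <- paste0("^", intToUtf8(sample(33:90, 1)), tok)
    if (runif(1) < 0.15) tok <- paste0(tok, "$")
    if (runif(1) < 0.2) {
      ins <- sample(1:3, 1)
      tok <- paste0(tok, sample(c("+", "-"), 1), ins,
                    paste(sample(c("A", "C", "G", "T", "a", "t"), ins,
                                 replace = TRUE), collapse = ""))
    }
    bases <- c(bases, tok)
    quals <- c(quals, intToUtf8(sample(33:74, 1)))
  }
  list(bases = paste(bases, collapse = ""),
       quals = paste(quals, collapse = ""))
}
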