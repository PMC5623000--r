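# Independent oracles and fixture builders shared across test files.
# Oracles deliberately avoid the code paths they check.

# quadratic reference implementation of the raw fingerprint: list every
# within-chromosome consecutive pair explicitly and increment one cell at
# a time using string keys.
naiveRawFingerprint <- function(variants, L = 20L, C = 20L) {
  pk <- pairKeys()
  raw <- matrix(0L, 144L, L, dimnames = list(pk, NULL))
  close <- matrix(0L, 144L, C, dimnames = list(pk, NULL))
  for (ch in unique(variants$chrom)) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    v <- v[!duplicated(v$pos), , drop = FALSE]
    if (nrow(v) < 2L) next
    for (i in seq_len(nrow(v) - 1L)) {
      key <- paste0(toupper(v$ref[i]), toupper(v$alt[i]),
                    toupper(v$ref[i + 1L]), toupper(v$alt[i + 1L]))
      d <- v$pos[i + 1L] - v$pos[i] - 1
      if (d < C) {
        close[key, d + 1L] <- close[key, d + 1L] + 1L
      } else {
        raw[key, (d %% L) + 1L] <- raw[key, (d %% L) + 1L] + 1L
      }
    }
  }
  list(raw = raw, close = close)
}

# average ranks computed from first principles (sorted uniques + cumulative
# counts), then the explicit Pearson product-moment formula.
manualSpearman <- function(x, y) {
  avgRank <- function(v) {
    s <- sort(unique(v))
    cnt <- tabulate(match(v, s), nbins = length(s))
    hi <- cumsum(cnt)
    (hi - (cnt - 1) / 2)[match(v, s)]
  }
  rx <- avgRank(x); ry <- avgRank(y)
  n <- length(rx)
  sxy <- sum(rx * ry) - n * mean(rx) * mean(ry)
  sxx <- sum(rx * rx) - n * mean(rx)^2
  syy <- sum(ry * ry) - n * mean(ry)^2
  sxy / sqrt(sxx * syy)
}

# independent two-pass z-scoring (population SD), column-then-row,
# cell-by-cell loops.
manualTwoPassZ <- function(m) {
  out <- m * 0
  for (j in seq_len(ncol(m))) {
    mu <- mean(m[, j])
    sdev <- sqrt(mean((m[, j] - mu)^2))
    out[, j] <- if (sdev > 0) (m[, j] - mu) / sdev else 0
  }
  for (i in seq_len(nrow(m))) {
    mu <- mean(out[i, ])
    sdev <- sqrt(mean((out[i, ] - mu)^2))
    out[i, ] <- if (sdev > 0) (out[i, ] - mu) / sdev else 0
  }
  out
}

# random sorted biallelic SNV stream over a few chromosomes
randomStream <- function(n, nChrom = 3L, maxPos = 5e4, seed = 1L) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  chrom <- sort(sample(as.character(seq_len(nChrom)), n, replace = TRUE))
  out <- do.call(rbind, lapply(split(seq_len(n), chrom), function(idx) {
    k <- length(idx)
    pos <- sort(sample.int(maxPos, k))
    ref <- sample(bases, k, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    data.frame(chrom = chrom[idx], pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# wrap an arbitrary count matrix as a RawFingerprint with consistent metadata
makeRawFp <- function(m, C = 0L, id = "m") {
  m <- matrix(as.integer(m), 144L, ncol(m), dimnames = list(pairKeys(), NULL))
  methods::new(Class = "RawFingerprint", id = id, L = ncol(m),
               C = as.integer(C),
               nSnvs = 0, nPairsRaw = sum(m), nPairsClose = 0,
               source = "constructed", kind = "raw", raw = m,
               close = matrix(0L, 144L, C, dimnames = list(pairKeys(), NULL)))
}

# wrap a value matrix as a NormalizedFingerprint (for comparison tests)
makeNormFp <- function(values, id, kind = "normalized") {
  values <- matrix(as.numeric(values), 144L, ncol(values),
                   dimnames = list(pairKeys(), NULL))
  methods::new(Class = "NormalizedFingerprint", id = id, L = ncol(values),
               C = 20L, nSnvs = 0, nPairsRaw = 0, nPairsClose = 0,
               source = "constructed", kind = kind, values = values)
}

normFpOf <- function(variants, id = "g", L = 20L, C = 20L) {
  normalize(computeRawFingerprint(variants, L = L, C = C, id = id))
}

# minimal multi-sample VCF exercising the reader's filtering rules
writeTestVcf <- function(path, lines) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", "S1", "S2", sep = "\t"),
               lines), path)
  path
}

vcfLine <- function(chrom, pos, ref, alt, gt1 = "0/1", gt2 = "0/0",
                    filter = "PASS") {
  paste(chrom, pos, ".", ref, alt, ".", filter, ".", "GT", gt1, gt2,
        sep = "\t")
}
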