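test_that("raw fingerprint matches the hand-traced example", {
  v <- data.frame(chrom = "1", pos = c(100, 150, 152),
                  ref = c("G", "T", "A"), alt = c("A", "C", "C"))
  fp <- computeRawFingerprint(v, L = 20, C = 20, id = "toy")
  # pair GA+TC: d = 150 - 100 - 1 = 49 >= C, folded to column 49 %% 20 = 9
  expect_equal(unname(rawMatrix(fp)["GATC", 10]), 1L)
  expect_equal(sum(rawMatrix(fp)), 1L)
  # pair TC+AC: d = 1 < C, close matrix column for d = 1
  expect_equal(unname(closeMatrix(fp)["TCAC", 2]), 1L)
  expect_equal(sum(closeMatrix(fp)), 1L)
  expect_equal(nSnvs(fp), 3)
  expect_equal(fp@nPairsRaw, 1)
  expect_equal(fp@nPairsClose, 1)
})

test_that("pairs never span chromosomes and singletons contribute nothing", {
  v <- data.frame(chrom = c("1", "2"), pos = c(100, 100),
                  ref = c("G", "T"), alt = c("A", "C"))
  fp <- computeRawFingerprint(v)
  expect_equal(fp@nPairsRaw + fp@nPairsClose, 0)
  empty <- computeRawFingerprint(v[0, ])
  expect_equal(nSnvs(empty), 0)
  expect_equal(sum(rawMatrix(empty)), 0L)
})

test_that("C = 0 disables the close matrix and d = 0 is a legal distance", {
  v <- data.frame(chrom = "1", pos = c(100, 101, 150),
                  ref = c("G", "T", "A"), alt = c("A", "C", "C"))
  fp0 <- computeRawFingerprint(v, L = 20, C = 0)
  expect_identical(dim(closeMatrix(fp0)), c(144L, 0L))
  expect_equal(fp0@nPairsRaw, 2)
  # adjacent positions give d = 0, folding to column 1
  expect_equal(unname(rawMatrix(fp0)["GATC", 1]), 1L)
  # with the default C = 20 the same pair lands in the close matrix at d = 0
  fp20 <- computeRawFingerprint(v, L = 20, C = 20)
  expect_equal(unname(closeMatrix(fp20)["GATC", 1]), 1L)
})

test_that("parameter validation and input checks fire", {
  v <- data.frame(chrom = "1", pos = c(1, 2), ref = "G", alt = "A")
  expect_error(computeRawFingerprint(v, L = 1), "L must be")
  expect_error(computeRawFingerprint(v, C = -1), "C must be")
  bad <- data.frame(chrom = "1", pos = c(1, 5), ref = c("G", "A"),
                    alt = c("A", "A"))
  expect_error(computeRawFingerprint(bad), "non-SNV")
})

test_that("raw + close pair counts conserve the consecutive-pair total", {
  for (s in 1:5) {
    v <- randomStream(300, nChrom = 4, seed = s)
    v <- v[!duplicated(paste(v$chrom, v$pos)), ]
    fp <- computeRawFingerprint(v, L = 7, C = 11)
    perChrom <- table(v$chrom)
    expect_equal(fp@nPairsRaw + fp@nPairsClose, sum(pmax(perChrom - 1, 0)))
    expect_equal(sum(rawMatrix(fp)) + sum(closeMatrix(fp)),
                 fp@nPairsRaw + fp@nPairsClose)
  }
})

test_that("merging per-chromosome partials is bit-identical to the whole", {
  for (s in 1:4) {
    v <- randomStream(400, nChrom = 5, seed = 10 + s)
    whole <- computeRawFingerprint(v, L = 20, C = 20, id = "g")
    parts <- lapply(split(v, v$chrom), computeRawFingerprint,
                    L = 20, C = 20, id = "g")
    merged <- mergeFingerprints(unname(parts), id = "g")
    expect_identical(rawMatrix(merged), rawMatrix(whole))
    expect_identical(closeMatrix(merged), closeMatrix(whole))
    expect_equal(nSnvs(merged), nSnvs(whole))
  }
  # arbitrary partitions of the chromosome set also merge exactly
  v <- randomStream(300, nChrom = 4, seed = 77)
  whole <- computeRawFingerprint(v, id = "g")
  pA <- computeRawFingerprint(v[v$chrom %in% c("1", "3"), ], id = "g")
  pB <- computeRawFingerprint(v[v$chrom %in% c("2", "4"), ], id = "g")
  expect_identical(rawMatrix(mergeFingerprints(pA, pB)), rawMatrix(whole))
})

test_that("merge identities and parameter guards hold", {
  v <- randomStream(100, seed = 3)
  fp <- computeRawFingerprint(v, id = "g")
  expect_identical(rawMatrix(mergeFingerprints(list(fp))), rawMatrix(fp))
  zero <- computeRawFingerprint(v[0, ], id = "z")
  expect_identical(rawMatrix(mergeFingerprints(fp, zero)), rawMatrix(fp))
  other <- computeRawFingerprint(v, L = 120, id = "g")
  expect_error(mergeFingerprints(fp, other), "parameter mismatch")
  expect_error(mergeFingerprints(fp, normalize(fp)), "raw fingerprints")
})

test_that("compute_raw agrees cell-for-cell with the quadratic oracle", {
  for (s in 1:3) {
    n <- c(50, 250, 500)[s]
    v <- randomStream(n, nChrom = 3, maxPos = 2000 + 500 * s, seed = 20 + s)
    fp <- computeRawFingerprint(v, L = 9, C = 6)
    oracle <- naiveRawFingerprint(v, L = 9, C = 6)
    expect_identical(rawMatrix(fp), oracle$raw)
    expect_identical(closeMatrix(fp), oracle$close)
  }
})

test_that("normalization is a column-then-row z-scoring (population SD)", {
  set.seed(5)
  m <- matrix(rpois(288, 9), 144, 2)
  fp <- makeRawFp(m)
  nf <- normalize(fp)
  expect_equal(unname(fpValues(nf)), unname(manualTwoPassZ(m)),
               tolerance = 1e-12)
  # every nondegenerate row has mean 0 and population SD 1
  v <- randomStream(2000, seed = 6)
  nv <- fpValues(normFpOf(v, L = 5))
  live <- apply(nv, 1, function(r) any(r != 0))
  expect_true(all(abs(rowMeans(nv[live, ])) < 1e-9))
  popSD <- apply(nv[live, ], 1, function(r) sqrt(mean((r - mean(r))^2)))
  expect_true(all(abs(popSD - 1) < 1e-9))
})

test_that("normalization kills affine transforms and degenerate inputs", {
  set.seed(8)
  m <- matrix(rpois(144 * 20, 6), 144, 20)
  a <- normalize(makeRawFp(m))
  b <- normalize(makeRawFp(3L * m + 2L))
  expect_equal(fpValues(a), fpValues(b), tolerance = 1e-9)
  # constant matrix (including all-zero / empty genome) -> all zeros
  const <- normalize(makeRawFp(matrix(5L, 144, 20)))
  expect_true(all(fpValues(const) == 0))
  emptyFp <- normalize(computeRawFingerprint(
    data.frame(chrom = character(), pos = numeric(),
               ref = character(), alt = character())))
  expect_true(all(fpValues(emptyFp) == 0))
})

test_that("binary fingerprint follows the odd-beats-even rule with ties to 0", {
  m <- matrix(0L, 144, 2)
  m[1, ] <- c(3L, 5L)   # second column larger -> bit 1
  m[2, ] <- c(5L, 3L)   # -> bit 0
  m[3, ] <- c(4L, 4L)   # tie -> bit 0
  bf <- binarize(makeRawFp(m))
  expect_identical(fpBits(bf)[1:3], c(1L, 0L, 0L))
  expect_true(all(fpBits(bf)[-(1:3)] == 0L))
  # empty genome: all ties at zero
  emptyBf <- binaryFingerprint(data.frame(chrom = character(), pos = numeric(),
                                          ref = character(), alt = character()))
  expect_identical(fpBits(emptyBf), rep(0L, 144))
  expect_error(binarize(makeRawFp(matrix(0L, 144, 20))), "L = 2")
})

test_that("binary fingerprint is a function of the L = 2 raw fingerprint only", {
  v <- randomStream(500, seed = 9)
  direct <- binaryFingerprint(v, C = 20, id = "g")
  viaRaw <- binarize(computeRawFingerprint(v, L = 2, C = 20, id = "g"))
  expect_identical(fpBits(direct), fpBits(viaRaw))
})

test_that("fingerprint files round-trip losslessly for every kind", {
  v <- randomStream(400, seed = 12)
  fp <- computeRawFingerprint(v, id = "g1", source = "test")
  for (ext in c(".fp", ".fp.gz")) {
    f <- tempfile(fileext = ext)
    writeFingerprint(fp, f)
    back <- readFingerprint(f)
    expect_s4_class(back, "RawFingerprint")
    expect_identical(rawMatrix(back), rawMatrix(fp))
    expect_identical(closeMatrix(back), closeMatrix(fp))
    expect_identical(nSnvs(back), nSnvs(fp))
    expect_identical(fpId(back), "g1")
  }
  nf <- normalize(fp)
  f <- tempfile(fileext = ".fp")
  writeFingerprint(nf, f)
  nback <- readFingerprint(f)
  expect_identical(fpValues(nback), fpValues(nf))  # full double precision
  expect_identical(fpKind(nback), "normalized")

  pop <- buildPopulation(list(nf), id = "POP")
  writeFingerprint(pop, f)
  pback <- readFingerprint(f)
  expect_s4_class(pback, "PopulationFingerprint")
  expect_identical(members(pback), "g1")

  bf <- binaryFingerprint(v, id = "g1")
  writeFingerprint(bf, f)
  bback <- readFingerprint(f)
  expect_identical(fpBits(bback), fpBits(bf))

  adj <- adjustToPopulation(nf, pop)
  writeFingerprint(adj, f)
  expect_identical(fpKind(readFingerprint(f)), "adjusted")
})

test_that("fingerprint files enforce kind, version and completeness", {
  v <- randomStream(100, seed = 13)
  fp <- computeRawFingerprint(v, id = "g")
  f <- tempfile(fileext = ".fp")
  writeFingerprint(normalize(fp), f)
  # a normalized file where a raw one is required
  expect_error(mergeFingerprints(readFingerprint(f), fp), "raw fingerprints")
  # merging files with different L fails
  f120 <- tempfile(fileext = ".fp")
  writeFingerprint(computeRawFingerprint(v, L = 120, id = "g"), f120)
  fp20 <- tempfile(fileext = ".fp")
  writeFingerprint(fp, fp20)
  expect_error(mergeFingerprints(readFingerprint(fp20),
                                 readFingerprint(f120)),
               "parameter mismatch")
  # truncation
  writeFingerprint(fp, f)
  lines <- readLines(f)
  writeLines(head(lines, 50), f)
  expect_error(readFingerprint(f), "truncated")
  # version guard
  writeLines(sub("gfp-version=1", "gfp-version=99", lines), f)
  expect_error(readFingerprint(f), "version")
  writeLines("just text", f)
  expect_error(readFingerprint(f), "not a fingerprint")
})
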