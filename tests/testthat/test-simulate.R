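smallModel <- function(seed = 5, ...) {
  cohortModel(nChroms = 3, totalLoci = 6000, seed = seed, ...)
}

test_that("cohort models are well-formed and bit-reproducible", {
  m1 <- smallModel()
  m2 <- smallModel()
  expect_identical(modelLoci(m1), modelLoci(m2))
  l <- modelLoci(m1)
  expect_true(all(tapply(l$pos, l$chrom, function(p) all(diff(p) > 0))))
  expect_true(all(l$freq > 0 & l$freq < 1))
  expect_true(all(l$key %in% snvKeys()))
  # transition fraction ~ tstv/(tstv+1) = 2/3
  pTs <- mean(l$key %in% c("AG", "GA", "CT", "TC"))
  expect_lt(abs(pTs - 2 / 3), 3 * sqrt(2 / 9 / nrow(l)) + 0.01)
  expect_error(cohortModel(nChroms = 2, totalLoci = 1000,
                           chromLengths = 1000), "too short")
})

test_that("pool spacing concentrates (d mod L) mass on the hashed column", {
  l <- modelLoci(smallModel(seed = 6))
  l1 <- l[l$chrom == "1", ]
  d <- l1$pos[-1] - l1$pos[-nrow(l1)] - 1
  peak <- pairRowIndex(l1$key[-nrow(l1)], l1$key[-1]) %% 20L
  hit <- mean(d %% 20L == peak)
  # expected w + (1 - w)/L = 0.525 under the default peak weight 0.5
  expect_gt(hit, 0.45)
  expect_lt(hit, 0.60)
})

test_that("cohort sampling is deterministic, sorted and frequency-faithful", {
  m <- smallModel()
  s1 <- simulateCohort(m, 3, seed = 9)
  s2 <- simulateCohort(m, 3, seed = 9)
  expect_identical(s1$genomes, s2$genomes)
  g <- s1$genomes[[1]]
  expect_true(all(tapply(g$pos, g$chrom, function(p) all(diff(p) > 0))))
  expect_identical(snvKey(g$ref, g$alt), snvKey(g$ref, g$alt))  # valid SNVs
  # observed locus sharing between two individuals matches the
  # carrier-probability expectation within 3 SDs
  cprob <- 1 - (1 - modelLoci(m)$freq)^2
  A <- paste(s1$genomes[[1]]$chrom, s1$genomes[[1]]$pos)
  B <- paste(s1$genomes[[2]]$chrom, s1$genomes[[2]]$pos)
  obs <- length(intersect(A, B))
  expd <- sum(cprob^2)
  sdd <- sqrt(sum(cprob^2 * (1 - cprob^2)))
  expect_lt(abs(obs - expd), 4 * sdd)
  # divergence 0 leaves all populations with identical frequencies
  s3 <- simulateCohort(m, 4, nPopulations = 2, divergence = 0, seed = 2)
  expect_equal(s3$popFreqs[, 1], s3$popFreqs[, 2])
})

test_that("pedigree children obey Mendelian transmission", {
  m <- smallModel(seed = 8)
  ped <- simulatePedigree(m, founders = c("F1", "F2"),
                          matings = data.frame(parent_a = "F1",
                                               parent_b = "F2",
                                               n_children = 2),
                          seed = 3)
  expect_setequal(names(ped$genomes), c("F1", "F2", "F1.F2.1", "F1.F2.2"))
  # every variant carried by a child exists in at least one parent
  key <- function(g) paste(g$chrom, g$pos)
  parentLoci <- union(key(ped$genomes$F1), key(ped$genomes$F2))
  expect_true(all(key(ped$genomes$F1.F2.1) %in% parentLoci))
  # allele counts: child genotype never exceeds what parents can transmit
  gC <- ped$genotypes$F1.F2.1
  expect_true(all(gC <= ceiling(ped$genotypes$F1 / 1) +
                       ceiling(ped$genotypes$F2 / 1)))
  # monozygotic duplicate: identical input gives correlation exactly 1
  twin <- normFpOf(ped$genomes$F1.F2.1, id = "twin", L = 10)
  self <- normFpOf(ped$genomes$F1.F2.1, id = "self", L = 10)
  expect_equal(compareFingerprints(twin, self)$score, 1.0)
  # malformed pedigrees fail
  expect_error(simulatePedigree(m, "F1",
                                data.frame(parent_a = "F1", parent_b = "F1",
                                           n_children = 1)), "distinct")
  expect_error(simulatePedigree(m, "F1",
                                data.frame(parent_a = "F1", parent_b = "QQ",
                                           n_children = 1)), "unknown parent")
})

test_that("relationship categories derive correctly from the parent map", {
  # three generations: grandparent, avuncular and cousin links
  m <- smallModel(seed = 12)
  ped <- simulatePedigree(
    m, founders = c("F1", "F2", "F3", "F4"),
    matings = data.frame(
      parent_a = c("F1", "F1.F2.1", "F1.F2.2"),
      parent_b = c("F2", "F3", "F4"),
      n_children = c(2, 1, 1)),
    seed = 1)
  rel <- relationshipCategories(names(ped$genomes), ped$parents)
  lookup <- function(a, b) {
    rel$relationship[(rel$id_a == a & rel$id_b == b) |
                     (rel$id_a == b & rel$id_b == a)]
  }
  expect_identical(lookup("F1.F2.1", "F1.F2.2"), "sibling")
  expect_identical(lookup("F1", "F1.F2.1"), "parent_child")
  expect_identical(lookup("F1", "F1.F2.1.F3.1"), "grandparent")
  expect_identical(lookup("F1.F2.2", "F1.F2.1.F3.1"), "avuncular")
  expect_identical(lookup("F1.F2.1.F3.1", "F1.F2.2.F4.1"), "cousin")
  expect_identical(lookup("F3", "F4"), "unrelated")
  expect_identical(lookup("F1", "F2"), "unrelated")
  expect_identical(lookup("F3", "F1.F2.2.F4.1"), "unrelated")
})

test_that("half-siblings share exactly one parent", {
  m <- smallModel(seed = 13)
  ped <- simulatePedigree(
    m, founders = c("F1", "F2", "F3"),
    matings = data.frame(parent_a = c("F1", "F1"), parent_b = c("F2", "F3"),
                         n_children = c(1, 1)),
    seed = 2)
  rel <- relationshipCategories(names(ped$genomes), ped$parents)
  hs <- rel$relationship[rel$id_a == "F1.F2.1" & rel$id_b == "F1.F3.1"]
  expect_identical(hs, "half_sibling")
})

test_that("dropout degradation is a seeded binomial thinning", {
  v <- randomStream(10000, nChrom = 4, maxPos = 5e6, seed = 21)
  expect_identical(degradeMissing(v, 0, seed = 1), v)
  expect_equal(nrow(degradeMissing(v, 1, seed = 1)), 0L)
  d1 <- degradeMissing(v, 0.5, seed = 7)
  d2 <- degradeMissing(v, 0.5, seed = 7)
  expect_identical(d1, d2)
  # retained count within 4 SD of Binomial(n, 0.5)
  expect_lt(abs(nrow(d1) - 5000), 4 * sqrt(10000 * 0.25))
  # order preserved (subset of the original sequence)
  expect_true(all(paste(d1$chrom, d1$pos) %in% paste(v$chrom, v$pos)))
  expect_false(is.unsorted(match(paste(d1$chrom, d1$pos),
                                 paste(v$chrom, v$pos))))
})

test_that("noise degradation inserts one intervening SNV per chosen pair", {
  v <- randomStream(400, nChrom = 2, maxPos = 1e6, seed = 22)
  v <- v[!duplicated(paste(v$chrom, v$pos)), ]
  expect_identical(degradeNoise(v, 0, seed = 1), v)
  # probability 1 on well-separated variants: n-1 insertions per chromosome
  noisy <- degradeNoise(v, 1, seed = 3)
  perChrom <- table(v$chrom)
  expect_equal(nrow(noisy), nrow(v) + sum(perChrom - 1))
  # insertions never collide and land strictly between their flanks
  expect_false(any(duplicated(paste(noisy$chrom, noisy$pos))))
  expect_true(all(tapply(noisy$pos, noisy$chrom,
                         function(p) all(diff(p) > 0))))
  # adjacent positions never receive insertions
  adj <- data.frame(chrom = "1", pos = c(100, 101, 102),
                    ref = c("G", "T", "A"), alt = c("A", "C", "C"))
  expect_identical(degradeNoise(adj, 1, seed = 1), adj)
  # determinism
  expect_identical(degradeNoise(v, 0.4, seed = 9),
                   degradeNoise(v, 0.4, seed = 9))
})

test_that("degradation commutes with chromosome partition and merge", {
  v <- randomStream(3000, nChrom = 3, maxPos = 2e6, seed = 25)
  v <- v[!duplicated(paste(v$chrom, v$pos)), ]
  deg <- degradeMissing(v, 0.3, seed = 4)
  whole <- computeRawFingerprint(deg, id = "g")
  parts <- lapply(split(deg, deg$chrom), computeRawFingerprint, id = "g")
  expect_identical(rawMatrix(mergeFingerprints(unname(parts))),
                   rawMatrix(whole))
})

test_that("robustness curve starts at perfect correlation", {
  v <- randomStream(2000, nChrom = 2, maxPos = 2e6, seed = 26)
  rc <- robustnessCurve(v, "missing", levels = c(0, 0.5), L = 10, seed = 2,
                        binary = TRUE)
  expect_equal(rc$correlation[1], 1.0)
  expect_equal(rc$binary[1], 1.0)
  expect_identical(names(rc), c("level", "correlation", "binary"))
  expect_true(all(rc$correlation >= -1 & rc$correlation <= 1))
  rs <- robustnessSummary(v, "missing", levels = c(0, 0.5), seeds = 1:2,
                          L = 10)
  expect_equal(rs$meanCorrelation[1], 1.0)
})
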