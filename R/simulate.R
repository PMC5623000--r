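#' Synthetic cohort model
#'
#' A \code{CohortModel} holds a shared population variant pool from which
#' individuals, populations and pedigrees are sampled: per-chromosome
#' sorted locus positions, a per-locus SNV key and an alternate-allele
#' frequency. The pool is generated as a sequential walk along each
#' chromosome. Keys are drawn with a transition:transversion bias
#' (\code{tstvRatio}, default 2:1, split evenly over the 4 transition and
#' 8 transversion keys). The gap to the next locus is
#' \code{g = Lref * G + r + 1} with \code{G} geometric (mean chosen so the
#' expected gap is \code{meanGap}) and \code{r} drawn from a categorical
#' over \code{0..Lref-1} that places \code{spacingPeakWeight} of its mass
#' on the column \code{pairRowIndex(prevKey, curKey) \%\% Lref}, the rest
#' uniform. Distances between consecutive pool loci thus carry genuine
#' key-pair-dependent (d mod L) structure, mirroring the key- and
#' distance-dependent spacing of real genomes; with purely uniform
#' spacing, normalized fingerprints would contain only sampling noise.
#' Allele frequencies are drawn as \code{0.01 + 0.98 * Beta(1, 3)},
#' skewed toward low frequencies as in real site-frequency spectra while
#' keeping desk-scale genomes variant-dense.
#'
#' @slot loci data.frame: chrom, pos, key, freq (positions strictly
#'   increasing within each chromosome; frequencies in (0, 1)).
#' @slot params list of the generation parameters.
#' @slot seed the seed the pool was generated under.
#'
#' @param nChroms number of autosomes (default 22).
#' @param totalLoci total pool size across chromosomes (default 200000).
#' @param chromLengths base-pair lengths, recycled to \code{nChroms};
#'   defaults to a comfortable multiple of the expected span. An error is
#'   raised when a chromosome is too short for its share of loci.
#' @param spacingPeakWeight fraction of each gap's (d mod Lref) mass on
#'   the key-pair-determined column (default 0.5).
#' @param tstvRatio transition:transversion weight (default 2).
#' @param meanGap expected inter-locus gap in bp (default 1000).
#' @param Lref fingerprint length the spacing structure is keyed to
#'   (default 20).
#' @param seed random seed; the pool is deterministic given the
#'   parameters and seed.
#' @return a \code{CohortModel}.
#' @examples
#' m <- cohortModel(nChroms = 2, totalLoci = 1000, seed = 1)
#' m
#' @aliases CohortModel-class
#' @exportClass CohortModel
#' @export
cohortModel <- function(nChroms = 22L, totalLoci = 200000L,
                        chromLengths = NULL, spacingPeakWeight = 0.5,
                        tstvRatio = 2, meanGap = 1000, Lref = 20L,
                        seed = 42L) {
  nChroms <- as.integer(nChroms); totalLoci <- as.integer(totalLoci)
  Lref <- as.integer(Lref)
  stopifnot(nChroms >= 1L, totalLoci >= nChroms, Lref >= 2L,
            spacingPeakWeight >= 0, spacingPeakWeight <= 1,
            tstvRatio > 0, meanGap > Lref)
  nPer <- rep(totalLoci %/% nChroms, nChroms)
  extra <- totalLoci %% nChroms
  if (extra > 0L) nPer[seq_len(extra)] <- nPer[seq_len(extra)] + 1L
  if (is.null(chromLengths)) {
    chromLengths <- ceiling(nPer * meanGap * 2 + 1e4)
  }
  chromLengths <- rep_len(as.numeric(chromLengths), nChroms)
  short <- chromLengths < nPer * meanGap * 1.25
  if (any(short)) {
    stop("chromosome(s) ", paste(which(short), collapse = ", "),
         " too short for the requested locus count at mean gap ", meanGap)
  }

  # transition keys among the 12: AG, GA, CT, TC
  isTs <- .SNV_KEYS %in% c("AG", "GA", "CT", "TC")
  keyProb <- ifelse(isTs, tstvRatio / (tstvRatio + 1) / 4,
                    1 / (tstvRatio + 1) / 8)
  meanG <- max((meanGap - 1 - (Lref - 1) / 2) / Lref, 0.5)
  pGeom <- 1 / (1 + meanG)
  w <- spacingPeakWeight

  loci <- .withSeed(seed, {
    parts <- vector("list", nChroms)
    for (ch in seq_len(nChroms)) {
      n <- nPer[ch]
      keyIdx <- sample.int(12L, n, replace = TRUE, prob = keyProb)
      pos <- numeric(n)
      pos[1L] <- sample.int(as.integer(meanGap), 1L)
      if (n >= 2L) {
        pairRow0 <- 12L * (keyIdx[-n] - 1L) + (keyIdx[-1L] - 1L)
        peakCol <- pairRow0 %% Lref
        r <- ifelse(runif(n - 1L) < w, peakCol,
                    sample.int(Lref, n - 1L, replace = TRUE) - 1L)
        G <- rgeom(n - 1L, pGeom)
        gaps <- Lref * G + r + 1
        pos[-1L] <- pos[1L] + cumsum(gaps)
      }
      if (pos[n] > chromLengths[ch]) {
        stop("chromosome ", ch, " too short: walked to ", pos[n],
             " of ", chromLengths[ch], " bp")
      }
      parts[[ch]] <- data.frame(chrom = as.character(ch), pos = pos,
                                key = .SNV_KEYS[keyIdx],
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, parts)
    out$freq <- 0.01 + 0.98 * rbeta(nrow(out), 1, 3)
    out
  })
  rownames(loci) <- NULL
  new(Class = "CohortModel", loci = loci,
      params = list(nChroms = nChroms, totalLoci = totalLoci,
                    chromLengths = chromLengths,
                    spacingPeakWeight = spacingPeakWeight,
                    tstvRatio = tstvRatio, meanGap = meanGap, Lref = Lref),
      seed = as.integer(seed))
}

#' @rdname cohortModel
setClass("CohortModel",
  representation(loci = "data.frame", params = "list", seed = "integer"))

setValidity("CohortModel", function(object) {
  msg <- character()
  l <- object@loci
  if (!all(c("chrom", "pos", "key", "freq") %in% names(l)))
    msg <- c(msg, "loci must have columns chrom, pos, key, freq")
  else {
    byChrom <- split(l$pos, l$chrom)
    if (!all(vapply(byChrom, function(p) all(diff(p) > 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within chromosomes")
    if (any(l$freq <= 0 | l$freq >= 1))
      msg <- c(msg, "frequencies must be in (0, 1)")
    if (!all(l$key %in% .SNV_KEYS)) msg <- c(msg, "invalid SNV keys")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortModel", function(object) {
  cat("CohortModel:", nrow(object@loci), "loci on",
      object@params$nChroms, "chromosomes",
      "(seed", paste0(object@seed, ")"), "\n")
  cat("  mean gap:", object@params$meanGap,
      " spacing peak weight:", object@params$spacingPeakWeight,
      " Ts/Tv:", object@params$tstvRatio, "\n")
})

#' @rdname cohortModel
#' @param x a \code{CohortModel}.
#' @export
modelLoci <- function(x) {
  stopifnot(is(x, "CohortModel"))
  x@loci
}

# variant stream (chrom, pos, ref, alt) for the carried loci of one
# genotype vector
.streamFromGenotypes <- function(model, genotypes) {
  l <- model@loci[genotypes >= 1L, , drop = FALSE]
  out <- data.frame(chrom = l$chrom, pos = l$pos,
                    ref = substr(l$key, 1L, 1L),
                    alt = substr(l$key, 2L, 2L),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Simulate a cohort of genomes from a shared pool
#'
#' Individuals are assigned to populations in contiguous blocks.
#' Population allele frequencies are obtained from the pool frequencies
#' by a logit-normal perturbation with standard deviation
#' \code{divergence} (0 means the populations are exchangeable and labels
#' carry no information). Genotypes are drawn per individual under
#' Hardy-Weinberg equilibrium; the variant stream of an individual is the
#' set of loci where at least one alternate allele was observed,
#' regardless of zygosity. Deterministic given the model and seed.
#'
#' @param model a \code{\link{cohortModel}}.
#' @param nIndividuals number of genomes.
#' @param nPopulations number of populations (default 1).
#' @param divergence SD of the per-population logit shift (>= 0).
#' @param seed random seed.
#' @param ids optional individual identifiers.
#' @return list with elements \code{genomes} (named list of variant
#'   data.frames), \code{populations} (named character vector of labels)
#'   and \code{popFreqs} (loci x populations frequency matrix).
#' @export
simulateCohort <- function(model, nIndividuals, nPopulations = 1L,
                           divergence = 0, seed = 1L, ids = NULL) {
  stopifnot(is(model, "CohortModel"), nIndividuals >= 1L,
            nPopulations >= 1L, divergence >= 0)
  nLoci <- nrow(model@loci)
  if (is.null(ids)) {
    ids <- sprintf("I%03d", seq_len(nIndividuals))
  }
  stopifnot(length(ids) == nIndividuals, !anyDuplicated(ids))
  popOf <- rep(seq_len(nPopulations),
               each = ceiling(nIndividuals / nPopulations))[seq_len(nIndividuals)]
  popNames <- sprintf("P%d", seq_len(nPopulations))

  .withSeed(seed, {
    shift <- matrix(rnorm(nLoci * nPopulations, 0, divergence),
                    nLoci, nPopulations)
    popFreqs <- plogis(qlogis(model@loci$freq) + shift)
    colnames(popFreqs) <- popNames
    genomes <- vector("list", nIndividuals)
    for (i in seq_len(nIndividuals)) {
      f <- popFreqs[, popOf[i]]
      g <- rbinom(nLoci, 1L, f) + rbinom(nLoci, 1L, f)
      genomes[[i]] <- .streamFromGenotypes(model, g)
    }
    names(genomes) <- ids
    populations <- popNames[popOf]
    names(populations) <- ids
    list(genomes = genomes, populations = populations, popFreqs = popFreqs)
  })
}

#' Degrade a genome by random variant dropout
#'
#' Emulates missing data (false negatives): each variant is independently
#' dropped with the given probability. Order is preserved; deterministic
#' given the seed.
#'
#' @param variants variant data.frame (chrom, pos, ref, alt).
#' @param fraction dropout probability in [0, 1].
#' @param seed random seed.
#' @return the thinned variant data.frame.
#' @export
degradeMissing <- function(variants, fraction, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  variants <- .checkStream(variants)
  if (fraction == 0 || nrow(variants) == 0L) return(variants)
  keep <- .withSeed(seed, runif(nrow(variants)) >= fraction)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degrade a genome by spurious intervening variants
#'
#' Emulates sequencing noise (false positives): for each within-chromosome
#' consecutive variant pair with at least one intervening reference
#' position, a spurious SNV is inserted with the given probability at a
#' uniformly chosen intervening position (never colliding with an existing
#' variant), with a uniformly chosen SNV key. The output is re-sorted
#' within chromosomes; deterministic given the seed. Pairs at adjacent
#' positions never receive insertions.
#'
#' @param variants variant data.frame (chrom, pos, ref, alt).
#' @param probability insertion probability per eligible pair, in [0, 1].
#' @param seed random seed.
#' @return the augmented variant data.frame.
#' @export
degradeNoise <- function(variants, probability, seed = 1L) {
  stopifnot(probability >= 0, probability <= 1)
  variants <- .checkStream(variants)
  n <- nrow(variants)
  if (probability == 0 || n < 2L) return(variants)
  sameChrom <- variants$chrom[-1L] == variants$chrom[-n]
  room <- variants$pos[-1L] - variants$pos[-n] >= 2
  eligible <- which(sameChrom & room)
  .withSeed(seed, {
    ins <- eligible[runif(length(eligible)) < probability]
    if (length(ins) == 0L) {
      out <- variants
    } else {
      lo <- variants$pos[ins]
      hi <- variants$pos[ins + 1L]
      newPos <- lo + 1 + floor(runif(length(ins)) * (hi - lo - 1))
      keyIdx <- sample.int(12L, length(ins), replace = TRUE)
      spurious <- data.frame(chrom = variants$chrom[ins], pos = newPos,
                             ref = substr(.SNV_KEYS[keyIdx], 1L, 1L),
                             alt = substr(.SNV_KEYS[keyIdx], 2L, 2L),
                             stringsAsFactors = FALSE)
      out <- rbind(variants, spurious)
      # preserve the original chromosome block order, sort within blocks
      chromOrder <- match(out$chrom, unique(variants$chrom))
      out <- out[order(chromOrder, out$pos), , drop = FALSE]
      rownames(out) <- NULL
    }
    out
  })
}
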