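#' Simulate genomes for a pedigree
#'
#' Founders are drawn from one population of the cohort model as pairs of
#' haplotypes (each haplotype carries the alternate allele at a locus with
#' the pool frequency). Each child haplotype is produced by recombining
#' the corresponding parent's two haplotypes: the crossover count per
#' chromosome per meiosis is Poisson with mean \code{recombRate}
#' (a uniform genetic map, one expected crossover per chromosome by
#' default), breakpoints are uniform along the chromosome, and the
#' starting haplotype is chosen at random. A child's genotype is the sum
#' of the two transmitted alleles. Deterministic given model, pedigree and
#' seed.
#'
#' The pedigree is given as founder ids plus a mating table; children of
#' one mating are named \code{<a>.<b>.<i>}. Parents must be founders or
#' previously generated children (which keeps the pedigree acyclic) and
#' must be distinct.
#'
#' @param model a \code{\link{cohortModel}}.
#' @param founders character vector of founder ids.
#' @param matings data.frame with columns \code{parent_a},
#'   \code{parent_b}, \code{n_children}.
#' @param recombRate expected crossovers per chromosome per meiosis
#'   (default 1).
#' @param seed random seed.
#' @return list with \code{genomes} (named list of variant data.frames
#'   for every pedigree member), \code{genotypes} (named list of 0/1/2
#'   vectors over the pool loci) and \code{parents} (named list mapping
#'   each child to its two parents).
#' @seealso \code{\link{relationshipCategories}} to label all pairs.
#' @export
simulatePedigree <- function(model, founders, matings, recombRate = 1,
                             seed = 1L) {
  stopifnot(is(model, "CohortModel"), length(founders) >= 1L,
            recombRate >= 0)
  stopifnot(all(c("parent_a", "parent_b", "n_children") %in% names(matings)))
  if (anyDuplicated(founders)) stop("duplicate founder ids")
  loci <- model@loci
  nLoci <- nrow(loci)
  chromIdx <- split(seq_len(nLoci), loci$chrom)
  chromLengths <- model@params$chromLengths
  names(chromLengths) <- as.character(seq_along(chromLengths))

  meiosis <- function(haps) {
    out <- integer(nLoci)
    for (ch in names(chromIdx)) {
      idx <- chromIdx[[ch]]
      k <- rpois(1L, recombRate)
      start <- sample.int(2L, 1L)
      if (k == 0L) {
        out[idx] <- haps[idx, start]
      } else {
        breaks <- sort(runif(k, 0, chromLengths[[ch]]))
        seg <- findInterval(loci$pos[idx], breaks)
        hapChoice <- (seg + start) %% 2L + 1L
        out[idx] <- haps[cbind(idx, hapChoice)]
      }
    }
    out
  }

  .withSeed(seed, {
    haps <- list()
    for (f in founders) {
      haps[[f]] <- cbind(rbinom(nLoci, 1L, loci$freq),
                         rbinom(nLoci, 1L, loci$freq))
    }
    parents <- list()
    for (r in seq_len(nrow(matings))) {
      a <- as.character(matings$parent_a[r])
      b <- as.character(matings$parent_b[r])
      if (a == b) stop("a child needs two distinct parents (mating ", r, ")")
      if (!a %in% names(haps) || !b %in% names(haps)) {
        stop("mating ", r, " references unknown parent(s); parents must be ",
             "founders or children of earlier matings")
      }
      for (i in seq_len(matings$n_children[r])) {
        child <- paste(a, b, i, sep = ".")
        if (child %in% names(haps)) stop("duplicate child id ", child)
        haps[[child]] <- cbind(meiosis(haps[[a]]), meiosis(haps[[b]]))
        parents[[child]] <- c(a, b)
      }
    }
    genotypes <- lapply(haps, rowSums)
    genomes <- lapply(genotypes, function(g) .streamFromGenotypes(model, g))
    list(genomes = genomes, genotypes = genotypes, parents = parents)
  })
}

#' Label all pairwise relationships in a simulated pedigree
#'
#' Derives the relationship category of every unordered pair of pedigree
#' members from the parent map: \code{parent_child}, \code{sibling} (both
#' parents shared), \code{half_sibling} (exactly one parent shared),
#' \code{grandparent}, \code{avuncular} (sibling of a parent),
#' \code{cousin} (parents are siblings), \code{unrelated} (no common
#' ancestor), everything else \code{other}.
#'
#' @param members character vector of all member ids.
#' @param parents named list mapping child ids to their two parents (as
#'   returned by \code{\link{simulatePedigree}}); founders are absent.
#' @return \code{data.frame}: \code{id_a}, \code{id_b}, \code{relationship}.
#' @export
relationshipCategories <- function(members, parents) {
  par <- function(x) if (x %in% names(parents)) parents[[x]] else character()
  ancestors <- function(x) {
    out <- character(); frontier <- par(x)
    while (length(frontier)) {
      out <- union(out, frontier)
      frontier <- unique(unlist(lapply(frontier, par)))
    }
    out
  }
  anc <- lapply(members, ancestors)
  names(anc) <- members
  sibs <- function(a, b) {
    pa <- par(a); pb <- par(b)
    length(pa) == 2L && length(pb) == 2L && length(intersect(pa, pb)) == 2L
  }
  category <- function(a, b) {
    pa <- par(a); pb <- par(b)
    if (a %in% pb || b %in% pa) return("parent_child")
    shared <- length(intersect(pa, pb))
    if (shared == 2L) return("sibling")
    if (shared == 1L) return("half_sibling")
    if (a %in% unlist(lapply(pb, par)) || b %in% unlist(lapply(pa, par))) {
      return("grandparent")
    }
    if (any(vapply(pb, function(p) sibs(a, p), logical(1))) ||
        any(vapply(pa, function(p) sibs(b, p), logical(1)))) {
      return("avuncular")
    }
    if (length(pa) && length(pb) &&
        any(outer(pa, pb, Vectorize(sibs)))) {
      return("cousin")
    }
    related <- length(intersect(union(anc[[a]], a), union(anc[[b]], b))) > 0L
    if (!related) return("unrelated")
    "other"
  }
  pairs <- utils::combn(sort(members), 2L)
  data.frame(id_a = pairs[1L, ], id_b = pairs[2L, ],
             relationship = mapply(category, pairs[1L, ], pairs[2L, ],
                                   USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}
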