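#' Build a population fingerprint
#'
#' A population fingerprint is the element-wise mean of the normalized
#' fingerprints of the individuals in the population. All members must
#' have been computed with the same \code{L} and \code{C}. Member
#' identifiers are stored so that leave-one-out recomputation is exact
#' without re-reading member files:
#' \code{(n * mean - x) / (n - 1)}.
#'
#' @param fps nonempty list of \code{\linkS4class{NormalizedFingerprint}}
#'   objects (kind \code{"normalized"}).
#' @param id population identifier.
#' @return a \code{\linkS4class{PopulationFingerprint}}.
#' @export
buildPopulation <- function(fps, id = "population") {
  if (length(fps) == 0L) stop("cannot build a population from no members")
  ok <- vapply(fps, function(f)
    is(f, "NormalizedFingerprint") && fpKind(f) %in% c("normalized"),
    logical(1))
  if (!all(ok)) stop("population members must be normalized fingerprints")
  L <- fpLength(fps[[1L]]); C <- closeCutoff(fps[[1L]])
  for (f in fps[-1L]) {
    if (fpLength(f) != L || closeCutoff(f) != C) {
      stop("parameter mismatch: all members must share L and C")
    }
  }
  mem <- vapply(fps, fpId, character(1))
  if (anyDuplicated(mem)) stop("duplicate member identifiers")
  values <- Reduce(`+`, lapply(fps, fpValues)) / length(fps)
  new(Class = "PopulationFingerprint",
      id = as.character(id), L = L, C = C,
      nSnvs = sum(vapply(fps, nSnvs, numeric(1))),
      nPairsRaw = 0, nPairsClose = 0,
      source = paste0("mean of ", length(fps), " members"),
      kind = "population", values = values, members = mem)
}

#' Adjust an individual fingerprint to a population
#'
#' Subtracts a population fingerprint from an individual's normalized
#' fingerprint. Population adjustment removes the similarity shared by
#' all members of a population, so adjusted fingerprints of unrelated
#' individuals show no correlation while related pairs remain strongly
#' correlated -- the basis for relatedness screening within cohorts.
#'
#' @param ind a \code{\linkS4class{NormalizedFingerprint}}.
#' @param pop a \code{\linkS4class{PopulationFingerprint}} with the same
#'   \code{L} and \code{C}.
#' @param leaveOneOut if \code{TRUE} and \code{ind} is a member of
#'   \code{pop}, the population mean is recomputed without \code{ind}
#'   before subtracting (errors if the population has a single member).
#' @return a \code{\linkS4class{NormalizedFingerprint}} of kind
#'   \code{"adjusted"}; its \code{source} records the population id.
#' @export
adjustToPopulation <- function(ind, pop, leaveOneOut = FALSE) {
  stopifnot(is(ind, "NormalizedFingerprint"), is(pop, "PopulationFingerprint"))
  if (fpLength(ind) != fpLength(pop) || closeCutoff(ind) != closeCutoff(pop)) {
    stop("parameter mismatch: individual and population must share L and C")
  }
  popValues <- fpValues(pop)
  if (leaveOneOut && fpId(ind) %in% members(pop)) {
    n <- length(members(pop))
    if (n == 1L) {
      stop("cannot leave out the only member of population '", fpId(pop), "'")
    }
    popValues <- (n * popValues - fpValues(ind)) / (n - 1)
  }
  new(Class = "NormalizedFingerprint",
      id = ind@id, L = ind@L, C = ind@C,
      nSnvs = ind@nSnvs, nPairsRaw = ind@nPairsRaw,
      nPairsClose = ind@nPairsClose,
      source = paste0(ind@source, " adjusted to ", fpId(pop)),
      kind = "adjusted", values = fpValues(ind) - popValues)
}

#' Classify a genome to its closest population
#'
#' Ranks candidate population fingerprints by Spearman correlation with
#' the individual's normalized fingerprint; the genome is assigned to the
#' population with the strongest correlation. With \code{leaveOneOut},
#' an individual that contributed to a population's mean is excluded from
#' that mean before comparison, avoiding self-match bias in
#' cross-validation; a single-member population is skipped with a warning
#' in that case. Ties are broken by population identifier.
#'
#' @param ind a \code{\linkS4class{NormalizedFingerprint}}.
#' @param pops list of \code{\linkS4class{PopulationFingerprint}} objects.
#' @param leaveOneOut logical.
#' @return \code{data.frame} with columns \code{population} and
#'   \code{score}, best match first.
#' @export
classifyPopulation <- function(ind, pops, leaveOneOut = FALSE) {
  if (length(pops) == 0L) stop("no candidate populations")
  rows <- lapply(pops, function(p) {
    vals <- fpValues(p)
    if (leaveOneOut && fpId(ind) %in% members(p)) {
      n <- length(members(p))
      if (n == 1L) {
        warning("population '", fpId(p),
                "' has a single member (the query); skipped")
        return(NULL)
      }
      vals <- (n * vals - fpValues(ind)) / (n - 1)
    }
    score <- .spearmanScore(as.vector(t(fpValues(ind))), as.vector(t(vals)))
    data.frame(population = fpId(p), score = score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) stop("no comparable populations left")
  out <- out[order(-out$score, out$population), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag unexpectedly related pairs by a robust outlier test
#'
#' Within-population correlations of population-adjusted fingerprints are
#' centered at zero for unrelated pairs; related pairs stand out on the
#' upper tail. Scores are converted to robust z values using the median
#' and the median absolute deviation,
#' \code{z = 0.6745 * (score - median) / MAD} (0.6745 is the normal
#' consistency constant), one-sided p-values are taken from the standard
#' normal upper tail, and Benjamini-Hochberg control is applied at the
#' given false discovery rate.
#'
#' @param pairs \code{data.frame} with columns \code{id_a}, \code{id_b},
#'   \code{score} (e.g. from \code{\link{allPairs}} on adjusted
#'   fingerprints); at least 10 pairs.
#' @param fdr false discovery rate in (0, 0.5]; default 0.05.
#' @return the input with added columns \code{robust_z}, \code{p},
#'   \code{q}, \code{flagged}, sorted by score descending.
#' @export
findRelatedOutliers <- function(pairs, fdr = 0.05) {
  stopifnot(all(c("id_a", "id_b", "score") %in% names(pairs)))
  if (nrow(pairs) < 10L) stop("need at least 10 pairs for outlier detection")
  if (!(fdr > 0 && fdr <= 0.5)) stop("fdr must be in (0, 0.5]")
  med <- median(pairs$score)
  madRaw <- median(abs(pairs$score - med))
  if (madRaw == 0) {
    stop("degenerate score distribution (MAD = 0); inspect the input scores")
  }
  z <- 0.6745 * (pairs$score - med) / madRaw
  p <- pnorm(z, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- pairs
  out$robust_z <- z
  out$p <- p
  out$q <- q
  out$flagged <- q <= fdr
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
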