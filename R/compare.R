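# row-major serialization of the comparable matrix, in canonical row order
.serializeFp <- function(fp) {
  if (is(fp, "NormalizedFingerprint")) return(as.vector(t(fp@values)))
  stop("cannot serialize fingerprints of kind '", fpKind(fp),
       "' for correlation; normalize first")
}

# Spearman correlation with the degenerate case pinned: a zero-variance
# vector (e.g. the all-zero fingerprint of an empty genome) yields 0 with
# a warning instead of NaN, so cohort-scale score tables stay total.
.spearmanScore <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero-variance fingerprint vector; correlation set to 0")
    return(0)
  }
  stats::cor(x, y, method = "spearman")
}

#' Compare two fingerprints
#'
#' Normalized (or population/population-adjusted) fingerprints are
#' serialized row-major into vectors of length \code{144 * L} and compared
#' by Spearman correlation (average ranks for ties). Comparing a
#' normalized fingerprint with a population-adjusted one -- or two
#' fingerprints adjusted to different populations -- is permitted; both
#' operands must share \code{L}. Binary fingerprints are compared by the
#' squared fraction of matching bits, \code{(matches / 144)^2}, in
#' \code{[0, 1]}.
#'
#' As documented defaults calibrated on real genome versions, Spearman
#' scores above 0.75 indicate two representations of the same genome;
#' lower values grade from close relatives down to unrelated individuals.
#'
#' @param a,b fingerprints of comparable kinds (both normalized-family or
#'   both binary).
#' @return one-row \code{data.frame}: \code{id_a}, \code{id_b},
#'   \code{score}, \code{n_features}.
#' @export
compareFingerprints <- function(a, b) {
  if (is(a, "BinaryFingerprint") || is(b, "BinaryFingerprint")) {
    if (!(is(a, "BinaryFingerprint") && is(b, "BinaryFingerprint"))) {
      stop("binary fingerprints can only be compared with binary fingerprints")
    }
    matches <- sum(a@bits == b@bits)
    return(data.frame(id_a = a@id, id_b = b@id,
                      score = (matches / 144)^2, n_features = 144L,
                      stringsAsFactors = FALSE))
  }
  if (is(a, "RawFingerprint") || is(b, "RawFingerprint")) {
    stop("raw fingerprints must be normalized before comparison")
  }
  if (fpLength(a) != fpLength(b)) {
    stop("parameter mismatch: cannot compare fingerprints with L = ",
         fpLength(a), " and L = ", fpLength(b))
  }
  x <- .serializeFp(a); y <- .serializeFp(b)
  data.frame(id_a = a@id, id_b = b@id,
             score = .spearmanScore(x, y), n_features = length(x),
             stringsAsFactors = FALSE)
}

#' All-against-all fingerprint comparison
#'
#' Computes the score of every unordered pair in a collection,
#' \code{n * (n - 1) / 2} rows in deterministic order (pairs sorted by
#' identifier). For normalized-family fingerprints each serialized vector
#' is rank-transformed once and all Pearson correlations of the rank
#' matrix are obtained in a single matrix product, so cohort-scale
#' comparisons (thousands of genomes, millions of pairs) take seconds.
#'
#' @param fps list of fingerprints, all of the same \code{L} and
#'   comparable kinds; identifiers must be unique.
#' @return \code{data.frame} with columns \code{id_a}, \code{id_b},
#'   \code{score}, \code{n_features}.
#' @seealso \code{\link{exportMatrix}} for a genomes x features table.
#' @export
allPairs <- function(fps) {
  n <- length(fps)
  ids <- vapply(fps, fpId, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate fingerprint identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (n < 2L) {
    return(data.frame(id_a = character(), id_b = character(),
                      score = numeric(), n_features = integer(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(ids)
  fps <- fps[ord]; ids <- ids[ord]

  binary <- vapply(fps, is, logical(1), "BinaryFingerprint")
  if (any(binary) && !all(binary)) {
    stop("cannot mix binary and matrix fingerprints in one comparison set")
  }
  if (all(binary)) {
    B <- vapply(fps, fpBits, integer(144L))   # 144 x n
    S <- 2L * B - 1L
    matches <- (144 + crossprod(S)) / 2
    scores <- (matches / 144)^2
    nf <- 144L
  } else {
    Ls <- vapply(fps, fpLength, integer(1))
    if (length(unique(Ls)) != 1L) {
      stop("parameter mismatch: fingerprints have different L: ",
           paste(unique(Ls), collapse = ", "))
    }
    V <- vapply(fps, .serializeFp, numeric(144L * Ls[1L]))
    R <- apply(V, 2L, rank)
    degenerate <- apply(V, 2L, sd) == 0
    if (any(degenerate)) {
      warning("zero-variance fingerprint vector(s): ",
              paste(ids[degenerate], collapse = ", "),
              "; their correlations set to 0")
    }
    scores <- suppressWarnings(stats::cor(R))
    scores[degenerate, ] <- 0
    scores[, degenerate] <- 0
    nf <- nrow(V)
  }
  ut <- upper.tri(scores)
  i <- row(scores)[ut]; j <- col(scores)[ut]
  out <- data.frame(id_a = ids[i], id_b = ids[j],
                    score = scores[ut], n_features = nf,
                    stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Rank candidate fingerprints by similarity to a query
#'
#' Scores the query against every candidate and returns the top \code{k}
#' by descending score; ties are broken by candidate identifier. A genome
#' present among the candidates (or a duplicate of it) ranks first --
#' correlation is maximal for identical inputs -- making this the
#' duplicate-detection workhorse.
#'
#' @param query a fingerprint.
#' @param candidates list of fingerprints comparable with \code{query}.
#' @param k number of matches to return (>= 1); values larger than the
#'   candidate count return the full ranking.
#' @return \code{data.frame}: \code{id}, \code{score}, sorted best-first.
#' @export
bestMatches <- function(query, candidates, k = 5L) {
  if (k < 1L) stop("k must be >= 1")
  ids <- vapply(candidates, fpId, character(1))
  scores <- vapply(candidates,
                   function(f) compareFingerprints(query, f)$score,
                   numeric(1))
  ord <- order(-scores, ids)
  head(data.frame(id = ids[ord], score = scores[ord],
                  stringsAsFactors = FALSE, row.names = NULL), k)
}

#' Export fingerprints as a genomes x features matrix
#'
#' Serializes each fingerprint row-major into one row of a
#' \code{n x (144 * L)} table (columns named \code{PAIRKEY.d}), suitable
#' for downstream embedding tools (PCA, t-SNE). Written as TSV when a
#' path is given.
#'
#' @param fps list of normalized-family fingerprints with identical
#'   \code{L}.
#' @param path optional TSV output path.
#' @return the matrix, invisibly when \code{path} is given.
#' @export
exportMatrix <- function(fps, path = NULL) {
  ids <- vapply(fps, fpId, character(1))
  if (anyDuplicated(ids)) stop("duplicate fingerprint identifiers")
  Ls <- vapply(fps, fpLength, integer(1))
  if (length(unique(Ls)) != 1L) stop("fingerprints have different L")
  M <- t(vapply(fps, .serializeFp, numeric(144L * Ls[1L])))
  rownames(M) <- ids
  colnames(M) <- paste0(rep(.PAIR_KEYS, each = Ls[1L]), ".",
                        rep(seq_len(Ls[1L]) - 1L, times = 144L))
  if (!is.null(path)) {
    write.table(M, path, sep = "\t", quote = FALSE, col.names = NA)
    return(invisible(M))
  }
  M
}
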