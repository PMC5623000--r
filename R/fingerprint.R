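#' Compute a raw genome fingerprint
#'
#' Tallies every pair of consecutive biallelic SNVs on the same chromosome
#' into a 144 x \code{L} count matrix. The row is the SNV pair key (the
#' concatenated ref/alt keys of both SNVs in canonical order, see
#' \code{\link{pairKeys}}); the column is the distance between the SNVs
#' folded modulo \code{L}. Distance is counted as the number of intervening
#' reference bases, \code{d = pos2 - pos1 - 1}, a convention recorded in
#' the fingerprint file format so fingerprints remain comparable. Pairs
#' closer than \code{C} intervening bases are tallied in a separate
#' 144 x \code{C} "close" matrix (column \code{j} holds \code{d = j - 1});
#' short-range spacing mostly reflects how each sequencing pipeline encodes
#' multi-nucleotide variants, so the close matrix is excluded from the
#' comparable fingerprint. Pairs never span chromosomes. Records at a
#' duplicated position are dropped beyond the first (a zero-length
#' self-pair is meaningless).
#'
#' An empty stream yields a valid all-zero fingerprint. Per-chromosome
#' partial fingerprints can be combined with
#' \code{\link{mergeFingerprints}}; the result is identical to
#' fingerprinting the concatenated stream.
#'
#' @param variants data.frame of SNVs (chrom, pos, ref, alt), grouped by
#'   chromosome and position-sorted, as returned by \code{\link{readSNVs}}.
#' @param L fingerprint length (number of distance columns), integer >= 2;
#'   default 20. Larger \code{L} (e.g. 120) retains more information for
#'   population-scale analyses.
#' @param C close cutoff, integer >= 0; default 20. \code{C = 0} disables
#'   the close matrix.
#' @param id identifier stored in the fingerprint.
#' @param source free-text provenance (defaults to \code{id}).
#' @return a \code{\linkS4class{RawFingerprint}}.
#' @examples
#' v <- data.frame(chrom = "1", pos = c(100, 150, 152),
#'                 ref = c("G", "T", "A"), alt = c("A", "C", "C"))
#' fp <- computeRawFingerprint(v, L = 20, C = 20, id = "toy")
#' rawMatrix(fp)["GATC", 10]   # distance 49 -> column 49 %% 20 = 9 (0-based)
#' closeMatrix(fp)["TCAC", 2]  # distance 1 < C
#' @export
computeRawFingerprint <- function(variants, L = 20L, C = 20L,
                                  id = "genome", source = id) {
  L <- as.integer(L); C <- as.integer(C)
  if (length(L) != 1L || is.na(L) || L < 2L) stop("L must be an integer >= 2")
  if (length(C) != 1L || is.na(C) || C < 0L) stop("C must be an integer >= 0")
  variants <- .checkStream(variants)
  variants <- .finishSnvs(variants, nrow(variants))

  raw <- matrix(0L, 144L, L, dimnames = list(.PAIR_KEYS, NULL))
  close <- matrix(0L, 144L, C, dimnames = list(.PAIR_KEYS, NULL))
  n <- nrow(variants)
  if (n >= 2L) {
    ref <- toupper(variants$ref); alt <- toupper(variants$alt)
    bad <- !.isSnvAllele(ref) | !.isSnvAllele(alt) | ref == alt
    if (any(bad)) {
      stop("non-SNV record(s) in stream at row(s) ",
           paste(head(which(bad), 3L), collapse = ", "))
    }
    keyIdx <- .snvKeyIndex(ref, alt)
    sameChrom <- variants$chrom[-1L] == variants$chrom[-n]
    d <- variants$pos[-1L] - variants$pos[-n] - 1
    row1 <- 12L * (keyIdx[-n] - 1L) + keyIdx[-1L]  # 1-based pair row
    d <- d[sameChrom]; row1 <- row1[sameChrom]

    isClose <- d < C
    if (any(!isClose)) {
      cols <- d[!isClose] %% L  # 0-based
      cnt <- tabulate(row1[!isClose] + 144 * cols, nbins = 144L * L)
      raw <- matrix(as.integer(cnt), 144L, L,
                    dimnames = list(.PAIR_KEYS, NULL))
    }
    if (any(isClose) && C > 0L) {
      cnt <- tabulate(row1[isClose] + 144 * d[isClose], nbins = 144L * C)
      close <- matrix(as.integer(cnt), 144L, C,
                      dimnames = list(.PAIR_KEYS, NULL))
    }
  }
  new(Class = "RawFingerprint",
      id = as.character(id), L = L, C = C,
      nSnvs = as.numeric(n), nPairsRaw = sum(raw), nPairsClose = sum(close),
      source = as.character(source), kind = "raw",
      raw = raw, close = close)
}

#' Merge per-chromosome (or per-file) partial raw fingerprints
#'
#' Raw fingerprints are additive: fingerprints computed on disjoint parts
#' of a genome (e.g. per-chromosome VCFs) combine by simple element-wise
#' summation into the whole-genome raw fingerprint. All parts must share
#' the same \code{L} and \code{C}.
#'
#' @param fps a list of \code{\linkS4class{RawFingerprint}} objects (or
#'   several passed via \code{...}).
#' @param ... alternative way to pass the fingerprints.
#' @param id identifier for the merged fingerprint (default: id of the
#'   first part).
#' @return a \code{\linkS4class{RawFingerprint}}.
#' @export
mergeFingerprints <- function(fps = NULL, ..., id = NULL) {
  if (is.null(fps)) fps <- list(...)
  if (is(fps, "GenomeFingerprint")) fps <- c(list(fps), list(...))
  if (length(fps) == 0L) stop("no fingerprints to merge")
  ok <- vapply(fps, is, logical(1), "RawFingerprint")
  if (!all(ok)) {
    stop("can only merge raw fingerprints; got kind(s): ",
         paste(unique(vapply(fps[!ok], fpKind, character(1))), collapse = ", "))
  }
  L <- fpLength(fps[[1L]]); C <- closeCutoff(fps[[1L]])
  for (f in fps[-1L]) {
    if (fpLength(f) != L || closeCutoff(f) != C) {
      stop("parameter mismatch: all parts must share L and C (found L=",
           fpLength(f), ", C=", closeCutoff(f), " vs L=", L, ", C=", C, ")")
    }
  }
  raw <- Reduce(`+`, lapply(fps, rawMatrix))
  close <- Reduce(`+`, lapply(fps, closeMatrix))
  new(Class = "RawFingerprint",
      id = as.character(if (is.null(id)) fpId(fps[[1L]]) else id),
      L = L, C = C,
      nSnvs = sum(vapply(fps, nSnvs, numeric(1))),
      nPairsRaw = sum(raw), nPairsClose = sum(close),
      source = paste0("merge(", paste(vapply(fps, fpId, character(1)),
                                      collapse = ","), ")"),
      kind = "raw", raw = raw, close = close)
}

# population-form z-scoring (divide by n, not n-1). A column/row with zero
# spread is centered and set to all zeros rather than dividing by zero,
# which keeps empty or tiny genomes well-defined.
.zscoreCols <- function(m) {
  mu <- colMeans(m)
  sdev <- sqrt(pmax(colMeans(m * m) - mu * mu, 0))
  x <- sweep(m, 2L, mu, `-`)
  sdev[sdev < 1e-12] <- Inf
  sweep(x, 2L, sdev, `/`)
}

#' Normalize a raw fingerprint
#'
#' Two-stage z-scoring of the raw count matrix: first by distance (each of
#' the \code{L} columns is centered and scaled over its 144 rows), then by
#' SNV pair key (each of the 144 rows of the intermediate matrix is
#' centered and scaled over its \code{L} columns). This order matters:
#' normalizing by key first fails to remove the internal structure of raw
#' fingerprints (transition/transversion frequency differences and
#' distance effects). Standard deviations use the population form (divide
#' by n); degenerate rows/columns (zero spread) become all zeros. The
#' close matrix is not normalized and is not carried into the result.
#'
#' @param object a \code{\linkS4class{RawFingerprint}}.
#' @param ... ignored.
#' @return a \code{\linkS4class{NormalizedFingerprint}} (kind
#'   \code{"normalized"}); every nondegenerate row has mean 0 and
#'   population SD 1.
#' @seealso \code{\link{computeRawFingerprint}},
#'   \code{\link{compareFingerprints}}
#' @aliases normalize
#' @export
setMethod("normalize", "RawFingerprint", function(object, ...) {
  step1 <- .zscoreCols(object@raw)
  values <- t(.zscoreCols(t(step1)))
  dimnames(values) <- list(.PAIR_KEYS, NULL)
  new(Class = "NormalizedFingerprint",
      id = object@id, L = object@L, C = object@C,
      nSnvs = object@nSnvs, nPairsRaw = object@nPairsRaw,
      nPairsClose = object@nPairsClose,
      source = object@source, kind = "normalized", values = values)
})

#' Binary (144-bit) genome fingerprint
#'
#' The minimal fingerprint: compute a raw fingerprint with \code{L = 2}
#' (distance parity), then emit one bit per SNV pair key -- 1 if
#' odd-parity distances (second column) outnumber even-parity distances
#' (first column), 0 otherwise (ties, including empty rows, give 0). No
#' normalization is applied. \code{binarize} derives the bits from an
#' existing \code{L = 2} raw fingerprint.
#'
#' @param variants SNV stream as for \code{\link{computeRawFingerprint}}.
#' @param C close cutoff (default 20), as for the raw fingerprint.
#' @param id identifier.
#' @param rf an \code{L = 2} \code{\linkS4class{RawFingerprint}}.
#' @return a \code{\linkS4class{BinaryFingerprint}}.
#' @export
binaryFingerprint <- function(variants, C = 20L, id = "genome") {
  binarize(computeRawFingerprint(variants, L = 2L, C = C, id = id))
}

#' @rdname binaryFingerprint
#' @export
binarize <- function(rf) {
  if (!is(rf, "RawFingerprint")) stop("binarize needs a raw fingerprint")
  if (fpLength(rf) != 2L) {
    stop("binary fingerprints derive from an L = 2 raw fingerprint; got L = ",
         fpLength(rf))
  }
  bits <- as.integer(rf@raw[, 2L] > rf@raw[, 1L])
  new(Class = "BinaryFingerprint",
      id = rf@id, L = 2L, C = rf@C,
      nSnvs = rf@nSnvs, nPairsRaw = rf@nPairsRaw,
      nPairsClose = rf@nPairsClose,
      source = rf@source, kind = "binary", bits = bits)
}
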