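#' Default degradation level grid
#'
#' The standard grid of degradation levels for robustness simulations:
#' 1, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50, 60, 70, 80, 90, 95 and 99
#' percent.
#'
#' @return numeric vector of fractions.
#' @export
robustnessLevels <- function() {
  c(0.01, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30, 0.35, 0.40, 0.45, 0.50,
    0.60, 0.70, 0.80, 0.90, 0.95, 0.99)
}

#' Robustness of a fingerprint to missing data or added noise
#'
#' For each degradation level, degrades the variant stream (random
#' dropout or spurious intervening variants), recomputes the normalized
#' \code{L}-column fingerprint and reports its Spearman correlation with
#' the fingerprint of the undegraded stream. At level 0 the correlation
#' is exactly 1. Optionally also tracks the binary (144-bit) fingerprint
#' similarity, which degrades faster than matrix fingerprints.
#'
#' \code{robustnessSummary} averages the curve over several degradation
#' seeds; use it to read off the largest level at which the mean
#' correlation stays at or above a working threshold (0.75 is the
#' documented default for calling two representations the same genome).
#'
#' @param variants the undegraded variant stream.
#' @param mode \code{"missing"} (dropout) or \code{"noise"} (spurious
#'   variants).
#' @param levels degradation fractions in [0, 1]; default
#'   \code{\link{robustnessLevels}}.
#' @param L,C fingerprint parameters (defaults 20, 20).
#' @param seed degradation seed; level \code{i} uses \code{seed + i}.
#' @param binary also compute binary-fingerprint similarity.
#' @return \code{robustnessCurve}: data.frame \code{level},
#'   \code{correlation} (and \code{binary} if requested).
#' @export
robustnessCurve <- function(variants, mode = c("missing", "noise"),
                            levels = robustnessLevels(), L = 20L, C = 20L,
                            seed = 1L, binary = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(levels >= 0 & levels <= 1))
  variants <- .checkStream(variants)
  ref <- normalize(computeRawFingerprint(variants, L = L, C = C, id = "ref"))
  refBin <- if (binary) binaryFingerprint(variants, C = C, id = "ref")
  degrade <- if (mode == "missing") degradeMissing else degradeNoise
  corr <- numeric(length(levels))
  binScore <- numeric(length(levels))
  for (i in seq_along(levels)) {
    deg <- degrade(variants, levels[i], seed = seed + i)
    fp <- normalize(computeRawFingerprint(deg, L = L, C = C, id = "deg"))
    corr[i] <- compareFingerprints(ref, fp)$score
    if (binary) {
      binScore[i] <- compareFingerprints(
        refBin, binaryFingerprint(deg, C = C, id = "deg"))$score
    }
  }
  out <- data.frame(level = levels, correlation = corr)
  if (binary) out$binary <- binScore
  out
}

#' @rdname robustnessCurve
#' @param seeds vector of degradation seeds to average over.
#' @return \code{robustnessSummary}: data.frame \code{level},
#'   \code{meanCorrelation} (and \code{meanBinary} if requested).
#' @export
robustnessSummary <- function(variants, mode = c("missing", "noise"),
                              levels = robustnessLevels(), seeds = 1:3,
                              L = 20L, C = 20L, binary = FALSE) {
  mode <- match.arg(mode)
  curves <- lapply(seeds, function(s)
    robustnessCurve(variants, mode, levels, L = L, C = C, seed = s,
                    binary = binary))
  out <- data.frame(
    level = levels,
    meanCorrelation = rowMeans(vapply(curves, `[[`, numeric(length(levels)),
                                      "correlation")))
  if (binary) {
    out$meanBinary <- rowMeans(vapply(curves, `[[`, numeric(length(levels)),
                                      "binary"))
  }
  out
}
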