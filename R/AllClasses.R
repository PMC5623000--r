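#' Fingerprint classes
#'
#' S4 containers for genome fingerprints. \code{GenomeFingerprint} is the
#' virtual parent carrying shared metadata: the fingerprint length \code{L}
#' (columns of the comparable matrix, default 20), the close cutoff
#' \code{C} (pairs separated by fewer than \code{C} intervening bases are
#' tallied in a separate 144 x \code{C} "close" matrix that carries
#' technology artifacts and is excluded from comparison), the number of
#' SNVs consumed and pairs tallied, a free-text \code{source} and the
#' \code{kind} tag.
#'
#' \describe{
#'   \item{\code{RawFingerprint}}{integer count matrices \code{raw}
#'     (144 x L) and \code{close} (144 x C); \code{kind = "raw"}.}
#'   \item{\code{NormalizedFingerprint}}{real 144 x L matrix after the
#'     two-stage z-scoring; \code{kind} is \code{"normalized"} or
#'     \code{"adjusted"} (population-adjusted).}
#'   \item{\code{PopulationFingerprint}}{a \code{NormalizedFingerprint}
#'     that is the element-wise mean over its \code{members};
#'     \code{kind = "population"}.}
#'   \item{\code{BinaryFingerprint}}{ordered vector of 144 bits derived
#'     from an L = 2 raw fingerprint; \code{kind = "binary"}.}
#' }
#'
#' @slot id character identifier of the genome (or population).
#' @slot L,C integer fingerprint length and close cutoff.
#' @slot nSnvs,nPairsRaw,nPairsClose numeric tallies of the input stream.
#' @slot source free-text provenance.
#' @slot kind one of raw, normalized, population, adjusted, binary.
#' @slot raw,close integer count matrices (RawFingerprint).
#' @slot values real matrix (NormalizedFingerprint).
#' @slot members character vector of member ids (PopulationFingerprint).
#' @slot bits integer 0/1 vector of length 144 (BinaryFingerprint).
#'
#' @name GenomeFingerprint-class
#' @aliases RawFingerprint-class NormalizedFingerprint-class
#'   PopulationFingerprint-class BinaryFingerprint-class
NULL

#' @rdname GenomeFingerprint-class
#' @exportClass GenomeFingerprint
setClass("GenomeFingerprint",
  representation("VIRTUAL",
    id = "character", L = "integer", C = "integer",
    nSnvs = "numeric", nPairsRaw = "numeric", nPairsClose = "numeric",
    source = "character", kind = "character"))

setValidity("GenomeFingerprint", function(object) {
  msg <- character()
  if (length(object@L) != 1L || object@L < 2L)
    msg <- c(msg, "L must be a single integer >= 2")
  if (length(object@C) != 1L || object@C < 0L)
    msg <- c(msg, "C must be a single integer >= 0")
  if (length(object@id) != 1L) msg <- c(msg, "id must be length 1")
  if (length(msg)) msg else TRUE
})

#' @rdname GenomeFingerprint-class
#' @exportClass RawFingerprint
setClass("RawFingerprint",
  contains = "GenomeFingerprint",
  representation(raw = "matrix", close = "matrix"))

setValidity("RawFingerprint", function(object) {
  msg <- character()
  if (!identical(dim(object@raw), c(144L, object@L)))
    msg <- c(msg, "raw matrix must be 144 x L")
  if (!identical(dim(object@close), c(144L, object@C)))
    msg <- c(msg, "close matrix must be 144 x C")
  if (any(object@raw < 0) || any(object@close < 0))
    msg <- c(msg, "count matrices must be nonnegative")
  if (!identical(rownames(object@raw), .PAIR_KEYS))
    msg <- c(msg, "raw matrix rows must be the 144 canonical pair keys")
  if (sum(object@raw) != object@nPairsRaw)
    msg <- c(msg, "raw matrix sum does not match nPairsRaw")
  if (sum(object@close) != object@nPairsClose)
    msg <- c(msg, "close matrix sum does not match nPairsClose")
  if (object@kind != "raw") msg <- c(msg, "kind must be 'raw'")
  if (length(msg)) msg else TRUE
})

#' @rdname GenomeFingerprint-class
#' @exportClass NormalizedFingerprint
setClass("NormalizedFingerprint",
  contains = "GenomeFingerprint",
  representation(values = "matrix"))

setValidity("NormalizedFingerprint", function(object) {
  msg <- character()
  if (!identical(dim(object@values), c(144L, object@L)))
    msg <- c(msg, "values matrix must be 144 x L")
  if (!identical(rownames(object@values), .PAIR_KEYS))
    msg <- c(msg, "values matrix rows must be the 144 canonical pair keys")
  if (!object@kind %in% c("normalized", "population", "adjusted"))
    msg <- c(msg, "kind must be normalized, population or adjusted")
  if (length(msg)) msg else TRUE
})

#' @rdname GenomeFingerprint-class
#' @exportClass PopulationFingerprint
setClass("PopulationFingerprint",
  contains = "NormalizedFingerprint",
  representation(members = "character"))

setValidity("PopulationFingerprint", function(object) {
  msg <- character()
  if (object@kind != "population") msg <- c(msg, "kind must be 'population'")
  if (length(object@members) < 1L)
    msg <- c(msg, "population must have at least one member")
  if (length(msg)) msg else TRUE
})

#' @rdname GenomeFingerprint-class
#' @exportClass BinaryFingerprint
setClass("BinaryFingerprint",
  contains = "GenomeFingerprint",
  representation(bits = "integer"))

setValidity("BinaryFingerprint", function(object) {
  msg <- character()
  if (length(object@bits) != 144L) msg <- c(msg, "bits must have length 144")
  if (!all(object@bits %in% c(0L, 1L))) msg <- c(msg, "bits must be 0 or 1")
  if (object@kind != "binary") msg <- c(msg, "kind must be 'binary'")
  if (length(msg)) msg else TRUE
})
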