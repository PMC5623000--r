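#' Fingerprint accessors
#'
#' Accessor generics for \code{\linkS4class{GenomeFingerprint}} objects:
#' identifier, fingerprint length \code{L}, close cutoff \code{C}, tallies,
#' kind tag, count/value matrices, member list and bit vector.
#'
#' @param x a fingerprint object.
#' @return \code{fpId}, \code{fpKind}: character; \code{fpLength},
#'   \code{closeCutoff}: integer; \code{nSnvs}: numeric;
#'   \code{rawMatrix}, \code{closeMatrix}, \code{fpValues}: matrix;
#'   \code{members}: character vector; \code{fpBits}: integer vector of
#'   length 144.
#' @name fingerprint-accessors
NULL

#' @rdname fingerprint-accessors
#' @export
setGeneric("fpId", function(x) standardGeneric("fpId"))
#' @rdname fingerprint-accessors
#' @export
setGeneric("fpKind", function(x) standardGeneric("fpKind"))
#' @rdname fingerprint-accessors
#' @export
setGeneric("fpLength", function(x) standardGeneric("fpLength"))
#' @rdname fingerprint-accessors
#' @export
setGeneric("closeCutoff", function(x) standardGeneric("closeCutoff"))
#' @rdname fingerprint-accessors
#' @export
setGeneric("nSnvs", function(x) standardGeneric("nSnvs"))
#' @rdname fingerprint-accessors
#' @export
setGeneric("rawMatrix", function(x) standardGeneric("rawMatrix"))
#' @rdname fingerprint-accessors
#' @export
setGeneric("closeMatrix", function(x) standardGeneric("closeMatrix"))
#' @rdname fingerprint-accessors
#' @export
setGeneric("fpValues", function(x) standardGeneric("fpValues"))
#' @rdname fingerprint-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname fingerprint-accessors
#' @export
setGeneric("fpBits", function(x) standardGeneric("fpBits"))

#' @rdname fingerprint-accessors
#' @export
setMethod("fpId", "GenomeFingerprint", function(x) x@id)
#' @rdname fingerprint-accessors
#' @export
setMethod("fpKind", "GenomeFingerprint", function(x) x@kind)
#' @rdname fingerprint-accessors
#' @export
setMethod("fpLength", "GenomeFingerprint", function(x) x@L)
#' @rdname fingerprint-accessors
#' @export
setMethod("closeCutoff", "GenomeFingerprint", function(x) x@C)
#' @rdname fingerprint-accessors
#' @export
setMethod("nSnvs", "GenomeFingerprint", function(x) x@nSnvs)
#' @rdname fingerprint-accessors
#' @export
setMethod("rawMatrix", "RawFingerprint", function(x) x@raw)
#' @rdname fingerprint-accessors
#' @export
setMethod("closeMatrix", "RawFingerprint", function(x) x@close)
#' @rdname fingerprint-accessors
#' @export
setMethod("fpValues", "NormalizedFingerprint", function(x) x@values)
#' @rdname fingerprint-accessors
#' @export
setMethod("members", "PopulationFingerprint", function(x) x@members)
#' @rdname fingerprint-accessors
#' @export
setMethod("fpBits", "BinaryFingerprint", function(x) x@bits)

setMethod("show", "RawFingerprint", function(object) {
  cat("RawFingerprint '", object@id, "'\n", sep = "")
  cat("  L:", object@L, " C:", object@C, "\n")
  cat("  SNVs:", object@nSnvs,
      " pairs:", object@nPairsRaw, "raw /", object@nPairsClose, "close\n")
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "NormalizedFingerprint", function(object) {
  cat(if (object@kind == "adjusted") "Population-adjusted" else "Normalized",
      " fingerprint '", object@id, "' (L = ", object@L, ")\n", sep = "")
  if (nzchar(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "PopulationFingerprint", function(object) {
  cat("PopulationFingerprint '", object@id, "' (L = ", object@L,
      ", ", length(object@members), " members)\n", sep = "")
})

setMethod("show", "BinaryFingerprint", function(object) {
  cat("BinaryFingerprint '", object@id, "': ",
      paste(object@bits, collapse = ""), "\n", sep = "")
})
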