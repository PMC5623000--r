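.BASES <- c("A", "C", "G", "T")

# 12 SNV keys in canonical (lexicographic) order: AC AG AT CA CG CT GA GC
# GT TA TC TG. Row order of all fingerprint matrices derives from this.
.SNV_KEYS <- local({
  k <- outer(.BASES, .BASES, paste0)
  sort(k[row(k) != col(k)])
})

# 144 SNV pair keys, row-major over (first key, second key), lexicographic.
.PAIR_KEYS <- as.vector(t(outer(.SNV_KEYS, .SNV_KEYS, paste0)))

#' Canonical SNV and SNV-pair keys
#'
#' An SNV key is the two-character concatenation of the reference and
#' alternate allele of a biallelic SNV (12 possible values). An SNV pair
#' key concatenates the keys of two consecutive SNVs on a chromosome
#' (144 possible values). The canonical order is lexicographic and fixes
#' the row order of all fingerprint matrices and their serialization,
#' so fingerprints are comparable across implementations.
#'
#' @return \code{snvKeys()}: character vector of the 12 SNV keys;
#'   \code{pairKeys()}: character vector of the 144 pair keys.
#' @examples
#' snvKeys()
#' head(pairKeys())
#' @export
snvKeys <- function() .SNV_KEYS

#' @rdname snvKeys
#' @export
pairKeys <- function() .PAIR_KEYS

#' Build the SNV key for a reference/alternate allele pair
#'
#' @param ref,alt single bases in \code{A,C,G,T} (case-insensitive);
#'   vectorized, \code{ref != alt} elementwise.
#' @return character vector of two-letter SNV keys, e.g. \code{"GA"} for
#'   reference G, alternate A.
#' @examples
#' snvKey("G", "A")
#' snvKey("g", "a")
#' @export
snvKey <- function(ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  bad <- !(ref %in% .BASES) | !(alt %in% .BASES) | ref == alt
  if (any(bad)) {
    stop("invalid SNV allele pair(s): ",
         paste(unique(paste0(ref[bad], ">", alt[bad])), collapse = ", "),
         " (need distinct single bases in A,C,G,T)")
  }
  paste0(ref, alt)
}

# 1-based index of an SNV key among the 12 canonical keys, from alleles.
.snvKeyIndex <- function(ref, alt) {
  ri <- match(ref, .BASES)
  ai <- match(alt, .BASES)
  (ri - 1L) * 3L + ai - (ai > ri)
}

#' Combine two SNV keys into an SNV pair key
#'
#' The pair key of two consecutive SNVs selects the fingerprint row; its
#' 0-based row index is \code{12 * index(first) + index(second)} in the
#' canonical key order.
#'
#' @param first,second valid SNV keys (see \code{\link{snvKey}}); vectorized.
#' @return \code{pairKey()}: four-character pair keys;
#'   \code{pairRowIndex()}: integer 0-based row indices in \code{0..143}.
#' @examples
#' pairKey("GA", "TC")
#' pairRowIndex("AC", "AC")  # 0
#' pairRowIndex("TG", "TG")  # 143
#' @export
pairKey <- function(first, second) {
  .checkSnvKeys(first)
  .checkSnvKeys(second)
  paste0(first, second)
}

#' @rdname pairKey
#' @export
pairRowIndex <- function(first, second) {
  .checkSnvKeys(first)
  .checkSnvKeys(second)
  12L * (match(first, .SNV_KEYS) - 1L) + (match(second, .SNV_KEYS) - 1L)
}

.checkSnvKeys <- function(k) {
  bad <- !(k %in% .SNV_KEYS)
  if (any(bad)) {
    stop("invalid SNV key(s): ", paste(unique(k[bad]), collapse = ", "))
  }
  invisible(TRUE)
}
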