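.GFP_VERSION <- 1L

#' Read and write fingerprint files
#'
#' Fingerprints are stored as plain text (gzipped when the path ends in
#' \code{.gz}). The format is self-describing: \code{##gfp-version=1}
#' followed by \code{##kind=}, \code{##id=}, \code{##L=}, \code{##C=},
#' \code{##snvs=}, \code{##pairs-raw=}, \code{##pairs-close=},
#' \code{##source=} header lines (population fingerprints add
#' \code{##members=}; the distance and SD conventions are recorded as
#' \code{##distance=intervening-bases} and \code{##sd=population}), then
#' 144 data rows \code{PAIRKEY<TAB>v0<TAB>...<TAB>v(L-1)} in canonical
#' pair-key order. Raw fingerprints append a \code{##close} section with
#' 144 x C rows; binary fingerprints carry a single 144-character 0/1
#' line. Values round-trip at full precision.
#'
#' @param fp a fingerprint object of any kind.
#' @param path file to write/read; \code{.gz} for compression.
#' @return \code{writeFingerprint}: the path, invisibly;
#'   \code{readFingerprint}: a fingerprint object of the stored kind.
#' @examples
#' v <- data.frame(chrom = "1", pos = c(100, 150, 200),
#'                 ref = "G", alt = "A")
#' f <- tempfile(fileext = ".fp")
#' writeFingerprint(computeRawFingerprint(v), f)
#' readFingerprint(f)
#' @export
writeFingerprint <- function(fp, path) {
  stopifnot(is(fp, "GenomeFingerprint"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  hdr <- c(
    paste0("##gfp-version=", .GFP_VERSION),
    paste0("##kind=", fp@kind),
    paste0("##id=", fp@id),
    paste0("##L=", fp@L),
    paste0("##C=", fp@C),
    paste0("##snvs=", format(fp@nSnvs, scientific = FALSE)),
    paste0("##pairs-raw=", format(fp@nPairsRaw, scientific = FALSE)),
    paste0("##pairs-close=", format(fp@nPairsClose, scientific = FALSE)),
    paste0("##source=", fp@source),
    "##distance=intervening-bases",
    "##sd=population")
  if (is(fp, "PopulationFingerprint")) {
    hdr <- c(hdr, paste0("##members=", paste(fp@members, collapse = ",")))
  }
  writeLines(hdr, con)
  if (is(fp, "BinaryFingerprint")) {
    writeLines(paste(fp@bits, collapse = ""), con)
  } else if (is(fp, "RawFingerprint")) {
    .writeMatrix(fp@raw, con, integer = TRUE)
    writeLines("##close", con)
    if (fp@C > 0L) .writeMatrix(fp@close, con, integer = TRUE)
  } else {
    .writeMatrix(fp@values, con, integer = FALSE)
  }
  invisible(path)
}

.writeMatrix <- function(m, con, integer) {
  fmtRow <- if (integer) {
    function(x) paste(x, collapse = "\t")
  } else {
    function(x) paste(sprintf("%.17g", x), collapse = "\t")
  }
  if (ncol(m) == 0L) {
    writeLines(rownames(m), con)
  } else {
    writeLines(paste(rownames(m), apply(m, 1L, fmtRow), sep = "\t"), con)
  }
  invisible(NULL)
}

#' @rdname writeFingerprint
#' @export
readFingerprint <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- tryCatch(readLines(con), finally = close(con))
  if (length(lines) == 0L || !startsWith(lines[1L], "##gfp-version=")) {
    stop("'", path, "' is not a fingerprint file (missing ##gfp-version)")
  }
  isHdr <- startsWith(lines, "##") & !(lines == "##close")
  hdrEnd <- which(!isHdr)[1L]
  if (is.na(hdrEnd)) stop("truncated fingerprint file '", path, "': no data")
  hdr <- lines[seq_len(hdrEnd - 1L)]
  kv <- sub("^##", "", hdr)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  getv <- function(k) {
    if (!k %in% keys) stop("fingerprint file '", path, "' lacks ##", k)
    vals[[k]]
  }
  version <- as.integer(getv("gfp-version"))
  if (is.na(version) || version != .GFP_VERSION) {
    stop("unsupported fingerprint format version '", vals[["gfp-version"]],
         "' in '", path, "'")
  }
  kind <- getv("kind")
  id <- getv("id")
  L <- as.integer(getv("L")); C <- as.integer(getv("C"))
  nSnvs <- as.numeric(getv("snvs"))
  nRaw <- as.numeric(getv("pairs-raw")); nClose <- as.numeric(getv("pairs-close"))
  src <- getv("source")
  body <- lines[hdrEnd:length(lines)]

  if (kind == "binary") {
    bitLine <- body[1L]
    if (is.na(bitLine) || nchar(bitLine) != 144L ||
        grepl("[^01]", bitLine)) {
      stop("truncated or corrupt binary fingerprint in '", path, "'")
    }
    bits <- as.integer(strsplit(bitLine, "")[[1L]])
    return(new(Class = "BinaryFingerprint", id = id, L = L, C = C, nSnvs = nSnvs,
               nPairsRaw = nRaw, nPairsClose = nClose, source = src,
               kind = "binary", bits = bits))
  }

  readBlock <- function(blk, ncols, integer) {
    if (length(blk) != 144L) {
      stop("truncated fingerprint file '", path, "': expected 144 data rows, found ",
           length(blk))
    }
    parts <- strsplit(blk, "\t", fixed = TRUE)
    rk <- vapply(parts, `[`, character(1), 1L)
    if (!identical(rk, .PAIR_KEYS)) {
      stop("fingerprint file '", path,
           "' rows are not the canonical pair keys in order")
    }
    if (ncols == 0L) return(matrix(0L, 144L, 0L,
                                   dimnames = list(.PAIR_KEYS, NULL)))
    if (any(lengths(parts) != ncols + 1L)) {
      stop("truncated row in fingerprint file '", path, "'")
    }
    x <- as.numeric(unlist(lapply(parts, `[`, -1L)))
    if (anyNA(x)) stop("non-numeric value in fingerprint file '", path, "'")
    m <- matrix(if (integer) as.integer(x) else x, 144L, ncols, byrow = TRUE,
                dimnames = list(.PAIR_KEYS, NULL))
    m
  }

  if (kind == "raw") {
    closeAt <- which(body == "##close")[1L]
    if (is.na(closeAt)) {
      stop("truncated raw fingerprint file '", path, "': missing ##close section")
    }
    raw <- readBlock(body[seq_len(closeAt - 1L)], L, integer = TRUE)
    closeRows <- body[-seq_len(closeAt)]
    closeRows <- closeRows[nzchar(closeRows)]
    close <- if (C == 0L) {
      matrix(0L, 144L, 0L, dimnames = list(.PAIR_KEYS, NULL))
    } else {
      readBlock(closeRows, C, integer = TRUE)
    }
    return(new(Class = "RawFingerprint", id = id, L = L, C = C, nSnvs = nSnvs,
               nPairsRaw = nRaw, nPairsClose = nClose, source = src,
               kind = "raw", raw = raw, close = close))
  }

  if (kind %in% c("normalized", "adjusted", "population")) {
    values <- readBlock(body[nzchar(body)], L, integer = FALSE)
    if (kind == "population") {
      mem <- strsplit(getv("members"), ",", fixed = TRUE)[[1L]]
      return(new(Class = "PopulationFingerprint", id = id, L = L, C = C,
                 nSnvs = nSnvs, nPairsRaw = nRaw, nPairsClose = nClose,
                 source = src, kind = "population", values = values,
                 members = mem))
    }
    return(new(Class = "NormalizedFingerprint", id = id, L = L, C = C,
               nSnvs = nSnvs, nPairsRaw = nRaw, nPairsClose = nClose,
               source = src, kind = kind, values = values))
  }
  stop("unknown fingerprint kind '", kind, "' in '", path, "'")
}
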