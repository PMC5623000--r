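#' Chromosome filters
#'
#' A chromosome filter decides which chromosome labels an SNV reader
#' emits. Labels are first normalized by stripping a leading \code{"chr"}.
#' Include patterns are matched as exact labels or anchored regular
#' expressions; a label matching any exclude pattern is never emitted,
#' regardless of the include list. The default human filter accepts the 22
#' autosomes and excludes everything else (sex chromosomes distort
#' relatedness estimates: shared X variants make a daughter look closer to
#' her mother than to her father). Non-human genomes are supported by
#' supplying the appropriate include list.
#'
#' @param include character vector of labels/regexes to keep; \code{NULL}
#'   keeps everything not excluded.
#' @param exclude character vector of labels/regexes to drop.
#' @param n number of autosomes for \code{autosomeFilter}.
#' @return a \code{chrom_filter} list with elements \code{include} and
#'   \code{exclude}.
#' @examples
#' f <- autosomeFilter()
#' genofp:::.chromKeep(c("1", "22", "X", "MT"), f)
#' @export
chromFilter <- function(include = NULL,
                        exclude = c("X", "Y", "M", "MT", "W", "Z")) {
  structure(list(include = include, exclude = exclude),
            class = "chrom_filter")
}

#' @rdname chromFilter
#' @export
autosomeFilter <- function(n = 22L) chromFilter(include = as.character(seq_len(n)))

# match labels (already chr-stripped) against a pattern list: exact label
# or anchored regex.
.matchAny <- function(labels, patterns) {
  if (is.null(patterns) || length(patterns) == 0L) {
    return(rep(FALSE, length(labels)))
  }
  hit <- labels %in% patterns
  for (p in setdiff(patterns, labels[hit])) {
    hit <- hit | grepl(paste0("^(?:", p, ")$"), labels, perl = TRUE)
  }
  hit
}

.chromKeep <- function(labels, filter) {
  stopifnot(inherits(filter, "chrom_filter"))
  inc <- if (is.null(filter$include)) rep(TRUE, length(labels))
         else .matchAny(labels, filter$include)
  inc & !.matchAny(labels, filter$exclude)
}

.normChrom <- function(chrom) sub("^chr", "", as.character(chrom))

#' Read biallelic autosomal SNVs from VCF or TSV
#'
#' Streams position-sorted biallelic SNVs for one sample out of a VCF
#' (plain or gzipped, single- or multi-sample) or a 4-column
#' whitespace-delimited table (chrom, 1-based pos, ref, alt; \code{#}
#' comment lines allowed). A record is emitted when (a) its chromosome
#' passes the filter, (b) REF and ALT are single bases in A,C,G,T
#' (case-insensitive) with a single ALT allele, and (c) the selected
#' sample's genotype carries at least one alternate allele (heterozygous
#' and homozygous-alternate are treated identically; a missing genotype
#' means not observed). Non-SNV records are skipped without breaking the
#' consecutiveness of flanking SNVs. Chromosome labels are normalized by
#' stripping a leading \code{"chr"}. Records at a duplicated position
#' (after filtering) are dropped beyond the first; the count of dropped
#' records is reported in the \code{"stats"} attribute. Unsorted positions
#' within a chromosome are an error (no silent re-sorting).
#'
#' @param path VCF (\code{.vcf}, \code{.vcf.gz}) or TSV file.
#' @param sample sample name for multi-sample VCFs; may be omitted for
#'   single-sample files.
#' @param chromFilter a \code{\link{chromFilter}}; default human autosomes.
#' @param format \code{"auto"} (by extension), \code{"vcf"} or \code{"tsv"}.
#' @param passOnly if \code{TRUE}, restrict to records with FILTER PASS
#'   (or \code{.}); by default FILTER is ignored.
#' @return a \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, grouped by chromosome and position-sorted,
#'   with an attribute \code{"stats"} (named numeric: \code{nInput},
#'   \code{nEmitted}, \code{nDuplicatesDropped}).
#' @examples
#' vcf <- system.file("extdata", "toy_genome.vcf", package = "genofp")
#' snvs <- readSNVs(vcf)
#' head(snvs)
#' attr(snvs, "stats")
#' @export
readSNVs <- function(path, sample = NULL, chromFilter = autosomeFilter(),
                     format = c("auto", "vcf", "tsv"), passOnly = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
              else "tsv"
  }
  if (format == "vcf") {
    .readSnvsVcf(path, sample, chromFilter, passOnly)
  } else {
    .readSnvsTsv(path, chromFilter)
  }
}

.isSnvAllele <- function(x) x %in% .BASES

.readSnvsVcf <- function(path, sample, filter, passOnly) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  fix <- vcf@fix
  nInput <- nrow(fix)
  if (nInput == 0L) {
    return(.finishSnvs(data.frame(chrom = character(), pos = numeric(),
                                  ref = character(), alt = character()),
                       0L))
  }
  chrom <- .normChrom(fix[, "CHROM"])
  pos <- suppressWarnings(as.numeric(fix[, "POS"]))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1L]
    stop("unparseable POS at VCF record ", bad, " of '", path, "'")
  }
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  keep <- .chromKeep(chrom, filter) &
    !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    .isSnvAllele(ref) & .isSnvAllele(alt)
  if (passOnly) {
    filt <- fix[, "FILTER"]
    keep <- keep & (is.na(filt) | filt %in% c("PASS", "."))
  }

  gt <- vcf@gt
  if (!is.null(gt) && ncol(gt) >= 2L) {
    samples <- colnames(gt)[-1L]
    if (is.null(sample)) {
      if (length(samples) > 1L) {
        stop("multi-sample VCF: choose one of ",
             paste(samples, collapse = ", "))
      }
      sample <- samples[1L]
    }
    if (!sample %in% samples) {
      stop("unknown sample '", sample, "'; available: ",
           paste(samples, collapse = ", "))
    }
    gtField <- vcfR::extract.gt(vcf, element = "GT")[, sample]
    # biallelic records only, so any '1' allele marks an alt carrier
    carrier <- !is.na(gtField) & grepl("1", gtField, fixed = TRUE)
    keep <- keep & carrier
  }
  # minimal VCFs without FORMAT/sample columns: every retained site counts

  out <- data.frame(chrom = chrom[keep], pos = pos[keep],
                    ref = ref[keep], alt = alt[keep],
                    stringsAsFactors = FALSE)
  .finishSnvs(out, nInput, file = path)
}

.readSnvsTsv <- function(path, filter) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- tryCatch(readLines(con), finally = close(con))
  lineNo <- seq_along(lines)
  keepLine <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keepLine]
  lineNo <- lineNo[keepLine]
  nInput <- length(lines)
  if (nInput == 0L) {
    return(.finishSnvs(data.frame(chrom = character(), pos = numeric(),
                                  ref = character(), alt = character()),
                       0L))
  }
  parts <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(parts)
  if (any(nf < 4L)) {
    stop("malformed variant table '", path, "' at line ",
         lineNo[which(nf < 4L)[1L]], ": expected 4 columns chrom pos ref alt")
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:4)), ncol = 4L, byrow = TRUE)
  pos <- suppressWarnings(as.numeric(m[, 2L]))
  if (anyNA(pos)) {
    stop("non-numeric position in '", path, "' at line ",
         lineNo[which(is.na(pos))[1L]])
  }
  chrom <- .normChrom(m[, 1L])
  ref <- toupper(m[, 3L])
  alt <- toupper(m[, 4L])
  keep <- .chromKeep(chrom, filter) & !grepl(",", alt, fixed = TRUE) &
    .isSnvAllele(ref) & .isSnvAllele(alt)
  out <- data.frame(chrom = chrom[keep], pos = pos[keep],
                    ref = ref[keep], alt = alt[keep],
                    stringsAsFactors = FALSE)
  .finishSnvs(out, nInput, file = path)
}

# shared tail of the readers: sortedness check, duplicate-position policy,
# stats attribute. Also used to validate in-memory streams.
.finishSnvs <- function(v, nInput, file = "<stream>") {
  n <- nrow(v)
  nDup <- 0L
  if (n >= 2L) {
    rl <- rle(v$chrom)
    if (anyDuplicated(rl$values)) {
      stop("input '", file, "' is not grouped by chromosome (chromosome ",
           rl$values[anyDuplicated(rl$values)], " appears in two blocks)")
    }
    sameChrom <- v$chrom[-1L] == v$chrom[-n]
    dpos <- v$pos[-1L] - v$pos[-n]
    bad <- which(sameChrom & dpos < 0)
    if (length(bad)) {
      stop("unsorted positions in '", file, "' on chromosome ",
           v$chrom[bad[1L]], ": ", v$pos[bad[1L]], " followed by ",
           v$pos[bad[1L] + 1L])
    }
    dup <- c(FALSE, sameChrom & dpos == 0)
    nDup <- sum(dup)
    if (nDup) v <- v[!dup, , drop = FALSE]
  }
  rownames(v) <- NULL
  attr(v, "stats") <- c(nInput = nInput, nEmitted = nrow(v),
                        nDuplicatesDropped = nDup)
  v
}

#' Write an SNV stream as TSV or single-sample VCF
#'
#' \code{writeSnvTsv} writes the 4-column table consumed by
#' \code{\link{readSNVs}}; \code{writeSnvVcf} writes a minimal VCF 4.2
#' single-sample file (genotypes default to \code{0/1}; the fingerprint is
#' zygosity-blind). A \code{.gz} suffix triggers gzip compression.
#'
#' @param variants data.frame with columns chrom, pos, ref, alt.
#' @param path output file.
#' @param sample sample name for the VCF genotype column.
#' @param genotypes optional vector of VCF GT strings, one per variant.
#' @return the path, invisibly.
#' @export
writeSnvTsv <- function(variants, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("# chrom\tpos\tref\talt", con)
  if (nrow(variants)) {
    writeLines(paste(variants$chrom, format(variants$pos, scientific = FALSE,
                                            trim = TRUE),
                     variants$ref, variants$alt, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname writeSnvTsv
#' @export
writeSnvVcf <- function(variants, path, sample = "SAMPLE", genotypes = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=genofp",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sample, sep = "\t")), con)
  if (nrow(variants)) {
    gt <- if (is.null(genotypes)) rep("0/1", nrow(variants)) else genotypes
    writeLines(paste(variants$chrom,
                     format(variants$pos, scientific = FALSE, trim = TRUE),
                     ".", variants$ref, variants$alt, ".", "PASS", ".",
                     "GT", gt, sep = "\t"), con)
  }
  invisible(path)
}

# validate an in-memory variant data.frame before fingerprinting
.checkStream <- function(variants) {
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("variant stream needs columns ", paste(need, collapse = ", "))
  }
  variants
}
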