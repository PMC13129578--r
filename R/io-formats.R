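#' Read a reference genome from FASTA
#'
#' Loads a multi-record FASTA file into a named \code{DNAStringSet}. Record
#' order is preserved, lowercase bases are uppercased, and contig names (the
#' first whitespace-delimited token of each header) must be unique and
#' non-empty.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A \code{\link[Biostrings]{DNAStringSet}} with one entry per contig.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt", ">chr2", "GGGG"), fa)
#' g <- readReference(fa)
#' names(g)   # "chr1" "chr2"
#' @export
readReference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  if (length(g) == 0L) stop("empty FASTA file: ", path)
  nm <- sub("\\s.*$", "", names(g))
  if (any(!nzchar(nm))) stop("empty contig name in ", path)
  if (anyDuplicated(nm))
    stop("duplicate contig name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(g) <- nm
  g <- Biostrings::DNAStringSet(toupper(as.character(g)))
  names(g) <- nm
  bad <- !grepl("^[ACGTN]*$", as.character(g))
  if (any(bad))
    stop("contig(s) with bases outside {A,C,G,T,N}: ",
         paste(nm[bad], collapse = ", "))
  g
}

#' Extract a reference subsequence
#'
#' Returns the bases \code{start..end} (1-based, inclusive) of a contig.
#' Requests reaching past the contig boundaries are truncated to the valid
#' range rather than raising an error, so flanks near chromosome ends degrade
#' gracefully; a start beyond the contig (or an empty range) yields \code{""}.
#'
#' @param genome A \code{DNAStringSet} as returned by
#'   \code{\link{readReference}}.
#' @param chrom Contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return A character string of bases (possibly empty).
#' @export
fetchSubsequence <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown contig: ", chrom)
  len <- length(genome[[chrom]])
  s <- max(1L, as.integer(start))
  e <- min(len, as.integer(end))
  if (s > e) return("")
  as.character(Biostrings::subseq(genome[[chrom]], s, e))
}

.normalizeGenotype <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  gt[gt == "1/0"] <- "0/1"
  gt
}

#' Read per-sample SV calls from a Sniffles-dialect VCF
#'
#' Parses one sample's structural-variant VCF (INFO keys \code{SVTYPE},
#' \code{SVLEN}, \code{END}, flags \code{PRECISE}/\code{IMPRECISE};
#' \code{FORMAT/GT}) into a call table. \code{SVLEN} is stored as an absolute
#' value (callers commonly emit negative lengths for deletions). Records with
#' no \code{SVTYPE} are skipped with a warning; non-BND records shorter than
#' \code{minLength} are dropped and the drop count is attached to the result
#' (attribute \code{"nDropped"}). Missing genotypes (\code{./.}) are
#' normalized to \code{0/0} with a warning; a record without a
#' \code{PRECISE}/\code{IMPRECISE} flag is treated as precise, so filtering
#' only ever removes records positively flagged imprecise.
#'
#' @param path Path to a VCF file.
#' @param sampleId Sample identifier to attach to every call.
#' @param minLength Minimum SV length in bp for non-BND types (default 50).
#' @return A \code{data.frame} with columns \code{sampleId}, \code{chrom},
#'   \code{pos}, \code{svType}, \code{length} (\code{NA} for BND),
#'   \code{end}, \code{genotype}, \code{precise}, \code{altSeq} (\code{NA}
#'   except for sequence-resolved insertions). Attributes \code{nDropped}
#'   (short records removed) and \code{nSkipped} (malformed records).
#' @export
readSampleCalls <- function(path, sampleId, minLength = 50) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- suppressWarnings(VariantAnnotation::readVcf(path))
  rr <- SummarizedExperiment::rowRanges(v)
  inf <- VariantAnnotation::info(v)
  n <- length(rr)
  getInfo <- function(key, default) {
    if (!key %in% names(inf)) return(rep(default, n))
    x <- inf[[key]]
    if (is(x, "List") || is.list(x))
      x <- vapply(x, function(e) if (length(e)) e[[1]] else default,
                  FUN.VALUE = default)
    x
  }
  svType <- as.character(getInfo("SVTYPE", NA_character_))
  svLen <- suppressWarnings(as.numeric(getInfo("SVLEN", NA_real_)))
  endIn <- suppressWarnings(as.numeric(getInfo("END", NA_real_)))
  # a record is imprecise only when positively flagged; an absent flag
  # leaves the record precise, so filtering never removes unflagged calls
  imprecise <- as.logical(getInfo("IMPRECISE", FALSE))
  imprecise[is.na(imprecise)] <- FALSE

  gtmat <- VariantAnnotation::geno(v)$GT
  gt <- if (is.null(gtmat)) rep("0/0", n) else as.character(gtmat[, 1])
  nmiss <- sum(gt %in% c("./.", ".|.", "."))
  if (nmiss > 0)
    warning(nmiss, " missing genotype(s) './.' normalized to 0/0 in ", path)
  gt[gt %in% c("./.", ".|.", ".")] <- "0/0"
  gt <- .normalizeGenotype(gt)
  if (!all(gt %in% GT_LEVELS))
    stop("unsupported genotype code(s) in ", path, ": ",
         paste(unique(gt[!gt %in% GT_LEVELS]), collapse = ", "))

  alt <- VariantAnnotation::alt(v)
  altChar <- vapply(seq_len(n), function(i) {
    a <- alt[[i]]
    a <- as.character(a)
    if (length(a) && grepl("^[ACGTNacgtn]+$", a[1])) toupper(a[1])
    else NA_character_
  }, character(1))

  pos <- BiocGenerics::start(rr)
  chrom <- as.character(GenomicRanges::seqnames(rr))

  skip <- is.na(svType) | !svType %in% SV_TYPES
  nSkipped <- sum(skip)
  if (nSkipped > 0)
    warning(nSkipped, " record(s) without a usable SVTYPE skipped in ", path)

  len <- abs(svLen)
  # fall back to END for length-less deletions/inversions/duplications
  noLen <- is.na(len) & svType %in% c("DEL", "INV", "DUP") & !is.na(endIn)
  len[noLen] <- endIn[noLen] - pos[noLen]
  insNoLen <- is.na(len) & svType == "INS" & !is.na(altChar)
  len[insNoLen] <- nchar(altChar[insNoLen])
  len[svType == "BND"] <- NA_real_

  end <- ifelse(svType %in% c("DEL", "INV", "DUP"), pos + len, pos)

  keep <- !skip
  short <- keep & svType != "BND" & (is.na(len) | len < minLength)
  nDropped <- sum(short)
  keep <- keep & !short

  out <- data.frame(
    sampleId = sampleId, chrom = chrom, pos = as.integer(pos),
    svType = svType, length = len, end = as.integer(round(end)),
    genotype = gt, precise = !imprecise,
    altSeq = ifelse(svType == "INS", altChar, NA_character_),
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "nDropped") <- nDropped
  attr(out, "nSkipped") <- nSkipped
  out
}

#' Write SV calls as a Sniffles-dialect VCF
#'
#' Serializes a call table (as returned by \code{\link{readSampleCalls}}) for
#' one sample back to VCF: deletions carry negative \code{SVLEN}, insertions
#' carry their sequence as ALT when available, \code{PRECISE}/\code{IMPRECISE}
#' flags and \code{GT} are emitted. Reading the file back with
#' \code{readSampleCalls} reproduces the calls field-wise.
#'
#' @param calls Call \code{data.frame} (single sample).
#' @param path Output VCF path.
#' @param sampleId Sample column name; defaults to the calls' sample id.
#' @param contigLengths Optional named vector of contig lengths for the
#'   header; contigs default to length 536870911 when unknown.
#' @return \code{path}, invisibly.
#' @export
writeSampleCalls <- function(calls, path, sampleId = NULL,
                             contigLengths = NULL) {
  if (is.null(sampleId))
    sampleId <- if (nrow(calls)) calls$sampleId[1] else "sample"
  chroms <- unique(calls$chrom)
  if (is.null(contigLengths))
    contigLengths <- stats::setNames(rep(536870911L, length(chroms)), chroms)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svCohort",
    sprintf("##contig=<ID=%s,length=%d>", names(contigLengths),
            as.integer(contigLengths)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the SV\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the SV\">",
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Precise breakpoints\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sampleId), collapse = "\t")
  )
  rows <- character(nrow(calls))
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$pos)
    calls <- calls[o, , drop = FALSE]
    for (i in seq_len(nrow(calls))) {
      r <- calls[i, ]
      flag <- if (isTRUE(r$precise)) "PRECISE" else "IMPRECISE"
      info <- paste0(flag, ";SVTYPE=", r$svType)
      if (!is.na(r$length)) {
        sl <- if (r$svType == "DEL") -r$length else r$length
        info <- paste0(info, ";SVLEN=", format(sl, scientific = FALSE))
      }
      if (r$svType %in% c("DEL", "INV", "DUP"))
        info <- paste0(info, ";END=", r$end)
      altField <- if (r$svType == "INS" && !is.na(r$altSeq)) r$altSeq
                  else paste0("<", r$svType, ">")
      rows[i] <- paste(r$chrom, r$pos, paste0("sv", i), "N", altField, "60",
                       "PASS", info, "GT", r$genotype, sep = "\t")
    }
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a gene track from a BED-like file
#'
#' Parses a tab-separated gene track whose first four columns are chromosome,
#' gene identifier, gene start and gene end, followed by any number of
#' free-text annotation columns. Coordinates are interpreted as 0-based
#' half-open (BED convention) and kept in that convention internally. Rows
#' with fewer than four columns or with \code{start >= end} are rejected with
#' a warning. Features are returned sorted by (chrom, start).
#'
#' @param path Path to the BED-like file. A first line starting with
#'   \code{#} is treated as a header supplying annotation column names.
#' @return A \code{data.frame} with columns \code{chrom}, \code{geneId},
#'   \code{start}, \code{end} and one column per annotation field; attribute
#'   \code{"annotationHeaders"} carries the annotation column names.
#' @export
readGeneTrack <- function(path) {
  if (!file.exists(path)) stop("gene track not found: ", path)
  lines <- readLines(path)
  annHeaders <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    hdr <- strsplit(sub("^#\\s*", "", lines[1]), "\t")[[1]]
    if (length(hdr) > 4) annHeaders <- hdr[-(1:4)]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  bad <- nc < 4
  if (any(bad))
    warning(sum(bad), " row(s) with fewer than 4 columns rejected")
  parts <- parts[!bad]
  if (!length(parts)) {
    out <- data.frame(chrom = character(0), geneId = character(0),
                      start = integer(0), end = integer(0))
    attr(out, "annotationHeaders") <- annHeaders %||% character(0)
    return(out)
  }
  nAnn <- max(lengths(parts)) - 4L
  rows <- lapply(parts, function(p) c(p, rep("", 4L + nAnn - length(p))))
  m <- do.call(rbind, rows)
  out <- data.frame(chrom = m[, 1], geneId = m[, 2],
                    start = suppressWarnings(as.integer(m[, 3])),
                    end = suppressWarnings(as.integer(m[, 4])),
                    stringsAsFactors = FALSE)
  if (nAnn > 0) {
    ann <- as.data.frame(m[, 4L + seq_len(nAnn), drop = FALSE],
                         stringsAsFactors = FALSE)
    if (is.null(annHeaders) || length(annHeaders) != nAnn)
      annHeaders <- paste0("annotation", seq_len(nAnn))
    names(ann) <- annHeaders
    out <- cbind(out, ann)
  } else annHeaders <- character(0)
  bad <- is.na(out$start) | is.na(out$end) | out$start >= out$end |
    !nzchar(out$geneId)
  if (any(bad))
    warning(sum(bad), " row(s) with invalid coordinates or ids rejected")
  out <- out[!bad, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "annotationHeaders") <- annHeaders
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
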