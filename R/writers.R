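.fmtNum <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) sprintf("%g", v), character(1)))
}

.cohortHeader <- function(samples) {
  c("Position", "Type", "Reliability", "Length", "Stdev_pos", "Stdev_len",
    samples, "SV_seq", "Upstream_seq", "Downstream_seq")
}

.cohortRows <- function(cohort) {
  st <- siteTable(cohort)
  gt <- genotypeCalls(cohort)
  samples <- cohortSamples(cohort)
  if (nrow(st) && anyNA(st$upstreamSeq))
    stop("sequences not attached; run attachSequences() first")
  vapply(seq_len(nrow(st)), function(i) {
    r <- st[i, ]
    paste(c(paste0(r$chrom, "-", r$pos), r$svType,
            if (isTRUE(r$precise)) "PRECISE" else "IMPRECISE",
            if (is.na(r$length)) "" else format(r$length, scientific = FALSE),
            .fmtNum(r$stdevPos), .fmtNum(r$stdevLen),
            gt[i, samples], r$svSeq, r$upstreamSeq, r$downstreamSeq),
          collapse = "\t")
  }, character(1))
}

#' Write the cohort SV table
#'
#' Writes the main tabular output: one tab-separated row per merged site,
#' sorted by (chrom, pos). Columns are the site position
#' (\code{chrom-pos}, hyphen-separated), SV type, reliability
#' (PRECISE/IMPRECISE), length (empty for BND), the position and length
#' standard deviations, one genotype column per sample in manifest order,
#' and the SV, upstream-flank and downstream-flank sequences. Output is
#' UTF-8 with \code{"\n"} line endings and a plain header line; identical
#' cohorts yield byte-identical files.
#'
#' @param cohort An \code{\linkS4class{SVCohort}} with sequences attached
#'   (\code{\link{attachSequences}}).
#' @param path Output path.
#' @return The written table as a \code{data.frame}, invisibly.
#' @export
writeCohortTable <- function(cohort, path) {
  hdr <- paste(.cohortHeader(cohortSamples(cohort)), collapse = "\t")
  rows <- .cohortRows(cohort)
  con <- file(path, open = "wb")
  writeLines(c(hdr, rows), con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(readCohortTable(path))
}

#' Read a cohort SV table back into a data.frame
#'
#' @param path Path to a file written by \code{\link{writeCohortTable}} or
#'   \code{\link{writeGeneTable}}.
#' @return A \code{data.frame} with character columns exactly as written.
#' @export
readCohortTable <- function(path) {
  utils::read.delim(path, colClasses = "character", check.names = FALSE)
}

#' Write the gene-annotated cohort SV table
#'
#' Restricts the cohort table to sites located in a gene body or in a gene's
#' upstream region, emitting one row per (site, gene context): the cohort
#' columns of \code{\link{writeCohortTable}} followed by the gene name, the
#' upstream and downstream neighboring gene names, the region label
#' (\code{genic} or \code{upstream}) and the track's annotation columns. A
#' site hitting several genes produces one row per gene.
#'
#' @param cohort An \code{SVCohort} with sequences attached.
#' @param track Gene track from \code{\link{readGeneTrack}}.
#' @param path Output path.
#' @param U Upstream window length in bp (default 2000).
#' @return The written table as a \code{data.frame}, invisibly.
#' @export
writeGeneTable <- function(cohort, track, path, U = 2000) {
  annHeaders <- attr(track, "annotationHeaders") %||% character(0)
  hdr <- paste(c(.cohortHeader(cohortSamples(cohort)),
                 "Gene", "Upstream_gene", "Downstream_gene", "Region",
                 annHeaders), collapse = "\t")
  baseRows <- .cohortRows(cohort)
  ctxs <- classifySites(cohort, track, U)
  rows <- character(0)
  for (i in seq_along(ctxs)) {
    cx <- ctxs[[i]]
    for (j in seq_len(nrow(cx))) {
      extra <- c(cx$geneId[j],
                 if (is.na(cx$upstreamGene[j])) "" else cx$upstreamGene[j],
                 if (is.na(cx$downstreamGene[j])) "" else cx$downstreamGene[j],
                 cx$region[j],
                 vapply(annHeaders, function(h) cx[[h]][j], character(1)))
      rows <- c(rows, paste(c(baseRows[i], extra), collapse = "\t"))
    }
  }
  con <- file(path, open = "wb")
  writeLines(c(hdr, rows), con, sep = "\n", useBytes = TRUE)
  close(con)
  invisible(readCohortTable(path))
}

#' Export a written table as CSV
#'
#' Cell-for-cell CSV export of a cohort or gene table, for use in
#' spreadsheet applications.
#'
#' @param tablePath Path to a TSV written by \code{\link{writeCohortTable}}
#'   or \code{\link{writeGeneTable}}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
exportSpreadsheet <- function(tablePath, path) {
  tab <- readCohortTable(tablePath)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
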