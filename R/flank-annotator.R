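#' Attach SV and flanking sequences to merged sites
#'
#' Fills the \code{svSeq}, \code{upstreamSeq} and \code{downstreamSeq}
#' columns of the site table from the reference genome. With 1-based
#' coordinates and a site at representative position \code{pos}:
#' \itemize{
#'   \item the upstream flank is the \code{flank} reference bases ending at
#'     the anchor base inclusive, \code{[pos - flank + 1, pos]} (the VCF
#'     anchor base at \code{pos} precedes the affected bases, so for
#'     deletions \code{upstreamSeq . svSeq . downstreamSeq} reassembles a
#'     contiguous reference substring);
#'   \item for DEL/INV/DUP the SV sequence is \code{[pos + 1, end]} and the
#'     downstream flank \code{[end + 1, end + flank]} (the VCF anchor base at
#'     \code{pos} precedes the affected bases);
#'   \item for INS the SV sequence is the inserted sequence of the member
#'     call nearest the representative position, and the downstream flank is
#'     \code{[pos + 1, pos + flank]} (the insertion sits between \code{pos}
#'     and \code{pos + 1});
#'   \item for BND the SV sequence is empty and the downstream flank is
#'     \code{[pos + 1, pos + flank]}.
#' }
#' All ranges are truncated at contig boundaries, so flanks near chromosome
#' ends are shorter than \code{flank} rather than an error.
#'
#' @param cohort An \code{\linkS4class{SVCohort}}.
#' @param genome A \code{DNAStringSet} from \code{\link{readReference}}.
#' @param flank Flank length in bp (default 300).
#' @return The cohort with sequence columns filled.
#' @export
attachSequences <- function(cohort, genome, flank = 300) {
  st <- siteTable(cohort)
  if (nrow(st) && !all(st$chrom %in% names(genome)))
    stop("site chromosome(s) absent from the reference: ",
         paste(setdiff(st$chrom, names(genome)), collapse = ", "))
  members <- siteMembers(cohort)
  for (i in seq_len(nrow(st))) {
    chrom <- st$chrom[i]; pos <- st$pos[i]; end <- st$end[i]
    st$upstreamSeq[i] <- fetchSubsequence(genome, chrom, pos - flank + 1, pos)
    if (st$svType[i] %in% c("DEL", "INV", "DUP")) {
      st$svSeq[i] <- fetchSubsequence(genome, chrom, pos + 1, end)
      st$downstreamSeq[i] <- fetchSubsequence(genome, chrom, end + 1,
                                              end + flank)
    } else if (st$svType[i] == "INS") {
      mem <- members[[i]]
      mem <- mem[order(abs(mem$pos - pos)), , drop = FALSE]
      alt <- mem$altSeq[!is.na(mem$altSeq)]
      nearest <- mem$altSeq[1]
      st$svSeq[i] <- if (!is.na(nearest)) nearest
                     else if (length(alt)) alt[1] else ""
      st$downstreamSeq[i] <- fetchSubsequence(genome, chrom, pos + 1,
                                              pos + flank)
    } else { # BND: no resolved variant sequence
      st$svSeq[i] <- ""
      st$downstreamSeq[i] <- fetchSubsequence(genome, chrom, pos + 1,
                                              pos + flank)
    }
  }
  newSVCohort(cohortSamples(cohort), st, genotypeCalls(cohort), members,
              mergeConstant(cohort))
}

#' Upstream region of a gene
#'
#' The upstream region of a gene is the window of up to \code{U} bp before
#' its start, truncated at the end of the nearest wholly-preceding gene on
#' the same chromosome (and at coordinate 0). Because the gene track carries
#' no strand column, "upstream" always means lower coordinates.
#'
#' @param geneId Gene identifier present in \code{track}.
#' @param track Gene track from \code{\link{readGeneTrack}} (0-based
#'   half-open coordinates).
#' @param U Upstream window length in bp (default 2000).
#' @return Integer vector \code{c(start, end)}: a 0-based half-open interval
#'   ending at the gene start; zero-width when the gene starts at 0 or abuts
#'   its predecessor.
#' @export
upstreamRegion <- function(geneId, track, U = 2000) {
  i <- match(geneId, track$geneId)
  if (is.na(i)) stop("gene not in track: ", geneId)
  gStart <- track$start[i]
  prior <- track$end[track$chrom == track$chrom[i] &
                     track$end <= gStart & track$geneId != geneId]
  lo <- max(c(gStart - U, 0L, prior))
  c(start = as.integer(min(lo, gStart)), end = as.integer(gStart))
}

# 1-based inclusive site interval used for gene intersection:
# DEL/INV/DUP span [pos, end]; INS and BND are anchored at the single base
# pos (the variant sits between pos and pos+1).
.siteInterval <- function(site) {
  if (site$svType %in% c("DEL", "INV", "DUP")) c(site$pos, site$end)
  else c(site$pos, site$pos)
}

#' Classify a merged site against the gene track
#'
#' Emits one gene context per gene whose body intersects the site interval
#' (\code{region = "genic"}) and one per gene whose upstream region (see
#' \code{\link{upstreamRegion}}) intersects it while its body does not
#' (\code{region = "upstream"}). Each context also carries the nearest gene
#' wholly before the site and the nearest gene wholly after it, plus the
#' gene's annotation columns. Sites touching no gene or upstream region
#' yield a zero-row result.
#'
#' @param site One-row site \code{data.frame} (a row of
#'   \code{\link{siteTable}}).
#' @param track Gene track from \code{\link{readGeneTrack}}.
#' @param U Upstream window length in bp (default 2000).
#' @return \code{data.frame} with columns \code{geneId}, \code{region},
#'   \code{upstreamGene}, \code{downstreamGene} and the track's annotation
#'   columns.
#' @export
classifySite <- function(site, track, U = 2000) {
  annHeaders <- attr(track, "annotationHeaders") %||% character(0)
  empty <- data.frame(geneId = character(0), region = character(0),
                      upstreamGene = character(0),
                      downstreamGene = character(0),
                      stringsAsFactors = FALSE)
  for (h in annHeaders) empty[[h]] <- character(0)
  tr <- track[track$chrom == site$chrom, , drop = FALSE]
  if (nrow(tr) == 0) return(empty)
  iv <- .siteInterval(site)
  siteRange <- IRanges::IRanges(iv[1], iv[2])
  # gene bodies in 1-based inclusive coordinates: [start+1, end]
  bodies <- IRanges::IRanges(tr$start + 1L, tr$end)
  genicIdx <- S4Vectors::queryHits(
    IRanges::findOverlaps(bodies, siteRange))
  upsIdx <- integer(0)
  for (j in seq_len(nrow(tr))) {
    if (j %in% genicIdx) next
    reg <- upstreamRegion(tr$geneId[j], track, U)
    if (reg["end"] <= reg["start"]) next
    # upstream region [a, b) 0-based covers 1-based bases [a+1, b]
    if (iv[2] >= reg["start"] + 1L && iv[1] <= reg["end"]) {
      upsIdx <- c(upsIdx, j)
    }
  }
  hits <- c(genicIdx, upsIdx)
  if (!length(hits)) return(empty)
  before <- which(tr$end < iv[1])       # 1-based end = tr$end
  after <- which(tr$start + 1L > iv[2])
  upNb <- if (length(before)) tr$geneId[before[which.max(tr$end[before])]]
          else NA_character_
  dnNb <- if (length(after)) tr$geneId[after[which.min(tr$start[after])]]
          else NA_character_
  out <- data.frame(
    geneId = tr$geneId[hits],
    region = c(rep("genic", length(genicIdx)),
               rep("upstream", length(upsIdx))),
    upstreamGene = upNb, downstreamGene = dnNb,
    stringsAsFactors = FALSE
  )
  for (h in annHeaders) out[[h]] <- tr[[h]][hits]
  out <- out[order(out$geneId, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify every site of a cohort
#'
#' @param cohort An \code{SVCohort}.
#' @param track Gene track.
#' @param U Upstream window length in bp.
#' @return A list with one \code{\link{classifySite}} result per site.
#' @export
classifySites <- function(cohort, track, U = 2000) {
  st <- siteTable(cohort)
  lapply(seq_len(nrow(st)),
         function(i) classifySite(st[i, , drop = FALSE], track, U))
}
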