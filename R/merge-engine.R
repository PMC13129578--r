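#' Positional-offset threshold for co-clustering two SV calls
#'
#' Two calls of the same type may be merged into one site when their
#' positional offset does not exceed \code{M * sqrt(min(lenA, lenB))}. The
#' threshold is monotone non-decreasing in both lengths and in \code{M}:
#' larger SVs (whose breakpoints are harder to place exactly) tolerate larger
#' offsets, and raising \code{M} relaxes the merge.
#'
#' @param lenA,lenB SV lengths in bp (non-negative).
#' @param M Dimensionless merge constant (default 250).
#' @return Threshold in bp.
#' @examples
#' pairThreshold(100, 64)        # 250 * sqrt(64) = 2000
#' @export
pairThreshold <- function(lenA, lenB, M = 250) {
  if (any(lenA < 0, na.rm = TRUE) || any(lenB < 0, na.rm = TRUE))
    stop("SV lengths must be non-negative")
  M * sqrt(pmin(lenA, lenB))
}

#' Cluster same-type SV calls along one chromosome
#'
#' Sorts calls by position and links sorted-adjacent calls i, i+1 whenever
#' their positional gap is at most \code{\link{pairThreshold}} of their two
#' lengths; clusters are the connected components of this chain
#' (single-linkage over the sorted order). Calls with undefined length (BND)
#' are compared with a fixed window of \code{M} bp.
#'
#' @param calls Call \code{data.frame} sharing one \code{chrom} and one
#'   \code{svType}.
#' @param M Merge constant.
#' @return A list of call \code{data.frame}s, each a cluster; every input
#'   call appears in exactly one cluster.
#' @export
clusterCalls <- function(calls, M = 250) {
  if (nrow(calls) == 0) return(list())
  if (length(unique(calls$chrom)) > 1)
    stop("clusterCalls requires a single chromosome")
  if (length(unique(calls$svType)) > 1)
    stop("clusterCalls requires a single SV type")
  o <- order(calls$pos, calls$sampleId,
             ifelse(is.na(calls$length), 0, calls$length))
  calls <- calls[o, , drop = FALSE]
  n <- nrow(calls)
  if (n == 1) return(list(calls))
  lenA <- calls$length[-n]
  lenB <- calls$length[-1]
  thr <- ifelse(is.na(lenA) | is.na(lenB), M,
                pairThreshold(ifelse(is.na(lenA), 0, lenA),
                              ifelse(is.na(lenB), 0, lenB), M))
  gap <- diff(calls$pos)
  breakAfter <- gap > thr
  cluster <- cumsum(c(1L, as.integer(breakAfter)))
  lapply(split(seq_len(n), cluster),
         function(idx) { d <- calls[idx, , drop = FALSE]; rownames(d) <- NULL; d })
}

.popSD <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(0)
  sqrt(mean((x - mean(x))^2))
}

.lowerMedian <- function(x) {
  x <- sort(x[!is.na(x)])
  if (!length(x)) return(NA_real_)
  x[ceiling(length(x) / 2)]
}

#' Summarize one cluster of calls into a merged site
#'
#' The representative position and length are the member medians (lower of
#' the two middles for even counts); dispersion is the population standard
#' deviation of member positions/lengths, so singleton clusters report 0; the
#' site is precise only when every member is precise. Every cohort sample
#' receives a genotype: samples with no member carry \code{0/0}. When a
#' sample contributes more than one member, the call nearest the
#' representative position wins, ties broken toward the higher-alt genotype.
#'
#' @param cluster Non-empty call \code{data.frame} (one chrom, one type).
#' @param cohortSamples Ordered character vector of all cohort sample ids.
#' @return A one-row list with elements \code{site} (one-row site
#'   \code{data.frame}), \code{genotypes} (named character vector over
#'   \code{cohortSamples}) and \code{members}.
#' @export
summarizeCluster <- function(cluster, cohortSamples) {
  if (nrow(cluster) == 0) stop("empty cluster")
  pos <- as.integer(.lowerMedian(cluster$pos))
  len <- .lowerMedian(cluster$length)
  type <- cluster$svType[1]
  end <- if (type %in% c("DEL", "INV", "DUP")) pos + as.integer(len) else pos
  gts <- stats::setNames(rep("0/0", length(cohortSamples)), cohortSamples)
  altRank <- c("0/0" = 0, "0/1" = 1, "1/1" = 2)
  for (s in unique(cluster$sampleId)) {
    mem <- cluster[cluster$sampleId == s, , drop = FALSE]
    if (nrow(mem) > 1) {
      d <- abs(mem$pos - pos)
      mem <- mem[order(d, -altRank[mem$genotype]), , drop = FALSE]
    }
    gts[s] <- mem$genotype[1]
  }
  site <- data.frame(
    chrom = cluster$chrom[1], pos = pos, svType = type,
    length = len, end = as.integer(end),
    stdevPos = .popSD(cluster$pos), stdevLen = .popSD(cluster$length),
    precise = all(cluster$precise),
    svSeq = NA_character_, upstreamSeq = NA_character_,
    downstreamSeq = NA_character_, stringsAsFactors = FALSE
  )
  list(site = site, genotypes = gts, members = cluster)
}

#' Merge per-sample SV call sets into a cohort
#'
#' Pools all samples' calls, partitions them by (chromosome, SV type) --
#' different SV types are never mixed within one merged site -- clusters each
#' partition with \code{\link{clusterCalls}} and summarizes each cluster with
#' \code{\link{summarizeCluster}}. The result carries one row per merged site,
#' sorted by (chrom, pos), with a genotype for every sample, and conserves
#' every input call as a site member.
#'
#' @param callsets Named list: sample id -> call \code{data.frame} (as from
#'   \code{\link{readSampleCalls}}). Names must be unique.
#' @param M Merge constant (default 250).
#' @return An \code{\linkS4class{SVCohort}}.
#' @export
mergeCohort <- function(callsets, M = 250) {
  samples <- names(callsets)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("callsets must be a named list of per-sample call tables")
  if (anyDuplicated(samples)) stop("duplicate sample id")
  pooled <- do.call(rbind, c(unname(callsets), list(make.row.names = FALSE)))
  if (is.null(pooled) || nrow(pooled) == 0) {
    return(newSVCohort(samples, .emptySites(),
                       matrix(character(0), 0, length(samples),
                              dimnames = list(NULL, samples)),
                       list(), M))
  }
  key <- paste(pooled$chrom, pooled$svType, sep = "\r")
  groups <- split(seq_len(nrow(pooled)), key)
  summaries <- list()
  for (g in groups) {
    cl <- clusterCalls(pooled[g, , drop = FALSE], M)
    summaries <- c(summaries, lapply(cl, summarizeCluster, samples))
  }
  sites <- do.call(rbind, c(lapply(summaries, `[[`, "site"),
                            list(make.row.names = FALSE)))
  gt <- do.call(rbind, lapply(summaries, `[[`, "genotypes"))
  colnames(gt) <- samples
  rownames(gt) <- NULL
  members <- lapply(summaries, `[[`, "members")
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  newSVCohort(samples, sites, gt[o, , drop = FALSE], members[o], M)
}

#' Export a cohort as a multi-sample VCF
#'
#' Writes one VCF record per merged site with INFO keys \code{SVTYPE},
#' \code{SVLEN}, \code{END}, \code{STDEV_POS}, \code{STDEV_LEN} and a
#' \code{PRECISE}/\code{IMPRECISE} flag, plus one \code{GT} column per
#' sample, for interoperability with standard VCF tooling.
#'
#' @param cohort An \code{SVCohort}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
exportMergedVcf <- function(cohort, path) {
  st <- siteTable(cohort)
  gt <- genotypeCalls(cohort)
  samples <- cohortSamples(cohort)
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svCohort",
    sprintf("##contig=<ID=%s>", unique(st$chrom)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Length of the SV\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the SV\">",
    "##INFO=<ID=STDEV_POS,Number=1,Type=Float,Description=\"Stdev of member positions\">",
    "##INFO=<ID=STDEV_LEN,Number=1,Type=Float,Description=\"Stdev of member lengths\">",
    "##INFO=<ID=PRECISE,Number=0,Type=Flag,Description=\"Precise breakpoints\">",
    "##INFO=<ID=IMPRECISE,Number=0,Type=Flag,Description=\"Imprecise breakpoints\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- vapply(seq_len(nrow(st)), function(i) {
    r <- st[i, ]
    flag <- if (isTRUE(r$precise)) "PRECISE" else "IMPRECISE"
    info <- paste0(flag, ";SVTYPE=", r$svType)
    if (!is.na(r$length)) {
      sl <- if (r$svType == "DEL") -r$length else r$length
      info <- paste0(info, ";SVLEN=", format(sl, scientific = FALSE),
                     ";END=", r$end)
    }
    info <- paste0(info, sprintf(";STDEV_POS=%g;STDEV_LEN=%g",
                                 r$stdevPos, r$stdevLen))
    paste(c(r$chrom, r$pos, paste0("site", i), "N",
            paste0("<", r$svType, ">"), "60", "PASS", info, "GT",
            gt[i, samples]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}
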