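#' SV density per megabase
#'
#' @param nSites Number of merged sites.
#' @param lengthBp Reference length in bp.
#' @return Sites per Mb (full precision).
#' @export
svDensity <- function(nSites, lengthBp) {
  if (any(lengthBp <= 0)) stop("lengthBp must be positive")
  nSites / (lengthBp / 1e6)
}

.threeGenotypeFlags <- function(gt) {
  if (nrow(gt) == 0) return(logical(0))
  apply(gt, 1, function(g) all(GT_LEVELS %in% g))
}

#' Per-chromosome site counts and densities
#'
#' Tallies merged sites per chromosome, their density per megabase, and the
#' number of three-genotype sites (sites at which all of 0/0, 0/1 and 1/1
#' occur across the cohort -- the preferred substrate for co-dominant
#' markers), with a "Total" row over the whole genome. Densities are
#' reported at full precision in \code{density} and rounded to 2 decimals in
#' \code{densityDisplay}.
#'
#' @param cohort An \code{\linkS4class{SVCohort}}.
#' @param genome A \code{DNAStringSet}, or a named numeric vector of contig
#'   lengths in bp. Every site chromosome must be present.
#' @return \code{data.frame} with columns \code{chrom}, \code{nSites},
#'   \code{lengthBp}, \code{density}, \code{densityDisplay},
#'   \code{nThreeGenotype}; last row is the genome-wide total.
#' @export
chromosomeSummary <- function(cohort, genome) {
  lens <- if (is.numeric(genome)) genome
          else stats::setNames(Biostrings::width(genome), names(genome))
  st <- siteTable(cohort)
  if (nrow(st) && !all(st$chrom %in% names(lens)))
    stop("unknown chromosome(s): ",
         paste(setdiff(st$chrom, names(lens)), collapse = ", "))
  three <- .threeGenotypeFlags(genotypeCalls(cohort))
  chroms <- names(lens)
  n <- vapply(chroms, function(c) sum(st$chrom == c), integer(1))
  n3 <- vapply(chroms, function(c) sum(three[st$chrom == c]), integer(1))
  out <- data.frame(chrom = chroms, nSites = n,
                    lengthBp = as.numeric(lens),
                    density = svDensity(n, as.numeric(lens)),
                    nThreeGenotype = n3, stringsAsFactors = FALSE)
  total <- data.frame(chrom = "Total", nSites = sum(n),
                      lengthBp = sum(as.numeric(lens)),
                      density = svDensity(sum(n), sum(as.numeric(lens))),
                      nThreeGenotype = sum(n3), stringsAsFactors = FALSE)
  out <- rbind(out, total)
  out$densityDisplay <- round(out$density, 2)
  rownames(out) <- NULL
  out
}

#' Per-sample SV counts by type and zygosity
#'
#' For each sample, counts the merged sites at which its genotype is not
#' 0/0, broken down by SV type, plus homozygous (1/1) and heterozygous
#' (0/1) totals. The identity \code{total = nHom + nHet = sum of type
#' counts} holds by construction.
#'
#' @param cohort An \code{SVCohort}.
#' @return \code{data.frame} with one row per sample: \code{sampleId},
#'   one column per SV type (\code{DEL}, \code{INS}, \code{BND}, \code{INV},
#'   \code{DUP}), \code{nHom}, \code{nHet}, \code{total}.
#' @export
sampleSummary <- function(cohort) {
  st <- siteTable(cohort)
  gt <- genotypeCalls(cohort)
  samples <- cohortSamples(cohort)
  typeOrder <- c("DEL", "INS", "BND", "INV", "DUP")
  rows <- lapply(samples, function(s) {
    g <- gt[, s]
    nz <- g != "0/0"
    tc <- vapply(typeOrder, function(tp) sum(nz & st$svType == tp),
                 integer(1))
    data.frame(sampleId = s, t(tc), nHom = sum(g == "1/1"),
               nHet = sum(g == "0/1"), total = sum(nz),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Homozygous/heterozygous ratio
#'
#' @param nHom Homozygous (1/1) site count.
#' @param nHet Heterozygous (0/1) site count; must be positive.
#' @return \code{nHom / nHet}.
#' @export
homHetRatio <- function(nHom, nHet) {
  if (any(nHet == 0)) stop("undefined ratio: nHet is zero")
  nHom / nHet
}

#' Length histogram of merged sites
#'
#' Bins site lengths into half-open bins \code{[50, 100), [100, 150), ...};
#' the last regular bin is closed at \code{overflowAt} and a single overflow
#' bin collects everything longer. Sites with undefined length (BND) are
#' excluded, so the counts sum to the number of length-defined sites.
#'
#' @param cohort An \code{SVCohort}, or a numeric vector of lengths.
#' @param binWidth Bin width in bp (default 50).
#' @param overflowAt Upper bound of the last regular bin (default 10000).
#' @param minLength Lower bound of the first bin (default 50).
#' @return \code{data.frame} with columns \code{binStart}, \code{binEnd}
#'   (\code{Inf} for the overflow bin), \code{label}, \code{count}.
#' @export
lengthHistogram <- function(cohort, binWidth = 50, overflowAt = 10000,
                            minLength = 50) {
  if (binWidth <= 0) stop("binWidth must be positive")
  lens <- if (is.numeric(cohort)) cohort else siteTable(cohort)$length
  lens <- lens[!is.na(lens)]
  starts <- seq(minLength, overflowAt - binWidth, by = binWidth)
  ends <- starts + binWidth
  counts <- vapply(seq_along(starts), function(i) {
    if (i == length(starts))  # last regular bin closed at overflowAt
      sum(lens >= starts[i] & lens <= ends[i])
    else
      sum(lens >= starts[i] & lens < ends[i])
  }, integer(1))
  out <- data.frame(
    binStart = c(starts, overflowAt), binEnd = c(ends, Inf),
    label = c(paste0("[", starts, ",", ends, ")"),
              paste0(">", overflowAt)),
    count = c(counts, sum(lens > overflowAt)),
    stringsAsFactors = FALSE)
  out$label[length(starts)] <- paste0("[", starts[length(starts)], ",",
                                      overflowAt, "]")
  nLow <- sum(lens < minLength)
  if (nLow > 0)
    warning(nLow, " site(s) below the minimum length excluded")
  out
}

#' SV type proportions
#'
#' Fraction of merged sites of each SV type over all sites (including BND,
#' so the four resolved types need not sum to 1).
#'
#' @param cohort An \code{SVCohort}, or a named numeric vector of per-type
#'   site counts.
#' @param total Total site count; defaults to the sum of counts (ignored
#'   when a cohort is given).
#' @return Named numeric vector of fractions.
#' @export
typeProportions <- function(cohort, total = NULL) {
  if (is.numeric(cohort)) {
    counts <- cohort
    if (is.null(total)) total <- sum(counts)
  } else {
    st <- siteTable(cohort)
    if (nrow(st) == 0) stop("empty cohort")
    counts <- table(st$svType)
    counts <- stats::setNames(as.numeric(counts), names(counts))
    total <- nrow(st)
  }
  counts / total
}

#' Select co-dominant marker candidate sites
#'
#' Keeps merged sites suitable for PCR marker design: SV type in
#' \code{allowedTypes} (insertions/deletions by default, whose product-size
#' difference is scored on a gel), representative length at most
#' \code{maxLen}, and all three genotypes (0/0, 0/1, 1/1) observed across
#' the cohort. When \code{referenceSample} is given, sites at which that
#' sample is homozygous-alt are excluded: the sample the reference genome
#' was built from should not carry reliable homozygous SVs against itself.
#'
#' @param cohort An \code{SVCohort}.
#' @param referenceSample Optional sample id to apply the homozygous-alt
#'   exclusion to.
#' @param maxLen Maximum representative length in bp (default 1000).
#' @param allowedTypes SV types eligible as markers (default INS and DEL).
#' @return The subsetted \code{SVCohort} of candidate sites.
#' @export
selectMarkerCandidates <- function(cohort, referenceSample = NULL,
                                   maxLen = 1000,
                                   allowedTypes = c("INS", "DEL")) {
  st <- siteTable(cohort)
  gt <- genotypeCalls(cohort)
  keep <- st$svType %in% allowedTypes & !is.na(st$length) &
    st$length <= maxLen & .threeGenotypeFlags(gt)
  if (!is.null(referenceSample)) {
    if (!referenceSample %in% cohortSamples(cohort))
      stop("unknown reference sample: ", referenceSample)
    keep <- keep & gt[, referenceSample] != "1/1"
  }
  cohort[keep]
}

#' Genotype concordance between two call tables
#'
#' Compares two genotype grids over the same markers and samples, e.g.
#' genotypes estimated from sequencing against genotypes read off
#' electrophoresis band patterns. The per-marker rate is the fraction of
#' samples at which the two grids agree; the summary is the unweighted mean
#' over markers. The comparison is symmetric in its two arguments.
#'
#' @param predicted,observed Character matrices (markers x samples) with
#'   matching dimensions; dimnames are carried through when present.
#' @return List with \code{perMarker} (named rates), \code{mean}, and
#'   \code{mismatches} (\code{data.frame} of marker, sample, predicted,
#'   observed for every disagreeing cell).
#' @export
genotypeConcordance <- function(predicted, observed) {
  predicted <- as.matrix(predicted)
  observed <- as.matrix(observed)
  if (!all(dim(predicted) == dim(observed)))
    stop("genotype grids have different dimensions")
  agree <- predicted == observed
  per <- rowMeans(agree)
  if (!is.null(rownames(predicted))) names(per) <- rownames(predicted)
  idx <- which(!agree, arr.ind = TRUE)
  markers <- if (!is.null(rownames(predicted))) rownames(predicted)[idx[, 1]]
             else as.character(idx[, 1])
  samp <- if (!is.null(colnames(predicted))) colnames(predicted)[idx[, 2]]
          else as.character(idx[, 2])
  mism <- data.frame(marker = markers, sample = samp,
                     predicted = predicted[idx], observed = observed[idx],
                     stringsAsFactors = FALSE)
  list(perMarker = per, mean = mean(per), mismatches = mism)
}
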