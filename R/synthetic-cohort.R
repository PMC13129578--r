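#' Simulate a reference genome
#'
#' Uniform random A/C/G/T contigs, deterministic for a fixed seed; file
#' bytes included when a FASTA is written.
#'
#' @param nChrom Number of contigs.
#' @param chromLength Length of each contig in bp.
#' @param seed Integer seed.
#' @param path Optional FASTA output path.
#' @return A named \code{DNAStringSet} (\code{chr1}, \code{chr2}, ...).
#' @export
simulateReference <- function(nChrom, chromLength, seed, path = NULL) {
  if (chromLength <= 0) stop("chromLength must be positive")
  set.seed(seed)
  seqs <- vapply(seq_len(nChrom), function(i)
    paste(sample(c("A", "C", "G", "T"), chromLength, replace = TRUE),
          collapse = ""), character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(nChrom))
  if (!is.null(path)) Biostrings::writeXStringSet(g, path, width = 80)
  g
}

#' Simulate a non-overlapping gene track
#'
#' Places genes left to right on each contig with random lengths and random
#' inter-gene gaps; a fraction of gaps is drawn below 2,000 bp so that
#' upstream-region truncation is exercised. Coordinates are 0-based
#' half-open as in the BED convention.
#'
#' @param genome A \code{DNAStringSet}.
#' @param nGenes Total number of genes.
#' @param lengthRange Gene length range in bp (default 500--3000).
#' @param minGap Minimum gap between genes in bp (default 200).
#' @param seed Integer seed.
#' @param path Optional BED-like output path (tab-separated, one annotation
#'   column).
#' @return A gene track \code{data.frame} as from \code{\link{readGeneTrack}}.
#' @export
simulateGeneTrack <- function(genome, nGenes, lengthRange = c(500, 3000),
                              minGap = 200, seed = 1, path = NULL) {
  set.seed(seed)
  lens <- Biostrings::width(genome)
  chroms <- rep(names(genome), length.out = nGenes)
  chroms <- sort(chroms)
  rows <- list()
  gid <- 0L
  for (ch in unique(chroms)) {
    nOn <- sum(chroms == ch)
    cl <- lens[match(ch, names(genome))]
    cursor <- 0L
    for (k in seq_len(nOn)) {
      # mix short gaps (< 2 kb, exercising upstream truncation) and long ones
      gap <- if (stats::runif(1) < 0.5)
        sample(seq(minGap, 1900), 1) else sample(seq(2000, 6000), 1)
      gl <- sample(seq(lengthRange[1], lengthRange[2]), 1)
      start <- cursor + gap
      end <- start + gl
      if (end > cl) stop("infeasible packing: genes do not fit on ", ch)
      gid <- gid + 1L
      rows[[gid]] <- data.frame(chrom = ch,
                                geneId = sprintf("g%04d", gid),
                                start = as.integer(start),
                                end = as.integer(end),
                                product = sprintf("protein%04d", gid),
                                stringsAsFactors = FALSE)
      cursor <- end
    }
  }
  track <- do.call(rbind, rows)
  track <- track[order(track$chrom, track$start), , drop = FALSE]
  rownames(track) <- NULL
  attr(track, "annotationHeaders") <- "product"
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    writeLines(c("#chrom\tgene\tstart\tend\tproduct",
                 sprintf("%s\t%s\t%d\t%d\t%s", track$chrom, track$geneId,
                         track$start, track$end, track$product)),
               con, sep = "\n")
    close(con)
  }
  track
}

#' Plant a truth table of cohort SVs
#'
#' Plants \code{nSites} SVs at positions spaced at least \code{minSpacing}
#' apart within each contig, with types drawn from \code{typeMix}, lengths
#' uniform in \code{lengthRange}, and per-site per-sample genotypes drawn
#' independently from \code{genotypeFreqs}; every site is forced to carry at
#' least one non-0/0 sample (a site nobody carries would be unobservable).
#' The spacing guard requires \code{minSpacing} to exceed the largest
#' possible merge threshold \code{250 * sqrt(max(lengthRange))}, so planted
#' sites can never co-cluster under the default merge constant and exact
#' recovery is a deterministic property rather than a statistical one.
#'
#' @param genome A \code{DNAStringSet}.
#' @param nSites Number of sites to plant.
#' @param typeMix Named fractions over INS/DEL/INV/DUP.
#' @param lengthRange SV length range in bp (default 50--1000).
#' @param nSamples Number of cohort samples (ids \code{S01}, \code{S02}, ...).
#' @param genotypeFreqs Named fractions over 0/0, 0/1, 1/1.
#' @param minSpacing Minimum distance between planted sites (default 50000).
#' @param seed Integer seed.
#' @return An object of class \code{svTruth}: list with \code{sites}
#'   (\code{data.frame}: chrom, pos, svType, length, altSeq), \code{genotypes}
#'   (sites x samples character matrix) and \code{samples}.
#' @export
plantCohort <- function(genome, nSites, typeMix = c(INS = 0.45, DEL = 0.45,
                                                    INV = 0.05, DUP = 0.05),
                        lengthRange = c(50, 1000), nSamples,
                        genotypeFreqs = c("0/0" = 0.4, "0/1" = 0.4,
                                          "1/1" = 0.2),
                        minSpacing = 50000, seed = 1) {
  maxThr <- 250 * sqrt(lengthRange[2])
  if (minSpacing <= maxThr)
    stop("minSpacing (", minSpacing, ") must exceed the maximum merge ",
         "threshold 250*sqrt(", lengthRange[2], ") = ", round(maxThr, 1))
  set.seed(seed)
  lens <- Biostrings::width(genome)
  margin <- lengthRange[2] + 500
  room <- 2000
  stride <- minSpacing + room
  capacity <- pmax(0L, floor((lens - 2 * margin) / stride))
  if (sum(capacity) < nSites)
    stop("infeasible spacing: genome holds at most ", sum(capacity),
         " sites at spacing ", minSpacing)
  # fill contigs in order
  perChrom <- integer(length(lens))
  left <- nSites
  for (i in seq_along(lens)) {
    perChrom[i] <- min(left, capacity[i])
    left <- left - perChrom[i]
  }
  samples <- sprintf("S%02d", seq_len(nSamples))
  rows <- list(); gts <- list()
  for (i in seq_along(lens)) {
    if (perChrom[i] == 0) next
    for (k in seq_len(perChrom[i])) {
      pos <- as.integer(margin + (k - 1) * stride +
                          sample(seq_len(room), 1))
      tp <- sample(names(typeMix), 1, prob = typeMix)
      len <- sample(seq(lengthRange[1], lengthRange[2]), 1)
      alt <- if (tp == "INS")
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = "") else NA_character_
      repeat {
        g <- sample(names(genotypeFreqs), nSamples, replace = TRUE,
                    prob = genotypeFreqs)
        if (any(g != "0/0")) break
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = names(genome)[i], pos = pos, svType = tp,
        length = as.numeric(len), altSeq = alt, stringsAsFactors = FALSE)
      gts[[length(gts) + 1L]] <- g
    }
  }
  sites <- do.call(rbind, rows)
  gt <- do.call(rbind, gts)
  colnames(gt) <- samples
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites, genotypes = gt[o, , drop = FALSE],
                 samples = samples), class = "svTruth")
}

#' Emit per-sample VCFs from a truth table
#'
#' Writes one Sniffles-dialect VCF per sample containing a record for every
#' site at which that sample's truth genotype is not 0/0. Positions and
#' lengths are perturbed by integer-rounded Gaussian noise (emulating
#' caller/read noise); lengths are clamped at 50 bp so jittered records
#' survive the caller's reporting threshold. Each record is flagged
#' IMPRECISE with probability \code{impreciseRate}. Deletions carry
#' negative SVLEN and an END field; insertions carry their sequence as ALT,
#' trimmed or padded to the jittered length.
#'
#' @param truth An \code{svTruth} from \code{\link{plantCohort}}.
#' @param posJitterSd,lenJitterSd Gaussian jitter SDs in bp (default 0).
#' @param impreciseRate Probability a record is flagged IMPRECISE.
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed.
#' @return Named character vector of VCF paths.
#' @export
emitVcfs <- function(truth, posJitterSd = 0, lenJitterSd = 0,
                     impreciseRate = 0, outDir, seed = 1) {
  if (impreciseRate < 0 || impreciseRate > 1)
    stop("impreciseRate must be in [0, 1]")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  sites <- truth$sites
  paths <- character(0)
  for (s in truth$samples) {
    carry <- which(truth$genotypes[, s] != "0/0")
    calls <- list()
    for (i in carry) {
      pos <- sites$pos[i] +
        as.integer(round(stats::rnorm(1, 0, posJitterSd)))
      len <- max(50, sites$length[i] +
                   as.integer(round(stats::rnorm(1, 0, lenJitterSd))))
      tp <- sites$svType[i]
      alt <- NA_character_
      if (tp == "INS") {
        alt <- sites$altSeq[i]
        if (nchar(alt) > len) alt <- substr(alt, 1, len)
        else if (nchar(alt) < len)
          alt <- paste0(alt, paste(rep("A", len - nchar(alt)),
                                   collapse = ""))
      }
      calls[[length(calls) + 1L]] <- data.frame(
        sampleId = s, chrom = sites$chrom[i], pos = pos, svType = tp,
        length = as.numeric(len),
        end = if (tp %in% c("DEL", "INV", "DUP")) pos + len else pos,
        genotype = truth$genotypes[i, s],
        precise = stats::runif(1) >= impreciseRate,
        altSeq = alt, stringsAsFactors = FALSE)
    }
    df <- if (length(calls)) do.call(rbind, calls) else
      data.frame(sampleId = character(0), chrom = character(0),
                 pos = integer(0), svType = character(0),
                 length = numeric(0), end = integer(0),
                 genotype = character(0), precise = logical(0),
                 altSeq = character(0), stringsAsFactors = FALSE)
    p <- file.path(outDir, paste0(s, ".vcf"))
    writeSampleCalls(df, p, sampleId = s)
    paths[s] <- p
  }
  paths
}

#' Score recovery of planted sites by a merged cohort
#'
#' Matches merged sites to truth sites one-to-one: a pair is eligible when
#' chromosome and SV type agree and the positional difference is at most
#' \code{matchWindow}; eligible pairs are assigned greedily by increasing
#' distance. Recall is matched truth sites over all truth sites; precision
#' is matched merged sites over all merged sites (reported as 1.0 with
#' \code{degenerate = TRUE} when the cohort is empty); genotype accuracy is
#' the fraction of agreeing (matched site x sample) genotype cells.
#'
#' @param truth An \code{svTruth}.
#' @param cohort An \code{\linkS4class{SVCohort}} over the same sample ids.
#' @param matchWindow Maximum positional difference in bp (default 1000).
#' @return List with \code{recall}, \code{precision},
#'   \code{genotypeAccuracy}, \code{nMatched}, \code{degenerate}.
#' @export
scoreRecovery <- function(truth, cohort, matchWindow = 1000) {
  st <- siteTable(cohort)
  nT <- nrow(truth$sites); nC <- nrow(st)
  if (nC == 0) {
    return(list(recall = 0, precision = 1.0, genotypeAccuracy = NA_real_,
                nMatched = 0L, degenerate = TRUE))
  }
  pairs <- list()
  for (i in seq_len(nT)) {
    cand <- which(st$chrom == truth$sites$chrom[i] &
                  st$svType == truth$sites$svType[i] &
                  abs(st$pos - truth$sites$pos[i]) <= matchWindow)
    for (j in cand)
      pairs[[length(pairs) + 1L]] <-
        c(i, j, abs(st$pos[j] - truth$sites$pos[i]))
  }
  matchedT <- rep(FALSE, nT); matchedC <- rep(FALSE, nC)
  tOf <- integer(0); cOf <- integer(0)
  if (length(pairs)) {
    pm <- do.call(rbind, pairs)
    pm <- pm[order(pm[, 3], pm[, 1], pm[, 2]), , drop = FALSE]
    for (r in seq_len(nrow(pm))) {
      i <- pm[r, 1]; j <- pm[r, 2]
      if (!matchedT[i] && !matchedC[j]) {
        matchedT[i] <- TRUE; matchedC[j] <- TRUE
        tOf <- c(tOf, i); cOf <- c(cOf, j)
      }
    }
  }
  acc <- NA_real_
  if (length(tOf)) {
    samples <- intersect(truth$samples, cohortSamples(cohort))
    predicted <- genotypeCalls(cohort)[cOf, samples, drop = FALSE]
    expected <- truth$genotypes[tOf, samples, drop = FALSE]
    acc <- mean(predicted == expected)
  }
  list(recall = sum(matchedT) / nT, precision = sum(matchedC) / nC,
       genotypeAccuracy = acc, nMatched = length(tOf), degenerate = FALSE)
}
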