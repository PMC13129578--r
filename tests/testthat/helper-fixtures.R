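# Shared fixture builders and independent oracles.

# Quick call-table constructor with sensible defaults.
mkCalls <- function(sampleId = "S1", chrom = "chr1", pos, svType = "DEL",
                    length = 100, genotype = "0/1", precise = TRUE,
                    altSeq = NA_character_) {
  n <- base::length(pos)
  rep_n <- function(x) rep(x, length.out = n)
  len <- rep_n(length)
  tp <- rep_n(svType)
  end <- ifelse(tp %in% c("DEL", "INV", "DUP"), pos + len, pos)
  data.frame(sampleId = rep_n(sampleId), chrom = rep_n(chrom),
             pos = as.integer(pos), svType = tp, length = as.numeric(len),
             end = as.integer(end), genotype = rep_n(genotype),
             precise = rep_n(precise), altSeq = rep_n(altSeq),
             stringsAsFactors = FALSE)
}

mkGenome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

writeFasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(seqs), function(n) c(paste0(">", n), seqs[[n]])))
  writeLines(lines, path)
  path
}

mkTrack <- function(chrom, geneId, start, end, annotation = NULL) {
  tr <- data.frame(chrom = chrom, geneId = geneId,
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    tr$product <- annotation
    attr(tr, "annotationHeaders") <- "product"
  } else attr(tr, "annotationHeaders") <- character(0)
  tr[order(tr$chrom, tr$start), , drop = FALSE]
}

# Independent clustering oracle: connected components (union-find) of the
# graph whose edges are sorted-adjacent call pairs within threshold.
oracleClusters <- function(calls, M = 250) {
  o <- order(calls$pos, calls$sampleId,
             ifelse(is.na(calls$length), 0, calls$length))
  calls <- calls[o, , drop = FALSE]
  n <- nrow(calls)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) for (i in seq_len(n - 1)) {
    la <- calls$length[i]; lb <- calls$length[i + 1]
    thr <- if (is.na(la) || is.na(lb)) M else M * sqrt(min(la, lb))
    if (abs(calls$pos[i + 1] - calls$pos[i]) <= thr)
      parent[findRoot(i + 1)] <- findRoot(i)
  }
  comp <- vapply(seq_len(n), findRoot, integer(1))
  unname(split(calls$pos, comp))
}

# Partition signature that ignores cluster order: sorted list of sorted
# member-position vectors.
clusterSignature <- function(clusters) {
  sig <- lapply(clusters, function(cl)
    sort(if (is.data.frame(cl)) cl$pos else cl))
  unname(sig[order(vapply(sig, min, numeric(1)))])
}

# Brute-force site-vs-gene classification by direct interval arithmetic.
oracleClassify <- function(site, track, U = 2000) {
  iv <- if (site$svType %in% c("DEL", "INV", "DUP")) c(site$pos, site$end)
        else c(site$pos, site$pos)
  tr <- track[track$chrom == site$chrom, , drop = FALSE]
  res <- list()
  for (j in seq_len(nrow(tr))) {
    g1 <- tr$start[j] + 1; g2 <- tr$end[j]       # 1-based gene body
    genic <- iv[2] >= g1 && iv[1] <= g2
    if (genic) { res[[length(res) + 1]] <- c(tr$geneId[j], "genic"); next }
    prior <- tr$end[tr$end <= tr$start[j] & tr$geneId != tr$geneId[j]]
    lo <- max(c(tr$start[j] - U, 0, prior))
    if (lo < tr$start[j] && iv[2] >= lo + 1 && iv[1] <= tr$start[j])
      res[[length(res) + 1]] <- c(tr$geneId[j], "upstream")
  }
  if (!length(res)) return(data.frame(geneId = character(0),
                                      region = character(0)))
  m <- do.call(rbind, res)
  out <- data.frame(geneId = m[, 1], region = m[, 2],
                    stringsAsFactors = FALSE)
  out[order(out$geneId, out$region), , drop = FALSE]
}

# One small merged cohort with known structure, reused across tests.
toyCohort <- function() {
  cs <- list(
    A = rbind(mkCalls("A", "chr1", c(1000, 60000), "DEL", c(100, 200),
                      genotype = c("0/1", "1/1")),
              mkCalls("A", "chr2", 5000, "INS", 80, genotype = "0/1",
                      altSeq = strrep("A", 80))),
    B = rbind(mkCalls("B", "chr1", c(1001, 60001), "DEL", c(100, 200),
                      genotype = c("1/1", "0/1"))),
    C = mkCalls("C", "chr1", 120000, "INV", 300, genotype = "0/1")
  )
  mergeCohort(cs)
}
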