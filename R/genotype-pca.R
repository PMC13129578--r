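#' Encode cohort genotypes as a 0/1/2 matrix
#'
#' Deterministic dosage-style encoding of the genotype calls: 0/0 (no SV)
#' becomes 0, 0/1 (heterozygous) 1, and 1/1 (homozygous) 2. Rows are samples
#' in manifest order; columns are sites in (chrom, pos) order, keyed
#' \code{"chrom-pos-type"}.
#'
#' @param cohort An \code{\linkS4class{SVCohort}} with at least one site.
#' @return Integer matrix (samples x sites).
#' @export
encodeGenotypes <- function(cohort) {
  if (nSites(cohort) == 0) stop("empty cohort")
  st <- siteTable(cohort)
  gt <- genotypeCalls(cohort)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/1" = 2L)
  m <- matrix(code[gt], nrow = nrow(gt), ncol = ncol(gt))
  m <- t(m)
  dimnames(m) <- list(cohortSamples(cohort),
                      paste(st$chrom, st$pos, st$svType, sep = "-"))
  m
}

#' PCA of the genotype matrix
#'
#' Centered, unit-variance principal component analysis of the 0/1/2
#' genotype matrix (via \code{\link[stats]{prcomp}}, i.e. singular-value
#' decomposition of the standardized matrix), for visualizing sample
#' relatedness. Zero-variance sites are dropped before scaling -- unit
#' scaling is undefined for constant columns -- and their number is
#' reported. Component signs are arbitrary, as for any PCA.
#'
#' @param m Integer matrix from \code{\link{encodeGenotypes}} (samples x
#'   sites), or an \code{SVCohort}.
#' @param center,scale Passed to \code{prcomp} (both default TRUE).
#' @return An object of class \code{svPca}: list with \code{scores}
#'   (samples x components), \code{loadings}, \code{explained}
#'   (per-component fraction of total variance, non-increasing),
#'   \code{nDroppedSites}.
#' @export
runGenotypePca <- function(m, center = TRUE, scale = TRUE) {
  if (is(m, "SVCohort")) m <- encodeGenotypes(m)
  if (nrow(m) < 2) stop("PCA requires at least 2 samples")
  v <- apply(m, 2, stats::var)
  keep <- v > 0
  nDropped <- sum(!keep)
  if (!any(keep)) stop("all sites are constant across samples")
  pr <- stats::prcomp(m[, keep, drop = FALSE], center = center,
                      scale. = scale)
  structure(list(
    scores = pr$x,
    loadings = pr$rotation,
    explained = pr$sdev^2 / sum(pr$sdev^2),
    nDroppedSites = nDropped
  ), class = "svPca")
}

#' @export
print.svPca <- function(x, ...) {
  cat("Genotype PCA:", nrow(x$scores), "samples,",
      ncol(x$scores), "components\n")
  cat("  explained (first 5):",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$explained, 5)),
             collapse = " "), "\n")
  cat("  constant sites dropped:", x$nDroppedSites, "\n")
  invisible(x)
}

#' Scatter plot of the first two principal components
#'
#' @param pca An \code{svPca} result.
#' @param path Output PNG path.
#' @return \code{path}, invisibly.
#' @export
plotPcaScores <- function(pca, path) {
  grDevices::png(path, width = 800, height = 800)
  on.exit(grDevices::dev.off())
  sc <- pca$scores
  plot(sc[, 1], sc[, 2],
       xlab = sprintf("PC1 (%.1f%%)", 100 * pca$explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * pca$explained[2]),
       pch = 19, col = "steelblue")
  graphics::text(sc[, 1], sc[, 2], labels = rownames(sc), pos = 3, cex = 0.8)
  invisible(path)
}
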