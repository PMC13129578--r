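#' Build the genotype-map matrix for one chromosome
#'
#' Lays out one row per merged site on the chromosome plus scaffold rows at
#' position 0, at every \code{scaffoldInterval}, and at the chromosome end,
#' so chromosomes render at a uniform physical scale. Cells hold one of four
#' categories: \code{no_sv} (0/0), \code{het} (0/1), \code{hom} (1/1), or
#' \code{scaffold} for the spacer rows (identical across samples). A
#' scaffold point coinciding with a site position keeps only the site row.
#'
#' @param cohort An \code{\linkS4class{SVCohort}}.
#' @param chrom Chromosome to render.
#' @param chromLength Chromosome length in bp (> 0).
#' @param scaffoldInterval Spacer interval in bp (default 50000).
#' @return An object of class \code{svPlotMatrix}: list with
#'   \code{positions} (sorted bp), \code{samples}, and \code{cells}
#'   (character matrix, rows x samples).
#' @export
buildPlotMatrix <- function(cohort, chrom, chromLength,
                            scaffoldInterval = 50000) {
  if (chromLength <= 0) stop("chromLength must be positive")
  st <- siteTable(cohort)
  gt <- genotypeCalls(cohort)
  samples <- cohortSamples(cohort)
  onChrom <- which(st$chrom == chrom)
  sitePos <- st$pos[onChrom]
  scaffold <- unique(c(seq(0, chromLength, by = scaffoldInterval),
                       chromLength))
  scaffold <- setdiff(scaffold, sitePos)
  pos <- c(sitePos, scaffold)
  kind <- c(rep("site", length(sitePos)), rep("scaffold", length(scaffold)))
  rowIdx <- c(onChrom, rep(NA_integer_, length(scaffold)))
  o <- order(pos)
  pos <- pos[o]; kind <- kind[o]; rowIdx <- rowIdx[o]
  cellOf <- c("0/0" = "no_sv", "0/1" = "het", "1/1" = "hom")
  cells <- matrix("scaffold", nrow = length(pos), ncol = length(samples),
                  dimnames = list(NULL, samples))
  isSite <- kind == "site"
  if (any(isSite))
    cells[isSite, ] <- matrix(cellOf[gt[rowIdx[isSite], , drop = FALSE]],
                              nrow = sum(isSite))
  structure(list(positions = pos, samples = samples, cells = cells),
            class = "svPlotMatrix")
}

.mapColors <- c(no_sv = "#00008B", het = "#228B22", hom = "#FFD700",
                scaffold = "#D3D3D3")

#' Render the genotype map
#'
#' Writes the per-chromosome genotype map as an image: the Y axis runs along
#' the chromosome in ascending position (one pixel row per matrix row), the
#' X axis holds samples in manifest order, and cells are colored dark blue
#' for 0/0 (SV seen in other samples only), green for heterozygous, yellow
#' for homozygous. Scaffold rows render light grey by default so "no site
#' here" is visually distinct from "no SV at a detected site"; set
#' \code{scaffoldDistinct = FALSE} to blend them into the 0/0 color. PNG
#' (written pixel-exactly, hence byte-deterministic) or SVG is chosen by the
#' file extension. The input matrix is never modified.
#'
#' @param pm An \code{svPlotMatrix} from \code{\link{buildPlotMatrix}}.
#' @param path Output path ending in \code{.png} or \code{.svg}.
#' @param cellWidth Pixel width per sample column (default 24).
#' @param cellHeight Pixel height per row (default 2).
#' @param scaffoldDistinct Render scaffold rows grey (default TRUE).
#' @return \code{path}, invisibly.
#' @export
renderGenotypeMap <- function(pm, path, cellWidth = 24, cellHeight = 2,
                              scaffoldDistinct = TRUE) {
  if (!length(pm$positions)) stop("empty plot matrix")
  cols <- .mapColors
  if (!scaffoldDistinct) cols["scaffold"] <- cols["no_sv"]
  nr <- nrow(pm$cells); ns <- ncol(pm$cells)
  ext <- tolower(tools::file_ext(path))
  if (ext == "svg") {
    rect <- character(0)
    for (i in seq_len(nr)) for (j in seq_len(ns))
      rect <- c(rect, sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
        (j - 1L) * cellWidth, (nr - i) * cellHeight, cellWidth, cellHeight,
        cols[pm$cells[i, j]]))
    svg <- c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
      ns * cellWidth, nr * cellHeight), rect, "</svg>")
    writeLines(svg, path)
    return(invisible(path))
  }
  rgbOf <- grDevices::col2rgb(cols) / 255
  img <- array(0, dim = c(nr, ns, 3))
  for (k in names(cols)) {
    hit <- pm$cells == k
    if (!any(hit)) next
    for (d in 1:3) {
      plane <- img[, , d]
      plane[hit] <- rgbOf[d, k]
      img[, , d] <- plane
    }
  }
  # ascending position bottom-to-top; expand to cell size
  img <- img[rev(seq_len(nr)), , , drop = FALSE]
  img <- img[rep(seq_len(nr), each = cellHeight),
             rep(seq_len(ns), each = cellWidth), , drop = FALSE]
  png::writePNG(img, path)
  invisible(path)
}
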