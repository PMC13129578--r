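#' Run the full SV-integration pipeline
#'
#' End-to-end driver: read per-sample VCFs, merge calls into cohort sites,
#' filter low-confidence sites, attach reference flanks, and write the
#' cohort SV table plus summary reports. When a gene track is supplied the
#' gene-annotated table is written as well (gene annotation is opt-in).
#' Progress and the effective parameters are echoed to standard error.
#'
#' @param vcfPaths Named character vector: sample id -> VCF path.
#' @param referencePath Reference FASTA path.
#' @param outDir Output directory (created if needed).
#' @param genePath Optional BED-like gene track path.
#' @param M Merge constant (default 250).
#' @param flank Flank length in bp (default 300).
#' @param upstreamLen Upstream window in bp (default 2000).
#' @param maxStdevPos,maxStdevLen Filter thresholds in bp (default 1.0).
#' @param dropImprecise Drop imprecise sites (default TRUE).
#' @param minSvLength Minimum SV length in bp (default 50).
#' @return Invisibly, a list with the filtered \code{SVCohort}, the filter
#'   report, and the paths of all files written.
#' @export
runPipeline <- function(vcfPaths, referencePath, outDir, genePath = NULL,
                        M = 250, flank = 300, upstreamLen = 2000,
                        maxStdevPos = 1.0, maxStdevLen = 1.0,
                        dropImprecise = TRUE, minSvLength = 50) {
  if (is.null(names(vcfPaths)) || any(!nzchar(names(vcfPaths))))
    stop("vcfPaths must be named by sample id")
  missing <- c(vcfPaths[!file.exists(vcfPaths)],
               referencePath[!file.exists(referencePath)],
               if (!is.null(genePath)) genePath[!file.exists(genePath)])
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  message("parameters: M=", M, " flank=", flank,
          " upstream=", upstreamLen, " maxStdevPos=", maxStdevPos,
          " maxStdevLen=", maxStdevLen, " minSvLength=", minSvLength)
  message("reading reference: ", referencePath)
  genome <- readReference(referencePath)
  message("reading ", length(vcfPaths), " sample VCF(s)")
  callsets <- lapply(names(vcfPaths), function(s)
    readSampleCalls(vcfPaths[[s]], s, minLength = minSvLength))
  names(callsets) <- names(vcfPaths)
  message("merging (M = ", M, ")")
  cohort <- mergeCohort(callsets, M = M)
  message("merged sites: ", nSites(cohort))
  fr <- filterSites(cohort, maxStdevPos = maxStdevPos,
                    maxStdevLen = maxStdevLen,
                    dropImprecise = dropImprecise, minLength = minSvLength)
  cohort <- fr$cohort
  message("sites after filtering: ", nSites(cohort))
  cohort <- attachSequences(cohort, genome, flank = flank)
  paths <- c(cohortTable = file.path(outDir, "sv_cohort_table.tsv"))
  writeCohortTable(cohort, paths[["cohortTable"]])
  if (!is.null(genePath)) {
    track <- readGeneTrack(genePath)
    paths["geneTable"] <- file.path(outDir, "sv_gene_table.tsv")
    writeGeneTable(cohort, track, paths[["geneTable"]], U = upstreamLen)
  }
  paths["chromSummary"] <- file.path(outDir, "chromosome_summary.tsv")
  utils::write.table(chromosomeSummary(cohort, genome),
                     paths[["chromSummary"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["sampleSummary"] <- file.path(outDir, "sample_summary.tsv")
  utils::write.table(sampleSummary(cohort), paths[["sampleSummary"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  paths["lengthHistogram"] <- file.path(outDir, "length_histogram.tsv")
  utils::write.table(lengthHistogram(cohort), paths[["lengthHistogram"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", length(paths), " output file(s) to ", outDir)
  invisible(list(cohort = cohort, report = fr$report, paths = paths))
}
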