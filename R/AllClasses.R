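#' @import methods
NULL

GT_LEVELS <- c("0/0", "0/1", "1/1")
SV_TYPES <- c("INS", "DEL", "INV", "DUP", "BND")

.emptySites <- function() {
  data.frame(
    chrom = character(0), pos = integer(0), svType = character(0),
    length = numeric(0), end = integer(0),
    stdevPos = numeric(0), stdevLen = numeric(0), precise = logical(0),
    svSeq = character(0), upstreamSeq = character(0),
    downstreamSeq = character(0),
    stringsAsFactors = FALSE
  )
}

#' SVCohort: merged structural variants across a sample cohort
#'
#' An \code{SVCohort} holds the result of integrating per-sample structural
#' variant (SV) calls into cohort-level merged sites: one row per reference
#' position at which the same SV was observed in one or more samples, with a
#' genotype (\code{0/0}, \code{0/1} or \code{1/1}) for every cohort sample at
#' every site.
#'
#' @slot samples Character vector of sample identifiers, in manifest order.
#' @slot sites \code{data.frame} with one row per merged site, sorted by
#'   (chrom, pos): columns \code{chrom}, \code{pos} (1-based representative
#'   position), \code{svType} (INS/DEL/INV/DUP/BND), \code{length}
#'   (representative length in bp, \code{NA} for BND), \code{end},
#'   \code{stdevPos}/\code{stdevLen} (population standard deviation of member
#'   positions/lengths), \code{precise} (all members precise), and the
#'   sequence columns \code{svSeq}, \code{upstreamSeq}, \code{downstreamSeq}
#'   (\code{NA} until \code{\link{attachSequences}} is called).
#' @slot genotypes Character matrix (sites x samples) of genotype codes.
#' @slot members List (one element per site) of \code{data.frame}s holding the
#'   constituent per-sample calls of each merged site.
#' @slot mergeM Numeric merge constant used to build the cohort (default 250).
#'
#' @seealso \code{\link{mergeCohort}}, \code{\link{filterSites}},
#'   \code{\link{attachSequences}}, \code{\link{writeCohortTable}}
#' @export
setClass("SVCohort", representation(
  samples = "character",
  sites = "data.frame",
  genotypes = "matrix",
  members = "list",
  mergeM = "numeric"
))

setValidity("SVCohort", function(object) {
  msg <- character(0)
  s <- object@samples
  if (anyDuplicated(s)) msg <- c(msg, "duplicate sample ids")
  if (any(!nzchar(s))) msg <- c(msg, "empty sample id")
  st <- object@sites
  need <- c("chrom", "pos", "svType", "length", "end", "stdevPos",
            "stdevLen", "precise", "svSeq", "upstreamSeq", "downstreamSeq")
  if (!all(need %in% names(st)))
    msg <- c(msg, "sites is missing required columns")
  else {
    if (nrow(st) > 0) {
      o <- order(st$chrom, st$pos)
      if (!identical(o, seq_len(nrow(st))))
        msg <- c(msg, "sites must be sorted by (chrom, pos)")
      if (!all(st$svType %in% SV_TYPES))
        msg <- c(msg, "unknown svType")
      if (any(st$stdevPos < 0, na.rm = TRUE) ||
          any(st$stdevLen < 0, na.rm = TRUE))
        msg <- c(msg, "negative dispersion")
    }
    if (nrow(object@genotypes) != nrow(st) ||
        ncol(object@genotypes) != length(s))
      msg <- c(msg, "genotype matrix dimensions do not match sites/samples")
    else if (length(object@genotypes) &&
             !all(object@genotypes %in% GT_LEVELS))
      msg <- c(msg, "genotypes must be 0/0, 0/1 or 1/1")
    if (length(object@members) != nrow(st))
      msg <- c(msg, "members list length does not match site count")
  }
  if (length(object@mergeM) != 1 || object@mergeM < 0)
    msg <- c(msg, "mergeM must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

newSVCohort <- function(samples, sites, genotypes, members, mergeM = 250) {
  new("SVCohort", samples = samples, sites = sites,
      genotypes = genotypes, members = members, mergeM = mergeM)
}

#' @describeIn SVCohort-accessors Number of merged sites.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @describeIn SVCohort-accessors Sample identifiers, in manifest order.
#' @export
setGeneric("cohortSamples", function(x) standardGeneric("cohortSamples"))

#' @describeIn SVCohort-accessors Site table (\code{data.frame}).
#' @export
setGeneric("siteTable", function(x) standardGeneric("siteTable"))

#' @describeIn SVCohort-accessors Genotype matrix (sites x samples).
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @describeIn SVCohort-accessors Constituent calls per site (list of
#'   \code{data.frame}s).
#' @export
setGeneric("siteMembers", function(x) standardGeneric("siteMembers"))

#' @describeIn SVCohort-accessors Merge constant M used to build the cohort.
#' @export
setGeneric("mergeConstant", function(x) standardGeneric("mergeConstant"))

#' Accessors for SVCohort objects
#'
#' Slot access for \code{\linkS4class{SVCohort}} goes through these accessors.
#'
#' @param x An \code{SVCohort}.
#' @return See the individual descriptions.
#' @name SVCohort-accessors
NULL

#' @rdname SVCohort-accessors
#' @export
setMethod("nSites", "SVCohort", function(x) nrow(x@sites))

#' @rdname SVCohort-accessors
#' @export
setMethod("cohortSamples", "SVCohort", function(x) x@samples)

#' @rdname SVCohort-accessors
#' @export
setMethod("siteTable", "SVCohort", function(x) x@sites)

#' @rdname SVCohort-accessors
#' @export
setMethod("genotypeCalls", "SVCohort", function(x) x@genotypes)

#' @rdname SVCohort-accessors
#' @export
setMethod("siteMembers", "SVCohort", function(x) x@members)

#' @rdname SVCohort-accessors
#' @export
setMethod("mergeConstant", "SVCohort", function(x) x@mergeM)

#' Subset an SVCohort by site
#'
#' @param x An \code{SVCohort}.
#' @param i Site indices (numeric or logical).
#' @param j,drop,... Ignored; sites are the only subsettable dimension.
#' @return An \code{SVCohort} restricted to the selected sites, order
#'   preserved.
#' @export
setMethod("[", "SVCohort", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) return(x)
  if (is.logical(i)) i <- which(i)
  st <- x@sites[i, , drop = FALSE]
  rownames(st) <- NULL
  gt <- x@genotypes[i, , drop = FALSE]
  newSVCohort(x@samples, st, gt, x@members[i], x@mergeM)
})

setMethod("show", "SVCohort", function(object) {
  st <- object@sites
  cat("SVCohort with", nrow(st), "merged sites across",
      length(object@samples), "samples\n")
  if (nrow(st)) {
    tt <- table(st$svType)
    cat("  types:", paste(names(tt), tt, sep = ":", collapse = " "), "\n")
    cat("  chroms:", paste(unique(st$chrom), collapse = ", "), "\n")
    cat("  sequences attached:",
        if (all(is.na(st$upstreamSeq))) "no" else "yes", "\n")
  }
  cat("  merge constant M =", object@mergeM, "\n")
})
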