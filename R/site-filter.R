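#' Filter low-confidence merged sites
#'
#' Removes a merged site when any of these criteria holds: (1) the standard
#' deviation of member positions is \code{maxStdevPos} or more, (2) the
#' standard deviation of member lengths is \code{maxStdevLen} or more,
#' (3) the site is flagged imprecise (when \code{dropImprecise}), or (4) the
#' representative length of a non-BND site fell below \code{minLength} after
#' merging. Thresholds are inclusive ("one or more" removes at exactly 1.0).
#' Each removed site is attributed to the first failing rule in the order
#' above, so the report's counts always sum to the input site count.
#'
#' @param cohort An \code{\linkS4class{SVCohort}}.
#' @param maxStdevPos,maxStdevLen Dispersion thresholds in bp (default 1.0).
#' @param dropImprecise Drop sites not flagged precise (default TRUE).
#' @param minLength Minimum representative length in bp for non-BND sites
#'   (default 50).
#' @return A list with elements \code{cohort} (the surviving sites, order
#'   preserved) and \code{report} (an \code{svFilterReport} with counts
#'   \code{kept}, \code{removedStdevPos}, \code{removedStdevLen},
#'   \code{removedImprecise}, \code{removedShort}).
#' @export
filterSites <- function(cohort, maxStdevPos = 1.0, maxStdevLen = 1.0,
                        dropImprecise = TRUE, minLength = 50) {
  if (maxStdevPos < 0 || maxStdevLen < 0 || minLength < 0)
    stop("thresholds must be non-negative")
  st <- siteTable(cohort)
  failPos <- st$stdevPos >= maxStdevPos
  failLen <- st$stdevLen >= maxStdevLen
  failImp <- if (dropImprecise) !st$precise else rep(FALSE, nrow(st))
  failShort <- st$svType != "BND" & !is.na(st$length) & st$length < minLength
  rule <- rep(0L, nrow(st))
  rule[failShort] <- 4L
  rule[failImp] <- 3L
  rule[failLen] <- 2L
  rule[failPos] <- 1L
  kept <- rule == 0L
  report <- structure(list(
    kept = sum(kept),
    removedStdevPos = sum(rule == 1L),
    removedStdevLen = sum(rule == 2L),
    removedImprecise = sum(rule == 3L),
    removedShort = sum(rule == 4L)
  ), class = "svFilterReport")
  list(cohort = cohort[kept], report = report)
}

#' @export
print.svFilterReport <- function(x, ...) {
  cat("SV site filter report\n")
  cat("  kept:               ", x$kept, "\n")
  cat("  removed (stdev pos):", x$removedStdevPos, "\n")
  cat("  removed (stdev len):", x$removedStdevLen, "\n")
  cat("  removed (imprecise):", x$removedImprecise, "\n")
  cat("  removed (short):    ", x$removedShort, "\n")
  invisible(x)
}
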