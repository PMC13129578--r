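test_that("chromosome summaries count sites, densities and 3-genotype sites", {
  co <- toyCohort()
  lens <- c(chr1 = 1e6, chr2 = 2e6)
  cs <- chromosomeSummary(co, lens)
  expect_equal(cs$nSites[cs$chrom == "chr1"], 3)
  expect_equal(cs$nSites[cs$chrom == "chr2"], 1)
  expect_equal(cs$density[cs$chrom == "chr1"], 3)
  tot <- cs[cs$chrom == "Total", ]
  expect_equal(tot$nSites, 4)
  expect_equal(tot$density, svDensity(4, 3e6))
  # both chr1 DEL sites carry {0/1, 1/1, 0/0} across A, B, C
  expect_equal(tot$nThreeGenotype, 2)
  expect_error(chromosomeSummary(co, c(chrX = 100)), "unknown chromosome")
})

test_that("three-genotype sites require all of 0/0, 0/1 and 1/1", {
  co <- mergeCohort(list(
    A = mkCalls("A", pos = c(1e5, 2e5), genotype = c("0/1", "0/1")),
    B = mkCalls("B", pos = c(1e5 + 1, 2e5 + 1), genotype = c("1/1", "1/1")),
    C = mkCalls("C", pos = 1e5 + 2, genotype = "0/1")))
  cs <- chromosomeSummary(co, c(chr1 = 1e6))
  # site 1 sees {0/1,1/1,0/1}: every sample is a member, so no 0/0 and it
  # does not count; site 2 sees {0/1,1/1,0/0} (C absent) and counts
  expect_equal(cs$nThreeGenotype[cs$chrom == "chr1"], 1)
})

test_that("per-sample tallies respect the zygosity identity", {
  co <- toyCohort()
  ss <- sampleSummary(co)
  a <- ss[ss$sampleId == "A", ]
  expect_equal(a$total, 3)
  expect_equal(a$nHom + a$nHet, a$total)
  expect_equal(a$DEL, 2); expect_equal(a$INS, 1)
  # brute-force recount on a random synthetic cohort
  set.seed(91)
  g <- simulateReference(2, 400000, seed = 91)
  truth <- plantCohort(g, nSites = 12, nSamples = 6, seed = 92)
  paths <- emitVcfs(truth, outDir = file.path(tempdir(), "ss"), seed = 93)
  cs <- lapply(names(paths), function(s) readSampleCalls(paths[[s]], s))
  names(cs) <- names(paths)
  co2 <- mergeCohort(cs)
  ss2 <- sampleSummary(co2)
  gt <- genotypeCalls(co2)
  st <- siteTable(co2)
  for (i in seq_len(nrow(ss2))) {
    s <- ss2$sampleId[i]
    expect_equal(ss2$total[i], sum(gt[, s] != "0/0"))
    expect_equal(ss2$nHom[i], sum(gt[, s] == "1/1"))
    typeSum <- sum(vapply(c("DEL", "INS", "BND", "INV", "DUP"),
                          function(tp) ss2[[tp]][i], numeric(1)))
    expect_equal(typeSum, ss2$total[i])
  }
})

test_that("hom/het ratio handles typical and degenerate inputs", {
  expect_equal(homHetRatio(158, 6048), 0.026, tolerance = 0.02)
  expect_equal(homHetRatio(0, 10), 0)
  expect_error(homHetRatio(5, 0), "zero")
})

test_that("length histogram bins half-open with closed last bin + overflow", {
  h <- lengthHistogram(c(50, 99, 100, 9999, 10000, 10001, 25000))
  expect_equal(h$count[h$binStart == 50], 2)
  expect_equal(h$count[h$binStart == 100], 1)
  # 10000 falls in the last regular (closed) bin, not the overflow
  expect_equal(h$count[h$binStart == 9950], 2)
  expect_equal(h$count[is.infinite(h$binEnd)], 2)
  expect_equal(sum(h$count), 7)
  expect_error(lengthHistogram(c(100), binWidth = 0), "positive")
})

test_that("BND sites are excluded from the length histogram", {
  co <- mergeCohort(list(A = mkCalls("A", pos = c(1e5, 2e5, 3e5),
                                     svType = "BND", length = NA)))
  h <- lengthHistogram(co)
  expect_equal(sum(h$count), 0)
  # histogram counts sum to length-defined site count in general
  co2 <- toyCohort()
  expect_equal(sum(lengthHistogram(co2)$count),
               sum(!is.na(siteTable(co2)$length)))
})

test_that("type proportions are fractions over all sites", {
  co <- toyCohort()
  p <- typeProportions(co)
  expect_equal(unname(p["DEL"]), 0.5)
  expect_equal(sum(p), 1)
  single <- mergeCohort(list(A = mkCalls("A", pos = 1e5)))
  expect_equal(unname(typeProportions(single)["DEL"]), 1)
  # count interface with an explicit total (BND contribute to the total)
  expect_equal(unname(typeProportions(c(DEL = 25), total = 100)["DEL"]),
               0.25)
})

test_that("marker candidates demand type, length and three genotypes", {
  cs <- list(
    A = mkCalls("A", pos = c(1e5, 2e5, 3e5, 4e5),
                svType = c("DEL", "INS", "DEL", "INV"),
                length = c(63, 1001, 80, 100),
                genotype = c("0/1", "0/1", "1/1", "0/1"),
                altSeq = c(NA, strrep("A", 1001), NA, NA)),
    B = mkCalls("B", pos = c(1e5 + 1, 2e5 + 1, 4e5 + 1),
                svType = c("DEL", "INS", "INV"),
                length = c(63, 1001, 100),
                genotype = c("1/1", "1/1", "1/1")),
    C = mkCalls("C", pos = integer(0)))
  co <- mergeCohort(cs)
  cand <- selectMarkerCandidates(co)
  st <- siteTable(cand)
  # DEL len 63 with {0/1,1/1,0/0}: kept; INS len 1001: too long;
  # DEL len 80 {1/1,0/0,0/0}: only two genotypes; INV: wrong type
  expect_equal(nSites(cand), 1)
  expect_equal(st$length, 63)
  # the reference-sample rule removes homozygous-alt sites
  co2 <- mergeCohort(list(
    A = mkCalls("A", pos = 1e5, length = 63, genotype = "1/1"),
    B = mkCalls("B", pos = 1e5 + 1, length = 63, genotype = "0/1"),
    C = mkCalls("C", pos = integer(0))))
  expect_equal(nSites(selectMarkerCandidates(co2)), 1)
  expect_equal(nSites(selectMarkerCandidates(co2, referenceSample = "A")), 0)
  expect_error(selectMarkerCandidates(co2, referenceSample = "Z"),
               "unknown reference sample")
})

test_that("genotype concordance counts per-marker agreement symmetrically", {
  p <- matrix(c("0/0", "0/1", "1/1", "0/0"), 2, 2,
              dimnames = list(c("m1", "m2"), c("s1", "s2")))
  o <- p; o["m2", "s2"] <- "0/1"
  cc <- genotypeConcordance(p, o)
  expect_equal(unname(cc$perMarker), c(1, 0.5))
  expect_equal(cc$mean, 0.75)
  expect_equal(cc$mismatches$marker, "m2")
  # symmetry and identity
  expect_equal(genotypeConcordance(o, p)$mean, cc$mean)
  expect_equal(genotypeConcordance(p, p)$mean, 1)
  expect_error(genotypeConcordance(p, o[1, , drop = FALSE]), "dimensions")
})
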