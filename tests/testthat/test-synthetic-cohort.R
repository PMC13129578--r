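test_that("reference simulation is seeded and well-formed", {
  fa1 <- tempfile(fileext = ".fa"); fa2 <- tempfile(fileext = ".fa")
  g1 <- simulateReference(2, 10000, seed = 101, path = fa1)
  g2 <- simulateReference(2, 10000, seed = 101, path = fa2)
  expect_equal(length(g1), 2)
  expect_equal(unname(Biostrings::width(g1)), c(10000L, 10000L))
  expect_identical(as.character(g1), as.character(g2))
  expect_identical(unname(tools::md5sum(fa1)), unname(tools::md5sum(fa2)))
  g3 <- simulateReference(2, 10000, seed = 102)
  expect_false(identical(as.character(g1), as.character(g3)))
  expect_error(simulateReference(1, 0, seed = 1), "positive")
})

test_that("simulated gene tracks are sorted, gapped and non-overlapping", {
  g <- simulateReference(2, 200000, seed = 103)
  tr <- simulateGeneTrack(g, 20, minGap = 200, seed = 104)
  expect_equal(nrow(tr), 20)
  for (ch in unique(tr$chrom)) {
    sub <- tr[tr$chrom == ch, ]
    expect_false(is.unsorted(sub$start))
    if (nrow(sub) > 1)
      expect_true(all(sub$start[-1] - sub$end[-nrow(sub)] >= 200))
  }
  # some inter-gene gaps fall below the default upstream window
  gaps <- unlist(lapply(unique(tr$chrom), function(ch) {
    sub <- tr[tr$chrom == ch, ]
    if (nrow(sub) > 1) sub$start[-1] - sub$end[-nrow(sub)] else numeric(0)
  }))
  expect_true(any(gaps < 2000))
  expect_identical(simulateGeneTrack(g, 20, seed = 104)$start, tr$start)
  expect_error(simulateGeneTrack(g, 5000, seed = 1), "infeasible")
})

test_that("planted truth respects spacing, forcing and genotype frequencies", {
  g <- simulateReference(4, 700000, seed = 105)
  truth <- plantCohort(g, nSites = 40, nSamples = 8, seed = 106)
  expect_equal(nrow(truth$sites), 40)
  for (ch in unique(truth$sites$chrom)) {
    p <- truth$sites$pos[truth$sites$chrom == ch]
    if (length(p) > 1) expect_true(all(diff(sort(p)) >= 50000))
  }
  # every site carries at least one non-0/0 sample
  expect_true(all(apply(truth$genotypes, 1, function(g) any(g != "0/0"))))
  # spacing guard refuses identifiability-breaking parameters
  expect_error(plantCohort(g, nSites = 5, nSamples = 2, minSpacing = 1000,
                           seed = 1), "exceed")
  # genotype frequencies recovered within 3-sigma binomial bounds
  big <- plantCohort(simulateReference(8, 800000, seed = 107),
                     nSites = 100, nSamples = 10, seed = 108)
  draws <- as.vector(big$genotypes)
  n <- length(draws)
  for (gtype in c("0/1", "1/1")) {
    pExp <- c("0/1" = 0.4, "1/1" = 0.2)[[gtype]]
    se <- sqrt(pExp * (1 - pExp) / n)
    expect_lt(abs(mean(draws == gtype) - pExp), 3 * se + 0.02)
  }
})

test_that("emitted VCFs mirror truth exactly at zero jitter", {
  g <- simulateReference(2, 500000, seed = 111)
  truth <- plantCohort(g, nSites = 16, nSamples = 4, seed = 112)
  vd <- file.path(tempdir(), "emit0")
  paths <- emitVcfs(truth, posJitterSd = 0, lenJitterSd = 0,
                    impreciseRate = 0, outDir = vd, seed = 113)
  expect_length(paths, 4)
  for (s in truth$samples) {
    calls <- readSampleCalls(paths[[s]], s)
    carry <- truth$genotypes[, s] != "0/0"
    expect_equal(nrow(calls), sum(carry))
    o <- order(truth$sites$chrom[carry], truth$sites$pos[carry])
    expect_equal(calls$pos, truth$sites$pos[carry][o])
    expect_equal(calls$length, truth$sites$length[carry][o])
    expect_true(all(calls$precise))
  }
  # the deletion dialect rule: negative SVLEN plus END in the file text
  lines <- unlist(lapply(paths, readLines))
  delLines <- lines[grepl("SVTYPE=DEL", lines)]
  expect_true(all(grepl("SVLEN=-", delLines)))
  expect_true(all(grepl("END=", delLines)))
  # determinism down to file bytes
  vd2 <- file.path(tempdir(), "emit0b")
  paths2 <- emitVcfs(truth, outDir = vd2, seed = 113)
  expect_identical(unname(tools::md5sum(paths[1])),
                   unname(tools::md5sum(paths2[1])))
  expect_error(emitVcfs(truth, impreciseRate = 2, outDir = vd), "\\[0, 1\\]")
})

test_that("recovery scoring matches truth one-to-one with conventions", {
  g <- simulateReference(2, 500000, seed = 121)
  truth <- plantCohort(g, nSites = 10, nSamples = 3, seed = 122)
  paths <- emitVcfs(truth, outDir = file.path(tempdir(), "rec"), seed = 123)
  cs <- lapply(names(paths), function(s) readSampleCalls(paths[[s]], s))
  names(cs) <- names(paths)
  co <- mergeCohort(cs)
  sc <- scoreRecovery(truth, co)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)
  expect_equal(sc$genotypeAccuracy, 1)
  # empty cohort: recall 0, precision degenerately 1 with a flag
  empty <- mergeCohort(list(S01 = mkCalls("S01", pos = integer(0))))
  sc0 <- scoreRecovery(truth, empty)
  expect_equal(sc0$recall, 0)
  expect_equal(sc0$precision, 1)
  expect_true(sc0$degenerate)
})

test_that("positional jitter feeds dispersion that the filter acts on", {
  g <- simulateReference(2, 600000, seed = 131)
  truth <- plantCohort(g, nSites = 20, nSamples = 6, seed = 132)
  paths <- emitVcfs(truth, posJitterSd = 0.5, outDir =
                      file.path(tempdir(), "jit"), seed = 133)
  cs <- lapply(names(paths), function(s) readSampleCalls(paths[[s]], s))
  names(cs) <- names(paths)
  co <- mergeCohort(cs)
  expect_equal(scoreRecovery(truth, co)$recall, 1)
  res <- filterSites(co)
  # the survivors are exactly the sites with stdevPos < 1 (and stdevLen < 1)
  st <- siteTable(co)
  manual <- st$stdevPos < 1 & st$stdevLen < 1
  expect_equal(nSites(res$cohort), sum(manual))
})

test_that("growing jitter never increases the filter survival rate", {
  g <- simulateReference(2, 600000, seed = 141)
  truth <- plantCohort(g, nSites = 15, nSamples = 6, seed = 142)
  surv <- vapply(c(0, 1, 2), function(sd) {
    frac <- vapply(1:7, function(k) {
      paths <- emitVcfs(truth, posJitterSd = sd,
                        outDir = file.path(tempdir(),
                                           paste0("mono", sd, "_", k)),
                        seed = 1000 + 10 * k + round(sd))
      cs <- lapply(names(paths), function(s) readSampleCalls(paths[[s]], s))
      names(cs) <- names(paths)
      co <- mergeCohort(cs)
      filterSites(co)$report$kept / nSites(co)
    }, numeric(1))
    mean(frac)
  }, numeric(1))
  expect_true(all(diff(surv) <= 0.05)) # non-increasing in expectation
})
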