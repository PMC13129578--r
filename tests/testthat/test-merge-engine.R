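test_that("pair threshold follows M * sqrt(min(lenA, lenB))", {
  expect_equal(pairThreshold(100, 64, 250), 2000)
  expect_equal(pairThreshold(50, 50, 250), 250 * sqrt(50))
  expect_equal(pairThreshold(123, 456, 0), 0)
  expect_error(pairThreshold(-1, 10), "non-negative")
  # monotone non-decreasing in both lengths and in M
  expect_true(pairThreshold(100, 100) >= pairThreshold(100, 50))
  expect_true(pairThreshold(100, 100, 300) >= pairThreshold(100, 100, 250))
})

test_that("adjacent-call chaining clusters by the positional threshold", {
  one <- clusterCalls(mkCalls("A", pos = c(1000, 1001), length = 100))
  expect_length(one, 1)
  two <- clusterCalls(mkCalls("A", pos = c(1000, 9000), length = 100))
  expect_length(two, 2)
  expect_error(clusterCalls(rbind(mkCalls(chrom = "chr1", pos = 1),
                                  mkCalls(chrom = "chr2", pos = 2))),
               "single chromosome")
  expect_error(clusterCalls(rbind(mkCalls(pos = 1, svType = "DEL"),
                                  mkCalls(pos = 2, svType = "INS"))),
               "single SV type")
})

test_that("clustering matches the union-find connected-components oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(20:100, 1)
    calls <- mkCalls(sample(paste0("S", 1:4), n, TRUE), "chr1",
                     pos = sort(sample(2e5, n)), length = sample(50:900, n))
    got <- clusterCalls(calls, M = 250)
    expect_identical(clusterSignature(got),
                     clusterSignature(oracleClusters(calls, M = 250)),
                     info = paste("seed", seed))
    expect_equal(sum(vapply(got, nrow, integer(1))), n)
  }
})

test_that("cluster summaries use median position and population dispersion", {
  cl <- mkCalls(c("A", "B"), pos = c(1000, 1001), length = 100)
  s <- summarizeCluster(cl, c("A", "B", "C"))
  expect_equal(s$site$pos, 1000)  # lower middle of an even count
  expect_equal(s$site$stdevPos, 0.5)
  expect_identical(unname(s$genotypes), c("0/1", "0/1", "0/0"))

  single <- summarizeCluster(mkCalls("A", pos = 500, length = 80),
                             c("A", "B", "C"))
  expect_equal(single$site$stdevPos, 0)
  expect_equal(single$site$stdevLen, 0)
  expect_identical(unname(single$genotypes), c("0/1", "0/0", "0/0"))

  three <- summarizeCluster(mkCalls(c("A", "B", "C"),
                                    pos = c(100, 102, 104), length = 100),
                            c("A", "B", "C"))
  expect_equal(three$site$stdevPos, sqrt(mean((c(100, 102, 104) - 102)^2)))
  expect_equal(three$site$stdevPos, 1.633, tolerance = 1e-3)
  expect_error(summarizeCluster(mkCalls("A", pos = integer(0)), "A"),
               "empty")
})

test_that("intra-sample duplicates resolve to the nearest, higher-alt call", {
  cl <- rbind(mkCalls("A", pos = c(1000, 1040), length = 400,
                      genotype = c("0/1", "1/1")),
              mkCalls("B", pos = 1020, length = 400, genotype = "0/1"))
  s <- summarizeCluster(cl, c("A", "B"))
  # representative pos = 1020; A's calls at distance 20 each: tie broken
  # toward the higher-alt genotype
  expect_identical(unname(s$genotypes["A"]), "1/1")
  expect_equal(nrow(s$members), 3) # all members conserved
})

test_that("cohort merging keeps types separate and conserves calls", {
  co <- mergeCohort(list(
    A = mkCalls("A", pos = 5000, length = 100),
    B = mkCalls("B", pos = 5001, length = 100)))
  expect_equal(nSites(co), 1)
  expect_identical(unname(genotypeCalls(co)[1, ]), c("0/1", "0/1"))

  mixed <- mergeCohort(list(
    A = mkCalls("A", pos = 5000, svType = "DEL", length = 100),
    B = mkCalls("B", pos = 5000, svType = "INS", length = 100,
                altSeq = strrep("A", 100))))
  expect_equal(nSites(mixed), 2)
  expect_identical(sort(siteTable(mixed)$svType), c("DEL", "INS"))

  expect_error(mergeCohort(setNames(list(mkCalls(pos = 1), mkCalls(pos = 2)),
                                    c("A", "A"))), "duplicate")
})

test_that("widely spaced planted sites are recovered exactly", {
  g <- simulateReference(5, 600000, seed = 21)
  truth <- plantCohort(g, nSites = 50, nSamples = 5,
                       lengthRange = c(50, 1000), minSpacing = 50000,
                       seed = 22)
  vd <- file.path(tempdir(), "merge-recov")
  paths <- emitVcfs(truth, outDir = vd, seed = 23)
  cs <- lapply(names(paths), function(s) readSampleCalls(paths[[s]], s))
  names(cs) <- names(paths)
  co <- mergeCohort(cs)
  expect_equal(nSites(co), 50)
  # genotypes equal truth at every planted site
  key <- paste(siteTable(co)$chrom, siteTable(co)$pos)
  tkey <- paste(truth$sites$chrom, truth$sites$pos)
  expect_setequal(key, tkey)
  m <- match(tkey, key)
  expect_identical(genotypeCalls(co)[m, truth$samples], truth$genotypes)
})

test_that("merging is invariant to sample and call order", {
  set.seed(31)
  mk <- function(s) mkCalls(s, "chr1", pos = sort(sample(1e6, 30)),
                            length = sample(50:500, 30),
                            genotype = sample(c("0/1", "1/1"), 30, TRUE))
  cs <- list(A = mk("A"), B = mk("B"), C = mk("C"))
  co1 <- mergeCohort(cs)
  shuffled <- lapply(cs[c("C", "A", "B")],
                     function(d) d[sample(nrow(d)), , drop = FALSE])
  co2 <- mergeCohort(shuffled)
  s1 <- siteTable(co1); s2 <- siteTable(co2)
  expect_equal(s1[c("chrom", "pos", "svType", "length", "stdevPos")],
               s2[c("chrom", "pos", "svType", "length", "stdevPos")])
  expect_identical(genotypeCalls(co1)[, c("A", "B", "C")],
                   genotypeCalls(co2)[, c("A", "B", "C")])
  # conservation: every input call lands in exactly one site
  expect_equal(sum(vapply(siteMembers(co1), nrow, integer(1))), 90)
})

test_that("raising M never increases the cluster count", {
  set.seed(41)
  calls <- mkCalls("A", pos = sort(sample(5e4, 60)),
                   length = sample(50:400, 60))
  counts <- vapply(c(0, 50, 250, 1000, 5000),
                   function(M) length(clusterCalls(calls, M)), integer(1))
  expect_true(all(diff(counts) <= 0))
})
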