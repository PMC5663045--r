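# The synthetic cohort generator and its contracts.

test_that("read support follows the thinned binomial model", {
  set.seed(71)
  rs <- simulateReadSupport(0, 0.8, rep(100L, 50))
  expect_true(all(rs$alt_reads == 0))
  expect_true(all(rs$ref_reads == 100))

  rs <- simulateReadSupport(1, 0.6, rep(10000L, 20))
  expect_equal(mean(rs$alt_reads / 10000), 0.30, tolerance = 0.01)

  rs <- simulateReadSupport(1, 1, rep(50000L, 20))
  expect_equal(mean(rs$alt_reads / 50000), 0.5, tolerance = 0.01)

  expect_error(simulateReadSupport(1.2, 1, 100), "clonalFraction")
  expect_error(simulateReadSupport(1, 0, 100), "purity")
})

test_that("tracks show the designed BAF and coverage signatures", {
  set.seed(72)
  null <- simulateTracks(nSites = 800, meanDepth = 100,
                         chromLens = .chr1Only)
  baf <- null$alt_reads / (null$ref_reads + null$alt_reads)
  expect_lt(mean(abs(baf - 0.5)), 0.1)

  seg <- GRanges("chr1", IRanges(5e7, 1.3e8), event_class = "cnLOH")
  tr <- simulateTracks(seg, nSites = 1200, meanDepth = 100, purity = 1,
                       chromLens = .chr1Only)
  on <- tr$pos >= 5e7 & tr$pos <= 1.3e8
  lr <- log2(tr$tumor_depth / tr$normal_depth)
  expect_lt(abs(mean(lr[on])), 0.1)
  bafOn <- (tr$alt_reads / tr$tumor_depth)[on]
  expect_gt(mean(abs(bafOn - 0.5)), 0.2)

  segDel <- GRanges("chr1", IRanges(5e7, 1.3e8), event_class = "deletion")
  trDel <- simulateTracks(segDel, nSites = 1200, meanDepth = 100,
                          purity = 1, chromLens = .chr1Only)
  on <- trDel$pos >= 5e7 & trDel$pos <= 1.3e8
  expect_lt(mean(log2(trDel$tumor_depth / trDel$normal_depth)[on]), -0.5)

  overlapping <- suppressWarnings(c(
    GRanges("chr1", IRanges(1e7, 3e7), event_class = "AI"),
    GRanges("chr1", IRanges(2e7, 4e7), event_class = "deletion")))
  expect_error(simulateTracks(overlapping, nSites = 100,
                              chromLens = .chr1Only), "overlap")
  beyond <- GRanges("chr1", IRanges(1e7, 2.5e8), event_class = "AI")
  expect_error(simulateTracks(beyond, nSites = 100,
                              chromLens = .chr1Only), "bounds")
})

test_that("invalid cohort configurations are rejected with messages", {
  expect_error(cohortConfig(groupFractions = c("H3/IDH1 mutant" = 0.5,
                                               "H3/IDH1 wildtype" = 0.2,
                                               "NF1 germline" = 0.2)),
               "sum to 1")
  expect_error(cohortConfig(nSharedPassengers = -1), "non-negative")
  expect_error(cohortConfig(tumorPurity = 1.4), "tumorPurity")
  expect_error(cohortConfig(callerSensitivity = c(caller_A = 2,
                                                  caller_B = 1,
                                                  caller_C = 1)),
               "sensitivities")
})

test_that("noise-free generation forces exact sharing of planted variants", {
  cfg <- cohortConfig(nPairs = 2,
                      groupFractions = c("H3/IDH1 mutant" = 0.5,
                                         "H3/IDH1 wildtype" = 0.5,
                                         "NF1 germline" = 0),
                      nSharedPassengers = 3L, nPrimaryPrivate = 0L,
                      nRecurrencePrivate = 0L, nGermline = 0L,
                      callerSensitivity = c(caller_A = 1, caller_B = 1,
                                            caller_C = 1),
                      callerFpRate = 0, nTrackSites = 400L, nProbes = 600L,
                      seed = 73L)
  sim <- simulateCohort(cfg, dir = withr::local_tempdir())
  for (pid in sim$groundTruth$pairIds) {
    keysOf <- function(sid) {
      calls <- readCallerVcfs(
        setNames(file.path(sim$dir, "vcf",
                           sprintf("%s_%s.vcf", sid,
                                   c("caller_A", "caller_B", "caller_C"))),
                 c("caller_A", "caller_B", "caller_C")), sid)
      sort(unique(sprintf("%s:%d:%s:%s", calls$chrom, calls$pos, calls$ref,
                          calls$alt)))
    }
    expect_identical(keysOf(paste0(pid, "_P")), keysOf(paste0(pid, "_R")))
  }
})

test_that("a hypermutator pair carries a multiplied variant load", {
  cfg <- smallCohortConfig(seed = 74, hypermutatorPairs = 1L,
                           hypermutatorMultiplier = 10)
  sim <- simulateCohort(cfg, dir = withr::local_tempdir())
  gt <- sim$groundTruth$variants
  load <- table(gt$pair[!gt$germline])
  hyper <- load[["SIM01"]]
  others <- load[setdiff(names(load), "SIM01")]
  expect_gte(hyper, 5 * max(others))
})

test_that("identical seeds give byte-identical runs; different seeds differ", {
  cfg <- cohortConfig(nPairs = 2, nTrackSites = 300L, nProbes = 500L,
                      nGermline = 5L, seed = 75L,
                      groupFractions = c("H3/IDH1 mutant" = 0.5,
                                         "H3/IDH1 wildtype" = 0.5,
                                         "NF1 germline" = 0))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateCohort(cfg, dir = d1)
  simulateCohort(cfg, dir = d2)
  sums <- function(d) {
    files <- sort(list.files(d, recursive = TRUE))
    setNames(unname(tools::md5sum(file.path(d, files))), files)
  }
  expect_identical(sums(d1), sums(d2))

  cfg2 <- cohortConfig(nPairs = 2, nTrackSites = 300L, nProbes = 500L,
                       nGermline = 5L, seed = 76L,
                       groupFractions = c("H3/IDH1 mutant" = 0.5,
                                          "H3/IDH1 wildtype" = 0.5,
                                          "NF1 germline" = 0))
  d3 <- withr::local_tempdir()
  simulateCohort(cfg2, dir = d3)
  expect_false(identical(sums(d1), sums(d3)))
})

test_that("planted drivers obey the published co-occurrence rules", {
  sim <- simulateCohort(smallCohortConfig(seed = 77),
                        dir = withr::local_tempdir())
  gt <- sim$groundTruth$variants
  for (pid in sim$groundTruth$pairIds) {
    pv <- gt[gt$pair == pid, ]
    h3 <- pv$gene %in% c("H3F3A", "IDH1", "HIST1H3B")
    if (any(h3)) {
      partner <- if (any(pv$gene == "HIST1H3B")) "ACVR1" else "TP53"
      expect_true(partner %in% pv$gene)
      expect_true(all(pv$timing[h3] == "shared"))
    }
  }
  # planted segments never overlap within a sample
  for (sid in names(sim$groundTruth$segments)) {
    gr <- sim$groundTruth$segments[[sid]]
    if (length(gr) > 1)
      expect_equal(sum(width(GenomicRanges::reduce(gr))), sum(width(gr)))
  }
})
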