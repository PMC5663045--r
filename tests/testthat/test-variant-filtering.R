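# Consensus building and the somatic filter cascade.

test_that("per-caller VCFs parse into calls, splitting multi-allelic records", {
  d <- withr::local_tempdir()
  f1 <- writeTestVcf(file.path(d, "a.vcf"),
                     "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:AD:DP\t0/1:60,40:100")
  calls <- readCallerVcfs(c(caller_A = f1), "S1")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$depth, 100L)
  expect_equal(calls$alt_reads, 40L)

  f2 <- writeTestVcf(file.path(d, "b.vcf"),
                     "chr2\t500\t.\tA\tC,T\t.\tPASS\t.\tGT:AD:DP\t1/2:50,30,20:100")
  calls <- readCallerVcfs(c(caller_A = f2), "S1")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$alt, c("C", "T"))
  expect_equal(calls$alt_reads, c(30L, 20L))

  f3 <- writeTestVcf(file.path(d, "empty.vcf"), character(0))
  expect_equal(nrow(readCallerVcfs(c(caller_A = f3), "S1")), 0L)

  # records without AD are skipped with a warning, not fatal
  f4 <- writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:100"),
    file.path(d, "noad.vcf"))
  expect_warning(calls <- readCallerVcfs(c(caller_A = file.path(d, "noad.vcf")),
                                         "S1"),
                 "skipped")
  expect_equal(nrow(calls), 0L)
})

test_that("consensus requires 2-of-3 callers and 10% read support", {
  pol <- filterPolicy()
  two <- rbind(makeCall("caller_A", 100, 40), makeCall("caller_B", 90, 35))
  cons <- buildConsensus(two, pol)
  expect_equal(cons$status, "candidate")
  expect_equal(cons$n_callers, 2L)

  one <- makeCall("caller_A", 100, 40)
  cons <- buildConsensus(one, pol)
  expect_equal(cons$status, "filtered")
  expect_match(cons$filter_reasons, "insufficient_callers")

  weak <- rbind(makeCall("caller_A", 100, 8), makeCall("caller_B", 90, 7))
  cons <- buildConsensus(weak, pol)
  expect_equal(cons$status, "filtered")
  expect_match(cons$filter_reasons, "low_read_support")

  # representative read counts come from the deepest caller
  uneven <- rbind(makeCall("caller_A", 80, 30), makeCall("caller_B", 120, 50))
  cons <- buildConsensus(uneven, pol)
  expect_equal(cons$depth, 120L)
  expect_equal(cons$maf, 50 / 120)

  # genes-of-interest exemption keeps a 8% TP53 variant alive for the MAF tier
  goiMap <- c("chr1:100:A:G" = "TP53")
  cons <- buildConsensus(weak, pol, geneOf = goiMap)
  expect_equal(cons$status, "candidate")
})

test_that("MAF tiers: inclusive 5% for genes of interest, exclusive 15% elsewhere", {
  pol <- filterPolicy()
  expect_equal(applyMafFilter(consensusRow(0.07, "TP53"), pol)$status,
               "candidate")
  expect_equal(applyMafFilter(consensusRow(0.07, "EGFR"), pol)$status,
               "filtered")
  expect_equal(applyMafFilter(consensusRow(0.30, "EGFR"), pol)$status,
               "candidate")
  # boundaries
  expect_equal(applyMafFilter(consensusRow(0.05, "H3F3A"), pol)$status,
               "candidate")
  expect_equal(applyMafFilter(consensusRow(0.0499, "H3F3A"), pol)$status,
               "filtered")
  expect_equal(applyMafFilter(consensusRow(0.15, "EGFR"), pol)$status,
               "filtered")
  expect_equal(applyMafFilter(consensusRow(0.1501, "EGFR"), pol)$status,
               "candidate")
  expect_match(applyMafFilter(consensusRow(0.07, "EGFR"), pol)$filter_reasons,
               "maf_below_threshold")
})

test_that("matched-normal rule: zero alt somatic, below-threshold flagged", {
  pol <- filterPolicy()
  expect_equal(
    classifySomaticWithNormal(consensusRow(normal_alt_reads = 0L), pol)$status,
    "somatic")
  expect_equal(
    classifySomaticWithNormal(consensusRow(normal_alt_reads = 1L), pol)$status,
    "review_flagged")
  v <- classifySomaticWithNormal(consensusRow(normal_alt_reads = 10L), pol)
  expect_equal(v$status, "filtered")
  expect_match(v$filter_reasons, "present_in_normal")
  expect_error(
    classifySomaticWithNormal(consensusRow(normal_alt_reads = -1L), pol),
    "non-negative")
})

test_that("no-normal rule: population filters then COSMIC/impact rescue", {
  pol <- filterPolicy()
  v <- classifySomaticWithoutNormal(consensusRow(pop_af_exac = 0.001), pol)
  expect_equal(v$status, "filtered")
  expect_match(v$filter_reasons, "population_polymorphism")
  # boundary is inclusive: at the cutoff the variant is removed
  expect_equal(
    classifySomaticWithoutNormal(consensusRow(pop_af_1000g = 0.0005),
                                 pol)$status, "filtered")
  expect_equal(
    classifySomaticWithoutNormal(consensusRow(pop_af_exac = 0.00005),
                                 pol)$status, "filtered")
  expect_equal(
    classifySomaticWithoutNormal(consensusRow(pop_af_exac = 0.00004,
                                              in_cosmic = TRUE),
                                 pol)$status, "putative_somatic")
  expect_equal(
    classifySomaticWithoutNormal(consensusRow(in_cosmic = TRUE), pol)$status,
    "putative_somatic")
  expect_equal(
    classifySomaticWithoutNormal(consensusRow(functional_impact = "medium"),
                                 pol)$status, "putative_somatic")
  v <- classifySomaticWithoutNormal(consensusRow(functional_impact = "low"),
                                    pol)
  expect_equal(v$status, "filtered")
  expect_match(v$filter_reasons, "no_somatic_evidence")
})

test_that("cascade invariants hold on randomized variant sets", {
  pol <- filterPolicy()
  set.seed(404)
  for (rep in 1:20) {
    n <- 30
    v <- consensusRow()[rep(1, n), ]
    v$key <- sprintf("chr1:%d:A:G", seq_len(n))
    v$maf <- runif(n)
    v$gene <- sample(c("TP53", "EGFR", "ATRX", "GENE1"), n, replace = TRUE)
    v$in_cosmic <- runif(n) < 0.3
    v$functional_impact <- sample(c("high", "medium", "low"), n,
                                  replace = TRUE)
    v$pop_af_exac <- ifelse(runif(n) < 0.2, runif(n, 0, 1e-3), 0)
    v$normal_alt_reads <- rbinom(n, 30, 0.1)
    rownames(v) <- NULL

    # order independence: MAF before normal equals normal before MAF
    a <- classifySomaticWithNormal(applyMafFilter(v, pol), pol)
    b <- applyMafFilter(classifySomaticWithNormal(v, pol), pol)
    expect_equal(a$status == "filtered", b$status == "filtered")

    # nothing with normal support is ever called somatic
    expect_false(any(a$status == "somatic" & a$normal_alt_reads > 0))

    # monotonicity: raising a threshold never retains more variants
    nKept <- function(p) sum(applyMafFilter(v, p)$status != "filtered")
    expect_lte(nKept(filterPolicy(otherMafMin = 0.25)),
               nKept(filterPolicy(otherMafMin = 0.15)))
    expect_lte(nKept(filterPolicy(goiMafMin = 0.10)),
               nKept(filterPolicy(goiMafMin = 0.05)))
  }
})

test_that("noise-free simulated samples are recovered exactly by the cascade", {
  cfg <- cohortConfig(nPairs = 2,
                      groupFractions = c("H3/IDH1 mutant" = 0.5,
                                         "H3/IDH1 wildtype" = 0.5,
                                         "NF1 germline" = 0),
                      nSharedPassengers = 3L, nPrimaryPrivate = 2L,
                      nRecurrencePrivate = 2L, nGermline = 6L,
                      callerSensitivity = c(caller_A = 1, caller_B = 1,
                                            caller_C = 1),
                      callerFpRate = 0, nTrackSites = 600L, nProbes = 800L,
                      seed = 99L)
  sim <- simulateCohort(cfg, dir = withr::local_tempdir())
  gt <- sim$groundTruth$variants
  ann <- readAnnotationTable(file.path(sim$dir, "annotation.tsv"))
  for (pid in sim$groundTruth$pairIds) {
    nc <- read.delim(file.path(sim$dir, "normal_counts",
                               sprintf("%s_normal_counts.tsv", pid)))
    for (role in c("P", "R")) {
      sid <- paste0(pid, "_", role)
      paths <- sapply(c("caller_A", "caller_B", "caller_C"), function(cl)
        file.path(sim$dir, "vcf", sprintf("%s_%s.vcf", sid, cl)))
      calls <- readCallerVcfs(paths, sid)
      res <- runFilterCascade(calls, ann, normalCounts = nc)
      kept <- retainedVariants(res, includeReviewFlagged = FALSE)
      timing <- if (role == "P") c("shared", "primary") else
        c("shared", "recurrence")
      want <- gt[gt$pair == pid & gt$timing %in% timing & !gt$germline, ]
      wantKeys <- sort(sprintf("%s:%d:%s:%s", want$chrom, want$pos,
                               want$ref, want$alt))
      expect_identical(sort(kept$key), wantKeys)
      expect_true(all(kept$status == "somatic"))
    }
  }
})
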