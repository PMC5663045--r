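# Joint coverage+BAF copy-number calling.

test_that("coverage normalization produces the expected log2 ratios", {
  tr <- data.frame(chrom = "chr1", pos = seq_len(100) * 1e6,
                   tumor_depth = 80, normal_depth = 80)
  bins <- normalizeCoverage(tr, binSize = 10)
  expect_true(all(abs(bins$log2_ratio) < 1e-12))

  tr2 <- tr
  tr2$tumor_depth <- 2 * tr2$normal_depth
  bins2 <- normalizeCoverage(tr2, binSize = 10)
  # both samples are median-scaled first, so a uniform doubling cancels out
  expect_true(all(abs(bins2$log2_ratio) < 1e-12))

  # a genuine relative change survives normalization: tumor doubled on half
  # the genome relative to its own median
  tr3 <- tr
  tr3$tumor_depth[1:30] <- 160
  bins3 <- normalizeCoverage(tr3, binSize = 10)
  expect_true(all(abs(bins3$log2_ratio[1:3] - 1) < 1e-12))
  expect_true(all(abs(bins3$log2_ratio[4:10]) < 1e-12))

  # planted single-copy deletion at purity 1 sits near log2(1/2)
  set.seed(41)
  seg <- GRanges("chr1", IRanges(4e7, 1.2e8), event_class = "deletion")
  sim <- simulateTracks(seg, nSites = 1500, meanDepth = 100, purity = 1,
                        chromLens = .chr1Only)
  bins4 <- normalizeCoverage(sim, binSize = 10)
  on <- bins4$start >= 4e7 & bins4$end <= 1.2e8
  expect_equal(mean(bins4$log2_ratio[on]), -1, tolerance = 0.15)
})

test_that("binary segmentation finds planted breakpoints", {
  expect_equal(nrow(segmentLog2(rep(0.01, 80))), 1L)

  set.seed(42)
  x <- c(rnorm(50, 0, 0.1), rnorm(50, -1, 0.1))
  seg <- segmentLog2(x)
  expect_equal(nrow(seg), 2L)
  expect_lte(abs(seg$end_bin[1] - 50), 2)

  y <- c(rnorm(60, 0, 0.1), rnorm(60, 1, 0.1), rnorm(60, -0.8, 0.1))
  seg2 <- segmentLog2(y)
  expect_equal(nrow(seg2), 3L)

  # too few bins: a single segment, never a split
  expect_equal(nrow(segmentLog2(rnorm(8))), 1L)
})

test_that("event classification covers all six state combinations", {
  expect_equal(classifyEvent("gain", "balanced"), "amplification")
  expect_equal(classifyEvent("gain", "imbalanced"), "amplification")
  expect_equal(classifyEvent("loss", "balanced"), "deletion")
  expect_equal(classifyEvent("loss", "imbalanced"), "deletion")
  expect_equal(classifyEvent("neutral", "imbalanced"), "cnLOH")
  expect_equal(classifyEvent("neutral", "balanced"), "none")
  expect_error(classifyEvent("weird", "balanced"))
})

test_that("breakpoint union partitions the hull and inherits states", {
  cov <- GRanges("chr1", IRanges(1, 100), coverage_state = "gain")
  ai <- GRanges("chr1", IRanges(51, 150))
  cells <- unionSegments(cov, ai, snapDistance = 0)
  expect_equal(start(cells), c(1, 51, 101))
  expect_equal(end(cells), c(50, 100, 150))
  expect_equal(mcols(cells)$event_class,
               c("amplification", "amplification", "cnLOH"))

  # no AI: the partition equals the coverage segmentation
  cov2 <- GRanges("chr1", IRanges(c(1, 101), c(100, 200)),
                  coverage_state = c("neutral", "loss"))
  cells2 <- unionSegments(cov2, GRanges(), snapDistance = 0)
  expect_equal(start(cells2), c(1, 101))
  expect_equal(mcols(cells2)$event_class, c("none", "deletion"))

  # identical breakpoints in both features collapse to the same partition
  cells3 <- unionSegments(cov2, GRanges("chr1", IRanges(101, 200)),
                          snapDistance = 0)
  expect_equal(length(cells3), 2L)
  expect_equal(mcols(cells3)$event_class, c("none", "deletion"))

  # partition property on random inputs: disjoint cover of the hull
  set.seed(43)
  for (i in 1:10) {
    st <- sort(sample.int(1e6, 3)) * 100
    cov <- GRanges("chr1", IRanges(st, st + sample.int(1e7, 3)),
                   coverage_state = sample(c("gain", "loss", "neutral"), 3,
                                           replace = TRUE))
    cov <- GenomicRanges::reduce(cov, with.revmap = FALSE)
    mcols(cov)$coverage_state <- sample(c("gain", "loss", "neutral"),
                                        length(cov), replace = TRUE)
    ai <- GRanges("chr1", IRanges(5e6, 5e6 + 1e7))
    cells <- unionSegments(cov, ai, snapDistance = 0)
    expect_equal(sum(width(cells)),
                 max(c(end(cov), end(ai))) - min(c(start(cov), start(ai))) + 1)
    expect_equal(anyDuplicated(start(cells)), 0L)
    expect_true(all(start(cells)[-1] > end(cells)[-length(cells)]))
  }
})

test_that("arm-level rollups require most of the arm to be affected", {
  arms <- readArmTable()
  q17 <- arms[arms$chrom == "chr17" & arms$arm == "q", ]
  full <- GRanges("chr17", IRanges(q17$start, q17$end),
                  coverage_state = "neutral", ai_state = "imbalanced",
                  event_class = "cnLOH")
  calls <- armLevelCalls(full)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$event_class, "cnLOH")
  expect_equal(calls$arm, "q")

  part <- GRanges("chr17",
                  IRanges(c(q17$start, q17$start + 5e6),
                          c(q17$start + 5e6 - 1, q17$end)),
                  event_class = c("deletion", "none"))
  expect_equal(nrow(armLevelCalls(part)), 0L)
})

test_that("swapping tumor and normal flips gains and losses", {
  set.seed(44)
  segs <- suppressWarnings(c(
    GRanges("chr1", IRanges(3e7, 1.1e8), event_class = "deletion"),
    GRanges("chr2", IRanges(4e7, 1.3e8), event_class = "amplification")))
  tr <- simulateTracks(segs, nSites = 2000, meanDepth = 90, purity = 1,
                       chromLens = .threeChroms)
  stateAt <- function(track, seg) {
    cnv <- callCNV(track, binSize = 10)
    cs <- cnv$coverageSegments
    hit <- cs[ovFrac(cs, seg) > 0.5 & as.character(seqnames(cs)) ==
                as.character(seqnames(seg))]
    unique(mcols(hit)$coverage_state)
  }
  expect_equal(stateAt(tr, segs[1]), "loss")
  expect_equal(stateAt(tr, segs[2]), "gain")
  sw <- tr
  sw$tumor_depth <- tr$normal_depth
  sw$normal_depth <- tr$tumor_depth
  expect_equal(stateAt(sw, segs[1]), "gain")
  expect_equal(stateAt(sw, segs[2]), "loss")
})
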