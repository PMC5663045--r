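# Probe filtering, top-variable selection, correlation-distance clustering.

betaFixture <- function(nProbes = 60, samples = c("A", "B")) {
  set.seed(51)
  m <- matrix(runif(nProbes * length(samples)), nProbes,
              dimnames = list(sprintf("cg%05d", seq_len(nProbes)), samples))
  ann <- data.frame(probe_id = rownames(m),
                    chrom = rep("chr1", nProbes),
                    is_snp_probe = FALSE, is_cross_reactive = FALSE)
  list(m = m, ann = ann)
}

test_that("probe filtering removes sex-chromosome, SNP and cross-reactive probes", {
  fx <- betaFixture(6)
  fx$ann$chrom <- c("chr1", "chrX", "chrY", "chr2", "chr3", "chr4")
  fx$ann$is_snp_probe[4] <- TRUE
  fx$ann$is_cross_reactive[5] <- TRUE
  se <- makeBetaMatrix(fx$m, fx$ann)
  kept <- filterProbes(se)
  expect_setequal(rownames(kept), c("cg00001", "cg00006"))

  fx$ann$is_snp_probe[] <- TRUE
  expect_equal(nrow(filterProbes(makeBetaMatrix(fx$m, fx$ann))), 0L)
})

test_that("top-variable selection ranks by sd with deterministic ties", {
  m <- rbind(cg1 = c(0.1, 0.9), cg2 = c(0.2, 0.8), cg3 = c(0.3, 0.7),
             cg4 = c(0.4, 0.6), cg5 = c(0.5, 0.5))
  colnames(m) <- c("A", "B")
  ann <- data.frame(probe_id = rownames(m), chrom = "chr1",
                    is_snp_probe = FALSE, is_cross_reactive = FALSE)
  se <- makeBetaMatrix(m, ann)
  top3 <- selectTopVariable(se, 3)
  expect_setequal(rownames(top3), c("cg1", "cg2", "cg3"))
  # a constant probe is never selected while non-constant ones remain
  expect_false("cg5" %in% rownames(selectTopVariable(se, 4)))
  expect_error(selectTopVariable(se, 10), "available")

  # exact ties resolve lexicographically by probe id
  m2 <- rbind(b = c(0.2, 0.8), a = c(0.2, 0.8), c = c(0.5, 0.5))
  colnames(m2) <- c("A", "B")
  ann2 <- data.frame(probe_id = rownames(m2), chrom = "chr1",
                     is_snp_probe = FALSE, is_cross_reactive = FALSE)
  expect_equal(rownames(selectTopVariable(makeBetaMatrix(m2, ann2), 1)),
               "a")
})

test_that("correlation distance behaves at its extremes and rejects degenerate samples", {
  x <- seq(0.1, 0.9, length.out = 20)
  m <- cbind(A = x, B = x, C = rev(x), D = rep(0.5, 20))
  rownames(m) <- sprintf("cg%02d", 1:20)
  d <- as.matrix(1 - cor(m[, 1:3]))
  expect_equal(unname(d["A", "B"]), 0)
  expect_equal(unname(d["A", "C"]), 2)

  cl <- clusterSamples(m[, 1:3], k = 2)
  expect_equal(clusterLabels(cl)[["A"]], clusterLabels(cl)[["B"]])
  expect_false(clusterLabels(cl)[["A"]] == clusterLabels(cl)[["C"]])
  # identical samples merge at height zero
  expect_equal(min(clusterTree(cl)$height), 0)
  # average-linkage heights are monotone non-decreasing
  expect_true(all(diff(clusterTree(cl)$height) >= -1e-12))

  expect_error(clusterSamples(m, k = 2), "D")
})

test_that("clustering recovers planted subgroups irrespective of sample order", {
  set.seed(52)
  nP <- 400
  truth <- rep(1:4, each = 4)
  names(truth) <- sprintf("S%02d", seq_along(truth))
  sig <- matrix(runif(nP * 4, 0.15, 0.55), nP)
  m <- sapply(seq_along(truth), function(i)
    pmin(1, pmax(0, sig[, truth[i]] + 0.3 * (runif(nP) < 0.25) *
                   0 + rnorm(nP, 0, 0.05))))
  # add a subgroup-specific shift on dedicated probe blocks
  for (g in 1:4) {
    block <- ((g - 1) * 80 + 1):(g * 80)
    m[block, truth == g] <- pmin(1, m[block, truth == g] + 0.3)
  }
  dimnames(m) <- list(sprintf("cg%04d", seq_len(nP)), names(truth))
  cl <- clusterSamples(m, k = 4)
  lab <- clusterLabels(cl)
  # perfect agreement up to label permutation
  expect_equal(length(unique(paste(truth, lab))), 4L)

  perm <- sample(ncol(m))
  cl2 <- clusterSamples(m[, perm], k = 4)
  lab2 <- clusterLabels(cl2)[names(truth)]
  expect_equal(length(unique(paste(lab, lab2))), 4L)
})

test_that("pair co-clustering reports per-pair labels and skips half pairs", {
  labels <- setNames(c(1L, 1L, 2L, 3L), c("P1_P", "P1_R", "P2_P", "P2_R"))
  tree <- hclust(dist(1:4))
  cl <- new("MethylationClusters", tree = tree, labels = labels, k = 3L,
            distanceMethod = "pearson")
  pairs <- data.frame(patient_id = c("P1", "P2", "P3"),
                      primary_sample_id = c("P1_P", "P2_P", "P3_P"),
                      recurrence_sample_id = c("P1_R", "P2_R", "P3_R"))
  expect_message(res <- pairCoClustering(cl, pairs), "P3")
  expect_equal(res$perPair, c(P1 = TRUE, P2 = FALSE))
  expect_equal(res$fraction, 0.5)
})
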