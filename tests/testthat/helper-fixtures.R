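suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# one-row per-caller variant observation
makeCall <- function(caller, depth, altReads, chrom = "chr1", pos = 100L,
                     ref = "A", alt = "G", sampleId = "S1") {
  data.frame(sample_id = sampleId, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, caller = caller,
             depth = as.integer(depth), alt_reads = as.integer(altReads),
             stringsAsFactors = FALSE)
}

# a consensus row ready for the downstream filters
consensusRow <- function(maf = 0.4, gene = "GENE1", status = "candidate",
                         in_cosmic = FALSE, functional_impact = "unknown",
                         pop_af_1000g = 0, pop_af_evs = 0, pop_af_exac = 0,
                         normal_alt_reads = NULL) {
  row <- data.frame(sample_id = "S1", chrom = "chr1", pos = 100L,
                    ref = "A", alt = "G", key = "chr1:100:A:G",
                    n_callers = 2L, callers_supporting = "caller_A,caller_B",
                    depth = 100L, alt_reads = as.integer(round(100 * maf)),
                    maf = maf, status = status, filter_reasons = "",
                    gene = gene, in_cosmic = in_cosmic,
                    functional_impact = functional_impact,
                    pop_af_1000g = pop_af_1000g, pop_af_evs = pop_af_evs,
                    pop_af_exac = pop_af_exac, stringsAsFactors = FALSE)
  if (!is.null(normal_alt_reads)) row$normal_alt_reads <- normal_alt_reads
  row
}

writeTestVcf <- function(path, records, sampleId = "S1",
                         format = "GT:AD:DP") {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleId, sep = "\t"),
    records), path)
  path
}

# fraction of each range in `a` covered by ranges in `b`
ovFrac <- function(a, b) {
  if (!length(a)) return(numeric(0))
  if (!length(b)) return(rep(0, length(a)))
  h <- suppressWarnings(findOverlaps(a, b))
  out <- rep(0, length(a))
  if (length(h)) {
    ww <- pmin(end(a)[queryHits(h)], end(b)[subjectHits(h)]) -
      pmax(start(a)[queryHits(h)], start(b)[subjectHits(h)]) + 1
    for (i in unique(queryHits(h)))
      out[i] <- sum(ww[queryHits(h) == i])
  }
  out / width(a)
}

# single-chromosome genome for fast AI/CNV simulations
.chr1Only <- c(chr1 = 249250621)
.threeChroms <- c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430)

# tiny but complete cohort configuration for end-to-end tests
smallCohortConfig <- function(seed, ...) {
  cohortConfig(nPairs = 4,
               groupFractions = c("H3/IDH1 mutant" = 0.5,
                                  "H3/IDH1 wildtype" = 0.25,
                                  "NF1 germline" = 0.25),
               nSharedPassengers = 4L, nPrimaryPrivate = 2L,
               nRecurrencePrivate = 3L, nGermline = 8L,
               nTrackSites = 900L, nProbes = 1500L,
               seed = seed, ...)
}

# run consensus + cascade + partition + grouping over a simulated run dir
runVariantStages <- function(dir, pairIds, policy = filterPolicy()) {
  ann <- readAnnotationTable(file.path(dir, "annotation.tsv"))
  callers <- c("caller_A", "caller_B", "caller_C")
  partitions <- list()
  groups <- character(0)
  for (pid in pairIds) {
    nc <- read.delim(file.path(dir, "normal_counts",
                               sprintf("%s_normal_counts.tsv", pid)))
    kept <- lapply(c(P = "P", R = "R"), function(role) {
      sid <- paste0(pid, "_", role)
      paths <- setNames(file.path(dir, "vcf",
                                  sprintf("%s_%s.vcf", sid, callers)),
                        callers)
      retainedVariants(
        runFilterCascade(readCallerVcfs(paths, sid), ann, nc, policy),
        includeReviewFlagged = FALSE)
    })
    partitions[[pid]] <- partitionPair(kept$P$key, kept$R$key)
    npaths <- setNames(file.path(dir, "vcf",
                                 sprintf("%s_N_%s.vcf", pid, callers)),
                       callers)
    npaths <- npaths[file.exists(npaths)]
    germ <- NULL
    if (length(npaths)) {
      ncons <- buildConsensus(readCallerVcfs(npaths, paste0(pid, "_N")),
                              policy)
      if (nrow(ncons)) {
        idx <- match(ncons$key, sprintf("%s:%d:%s:%s", ann$chrom, ann$pos,
                                        ann$ref, ann$alt))
        ncons$gene <- ann$gene[idx]
        ncons$effect <- ann$effect[idx]
        germ <- ncons[ncons$status != "filtered", , drop = FALSE]
      }
    }
    tum <- rbind(kept$P[, c("gene", "protein_change")],
                 kept$R[, c("gene", "protein_change")])
    groups[pid] <- assignGroup(tum, germ)
  }
  list(partitions = partitions, groups = groups)
}

# expected per-pair partition counts from planted ground truth
truthCounts <- function(gt, pid) {
  pv <- gt[gt$pair == pid & !gt$germline, ]
  c(shared = sum(pv$timing == "shared"),
    primary_only = sum(pv$timing == "primary"),
    recurrence_only = sum(pv$timing == "recurrence"))
}
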