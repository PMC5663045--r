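# End-to-end driver over a run directory laid out as by simulateCohort():
#   clinical.tsv, annotation.tsv, vcf/<sample>_<caller>.vcf,
#   normal_counts/<pair>_normal_counts.tsv, tracks/<sample>_track.tsv,
#   methylation/beta.tsv + probe_annotation.tsv

samplePaths <- function(dir, sampleId, callers = .CALLERS) {
  p <- file.path(dir, "vcf", sprintf("%s_%s.vcf", sampleId, callers))
  names(p) <- callers
  p[file.exists(p)]
}

cascadeForSample <- function(dir, sampleId, annotation, normalCounts,
                             policy) {
  paths <- samplePaths(dir, sampleId)
  if (!length(paths)) stop("no VCFs found for sample ", sampleId)
  calls <- readCallerVcfs(paths, sampleId)
  runFilterCascade(calls, annotation, normalCounts, policy)
}

#' Run the full paired-tumor pipeline on a run directory
#'
#' Executes, for every pair in the clinical table: the multi-caller
#' consensus and somatic filter cascade for both tumors (using matched
#' normal counts when present), temporal partitioning and molecular-group
#' assignment, allelic-imbalance detection and primary/recurrence region
#' comparison, joint coverage+BAF copy-number calling with arm-level
#' rollups, methylation clustering with pair co-clustering, and the cohort
#' summary. All stage outputs are written as TSV/BED/JSON under `outDir`.
#'
#' @param dir input run directory (see [simulateCohort()] for the layout).
#' @param outDir output directory (default `file.path(dir, "results")`).
#' @param policy a [FilterPolicy-class].
#' @param k flat methylation clusters.
#' @param aiMinDepth,aiWindow,aiAlpha AI parameters.
#' @param cnvBinSize coverage bin size.
#' @return Invisibly, a list with `partitions`, `groups`, `aiComparisons`,
#'   `burden`, `tests`, `coClustering`, `summary`, `outDir`.
#' @export
runPipeline <- function(dir, outDir = file.path(dir, "results"),
                        policy = filterPolicy(), k = 4L,
                        aiMinDepth = 10, aiWindow = 25L, aiAlpha = 0.05,
                        cnvBinSize = 25L) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  pairs <- readClinicalTable(file.path(dir, "clinical.tsv"))
  annotation <- readAnnotationTable(file.path(dir, "annotation.tsv"))
  armTable <- readArmTable()

  partitions <- list()
  groups <- character(0)
  aiComparisons <- list()
  pairVariants <- list()
  written <- character(0)

  for (i in seq_len(nrow(pairs))) {
    pid <- pairs$patient_id[i]
    ncPath <- file.path(dir, "normal_counts",
                        sprintf("%s_normal_counts.tsv", pid))
    normalCounts <- if (file.exists(ncPath)) read.delim(ncPath) else NULL
    consP <- cascadeForSample(dir, pairs$primary_sample_id[i], annotation,
                              normalCounts, policy)
    consR <- cascadeForSample(dir, pairs$recurrence_sample_id[i],
                              annotation, normalCounts, policy)
    for (cons in list(consP, consR)) {
      f <- file.path(outDir, sprintf("consensus_%s.tsv",
                                     cons$sample_id[1] %||% pid))
      write.table(cons, f, sep = "\t", quote = FALSE, row.names = FALSE)
      written <- c(written, f)
    }
    keptP <- retainedVariants(consP)
    keptR <- retainedVariants(consR)
    partitions[[pid]] <- partitionPair(keptP$key, keptR$key)
    # germline evidence: consensus calls from the matched normal, if any
    germ <- NULL
    npaths <- samplePaths(dir, paste0(pid, "_N"))
    if (length(npaths)) {
      ncalls <- readCallerVcfs(npaths, paste0(pid, "_N"))
      ncons <- buildConsensus(ncalls, policy)
      if (nrow(ncons)) {
        idx <- match(ncons$key, variantKey(annotation$chrom,
                                           annotation$pos,
                                           annotation$ref,
                                           annotation$alt))
        ncons$gene <- annotation$gene[idx]
        ncons$effect <- annotation$effect[idx]
        germ <- ncons[ncons$status != "filtered", , drop = FALSE]
      }
    }
    tumor <- rbind(keptP[, c("gene", "protein_change")],
                   keptR[, c("gene", "protein_change")])
    groups[pid] <- assignGroup(tumor, germ)
    pairVariants[[pid]] <- list(primary = keptP, recurrence = keptR)

    aiSegs <- list()
    for (role in c("P", "R")) {
      sid <- paste0(pid, "_", role)
      tp <- file.path(dir, "tracks", sprintf("%s_track.tsv", sid))
      if (!file.exists(tp)) next
      track <- readBafTrack(tp)
      sites <- selectHetSites(track, minDepth = aiMinDepth)
      aiSegs[[role]] <- detectAI(sites, window = aiWindow,
                                 alpha = aiAlpha, armTable = armTable)
      f <- file.path(outDir, sprintf("ai_%s.bed", sid))
      writeSegmentsBed(aiSegs[[role]], f, nameCol = "arm")
      written <- c(written, f)
      cnv <- callCNV(track, binSize = cnvBinSize, aiWindow = aiWindow,
                     aiAlpha = aiAlpha, minDepth = aiMinDepth,
                     armTable = armTable)
      ev <- cnv$events
      evDf <- data.frame(chrom = as.character(seqnames(ev)),
                         start = start(ev), end = end(ev),
                         coverage_state = mcols(ev)$coverage_state,
                         ai_state = mcols(ev)$ai_state,
                         event_class = mcols(ev)$event_class)
      f <- file.path(outDir, sprintf("cnv_events_%s.tsv", sid))
      write.table(evDf, f, sep = "\t", quote = FALSE, row.names = FALSE)
      f2 <- file.path(outDir, sprintf("cnv_arm_calls_%s.tsv", sid))
      write.table(cnv$armCalls, f2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      written <- c(written, f, f2)
    }
    if (length(aiSegs) == 2)
      aiComparisons[[pid]] <- compareAIRegions(aiSegs$P, aiSegs$R)
  }

  partDf <- do.call(rbind, lapply(names(partitions), function(pid)
    data.frame(pair = pid, t(partitions[[pid]]$counts))))
  write.table(partDf, file.path(outDir, "partitions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(pair = names(groups), molecular_group = groups),
              file.path(outDir, "groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cons <- conservationMatrix(pairVariants)
  write.table(cons$genes, file.path(outDir, "conservation_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  burden <- burdenTable(partitions, aiComparisons)
  write.table(burden, file.path(outDir, "burden.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tests <- tryCatch(compareBurdens(burden), error = function(e) {
    warning("paired burden test unavailable: ", conditionMessage(e))
    NULL
  })

  coClustering <- NULL
  betaPath <- file.path(dir, "methylation", "beta.tsv")
  if (file.exists(betaPath)) {
    se <- readBetaMatrix(betaPath,
                         file.path(dir, "methylation",
                                   "probe_annotation.tsv"))
    se <- filterProbes(se)
    nTop <- min(3000L, nrow(se))
    clusters <- clusterSamples(selectTopVariable(se, nTop), k = k)
    writeDendrogramNewick(clusters,
                          file.path(outDir, "methylation_dendrogram.nwk"))
    write.table(data.frame(sample = names(clusterLabels(clusters)),
                           cluster = clusterLabels(clusters)),
                file.path(outDir, "methylation_clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    coClustering <- pairCoClustering(clusters, pairs)
    write.table(data.frame(pair = names(coClustering$perPair),
                           co_cluster = coClustering$perPair),
                file.path(outDir, "co_clustering.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  summary <- summarizeClinical(pairs)
  jsonlite::write_json(
    list(clinical = summary, tests = tests,
         group_counts = as.list(summary$group_counts)),
    file.path(outDir, "cohort_summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, force = TRUE)

  invisible(list(partitions = partitions, groups = groups,
                 aiComparisons = aiComparisons, burden = burden,
                 tests = tests, coClustering = coClustering,
                 summary = summary, outDir = outDir))
}
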