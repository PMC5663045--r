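# Methylation subgroup clustering: probe filtering, top-variable probe
# selection, average-linkage clustering on correlation distance, and
# pair co-clustering.

#' Remove sex-chromosome, SNP-overlapping and cross-reactive probes
#'
#' @param se beta SummarizedExperiment ([readBetaMatrix()] /
#'   [makeBetaMatrix()]); `rowData` must carry `chrom`, `is_snp_probe`,
#'   `is_cross_reactive`.
#' @return The filtered SummarizedExperiment (possibly with zero probes;
#'   downstream selection errors in that case).
#' @export
filterProbes <- function(se) {
  rd <- SummarizedExperiment::rowData(se)
  need <- c("chrom", "is_snp_probe", "is_cross_reactive")
  if (!all(need %in% names(rd)))
    stop("probe annotation must carry: ", paste(need, collapse = ", "))
  chrom <- sub("^chr", "", as.character(rd$chrom))
  drop <- chrom %in% c("X", "Y") | as.logical(rd$is_snp_probe) |
    as.logical(rd$is_cross_reactive)
  se[!drop, ]
}

#' Select the most variable probes
#'
#' Probes are ranked by the sample standard deviation (n-1 denominator) of
#' their beta values and the top `nProbes` retained; ties are broken by
#' probe id in lexicographic order, so selection is deterministic.
#'
#' @param se beta SummarizedExperiment.
#' @param nProbes probes to keep (default 3000).
#' @return The SummarizedExperiment restricted to the selected probes.
#' @export
selectTopVariable <- function(se, nProbes = 3000L) {
  if (nrow(se) < nProbes)
    stop(sprintf("only %d probes available, %d requested", nrow(se),
                 nProbes))
  beta <- SummarizedExperiment::assay(se, "beta")
  sds <- apply(beta, 1, sd)
  ord <- order(-sds, rownames(beta))
  se[ord[seq_len(nProbes)], ]
}

#' Cluster samples on correlation distance
#'
#' Pairwise distance is `1 - cor(sample_i, sample_j)` over the selected
#' probes (Pearson by default, Spearman via `method`), followed by
#' average-linkage agglomeration and a flat cut at `k` clusters.
#'
#' @param se beta SummarizedExperiment (typically after [filterProbes()]
#'   and [selectTopVariable()]), or a probes-by-samples matrix.
#' @param k number of flat clusters (default 4, the number of methylation
#'   subgroups this cohort type exhibits: K27M, G34R/V, IDH1, wildtype).
#' @param method correlation flavour, `"pearson"` (default) or
#'   `"spearman"`.
#' @return A [MethylationClusters-class].
#' @export
clusterSamples <- function(se, k = 4L, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  beta <- if (is(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, "beta") else as.matrix(se)
  if (ncol(beta) < 2) stop("need at least two samples")
  sds <- apply(beta, 2, sd)
  if (any(sds == 0))
    stop("zero-variance sample(s): ",
         paste(colnames(beta)[sds == 0], collapse = ", "),
         " (correlation distance undefined)")
  d <- as.dist(1 - cor(beta, method = method))
  tree <- hclust(d, method = "average")
  labels <- cutree(tree, k = k)
  new("MethylationClusters", tree = tree,
      labels = setNames(as.integer(labels), names(labels)),
      k = as.integer(k), distanceMethod = method)
}

#' Export a clustering tree as newick
#'
#' @param clusters a [MethylationClusters-class].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
writeDendrogramNewick <- function(clusters, path) {
  phy <- ape::as.phylo(clusterTree(clusters))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Do primary and recurrence co-cluster?
#'
#' A pair co-clusters when both members carry the same flat label at `k`.
#' Pairs with only one member among the clustered samples are skipped with
#' a message (mirroring cohorts where one member's array failed QC).
#'
#' @param clusters a [MethylationClusters-class].
#' @param pairs data.frame with `patient_id`, `primary_sample_id`,
#'   `recurrence_sample_id` ([readClinicalTable()]).
#' @return A list with `perPair` (named logical) and `fraction` (fraction
#'   of evaluable pairs that co-cluster).
#' @export
pairCoClustering <- function(clusters, pairs) {
  labels <- clusterLabels(clusters)
  res <- logical(0)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs$primary_sample_id[i]
    r <- pairs$recurrence_sample_id[i]
    if (!(p %in% names(labels)) || !(r %in% names(labels))) {
      message("pair ", pairs$patient_id[i],
              ": only one member clustered, skipped")
      next
    }
    res[pairs$patient_id[i]] <- labels[[p]] == labels[[r]]
  }
  list(perPair = res,
       fraction = if (length(res)) mean(res) else NA_real_)
}
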