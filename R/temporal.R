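# Shared/private partitioning of a pair's variants, molecular grouping,
# and the gene x pair conservation matrix.

.H3_IDH1_DRIVERS <- list(
  H3F3A = c("K27M", "G34V", "G34R"),
  HIST1H3B = "K27M"
)

#' Partition a pair's variants into shared and private sets
#'
#' @param primaryKeys,recurrenceKeys character vectors of variant keys
#'   (`chrom:pos:ref:alt`), identically constructed in both samples.
#' @return A list with `shared`, `primary_only`, `recurrence_only` key sets
#'   and the corresponding `counts` (the three sets are disjoint and cover
#'   the union).
#' @examples
#' partitionPair(c("A", "B"), c("B", "C"))$counts
#' @export
partitionPair <- function(primaryKeys, recurrenceKeys) {
  p <- unique(primaryKeys)
  r <- unique(recurrenceKeys)
  out <- list(shared = intersect(p, r),
              primary_only = setdiff(p, r),
              recurrence_only = setdiff(r, p))
  out$counts <- c(shared = length(out$shared),
                  primary_only = length(out$primary_only),
                  recurrence_only = length(out$recurrence_only))
  out
}

hasDriver <- function(variants) {
  if (nrow(variants) == 0) return(FALSE)
  pc <- toupper(trimws(variants$protein_change))
  for (gene in names(.H3_IDH1_DRIVERS)) {
    if (any(variants$gene == gene & pc %in% .H3_IDH1_DRIVERS[[gene]]))
      return(TRUE)
  }
  # any IDH1 codon-132 substitution (R132H, R132S, ...)
  any(variants$gene == "IDH1" & grepl("^R132", pc))
}

#' Assign a pair's molecular group
#'
#' A pair is H3/IDH1 mutant when either tumor carries an H3F3A K27M, G34V or
#' G34R, HIST1H3B K27M, or IDH1 R132* substitution; otherwise NF1 germline
#' when a germline truncating NF1 variant is present; otherwise H3/IDH1
#' wildtype. H3/IDH1 status takes precedence over NF1 germline (the three
#' groups are disjoint); conflicting evidence is resolved that way with a
#' message.
#'
#' @param tumorVariants data.frame of the pair's tumor variants (both
#'   samples) with `gene` and `protein_change` columns.
#' @param germlineVariants optional data.frame of germline variants with
#'   `gene` and `effect` columns.
#' @return One of `"H3/IDH1 mutant"`, `"NF1 germline"`,
#'   `"H3/IDH1 wildtype"`.
#' @export
assignGroup <- function(tumorVariants, germlineVariants = NULL) {
  h3 <- hasDriver(tumorVariants)
  nf1 <- !is.null(germlineVariants) && nrow(germlineVariants) > 0 &&
    any(germlineVariants$gene == "NF1" &
          germlineVariants$effect %in% c("frameshift", "stopgain",
                                         "splice", "indel"))
  if (h3) {
    if (nf1)
      message("both H3/IDH1 driver and germline NF1 present; ",
              "assigning H3/IDH1 mutant by precedence")
    return("H3/IDH1 mutant")
  }
  if (nf1) return("NF1 germline")
  "H3/IDH1 wildtype"
}

#' Gene-by-pair conservation matrix
#'
#' For every gene mutated anywhere in the cohort and every pair, reports
#' whether the gene is altered in both tumors (`shared`), only the primary
#' (`primary_only`), only the recurrence (`recurrence_only`), or neither
#' (`absent`). Gene-level sharing is used (same gene mutated in both tumors,
#' not necessarily the identical variant); variant-level sharing is what
#' [partitionPair()] provides. Pathway rollups mark a pathway altered in a
#' sample when any member gene is.
#'
#' @param pairVariants named list (one element per pair) of lists with
#'   `primary` and `recurrence` variant data.frames carrying `gene` columns.
#' @param pathwayMap data.frame `gene`/`pathway`; defaults to the bundled
#'   curated map.
#' @return A list with `genes` and `pathways`, each a data.frame of status
#'   codes (rows: gene or pathway, columns: pairs); gene rows carry their
#'   pathway as an attribute column.
#' @export
conservationMatrix <- function(pairVariants, pathwayMap = readPathwayMap()) {
  pairs <- names(pairVariants)
  allGenes <- sort(unique(unlist(lapply(pairVariants, function(pv)
    c(pv$primary$gene, pv$recurrence$gene)))))
  allGenes <- allGenes[!is.na(allGenes) & allGenes != "."]
  status <- function(inP, inR) {
    if (inP && inR) "shared"
    else if (inP) "primary_only"
    else if (inR) "recurrence_only"
    else "absent"
  }
  geneMat <- sapply(pairs, function(pid) {
    pv <- pairVariants[[pid]]
    vapply(allGenes, function(g)
      status(g %in% pv$primary$gene, g %in% pv$recurrence$gene), "")
  })
  geneMat <- matrix(geneMat, nrow = length(allGenes),
                    dimnames = list(allGenes, pairs))
  pw <- pathwayMap$pathway[match(allGenes, pathwayMap$gene)]
  pw[is.na(pw)] <- "other"
  pathways <- sort(unique(pw))
  pwMat <- sapply(pairs, function(pid) {
    pv <- pairVariants[[pid]]
    vapply(pathways, function(p) {
      members <- allGenes[pw == p]
      status(any(members %in% pv$primary$gene),
             any(members %in% pv$recurrence$gene))
    }, "")
  })
  pwMat <- matrix(pwMat, nrow = length(pathways),
                  dimnames = list(pathways, pairs))
  genes <- as.data.frame(geneMat, stringsAsFactors = FALSE)
  genes <- cbind(data.frame(gene = allGenes, pathway = pw,
                            stringsAsFactors = FALSE), genes)
  rownames(genes) <- NULL
  list(genes = genes,
       pathways = as.data.frame(pwMat, stringsAsFactors = FALSE))
}

#' Paired t-test from first principles
#'
#' Computes the paired statistic directly:
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample (n-1) standard
#' deviation of the differences `d = x - y`, `df = n - 1`, and a two-sided
#' p-value from the t distribution. Identical columns (zero-variance
#' differences) are an error, as the statistic is undefined.
#'
#' @param x,y numeric vectors of equal length (n >= 2), paired by position.
#' @return A list with `t`, `df`, `p`.
#' @examples
#' pairedTTest(c(1, 2, 4), c(2, 3, 3))
#' @export
pairedTTest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2) stop("need at least two pairs")
  d <- x - y
  s <- sd(d)
  if (!is.finite(s) || s == 0)
    stop("zero-variance differences: paired t statistic undefined")
  tstat <- mean(d) / (s / sqrt(n))
  df <- n - 1
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}
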