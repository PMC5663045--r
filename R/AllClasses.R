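#' @import methods
#' @importFrom stats median sd rbinom rpois runif rnorm cor p.adjust pt
#'   pchisq hclust cutree as.dist setNames quantile
#' @importFrom utils read.delim write.table packageVersion
NULL

.CALLERS <- c("caller_A", "caller_B", "caller_C")
.GROUPS <- c("H3/IDH1 mutant", "H3/IDH1 wildtype", "NF1 germline")

#' Filter policy for the somatic variant cascade
#'
#' Holds every threshold of the variant filter cascade: consensus caller
#' support, minimum read-support fraction, the two-tier mutant allele
#' frequency (MAF) floors (a relaxed 5% floor for genes of interest versus
#' 15% elsewhere), population allele-frequency cutoffs used when no matched
#' normal is available, and the matched-normal review threshold.
#'
#' @slot minCallers integer, callers that must report a variant (default 2 of 3).
#' @slot minReadSupport numeric, minimum alt_reads/depth for the representative
#'   caller (default 0.10).
#' @slot goiMafMin numeric, inclusive MAF floor for genes of interest
#'   (default 0.05).
#' @slot otherMafMin numeric, exclusive MAF floor for all other genes
#'   (default 0.15).
#' @slot genesOfInterest character, genes eligible for the relaxed MAF tier.
#' @slot popAfMax1000gEvs numeric, maximum population AF in 1000 Genomes / EVS
#'   (default 5e-4); variants at or above are treated as germline polymorphisms.
#' @slot popAfMaxExac numeric, maximum ExAC AF (default 5e-5).
#' @slot normalReviewThreshold integer, variants with fewer normal alt reads
#'   than this (but more than zero) are flagged for manual review rather than
#'   discarded (default 2).
#' @slot goiReadSupportExempt logical, if TRUE the 10% read-support rule is
#'   waived for genes of interest so the relaxed 5% MAF tier can operate.
#' @export
setClass("FilterPolicy",
  representation(
    minCallers = "integer",
    minReadSupport = "numeric",
    goiMafMin = "numeric",
    otherMafMin = "numeric",
    genesOfInterest = "character",
    popAfMax1000gEvs = "numeric",
    popAfMaxExac = "numeric",
    normalReviewThreshold = "integer",
    goiReadSupportExempt = "logical"
  )
)

setValidity("FilterPolicy", function(object) {
  msg <- character(0)
  if (object@minCallers < 1L)
    msg <- c(msg, "minCallers must be >= 1")
  if (!(object@goiMafMin > 0 && object@goiMafMin <= object@otherMafMin &&
        object@otherMafMin < 1))
    msg <- c(msg, "need 0 < goiMafMin <= otherMafMin < 1")
  if (object@minReadSupport < 0 || object@minReadSupport > 1)
    msg <- c(msg, "minReadSupport must be in [0, 1]")
  if (object@popAfMax1000gEvs < 0 || object@popAfMaxExac < 0)
    msg <- c(msg, "population AF cutoffs must be non-negative")
  if (object@normalReviewThreshold < 1L)
    msg <- c(msg, "normalReviewThreshold must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a FilterPolicy
#'
#' Defaults reproduce the published cascade: 2-of-3 caller consensus, >= 10%
#' read support, MAF >= 5% for genes of interest (H3F3A, TP53, ATRX, ZMYND11,
#' LZTR1) and > 15% otherwise, population AF < 5e-4 (1000 Genomes / EVS) and
#' < 5e-5 (ExAC) when no normal is available, and manual review below 2 alt
#' reads in the matched normal.
#'
#' @param minCallers callers required for consensus.
#' @param minReadSupport minimum alt-read fraction.
#' @param goiMafMin inclusive MAF floor for genes of interest.
#' @param otherMafMin exclusive MAF floor elsewhere.
#' @param genesOfInterest character vector of gene symbols.
#' @param popAfMax1000gEvs population AF cutoff for 1000 Genomes and EVS.
#' @param popAfMaxExac population AF cutoff for ExAC.
#' @param normalReviewThreshold normal alt-read count below which a non-zero
#'   observation is review-flagged instead of filtered.
#' @param goiReadSupportExempt waive the read-support rule for genes of
#'   interest (see the methods vignette).
#' @return A [FilterPolicy-class] object.
#' @examples
#' filterPolicy()
#' filterPolicy(otherMafMin = 0.2)
#' @export
filterPolicy <- function(minCallers = 2L,
                         minReadSupport = 0.10,
                         goiMafMin = 0.05,
                         otherMafMin = 0.15,
                         genesOfInterest = c("H3F3A", "TP53", "ATRX",
                                             "ZMYND11", "LZTR1"),
                         popAfMax1000gEvs = 0.0005,
                         popAfMaxExac = 0.00005,
                         normalReviewThreshold = 2L,
                         goiReadSupportExempt = TRUE) {
  new("FilterPolicy",
      minCallers = as.integer(minCallers),
      minReadSupport = minReadSupport,
      goiMafMin = goiMafMin,
      otherMafMin = otherMafMin,
      genesOfInterest = genesOfInterest,
      popAfMax1000gEvs = popAfMax1000gEvs,
      popAfMaxExac = popAfMaxExac,
      normalReviewThreshold = as.integer(normalReviewThreshold),
      goiReadSupportExempt = goiReadSupportExempt)
}

#' @describeIn FilterPolicy-class genes eligible for the relaxed MAF tier
#' @param x a `FilterPolicy`
#' @export
genesOfInterest <- function(x) {
  stopifnot(is(x, "FilterPolicy"))
  x@genesOfInterest
}

setMethod("show", "FilterPolicy", function(object) {
  cat("FilterPolicy\n")
  cat(sprintf("  consensus        : %d of %d callers, read support >= %.0f%%%s\n",
              object@minCallers, length(.CALLERS),
              100 * object@minReadSupport,
              if (object@goiReadSupportExempt) " (waived for GOI)" else ""))
  cat(sprintf("  MAF tiers        : >= %.0f%% for %s; > %.0f%% otherwise\n",
              100 * object@goiMafMin,
              paste(object@genesOfInterest, collapse = ", "),
              100 * object@otherMafMin))
  cat(sprintf("  population AF    : < %g (1000G/EVS), < %g (ExAC)\n",
              object@popAfMax1000gEvs, object@popAfMaxExac))
  cat(sprintf("  normal review at : < %d alt reads\n",
              object@normalReviewThreshold))
})

#' Configuration of a synthetic paired-tumor cohort
#'
#' Defines the study conditions the simulator emulates: cohort size, the
#' fractions of the three molecular groups, planted shared and private
#' passenger counts, an optional hypermutator pair, per-caller sensitivity and
#' false-positive rates, sequencing depth, tumor purity, and structural events
#' (allelic imbalance, amplification, deletion, copy-neutral LOH) per sample.
#'
#' @slot nPairs integer, number of primary/recurrence pairs.
#' @slot groupFractions named numeric over the three molecular groups,
#'   summing to 1.
#' @slot nSharedPassengers,nPrimaryPrivate,nRecurrencePrivate integers,
#'   planted passenger counts per pair.
#' @slot hypermutatorPairs integer vector of pair indices with a hypermutator
#'   phenotype.
#' @slot hypermutatorMultiplier numeric multiplier on that pair's passenger
#'   counts.
#' @slot callerSensitivity named numeric in [0,1] per caller.
#' @slot callerFpRate numeric, expected false positives per sample per caller.
#' @slot meanDepth numeric, mean sequencing depth (default 69, the cohort's
#'   reported exome average).
#' @slot tumorPurity numeric in (0,1].
#' @slot sharedClonalFraction,privateClonalFraction numerics in (0,1], cancer
#'   cell fractions of shared and private passengers.
#' @slot nGermline integer, germline heterozygous variants per pair.
#' @slot nTrackSites integer, heterozygous sites in the coverage/BAF track.
#' @slot nSegmentsPerSample integer, planted structural events per tumor.
#' @slot wholeGenomeCnlohPair integer vector; recurrences of these pairs get
#'   genome-wide copy-neutral LOH.
#' @slot bafCenters numeric length-2, BAF centers of a single-copy event.
#' @slot nProbes integer, methylation probes simulated.
#' @slot methShift numeric, between-subgroup beta shift on signature probes.
#' @slot methNoiseSd,methPairSd numerics, probe-level and pair-level noise.
#' @slot seed integer RNG seed.
#' @export
setClass("CohortConfig",
  representation(
    nPairs = "integer",
    groupFractions = "numeric",
    nSharedPassengers = "integer",
    nPrimaryPrivate = "integer",
    nRecurrencePrivate = "integer",
    hypermutatorPairs = "integer",
    hypermutatorMultiplier = "numeric",
    callerSensitivity = "numeric",
    callerFpRate = "numeric",
    meanDepth = "numeric",
    tumorPurity = "numeric",
    sharedClonalFraction = "numeric",
    privateClonalFraction = "numeric",
    nGermline = "integer",
    nTrackSites = "integer",
    nSegmentsPerSample = "integer",
    wholeGenomeCnlohPair = "integer",
    bafCenters = "numeric",
    nProbes = "integer",
    methShift = "numeric",
    methNoiseSd = "numeric",
    methPairSd = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  if (object@nPairs < 1L) msg <- c(msg, "nPairs must be positive")
  if (abs(sum(object@groupFractions) - 1) > 1e-8)
    msg <- c(msg, "group fractions must sum to 1")
  if (any(object@groupFractions < 0))
    msg <- c(msg, "group fractions must be non-negative")
  if (!identical(sort(names(object@groupFractions)), sort(.GROUPS)))
    msg <- c(msg, sprintf("groupFractions must be named by: %s",
                          paste(.GROUPS, collapse = ", ")))
  if (any(object@callerSensitivity < 0 | object@callerSensitivity > 1))
    msg <- c(msg, "caller sensitivities must be in [0, 1]")
  if (object@callerFpRate < 0) msg <- c(msg, "callerFpRate must be >= 0")
  counts <- c(object@nSharedPassengers, object@nPrimaryPrivate,
              object@nRecurrencePrivate, object@nGermline,
              object@nSegmentsPerSample)
  if (any(counts < 0L)) msg <- c(msg, "planted counts must be non-negative")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
  if (object@tumorPurity <= 0 || object@tumorPurity > 1)
    msg <- c(msg, "tumorPurity must be in (0, 1]")
  cf <- c(object@sharedClonalFraction, object@privateClonalFraction)
  if (any(cf <= 0 | cf > 1))
    msg <- c(msg, "clonal fractions must be in (0, 1]")
  if (length(object@bafCenters) != 2L ||
      any(object@bafCenters < 0 | object@bafCenters > 1))
    msg <- c(msg, "bafCenters must be two values in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' Defaults emulate the study cohort: 16 pairs split 7/16, 7/16, 2/16 across
#' the H3/IDH1-mutant, H3/IDH1-wildtype and NF1-germline groups, mean exome
#' depth 69x, one hypermutator pair, and single-copy events with BAF centers
#' at 0.2/0.8.
#'
#' @param nPairs number of primary/recurrence pairs.
#' @param groupFractions named fractions over the three molecular groups.
#' @param nSharedPassengers,nPrimaryPrivate,nRecurrencePrivate passenger
#'   counts planted per pair.
#' @param hypermutatorPairs indices of hypermutator pairs.
#' @param hypermutatorMultiplier passenger-count multiplier for those pairs.
#' @param callerSensitivity per-caller detection probability.
#' @param callerFpRate expected false positives per sample per caller.
#' @param meanDepth mean sequencing depth.
#' @param tumorPurity tumor cell fraction.
#' @param sharedClonalFraction,privateClonalFraction cancer-cell fractions of
#'   shared (clonal) and private (subclonal) passengers.
#' @param nGermline germline heterozygous variants per pair.
#' @param nTrackSites heterozygous sites in each coverage/BAF track.
#' @param nSegmentsPerSample planted structural events per tumor sample.
#' @param wholeGenomeCnlohPair pair indices whose recurrence receives
#'   genome-wide copy-neutral LOH.
#' @param bafCenters BAF centers for single-copy events.
#' @param nProbes,methShift,methNoiseSd,methPairSd methylation simulation
#'   parameters.
#' @param seed RNG seed; identical configs and seeds give byte-identical runs.
#' @return A [CohortConfig-class] object.
#' @examples
#' cohortConfig(nPairs = 4, seed = 1)
#' @export
cohortConfig <- function(nPairs = 16L,
                         groupFractions = c("H3/IDH1 mutant" = 7 / 16,
                                            "H3/IDH1 wildtype" = 7 / 16,
                                            "NF1 germline" = 2 / 16),
                         nSharedPassengers = 6L,
                         nPrimaryPrivate = 3L,
                         nRecurrencePrivate = 4L,
                         hypermutatorPairs = integer(0),
                         hypermutatorMultiplier = 10,
                         callerSensitivity = c(caller_A = 0.95,
                                               caller_B = 0.95,
                                               caller_C = 0.95),
                         callerFpRate = 2,
                         meanDepth = 69,
                         tumorPurity = 0.8,
                         sharedClonalFraction = 1,
                         privateClonalFraction = 0.8,
                         nGermline = 20L,
                         nTrackSites = 4000L,
                         nSegmentsPerSample = 2L,
                         wholeGenomeCnlohPair = integer(0),
                         bafCenters = c(0.2, 0.8),
                         nProbes = 8000L,
                         methShift = 0.3,
                         methNoiseSd = 0.05,
                         methPairSd = 0.02,
                         seed = 1L) {
  new("CohortConfig",
      nPairs = as.integer(nPairs),
      groupFractions = groupFractions,
      nSharedPassengers = as.integer(nSharedPassengers),
      nPrimaryPrivate = as.integer(nPrimaryPrivate),
      nRecurrencePrivate = as.integer(nRecurrencePrivate),
      hypermutatorPairs = as.integer(hypermutatorPairs),
      hypermutatorMultiplier = hypermutatorMultiplier,
      callerSensitivity = callerSensitivity,
      callerFpRate = callerFpRate,
      meanDepth = meanDepth,
      tumorPurity = tumorPurity,
      sharedClonalFraction = sharedClonalFraction,
      privateClonalFraction = privateClonalFraction,
      nGermline = as.integer(nGermline),
      nTrackSites = as.integer(nTrackSites),
      nSegmentsPerSample = as.integer(nSegmentsPerSample),
      wholeGenomeCnlohPair = as.integer(wholeGenomeCnlohPair),
      bafCenters = bafCenters,
      nProbes = as.integer(nProbes),
      methShift = methShift,
      methNoiseSd = methNoiseSd,
      methPairSd = methPairSd,
      seed = as.integer(seed))
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig\n")
  cat(sprintf("  %d pairs (%s)\n", object@nPairs,
              paste(sprintf("%s: %.0f%%", names(object@groupFractions),
                            100 * object@groupFractions), collapse = ", ")))
  cat(sprintf("  passengers/pair  : %d shared, %d primary-only, %d recurrence-only\n",
              object@nSharedPassengers, object@nPrimaryPrivate,
              object@nRecurrencePrivate))
  if (length(object@hypermutatorPairs))
    cat(sprintf("  hypermutator     : pair(s) %s (x%g)\n",
                paste(object@hypermutatorPairs, collapse = ","),
                object@hypermutatorMultiplier))
  cat(sprintf("  depth %gx, purity %.2f, caller FP rate %g, seed %d\n",
              object@meanDepth, object@tumorPurity, object@callerFpRate,
              object@seed))
})

#' Hierarchical methylation clustering result
#'
#' Wraps the average-linkage tree built on correlation distance over the most
#' variable probes, together with flat cluster labels at `k`.
#'
#' @slot tree the `hclust` object (merge heights are non-decreasing under
#'   average linkage on a proper dissimilarity).
#' @slot labels named integer vector of flat cluster labels per sample.
#' @slot k integer, number of flat clusters.
#' @slot distanceMethod character, "pearson" or "spearman".
#' @export
setClass("MethylationClusters",
  representation(
    tree = "ANY",
    labels = "integer",
    k = "integer",
    distanceMethod = "character"
  )
)

setValidity("MethylationClusters", function(object) {
  msg <- character(0)
  if (!inherits(object@tree, "hclust"))
    msg <- c(msg, "tree must be an hclust object")
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by sample")
  if (length(msg)) msg else TRUE
})

#' @describeIn MethylationClusters-class flat cluster labels per sample
#' @param x a `MethylationClusters`
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "MethylationClusters"))
  x@labels
}

#' @describeIn MethylationClusters-class the average-linkage tree
#' @export
clusterTree <- function(x) {
  stopifnot(is(x, "MethylationClusters"))
  x@tree
}

setMethod("show", "MethylationClusters", function(object) {
  cat(sprintf("MethylationClusters: %d samples, k = %d (%s distance)\n",
              length(object@labels), object@k, object@distanceMethod))
  print(table(object@labels))
})
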