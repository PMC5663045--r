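# Multi-caller consensus and the somatic filter cascade.
#
# Statuses: "somatic" (zero alt reads in the matched normal),
# "putative_somatic" (no normal; survives population filters and is rescued
# by COSMIC membership or high/medium functional impact), "review_flagged"
# (1..normalReviewThreshold-1 alt reads in the normal; the original study
# resolved these by manual inspection of alignments, which a pipeline cannot
# automate), "candidate" (consensus passed, somatic status not yet
# assessed), and "filtered" with machine-readable reasons.

#' Read per-caller VCFs into variant calls
#'
#' Parses one VCF 4.2 per caller (FORMAT `GT:AD:DP`) into a flat table of
#' per-caller observations. Multi-allelic records are split into one call
#' per ALT allele, with that allele's AD entry as `alt_reads`. Records
#' without parseable AD/DP are skipped with a warning. Indel left-alignment
#' is not attempted: variants are keyed by the exact
#' (chrom, pos, ref, alt) strings, which is safe for normalized input (and
#' for the bundled simulator) but a documented limitation for arbitrary
#' real-world VCFs.
#'
#' @param paths named character vector, one VCF path per caller; names are
#'   the caller labels.
#' @param sampleId sample identifier attached to every call.
#' @return data.frame with columns `sample_id, chrom, pos, ref, alt, caller,
#'   depth, alt_reads`.
#' @export
readCallerVcfs <- function(paths, sampleId) {
  if (is.null(names(paths)) || any(names(paths) == ""))
    stop("paths must be named by caller")
  out <- lapply(names(paths), function(cl) {
    v <- vcfR::read.vcfR(paths[[cl]], verbose = FALSE)
    fx <- vcfR::getFIX(v)
    if (is.null(fx) || nrow(v@gt) == 0) {
      return(data.frame(sample_id = character(0), chrom = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), caller = character(0),
                        depth = integer(0), alt_reads = integer(0)))
    }
    if (is.null(dim(fx))) fx <- t(as.matrix(fx))
    fx <- as.data.frame(fx, stringsAsFactors = FALSE)
    ad <- tryCatch(as.vector(vcfR::extract.gt(v, "AD")),
                   error = function(e) rep(NA_character_, nrow(fx)))
    dp <- tryCatch(as.vector(vcfR::extract.gt(v, "DP")),
                   error = function(e) rep(NA_character_, nrow(fx)))
    rows <- list()
    skipped <- 0L
    for (i in seq_len(nrow(fx))) {
      alts <- strsplit(fx$ALT[i], ",", fixed = TRUE)[[1]]
      adParts <- suppressWarnings(
        as.integer(strsplit(ad[i] %||% "", ",", fixed = TRUE)[[1]]))
      depth <- suppressWarnings(as.integer(dp[i]))
      if (is.na(depth) || length(adParts) < 2 || anyNA(adParts)) {
        skipped <- skipped + 1L
        next
      }
      for (k in seq_along(alts)) {
        altReads <- if (length(adParts) >= k + 1) adParts[k + 1] else NA
        if (is.na(altReads)) { skipped <- skipped + 1L; next }
        rows[[length(rows) + 1]] <- data.frame(
          sample_id = sampleId, chrom = fx$CHROM[i],
          pos = as.integer(fx$POS[i]), ref = fx$REF[i], alt = alts[k],
          caller = cl, depth = depth, alt_reads = altReads,
          stringsAsFactors = FALSE)
      }
    }
    if (skipped > 0)
      warning(sprintf("%s (%s): skipped %d record(s) without usable AD/DP",
                      sampleId, cl, skipped))
    if (length(rows)) do.call(rbind, rows) else
      data.frame(sample_id = character(0), chrom = character(0),
                 pos = integer(0), ref = character(0), alt = character(0),
                 caller = character(0), depth = integer(0),
                 alt_reads = integer(0))
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

emptyConsensus <- function() {
  data.frame(sample_id = character(0), chrom = character(0),
             pos = integer(0), ref = character(0), alt = character(0),
             key = character(0), n_callers = integer(0),
             callers_supporting = character(0), depth = integer(0),
             alt_reads = integer(0), maf = numeric(0),
             status = character(0), filter_reasons = character(0),
             stringsAsFactors = FALSE)
}

addReason <- function(reasons, new) {
  ifelse(reasons == "", new, paste(reasons, new, sep = ";"))
}

#' Merge per-caller calls into consensus variants
#'
#' Variants are keyed by exact (chrom, pos, ref, alt). A variant is retained
#' when at least `minCallers` callers report it and the representative
#' caller's read-support fraction (`alt_reads / depth`) meets
#' `minReadSupport`. When callers disagree on read counts, the caller with
#' the maximum depth is the representative (deterministic, and favors the
#' best-covered evidence). Failed rules are recorded in `filter_reasons`;
#' failing variants keep `status = "filtered"` rather than being dropped.
#'
#' When `gene` annotation is supplied and the policy sets
#' `goiReadSupportExempt`, the read-support rule is waived for genes of
#' interest so that the relaxed 5% MAF tier can act on them.
#'
#' @param calls data.frame from [readCallerVcfs()]; all rows must share one
#'   `sample_id`.
#' @param policy a [FilterPolicy-class].
#' @param geneOf optional named character vector mapping variant key
#'   (`chrom:pos:ref:alt`) to gene symbol, used only for the
#'   genes-of-interest read-support exemption.
#' @return One row per variant key: consensus columns plus `status`
#'   ("candidate" or "filtered") and `filter_reasons`.
#' @export
buildConsensus <- function(calls, policy = filterPolicy(), geneOf = NULL) {
  if (nrow(calls) == 0) return(emptyConsensus())
  if (length(unique(calls$sample_id)) != 1)
    stop("all calls must come from a single sample")
  stopifnot(all(calls$alt_reads <= calls$depth), all(calls$pos >= 1),
            all(calls$ref != calls$alt))
  calls$key <- variantKey(calls$chrom, calls$pos, calls$ref, calls$alt)
  split_ <- split(calls, calls$key)
  out <- do.call(rbind, lapply(split_, function(g) {
    rep_ <- g[which.max(g$depth), , drop = FALSE]
    data.frame(sample_id = rep_$sample_id, chrom = rep_$chrom,
               pos = rep_$pos, ref = rep_$ref, alt = rep_$alt,
               key = rep_$key, n_callers = length(unique(g$caller)),
               callers_supporting = paste(sort(unique(g$caller)),
                                          collapse = ","),
               depth = rep_$depth, alt_reads = rep_$alt_reads,
               maf = rep_$alt_reads / rep_$depth,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$status <- "candidate"
  out$filter_reasons <- ""
  low <- out$n_callers < policy@minCallers
  out$filter_reasons[low] <- addReason(out$filter_reasons[low],
                                       "insufficient_callers")
  exempt <- rep(FALSE, nrow(out))
  if (!is.null(geneOf) && policy@goiReadSupportExempt)
    exempt <- geneOf[out$key] %in% policy@genesOfInterest &
      !is.na(geneOf[out$key])
  weak <- out$maf < policy@minReadSupport & !exempt
  out$filter_reasons[weak] <- addReason(out$filter_reasons[weak],
                                        "low_read_support")
  out$status[low | weak] <- "filtered"
  out[order(out$chrom, out$pos, out$alt), , drop = FALSE]
}

#' Apply the two-tier mutant allele frequency filter
#'
#' A variant is kept when its gene is in the genes-of-interest set and
#' `maf >= goiMafMin` (inclusive 5% tier), or when `maf > otherMafMin`
#' (exclusive 15% tier) regardless of gene. Anything else is filtered with
#' reason `maf_below_threshold`. Already-filtered variants pass through
#' unchanged.
#'
#' @param variants consensus data.frame with `maf` and `gene` columns.
#' @param policy a [FilterPolicy-class].
#' @return The data.frame with updated `status` / `filter_reasons`.
#' @export
applyMafFilter <- function(variants, policy = filterPolicy()) {
  if (nrow(variants) == 0) return(variants)
  if (!"gene" %in% names(variants))
    stop("variants need a gene column (join the annotation first)")
  goi <- variants$gene %in% policy@genesOfInterest & !is.na(variants$gene)
  keep <- (goi & variants$maf >= policy@goiMafMin) |
    (variants$maf > policy@otherMafMin)
  fail <- !keep & variants$status != "filtered"
  variants$filter_reasons[fail] <- addReason(variants$filter_reasons[fail],
                                             "maf_below_threshold")
  variants$status[fail] <- "filtered"
  variants
}

#' Classify somatic status against a matched normal
#'
#' Zero alt reads in the normal make a variant somatic. A non-zero count
#' below the review threshold (default 2) is flagged for manual review, as
#' such observations are usually alignment artifacts but cannot be resolved
#' automatically. At or above the threshold, the variant is filtered as
#' present in the normal.
#'
#' @param variants consensus data.frame with a `normal_alt_reads` column.
#' @param policy a [FilterPolicy-class].
#' @return The data.frame with `status` in
#'   somatic/review_flagged/filtered for previously unfiltered rows.
#' @export
classifySomaticWithNormal <- function(variants, policy = filterPolicy()) {
  if (nrow(variants) == 0) return(variants)
  if (!"normal_alt_reads" %in% names(variants))
    stop("variants need a normal_alt_reads column")
  nar <- variants$normal_alt_reads
  if (any(is.na(nar)) || any(nar < 0))
    stop("normal_alt_reads must be non-negative for every variant")
  active <- variants$status != "filtered"
  variants$status[active & nar == 0] <- "somatic"
  variants$status[active & nar > 0 &
                    nar < policy@normalReviewThreshold] <- "review_flagged"
  inNormal <- active & nar >= policy@normalReviewThreshold
  variants$filter_reasons[inNormal] <-
    addReason(variants$filter_reasons[inNormal], "present_in_normal")
  variants$status[inNormal] <- "filtered"
  variants
}

#' Classify putative somatic status without a matched normal
#'
#' Removes likely germline polymorphisms using population allele
#' frequencies (filtered at >= 5e-4 in 1000 Genomes or EVS, >= 5e-5 in
#' ExAC; absent values are treated as 0, i.e. novel), then keeps the
#' survivors as `putative_somatic` only when rescued by COSMIC membership or
#' high/medium functional impact; everything else is filtered with reason
#' `no_somatic_evidence`.
#'
#' @param variants consensus data.frame with `pop_af_1000g`, `pop_af_evs`,
#'   `pop_af_exac`, `in_cosmic` and `functional_impact` columns.
#' @param policy a [FilterPolicy-class].
#' @return The data.frame with updated `status` / `filter_reasons`.
#' @export
classifySomaticWithoutNormal <- function(variants,
                                         policy = filterPolicy()) {
  if (nrow(variants) == 0) return(variants)
  for (col in c("pop_af_1000g", "pop_af_evs", "pop_af_exac")) {
    if (!col %in% names(variants)) variants[[col]] <- 0
    variants[[col]][is.na(variants[[col]])] <- 0
  }
  if (!"in_cosmic" %in% names(variants)) variants$in_cosmic <- FALSE
  if (!"functional_impact" %in% names(variants))
    variants$functional_impact <- "unknown"
  active <- variants$status != "filtered"
  poly <- variants$pop_af_1000g >= policy@popAfMax1000gEvs |
    variants$pop_af_evs >= policy@popAfMax1000gEvs |
    variants$pop_af_exac >= policy@popAfMaxExac
  hit <- active & poly
  variants$filter_reasons[hit] <- addReason(variants$filter_reasons[hit],
                                            "population_polymorphism")
  variants$status[hit] <- "filtered"
  active <- variants$status != "filtered"
  rescued <- variants$in_cosmic |
    variants$functional_impact %in% c("high", "medium")
  keep <- active & rescued
  drop <- active & !rescued
  variants$status[keep] <- "putative_somatic"
  variants$filter_reasons[drop] <- addReason(variants$filter_reasons[drop],
                                             "no_somatic_evidence")
  variants$status[drop] <- "filtered"
  variants
}

#' Run the full somatic filter cascade for one sample
#'
#' Joins annotation onto the consensus (by exact chrom:pos:ref:alt key),
#' applies the MAF tiers, then the matched-normal rule when normal counts
#' are available or the population-frequency + COSMIC/impact rescue path
#' when they are not. Each rule reads only its own fields, so the final
#' status of any variant is independent of rule order.
#'
#' @param calls per-caller calls for one sample ([readCallerVcfs()]).
#' @param annotation annotation data.frame ([readAnnotationTable()]).
#' @param normalCounts optional data.frame with `chrom, pos, ref, alt,
#'   normal_alt_reads`; when NULL the no-normal path is used.
#' @param policy a [FilterPolicy-class].
#' @return Annotated consensus data.frame with final `status` and
#'   `filter_reasons`.
#' @export
runFilterCascade <- function(calls, annotation, normalCounts = NULL,
                             policy = filterPolicy()) {
  annotation$key <- variantKey(annotation$chrom, annotation$pos,
                               annotation$ref, annotation$alt)
  geneOf <- setNames(annotation$gene, annotation$key)
  cons <- buildConsensus(calls, policy, geneOf = geneOf)
  if (nrow(cons) == 0) return(cons)
  idx <- match(cons$key, annotation$key)
  for (col in c("gene", "effect", "protein_change", "pop_af_1000g",
                "pop_af_evs", "pop_af_exac", "in_cosmic",
                "functional_impact")) {
    cons[[col]] <- if (col %in% names(annotation)) annotation[[col]][idx]
      else NA
  }
  cons$gene[is.na(cons$gene)] <- "."
  cons <- applyMafFilter(cons, policy)
  if (!is.null(normalCounts)) {
    nkey <- variantKey(normalCounts$chrom, normalCounts$pos,
                       normalCounts$ref, normalCounts$alt)
    cons$normal_alt_reads <- normalCounts$normal_alt_reads[
      match(cons$key, nkey)]
    # sites never observed in the normal data are taken as zero-alt
    cons$normal_alt_reads[is.na(cons$normal_alt_reads)] <- 0L
    cons <- classifySomaticWithNormal(cons, policy)
  } else {
    cons <- classifySomaticWithoutNormal(cons, policy)
  }
  cons
}

#' Retained (non-filtered) variants of a cascade result
#'
#' @param variants a cascade result data.frame.
#' @param includeReviewFlagged keep review-flagged variants (default TRUE;
#'   they are reported but marked).
#' @return The subset with status somatic/putative_somatic (and optionally
#'   review_flagged).
#' @export
retainedVariants <- function(variants, includeReviewFlagged = TRUE) {
  keep <- c("somatic", "putative_somatic",
            if (includeReviewFlagged) "review_flagged")
  variants[variants$status %in% keep, , drop = FALSE]
}
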