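# Joint coverage + B-allele-frequency copy-number calling: median-normalized
# log2 coverage ratios are segmented by recursive binary segmentation, the
# breakpoint union with allelic-imbalance segments partitions each
# chromosome, and each cell is classified from its (coverage, AI) states:
# gain -> amplification, loss -> deletion, neutral+imbalanced -> copy-neutral
# LOH, neutral+balanced -> none.

#' Bin and normalize tumor/normal coverage
#'
#' Groups consecutive track sites into bins of `binSize` targets per
#' chromosome, divides each sample's depths by its genome-wide median
#' (median, not mean, so focal events do not skew the library-size factor),
#' and reports the per-bin log2 ratio of normalized tumor over normalized
#' normal coverage. Bins whose mean normal depth falls below
#' `minNormalDepth` are dropped.
#'
#' @param track data.frame with `chrom, pos, tumor_depth, normal_depth`,
#'   tumor and normal on the same positions.
#' @param binSize sites per bin (default 25).
#' @param minNormalDepth minimum mean normal depth per bin (default 10).
#' @return data.frame of bins: `chrom, start, end, n_sites,
#'   tumor_depth_mean, normal_depth_mean, log2_ratio` (1-based inclusive
#'   coordinates).
#' @export
normalizeCoverage <- function(track, binSize = 25L, minNormalDepth = 10) {
  need <- c("chrom", "pos", "tumor_depth", "normal_depth")
  if (!all(need %in% names(track)))
    stop("track must have columns: ", paste(need, collapse = ", "))
  track <- track[order(track$chrom, track$pos), , drop = FALSE]
  tMed <- median(track$tumor_depth)
  nMed <- median(track$normal_depth)
  if (tMed <= 0 || nMed <= 0) stop("median depth must be positive")
  bins <- do.call(rbind, lapply(split(track, track$chrom), function(tr) {
    n <- nrow(tr)
    nBin <- floor(n / binSize)
    if (nBin == 0) return(NULL)
    g <- rep(seq_len(nBin), each = binSize)
    tr <- tr[seq_len(nBin * binSize), , drop = FALSE]
    data.frame(
      chrom = tr$chrom[1],
      start = tapply(tr$pos, g, min),
      end = tapply(tr$pos, g, max),
      n_sites = as.integer(binSize),
      tumor_depth_mean = as.numeric(tapply(tr$tumor_depth, g, mean)),
      normal_depth_mean = as.numeric(tapply(tr$normal_depth, g, mean)),
      stringsAsFactors = FALSE)
  }))
  if (is.null(bins)) stop("no chromosome has enough sites for one bin")
  rownames(bins) <- NULL
  bins <- bins[bins$normal_depth_mean >= minNormalDepth, , drop = FALSE]
  bins$log2_ratio <- log2((bins$tumor_depth_mean / tMed) /
                          (bins$normal_depth_mean / nMed))
  bins
}

bestSplit <- function(x, minBins) {
  n <- length(x)
  ks <- minBins:(n - minBins)
  if (!length(ks)) return(NULL)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  tot <- cs[n]
  tot2 <- cs2[n]
  eps <- 1e-10 * max(1, max(abs(x)))
  tstat <- vapply(ks, function(k) {
    n1 <- k; n2 <- n - k
    m1 <- cs[k] / n1
    m2 <- (tot - cs[k]) / n2
    ss1 <- cs2[k] - n1 * m1^2
    ss2 <- (tot2 - cs2[k]) - n2 * m2^2
    pooled <- (ss1 + ss2) / (n - 2)
    if (pooled <= eps^2) {
      if (abs(m1 - m2) <= eps) return(0) else return(Inf)
    }
    (m1 - m2) / sqrt(pooled * (1 / n1 + 1 / n2))
  }, 1.0)
  k <- ks[which.max(abs(tstat))]
  list(k = k, t = abs(tstat[which(ks == k)]))
}

#' Segment a log2-ratio profile by recursive binary segmentation
#'
#' Recursively splits at the point maximizing the two-sample t statistic
#' between the left and right means, accepting a split when |t| exceeds
#' `tThreshold`; segments shorter than `2 * minBins` are never split
#' further. Simpler than full circular binary segmentation but adequate for
#' the large events this caller targets.
#'
#' @param bins data.frame from [normalizeCoverage()] restricted to one
#'   chromosome (or any ordered numeric profile via `values`).
#' @param tThreshold split-acceptance threshold on |t| (default 5).
#' @param minBins minimum bins per segment (default 5).
#' @return data.frame of segments: `start_bin, end_bin, n_bins, mean_log2`
#'   plus `chrom, start, end` when bin coordinates are present.
#' @export
segmentLog2 <- function(bins, tThreshold = 5, minBins = 5L) {
  x <- if (is.data.frame(bins)) bins$log2_ratio else as.numeric(bins)
  n <- length(x)
  if (n == 0) stop("no bins to segment")
  bounds <- list()
  recurse <- function(i, j) {
    if (max(x[i:j]) - min(x[i:j]) < 1e-10 || j - i + 1 < 2 * minBins) {
      bounds[[length(bounds) + 1]] <<- c(i, j)
      return(invisible())
    }
    sp <- bestSplit(x[i:j], minBins)
    if (is.null(sp) || sp$t <= tThreshold) {
      bounds[[length(bounds) + 1]] <<- c(i, j)
      return(invisible())
    }
    recurse(i, i + sp$k - 1)
    recurse(i + sp$k, j)
  }
  recurse(1, n)
  bm <- do.call(rbind, bounds)
  bm <- bm[order(bm[, 1]), , drop = FALSE]
  out <- data.frame(start_bin = bm[, 1], end_bin = bm[, 2],
                    n_bins = bm[, 2] - bm[, 1] + 1L,
                    mean_log2 = vapply(seq_len(nrow(bm)), function(r)
                      mean(x[bm[r, 1]:bm[r, 2]]), 1.0))
  if (is.data.frame(bins) && all(c("chrom", "start", "end") %in%
                                 names(bins))) {
    out$chrom <- bins$chrom[out$start_bin]
    out$start <- bins$start[out$start_bin]
    out$end <- bins$end[out$end_bin]
  }
  out
}

#' Classify a copy-number event from its coverage and AI states
#'
#' The event class is a pure function of the two states: any gain is an
#' amplification and any loss a deletion regardless of allelic status;
#' coverage-neutral imbalance is copy-neutral LOH; neutral and balanced is
#' no event.
#'
#' @param coverageState character, `"gain"`, `"loss"` or `"neutral"`.
#' @param aiState character, `"imbalanced"` or `"balanced"`.
#' @return character vector of `"amplification"`, `"deletion"`, `"cnLOH"`
#'   or `"none"`.
#' @examples
#' classifyEvent("neutral", "imbalanced")
#' @export
classifyEvent <- function(coverageState, aiState) {
  stopifnot(all(coverageState %in% c("gain", "loss", "neutral")),
            all(aiState %in% c("imbalanced", "balanced")))
  ifelse(coverageState == "gain", "amplification",
  ifelse(coverageState == "loss", "deletion",
  ifelse(aiState == "imbalanced", "cnLOH", "none")))
}

#' Partition a chromosome by the union of coverage and AI breakpoints
#'
#' The union of all segment boundaries from both features defines a
#' partition of the convex hull. Because the two features estimate the same
#' underlying breakpoint at different resolutions (coverage bins versus AI
#' site windows), boundaries closer than `snapDistance` are clustered and
#' replaced by their median before partitioning, which prevents spurious
#' sliver cells at event edges. Each cell then takes its coverage state
#' from the coverage segment with maximal overlap (neutral when uncovered)
#' and is called imbalanced when AI segments cover at least half of it.
#' Adjacent cells with identical states are merged and classified via
#' [classifyEvent()].
#'
#' @param covSegments GRanges with a `coverage_state` metadata column.
#' @param aiSegments GRanges of allelic-imbalance segments.
#' @param snapDistance breakpoints closer than this are treated as one
#'   (default 5e6 bases, about the positional uncertainty of a 25-site AI
#'   window at exome marker density).
#' @return GRanges partition with `coverage_state`, `ai_state` and
#'   `event_class` metadata.
#' @export
unionSegments <- function(covSegments, aiSegments, snapDistance = 5e6) {
  chroms <- union(as.character(seqnames(covSegments)),
                  as.character(seqnames(aiSegments)))
  cells <- GRanges()
  for (cn in chroms) {
    cs <- covSegments[as.character(seqnames(covSegments)) == cn]
    as_ <- aiSegments[as.character(seqnames(aiSegments)) == cn]
    # breakpoints in half-open form, then back to 1-based inclusive cells
    bp <- sort(unique(c(start(cs) - 1L, end(cs), start(as_) - 1L,
                        end(as_))))
    if (length(bp) < 2) next
    lo <- min(bp); hi <- max(bp)
    # cluster breakpoints closer than snapDistance; keep cluster medians
    cl <- cumsum(c(1, diff(bp) > snapDistance))
    bp <- as.integer(round(tapply(bp, cl, median)))
    if (length(bp) < 2) {
      bp <- c(lo, hi)
    } else {
      bp[1] <- lo
      bp[length(bp)] <- hi
      bp <- sort(unique(bp))
    }
    st <- bp[-length(bp)] + 1L
    en <- bp[-1]
    cell <- GRanges(cn, IRanges(st, en))
    ovWith <- function(targets) {
      hits <- suppressWarnings(findOverlaps(cell, targets))
      w <- rep(0, length(cell))
      if (length(hits)) {
        ww <- pmin(end(cell)[queryHits(hits)],
                   end(targets)[subjectHits(hits)]) -
          pmax(start(cell)[queryHits(hits)],
               start(targets)[subjectHits(hits)]) + 1
        w <- vapply(seq_along(cell), function(i)
          sum(ww[queryHits(hits) == i]), 1.0)
      }
      w
    }
    covState <- rep("neutral", length(cell))
    hits <- suppressWarnings(findOverlaps(cell, cs))
    if (length(hits)) {
      ww <- pmin(end(cell)[queryHits(hits)], end(cs)[subjectHits(hits)]) -
        pmax(start(cell)[queryHits(hits)], start(cs)[subjectHits(hits)]) + 1
      for (i in unique(queryHits(hits))) {
        sel <- which(queryHits(hits) == i)
        covState[i] <- mcols(cs)$coverage_state[
          subjectHits(hits)[sel[which.max(ww[sel])]]]
      }
    }
    aiState <- ifelse(ovWith(as_) >= 0.5 * width(cell),
                      "imbalanced", "balanced")
    # merge adjacent cells with identical states
    keepRuns <- list()
    r <- 1L
    for (i in seq_along(cell)[-1]) {
      if (covState[i] == covState[i - 1] && aiState[i] == aiState[i - 1] &&
          start(cell)[i] == end(cell)[i - 1] + 1L) {
        r <- c(r, i)
      } else {
        keepRuns[[length(keepRuns) + 1]] <- r
        r <- i
      }
    }
    keepRuns[[length(keepRuns) + 1]] <- r
    merged <- GRanges(cn, IRanges(
      vapply(keepRuns, function(ii) start(cell)[ii[1]], 1L),
      vapply(keepRuns, function(ii) end(cell)[ii[length(ii)]], 1L)))
    mcols(merged)$coverage_state <- covState[vapply(keepRuns, `[`, 1L, 1)]
    mcols(merged)$ai_state <- aiState[vapply(keepRuns, `[`, 1L, 1)]
    cells <- suppressWarnings(c(cells, merged))
  }
  if (length(cells))
    mcols(cells)$event_class <- classifyEvent(mcols(cells)$coverage_state,
                                              mcols(cells)$ai_state)
  sort(cells)
}

#' Roll segment-level events up to chromosome arms
#'
#' An arm-level event of a class is emitted when cells of that class cover
#' at least `minFraction` of the arm's analyzable bases (bases covered by
#' any cell of the partition, whatever its class).
#'
#' @param events GRanges partition from [unionSegments()] (needs
#'   `event_class`).
#' @param armTable chromosome-arm table (default bundled GRCh37).
#' @param minFraction coverage fraction required (default 0.7).
#' @return data.frame `chrom, arm, event_class, fraction` of arm-level
#'   calls.
#' @export
armLevelCalls <- function(events, armTable = readArmTable(),
                          minFraction = 0.7) {
  out <- list()
  armsGr <- GRanges(armTable$chrom,
                    IRanges(armTable$start, armTable$end),
                    arm = armTable$arm)
  for (i in seq_along(armsGr)) {
    arm <- armsGr[i]
    hits <- suppressWarnings(findOverlaps(events, arm))
    if (!length(hits)) next
    qh <- queryHits(hits)
    ovWidth <- pmin(end(events)[qh], end(arm)) -
      pmax(start(events)[qh], start(arm)) + 1L
    analyzable <- sum(ovWidth)
    if (analyzable == 0) next
    for (cls in c("amplification", "deletion", "cnLOH")) {
      w <- sum(ovWidth[mcols(events)$event_class[qh] == cls])
      frac <- w / analyzable
      if (frac >= minFraction)
        out[[length(out) + 1]] <- data.frame(
          chrom = as.character(seqnames(arm)), arm = mcols(arm)$arm,
          event_class = cls, fraction = frac, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), arm = character(0),
                      event_class = character(0), fraction = numeric(0)))
  do.call(rbind, out)
}

#' Joint coverage + BAF copy-number calling for one tumor/normal pair
#'
#' Runs the full caller: coverage binning and median normalization, binary
#' segmentation of the log2 ratio per chromosome, allelic-imbalance
#' detection on the same track, the breakpoint-union partition, event
#' classification, and arm-level rollups.
#'
#' @param track coverage/BAF track with matched-normal depths
#'   ([readBafTrack()]).
#' @param binSize sites per coverage bin.
#' @param gainThreshold,lossThreshold log2-ratio thresholds for gain/loss
#'   states (defaults +0.3 / -0.3, chosen to catch single-copy events at
#'   purity >= 0.6).
#' @param tThreshold,minBins segmentation parameters ([segmentLog2()]).
#' @param aiWindow,aiAlpha AI detection parameters ([detectAI()]).
#' @param minDepth minimum per-site depth for heterozygous-site selection.
#' @param snapDistance breakpoint snapping tolerance ([unionSegments()]);
#'   by default 1.5 AI windows of median marker spacing, the positional
#'   uncertainty of an AI boundary.
#' @param armTable chromosome-arm table.
#' @param armMinFraction arm-level coverage fraction ([armLevelCalls()]).
#' @return A list with `bins`, `coverageSegments` (GRanges),
#'   `aiSegments` (GRanges), `events` (GRanges partition with
#'   `event_class`), and `armCalls` (data.frame).
#' @export
callCNV <- function(track, binSize = 25L, gainThreshold = 0.3,
                    lossThreshold = -0.3, tThreshold = 5, minBins = 5L,
                    aiWindow = 25L, aiAlpha = 0.05, minDepth = 10,
                    snapDistance = NULL, armTable = readArmTable(),
                    armMinFraction = 0.7) {
  bins <- normalizeCoverage(track, binSize = binSize)
  covSegs <- do.call(rbind, lapply(split(bins, bins$chrom), function(b) {
    if (nrow(b) == 0) return(NULL)
    segmentLog2(b, tThreshold = tThreshold, minBins = minBins)
  }))
  covGr <- GRanges(covSegs$chrom, IRanges(covSegs$start, covSegs$end))
  mcols(covGr)$mean_log2 <- covSegs$mean_log2
  mcols(covGr)$coverage_state <-
    ifelse(covSegs$mean_log2 >= gainThreshold, "gain",
    ifelse(covSegs$mean_log2 <= lossThreshold, "loss", "neutral"))
  sites <- selectHetSites(readBafTrackDF(track), minDepth = minDepth)
  aiGr <- detectAI(sites, window = aiWindow, alpha = aiAlpha,
                   armTable = armTable)
  if (is.null(snapDistance)) {
    # breakpoint uncertainty is about one AI window of markers
    spacing <- median(unlist(lapply(split(sites$pos, sites$chrom), diff)))
    snapDistance <- if (is.finite(spacing)) 1.5 * aiWindow * spacing else 0
  }
  events <- unionSegments(covGr, aiGr, snapDistance = snapDistance)
  list(bins = bins, coverageSegments = sort(covGr), aiSegments = aiGr,
       events = events,
       armCalls = armLevelCalls(events, armTable, armMinFraction))
}
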