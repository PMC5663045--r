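# Allelic imbalance detection from tumor B-allele frequencies.
#
# The statistic: at a heterozygous site with depth d, the null
# (balanced-allele) BAF is Binomial(d, 0.5)/d, so z = (baf - 0.5) * 2*sqrt(d)
# is approximately standard normal. Over non-overlapping windows of `window`
# consecutive sites per chromosome arm, the score T = sum(z^2) is compared
# with its null chi-square(window) upper tail; Benjamini-Hochberg correction
# is applied across all windows of the sample, and runs of adjacent
# significant windows are merged into maximal segments trimmed to their
# first/last site. The test is self-contained per window (no genome-wide
# reference), so it keeps full power when imbalance is genome-wide, e.g.
# after whole-genome copy-neutral LOH; squaring makes every result
# invariant under the allele relabelling baf -> 1 - baf.

#' Select candidate heterozygous sites from a track
#'
#' Keeps sites with sufficient depth; when a matched-normal track is
#' supplied, sites must be heterozygous in the normal (normal BAF inside
#' `hetBand`), otherwise tumor BAF in (0.05, 0.95) is used to exclude
#' homozygous sites, mirroring tumor-only operation.
#'
#' @param track data.frame from [readBafTrack()] (needs a `baf` column).
#' @param minDepth minimum `ref_reads + alt_reads` (default 10).
#' @param hetBand normal-BAF band defining heterozygosity
#'   (default c(0.3, 0.7)).
#' @param normalTrack optional matched-normal track with `chrom, pos, baf`.
#' @return The filtered track, sorted by chromosome and position.
#' @export
selectHetSites <- function(track, minDepth = 10, hetBand = c(0.3, 0.7),
                           normalTrack = NULL) {
  if (!"baf" %in% names(track))
    track$baf <- track$alt_reads / (track$ref_reads + track$alt_reads)
  depth <- track$ref_reads + track$alt_reads
  keep <- depth >= minDepth
  if (!is.null(normalTrack)) {
    nkey <- paste(normalTrack$chrom, normalTrack$pos)
    nbaf <- normalTrack$baf[match(paste(track$chrom, track$pos), nkey)]
    keep <- keep & !is.na(nbaf) & nbaf >= hetBand[1] & nbaf <= hetBand[2]
  } else {
    keep <- keep & track$baf > 0.05 & track$baf < 0.95
  }
  out <- track[keep, , drop = FALSE]
  out[order(out$chrom, out$pos), , drop = FALSE]
}

armOfSites <- function(chrom, pos, armTable) {
  arm <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(armTable))) {
    hit <- chrom == armTable$chrom[i] & pos >= armTable$start[i] &
      pos <= armTable$end[i]
    arm[hit] <- armTable$arm[i]
  }
  arm
}

#' Detect allelic-imbalance segments
#'
#' Windows are non-overlapping runs of at least `window` consecutive sites
#' per chromosome arm; within each, the depth-weighted score
#' `T = sum(4 * depth * (baf - 0.5)^2)` is referred to its null
#' chi-square distribution (upper tail), with Benjamini-Hochberg correction
#' across all windows of the sample and merging of adjacent significant
#' windows into maximal segments. Chromosome arms with fewer than `window`
#' usable sites yield no call.
#'
#' @param sites selected heterozygous sites ([selectHetSites()]).
#' @param window sites per non-overlapping window (default 25).
#' @param alpha Benjamini-Hochberg threshold across all windows of the
#'   sample (default 0.05).
#' @param minDev minimum mean folded BAF deviation a significant window must
#'   show before it is reported (default 0.1): an effect-size floor that
#'   keeps borderline noise windows out when strong events elsewhere relax
#'   the BH cut, while staying below the ~0.15 deviation of a single-copy
#'   event at 60% aberrant-cell fraction.
#' @param armTable chromosome-arm table (default bundled GRCh37).
#' @return A [GenomicRanges::GRanges] of AI segments with metadata `arm`,
#'   `n_sites`, `mean_folded_dev`, `q_value`.
#' @examples
#' set.seed(1)
#' seg <- GenomicRanges::GRanges("chr2", IRanges::IRanges(5e7, 1.5e8),
#'                               event_class = "AI")
#' tr <- simulateTracks(seg, nSites = 2000, meanDepth = 100)
#' ai <- detectAI(selectHetSites(readBafTrackDF(tr)))
#' @export
detectAI <- function(sites, window = 25L, alpha = 0.05, minDev = 0.1,
                     armTable = readArmTable()) {
  empty <- GRanges()
  if (nrow(sites) == 0) return(empty)
  if (!"baf" %in% names(sites))
    sites$baf <- sites$alt_reads / (sites$ref_reads + sites$alt_reads)
  sites$folded <- abs(sites$baf - 0.5)
  sites$arm <- armOfSites(sites$chrom, sites$pos, armTable)
  sites <- sites[!is.na(sites$arm), , drop = FALSE]
  if (nrow(sites) == 0) return(empty)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  globalFolded <- sites$folded

  # an arm's sites are divided into floor(n/window) contiguous chunks of
  # (nearly) equal size, so every site belongs to a window of >= `window`
  # sites; arms with fewer than `window` sites yield no call
  winTab <- list()
  for (key in unique(paste(sites$chrom, sites$arm))) {
    idx <- which(paste(sites$chrom, sites$arm) == key)
    nWin <- floor(length(idx) / window)
    if (nWin == 0) next
    sizes <- rep(floor(length(idx) / nWin), nWin)
    extra <- length(idx) - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    stops <- cumsum(sizes)
    starts <- c(1L, stops[-length(stops)] + 1L)
    for (w in seq_len(nWin)) {
      wi <- idx[starts[w]:stops[w]]
      winTab[[length(winTab) + 1]] <- list(
        chrom = sites$chrom[wi[1]], arm = sites$arm[wi[1]],
        start = sites$pos[wi[1]], end = sites$pos[wi[length(wi)]],
        idx = wi, winNo = w)
    }
  }
  if (!length(winTab)) return(empty)

  siteDepth <- sites$ref_reads + sites$alt_reads
  z2 <- (sites$baf - 0.5)^2 * 4 * siteDepth
  pvals <- vapply(winTab, function(w) {
    pchisq(sum(z2[w$idx]), df = length(w$idx), lower.tail = FALSE)
  }, 1.0)
  pvals[is.na(pvals)] <- 1
  qvals <- p.adjust(pvals, method = "BH")
  winDev <- vapply(winTab, function(w) mean(globalFolded[w$idx]), 1.0)
  sig <- which(qvals <= alpha & winDev >= minDev)
  if (!length(sig)) return(empty)

  # merge runs of adjacent significant windows within an arm
  segs <- list()
  ord <- sig[order(vapply(winTab[sig], function(w)
    paste(w$chrom, w$arm), ""),
    vapply(winTab[sig], function(w) w$winNo, 1))]
  cur <- NULL
  for (j in ord) {
    w <- winTab[[j]]
    if (!is.null(cur) && cur$chrom == w$chrom && cur$arm == w$arm &&
        w$winNo == cur$lastWin + 1) {
      cur$end <- w$end
      cur$idx <- c(cur$idx, w$idx)
      cur$q <- min(cur$q, qvals[j])
      cur$lastWin <- w$winNo
    } else {
      if (!is.null(cur)) segs[[length(segs) + 1]] <- cur
      cur <- list(chrom = w$chrom, arm = w$arm, start = w$start,
                  end = w$end, idx = w$idx, q = qvals[j], lastWin = w$winNo)
    }
  }
  segs[[length(segs) + 1]] <- cur

  gr <- GRanges(
    vapply(segs, `[[`, "", "chrom"),
    IRanges(vapply(segs, `[[`, 1, "start"), vapply(segs, `[[`, 1, "end"))
  )
  mcols(gr)$arm <- vapply(segs, `[[`, "", "arm")
  mcols(gr)$n_sites <- vapply(segs, function(s) length(s$idx), 1L)
  mcols(gr)$mean_folded_dev <- vapply(segs, function(s)
    mean(globalFolded[s$idx]), 1.0)
  mcols(gr)$q_value <- vapply(segs, `[[`, 1.0, "q")
  sort(gr)
}

#' Wrap a simulated track as a BAF track
#'
#' Convenience for in-memory tracks from [simulateTracks()]: adds the `baf`
#' column that [readBafTrack()] computes when reading from disk.
#'
#' @param track a track data.frame.
#' @return The track with a `baf` column.
#' @export
readBafTrackDF <- function(track) {
  track$baf <- track$alt_reads / (track$ref_reads + track$alt_reads)
  track[order(track$chrom, track$pos), , drop = FALSE]
}

#' Compare AI regions between primary and recurrence
#'
#' A segment is shared when any segment of the partner sample on the same
#' chromosome overlaps it by at least 1 bp; segments are counted once each,
#' per list, regardless of region size. A segment split across two partner
#' segments therefore contributes asymmetric shared counts, which are
#' reported separately.
#'
#' @param primarySegments,recurrenceSegments GRanges from [detectAI()].
#' @return A named integer vector: `shared_primary`, `shared_recurrence`,
#'   `primary_only`, `recurrence_only`, and `shared` (the primary-list
#'   shared count, equal to `shared_recurrence` whenever the overlap is
#'   one-to-one).
#' @export
compareAIRegions <- function(primarySegments, recurrenceSegments) {
  hits <- suppressWarnings(
    findOverlaps(primarySegments, recurrenceSegments))
  sharedP <- length(unique(queryHits(hits)))
  sharedR <- length(unique(subjectHits(hits)))
  c(shared = sharedP,
    shared_primary = sharedP,
    shared_recurrence = sharedR,
    primary_only = length(primarySegments) - sharedP,
    recurrence_only = length(recurrenceSegments) - sharedR)
}
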