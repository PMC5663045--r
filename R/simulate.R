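# Synthetic paired-tumor cohort generator. Everything downstream (consensus
# filtering, temporal partitioning, AI/CNV calling, methylation clustering)
# is validated against the ground truth planted here.

.AA <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]

# Grouping drivers carry canonical hotspot annotations; partner mutations
# respect the co-occurrence rule (H3/IDH1 drivers always with a TP53 or,
# for histone 3.1, an ACVR1 partner).
.DRIVER_SETS <- list(
  list(gene = "H3F3A", protein = "K27M", chrom = "chr1", pos = 226252135,
       partner = "TP53", meth = "K27M", midline = TRUE),
  list(gene = "H3F3A", protein = "G34V", chrom = "chr1", pos = 226252155,
       partner = "TP53", meth = "G34", midline = FALSE),
  list(gene = "HIST1H3B", protein = "K27M", chrom = "chr6", pos = 26031979,
       partner = "ACVR1", meth = "K27M", midline = TRUE),
  list(gene = "IDH1", protein = "R132H", chrom = "chr2", pos = 209113112,
       partner = "TP53", meth = "IDH1", midline = FALSE)
)
.PARTNER_LOCI <- list(
  TP53 = list(chrom = "chr17", pos = 7577121, protein = "R273C"),
  ACVR1 = list(chrom = "chr2", pos = 158622516, protein = "R258G")
)
.NF1_LOCUS <- list(chrom = "chr17", pos = 29553485, protein = "Q1174fs")

chromLengths <- function(armTable = readArmTable()) {
  lens <- tapply(as.numeric(armTable$end), armTable$chrom,
                 max)[unique(armTable$chrom)]
  setNames(as.numeric(lens), names(lens))
}

#' Simulate read support at a heterozygous somatic variant
#'
#' Alt reads are binomially thinned by tumor purity and the variant's cancer
#' cell (clonal) fraction: on a diploid background a fully clonal
#' heterozygous variant in a pure tumor has expected mutant allele frequency
#' 0.5, scaled down by `purity * clonalFraction`.
#'
#' @param clonalFraction cancer-cell fraction of the variant, in [0, 1].
#' @param purity tumor purity, in (0, 1].
#' @param depth total read depth (positive integer).
#' @return A list with integer `ref_reads` and `alt_reads`
#'   (`alt_reads ~ Binomial(depth, purity * clonalFraction / 2)`).
#' @examples
#' set.seed(1)
#' simulateReadSupport(1, 0.6, 100)
#' @export
simulateReadSupport <- function(clonalFraction, purity, depth) {
  if (any(clonalFraction < 0) || any(clonalFraction > 1))
    stop("clonalFraction must be in [0, 1]")
  if (any(purity <= 0) || any(purity > 1))
    stop("purity must be in (0, 1]")
  if (any(depth < 1)) stop("depth must be a positive integer")
  alt <- rbinom(length(depth), size = depth,
                prob = purity * clonalFraction / 2)
  list(ref_reads = depth - alt, alt_reads = alt)
}

#' Simulate a coverage/BAF track with planted structural events
#'
#' Emits per-site tumor allele counts and tumor/normal depths over randomly
#' placed heterozygous sites. Off any planted segment, BAF is binomial around
#' 0.5 and the coverage ratio is flat. On planted events: allelic imbalance
#' (AI) and copy-neutral LOH shift BAF symmetrically to the configured
#' centers without altering coverage; deletions shift BAF and depress
#' coverage; amplifications raise coverage (and skew BAF towards the 2:1
#' allele ratio).
#'
#' @param segments a [GenomicRanges::GRanges] of planted events with a
#'   metadata column `event_class` in
#'   `c("amplification", "deletion", "cnLOH", "AI")`; must not overlap.
#' @param nSites number of heterozygous sites genome-wide.
#' @param meanDepth mean sequencing depth (tumor off-segment and normal).
#' @param purity aberrant cell fraction used for the coverage shift.
#' @param bafCenters length-2 BAF centers for single-copy events
#'   (default 0.2/0.8).
#' @param chromLens named vector of chromosome lengths; defaults to the
#'   bundled GRCh37 table.
#' @return A data.frame track: `chrom, pos, ref_reads, alt_reads,
#'   tumor_depth, normal_depth` (1-based positions, sorted).
#' @examples
#' set.seed(1)
#' seg <- GenomicRanges::GRanges("chr17", IRanges::IRanges(3e7, 7e7),
#'                               event_class = "cnLOH")
#' tr <- simulateTracks(seg, nSites = 500, meanDepth = 80)
#' @export
simulateTracks <- function(segments = GenomicRanges::GRanges(),
                           nSites = 4000, meanDepth = 69, purity = 1,
                           bafCenters = c(0.2, 0.8), chromLens = NULL) {
  if (is.null(chromLens)) chromLens <- chromLengths()
  if (length(segments)) {
    if (!"event_class" %in% names(mcols(segments)))
      stop("segments need an event_class metadata column")
    if (length(GenomicRanges::reduce(segments)) < length(segments) ||
        sum(width(GenomicRanges::reduce(segments))) < sum(width(segments)))
      stop("planted segments must not overlap within a sample")
    segChrom <- as.character(seqnames(segments))
    if (!all(segChrom %in% names(chromLens)))
      stop("segment chromosome outside the genome table")
    if (any(end(segments) > chromLens[segChrom]))
      stop("planted segments exceed chromosome bounds")
  }
  # allocate sites across chromosomes proportionally to length
  chromLens <- setNames(as.numeric(chromLens), names(chromLens))
  nSites <- as.numeric(nSites)
  alloc <- floor(nSites * chromLens / sum(chromLens))
  rem <- nSites - sum(alloc)
  if (rem > 0) {
    extra <- order(nSites * chromLens / sum(chromLens) - alloc,
                   decreasing = TRUE)[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1L
  }
  chrom <- rep(names(chromLens), alloc)
  pos <- unlist(lapply(names(chromLens), function(cn) {
    if (alloc[cn] == 0) return(integer(0))
    sort(sample.int(chromLens[[cn]], alloc[[cn]]))
  }), use.names = FALSE)
  n <- length(pos)
  cls <- rep("none", n)
  if (length(segments)) {
    sitesGr <- GRanges(chrom, IRanges(pos, pos))
    hits <- suppressWarnings(findOverlaps(sitesGr, segments))
    cls[queryHits(hits)] <- mcols(segments)$event_class[subjectHits(hits)]
  }
  covMult <- ifelse(cls == "amplification", (2 + purity) / 2,
             ifelse(cls == "deletion", (2 - purity) / 2, 1))
  tumorDepth <- pmax(1L, rpois(n, meanDepth * covMult))
  normalDepth <- pmax(1L, rpois(n, meanDepth))
  pHi <- (1 + purity) / (2 + purity)   # BAF skew of the gained allele
  p <- rep(0.5, n)
  shifted <- cls %in% c("AI", "cnLOH", "deletion")
  p[shifted] <- sample(bafCenters, sum(shifted), replace = TRUE)
  ampl <- cls == "amplification"
  p[ampl] <- sample(c(1 - pHi, pHi), sum(ampl), replace = TRUE)
  alt <- rbinom(n, tumorDepth, p)
  data.frame(chrom = chrom, pos = pos,
             ref_reads = tumorDepth - alt, alt_reads = alt,
             tumor_depth = tumorDepth, normal_depth = normalDepth,
             stringsAsFactors = FALSE)
}

writeSimpleVcf <- function(vars, sampleId, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=gliomaPairs-simulator",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleId, sep = "\t")
  ), con)
  if (nrow(vars)) {
    vars <- vars[order(vars$chrom, vars$pos, vars$alt), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD:DP\t0/1:%d,%d:%d",
                    vars$chrom, vars$pos, vars$ref, vars$alt,
                    vars$depth - vars$alt_reads, vars$alt_reads, vars$depth)
    writeLines(body, con)
  }
  invisible(path)
}

randomAlleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  list(ref = ref, alt = unname(alt))
}

randomPositions <- function(n, chromLens, used) {
  out <- data.frame(chrom = character(0), pos = integer(0))
  while (nrow(out) < n) {
    m <- n - nrow(out)
    chrom <- sample(names(chromLens), m, replace = TRUE,
                    prob = chromLens / sum(chromLens))
    pos <- vapply(chrom, function(cn) sample.int(chromLens[[cn]], 1), 1L)
    key <- paste(chrom, pos)
    keep <- !(key %in% used) & !duplicated(key)
    used <- c(used, key[keep])
    out <- rbind(out, data.frame(chrom = chrom[keep], pos = pos[keep],
                                 stringsAsFactors = FALSE))
  }
  list(sites = out, used = used)
}

randomProtein <- function(n) {
  paste0(sample(.AA, n, replace = TRUE),
         sample(100:900, n, replace = TRUE),
         sample(.AA, n, replace = TRUE))
}

plantSegments <- function(nSeg, chromLens, minLen = 2e7, maxLen = 6e7,
                          classes = c("amplification", "deletion",
                                      "cnLOH", "AI")) {
  if (nSeg == 0) return(GRanges())
  out <- GRanges()
  tries <- 0
  while (length(out) < nSeg && tries < 200) {
    tries <- tries + 1
    cn <- sample(names(chromLens), 1, prob = chromLens / sum(chromLens))
    len <- round(runif(1, minLen, min(maxLen, chromLens[[cn]] - 1)))
    st <- sample.int(chromLens[[cn]] - len, 1)
    cand <- GRanges(cn, IRanges(st, st + len - 1L),
                    event_class = sample(classes, 1))
    if (!length(suppressWarnings(findOverlaps(cand, out))))
      out <- suppressWarnings(c(out, cand))
  }
  out
}

#' Simulate a paired primary/recurrence tumor cohort with ground truth
#'
#' Emits a complete run directory: per-caller VCFs for each tumor and for the
#' matched normal, per-sample coverage/BAF tracks with planted structural
#' events, a probe-level beta matrix with methylation subgroup structure, a
#' cohort annotation table, matched-normal allele counts, a clinical table,
#' the planted ground truth, and a JSON manifest. Identical configurations
#' and seeds produce byte-identical output files.
#'
#' Planted biology follows the cohort the package models: every H3/IDH1
#' grouping driver is clonal, shared between primary and recurrence, and
#' accompanied by its obligate partner (TP53, or ACVR1 for the histone 3.1
#' K27M); NF1-germline pairs carry a germline truncating NF1 variant and
#' acquire 17q copy-neutral LOH at recurrence; optional hypermutator pairs
#' have their passenger counts multiplied.
#'
#' @param config a [CohortConfig-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `dir`, `config` and `groundTruth`
#'   (per-sample variants, planted segments as a GRangesList, molecular group
#'   and methylation cluster per pair).
#' @examples
#' \donttest{
#' sim <- simulateCohort(cohortConfig(nPairs = 2, nTrackSites = 500,
#'                                    nProbes = 1000, seed = 7),
#'                       dir = tempfile())
#' names(sim$groundTruth)
#' }
#' @export
simulateCohort <- function(config, dir = tempfile("cohort_")) {
  stopifnot(is(config, "CohortConfig"))
  methods::validObject(config)
  set.seed(config@seed)
  arms <- readArmTable()
  lens <- chromLengths(arms)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("vcf", "tracks", "normal_counts", "methylation",
                "ground_truth"))
    dir.create(file.path(dir, sub), showWarnings = FALSE)

  nPairs <- config@nPairs
  fr <- config@groupFractions[.GROUPS]
  nGroup <- floor(fr * nPairs)
  while (sum(nGroup) < nPairs) {
    i <- which.max(fr * nPairs - nGroup)
    nGroup[i] <- nGroup[i] + 1L
  }
  groups <- rep(.GROUPS, nGroup)
  pairIds <- sprintf("SIM%02d", seq_len(nPairs))

  usedPos <- character(0)
  allVariants <- list()
  annotation <- list()
  trueSegments <- list()
  clinical <- list()
  methCluster <- character(nPairs)
  geneGroupPool <- setdiff(readPathwayMap()$gene,
                           c("H3F3A", "HIST1H3B", "IDH1", "NF1"))
  driverIdx <- 0

  makePassengers <- function(nv, pair, timing, cf) {
    if (nv == 0) return(NULL)
    rp <- randomPositions(nv, lens, usedPos)
    usedPos <<- rp$used
    al <- randomAlleles(nv)
    fromPool <- runif(nv) < 0.3
    genes <- ifelse(fromPool,
                    sample(geneGroupPool, nv, replace = TRUE),
                    sprintf("GENE%05d", sample.int(99999, nv)))
    data.frame(pair = pair, timing = timing,
               chrom = rp$sites$chrom, pos = rp$sites$pos,
               ref = al$ref, alt = al$alt, gene = genes,
               effect = sample(c("missense", "frameshift", "stopgain"),
                               nv, replace = TRUE, prob = c(.8, .1, .1)),
               protein_change = randomProtein(nv),
               clonal_fraction = cf, germline = FALSE,
               in_cosmic = runif(nv) < 0.1,
               functional_impact = sample(c("high", "medium", "low",
                                            "unknown"),
                                          nv, replace = TRUE,
                                          prob = c(.15, .35, .35, .15)),
               pop_af_1000g = 0, pop_af_evs = 0, pop_af_exac = 0,
               stringsAsFactors = FALSE)
  }

  fixedVariant <- function(pair, timing, gene, chrom, pos, protein, effect,
                           cf = 1, germline = FALSE) {
    usedPos <<- c(usedPos, paste(chrom, pos))
    data.frame(pair = pair, timing = timing, chrom = chrom, pos = pos,
               ref = "C", alt = "T", gene = gene, effect = effect,
               protein_change = protein, clonal_fraction = cf,
               germline = germline, in_cosmic = TRUE,
               functional_impact = "high",
               pop_af_1000g = 0, pop_af_evs = 0, pop_af_exac = 0,
               stringsAsFactors = FALSE)
  }

  for (i in seq_len(nPairs)) {
    pid <- pairIds[i]
    grp <- groups[i]
    mult <- if (i %in% config@hypermutatorPairs)
      config@hypermutatorMultiplier else 1
    vlist <- list()
    midline <- FALSE
    if (grp == "H3/IDH1 mutant") {
      driverIdx <- driverIdx + 1
      ds <- .DRIVER_SETS[[(driverIdx - 1) %% length(.DRIVER_SETS) + 1]]
      part <- .PARTNER_LOCI[[ds$partner]]
      vlist$driver <- fixedVariant(pid, "shared", ds$gene, ds$chrom,
                                   ds$pos + i, ds$protein, "missense")
      vlist$partner <- fixedVariant(pid, "shared", ds$partner, part$chrom,
                                    part$pos + i, part$protein, "missense")
      methCluster[i] <- ds$meth
      midline <- ds$midline
    } else if (grp == "NF1 germline") {
      vlist$nf1 <- fixedVariant(pid, "shared", "NF1", .NF1_LOCUS$chrom,
                                .NF1_LOCUS$pos + i, .NF1_LOCUS$protein,
                                "frameshift", germline = TRUE)
      methCluster[i] <- "WT"
    } else {
      vlist$tp53 <- fixedVariant(pid, "shared", "TP53",
                                 .PARTNER_LOCI$TP53$chrom,
                                 .PARTNER_LOCI$TP53$pos + 100 + i,
                                 randomProtein(1), "missense")
      methCluster[i] <- "WT"
    }
    vlist$shared <- makePassengers(round(config@nSharedPassengers * mult),
                                   pid, "shared",
                                   config@sharedClonalFraction)
    vlist$pOnly <- makePassengers(round(config@nPrimaryPrivate * mult),
                                  pid, "primary",
                                  config@privateClonalFraction)
    vlist$rOnly <- makePassengers(round(config@nRecurrencePrivate * mult),
                                  pid, "recurrence",
                                  config@privateClonalFraction)
    if (config@nGermline > 0) {
      g <- makePassengers(config@nGermline, pid, "germline", 1)
      g$germline <- TRUE
      g$in_cosmic <- FALSE
      g$functional_impact <- "low"
      common <- runif(nrow(g)) < 0.3      # known polymorphisms
      g$pop_af_1000g[common] <- 0.01
      g$pop_af_exac[common] <- 0.01
      vlist$germ <- g
    }
    allVariants[[pid]] <- do.call(rbind, vlist)

    # planted structural events: first half shared, rest private
    nSeg <- config@nSegmentsPerSample
    shared <- plantSegments(ceiling(nSeg / 2), lens)
    segP <- shared
    k <- nSeg - length(shared)
    while (k > 0) {
      cand <- plantSegments(1, lens)
      if (!length(suppressWarnings(findOverlaps(cand, segP)))) {
        segP <- suppressWarnings(c(segP, cand)); k <- k - 1
      }
    }
    segR <- shared
    if (grp == "NF1 germline") {
      q17 <- arms[arms$chrom == "chr17" & arms$arm == "q", ]
      cand <- GRanges("chr17", IRanges(q17$start, q17$end),
                      event_class = "cnLOH")
      if (!length(suppressWarnings(findOverlaps(cand, segR))))
        segR <- suppressWarnings(c(segR, cand))
    }
    k <- nSeg - length(segR) + length(shared)
    while (k > 0) {
      cand <- plantSegments(1, lens)
      if (!length(suppressWarnings(findOverlaps(cand, segR)))) {
        segR <- suppressWarnings(c(segR, cand)); k <- k - 1
      }
    }
    if (i %in% config@wholeGenomeCnlohPair) {
      segR <- GRanges(arms$chrom, IRanges(arms$start, arms$end),
                      event_class = "cnLOH")
    }
    trueSegments[[paste0(pid, "_P")]] <- sort(segP)
    trueSegments[[paste0(pid, "_R")]] <- sort(segR)

    clinical[[pid]] <- data.frame(
      molecular_group = grp, case_id = pid,
      age_years = sample(4:29, 1),
      sex = sample(c("M", "F"), 1),
      primary_dx = "GBM", recurrence_dx = "GBM",
      ttp_months = round(exp(rnorm(1, log(13), 0.6)), 1),
      interval_months = NA,
      location = if (midline) "midline" else "hemisphere",
      sublocation = if (midline) sample(c("Pons", "Spine", "Thalamus"), 1)
        else NA,
      surgery1 = sample(c("GTR", "STR", "Biopsy"), 1),
      surgery2 = sample(c("GTR", "STR", "NA (autopsy)"), 1),
      germline_available = "Yes",
      treatments = sample(c("RT+ TMZ, TMZ", "RT, bevacizumab",
                            "RT + TMZ, TMZ + bevacizumab", "Surgery"), 1),
      stringsAsFactors = FALSE)
  }

  files <- character(0)
  callers <- names(config@callerSensitivity)

  emitVcfs <- function(vars, sampleId, maf) {
    for (cl in callers) {
      seen <- runif(nrow(vars)) < config@callerSensitivity[[cl]]
      obs <- vars[seen, , drop = FALSE]
      depth <- pmax(1L, rpois(nrow(obs), config@meanDepth))
      altReads <- pmax(1L, rbinom(nrow(obs), depth, maf[seen]))
      body <- data.frame(chrom = obs$chrom, pos = obs$pos, ref = obs$ref,
                         alt = obs$alt, depth = depth,
                         alt_reads = pmin(altReads, depth),
                         stringsAsFactors = FALSE)
      nFp <- rpois(1, config@callerFpRate)
      if (nFp > 0) {
        rp <- randomPositions(nFp, lens, usedPos)
        usedPos <<- rp$used
        al <- randomAlleles(nFp)
        fdepth <- pmax(1L, rpois(nFp, config@meanDepth))
        falt <- pmax(1L, rbinom(nFp, fdepth, runif(nFp, 0.02, 0.12)))
        body <- rbind(body,
                      data.frame(chrom = rp$sites$chrom, pos = rp$sites$pos,
                                 ref = al$ref, alt = al$alt, depth = fdepth,
                                 alt_reads = pmin(falt, fdepth),
                                 stringsAsFactors = FALSE))
        annotation[[length(annotation) + 1]] <<- data.frame(
          chrom = rp$sites$chrom, pos = rp$sites$pos, ref = al$ref,
          alt = al$alt, gene = sprintf("GENE%05d", sample.int(99999, nFp)),
          effect = "missense", protein_change = randomProtein(nFp),
          in_cosmic = FALSE, functional_impact = "low",
          pop_af_1000g = 0, pop_af_evs = 0, pop_af_exac = 0,
          stringsAsFactors = FALSE)
      }
      f <- file.path("vcf", sprintf("%s_%s.vcf", sampleId, cl))
      writeSimpleVcf(body, sampleId, file.path(dir, f))
      files <- c(files, f)
    }
    files
  }

  purity <- config@tumorPurity
  for (i in seq_len(nPairs)) {
    pid <- pairIds[i]
    vars <- allVariants[[pid]]
    annotation[[length(annotation) + 1]] <- vars[, c(
      "chrom", "pos", "ref", "alt", "gene", "effect", "protein_change",
      "in_cosmic", "functional_impact", "pop_af_1000g", "pop_af_evs",
      "pop_af_exac")]
    mafOf <- function(v) ifelse(v$germline, 0.5,
                                purity * v$clonal_fraction / 2)
    pv <- vars[vars$timing %in% c("shared", "primary") | vars$germline, ]
    rv <- vars[vars$timing %in% c("shared", "recurrence") | vars$germline, ]
    files <- emitVcfs(pv, paste0(pid, "_P"), mafOf(pv))
    files <- emitVcfs(rv, paste0(pid, "_R"), mafOf(rv))
    gl <- vars[vars$germline, , drop = FALSE]
    files <- emitVcfs(gl, paste0(pid, "_N"), rep(0.5, nrow(gl)))

    # matched-normal allele counts at every candidate site of the pair
    ndepth <- pmax(1L, rpois(nrow(vars), config@meanDepth))
    nalt <- ifelse(vars$germline, rbinom(nrow(vars), ndepth, 0.5), 0L)
    nc <- data.frame(chrom = vars$chrom, pos = vars$pos, ref = vars$ref,
                     alt = vars$alt, normal_alt_reads = nalt,
                     normal_depth = ndepth, stringsAsFactors = FALSE)
    f <- file.path("normal_counts", sprintf("%s_normal_counts.tsv", pid))
    write.table(nc[order(nc$chrom, nc$pos), ], file.path(dir, f),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)

    for (suffix in c("_P", "_R")) {
      sid <- paste0(pid, suffix)
      tr <- simulateTracks(trueSegments[[sid]], config@nTrackSites,
                           config@meanDepth, purity = purity,
                           bafCenters = config@bafCenters, chromLens = lens)
      f <- file.path("tracks", sprintf("%s_track.tsv", sid))
      write.table(tr, file.path(dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      files <- c(files, f)
    }
  }

  # --- methylation: subgroup means + pair effect + probe noise -------------
  nP <- config@nProbes
  probeIds <- sprintf("cg%07d", seq_len(nP))
  probeChrom <- sample(paste0("chr", 1:22), nP, replace = TRUE)
  nXY <- max(1L, round(0.03 * nP))
  probeChrom[sample.int(nP, nXY)] <- sample(c("chrX", "chrY"), nXY,
                                            replace = TRUE)
  isSnp <- runif(nP) < 0.025
  isCross <- runif(nP) < 0.025
  clusters <- c("K27M", "G34", "IDH1", "WT")
  clean <- which(!(probeChrom %in% c("chrX", "chrY")) & !isSnp & !isCross)
  nSig <- min(length(clean), 1600L)
  sigIdx <- sample(clean, nSig)
  sigCluster <- sample(clusters, nSig, replace = TRUE)
  baseline <- runif(nP, 0.15, 0.85)
  samples <- as.vector(rbind(paste0(pairIds, "_P"), paste0(pairIds, "_R")))
  beta <- matrix(0, nP, length(samples),
                 dimnames = list(probeIds, samples))
  for (i in seq_len(nPairs)) {
    mu <- baseline
    up <- sigCluster == methCluster[i]
    mu[sigIdx[up]] <- pmin(0.98, mu[sigIdx[up]] + config@methShift)
    pairEff <- rnorm(nP, 0, config@methPairSd)
    for (suffix in c("_P", "_R")) {
      v <- mu + pairEff + rnorm(nP, 0, config@methNoiseSd)
      beta[, paste0(pairIds[i], suffix)] <- pmin(1, pmax(0, v))
    }
  }
  f <- file.path("methylation", "beta.tsv")
  write.table(data.frame(probe_id = probeIds, round(beta, 4),
                         check.names = FALSE),
              file.path(dir, f), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)
  probeAnn <- data.frame(probe_id = probeIds, chrom = probeChrom,
                         is_snp_probe = isSnp, is_cross_reactive = isCross,
                         stringsAsFactors = FALSE)
  f <- file.path("methylation", "probe_annotation.tsv")
  write.table(probeAnn, file.path(dir, f), sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)

  # --- cohort-level files --------------------------------------------------
  clin <- do.call(rbind, clinical)
  write.table(clin, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ann <- unique(do.call(rbind, annotation))
  ann <- ann[order(ann$chrom, ann$pos, ann$alt), ]
  write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  files <- c(files, "clinical.tsv", "annotation.tsv")

  gtVars <- do.call(rbind, allVariants)
  rownames(gtVars) <- NULL
  write.table(gtVars, file.path(dir, "ground_truth", "variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  segDf <- do.call(rbind, lapply(names(trueSegments), function(sid) {
    gr <- trueSegments[[sid]]
    if (!length(gr)) return(NULL)
    data.frame(sample = sid, chrom = as.character(seqnames(gr)),
               start = start(gr), end = end(gr),
               event_class = mcols(gr)$event_class,
               stringsAsFactors = FALSE)
  }))
  write.table(segDf, file.path(dir, "ground_truth", "segments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(pair = pairIds, molecular_group = groups,
                         methylation_cluster = methCluster),
              file.path(dir, "ground_truth", "groups.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, file.path("ground_truth",
                              c("variants.tsv", "segments.tsv",
                                "groups.tsv")))

  cfgList <- s4ToList(config)
  yaml::write_yaml(cfgList, file.path(dir, "config.yaml"))
  files <- c(files, "config.yaml")
  writeManifest(dir, cfgList, config@seed, files)

  gt <- list(variants = gtVars,
             segments = GenomicRanges::GRangesList(trueSegments),
             groups = setNames(groups, pairIds),
             methylationCluster = setNames(methCluster, pairIds),
             pairIds = pairIds)
  invisible(list(dir = dir, config = config, groundTruth = gt))
}
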