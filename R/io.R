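#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   reduce mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom BiocGenerics sort
NULL

#' Load a chromosome-arm table
#'
#' Returns the bundled GRCh37 arm boundaries (p/q per autosome, 1-based
#' inclusive) unless another table with columns `chrom, arm, start, end` is
#' supplied.
#'
#' @param path optional path to a tab-delimited arm table.
#' @return A data.frame with columns `chrom`, `arm`, `start`, `end`.
#' @examples
#' head(readArmTable())
#' @export
readArmTable <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "grch37_arms.tsv", package = "gliomaPairs")
  arms <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "arm", "start", "end")
  if (!all(need %in% names(arms)))
    stop("arm table must have columns: ", paste(need, collapse = ", "))
  arms
}

#' Load the gene-to-pathway map
#'
#' The bundled map assigns each curated gene to one of the pathway groups
#' used in the conservation matrix (RTK, PI3K, histone modifiers, integrin,
#' cadherin, TP53 pathway, other). Users may supply their own two-column
#' (`gene`, `pathway`) table.
#'
#' @param path optional path to a tab-delimited map.
#' @return A data.frame with columns `gene` and `pathway`.
#' @export
readPathwayMap <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pathway_map.tsv", package = "gliomaPairs")
  map <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "pathway") %in% names(map)))
    stop("pathway map must have columns gene, pathway")
  map
}

#' Read a clinical cohort table
#'
#' Parses a tab-delimited clinical table (one row per primary/recurrence
#' pair) into typed records. The bundled fixture
#' `system.file("extdata", "table1_clinical.tsv", package = "gliomaPairs")`
#' transcribes the published 16-pair cohort.
#'
#' @param path path to the TSV.
#' @return A data.frame with one row per pair: `patient_id`,
#'   `primary_sample_id`, `recurrence_sample_id`, `molecular_group`,
#'   `age_years`, `sex`, `location`, `sublocation`, `ttp_months`,
#'   `interval_months`, `germline_available`, `treatments`.
#' @examples
#' tbl <- readClinicalTable(system.file("extdata", "table1_clinical.tsv",
#'                                      package = "gliomaPairs"))
#' nrow(tbl)
#' @export
readClinicalTable <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (nrow(raw) == 0L) stop("clinical table is empty: ", path)
  need <- c("molecular_group", "case_id", "age_years", "sex", "ttp_months",
            "location", "germline_available", "treatments")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("clinical table missing columns: ", paste(missing, collapse = ", "))
  loc <- tolower(trimws(raw$location))
  bad <- which(!loc %in% c("midline", "hemisphere"))
  if (length(bad))
    stop(sprintf("unknown location '%s' in row %d (case %s)",
                 raw$location[bad[1]], bad[1], raw$case_id[bad[1]]))
  ttp <- as.numeric(raw$ttp_months)
  if (any(is.na(ttp) | ttp <= 0))
    stop("time to progression must be a positive number for every pair")
  data.frame(
    patient_id = raw$case_id,
    primary_sample_id = paste0(raw$case_id, "_P"),
    recurrence_sample_id = paste0(raw$case_id, "_R"),
    molecular_group = raw$molecular_group,
    age_years = as.numeric(raw$age_years),
    sex = toupper(trimws(raw$sex)),
    location = loc,
    sublocation = if ("sublocation" %in% names(raw)) raw$sublocation else NA,
    ttp_months = ttp,
    interval_months = if ("interval_months" %in% names(raw))
      as.numeric(raw$interval_months) else NA_real_,
    germline_available = toupper(trimws(raw$germline_available)) %in%
      c("YES", "TRUE", "1"),
    treatments = raw$treatments,
    stringsAsFactors = FALSE
  )
}

#' Read a coverage/BAF track
#'
#' @param path TSV with columns `chrom, pos, ref_reads, alt_reads,
#'   tumor_depth, normal_depth` (1-based positions).
#' @return The track as a data.frame with an added `baf` column
#'   (alt / (ref + alt)).
#' @export
readBafTrack <- function(path) {
  tr <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref_reads", "alt_reads")
  if (!all(need %in% names(tr)))
    stop("track must have columns: ", paste(need, collapse = ", "))
  tot <- tr$ref_reads + tr$alt_reads
  if (any(tot <= 0)) stop("every track site needs ref_reads + alt_reads > 0")
  tr$baf <- tr$alt_reads / tot
  tr[order(tr$chrom, tr$pos), , drop = FALSE]
}

#' Read a variant annotation table
#'
#' Joins are made on the exact (chrom, pos, ref, alt) key. Expected columns:
#' `gene`, `effect`, `protein_change`, `pop_af_1000g`, `pop_af_evs`,
#' `pop_af_exac`, `in_cosmic`, `functional_impact`; absent population AFs are
#' treated as 0 (novel variant).
#'
#' @param path TSV path.
#' @return data.frame keyed by chrom/pos/ref/alt.
#' @export
readAnnotationTable <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(ann)))
    stop("annotation table must have columns: ", paste(need, collapse = ", "))
  for (col in c("pop_af_1000g", "pop_af_evs", "pop_af_exac")) {
    if (!col %in% names(ann)) ann[[col]] <- 0
    ann[[col]][is.na(ann[[col]])] <- 0
  }
  if (!"in_cosmic" %in% names(ann)) ann$in_cosmic <- FALSE
  if (!"functional_impact" %in% names(ann)) ann$functional_impact <- "unknown"
  ann
}

variantKey <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

#' Write segments to BED
#'
#' Internal GRanges coordinates are 1-based inclusive; BED output follows the
#' BED convention (0-based half-open). The score column carries
#' `-log10(q_value)` when a `q_value` metadata column is present.
#'
#' @param gr a GRanges of segments.
#' @param path output path.
#' @param nameCol optional metadata column used for the BED name field.
#' @return Invisibly, the path.
#' @export
writeSegmentsBed <- function(gr, path, nameCol = NULL) {
  score <- if ("q_value" %in% names(mcols(gr))) {
    q <- pmax(mcols(gr)$q_value, 1e-300)
    round(-log10(q), 3)
  } else rep(0, length(gr))
  nm <- if (!is.null(nameCol) && nameCol %in% names(mcols(gr)))
    as.character(mcols(gr)[[nameCol]]) else rep(".", length(gr))
  bed <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L,
                    end = end(gr),
                    name = nm,
                    score = score)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a probe-level beta matrix
#'
#' @param betaPath TSV of beta values, probes in rows (first column
#'   `probe_id`), samples in columns.
#' @param annotPath TSV of probe annotation with columns `probe_id`, `chrom`,
#'   `is_snp_probe`, `is_cross_reactive`.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay `beta`
#'   and the annotation in `rowData`.
#' @export
readBetaMatrix <- function(betaPath, annotPath) {
  b <- read.delim(betaPath, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(b)[1] != "probe_id") stop("first beta column must be probe_id")
  ann <- read.delim(annotPath, stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "is_snp_probe", "is_cross_reactive")
  if (!all(need %in% names(ann)))
    stop("probe annotation must have columns: ", paste(need, collapse = ", "))
  m <- as.matrix(b[, -1, drop = FALSE])
  rownames(m) <- b$probe_id
  ann <- ann[match(b$probe_id, ann$probe_id), , drop = FALSE]
  if (anyNA(ann$probe_id)) stop("annotation missing for some probes")
  makeBetaMatrix(m, ann)
}

#' Assemble a beta-value SummarizedExperiment
#'
#' @param beta numeric matrix in [0,1], probes x samples, rownames are probe
#'   ids.
#' @param annotation data.frame with `probe_id`, `chrom`, `is_snp_probe`,
#'   `is_cross_reactive`, aligned to the rows of `beta`.
#' @return A SummarizedExperiment with assay `beta`.
#' @export
makeBetaMatrix <- function(beta, annotation) {
  if (anyNA(beta)) stop("beta matrix must not contain missing values")
  if (any(beta < 0 | beta > 1)) stop("beta values must lie in [0, 1]")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(beta = beta),
    rowData = S4Vectors::DataFrame(annotation, row.names = rownames(beta))
  )
}

configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Every pipeline run directory carries a JSON manifest listing the inputs,
#' the configuration hash, the seed and the package version, so a run is
#' reproducible from its manifest alone. The hash changes iff any
#' configuration parameter changes.
#'
#' @param dir run directory.
#' @param config a list (or S4 config coerced to a list) of parameters.
#' @param seed the RNG seed used.
#' @param files character vector of files the run wrote, relative to `dir`.
#' @return Invisibly, the manifest path.
#' @export
writeManifest <- function(dir, config, seed, files) {
  manifest <- list(
    package = "gliomaPairs",
    version = as.character(packageVersion("gliomaPairs")),
    seed = seed,
    config_hash = configHash(config),
    config = config,
    files = sort(files)
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

s4ToList <- function(x) {
  out <- lapply(methods::slotNames(x), function(s) methods::slot(x, s))
  names(out) <- methods::slotNames(x)
  out
}
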