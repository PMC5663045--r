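# Cohort-level clinical and burden summaries.

#' Tokenize a free-text treatment string
#'
#' Treatment fields are comma- and plus-separated free text
#' (e.g. `"RT+ TMZ, TMZ + bevacizumab"`); tokens are split on `,` and `+`,
#' trimmed, and matched case-insensitively against the controlled
#' vocabulary, so counting is deterministic.
#'
#' @param x character vector of treatment strings.
#' @param vocabulary tokens to recognize (default upper-case as given).
#' @return A list of character vectors of recognized tokens (upper-cased),
#'   one per input.
#' @export
tokenizeTreatments <- function(x, vocabulary = c("RT", "TMZ")) {
  lapply(strsplit(x, "[,+]"), function(tok) {
    tok <- toupper(trimws(tok))
    intersect(unique(tok), toupper(vocabulary))
  })
}

medianSummary <- function(x) {
  x <- x[!is.na(x)]
  list(n = length(x),
       median = median(x),
       median_rounded = as.integer(round(median(x))),
       range = range(x),
       range_rounded = as.integer(round(range(x))))
}

#' Summarize a clinical cohort
#'
#' Computes the cohort descriptors: medians (even-n values use the
#' average-of-middle-two convention; reported raw and rounded to the
#' nearest integer, since months and years are conventionally printed as
#' integers), treatment counts by token membership, location counts and
#' molecular-group counts. Missing fields are excluded per statistic with a
#' warning and the evaluable n reported.
#'
#' @param pairs data.frame from [readClinicalTable()].
#' @return A list: `n_pairs`, `age` and `ttp` median summaries,
#'   `n_radiation`, `n_tmz`, `n_midline`, `n_hemispheric`, `group_counts`.
#' @examples
#' tbl <- readClinicalTable(system.file("extdata", "table1_clinical.tsv",
#'                                      package = "gliomaPairs"))
#' summarizeClinical(tbl)$age$median
#' @export
summarizeClinical <- function(pairs) {
  if (anyNA(pairs$age_years))
    warning(sum(is.na(pairs$age_years)), " pair(s) missing age, excluded")
  if (anyNA(pairs$ttp_months))
    warning(sum(is.na(pairs$ttp_months)),
            " pair(s) missing time to progression, excluded")
  tokens <- tokenizeTreatments(pairs$treatments)
  groups <- table(factor(pairs$molecular_group, levels = .GROUPS))
  list(
    n_pairs = nrow(pairs),
    age = medianSummary(pairs$age_years),
    ttp = medianSummary(pairs$ttp_months),
    n_radiation = sum(vapply(tokens, function(t) "RT" %in% t, TRUE)),
    n_tmz = sum(vapply(tokens, function(t) "TMZ" %in% t, TRUE)),
    n_midline = sum(pairs$location == "midline"),
    n_hemispheric = sum(pairs$location == "hemisphere"),
    group_counts = groups
  )
}

#' Per-pair mutation and allelic-imbalance burden table
#'
#' One row per pair with six counts: SNVs and AI regions, each split into
#' shared / primary-only / recurrence-only, plus per-sample totals
#' (shared + private).
#'
#' @param partitions named list of [partitionPair()] results (one per
#'   pair).
#' @param aiComparisons optional named list of [compareAIRegions()] results
#'   on the same pairs.
#' @return data.frame with one row per pair.
#' @export
burdenTable <- function(partitions, aiComparisons = NULL) {
  out <- do.call(rbind, lapply(names(partitions), function(pid) {
    ct <- partitions[[pid]]$counts
    row <- data.frame(
      pair = pid,
      snv_shared = unname(ct["shared"]),
      snv_primary_only = unname(ct["primary_only"]),
      snv_recurrence_only = unname(ct["recurrence_only"]),
      stringsAsFactors = FALSE)
    if (!is.null(aiComparisons) && pid %in% names(aiComparisons)) {
      ai <- aiComparisons[[pid]]
      row$ai_shared <- unname(ai["shared"])
      row$ai_primary_only <- unname(ai["primary_only"])
      row$ai_recurrence_only <- unname(ai["recurrence_only"])
    } else {
      row$ai_shared <- NA_integer_
      row$ai_primary_only <- NA_integer_
      row$ai_recurrence_only <- NA_integer_
    }
    row
  }))
  out$snv_primary_total <- out$snv_shared + out$snv_primary_only
  out$snv_recurrence_total <- out$snv_shared + out$snv_recurrence_only
  out$ai_primary_total <- out$ai_shared + out$ai_primary_only
  out$ai_recurrence_total <- out$ai_shared + out$ai_recurrence_only
  out
}

#' Paired tests on primary versus recurrence burdens
#'
#' Applies [pairedTTest()] to per-pair primary totals versus recurrence
#' totals, separately for SNV counts and AI region counts. Zero-variance
#' differences propagate the underlying error with its message.
#'
#' @param table a [burdenTable()] result.
#' @return A list with `snv` and (when AI counts are present) `ai`, each a
#'   `pairedTTest` result (`t`, `df`, `p`).
#' @export
compareBurdens <- function(table) {
  out <- list(snv = pairedTTest(table$snv_primary_total,
                                table$snv_recurrence_total))
  if (!anyNA(table$ai_primary_total))
    out$ai <- pairedTTest(table$ai_primary_total,
                          table$ai_recurrence_total)
  out
}
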