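#' Apply the call-confidence filter
#'
#' CNV-SNP callers attach a confidence score to every call, with lower
#' values indicating more certainty; only calls with confidence strictly
#' below the threshold are trusted. Calls at or above the threshold are set
#' to missing. The default threshold of 0.1 follows the caller developers'
#' recommendation.
#'
#' @param table A [genotype_table()].
#' @param threshold Confidence cutoff in `(0, 1]`; a call is retained iff
#'   `confidence < threshold` (strict).
#' @return The filtered `genotype_table`; the number of calls converted to
#'   missing is recorded in attribute `n_filtered`.
#' @export
apply_confidence_filter <- function(table, threshold = 0.1) {
  stopifnot(inherits(table, "genotype_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]", call. = FALSE)
  }
  drop <- !is.na(table$confidence) & table$confidence >= threshold
  table$a[drop] <- NA_integer_
  table$b[drop] <- NA_integer_
  table$confidence[drop] <- NA_real_
  attr(table, "n_filtered") <- sum(drop)
  table
}

#' Encode a marker's joint allelic / copy-number design
#'
#' The joint association model regresses the trait on two per-sample
#' genotype terms: the allele contrast `a - b` (additive SNP-allele effect)
#' and the copy total `a + b` (additive copy-number effect). For fully
#' diploid markers the contrast is the usual additive dosage recoded to
#' \{-2, 0, 2\} and the total is constant at 2.
#'
#' @param table A [genotype_table()].
#' @param marker_index Integer index of the marker (1-based), or a marker id.
#' @param .allow_degenerate If `FALSE` (default) a marker with no usable
#'   call raises a classed error (`jointgwas_degenerate_design`); scanning
#'   code sets `TRUE` and handles the empty design itself.
#' @return A list of class `joint_design`: `contrast`, `total` (numeric,
#'   `NA` where unusable), `usable_mask` (logical), `samples`, `marker_id`.
#' @export
encode_joint_design <- function(table, marker_index, .allow_degenerate = FALSE) {
  stopifnot(inherits(table, "genotype_table"))
  if (is.character(marker_index)) {
    marker_index <- match(marker_index, table$markers$marker_id)
  }
  if (is.na(marker_index) || marker_index < 1L ||
      marker_index > nrow(table$markers)) {
    stop("marker_index out of range", call. = FALSE)
  }
  a <- as.numeric(table$a[marker_index, ])
  b <- as.numeric(table$b[marker_index, ])
  usable <- !is.na(a)
  if (!any(usable) && !.allow_degenerate) {
    stop(structure(
      class = c("jointgwas_degenerate_design", "error", "condition"),
      list(message = sprintf("marker %s has no usable call",
                             table$markers$marker_id[marker_index]),
           call = NULL)))
  }
  structure(
    list(contrast = a - b, total = a + b, usable_mask = usable,
         samples = table$samples,
         marker_id = table$markers$marker_id[marker_index]),
    class = "joint_design"
  )
}

#' Allele and copy-number frequencies of one marker
#'
#' The minor-allele frequency is computed over all copies present,
#' `min(sum(a), sum(b)) / sum(a + b)`, so it remains well defined at
#' copy-number-variable loci. The CNV rate is the fraction of usable
#' samples whose total copy number differs from 2.
#'
#' @param design A [encode_joint_design()] result.
#' @return A one-row tibble with columns `maf` and `cnv_rate`.
#' @export
marker_frequencies <- function(design) {
  stopifnot(inherits(design, "joint_design"))
  u <- design$usable_mask
  if (!any(u)) stop("no usable sample for this marker", call. = FALSE)
  tot <- design$total[u]
  con <- design$contrast[u]
  sum_a <- sum((tot + con) / 2)
  sum_b <- sum((tot - con) / 2)
  denom <- sum(tot)
  maf <- if (denom > 0) min(sum_a, sum_b) / denom else 0
  tibble::tibble(maf = maf, cnv_rate = mean(tot != 2))
}

#' Marker-level quality-control filter
#'
#' Removes markers whose call rate (after the confidence filter) falls
#' below `min_call_rate` or whose minor-allele frequency falls below
#' `min_maf`. Defaults follow common array-QC practice; both are
#' configurable.
#'
#' @param table A [genotype_table()].
#' @param min_call_rate Minimum fraction of non-missing calls, in `[0, 1]`.
#' @param min_maf Minimum minor-allele frequency, in `[0, 1]`.
#' @return The filtered `genotype_table`; attribute `qc_log` records how
#'   many markers each criterion removed.
#' @export
qc_filter <- function(table, min_call_rate = 0.95, min_maf = 0.01) {
  stopifnot(inherits(table, "genotype_table"),
            min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  m <- nrow(table$markers)
  if (m == 0L) return(table)
  usable <- !is.na(table$a)
  call_rate <- rowMeans(usable)
  a_sum <- rowSums(table$a, na.rm = TRUE)
  b_sum <- rowSums(table$b, na.rm = TRUE)
  denom <- a_sum + b_sum
  maf <- ifelse(denom > 0, pmin(a_sum, b_sum) / denom, 0)
  fail_cr <- call_rate < min_call_rate
  fail_maf <- !fail_cr & maf < min_maf
  keep <- !(fail_cr | fail_maf)
  out <- table[keep, ]
  attr(out, "qc_log") <- tibble::tibble(
    criterion = c("call_rate", "maf"),
    removed = c(sum(fail_cr), sum(fail_maf))
  )
  out
}
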