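#' CNV-aware genotype table
#'
#' A `genotype_table` holds, for every marker and sample, a CNV-SNP call:
#' the count `a` of A alleles and the count `b` of B alleles present on
#' however many genomic copies the sample carries at that locus (so `a + b`
#' is the total copy number, 0 permitted for a homozygous deletion), plus a
#' per-call confidence score in `[0, 1]` where *lower* means more certain.
#' Missing calls are stored as `NA` in all three matrices.
#'
#' @param markers A data frame with columns `marker_id`, `chrom`, `pos`
#'   (1-based base pair), `allele_a`, `allele_b`. Marker ids must be unique
#'   and positions at least 1.
#' @param samples Character vector of unique sample identifiers.
#' @param a,b Integer matrices (markers x samples) of allele counts;
#'   `NA` marks a missing call. Counts must be non-negative and `a + b`
#'   must not exceed `max_copy`.
#' @param confidence Numeric matrix (markers x samples) of call-confidence
#'   scores in `[0, 1]`; `NA` where the call is missing.
#' @param max_copy Largest total copy number permitted (default 4, the
#'   usual copy-state ceiling of array-based CNV callers).
#'
#' @return An object of class `genotype_table`.
#' @seealso [read_genotype_table()], [apply_confidence_filter()],
#'   [encode_joint_design()]
#' @export
genotype_table <- function(markers, samples, a, b, confidence, max_copy = 4L) {
  markers <- tibble::as_tibble(markers)
  required <- c("marker_id", "chrom", "pos", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols) > 0L) {
    stop("markers is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  markers <- markers[required]
  markers$marker_id <- as.character(markers$marker_id)
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  samples <- as.character(samples)

  a <- as.matrix(a); b <- as.matrix(b); confidence <- as.matrix(confidence)
  storage.mode(a) <- "integer"
  storage.mode(b) <- "integer"
  storage.mode(confidence) <- "double"
  dimnames(a) <- dimnames(b) <- dimnames(confidence) <-
    list(markers$marker_id, samples)

  obj <- structure(
    list(markers = markers, samples = samples,
         a = a, b = b, confidence = confidence),
    max_copy = as.integer(max_copy),
    class = "genotype_table"
  )
  validate_genotype_table(obj)
}

validate_genotype_table <- function(x) {
  m <- nrow(x$markers); n <- length(x$samples)
  for (nm in c("a", "b", "confidence")) {
    if (!identical(dim(x[[nm]]), c(m, n))) {
      stop("'", nm, "' matrix must be ", m, " x ", n, call. = FALSE)
    }
  }
  if (anyDuplicated(x$markers$marker_id)) {
    stop("duplicate marker_id in genotype table", call. = FALSE)
  }
  if (anyDuplicated(x$samples)) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  if (m > 0 && any(x$markers$pos < 1L, na.rm = TRUE)) {
    stop("marker positions must be >= 1", call. = FALSE)
  }
  miss_a <- is.na(x$a)
  if (!identical(miss_a, is.na(x$b))) {
    stop("a and b must be missing at the same calls", call. = FALSE)
  }
  if (any(x$a < 0L, na.rm = TRUE) || any(x$b < 0L, na.rm = TRUE)) {
    stop("negative allele counts are not allowed", call. = FALSE)
  }
  total <- x$a + x$b
  if (any(total > attr(x, "max_copy"), na.rm = TRUE)) {
    stop("total copy number exceeds max_copy (", attr(x, "max_copy"), ")",
         call. = FALSE)
  }
  cf <- x$confidence
  if (any(cf < 0 | cf > 1, na.rm = TRUE)) {
    stop("confidence scores must lie in [0, 1]", call. = FALSE)
  }
  x
}

#' @export
print.genotype_table <- function(x, ...) {
  n_miss <- sum(is.na(x$a))
  cat(sprintf("<genotype_table> %d markers x %d samples (%.1f%% missing calls)\n",
              nrow(x$markers), length(x$samples),
              if (length(x$a)) 100 * n_miss / length(x$a) else 0))
  print(utils::head(x$markers, 5))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) c(nrow(x$markers), length(x$samples))

#' Subset a genotype table by marker and/or sample
#'
#' @param x A [genotype_table()].
#' @param i Marker index (integer, logical, or marker ids).
#' @param j Sample index (integer, logical, or sample ids).
#' @param ... Unused.
#' @return A `genotype_table`.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$markers))
  if (missing(j)) j <- seq_along(x$samples)
  if (is.character(i)) i <- match(i, x$markers$marker_id)
  if (is.character(j)) j <- match(j, x$samples)
  genotype_table(
    markers = x$markers[i, , drop = FALSE],
    samples = x$samples[j],
    a = x$a[i, j, drop = FALSE],
    b = x$b[i, j, drop = FALSE],
    confidence = x$confidence[i, j, drop = FALSE],
    max_copy = attr(x, "max_copy")
  )
}

#' Tidy a genotype table into a long tibble
#'
#' One row per (marker, sample) call with columns `marker_id`, `chrom`,
#' `pos`, `sample_id`, `a`, `b`, `confidence`, `missing`.
#'
#' @param x A [genotype_table()].
#' @param ... Unused.
#' @return A tibble in long format.
#' @method tidy genotype_table
#' @export
tidy.genotype_table <- function(x, ...) {
  m <- nrow(x$markers); n <- length(x$samples)
  tibble::tibble(
    marker_id = rep(x$markers$marker_id, times = n),
    chrom = rep(x$markers$chrom, times = n),
    pos = rep(x$markers$pos, times = n),
    sample_id = rep(x$samples, each = m),
    a = as.vector(x$a),
    b = as.vector(x$b),
    confidence = as.vector(x$confidence),
    missing = as.vector(is.na(x$a))
  )
}

#' Per-marker allele and copy-number summaries
#'
#' @param x A [genotype_table()].
#' @param ... Unused.
#' @return A tibble with one row per marker: call rate, minor-allele
#'   frequency over all copies, and the fraction of non-diploid calls.
#' @method glance genotype_table
#' @export
glance.genotype_table <- function(x, ...) {
  freq <- purrr::map_dfr(seq_len(nrow(x$markers)), function(i) {
    d <- encode_joint_design(x, i, .allow_degenerate = TRUE)
    if (!any(d$usable_mask)) {
      return(tibble::tibble(call_rate = 0, maf = NA_real_, cnv_rate = NA_real_))
    }
    f <- marker_frequencies(d)
    tibble::tibble(call_rate = mean(d$usable_mask),
                   maf = f$maf, cnv_rate = f$cnv_rate)
  })
  dplyr::bind_cols(x$markers[, c("marker_id", "chrom", "pos")], freq)
}
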