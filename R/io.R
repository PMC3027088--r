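# TSV dialects consumed by the pipeline.
#
# Genotype table: header "marker_id chrom pos allele_a allele_b <s1> <s2> ...",
# one row per marker; each sample cell is "a,b,conf" or "." for missing.
# Roster:   header "family_id individual_id sex center".
# PhenoCov: header "individual_id trait age sex center [pc1..pcK]".
# Writers emit a deterministic column order and 6 significant digits for reals.

fmt_real <- function(x) {
  out <- formatC(x, digits = 6, format = "g")
  out[is.na(x)] <- "NA"
  out
}

#' Read a CNV-SNP genotype table
#'
#' Parses the tab-separated genotype dialect: five marker-metadata columns
#' (`marker_id`, `chrom`, `pos`, `allele_a`, `allele_b`) followed by one
#' column per sample whose cells are `"a,b,confidence"` triplets, or the
#' sentinel `"."` for a missing call.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param permissive If `TRUE`, malformed triplets become missing calls
#'   instead of raising a format error.
#' @param max_copy Maximum total copy number accepted (default 4).
#' @return A [genotype_table()].
#' @export
read_genotype_table <- function(path, permissive = FALSE, max_copy = 4L) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  meta_cols <- c("marker_id", "chrom", "pos", "allele_a", "allele_b")
  if (ncol(raw) < length(meta_cols) ||
      !identical(names(raw)[seq_along(meta_cols)], meta_cols)) {
    stop("genotype table must start with columns: ",
         paste(meta_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(raw$marker_id)) {
    stop("duplicate marker_id in genotype file", call. = FALSE)
  }
  samples <- names(raw)[-seq_along(meta_cols)]
  m <- nrow(raw)
  cells <- as.matrix(raw[, samples, drop = FALSE])
  if (anyNA(cells) || any(cells == "")) {
    stop("ragged or empty genotype cell found", call. = FALSE)
  }
  a <- matrix(NA_integer_, m, length(samples))
  b <- matrix(NA_integer_, m, length(samples))
  cf <- matrix(NA_real_, m, length(samples))
  present <- cells != "."
  if (any(present)) {
    parts <- strsplit(cells[present], ",", fixed = TRUE)
    ok <- lengths(parts) == 3L
    flat <- matrix(NA_character_, sum(present), 3L)
    flat[ok, ] <- matrix(unlist(parts[ok]), ncol = 3L, byrow = TRUE)
    av <- suppressWarnings(as.integer(flat[, 1]))
    bv <- suppressWarnings(as.integer(flat[, 2]))
    cv <- suppressWarnings(as.numeric(flat[, 3]))
    bad <- !ok | is.na(av) | is.na(bv) | is.na(cv)
    neg <- !bad & (av < 0L | bv < 0L)
    if (any(neg)) stop("negative allele count in genotype file", call. = FALSE)
    if (any(bad) && !permissive) {
      stop("malformed genotype cell(s), e.g. '",
           cells[present][which(bad)[1]],
           "' (set permissive = TRUE to treat as missing)", call. = FALSE)
    }
    av[bad] <- NA_integer_; bv[bad] <- NA_integer_; cv[bad] <- NA_real_
    a[present] <- av; b[present] <- bv; cf[present] <- cv
  }
  genotype_table(
    markers = tibble::tibble(
      marker_id = raw$marker_id, chrom = raw$chrom,
      pos = as.integer(raw$pos),
      allele_a = raw$allele_a, allele_b = raw$allele_b),
    samples = samples, a = a, b = b, confidence = cf, max_copy = max_copy
  )
}

#' Write a CNV-SNP genotype table
#'
#' Inverse of [read_genotype_table()]: `read(write(t))` reproduces `t`
#' exactly (confidence scores are emitted with 6 significant digits, so
#' tables produced by the simulator, which rounds to the same precision,
#' round-trip bit-exactly).
#'
#' @param table A [genotype_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(table, path) {
  stopifnot(inherits(table, "genotype_table"))
  m <- nrow(table$markers)
  cells <- matrix(".", m, length(table$samples))
  present <- !is.na(table$a)
  cells[present] <- paste(table$a[present], table$b[present],
                          fmt_real(table$confidence[present]), sep = ",")
  out <- dplyr::bind_cols(
    dplyr::mutate(table$markers, pos = as.character(.data$pos)),
    tibble::as_tibble(cells, .name_repair = ~ table$samples)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a family roster
#'
#' The roster lists one row per genotyped individual with its sibship:
#' columns `family_id`, `individual_id`, `sex` (1 = male, 2 = female) and
#' `center` (recruitment center). Parents are not part of the design, so
#' only flat family membership is recorded.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble of class `roster`.
#' @export
read_roster <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    family_id = "c", individual_id = "c", sex = "i", center = "c"),
    progress = FALSE)
  as_roster(x)
}

#' Coerce a data frame to a validated roster
#'
#' @param x Data frame with columns `family_id`, `individual_id`, `sex`,
#'   `center`.
#' @return A tibble of class `roster`.
#' @export
as_roster <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("family_id", "individual_id", "sex", "center")
  if (!all(required %in% names(x))) {
    stop("roster needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$individual_id)) {
    stop("duplicate individual_id in roster", call. = FALSE)
  }
  if (!all(x$sex %in% c(1L, 2L))) {
    stop("sex must be coded 1/2", call. = FALSE)
  }
  class(x) <- c("roster", class(x))
  x
}

#' Write a family roster
#' @param roster A roster tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roster <- function(roster, path) {
  readr::write_tsv(roster[c("family_id", "individual_id", "sex", "center")],
                   path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Columns `individual_id`, `trait` (a positive quantitative trait such as
#' an aortic root diameter in cm; it is log-transformed by the model),
#' `age` (years), `sex`, `center`, and optionally precomputed principal
#' component scores `pc1..pcK`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble of class `phenocov`.
#' @export
read_phenocov <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(
    individual_id = "c", trait = "d", age = "d", sex = "i", center = "c",
    .default = "d"), progress = FALSE)
  as_phenocov(x)
}

#' Coerce a data frame to a validated phenotype/covariate table
#'
#' @param x Data frame with columns `individual_id`, `trait`, `age`, `sex`,
#'   `center` (plus optional `pc*` columns).
#' @return A tibble of class `phenocov`.
#' @export
as_phenocov <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("individual_id", "trait", "age", "sex", "center")
  if (!all(required %in% names(x))) {
    stop("phenotype table needs columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(x$individual_id)) {
    stop("duplicate individual_id in phenotype table", call. = FALSE)
  }
  if (any(!is.na(x$trait) & x$trait <= 0)) {
    stop("trait must be > 0 (the model log-transforms it)", call. = FALSE)
  }
  if (any(!is.na(x$age) & x$age < 0)) {
    stop("age must be >= 0", call. = FALSE)
  }
  class(x) <- c("phenocov", class(x))
  x
}

#' Write a phenotype/covariate table
#' @param pheno A phenocov tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenocov <- function(pheno, path) {
  pc_cols <- grep("^pc[0-9]+$", names(pheno), value = TRUE)
  out <- pheno[c("individual_id", "trait", "age", "sex", "center", pc_cols)]
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(v) fmt_real(v))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Published top-marker summary statistics
#'
#' The top ten markers from each stage of the aortic-root-diameter family
#' GWAS the pipeline was designed around, as published: chromosome,
#' position, marker id, MAF, stage-1 screen p-value, stage-2 SNP effect
#' (x 1e-3 on the ln scale) with its standard error, and the stage-2
#' mixed-model p-value. Useful as a worked example for
#' [flag_significance()].
#'
#' @return A tibble with 11 rows.
#' @export
published_top_markers <- function() {
  path <- system.file("extdata", "ard_top_markers.tsv", package = "jointgwas")
  readr::read_tsv(path, col_types = readr::cols(
    chrom = "c", pos = "i", marker_id = "c", .default = "d"),
    progress = FALSE)
}
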