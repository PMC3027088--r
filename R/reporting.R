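# Diagnostics (genomic inflation, QQ, Manhattan tables), run reports, and
# result serialization.

#' Genomic inflation factor (lambda)
#'
#' The genomic-control lambda: the median of the association chi-square
#' statistics divided by the null median of a 1-df chi-square
#' (`qchisq(0.5, 1)` = 0.4549). P-values from multi-df tests are first
#' converted through the 1-df chi-square quantile, the usual convention
#' for mixed-df scans. Lambda near 1 indicates a well-calibrated test;
#' below 1 a conservative one (the hallmark of the GRAMMAR screen in
#' family data); above 1 inflation, e.g. from population stratification.
#'
#' @param p_values P-values in `(0, 1]`.
#' @param warn_few Warn when fewer than 100 p-values are supplied.
#' @return Lambda (a single number).
#' @export
genomic_inflation_lambda <- function(p_values, warn_few = TRUE) {
  if (length(p_values) == 0L) stop("no p-values supplied", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (warn_few && length(p_values) < 100L) {
    warning("lambda estimated from fewer than 100 p-values", call. = FALSE)
  }
  chi <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Quantile-quantile points for a set of p-values
#'
#' @param p_values P-values in `(0, 1]`.
#' @return A tibble with `expected` = `-log10((i - 0.5) / n)` and
#'   `observed` = sorted `-log10(p)`, both in matching (decreasing) order.
#' @export
qq_points <- function(p_values) {
  n <- length(p_values)
  if (n == 0L) stop("no p-values supplied", call. = FALSE)
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  tibble::tibble(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(p_values))
  )
}

#' Genome-ordered table for Manhattan plotting
#'
#' Orders markers by chromosome then position and adds a cumulative
#' plotting coordinate: each chromosome's positions are offset by the end
#' of the previous chromosome.
#'
#' @param results A tibble with `chrom`, `pos` and a p-value column.
#' @param p_col Name of the p-value column to plot (default picks
#'   `stage2_p` if present, else `stage1_p`).
#' @return A tibble: `chrom`, `pos`, `offset`, `cum_pos`, `neglog10_p`,
#'   `stage`, `significant`.
#' @export
manhattan_table <- function(results, p_col = NULL) {
  if (nrow(results) == 0L) stop("empty results table", call. = FALSE)
  if (is.null(p_col)) {
    p_col <- if ("stage2_p" %in% names(results)) "stage2_p" else "stage1_p"
  }
  dat <- results |>
    dplyr::mutate(.chrom_num = suppressWarnings(as.numeric(.data$chrom))) |>
    dplyr::arrange(.data$.chrom_num, .data$chrom, .data$pos)
  chrom_levels <- unique(dat$chrom)
  max_pos <- vapply(chrom_levels,
                    function(cc) max(dat$pos[dat$chrom == cc]), numeric(1))
  offsets <- tibble::tibble(
    chrom = chrom_levels,
    offset = unname(cumsum(dplyr::lag(unname(max_pos), default = 0))))
  dat |>
    dplyr::left_join(offsets, by = "chrom") |>
    dplyr::transmute(
      marker_id = if ("marker_id" %in% names(results)) .data$marker_id else NA,
      chrom = .data$chrom, pos = .data$pos, offset = .data$offset,
      cum_pos = .data$offset + .data$pos,
      neglog10_p = -log10(.data[[p_col]]),
      stage = p_col,
      significant = if ("significant" %in% names(results))
        .data$significant else NA
    )
}

#' QQ plot of association p-values
#'
#' @param p_values P-values in `(0, 1]`.
#' @return A ggplot object.
#' @export
plot_qq <- function(p_values) {
  pts <- qq_points(p_values)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(Expected ~ -log[10](p)),
                  y = expression(Observed ~ -log[10](p)),
                  subtitle = sprintf("lambda = %.3f",
                                     genomic_inflation_lambda(p_values,
                                                              warn_few = FALSE))) +
    ggplot2::theme_minimal()
}

#' Manhattan plot of a genome scan
#'
#' @param results A scan results tibble (see [manhattan_table()]).
#' @param p_col P-value column to plot.
#' @param alpha Genome-wide threshold drawn as a horizontal line.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, p_col = NULL, alpha = 5e-7) {
  mt <- manhattan_table(results, p_col)
  mt$chrom <- factor(mt$chrom, levels = unique(mt$chrom))
  ggplot2::ggplot(mt, ggplot2::aes(x = .data$cum_pos, y = .data$neglog10_p,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.7, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2,
                        colour = "red") +
    ggplot2::labs(x = "Genomic position", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}

#' @method autoplot jointgwas_run
#' @export
autoplot.jointgwas_run <- function(object, type = c("manhattan", "qq"), ...) {
  type <- match.arg(type)
  if (type == "manhattan") {
    plot_manhattan(object$stage1, p_col = "stage1_p",
                   alpha = object$report$config$genomewide_alpha)
  } else {
    tested <- object$stage1$stage1_df > 0L
    plot_qq(object$stage1$stage1_p[tested])
  }
}

new_run_report <- function(counts, lambda_stage1, lambda_stage2,
                           stage1_cutoff, n_significant, config,
                           log_lines, elapsed_s) {
  structure(list(counts = counts, lambda_stage1 = lambda_stage1,
                 lambda_stage2 = lambda_stage2,
                 stage1_cutoff = stage1_cutoff,
                 n_significant = n_significant, config = config,
                 log_lines = log_lines, elapsed_s = elapsed_s),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Two-stage joint SNP/CNV scan report\n")
  cat("-----------------------------------\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %-22s %d\n", x$counts$stage[i], x$counts$n[i]))
  }
  cat(sprintf("  lambda (stage 1)       %.3f\n", x$lambda_stage1))
  cat(sprintf("  lambda (stage 2)       %.3f\n", x$lambda_stage2))
  cat(sprintf("  stage-1 p cutoff       %.3g\n", x$stage1_cutoff))
  cat(sprintf("  significant markers    %d\n", x$n_significant))
  cat(sprintf("  elapsed                %.1f s\n", x$elapsed_s))
  invisible(x)
}

#' Serialize a run report to a structured YAML file
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  yaml::write_yaml(list(
    counts = stats::setNames(as.list(report$counts$n), report$counts$stage),
    lambda_stage1 = report$lambda_stage1,
    lambda_stage2 = report$lambda_stage2,
    stage1_cutoff = report$stage1_cutoff,
    n_significant = report$n_significant,
    config = report$config,
    elapsed_s = report$elapsed_s,
    log = report$log_lines
  ), path)
  invisible(path)
}

#' Write / read an association results table
#'
#' Reals are written with 6 significant digits; reading back reproduces
#' every field to that printed precision.
#'
#' @param results A results tibble.
#' @param path File path.
#' @return `path` (writer, invisibly) or the tibble (reader).
#' @export
write_results_table <- function(results, path) {
  out <- results
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], fmt_real)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  spec <- c(marker_id = "c", chrom = "c", pos = "i",
            tested_terms = "c", stage1_terms = "c",
            stage1_dropped = "c", stage2_dropped = "c", stage2_note = "c",
            significant = "l", df = "i", stage1_df = "i", n_used = "i")
  hdr <- names(readr::read_tsv(path, n_max = 0,
                               col_types = readr::cols(.default = "c"),
                               progress = FALSE))
  ct <- do.call(readr::cols,
                c(as.list(spec[intersect(names(spec), hdr)]),
                  list(.default = "d")))
  readr::read_tsv(path, col_types = ct, progress = FALSE)
}
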