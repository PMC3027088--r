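# Two-stage genome scan: GRAMMAR residual screen over every marker, then a
# full family mixed-model refit of the top-ranked markers.

# Assemble the null-model covariate design shared by both stages:
# intercept, pc1..pc_n_pcs, age, age^2 (built internally), sex indicator,
# center indicators. Returns the rows with complete data, in pheno order.
build_covariate_design <- function(pheno, roster, pcs = NULL, n_pcs = 4L,
                                   trait_is_log = FALSE, center_age = FALSE) {
  stopifnot(inherits(pheno, "phenocov"))
  dat <- dplyr::inner_join(
    tibble::as_tibble(pheno),
    tibble::as_tibble(roster)[c("family_id", "individual_id")],
    by = "individual_id")
  if (nrow(dat) < nrow(pheno)) {
    message(nrow(pheno) - nrow(dat), " phenotyped individuals absent from roster, dropped")
  }
  pc_mat <- NULL
  if (n_pcs > 0L) {
    if (!is.null(pcs)) {
      stopifnot(inherits(pcs, "pc_result"))
      idx <- match(dat$individual_id, pcs$samples)
      if (anyNA(idx)) stop("PC scores missing for some individuals", call. = FALSE)
      pc_mat <- pcs$scores[idx, seq_len(n_pcs), drop = FALSE]
    } else {
      pc_cols <- paste0("pc", seq_len(n_pcs))
      if (!all(pc_cols %in% names(dat))) {
        stop("n_pcs = ", n_pcs, " but no PC scores supplied", call. = FALSE)
      }
      pc_mat <- as.matrix(dat[pc_cols])
    }
    colnames(pc_mat) <- paste0("pc", seq_len(n_pcs))
  }
  age <- if (center_age) dat$age - mean(dat$age, na.rm = TRUE) else dat$age
  X <- cbind(`(Intercept)` = 1, pc_mat, age = age, age2 = age^2,
             sex = as.numeric(dat$sex == 2L))
  centers <- sort(unique(dat$center))
  if (length(centers) > 1L) {
    for (ct in centers[-1L]) {
      X <- cbind(X, as.numeric(dat$center == ct))
      colnames(X)[ncol(X)] <- paste0("center", ct)
    }
  }
  y <- if (trait_is_log) dat$trait else log(dat$trait)
  complete <- stats::complete.cases(X) & !is.na(y)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message(n_dropped, " individuals dropped for incomplete covariates")
  }
  X <- X[complete, , drop = FALSE]
  # drop aliased covariate columns (e.g. a single recruitment center)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    warning("dropping aliased covariate column(s): ",
            paste(aliased, collapse = ", "), call. = FALSE)
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
  }
  list(y = y[complete], X = X,
       families = dat$family_id[complete],
       individual_id = dat$individual_id[complete],
       n_dropped = n_dropped)
}

#' Fit the null (no-genotype) mixed model
#'
#' Regresses the ln trait on the leading principal components, age,
#' age-squared (constructed internally), sex and recruitment center, with
#' a family random intercept estimated by REML. This is the once-per-study
#' fit whose conditional residuals drive the first-stage genome screen.
#'
#' @param pheno A `phenocov` tibble (see [read_phenocov()]).
#' @param roster A roster tibble mapping individuals to families.
#' @param pcs Optional [compute_genotype_pcs()] result; if `NULL`,
#'   `pc1..pcK` columns of `pheno` are used.
#' @param n_pcs Number of principal components entering as covariates
#'   (default 4; 0 to omit).
#' @param trait_is_log Set `TRUE` when the trait column is already on the
#'   log scale (no second log is applied).
#' @param center_age If `TRUE`, age is mean-centered before squaring.
#' @param min_n Minimum number of complete-covariate individuals required.
#' @return An `lmm_fit` carrying the design (`$X_null`, `$y`,
#'   `$individual_id`) for downstream stages.
#' @export
fit_null_model <- function(pheno, roster, pcs = NULL, n_pcs = 4L,
                           trait_is_log = FALSE, center_age = FALSE,
                           min_n = 50L) {
  d <- build_covariate_design(pheno, roster, pcs, n_pcs,
                              trait_is_log, center_age)
  if (length(d$y) < min_n) {
    stop("only ", length(d$y), " individuals with complete covariates ",
         "(need >= ", min_n, ")", call. = FALSE)
  }
  fit <- fit_lmm_reml(d$y, d$X, d$families)
  fit$X_null <- d$X
  fit$y <- d$y
  fit$individual_id <- d$individual_id
  fit
}

#' Conditional residuals of the null fit, keyed by individual
#'
#' @param null_fit A [fit_null_model()] result.
#' @return A tibble: `individual_id`, `ystar` (the conditional residual).
#' @export
grammar_residuals <- function(null_fit) {
  stopifnot(!is.null(null_fit$individual_id))
  tibble::tibble(individual_id = null_fit$individual_id,
                 ystar = conditional_residuals(null_fit))
}

# Decide which genotype terms enter a marker's design.
# contrast / total are numeric vectors over the usable samples; covariates
# (for the collinearity check) default to an intercept.
retain_genotype_terms <- function(contrast, total, X_cov = NULL,
                                  var_tol = 1e-12, sv_tol = 1e-8) {
  terms <- list()
  reasons <- c()
  v_c <- stats::var(contrast)
  v_t <- stats::var(total)
  if (is.na(v_c) || v_c < var_tol) reasons["allele_contrast"] <- "invariant"
  else terms$allele_contrast <- contrast
  if (is.na(v_t) || v_t < var_tol) reasons["copy_total"] <- "invariant"
  else terms$copy_total <- total
  if (length(terms) == 2L) {
    G <- cbind(terms$allele_contrast, terms$copy_total)
    if (is.null(X_cov)) X_cov <- matrix(1, nrow(G), 1L)
    R <- G - X_cov %*% qr.coef(qr(X_cov), G)
    sv <- svd(R, nu = 0, nv = 0)$d
    if (sv[2] < sv_tol * max(sv[1], 1)) {
      reasons["copy_total"] <- "collinear"
      terms$copy_total <- NULL
    }
  }
  list(terms = terms, reasons = reasons)
}

#' First-stage GRAMMAR genome screen
#'
#' Regresses the conditional residuals of the null mixed model on each
#' marker's retained genotype terms (allele contrast `a - b` and copy
#' total `a + b`) by ordinary least squares, and tests the terms jointly
#' with a Wald chi-square. Markers with no retainable term (all calls
#' missing, or both terms invariant) receive `stage1_p = 1` and a recorded
#' reason; they are never fatal.
#'
#' @param genotypes A [genotype_table()] (already confidence- and
#'   QC-filtered).
#' @param residuals A tibble from [grammar_residuals()] (columns
#'   `individual_id`, `ystar`), or a named numeric vector.
#' @param allele_only If `TRUE`, only the allele-contrast term is tested
#'   (for comparing the joint test against a SNP-only scan).
#' @return A tibble with one row per marker: frequencies, stage-1
#'   statistic, degrees of freedom, p-value, tested terms and drop
#'   reasons.
#' @export
stage1_grammar_scan <- function(genotypes, residuals, allele_only = FALSE) {
  stopifnot(inherits(genotypes, "genotype_table"))
  if (is.numeric(residuals)) {
    residuals <- tibble::tibble(individual_id = names(residuals),
                                ystar = unname(residuals))
  }
  idx <- match(residuals$individual_id, genotypes$samples)
  if (anyNA(idx)) {
    stop("residuals include individuals absent from the genotype table",
         call. = FALSE)
  }
  ystar <- residuals$ystar
  m <- nrow(genotypes$markers)
  a_all <- genotypes$a[, idx, drop = FALSE]
  b_all <- genotypes$b[, idx, drop = FALSE]

  out <- vector("list", m)
  for (i in seq_len(m)) {
    a <- as.numeric(a_all[i, ]); b <- as.numeric(b_all[i, ])
    use <- !is.na(a)
    n_use <- sum(use)
    row <- list(maf = NA_real_, cnv_rate = NA_real_, n_used = n_use,
                stage1_stat = 0, stage1_df = 0L, stage1_p = 1,
                stage1_terms = "", stage1_dropped = "")
    if (n_use == 0L) {
      row$stage1_dropped <- "allele_contrast:invariant;copy_total:invariant"
      out[[i]] <- row; next
    }
    contrast <- (a - b)[use]; total <- (a + b)[use]
    tot_sum <- sum(total)
    sum_a <- sum(a[use]); sum_b <- sum(b[use])
    row$maf <- if (tot_sum > 0) min(sum_a, sum_b) / tot_sum else 0
    row$cnv_rate <- mean(total != 2)
    ret <- retain_genotype_terms(contrast, total)
    if (allele_only) ret$terms$copy_total <- NULL
    if (length(ret$terms) == 0L || n_use <= length(ret$terms) + 1L) {
      row$stage1_dropped <- paste0(names(ret$reasons), ":", ret$reasons,
                                   collapse = ";")
      out[[i]] <- row; next
    }
    Z <- cbind(1, do.call(cbind, ret$terms))
    yv <- ystar[use]
    ZtZ <- crossprod(Z)
    ch <- tryCatch(chol(ZtZ), error = function(e) NULL)
    if (is.null(ch)) {
      row$stage1_dropped <- "copy_total:collinear"
      out[[i]] <- row; next
    }
    bhat <- backsolve(ch, forwardsolve(t(ch), crossprod(Z, yv)))
    rss <- sum(yv^2) - sum(crossprod(Z, yv) * bhat)
    s2 <- rss / (n_use - ncol(Z))
    Vinv <- chol2inv(ch)
    gi <- 1L + seq_along(ret$terms)
    Cg <- s2 * Vinv[gi, gi, drop = FALSE]
    bg <- bhat[gi]
    stat <- drop(crossprod(bg, solve(Cg, bg)))
    df <- length(gi)
    row$stage1_stat <- stat
    row$stage1_df <- df
    row$stage1_p <- stats::pchisq(stat, df, lower.tail = FALSE)
    row$stage1_terms <- paste(names(ret$terms), collapse = ",")
    row$stage1_dropped <- paste0(names(ret$reasons), ":", ret$reasons,
                                 collapse = ";")
    out[[i]] <- row
  }
  dplyr::bind_cols(
    genotypes$markers[, c("marker_id", "chrom", "pos")],
    dplyr::bind_rows(lapply(out, tibble::as_tibble))
  )
}

#' Select the top-K markers from the first-stage screen
#'
#' Keeps the `k` smallest stage-1 p-values; ties are broken by genomic
#' order (chromosome, position) then marker id, so the screen is
#' deterministic.
#'
#' @param results Stage-1 scan tibble.
#' @param k Number of markers to carry into the second stage.
#' @return A list of class `screen_result`: `marker_ids` (ranked),
#'   `k`, and `p_cutoff_attained` (largest admitted stage-1 p).
#' @export
select_top_k <- function(results, k = 1000L) {
  stopifnot(k >= 1L)
  if (nrow(results) < k) {
    warning("only ", nrow(results), " markers available (k = ", k, ")",
            call. = FALSE)
  }
  ord <- results |>
    dplyr::mutate(.chrom_num = suppressWarnings(as.numeric(.data$chrom))) |>
    dplyr::arrange(.data$stage1_p, .data$.chrom_num, .data$chrom,
                   .data$pos, .data$marker_id)
  sel <- utils::head(ord, k)
  structure(list(marker_ids = sel$marker_id, k = as.integer(k),
                 p_cutoff_attained = max(sel$stage1_p)),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d markers screened in (k = %d), attained stage-1 p cutoff %.3g\n",
              length(x$marker_ids), x$k, x$p_cutoff_attained))
  invisible(x)
}

#' Second-stage full mixed-model scan
#'
#' Refits, for each screened marker, the full model: ln trait on the
#' retained genotype terms plus principal components, age, age-squared,
#' sex and center, with a family random intercept; variance components are
#' re-estimated per marker by REML. The retained genotype terms are tested
#' jointly by a Wald chi-square.
#'
#' @param genotypes A [genotype_table()].
#' @param pheno,roster,pcs,n_pcs,trait_is_log,center_age As in
#'   [fit_null_model()].
#' @param markers Marker ids to refit (e.g. `screen$marker_ids`); default
#'   all markers in the table.
#' @param allele_only If `TRUE`, only the allele-contrast term enters.
#' @return A tibble with one row per refitted marker: `beta1`/`se1`
#'   (allele contrast), `beta2`/`se2` (copy total), joint statistic,
#'   degrees of freedom, `stage2_p`, and term bookkeeping. Markers whose
#'   refit fails are reported with `stage2_p = NA`.
#' @export
stage2_full_scan <- function(genotypes, pheno, roster, pcs = NULL,
                             n_pcs = 4L, markers = NULL,
                             trait_is_log = FALSE, center_age = FALSE,
                             allele_only = FALSE) {
  stopifnot(inherits(genotypes, "genotype_table"))
  d <- build_covariate_design(pheno, roster, pcs, n_pcs,
                              trait_is_log, center_age)
  idx <- match(d$individual_id, genotypes$samples)
  if (anyNA(idx)) {
    stop("phenotyped individuals absent from the genotype table", call. = FALSE)
  }
  if (is.null(markers)) markers <- genotypes$markers$marker_id
  mi <- match(markers, genotypes$markers$marker_id)
  if (anyNA(mi)) stop("unknown marker id in 'markers'", call. = FALSE)

  a_all <- genotypes$a[, idx, drop = FALSE]
  b_all <- genotypes$b[, idx, drop = FALSE]
  out <- vector("list", length(mi))
  for (j in seq_along(mi)) {
    i <- mi[j]
    a <- as.numeric(a_all[i, ]); b <- as.numeric(b_all[i, ])
    use <- !is.na(a)
    n_use <- sum(use)
    row <- list(maf = NA_real_, cnv_rate = NA_real_, n_used = n_use,
                beta1 = NA_real_, se1 = NA_real_,
                beta2 = NA_real_, se2 = NA_real_,
                stage2_stat = NA_real_, df = 0L, stage2_p = NA_real_,
                tested_terms = "", stage2_dropped = "", stage2_note = "")
    if (n_use == 0L) {
      row$stage2_p <- 1; row$stage2_stat <- 0
      row$stage2_dropped <- "allele_contrast:invariant;copy_total:invariant"
      out[[j]] <- row; next
    }
    contrast <- (a - b)[use]; total <- (a + b)[use]
    tot_sum <- sum(total)
    row$maf <- if (tot_sum > 0) min(sum(a[use]), sum(b[use])) / tot_sum else 0
    row$cnv_rate <- mean(total != 2)
    Xc <- d$X[use, , drop = FALSE]
    ret <- retain_genotype_terms(contrast, total, X_cov = Xc)
    if (allele_only) ret$terms$copy_total <- NULL
    if (length(ret$terms) == 0L) {
      row$stage2_p <- 1; row$stage2_stat <- 0
      row$stage2_dropped <- paste0(names(ret$reasons), ":", ret$reasons,
                                   collapse = ";")
      out[[j]] <- row; next
    }
    Xm <- cbind(Xc, do.call(cbind, ret$terms))
    colnames(Xm) <- c(colnames(Xc), names(ret$terms))
    fit <- tryCatch(
      fit_lmm_reml(d$y[use], Xm, d$families[use]),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      row$stage2_note <- if (is.null(fit)) "fit_error" else "not_converged"
      out[[j]] <- row; next
    }
    wt <- wald_joint_test(fit, names(ret$terms), dropped_reason = ret$reasons)
    if ("allele_contrast" %in% fit$fixed_names) {
      row$beta1 <- unname(fit$fixed_estimates["allele_contrast"])
      row$se1 <- sqrt(fit$fixed_covariance["allele_contrast", "allele_contrast"])
    }
    if ("copy_total" %in% fit$fixed_names) {
      row$beta2 <- unname(fit$fixed_estimates["copy_total"])
      row$se2 <- sqrt(fit$fixed_covariance["copy_total", "copy_total"])
    }
    row$stage2_stat <- wt$statistic
    row$df <- wt$df
    row$stage2_p <- wt$p_value
    row$tested_terms <- wt$tested_terms
    row$stage2_dropped <- wt$dropped_reason
    out[[j]] <- row
  }
  dplyr::bind_cols(
    genotypes$markers[mi, c("marker_id", "chrom", "pos")],
    dplyr::bind_rows(lapply(out, tibble::as_tibble))
  )
}

#' Flag genome-wide significant markers
#'
#' A marker is significant iff its second-stage p-value is strictly below
#' the genome-wide threshold (default `5e-7`).
#'
#' @param results A tibble with a `stage2_p` column.
#' @param genomewide_alpha Significance threshold (strict inequality).
#' @return `results` with a logical `significant` column.
#' @export
flag_significance <- function(results, genomewide_alpha = 5e-7) {
  dplyr::mutate(results,
    significant = !is.na(.data$stage2_p) & .data$df > 0L &
      .data$stage2_p < genomewide_alpha)
}

#' Run the full two-stage joint SNP/CNV association scan
#'
#' Orchestrates the whole pipeline on in-memory objects: confidence
#' filter, marker QC, genotype PCA, null mixed-model fit, conditional
#' residuals, first-stage GRAMMAR screen, top-K selection, second-stage
#' mixed-model refits, and genome-wide significance flagging.
#'
#' @param genotypes A raw [genotype_table()].
#' @param pheno A `phenocov` tibble.
#' @param roster A roster tibble.
#' @param confidence_threshold Call-confidence cutoff (strict; default
#'   0.1).
#' @param min_call_rate,min_maf Marker QC thresholds.
#' @param n_pcs Number of genotype principal components (0 to skip PCA).
#' @param k Number of markers carried into the second stage.
#' @param genomewide_alpha Genome-wide significance threshold.
#' @param trait_is_log,center_age,allele_only Passed through to the
#'   stages.
#' @return A list of class `jointgwas_run`: `results` (per screened
#'   marker, stage-1 and stage-2 columns merged, ordered by stage-2 p),
#'   `stage1` (all markers), `screen`, `pcs`, `null_fit`, and `report`
#'   (a [run_report]).
#' @export
run_joint_gwas <- function(genotypes, pheno, roster,
                           confidence_threshold = 0.1,
                           min_call_rate = 0.95, min_maf = 0.01,
                           n_pcs = 4L, k = 1000L,
                           genomewide_alpha = 5e-7,
                           trait_is_log = FALSE, center_age = FALSE,
                           allele_only = FALSE) {
  t0 <- Sys.time()
  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  n_markers_in <- nrow(genotypes$markers)
  note("input: %d markers x %d samples, %d families",
       n_markers_in, length(genotypes$samples),
       length(unique(roster$family_id)))

  gt <- apply_confidence_filter(genotypes, confidence_threshold)
  note("confidence filter (< %.3g): %d calls set missing",
       confidence_threshold, attr(gt, "n_filtered"))
  gt <- qc_filter(gt, min_call_rate = min_call_rate, min_maf = min_maf)
  qc <- attr(gt, "qc_log")
  note("marker QC: %d removed by call rate, %d by MAF; %d markers remain",
       qc$removed[1], qc$removed[2], nrow(gt$markers))

  pcs <- NULL
  if (n_pcs > 0L) {
    pcs <- compute_genotype_pcs(gt, n_components = n_pcs, min_maf = min_maf)
    note("PCA: %d components from %d markers", n_pcs,
         length(pcs$markers_used))
  }
  null_fit <- fit_null_model(pheno, roster, pcs = pcs, n_pcs = n_pcs,
                             trait_is_log = trait_is_log,
                             center_age = center_age)
  note("null model: n = %d, sigma2_family = %.4g, sigma2_resid = %.4g",
       null_fit$n_used, null_fit$sigma2_family, null_fit$sigma2_resid)

  ystar <- grammar_residuals(null_fit)
  stage1 <- stage1_grammar_scan(gt, ystar, allele_only = allele_only)
  tested1 <- stage1$stage1_df > 0L
  lambda1 <- if (sum(tested1) > 0) {
    genomic_inflation_lambda(stage1$stage1_p[tested1], warn_few = FALSE)
  } else NA_real_
  note("stage 1: %d markers tested, lambda = %.3f", sum(tested1), lambda1)

  screen <- select_top_k(stage1, k = min(k, nrow(stage1)))
  note("screen: top %d markers, attained p cutoff %.3g",
       length(screen$marker_ids), screen$p_cutoff_attained)

  stage2 <- stage2_full_scan(gt, pheno, roster, pcs = pcs, n_pcs = n_pcs,
                             markers = screen$marker_ids,
                             trait_is_log = trait_is_log,
                             center_age = center_age,
                             allele_only = allele_only)
  stage2 <- flag_significance(stage2, genomewide_alpha)
  tested2 <- !is.na(stage2$stage2_p) & stage2$df > 0L
  lambda2 <- if (sum(tested2) > 0) {
    genomic_inflation_lambda(stage2$stage2_p[tested2], warn_few = FALSE)
  } else NA_real_
  note("stage 2: %d markers refitted, lambda = %.3f, %d significant at %.2g",
       nrow(stage2), lambda2, sum(stage2$significant), genomewide_alpha)

  results <- stage2 |>
    dplyr::left_join(
      stage1[c("marker_id", "stage1_stat", "stage1_df", "stage1_p")],
      by = "marker_id") |>
    dplyr::arrange(.data$stage2_p, .data$stage1_p) |>
    dplyr::relocate("stage1_p", .before = "stage2_p")

  report <- new_run_report(
    counts = tibble::tibble(
      stage = c("input_markers", "post_qc_markers", "screened_markers",
                "individuals_modeled", "families"),
      n = c(n_markers_in, nrow(gt$markers), length(screen$marker_ids),
            null_fit$n_used, length(unique(roster$family_id)))),
    lambda_stage1 = lambda1, lambda_stage2 = lambda2,
    stage1_cutoff = screen$p_cutoff_attained,
    n_significant = sum(stage2$significant),
    config = list(confidence_threshold = confidence_threshold,
                  min_call_rate = min_call_rate, min_maf = min_maf,
                  n_pcs = n_pcs, k = k, genomewide_alpha = genomewide_alpha,
                  allele_only = allele_only),
    log_lines = log_lines,
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  structure(list(results = results, stage1 = stage1, screen = screen,
                 pcs = pcs, null_fit = null_fit, report = report),
            class = "jointgwas_run")
}

#' @export
print.jointgwas_run <- function(x, ...) {
  print(x$report)
  cat("\nTop markers:\n")
  print(utils::head(x$results[c("marker_id", "chrom", "pos", "maf",
                                "stage1_p", "stage2_p", "significant")], 5))
  invisible(x)
}

#' Tidy the results of a two-stage run
#' @param x A `jointgwas_run`.
#' @param ... Unused.
#' @return The merged per-marker results tibble.
#' @method tidy jointgwas_run
#' @export
tidy.jointgwas_run <- function(x, ...) x$results

#' One-row summary of a two-stage run
#' @param x A `jointgwas_run`.
#' @param ... Unused.
#' @return A one-row tibble with marker counts, both inflation factors,
#'   the attained screen cutoff and the number of significant markers.
#' @method glance jointgwas_run
#' @export
glance.jointgwas_run <- function(x, ...) {
  cts <- stats::setNames(x$report$counts$n, x$report$counts$stage)
  tibble::tibble(
    n_markers = unname(cts["input_markers"]),
    n_post_qc = unname(cts["post_qc_markers"]),
    n_screened = unname(cts["screened_markers"]),
    n_individuals = unname(cts["individuals_modeled"]),
    lambda_stage1 = x$report$lambda_stage1,
    lambda_stage2 = x$report$lambda_stage2,
    stage1_cutoff = x$report$stage1_cutoff,
    n_significant = x$report$n_significant
  )
}

#' Run the pipeline from a configuration list or YAML file
#'
#' The configuration either names input files (`genotype_file`,
#' `roster_file`, `phenocov_file`) or requests a simulation
#' (`simulate: {seed: ..., <sim_config fields>}`), plus any of the
#' analysis settings of [run_joint_gwas()] (`confidence_threshold`,
#' `min_call_rate`, `min_maf`, `n_pcs`, `k`, `genomewide_alpha`, ...).
#' If `output_dir` is set, the results table, the stage-1 table and the
#' run report are written there as TSV / YAML.
#'
#' @param config A named list, or the path of a YAML file.
#' @return Invisibly, the [run_joint_gwas()] result.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    seed <- sim_args$seed %||% 1L
    sim_args$seed <- NULL
    # YAML parses vectors (histograms, ranges) as named lists
    sim_args <- lapply(sim_args, function(x) if (is.list(x)) unlist(x) else x)
    cfg <- do.call(sim_config, sim_args)
    sim <- simulate_study(cfg, seed = seed)
    genotypes <- sim$genotypes; pheno <- sim$pheno; roster <- sim$roster
  } else {
    genotypes <- read_genotype_table(config$genotype_file)
    roster <- read_roster(config$roster_file)
    pheno <- read_phenocov(config$phenocov_file)
  }
  run_args <- config[intersect(names(config), names(formals(run_joint_gwas)))]
  run <- do.call(run_joint_gwas,
                 c(list(genotypes = genotypes, pheno = pheno,
                        roster = roster), run_args))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_results_table(run$results,
                        file.path(config$output_dir, "results.tsv"))
    write_results_table(run$stage1,
                        file.path(config$output_dir, "stage1.tsv"))
    write_run_report(run$report,
                     file.path(config$output_dir, "report.yaml"))
  }
  invisible(run)
}
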