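#' Genotype principal components for stratification adjustment
#'
#' Computes the leading principal components of the standardized genotype
#' dosage matrix, for use as fixed covariates against population
#' stratification. Markers are restricted to effectively diploid loci
#' (fraction of non-diploid usable calls at most `max_cnv_rate`) passing
#' `min_maf`; the per-marker dosage is the count of B alleles,
#' mean-imputed where missing, centered, and scaled by `sqrt(p (1 - p))`
#' with `p` the allele-frequency estimate. Scores and eigenvalues come
#' from the eigendecomposition of the individual-by-individual covariance
#' of the standardized dosages. Each component's sign is fixed so that the
#' sum of its marker loadings is non-negative, making results reproducible
#' and invariant to marker order.
#'
#' @param table A [genotype_table()].
#' @param n_components Number of components to return.
#' @param min_maf Minimum minor-allele frequency of markers entering the
#'   PCA.
#' @param max_cnv_rate Markers with a larger fraction of non-diploid calls
#'   are excluded (dosage scaling assumes diploidy).
#' @param thin_every Optional integer: keep every `thin_every`-th eligible
#'   marker (a cheap stand-in for LD pruning; default 1 = no thinning).
#' @return An object of class `pc_result`: `scores` (individuals x K,
#'   columns `pc1..pcK`, each zero-mean), `eigenvalues` (nonincreasing),
#'   `markers_used`, `samples`.
#' @export
compute_genotype_pcs <- function(table, n_components = 4L, min_maf = 0.01,
                                 max_cnv_rate = 0.01, thin_every = 1L) {
  stopifnot(inherits(table, "genotype_table"), n_components >= 1L)
  n <- length(table$samples)
  if (n < n_components + 1L) {
    stop("need at least n_components + 1 individuals", call. = FALSE)
  }
  tot <- table$a + table$b
  usable <- !is.na(tot)
  n_usable <- rowSums(usable)
  cnv_rate <- rowSums(tot != 2L, na.rm = TRUE) / pmax(n_usable, 1L)
  a_sum <- rowSums(table$a, na.rm = TRUE)
  b_sum <- rowSums(table$b, na.rm = TRUE)
  denom <- a_sum + b_sum
  maf <- ifelse(denom > 0, pmin(a_sum, b_sum) / denom, 0)
  keep <- n_usable > 0L & cnv_rate <= max_cnv_rate & maf >= min_maf
  keep_idx <- which(keep)
  if (thin_every > 1L) {
    keep_idx <- keep_idx[seq(1L, length(keep_idx), by = as.integer(thin_every))]
  }
  if (length(keep_idx) < n_components) {
    stop("fewer usable markers (", length(keep_idx),
         ") than requested components", call. = FALSE)
  }

  # individuals x markers standardized dosage (B-allele count)
  D <- t(table$b[keep_idx, , drop = FALSE])
  storage.mode(D) <- "double"
  mu <- colMeans(D, na.rm = TRUE)
  for (j in seq_len(ncol(D))) {
    dj <- D[, j]
    dj[is.na(dj)] <- mu[j]
    D[, j] <- dj - mu[j]
  }
  p_hat <- mu / 2
  sdv <- sqrt(pmax(p_hat * (1 - p_hat), .Machine$double.eps))
  Z <- sweep(D, 2L, sdv, "/")

  K <- tcrossprod(Z) / ncol(Z)
  eig <- eigen(K, symmetric = TRUE)
  vals <- pmax(eig$values[seq_len(n_components)], 0)
  vecs <- eig$vectors[, seq_len(n_components), drop = FALSE]
  # sign convention: loading sum non-negative
  for (j in seq_len(n_components)) {
    if (sum(crossprod(Z, vecs[, j])) < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- sweep(vecs, 2L, sqrt(vals), "*")
  # exact zero column means (degenerate zero-eigenvalue components can
  # otherwise pick up the constant direction at machine precision)
  scores <- sweep(scores, 2L, colMeans(scores), "-")
  colnames(scores) <- paste0("pc", seq_len(n_components))
  rownames(scores) <- table$samples
  structure(list(scores = scores, eigenvalues = vals,
                 markers_used = table$markers$marker_id[keep_idx],
                 samples = table$samples),
            class = "pc_result")
}

#' @export
print.pc_result <- function(x, ...) {
  cat(sprintf("<pc_result> %d individuals x %d components (%d markers)\n",
              nrow(x$scores), ncol(x$scores), length(x$markers_used)))
  cat("eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy principal-component scores
#'
#' @param x A `pc_result`.
#' @param ... Unused.
#' @return A tibble: `individual_id` plus one column per component.
#' @method tidy pc_result
#' @export
tidy.pc_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(individual_id = x$samples),
                   tibble::as_tibble(x$scores))
}

#' Choose how many principal components enter the model
#'
#' With `rule = "fixed_k"` (the default, `k = 4`) the choice mirrors the
#' usual eyeball-the-eigenvalues decision resolved in advance. With
#' `rule = "eigenvalue_gap"` the number returned is the index just before
#' the largest successive eigenvalue ratio drop.
#'
#' @param eigenvalues Nonincreasing nonnegative eigenvalues.
#' @param rule `"fixed_k"` or `"eigenvalue_gap"`.
#' @param k Number of components under `fixed_k`.
#' @return An integer count of components.
#' @export
select_num_pcs <- function(eigenvalues, rule = c("fixed_k", "eigenvalue_gap"),
                           k = 4L) {
  rule <- match.arg(rule)
  if (rule == "fixed_k") {
    if (length(eigenvalues) < k) {
      stop("fewer eigenvalues than k", call. = FALSE)
    }
    return(as.integer(k))
  }
  if (length(eigenvalues) < 2L) return(1L)
  ratios <- eigenvalues[-length(eigenvalues)] /
    pmax(eigenvalues[-1L], .Machine$double.eps)
  if (max(ratios) <= 1 + 1e-12) {
    warning("no eigenvalue gap found; defaulting to 1 component",
            call. = FALSE)
    return(1L)
  }
  as.integer(which.max(ratios))
}
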