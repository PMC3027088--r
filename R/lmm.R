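# Family random-intercept linear mixed model, fitted by REML.
#
# The model is y = X beta + Z gamma + eps with one random intercept per
# family, so V = sigma2_family * J_blocks + sigma2_resid * I. Within a
# family of size s the covariance is exchangeable and V's blocks invert in
# closed form:
#   V_f^{-1} = (1/s2r) * (I - c_f * J),  c_f = s2f / (s2r + s * s2f)
#   log|V_f| = (s - 1) * log s2r + log(s2r + s * s2f)
# All crossproducts are accumulated blockwise via per-family column sums,
# giving O(n) likelihood evaluations. Fitting profiles the variance ratio
# theta = s2f / s2r on a log grid followed by golden-section refinement.

# Blockwise accumulation of M' W^{-1} M for W = I + theta * J_blocks.
# S = rowsum(M, fam) must be precomputed; sizes are family sizes in the
# same order as S's rows.
wmetric_crossprod <- function(MtM, S, sizes, theta) {
  if (theta == 0) return(MtM)
  cf <- theta / (1 + sizes * theta)
  MtM - crossprod(S, S * cf)
}

#' Restricted log-likelihood of the family random-intercept model
#'
#' Evaluates the REML log-likelihood of `y` under
#' `V = sigma2_family * (family block product) + sigma2_resid * I`,
#' block-by-block in O(n). The formula is the standard restricted
#' likelihood `-0.5 * [(n-p) log 2*pi + log|V| + log|X'V^-1 X| + r'V^-1 r]`
#' with `r` the generalized-least-squares residual, matching the criterion
#' mixed-model software maximizes.
#'
#' @param y Numeric response vector.
#' @param X Design matrix (full column rank on the used rows).
#' @param families Family identifier per sample (coerced to factor).
#' @param sigma2_family Family variance component, `>= 0`.
#' @param sigma2_resid Residual variance component, `> 0`.
#' @return The restricted log-likelihood (a single number).
#' @export
reml_loglik <- function(y, X, families, sigma2_family, sigma2_resid) {
  if (sigma2_resid <= 0) stop("sigma2_resid must be > 0", call. = FALSE)
  if (sigma2_family < 0) stop("sigma2_family must be >= 0", call. = FALSE)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, length(families) == n)
  fam <- factor(families)
  sizes <- as.numeric(tabulate(fam))
  M <- cbind(X, y)
  S <- rowsum(M, fam)
  theta <- sigma2_family / sigma2_resid
  Aw <- wmetric_crossprod(crossprod(M), S, sizes, theta)
  XtWX <- Aw[seq_len(p), seq_len(p), drop = FALSE]
  XtWy <- Aw[seq_len(p), p + 1L]
  ytWy <- Aw[p + 1L, p + 1L]
  ch <- chol(XtWX)
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  quad <- (ytWy - sum(XtWy * beta)) / sigma2_resid
  logdet_V <- (n - length(sizes)) * log(sigma2_resid) +
    sum(log(sigma2_resid + sizes * sigma2_family))
  # log|X'V^-1 X| = log|X'W^-1 X| - p log s2r
  logdet_XtVX <- 2 * sum(log(diag(ch))) - p * log(sigma2_resid)
  -0.5 * ((n - p) * log(2 * pi) + logdet_V + logdet_XtVX + quad)
}

# Profiled REML criterion in theta: sigma2_resid is solved in closed form.
# Returns the profile log-likelihood plus the ingredients the fitter needs.
profile_reml <- function(theta, MtM, S, sizes, n, p) {
  Aw <- wmetric_crossprod(MtM, S, sizes, theta)
  XtWX <- Aw[seq_len(p), seq_len(p), drop = FALSE]
  XtWy <- Aw[seq_len(p), p + 1L]
  ytWy <- Aw[p + 1L, p + 1L]
  ch <- tryCatch(chol(XtWX), error = function(e) NULL)
  if (is.null(ch)) return(list(ll = -Inf))
  beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
  rss <- ytWy - sum(XtWy * beta)
  if (rss <= 0) return(list(ll = -Inf))
  s2r <- rss / (n - p)
  ll <- -0.5 * ((n - p) * (log(2 * pi) + log(s2r) + 1) +
                  sum(log(1 + sizes * theta)) + 2 * sum(log(diag(ch))))
  list(ll = ll, beta = beta, s2r = s2r, chol = ch)
}

#' Fit the family random-intercept model by REML
#'
#' Maximizes the restricted likelihood over `(sigma2_family >= 0,
#' sigma2_resid > 0)` by profiling the variance ratio on a log-spaced grid
#' and refining the best bracket with golden-section search. Fixed effects
#' are the generalized-least-squares solution at the optimum; family
#' effects are predicted by their BLUPs (shrunken family residual means).
#'
#' @param y Numeric response vector.
#' @param X Design matrix with column names (an intercept column included
#'   by the caller).
#' @param families Family identifier per sample.
#' @param tol Convergence tolerance on the profiled ratio (default `1e-8`).
#' @param theta_grid Log-spaced grid of variance ratios scanned before
#'   refinement.
#' @return An object of class `lmm_fit`: fixed-effect estimates and their
#'   covariance, `sigma2_family`, `sigma2_resid`, per-family BLUPs, the
#'   REML log-likelihood, `converged`, and `n_used`.
#' @export
fit_lmm_reml <- function(y, X, families, tol = 1e-8,
                         theta_grid = c(0, exp(seq(log(1e-4), log(1e3),
                                                   length.out = 41)))) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y); p <- ncol(X)
  stopifnot(nrow(X) == n, length(families) == n)
  if (n <= p + 1L) stop("too few samples to fit the model", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < p) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fam <- factor(families)
  sizes <- as.numeric(tabulate(fam))
  M <- cbind(X, y)
  MtM <- crossprod(M)
  S <- rowsum(M, fam)

  lls <- vapply(theta_grid, function(th)
    profile_reml(th, MtM, S, sizes, n, p)$ll, numeric(1))
  best <- which.max(lls)
  lo <- theta_grid[max(1L, best - 1L)]
  hi <- theta_grid[min(length(theta_grid), best + 1L)]
  converged <- is.finite(lls[best])
  theta <- theta_grid[best]
  if (converged && hi > lo) {
    opt <- stats::optimize(function(th) profile_reml(th, MtM, S, sizes, n, p)$ll,
                           interval = c(lo, hi), maximum = TRUE, tol = tol)
    if (opt$objective >= lls[best]) theta <- opt$maximum
  }
  prof <- profile_reml(theta, MtM, S, sizes, n, p)
  if (!is.finite(prof$ll)) {
    converged <- FALSE
    prof <- profile_reml(0, MtM, S, sizes, n, p)
    theta <- 0
  }
  s2r <- prof$s2r
  s2f <- theta * s2r
  beta <- drop(prof$beta)
  names(beta) <- colnames(X)
  XtWX_inv <- chol2inv(prof$chol)
  vcov_beta <- s2r * XtWX_inv
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))

  r <- y - drop(X %*% beta)
  rsum <- drop(rowsum(r, fam))
  blups <- s2f * rsum / (s2r + sizes * s2f)
  names(blups) <- levels(fam)

  structure(list(
    fixed_names = colnames(X),
    fixed_estimates = beta,
    fixed_covariance = vcov_beta,
    sigma2_family = s2f,
    sigma2_resid = s2r,
    family_blups = blups,
    reml_loglik = prof$ll,
    converged = converged,
    n_used = n,
    families = fam,
    residual_fixed = r
  ), class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf(
    "<lmm_fit> n = %d, %d fixed effects | sigma2_family = %.4g, sigma2_resid = %.4g\nREML loglik = %.4f%s\n",
    x$n_used, length(x$fixed_estimates), x$sigma2_family, x$sigma2_resid,
    x$reml_loglik, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Tidy a fitted family mixed model
#'
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `term`, `estimate`,
#'   `std.error`, `statistic` (Wald z), `p.value`.
#' @method tidy lmm_fit
#' @export
tidy.lmm_fit <- function(x, ...) {
  se <- sqrt(diag(x$fixed_covariance))
  z <- x$fixed_estimates / se
  tibble::tibble(
    term = x$fixed_names,
    estimate = unname(x$fixed_estimates),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  )
}

#' One-row summary of a fitted family mixed model
#'
#' @param x An `lmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: variance components, intraclass correlation,
#'   REML log-likelihood, sample size, convergence flag.
#' @method glance lmm_fit
#' @export
glance.lmm_fit <- function(x, ...) {
  tibble::tibble(
    sigma2_family = x$sigma2_family,
    sigma2_resid = x$sigma2_resid,
    icc = x$sigma2_family / (x$sigma2_family + x$sigma2_resid),
    reml_loglik = x$reml_loglik,
    n_used = x$n_used,
    converged = x$converged
  )
}

#' Conditional (GRAMMAR) residuals of a null mixed-model fit
#'
#' Subtracts from the phenotype both the fitted fixed part and the
#' individual's predicted family effect (BLUP), yielding the residual
#' trait the first-stage genome scan regresses on genotype. When the
#' family variance is estimated at zero the BLUPs vanish and these are the
#' ordinary least-squares residuals.
#'
#' @param fit An `lmm_fit` from the null (no-genotype) model.
#' @param y The response the model was fitted to (defaults to the stored
#'   fixed-part residual, in which case only BLUP subtraction remains).
#' @param X_null The null design matrix used for the fit.
#' @return Numeric vector of conditional residuals, one per fitted sample.
#' @export
conditional_residuals <- function(fit, y = NULL, X_null = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!fit$converged) stop("null-model fit did not converge", call. = FALSE)
  if (is.null(y)) {
    r <- fit$residual_fixed
  } else {
    if (length(y) != fit$n_used) stop("y length mismatch", call. = FALSE)
    if (is.null(X_null)) stop("X_null required when y is supplied", call. = FALSE)
    r <- y - drop(as.matrix(X_null) %*% fit$fixed_estimates)
  }
  r - unname(fit$family_blups[as.character(fit$families)])
}

#' Joint Wald test of the genotype terms
#'
#' Tests the retained genotype terms (allele contrast and/or copy total)
#' jointly: `statistic = b' C^{-1} b` with `C` their covariance submatrix,
#' referred to a chi-square with as many degrees of freedom as terms
#' retained. Terms dropped before the fit (invariant or collinear) reduce
#' the degrees of freedom; with nothing retained the statistic is 0 and
#' the p-value 1.
#'
#' @param fit An `lmm_fit`.
#' @param term_labels Genotype term names to test (those present among
#'   `fit$fixed_names` are used).
#' @param dropped_reason Optional named reasons for terms absent from the
#'   fit, propagated into the result.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `tested_terms`,
#'   `dropped_reason`.
#' @export
wald_joint_test <- function(fit,
                            term_labels = c("allele_contrast", "copy_total"),
                            dropped_reason = NULL) {
  stopifnot(inherits(fit, "lmm_fit"))
  present <- intersect(term_labels, fit$fixed_names)
  reasons <- character()
  if (!is.null(dropped_reason)) {
    reasons <- paste0(names(dropped_reason), ":", unname(dropped_reason))
  }
  if (length(present) == 0L) {
    return(tibble::tibble(statistic = 0, df = 0L, p_value = 1,
                          tested_terms = paste(character(), collapse = ","),
                          dropped_reason = paste(reasons, collapse = ";")))
  }
  bhat <- fit$fixed_estimates[present]
  C <- fit$fixed_covariance[present, present, drop = FALSE]
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch) && length(present) > 1L) {
    # singular joint covariance: fall back to the first term alone
    reasons <- c(reasons, paste0(present[2], ":collinear"))
    present <- present[1]
    bhat <- fit$fixed_estimates[present]
    C <- fit$fixed_covariance[present, present, drop = FALSE]
    ch <- chol(C)
  }
  stat <- drop(crossprod(forwardsolve(t(ch), bhat)))
  df <- length(present)
  tibble::tibble(
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
    tested_terms = paste(present, collapse = ","),
    dropped_reason = paste(reasons, collapse = ";")
  )
}
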