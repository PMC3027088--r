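# Fixtures are built in code; oracles here are deliberately naive
# (dense matrices, explicit inverses) and independent of the package's
# blockwise implementations.

# A small genotype table with known calls, including a CNV locus and a
# missing call.
make_toy_table <- function() {
  markers <- tibble::tibble(
    marker_id = c("rs1", "rs2", "rs3"),
    chrom = c("7", "7", "20"),
    pos = c(65255030L, 65733463L, 1889171L),
    allele_a = "A", allele_b = "B"
  )
  #            s1        s2        s3        s4
  a <- rbind(c(1L,       2L,       0L,       1L),   # rs1 diploid
             c(2L,       1L,       1L,       NA),   # rs2 incl. CNV (2,1)
             c(0L,       0L,       1L,       2L))   # rs3 diploid
  b <- rbind(c(1L,       0L,       2L,       1L),
             c(1L,       0L,       0L,       NA),
             c(2L,       2L,       1L,       0L))
  conf <- rbind(c(0.02, 0.05, 0.01, 0.09),
                c(0.05, 0.12, 0.03, NA),
                c(0.01, 0.02, 0.04, 0.06))
  genotype_table(markers, paste0("s", 1:4), a, b, conf)
}

# Random genotype table for round-trip / property tests; confidences are
# rounded to the writer's precision.
random_table <- function(m = 10L, n = 10L, seed = 1L, missing_rate = 0.1) {
  withr::local_seed(seed)
  a <- matrix(rbinom(m * n, 2L, 0.4), m, n)
  b <- 2L - a
  cnv <- matrix(runif(m * n) < 0.05, m, n)
  b[cnv] <- pmax(b[cnv] - 1L, 0L)
  conf <- matrix(signif(rbeta(m * n, 0.5, 30), 6), m, n)
  miss <- matrix(runif(m * n) < missing_rate, m, n)
  a[miss] <- NA_integer_; b[miss] <- NA_integer_; conf[miss] <- NA_real_
  markers <- tibble::tibble(
    marker_id = sprintf("m%03d", seq_len(m)),
    chrom = as.character(rep_len(1:3, m)),
    pos = seq_len(m) * 100L,
    allele_a = "A", allele_b = "B")
  genotype_table(markers, sprintf("s%03d", seq_len(n)), a, b, conf)
}

# Dense-matrix REML log-likelihood: explicit V, inverse and determinants.
dense_reml_loglik <- function(y, X, families, s2f, s2r) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  fam <- factor(families)
  Z <- stats::model.matrix(~ fam - 1)
  V <- s2f * tcrossprod(Z) + s2r * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       t(r) %*% Vi %*% r))
}

# Grid + Nelder-Mead refinement of the dense restricted likelihood over
# (log s2f, log s2r); an independent fitting oracle.
dense_reml_fit_oracle <- function(y, X, families) {
  obj <- function(par) -dense_reml_loglik(y, X, families,
                                          exp(par[1]), exp(par[2]))
  v0 <- stats::var(y)
  grid <- expand.grid(lf = log(v0 * c(1e-4, 0.01, 0.1, 0.5, 1, 2, 5)),
                      lr = log(v0 * c(0.01, 0.1, 0.5, 1, 2, 5)))
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(sigma2_family = exp(opt$par[1]), sigma2_resid = exp(opt$par[2]),
       loglik = -opt$value)
}

# Joint Wald chi-square of genotype terms in an OLS fit, from raw normal
# equations (an independent stage-1 oracle).
ols_joint_wald <- function(y, G) {
  Z <- cbind(1, G)
  ZtZ <- t(Z) %*% Z
  bhat <- solve(ZtZ, t(Z) %*% y)
  rss <- sum((y - Z %*% bhat)^2)
  s2 <- rss / (length(y) - ncol(Z))
  covb <- s2 * solve(ZtZ)
  gi <- 1 + seq_len(ncol(G))
  stat <- as.numeric(t(bhat[gi]) %*% solve(covb[gi, gi]) %*% bhat[gi])
  list(stat = stat,
       p = stats::pchisq(stat, df = ncol(G), lower.tail = FALSE))
}

# Minimal hand-built lmm_fit for closed-form Wald checks.
fake_lmm_fit <- function(estimates, covariance) {
  covariance <- as.matrix(covariance)
  dimnames(covariance) <- list(names(estimates), names(estimates))
  structure(list(
    fixed_names = names(estimates),
    fixed_estimates = estimates,
    fixed_covariance = covariance,
    sigma2_family = 0, sigma2_resid = 1,
    family_blups = numeric(), reml_loglik = 0,
    converged = TRUE, n_used = length(estimates)
  ), class = "lmm_fit")
}
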