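# REML engine: blockwise likelihood vs dense oracle, fitting vs grid
# oracle and lme4, BLUP algebra, Wald tests.

make_lmm_fixture <- function(seed = 1L, n_fam = 2L, fam_size = 3L,
                             s2f = 0.5, s2r = 1) {
  withr::local_seed(seed)
  n <- n_fam * fam_size
  fam <- rep(sprintf("F%02d", seq_len(n_fam)), each = fam_size)
  X <- cbind(1, stats::rnorm(n), stats::rnorm(n))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  gamma <- stats::rnorm(n_fam, 0, sqrt(s2f))
  y <- drop(X %*% c(1, 0.5, -0.25)) + gamma[as.integer(factor(fam))] +
    stats::rnorm(n, 0, sqrt(s2r))
  list(y = y, X = X, fam = fam)
}

test_that("blockwise REML log-likelihood equals the dense-matrix oracle", {
  fx <- make_lmm_fixture(seed = 2L, n_fam = 2L, fam_size = 3L)
  for (pars in list(c(0.5, 1), c(2, 0.3), c(0, 1.7), c(1e-3, 5))) {
    expect_equal(
      reml_loglik(fx$y, fx$X, fx$fam, pars[1], pars[2]),
      dense_reml_loglik(fx$y, fx$X, fx$fam, pars[1], pars[2]),
      tolerance = 1e-10)
  }
  # larger mixed-size fixtures, several seeds
  for (seed in 3:6) {
    withr::local_seed(seed)
    fam <- rep(seq_len(12L), times = rep_len(c(1L, 2L, 5L, 8L), 12L))[1:46]
    n <- length(fam)
    X <- cbind(1, stats::rnorm(n))
    y <- stats::rnorm(n) + fam * 0.05
    expect_equal(reml_loglik(y, X, fam, 0.7, 0.9),
                 dense_reml_loglik(y, X, fam, 0.7, 0.9),
                 tolerance = 1e-10)
  }
  expect_error(reml_loglik(fx$y, fx$X, fx$fam, 0.5, 0), "sigma2_resid")
})

test_that("with singleton families only the variance total matters", {
  withr::local_seed(7L)
  n <- 30L
  y <- stats::rnorm(n); X <- cbind(1, stats::rnorm(n))
  fam <- as.character(seq_len(n))
  expect_equal(reml_loglik(y, X, fam, 0, 2),
               reml_loglik(y, X, fam, 1.5, 0.5), tolerance = 1e-10)
  expect_equal(reml_loglik(y, X, fam, 1.9, 0.1),
               reml_loglik(y, X, fam, 0, 2), tolerance = 1e-8)
})

test_that("REML fit recovers the grand mean and matches the dense grid oracle", {
  fit <- fit_lmm_reml(c(1, 1, 2, 2), matrix(1, 4, 1),
                      c("F1", "F1", "F2", "F2"))
  expect_equal(unname(fit$fixed_estimates[1]), 1.5)

  withr::local_seed(8L)
  n_fam <- 10L; fam_size <- 4L
  fam <- rep(sprintf("F%02d", seq_len(n_fam)), each = fam_size)
  X <- cbind(1, stats::rnorm(n_fam * fam_size))
  colnames(X) <- c("(Intercept)", "x1")
  gamma <- stats::rnorm(n_fam, 0, sqrt(2))
  y <- drop(X %*% c(2, 1)) + gamma[as.integer(factor(fam))] +
    stats::rnorm(n_fam * fam_size, 0, 1)
  fit <- fit_lmm_reml(y, X, fam)
  oracle <- dense_reml_fit_oracle(y, X, fam)
  expect_equal(fit$sigma2_family, oracle$sigma2_family, tolerance = 1e-4)
  expect_equal(fit$sigma2_resid, oracle$sigma2_resid, tolerance = 1e-4)
  expect_gte(fit$reml_loglik + 1e-8, oracle$loglik)
  # reported optimum dominates every point of a profile grid
  for (th in c(0, 0.1, 0.5, 1, 2, 5, 10)) {
    expect_gte(fit$reml_loglik + 1e-8,
               dense_reml_loglik(y, X, fam, th * fit$sigma2_resid,
                                 fit$sigma2_resid))
  }
})

test_that("fit agrees with lme4 on estimates, likelihood and BLUPs", {
  skip_if_not_installed("lme4")
  fx <- make_lmm_fixture(seed = 9L, n_fam = 15L, fam_size = 4L,
                         s2f = 0.8, s2r = 1.2)
  fit <- fit_lmm_reml(fx$y, fx$X, fx$fam)
  dat <- data.frame(y = fx$y, x1 = fx$X[, 2], x2 = fx$X[, 3], fam = fx$fam)
  lfit <- lme4::lmer(y ~ x1 + x2 + (1 | fam), data = dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lfit))
  expect_equal(fit$sigma2_family, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$fixed_estimates),
               unname(lme4::fixef(lfit)), tolerance = 1e-5)
  expect_equal(fit$reml_loglik, as.numeric(stats::logLik(lfit)),
               tolerance = 1e-6)
  expect_equal(unname(fit$family_blups),
               unname(lme4::ranef(lfit)$fam[[1]]), tolerance = 1e-4)
  expect_equal(unname(sqrt(diag(fit$fixed_covariance))),
               unname(stats::coef(summary(lfit))[, "Std. Error"]),
               tolerance = 1e-4)
})

test_that("the family variance hits the zero boundary often under a null", {
  n_boundary <- 0L
  for (rep in seq_len(100L)) {
    withr::local_seed(1000L + rep)
    fam <- rep(sprintf("F%02d", 1:10), each = 4L)
    y <- stats::rnorm(40L)            # no family signal at all
    fit <- fit_lmm_reml(y, matrix(1, 40L, 1L), fam)
    if (fit$sigma2_family <= 1e-8 * fit$sigma2_resid) {
      n_boundary <- n_boundary + 1L
    }
  }
  expect_gte(n_boundary, 50L)
})

test_that("fit is invariant to sample reordering and family relabeling", {
  fx <- make_lmm_fixture(seed = 10L, n_fam = 8L, fam_size = 3L)
  fit <- fit_lmm_reml(fx$y, fx$X, fx$fam)
  withr::local_seed(11L)
  perm <- sample(length(fx$y))
  fit_p <- fit_lmm_reml(fx$y[perm], fx$X[perm, ], fx$fam[perm])
  expect_equal(fit$fixed_estimates, fit_p$fixed_estimates, tolerance = 1e-6)
  expect_equal(fit$sigma2_family, fit_p$sigma2_family, tolerance = 1e-6)
  relab <- stats::setNames(sprintf("G%02d", 8:1), unique(fx$fam))
  fit_r <- fit_lmm_reml(fx$y, fx$X, unname(relab[fx$fam]))
  expect_equal(fit$reml_loglik, fit_r$reml_loglik, tolerance = 1e-9)
  expect_equal(sort(unname(fit$family_blups)),
               sort(unname(fit_r$family_blups)), tolerance = 1e-6)
})

test_that("rank-deficient designs name the aliased column", {
  withr::local_seed(12L)
  X <- cbind(`(Intercept)` = 1, a = stats::rnorm(20))
  X <- cbind(X, twice_a = 2 * X[, "a"])
  expect_error(fit_lmm_reml(stats::rnorm(20), X, rep(1:5, each = 4)),
               "twice_a")
})

test_that("conditional residuals subtract BLUPs and are orthogonal to the design", {
  fx <- make_lmm_fixture(seed = 13L, n_fam = 10L, fam_size = 4L,
                         s2f = 1, s2r = 1)
  fit <- fit_lmm_reml(fx$y, fx$X, fx$fam)
  ystar <- conditional_residuals(fit)
  # hand BLUP algebra on the fit's own components
  r <- fx$y - drop(fx$X %*% fit$fixed_estimates)
  for (f in unique(fx$fam)) {
    idx <- fx$fam == f
    s <- sum(idx)
    blup <- fit$sigma2_family * sum(r[idx]) /
      (fit$sigma2_resid + s * fit$sigma2_family)
    expect_equal(unname(fit$family_blups[f]), blup, tolerance = 1e-10)
    expect_equal(ystar[idx], r[idx] - blup, tolerance = 1e-10)
  }
  # X' Ystar = 0 exactly for GLS residuals minus BLUPs
  expect_true(all(abs(crossprod(fx$X, ystar)) < 1e-8))
  expect_lt(abs(mean(ystar)), 1e-8)

  # sigma2_family at zero -> ordinary residuals
  withr::local_seed(14L)
  y0 <- stats::rnorm(40L)
  fit0 <- fit_lmm_reml(y0, fx$X, fx$fam)
  if (fit0$sigma2_family == 0) {
    expect_equal(conditional_residuals(fit0),
                 y0 - drop(fx$X %*% fit0$fixed_estimates), tolerance = 1e-12)
  }
})

test_that("the joint Wald test follows its closed forms", {
  # both estimates zero -> statistic 0, p 1
  fit <- fake_lmm_fit(c(allele_contrast = 0, copy_total = 0), diag(2))
  res <- wald_joint_test(fit)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 2L)

  # single retained term with estimate/se = 2 -> stat 4, p = 0.0455
  fit1 <- fake_lmm_fit(c(allele_contrast = 0.2),
                       matrix(0.01, dimnames = list("allele_contrast",
                                                    "allele_contrast")))
  res1 <- wald_joint_test(fit1, "allele_contrast",
                          dropped_reason = c(copy_total = "invariant"))
  expect_equal(res1$statistic, 4)
  expect_equal(res1$df, 1L)
  expect_equal(res1$p_value, 0.04550026, tolerance = 1e-6)
  expect_match(res1$dropped_reason, "copy_total:invariant")

  # nothing retained -> df 0, p 1
  res0 <- wald_joint_test(fake_lmm_fit(c(x = 1), matrix(1)), character())
  expect_equal(res0$df, 0L)
  expect_equal(res0$p_value, 1)
})
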