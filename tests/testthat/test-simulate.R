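# The sibship study simulator: roster structure, Mendelian genotype
# correlation, variance-component structure of the generated trait.

test_that("the default histogram yields the full cohort roster", {
  roster <- build_roster(default_family_histogram(), seed = 1L)
  expect_equal(length(unique(roster$family_id)), 421L)
  expect_equal(nrow(roster), 1086L)
  sizes <- table(table(roster$family_id))
  expect_equal(unname(sizes[["2"]]), 160L)

  single <- build_roster(c(`3` = 1L), seed = 2L)
  expect_equal(nrow(single), 3L)
  expect_equal(length(unique(single$family_id)), 1L)

  expect_error(build_roster(c(`2` = 0L)), "empty")
})

test_that("simulation is reproducible: same config and seed, identical output", {
  cfg <- sim_config(n_markers = 50L, family_size_histogram = c(`2` = 20L),
                    n_causal = 1L)
  s1 <- simulate_study(cfg, seed = 5L)
  s2 <- simulate_study(cfg, seed = 5L)
  expect_identical(s1$genotypes$a, s2$genotypes$a)
  expect_identical(s1$genotypes$confidence, s2$genotypes$confidence)
  expect_identical(s1$pheno$trait, s2$pheno$trait)
  s3 <- simulate_study(cfg, seed = 6L)
  expect_false(identical(s1$pheno$trait, s3$pheno$trait))
})

test_that("without CNV loci every call is diploid; sibs correlate ~ 0.5", {
  cfg <- sim_config(n_markers = 2000L, family_size_histogram = c(`2` = 100L),
                    cnv_locus_fraction = 0, divergence = 0)
  roster <- build_roster(cfg$family_size_histogram, seed = 3L)
  g <- simulate_genotypes(roster, cfg, seed = 4L)
  expect_true(all(g$genotypes$a + g$genotypes$b == 2L))

  # mean across sib pairs of the across-marker dosage correlation,
  # after centering each marker at its sample mean (kinship expectation)
  dos <- g$genotypes$b - rowMeans(g$genotypes$b)
  sib1 <- dos[, seq(1, 199, by = 2)]
  sib2 <- dos[, seq(2, 200, by = 2)]
  cors <- vapply(seq_len(100L), function(j) {
    suppressWarnings(stats::cor(sib1[, j], sib2[, j]))
  }, numeric(1))
  expect_lt(abs(mean(cors, na.rm = TRUE) - 0.5), 0.05)

  # singletons with no divergence are unrelated
  cfg0 <- sim_config(n_markers = 2000L, family_size_histogram = c(`1` = 100L),
                     cnv_locus_fraction = 0, divergence = 0)
  r0 <- build_roster(cfg0$family_size_histogram, seed = 5L)
  g0 <- simulate_genotypes(r0, cfg0, seed = 6L)
  d0 <- g0$genotypes$b - rowMeans(g0$genotypes$b)
  cors0 <- vapply(seq(1, 99, by = 2), function(j) {
    suppressWarnings(stats::cor(d0[, j], d0[, j + 1L]))
  }, numeric(1))
  expect_lt(abs(mean(cors0, na.rm = TRUE)), 0.05)
})

test_that("generated allele frequencies converge to the configured values", {
  cfg <- sim_config(n_markers = 40L, family_size_histogram = c(`1` = 5000L),
                    cnv_locus_fraction = 0, divergence = 0)
  roster <- build_roster(cfg$family_size_histogram, seed = 7L)
  g <- simulate_genotypes(roster, cfg, seed = 8L)
  freq_b <- rowMeans(g$genotypes$b) / 2
  expect_true(all(abs(freq_b - g$truth$ancestral_freq) < 0.02))
})

test_that("CNV loci segregate with about the configured allele frequency", {
  cfg <- sim_config(n_markers = 400L, family_size_histogram = c(`1` = 1000L),
                    cnv_locus_fraction = 1, cnv_allele_freq = 0.005,
                    divergence = 0)
  roster <- build_roster(cfg$family_size_histogram, seed = 9L)
  g <- simulate_genotypes(roster, cfg, seed = 10L)
  tot <- g$genotypes$a + g$genotypes$b
  # each haplotype carries the deletion with prob 0.005 -> P(total != 2)
  # per call ~ 1 - (1 - 0.005)^2 ~ 0.00998
  expect_equal(mean(tot != 2L), 0.00998, tolerance = 0.15)
  expect_true(all(tot >= 0L & tot <= 2L))  # deletions only
})

test_that("a degenerate phenotype config yields the constant trait", {
  cfg <- sim_config(n_markers = 10L, family_size_histogram = c(`2` = 5L),
                    phi_age = 0, phi_age2 = 0, phi_sex = 0, phi_center = 0,
                    phi_ancestry = 0, sigma2_family = 0, sigma2_resid = 0,
                    alpha = log(3.26))
  sim <- simulate_study(cfg, seed = 11L)
  expect_true(all(abs(sim$pheno$trait - 3.26) < 1e-5))
})

test_that("ln-trait intraclass correlation matches the variance components", {
  cfg <- sim_config(n_markers = 5L, family_size_histogram = c(`2` = 400L),
                    phi_age = 0, phi_age2 = 0, phi_sex = 0, phi_center = 0,
                    phi_ancestry = 0, sigma2_family = 0.01,
                    sigma2_resid = 0.01)
  sim <- simulate_study(cfg, seed = 12L)
  ln_t <- log(sim$pheno$trait)
  icc <- stats::cor(ln_t[seq(1, 799, by = 2)], ln_t[seq(2, 800, by = 2)])
  expect_lt(abs(icc - 0.5), 0.05)
})

test_that("a single causal diploid marker shifts homozygote means by 4 * beta1", {
  markers <- tibble::tibble(marker_id = "m1", chrom = "1", pos = 1L,
                            allele_a = "A", allele_b = "B")
  a <- matrix(c(2L, 2L, 0L, 0L), 1)  # two AA and two BB homozygotes
  b <- 2L - a
  gt <- genotype_table(markers, paste0("I", 1:4), a, b, matrix(0.01, 1, 4))
  roster <- as_roster(tibble::tibble(
    family_id = paste0("F", 1:4), individual_id = paste0("I", 1:4),
    sex = 1L, center = "c"))
  cfg <- sim_config(n_markers = 1L, phi_age = 0, phi_age2 = 0, phi_sex = 0,
                    phi_center = 0, phi_ancestry = 0,
                    sigma2_family = 0, sigma2_resid = 0)
  out <- simulate_phenocov(
    roster, gt, cfg, seed = 13L,
    causal_markers = tibble::tibble(marker_id = "m1", beta1 = 0.05,
                                    beta2 = 0))
  ln_t <- log(out$pheno$trait)
  # contrast 2 vs -2 at beta1 = 0.05 -> ln difference exactly 0.2
  expect_lt(abs(ln_t[1] - ln_t[3] - 0.2), 1e-5)
  expect_error(
    simulate_phenocov(roster, gt, cfg, seed = 13L,
                      causal_markers = tibble::tibble(
                        marker_id = "nope", beta1 = 0.1, beta2 = 0)),
    "absent")
})
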