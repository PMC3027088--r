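# Sibship-design study simulator.
#
# The generator mirrors the hypertensive-sibship cohort design the
# pipeline targets:
# sibships of size 1-10 without genotyped parents, two-population admixture,
# biallelic markers with common minor alleles, a small fraction of loci
# carrying a rare copy-number allele, and an ln-scale trait built additively
# from covariates, causal genotype terms, a shared family deviation and
# residual noise.

#' Default sibship-size histogram
#'
#' The family-size distribution of the hypertensive African American
#' sibship cohort the pipeline emulates: 421 families totalling 1,086
#' genotyped individuals.
#'
#' @return Named integer vector mapping family size to number of families.
#' @export
default_family_histogram <- function() {
  c(`1` = 99L, `2` = 160L, `3` = 69L, `4` = 48L, `5` = 23L,
    `6` = 10L, `7` = 8L, `8` = 0L, `9` = 3L, `10` = 1L)
}

#' Simulation configuration
#'
#' Bundles every tunable of the study simulator. Defaults reproduce the
#' cohort the pipeline was designed around: the sibship histogram of
#' [default_family_histogram()]; common biallelic markers with ancestral
#' minor-allele frequencies drawn uniformly on `maf_range`; a fraction
#' `cnv_locus_fraction` of loci carrying a rare deletion (or duplication)
#' allele of frequency `cnv_allele_freq`; two founder populations with
#' Balding-Nichols per-marker frequency divergence and Beta-distributed
#' per-family admixture; an ln-scale trait with intercept `ln(3.26)`,
#' age/age-squared/sex/center effects, an ancestry effect, and variance
#' components `sigma2_family` / `sigma2_resid` chosen so the family share
#' of the ln-trait variance is 0.4 at a total of 0.0135.
#'
#' @param n_markers Number of markers to simulate.
#' @param family_size_histogram Named vector, size -> number of families.
#' @param maf_range Range the ancestral allele frequency is drawn from.
#' @param cnv_locus_fraction Fraction of loci carrying a copy-number allele.
#' @param cnv_allele_freq Population frequency of the copy-number allele.
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @param divergence Balding-Nichols Fst-like divergence between the two
#'   founder populations.
#' @param admixture_beta Length-2 shape of the Beta distribution the
#'   per-family admixture proportion is drawn from.
#' @param n_causal Number of causal markers (0 for a null genome).
#' @param beta1 Per-allele-contrast effect on the ln trait at causal loci.
#' @param beta2 Per-copy effect on the ln trait at causal loci.
#' @param causal_cnv If `TRUE` causal markers are placed at CNV loci
#'   (so `beta2` has something to act on).
#' @param alpha Intercept of the ln trait.
#' @param phi_age,phi_age2,phi_sex,phi_center,phi_ancestry Fixed covariate
#'   effects on the ln trait (`phi_sex` multiplies an indicator of sex
#'   code 2, `phi_center` an indicator of the second center,
#'   `phi_ancestry` the admixture proportion).
#' @param sigma2_family,sigma2_resid Variance of the shared family
#'   deviation and of the residual, on the ln scale.
#' @param age_mean,age_sd,age_range Age distribution (normal, truncated).
#' @param p_female Probability of sex code 2.
#' @param center_levels,center_prob Recruitment centers and their weights.
#' @param confidence_shape Length-2 shape of the Beta distribution of
#'   call-confidence scores (default `Beta(0.5, 30)`, leaving about 1% of
#'   calls above the 0.1 confidence cutoff so the filter is exercised
#'   without gutting the marker-level call rate).
#' @param missing_rate Additional rate of at-random missing calls.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_markers = 2000L,
                       family_size_histogram = default_family_histogram(),
                       maf_range = c(0.16, 0.44),
                       cnv_locus_fraction = 0.05,
                       cnv_allele_freq = 0.005,
                       cnv_type = c("deletion", "duplication"),
                       divergence = 0.1,
                       admixture_beta = c(1, 1),
                       n_causal = 0L,
                       beta1 = 0.05,
                       beta2 = 0,
                       causal_cnv = FALSE,
                       alpha = log(3.26),
                       phi_age = 0.004,
                       phi_age2 = -2e-5,
                       phi_sex = -0.06,
                       phi_center = 0.01,
                       phi_ancestry = 0.15,
                       sigma2_family = 0.0054,
                       sigma2_resid = 0.0081,
                       age_mean = 43.9, age_sd = 13.4,
                       age_range = c(18, 85),
                       p_female = 0.666,
                       center_levels = c("AL", "NC"),
                       center_prob = c(856, 230) / 1086,
                       confidence_shape = c(0.5, 30),
                       missing_rate = 0) {
  cfg <- list(
    n_markers = as.integer(n_markers),
    family_size_histogram = family_size_histogram,
    maf_range = maf_range,
    cnv_locus_fraction = cnv_locus_fraction,
    cnv_allele_freq = cnv_allele_freq,
    cnv_type = match.arg(cnv_type),
    divergence = divergence,
    admixture_beta = admixture_beta,
    n_causal = as.integer(n_causal),
    beta1 = beta1, beta2 = beta2, causal_cnv = causal_cnv,
    alpha = alpha, phi_age = phi_age, phi_age2 = phi_age2,
    phi_sex = phi_sex, phi_center = phi_center,
    phi_ancestry = phi_ancestry,
    sigma2_family = sigma2_family, sigma2_resid = sigma2_resid,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    p_female = p_female,
    center_levels = center_levels, center_prob = center_prob,
    confidence_shape = confidence_shape,
    missing_rate = missing_rate
  )
  stopifnot(cfg$n_markers >= 1L,
            all(cfg$family_size_histogram >= 0),
            cfg$cnv_locus_fraction >= 0, cfg$cnv_locus_fraction <= 1,
            cfg$cnv_allele_freq >= 0, cfg$cnv_allele_freq <= 1,
            cfg$divergence >= 0, cfg$divergence < 1,
            cfg$sigma2_family >= 0, cfg$sigma2_resid >= 0,
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Build a sibship roster from a family-size histogram
#'
#' Creates `sum(histogram)` families; a family of size `s` contributes `s`
#' individuals. Sex is Bernoulli(`p_female`) (code 2 = female) and the
#' recruitment center is sampled with the configured weights; both are
#' shared draws per individual, not per family.
#'
#' @param histogram Named vector mapping family size to family count.
#' @param seed Integer RNG seed.
#' @param p_female Probability of sex code 2.
#' @param center_levels,center_prob Centers and sampling weights.
#' @return A tibble of class `roster`.
#' @export
build_roster <- function(histogram = default_family_histogram(), seed = 1L,
                         p_female = 0.666,
                         center_levels = c("AL", "NC"),
                         center_prob = c(856, 230) / 1086) {
  histogram <- histogram[histogram > 0]
  if (length(histogram) == 0L) stop("empty family-size histogram", call. = FALSE)
  sizes <- rep(as.integer(names(histogram)), times = as.integer(histogram))
  n_fam <- length(sizes)
  n_ind <- sum(sizes)
  fam_ids <- sprintf("F%04d", seq_len(n_fam))
  withr::local_seed(seed)
  roster <- tibble::tibble(
    family_id = rep(fam_ids, times = sizes),
    individual_id = sprintf("I%05d", seq_len(n_ind)),
    sex = 1L + stats::rbinom(n_ind, 1L, p_female),
    center = sample(center_levels, n_ind, replace = TRUE, prob = center_prob)
  )
  as_roster(roster)
}

# Draw founder-population allele frequencies under a Balding-Nichols model:
# each population's frequency is Beta(p(1-F)/F, (1-p)(1-F)/F) around the
# ancestral p; F = 0 collapses both populations onto p.
bn_population_freqs <- function(p, fst) {
  if (fst <= 0) return(cbind(p, p))
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  cbind(stats::rbeta(length(p), a, b), stats::rbeta(length(p), a, b))
}

#' Simulate CNV-SNP genotypes on a sibship roster
#'
#' Per family, two latent parental diplotypes are drawn from the family's
#' admixture-mixed allele frequencies; each sibling inherits one haplotype
#' from each parent per marker, which induces the expected within-family
#' genotype correlation of 1/2. At CNV loci a deletion (or duplication)
#' allele segregates like a Mendelian allele on haplotypes: a deleted
#' haplotype contributes no copy, a duplicated one contributes two copies
#' of its SNP allele. Call-confidence scores are drawn from the configured
#' Beta distribution and rounded to 6 significant digits (the precision
#' of the file dialect).
#'
#' @param roster A roster tibble (see [build_roster()]).
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return A list: `genotypes` (a [genotype_table()]) and `truth`, a list
#'   holding per-family ancestry proportions, per-marker population
#'   frequencies, and which loci carry a copy-number allele.
#' @export
simulate_genotypes <- function(roster, config = sim_config(), seed = 1L) {
  stopifnot(inherits(roster, "roster"), inherits(config, "sim_config"))
  withr::local_seed(seed)
  m <- config$n_markers
  n <- nrow(roster)
  fam <- factor(roster$family_id, levels = unique(roster$family_id))
  fam_sizes <- tabulate(fam)
  n_fam <- nlevels(fam)

  p_anc <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  pf <- bn_population_freqs(p_anc, config$divergence)
  is_cnv <- stats::runif(m) < config$cnv_locus_fraction
  ancestry_fam <- stats::rbeta(n_fam, config$admixture_beta[1],
                               config$admixture_beta[2])

  a_mat <- matrix(0L, m, n)
  b_mat <- matrix(0L, m, n)
  dup <- config$cnv_type == "duplication"
  col0 <- 0L
  for (f in seq_len(n_fam)) {
    q <- ancestry_fam[f]
    p_fam <- q * pf[, 1] + (1 - q) * pf[, 2]  # P(allele B) in this family
    # 4 parental haplotypes: columns 1-2 mother, 3-4 father
    hap_b <- matrix(stats::rbinom(4L * m, 1L, p_fam), m, 4L)
    hap_del <- matrix(0L, m, 4L)
    if (any(is_cnv) && config$cnv_allele_freq > 0) {
      hap_del[is_cnv, ] <- stats::rbinom(4L * sum(is_cnv), 1L,
                                         config$cnv_allele_freq)
    }
    for (s in seq_len(fam_sizes[f])) {
      pick_m <- sample.int(2L, m, replace = TRUE)
      pick_f <- 2L + sample.int(2L, m, replace = TRUE)
      idx_m <- cbind(seq_len(m), pick_m)
      idx_f <- cbind(seq_len(m), pick_f)
      # copies contributed by each inherited haplotype
      cp_m <- if (dup) 1L + hap_del[idx_m] else 1L - hap_del[idx_m]
      cp_f <- if (dup) 1L + hap_del[idx_f] else 1L - hap_del[idx_f]
      bcnt <- hap_b[idx_m] * cp_m + hap_b[idx_f] * cp_f
      tot <- cp_m + cp_f
      col0 <- col0 + 1L
      a_mat[, col0] <- tot - bcnt
      b_mat[, col0] <- bcnt
    }
  }

  conf <- matrix(signif(stats::rbeta(m * n, config$confidence_shape[1],
                                     config$confidence_shape[2]), 6), m, n)
  if (config$missing_rate > 0) {
    drop <- matrix(stats::runif(m * n) < config$missing_rate, m, n)
    a_mat[drop] <- NA_integer_; b_mat[drop] <- NA_integer_
    conf[drop] <- NA_real_
  }

  markers <- tibble::tibble(
    marker_id = sprintf("mk%05d", seq_len(m)),
    chrom = as.character(1L + (seq_len(m) - 1L) %% 22L),
    pos = 1000L * (1L + (seq_len(m) - 1L) %/% 22L),
    allele_a = "A", allele_b = "B"
  )
  gt <- genotype_table(markers, roster$individual_id, a_mat, b_mat, conf,
                       max_copy = if (dup) 6L else 4L)
  truth <- list(
    ancestry = stats::setNames(ancestry_fam[as.integer(fam)],
                               roster$individual_id),
    pop_freqs = pf, ancestral_freq = p_anc,
    cnv_loci = markers$marker_id[is_cnv]
  )
  list(genotypes = gt, truth = truth)
}

#' Simulate the phenotype/covariate table
#'
#' Generates the ln-scale trait additively: intercept, age, age-squared,
#' sex and center effects, an ancestry effect (the generative stand-in for
#' what principal components adjust for), causal genotype contributions
#' `beta1 * (a - b) + beta2 * (a + b)`, a family deviation shared by all
#' sibs (`Normal(0, sigma2_family)`), and residual noise
#' (`Normal(0, sigma2_resid)`). The stored trait is `exp(ln trait)`,
#' rounded to 6 significant digits so written tables round-trip exactly.
#'
#' @param roster A roster tibble.
#' @param genotypes A [genotype_table()] over the same individuals.
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @param truth Truth list from [simulate_genotypes()] (for ancestry);
#'   if `NULL` the ancestry effect is skipped.
#' @param causal_markers Optional tibble with columns `marker_id`, `beta1`,
#'   `beta2` overriding the config's causal settings.
#' @return A list: `pheno` (a `phenocov` tibble) and `truth` (a list of
#'   class `sim_truth` recording every generative parameter, the causal
#'   markers, and the drawn family effects).
#' @export
simulate_phenocov <- function(roster, genotypes, config = sim_config(),
                              seed = 1L, truth = NULL,
                              causal_markers = NULL) {
  stopifnot(inherits(roster, "roster"), inherits(genotypes, "genotype_table"))
  if (!identical(genotypes$samples, roster$individual_id)) {
    stop("genotype samples must match the roster individuals", call. = FALSE)
  }
  withr::local_seed(seed)
  n <- nrow(roster)
  fam <- factor(roster$family_id, levels = unique(roster$family_id))

  age <- stats::rnorm(n, config$age_mean, config$age_sd)
  lo <- config$age_range[1]; hi <- config$age_range[2]
  while (any(bad <- age < lo | age > hi)) {
    age[bad] <- stats::rnorm(sum(bad), config$age_mean, config$age_sd)
  }
  age <- signif(age, 6)

  if (is.null(causal_markers)) {
    causal_markers <- pick_causal_markers(genotypes, config, truth)
  }
  g_term <- numeric(n)
  if (nrow(causal_markers) > 0L) {
    idx <- match(causal_markers$marker_id, genotypes$markers$marker_id)
    if (anyNA(idx)) {
      stop("causal marker absent from genotype table: ",
           paste(causal_markers$marker_id[is.na(idx)], collapse = ", "),
           call. = FALSE)
    }
    for (r in seq_len(nrow(causal_markers))) {
      d <- encode_joint_design(genotypes, idx[r], .allow_degenerate = TRUE)
      contr <- ifelse(d$usable_mask, d$contrast, 0)
      tot <- ifelse(d$usable_mask, d$total, 2)
      g_term <- g_term + causal_markers$beta1[r] * contr +
        causal_markers$beta2[r] * tot
    }
  }

  ancestry <- if (!is.null(truth)) unname(truth$ancestry[roster$individual_id])
              else numeric(n)
  gamma_fam <- stats::rnorm(nlevels(fam), 0, sqrt(config$sigma2_family))
  eps <- stats::rnorm(n, 0, sqrt(config$sigma2_resid))
  ln_trait <- config$alpha +
    config$phi_age * age + config$phi_age2 * age^2 +
    config$phi_sex * (roster$sex == 2L) +
    config$phi_center * (roster$center == config$center_levels[2]) +
    config$phi_ancestry * ancestry +
    g_term + gamma_fam[as.integer(fam)] + eps

  pheno <- as_phenocov(tibble::tibble(
    individual_id = roster$individual_id,
    trait = signif(exp(ln_trait), 6),
    age = age, sex = roster$sex, center = roster$center
  ))
  sim_truth <- structure(list(
    causal_markers = causal_markers,
    variance_components = c(sigma2_family = config$sigma2_family,
                            sigma2_resid = config$sigma2_resid),
    covariate_effects = c(alpha = config$alpha, phi_age = config$phi_age,
                          phi_age2 = config$phi_age2, phi_sex = config$phi_sex,
                          phi_center = config$phi_center,
                          phi_ancestry = config$phi_ancestry),
    ancestry = ancestry,
    family_effects = stats::setNames(gamma_fam, levels(fam))
  ), class = "sim_truth")
  list(pheno = pheno, truth = sim_truth)
}

# Causal loci default to common diploid markers (or CNV loci when the
# config asks for copy-number-borne effects), chosen deterministically as
# the first qualifying markers so a (config, seed) pair is reproducible.
pick_causal_markers <- function(genotypes, config, truth = NULL) {
  if (config$n_causal == 0L) {
    return(tibble::tibble(marker_id = character(), beta1 = numeric(),
                          beta2 = numeric()))
  }
  ids <- genotypes$markers$marker_id
  if (config$causal_cnv && !is.null(truth)) {
    pool <- intersect(ids, truth$cnv_loci)
  } else if (!is.null(truth)) {
    pool <- setdiff(ids, truth$cnv_loci)
  } else {
    pool <- ids
  }
  if (length(pool) < config$n_causal) {
    stop("not enough eligible markers for the requested causal count",
         call. = FALSE)
  }
  take <- pool[seq(1L, length(pool), length.out = config$n_causal)]
  tibble::tibble(marker_id = take,
                 beta1 = rep_len(config$beta1, config$n_causal),
                 beta2 = rep_len(config$beta2, config$n_causal))
}

#' Simulate a complete study (roster, genotypes, phenotypes)
#'
#' Convenience wrapper chaining [build_roster()], [simulate_genotypes()]
#' and [simulate_phenocov()] with sub-seeds derived from `seed`.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return A list: `roster`, `genotypes`, `pheno`, `truth` (merged
#'   genotype + phenotype truth).
#' @export
simulate_study <- function(config = sim_config(), seed = 1L) {
  seed <- as.integer(seed)
  roster <- build_roster(config$family_size_histogram, seed = seed,
                         p_female = config$p_female,
                         center_levels = config$center_levels,
                         center_prob = config$center_prob)
  g <- simulate_genotypes(roster, config, seed = (seed + 1001L) %% .Machine$integer.max)
  p <- simulate_phenocov(roster, g$genotypes, config,
                         seed = (seed + 2002L) %% .Machine$integer.max,
                         truth = g$truth)
  truth <- p$truth
  truth$cnv_loci <- g$truth$cnv_loci
  truth$pop_freqs <- g$truth$pop_freqs
  list(roster = roster, genotypes = g$genotypes, pheno = p$pheno,
       truth = truth)
}
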