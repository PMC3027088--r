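---
title: "Two-stage joint SNP/CNV association scans in family data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage joint SNP/CNV association scans in family data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jointgwas)
```

## The model

`jointgwas` analyses quantitative traits in sibship cohorts genotyped with
CNV-aware calls. At each locus a sample's genotype is a pair of counts
`(a, b)`: how many copies of SNP allele A and allele B it carries on
however many genomic copies are present. The total `a + b` is the copy
number (2 for a normal diploid call, 1 or 0 under deletions, 3-4 under
duplications); the difference `a - b` is the allele contrast. Copy-number
variation and allelic variation at the same locus are therefore tested
*jointly* in one linear predictor:

    y = alpha + beta1 (a - b) + beta2 (a + b) + ...

`beta1` is the additive SNP-allele effect and `beta2` the additive
copy-number effect; the joint null hypothesis is `beta1 = beta2 = 0`,
tested with a Wald chi-square on 2 degrees of freedom. When either term is
invariant in the sample — the overwhelmingly common case is a fully
diploid locus, where `a + b` is constant at 2 — the model collapses to a
single 1-df test of the remaining term, and the bookkeeping of dropped
terms (`invariant`, `collinear`) is carried into every result row.

The full per-marker model for a trait such as aortic root diameter
(analysed on the natural-log scale, `trait > 0` is enforced at I/O) adds
fixed covariates and a family random intercept:

    ln(trait) = alpha + beta1 (a - b) + beta2 (a + b)
              + sum_j phi_j PC_j + phi_age Age + phi_age2 Age^2
              + phi_sex Sex + phi_center Center
              + gamma_family + epsilon

with `gamma_family ~ N(0, sigma2_family)` shared by all members of a
sibship and `epsilon ~ N(0, sigma2_resid)`. Sibships enter only as a
random intercept: the cohorts this targets recruited siblings without
genotyped parents, so richer pedigree structure is unidentifiable anyway.

## The two-stage (GRAMMAR) procedure

Refitting the mixed model at every one of ~10^6 markers is wasteful, so
the genome scan runs in two stages:

1. **GRAMMAR screen.** The covariate-only mixed model is fitted once
   (`fit_null_model()`), and each individual's *conditional residual* is
   formed: phenotype minus fitted fixed part minus the family's predicted
   random effect (BLUP). Each marker is then tested by ordinary least
   squares of these residuals on its retained genotype terms
   (`stage1_grammar_scan()`). This is fast and — by construction —
   conservative: subtracting the shrunken family means removes part of
   the genetic signal along with the relatedness, which visibly depresses
   the quantile-quantile plot of stage-1 p-values whenever
   `sigma2_family > 0`. The screen is used only for *ranking*.
2. **Full refit.** The `k` most promising markers (default 1,000; ties
   broken deterministically by genomic position then marker id) are
   refitted with the full mixed model, re-estimating the variance
   components per marker (`stage2_full_scan()`). Stage-2 p-values are the
   reported ones, and genome-wide significance uses the conventional
   fixed threshold `p < 5e-7`, strictly.

A faster stage-2 variant that freezes the null model's variance
components is available behind `stage2_full_scan()`'s interface by
design choice we did *not* default to: per-marker REML refitting is what
the reported p-values mean here.

## The REML engine

The only random effect is a family intercept, so the phenotypic
covariance is block diagonal with exchangeable blocks
`V_f = sigma2_resid I + sigma2_family J`. Each block inverts in closed
form, and all crossproducts are accumulated from per-family column sums,
giving O(n) likelihood evaluations (`reml_loglik()`). Fitting profiles
the variance ratio `theta = sigma2_family / sigma2_resid` — the residual
variance then has a closed-form optimum — on a log-spaced grid
(`0, 1e-4 ... 1e3`, 41 points) followed by golden-section refinement to a
`1e-8` tolerance; `sigma2_family` is clamped at the zero boundary rather
than allowed negative. This simple scheme is unimodal in practice,
trivially checkable against a dense-matrix oracle (the tests do exactly
that, to 1e-10 on the likelihood and 1e-4 on fitted components, and
cross-check against `lme4::lmer`), and fast enough that thousands of
per-marker refits cost well under a minute.

Numerical edge cases handled explicitly: all-singleton rosters make the
two variance components non-identifiable (only their sum matters) — the
profile is flat and the fitter deterministically returns the boundary,
which leaves every downstream p-value identical to ordinary least
squares; genotype terms with sample variance below `1e-12` are dropped as
invariant; collinearity between contrast and total (after projection on
the covariates) is detected at a `1e-8` relative singular-value tolerance
and recorded as `collinear` with the df reduced.

## Stratification adjustment

Population structure is controlled the standard way: principal components
of the standardized genotype dosage matrix enter the model as fixed
covariates. Markers used for the PCA are restricted to effectively
diploid loci (non-diploid call fraction at most 1%) because the
`sqrt(p(1-p))` dosage scaling assumes diploidy; missing dosages are
mean-imputed. Four components is the default, mirroring the
eigenvalue-inspection choice the analysis design fixed in advance;
`select_num_pcs()` also offers an automatic eigenvalue-gap rule. Signs
are fixed so each component's loading sum is non-negative, which makes
scores reproducible and invariant to marker order. We compute PCs on all
individuals including relatives; with many small sibships the leading
components still track ancestry (the tests require `|r| > 0.9` against
the simulator's true admixture proportions), but users with large
pedigrees should be aware of the known relatedness artifact in PCA.

## What the simulator emulates — and what it does not

`sim_config()` / `simulate_study()` generate studies with the structure
the pipeline assumes, so every stage is exercisable with no external
data. Defaults reproduce the cohort the package was designed around:

* **Roster**: the family-size histogram `{1:99, 2:160, 3:69, 4:48, 5:23,
  6:10, 7:8, 9:3, 10:1}` — 421 families, 1,086 individuals; 66.6%
  female; recruitment centers weighted 856:230.
* **Genotypes**: per family, two latent parental diplotypes are drawn
  from the family's ancestry-mixed allele frequencies and siblings
  inherit Mendelianly, giving the expected within-sibship genotype
  correlation of 1/2. Ancestral minor-allele frequencies are uniform on
  (0.16, 0.44), the range of the study's top markers. Two founder
  populations diverge under a Balding-Nichols model (Fst-like 0.1) and
  per-family admixture proportions are Beta-distributed — uniform
  Beta(1, 1) by default, the minimal choice that makes PC adjustment
  consequential. 5% of loci carry a rare deletion allele at frequency
  0.005 (a sub-1% CNV rate per locus, matching the rarity of copy-number
  events in the motivating study); a deleted haplotype contributes no
  copy, a duplicated one two copies of its allele.
* **Phenotype**: `ln(trait)` is built additively with intercept
  `ln(3.26)` (the cohort's mean aortic root diameter in cm) and total
  variance 0.0135 (`(0.38/3.26)^2`, the delta-method ln-scale variance of
  the cohort's `3.26 +/- 0.38 cm`), split `sigma2_family = 0.0054` /
  `sigma2_resid = 0.0081` so the family share is 0.4. Age is
  `N(43.9, 13.4^2)` truncated to [18, 85]. Covariate effects default to
  plausible magnitudes (`phi_age = 0.004` per year, `phi_age2 = -2e-5`,
  `phi_sex = -0.06` for females, `phi_center = 0.01`,
  `phi_ancestry = 0.15`); they exist so covariate adjustment has
  something to do, and all are configurable.
* **Confidence scores**: Beta(0.5, 30), leaving about 1.2% of calls above
  the strict `< 0.1` confidence filter, so the filter and the 0.95
  call-rate QC are both exercised without discarding the genome.

The simulator deliberately does **not** emulate: linkage disequilibrium
(markers are independent, so screen-stage order statistics are cleaner
than on a real genome); genotype-calling error structure beyond the
confidence score; multi-locus CNV segments (each CNV locus segregates
independently); non-normal phenotype residuals; parental genotypes
(parents are latent, matching sib-based ascertainment). Passing tests
therefore demonstrate the statistical machinery is correct under the
stated model, not that a real array dataset would be free of the QC and
LD complications those features create.

## Problem sizes and calibration checks

The test suite's scientific acceptance checks run at desk scale, chosen
to keep the whole suite within a coffee break while leaving Monte-Carlo
noise well inside the asserted windows: null calibration uses 600
individuals (200 sibships of 3) and 5,000 diploid markers — stage-2
rejection at the 5% level must fall inside the 99% binomial interval,
and the stage-1 inflation factor must sit below 1 with family variance
and inside [0.9, 1.1] without; two-stage consistency uses 5 causal
markers (`beta1 = 0.05`) among 5,000 with a k = 500 screen, requiring at
least 9 of the exhaustive top ten in the two-stage top ten; effect
recovery uses 100 replicates at n = 1,000; stratification control uses
600 singletons at divergence 0.1, requiring lambda in [0.9, 1.1] with 4
PCs and above 1.1 with none. `scripts/acceptance.R` re-runs the same
computations (some at 2,000 markers / 50 replicates) from scratch under
a caller-supplied seed.

## Known limitations

* The GRAMMAR screen's conservativeness means true associations near the
  selection boundary can be lost; the stage-2 refit cannot rescue a
  marker the screen never forwards. This is inherent to the two-stage
  design and is why the consistency property is checked rather than
  assumed.
* Conditional residuals are computed once from the null fit; per-marker
  missingness simply subsets that vector (complete-case within marker),
  faithful to the one-null-fit design rather than re-residualizing.
* The Wald chi-square is a large-sample test; at small n an F-flavoured
  variant would be preferable and the OLS screen exposes one path to it,
  but the package reports chi-square p-values as is conventional at
  GWAS scale.
* Only autosomes are in scope; no Mendelian-inconsistency QC is
  attempted because parents are ungenotyped in the targeted designs, and
  no multiple-testing layer beyond the fixed genome-wide threshold is
  provided.

## A worked example

```{r example, eval = FALSE}
library(jointgwas)

cfg <- sim_config(n_markers = 2000, n_causal = 1, beta1 = 0.08)
sim <- simulate_study(cfg, seed = 1)

run <- run_joint_gwas(sim$genotypes, sim$pheno, sim$roster, k = 200)
glance(run)          # marker counts, both lambdas, screen cutoff
head(tidy(run))      # per-marker results, stage-2 ordered
autoplot(run)        # Manhattan plot of the screen
autoplot(run, "qq")  # the conservative stage-1 QQ plot
```

The same pipeline is scriptable from a shell via the launcher in
`inst/scripts/jointgwas` (`simulate`, `qc`, `pca`, `stage1`, `stage2`,
`run`, `report` subcommands over the documented TSV dialects).
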