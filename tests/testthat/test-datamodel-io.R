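# Genotype/roster/phenotype containers, file dialects, and call filtering.

test_that("genotype cells parse to calls, sentinels and CNV counts", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "marker_id\tchrom\tpos\tallele_a\tallele_b\ts1\ts2\ts3",
    "rs1\t7\t65255030\tA\tB\t1,1,0.02\t.\t2,1,0.05"),
    path)
  gt <- read_genotype_table(path)
  expect_equal(dim(gt), c(1L, 3L))
  expect_equal(unname(gt$a[1, "s1"]), 1L)
  expect_equal(unname(gt$b[1, "s1"]), 1L)
  expect_equal(unname(gt$confidence[1, "s1"]), 0.02)
  expect_true(is.na(gt$a[1, "s2"]))           # "." sentinel
  expect_equal(unname(gt$a[1, "s3"]), 2L)     # duplication carrying two A
  expect_equal(unname(gt$b[1, "s3"]), 1L)
})

test_that("malformed genotype input raises format errors (or missing when permissive)", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "marker_id\tchrom\tpos\tallele_a\tallele_b\ts1",
    "rs1\t1\t100\tA\tB\t1,1",
    "rs2\t1\t200\tA\tB\t1,1,0.05"), path)
  expect_error(read_genotype_table(path), "malformed")
  gt <- read_genotype_table(path, permissive = TRUE)
  expect_true(is.na(gt$a[1, 1]))
  expect_equal(unname(gt$a[2, 1]), 1L)

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "marker_id\tchrom\tpos\tallele_a\tallele_b\ts1",
    "rs1\t1\t100\tA\tB\t1,1,0.05",
    "rs1\t1\t200\tA\tB\t1,1,0.05"), dup)
  expect_error(read_genotype_table(dup), "duplicate")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "marker_id\tchrom\tpos\tallele_a\tallele_b\ts1",
    "rs1\t1\t100\tA\tB\t-1,1,0.05"), neg)
  expect_error(read_genotype_table(neg), "negative")
})

test_that("genotype tables round-trip exactly and writes are byte-stable", {
  gt <- random_table(10L, 10L, seed = 42L)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(gt, p1)
  back <- read_genotype_table(p1)
  expect_identical(back$markers, gt$markers)
  expect_identical(back$samples, gt$samples)
  expect_identical(back$a, gt$a)
  expect_identical(back$b, gt$b)
  expect_equal(back$confidence, gt$confidence, tolerance = 0)
  write_genotype_table(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  empty <- gt[integer(0), ]
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_genotype_table(empty, p3)
  expect_length(readLines(p3), 1L)  # header only
})

test_that("roster and phenotype tables validate and round-trip", {
  roster <- as_roster(tibble::tibble(
    family_id = c("F1", "F1"), individual_id = c("I1", "I2"),
    sex = c(2L, 1L), center = "ctrA"))
  expect_equal(length(unique(roster$family_id)), 1L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_roster(roster, p)
  expect_equal(tibble::as_tibble(read_roster(p))[],
               tibble::as_tibble(roster)[])

  expect_error(as_roster(tibble::tibble(
    family_id = "F1", individual_id = c("I1", "I1"), sex = 1L,
    center = "c")), "duplicate")

  expect_error(as_phenocov(tibble::tibble(
    individual_id = "I1", trait = 0, age = 40, sex = 1L, center = "c")),
    "trait")

  ph <- as_phenocov(tibble::tibble(
    individual_id = c("I1", "I2"), trait = c(3.26, 2.9),
    age = c(44.5, 39.25), sex = c(1L, 2L), center = "c"))
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_phenocov(ph, pp)
  expect_equal(tibble::as_tibble(read_phenocov(pp))[],
               tibble::as_tibble(ph)[])
})

test_that("confidence filter is strict at the boundary, idempotent and monotone", {
  gt <- make_toy_table()
  f <- apply_confidence_filter(gt, 0.1)
  expect_equal(unname(f$a[1, 1]), 1L)       # conf 0.02 retained
  expect_true(is.na(f$a[2, 2]))             # conf 0.12 dropped
  expect_equal(unname(f$confidence[1, 4]), 0.09)  # 0.09 < 0.1 retained

  bd <- gt
  bd$confidence[1, 1] <- 0.1               # exactly at threshold
  fb <- apply_confidence_filter(bd, 0.1)
  expect_true(is.na(fb$a[1, 1]))           # boundary is exclusive

  # threshold 1 keeps everything already < 1
  expect_identical(apply_confidence_filter(gt, 1)$a, gt$a)
  # idempotent
  expect_identical(apply_confidence_filter(f, 0.1)$a, f$a)
  # monotone: a lower threshold never retains what a higher one dropped
  for (thr in c(0.02, 0.05, 0.08)) {
    lo <- apply_confidence_filter(gt, thr)
    expect_true(all(is.na(lo$a) | !is.na(f$a) | thr > 0.1))
    expect_true(all(which(is.na(f$a)) %in% which(is.na(lo$a))))
  }
})

test_that("joint design encodes contrast/total with the expected invariants", {
  gt <- make_toy_table()
  d1 <- encode_joint_design(gt, 1L)
  expect_equal(d1$contrast[1], 0)  # a=1,b=1 heterozygote
  expect_equal(d1$total[1], 2)
  d2 <- encode_joint_design(gt, "rs2")
  expect_equal(d2$contrast[2], 1)  # a=1,b=0 hemizygous deletion
  expect_equal(d2$total[2], 1)
  expect_equal(d2$contrast[1], 1)  # a=2,b=1 duplicated locus
  expect_equal(d2$total[1], 3)
  expect_false(d2$usable_mask[4])

  # |contrast| <= total over every usable call of a random table
  rt <- random_table(20L, 30L, seed = 3L)
  for (i in seq_len(20L)) {
    d <- encode_joint_design(rt, i, .allow_degenerate = TRUE)
    u <- d$usable_mask
    expect_true(all(abs(d$contrast[u]) <= d$total[u]))
  }

  # degenerate marker signals a classed error
  gt$a[3, ] <- NA_integer_; gt$b[3, ] <- NA_integer_
  gt$confidence[3, ] <- NA_real_
  expect_error(encode_joint_design(gt, 3L),
               class = "jointgwas_degenerate_design")
})

test_that("marker frequencies match hand counts", {
  gt <- make_toy_table()
  d <- encode_joint_design(gt, 1L)
  # rs1: a-counts 1,2,0,1 over 4 diploid samples -> 4 A of 8 copies
  f <- marker_frequencies(d)
  expect_equal(f$maf, 0.5)
  expect_equal(f$cnv_rate, 0)

  # 10 samples, a-counts {2,2,1,1,1,1,1,1,0,0}, all diploid -> maf 0.5
  a <- matrix(c(2L,2L,1L,1L,1L,1L,1L,1L,0L,0L), 1)
  b <- 2L - a
  g10 <- genotype_table(
    tibble::tibble(marker_id = "m", chrom = "1", pos = 1L,
                   allele_a = "A", allele_b = "B"),
    paste0("s", 1:10), a, b, matrix(0.01, 1, 10))
  expect_equal(marker_frequencies(encode_joint_design(g10, 1L))$maf, 0.5)

  # 99 diploid + 1 single-copy sample -> cnv_rate 0.01
  a <- matrix(1L, 1, 100); b <- matrix(1L, 1, 100)
  b[1, 100] <- 0L
  g100 <- genotype_table(
    tibble::tibble(marker_id = "m", chrom = "1", pos = 1L,
                   allele_a = "A", allele_b = "B"),
    sprintf("s%03d", 1:100), a, b, matrix(0.01, 1, 100))
  expect_equal(marker_frequencies(encode_joint_design(g100, 1L))$cnv_rate,
               0.01)

  # fully diploid markers: maf equals the standard biallelic frequency and
  # contrast lives on {-2, 0, 2} with total == 2
  rt <- random_table(15L, 40L, seed = 9L, missing_rate = 0)
  for (i in seq_len(15L)) {
    d <- encode_joint_design(rt, i)
    if (all(d$total == 2)) {
      expect_true(all(d$contrast %in% c(-2, 0, 2)))
      dos <- (2 - d$contrast) / 2   # B dosage in {0, 1, 2}
      p <- sum(dos) / (2 * length(dos))
      expect_equal(marker_frequencies(d)$maf, min(p, 1 - p))
    }
  }
})

test_that("marker QC removes low call-rate and monomorphic markers only", {
  gt <- random_table(100L, 40L, seed = 5L, missing_rate = 0)
  # thresholds 0 -> identity
  expect_identical(qc_filter(gt, 0, 0)$markers, gt$markers)

  # marker with 50% missing fails a 0.95 call-rate floor
  gt$a[1, 1:20] <- NA_integer_; gt$b[1, 1:20] <- NA_integer_
  gt$confidence[1, 1:20] <- NA_real_
  # monomorphic marker fails MAF
  gt$a[2, ] <- 2L; gt$b[2, ] <- 0L
  out <- qc_filter(gt, min_call_rate = 0.95, min_maf = 0.01)
  expect_false("m001" %in% out$markers$marker_id)
  expect_false("m002" %in% out$markers$marker_id)
  log <- attr(out, "qc_log")
  expect_equal(log$removed[log$criterion == "call_rate"], 1L)
  expect_true(log$removed[log$criterion == "maf"] >= 1L)
})
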