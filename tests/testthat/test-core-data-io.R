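test_that("genotype strings map to dosage, heterozygote order-insensitive", {
  loci <- tp53_axis_loci()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "subject_id\tstatus\tsex\tage_ge60\tTP53_rs1042522\tMDM2_rs2279744",
    "S1\t1\tM\t1\tArg/Pro\tTG",
    "S2\t0\tF\t0\tPro/Arg\tGT",
    "S3\tcase\t1\t0\tPro/Pro\tT/T",
    "S4\tcontrol\t0\t1\tArg/Arg\tGG"), tmp)
  ch <- read_cohort(tmp, loci)
  expect_identical(ch$data$status, c(1L, 0L, 1L, 0L))
  expect_identical(ch$data$sex, c(1L, 0L, 1L, 0L))
  expect_identical(ch$data$TP53_rs1042522, c(1L, 1L, 2L, 0L))
  expect_identical(ch$data$MDM2_rs2279744, c(1L, 1L, 0L, 2L))
})

test_that("unparseable genotypes become missing with a warning; bad columns are hard errors", {
  loci <- tp53_axis_loci()
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,status,sex,age_ge60,TP53_rs1042522",
               "S1,1,0,1,Arg/Xyz", "S2,0,1,0,Arg/Arg"), tmp)
  expect_warning(ch <- read_cohort(tmp, loci), "1 genotype")
  expect_identical(ch$data$TP53_rs1042522, c(NA_integer_, 0L))

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tstatus\tsex\tTP53_rs1042522", "S1\t1\t0\tArg/Arg"), tmp2)
  expect_error(read_cohort(tmp2, loci), "age_ge60")
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject_id\tstatus\tsex\tage_ge60\tUNKNOWN_locus",
               "S1\t1\t0\t1\tA/A"), tmp3)
  expect_error(read_cohort(tmp3, loci), "UNKNOWN_locus")
})

test_that("write -> read -> write round-trips byte-identically on a generated cohort", {
  ch <- simulate_cohort(sim_preset("table1_controls", seed = 42))
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(ch, f1)
  ch2 <- read_cohort(f1, ch$loci)
  write_cohort(ch2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(ch2$data$TP53_rs1042522, ch$data$TP53_rs1042522)
})

test_that("locus config round-trips through YAML", {
  loci <- tp53_axis_loci()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_locus_config(loci, tmp)
  loci2 <- read_locus_config(tmp)
  expect_equal(lapply(loci2, unclass), lapply(loci, unclass))
})

test_that("genotype_counts matches Table-1-style tabulation and an independent recount", {
  ch <- cohort_from_counts(table1_counts())
  gc <- genotype_counts(ch, "TP53_rs1042522")
  expect_equal(unname(gc$counts["control", ]), c(217, 152, 37))
  expect_equal(unname(round(gc$percent["control", ], 1)), c(53.4, 37.4, 9.1))
  # brute-force recount oracle on a simulated cohort
  sim <- simulate_cohort(sim_preset("table1_controls", seed = 9,
                                    n_cases = 150, n_controls = 170))
  for (id in names(sim$loci)) {
    gc2 <- genotype_counts(sim, id)
    manual <- sapply(0:2, function(dd)
      sapply(0:1, function(ss)
        sum(sim$data$status == ss & sim$data[[id]] == dd, na.rm = TRUE)))
    expect_equal(unname(gc2$counts), unname(manual))
    expect_equal(rowSums(gc2$counts) + gc2$missing,
                 c(control = n_controls(sim), case = n_cases(sim)))
  }
})

test_that("tabulation of an empty cohort is all zero", {
  loci <- tp53_axis_loci()[1]
  d <- data.frame(subject_id = character(0), status = integer(0),
                  sex = integer(0), age_ge60 = integer(0),
                  TP53_rs1042522 = integer(0), check.names = FALSE)
  ch <- cohort(d, loci)
  expect_true(all(genotype_counts(ch, "TP53_rs1042522")$counts == 0))
})

test_that("demographics reproduce the reported ratio and sex association", {
  ch <- cohort_from_counts(table1_counts())
  # overwrite sex with the reported margins: cases 215 M / 188 F, controls 181 M / 225 F
  d <- ch$data
  d$sex[d$status == 1L] <- rep(c(1L, 0L), c(215, 188))
  d$sex[d$status == 0L] <- rep(c(1L, 0L), c(181, 225))
  ch <- cohort(d, ch$loci)
  dm <- summarize_demographics(ch)
  expect_equal(round(dm$mf_ratio_cases, 2), 1.14)
  expect_equal(round(dm$sex_p, 3), 0.013)
  # equal sex counts in both groups: ratio 1, p = 1
  d$sex <- rep_len(0:1, nrow(d))
  d <- d[order(d$status, d$sex), ]
  dm2 <- summarize_demographics(cohort(d, ch$loci))
  expect_equal(dm2$mf_ratio_cases, 1, tolerance = 0.02)
  # cross-module consistency: same chi-square as contingency_test
  ct <- contingency_test(dm$sex_counts, test = "pearson")
  expect_equal(dm$sex_chisq, ct$statistic, tolerance = 1e-12)
  expect_equal(dm$sex_p, ct$p, tolerance = 1e-12)
})

test_that("dosage coding is involution-safe across all loci", {
  for (locus in tp53_axis_loci()) {
    enc <- tp53axis:::.format_genotypes(0:2, locus)
    dec <- tp53axis:::.parse_genotypes(enc, locus)
    expect_identical(dec, 0:2)
    # heterozygote symmetry
    flip <- paste(locus$allele_var, locus$allele_wt, sep = "/")
    expect_identical(tp53axis:::.parse_genotypes(flip, locus), 1L)
  }
})
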