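test_that("cells partition the complete-genotype subjects", {
  ch <- simulate_cohort(sim_preset("paper_replica", seed = 14))
  # two loci: all 9 combinations at this sample size
  ce2 <- enumerate_cells(ch, c("MDM2_rs2279744", "TP53_rs1042522"))
  expect_equal(sum(ce2$cells$n_case + ce2$cells$n_control), nrow(ch$data))
  expect_lte(nrow(ce2$cells), 9)
  # four loci: <= 81 cells, still a partition
  ce4 <- enumerate_cells(ch, names(ch$loci))
  expect_lte(nrow(ce4$cells), 81)
  expect_equal(sum(ce4$cells$n_case + ce4$cells$n_control), nrow(ch$data))
  # recount oracle: group-by on pasted genotype labels
  d <- ch$data
  key <- paste(d$MDM2_rs2279744, d$TP53_rs1042522)
  expect_equal(sort(as.integer(table(key))),
               sort(ce2$cells$n_case + ce2$cells$n_control))
  expect_error(enumerate_cells(ch, c("TP53_rs1042522", "TP53_rs1042522")),
               "duplicate")
})

test_that("step-1 closed form equals the per-cell glm and the H/L/O rule is verbatim", {
  ch <- simulate_cohort(sim_preset("paper_replica", seed = 15,
                                   n_cases = 300, n_controls = 300))
  ce <- categorize_cells(enumerate_cells(ch, c("MDM2_rs2279744", "TP53_rs1042522")))
  cc <- ce$cells
  for (k in which(!cc$flagged)) {
    ind <- as.numeric(ce$membership == k)
    g <- glm(ce$y ~ ind, family = binomial(),
             control = glm.control(epsilon = 1e-12))
    expect_lt(abs(cc$beta[k] - unname(coef(g)["ind"])), 1e-6)
    expect_lt(abs(cc$p_step1[k] -
                    summary(g)$coefficients["ind", "Pr(>|z|)"]), 1e-6)
  }
  # category is a pure function of (sign, p, threshold)
  ok <- !cc$flagged
  expect_identical(cc$category[ok],
                   ifelse(cc$p_step1[ok] >= 0.10, "O",
                          ifelse(cc$beta[ok] > 0, "H", "L")))
  expect_true(all(cc$category[cc$flagged] == "O"))
})

test_that("threshold boundary and degenerate cells are forced to no-evidence", {
  # a cell with p ~ 0.2 stays O whatever the sign of beta
  loci <- tp53_axis_loci()[c("TP53_rs1042522", "MDM2_rs2279744")]
  d <- data.frame(subject_id = sprintf("S%03d", 1:200),
                  status = rep(0:1, each = 100), sex = 0L, age_ge60 = 0L,
                  TP53_rs1042522 = c(rep(0L, 80), rep(2L, 20),
                                     rep(0L, 73), rep(2L, 27)),
                  MDM2_rs2279744 = 0L, check.names = FALSE)
  ch <- cohort(d, loci)
  ce <- categorize_cells(enumerate_cells(ch, names(loci)))
  hom <- ce$cells$TP53_rs1042522 == 2L
  expect_gt(ce$cells$p_step1[hom], 0.10)
  expect_identical(ce$cells$category[hom], "O")
  # all-case cell (degenerate 2x2) is flagged O
  d2 <- d
  d2$TP53_rs1042522[d2$status == 0L] <- 0L  # no controls with hom-variant
  ce2 <- categorize_cells(enumerate_cells(cohort(d2, loci), names(loci)))
  hom2 <- ce2$cells$TP53_rs1042522 == 2L
  expect_identical(ce2$cells$category[hom2], "O")
  expect_true(all(ce2$cells$flagged[hom2]))
})

test_that("a planted high-risk cell is recovered", {
  hits <- 0L; n_rep <- 20L
  for (s in seq_len(n_rep)) {
    cfg <- sim_preset("null", seed = 900 + s, n_cases = 400, n_controls = 400)
    # cell-specific OR 3 on the common double-heterozygote cell
    cfg$betas <- c("MDM2_rs2279744.overdominant:TP53_rs1042522.overdominant" = log(3))
    ch <- simulate_cohort(cfg)
    ce <- categorize_cells(enumerate_cells(ch, c("MDM2_rs2279744", "TP53_rs1042522")))
    cc <- ce$cells
    planted <- cc$MDM2_rs2279744 == 1L & cc$TP53_rs1042522 == 1L
    if (any(planted) && cc$category[planted] == "H") hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep) - 2L)
})

test_that("step-2 Wald mapping matches the published chi-square(1) convention", {
  W <- c(3.09, 2.97, 2.80, 10.70, 3.49, 7.15, 2.85, 2.75, 8.39, 16.79)
  p_printed <- c(0.078, 0.085, 0.094, 0.001, 0.062, 0.008, 0.092, 0.097,
                 0.004, 0.00004)
  p_comp <- pchisq(W, 1, lower.tail = FALSE)
  # printed W values are themselves rounded: agree within one print ulp
  expect_true(all(abs(p_comp - p_printed) < 1e-3))
})

test_that("step-2 fits adjust for main effects and covariates; empty categories give NA", {
  ch <- simulate_cohort(sim_preset("paper_replica", seed = 16))
  combo <- c("MDM2_rs2279744", "TP53_rs1042522")
  ce <- categorize_cells(enumerate_cells(ch, combo))
  res <- step2_test(ce)
  expect_s3_class(res, "mbmdr_result")
  if (res$N_H > 0) {
    # oracle: direct glm with the same design
    cc <- ce$cells
    Hind <- as.numeric(cc$category[ce$membership] == "H")
    d <- data.frame(y = ce$y, H = Hind, ce$dosages, ce$covars)
    g <- glm(y ~ ., data = d, family = binomial(),
             control = glm.control(epsilon = 1e-12))
    expect_equal(res$beta_H, unname(coef(g)["H"]), tolerance = 1e-6)
    W_oracle <- unname((coef(g)["H"] / summary(g)$coefficients["H", "Std. Error"])^2)
    expect_equal(res$W_H, W_oracle, tolerance = 1e-5)
    expect_equal(res$p_H, pchisq(res$W_H, 1, lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_equal(res$min_p, min(c(res$p_H, res$p_L), na.rm = TRUE))
  # force an all-O categorization: no H and no L -> NA statistics
  ce0 <- categorize_cells(enumerate_cells(ch, combo), threshold = 1e-12)
  res0 <- step2_test(ce0)
  expect_true(is.na(res0$beta_H) && is.na(res0$W_H) && is.na(res0$p_H))
  expect_equal(res0$N_H, 0)
})

test_that("permutation p has the +1 convention, determinism, and flags the all-NA case", {
  ch <- simulate_cohort(sim_preset("paper_replica", seed = 17))
  combo <- c("MDM2_rs2279744", "TP53_rs1042522")
  r1 <- permutation_correct(ch, combo, n_perm = 99, seed = 5)
  r2 <- permutation_correct(ch, combo, n_perm = 99, seed = 5)
  expect_identical(r1$perm_p, r2$perm_p)
  expect_gte(r1$perm_p, 1 / 100)
  expect_lte(r1$perm_p, 1)
  # no H and no L anywhere: perm_p = 1 with flag
  r0 <- permutation_correct(ch, combo, n_perm = 9, seed = 5, threshold = 1e-12)
  expect_equal(r0$perm_p, 1)
  expect_true(r0$flagged)
})

test_that("scan covers 6 + 4 + 1 combinations and rows are reproducible", {
  ch <- simulate_cohort(sim_preset("paper_replica", seed = 18,
                                   n_cases = 200, n_controls = 200))
  res <- scan_combinations(ch, orders = 2:4, n_perm = 20, seed = 99)
  tb <- mbmdr_table(res)
  expect_equal(nrow(tb), 11)
  expect_equal(as.integer(table(tb$order)), c(6L, 4L, 1L))
  # a single row rerun with its own child seed reproduces perm_p exactly
  i <- 3L
  again <- permutation_correct(ch, res[[i]]$combo, n_perm = 20,
                               seed = res[[i]]$seed)
  expect_identical(again$perm_p, res[[i]]$perm_p)
})
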