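test_that("crude odds ratios and Wald intervals match the published genotype table", {
  # TP53 recessive
  r <- crude_or_from_counts(68, 335, 37, 369)
  expect_equal(round(r$or, 2), 2.02)
  expect_equal(round(r$ci, 2), c(1.32, 3.10))
  # MDM4 codominant AC vs CC
  r2 <- crude_or_from_counts(144, 57, 114, 83)
  expect_equal(round(r2$or, 2), 1.84)
  expect_equal(round(r2$ci, 2), c(1.21, 2.79))
  # symmetric table
  expect_equal(crude_or_from_counts(10, 10, 10, 10)$or, 1)
  # zero cell: Haldane-Anscombe correction flagged
  r3 <- crude_or_from_counts(5, 0, 3, 7)
  expect_true(r3$corrected)
  expect_true(is.finite(r3$or))
})

test_that("single-column GLM fits equal the 2x2 closed form exactly", {
  ch <- cohort_from_counts(table1_counts())
  checks <- list(
    list(locus = "TP53_rs1042522", coding = "recessive",
         cells = c(68, 335, 37, 369)),
    list(locus = "TP53_rs1042522", coding = "overdominant",
         cells = c(110, 293, 152, 254)),
    list(locus = "MDM4_rs4245739", coding = "dominant",
         cells = c(346, 57, 323, 83)),
    list(locus = "MDM2_rs2279744", coding = "dominant",
         cells = c(268, 135, 265, 141)),
    list(locus = "MDM2_rs3730485", coding = "recessive",
         cells = c(50, 353, 58, 348)))
  for (cs in checks) {
    fit <- fit_locus(ch, cs$locus, cs$coding)
    ref <- do.call(crude_or_from_counts, as.list(cs$cells))
    expect_equal(fit$levels$beta, ref$log_or, tolerance = 1e-6,
                 label = paste(cs$locus, cs$coding, "beta"))
    expect_equal(fit$levels$se, ref$se, tolerance = 1e-6)
    expect_equal(fit$levels$or, ref$or, tolerance = 1e-6)
  }
})

test_that("codominant per-level ORs equal the cross-product ratios vs reference", {
  ch <- cohort_from_counts(table1_counts())
  fit <- fit_locus(ch, "TP53_rs1042522", "codominant")
  het <- crude_or_from_counts(110, 225, 152, 217)
  hom <- crude_or_from_counts(68, 225, 37, 217)
  expect_equal(fit$levels$or, c(het$or, hom$or), tolerance = 1e-6)
  expect_equal(round(fit$levels$or[2], 2), 1.77)
  expect_equal(round(fit$levels$ci_lo[2], 2), 1.14)
  expect_equal(round(fit$levels$ci_hi[2], 2), 2.76)
  expect_equal(fit$df, 2L)
})

test_that("model LRT p-values reproduce the published crude column", {
  ch <- cohort_from_counts(table1_counts())
  p <- vapply(c("codominant", "dominant", "recessive", "overdominant"),
              function(cd) fit_locus(ch, "TP53_rs1042522", cd)$p, 0)
  expect_true(all(abs(unname(p) - c(0.0003, 0.4960, 0.0009, 0.0020)) <= 2e-4))
})

test_that("an exactly proportional cohort gives OR 1 and LRT p 1", {
  loci <- tp53_axis_loci()[1]
  d <- data.frame(subject_id = sprintf("S%03d", 1:120),
                  status = rep(0:1, each = 60), sex = 0L, age_ge60 = 0L,
                  TP53_rs1042522 = rep(rep(0:2, c(30, 20, 10)), 2),
                  check.names = FALSE)
  ch <- cohort(d, loci)
  for (cd in c("dominant", "recessive", "overdominant")) {
    fit <- fit_locus(ch, "TP53_rs1042522", cd)
    expect_equal(fit$levels$or, 1, tolerance = 1e-8)
    expect_equal(fit$p, 1, tolerance = 1e-8)
  }
})

test_that("logistic coefficients agree with an independent Newton refit", {
  # oracle: plain Newton-Raphson on the log-likelihood from a different start
  newton_logistic <- function(X, y, iter = 200) {
    X <- cbind(1, X)
    ll <- function(b) sum(y * drop(X %*% b) - log(1 + exp(drop(X %*% b))))
    b <- rep(0.3, ncol(X))  # deliberately not the IRLS start
    for (i in seq_len(iter)) {
      p <- 1 / (1 + exp(-drop(X %*% b)))
      g <- crossprod(X, y - p)
      H <- crossprod(X * pmax(p * (1 - p), 1e-10))
      step <- drop(solve(H, g))
      # damped Newton: halve until the log-likelihood does not decrease
      lam <- 1
      while (ll(b + lam * step) < ll(b) && lam > 1e-8) lam <- lam / 2
      b <- b + lam * step
      if (max(abs(lam * step)) < 1e-12) break
    }
    drop(b)
  }
  for (s in 1:10) {
    cfg <- sim_preset("paper_replica", seed = 400 + s,
                      n_cases = 150, n_controls = 150)
    ch <- simulate_cohort(cfg)
    fit <- fit_locus(ch, "TP53_rs1042522", "dominant", adjust = TRUE)
    X <- cbind(as.numeric(ch$data$TP53_rs1042522 >= 1),
               ch$data$age_ge60, ch$data$sex)
    oracle <- newton_logistic(X, ch$data$status)
    expect_equal(fit$levels$beta, oracle[2], tolerance = 1e-6)
  }
})

test_that("BH adjustment reproduces the published FDR column and its algebra", {
  adj <- bh_adjust(c(0.0003, 0.0009, 0.0020, 0.4960))
  expect_true(all(abs(adj - c(0.0012, 0.0019, 0.0027, 0.4960)) <= 2e-4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.05, 4)), rep(0.05, 4))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  # property: adjusted >= raw, monotone in sorted order
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:8, 1))
    a <- bh_adjust(p)
    expect_true(all(a >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(a[o]) >= -1e-12))
  }
})

test_that("association_table families and columns are coherent", {
  ch <- simulate_cohort(sim_preset("paper_replica", seed = 21,
                                   n_cases = 250, n_controls = 250))
  at <- association_table(ch)
  expect_true(all(at$p_fdr_crude >= at$p_crude - 1e-12, na.rm = TRUE))
  expect_true(all(at$p_fdr_adj >= at$p_adj - 1e-12, na.rm = TRUE))
  # per locus: 4 codings, codominant contributes 3 rows, others 2
  expect_equal(nrow(at), 4 * (3 + 2 + 2 + 2))
  # CI brackets OR
  nonref <- !is.na(at$or_crude)
  expect_true(all(at$ci_lo_crude[nonref] <= at$or_crude[nonref] &
                    at$or_crude[nonref] <= at$ci_hi_crude[nonref]))
})

test_that("interaction model arithmetic and planted-beta recovery", {
  expect_equal(round(stratum_or(0.51, 1.22), 2), 5.64)
  expect_equal(round(exp(-0.92), 2), 0.40)
  # planted interaction is recovered inside its CI most of the time
  hits <- 0L; n_rep <- 20L
  for (s in seq_len(n_rep)) {
    ch <- simulate_cohort(sim_preset("paper_replica", seed = 600 + s))
    it <- fit_interaction_model(ch)
    row <- it$coefficients[it$coefficients$term ==
                             "MDM2_rs2279744:TP53_rs1042522", ]
    lo <- row$beta - 1.959964 * row$se; hi <- row$beta + 1.959964 * row$se
    if (lo <= 1.22 && 1.22 <= hi) hits <- hits + 1L
  }
  expect_gte(hits, 15L)
  # derived stratum OR equals exp(beta_main + beta_int) of the same fit
  ch <- simulate_cohort(sim_preset("paper_replica", seed = 699))
  it <- fit_interaction_model(ch)
  b <- it$coefficients
  expect_equal(it$strata$or_within_risk[1],
               exp(b$beta[b$term == "TP53_rs1042522"] +
                     b$beta[b$term == "MDM2_rs2279744:TP53_rs1042522"]),
               tolerance = 1e-12)
  expect_equal(it$coefficients$or, exp(it$coefficients$beta), tolerance = 1e-12)
})
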