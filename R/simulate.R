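#' Simulation configuration for synthetic case-control cohorts
#'
#' The generator draws, per candidate subject: a pair of two-locus MDM2
#' haplotypes (rs2279744 x rs3730485) from `hap_freqs_mdm2`, genotypes for
#' TP53 and MDM4 from their variant-allele frequencies with an inbreeding
#' coefficient governing departure from Hardy-Weinberg proportions
#' (P(hom var) = f p + (1-f) p^2, P(het) = (1-f) 2 p (1-p)), Bernoulli
#' covariates, and disease status from a logistic model
#' `expit(beta0 + sum(betas * design))`. Candidates are accepted until
#' exactly `n_cases` cases and `n_controls` controls are collected.
#'
#' For the MDM2 pair the inbreeding coefficients act at the locus level:
#' with probability `f` the second gamete's allele at that locus is copied
#' from the first, which reproduces the single-locus F-model marginals while
#' retaining the haplotype-frequency linkage disequilibrium.
#'
#' @param n_cases,n_controls Target group sizes.
#' @param hap_freqs_mdm2 Length-4 frequencies of the rs2279744 x rs3730485
#'   haplotypes in the order T-I, T-D, G-I, G-D (wildtype alleles T and I);
#'   must sum to 1.
#' @param maf_tp53,maf_mdm4 Variant-allele (Pro, A) frequencies.
#' @param inbreeding_f Named per-locus inbreeding coefficients in `[0, 1)`;
#'   unnamed loci default to 0.
#' @param p_age_ge60,p_male Covariate Bernoulli probabilities.
#' @param beta0 Baseline log-odds of disease.
#' @param betas Named numeric vector of log-odds terms. Names are `":"`-
#'   separated products of factors, each factor either a covariate
#'   (`"age_ge60"`, `"male"`) or `"<locus_id>.<coding>"` with coding one of
#'   `dominant`, `recessive`, `overdominant`, `additive`, e.g.
#'   `"MDM2_rs2279744.recessive:TP53_rs1042522.recessive"`.
#' @param seed Default RNG seed used by [simulate_cohort].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 403, n_controls = 406,
                       hap_freqs_mdm2 = c(0.25, 0.25, 0.25, 0.25),
                       maf_tp53 = 0.28, maf_mdm4 = 0.66,
                       inbreeding_f = c(TP53_rs1042522 = 0, MDM2_rs2279744 = 0,
                                        MDM2_rs3730485 = 0, MDM4_rs4245739 = 0),
                       p_age_ge60 = 0.52, p_male = 0.49,
                       beta0 = -1, betas = numeric(0), seed = 1L) {
  stopifnot(n_cases > 0, n_controls > 0)
  hap_freqs_mdm2 <- as.numeric(hap_freqs_mdm2)
  if (length(hap_freqs_mdm2) != 4L || any(hap_freqs_mdm2 < 0) ||
      abs(sum(hap_freqs_mdm2) - 1) > 1e-8)
    .stopf("hap_freqs_mdm2 must be 4 nonnegative frequencies summing to 1")
  names(hap_freqs_mdm2) <- c("T-I", "T-D", "G-I", "G-D")
  for (p in c(maf_tp53, maf_mdm4, p_age_ge60, p_male))
    if (p < 0 || p > 1) .stopf("frequencies must lie in [0, 1]")
  f <- c(TP53_rs1042522 = 0, MDM2_rs2279744 = 0,
         MDM2_rs3730485 = 0, MDM4_rs4245739 = 0)
  f[names(inbreeding_f)] <- inbreeding_f
  if (any(f < 0 | f >= 1)) .stopf("inbreeding_f must lie in [0, 1)")
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 hap_freqs_mdm2 = hap_freqs_mdm2, maf_tp53 = maf_tp53,
                 maf_mdm4 = maf_mdm4, inbreeding_f = f,
                 p_age_ge60 = p_age_ge60, p_male = p_male,
                 beta0 = beta0, betas = unlist(betas), seed = as.integer(seed)),
            class = "sim_config")
}

# Table-1 control genotype counts: the empirical basis for the shipped presets.
.control_counts <- function() {
  list(TP53_rs1042522 = c(217, 152, 37),
       MDM2_rs2279744 = c(141, 197, 68),
       MDM2_rs3730485 = c(179, 169, 58),
       MDM4_rs4245739 = c(83, 114, 209))
}

# variant-allele frequency and inbreeding coefficient implied by a genotype
# count triple (n_wtwt, n_het, n_varvar); f clamped into [0, 1)
.freq_f_from_counts <- function(cnt) {
  n <- sum(cnt)
  p <- (cnt[2] + 2 * cnt[3]) / (2 * n)
  h_exp <- 2 * p * (1 - p)
  f <- if (h_exp > 0) 1 - (cnt[2] / n) / h_exp else 0
  c(p = unname(p), f = max(0, min(unname(f), 1 - 1e-9)))
}

# haplotype frequencies (T-I, T-D, G-I, G-D) achieving |D'| = dprime at the
# given variant-allele frequencies, variant alleles positively associated
.hap_freqs_for_dprime <- function(p_g, p_d, dprime) {
  dmax <- min(p_g * (1 - p_d), (1 - p_g) * p_d)
  D <- dprime * dmax
  c((1 - p_g) * (1 - p_d) + D, (1 - p_g) * p_d - D,
    p_g * (1 - p_d) - D, p_g * p_d + D)
}

#' Shipped simulation presets
#'
#' * `"table1_controls"`: allele frequencies and per-locus inbreeding
#'   coefficients derived from the control genotype counts of the study's
#'   association table; MDM2 haplotype frequencies tuned so the expected
#'   |D'| is 0.89 (the reported control-group value); no genetic or
#'   covariate effects (`betas = 0`), so cases and controls are exchangeable.
#' * `"null"`: same genotype structure, Hardy-Weinberg proportions
#'   everywhere (all f = 0), no effects; for type-I calibration.
#' * `"paper_replica"` (alias `"interaction_gg_propro"`): `table1_controls`
#'   genotype structure plus the recessive-coded main-effect and interaction
#'   log-odds of the study's joint logistic model (-0.41, 0.51, 0.10, 0.26;
#'   GG x Pro/Pro +1.22, AA x DD -0.92) and covariate effects implied by the
#'   reported demographic margins (male +0.35, age >= 60 -0.23).
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [sim_config] (e.g. `n_cases`, `seed`).
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("table1_controls", "null", "paper_replica",
                                "interaction_gg_propro"), ...) {
  name <- match.arg(name)
  cc <- .control_counts()
  pf <- lapply(cc, .freq_f_from_counts)
  hap <- .hap_freqs_for_dprime(pf$MDM2_rs2279744["p"], pf$MDM2_rs3730485["p"], 0.89)
  base <- list(hap_freqs_mdm2 = hap / sum(hap),
               maf_tp53 = pf$TP53_rs1042522["p"],
               maf_mdm4 = pf$MDM4_rs4245739["p"],
               inbreeding_f = vapply(pf, `[[`, 0, "f"),
               p_age_ge60 = 0.52, p_male = 0.49)
  if (name == "null")
    base$inbreeding_f[] <- 0
  if (name %in% c("paper_replica", "interaction_gg_propro"))
    base$betas <- c(
      "MDM2_rs2279744.recessive" = -0.41,
      "TP53_rs1042522.recessive" = 0.51,
      "MDM4_rs4245739.recessive" = 0.10,
      "MDM2_rs3730485.recessive" = 0.26,
      "MDM2_rs2279744.recessive:TP53_rs1042522.recessive" = 1.22,
      "MDM4_rs4245739.recessive:MDM2_rs3730485.recessive" = -0.92,
      "male" = 0.35, "age_ge60" = -0.23)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# evaluate one design term (":"-separated product) on dosage/covariate columns
.term_value <- function(term, dos, covars) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  val <- rep(1, nrow(dos))
  for (p in parts) {
    if (p %in% colnames(covars)) { val <- val * covars[, p]; next }
    m <- regmatches(p, regexec("^(.*)\\.(dominant|recessive|overdominant|additive)$", p))[[1]]
    if (length(m) != 3L || !m[2] %in% colnames(dos))
      .stopf("unknown design term: %s", p)
    d <- dos[, m[2]]
    val <- val * switch(m[3], dominant = as.numeric(d >= 1),
                        recessive = as.numeric(d == 2),
                        overdominant = as.numeric(d == 1), additive = d)
  }
  val
}

#' Simulate a case-control cohort
#'
#' Rejection-samples candidate subjects from the population model until the
#' case and control quotas are both filled (deterministic under `seed`).
#'
#' @param config A [sim_config] (often from [sim_preset]).
#' @param seed RNG seed; defaults to `config$seed`.
#' @param loci Locus panel (defaults to [tp53_axis_loci]).
#' @param max_batches Attempt cap: each batch draws `max(4096, 4 * n)`
#'   candidates; exceeding the cap (quota unreachable, e.g. a baseline
#'   log-odds so extreme one group almost never occurs) is an error.
#' @return A [cohort].
#' @export
simulate_cohort <- function(config, seed = config$seed,
                            loci = tp53_axis_loci(), max_batches = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    need_ca <- config$n_cases; need_co <- config$n_controls
    keep <- vector("list", 0L); batches <- 0L
    B <- max(4096L, 4L * (need_ca + need_co))
    while ((need_ca > 0L || need_co > 0L) && batches < max_batches) {
      batches <- batches + 1L
      cand <- .draw_candidates(config, B)
      if (need_ca > 0L) {
        i <- which(cand$status == 1L)[seq_len(min(need_ca, sum(cand$status == 1L)))]
        need_ca <- need_ca - length(i)
      } else i <- integer(0)
      if (need_co > 0L) {
        j <- which(cand$status == 0L)[seq_len(min(need_co, sum(cand$status == 0L)))]
        need_co <- need_co - length(j)
      } else j <- integer(0)
      if (length(i) || length(j)) keep[[length(keep) + 1L]] <- cand[sort(c(i, j)), ]
    }
    if (need_ca > 0L || need_co > 0L)
      .stopf("case/control quota unreachable after %d batches; check beta0/betas",
             batches)
    d <- do.call(rbind, keep)
    d$subject_id <- sprintf("S%05d", seq_len(nrow(d)))
    d <- d[c("subject_id", "status", "sex", "age_ge60", names(loci))]
    cohort(d, loci)
  })
}

.draw_candidates <- function(config, B) {
  hap <- config$hap_freqs_mdm2
  # haplotype index 1..4 -> variant-allele indicators (rs2279744, rs3730485)
  a_of <- c(0L, 0L, 1L, 1L); b_of <- c(0L, 1L, 0L, 1L)
  h1 <- sample.int(4L, B, TRUE, prob = hap)
  h2 <- sample.int(4L, B, TRUE, prob = hap)
  a1 <- a_of[h1]; b1 <- b_of[h1]; a2 <- a_of[h2]; b2 <- b_of[h2]
  f <- config$inbreeding_f
  a2 <- ifelse(stats::runif(B) < f["MDM2_rs2279744"], a1, a2)
  b2 <- ifelse(stats::runif(B) < f["MDM2_rs3730485"], b1, b2)
  dos <- cbind(
    TP53_rs1042522 = .draw_fmodel(B, config$maf_tp53, f["TP53_rs1042522"]),
    MDM2_rs2279744 = a1 + a2,
    MDM2_rs3730485 = b1 + b2,
    MDM4_rs4245739 = .draw_fmodel(B, config$maf_mdm4, f["MDM4_rs4245739"]))
  covars <- cbind(age_ge60 = stats::rbinom(B, 1L, config$p_age_ge60),
                  male = stats::rbinom(B, 1L, config$p_male))
  eta <- rep(config$beta0, B)
  for (term in names(config$betas))
    eta <- eta + config$betas[[term]] * .term_value(term, dos, covars)
  status <- stats::rbinom(B, 1L, expit(eta))
  data.frame(status = status, sex = covars[, "male"],
             age_ge60 = covars[, "age_ge60"], dos, check.names = FALSE)
}

.draw_fmodel <- function(B, p, f) {
  p2 <- f * p + (1 - f) * p^2
  p1 <- (1 - f) * 2 * p * (1 - p)
  sample(0:2, B, TRUE, prob = c(1 - p1 - p2, p1, p2))
}

#' Closed-form linkage disequilibrium implied by a simulation configuration
#'
#' @param x A [sim_config], or a length-4 haplotype-frequency vector in the
#'   T-I, T-D, G-I, G-D order.
#' @return List with `D` (signed, wildtype-wildtype convention
#'   `D = p(T-I) - p(T) p(I)`), `D_prime` (absolute), and `r2`.
#' @export
expected_ld <- function(x) {
  h <- if (inherits(x, "sim_config")) x$hap_freqs_mdm2 else as.numeric(x)
  if (length(h) != 4L || abs(sum(h) - 1) > 1e-8)
    .stopf("need 4 haplotype frequencies summing to 1")
  h <- unname(h)
  p_t <- h[1] + h[2]; p_i <- h[1] + h[3]           # wildtype allele freqs
  if (p_t %in% c(0, 1) || p_i %in% c(0, 1))
    .stopf("monomorphic locus: D' undefined")
  D <- h[1] - p_t * p_i
  p_g <- 1 - p_t; p_d <- 1 - p_i                   # variant allele freqs
  dmax <- if (D >= 0) min(p_g * (1 - p_d), (1 - p_g) * p_d)
          else min(p_g * p_d, (1 - p_g) * (1 - p_d))
  list(D = D, D_prime = if (dmax > 0) abs(D) / dmax else NA_real_,
       r2 = D^2 / (p_g * (1 - p_g) * p_d * (1 - p_d)))
}
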