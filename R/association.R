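#' Inheritance-coding design columns
#'
#' Maps variant-allele dosage to regression design columns: codominant (two
#' dummies against the dosage-0 reference), dominant (any variant allele),
#' recessive (two variant alleles), overdominant (heterozygote), additive
#' (dosage itself).
#'
#' @param dosage Integer vector of dosages 0/1/2 (NA allowed).
#' @param coding One of `"codominant"`, `"dominant"`, `"recessive"`,
#'   `"overdominant"`, `"additive"`.
#' @param labels Optional genotype label triple used to name columns.
#' @return Numeric matrix with 1 column (2 for codominant).
#' @export
genetic_design <- function(dosage,
                           coding = c("codominant", "dominant", "recessive",
                                      "overdominant", "additive"),
                           labels = c("wt/wt", "wt/var", "var/var")) {
  coding <- match.arg(coding)
  d <- as.integer(dosage)
  switch(coding,
    codominant = {
      m <- cbind(as.numeric(d == 1L), as.numeric(d == 2L))
      colnames(m) <- labels[2:3]; m
    },
    dominant = {
      m <- cbind(as.numeric(d >= 1L))
      colnames(m) <- paste(labels[2], "+", labels[3]); m
    },
    recessive = {
      m <- cbind(as.numeric(d == 2L)); colnames(m) <- labels[3]; m
    },
    overdominant = {
      m <- cbind(as.numeric(d == 1L)); colnames(m) <- labels[2]; m
    },
    additive = { m <- cbind(d); colnames(m) <- "additive"; m })
}

# exposed/unexposed reference labels per coding, for report rows
.coding_reference <- function(coding, labels) {
  switch(coding,
    codominant = labels[1],
    dominant = labels[1],
    recessive = paste(labels[1], "+", labels[2]),
    overdominant = paste(labels[1], "+", labels[3]),
    additive = labels[1])
}

#' Crude odds ratio from a 2 x 2 table
#'
#' `OR = (a d) / (b c)` with the Wald 95% interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell
#' triggers the Haldane-Anscombe +0.5 correction, flagged in the result.
#'
#' @param a Exposed cases. @param b Unexposed cases.
#' @param c Exposed controls. @param d Unexposed controls.
#' @return List with `or`, `ci` (length 2), `log_or`, `se`, `corrected`.
#' @export
#' @examples
#' crude_or_from_counts(68, 335, 37, 369)  # OR 2.02 (1.32-3.10)
crude_or_from_counts <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0))
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  log_or <- log(cells["a"] * cells["d"] / (cells["b"] * cells["c"]))
  se <- sqrt(sum(1 / cells))
  list(or = unname(exp(log_or)),
       ci = unname(exp(log_or + c(-1, 1) * .Z95 * se)),
       log_or = unname(log_or), se = unname(se), corrected = corrected)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up BH with monotonicity enforcement; in the association report the
#' family is the four inheritance codings of one locus (crude and adjusted
#' p-values adjusted as separate families).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  stats::p.adjust(p, method = "BH")
}

# internal: logistic fit returning coefficients and log-likelihood pieces.
# Builds y ~ [design] + covariates via glm; flags separation/non-convergence.
.logistic_fit <- function(y, design, covars = NULL) {
  X <- if (is.null(covars)) design else cbind(design, covars)
  if (is.null(X) || ncol(X) == 0L) {
    df <- data.frame(y = y)
    fit <- stats::glm(y ~ 1, data = df, family = stats::binomial(),
                      control = stats::glm.control(epsilon = 1e-12, maxit = 100))
    return(list(fit = fit, coef = summary(fit)$coefficients,
                deviance = fit$deviance, flagged = !fit$converged))
  }
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- stats::glm(y ~ ., data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  cf <- summary(fit)$coefficients
  rownames(cf) <- gsub("`", "", rownames(cf), fixed = TRUE)
  flagged <- !fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    anyNA(stats::coef(fit))
  list(fit = fit, coef = cf, deviance = fit$deviance, flagged = flagged)
}

#' Single-locus logistic association under one inheritance coding
#'
#' Maximum-likelihood logistic regression of case-control status on the
#' coding's design column(s); per-level odds ratios with Wald 95% intervals;
#' a single model p-value from the likelihood-ratio test against the nested
#' null (2 df for codominant, 1 df otherwise). With `adjust = TRUE` both
#' models contain the age-group and sex covariates, so the LRT isolates the
#' genetic term(s).
#'
#' @param x A [cohort].
#' @param locus_id Locus to test.
#' @param coding Inheritance coding (see [genetic_design]).
#' @param adjust Include `age_ge60` and `sex` covariates.
#' @return Object of class `assoc_result`: data frame `levels` (level label,
#'   beta, se, or, ci_lo, ci_hi), `p` (LRT), `df`, `counts` (status x coding
#'   level), `flagged`.
#' @export
fit_locus <- function(x, locus_id,
                      coding = c("codominant", "dominant", "recessive",
                                 "overdominant"),
                      adjust = FALSE) {
  coding <- match.arg(coding)
  stopifnot(inherits(x, "cohort"))
  if (!locus_id %in% names(x$loci)) .stopf("unknown locus: %s", locus_id)
  labels <- x$loci[[locus_id]]$genotype_labels
  d <- x$data
  ok <- !is.na(d[[locus_id]])
  d <- d[ok, ]
  design <- genetic_design(d[[locus_id]], coding, labels)
  covars <- if (adjust) cbind(age_ge60 = d$age_ge60, sex = d$sex) else NULL
  level_counts <- table(factor(d$status, 0:1, c("control", "case")),
                        if (coding == "codominant")
                          factor(d[[locus_id]], 0:2, labels)
                        else factor(design[, 1], 0:1,
                                    c(.coding_reference(coding, labels),
                                      colnames(design)[1])))
  degenerate <- any(colSums(level_counts) == 0)
  full <- .logistic_fit(d$status, design, covars)
  null <- .logistic_fit(d$status, matrix(numeric(0), nrow(d), 0), covars)
  k <- ncol(design)
  stat <- .lrt_stat(full$fit, null$fit)
  flagged <- full$flagged || degenerate
  idx <- match(colnames(design), rownames(full$coef))
  beta <- ifelse(is.na(idx), NA_real_, full$coef[idx, "Estimate"])
  se <- ifelse(is.na(idx), NA_real_, full$coef[idx, "Std. Error"])
  levels_df <- data.frame(
    level = colnames(design), beta = beta, se = se, or = exp(beta),
    ci_lo = exp(beta - .Z95 * se), ci_hi = exp(beta + .Z95 * se),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(locus_id = locus_id, coding = coding, adjust = adjust,
                 reference = .coding_reference(coding, labels),
                 levels = levels_df,
                 p = if (flagged) NA_real_ else .lrt_p(stat, k),
                 lrt = stat, df = k, counts = unclass(level_counts),
                 flagged = flagged),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s, %s%s: LRT p = %.4g (df = %d)%s\n",
              x$locus_id, x$coding, if (x$adjust) " (adjusted)" else "",
              x$p, x$df, if (x$flagged) " [FLAGGED]" else ""))
  print(cbind(level = x$levels$level,
              round(x$levels[c("or", "ci_lo", "ci_hi")], 3)))
  invisible(x)
}

#' Full association report across loci, codings, crude and adjusted
#'
#' One row per (locus, coding, genotype level), with group counts and
#' percentages, crude and covariate-adjusted odds ratios with Wald 95%
#' intervals, LRT p-values, and BH-FDR p-values where the family is the
#' four codings of each locus (crude and adjusted corrected separately).
#'
#' @param x A [cohort].
#' @param loci Locus ids (default: all).
#' @param codings Codings to fit.
#' @return Data frame shaped like the field's genotype-distribution tables.
#' @export
association_table <- function(x, loci = names(x$loci),
                              codings = c("codominant", "dominant",
                                          "recessive", "overdominant")) {
  rows <- list()
  for (id in loci) {
    fits_c <- lapply(codings, function(cd) fit_locus(x, id, cd, adjust = FALSE))
    fits_a <- lapply(codings, function(cd) fit_locus(x, id, cd, adjust = TRUE))
    pf_c <- bh_adjust(vapply(fits_c, `[[`, 0, "p"))
    pf_a <- bh_adjust(vapply(fits_a, `[[`, 0, "p"))
    for (i in seq_along(codings)) {
      fc <- fits_c[[i]]; fa <- fits_a[[i]]
      lv <- fc$levels
      cnt <- fc$counts
      pct <- 100 * prop.table(cnt, 1)
      lev_names <- c(fc$reference, lv$level)
      for (j in seq_along(lev_names)) {
        ln <- lev_names[j]
        ref <- j == 1L
        k <- j - 1L
        rows[[length(rows) + 1L]] <- data.frame(
          locus = id, coding = codings[i], level = ln,
          n_control = cnt["control", ln], pct_control = pct["control", ln],
          n_case = cnt["case", ln], pct_case = pct["case", ln],
          or_crude = if (ref) NA_real_ else lv$or[k],
          ci_lo_crude = if (ref) NA_real_ else lv$ci_lo[k],
          ci_hi_crude = if (ref) NA_real_ else lv$ci_hi[k],
          p_crude = fc$p, p_fdr_crude = pf_c[i],
          or_adj = if (ref) NA_real_ else fa$levels$or[k],
          ci_lo_adj = if (ref) NA_real_ else fa$levels$ci_lo[k],
          ci_hi_adj = if (ref) NA_real_ else fa$levels$ci_hi[k],
          p_adj = fa$p, p_fdr_adj = pf_a[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Joint two-pair gene-gene interaction logistic model
#'
#' Single logistic model containing the recessive-coded main effects of all
#' four loci, product (interaction) terms for the requested locus pairs, and
#' the age-group and sex covariates. Per-term Wald statistics and, for each
#' pair (A, B), the derived stratum odds ratio for B's risk genotype within
#' A's risk genotype, `exp(beta_B + beta_AB)`.
#'
#' @param x A [cohort].
#' @param pairs List of length-2 character vectors of locus ids.
#' @param coding Inheritance coding for every term (default recessive).
#' @param adjust Include covariates (default TRUE).
#' @return Object of class `interaction_fit` with `coefficients` (term,
#'   beta, se, or, ci_lo, ci_hi, p Wald) and `strata` (per pair, odds ratio
#'   of the second locus's risk genotype within and outside the first
#'   locus's risk genotype).
#' @export
fit_interaction_model <- function(x,
    pairs = list(c("MDM2_rs2279744", "TP53_rs1042522"),
                 c("MDM4_rs4245739", "MDM2_rs3730485")),
    coding = "recessive", adjust = TRUE) {
  stopifnot(inherits(x, "cohort"))
  main_loci <- names(x$loci)
  d <- x$data
  ok <- stats::complete.cases(d[main_loci])
  d <- d[ok, ]
  design <- do.call(cbind, lapply(main_loci, function(id) {
    m <- genetic_design(d[[id]], coding, x$loci[[id]]$genotype_labels)
    colnames(m) <- id
    m
  }))
  for (pr in pairs) {
    stopifnot(all(pr %in% main_loci))
    design <- cbind(design, design[, pr[1]] * design[, pr[2]])
    colnames(design)[ncol(design)] <- paste(pr, collapse = ":")
  }
  covars <- if (adjust) cbind(age_ge60 = d$age_ge60, sex = d$sex) else NULL
  fit <- .logistic_fit(d$status, design, covars)
  cf <- fit$coef
  terms <- rownames(cf)[-1]
  # glm backtick-quotes non-syntactic names; map back to design columns
  terms_clean <- gsub("`", "", terms, fixed = TRUE)
  coefs <- data.frame(
    term = terms_clean, beta = cf[-1, "Estimate"], se = cf[-1, "Std. Error"],
    or = exp(cf[-1, "Estimate"]),
    ci_lo = exp(cf[-1, "Estimate"] - .Z95 * cf[-1, "Std. Error"]),
    ci_hi = exp(cf[-1, "Estimate"] + .Z95 * cf[-1, "Std. Error"]),
    p = cf[-1, "Pr(>|z|)"], row.names = NULL, stringsAsFactors = FALSE)
  beta_of <- function(term) coefs$beta[match(term, coefs$term)]
  strata <- do.call(rbind, lapply(pairs, function(pr) {
    b_main <- beta_of(pr[2])
    b_int <- beta_of(paste(pr, collapse = ":"))
    data.frame(stratifier = pr[1], effect_locus = pr[2],
               or_within_risk = stratum_or(b_main, b_int),
               or_outside_risk = exp(b_main), stringsAsFactors = FALSE)
  }))
  structure(list(coefficients = coefs, strata = strata, coding = coding,
                 adjust = adjust, n = nrow(d), flagged = fit$flagged),
            class = "interaction_fit")
}

#' Stratum odds ratio from main-effect and interaction coefficients
#'
#' In a logistic model with indicator main effects and a product term, the
#' odds ratio for the effect locus's risk genotype within the stratifier's
#' risk genotype is `exp(beta_main + beta_interaction)`.
#'
#' @param beta_main Main-effect log-odds of the effect locus.
#' @param beta_interaction Product-term log-odds.
#' @return The stratum odds ratio.
#' @export
#' @examples
#' stratum_or(0.51, 1.22)  # 5.64
stratum_or <- function(beta_main, beta_interaction) {
  exp(beta_main + beta_interaction)
}

#' @export
print.interaction_fit <- function(x, ...) {
  cat(sprintf("<interaction_fit> %s coding, n = %d%s\n", x$coding, x$n,
              if (x$flagged) " [FLAGGED]" else ""))
  print(cbind(term = x$coefficients$term,
              round(x$coefficients[c("beta", "se", "or", "ci_lo", "ci_hi", "p")], 3)))
  invisible(x)
}
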