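#' Pairwise epistasis likelihood-ratio matrix
#'
#' For one inheritance coding, a loci x loci matrix of covariate-adjusted
#' likelihood-ratio p-values with the conventional three-zone layout:
#'
#' * upper triangle: the interaction test — full two-locus model with
#'   genotype product term(s) versus the additive two-locus model (df = 1
#'   for single-column codings, up to 4 for codominant);
#' * diagonal: each locus versus the covariate-only model;
#' * lower triangle: the additive two-locus model versus the better (higher
#'   log-likelihood) of the two single-locus models, ties broken by row
#'   locus order.
#'
#' All models contain the age-group and sex covariates. Every comparison is
#' made on the subjects with complete data for the pair, so the models are
#' strictly nested. Design columns that are constant in the data are
#' dropped, reducing the df of the affected cell; a cell whose df drops to
#' zero is NA.
#'
#' @param x A [cohort].
#' @param coding Inheritance coding (see [genetic_design]).
#' @param adjust Include covariates (default TRUE, the reported convention).
#' @return Object of class `epistasis_matrix`: list with `p` (matrix),
#'   `df` (matrix of test df), `coding`, and a `legend` string.
#' @export
epistasis_matrix <- function(x,
                             coding = c("codominant", "dominant",
                                        "recessive", "overdominant"),
                             adjust = TRUE) {
  coding <- match.arg(coding)
  stopifnot(inherits(x, "cohort"))
  ids <- names(x$loci)
  if (length(ids) < 2L) .stopf("need at least 2 loci")
  k <- length(ids)
  P <- DF <- matrix(NA_real_, k, k, dimnames = list(ids, ids))

  dsg <- function(d, id, i) {
    m <- genetic_design(d[[id]], coding, x$loci[[id]]$genotype_labels)
    colnames(m) <- paste0("L", i, "_", seq_len(ncol(m)))
    m[, apply(m, 2, stats::var) > 0, drop = FALSE]   # drop constant columns
  }
  cov_of <- function(d) if (adjust) cbind(age_ge60 = d$age_ge60, sex = d$sex) else NULL
  lr <- function(fit_full, fit_red) {
    df <- fit_full$fit$rank - fit_red$fit$rank
    if (df <= 0) return(c(NA_real_, NA_real_))
    c(.lrt_p(.lrt_stat(fit_full$fit, fit_red$fit), df), df)
  }

  # diagonal: locus vs covariate-only on that locus's complete cases
  for (i in seq_len(k)) {
    d <- x$data[!is.na(x$data[[ids[i]]]), ]
    gi <- dsg(d, ids[i], 1L)
    if (ncol(gi) == 0L) next
    f1 <- .logistic_fit(d$status, gi, cov_of(d))
    f0 <- .logistic_fit(d$status, matrix(numeric(0), nrow(d), 0), cov_of(d))
    v <- lr(f1, f0); P[i, i] <- v[1]; DF[i, i] <- v[2]
  }

  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- x$data[!is.na(x$data[[ids[i]]]) & !is.na(x$data[[ids[j]]]), ]
    gi <- dsg(d, ids[i], 1L); gj <- dsg(d, ids[j], 2L)
    if (ncol(gi) == 0L || ncol(gj) == 0L) next
    inter <- do.call(cbind, lapply(seq_len(ncol(gi)), function(a)
      vapply(seq_len(ncol(gj)), function(b) gi[, a] * gj[, b],
             numeric(nrow(d)))))
    colnames(inter) <- paste0("I", seq_len(ncol(inter)))
    inter <- inter[, apply(inter, 2, stats::var) > 0, drop = FALSE]
    cv <- cov_of(d)
    f_i <- .logistic_fit(d$status, gi, cv)
    f_j <- .logistic_fit(d$status, gj, cv)
    f_add <- .logistic_fit(d$status, cbind(gi, gj), cv)
    # upper: interaction vs additive
    if (ncol(inter) > 0L) {
      f_full <- .logistic_fit(d$status, cbind(gi, gj, inter), cv)
      v <- lr(f_full, f_add); P[i, j] <- v[1]; DF[i, j] <- v[2]
    }
    # lower: additive vs best single (higher log-likelihood, tie -> row locus)
    best <- if (f_j$deviance < f_i$deviance) f_j else f_i
    v <- lr(f_add, best); P[j, i] <- v[1]; DF[j, i] <- v[2]
  }

  structure(list(p = P, df = DF, coding = coding, adjust = adjust,
                 legend = paste("upper: pairwise interaction LRT;",
                                "diagonal: single-locus LRT;",
                                "lower: two-locus vs best single-locus LRT")),
            class = "epistasis_matrix")
}

#' @export
print.epistasis_matrix <- function(x, ...) {
  cat(sprintf("<epistasis_matrix> %s coding%s\n  %s\n", x$coding,
              if (x$adjust) ", covariate-adjusted" else "", x$legend))
  print(round(x$p, 3))
  invisible(x)
}
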