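#' Enumerate multi-locus genotype cells for an MB-MDR combination
#'
#' One cell per observed multi-locus genotype (up to `3^k` for `k` loci);
#' unobserved combinations are omitted. Subjects missing any of the combo's
#' genotypes are excluded (complete-case per combination).
#'
#' @param x A [cohort].
#' @param combo Character vector of 2-4 distinct locus ids.
#' @return Object of class `mbmdr_cells`: `cells` data frame (genotype
#'   `label`, per-locus dosages, `n_case`, `n_control`), integer
#'   `membership` assigning each retained subject to a cell, `y` status
#'   vector, `covars`, `dosages` matrix, and `combo`.
#' @export
enumerate_cells <- function(x, combo) {
  stopifnot(inherits(x, "cohort"))
  if (anyDuplicated(combo)) .stopf("combo contains duplicate loci")
  if (length(combo) < 2L || length(combo) > 4L)
    .stopf("combo size must be 2-4")
  miss <- setdiff(combo, names(x$loci))
  if (length(miss)) .stopf("unknown locus: %s", paste(miss, collapse = ", "))
  d <- x$data
  ok <- stats::complete.cases(d[combo])
  d <- d[ok, ]
  dos <- as.matrix(d[combo])
  key <- as.integer(dos %*% 3^(seq_along(combo) - 1L))   # base-3 cell code
  cells_key <- sort(unique(key))
  membership <- match(key, cells_key)
  lab_of <- function(ck) {
    digits <- (ck %/% 3^(seq_along(combo) - 1L)) %% 3L
    paste(vapply(seq_along(combo), function(i)
      x$loci[[combo[i]]]$genotype_labels[digits[i] + 1L], ""), collapse = " + ")
  }
  cells <- data.frame(label = vapply(cells_key, lab_of, ""),
                      stringsAsFactors = FALSE)
  for (i in seq_along(combo))
    cells[[combo[i]]] <- as.integer((cells_key %/% 3^(i - 1L)) %% 3L)
  cells$n_case <- as.integer(rowsum(d$status, membership))
  cells$n_control <- as.integer(rowsum(1L - d$status, membership))
  structure(list(cells = cells, membership = membership, y = d$status,
                 covars = cbind(age_ge60 = d$age_ge60, sex = d$sex),
                 dosages = dos, combo = combo),
            class = "mbmdr_cells")
}

# vectorized closed-form step-1 statistics for the unadjusted per-cell
# logistic model status ~ 1{cell}: the model is a saturated 2x2, so the MLE
# log-odds and Wald test have closed forms identical to the glm fit
.step1_closed <- function(a, ctrl, n_case_tot, n_control_tot) {
  b <- n_case_tot - a; d <- n_control_tot - ctrl
  valid <- a > 0 & b > 0 & ctrl > 0 & d > 0
  beta <- se <- p <- rep(NA_real_, length(a))
  beta[valid] <- log(a[valid] * d[valid] / (b[valid] * ctrl[valid]))
  se[valid] <- sqrt(1 / a[valid] + 1 / b[valid] + 1 / ctrl[valid] + 1 / d[valid])
  p[valid] <- 2 * stats::pnorm(-abs(beta[valid] / se[valid]))
  list(beta = beta, p = p, valid = valid)
}

# category labels from step-1 results: H iff beta > 0 & p < threshold,
# L iff beta < 0 & p < threshold, else O; undersized/degenerate cells -> O
.categorize <- function(beta, p, valid, n_cell, threshold, min_cell) {
  cat <- rep("O", length(beta))
  usable <- valid & n_cell >= min_cell & !is.na(p)
  cat[usable & beta > 0 & p < threshold] <- "H"
  cat[usable & beta < 0 & p < threshold] <- "L"
  cat
}

#' Categorize MB-MDR cells as high-risk, low-risk, or no-evidence
#'
#' Step 1 of MB-MDR: each cell is tested by a logistic regression of status
#' on the cell-membership indicator (cell versus all other subjects). Cells
#' with positive coefficient and p below `threshold` become `H`, negative
#' coefficient and p below `threshold` become `L`, all others `O`. Cells
#' smaller than `min_cell` subjects, or degenerate (all-case/all-control,
#' infinite log-odds), are forced to `O` and flagged.
#'
#' @param cells An [enumerate_cells] result.
#' @param threshold Step-1 p-value threshold (default 0.10).
#' @param min_cell Minimum subjects per testable cell (default 5).
#' @param step1_adjust Also include the age-group and sex covariates in the
#'   per-cell regressions (default FALSE: the classical unadjusted step 1;
#'   covariates then enter at step 2).
#' @return `cells` with columns `beta`, `p_step1`, `category`, `flagged`
#'   added to its `cells` data frame.
#' @export
categorize_cells <- function(cells, threshold = 0.10, min_cell = 5L,
                             step1_adjust = FALSE) {
  stopifnot(inherits(cells, "mbmdr_cells"))
  cc <- cells$cells
  n_cell <- cc$n_case + cc$n_control
  if (!step1_adjust) {
    s1 <- .step1_closed(cc$n_case, cc$n_control, sum(cells$y),
                        sum(1L - cells$y))
  } else {
    K <- nrow(cc)
    beta <- p <- rep(NA_real_, K); valid <- rep(FALSE, K)
    for (k in seq_len(K)) {
      ind <- as.numeric(cells$membership == k)
      if (stats::var(ind) == 0) next
      f <- .logistic_fit(cells$y, cbind(cell = ind), cells$covars)
      if (f$flagged || !"cell" %in% rownames(f$coef)) next
      beta[k] <- f$coef["cell", "Estimate"]
      p[k] <- f$coef["cell", "Pr(>|z|)"]
      valid[k] <- TRUE
    }
    s1 <- list(beta = beta, p = p, valid = valid)
  }
  cc$beta <- s1$beta
  cc$p_step1 <- s1$p
  cc$category <- .categorize(s1$beta, s1$p, s1$valid, n_cell, threshold, min_cell)
  cc$flagged <- !s1$valid | n_cell < min_cell
  cells$cells <- cc
  cells$threshold <- threshold
  cells$min_cell <- min_cell
  cells$step1_adjust <- step1_adjust
  cells
}

# weighted-least-squares Wald statistic for one column of a logistic fit,
# via glm.fit on a prebuilt model matrix (fast path for permutations)
.wald_for_column <- function(X, y, col) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  b <- fit$coefficients[col]
  if (is.na(b) || !fit$converged || abs(b) > 15 || fit$rank < ncol(X))
    return(c(beta = NA_real_, W = NA_real_, p = NA_real_))
  Xw <- X * sqrt(fit$weights)
  V <- tryCatch(chol2inv(chol(crossprod(Xw))), error = function(e) NULL)
  if (is.null(V)) return(c(beta = NA_real_, W = NA_real_, p = NA_real_))
  se <- sqrt(V[match(col, colnames(X)), match(col, colnames(X))])
  W <- unname((b / se)^2)
  c(beta = unname(b), W = W, p = stats::pchisq(W, 1, lower.tail = FALSE))
}

# step-2 design: intercept, additive dosages of the combo's loci, covariates
.step2_base <- function(cells) {
  X <- cbind(`(Intercept)` = 1, cells$dosages, cells$covars)
  # drop aliased/constant columns other than the intercept
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, stats::var) > 0)
  X[, keep, drop = FALSE]
}

#' MB-MDR step-2 association test of the merged risk groups
#'
#' Step 2 of MB-MDR: cells with the same category are merged into a
#' three-level variable (H / L / O). The H group is tested against the
#' remaining subjects by logistic regression of status on the H indicator
#' plus additive-coded main effects of the combination's loci and the
#' age-group and sex covariates; likewise for L. Wald statistics
#' `W = (beta/se)^2` are referred to the 1-df chi-square upper tail. An
#' empty category yields NA results for that side.
#'
#' @param cells A categorized [categorize_cells] result.
#' @return Object of class `mbmdr_result`.
#' @export
step2_test <- function(cells) {
  stopifnot(inherits(cells, "mbmdr_cells"), !is.null(cells$cells$category))
  cc <- cells$cells
  X0 <- .step2_base(cells)
  cat_subj <- cc$category[cells$membership]
  res <- list(combo = cells$combo)
  for (side in c("H", "L")) {
    sel <- cc$category == side
    nm <- paste0("N_", side)
    res[[nm]] <- sum(sel)
    res[[paste0("genotypes_", side)]] <- cc$label[sel]
    if (!any(sel)) {
      res[[paste0("beta_", side)]] <- res[[paste0("W_", side)]] <-
        res[[paste0("p_", side)]] <- NA_real_
      next
    }
    ind <- as.numeric(cat_subj == side)
    w <- .wald_for_column(cbind(X0, risk = ind), cells$y, "risk")
    res[[paste0("beta_", side)]] <- w[["beta"]]
    res[[paste0("W_", side)]] <- w[["W"]]
    res[[paste0("p_", side)]] <- w[["p"]]
  }
  ps <- c(res$p_H, res$p_L)
  res$min_p <- if (all(is.na(ps))) NA_real_ else min(ps, na.rm = TRUE)
  res$threshold <- cells$threshold
  structure(res, class = "mbmdr_result")
}

#' @export
print.mbmdr_result <- function(x, ...) {
  cat(sprintf("<mbmdr_result> %s\n", paste(x$combo, collapse = " + ")))
  cat(sprintf("  H: N=%d beta=%.3g W=%.3g p=%.3g | L: N=%d beta=%.3g W=%.3g p=%.3g\n",
              x$N_H, x$beta_H, x$W_H, x$p_H, x$N_L, x$beta_L, x$W_L, x$p_L))
  if (!is.null(x$perm_p))
    cat(sprintf("  permutation-corrected p = %.4g (%d permutations)\n",
                x$perm_p, x$n_perm))
  invisible(x)
}

#' Max-Wald permutation correction for one MB-MDR combination
#'
#' Runs the full two-step MB-MDR on the observed data, then on `n_perm`
#' datasets in which the case/control labels are shuffled while genotypes
#' and covariates stay with their subjects. The observed
#' `max(W_H, W_L)` is referred to the permutation distribution of the same
#' maximum (0 when both sides are NA in a permutation);
#' `perm_p = (1 + #\{perm >= observed\}) / (n_perm + 1)`. Deterministic
#' under `seed`.
#'
#' @param x A [cohort].
#' @param combo Character vector of 2-4 locus ids.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed.
#' @inheritParams categorize_cells
#' @return An `mbmdr_result` with `perm_p`, `n_perm`, `seed` and
#'   `obs_max_W` added. When the observed maximum is NA (no H and no L
#'   group), `perm_p = 1` and the result is flagged.
#' @export
permutation_correct <- function(x, combo, n_perm = 1000L, seed = 1L,
                                threshold = 0.10, min_cell = 5L,
                                step1_adjust = FALSE) {
  stopifnot(n_perm >= 1L)
  cells <- categorize_cells(enumerate_cells(x, combo), threshold = threshold,
                            min_cell = min_cell, step1_adjust = step1_adjust)
  obs <- step2_test(cells)
  obs_max <- suppressWarnings(max(c(obs$W_H, obs$W_L), na.rm = TRUE))
  if (!is.finite(obs_max)) {
    obs$perm_p <- 1
    obs$n_perm <- as.integer(n_perm)
    obs$seed <- seed
    obs$obs_max_W <- NA_real_
    obs$flagged <- TRUE
    return(obs)
  }
  X0 <- .step2_base(cells)
  n_cell <- cells$cells$n_case + cells$cells$n_control
  m <- cells$membership
  y <- cells$y
  n_case_tot <- sum(y); n_control_tot <- length(y) - n_case_tot
  perm_max <- .with_seed(seed, vapply(seq_len(n_perm), function(b) {
    yp <- sample(y)
    a <- as.integer(rowsum(yp, m))
    if (!step1_adjust) {
      s1 <- .step1_closed(a, n_cell - a, n_case_tot, n_control_tot)
      cat <- .categorize(s1$beta, s1$p, s1$valid, n_cell, threshold, min_cell)
    } else {
      tmp <- cells
      tmp$y <- yp
      tmp <- categorize_cells(tmp, threshold, min_cell, step1_adjust = TRUE)
      cat <- tmp$cells$category
    }
    cat_subj <- cat[m]
    ws <- vapply(c("H", "L"), function(side) {
      if (!any(cat == side)) return(NA_real_)
      w <- .wald_for_column(cbind(X0, risk = as.numeric(cat_subj == side)),
                            yp, "risk")
      w[["W"]]
    }, 0)
    if (all(is.na(ws))) 0 else max(ws, na.rm = TRUE)
  }, 0))
  obs$perm_p <- (1 + sum(perm_max >= obs_max)) / (n_perm + 1)
  obs$n_perm <- as.integer(n_perm)
  obs$seed <- seed
  obs$obs_max_W <- obs_max
  obs$flagged <- FALSE
  obs
}

#' Scan all locus combinations of the given orders
#'
#' Runs the complete MB-MDR procedure (cell enumeration, categorization,
#' merged-group testing, max-Wald permutation correction) for every
#' combination of the cohort's loci at each requested order. Each
#' combination receives a deterministically derived child seed, so any row
#' is independently reproducible.
#'
#' @param x A [cohort].
#' @param orders Integer vector of combination orders (subset of 2:4).
#' @param n_perm Permutations per combination.
#' @param seed Master seed.
#' @inheritParams categorize_cells
#' @return List of `mbmdr_result` objects; see [mbmdr_table] for the
#'   tabular report.
#' @export
scan_combinations <- function(x, orders = 2:4, n_perm = 1000L, seed = 1L,
                              threshold = 0.10, min_cell = 5L,
                              step1_adjust = FALSE) {
  ids <- names(x$loci)
  stopifnot(length(ids) >= max(orders))
  results <- list()
  idx <- 0L
  for (ord in sort(orders)) {
    for (cmb in as.data.frame(utils::combn(ids, ord), stringsAsFactors = FALSE)) {
      idx <- idx + 1L
      results[[idx]] <- permutation_correct(
        x, as.character(cmb), n_perm = n_perm,
        seed = .child_seed(seed, idx), threshold = threshold,
        min_cell = min_cell, step1_adjust = step1_adjust)
    }
  }
  results
}

#' Tabulate MB-MDR results in the conventional report shape
#'
#' @param results List of `mbmdr_result` objects from [scan_combinations]
#'   or [permutation_correct].
#' @return Data frame with one row per combination: model, N_H, H genotype
#'   labels, beta_H, W_H, p_H, the same for L, min_p and the
#'   permutation-corrected p.
#' @export
mbmdr_table <- function(results) {
  if (inherits(results, "mbmdr_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(
      model = paste(r$combo, collapse = "+"), order = length(r$combo),
      N_H = r$N_H, genotypes_H = paste(r$genotypes_H, collapse = ", "),
      beta_H = r$beta_H, W_H = r$W_H, p_H = r$p_H,
      N_L = r$N_L, genotypes_L = paste(r$genotypes_L, collapse = ", "),
      beta_L = r$beta_L, W_L = r$W_L, p_L = r$p_L,
      min_p = r$min_p,
      perm_p = if (is.null(r$perm_p)) NA_real_ else r$perm_p,
      n_perm = if (is.null(r$n_perm)) NA_integer_ else r$n_perm,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
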