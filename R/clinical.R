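#' Chi-square / Fisher contingency test with automatic selection
#'
#' Pearson chi-square (no continuity correction) by default; Fisher's exact
#' test whenever any expected cell count is below 5. For tables larger than
#' 2 x 2 the exact test falls back to Monte-Carlo p-value simulation
#' (seeded) if the network algorithm fails.
#'
#' @param tab Matrix of nonnegative integer counts, at least 2 x 2.
#' @param test `"auto"` (expected-count rule), `"pearson"`, or `"fisher"`.
#' @param B Monte-Carlo replicates for large-table Fisher fallback.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return Object of class `contingency_result`: `table`, `test_used`,
#'   `statistic` (NA for Fisher), `p`, `expected`.
#' @export
contingency_test <- function(tab, test = c("auto", "pearson", "fisher"),
                             B = 2000L, seed = 1L) {
  test <- match.arg(test)
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), nrow(tab) >= 2L, ncol(tab) >= 2L)
  if (any(rowSums(tab) == 0))
    .stopf("degenerate table: row %d has zero margin", which(rowSums(tab) == 0)[1])
  if (any(colSums(tab) == 0))
    .stopf("degenerate table: column %d has zero margin", which(colSums(tab) == 0)[1])
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (test == "auto") test <- if (any(expected < 5)) "fisher" else "pearson"
  if (test == "pearson") {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    out <- list(statistic = unname(ct$statistic), p = ct$p.value)
  } else {
    ft <- tryCatch(stats::fisher.test(tab),
                   error = function(e) .with_seed(seed,
                     stats::fisher.test(tab, simulate.p.value = TRUE, B = B)))
    out <- list(statistic = NA_real_, p = ft$p.value)
  }
  structure(list(table = tab, test_used = test, statistic = out$statistic,
                 p = out$p, expected = expected),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> %s test: p = %.4g\n", x$test_used, x$p))
  print(x$table)
  invisible(x)
}

#' Post-hoc pairwise contrasts with BH adjustment
#'
#' After a significant omnibus test, decomposes an r x c table into 2 x 2
#' contrasts, tests each with [contingency_test] (auto selection), and
#' adjusts the family with Benjamini-Hochberg.
#'
#' Default contrast family is `"level_vs_rest"`: each (row level, column
#' level) pair collapsed to (that row vs the rest) x (that column vs the
#' rest) — the "this genotype with this outcome level versus all others"
#' reading. `"pairwise"` instead tests every row-pair x column-pair 2 x 2
#' subtable.
#'
#' @param tab Matrix of counts.
#' @param contrasts Contrast family.
#' @param test Passed to [contingency_test].
#' @return Data frame with one row per contrast: description, test used,
#'   raw `p`, and `p_fdr`.
#' @export
posthoc_pairwise <- function(tab, contrasts = c("level_vs_rest", "pairwise"),
                             test = "auto") {
  contrasts <- match.arg(contrasts)
  tab <- as.matrix(tab)
  rn <- rownames(tab) %||% paste0("row", seq_len(nrow(tab)))
  cn <- colnames(tab) %||% paste0("col", seq_len(ncol(tab)))
  rows <- list()
  if (contrasts == "level_vs_rest") {
    ri <- if (nrow(tab) > 2L) seq_len(nrow(tab)) else 1L
    ci <- if (ncol(tab) > 2L) seq_len(ncol(tab)) else 1L
    for (i in ri) for (j in ci) {
      t2 <- matrix(c(tab[i, j], sum(tab[i, -j]),
                     sum(tab[-i, j]), sum(tab[-i, -j])), 2, byrow = TRUE)
      ct <- contingency_test(t2, test = test)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = sprintf("%s vs rest | %s vs rest", rn[i], cn[j]),
        test_used = ct$test_used, p = ct$p, stringsAsFactors = FALSE)
    }
  } else {
    for (i1 in seq_len(nrow(tab) - 1L)) for (i2 in (i1 + 1L):nrow(tab))
      for (j1 in seq_len(ncol(tab) - 1L)) for (j2 in (j1 + 1L):ncol(tab)) {
        t2 <- tab[c(i1, i2), c(j1, j2)]
        ct <- contingency_test(t2, test = test)
        rows[[length(rows) + 1L]] <- data.frame(
          contrast = sprintf("%s vs %s | %s vs %s", rn[i1], rn[i2], cn[j1], cn[j2]),
          test_used = ct$test_used, p = ct$p, stringsAsFactors = FALSE)
      }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Omnibus + conditional post-hoc analysis of one categorical feature
#'
#' Runs [contingency_test] and attaches [posthoc_pairwise] contrasts only
#' when the omnibus p is below `alpha` and the table is larger than 2 x 2.
#'
#' @inheritParams contingency_test
#' @param alpha Omnibus significance gate for post-hoc testing.
#' @param contrasts Passed to [posthoc_pairwise].
#' @return A `contingency_result` with a `posthoc` data frame (or NULL).
#' @export
clinical_feature_test <- function(tab, test = "auto", alpha = 0.05,
                                  contrasts = "level_vs_rest") {
  res <- contingency_test(tab, test = test)
  res$posthoc <-
    if (res$p < alpha && (nrow(res$table) > 2L || ncol(res$table) > 2L))
      posthoc_pairwise(res$table, contrasts = contrasts, test = test)
    else NULL
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
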