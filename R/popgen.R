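#' Hardy-Weinberg equilibrium test from genotype counts
#'
#' Pearson chi-square with 1 df comparing observed genotype counts to the
#' expectations p^2, 2pq, q^2 at the estimated allele frequency. No
#' continuity correction. A monomorphic sample is in equilibrium by
#' convention: `chi2 = 0, p = 1`.
#'
#' @param counts Length-3 counts `(n_wtwt, n_het, n_varvar)`.
#' @return List with `chi2`, `p`, `q_var` (variant-allele frequency), `n`.
#' @export
#' @examples
#' hwe_test(c(25, 50, 25))  # exact HW proportions: chi2 = 0
hwe_test <- function(counts) {
  counts <- as.numeric(counts)
  stopifnot(length(counts) == 3L, all(counts >= 0))
  n <- sum(counts)
  if (n <= 0) .stopf("empty genotype counts")
  q <- (counts[2] + 2 * counts[3]) / (2 * n)
  if (q <= 0 || q >= 1)
    return(list(chi2 = 0, p = 1, q_var = q, n = n))
  expd <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- sum((counts - expd)^2 / expd)
  list(chi2 = chi2, p = stats::pchisq(chi2, 1, lower.tail = FALSE),
       q_var = q, n = n)
}

#' Per-locus Hardy-Weinberg tests for a cohort
#'
#' @param x A [cohort].
#' @param group `"all"`, `"case"` or `"control"`.
#' @return Data frame with one row per locus: counts, variant frequency,
#'   chi-square statistic and p-value.
#' @export
hwe_table <- function(x, group = c("all", "case", "control")) {
  group <- match.arg(group)
  keep <- switch(group, all = rep(TRUE, nrow(x$data)),
                 case = x$data$status == 1L, control = x$data$status == 0L)
  rows <- lapply(names(x$loci), function(id) {
    dose <- x$data[[id]][keep]
    cnt <- vapply(0:2, function(d) sum(!is.na(dose) & dose == d), 0L)
    h <- hwe_test(cnt)
    data.frame(locus = id, group = group, n_wtwt = cnt[1], n_het = cnt[2],
               n_varvar = cnt[3], q_var = h$q_var, chi2 = h$chi2, p = h$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# EM over the 3x3 unphased two-locus genotype table. Haplotypes indexed by
# variant-allele indicators (A, B): 1 = 00, 2 = 01, 3 = 10, 4 = 11. Only the
# double-heterozygote cell mixes two phase resolutions (00/11 vs 01/10).
.em_core <- function(tab, tol = 1e-8, max_iter = 1000L) {
  stopifnot(all(dim(tab) == c(3L, 3L)), all(tab >= 0))
  n <- sum(tab)
  if (n <= 0) .stopf("empty genotype table")
  pA <- sum(tab * matrix(0:2, 3, 3)) / (2 * n)        # variant freq locus A (rows)
  pB <- sum(tab * matrix(0:2, 3, 3, byrow = TRUE)) / (2 * n)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) .stopf("monomorphic locus: LD undefined")
  # fixed haplotype contributions from unambiguous cells
  base <- c(`00` = 2 * tab[1, 1] + tab[1, 2] + tab[2, 1],
            `01` = 2 * tab[1, 3] + tab[1, 2] + tab[2, 3],
            `10` = 2 * tab[3, 1] + tab[2, 1] + tab[3, 2],
            `11` = 2 * tab[3, 3] + tab[3, 2] + tab[2, 3])
  ndh <- tab[2, 2]
  f <- c((1 - pA) * (1 - pB), (1 - pA) * pB, pA * (1 - pB), pA * pB)
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    ll_trace <- c(ll_trace, .em_loglik(tab, f))
    cis <- f[1] * f[4]
    pc <- if (cis + f[2] * f[3] > 0) cis / (cis + f[2] * f[3]) else 0.5
    cnt <- base + ndh * c(pc, 1 - pc, 1 - pc, pc)
    f_new <- cnt / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
  }
  ll_full <- .em_loglik(tab, f)
  ll_trace <- c(ll_trace, ll_full)
  f_ind <- c((1 - pA) * (1 - pB), (1 - pA) * pB, pA * (1 - pB), pA * pB)
  lrt <- 2 * (ll_full - .em_loglik(tab, f_ind))
  D <- f[4] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  structure(list(freqs = stats::setNames(f, c("wt-wt", "wt-var", "var-wt", "var-var")),
                 D = D,
                 D_prime = if (dmax > 0) abs(D) / dmax else NA_real_,
                 r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
                 loglik = ll_full, loglik_trace = ll_trace, n_iter = it,
                 p_value = .lrt_p(lrt, 1), lrt = max(lrt, 0), n = n,
                 allele_freq = c(A = pA, B = pB)),
            class = "hap_estimate")
}

# multinomial log-likelihood of a 3x3 genotype table under random union of
# gametes with haplotype frequencies f (indexing as in .em_core)
.em_loglik <- function(tab, f) {
  dA <- c(0L, 0L, 1L, 1L); dB <- c(0L, 1L, 0L, 1L)
  P <- matrix(0, 3, 3)
  for (h in 1:4) for (k in 1:4) {
    P[dA[h] + dA[k] + 1L, dB[h] + dB[k] + 1L] <-
      P[dA[h] + dA[k] + 1L, dB[h] + dB[k] + 1L] + f[h] * f[k]
  }
  keep <- tab > 0
  sum(tab[keep] * log(pmax(P[keep], 1e-300)))
}

#' EM haplotype-frequency estimation and D' for a locus pair
#'
#' Estimates the four two-locus haplotype frequencies from unphased
#' genotypes by EM (initialized at linkage equilibrium, convergence when the
#' largest frequency change is below `tol`), then derives the signed
#' disequilibrium `D`, the standardized `|D'|`, `r2`, and a 1-df
#' likelihood-ratio p-value for D = 0.
#'
#' @param x A [cohort].
#' @param locus_a,locus_b Locus ids.
#' @param group Subjects to use: `"all"`, `"case"` or `"control"`.
#' @param tol,max_iter EM convergence controls.
#' @return Object of class `hap_estimate` with fields `freqs`, `D`,
#'   `D_prime`, `r2`, `loglik`, `loglik_trace`, `n_iter`, `p_value`.
#' @export
em_haplotypes <- function(x, locus_a, locus_b, group = c("all", "case", "control"),
                          tol = 1e-8, max_iter = 1000L) {
  group <- match.arg(group)
  stopifnot(inherits(x, "cohort"))
  for (id in c(locus_a, locus_b))
    if (!id %in% names(x$loci)) .stopf("unknown locus: %s", id)
  keep <- switch(group, all = rep(TRUE, nrow(x$data)),
                 case = x$data$status == 1L, control = x$data$status == 0L)
  da <- x$data[[locus_a]][keep]; db <- x$data[[locus_b]][keep]
  ok <- !is.na(da) & !is.na(db)
  tab <- matrix(0L, 3, 3)
  for (i in 0:2) for (j in 0:2) tab[i + 1, j + 1] <- sum(da[ok] == i & db[ok] == j)
  est <- .em_core(tab, tol = tol, max_iter = max_iter)
  est$locus_pair <- c(locus_a, locus_b)
  est$group <- group
  est
}

#' @export
print.hap_estimate <- function(x, ...) {
  cat(sprintf("<hap_estimate> %s (n = %d, %d EM iterations)\n",
              if (!is.null(x$locus_pair)) paste(x$locus_pair, collapse = " x ")
              else "2 loci", x$n, x$n_iter))
  cat(sprintf("  D = %.4f  |D'| = %.3f  r2 = %.3f  LRT p = %.3g\n",
              x$D, x$D_prime, x$r2, x$p_value))
  invisible(x)
}

#' Linkage disequilibrium for all locus pairs of a cohort
#'
#' @inheritParams em_haplotypes
#' @return Data frame with one row per unordered locus pair.
#' @export
ld_table <- function(x, group = c("all", "case", "control")) {
  group <- match.arg(group)
  ids <- names(x$loci)
  pairs <- utils::combn(ids, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    e <- em_haplotypes(x, pr[1], pr[2], group = group)
    data.frame(locus_a = pr[1], locus_b = pr[2], group = group, D = e$D,
               D_prime = e$D_prime, r2 = e$r2, p = e$p_value,
               n_iter = e$n_iter, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
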