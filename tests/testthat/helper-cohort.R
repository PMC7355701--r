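# Builders used across the suite.

# cohort reconstructed from per-group genotype count triples
# counts: named list locus_id -> list(control = c(n0, n1, n2), case = c(...))
cohort_from_counts <- function(counts, loci = tp53_axis_loci()) {
  ids <- names(counts)
  grp <- lapply(c(control = 0L, case = 1L), function(st) {
    dose_cols <- lapply(ids, function(id) {
      cnt <- counts[[id]][[if (st == 0L) "control" else "case"]]
      rep(0:2, times = cnt)
    })
    n <- length(dose_cols[[1]])
    stopifnot(all(vapply(dose_cols, length, 0L) == n))
    df <- data.frame(status = rep(st, n), sex = rep_len(0:1, n),
                     age_ge60 = rep_len(c(0L, 0L, 1L), n))
    for (i in seq_along(ids)) df[[ids[i]]] <- dose_cols[[i]]
    df
  })
  d <- rbind(grp$control, grp$case)
  d <- cbind(subject_id = sprintf("S%04d", seq_len(nrow(d))), d)
  cohort(d, loci[ids])
}

# published genotype-count triples (control and AML groups)
table1_counts <- function() {
  list(
    TP53_rs1042522 = list(control = c(217, 152, 37), case = c(225, 110, 68)),
    MDM2_rs2279744 = list(control = c(141, 197, 68), case = c(135, 213, 55)),
    MDM2_rs3730485 = list(control = c(179, 169, 58), case = c(168, 185, 50)),
    MDM4_rs4245739 = list(control = c(83, 114, 209), case = c(57, 144, 202))
  )
}

# small hand-made cohort with known dosages for IO round-trips
tiny_cohort <- function() {
  loci <- tp53_axis_loci()[c("TP53_rs1042522", "MDM2_rs2279744")]
  d <- data.frame(
    subject_id = paste0("S", 1:6),
    status = c(1L, 1L, 1L, 0L, 0L, 0L),
    sex = c(1L, 0L, 1L, 0L, 1L, 0L),
    age_ge60 = c(1L, 0L, 0L, 1L, 1L, 0L),
    TP53_rs1042522 = c(0L, 1L, 2L, 0L, 1L, NA),
    MDM2_rs2279744 = c(2L, 1L, 0L, 1L, NA, 0L),
    check.names = FALSE)
  cohort(d, loci)
}
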