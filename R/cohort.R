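#' Construct a case-control cohort
#'
#' @param data Data frame with columns `subject_id`, `status` (1 = case,
#'   0 = control), `sex` (1 = male, 0 = female), `age_ge60` (1 = aged >= 60)
#'   and one integer dosage column (0/1/2 count of the variant allele, NA
#'   allowed) per locus, named by `locus_id`.
#' @param loci Named list of [locus_def] objects; every dosage column must be
#'   declared here.
#' @return Object of class `cohort`.
#' @export
cohort <- function(data, loci) {
  stopifnot(is.data.frame(data))
  need <- c("subject_id", "status", "sex", "age_ge60")
  miss <- setdiff(need, names(data))
  if (length(miss))
    .stopf("cohort table is missing mandatory column(s): %s",
           paste(miss, collapse = ", "))
  if (is.null(names(loci)))
    loci <- stats::setNames(loci, vapply(loci, `[[`, "", "locus_id"))
  extra <- setdiff(names(data), c(need, names(loci)))
  if (length(extra))
    .stopf("genotype column(s) absent from locus config: %s",
           paste(extra, collapse = ", "))
  for (v in c("status", "sex", "age_ge60")) {
    data[[v]] <- as.integer(data[[v]])
    if (any(!data[[v]] %in% c(0L, 1L)))
      .stopf("column %s must be binary 0/1", v)
  }
  for (id in intersect(names(loci), names(data))) {
    data[[id]] <- as.integer(data[[id]])
    bad <- !is.na(data[[id]]) & !data[[id]] %in% 0:2
    if (any(bad)) .stopf("locus %s: dosage values must be 0, 1, 2 or NA", id)
  }
  data$subject_id <- as.character(data$subject_id)
  structure(list(data = data, loci = loci[intersect(names(loci), names(data))]),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d cases / %d controls), %d loci: %s\n",
              nrow(x$data), n_cases(x), n_controls(x), length(x$loci),
              paste(names(x$loci), collapse = ", ")))
  invisible(x)
}

#' @rdname cohort
#' @param x A `cohort`.
#' @export
n_cases <- function(x) sum(x$data$status == 1L)

#' @rdname cohort
#' @export
n_controls <- function(x) sum(x$data$status == 0L)

#' Read a cohort table plus locus configuration
#'
#' The table is delimited text (tab or comma, auto-detected from the header
#' line) with columns `subject_id`, `status`, `sex`, `age_ge60` and one
#' genotype column per configured locus. Genotype strings are `"a/b"` allele
#' pairs, order-insensitive for heterozygotes (compact `"TG"` form accepted
#' for single-character alleles). Status accepts 0/1 or control/case labels;
#' sex accepts 0/1 or F/M. Unparseable genotypes become missing and their
#' count is reported as a warning.
#'
#' @param table_path Path to the subject table.
#' @param loci Either a named list of [locus_def]s or a path to a locus
#'   config file (see [read_locus_config]).
#' @return A [cohort].
#' @export
read_cohort <- function(table_path, loci = tp53_axis_loci()) {
  if (is.character(loci)) loci <- read_locus_config(loci)
  if (!file.exists(table_path)) .stopf("cohort table not found: %s", table_path)
  header <- readLines(table_path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(table_path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           na.strings = character())
  need <- c("subject_id", "status", "sex", "age_ge60")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    .stopf("cohort table is missing mandatory column(s): %s",
           paste(miss, collapse = ", "))
  gcols <- setdiff(names(raw), need)
  absent <- setdiff(gcols, names(loci))
  if (length(absent))
    .stopf("genotype column(s) absent from locus config: %s",
           paste(absent, collapse = ", "))
  out <- data.frame(subject_id = raw$subject_id,
                    status = .parse_binary(raw$status, c("control", "ctrl"),
                                           c("case", "aml"), "status"),
                    sex = .parse_binary(raw$sex, c("f", "female"),
                                        c("m", "male"), "sex"),
                    age_ge60 = .parse_binary(raw$age_ge60, NULL, NULL, "age_ge60"),
                    stringsAsFactors = FALSE, check.names = FALSE)
  n_bad <- 0L
  for (id in gcols) {
    dose <- .parse_genotypes(raw[[id]], loci[[id]])
    n_bad <- n_bad + sum(is.na(dose) & nzchar(trimws(raw[[id]])) &
                           trimws(raw[[id]]) != "NA")
    out[[id]] <- dose
  }
  if (n_bad > 0L)
    .warnf("%d genotype value(s) could not be parsed and were set to missing", n_bad)
  cohort(out, loci[gcols])
}

.parse_binary <- function(x, zero_tokens, one_tokens, what) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("0", zero_tokens)] <- 0L
  out[x %in% c("1", one_tokens)] <- 1L
  if (anyNA(out)) .stopf("column %s: unrecognized value(s)", what)
  out
}

#' Write a cohort back to delimited text
#'
#' Genotypes are written in canonical wildtype-first `"a/b"` form so that
#' write -> read -> write round-trips byte-identically.
#'
#' @param x A [cohort].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(inherits(x, "cohort"))
  out <- x$data[c("subject_id", "status", "sex", "age_ge60")]
  for (id in names(x$loci))
    out[[id]] <- .format_genotypes(x$data[[id]], x$loci[[id]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Genotype counts by case-control status
#'
#' @param x A [cohort].
#' @param locus_id Locus to tabulate.
#' @return Object of class `genotype_counts`: a list with the 2 x 3
#'   `counts` matrix (rows control/case, columns the locus genotype labels,
#'   missing genotypes excluded), matching `percent` matrix, and the number
#'   of subjects excluded for missingness per group.
#' @export
genotype_counts <- function(x, locus_id) {
  stopifnot(inherits(x, "cohort"))
  if (!locus_id %in% names(x$loci)) .stopf("unknown locus: %s", locus_id)
  dose <- x$data[[locus_id]]
  status <- x$data$status
  counts <- matrix(0L, 2, 3,
                   dimnames = list(c("control", "case"),
                                   x$loci[[locus_id]]$genotype_labels))
  for (s in 0:1) for (d in 0:2)
    counts[s + 1L, d + 1L] <- sum(status == s & !is.na(dose) & dose == d)
  grp_n <- rowSums(counts)
  percent <- counts / ifelse(grp_n > 0, grp_n, NA_real_) * 100
  missing <- c(control = sum(status == 0L & is.na(dose)),
               case = sum(status == 1L & is.na(dose)))
  structure(list(locus_id = locus_id, counts = counts, percent = percent,
                 missing = missing),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> %s (missing: %d control, %d case)\n",
              x$locus_id, x$missing["control"], x$missing["case"]))
  print(x$counts)
  invisible(x)
}

#' Cohort demographics summary
#'
#' Group sizes, sex and age-group counts, the male-to-female ratio in cases,
#' and the Pearson chi-square test (no continuity correction) of sex against
#' status.
#'
#' @param x A [cohort].
#' @return List with `n`, `sex_counts` and `age_counts` (2 x 2, status by
#'   level), `mf_ratio_cases`, `sex_chisq`, `sex_p`.
#' @export
summarize_demographics <- function(x) {
  stopifnot(inherits(x, "cohort"))
  if (nrow(x$data) == 0L) .stopf("empty cohort")
  d <- x$data
  sex_counts <- table(factor(d$status, 0:1, c("control", "case")),
                      factor(d$sex, 0:1, c("female", "male")))
  age_counts <- table(factor(d$status, 0:1, c("control", "case")),
                      factor(d$age_ge60, 0:1, c("lt60", "ge60")))
  m <- sex_counts["case", "male"]; f <- sex_counts["case", "female"]
  ratio <- if (f > 0 && n_cases(x) > 0) m / f else NA_real_
  ct <- if (all(dim(sex_counts) == 2) && all(rowSums(sex_counts) > 0) &&
            all(colSums(sex_counts) > 0))
    stats::chisq.test(sex_counts, correct = FALSE) else NULL
  list(n = c(control = n_controls(x), case = n_cases(x)),
       sex_counts = unclass(sex_counts), age_counts = unclass(age_counts),
       mf_ratio_cases = ratio,
       sex_chisq = if (is.null(ct)) NA_real_ else unname(ct$statistic),
       sex_p = if (is.null(ct)) NA_real_ else ct$p.value)
}
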