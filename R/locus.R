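#' Define a biallelic locus
#'
#' A locus definition fixes the wildtype/variant allele orientation and the
#' display labels for the three genotypes. Orientation is always explicit in
#' configuration, never inferred from sample frequency: for variants such as
#' MDM4 rs4245739 the reference/ancestral annotation has flipped between
#' genome-browser releases, so frequency-based guessing is unsafe.
#'
#' @param locus_id Unique identifier, e.g. `"TP53_rs1042522"`.
#' @param gene Gene symbol.
#' @param allele_wt,allele_var Allele labels (amino acid, base, or I/D for an
#'   indel); must differ.
#' @param genotype_labels Optional ordered triple of display labels for
#'   (wt/wt, wt/var, var/var); defaults to compact `paste0` labels when both
#'   alleles are single characters, `"wt/var"` style otherwise.
#' @return An object of class `locus_def`.
#' @export
#' @examples
#' locus_def("TP53_rs1042522", "TP53", "Arg", "Pro",
#'           c("Arg/Arg", "Arg/Pro", "Pro/Pro"))
locus_def <- function(locus_id, gene, allele_wt, allele_var,
                      genotype_labels = NULL) {
  stopifnot(is.character(locus_id), nzchar(locus_id))
  if (identical(allele_wt, allele_var))
    .stopf("locus %s: wildtype and variant allele labels must differ", locus_id)
  if (is.null(genotype_labels)) {
    sep <- if (nchar(allele_wt) == 1L && nchar(allele_var) == 1L) "" else "/"
    genotype_labels <- c(paste(allele_wt, allele_wt, sep = sep),
                         paste(allele_wt, allele_var, sep = sep),
                         paste(allele_var, allele_var, sep = sep))
  }
  genotype_labels <- as.character(genotype_labels)
  if (length(genotype_labels) != 3L || anyDuplicated(genotype_labels))
    .stopf("locus %s: genotype_labels must be 3 distinct labels", locus_id)
  structure(list(locus_id = locus_id, gene = gene,
                 allele_wt = allele_wt, allele_var = allele_var,
                 genotype_labels = genotype_labels),
            class = "locus_def")
}

#' @export
print.locus_def <- function(x, ...) {
  cat(sprintf("<locus_def> %s (%s): %s>%s [%s]\n", x$locus_id, x$gene,
              x$allele_wt, x$allele_var, paste(x$genotype_labels, collapse = ", ")))
  invisible(x)
}

#' Default locus panel: TP53 rs1042522, MDM2 rs2279744/rs3730485, MDM4 rs4245739
#'
#' The shipped orientation encodes the variant allele as Pro, G, D (deletion)
#' and A respectively, matching the genotype rows of the study's association
#' table (for MDM4 the C allele is the current reference, C > A).
#'
#' @return Named list of [locus_def] objects.
#' @export
tp53_axis_loci <- function() {
  defs <- list(
    locus_def("TP53_rs1042522", "TP53", "Arg", "Pro",
              c("Arg/Arg", "Arg/Pro", "Pro/Pro")),
    locus_def("MDM2_rs2279744", "MDM2", "T", "G", c("TT", "TG", "GG")),
    locus_def("MDM2_rs3730485", "MDM2", "I", "D", c("II", "ID", "DD")),
    locus_def("MDM4_rs4245739", "MDM4", "C", "A", c("CC", "AC", "AA"))
  )
  stats::setNames(defs, vapply(defs, `[[`, "", "locus_id"))
}

#' Read a locus configuration file
#'
#' @param path YAML (or JSON) file with one entry per locus; each entry needs
#'   `locus_id`, `gene`, `allele_wt`, `allele_var` and optionally
#'   `genotype_labels`.
#' @return Named list of [locus_def] objects.
#' @export
read_locus_config <- function(path) {
  if (!file.exists(path)) .stopf("locus config not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE) else yaml::read_yaml(path)
  defs <- lapply(raw, function(e) {
    locus_def(e$locus_id, e$gene, e$allele_wt, e$allele_var,
              if (!is.null(e$genotype_labels)) unlist(e$genotype_labels))
  })
  stats::setNames(defs, vapply(defs, `[[`, "", "locus_id"))
}

#' Write a locus configuration file
#'
#' @param loci Named list of [locus_def] objects.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_locus_config <- function(loci, path) {
  yaml::write_yaml(lapply(unname(loci), unclass), path)
  invisible(path)
}

# Parse genotype strings into variant-allele dosage 0/1/2.
# Accepts "Arg/Pro" token form (order-insensitive) and, for single-character
# alleles, the compact two-letter form used in the field's tables ("TG").
# Unparseable entries become NA; the caller counts and reports them.
.parse_genotypes <- function(x, locus) {
  x <- trimws(as.character(x))
  out <- rep(NA_integer_, length(x))
  ok <- !is.na(x) & nzchar(x) & x != "NA"
  if (!any(ok)) return(out)
  toks <- strsplit(x[ok], "/", fixed = TRUE)
  compact <- nchar(locus$allele_wt) == 1L && nchar(locus$allele_var) == 1L
  dose <- vapply(toks, function(tk) {
    if (length(tk) == 1L && compact && nchar(tk) == 2L)
      tk <- c(substr(tk, 1, 1), substr(tk, 2, 2))
    if (length(tk) != 2L) return(NA_integer_)
    tk <- trimws(tk)
    if (!all(tk %in% c(locus$allele_wt, locus$allele_var))) return(NA_integer_)
    sum(tk == locus$allele_var)
  }, integer(1))
  out[ok] <- dose
  out
}

# dosage -> canonical wt-first "a/b" string (round-trip safe); NA -> ""
.format_genotypes <- function(dosage, locus) {
  lab <- c(paste(locus$allele_wt, locus$allele_wt, sep = "/"),
           paste(locus$allele_wt, locus$allele_var, sep = "/"),
           paste(locus$allele_var, locus$allele_var, sep = "/"))
  ifelse(is.na(dosage), "", lab[dosage + 1L])
}
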