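#' Read GWAS summary statistics (PLINK association dialect)
#'
#' Tab-separated with header columns `SNP`, `A1` (effect allele), `A2`,
#' `OR` (or `BETA` for log-scale weights), `P`, optionally `SE`. `OR` is
#' converted to the natural-log scale; a `BETA` column is ingested as-is.
#' Malformed records (non-positive OR, P outside (0, 1], missing fields)
#' are rejected with their line numbers.
#'
#' @param path file path.
#' @return A `sumstats` data frame.
#' @export
read_summary_stats <- function(path) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("SNP", "A1", "A2", "P")
  miss <- setdiff(need, names(d))
  if (length(miss) || !any(c("OR", "BETA") %in% names(d))) {
    stop_param("summary-stat file must have columns SNP/A1/A2/OR (or BETA)/P; missing: ",
               paste(c(miss, if (!any(c("OR", "BETA") %in% names(d))) "OR|BETA"),
                     collapse = ", "))
  }
  lines <- seq_len(nrow(d)) + 1L  # header is line 1
  if ("OR" %in% names(d)) {
    or <- suppressWarnings(as.numeric(d$OR))
    bad <- is.na(or) | or <= 0
    if (any(bad)) {
      stop_param("invalid OR (must be > 0) at line(s): ",
                 paste(utils::head(lines[bad], 5), collapse = ", "))
    }
    log_or <- log(or)
  } else {
    log_or <- suppressWarnings(as.numeric(d$BETA))
    if (anyNA(log_or)) {
      stop_param("invalid BETA at line(s): ",
                 paste(utils::head(lines[is.na(log_or)], 5), collapse = ", "))
    }
  }
  p <- suppressWarnings(as.numeric(d$P))
  bad <- is.na(p) | p <= 0 | p > 1
  if (any(bad)) {
    stop_param("invalid P (must be in (0, 1]) at line(s): ",
               paste(utils::head(lines[bad], 5), collapse = ", "))
  }
  se <- if ("SE" %in% names(d)) suppressWarnings(as.numeric(d$SE)) else NA_real_
  summary_stats(d$SNP, d$A1, d$A2, log_or, se, p)
}

#' Write summary statistics in the PLINK association dialect
#'
#' @param stats a `sumstats` data frame.
#' @param path output path.
#' @export
write_summary_stats <- function(stats, path) {
  stopifnot(inherits(stats, "sumstats"))
  out <- data.frame(SNP = stats$snp_id, A1 = stats$effect_allele,
                    A2 = stats$other_allele,
                    OR = format(exp(stats$log_or), digits = 17),
                    SE = format(stats$se, digits = 17),
                    P = format(stats$p_value, digits = 17))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an additive-dosage genotype matrix (PLINK `.raw`-style)
#'
#' Tab-separated with header `FID`, `IID`, then one column per SNP named
#' `snp_effectallele` (e.g. `rs42_A`); dosages in \{0, 1, 2\} with `NA`
#' for missing. Ragged rows and out-of-range dosages are rejected with
#' line numbers.
#'
#' @param path file path.
#' @return A `geno_matrix`.
#' @export
read_genotypes <- function(path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop_param(sprintf("ragged row at line %d (%d fields, expected %d)",
                       bad, nf[bad], nf[1]))
  }
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("FID", "IID") %in% names(d)[1:2])) {
    stop_param("genotype file must start with FID and IID columns")
  }
  snp_cols <- names(d)[-(1:2)]
  raw <- as.matrix(d[, -(1:2), drop = FALSE])
  chr <- trimws(as.character(raw))
  bad <- which(matrix(!(chr %in% c("0", "1", "2", "NA") | is.na(raw)),
                      nrow(raw), ncol(raw)), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_param(sprintf("dosage outside {0,1,2,NA} at line %d, column %s",
                       bad[1, 1] + 1L, snp_cols[bad[1, 2]]))
  }
  g <- raw
  suppressWarnings(storage.mode(g) <- "double")
  snps <- sub("_[^_]*$", "", snp_cols)
  alleles <- sub("^.*_", "", snp_cols)
  geno_matrix(g, snps, alleles, individual_ids = d$IID)
}

#' Write a genotype matrix in the PLINK `.raw`-style dialect
#'
#' @param genotypes a `geno_matrix`.
#' @param path output path.
#' @export
write_genotypes <- function(genotypes, path) {
  g <- unclass(genotypes)
  out <- data.frame(FID = rownames(g), IID = rownames(g), g,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a phenotype/score table
#'
#' Plain tab-separated tables with a header row; `NA` marks missing.
#'
#' @param x data frame to write.
#' @param path file path.
#' @return `read_table_tsv` returns a data frame.
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
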