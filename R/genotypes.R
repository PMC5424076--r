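#' Construct an additive genotype matrix
#'
#' The package's genotype container is a plain integer matrix of additive
#' effect-allele dosages (0/1/2, `NA` for missing) with individuals in rows
#' and SNPs in columns, carrying the SNP identifiers and their counted
#' (effect) alleles. This mirrors the PLINK `.raw` additive coding, where
#' each column is named `snp_effectallele`.
#'
#' @param x numeric matrix of dosages in \{0, 1, 2, NA\}.
#' @param snp_ids character vector of SNP identifiers, one per column.
#' @param effect_alleles character vector of counted alleles, one per column.
#' @param individual_ids character vector of row identifiers.
#' @return A `geno_matrix`: an integer matrix with `snp_ids` and
#'   `effect_alleles` attributes, rownames = individuals,
#'   colnames = `snp_effectallele`.
#' @export
geno_matrix <- function(x, snp_ids, effect_alleles,
                        individual_ids = rownames(x)) {
  x <- as.matrix(x)
  if (length(snp_ids) != ncol(x) || length(effect_alleles) != ncol(x)) {
    stop_param("`snp_ids` and `effect_alleles` must have one entry per column")
  }
  if (anyDuplicated(snp_ids)) stop_param("SNP ids must be unique")
  bad <- !(x %in% c(0, 1, 2) | is.na(x))
  if (any(bad)) stop_param("genotype dosages must be in {0, 1, 2, NA}")
  storage.mode(x) <- "integer"
  if (is.null(individual_ids)) individual_ids <- paste0("id", seq_len(nrow(x)))
  rownames(x) <- individual_ids
  colnames(x) <- paste0(snp_ids, "_", effect_alleles)
  attr(x, "snp_ids") <- as.character(snp_ids)
  attr(x, "effect_alleles") <- as.character(effect_alleles)
  class(x) <- c("geno_matrix", class(x))
  x
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d individuals x %d SNPs (%.2f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

snp_ids_of <- function(g) attr(g, "snp_ids") %||% colnames(g)
effect_alleles_of <- function(g) {
  attr(g, "effect_alleles") %||% sub("^.*_", "", colnames(g))
}

#' Estimate effect-allele frequencies from a genotype matrix
#'
#' @param g a `geno_matrix`.
#' @return Numeric vector of per-SNP effect-allele frequencies
#'   (missing genotypes excluded).
#' @export
allele_frequencies <- function(g) {
  colMeans(unclass(g), na.rm = TRUE) / 2
}

#' @noRd
subset_geno <- function(g, rows = NULL, cols = NULL) {
  snp <- snp_ids_of(g); ea <- effect_alleles_of(g)
  m <- unclass(g)
  if (!is.null(rows)) m <- m[rows, , drop = FALSE]
  if (!is.null(cols)) { m <- m[, cols, drop = FALSE]; snp <- snp[cols]; ea <- ea[cols] }
  geno_matrix(m, snp, ea, rownames(m))
}
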