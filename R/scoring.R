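#' Construct a summary-statistics table
#'
#' Per-SNP discovery GWAS results: effect/other allele, natural-log odds
#' ratio, its standard error, and the association P-value.
#'
#' @param snp_id,effect_allele,other_allele character vectors.
#' @param log_or,se,p_value numeric vectors; `p_value` in `(0, 1]`,
#'   `log_or` finite, `se` positive (may be `NA` when unknown).
#' @return A `sumstats` data frame.
#' @export
summary_stats <- function(snp_id, effect_allele, other_allele,
                          log_or, se = NA_real_, p_value) {
  if (anyDuplicated(snp_id)) stop_param("SNP ids must be unique")
  if (any(!is.finite(log_or))) stop_param("log_or must be finite")
  if (any(!is.finite(p_value) | p_value <= 0 | p_value > 1)) {
    stop_param("p_value must lie in (0, 1]")
  }
  out <- data.frame(snp_id = as.character(snp_id),
                    effect_allele = toupper(effect_allele),
                    other_allele = toupper(other_allele),
                    log_or = as.numeric(log_or),
                    se = as.numeric(se),
                    p_value = as.numeric(p_value),
                    stringsAsFactors = FALSE)
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Greedy sliding-window LD pruning
#'
#' Selects SNPs in approximate linkage equilibrium: within each sliding
#' window, a SNP whose squared Pearson genotype correlation with any
#' earlier retained SNP in the window reaches `r2_threshold` is dropped.
#' Deterministic given the input column order (PLINK
#' `--indep-pairwise`-style). Monomorphic SNPs have undefined correlation
#' and are retained by convention (reported in the `monomorphic`
#' attribute).
#'
#' @param genotypes a `geno_matrix` (the target-cohort genotypes).
#' @param r2_threshold prune at squared correlation >= this, in `(0, 1]`.
#' @param window_size window width in SNPs (>= 2).
#' @param step window shift in SNPs.
#' @return Character vector of retained SNP ids, with attribute
#'   `monomorphic` listing SNPs kept by convention.
#' @export
ld_prune <- function(genotypes, r2_threshold = 0.25, window_size = 50L,
                     step = 5L) {
  check_fraction(r2_threshold, "r2_threshold", 0, 1 + 1e-12)
  window_size <- check_count(window_size, "window_size", min = 2L)
  step <- check_count(step, "step", min = 1L)
  g <- unclass(genotypes)
  snps <- snp_ids_of(genotypes)
  m <- ncol(g)
  sds <- apply(g, 2L, stats::sd, na.rm = TRUE)
  mono <- which(is.na(sds) | sds == 0)
  keep <- rep(TRUE, m)
  starts <- unique(c(seq(1L, max(1L, m - 1L), by = step)))
  for (s in starts) {
    win <- s:min(m, s + window_size - 1L)
    win <- win[keep[win]]
    if (length(win) < 2L) next
    polym <- setdiff(win, mono)
    if (length(polym) < 2L) next
    cc <- suppressWarnings(stats::cor(g[, polym, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    for (j in seq_along(polym)[-1L]) {
      earlier <- which(keep[polym][seq_len(j - 1L)])
      if (!length(earlier)) next
      if (any(cc[earlier, j]^2 >= r2_threshold, na.rm = TRUE)) {
        keep[polym[j]] <- FALSE
      }
    }
  }
  out <- snps[keep]
  attr(out, "monomorphic") <- snps[mono]
  out
}

#' Select scoring weights by P-value threshold
#'
#' Keeps SNPs with discovery `p_value < p_threshold` (strict inequality),
#' optionally dropping strand-ambiguous A/T and C/G SNPs, and orients each
#' weight to its risk allele: SNPs with a negative log odds ratio are
#' flipped so the counted allele is the one more common in cases than
#' controls, leaving every weight positive. (Score rankings are unchanged
#' by orientation; standardization absorbs the constant offsets.)
#'
#' @param stats a `sumstats` table.
#' @param p_threshold inclusion threshold in `(0, 1]` (default 0.5).
#' @param drop_ambiguous drop A/T and C/G SNPs? Default `TRUE`.
#' @param orient_to_risk flip alleles so weights are positive? Default
#'   `TRUE`.
#' @param keep_snps optional character vector (e.g. from [ld_prune()]);
#'   only these SNPs are eligible.
#' @return A `scoring_weights` data frame (`snp_id`, `effect_allele`,
#'   `other_allele`, `weight`) with attributes `threshold_used` and
#'   `n_selected`.
#' @export
select_weights <- function(stats, p_threshold = 0.5, drop_ambiguous = TRUE,
                           orient_to_risk = TRUE, keep_snps = NULL) {
  stopifnot(inherits(stats, "sumstats"))
  check_fraction(p_threshold, "p_threshold", 0, 1 + 1e-12)
  sel <- stats$p_value < p_threshold
  if (drop_ambiguous) {
    sel <- sel & !is_ambiguous_pair(stats$effect_allele, stats$other_allele)
  }
  if (!is.null(keep_snps)) sel <- sel & stats$snp_id %in% keep_snps
  w <- stats[sel, , drop = FALSE]
  weight <- w$log_or
  ea <- w$effect_allele; oa <- w$other_allele
  if (orient_to_risk) {
    flip <- weight < 0
    tmp <- ea[flip]; ea[flip] <- oa[flip]; oa[flip] <- tmp
    weight[flip] <- -weight[flip]
  }
  out <- data.frame(snp_id = w$snp_id, effect_allele = ea, other_allele = oa,
                    weight = weight, stringsAsFactors = FALSE)
  attr(out, "threshold_used") <- p_threshold
  attr(out, "n_selected") <- nrow(out)
  class(out) <- c("scoring_weights", "data.frame")
  out
}

#' Compute polygenic risk scores
#'
#' The raw score of individual i is the weighted mean number of score
#' alleles, `sum_j w_j * g_ij / M_i`, with weights the (log odds ratio)
#' scoring weights and `g_ij` the dosage of the weight's effect allele.
#' Genotype columns counted on the opposite allele are flipped
#' (`g -> 2 - g`) during alignment. Under the `"skip"` missing policy
#' `M_i` is the number of SNPs observed for individual i; under
#' `"impute_mean"` every selected SNP contributes, with missing dosages
#' replaced by twice the sample allele frequency.
#'
#' @param genotypes a `geno_matrix`.
#' @param weights a `scoring_weights` table; every weight SNP must be
#'   present in the genotype matrix with a matching allele pair.
#' @param missing_policy `"skip"` (default) or `"impute_mean"`.
#' @return A `score_set` data frame: `individual_id`, `raw_score`,
#'   `n_snps_used`, `std_score` (`NA` until [standardize_scores()]).
#'   Individuals with no usable SNP get `NA` with a warning.
#' @export
compute_scores <- function(genotypes, weights,
                           missing_policy = c("skip", "impute_mean")) {
  stopifnot(inherits(weights, "scoring_weights"))
  missing_policy <- match.arg(missing_policy)
  snps <- snp_ids_of(genotypes)
  eas <- effect_alleles_of(genotypes)
  idx <- match(weights$snp_id, snps)
  if (anyNA(idx)) {
    stop_param(sprintf("%d weight SNPs absent from the genotype matrix (first: %s)",
                       sum(is.na(idx)), weights$snp_id[which(is.na(idx))[1]]))
  }
  g <- unclass(genotypes)[, idx, drop = FALSE]
  storage.mode(g) <- "double"
  geno_allele <- eas[idx]
  same <- geno_allele == weights$effect_allele
  flip <- geno_allele == weights$other_allele
  if (any(!same & !flip)) {
    bad <- weights$snp_id[which(!same & !flip)[1]]
    stop_param(sprintf("allele mismatch between weights and genotypes (first: %s)", bad))
  }
  g[, flip] <- 2 - g[, flip, drop = FALSE]
  w <- weights$weight

  obs <- !is.na(g)
  if (missing_policy == "impute_mean") {
    freq <- colMeans(g, na.rm = TRUE) / 2
    for (j in which(colSums(!obs) > 0)) g[!obs[, j], j] <- 2 * freq[j]
    m_used <- rep.int(ncol(g), nrow(g))
    num <- as.vector(g %*% w)
  } else {
    g0 <- g; g0[!obs] <- 0
    num <- as.vector(g0 %*% w)
    m_used <- rowSums(obs)
  }
  raw <- num / m_used
  none <- m_used == 0
  if (any(none)) {
    raw[none] <- NA_real_
    warning(sprintf("%d individual(s) had no usable score SNPs; score set to NA",
                    sum(none)), call. = FALSE)
  }
  out <- data.frame(individual_id = rownames(genotypes) %||%
                      paste0("id", seq_len(nrow(g))),
                    raw_score = raw,
                    n_snps_used = as.integer(m_used),
                    std_score = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_set", "data.frame")
  out
}

#' Standardize polygenic scores within the analysis sample
#'
#' Fills `std_score = (raw - mean) / sd` using the sample's own mean and
#' SD (denominator n - 1). Individuals with missing raw scores stay
#' missing and are excluded from the mean/SD.
#'
#' @param scores a `score_set`.
#' @return The `score_set` with `std_score` filled.
#' @export
standardize_scores <- function(scores) {
  stopifnot(inherits(scores, "score_set"))
  x <- scores$raw_score
  ok <- !is.na(x)
  if (sum(ok) < 2L) stop_param("need >= 2 defined raw scores to standardize")
  s <- stats::sd(x[ok])
  if (s == 0) stop_param("raw scores have zero variance; cannot standardize")
  scores$std_score <- (x - mean(x[ok])) / s
  scores
}

#' Method-of-moments relatedness (pi-hat) between two cohorts
#'
#' Estimates the genome-wide relationship coefficient for each
#' cross-cohort pair from standardized genotypes given allele frequencies:
#' `pi_hat = mean_j [(g_aj - 2p_j)(g_bj - 2p_j) / (2 p_j (1 - p_j))]`.
#' Expectation ~1 for self-pairs, 0.5 for parent-offspring, 0 for
#' unrelated pairs. Pairs at or above the threshold (default 12.5%,
#' third-degree relatives) are flagged for removal.
#'
#' @param genotypes_a,genotypes_b `geno_matrix` objects sharing SNPs
#'   (matched by SNP id; allele flips handled).
#' @param pi_hat_threshold flagging threshold (default 0.125).
#' @param freqs optional numeric vector of effect-allele frequencies for
#'   the shared SNPs (in `genotypes_a`'s allele orientation); estimated
#'   from the pooled samples when `NULL`.
#' @return Data frame `id_a`, `id_b`, `pi_hat`, `flagged`, one row per
#'   cross pair.
#' @export
relatedness_filter <- function(genotypes_a, genotypes_b,
                               pi_hat_threshold = 0.125, freqs = NULL) {
  snps_a <- snp_ids_of(genotypes_a); snps_b <- snp_ids_of(genotypes_b)
  shared <- intersect(snps_a, snps_b)
  if (!length(shared)) stop_param("no shared SNPs between the cohorts")
  if (length(shared) < 100L) {
    warning(sprintf("only %d shared SNPs; pi-hat estimates are unstable",
                    length(shared)), call. = FALSE)
  }
  ia <- match(shared, snps_a); ib <- match(shared, snps_b)
  ga <- unclass(genotypes_a)[, ia, drop = FALSE]
  gb <- unclass(genotypes_b)[, ib, drop = FALSE]
  storage.mode(ga) <- "double"; storage.mode(gb) <- "double"
  ea <- effect_alleles_of(genotypes_a)[ia]
  eb <- effect_alleles_of(genotypes_b)[ib]
  flip <- eb != ea
  gb[, flip] <- 2 - gb[, flip, drop = FALSE]
  if (is.null(freqs)) {
    freqs <- colMeans(rbind(ga, gb), na.rm = TRUE) / 2
  }
  ok <- freqs > 0 & freqs < 1
  ga <- ga[, ok, drop = FALSE]; gb <- gb[, ok, drop = FALSE]
  p2 <- 2 * freqs[ok]; den <- sqrt(p2 * (1 - freqs[ok]))
  za <- sweep(sweep(ga, 2L, p2, "-"), 2L, den, "/")
  zb <- sweep(sweep(gb, 2L, p2, "-"), 2L, den, "/")
  za[is.na(za)] <- 0; zb[is.na(zb)] <- 0
  k <- tcrossprod(za, zb) / ncol(za)
  out <- data.frame(id_a = rep(rownames(ga) %||% seq_len(nrow(ga)), times = nrow(gb)),
                    id_b = rep(rownames(gb) %||% seq_len(nrow(gb)), each = nrow(ga)),
                    pi_hat = as.vector(k),
                    stringsAsFactors = FALSE)
  out$flagged <- out$pi_hat >= pi_hat_threshold
  out
}
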