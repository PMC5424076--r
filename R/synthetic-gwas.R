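#' Specify a polygenic case-control architecture
#'
#' Describes the generative model for the discovery sample: a
#' liability-threshold model in which `n_causal` SNPs carry standardized
#' liability effects summing to `h2_liability` of the liability variance,
#' disease status is liability above the prevalence-determined threshold,
#' and cases/controls are ascertained to fixed counts. Defaults follow the
#' clinical ADHD discovery design of 727 cases and 5081 population controls
#' with an assumed population prevalence of 5%.
#'
#' @param n_causal number of causal SNPs.
#' @param h2_liability liability-scale heritability in `[0, 1)`.
#' @param prevalence population prevalence in `(0, 1)`.
#' @param n_cases,n_controls ascertained sample sizes.
#' @param seed integer seed for the GWAS substream.
#' @return An `architecture_spec` list.
#' @export
architecture_spec <- function(n_causal = 200L, h2_liability = 0.3,
                              prevalence = 0.05,
                              n_cases = 727L, n_controls = 5081L,
                              seed = 1L) {
  check_fraction(prevalence, "prevalence")
  if (!(is.numeric(h2_liability) && h2_liability >= 0 && h2_liability < 1)) {
    stop_param("`h2_liability` must be in [0, 1)")
  }
  n_causal <- check_count(n_causal, "n_causal", min = 0L)
  structure(list(n_causal = n_causal, h2_liability = h2_liability,
                 prevalence = prevalence,
                 n_cases = check_count(n_cases, "n_cases"),
                 n_controls = check_count(n_controls, "n_controls"),
                 seed = as.integer(seed)),
            class = "architecture_spec")
}

#' Simulate a case-control discovery GWAS
#'
#' Draws cases and controls under the liability-threshold model and runs a
#' per-SNP 2x2 allele-count association test, returning PLINK-style summary
#' statistics (log odds ratio, SE, Wald P). Causal SNPs receive Gaussian
#' liability effects on the standardized genotype scale, rescaled so their
#' variance contribution equals `h2_liability`; residual liability is
#' standard normal. Individuals are simulated in batches and kept until the
#' requested numbers of cases and controls are reached, so memory stays
#' bounded for large panels.
#'
#' Cells with zero allele counts get the Haldane-Anscombe 0.5 correction
#' and are flagged in the `continuity_corrected` column.
#'
#' @param freqs an `allele_freq_set`.
#' @param spec an `architecture_spec`.
#' @param keep_genotypes keep a subsample of case/control genotypes (for
#'   cross-cohort relatedness checks)? Default `FALSE`.
#' @param keep_max maximum individuals retained when `keep_genotypes`.
#' @param batch_size individuals simulated per batch.
#' @return A `sumstats` data frame (see [summary_stats()]) with extra
#'   columns `causal` and `true_beta` recording the generative truth, and,
#'   if requested, a `genotypes` attribute.
#' @export
simulate_discovery_gwas <- function(freqs, spec = architecture_spec(),
                                    keep_genotypes = FALSE,
                                    keep_max = 200L,
                                    batch_size = 2000L) {
  stopifnot(inherits(freqs, "allele_freq_set"), inherits(spec, "architecture_spec"))
  m <- length(freqs$snp_ids)
  if (m < 1L) stop_param("`freqs` is empty")
  if (spec$n_causal > m) stop_param("n_causal exceeds the number of SNPs")
  set.seed(spec$seed)
  p <- freqs$effect_allele_freq

  beta <- numeric(m)
  causal <- rep(FALSE, m)
  if (spec$n_causal > 0L && spec$h2_liability > 0) {
    idx <- sample.int(m, spec$n_causal)
    b <- stats::rnorm(spec$n_causal)
    b <- b * sqrt(spec$h2_liability / sum(b^2))
    beta[idx] <- b
    causal[idx] <- TRUE
  }
  thresh <- stats::qnorm(1 - spec$prevalence)
  sd_env <- sqrt(1 - spec$h2_liability)
  denom <- sqrt(2 * p * (1 - p))

  # accumulate effect-allele counts among cases and controls
  case_counts <- numeric(m); ctrl_counts <- numeric(m)
  n_case <- 0L; n_ctrl <- 0L
  kept <- list(); kept_status <- integer(0)
  while (n_case < spec$n_cases || n_ctrl < spec$n_controls) {
    g <- draw_hw_genotypes(freqs, batch_size)
    z <- sweep(sweep(g, 2L, 2 * p, "-"), 2L, denom, "/")
    liab <- as.vector(z %*% beta) + stats::rnorm(batch_size, sd = sd_env)
    is_case <- liab > thresh
    take_case <- which(is_case)[seq_len(min(sum(is_case), spec$n_cases - n_case))]
    take_ctrl <- which(!is_case)[seq_len(min(sum(!is_case), spec$n_controls - n_ctrl))]
    if (length(take_case)) {
      case_counts <- case_counts + colSums(g[take_case, , drop = FALSE])
      n_case <- n_case + length(take_case)
    }
    if (length(take_ctrl)) {
      ctrl_counts <- ctrl_counts + colSums(g[take_ctrl, , drop = FALSE])
      n_ctrl <- n_ctrl + length(take_ctrl)
    }
    if (keep_genotypes && length(kept_status) < keep_max) {
      room <- keep_max - length(kept_status)
      take <- c(take_case, take_ctrl)[seq_len(min(room, length(take_case) + length(take_ctrl)))]
      if (length(take)) {
        kept[[length(kept) + 1L]] <- g[take, , drop = FALSE]
        kept_status <- c(kept_status, as.integer(is_case[take]))
      }
    }
  }

  # 2x2 allele-count table per SNP: effect/other allele in cases/controls
  a <- case_counts;                    b2 <- 2 * spec$n_cases - case_counts
  c2 <- ctrl_counts;                   d <- 2 * spec$n_controls - ctrl_counts
  corrected <- (a == 0) | (b2 == 0) | (c2 == 0) | (d == 0)
  a[corrected] <- a[corrected] + 0.5; b2[corrected] <- b2[corrected] + 0.5
  c2[corrected] <- c2[corrected] + 0.5; d[corrected] <- d[corrected] + 0.5
  log_or <- log(a * d / (b2 * c2))
  se <- sqrt(1 / a + 1 / b2 + 1 / c2 + 1 / d)
  pval <- 2 * stats::pnorm(-abs(log_or / se))
  pval <- pmax(pval, .Machine$double.xmin)  # keep inside (0, 1]

  out <- summary_stats(snp_id = freqs$snp_ids,
                       effect_allele = freqs$effect_allele,
                       other_allele = freqs$other_allele,
                       log_or = log_or, se = se, p_value = pval)
  out$continuity_corrected <- corrected
  out$causal <- causal
  out$true_beta <- beta
  if (keep_genotypes) {
    gm <- do.call(rbind, kept)
    rownames(gm) <- sprintf("disc%d", seq_len(nrow(gm)))
    attr(out, "genotypes") <- geno_matrix(gm, freqs$snp_ids, freqs$effect_allele)
    attr(out, "genotype_status") <- kept_status
  }
  out
}
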