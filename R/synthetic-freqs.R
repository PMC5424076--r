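#' Simulate effect-allele frequencies
#'
#' Draws per-SNP effect-allele frequencies uniformly on
#' `[freq_low, freq_high]`, the substrate for the discovery GWAS and the
#' target-cohort duo simulation. Optionally assigns SNPs to LD blocks,
#' used only by the block-LD genotype mode that exercises pruning.
#'
#' @param n_snps number of SNPs.
#' @param freq_low,freq_high frequency bounds, `0 < freq_low < freq_high < 1`.
#' @param seed integer seed.
#' @param ld_block_size if `> 1`, consecutive SNPs are grouped into blocks
#'   of this size and the block label recorded.
#' @return An `allele_freq_set`: list with `snp_ids`, `effect_allele_freq`,
#'   and `ld_block` (`NULL` when no blocks were assigned).
#' @export
simulate_allele_freqs <- function(n_snps, freq_low = 0.05, freq_high = 0.95,
                                  seed = 1L, ld_block_size = 1L) {
  n_snps <- check_count(n_snps, "n_snps")
  if (!(is.numeric(freq_low) && is.numeric(freq_high) &&
        freq_low > 0 && freq_high < 1 && freq_low < freq_high)) {
    stop_param("require 0 < freq_low < freq_high < 1")
  }
  set.seed(seed)
  f <- stats::runif(n_snps, freq_low, freq_high)
  blocks <- NULL
  if (ld_block_size > 1L) {
    blocks <- rep(seq_len(ceiling(n_snps / ld_block_size)),
                  each = ld_block_size)[seq_len(n_snps)]
    # a block shares one frequency so the copy-model LD is well defined
    f <- f[!duplicated(blocks)][blocks]
  }
  al <- random_allele_pairs(n_snps)
  structure(list(snp_ids = sprintf("rs%d", seq_len(n_snps)),
                 effect_allele_freq = f,
                 effect_allele = al$a1, other_allele = al$a2,
                 ld_block = blocks),
            class = "allele_freq_set")
}

#' @export
print.allele_freq_set <- function(x, ...) {
  cat(sprintf("<allele_freq_set> %d SNPs, freq range [%.3f, %.3f]%s\n",
              length(x$snp_ids), min(x$effect_allele_freq),
              max(x$effect_allele_freq),
              if (is.null(x$ld_block)) "" else
                sprintf(", %d LD blocks", length(unique(x$ld_block)))))
  invisible(x)
}

#' Draw Hardy-Weinberg genotypes, optionally with block LD
#'
#' Independent SNPs are binomial(2, p). In block-LD mode haplotypes within
#' a block copy the block's first SNP with probability `ld_r`, giving an
#' anchor-member genotype correlation of `ld_r` (member-member `ld_r^2`);
#' this is a pruning exercise, not a model of real LD.
#'
#' @param freqs an `allele_freq_set`.
#' @param n number of individuals.
#' @param ld_r within-block haplotype copy probability.
#' @return Integer matrix `n x n_snps` of dosages.
#' @keywords internal
draw_hw_genotypes <- function(freqs, n, ld_r = 0.6) {
  p <- freqs$effect_allele_freq
  m <- length(p)
  if (is.null(freqs$ld_block)) {
    h1 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
    h2 <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
    return(h1 + h2)
  }
  blocks <- freqs$ld_block
  draw_hap <- function() {
    h <- matrix(stats::rbinom(n * m, 1L, rep(p, each = n)), n, m)
    anchor <- !duplicated(blocks)
    anchor_col <- match(blocks, blocks[anchor])
    anchor_idx <- which(anchor)[anchor_col]
    copy <- matrix(stats::runif(n * m) < ld_r, n, m)
    copy[, anchor] <- FALSE
    h[copy] <- h[, anchor_idx, drop = FALSE][copy]
    h
  }
  draw_hap() + draw_hap()
}
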