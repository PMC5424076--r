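# shared fixture builders; everything is generated in code at test time

# tiny genotype matrix from explicit dosage columns
make_geno <- function(..., snp_ids = NULL, effect_alleles = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  k <- ncol(m)
  geno_matrix(m,
              snp_ids = snp_ids %||% sprintf("rs%d", seq_len(k)),
              effect_alleles = effect_alleles %||% rep("A", k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# score_set wrapper around an explicit standardized vector
make_score_set <- function(ids, z) {
  out <- data.frame(individual_id = ids, raw_score = z,
                    n_snps_used = 1L, std_score = as.vector(scale(z)),
                    stringsAsFactors = FALSE)
  class(out) <- c("score_set", "data.frame")
  out
}

# small phenotype dataset from the preset path equations, driven by
# simulated duos so sex and scores flow through package code
quick_mediation_data <- function(n, preset = mediation_preset(), seed = 1L) {
  freqs <- simulate_allele_freqs(2, seed = seed)
  duos <- simulate_duos(freqs, n, seed = seed, p_male = preset$p_male)
  set.seed(seed + 7L)
  sc <- make_score_set(rownames(duos$children), stats::rnorm(n))
  sm <- make_score_set(rownames(duos$mothers), stats::rnorm(n))
  simulate_phenotypes(duos, sc, sm, preset, seed = seed + 13L)
}

subset_geno_cols <- function(g, cols) prsmediate:::subset_geno(g, cols = cols)

# null preset: no genetic paths anywhere
null_preset <- function() {
  mediation_preset(total_effect_gcse = 0, total_effect_ks3 = 0,
                   path_a_iq = 0, path_a_adhd = 0,
                   indirect_iq = 0, indirect_adhd = 0,
                   mediator_residual_cor = 0,
                   ks5_log_or = 0, mother_iq_beta = 0, mother_edu_beta = 0)
}
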