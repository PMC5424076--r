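# synthetic-data module: allele frequencies, discovery GWAS, duos, phenotypes

test_that("simulate_allele_freqs respects bounds and is seed-deterministic", {
  f <- simulate_allele_freqs(5000, 0.05, 0.95, seed = 1)
  expect_length(f$effect_allele_freq, 5000)
  expect_true(all(f$effect_allele_freq >= 0.05 & f$effect_allele_freq <= 0.95))
  expect_false(anyDuplicated(f$snp_ids) > 0)

  f1 <- simulate_allele_freqs(1, 0.49, 0.51, seed = 7)
  expect_lt(abs(f1$effect_allele_freq - 0.5), 0.01)

  # Monte-Carlo mean of Uniform(0.05, 0.95); oracle = direct averaging
  f2 <- simulate_allele_freqs(10000, 0.05, 0.95, seed = 2)
  expect_equal(mean(f2$effect_allele_freq), 0.50, tolerance = 0.01)

  expect_identical(simulate_allele_freqs(100, seed = 3),
                   simulate_allele_freqs(100, seed = 3))
  expect_error(simulate_allele_freqs(10, 0.9, 0.1), "freq_low")
})

test_that("null-architecture GWAS is calibrated and effect-free", {
  freqs <- simulate_allele_freqs(2000, seed = 5)
  spec <- architecture_spec(n_causal = 0, h2_liability = 0,
                            n_cases = 300, n_controls = 1000, seed = 5)
  ss <- simulate_discovery_gwas(freqs, spec)
  # type-I error of the allele-count test at alpha = 0.05
  expect_gt(mean(ss$p_value < 0.05), 0.03)
  expect_lt(mean(ss$p_value < 0.05), 0.07)
  expect_true(all(ss$true_beta == 0))
  expect_equal(mean(ss$log_or), 0, tolerance = 0.01)
})

test_that("null-architecture GWAS P-values are ~Uniform(0,1) across seeds", {
  freqs <- simulate_allele_freqs(500, seed = 2)
  pass <- vapply(1:10, function(s) {
    ss <- simulate_discovery_gwas(freqs, architecture_spec(
      n_causal = 0, h2_liability = 0, n_cases = 200, n_controls = 600,
      seed = s))
    suppressWarnings(stats::ks.test(ss$p_value, "punif")$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 9)
})

test_that("causal SNPs' estimated log OR tracks the generative effect sign", {
  freqs <- simulate_allele_freqs(2000, seed = 3)
  spec <- architecture_spec(n_causal = 200, h2_liability = 0.3,
                            prevalence = 0.05, n_cases = 727,
                            n_controls = 5081, seed = 3)
  ss <- simulate_discovery_gwas(freqs, spec)
  expect_equal(sum(ss$causal), 200)
  conc <- mean(sign(ss$log_or[ss$causal]) == sign(ss$true_beta[ss$causal]))
  expect_gt(conc, 0.5)
})

test_that("duo simulation is Mendelian-consistent with ~0.5 transmission correlation", {
  freqs <- simulate_allele_freqs(2000, seed = 4)
  duos <- simulate_duos(freqs, 1000, seed = 4)
  expect_true(check_mendelian(duos))

  gm <- unclass(duos$mothers); gc <- unclass(duos$children)
  # mother homozygous 0 forces child into {0, 1}
  expect_true(all(gc[gm == 0L] %in% c(0L, 1L)))
  # parent-offspring additive correlation 1/2 under random mating
  r <- vapply(seq_len(ncol(gm)), function(j) stats::cor(gm[, j], gc[, j]),
              numeric(1))
  expect_equal(mean(r), 0.5, tolerance = 0.02)
  # transmission preserves allele frequency
  expect_equal(mean(allele_frequencies(duos$children) -
                      allele_frequencies(duos$mothers)), 0, tolerance = 0.005)

  # tampering is caught (pick a homozygous mother so the violation is forced)
  hom <- which(gm != 1L, arr.ind = TRUE)[1, ]
  duos$children[hom[1], hom[2]] <- 2L - gm[hom[1], hom[2]]
  expect_error(check_mendelian(duos), "Mendelian")
})

test_that("mother-child standardized score correlation is ~0.5 with many SNPs", {
  co <- simulate_cohort(2000, n_snps = 2000, seed = 6,
                        architecture = architecture_spec(
                          n_cases = 300, n_controls = 1000))
  r <- stats::cor(co$scores_child$std_score, co$scores_mother$std_score)
  expect_gte(r, 0.46)
  expect_lte(r, 0.54)
})

test_that("mediation preset enforces the linear path identity by construction", {
  p <- mediation_preset()
  expect_equal(implied_total_effect(p, "gcse"),
               p$path_c_direct + p$path_a_iq * p$path_b_iq +
                 p$path_a_adhd * p$path_b_adhd)
  expect_equal(implied_total_effect(p, "gcse"), -4.0)
  expect_equal(implied_total_effect(p, "ks3"), -1.4)
  # two-mediator indirects match the stated decomposition
  expect_equal(p$path_a_iq * p$path_b_iq + p$path_a_adhd * p$path_b_adhd,
               -2.5)
  expect_error(mediation_preset(gcse_sd = 5), "SD too small")
  expect_warning(mediation_preset(gcse_mean = 500), "clipping range")
})

test_that("null preset produces no PRS-outcome association", {
  ph <- quick_mediation_data(3000, null_preset(), seed = 8)
  fit <- summary(stats::lm(gcse ~ prs_child + sex, ph))$coefficients
  expect_lt(abs(fit["prs_child", 1]), 2 * fit["prs_child", 2])
})

test_that("calibrated preset reproduces the cohort phenotype moments", {
  ph <- quick_mediation_data(7000, seed = 9)
  expect_equal(mean(ph$gcse), 328.2, tolerance = 0.02 * 328.2)
  expect_equal(stats::sd(ph$gcse), 89.9, tolerance = 0.05 * 89.9)
  ph2 <- quick_mediation_data(5000, seed = 10)
  expect_equal(mean(ph2$iq), 91.9, tolerance = 0.02 * 91.9)
  expect_equal(stats::sd(ph2$iq), 13, tolerance = 0.02 * 13)
  # clipping is reported and bounds respected
  expect_named(attr(ph, "clipping"), c("ks3", "gcse"))
  expect_true(all(ph$gcse >= 0 & ph$gcse <= 483))
  expect_true(all(ph$ks3 >= 0 & ph$ks3 <= 141))
  expect_true(all(ph$mother_education %in% 1:5))
  expect_true(all(ph$ks5_sat %in% 0:1))
})

test_that("block-LD mode induces within-block correlation for pruning to find", {
  freqs <- simulate_allele_freqs(50, seed = 11, ld_block_size = 10)
  set.seed(11)
  g <- prsmediate:::draw_hw_genotypes(freqs, 1500, ld_r = 0.6)
  # anchor-member correlation ~ld_r within the first block
  r1 <- stats::cor(g[, 1], g[, 2])
  expect_gt(r1, 0.4)
  # across blocks independent
  expect_lt(abs(stats::cor(g[, 1], g[, 11])), 0.15)
})
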