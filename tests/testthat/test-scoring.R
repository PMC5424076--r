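# scoring module: pruning, weight selection, score computation, relatedness

test_that("ld_prune drops duplicated columns and keeps independent ones", {
  set.seed(1)
  x <- rbinom(500, 2, 0.4)
  g <- make_geno(x, x, rbinom(500, 2, 0.3))
  kept <- ld_prune(g, r2_threshold = 0.25)
  expect_true("rs1" %in% kept)
  expect_false("rs2" %in% kept)

  # mutually independent SNPs rarely reach r2 = 0.25 at n = 500
  gi <- geno_matrix(matrix(rbinom(500 * 100, 2, 0.5), 500, 100),
                    sprintf("rs%d", 1:100), rep("A", 100))
  kept_i <- ld_prune(gi, r2_threshold = 0.25)
  expect_gte(length(kept_i), 95)

  # threshold 1 never met by distinct non-identical columns
  kept_all <- ld_prune(gi, r2_threshold = 1.0)
  expect_length(kept_all, 100)

  # idempotence: pruning the pruned set changes nothing
  gp <- geno_matrix(unclass(gi)[, match(kept_i, attr(gi, "snp_ids")), drop = FALSE],
                    kept_i, rep("A", length(kept_i)))
  expect_identical(as.character(ld_prune(gp, 0.25)), as.character(kept_i))

  # monomorphic SNPs are retained by convention and reported
  gm <- make_geno(rep(1L, 500), rbinom(500, 2, 0.5))
  km <- ld_prune(gm, 0.25)
  expect_true("rs1" %in% km)
  expect_identical(attr(km, "monomorphic"), "rs1")
})

test_that("select_weights applies a strict threshold and handles ambiguity", {
  ss <- summary_stats(c("a", "b", "c"), c("A", "A", "A"), c("C", "C", "C"),
                      log_or = c(0.1, 0.2, 0.3), p_value = c(0.2, 0.5, 0.7))
  w <- select_weights(ss, 0.5)
  expect_identical(w$snp_id, "a")

  w_all <- select_weights(ss, 1.0, drop_ambiguous = FALSE)
  expect_equal(nrow(w_all), 3)

  # monotone in the threshold
  ns <- vapply(c(0.1, 0.5, 1.0), function(t) nrow(select_weights(ss, t)),
               numeric(1))
  expect_true(all(diff(ns) >= 0))

  # A/T and C/G SNPs dropped by default
  amb <- summary_stats(c("x", "y"), c("A", "A"), c("T", "C"),
                       log_or = c(0.5, 0.5), p_value = c(0.01, 0.01))
  expect_identical(select_weights(amb, 0.5)$snp_id, "y")
  expect_equal(nrow(select_weights(amb, 0.5, drop_ambiguous = FALSE)), 2)

  # risk-allele orientation flips negative weights
  neg <- summary_stats("z", "A", "G", log_or = -0.4, p_value = 0.1)
  wo <- select_weights(neg, 0.5)
  expect_equal(wo$weight, 0.4)
  expect_identical(wo$effect_allele, "G")
})

test_that("compute_scores matches hand-computed weighted means", {
  # one SNP, OR = 2, genotype 2 -> 2 ln 2
  w1 <- select_weights(summary_stats("rs1", "A", "G", log(2), p_value = 0.1), 1)
  g1 <- make_geno(c(2L, 0L))
  s1 <- compute_scores(g1, w1)
  expect_equal(s1$raw_score, c(2 * log(2), 0), tolerance = 1e-12)

  # two SNPs w = (ln 2, ln 1.5), genotypes (1, 2) -> 0.7520
  w2 <- select_weights(summary_stats(c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                                     c(log(2), log(1.5)), p_value = c(0.1, 0.1)), 1)
  g2 <- make_geno(1L, 2L)
  expect_equal(compute_scores(g2, w2)$raw_score,
               (log(2) * 1 + log(1.5) * 2) / 2, tolerance = 1e-12)
  expect_equal(compute_scores(g2, w2)$raw_score, 0.7520, tolerance = 1e-4)
})

test_that("scoring is linear in the weights and allele-flip invariant", {
  set.seed(2)
  g <- geno_matrix(matrix(rbinom(50 * 20, 2, 0.4), 50, 20),
                   sprintf("rs%d", 1:20),
                   sample(c("A", "G"), 20, replace = TRUE))
  ss <- summary_stats(sprintf("rs%d", 1:20),
                      attr(g, "effect_alleles"),
                      ifelse(attr(g, "effect_alleles") == "A", "G", "A"),
                      log_or = rnorm(20, 0, 0.2),
                      p_value = runif(20))
  w <- select_weights(ss, 1.0, orient_to_risk = FALSE)
  s <- standardize_scores(compute_scores(g, w))

  # linearity: weights scaled by k scale raw scores by k, std unchanged
  w3 <- w; w3$weight <- 3 * w$weight
  s3 <- standardize_scores(compute_scores(g, w3))
  expect_equal(s3$raw_score, 3 * s$raw_score, tolerance = 1e-12)
  expect_equal(s3$std_score, s$std_score, tolerance = 1e-10)

  # allele flip: recode one SNP to the other allele, negate its weight
  wf <- w
  wf$effect_allele[1] <- w$other_allele[1]
  wf$other_allele[1] <- w$effect_allele[1]
  wf$weight[1] <- -w$weight[1]
  sf <- standardize_scores(compute_scores(g, wf))
  expect_equal(sf$std_score, s$std_score, tolerance = 1e-10)
})

test_that("missing-genotype policies agree on complete data and differ sensibly", {
  set.seed(3)
  m <- matrix(rbinom(40 * 10, 2, 0.5), 40, 10)
  g <- geno_matrix(m, sprintf("rs%d", 1:10), rep("A", 10))
  ss <- summary_stats(sprintf("rs%d", 1:10), rep("A", 10), rep("G", 10),
                      log_or = runif(10, 0.05, 0.4), p_value = runif(10))
  w <- select_weights(ss, 1.0)
  expect_equal(compute_scores(g, w, "skip")$raw_score,
               compute_scores(g, w, "impute_mean")$raw_score, tolerance = 1e-12)

  m2 <- m; m2[1, 1] <- NA
  g2 <- geno_matrix(m2, sprintf("rs%d", 1:10), rep("A", 10))
  sk <- compute_scores(g2, w, "skip")
  im <- compute_scores(g2, w, "impute_mean")
  expect_equal(sk$n_snps_used[1], 9L)
  expect_equal(im$n_snps_used[1], 10L)
  # impute_mean fills with 2 * frequency of the observed genotypes
  fr <- mean(m2[-1, 1]) / 2
  manual <- (sum(w$weight * m2[1, ], na.rm = TRUE) + w$weight[1] * 2 * fr) / 10
  expect_equal(im$raw_score[1], manual, tolerance = 1e-12)

  # all-missing individual -> NA with warning
  m3 <- m; m3[2, ] <- NA
  g3 <- geno_matrix(m3, sprintf("rs%d", 1:10), rep("A", 10))
  expect_warning(s3 <- compute_scores(g3, w, "skip"), "no usable")
  expect_true(is.na(s3$raw_score[2]))
})

test_that("standardize_scores matches the z-score definition and rejects degeneracy", {
  s <- make_score_set(c("a", "b", "c"), c(1, 2, 3))
  s$std_score <- NA_real_
  out <- standardize_scores(s)
  expect_equal(out$std_score, c(-1, 0, 1))
  expect_lt(abs(mean(out$std_score)), 1e-8)
  s$raw_score <- rep(2, 3)
  expect_error(standardize_scores(s), "zero variance")
})

test_that("pi-hat recovers self, unrelated and parent-offspring relatedness", {
  freqs <- simulate_allele_freqs(2000, seed = 12)
  duos <- simulate_duos(freqs, 60, seed = 12)
  self <- relatedness_filter(duos$mothers, duos$mothers)
  d_self <- self$pi_hat[self$id_a == self$id_b]
  expect_equal(mean(d_self), 1, tolerance = 0.05)

  cross <- relatedness_filter(duos$mothers, duos$children)
  same_duo <- sub("_m$", "", cross$id_a) == sub("_c$", "", cross$id_b)
  expect_equal(mean(cross$pi_hat[same_duo]), 0.5, tolerance = 0.05)
  expect_equal(mean(cross$pi_hat[!same_duo]), 0, tolerance = 0.05)
  # parent-offspring pairs are flagged at the 12.5% threshold
  expect_true(all(cross$flagged[same_duo]))

  small <- subset_geno_cols(duos$mothers, 1:50)
  expect_warning(relatedness_filter(small, small), "unstable")
})
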