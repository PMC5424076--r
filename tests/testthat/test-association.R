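# association module: model fitting, Nagelkerke delta-R2, LRT, stratification

sim_linear <- function(n, beta, noise_sd, seed) {
  set.seed(seed)
  z <- rnorm(n)
  data.frame(z = z, sex = rbinom(n, 1, 0.5),
             y = beta * z + rnorm(n, sd = noise_sd))
}

test_that("fit_model recovers a generative linear effect at the study's scale", {
  # beta = -0.8 IQ points per SD, noise SD 13, n = 3858
  hits <- vapply(1:200, function(s) {
    d <- sim_linear(3858, -0.8, 13, seed = s)
    r <- fit_model(d, model_spec("y", "z", "sex"))
    abs(r$beta - (-0.8)) <= 0.8  # within the reported interval width of truth
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("the null model has ~95% Wald coverage of zero", {
  inside <- vapply(1:200, function(s) {
    d <- sim_linear(400, 0, 1, seed = 1000 + s)
    r <- fit_model(d, model_spec("y", "z", "sex"))
    abs(r$beta) < 2 * r$se
  }, logical(1))
  expect_gte(mean(inside), 0.90)
  expect_lte(mean(inside), 0.99)
})

test_that("fit_model recovers a logistic OR of 0.90 at the cohort scale", {
  est <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    n <- 6928
    z <- rnorm(n)
    y <- rbinom(n, 1, plogis(qlogis(0.6) + log(0.90) * z))
    d <- data.frame(z = z, sex = rbinom(n, 1, 0.5), y = y)
    r <- fit_model(d, model_spec("y", "z", "sex", family = "logistic"))
    log(r$odds_ratio)
  }, numeric(1))
  expect_equal(mean(est), log(0.90), tolerance = 0.15)
  # CI bracket and OR consistency on one fit
  set.seed(2001)
  d <- data.frame(z = rnorm(2000), sex = rbinom(2000, 1, 0.5))
  d$y <- rbinom(2000, 1, plogis(-0.3 * d$z))
  r <- fit_model(d, model_spec("y", "z", "sex", family = "logistic"))
  expect_true(r$ci[1] <= r$beta && r$beta <= r$ci[2])
  expect_equal(r$odds_ratio, exp(r$beta))
})

test_that("Nagelkerke delta matches brute-force likelihood on an enumerable toy", {
  # 20 observations, binary predictor; 3/10 vs 7/10 successes
  x <- rep(0:1, each = 10)
  y <- c(rep(1, 3), rep(0, 7), rep(1, 7), rep(0, 3))
  d <- data.frame(x = x, y = y)
  full <- glm(y ~ x, data = d, family = binomial(),
              control = glm.control(epsilon = 1e-12))
  null <- glm(y ~ 1, data = d, family = binomial(),
              control = glm.control(epsilon = 1e-12))
  # oracle: explicit Bernoulli likelihood at the closed-form MLEs
  ll1 <- 2 * (3 * log(0.3) + 7 * log(0.7))
  ll0 <- 20 * log(0.5)
  r2_oracle <- (1 - exp(2 * (ll0 - ll1) / 20)) / (1 - exp(2 * ll0 / 20))
  expect_equal(nagelkerke_delta(full, null), r2_oracle, tolerance = 1e-8)
  expect_identical(nagelkerke_delta(full, full), 0)
})

test_that("Nagelkerke R2 is invariant to affine outcome rescaling (linear)", {
  set.seed(5)
  d <- data.frame(z = rnorm(500))
  d$y <- 0.5 * d$z + rnorm(500)
  d$y2 <- 100 + 7 * d$y
  r_a <- nagelkerke_r2(lm(y ~ z, d))
  r_b <- nagelkerke_r2(lm(y2 ~ z, d))
  expect_equal(r_a, r_b, tolerance = 1e-10)
})

test_that("a pure-noise predictor adds a tiny non-negative delta-R2", {
  set.seed(6)
  d <- data.frame(z = rnorm(5000), noise = rnorm(5000))
  d$y <- 0.3 * d$z + rnorm(5000)
  full <- lm(y ~ z + noise, d)
  null <- lm(y ~ z, d)
  delta <- nagelkerke_delta(full, null)
  expect_gte(delta, 0)
  expect_lt(delta, 0.01)
})

test_that("LRT has boundary value 1, detects strong effects, and agrees with Wald", {
  set.seed(7)
  d <- data.frame(z = rnorm(1000))
  d$y <- 0.5 * d$z + rnorm(1000)  # beta*SD/noise = 0.5
  full <- lm(y ~ z, d)
  null <- lm(y ~ 1, d)
  expect_identical(lrt_pvalue(full, full), 1)
  expect_lt(lrt_pvalue(full, null), 1e-10)

  # Wald and LRT P agree within 10% relative error under the null at n >= 1000
  rel <- vapply(1:20, function(s) {
    dd <- sim_linear(1000, 0, 1, seed = 3000 + s)
    f <- lm(y ~ z, dd); n0 <- lm(y ~ 1, dd)
    p_lrt <- lrt_pvalue(f, n0)
    p_wald <- summary(f)$coefficients["z", 4]
    abs(p_lrt - p_wald) / p_wald
  }, numeric(1))
  expect_lt(stats::median(rel), 0.10)

  # non-nested misfit is rejected
  d2 <- data.frame(a = rnorm(100), b = rnorm(100))
  d2$y <- d2$a + rnorm(100)
  expect_error(lrt_pvalue(lm(y ~ b, d2), lm(y ~ a, d2)), "nested")
})

test_that("sex stratification and interaction testing behave under both regimes", {
  set.seed(8)
  n <- 4000
  sexes <- sample(c("female", "male"), n, replace = TRUE)
  z <- rnorm(n)
  # different slopes: -1 for males, 0 for females
  y <- ifelse(sexes == "male", -1, 0) * z + rnorm(n)
  d <- data.frame(z = z, sex = sexes, y = y)
  res <- sex_stratified(d, model_spec("y", "z", "sex"))
  expect_named(res$strata, c("female", "male"))
  expect_lt(res$interaction_p, 0.01)
  expect_lt(abs(res$strata$male$beta - (-1)), 0.15)
  expect_lt(abs(res$strata$female$beta), 0.15)

  # equal slopes: stratified estimates bracket the pooled one
  y2 <- -0.5 * z + rnorm(n)
  d2 <- data.frame(z = z, sex = sexes, y = y2)
  res2 <- sex_stratified(d2, model_spec("y", "z", "sex"))
  pooled <- fit_model(d2, model_spec("y", "z", "sex"))$beta
  lo <- min(res2$strata$female$beta, res2$strata$male$beta)
  hi <- max(res2$strata$female$beta, res2$strata$male$beta)
  expect_gte(pooled, lo - 1e-9)
  expect_lte(pooled, hi + 1e-9)
  expect_gt(res2$interaction_p, 0)
  expect_lte(res2$interaction_p, 1)

  expect_error(sex_stratified(d[d$sex == "male", ], model_spec("y", "z", "sex")),
               "two levels")
})

test_that("mutual mother/child adjustment shrinks a non-generative child effect", {
  # only the maternal path is generative; scores correlate ~0.5
  shrunk <- vapply(1:200, function(s) {
    set.seed(4000 + s)
    n <- 500
    zm <- rnorm(n)
    zc <- 0.5 * zm + sqrt(0.75) * rnorm(n)
    y <- -1 * zm + rnorm(n, sd = 3)
    d <- data.frame(zm = zm, zc = zc, y = y)
    unadj <- coef(lm(y ~ zc, d))["zc"]
    adj <- coef(lm(y ~ zc + zm, d))["zc"]
    abs(adj) < abs(unadj)
  }, logical(1))
  expect_gt(mean(shrunk), 0.9)
})

test_that("fit_model raises the documented errors", {
  set.seed(9)
  d <- data.frame(z = rnorm(50), sex = rbinom(50, 1, 0.5))
  d$y <- d$z + rnorm(50)
  d$z2 <- d$z  # exact collinearity
  expect_error(fit_model(d, model_spec("y", "z", "z2")), "rank-deficient")
  d$const <- 1
  expect_error(fit_model(d[1:8, ], model_spec("y", "z", "sex")), "complete cases")
  # perfect separation names the failure
  ds <- data.frame(z = c(rnorm(30, -3), rnorm(30, 3)),
                   y = rep(c(0, 1), each = 30))
  expect_error(fit_model(ds, model_spec("y", "z", family = "logistic")),
               "separation")
})
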