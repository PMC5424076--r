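#' Specify a PRS-outcome regression model
#'
#' The contrast of interest is the `exposure` (a standardized polygenic
#' score column); `covariates` (typically sex, optionally a second score
#' for mutual mother/child adjustment) are present in both the full and
#' the null model, so the likelihood-ratio test and the Nagelkerke
#' pseudo-R2 difference isolate the score's contribution.
#'
#' @param outcome outcome column name.
#' @param exposure exposure (score) column name.
#' @param covariates character vector of covariate column names.
#' @param family `"linear"` or `"logistic"`.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome, exposure, covariates = character(),
                       family = c("linear", "logistic")) {
  family <- match.arg(family)
  vars <- c(outcome, exposure, covariates)
  if (anyDuplicated(vars)) stop_param("outcome, exposure and covariates must be distinct")
  structure(list(outcome = outcome, exposure = exposure,
                 covariates = covariates, family = family),
            class = "model_spec")
}

fit_one <- function(data, outcome, rhs, family) {
  f <- stats::reformulate(if (length(rhs)) rhs else "1", response = outcome)
  if (family == "linear") {
    stats::lm(f, data = data)
  } else {
    withCallingHandlers(
      stats::glm(f, data = data, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          stop_param(sprintf("perfect separation fitting %s ~ %s",
                             outcome, paste(rhs, collapse = " + ")))
        }
        invokeRestart("muffleWarning")
      })
  }
}

#' Fit a PRS-outcome association model
#'
#' Fits the full model (exposure + covariates) and the null model
#' (covariates only) on the same complete-case rows by maximum likelihood
#' (OLS for linear outcomes, IRLS for logistic), and reports the exposure
#' coefficient with a 95% Wald confidence interval, the likelihood-ratio
#' P-value and the Nagelkerke pseudo-R2 difference of the two models, the
#' variance-explained measure used for polygenic scores.
#'
#' @param data data frame with the model columns.
#' @param spec a [model_spec()].
#' @return A `regression_result` list: `beta`, `ci` (95%), `se`,
#'   `odds_ratio` and `or_ci` (logistic only), `lrt_p`,
#'   `delta_nagelkerke_r2`, `n_used`, plus the fitted `full`/`null`
#'   models.
#' @export
fit_model <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  vars <- c(spec$outcome, spec$exposure, spec$covariates)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop_param("missing columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  n_par <- length(vars) + 1L
  if (nrow(d) < n_par + 9L) stop_param("fewer complete cases than predictors + 10")
  y <- d[[spec$outcome]]
  if (spec$family == "linear" && stats::var(y) == 0) {
    stop_param("outcome has zero variance")
  }
  if (spec$family == "logistic" && length(unique(y)) != 2L) {
    stop_param("logistic family requires a binary outcome")
  }
  full <- fit_one(d, spec$outcome, c(spec$exposure, spec$covariates), spec$family)
  null <- fit_one(d, spec$outcome, spec$covariates, spec$family)
  cf <- stats::coef(full)
  if (anyNA(cf)) {
    stop_param("rank-deficient design: ", paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  est <- summary(full)$coefficients
  term <- spec$exposure
  beta <- est[term, 1L]; se <- est[term, 2L]
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  res <- list(term = term, beta = beta, se = se, ci = ci,
              odds_ratio = if (spec$family == "logistic") exp(beta) else NA_real_,
              or_ci = if (spec$family == "logistic") exp(ci) else c(NA_real_, NA_real_),
              lrt_p = lrt_pvalue(full, null),
              delta_nagelkerke_r2 = nagelkerke_delta(full, null),
              n_used = nrow(d), family = spec$family,
              full = full, null = null)
  class(res) <- "regression_result"
  res
}

#' @export
print.regression_result <- function(x, digits = 3, ...) {
  cat(sprintf("<regression_result> %s (n = %d)\n", x$term, x$n_used))
  if (x$family == "logistic") {
    cat(sprintf("  OR = %.*f (%.*f to %.*f)\n", digits, x$odds_ratio,
                digits, x$or_ci[1], digits, x$or_ci[2]))
  } else {
    cat(sprintf("  beta = %.*f (%.*f to %.*f)\n", digits, x$beta,
                digits, x$ci[1], digits, x$ci[2]))
  }
  cat(sprintf("  LRT P = %.3g, delta Nagelkerke R2 = %.4f\n",
              x$lrt_p, x$delta_nagelkerke_r2))
  invisible(x)
}

model_n <- function(fit) {
  stats::nobs(fit)
}

loglik_intercept_only <- function(fit) {
  mf <- stats::model.frame(fit)
  y <- stats::model.response(mf)
  if (inherits(fit, "glm")) {
    as.numeric(stats::logLik(stats::glm(y ~ 1, family = stats::binomial())))
  } else {
    as.numeric(stats::logLik(stats::lm(y ~ 1)))
  }
}

#' Nagelkerke pseudo-R2 of a fitted model
#'
#' For logistic models,
#' `R2 = [1 - (L0/L1)^(2/n)] / [1 - L0^(2/n)]`, with `L1` the model's
#' maximum likelihood, `L0` the intercept-only likelihood on the same
#' rows, and n the number of observations. For linear models the
#' likelihood-ratio (Cox-Snell) term `1 - (L0/L1)^(2/n)` computed from
#' Gaussian maximum-likelihood values equals the classical coefficient of
#' determination and is returned without the `1 - L0^(2/n)` rescaling:
#' for a continuous outcome `L0` is a density and the rescaling would
#' make the measure depend on the outcome's unit of measurement, whereas
#' a variance-explained measure must be invariant to affine rescaling.
#'
#' @param fit an `lm` or binomial `glm` fit.
#' @return The pseudo-R2 in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  n <- model_n(fit)
  ll1 <- as.numeric(stats::logLik(fit))
  ll0 <- loglik_intercept_only(fit)
  cox_snell <- 1 - exp(2 * (ll0 - ll1) / n)
  if (inherits(fit, "glm")) {
    cox_snell / (1 - exp(2 * ll0 / n))
  } else {
    cox_snell
  }
}

#' Nagelkerke pseudo-R2 difference between nested models
#'
#' The variance explained by a polygenic score is reported as the
#' Nagelkerke pseudo-R2 of the full model minus that of the null model
#' (covariates only), both computed against the intercept-only likelihood
#' on the same rows.
#'
#' @param full,null fitted models on identical rows, `null` nested in
#'   `full`.
#' @return `R2_full - R2_null`.
#' @export
nagelkerke_delta <- function(full, null) {
  if (model_n(full) != model_n(null)) {
    stop_param("full and null models were fitted on different samples")
  }
  nagelkerke_r2(full) - nagelkerke_r2(null)
}

#' Likelihood-ratio test P-value for nested models
#'
#' `P = Pr(chi^2_df >= 2 (ll_full - ll_null))` with df the difference in
#' parameter counts.
#'
#' @param full,null nested fitted models on identical rows.
#' @return The LRT P-value (1 when the fits coincide).
#' @export
lrt_pvalue <- function(full, null) {
  if (model_n(full) != model_n(null)) {
    stop_param("full and null models were fitted on different samples")
  }
  df <- attr(stats::logLik(full), "df") - attr(stats::logLik(null), "df")
  stat <- 2 * (as.numeric(stats::logLik(full)) - as.numeric(stats::logLik(null)))
  if (stat < -1e-6) stop_param("negative deviance difference: models not nested?")
  stat <- max(stat, 0)
  if (df <= 0) return(1)
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Sex-stratified association and interaction test
#'
#' Refits the model within each sex and tests effect-modification by
#' adding an exposure-by-sex interaction term to the pooled model; the
#' interaction P-value comes from a likelihood-ratio test of that term.
#'
#' @param data data frame including a `sex_col` column with two levels.
#' @param spec a [model_spec()]; `sex_col` need not be among its
#'   covariates for the stratified fits (it is dropped within strata).
#' @param sex_col name of the sex column.
#' @return List with per-stratum `regression_result`s and
#'   `interaction_p`.
#' @export
sex_stratified <- function(data, spec, sex_col = "sex") {
  stopifnot(inherits(spec, "model_spec"))
  sexes <- sort(unique(stats::na.omit(data[[sex_col]])))
  if (length(sexes) != 2L) stop_param("`", sex_col, "` must have exactly two levels")
  strata <- lapply(sexes, function(s) {
    sub <- data[data[[sex_col]] == s & !is.na(data[[sex_col]]), , drop = FALSE]
    if (nrow(sub) < 30L) stop_param("stratum ", s, " has fewer than 30 rows")
    sub_spec <- model_spec(spec$outcome, spec$exposure,
                           setdiff(spec$covariates, sex_col), spec$family)
    fit_model(sub, sub_spec)
  })
  names(strata) <- as.character(sexes)

  covs <- union(spec$covariates, sex_col)
  vars <- c(spec$outcome, spec$exposure, covs)
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  d$.sex01 <- as.numeric(d[[sex_col]] == sexes[2])
  d$.inter <- d[[spec$exposure]] * d$.sex01
  rhs_base <- c(spec$exposure, setdiff(covs, sex_col), ".sex01")
  pooled <- fit_one(d, spec$outcome, rhs_base, spec$family)
  inter <- fit_one(d, spec$outcome, c(rhs_base, ".inter"), spec$family)
  list(strata = strata, interaction_p = lrt_pvalue(inter, pooled))
}
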