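#' Sobel and Goodman standard errors of an indirect effect
#'
#' For indirect effect `a*b` with path standard errors `s_a`, `s_b`:
#' Sobel `sqrt(a^2 s_b^2 + b^2 s_a^2)`; Goodman I adds `s_a^2 s_b^2`
#' under the root; Goodman II subtracts it (`NA` when the radicand is
#' negative).
#'
#' @param a,s_a exposure-to-mediator coefficient and its SE.
#' @param b,s_b mediator-to-outcome coefficient (exposure-adjusted) and
#'   its SE.
#' @return Named list `sobel`, `goodman1`, `goodman2`.
#' @export
sobel_standard_errors <- function(a, s_a, b, s_b) {
  core <- a^2 * s_b^2 + b^2 * s_a^2
  extra <- s_a^2 * s_b^2
  g2 <- core - extra
  list(sobel = sqrt(core),
       goodman1 = sqrt(core + extra),
       goodman2 = if (g2 >= 0) sqrt(g2) else NA_real_)
}

fit_ols <- function(d, outcome, rhs) {
  stats::lm(stats::reformulate(rhs, response = outcome), data = d)
}

coef_se <- function(fit, term) {
  s <- summary(fit)$coefficients
  c(est = s[term, 1L], se = s[term, 2L])
}

mediation_frame <- function(data, vars) {
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop_param("missing columns: ", paste(miss, collapse = ", "))
  d <- data[stats::complete.cases(data[vars]), vars, drop = FALSE]
  if (nrow(d) < length(vars) + 10L) stop_param("too few complete cases")
  d
}

#' Sobel-Goodman single-mediator decomposition
#'
#' Decomposes the effect of a standardized polygenic score on an
#' educational outcome through one mediator (IQ or childhood ADHD
#' symptoms) with three OLS regressions sharing the covariate set:
#' outcome ~ exposure (+covariates) for the total effect c;
#' mediator ~ exposure for path a; outcome ~ exposure + mediator for path
#' b and the direct effect c'. The indirect effect is `a*b`, tested
#' against its Sobel standard error; with identical covariates the OLS
#' identity `c = c' + a*b` holds exactly. The proportion mediated is
#' `a*b / c` (missing when c = 0).
#'
#' @param data data frame.
#' @param exposure,mediator,outcome column names.
#' @param covariates character vector of covariate column names included
#'   in all three regressions (typically `"sex"`).
#' @return A `mediation_result` list with paths `a`, `b`, `c`, `c_prime`
#'   (each with SE), `indirect`, `se_sobel`, `se_goodman1`,
#'   `se_goodman2`, `z`, `p`, `proportion_mediated`, `n_used`.
#' @export
sobel_goodman <- function(data, exposure, mediator, outcome,
                          covariates = character()) {
  d <- mediation_frame(data, c(exposure, mediator, outcome, covariates))
  m_tot <- fit_ols(d, outcome, c(exposure, covariates))
  m_med <- fit_ols(d, mediator, c(exposure, covariates))
  m_out <- fit_ols(d, outcome, c(exposure, mediator, covariates))
  cc <- coef_se(m_tot, exposure)
  aa <- coef_se(m_med, exposure)
  bb <- coef_se(m_out, mediator)
  cp <- coef_se(m_out, exposure)
  ind <- unname(aa["est"] * bb["est"])
  ses <- sobel_standard_errors(aa["est"], aa["se"], bb["est"], bb["se"])
  z <- ind / ses$sobel
  res <- list(exposure = exposure, mediator = mediator, outcome = outcome,
              covariates = covariates,
              a = unname(aa["est"]), se_a = unname(aa["se"]),
              b = unname(bb["est"]), se_b = unname(bb["se"]),
              c = unname(cc["est"]), se_c = unname(cc["se"]),
              c_prime = unname(cp["est"]), se_c_prime = unname(cp["se"]),
              indirect = ind,
              se_sobel = unname(ses$sobel),
              se_goodman1 = unname(ses$goodman1),
              se_goodman2 = unname(ses$goodman2),
              z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
              proportion_mediated = if (cc["est"] != 0) unname(ind / cc["est"]) else NA_real_,
              n_used = nrow(d))
  class(res) <- "mediation_result"
  res
}

#' @export
print.mediation_result <- function(x, digits = 3, ...) {
  f <- function(v) formatC(v, digits = digits, format = "g")
  cat(sprintf("<mediation_result> %s -> %s -> %s (n = %d)\n",
              x$exposure, x$mediator, x$outcome, x$n_used))
  cat(sprintf("            a = %s (SE %s)\n", f(x$a), f(x$se_a)))
  cat(sprintf("        %s\n", x$mediator))
  cat(sprintf("            b = %s (SE %s)\n", f(x$b), f(x$se_b)))
  cat(sprintf("  total    c  = %s   direct c' = %s\n", f(x$c), f(x$c_prime)))
  cat(sprintf("  indirect a*b = %s (Sobel SE %s, z = %s, P = %s)\n",
              f(x$indirect), f(x$se_sobel), f(x$z), f(x$p)))
  if (!is.na(x$proportion_mediated)) {
    cat(sprintf("  proportion mediated = %.1f%%\n", 100 * x$proportion_mediated))
  }
  if (!is.null(x$bootstrap)) {
    cat(sprintf("  bootstrap %s CI (%d reps): [%s, %s]\n",
                x$bootstrap$ci_type, x$bootstrap$n_boot_used,
                f(x$bootstrap$ci[1]), f(x$bootstrap$ci[2])))
  }
  invisible(x)
}

# least squares via .lm.fit, unpivoted; NULL on rank deficiency so a
# degenerate bootstrap resample can be dropped rather than silently misread
fast_ols_coef <- function(X, y) {
  f <- tryCatch(.lm.fit(X, y), error = function(e) NULL)
  if (is.null(f) || f$rank < ncol(X)) return(NULL)
  if (is.matrix(y)) {
    b <- matrix(NA_real_, ncol(X), ncol(y))
    b[f$pivot, ] <- f$coefficients
  } else {
    b <- numeric(ncol(X))
    b[f$pivot] <- f$coefficients
  }
  b
}

# fast resampled indirect effects on prebuilt design matrices
boot_indirect_reps <- function(X_med, y_med, X_out, y_out, a_col, b_col,
                               n_boot, seed) {
  set.seed(seed)
  n <- length(y_med)
  reps <- rep(NA_real_, n_boot)
  for (r in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bm <- fast_ols_coef(X_med[idx, , drop = FALSE], y_med[idx])
    bo <- fast_ols_coef(X_out[idx, , drop = FALSE], y_out[idx])
    if (is.null(bm) || is.null(bo)) next
    a_r <- bm[a_col]
    b_r <- bo[b_col]
    if (is.finite(a_r) && is.finite(b_r)) reps[r] <- a_r * b_r
  }
  reps
}

boot_ci <- function(reps, point, ci_type, level = 0.95) {
  alpha <- 1 - level
  if (ci_type == "percentile") {
    stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  } else {
    # bias-corrected (BC, no acceleration)
    z0 <- stats::qnorm(mean(reps < point))
    lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha / 2))
    hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha / 2))
    stats::quantile(reps, c(lo, hi), names = FALSE, type = 7)
  }
}

#' Bootstrap confidence interval for an indirect effect
#'
#' Case resampling of whole rows: the mediator and outcome regressions
#' are refitted on each resample and the indirect effect `a*b`
#' recomputed; the CI is the percentile interval of the replicates by
#' default (bias-corrected optional). Degenerate resamples (singular fits
#' or non-finite paths) are dropped and counted. Deterministic given
#' `seed`.
#'
#' @inheritParams sobel_goodman
#' @param n_boot number of replications (>= 100; the conventional choice
#'   is 1000).
#' @param seed integer seed.
#' @param ci_type `"percentile"` (default) or `"bias_corrected"`.
#' @return The [sobel_goodman()] result with a `bootstrap` element:
#'   `ci`, `se` (SD of replicates), `n_boot`, `n_boot_used`, `ci_type`,
#'   `replicates`.
#' @export
bootstrap_indirect <- function(data, exposure, mediator, outcome,
                               covariates = character(), n_boot = 1000L,
                               seed = 1L,
                               ci_type = c("percentile", "bias_corrected")) {
  ci_type <- match.arg(ci_type)
  n_boot <- check_count(n_boot, "n_boot", min = 100L)
  res <- sobel_goodman(data, exposure, mediator, outcome, covariates)
  d <- mediation_frame(data, c(exposure, mediator, outcome, covariates))
  rhs_med <- stats::reformulate(c(exposure, covariates))
  rhs_out <- stats::reformulate(c(exposure, mediator, covariates))
  X_med <- stats::model.matrix(rhs_med, d)
  X_out <- stats::model.matrix(rhs_out, d)
  reps <- boot_indirect_reps(X_med, d[[mediator]], X_out, d[[outcome]],
                             a_col = match(exposure, colnames(X_med)),
                             b_col = match(mediator, colnames(X_out)),
                             n_boot, seed)
  ok <- is.finite(reps)
  if (sum(ok) < 2L) stop_param("bootstrap produced no usable replicates")
  res$bootstrap <- list(ci = boot_ci(reps[ok], res$indirect, ci_type),
                        se = stats::sd(reps[ok]),
                        n_boot = n_boot, n_boot_used = sum(ok),
                        dropped = n_boot - sum(ok),
                        ci_type = ci_type, replicates = reps[ok])
  res
}

# one-step feasible GLS for a SUR system; returns per-equation coefficient
# lists and their system covariance
sur_fgls <- function(X_list, y_list) {
  k <- length(X_list)
  n <- length(y_list[[1]])
  ols <- lapply(seq_len(k), function(i) .lm.fit(X_list[[i]], y_list[[i]]))
  E <- vapply(ols, function(f) f$residuals, numeric(n))
  Sigma <- crossprod(E) / n
  W <- solve(Sigma)
  p <- vapply(X_list, ncol, integer(1))
  off <- c(0L, cumsum(p))
  P <- sum(p)
  A <- matrix(0, P, P); bvec <- numeric(P)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    ri <- (off[i] + 1L):off[i + 1L]
    rj <- (off[j] + 1L):off[j + 1L]
    A[ri, rj] <- A[ri, rj] + W[i, j] * crossprod(X_list[[i]], X_list[[j]])
    bvec[ri] <- bvec[ri] + W[i, j] * crossprod(X_list[[i]], y_list[[j]])
  }
  V <- solve(A)
  beta <- as.vector(V %*% bvec)
  coefs <- lapply(seq_len(k), function(i) {
    b <- beta[(off[i] + 1L):off[i + 1L]]
    names(b) <- colnames(X_list[[i]])
    b
  })
  ses <- lapply(seq_len(k), function(i) {
    s <- sqrt(diag(V)[(off[i] + 1L):off[i + 1L]])
    names(s) <- colnames(X_list[[i]])
    s
  })
  list(coefficients = coefs, se = ses, sigma = Sigma)
}

#' Two-mediator decomposition via seemingly unrelated regression
#'
#' Estimates the mediator equations (each mediator ~ exposure +
#' covariates) and the outcome equation (outcome ~ exposure + mediators +
#' covariates) jointly as a seemingly-unrelated-regression system by
#' one-step feasible GLS, allowing correlated equation errors. Because
#' the mediator equations share their regressors and the outcome-equation
#' OLS residuals are orthogonal to the mediators in-sample, the point
#' estimates coincide with per-equation OLS; the system is still
#' estimated for its joint covariance. Per-mediator indirect effects are
#' `a_j * b_j`; attribution is each mediator's share of the total
#' indirect effect. Bootstrap (case resampling) provides SEs and CIs.
#'
#' @param data data frame.
#' @param exposure,outcome column names.
#' @param mediators character vector of >= 2 mediator column names.
#' @param covariates covariate column names shared by all equations.
#' @param n_boot bootstrap replications (0 disables the bootstrap).
#' @param seed integer seed for the bootstrap substream.
#' @param ci_type `"percentile"` or `"bias_corrected"`.
#' @return A `multi_mediation_result` list: per-mediator `a`, `b`,
#'   `indirect`, `attribution`; `total_indirect`, `direct`, `total`,
#'   `n_used`; bootstrap `se`/`ci` per quantity when `n_boot > 0`.
#' @export
multiple_mediation_sur <- function(data, exposure, mediators, outcome,
                                   covariates = character(), n_boot = 1000L,
                                   seed = 1L,
                                   ci_type = c("percentile", "bias_corrected")) {
  ci_type <- match.arg(ci_type)
  if (length(mediators) < 2L) stop_param("need at least two mediators")
  d <- mediation_frame(data, c(exposure, mediators, outcome, covariates))
  cm <- stats::cor(d[mediators])
  if (any(abs(cm[upper.tri(cm)]) > 0.99)) {
    stop_param("mediators are (near-)collinear: |r| > 0.99")
  }
  X_med <- stats::model.matrix(stats::reformulate(c(exposure, covariates)), d)
  X_out <- stats::model.matrix(stats::reformulate(c(exposure, mediators, covariates)), d)
  X_list <- c(replicate(length(mediators), X_med, simplify = FALSE), list(X_out))
  y_list <- c(lapply(mediators, function(m) d[[m]]), list(d[[outcome]]))
  fit <- sur_fgls(X_list, y_list)

  k <- length(mediators)
  a <- vapply(seq_len(k), function(j) fit$coefficients[[j]][[exposure]], numeric(1))
  se_a <- vapply(seq_len(k), function(j) fit$se[[j]][[exposure]], numeric(1))
  b <- vapply(mediators, function(m) fit$coefficients[[k + 1L]][[m]], numeric(1))
  se_b <- vapply(mediators, function(m) fit$se[[k + 1L]][[m]], numeric(1))
  c_prime <- fit$coefficients[[k + 1L]][[exposure]]
  indirect <- a * b
  total_indirect <- sum(indirect)
  total <- c_prime + total_indirect
  attribution <- if (total_indirect != 0) indirect / total_indirect else
    rep(NA_real_, k)

  res <- list(exposure = exposure, mediators = mediators, outcome = outcome,
              covariates = covariates,
              a = stats::setNames(a, mediators),
              se_a = stats::setNames(se_a, mediators),
              b = b, se_b = se_b,
              indirect = stats::setNames(indirect, mediators),
              attribution = stats::setNames(attribution, mediators),
              total_indirect = total_indirect,
              direct = c_prime, total = total,
              n_used = nrow(d))
  class(res) <- "multi_mediation_result"
  if (n_boot > 0L) {
    n_boot <- check_count(n_boot, "n_boot", min = 100L)
    set.seed(seed)
    n <- nrow(d)
    reps <- matrix(NA_real_, n_boot, k + 1L)
    a_col <- match(exposure, colnames(X_med))
    b_cols <- match(mediators, colnames(X_out))
    y_med <- as.matrix(d[mediators])
    y_out <- d[[outcome]]
    for (r in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      bm <- fast_ols_coef(X_med[idx, , drop = FALSE],
                          y_med[idx, , drop = FALSE])
      bo <- fast_ols_coef(X_out[idx, , drop = FALSE], y_out[idx])
      if (is.null(bm) || is.null(bo)) next
      a_r <- bm[a_col, ]
      b_r <- bo[b_cols]
      if (all(is.finite(a_r)) && all(is.finite(b_r))) {
        reps[r, ] <- c(a_r * b_r, sum(a_r * b_r))
      }
    }
    ok <- stats::complete.cases(reps)
    if (sum(ok) < 2L) stop_param("bootstrap produced no usable replicates")
    reps <- reps[ok, , drop = FALSE]
    points <- c(indirect, total_indirect)
    cis <- lapply(seq_len(k + 1L), function(j) boot_ci(reps[, j], points[j], ci_type))
    res$bootstrap <- list(
      se = stats::setNames(apply(reps, 2L, stats::sd),
                           c(mediators, "total_indirect")),
      ci = stats::setNames(cis, c(mediators, "total_indirect")),
      n_boot = n_boot, n_boot_used = sum(ok), ci_type = ci_type)
  }
  res
}

#' @export
print.multi_mediation_result <- function(x, digits = 3, ...) {
  f <- function(v) formatC(v, digits = digits, format = "g")
  cat(sprintf("<multi_mediation_result> %s -> {%s} -> %s (n = %d)\n",
              x$exposure, paste(x$mediators, collapse = ", "), x$outcome,
              x$n_used))
  for (m in x$mediators) {
    cat(sprintf("  %-14s a = %s, b = %s, indirect = %s (%.0f%% of indirect)\n",
                m, f(x$a[[m]]), f(x$b[[m]]), f(x$indirect[[m]]),
                100 * x$attribution[[m]]))
  }
  cat(sprintf("  total indirect = %s, direct = %s, total = %s\n",
              f(x$total_indirect), f(x$direct), f(x$total)))
  if (!is.null(x$bootstrap)) {
    ci <- x$bootstrap$ci$total_indirect
    cat(sprintf("  bootstrap %s CI for total indirect (%d reps): [%s, %s]\n",
                x$bootstrap$ci_type, x$bootstrap$n_boot_used, f(ci[1]), f(ci[2])))
  }
  invisible(x)
}
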