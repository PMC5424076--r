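# moments of a doubly clipped normal Y = min(max(X, L), U), X ~ N(mu, sd)
clipped_normal_moments <- function(mu, sd, L, U) {
  a <- (L - mu) / sd; b <- (U - mu) / sd
  Fa <- stats::pnorm(a); Fb <- stats::pnorm(b)
  fa <- stats::dnorm(a); fb <- stats::dnorm(b)
  m1 <- L * Fa + U * (1 - Fb) + mu * (Fb - Fa) - sd * (fb - fa)
  m2 <- L^2 * Fa + U^2 * (1 - Fb) +
    (mu^2 + sd^2) * (Fb - Fa) + 2 * mu * sd * (fa - fb) +
    sd^2 * (ifelse(is.finite(a), a * fa, 0) - ifelse(is.finite(b), b * fb, 0))
  c(mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# invert the clipped-normal moments: find the pre-clip (mu, sd) whose
# clipped mean/SD match the stated (published) values
solve_preclip <- function(target_mean, target_sd, L, U) {
  obj <- function(par) {
    m <- clipped_normal_moments(par[1], exp(par[2]), L, U)
    (m["mean"] - target_mean)^2 + (m["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' Define the generative mediation structure for synthetic phenotypes
#'
#' The preset states the world the phenotype simulator draws from: a linear
#' path model in which the standardized child polygenic score Z lowers IQ
#' and raises childhood ADHD symptoms (paths a), both mediators feed the
#' GCSE capped point score (paths b), and a direct path c' remains, so that
#' the total effect is exactly `c' + a_iq*b_iq + a_adhd*b_adhd`. Key Stage 3
#' shares the same mediators with path coefficients scaled so its total
#' effect matches `total_effect_ks3`. Sitting Key Stage 5 is a logistic
#' function of Z. Maternal IQ and a 5-level education scale depend on the
#' maternal standardized score.
#'
#' Defaults are calibrated so that the published effect sizes of the ADHD
#' polygenic-score literature are the generative truth: a total GCSE effect
#' of -4.0 points per SD of score, an IQ path of -0.8 IQ points per SD,
#' two-mediator indirect effects of -1.975 (IQ; 79% of a -2.5 total
#' indirect) and -0.525 (ADHD symptoms), and single-mediator proportions
#' mediated of ~49% (IQ) and 16% (ADHD symptoms). Because a single-mediator
#' regression coefficient absorbs part of the omitted mediator's path
#' through the residual correlation of the two mediators, that correlation
#' is solved in closed form from the 16% single-mediator target:
#' `rho = (prop*total/a_adhd - b_adhd) * s_adhd / (b_iq * s_iq)`
#' where `s_*` are mediator residual SDs. Phenotype means and SDs default
#' to the published cohort values (GCSE 328.2/89.9, KS3 106.2/24.4, child
#' IQ 91.9/13, maternal IQ 98.9/13.9).
#'
#' Residual SDs are derived from the stated marginal SDs by subtracting the
#' modelled variance components; an error is raised if a stated SD is too
#' small to accommodate them.
#'
#' @param total_effect_gcse total effect of Z on GCSE points (per SD).
#' @param total_effect_ks3 total effect of Z on KS3 points (per SD).
#' @param path_a_iq effect of Z on IQ (IQ points per SD).
#' @param path_a_adhd effect of Z on ADHD symptom score (units per SD).
#' @param indirect_iq,indirect_adhd two-mediator indirect effects
#'   `a_j * b_j` on GCSE points; the b paths are derived from these.
#' @param single_prop_adhd target single-mediator proportion mediated via
#'   ADHD symptoms, used to calibrate the mediator residual correlation
#'   (ignored when `mediator_residual_cor` is supplied).
#' @param mediator_residual_cor residual correlation between IQ and ADHD
#'   symptoms given Z and sex; `NULL` (default) calibrates it from
#'   `single_prop_adhd`.
#' @param iq_mean,iq_sd,adhd_mean,adhd_sd,gcse_mean,gcse_sd,ks3_mean,ks3_sd
#'   marginal phenotype means and SDs.
#' @param sex_effect_gcse,sex_effect_ks3,sex_effect_adhd male-minus-female
#'   mean differences (girls outperform at GCSE/KS3; boys carry more
#'   symptoms); applied centered so phenotype means are preserved.
#' @param p_male male fraction used for centering.
#' @param ks5_prob_sat marginal probability of sitting Key Stage 5.
#' @param ks5_log_or log odds ratio of sitting KS5 per SD of Z
#'   (default `log(0.90)`).
#' @param mother_iq_mean,mother_iq_sd,mother_iq_beta maternal IQ model.
#' @param mother_edu_beta observed linear slope of the 5-level education
#'   scale on the maternal standardized score; converted internally to a
#'   latent-Gaussian slope (quintile thresholds).
#' @param ks3_range,gcse_range clipping bounds of the academic scores. The
#'   published means/SDs describe the *capped* scores, so the pre-clip
#'   Gaussian location/scale are solved from the clipped-normal moment
#'   equations; clipping then reproduces the stated moments rather than
#'   shrinking them.
#' @return A `mediation_preset` list with the stated and derived
#'   parameters (`path_b_iq`, `path_b_adhd`, `path_c_direct`, residual
#'   SDs, `rho`, KS3-scaled paths, latent education slope).
#' @seealso [simulate_phenotypes()], [implied_total_effect()]
#' @export
mediation_preset <- function(total_effect_gcse = -4.0,
                             total_effect_ks3 = -1.4,
                             path_a_iq = -0.8,
                             path_a_adhd = 0.3,
                             indirect_iq = 0.79 * -2.5,
                             indirect_adhd = 0.21 * -2.5,
                             single_prop_adhd = 0.16,
                             mediator_residual_cor = NULL,
                             iq_mean = 91.9, iq_sd = 13,
                             adhd_mean = 3, adhd_sd = 3,
                             gcse_mean = 328.2, gcse_sd = 89.9,
                             ks3_mean = 106.2, ks3_sd = 24.4,
                             sex_effect_gcse = -15,
                             sex_effect_ks3 = -4,
                             sex_effect_adhd = 1,
                             p_male = 0.511,
                             ks5_prob_sat = 4146 / (4146 + 2782),
                             ks5_log_or = log(0.90),
                             mother_iq_mean = 98.9, mother_iq_sd = 13.9,
                             mother_iq_beta = -0.6,
                             mother_edu_beta = -0.09,
                             ks3_range = c(0, 141),
                             gcse_range = c(0, 483)) {
  if (path_a_iq == 0 && indirect_iq != 0)
    stop_param("indirect_iq nonzero but path_a_iq is 0")
  if (path_a_adhd == 0 && indirect_adhd != 0)
    stop_param("indirect_adhd nonzero but path_a_adhd is 0")
  path_b_iq <- if (path_a_iq != 0) indirect_iq / path_a_iq else 0
  path_b_adhd <- if (path_a_adhd != 0) indirect_adhd / path_a_adhd else 0
  path_c_direct <- total_effect_gcse - indirect_iq - indirect_adhd
  v_sex <- p_male * (1 - p_male)

  s_iq <- iq_sd^2 - path_a_iq^2
  s_adhd <- adhd_sd^2 - path_a_adhd^2 - v_sex * sex_effect_adhd^2
  if (s_iq <= 0 || s_adhd <= 0)
    stop_param("stated mediator SDs are too small for the stated paths")
  s_iq <- sqrt(s_iq); s_adhd <- sqrt(s_adhd)

  rho <- mediator_residual_cor
  if (is.null(rho)) {
    rho <- 0
    if (path_a_adhd != 0 && path_b_iq != 0 && total_effect_gcse != 0) {
      b_single_adhd <- single_prop_adhd * total_effect_gcse / path_a_adhd
      rho <- (b_single_adhd - path_b_adhd) * s_adhd / (path_b_iq * s_iq)
    }
  }
  check_fraction(rho, "mediator_residual_cor", -1, 1)

  sex_total_gcse <- sex_effect_gcse + path_b_adhd * sex_effect_adhd
  v_model_gcse <- total_effect_gcse^2 +
    path_b_iq^2 * s_iq^2 + path_b_adhd^2 * s_adhd^2 +
    2 * path_b_iq * path_b_adhd * rho * s_iq * s_adhd +
    v_sex * sex_total_gcse^2
  in_range <- function(m, r) m >= r[1] && m <= r[2]
  if (!in_range(gcse_mean, gcse_range) || !in_range(ks3_mean, ks3_range)) {
    warning("preset implies an academic-score mean outside its clipping range;",
            " expect heavy clipping", call. = FALSE)
  }
  pre_gcse <- if (in_range(gcse_mean, gcse_range)) {
    solve_preclip(gcse_mean, gcse_sd, gcse_range[1], gcse_range[2])
  } else c(mean = gcse_mean, sd = gcse_sd)
  s_gcse <- pre_gcse["sd"]^2 - v_model_gcse
  if (s_gcse <= 0) stop_param("stated GCSE SD too small for the stated paths")
  s_gcse <- sqrt(s_gcse)

  ks3_scale <- if (total_effect_gcse != 0) total_effect_ks3 / total_effect_gcse else 0
  b_iq_ks3 <- ks3_scale * path_b_iq
  b_adhd_ks3 <- ks3_scale * path_b_adhd
  c_direct_ks3 <- total_effect_ks3 - b_iq_ks3 * path_a_iq - b_adhd_ks3 * path_a_adhd
  sex_total_ks3 <- sex_effect_ks3 + b_adhd_ks3 * sex_effect_adhd
  v_model_ks3 <- total_effect_ks3^2 +
    b_iq_ks3^2 * s_iq^2 + b_adhd_ks3^2 * s_adhd^2 +
    2 * b_iq_ks3 * b_adhd_ks3 * rho * s_iq * s_adhd +
    v_sex * sex_total_ks3^2
  pre_ks3 <- if (in_range(ks3_mean, ks3_range)) {
    solve_preclip(ks3_mean, ks3_sd, ks3_range[1], ks3_range[2])
  } else c(mean = ks3_mean, sd = ks3_sd)
  s_ks3 <- pre_ks3["sd"]^2 - v_model_ks3
  if (s_ks3 <= 0) stop_param("stated KS3 SD too small for the stated paths")
  s_ks3 <- sqrt(s_ks3)

  # observed ordinal slope -> latent slope: attenuation sum(phi(thresholds))
  qthr <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8))
  mother_edu_beta_latent <- mother_edu_beta / sum(stats::dnorm(qthr))
  m_iq_resid <- mother_iq_sd^2 - mother_iq_beta^2
  if (m_iq_resid <= 0) stop_param("maternal IQ SD too small for its path")

  structure(list(
    path_a_iq = path_a_iq, path_a_adhd = path_a_adhd,
    path_b_iq = path_b_iq, path_b_adhd = path_b_adhd,
    path_c_direct = path_c_direct,
    total_effect_gcse = total_effect_gcse,
    total_effect_ks3 = total_effect_ks3,
    b_iq_ks3 = b_iq_ks3, b_adhd_ks3 = b_adhd_ks3,
    c_direct_ks3 = c_direct_ks3,
    rho = rho,
    iq_mean = iq_mean, iq_sd = iq_sd,
    adhd_mean = adhd_mean, adhd_sd = adhd_sd,
    gcse_mean = gcse_mean, gcse_sd = gcse_sd,
    ks3_mean = ks3_mean, ks3_sd = ks3_sd,
    gcse_mean_preclip = unname(pre_gcse["mean"]),
    ks3_mean_preclip = unname(pre_ks3["mean"]),
    sd_iq_resid = s_iq, sd_adhd_resid = s_adhd,
    sd_gcse_resid = s_gcse, sd_ks3_resid = s_ks3,
    sex_effect_gcse = sex_effect_gcse, sex_effect_ks3 = sex_effect_ks3,
    sex_effect_adhd = sex_effect_adhd, p_male = p_male,
    ks5_intercept = stats::qlogis(ks5_prob_sat), ks5_log_or = ks5_log_or,
    mother_iq_mean = mother_iq_mean, mother_iq_sd = mother_iq_sd,
    mother_iq_beta = mother_iq_beta,
    sd_mother_iq_resid = sqrt(m_iq_resid),
    mother_edu_beta = mother_edu_beta,
    mother_edu_beta_latent = mother_edu_beta_latent,
    edu_thresholds = qthr,
    ks3_range = ks3_range, gcse_range = gcse_range),
    class = "mediation_preset")
}

#' Total effect of the polygenic score implied by a preset
#'
#' The linear identity `total = c' + a_iq*b_iq + a_adhd*b_adhd` holds by
#' construction; this accessor recomputes it from the path coefficients.
#'
#' @param preset a `mediation_preset`.
#' @param outcome `"gcse"` or `"ks3"`.
#' @return The implied total effect (outcome points per SD of score).
#' @export
implied_total_effect <- function(preset, outcome = c("gcse", "ks3")) {
  stopifnot(inherits(preset, "mediation_preset"))
  outcome <- match.arg(outcome)
  if (outcome == "gcse") {
    preset$path_c_direct + preset$path_a_iq * preset$path_b_iq +
      preset$path_a_adhd * preset$path_b_adhd
  } else {
    preset$c_direct_ks3 + preset$path_a_iq * preset$b_iq_ks3 +
      preset$path_a_adhd * preset$b_adhd_ks3
  }
}

#' @export
print.mediation_preset <- function(x, ...) {
  cat("<mediation_preset>\n")
  cat(sprintf("  Z -> IQ:            a = %+.3f (resid SD %.2f)\n",
              x$path_a_iq, x$sd_iq_resid))
  cat(sprintf("  Z -> ADHD symptoms: a = %+.3f (resid SD %.2f, rho = %+.4f)\n",
              x$path_a_adhd, x$sd_adhd_resid, x$rho))
  cat(sprintf("  IQ -> GCSE:   b = %+.3f   ADHD -> GCSE: b = %+.3f\n",
              x$path_b_iq, x$path_b_adhd))
  cat(sprintf("  direct c' = %+.3f, total = %+.3f GCSE points per SD\n",
              x$path_c_direct, implied_total_effect(x)))
  invisible(x)
}

#' Simulate phenotypes for a duo cohort from a mediation preset
#'
#' Generates child IQ, ADHD symptom score, KS3 and GCSE points, a KS5
#' sitting indicator, and maternal IQ/education from the standardized
#' polygenic scores of children and mothers under the preset's linear path
#' model with Gaussian noise. Academic scores are clipped to their
#' published ranges; the clipped counts are recorded in the `clipping`
#' attribute. Maternal education is a latent Gaussian thresholded into
#' five ordered levels at population quintiles.
#'
#' @param duos a `duo_cohort`.
#' @param child_scores,mother_scores `score_set`s with standardized scores
#'   (`std_score`), aligned with the cohort's children and mothers.
#' @param preset a `mediation_preset`.
#' @param seed integer seed for the phenotype substream.
#' @return A data frame with one row per duo: `duo_id`, `child_id`,
#'   `mother_id`, `sex`, `prs_child`, `prs_mother`, `iq`, `adhd_symptoms`,
#'   `ks3`, `gcse`, `ks5_sat`, `mother_iq`, `mother_education`.
#' @export
simulate_phenotypes <- function(duos, child_scores, mother_scores, preset,
                                seed = 1L) {
  stopifnot(inherits(duos, "duo_cohort"), inherits(preset, "mediation_preset"),
            inherits(child_scores, "score_set"),
            inherits(mother_scores, "score_set"))
  n <- length(duos$duo_ids)
  if (nrow(child_scores) != n || nrow(mother_scores) != n) {
    stop_param("score sets must have one row per duo")
  }
  z_c <- child_scores$std_score[match(rownames(duos$children),
                                      child_scores$individual_id)]
  z_m <- mother_scores$std_score[match(rownames(duos$mothers),
                                       mother_scores$individual_id)]
  for (z in list(z_c, z_m)) {
    if (anyNA(z)) stop_param("score ids do not match the duo cohort")
    if (abs(mean(z)) > 1e-6 || abs(stats::sd(z) - 1) > 1e-6) {
      stop_param("scores must be standardized (see `standardize_scores()`)")
    }
  }
  set.seed(seed)
  p <- preset
  sexc <- as.numeric(duos$child_sex == "male") - p$p_male

  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  e_iq <- p$sd_iq_resid * z1
  e_adhd <- p$sd_adhd_resid * (p$rho * z1 + sqrt(1 - p$rho^2) * z2)

  iq <- p$iq_mean + p$path_a_iq * z_c + e_iq
  adhd <- p$adhd_mean + p$path_a_adhd * z_c + p$sex_effect_adhd * sexc + e_adhd
  iq_dev <- iq - p$iq_mean
  adhd_dev <- adhd - p$adhd_mean

  gcse <- p$gcse_mean_preclip + p$path_c_direct * z_c +
    p$path_b_iq * iq_dev + p$path_b_adhd * adhd_dev +
    p$sex_effect_gcse * sexc + stats::rnorm(n, sd = p$sd_gcse_resid)
  ks3 <- p$ks3_mean_preclip + p$c_direct_ks3 * z_c +
    p$b_iq_ks3 * iq_dev + p$b_adhd_ks3 * adhd_dev +
    p$sex_effect_ks3 * sexc + stats::rnorm(n, sd = p$sd_ks3_resid)

  clip <- function(x, r) pmin(pmax(x, r[1]), r[2])
  n_clip <- c(ks3 = sum(ks3 < p$ks3_range[1] | ks3 > p$ks3_range[2]),
              gcse = sum(gcse < p$gcse_range[1] | gcse > p$gcse_range[2]))
  ks3 <- clip(ks3, p$ks3_range)
  gcse <- clip(gcse, p$gcse_range)

  ks5 <- stats::rbinom(n, 1L, stats::plogis(p$ks5_intercept + p$ks5_log_or * z_c))
  mother_iq <- p$mother_iq_mean + p$mother_iq_beta * z_m +
    stats::rnorm(n, sd = p$sd_mother_iq_resid)
  lat <- p$mother_edu_beta_latent * z_m +
    stats::rnorm(n, sd = sqrt(1 - p$mother_edu_beta_latent^2))
  mother_edu <- findInterval(lat, p$edu_thresholds) + 1L

  out <- data.frame(duo_id = duos$duo_ids,
                    child_id = rownames(duos$children),
                    mother_id = rownames(duos$mothers),
                    sex = duos$child_sex,
                    prs_child = z_c, prs_mother = z_m,
                    iq = iq, adhd_symptoms = adhd,
                    ks3 = ks3, gcse = gcse, ks5_sat = ks5,
                    mother_iq = mother_iq,
                    mother_education = mother_edu,
                    stringsAsFactors = FALSE)
  attr(out, "clipping") <- n_clip
  out
}
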