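#' Simulate a complete scored cohort
#'
#' End-to-end convenience for the synthetic world: simulate allele
#' frequencies, a liability-threshold discovery GWAS, Mendelian
#' mother-child duos, score both generations with the same discovery
#' weights (P < `p_threshold`, ambiguous SNPs dropped), standardize the
#' scores within each generation, and generate phenotypes from the
#' mediation preset. Each stage draws its seed from the root seed via a
#' named substream, so stages are independently reproducible.
#'
#' @param n_duos number of mother-child duos.
#' @param n_snps number of SNPs.
#' @param preset a [mediation_preset()].
#' @param seed root seed.
#' @param architecture an [architecture_spec()]; its `seed` is
#'   overwritten by the `"gwas"` substream.
#' @param p_threshold scoring P-value threshold (default 0.5).
#' @param freq_low,freq_high allele-frequency bounds.
#' @return A `prs_cohort` list: `freqs`, `sumstats`, `weights`, `duos`,
#'   `scores_child`, `scores_mother`, `phenotypes`, `seed`.
#' @export
simulate_cohort <- function(n_duos, n_snps = 2000L,
                            preset = mediation_preset(), seed = 1L,
                            architecture = architecture_spec(),
                            p_threshold = 0.5,
                            freq_low = 0.05, freq_high = 0.95) {
  freqs <- simulate_allele_freqs(n_snps, freq_low, freq_high,
                                 seed = derive_seed(seed, "freqs"))
  architecture$seed <- derive_seed(seed, "gwas")
  ss <- simulate_discovery_gwas(freqs, architecture)
  w <- select_weights(ss, p_threshold = p_threshold, drop_ambiguous = TRUE)
  duos <- simulate_duos(freqs, n_duos, seed = derive_seed(seed, "duos"),
                        p_male = preset$p_male)
  sc <- standardize_scores(compute_scores(duos$children, w))
  sm <- standardize_scores(compute_scores(duos$mothers, w))
  ph <- simulate_phenotypes(duos, sc, sm, preset,
                            seed = derive_seed(seed, "phenotypes"))
  structure(list(freqs = freqs, sumstats = ss, weights = w, duos = duos,
                 scores_child = sc, scores_mother = sm, phenotypes = ph,
                 seed = seed),
            class = "prs_cohort")
}

#' @export
print.prs_cohort <- function(x, ...) {
  cat(sprintf("<prs_cohort> %d duos, %d SNPs (%d scored), root seed %s\n",
              length(x$duos$duo_ids), length(x$freqs$snp_ids),
              nrow(x$weights), format(x$seed)))
  invisible(x)
}

pipeline_defaults <- function() {
  list(
    seed = 1, out_dir = "prsmediate_run", verbosity = "info",
    sim_n_snps = 2000, sim_n_duos = 2000,
    sim_n_causal = 200, sim_h2_liability = 0.3, sim_prevalence = 0.05,
    sim_n_cases = 727, sim_n_controls = 5081,
    score_p_threshold = 0.5, score_r2 = 0.25, score_window = 50,
    score_step = 5, score_missing_policy = "skip",
    score_drop_ambiguous = TRUE, score_pi_hat_threshold = 0.125,
    mediate_n_boot = 1000, mediate_ci_type = "percentile")
}

#' Pipeline configuration
#'
#' A flat, human-editable key-value configuration covering every stage
#' (keys are stage-prefixed: `sim_*`, `score_*`, `mediate_*`). Unknown
#' keys are rejected; the file representation round-trips losslessly.
#'
#' @param ... overrides of the default keys, e.g. `sim_n_duos = 500`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop_param("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration file
#'
#' The file format is one `key = value` pair per line; `#` starts a
#' comment. Types are restored from the defaults' types.
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, format(config[[k]], digits = 17))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop_param("malformed config line: ", lines[which(bad)[1]])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  defaults <- pipeline_defaults()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown)) {
    stop_param("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- defaults
  for (i in seq_along(keys)) {
    k <- keys[i]
    cfg[[k]] <- switch(class(defaults[[k]])[1],
                       numeric = as.numeric(vals[i]),
                       logical = as.logical(vals[i]),
                       vals[i])
  }
  structure(cfg, class = "pipeline_config")
}

run_logger <- function(path, level = "info") {
  levels <- c(debug = 0L, info = 1L, warning = 2L, error = 3L)
  min_lvl <- levels[[level]]
  function(lvl, msg, ...) {
    if (levels[[lvl]] < min_lvl) return(invisible())
    rec <- c(list(level = lvl, message = msg), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = path, append = TRUE, sep = "")
    invisible()
  }
}

assoc_row <- function(res, outcome, predictor) {
  est <- if (res$family == "logistic") res$odds_ratio else res$beta
  ci <- if (res$family == "logistic") res$or_ci else res$ci
  data.frame(Outcome = outcome, Predictor = predictor, N = res$n_used,
             Estimate = est, CI_low = ci[1], CI_high = ci[2],
             P = res$lrt_p, Delta_R2 = res$delta_nagelkerke_r2,
             stringsAsFactors = FALSE)
}

#' Run the full pipeline: simulate, score, filter, associate, mediate
#'
#' Executes every stage on the synthetic world described by the config
#' and writes the result bundle to the output directory: the simulated
#' summary statistics, genotype, score and phenotype files; association
#' tables shaped like the study's child-outcome, maternal-outcome and
#' cross-generation tables; single-mediator and two-mediator mediation
#' summaries; and a JSON-lines log recording every parameter and seed.
#' Any stage failure aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param preset a [mediation_preset()] (the generative phenotype world).
#' @return Invisibly, a list with the in-memory results (`cohort`,
#'   `table1`, `table2`, `table3`, `mediation`), with the output
#'   directory as attribute `out_dir`.
#' @export
run_all <- function(config = pipeline_config(), preset = mediation_preset()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log <- run_logger(file.path(out, "log.jsonl"), config$verbosity)
  log("info", "run-all started", config = unclass(config))
  write_config(config, file.path(out, "config.txt"))

  stage <- function(name, expr) {
    log("info", paste("stage", name, "started"))
    tryCatch(expr, error = function(e) {
      log("error", paste("stage", name, "failed"), detail = conditionMessage(e))
      stop_param(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }

  cohort <- NULL; flagged <- NULL
  stage("simulate", {
    freqs <- simulate_allele_freqs(config$sim_n_snps,
                                   seed = derive_seed(config$seed, "freqs"))
    arch <- architecture_spec(n_causal = config$sim_n_causal,
                              h2_liability = config$sim_h2_liability,
                              prevalence = config$sim_prevalence,
                              n_cases = config$sim_n_cases,
                              n_controls = config$sim_n_controls,
                              seed = derive_seed(config$seed, "gwas"))
    ss <- simulate_discovery_gwas(freqs, arch, keep_genotypes = TRUE,
                                  keep_max = 100L)
    duos <- simulate_duos(freqs, config$sim_n_duos,
                          seed = derive_seed(config$seed, "duos"),
                          p_male = preset$p_male)
    write_summary_stats(ss, file.path(out, "discovery_sumstats.tsv"))
    write_genotypes(duos$children, file.path(out, "genotypes_children.tsv"))
    write_genotypes(duos$mothers, file.path(out, "genotypes_mothers.tsv"))
    cohort <- list(freqs = freqs, sumstats = ss, duos = duos)
    log("info", "simulate done", n_snps = length(freqs$snp_ids),
        n_duos = length(duos$duo_ids))
  })

  stage("score", {
    pruned <- ld_prune(cohort$duos$children, r2_threshold = config$score_r2,
                       window_size = config$score_window,
                       step = config$score_step)
    w <- select_weights(cohort$sumstats,
                        p_threshold = config$score_p_threshold,
                        drop_ambiguous = isTRUE(config$score_drop_ambiguous),
                        keep_snps = pruned)
    sc <- standardize_scores(
      compute_scores(cohort$duos$children, w, config$score_missing_policy))
    sm <- standardize_scores(
      compute_scores(cohort$duos$mothers, w, config$score_missing_policy))
    write_table_tsv(sc, file.path(out, "scores_children.tsv"))
    write_table_tsv(sm, file.path(out, "scores_mothers.tsv"))
    cohort$weights <- w; cohort$scores_child <- sc; cohort$scores_mother <- sm
    log("info", "score done", n_pruned = length(pruned), n_selected = nrow(w))
  })

  stage("relatedness", {
    disc <- attr(cohort$sumstats, "genotypes")
    rel <- relatedness_filter(cohort$duos$children, disc,
                              pi_hat_threshold = config$score_pi_hat_threshold)
    flagged <- unique(rel$id_a[rel$flagged])
    if (length(flagged) > 0.2 * length(cohort$duos$duo_ids)) {
      # pi-hat SE is ~1/sqrt(n_snps); at toy SNP counts the 12.5% threshold
      # sits within sampling noise and unrelated pairs get mass-flagged
      warning(sprintf(paste("relatedness filter flagged %d of %d children;",
                            "pi-hat is unstable at %d SNPs"),
                      length(flagged), length(cohort$duos$duo_ids),
                      length(cohort$freqs$snp_ids)), call. = FALSE)
    }
    if (length(flagged)) {
      keep <- !(rownames(cohort$duos$children) %in% flagged)
      cohort$duos$children <- subset_geno(cohort$duos$children, rows = keep)
      cohort$duos$mothers <- subset_geno(cohort$duos$mothers, rows = keep)
      cohort$duos$duo_ids <- cohort$duos$duo_ids[keep]
      cohort$duos$child_sex <- cohort$duos$child_sex[keep]
      cohort$scores_child <- standardize_scores(
        compute_scores(cohort$duos$children, cohort$weights,
                       config$score_missing_policy))
      cohort$scores_mother <- standardize_scores(
        compute_scores(cohort$duos$mothers, cohort$weights,
                       config$score_missing_policy))
    }
    log("info", "relatedness done", n_flagged = length(flagged))
  })

  ph <- NULL
  stage("phenotypes", {
    ph <- simulate_phenotypes(cohort$duos, cohort$scores_child,
                               cohort$scores_mother, preset,
                               seed = derive_seed(config$seed, "phenotypes"))
    write_table_tsv(ph, file.path(out, "phenotypes.tsv"))
    log("info", "phenotypes done",
        clipped = as.list(attr(ph, "clipping")))
  })

  t1 <- t2 <- t3 <- NULL
  stage("associate", {
    t1 <- rbind(
      assoc_row(fit_model(ph, model_spec("iq", "prs_child", "sex")),
                "IQ age 15.5", "Child PRS"),
      assoc_row(fit_model(ph, model_spec("ks3", "prs_child", "sex")),
                "Key Stage 3 points", "Child PRS"),
      assoc_row(fit_model(ph, model_spec("gcse", "prs_child", "sex")),
                "Capped GCSE points", "Child PRS"),
      assoc_row(fit_model(ph, model_spec("ks5_sat", "prs_child", "sex",
                                         family = "logistic")),
                "Sat Key Stage 5", "Child PRS"))
    t2 <- rbind(
      assoc_row(fit_model(ph, model_spec("mother_education", "prs_mother")),
                "Mother's highest qualification", "Maternal PRS"),
      assoc_row(fit_model(ph, model_spec("mother_iq", "prs_mother")),
                "Maternal total IQ", "Maternal PRS"))
    t3 <- rbind(
      assoc_row(fit_model(ph, model_spec("ks3", "prs_mother",
                                         c("prs_child", "sex"))),
                "Key Stage 3 points", "Maternal PRS adj. child PRS"),
      assoc_row(fit_model(ph, model_spec("ks3", "prs_mother", "sex")),
                "Key Stage 3 points", "Maternal PRS"),
      assoc_row(fit_model(ph, model_spec("gcse", "prs_mother",
                                         c("prs_child", "sex"))),
                "Capped GCSE points", "Maternal PRS adj. child PRS"),
      assoc_row(fit_model(ph, model_spec("gcse", "prs_mother", "sex")),
                "Capped GCSE points", "Maternal PRS"),
      assoc_row(fit_model(ph, model_spec("mother_education", "prs_child",
                                         "prs_mother")),
                "Mother's highest qualification", "Child PRS adj. maternal PRS"))
    write_table_tsv(t1, file.path(out, "table1_child_outcomes.tsv"))
    write_table_tsv(t2, file.path(out, "table2_maternal_outcomes.tsv"))
    write_table_tsv(t3, file.path(out, "table3_cross_generation.tsv"))
    log("info", "associate done")
  })

  med <- NULL
  stage("mediate", {
    med_iq <- bootstrap_indirect(ph, "prs_child", "iq", "gcse", "sex",
                                 n_boot = config$mediate_n_boot,
                                 seed = derive_seed(config$seed, "bootstrap"),
                                 ci_type = config$mediate_ci_type)
    med_adhd <- bootstrap_indirect(ph, "prs_child", "adhd_symptoms", "gcse",
                                   "sex", n_boot = config$mediate_n_boot,
                                   seed = derive_seed(config$seed, "bootstrap"),
                                   ci_type = config$mediate_ci_type)
    med_multi <- multiple_mediation_sur(ph, "prs_child",
                                        c("iq", "adhd_symptoms"), "gcse",
                                        "sex", n_boot = config$mediate_n_boot,
                                        seed = derive_seed(config$seed, "bootstrap"),
                                        ci_type = config$mediate_ci_type)
    for (nm in c("iq", "adhd")) {
      obj <- if (nm == "iq") med_iq else med_adhd
      con <- file(file.path(out, sprintf("mediation_%s.txt", nm)), "w")
      sink(con); print(obj); sink(); close(con)
    }
    con <- file(file.path(out, "mediation_multi.txt"), "w")
    sink(con); print(med_multi); sink(); close(con)
    jl <- file.path(out, "mediation.jsonl")
    unlink(jl)
    for (obj in list(med_iq, med_adhd)) {
      rec <- obj[c("exposure", "mediator", "outcome", "a", "b", "c",
                   "c_prime", "indirect", "se_sobel", "z", "p",
                   "proportion_mediated", "n_used")]
      rec$bootstrap_ci <- obj$bootstrap$ci
      cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
          file = jl, append = TRUE, sep = "")
    }
    rec <- list(exposure = med_multi$exposure, mediators = med_multi$mediators,
                outcome = med_multi$outcome,
                indirect = as.list(med_multi$indirect),
                attribution = as.list(med_multi$attribution),
                total_indirect = med_multi$total_indirect,
                direct = med_multi$direct, total = med_multi$total,
                bootstrap_ci = med_multi$bootstrap$ci)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = jl, append = TRUE, sep = "")
    med <- list(iq = med_iq, adhd = med_adhd, multi = med_multi)
    log("info", "mediate done")
  })

  log("info", "run-all finished")
  res <- list(cohort = cohort, phenotypes = ph, table1 = t1, table2 = t2,
              table3 = t3, mediation = med, flagged = flagged)
  attr(res, "out_dir") <- out
  invisible(res)
}
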