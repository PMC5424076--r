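#' Simulate mother-child duos under Mendelian transmission
#'
#' Mothers are drawn from Hardy-Weinberg proportions at the given allele
#' frequencies; a father is simulated per duo from the same frequencies and
#' discarded (random mating); the child receives one uniformly chosen
#' maternal allele and one paternal allele per SNP. Under this model the
#' parent-offspring additive genotype correlation is 1/2 per SNP, and with
#' thousands of independent score SNPs the mother-child polygenic score
#' correlation is ~0.5 (cohort studies report ~0.46).
#'
#' Child sex is drawn independently of the genotypes (default 51.1% male,
#' the male fraction typical of population birth cohorts).
#'
#' @param freqs an `allele_freq_set`.
#' @param n_duos number of mother-child pairs.
#' @param seed integer seed.
#' @param p_male probability a child is male.
#' @return A `duo_cohort`: list with `mothers` and `children`
#'   (`geno_matrix`), `duo_ids`, and `child_sex` (`"male"`/`"female"`).
#' @export
simulate_duos <- function(freqs, n_duos, seed = 1L, p_male = 0.511) {
  stopifnot(inherits(freqs, "allele_freq_set"))
  n_duos <- check_count(n_duos, "n_duos")
  check_fraction(p_male, "p_male")
  set.seed(seed)
  mothers <- draw_hw_genotypes(freqs, n_duos)
  fathers <- draw_hw_genotypes(freqs, n_duos)
  # transmitted maternal allele: for g=1 a fair coin, for g=0/2 forced
  transmit <- function(g) {
    het <- g == 1L
    out <- g %/% 2L                       # 0 -> 0, 2 -> 1
    out[het] <- stats::rbinom(sum(het), 1L, 0.5)
    out
  }
  children <- transmit(mothers) + transmit(fathers)
  duo_ids <- sprintf("duo%d", seq_len(n_duos))
  mg <- geno_matrix(mothers, freqs$snp_ids, freqs$effect_allele, paste0(duo_ids, "_m"))
  cg <- geno_matrix(children, freqs$snp_ids, freqs$effect_allele, paste0(duo_ids, "_c"))
  sex <- ifelse(stats::runif(n_duos) < p_male, "male", "female")
  structure(list(mothers = mg, children = cg,
                 duo_ids = duo_ids, child_sex = sex),
            class = "duo_cohort")
}

#' @export
print.duo_cohort <- function(x, ...) {
  cat(sprintf("<duo_cohort> %d mother-child duos x %d SNPs (%.1f%% male children)\n",
              length(x$duo_ids), ncol(x$mothers),
              100 * mean(x$child_sex == "male")))
  invisible(x)
}

#' Check Mendelian consistency of a duo cohort
#'
#' For every duo x SNP, a maternal transmitted allele in \{0, 1\} compatible
#' with the maternal genotype must exist: a child cannot carry fewer than
#' `max(0, g_mother - 1)` nor more than `min(2, g_mother + 1)` copies once
#' the paternal allele is accounted for.
#'
#' @param duos a `duo_cohort`.
#' @return `TRUE` invisibly if consistent; otherwise an error listing the
#'   first violations.
#' @export
check_mendelian <- function(duos) {
  stopifnot(inherits(duos, "duo_cohort"))
  gm <- unclass(duos$mothers); gc <- unclass(duos$children)
  bad <- which(gc < pmax(0L, gm - 1L) | gc > pmin(2L, gm + 1L), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_param(sprintf("Mendelian inconsistency at %d duo x SNP entries (first: duo %d, SNP %d)",
                       nrow(bad), bad[1, 1], bad[1, 2]))
  }
  invisible(TRUE)
}
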