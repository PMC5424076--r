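#' Derive a reproducible substream seed
#'
#' All stochastic stages draw their seed from one root seed plus a stream
#' name, so that e.g. the genotype simulation can be reproduced without
#' re-running the discovery GWAS. The derivation is a simple polynomial
#' string hash folded into the root seed modulo 2^31 - 1, keeping the
#' result a valid R integer seed.
#'
#' @param root_seed integer root seed.
#' @param stream character scalar naming the substream
#'   (e.g. `"gwas"`, `"duos"`, `"phenotypes"`, `"bootstrap"`).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(root_seed, stream) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L, is.finite(root_seed))
  stopifnot(is.character(stream), length(stream) == 1L, nzchar(stream))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  s <- (abs(as.numeric(root_seed)) %% m)
  as.integer(((s * 48271) %% m + h) %% (m - 1) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

check_fraction <- function(x, name, lo = 0, hi = 1, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > lo && x < hi else x >= lo && x <= hi)
  if (!ok) {
    stop_param(sprintf("`%s` must be a fraction in %s%g, %g%s, got %s",
                       name, if (open) "(" else "[", lo, hi,
                       if (open) ")" else "]", format(x)))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    x >= min && x == round(x)
  if (!ok) stop_param(sprintf("`%s` must be an integer >= %d", name, min))
  invisible(as.integer(x))
}

#' @noRd
random_allele_pairs <- function(n, seed = NULL) {
  # unordered pairs of distinct nucleotides; 1/3 are strand-ambiguous (A/T, C/G)
  nt <- c("A", "C", "G", "T")
  a1 <- sample(nt, n, replace = TRUE)
  shift <- sample.int(3L, n, replace = TRUE)
  a2 <- nt[((match(a1, nt) - 1L + shift) %% 4L) + 1L]
  list(a1 = a1, a2 = a2)
}

#' Identify strand-ambiguous allele pairs
#'
#' A/T and C/G SNPs cannot be oriented across genotyping platforms without
#' strand information and are dropped from scoring by default.
#'
#' @param a1,a2 character vectors of alleles.
#' @return Logical vector, `TRUE` for ambiguous pairs.
#' @export
is_ambiguous_pair <- function(a1, a2) {
  p <- paste0(pmin(toupper(a1), toupper(a2)), pmax(toupper(a1), toupper(a2)))
  p %in% c("AT", "CG")
}
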