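# Population-callset variant filtering.

#' Per-variant missingness and minor allele frequency
#'
#' Missingness is the fraction of individuals with a missing genotype; the
#' minor allele frequency is computed over non-missing alleles only.
#'
#' @param callset A [pop_callset()].
#' @return Data frame with one row per variant: `missingness`, `maf`.
#' @export
variant_stats <- function(callset) {
  stopifnot(inherits(callset, "pop_callset"))
  g <- callset$geno
  n_obs <- colSums(!is.na(g))
  missingness <- colSums(is.na(g)) / nrow(g)   # exact ratio, no 1-x rounding
  alt_freq <- ifelse(n_obs > 0, colSums(g, na.rm = TRUE) / (2 * n_obs), NA_real_)
  data.frame(missingness = missingness, maf = pmin(alt_freq, 1 - alt_freq))
}

#' Filter a population callset on missingness and minor allele frequency
#'
#' Retains exactly the variants with genotype missingness strictly below
#' `max_missing` and minor allele frequency strictly above `min_maf` (the
#' standard panel-preparation filter for this analysis: missingness < 20%,
#' MAF > 1%). Individuals are never removed; the operation is idempotent.
#'
#' @param callset A [pop_callset()].
#' @param max_missing Missingness threshold in (0,1); variants with
#'   missingness `< max_missing` are kept.
#' @param min_maf MAF threshold in (0,1); variants with MAF `> min_maf` are
#'   kept.
#' @return The filtered [pop_callset()].
#' @export
filter_population_callset <- function(callset, max_missing = 0.20,
                                      min_maf = 0.01) {
  assert_scalar_prob(max_missing, "max_missing", lo_open = TRUE, hi_open = TRUE)
  assert_scalar_prob(min_maf, "min_maf", lo_open = TRUE, hi_open = TRUE)
  st <- variant_stats(callset)
  keep <- !is.na(st$maf) & st$missingness < max_missing & st$maf > min_maf
  message(sprintf("filter_population_callset: retained %d of %d variants (missingness < %g, MAF > %g)",
                  sum(keep), nrow(st), max_missing, min_maf))
  if (!any(keep)) warning("no variants pass the population filters", call. = FALSE)
  subset_variants(callset, which(keep))
}
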