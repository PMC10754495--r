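# Containers for the two variant callsets: the population reference panel
# (diploid genotypes for I individuals at V biallelic variants, optionally
# phased) and a soil sample's phased calls.

#' Construct a population variant callset
#'
#' The reference panel: diploid genotypes (alt-allele counts 0/1/2, `NA` for
#' missing) for `I` individuals at `V` biallelic variants, with optional
#' phasing. Usually produced by [read_population_vcf()] or
#' [simulate_population()] rather than called directly.
#'
#' @param individuals Character vector of sample identifiers (length `I`).
#' @param variants Data frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`; one row per variant, unique on all four columns jointly.
#' @param geno Integer `I x V` matrix of alt-allele counts in `{0,1,2}`, `NA`
#'   for missing.
#' @param hap1,hap2 Optional `I x V` matrices of per-chromosome alt-allele
#'   indicators (`0`/`1`), `NA` where the entry is unphased or missing.
#' @param ps Optional `I x V` matrix of phase-set identifiers (`NA` where
#'   unphased).
#' @param phased Optional logical `I x V` matrix recording which entries carry
#'   a phased (`|`) genotype separator.
#' @return An object of class `pop_callset`.
#' @export
pop_callset <- function(individuals, variants, geno,
                        hap1 = NULL, hap2 = NULL, ps = NULL, phased = NULL) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  obj <- structure(
    list(individuals = as.character(individuals), variants = variants,
         geno = geno, hap1 = hap1, hap2 = hap2, ps = ps, phased = phased),
    class = "pop_callset")
  validate_pop_callset(obj)
}

validate_variants <- function(variants) {
  need <- c("contig", "pos", "ref", "alt")
  if (!all(need %in% names(variants))) {
    stop("`variants` needs columns contig, pos, ref, alt", call. = FALSE)
  }
  if (nrow(variants)) {
    if (any(variants$pos < 1)) stop("variant positions must be >= 1", call. = FALSE)
    if (any(!nzchar(variants$ref)) || any(!nzchar(variants$alt))) {
      stop("ref and alt alleles must be non-empty", call. = FALSE)
    }
    if (any(variants$ref == variants$alt)) {
      stop("ref and alt alleles must differ", call. = FALSE)
    }
    keys <- variant_key(variants$contig, variants$pos, variants$ref, variants$alt)
    if (anyDuplicated(keys)) {
      stop("duplicate variant record(s): ",
           paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
    }
  }
  invisible(variants)
}

validate_pop_callset <- function(x) {
  stopifnot(inherits(x, "pop_callset"))
  validate_variants(x$variants)
  I <- length(x$individuals); V <- nrow(x$variants)
  if (!is.matrix(x$geno) || nrow(x$geno) != I || ncol(x$geno) != V) {
    stop(sprintf("genotype matrix must be %d x %d", I, V), call. = FALSE)
  }
  bad <- !(x$geno %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("genotypes must be alt-allele counts in {0,1,2} or NA",
                     call. = FALSE)
  if (anyDuplicated(x$individuals)) stop("duplicate individual identifiers",
                                         call. = FALSE)
  for (nm in c("hap1", "hap2", "ps", "phased")) {
    m <- x[[nm]]
    if (!is.null(m) && (!is.matrix(m) || any(dim(m) != c(I, V)))) {
      stop(sprintf("`%s` must be an %d x %d matrix", nm, I, V), call. = FALSE)
    }
  }
  if (!is.null(x$hap1) && !is.null(x$hap2)) {
    both <- !is.na(x$hap1) & !is.na(x$hap2) & !is.na(x$geno)
    if (any(both) && any((x$hap1 + x$hap2)[both] != x$geno[both])) {
      stop("phased alleles inconsistent with genotype counts", call. = FALSE)
    }
  }
  x
}

pop_keys <- function(pop) {
  variant_key(pop$variants$contig, pop$variants$pos,
              pop$variants$ref, pop$variants$alt)
}

# Subset a population callset to a set of variant indices, preserving order.
subset_variants <- function(pop, idx) {
  pop$variants <- pop$variants[idx, , drop = FALSE]
  rownames(pop$variants) <- NULL
  for (nm in c("geno", "hap1", "hap2", "ps", "phased")) {
    if (!is.null(pop[[nm]])) pop[[nm]] <- pop[[nm]][, idx, drop = FALSE]
  }
  pop
}

#' @export
print.pop_callset <- function(x, ...) {
  V <- nrow(x$variants)
  miss <- if (V) mean(is.na(x$geno)) else 0
  cat(sprintf("Population callset: %d individuals x %d variants (%.1f%% missing genotypes)\n",
              length(x$individuals), V, 100 * miss))
  if (!is.null(x$hap1)) cat("  phasing: present\n")
  invisible(x)
}

#' Construct a soil-sample callset
#'
#' Per-variant phased diploid calls from one environmental sample, each allele
#' recorded as an alt-allele indicator, with the phase-set identifier that
#' groups calls into haplotype blocks. Usually produced by [read_soil_vcf()]
#' or [simulate_soil_sample()].
#'
#' @param calls Data frame with columns `contig`, `pos`, `ref`, `alt`, `a1`,
#'   `a2` (alt-allele indicators in `{0,1}`), `phased` (logical), `ps`
#'   (phase-set identifier, `NA` when absent).
#' @param sample_id Sample identifier.
#' @return An object of class `soil_callset`.
#' @export
soil_callset <- function(calls, sample_id = "soil") {
  calls <- as.data.frame(calls, stringsAsFactors = FALSE)
  obj <- structure(list(sample_id = sample_id, calls = calls),
                   class = "soil_callset")
  validate_soil_callset(obj)
}

validate_soil_callset <- function(x) {
  stopifnot(inherits(x, "soil_callset"))
  calls <- x$calls
  need <- c("contig", "pos", "ref", "alt", "a1", "a2", "phased", "ps")
  if (!all(need %in% names(calls))) {
    stop("soil calls need columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  validate_variants(calls)
  if (nrow(calls)) {
    ok <- calls$a1 %in% c(0L, 1L, NA) & calls$a2 %in% c(0L, 1L, NA)
    if (!all(ok)) stop("soil alleles must be ref/alt indicators in {0,1}",
                       call. = FALSE)
    # a phase set must not span two contigs
    with_ps <- !is.na(calls$ps)
    if (any(with_ps)) {
      span <- tapply(calls$contig[with_ps], calls$ps[with_ps],
                     function(z) length(unique(z)))
      if (any(span > 1)) {
        stop("phase set(s) spanning multiple contigs: ",
             paste(names(span)[span > 1], collapse = ", "), call. = FALSE)
      }
    }
  }
  x
}

#' @export
print.soil_callset <- function(x, ...) {
  n <- nrow(x$calls)
  nps <- length(unique(x$calls$ps[!is.na(x$calls$ps)]))
  cat(sprintf("Soil callset '%s': %d calls in %d phase set(s)\n",
              x$sample_id, n, nps))
  invisible(x)
}
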