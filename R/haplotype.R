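# Haplotype construction from soil phase blocks, exact matching against the
# population panel, and per-individual haplotype agreement scores.

#' Restrict soil calls to variants present in the population callset
#'
#' A soil call is retained only when a population variant is identical in
#' location and alleles, i.e. the full `(contig, pos, ref, alt)` key matches.
#' This exact-match requirement is the guard against sequencing error in
#' degraded, error-prone environmental reads.
#'
#' @param soil A [soil_callset()].
#' @param pop A [pop_callset()].
#' @return The filtered [soil_callset()].
#' @export
intersect_variants <- function(soil, pop) {
  stopifnot(inherits(soil, "soil_callset"), inherits(pop, "pop_callset"))
  keys <- variant_key(soil$calls$contig, soil$calls$pos,
                      soil$calls$ref, soil$calls$alt)
  keep <- keys %in% pop_keys(pop)
  message(sprintf("intersect_variants: retained %d of %d soil calls",
                  sum(keep), length(keep)))
  if (!any(keep) && length(keep)) {
    warning("no soil calls match the population callset", call. = FALSE)
  }
  soil$calls <- soil$calls[keep, , drop = FALSE]
  rownames(soil$calls) <- NULL
  soil
}

new_haplotype <- function(contig, pos, ref, alt, allele, block) {
  ord <- order(pos)
  structure(list(contig = contig, pos = pos[ord], ref = ref[ord],
                 alt = alt[ord], allele = as.integer(allele[ord]),
                 block = block),
            class = "edna_haplotype")
}

hap_key <- function(h) {
  paste(h$contig, paste(h$pos, collapse = ","),
        paste(h$ref, h$alt, sep = ">", collapse = ","),
        paste(h$allele, collapse = ""), sep = "|")
}

#' @export
print.edna_haplotype <- function(x, ...) {
  cat(sprintf("Haplotype on %s (block %s), %d sites: %s\n", x$contig,
              as.character(x$block), length(x$pos),
              paste0(x$pos, ":", ifelse(x$allele == 1L, x$alt, x$ref),
                     collapse = " ")))
  invisible(x)
}

#' @export
print.edna_haplotypes <- function(x, ...) {
  cat(sprintf("%d soil haplotype(s)\n", length(x)))
  for (h in head(x, 10)) print(h)
  if (length(x) > 10) cat("...\n")
  invisible(x)
}

#' Assemble soil haplotypes from phase blocks
#'
#' Each phase block contributes its two phased allele strings as candidate
#' haplotypes. Unphased heterozygous calls carry no allele-to-chromosome
#' assignment and are excluded (and counted); homozygous calls without a
#' phase set are phase-constant and join every block whose positional span
#' encloses them on the same contig. Blocks shorter than `min_sites` are
#' discarded and duplicated haplotype observations are removed.
#'
#' @param soil A [soil_callset()], typically already passed through
#'   [intersect_variants()].
#' @param min_sites Minimum number of sites per haplotype (default 2; a
#'   single-site haplotype is just a genotype observation).
#' @return List of haplotypes with class `edna_haplotypes`.
#' @export
build_soil_haplotypes <- function(soil, min_sites = 2L) {
  stopifnot(inherits(soil, "soil_callset"), min_sites >= 1L)
  calls <- soil$calls
  if (!nrow(calls)) return(structure(list(), class = "edna_haplotypes"))
  in_block <- calls$phased & !is.na(calls$ps)
  het <- calls$a1 != calls$a2
  skipped_het <- sum(!in_block & het)
  if (skipped_het) {
    message(skipped_het, " unphased heterozygous call(s) excluded from haplotypes")
  }
  loose_hom <- which(!in_block & !het)
  blocks <- split(which(in_block),
                  paste(calls$contig[in_block], calls$ps[in_block], sep = "\r"))
  haps <- list()
  for (bn in names(blocks)) {
    idx <- blocks[[bn]]
    contig <- calls$contig[idx[1]]
    span <- range(calls$pos[idx])
    join <- loose_hom[calls$contig[loose_hom] == contig &
                        calls$pos[loose_hom] >= span[1] &
                        calls$pos[loose_hom] <= span[2] &
                        !(calls$pos[loose_hom] %in% calls$pos[idx])]
    idx <- c(idx, join)
    for (copy in 1:2) {
      al <- if (copy == 1) calls$a1[idx] else calls$a2[idx]
      haps[[length(haps) + 1L]] <- new_haplotype(
        contig, calls$pos[idx], calls$ref[idx], calls$alt[idx], al,
        block = calls$ps[blocks[[bn]][1]])
    }
  }
  haps <- haps[vapply(haps, function(h) length(h$pos) >= min_sites, logical(1))]
  if (length(haps)) haps <- haps[!duplicated(vapply(haps, hap_key, ""))]
  structure(haps, class = "edna_haplotypes")
}

# Match one haplotype against every individual at once.
# Returns an integer vector over individuals with values 1/0/NA.
match_haplotype_all <- function(h, pop, mode = c("consistency", "phased")) {
  mode <- match.arg(mode)
  cols <- match(variant_key(h$contig, h$pos, h$ref, h$alt), pop_keys(pop))
  if (anyNA(cols)) {
    stop("haplotype site(s) absent from the population callset: ",
         paste(h$pos[is.na(cols)], collapse = ", "), call. = FALSE)
  }
  k <- length(cols)
  G <- pop$geno[, cols, drop = FALSE]
  I <- nrow(G)
  req <- matrix(h$allele, I, k, byrow = TRUE)
  if (mode == "consistency") {
    ok <- (req == 1L & G >= 1L) | (req == 0L & G <= 1L)
    res <- as.integer(rowSums(ok) == k)    # NA genotype anywhere -> NA
  } else {
    if (is.null(pop$hap1)) return(rep(NA_integer_, I))
    H1 <- pop$hap1[, cols, drop = FALSE]
    H2 <- pop$hap2[, cols, drop = FALSE]
    PS <- pop$ps[, cols, drop = FALSE]
    one_block <- rowSums(PS == PS[, 1]) == k   # NA if any PS missing
    m1 <- rowSums(H1 == req) == k
    m2 <- rowSums(H2 == req) == k
    res <- as.integer(m1 | m2)
    res[is.na(m1) | is.na(m2) | is.na(one_block)] <- NA_integer_
    res[!is.na(one_block) & !one_block] <- NA_integer_
  }
  names(res) <- pop$individuals
  res
}

#' Match a haplotype against one individual
#'
#' In `consistency` mode the indicator is 1 iff, at every site, the
#' haplotype's allele is carried by the individual's (unphased) genotype: an
#' alt allele requires an alt-allele count of at least 1, a ref allele a count
#' of at most 1. In `phased` mode it is 1 iff one of the individual's phased
#' chromosomes carries exactly the haplotype's alleles across all sites within
#' a single population phase block. The result is `NA` (missing) whenever any
#' required genotype — or, in phased mode, phase — of the individual is
#' missing at any site.
#'
#' @param h A haplotype from [build_soil_haplotypes()].
#' @param pop A [pop_callset()] containing every site of `h`.
#' @param individual Individual identifier.
#' @param mode `"consistency"` (default) or `"phased"`.
#' @return `1L`, `0L`, or `NA`.
#' @export
match_individual <- function(h, pop, individual,
                             mode = c("consistency", "phased")) {
  i <- match(individual, pop$individuals)
  if (is.na(i)) stop("unknown individual: ", individual, call. = FALSE)
  unname(match_haplotype_all(h, pop, mode)[i])
}

#' Retain haplotypes carried by at least one population individual
#'
#' Only haplotypes that match between the soil sample and the population
#' callset are kept (indicator 1 for at least one individual); haplotypes with
#' all indicators missing are also removed.
#'
#' @param haps Haplotype list from [build_soil_haplotypes()].
#' @param pop A [pop_callset()].
#' @param mode Matching mode, see [match_individual()].
#' @return The retained haplotypes (`edna_haplotypes`).
#' @export
filter_population_matched <- function(haps, pop,
                                      mode = c("consistency", "phased")) {
  mode <- match.arg(mode)
  keep <- vapply(haps, function(h) {
    r <- match_haplotype_all(h, pop, mode)
    isTRUE(any(r == 1L, na.rm = TRUE))
  }, logical(1))
  message(sprintf("filter_population_matched: retained %d of %d haplotypes",
                  sum(keep), length(keep)))
  structure(unclass(haps)[keep], class = "edna_haplotypes")
}

#' Construct a match matrix
#'
#' Wraps a raw J x I indicator matrix (1 = match, 0 = mismatch, `NA` =
#' missing) together with its mean-imputed view: each missing entry is
#' replaced by the mean of the non-missing entries of its row (per-haplotype
#' mean imputation across individuals). Rows with all entries missing are
#' removed before imputation.
#'
#' @param raw J x I matrix with entries in `{0, 1, NA}`.
#' @param individuals Individual identifiers (default: `colnames(raw)`).
#' @param haplotypes Optional haplotype list aligned with the rows.
#' @return An object of class `match_matrix` with elements `raw`, `imputed`,
#'   `individuals`, `haplotypes`.
#' @export
match_matrix <- function(raw, individuals = colnames(raw), haplotypes = NULL) {
  raw <- as.matrix(raw)
  if (is.null(individuals)) individuals <- paste0("ind", seq_len(ncol(raw)))
  if (!all(raw %in% c(0L, 1L, NA))) {
    stop("raw match indicators must be 0, 1 or NA", call. = FALSE)
  }
  all_missing <- rowSums(!is.na(raw)) == 0L
  if (any(all_missing)) {
    message(sum(all_missing), " fully-missing haplotype row(s) removed")
    raw <- raw[!all_missing, , drop = FALSE]
    if (!is.null(haplotypes)) haplotypes <- haplotypes[!all_missing]
  }
  if (nrow(raw) == 0L) stop("no haplotypes retained", call. = FALSE)
  storage.mode(raw) <- "integer"
  imputed <- raw
  storage.mode(imputed) <- "double"
  rm_ <- rowMeans(raw, na.rm = TRUE)
  nas <- which(is.na(imputed), arr.ind = TRUE)
  if (nrow(nas)) imputed[nas] <- rm_[nas[, 1]]
  dimnames(raw) <- dimnames(imputed) <- list(NULL, individuals)
  structure(list(raw = raw, imputed = imputed,
                 individuals = as.character(individuals),
                 haplotypes = haplotypes),
            class = "match_matrix")
}

#' @export
print.match_matrix <- function(x, ...) {
  cat(sprintf("Match matrix: %d haplotypes x %d individuals (%d missing indicator(s))\n",
              nrow(x$raw), ncol(x$raw), sum(is.na(x$raw))))
  invisible(x)
}

#' Build the haplotype x individual match matrix
#'
#' Applies [match_individual()] for every retained haplotype and individual
#' and assembles the raw and mean-imputed views.
#'
#' @param haps Haplotypes, already passed through
#'   [filter_population_matched()].
#' @param pop A [pop_callset()].
#' @param mode Matching mode, see [match_individual()].
#' @return A [match_matrix()].
#' @export
build_match_matrix <- function(haps, pop, mode = c("consistency", "phased")) {
  mode <- match.arg(mode)
  if (length(haps) == 0L) stop("no haplotypes retained", call. = FALSE)
  raw <- t(vapply(haps, match_haplotype_all, integer(length(pop$individuals)),
                  pop = pop, mode = mode))
  match_matrix(raw, individuals = pop$individuals, haplotypes = unclass(haps))
}

#' Per-individual haplotype agreement scores
#'
#' For each individual, the percentage of the sample's retained haplotypes
#' that the individual carries, computed over the haplotypes whose indicator
#' is non-missing for that individual: `score = 100 * n_matched /
#' n_evaluated`. Individuals with no evaluable haplotype get `NA` (not
#' assessable).
#'
#' @param M A [match_matrix()].
#' @return A data frame of class `agreement_report` with columns `individual`,
#'   `n_matched`, `n_evaluated`, `score`, and attribute `J_total` (number of
#'   retained haplotypes).
#' @export
agreement_scores <- function(M) {
  stopifnot(inherits(M, "match_matrix"))
  raw <- M$raw
  n_eval <- colSums(!is.na(raw))
  n_match <- colSums(raw == 1L, na.rm = TRUE)
  score <- ifelse(n_eval > 0L, 100 * n_match / n_eval, NA_real_)
  out <- data.frame(individual = M$individuals, n_matched = n_match,
                    n_evaluated = n_eval, score = score,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "J_total") <- nrow(raw)
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' @export
print.agreement_report <- function(x, n = 10L, ...) {
  cat(sprintf("Haplotype agreement scores (J = %d retained haplotypes)\n",
              attr(x, "J_total")))
  ord <- order(-replace(x$score, is.na(x$score), -Inf), x$individual)
  print.data.frame(head(x[ord, , drop = FALSE], n), row.names = FALSE)
  if (nrow(x) > n) cat("... (", nrow(x) - n, " more)\n", sep = "")
  invisible(x)
}
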