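# Small in-code fixtures shared across tests.

# A hand-specified population callset. `geno` is an I x V matrix of
# alt-allele counts; variants default to one contig, distinct positions,
# A>G at every site unless overridden.
tiny_pop <- function(geno, individuals = NULL, contig = "S1", pos = NULL,
                     ref = NULL, alt = NULL) {
  geno <- as.matrix(geno)
  I <- nrow(geno); V <- ncol(geno)
  if (is.null(individuals)) individuals <- LETTERS[seq_len(I)]
  if (is.null(pos)) pos <- 100L * seq_len(V)
  if (is.null(ref)) ref <- rep("A", V)
  if (is.null(alt)) alt <- rep("G", V)
  rownames(geno) <- individuals
  pop_callset(individuals,
              data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE),
              geno)
}

# A haplotype object matching the internal layout produced by
# build_soil_haplotypes().
tiny_hap <- function(pos, allele, contig = "S1", ref = NULL, alt = NULL,
                     block = "b1") {
  V <- length(pos)
  if (is.null(ref)) ref <- rep("A", V)
  if (is.null(alt)) alt <- rep("G", V)
  structure(list(contig = contig, pos = as.integer(pos), ref = ref, alt = alt,
                 allele = as.integer(allele), block = block),
            class = "edna_haplotype")
}

as_hapset <- function(...) structure(list(...), class = "edna_haplotypes")

# Write VCF body lines under a minimal valid header.
write_test_vcf <- function(records, samples, extra_header = character(0)) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=S1>", "##contig=<ID=S2>",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">",
               extra_header,
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t"),
               records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, fmt, ...) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", fmt, ...),
        collapse = "\t")
}

# Independent brute-force oracle for consistency-mode matching: enumerate
# every per-site allele assignment allowed by the individual's genotypes and
# test whether the haplotype's allele string is among them.
oracle_consistency <- function(h, pop, individual) {
  i <- match(individual, pop$individuals)
  keys <- paste(pop$variants$contig, pop$variants$pos, pop$variants$ref,
                pop$variants$alt)
  cols <- match(paste(h$contig, h$pos, h$ref, h$alt), keys)
  g <- pop$geno[i, cols]
  if (anyNA(g)) return(NA_integer_)
  allowed <- lapply(g, function(x) switch(as.character(x),
                                          "0" = 0L, "1" = c(0L, 1L), "2" = 1L))
  grid <- as.matrix(expand.grid(allowed))
  hit <- any(apply(grid, 1, function(row) all(row == h$allele)))
  as.integer(hit)
}

# One simulated sample pushed through matching, shared by several tests.
simulate_matched <- function(I = 20, V = 200, contributors = "ind001",
                             weights = NULL, J = 12, site_error = 0,
                             missingness = 0.05, mode = "consistency",
                             seed = 1, pedigree = NULL, alien_fraction = 0) {
  pop <- simulate_population(I, V, block_length = 5, missingness = missingness,
                             pedigree = pedigree, seed = seed)
  sim <- simulate_soil_sample(pop, contributors, weights, J = J,
                              site_error = site_error,
                              alien_fraction = alien_fraction, seed = seed + 1)
  haps <- suppressMessages(
    filter_population_matched(
      build_soil_haplotypes(suppressMessages(intersect_variants(sim$soil, pop))),
      pop, mode))
  M <- suppressMessages(build_match_matrix(haps, pop, mode))
  list(pop = pop, sim = sim, haps = haps, M = M)
}
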