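# Synthetic population callsets and soil samples with full ground truth, so
# every downstream stage is testable without controlled-access data.

#' Simulate a population variant callset
#'
#' Founders' chromosome alleles are drawn independently per site with
#' alt-allele probability equal to the site's minor allele frequency, drawn
#' uniformly from `maf_range`. Variants are laid out on `n_contigs` contigs
#' and grouped into phase blocks of `block_length` consecutive sites.
#' Pedigree children inherit one whole per-block haplotype from each parent
#' (Mendelian segregation per block, no recombination within a block).
#' Genotype missingness is applied to the released callset after the phased
#' truth is stored, so the ground truth stays complete.
#'
#' @param I Number of individuals.
#' @param V Number of biallelic variants.
#' @param n_contigs Number of contigs the variants are spread over.
#' @param block_length Sites per phase block.
#' @param maf_range Range of the uniform minor-allele-frequency law, within
#'   (0, 0.5].
#' @param missingness Per-entry probability of a missing genotype, in
#'   \[0, 0.5).
#' @param pedigree Optional data frame (or list of length-3 vectors) with
#'   columns/elements `child`, `parentA`, `parentB`, all referring to
#'   identifiers among the `I` individuals; listed children receive inherited
#'   rather than founder genotypes, in order, so chains are allowed.
#' @param seed Optional integer seed; fixed seed gives identical callsets.
#' @return A [pop_callset()] with phased entries; the complete phased truth is
#'   attached as `attr(, "sim")` (full `hap1`/`hap2`, per-site `maf`, block
#'   layout, pedigree).
#' @export
simulate_population <- function(I, V, n_contigs = 1L, block_length = 5L,
                                maf_range = c(0.05, 0.5), missingness = 0,
                                pedigree = NULL, seed = NULL) {
  stopifnot(I >= 1L, V >= 1L, n_contigs >= 1L, block_length >= 1L)
  assert_scalar_prob(missingness, "missingness", lo = 0, hi = 0.5, hi_open = TRUE)
  stopifnot(length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  maybe_seed(seed)
  individuals <- sprintf("ind%03d", seq_len(I))

  contig_of <- sort(rep_len(seq_len(n_contigs), V))
  pos <- unlist(lapply(split(seq_len(V), contig_of), function(ix)
    1000L * seq_along(ix)), use.names = FALSE)
  contig <- paste0("chr", contig_of)
  # phase blocks: consecutive runs of block_length sites within a contig
  block_of <- integer(V); nb <- 0L
  for (cg in unique(contig_of)) {
    ix <- which(contig_of == cg)
    local_block <- (seq_along(ix) - 1L) %/% block_length
    block_of[ix] <- nb + local_block + 1L
    nb <- nb + max(local_block) + 1L
  }
  # phase-set ids: block start position, offset per contig so they are
  # globally unique even though positions restart on every contig
  ps_of <- vapply(seq_len(V), function(j)
    10000000L * contig_of[j] + pos[which(block_of == block_of[j])[1]],
    integer(1))

  maf <- runif(V, maf_range[1], maf_range[2])
  base <- c("A", "C", "G", "T")
  ref <- sample(base, V, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(base, r), 1L), character(1))
  variants <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                         stringsAsFactors = FALSE)

  hap1 <- matrix(rbinom(I * V, 1L, rep(maf, each = I)), I, V)
  hap2 <- matrix(rbinom(I * V, 1L, rep(maf, each = I)), I, V)
  rownames(hap1) <- rownames(hap2) <- individuals

  if (!is.null(pedigree)) {
    if (!is.data.frame(pedigree)) {
      pedigree <- as.data.frame(do.call(rbind, pedigree),
                                stringsAsFactors = FALSE)
      names(pedigree) <- c("child", "parentA", "parentB")
    }
    blocks_idx <- split(seq_len(V), block_of)
    done <- setdiff(individuals, pedigree$child)
    for (r in seq_len(nrow(pedigree))) {
      ch <- pedigree$child[r]; pa <- pedigree$parentA[r]; pb <- pedigree$parentB[r]
      if (!all(c(ch, pa, pb) %in% individuals) || !all(c(pa, pb) %in% done)) {
        stop("invalid pedigree row ", r,
             ": child and parents must exist and parents must precede children",
             call. = FALSE)
      }
      for (bix in blocks_idx) {
        hap1[ch, bix] <- if (runif(1) < 0.5) hap1[pa, bix] else hap2[pa, bix]
        hap2[ch, bix] <- if (runif(1) < 0.5) hap1[pb, bix] else hap2[pb, bix]
      }
      done <- c(done, ch)
    }
  }

  geno <- hap1 + hap2
  ps <- matrix(rep(as.character(ps_of), each = I), I, V)
  phased <- matrix(TRUE, I, V)
  if (missingness > 0) {
    mask <- matrix(runif(I * V) < missingness, I, V)
    geno[mask] <- NA_integer_
    phased[mask] <- FALSE
  }
  h1 <- hap1; h2 <- hap2
  h1[!phased] <- NA_integer_; h2[!phased] <- NA_integer_
  ps[!phased] <- NA_character_
  rownames(geno) <- rownames(ps) <- rownames(phased) <- individuals

  out <- pop_callset(individuals, variants, geno, hap1 = h1, hap2 = h2,
                     ps = ps, phased = phased)
  attr(out, "sim") <- list(hap1 = hap1, hap2 = hap2, maf = maf,
                           block_of = block_of, ps_of = ps_of,
                           pedigree = pedigree, seed = seed)
  out
}

#' Simulate a soil sample from a weighted mixture of contributors
#'
#' Each of the `J` haplotype observations draws a contributor according to
#' `weights`, a chromosome copy uniformly, and a phase block uniformly
#' (without replacement across observations, so the emitted VCF keeps one
#' record per site); the block is truncated to a drawn number of sites
#' (shifted Poisson, minimum `sites_min`, mean `sites_mean`) and each allele
#' is flipped with probability `site_error`. With probability
#' `alien_fraction` an observation instead carries uniformly random alleles —
#' background DNA whose haplotype need not exist in the population. Every
#' observation is emitted as one sequenced molecule: a phased record pair
#' `a|a` under a fresh phase set.
#'
#' @param pop A simulated [pop_callset()] from [simulate_population()] (the
#'   attached phased truth is required).
#' @param contributors Identifiers of the contributing individuals.
#' @param weights Positive mixing weights, same length, summing to 1
#'   (default: equal).
#' @param J Number of haplotype observations.
#' @param sites_mean,sites_min Shifted-Poisson law for sites per haplotype.
#' @param site_error Per-site allele-flip probability in \[0, 0.5).
#' @param alien_fraction Fraction of observations with random alleles, in
#'   \[0, 1).
#' @param seed Optional integer seed.
#' @param sample_id Identifier for the emitted soil callset.
#' @return A list with elements `soil` (a [soil_callset()]) and `truth` (data
#'   frame with per-observation source individual, chromosome copy, block,
#'   error count and alien flag).
#' @export
simulate_soil_sample <- function(pop, contributors, weights = NULL, J = 30L,
                                 sites_mean = 4, sites_min = 2L,
                                 site_error = 0, alien_fraction = 0,
                                 seed = NULL, sample_id = "soil") {
  sim <- attr(pop, "sim")
  if (is.null(sim)) stop("`pop` must come from simulate_population()", call. = FALSE)
  if (!all(contributors %in% pop$individuals)) {
    stop("contributor(s) not in the population: ",
         paste(setdiff(contributors, pop$individuals), collapse = ", "),
         call. = FALSE)
  }
  nc <- length(contributors)
  if (is.null(weights)) weights <- rep(1 / nc, nc)
  stopifnot(length(weights) == nc, all(weights > 0))
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)
  assert_scalar_prob(site_error, "site_error", lo = 0, hi = 0.5, hi_open = TRUE)
  assert_scalar_prob(alien_fraction, "alien_fraction", lo = 0, hi = 1,
                     hi_open = TRUE)
  stopifnot(sites_min >= 1L, sites_mean >= sites_min)
  maybe_seed(seed)

  blocks_idx <- split(seq_len(nrow(pop$variants)), sim$block_of)
  if (J > length(blocks_idx)) {
    stop(sprintf("J = %d exceeds the %d available phase blocks", J,
                 length(blocks_idx)), call. = FALSE)
  }
  picked_blocks <- sample(names(blocks_idx), J)
  src <- sample(contributors, J, replace = TRUE, prob = weights)
  copy <- sample(1:2, J, replace = TRUE)
  alien <- runif(J) < alien_fraction
  k_sites <- pmax(sites_min, sites_min + rpois(J, max(0, sites_mean - sites_min)))

  rows <- vector("list", J)
  truth <- data.frame(obs = seq_len(J),
                      contributor = ifelse(alien, NA_character_, src),
                      copy = ifelse(alien, NA_integer_, copy),
                      block = picked_blocks, n_sites = NA_integer_,
                      n_errors = 0L, alien = alien,
                      stringsAsFactors = FALSE)
  for (o in seq_len(J)) {
    bix <- blocks_idx[[picked_blocks[o]]]
    k <- min(k_sites[o], length(bix))
    bix <- bix[seq_len(k)]
    if (alien[o]) {
      al <- rbinom(k, 1L, 0.5)
    } else {
      hap <- if (copy[o] == 1) sim$hap1 else sim$hap2
      al <- hap[src[o], bix]
      flips <- runif(k) < site_error
      al[flips] <- 1L - al[flips]
      truth$n_errors[o] <- sum(flips)
    }
    truth$n_sites[o] <- k
    rows[[o]] <- data.frame(contig = pop$variants$contig[bix],
                            pos = pop$variants$pos[bix],
                            ref = pop$variants$ref[bix],
                            alt = pop$variants$alt[bix],
                            a1 = as.integer(al), a2 = as.integer(al),
                            phased = TRUE,
                            ps = as.character(sim$ps_of[bix[1]]),
                            stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, rows)
  calls <- calls[order(calls$contig, calls$pos), , drop = FALSE]
  rownames(calls) <- NULL
  list(soil = soil_callset(calls, sample_id = sample_id), truth = truth)
}

fixture_scenarios <- list(
  single = list(I = 20L, V = 250L, block_length = 5L, missingness = 0.05,
                contributors = "ind001", weights = 1, J = 15L,
                site_error = 0, alien_fraction = 0, pedigree = TRUE),
  pair = list(I = 20L, V = 250L, block_length = 5L, missingness = 0.05,
              contributors = c("ind001", "ind002"), weights = c(0.5, 0.5),
              J = 30L, site_error = 0.02, alien_fraction = 0, pedigree = TRUE),
  trio_with_relative = list(I = 20L, V = 250L, block_length = 5L,
                            missingness = 0.05,
                            contributors = c("ind001", "ind003", "ind004"),
                            weights = c(0.5, 0.3, 0.2), J = 30L,
                            site_error = 0.02, alien_fraction = 0,
                            pedigree = TRUE),
  crowded = list(I = 20L, V = 250L, block_length = 5L, missingness = 0.05,
                 contributors = sprintf("ind%03d", 1:6),
                 weights = c(6, 5, 4, 3, 2, 1) / 21, J = 40L,
                 site_error = 0.05, alien_fraction = 0.1, pedigree = TRUE)
)

#' Write a ready-made synthetic fixture to disk
#'
#' Generates a population VCF, a soil VCF, a ground-truth TSV and the
#' configuration used, for one of four scenarios: `"single"` (one error-free
#' contributor), `"pair"` (two equal contributors with sequencing error),
#' `"trio_with_relative"` (three contributors; the panel contains a
#' parent-offspring pair, `ind020` being the offspring of contributor
#' `ind001`, to exercise relative confusion), and `"crowded"` (six
#' contributors, higher error, alien haplotypes). Regenerating with the same
#' seed reproduces the files byte for byte.
#'
#' @param dir Output directory (created if needed).
#' @param scenario One of `"single"`, `"pair"`, `"trio_with_relative"`,
#'   `"crowded"`.
#' @param seed Integer seed.
#' @return Named character vector of the written file paths, invisibly.
#' @export
make_fixture <- function(dir, scenario = c("single", "pair",
                                           "trio_with_relative", "crowded"),
                         seed = 1L) {
  scenario <- match.arg(scenario)
  cfg <- fixture_scenarios[[scenario]]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ped <- data.frame(child = "ind020", parentA = "ind001", parentB = "ind002",
                    stringsAsFactors = FALSE)
  pop <- simulate_population(cfg$I, cfg$V, block_length = cfg$block_length,
                             missingness = cfg$missingness, pedigree = ped,
                             seed = stage_seed(seed, paste0("pop_", scenario)))
  sim <- simulate_soil_sample(pop, cfg$contributors, cfg$weights, J = cfg$J,
                              site_error = cfg$site_error,
                              alien_fraction = cfg$alien_fraction,
                              seed = stage_seed(seed, paste0("soil_", scenario)),
                              sample_id = paste0("soil_", scenario))
  paths <- c(population = file.path(dir, "population.vcf"),
             soil = file.path(dir, "soil.vcf"),
             truth = file.path(dir, "truth.tsv"),
             config = file.path(dir, "config.json"))
  write_vcf(pop, paths[["population"]])
  write_vcf(sim$soil, paths[["soil"]])
  write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(c(list(scenario = scenario, seed = seed,
                              pedigree = ped), cfg[names(cfg) != "pedigree"]),
                       paths[["config"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
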