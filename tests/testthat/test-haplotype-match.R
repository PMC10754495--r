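# Haplotype construction, exact matching and agreement scores.

test_that("variant intersection requires identity of location and alleles", {
  pop <- tiny_pop(matrix(1L, 2, 1), pos = 100L)   # S1:100 A>G
  mk <- function(pos, ref, alt) {
    soil_callset(data.frame(contig = "S1", pos = pos, ref = ref, alt = alt,
                            a1 = 0L, a2 = 1L, phased = TRUE, ps = "1",
                            stringsAsFactors = FALSE))
  }
  expect_equal(nrow(suppressMessages(intersect_variants(mk(100L, "A", "G"), pop))$calls), 1L)
  expect_equal(nrow(suppressWarnings(suppressMessages(
    intersect_variants(mk(100L, "A", "T"), pop)))$calls), 0L)
  expect_equal(nrow(suppressWarnings(suppressMessages(
    intersect_variants(mk(101L, "A", "G"), pop)))$calls), 0L)
})

test_that("phase blocks yield two haplotypes, thresholded and deduplicated", {
  calls <- data.frame(
    contig = "S1", pos = c(100L, 200L, 300L),
    ref = "A", alt = "G",
    a1 = c(0L, 1L, 0L), a2 = c(1L, 0L, 1L),
    phased = TRUE, ps = "100", stringsAsFactors = FALSE)
  haps <- build_soil_haplotypes(soil_callset(calls))
  expect_length(haps, 2L)
  expect_equal(haps[[1]]$allele, c(0L, 1L, 0L))
  expect_equal(haps[[2]]$allele, c(1L, 0L, 1L))
  # single-site block falls below min_sites = 2
  one <- soil_callset(data.frame(contig = "S1", pos = 100L, ref = "A",
                                 alt = "G", a1 = 0L, a2 = 1L, phased = TRUE,
                                 ps = "100", stringsAsFactors = FALSE))
  expect_length(build_soil_haplotypes(one), 0L)
  expect_length(build_soil_haplotypes(one, min_sites = 1L), 2L)
  # an all-homozygous block collapses to one haplotype after deduplication
  hom <- calls; hom$a1 <- c(1L, 0L, 1L); hom$a2 <- hom$a1
  expect_length(build_soil_haplotypes(soil_callset(hom)), 1L)
})

test_that("unphased het calls are excluded; loose homozygous calls join spanning blocks", {
  calls <- data.frame(
    contig = "S1", pos = c(100L, 300L, 200L, 150L, 500L),
    ref = "A", alt = "G",
    a1 = c(0L, 1L, 0L, 1L, 1L), a2 = c(1L, 0L, 1L, 1L, 0L),
    phased = c(TRUE, TRUE, FALSE, FALSE, FALSE),
    ps = c("100", "100", NA, NA, NA), stringsAsFactors = FALSE)
  expect_message(haps <- build_soil_haplotypes(soil_callset(calls)),
                 "unphased heterozygous")
  # block spans 100-300: the hom call at 150 joins it, the unphased het at
  # 200 and the hom outside the span at 500 do not
  expect_length(haps, 2L)
  expect_equal(haps[[1]]$pos, c(100L, 150L, 300L))
  expect_equal(haps[[1]]$allele, c(0L, 1L, 1L))
  expect_equal(haps[[2]]$allele, c(1L, 1L, 0L))
})

test_that("consistency matching follows the carried-allele rule with missing propagation", {
  # sites S1:100 A>G and S1:200 A>T; alleles required: G (alt), T (alt)
  pop <- tiny_pop(rbind(c(1L, 2L), c(0L, 2L), c(1L, NA)),
                  alt = c("G", "T"))
  h <- tiny_hap(c(100L, 200L), c(1L, 1L), alt = c("G", "T"))
  expect_equal(match_individual(h, pop, "A"), 1L)   # A/G + T/T carries both
  expect_equal(match_individual(h, pop, "B"), 0L)   # A/A at 100
  expect_true(is.na(match_individual(h, pop, "C"))) # missing genotype at 200
  # ref allele requires alt count <= 1
  href <- tiny_hap(100L, 0L, ref = "A", alt = "G")
  pop1 <- tiny_pop(matrix(c(2L, 1L), 2, 1))
  expect_equal(match_individual(href, pop1, "A"), 0L)
  expect_equal(match_individual(href, pop1, "B"), 1L)
  expect_error(match_individual(tiny_hap(c(100L, 999L), c(1L, 1L)), pop, "A"),
               "absent")
})

test_that("consistency matching agrees with the brute-force enumeration oracle", {
  set.seed(71)
  for (rep in 1:30) {
    I <- sample(2:6, 1); k <- sample(1:5, 1)
    geno <- matrix(sample(c(0:2, NA), I * k, replace = TRUE,
                          prob = c(.3, .3, .3, .1)), I, k)
    pop <- tiny_pop(geno, individuals = sprintf("i%d", seq_len(I)))
    h <- tiny_hap(100L * seq_len(k), sample(0:1, k, replace = TRUE))
    for (ind in pop$individuals) {
      expect_identical(match_individual(h, pop, ind),
                       oracle_consistency(h, pop, ind))
    }
  }
})

test_that("phased matching requires one chromosome in one phase block", {
  g <- rbind(c(1L, 1L), c(1L, 1L), c(1L, 1L))
  ind <- c("A", "B", "C")
  h1 <- rbind(c(1L, 0L), c(0L, 0L), c(1L, 0L))
  h2 <- rbind(c(0L, 1L), c(1L, 1L), c(0L, 1L))
  ps <- rbind(c("1", "1"), c("1", "1"), c("1", "2"))  # C spans two blocks
  pop <- pop_callset(ind,
                     data.frame(contig = "S1", pos = c(100L, 200L),
                                ref = "A", alt = "G"),
                     structure(g, dimnames = list(ind, NULL)),
                     hap1 = h1, hap2 = h2, ps = ps,
                     phased = matrix(TRUE, 3, 2))
  h <- tiny_hap(c(100L, 200L), c(1L, 0L))
  expect_equal(match_individual(h, pop, "A", mode = "phased"), 1L)
  expect_equal(match_individual(h, pop, "B", mode = "phased"), 0L)
  expect_true(is.na(match_individual(h, pop, "C", mode = "phased")))
  # but B is consistent in genotype terms: both sites are het
  expect_equal(match_individual(h, pop, "B", mode = "consistency"), 1L)
})

test_that("population-match filter keeps haplotypes carried by someone", {
  pop <- tiny_pop(rbind(c(2L, 0L), c(0L, 2L), c(NA, NA)))
  kept <- tiny_hap(c(100L, 200L), c(1L, 0L))      # matches A
  alien <- tiny_hap(c(100L, 200L), c(1L, 1L))     # matches nobody
  haps <- suppressMessages(
    filter_population_matched(as_hapset(kept, alien), pop))
  expect_length(haps, 1L)
  expect_equal(haps[[1]]$allele, kept$allele)
  # all-missing indicators never count as a match
  popNA <- tiny_pop(matrix(NA_integer_, 2, 2))
  expect_length(suppressMessages(
    filter_population_matched(as_hapset(kept), popNA)), 0L)
})

test_that("mean imputation fills missing indicators with the row mean", {
  raw <- rbind(c(1L, NA, 0L, 0L), c(1L, 1L, 0L, 1L), c(NA, NA, NA, NA))
  M <- suppressMessages(match_matrix(raw))
  expect_equal(nrow(M$raw), 2L)                   # fully-missing row removed
  expect_equal(unname(M$imputed[1, ]), c(1, 1 / 3, 0, 0))
  expect_equal(unname(M$imputed[2, ]), c(1, 1, 0, 1))  # untouched where observed
  expect_error(suppressMessages(match_matrix(matrix(NA_integer_, 1, 2))),
               "no haplotypes")
  expect_error(match_matrix(matrix(0.5, 1, 2)), "0, 1 or NA")
})

test_that("agreement scores are percentages over evaluable haplotypes", {
  raw <- rbind(c(1L, 1L, NA), c(1L, 0L, NA), c(1L, 1L, NA), c(0L, 1L, 1L))
  M <- match_matrix(raw, individuals = c("A", "B", "C"))
  ag <- agreement_scores(M)
  expect_equal(attr(ag, "J_total"), 4L)
  expect_equal(ag$score[ag$individual == "A"], 75)     # 3 of 4
  expect_equal(ag$n_evaluated[ag$individual == "C"], 1L)
  expect_equal(ag$score[ag$individual == "C"], 100)    # missing excluded
  expect_true(all(ag$score >= 0 & ag$score <= 100, na.rm = TRUE))
  # not-assessable individual
  M2 <- match_matrix(rbind(c(1L, NA)), individuals = c("A", "B"))
  expect_true(is.na(agreement_scores(M2)$score[2]))
  # permuting individuals permutes the report identically
  perm <- c(2L, 3L, 1L)
  Mp <- match_matrix(raw[, perm], individuals = c("A", "B", "C")[perm])
  agp <- agreement_scores(Mp)
  expect_equal(agp[match(ag$individual, agp$individual), "score"], ag$score)
})

test_that("an error-free single-source sample scores 100 in phased mode", {
  x <- simulate_matched(I = 15, V = 150, contributors = "ind005", J = 10,
                        site_error = 0, mode = "phased", seed = 9)
  ag <- agreement_scores(x$M)
  expect_equal(ag$score[ag$individual == "ind005"], 100)
})
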