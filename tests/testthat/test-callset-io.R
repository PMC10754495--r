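# Reading, validating, filtering and writing VCF callsets.

test_that("population VCF parsing keeps genotypes, missingness and phase", {
  p <- write_test_vcf(
    c(vcf_rec("S1", 100, "A", "G", "GT:PS", "0|1:100", "0/0:."),
      vcf_rec("S1", 200, "C", "T", "GT:PS", "1|1:100", "./.:."),
      vcf_rec("S1", 300, "AT", "A", "GT:PS", "0/1:.", "1/1:.")),
    samples = c("s1", "s2"))
  pop <- read_population_vcf(p)
  expect_equal(length(pop$individuals), 2L)
  expect_equal(nrow(pop$variants), 3L)
  expect_equal(unname(pop$geno[, 1]), c(1L, 0L))
  expect_true(is.na(pop$geno["s2", 2]))          # ./. is missing, not 0
  expect_equal(unname(pop$geno["s1", 2]), 2L)
  # indel alleles are accepted verbatim
  expect_equal(pop$variants$ref[3], "AT")
  # phase recorded only where the separator was |
  expect_true(pop$phased["s1", 1])
  expect_false(pop$phased["s1", 3])
  expect_equal(unname(pop$hap1["s1", 1]), 0L)
  expect_equal(unname(pop$hap2["s1", 1]), 1L)
  expect_equal(unname(pop$ps["s1", 1]), "100")
  expect_true(is.na(pop$ps["s2", 1]))
})

test_that("multiallelic records are rejected by default and split on request", {
  p <- write_test_vcf(
    c(vcf_rec("S1", 100, "A", "G,T", "GT", "1/2", "0/1"),
      vcf_rec("S1", 200, "C", "T", "GT", "0/0", "0/1")),
    samples = c("s1", "s2"))
  expect_error(read_population_vcf(p), "multiallelic")
  pop <- read_population_vcf(p, split_multiallelic = TRUE)
  expect_equal(nrow(pop$variants), 3L)
  expect_equal(pop$variants$alt[1:2], c("G", "T"))
  # 1/2 splits to one copy of each alternate allele
  expect_equal(unname(pop$geno[, 1]), c(1L, 1L))  # allele G
  expect_equal(unname(pop$geno[, 2]), c(1L, 0L))  # allele T
})

test_that("gVCF non-variant blocks are ignored", {
  p <- write_test_vcf(
    c(vcf_rec("S1", 100, "A", "<NON_REF>", "GT", "0/0"),
      vcf_rec("S1", 200, "C", "T", "GT", "0/1"),
      vcf_rec("S1", 300, "G", ".", "GT", "0/0")),
    samples = "s1")
  pop <- suppressMessages(read_population_vcf(p))
  expect_equal(nrow(pop$variants), 1L)
  expect_equal(pop$variants$pos, 200L)
})

test_that("duplicate variant records are a validation error", {
  p <- write_test_vcf(
    c(vcf_rec("S1", 100, "A", "G", "GT", "0/1"),
      vcf_rec("S1", 100, "A", "G", "GT", "0/0")),
    samples = "s1")
  expect_error(read_population_vcf(p), "duplicate")
  expect_error(tiny_pop(matrix(0L, 1, 2), pos = c(100L, 100L)), "duplicate")
})

test_that("malformed input produces a parse error naming the file", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c("not a vcf at all", "##nothing"), p)
  expect_error(read_population_vcf(p), basename(p))
  expect_error(read_population_vcf(tempfile()), "not found")
})

test_that("soil reader flags phase, drops missing calls, rejects cross-contig phase sets", {
  p <- write_test_vcf(
    c(vcf_rec("S1", 100, "A", "G", "GT:PS", "0|1:100"),
      vcf_rec("S1", 200, "C", "T", "GT:PS", "1|1:100"),
      vcf_rec("S1", 300, "G", "A", "GT:PS", "0/1:."),
      vcf_rec("S1", 400, "T", "C", "GT:PS", "./.:.")),
    samples = "soil1")
  soil <- suppressMessages(read_soil_vcf(p))
  expect_s3_class(soil, "soil_callset")
  expect_equal(soil$sample_id, "soil1")
  expect_equal(nrow(soil$calls), 3L)              # missing call dropped
  expect_equal(soil$calls$phased, c(TRUE, TRUE, FALSE))
  expect_equal(soil$calls$ps, c("100", "100", NA))
  bad <- write_test_vcf(
    c(vcf_rec("S1", 100, "A", "G", "GT:PS", "0|1:7"),
      vcf_rec("S2", 100, "A", "G", "GT:PS", "1|0:7")),
    samples = "soil1")
  expect_error(read_soil_vcf(bad), "phase set")
})

test_that("write/read round trip is the identity on simulated callsets", {
  pop <- simulate_population(8, 60, n_contigs = 2, block_length = 4,
                             missingness = 0.1, seed = 42)
  sim <- simulate_soil_sample(pop, "ind003", J = 6, seed = 43)
  d <- tempfile(); dir.create(d)
  write_vcf(pop, file.path(d, "pop.vcf"))
  write_vcf(sim$soil, file.path(d, "soil.vcf"))
  pop2 <- read_population_vcf(file.path(d, "pop.vcf"))
  expect_identical(pop2$individuals, pop$individuals)
  expect_identical(pop2$variants, pop$variants)
  expect_identical(unname(pop2$geno), unname(pop$geno))
  expect_identical(unname(pop2$hap1), unname(pop$hap1))
  expect_identical(unname(pop2$hap2), unname(pop$hap2))
  expect_identical(unname(pop2$ps), unname(pop$ps))
  soil2 <- read_soil_vcf(file.path(d, "soil.vcf"))
  expect_identical(soil2$calls, sim$soil$calls)
  # conventions on the emitted text itself
  txt <- readLines(file.path(d, "pop.vcf"))
  body <- txt[!startsWith(txt, "#")]
  expect_true(any(grepl("\\./\\.", body)))        # missing emitted as ./.
  expect_true(any(grepl("[01]\\|[01]:", body)))   # phased emitted as | + PS
})

test_that("population filter applies strict missingness and MAF thresholds", {
  # 10 individuals; v1: 2/10 missing (20%, not < 20% -> out);
  # v2: MAF 1/20 = 5% -> in; v3: monomorphic -> out; v4: clean common -> in
  g <- cbind(c(NA, NA, rep(1L, 8)),
             c(1L, rep(0L, 9)),
             rep(0L, 10),
             rep(1L, 10))
  pop <- tiny_pop(g, individuals = sprintf("i%02d", 1:10))
  st <- variant_stats(pop)
  expect_equal(st$missingness[1], 0.2)
  expect_equal(st$maf[2], 0.05)
  f <- suppressMessages(filter_population_callset(pop))
  expect_equal(f$variants$pos, c(200L, 400L))
  expect_equal(length(f$individuals), 10L)        # individuals never removed
  # recomputing the criteria on the result confirms them, and the filter
  # is idempotent
  st2 <- variant_stats(f)
  expect_true(all(st2$missingness < 0.2 & st2$maf > 0.01))
  f2 <- suppressMessages(filter_population_callset(f))
  expect_identical(f2$variants, f$variants)
  expect_identical(f2$geno, f$geno)
  expect_warning(suppressMessages(
    filter_population_callset(pop, max_missing = 0.01, min_maf = 0.6)),
    "no variants")
  expect_error(filter_population_callset(pop, max_missing = 1.2), "max_missing")
})

test_that("phase consistency with genotypes is validated", {
  g <- matrix(1L, 1, 1, dimnames = list("A", NULL))
  h1 <- matrix(1L, 1, 1); h2 <- matrix(1L, 1, 1)  # 1|1 contradicts geno 1
  expect_error(
    pop_callset("A", data.frame(contig = "S1", pos = 1L, ref = "A", alt = "G"),
                g, hap1 = h1, hap2 = h2,
                ps = matrix("1", 1, 1), phased = matrix(TRUE, 1, 1)),
    "inconsistent")
})
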