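# VCF input/output. Parsing is delegated to vcfR; genotype-string
# interpretation and the plain-text emitter live here.

# Parse a variants x samples matrix of GT strings into diploid allele-index
# matrices. Returns list(a1, a2, phased); NA where the allele is ".".
parse_gt_strings <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  nsep <- vapply(gregexpr("[/|]", u), function(m) sum(m > 0), integer(1))
  if (any(nsep == 0)) {
    stop("haploid or malformed GT field: '", u[nsep == 0][1], "'", call. = FALSE)
  }
  if (any(nsep > 1)) {
    stop("polyploid GT field not supported: '", u[nsep > 1][1], "'", call. = FALSE)
  }
  p1 <- sub("^([^/|]*)[/|].*$", "\\1", u)
  p2 <- sub("^.*[/|]([^/|]*)$", "\\1", u)
  to_int <- function(z) suppressWarnings(ifelse(z == ".", NA_integer_,
                                                as.integer(z)))
  i1 <- to_int(p1); i2 <- to_int(p2)
  bad <- (p1 != "." & is.na(i1)) | (p2 != "." & is.na(i2))
  if (any(bad)) stop("malformed GT field: '", u[bad][1], "'", call. = FALSE)
  map <- function(vals) {
    out <- matrix(NA_integer_, nrow(gt), ncol(gt))
    out[] <- vals[match(as.vector(gt), u)]
    out
  }
  phased <- matrix(FALSE, nrow(gt), ncol(gt))
  phased[] <- grepl("|", as.vector(gt), fixed = TRUE)
  phased[is.na(gt)] <- FALSE
  list(a1 = map(i1), a2 = map(i2), phased = phased)
}

# Read a VCF through vcfR and return the pieces all readers need.
# Non-variant (gVCF) records are dropped; multiallelic records are either
# rejected or split into biallelic records depending on `split_multiallelic`.
read_vcf_core <- function(path, split_multiallelic = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- v@fix
  if (ncol(v@gt) < 2L) stop("VCF '", path, "' has no sample columns", call. = FALSE)
  samples <- colnames(v@gt)[-1]
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]

  keep <- !is.na(alt) & !(alt %in% c(".", "<NON_REF>", "<*>"))
  n_gvcf <- sum(!keep)
  if (n_gvcf) message(n_gvcf, " non-variant (gVCF) record(s) ignored")

  gt <- vcfR::extract.gt(v, element = "GT")
  ps <- if (any(grepl("PS", v@gt[, "FORMAT"], fixed = TRUE))) {
    vcfR::extract.gt(v, element = "PS")
  } else {
    matrix(NA_character_, nrow(gt), ncol(gt))
  }
  idx <- which(keep)
  chrom <- chrom[idx]; pos <- pos[idx]; ref <- ref[idx]; alt <- alt[idx]
  gt <- gt[idx, , drop = FALSE]; ps <- ps[idx, , drop = FALSE]
  parsed <- parse_gt_strings(gt)

  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi) && !split_multiallelic) {
    stop(sprintf("multiallelic record at %s:%d (%s>%s); set split_multiallelic = TRUE to normalize",
                 chrom[multi][1], pos[multi][1], ref[multi][1], alt[multi][1]),
         call. = FALSE)
  }
  if (any(multi)) {
    alts <- strsplit(alt, ",", fixed = TRUE)
    nalt <- lengths(alts)
    row_of <- rep(seq_along(alt), nalt)
    k_of <- unlist(lapply(nalt, seq_len))
    # recode allele indices against each split alternate allele
    a1 <- parsed$a1[row_of, , drop = FALSE]
    a2 <- parsed$a2[row_of, , drop = FALSE]
    kcol <- matrix(k_of, nrow = length(row_of), ncol = ncol(a1))
    a1 <- ifelse(is.na(a1), NA_integer_, as.integer(a1 == kcol))
    a2 <- ifelse(is.na(a2), NA_integer_, as.integer(a2 == kcol))
    parsed$a1 <- a1; parsed$a2 <- a2
    parsed$phased <- parsed$phased[row_of, , drop = FALSE]
    ps <- ps[row_of, , drop = FALSE]
    chrom <- chrom[row_of]; pos <- pos[row_of]; ref <- ref[row_of]
    alt <- unlist(alts)
  } else {
    a1 <- parsed$a1; a2 <- parsed$a2
    bad <- (!is.na(a1) & a1 > 1) | (!is.na(a2) & a2 > 1)
    if (any(bad)) {
      r <- which(rowSums(bad) > 0)[1]
      stop(sprintf("allele index >1 at biallelic record %s:%d", chrom[r], pos[r]),
           call. = FALSE)
    }
  }
  list(samples = samples,
       variants = data.frame(contig = chrom, pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE),
       a1 = parsed$a1, a2 = parsed$a2, phased = parsed$phased, ps = ps)
}

#' Read a population variant callset from VCF
#'
#' Reads diploid GT fields for all samples; missing genotypes (`./.`) are kept
#' as `NA`, phased separators and PS phase-set tags are recorded. gVCF
#' non-variant blocks are ignored. Multiallelic records are rejected unless
#' `split_multiallelic = TRUE`, in which case they are normalized into one
#' biallelic record per alternate allele.
#'
#' @param path Path to a VCF (optionally bgzipped).
#' @param split_multiallelic Split multiallelic records instead of rejecting
#'   them.
#' @return A [pop_callset()].
#' @export
read_population_vcf <- function(path, split_multiallelic = FALSE) {
  core <- read_vcf_core(path, split_multiallelic)
  I <- length(core$samples)
  geno <- t(core$a1) + t(core$a2)              # I x V alt-allele counts
  phased <- t(core$phased)
  hap1 <- t(core$a1); hap2 <- t(core$a2)
  hap1[!phased] <- NA_integer_; hap2[!phased] <- NA_integer_
  ps <- t(core$ps); ps[!phased] <- NA_character_
  rownames(geno) <- rownames(phased) <- rownames(hap1) <-
    rownames(hap2) <- rownames(ps) <- core$samples
  if (!any(phased)) { hap1 <- hap2 <- ps <- NULL; phased <- NULL }
  pop_callset(core$samples, core$variants, geno,
              hap1 = hap1, hap2 = hap2, ps = ps, phased = phased)
}

#' Read a soil-sample callset from VCF
#'
#' Reads the phased diploid calls of one sample. Unphased records are kept but
#' flagged (`phased = FALSE`); [build_soil_haplotypes()] later excludes
#' unphased heterozygous calls from haplotype construction. Records with a
#' fully missing genotype are dropped.
#'
#' @inheritParams read_population_vcf
#' @param sample Sample name or index to read (default: the first sample).
#' @return A [soil_callset()].
#' @export
read_soil_vcf <- function(path, sample = 1L, split_multiallelic = FALSE) {
  core <- read_vcf_core(path, split_multiallelic)
  if (is.character(sample)) {
    j <- match(sample, core$samples)
    if (is.na(j)) stop("sample '", sample, "' not in VCF", call. = FALSE)
  } else j <- as.integer(sample)
  calls <- data.frame(core$variants,
                      a1 = core$a1[, j], a2 = core$a2[, j],
                      phased = core$phased[, j], ps = core$ps[, j],
                      stringsAsFactors = FALSE)
  n_missing <- sum(is.na(calls$a1) & is.na(calls$a2))
  if (n_missing) message(n_missing, " call(s) with missing genotype dropped")
  calls <- calls[!(is.na(calls$a1) & is.na(calls$a2)), , drop = FALSE]
  rownames(calls) <- NULL
  soil_callset(calls, sample_id = core$samples[j])
}

vcf_header <- function(contigs, with_ps) {
  c("##fileformat=VCFv4.2",
    "##source=ednaident",
    paste0("##contig=<ID=", contigs, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (with_ps)
      "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set\">")
}

#' Write a callset to VCF
#'
#' Emits VCF 4.2 with GT (and, where phase is present, PS) fields. Missing
#' genotypes become `./.`, phased entries use the `|` separator plus a PS tag.
#' `read_population_vcf(write_vcf(x))` reproduces genotypes, phase, sample and
#' variant order exactly.
#'
#' @param x A [pop_callset()] or [soil_callset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) UseMethod("write_vcf")

#' @export
write_vcf.pop_callset <- function(x, path) {
  I <- length(x$individuals); V <- nrow(x$variants)
  with_ps <- !is.null(x$ps) && any(!is.na(x$ps))
  g <- x$geno
  phased <- if (is.null(x$phased)) matrix(FALSE, I, V) else x$phased & !is.na(g)
  gt <- matrix("./.", I, V)
  gt[!is.na(g) & g == 0L] <- "0/0"
  gt[!is.na(g) & g == 1L] <- "0/1"
  gt[!is.na(g) & g == 2L] <- "1/1"
  if (!is.null(x$hap1)) {
    ph <- phased & !is.na(x$hap1) & !is.na(x$hap2)
    gt[ph] <- paste0(x$hap1[ph], "|", x$hap2[ph])
  }
  if (with_ps) {
    psf <- ifelse(is.na(x$ps), ".", as.character(x$ps))
    gt <- matrix(paste0(gt, ":", psf), I, V)
  }
  fmt <- if (with_ps) "GT:PS" else "GT"
  body <- apply(gt, 2, paste, collapse = "\t")    # one string per variant
  lines <- paste(x$variants$contig,
                 format(x$variants$pos, scientific = FALSE, trim = TRUE),
                 ".", x$variants$ref, x$variants$alt, ".", "PASS", ".",
                 fmt, body, sep = "\t")
  hdr <- vcf_header(unique(x$variants$contig), with_ps)
  col <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", x$individuals), collapse = "\t")
  writeLines(c(hdr, col, lines), path)
  invisible(path)
}

#' @export
write_vcf.soil_callset <- function(x, path) {
  calls <- x$calls
  with_ps <- any(!is.na(calls$ps))
  sep <- ifelse(calls$phased, "|", "/")
  al <- function(a) ifelse(is.na(a), ".", as.character(a))
  gt <- paste0(al(calls$a1), sep, al(calls$a2))
  if (with_ps) gt <- paste0(gt, ":", ifelse(is.na(calls$ps), ".", calls$ps))
  fmt <- if (with_ps) "GT:PS" else "GT"
  lines <- paste(calls$contig,
                 format(calls$pos, scientific = FALSE, trim = TRUE),
                 ".", calls$ref, calls$alt, ".", "PASS", ".", fmt, gt,
                 sep = "\t")
  hdr <- vcf_header(unique(calls$contig), with_ps)
  col <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                 "FORMAT", x$sample_id), collapse = "\t")
  writeLines(c(hdr, col, lines), path)
  invisible(path)
}
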