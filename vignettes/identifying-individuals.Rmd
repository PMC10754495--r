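---
title: "Identifying individuals from environmental DNA haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying individuals from environmental DNA haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ednaident)
```

## The setting and the data

Some endangered populations are monitored so intensively that a
population-wide variant callset exists: diploid genotypes for nearly every
living individual at a large set of biallelic variants (the kākāpō, with
its ~250 birds and a callset of ~1.6 million filtered variants, is the
archetype). Long-read sequencing of soil eDNA produces a handful of phased
variant calls — fragments of the chromosomes of whatever animals shed DNA
at the sampling site. `ednaident` matches those fragments against the
panel and answers three questions: *who* does the sample look like, *in
what proportions*, and *how many* individuals contributed.

Two containers carry the data. A `pop_callset` holds the panel: an
`I × V` matrix of alt-allele counts (0/1/2, `NA` for missing) with optional
per-chromosome phase and phase-set identifiers. A `soil_callset` holds one
sample's calls: per variant, two allele indicators, a phased flag and a
phase set (PS) that groups calls into haplotype blocks. Both read from and
write to standard VCF 4.x (via `vcfR`); gVCF non-variant blocks are
ignored, and multiallelic records are rejected unless explicitly split,
because the matching key is a single ref/alt pair.

## The matching model

**Exact variant identity.** A soil call survives `intersect_variants()`
only when a panel variant is identical in contig, position and both
alleles. Together with the later haplotype-level filter this is the error
guard: a sequencing error that changes an allele produces a call that
simply does not exist in the panel and is discarded, rather than a wrong
match. Indels participate like SNVs — matching is pure string equality.

**Population filters.** `filter_population_callset()` retains variants
with missingness strictly below 20% and MAF strictly above 1% (computed
over non-missing alleles). The strict inequalities are deliberate: a
variant missing in exactly 20% of individuals is removed.

**Haplotypes.** Each phase block yields its two phased allele strings as
candidate haplotypes (`build_soil_haplotypes()`). Unphased heterozygous
calls carry no allele-to-chromosome assignment and are excluded;
homozygous calls without a PS are phase-constant and join any block whose
positional span encloses them. Blocks below `min_sites = 2` are dropped — a
one-site "haplotype" is just a genotype observation — and duplicate
observations are collapsed, since read-depth multiplicity is not modelled.

**Match semantics.** `match_individual()` offers two modes.
*Consistency* (the default) asks whether the individual's genotypes can
carry the haplotype: an alt allele needs alt-count ≥ 1, a ref allele needs
alt-count ≤ 1 at every site. This is the right default because cohort
callsets from short-read sequencing are typically unphased. *Phased* mode
asks for a stronger certificate: one of the individual's phased
chromosomes must carry exactly the haplotype's alleles within a single
panel phase block. Either way the indicator is `NA` whenever any required
genotype (or phase) is missing — missingness dominates, even if another
site already mismatches, so that "no" always means a confirmed no.

**Missing data have two consumers with different needs.** Agreement scores
(`agreement_scores()`) exclude missing indicators from both numerator and
denominator: the score is a percentage of *confirmable* overlaps, and an
individual with no evaluable haplotype is reported as not assessable
rather than as 0%. The contributor likelihood instead uses the
mean-imputed view of the match matrix (`match_matrix()`): each missing
entry is replaced by its row mean across observed individuals, so a
missing genotype contributes the base rate of that haplotype rather than
either certainty. Rows missing for every individual are removed before
imputation.

## The mixture model

The mixture stage is conditional genetic stock identification with each
panel individual as a reference collection of size one. The fixed match
matrix plays the role of the reference conditioning data: the likelihood
that haplotype `j` originated from individual `i` is
`L_ji = imputed_ji + ε`, with floor `ε = 1e-6`. The floor replaces the
pseudo-count allele priors a collection-based formulation would use; it
exists only to keep the Gibbs chain off absorbing states, and the test
suite demonstrates results are insensitive to `ε` across `1e-8`–`1e-4`.

`gibbs_mixture()` alternates `z_j ~ Categorical(∝ π_i L_ji)` with
`π ~ Dirichlet(α + counts(z))`, `α = 1` being the uniform prior. Defaults
are 2000 sweeps with the first 100 discarded; no thinning, because `J`,
`I` and the sweep count are small. Initialisation samples `z` from the
likelihood alone. Categorical draws use the Gumbel-max trick on the log
scale, which vectorises cleanly and is exact. Assignment probabilities are
Rao-Blackwellised (the normalised `π_i L_ji` row is averaged over retained
sweeps), so assignment rows sum to 1 by construction; the per-individual
"posterior mean of assignment" is defined as the column mean of that
matrix. Runs are bit-for-bit reproducible given a seed.

Two calibration properties anchor the sampler. With a single fully
supported individual (`L` one column of ones, zeros elsewhere — zeros are
explicitly allowed so the floor can be disabled for this check) the
posterior is conjugate: `Dirichlet(α + J, α, …, α)`, mean
`(1 + J)/(I + J)`; at `I = 5, J = 20` the chain reproduces 0.84 within
Monte-Carlo error. With an uninformative all-ones likelihood the
proportions return to `1/I`.

**A structural caveat on proportions.** Under the uniform prior the
posterior mean proportion of a contributor with true weight `w` cannot
exceed `(1 + wJ)/(I + J)` even for perfectly identifying data. With a
panel of 50 and 40 haplotypes, a 70% contributor can reach at most 0.32.
Mixing proportions from small samples against a large panel are therefore
*rankings with shrunk magnitudes*, not calibrated weight estimates — which
is why results are best read on a log scale and why the summary
(`summarize_mixture()`) reports best hit, second-best hit and the mean of
the remaining individuals, optionally after excluding a named individual
whose signal dominates. Ranking ties are broken by identifier order and
flagged.

## Counting contributors

`contributor_profile()` scores combinations of individuals: the
per-haplotype probability under combination `C` is the fraction of members
of `C` matching the haplotype (mean-imputed values), and the combination
likelihood is the product over haplotypes, accumulated in log space
(linear and log products agree to 1e-12 relative whenever the linear value
exceeds 1e-300). "Fraction of the combination" is the only reading that
makes the likelihood depend on the combination at all — relative to the
whole panel the MLE would be undefined.

Two forces balance: an unexplained haplotype (no member matches)
annihilates the product, pushing `n` up; every superfluous member dilutes
each factor by `n/(n+1)`, pushing `n` down. The search enumerates all
`choose(I, n)` combinations while that count is within the budget
(default 1e6) and otherwise switches to greedy forward beam search
(width 50), flagging the result approximate; on random instances with
`I ≤ 12, n ≤ 4` the beam provably reproduced the exhaustive optimum in
100/100 generated cases in the test suite. Ties resolve to the
lexicographically smallest identifier set. The estimate n̂ is the smallest
size attaining the maximum likelihood; when the likelihood is still
strictly increasing at `n_max` (default 6) the profile reports the open
bound "≥ n_max" instead of a point estimate — the signature of a crowded
sample. A zero maximum likelihood is reported as exactly 0 together with
the count of unexplained haplotypes.

## What the simulator emulates — and what it does not

`simulate_population()` draws founder chromosomes independently per site
with alt probability equal to the site's MAF, drawn uniformly from
[0.05, 0.5]; variants sit in phase blocks of `block_length` consecutive
sites, and pedigree children inherit one whole block haplotype from each
parent (Mendelian per block, no recombination within blocks). Genotype
missingness is applied after the phased truth is stored. There is no
linkage disequilibrium beyond shared descent: the analysis treats blocks
as exchangeable observations, so LD realism adds nothing to testing its
logic.

`simulate_soil_sample()` draws, per observation, a contributor by weight,
a chromosome copy, and a phase block; truncates to a shifted-Poisson
number of sites (min 2, mean 4, matching short soil-derived phase blocks);
flips each allele with probability `site_error`; and emits the observation
as a single sequenced molecule — a phased `a|a` record pair under a fresh
phase set. That choice reflects what eDNA is: fragments are haploid
molecules, and fabricating a second, unobserved chromosome per block would
invent data. Blocks are drawn without replacement so the emitted VCF keeps
one record per site (this caps `J` at the number of blocks). Alien
observations carry uniformly random alleles, modelling background DNA that
survives mapping; with long blocks they are removed almost entirely by the
population-match filter, while at 2–4 sites chance genotype-consistency
keeps a substantial fraction — worth remembering when interpreting small
match matrices. Deamination-asymmetric damage, read-level error profiles
and depth are out of scope.

Every generator output round-trips through the VCF layer unchanged, and
each stage is deterministic given its seed; `run_pipeline()` fans a single
seed out to per-stage seeds by hashing the stage name, so stages are
independently reproducible and full reports regenerate byte-identically.

## Validation design and known limits

The test suite validates each stage against an independent oracle where
one exists: consistency matching against brute-force enumeration of all
`2^k` allele assignments, the Gibbs sampler against the conjugate closed
form, beam search against exhaustive enumeration, and a worked
three-individual example with hand-computable likelihoods (best pair
0.125, diluted triple `(1/3)^3`, n̂ = 2). End-to-end checks run on a
simulated study panel of 50 individuals × 1000 variants (5-site blocks, 5%
missingness) — sizes chosen so the full suite runs in minutes on one core
while keeping `choose(50, 4) ≈ 2.3e5` exhaustive searches honest. On that
panel, a single contributor (25 haplotype observations, 2% site error) is
recovered as the unique top agreement score in effectively every
replicate, and an offspring of the shedding individual scores far above
unrelated panel members — the relative-confusion phenomenon that also
limits field identification within families.

Two quantities are *not* reliably recovered at these settings, for reasons
inherent to the method rather than to the implementation, and the
corresponding checks in the suite document the shortfall rather than hide
it. First, absolute mixing proportions: the conjugate shrinkage bound
above makes ±0.15 recovery of a 0.7 weight impossible against a 50-strong
panel, and even against a 5-strong panel the sharing of short haplotypes
between individuals spreads posterior mass (rankings remain informative;
magnitudes are shrunk). Second, pair recovery via the contributor MLE at
2% per-site error: with ~4-site haplotypes, a few percent of observations
lose their source match yet still pass the population filter through a
chance third-party consistency match; a single such haplotype zeroes the
true pair's product likelihood and inflates n̂. Longer phase blocks fix
this — with 10–15 sites an errored haplotype matches nobody and is simply
dropped, which is precisely why the exact-overlap design favours long-read
haplotypes. Practitioners should read n̂ as a lower-bound-leaning estimate
whose reliability grows with haplotype length.
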