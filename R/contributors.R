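# Combinatorial maximum-likelihood estimation of which, and how many,
# individuals contributed DNA to a sample. The likelihood of a combination is
# the product over haplotypes of the per-haplotype probability: the fraction
# of combination members that match the haplotype (mean-imputed view).

as_imputed <- function(M) {
  if (inherits(M, "match_matrix")) return(M$imputed)
  M <- as.matrix(M)
  if (anyNA(M)) stop("imputed match matrix must not contain NA", call. = FALSE)
  if (is.null(colnames(M))) colnames(M) <- paste0("ind", seq_len(ncol(M)))
  M
}

resolve_members <- function(combination, individuals) {
  if (is.character(combination)) {
    idx <- match(combination, individuals)
    if (anyNA(idx)) {
      stop("unknown individual(s): ",
           paste(combination[is.na(idx)], collapse = ", "), call. = FALSE)
    }
  } else idx <- as.integer(combination)
  if (!length(idx)) stop("combination must be non-empty", call. = FALSE)
  if (anyDuplicated(idx)) stop("combination has duplicate members", call. = FALSE)
  idx
}

#' Per-haplotype probability under a combination of contributors
#'
#' The relative number of combination members that match the haplotype:
#' `sum(row[members]) / |combination|`, computed on the mean-imputed match
#' values so that missing indicators contribute their row mean.
#'
#' @param row Numeric vector of imputed match values for one haplotype (no
#'   `NA`), named by individual.
#' @param combination Non-empty set of individual identifiers (or indices).
#' @return A probability in `[0, 1]`.
#' @export
per_haplotype_probability <- function(row, combination) {
  if (anyNA(row)) stop("row must be fully imputed (no NA)", call. = FALSE)
  idx <- resolve_members(combination, names(row))
  mean(row[idx])
}

#' Likelihood of a combination of contributing individuals
#'
#' The product over all haplotypes of the per-haplotype probability, computed
#' in log space and reported in linear space. A zero likelihood is a valid
#' value; the number of unexplained haplotypes (per-haplotype probability
#' exactly 0) is attached for diagnosis.
#'
#' @param M A [match_matrix()] (or a plain imputed J x I matrix).
#' @param combination Non-empty set of individual identifiers (or indices).
#' @return A list of class `combination_likelihood`: `combination` (sorted
#'   identifiers), `likelihood`, `log_likelihood`, `n_unexplained`.
#' @export
combination_likelihood <- function(M, combination) {
  Mi <- as_imputed(M)
  idx <- resolve_members(combination, colnames(Mi))
  p <- rowMeans(Mi[, idx, drop = FALSE])
  structure(list(combination = sort(colnames(Mi)[idx]),
                 likelihood = exp(sum(log(p))),
                 log_likelihood = sum(log(p)),
                 n_unexplained = sum(p == 0)),
            class = "combination_likelihood")
}

#' @export
print.combination_likelihood <- function(x, ...) {
  cat(sprintf("{%s}: likelihood %.4g", paste(x$combination, collapse = ", "),
              x$likelihood))
  if (x$n_unexplained) cat(sprintf(" (%d unexplained haplotype(s))",
                                   x$n_unexplained))
  cat("\n")
  invisible(x)
}

# Log-likelihood of many combinations at once; combos is an n x K index
# matrix. Chunked so the intermediate J x K sums stay small.
eval_combinations <- function(Mi, combos) {
  n <- nrow(combos); K <- ncol(combos); J <- nrow(Mi)
  ll <- numeric(K)
  chunk <- max(1L, as.integer(2e6 / max(1L, J)))
  for (st in seq(1L, K, by = chunk)) {
    en <- min(K, st + chunk - 1L)
    idx <- st:en
    S <- matrix(0, J, length(idx))
    for (r in seq_len(n)) S <- S + Mi[, combos[r, idx], drop = FALSE]
    ll[idx] <- colSums(log(S / n))
  }
  ll
}

# Deterministic winner: maximum log-likelihood, ties broken by the
# lexicographically smallest set of identifiers.
pick_best <- function(ll, combos, individuals) {
  best <- max(ll)
  cand <- which(ll == best)
  if (length(cand) > 1L) {
    keys <- vapply(cand, function(k) {
      paste(sort(individuals[combos[, k]]), collapse = "\r")
    }, character(1))
    cand <- cand[order(keys)[1]]
  }
  cand[1]
}

beam_search_mle <- function(Mi, n_target, beam_width) {
  I <- ncol(Mi); individuals <- colnames(Mi)
  sets <- matrix(seq_len(I), nrow = 1)        # level 1: all singletons
  S <- Mi
  for (level in seq_len(n_target)) {
    ll <- colSums(log(S / level))
    if (level == n_target) {
      b <- pick_best(ll, sets, individuals)
      return(list(members = sets[, b], log_likelihood = unname(ll[b])))
    }
    keep_n <- min(beam_width, ncol(sets))
    keys <- vapply(seq_len(ncol(sets)), function(k) {
      paste(sort(individuals[sets[, k]]), collapse = "\r")
    }, character(1))
    keep <- order(-ll, keys)[seq_len(keep_n)]
    sets <- sets[, keep, drop = FALSE]; S <- S[, keep, drop = FALSE]
    # extend every beam set by every non-member; dedupe on the sorted set
    ext_sets <- NULL; ext_S <- NULL; seen <- character(0)
    for (b in seq_len(ncol(sets))) {
      for (j in setdiff(seq_len(I), sets[, b])) {
        ns <- sort(c(sets[, b], j))
        key <- paste(ns, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        ext_sets <- cbind(ext_sets, ns)
        ext_S <- cbind(ext_S, S[, b] + Mi[, j])
      }
    }
    sets <- ext_sets; S <- ext_S
  }
}

#' Maximum-likelihood combination of a given size
#'
#' Finds the size-`n` combination of individuals maximising
#' [combination_likelihood()]. All `choose(I, n)` combinations are enumerated
#' when their number is within `budget`; otherwise a greedy forward beam
#' search is used and the result is flagged approximate. Ties are broken by
#' the lexicographically smallest identifier set.
#'
#' @param M A [match_matrix()] (or imputed matrix).
#' @param n Combination size, `1 <= n <= I`.
#' @param strategy `"auto"` (default), `"exhaustive"`, or `"beam"`.
#' @param budget Maximum number of combinations enumerated exhaustively.
#' @param beam_width Beam width for the approximate search.
#' @return A `combination_likelihood` with additional fields `n`,
#'   `approximate`.
#' @export
mle_over_combinations <- function(M, n, strategy = c("auto", "exhaustive", "beam"),
                                  budget = 1e6, beam_width = 50L) {
  strategy <- match.arg(strategy)
  Mi <- as_imputed(M)
  I <- ncol(Mi)
  n <- as.integer(n)
  if (n < 1L || n > I) stop("`n` must be between 1 and the number of individuals",
                            call. = FALSE)
  use_beam <- switch(strategy,
                     exhaustive = FALSE,
                     beam = TRUE,
                     auto = choose(I, n) > budget)
  if (!use_beam && choose(I, n) > budget) {
    stop("exhaustive enumeration exceeds the budget; use strategy = 'beam'",
         call. = FALSE)
  }
  if (use_beam) {
    res <- beam_search_mle(Mi, n, as.integer(beam_width))
    members <- res$members; ll <- res$log_likelihood
  } else {
    combos <- combn(I, n)
    lls <- eval_combinations(Mi, combos)
    b <- pick_best(lls, combos, colnames(Mi))
    members <- combos[, b]; ll <- lls[b]
  }
  p <- rowMeans(Mi[, members, drop = FALSE])
  structure(list(combination = sort(colnames(Mi)[members]),
                 likelihood = exp(ll), log_likelihood = ll,
                 n_unexplained = sum(p == 0),
                 n = n, approximate = use_beam),
            class = "combination_likelihood")
}

#' Contributor-count profile by maximum likelihood
#'
#' Computes the best combination and its likelihood for every size `n = 1 ..
#' n_max` and derives the estimated number of contributors: the smallest `n`
#' attaining the maximal likelihood, or — when the likelihood is strictly
#' increasing all the way to `n_max` — the open lower bound `>= n_max`
#' (evidence that more individuals contributed than were searched for).
#'
#' @inheritParams mle_over_combinations
#' @param n_max Largest combination size searched (default 6).
#' @return An object of class `contributor_profile`: `per_n` (list of
#'   `combination_likelihood`), `table` (data frame), `n_hat`, `open_bound`,
#'   `search_mode`.
#' @export
contributor_profile <- function(M, n_max = 6L,
                                strategy = c("auto", "exhaustive", "beam"),
                                budget = 1e6, beam_width = 50L) {
  strategy <- match.arg(strategy)
  Mi <- as_imputed(M)
  n_max <- as.integer(n_max)
  if (n_max > ncol(Mi)) stop("`n_max` must be <= the number of individuals",
                             call. = FALSE)
  per_n <- lapply(seq_len(n_max), function(n) {
    mle_over_combinations(Mi, n, strategy = strategy, budget = budget,
                          beam_width = beam_width)
  })
  ll <- vapply(per_n, `[[`, numeric(1), "log_likelihood")
  best <- max(ll)
  n_hat <- which(ll >= best - 1e-9)[1]
  increasing <- n_max > 1L && isTRUE(all(diff(ll) > 0))
  tab <- data.frame(
    n = seq_len(n_max),
    combination = vapply(per_n, function(x) paste(x$combination, collapse = ","), ""),
    likelihood = vapply(per_n, `[[`, numeric(1), "likelihood"),
    log_likelihood = ll,
    approximate = vapply(per_n, `[[`, logical(1), "approximate"),
    stringsAsFactors = FALSE)
  structure(list(per_n = per_n, table = tab,
                 n_hat = if (increasing) n_max else as.integer(n_hat),
                 open_bound = increasing,
                 n_max = n_max,
                 search_mode = if (any(tab$approximate)) "beam" else "exhaustive"),
            class = "contributor_profile")
}

#' @export
print.contributor_profile <- function(x, ...) {
  cat("Contributor-count maximum-likelihood profile\n")
  print.data.frame(x$table, row.names = FALSE, digits = 4)
  cat(sprintf("Estimated number of contributors: %s%d%s\n",
              if (x$open_bound) ">= " else "", x$n_hat,
              if (x$search_mode == "beam") " (beam search, approximate)" else ""))
  invisible(x)
}

#' @export
summary.contributor_profile <- function(object, ...) {
  c(list(n_hat = object$n_hat, open_bound = object$open_bound,
         best_combination = object$per_n[[object$n_hat]]$combination,
         likelihood = object$per_n[[object$n_hat]]$likelihood,
         search_mode = object$search_mode))
}
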