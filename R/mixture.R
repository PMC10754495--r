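# Dirichlet-categorical mixture over individuals, fitted by Gibbs sampling:
# the genetic-stock-identification step, with each reference individual
# treated as a reference collection of size one and the fixed match matrix
# playing the role of the conditioning reference data.

#' Haplotype x individual likelihood matrix
#'
#' Converts the mean-imputed match matrix into mixture-component likelihoods
#' by adding a small floor: `L[j,i] = imputed[j,i] + epsilon`. The floor
#' prevents absorbing states in the Gibbs sampler while leaving the ranking
#' of individuals untouched (results are insensitive to `epsilon` across
#' several orders of magnitude; see the package vignette).
#'
#' @param M A [match_matrix()].
#' @param epsilon Likelihood floor in (0, 0.01].
#' @return A J x I matrix with all entries > 0.
#' @export
likelihood_matrix <- function(M, epsilon = 1e-6) {
  stopifnot(inherits(M, "match_matrix"))
  assert_scalar_prob(epsilon, "epsilon", lo = 0, hi = 0.01, lo_open = TRUE)
  M$imputed + epsilon
}

#' Fit the individual mixture by Gibbs sampling
#'
#' Alternates between sampling the source individual `z[j]` of every
#' haplotype (categorical, probability proportional to `pi[i] * L[j,i]`) and
#' the mixing proportions `pi` (Dirichlet with concentration `alpha +
#' counts(z)`; `alpha = 1` is the uniform prior). The first `burn_in` sweeps
#' are discarded; posterior means are computed over the retained sweeps.
#' Assignment probabilities are Rao-Blackwellised: at each retained sweep the
#' normalised `pi[i] * L[j,i]` row is accumulated.
#'
#' Likelihood entries may be exactly zero (e.g. with the floor disabled for
#' calibration checks) as long as every row has a positive sum.
#'
#' @param L J x I nonnegative likelihood matrix, e.g. from
#'   [likelihood_matrix()]; column names identify individuals.
#' @param iterations Total Gibbs sweeps (default 2000).
#' @param burn_in Discarded initial sweeps (default 100).
#' @param alpha Dirichlet concentration parameter (default 1, the uniform
#'   prior).
#' @param seed Optional integer seed; identical seeds give identical traces.
#' @return An object of class `edna_mixture`: `proportions` (posterior mean
#'   mixing proportions, sums to 1), `assignment` (J x I posterior assignment
#'   probabilities, rows sum to 1), `individual_means` (column means of
#'   `assignment`), `trace` (retained sweeps x I matrix of sampled
#'   proportions), plus the configuration.
#' @export
gibbs_mixture <- function(L, iterations = 2000L, burn_in = 100L, alpha = 1,
                          seed = NULL) {
  L <- as.matrix(L)
  J <- nrow(L); I <- ncol(L)
  if (J < 1L) stop("no haplotypes: empty likelihood matrix", call. = FALSE)
  if (any(!is.finite(L)) || any(L < 0)) {
    stop("likelihood matrix must be finite and nonnegative", call. = FALSE)
  }
  if (any(rowSums(L) <= 0)) {
    stop("every haplotype needs a positive likelihood for some individual",
         call. = FALSE)
  }
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  iterations <- as.integer(iterations); burn_in <- as.integer(burn_in)
  if (burn_in >= iterations) stop("`burn_in` must be < `iterations`", call. = FALSE)
  ind <- colnames(L) %||% paste0("ind", seq_len(I))
  n_keep <- iterations - burn_in

  if (I == 1L) {
    trace <- matrix(1, n_keep, 1, dimnames = list(NULL, ind))
    assignment <- matrix(1, J, 1, dimnames = list(NULL, ind))
    return(structure(list(proportions = setNames(1, ind),
                          assignment = assignment,
                          individual_means = setNames(1, ind), trace = trace,
                          iterations = iterations, burn_in = burn_in,
                          alpha = alpha, seed = seed),
                     class = "edna_mixture"))
  }

  maybe_seed(seed)
  logL <- log(L)                      # -Inf where L == 0 is fine
  # sweep 0: z from the likelihood alone (Gumbel-max categorical draw)
  gumbel <- function() -log(-log(matrix(runif(J * I), J, I)))
  z <- max.col(logL + gumbel(), ties.method = "first")
  trace <- matrix(NA_real_, n_keep, I, dimnames = list(NULL, ind))
  assign_acc <- matrix(0, J, I)
  for (t in seq_len(iterations)) {
    counts <- tabulate(z, I)
    g <- rgamma(I, alpha + counts)
    pi_ <- g / sum(g)
    W <- L * rep(pi_, each = J)
    z <- max.col(log(W) + gumbel(), ties.method = "first")
    if (t > burn_in) {
      trace[t - burn_in, ] <- pi_
      assign_acc <- assign_acc + W / rowSums(W)
    }
  }
  assignment <- assign_acc / n_keep
  dimnames(assignment) <- list(NULL, ind)
  structure(list(proportions = colMeans(trace),
                 assignment = assignment,
                 individual_means = colMeans(assignment),
                 trace = trace,
                 iterations = iterations, burn_in = burn_in, alpha = alpha,
                 seed = seed),
            class = "edna_mixture")
}

#' Fit the mixture directly from a match matrix
#'
#' Convenience wrapper: [likelihood_matrix()] followed by [gibbs_mixture()].
#'
#' @inheritParams gibbs_mixture
#' @inheritParams likelihood_matrix
#' @return An `edna_mixture`, see [gibbs_mixture()].
#' @export
fit_mixture <- function(M, iterations = 2000L, burn_in = 100L, alpha = 1,
                        epsilon = 1e-6, seed = NULL) {
  gibbs_mixture(likelihood_matrix(M, epsilon), iterations = iterations,
                burn_in = burn_in, alpha = alpha, seed = seed)
}

#' @export
print.edna_mixture <- function(x, n = 5L, ...) {
  cat(sprintf("Individual mixture (Gibbs: %d sweeps, burn-in %d, alpha = %g)\n",
              x$iterations, x$burn_in, x$alpha))
  p <- sort(x$proportions, decreasing = TRUE)
  cat("Top posterior mean mixing proportions:\n")
  print(round(head(p, n), 4))
  invisible(x)
}

#' @export
coef.edna_mixture <- function(object, ...) object$proportions

#' @export
summary.edna_mixture <- function(object, top_k = 3L, exclude = NULL, ...) {
  summarize_mixture(object, top_k = top_k, exclude = exclude)
}

#' @export
plot.edna_mixture <- function(x, k = 3L, ...) {
  ord <- order(x$proportions, decreasing = TRUE)
  sel <- ord[seq_len(min(k, length(ord)))]
  graphics::matplot(x$trace[, sel, drop = FALSE], type = "l", lty = 1,
                    xlab = "retained sweep", ylab = "mixing proportion", ...)
  graphics::legend("topright", legend = colnames(x$trace)[sel],
                   col = seq_along(sel), lty = 1, bty = "n")
  invisible(x)
}

#' Ranked summary of a fitted mixture
#'
#' Ranks individuals by posterior mean mixing proportion and reports the best
#' hit, the second-best hit, and the mean proportion of all remaining
#' individuals — the reporting layout used for mixture heatmaps. An exclusion
#' list re-ranks after removing named individuals (e.g. to look past an
#' omnipresent signal). Ties are broken deterministically by identifier order
#' and flagged.
#'
#' @param result An `edna_mixture` from [gibbs_mixture()].
#' @param top_k How many ranked individuals to report (clipped to I with a
#'   warning).
#' @param exclude Character vector of individuals to drop before ranking.
#' @return A list of class `mixture_summary`: `ranking` (data frame), `best`,
#'   `second`, `mean_remaining`, `tied` (logical), `excluded`.
#' @export
summarize_mixture <- function(result, top_k = 3L, exclude = NULL) {
  stopifnot(inherits(result, "edna_mixture"))
  p <- result$proportions
  if (!is.null(exclude)) p <- p[!(names(p) %in% exclude)]
  if (!length(p)) stop("all individuals excluded", call. = FALSE)
  if (top_k > length(p)) {
    warning("top_k exceeds the number of individuals; clipping", call. = FALSE)
    top_k <- length(p)
  }
  ord <- order(-p, names(p))
  ranking <- data.frame(rank = seq_along(p), individual = names(p)[ord],
                        proportion = unname(p[ord]),
                        row.names = NULL, stringsAsFactors = FALSE)
  tied <- length(p) > 1L && isTRUE(all.equal(ranking$proportion[1],
                                             ranking$proportion[2]))
  structure(list(ranking = head(ranking, top_k),
                 best = ranking$individual[1],
                 second = if (length(p) > 1L) ranking$individual[2] else NA_character_,
                 mean_remaining = if (length(p) > 2L)
                   mean(ranking$proportion[-(1:2)]) else NA_real_,
                 tied = tied, excluded = exclude),
            class = "mixture_summary")
}

#' @export
print.mixture_summary <- function(x, ...) {
  if (!is.null(x$excluded)) {
    cat("Excluded from ranking:", paste(x$excluded, collapse = ", "), "\n")
  }
  cat(sprintf("Best hit: %s; second-best: %s; mean of remaining: %s\n",
              x$best, x$second,
              ifelse(is.na(x$mean_remaining), "NA",
                     format(x$mean_remaining, digits = 4))))
  if (x$tied) cat("note: best hit tied, resolved by identifier order\n")
  print.data.frame(x$ranking, row.names = FALSE)
  invisible(x)
}
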