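#' Smoking prevalence
#'
#' Fraction of agents currently smoking, S(t)/N.
#'
#' @param states 0/1 behaviour vector.
#' @return A number in `[0, 1]`.
#' @export
prevalence <- function(states) mean(states)

#' Eigenvector centrality of the contact network
#'
#' Components of the leading eigenvector of the contact network's adjacency
#' matrix, rescaled so the maximum component equals 1. Agents embedded in
#' dense, well-connected substructures score high; in a disconnected graph
#' the components outside the dominant-eigenvalue component are (numerically)
#' zero.
#'
#' @param contact undirected `igraph` contact network.
#' @return Nonnegative numeric vector with maximum 1 (all zeros, with a
#'   warning, for an edgeless graph).
#' @export
eigenvector_centrality <- function(contact) {
  stopifnot(igraph::is_igraph(contact))
  if (igraph::ecount(contact) == 0) {
    warning("edgeless graph: eigenvector centrality undefined, returning zeros")
    return(numeric(igraph::vcount(contact)))
  }
  v <- igraph::eigen_centrality(contact, directed = FALSE,
                                options = list(tol = 1e-10))$vector
  unname(v)
}

#' Conditional probability of smoking at social distance d
#'
#' Probability that a randomly drawn ego smokes given that a randomly drawn
#' alter at shortest-path distance exactly d in the contact network smokes:
#' the fraction, over all ordered pairs (ego, alter) with d(ego, alter) = d
#' and a smoking alter, of pairs whose ego also smokes. A pooled ordered-pair
#' estimator is used by default; `per_ego = TRUE` instead averages the
#' per-ego smoker fractions of their distance-d smoking alters. Rising
#' values at small d during a transition signal behavioural clustering of
#' the remaining smokers.
#'
#' @param contact undirected `igraph` contact network, or a precomputed
#'   distance matrix.
#' @param states 0/1 behaviour vector.
#' @param d social distance (integer >= 1).
#' @param per_ego average per ego instead of pooling ordered pairs.
#' @return A probability, or `NA_real_` when no pair at distance d has a
#'   smoking alter (undefined, flagged rather than zero).
#' @export
conditional_smoking_probability <- function(contact, states, d,
                                            per_ego = FALSE) {
  if (d < 1 || d != round(d)) stop("`d` must be an integer >= 1",
                                   call. = FALSE)
  dm <- if (igraph::is_igraph(contact)) igraph::distances(contact)
        else as.matrix(contact)
  cp_from_distances(dm, states, d, per_ego = per_ego)
}

cp_from_distances <- function(dm, states, d, per_ego = FALSE) {
  shell <- dm == d
  smoking_alter <- shell & rep(states == 1L, each = nrow(dm))  # by column j
  if (per_ego) {
    denom_i <- rowSums(smoking_alter)
    has <- denom_i > 0
    if (!any(has)) return(NA_real_)
    mean(states[has])  # ego smokes or not; alters at distance d all smoke
  } else {
    denom <- sum(smoking_alter)
    if (denom == 0) return(NA_real_)
    sum(smoking_alter[states == 1L, , drop = FALSE]) / denom
  }
}

# Conditional smoking probability for d = 1..dmax from one distance matrix.
# Pooled ordered-pair estimator, all distances in two tabulation passes.
cp_profile <- function(dm, states, dmax = 5L) {
  sm <- states == 1L
  d_alter <- dm[, sm, drop = FALSE]      # pairs with smoking alter
  d_alter <- d_alter[is.finite(d_alter) & d_alter >= 1 & d_alter <= dmax]
  denom <- tabulate(d_alter, nbins = dmax)
  d_both <- dm[sm, sm, drop = FALSE]
  d_both <- d_both[is.finite(d_both) & d_both >= 1 & d_both <= dmax]
  num <- tabulate(d_both, nbins = dmax)
  ifelse(denom > 0, num / denom, NA_real_)
}

#' Percentile bootstrap confidence interval across runs
#'
#' Resamples the per-run values with replacement `reps` times and returns
#' percentile intervals of the resampled means. Several levels share the
#' same resamples, so a 99% interval always contains the corresponding 95%
#' interval.
#'
#' @param run_values numeric vector of per-run values (`NA`s dropped).
#' @param level confidence level(s), e.g. `c(0.95, 0.99)`.
#' @param reps number of bootstrap resamples (default 2000).
#' @param seed optional integer seed.
#' @return A matrix with one row per level and columns `lower`, `upper`.
#' @export
bootstrap_ci <- function(run_values, level = 0.95, reps = 2000L,
                         seed = NULL) {
  x <- run_values[!is.na(run_values)]
  if (length(x) < 2) {
    warning("fewer than 2 runs: degenerate bootstrap interval")
    v <- if (length(x)) x else NA_real_
    out <- matrix(v, length(level), 2)
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx <- matrix(sample.int(length(x), length(x) * reps, replace = TRUE),
                  nrow = reps)
    means <- rowMeans(matrix(x[idx], nrow = reps))
    out <- t(vapply(level, function(l)
      unname(quantile(means, c((1 - l) / 2, 1 - (1 - l) / 2))),
      numeric(2)))
  }
  dimnames(out) <- list(paste0(level * 100, "%"), c("lower", "upper"))
  out
}
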