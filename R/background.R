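#' Parameters of the small-world substrate
#'
#' Bundles the parameters of the Watts-Strogatz substrate that underlies the
#' time-invariant background proximity: `n_agents` nodes, even mean degree
#' `mean_degree`, and rewiring probability `rewiring_prob`. Defaults follow
#' the smoking experiment (z = 10, p_w = 0.03).
#'
#' @param n_agents positive integer, number of agents N.
#' @param mean_degree even positive integer z, with z < N.
#' @param rewiring_prob rewiring probability p_w in `[0, 1]`.
#' @param seed integer seed for the substrate draw.
#' @return A list of class `substrate_params`.
#' @export
substrate_params <- function(n_agents, mean_degree = 10, rewiring_prob = 0.03,
                             seed = 1L) {
  if (n_agents < 3 || n_agents != round(n_agents))
    stop("`n_agents` must be an integer >= 3", call. = FALSE)
  if (mean_degree %% 2 != 0 || mean_degree < 2)
    stop("`mean_degree` must be a positive even integer", call. = FALSE)
  if (mean_degree >= n_agents)
    stop("`mean_degree` must be smaller than `n_agents`", call. = FALSE)
  if (rewiring_prob < 0 || rewiring_prob > 1)
    stop("`rewiring_prob` must lie in [0, 1]", call. = FALSE)
  structure(list(n_agents = as.integer(n_agents),
                 mean_degree = as.integer(mean_degree),
                 rewiring_prob = rewiring_prob,
                 seed = as.integer(seed)),
            class = "substrate_params")
}

#' Generate the Watts-Strogatz substrate network
#'
#' Draws the small-world graph on which the background proximity is based.
#' Rewiring relocates edges without changing their number, so the substrate
#' always has exactly N z / 2 edges.
#'
#' @param params a [substrate_params()] object.
#' @return An undirected simple `igraph` graph with N nodes.
#' @examples
#' g <- generate_ws_network(substrate_params(100, 10, 0.03, seed = 1))
#' igraph::ecount(g)  # 500
#' @export
generate_ws_network <- function(params) {
  stopifnot(inherits(params, "substrate_params"))
  set.seed(params$seed)
  igraph::sample_smallworld(dim = 1, size = params$n_agents,
                            nei = params$mean_degree %/% 2,
                            p = params$rewiring_prob,
                            loops = FALSE, multiple = FALSE)
}

#' Build the time-invariant background proximity matrix
#'
#' Background proximity B encodes rigid social ties (family, long-term
#' factors) that the model does not resolve. It is a linear combination of
#' the social distance in the substrate and symmetric uniform noise,
#'   B_ij = max(floor, 1 - decrement * (d_ij - 1) - noise_amp * zeta_ij),
#' with zeta_ij = zeta_ji ~ U(0, 1) drawn once per unordered pair. Adjacent
#' pairs without noise get proximity 1; beyond a few degrees of separation
#' the floor (0.2) applies, reflecting that very distant pairs are not
#' meaningfully distinguished. Disconnected pairs sit at the floor. The
#' default decrement (0.2) makes a behaviour match in the proximity mixture
#' worth 1.25 background degrees, keeping homophilic rewiring local.
#'
#' @param substrate `igraph` substrate, e.g. from [generate_ws_network()].
#' @param decrement proximity lost per degree of social distance (c_d).
#' @param noise_amp amplitude of the uniform noise component (c_zeta).
#' @param floor minimum off-diagonal proximity.
#' @param seed integer seed for the noise draw.
#' @return A list of class `background_proximity` with elements `values`
#'   (symmetric N x N matrix, zero diagonal), and the parameters used.
#' @export
build_background_proximity <- function(substrate, decrement = 0.2,
                                       noise_amp = 0.2, floor = 0.2,
                                       seed = 1L) {
  stopifnot(igraph::is_igraph(substrate), decrement > 0, noise_amp >= 0)
  n <- igraph::vcount(substrate)
  d <- igraph::distances(substrate)
  set.seed(seed)
  zeta <- matrix(0, n, n)
  ut <- upper.tri(zeta)
  zeta[ut] <- runif(sum(ut))
  zeta <- zeta + t(zeta)
  b <- 1 - decrement * (d - 1) - noise_amp * zeta
  b[!is.finite(d)] <- floor        # disconnected pairs: no distinction left
  b <- pmax(b, floor)
  diag(b) <- 0
  structure(list(values = b, decrement = decrement, noise_amp = noise_amp,
                 floor = floor, seed = as.integer(seed)),
            class = "background_proximity")
}

# Accept either a background_proximity object or a bare matrix.
proximity_values <- function(background) {
  if (inherits(background, "background_proximity")) background$values
  else as.matrix(background)
}

#' @export
print.background_proximity <- function(x, ...) {
  off <- x$values[upper.tri(x$values)]
  cat(sprintf(
    "<background_proximity> %d agents, floor %.2f, off-diagonal range [%.3f, %.3f]\n",
    nrow(x$values), x$floor, min(off), max(off)))
  invisible(x)
}
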