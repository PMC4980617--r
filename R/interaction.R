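#' Interaction probability parameters
#'
#' Parameters of the distance-dependent interaction kernel: `scale` (beta) is
#' the probability that two direct contacts interact in a given step,
#' `baseline` (epsilon) the floor probability for incidental meetings between
#' distant or disconnected agents, and `decay_distance` (delta) the typical
#' social distance of the exponential decay. Defaults beta = 0.8,
#' epsilon = 0.03, delta = 2 follow the "three degrees of separation"
#' calibration of social influence.
#'
#' @param scale interaction probability at distance 1 (beta).
#' @param baseline incidental-meeting probability (epsilon).
#' @param decay_distance e-folding distance of the decay (delta).
#' @return A list of class `interaction_params`.
#' @export
interaction_params <- function(scale = 0.8, baseline = 0.03,
                               decay_distance = 2) {
  if (!(baseline > 0 && baseline <= scale && scale <= 1))
    stop("need 0 < baseline <= scale <= 1", call. = FALSE)
  if (decay_distance <= 0) stop("`decay_distance` must be positive",
                                call. = FALSE)
  structure(list(scale = scale, baseline = baseline,
                 decay_distance = decay_distance),
            class = "interaction_params")
}

#' All-pairs social distances and shell counts
#'
#' Computes shortest-path lengths between all agent pairs of the contact
#' network (`Inf` for disconnected pairs) together with the shell counts
#' L(d): the number of unordered pairs at each finite distance d. L(d)
#' normalises the interaction kernel for the skewed distribution of
#' shortest-path lengths in small-world graphs.
#'
#' @param contact undirected simple `igraph` contact network.
#' @return A list of class `distance_summary` with `distances` (N x N
#'   matrix) and `shell_counts` (named integer vector indexed by d).
#' @export
shortest_path_distances <- function(contact) {
  stopifnot(igraph::is_igraph(contact))
  d <- igraph::distances(contact)
  .distance_summary(d)
}

.distance_summary <- function(d) {
  ut <- d[upper.tri(d)]
  finite <- ut[is.finite(ut) & ut > 0]
  if (length(finite)) {
    tab <- tabulate(finite)
    keep <- tab > 0L
    counts <- tab[keep]
    names(counts) <- which(keep)
  } else {
    counts <- integer(0)
  }
  structure(list(distances = d, shell_counts = counts),
            class = "distance_summary")
}

#' Distance-dependent interaction probability matrix
#'
#' Assigns every agent pair an interaction probability from its social
#' distance d in the contact network:
#' \deqn{\pi_{ij} = \beta \quad (d = 1), \qquad
#'       \pi_{ij} = \max\{\varepsilon,\;
#'       \beta \frac{L(1)}{L(d)} e^{-(d-1)/\delta}\} \quad (1 < d < \infty),
#'       \qquad \pi_{ij} = \varepsilon \quad (d = \infty).}
#' Direct contacts interact with probability exactly beta; the probability
#' decays approximately exponentially with distance, normalised by the shell
#' counts L(d); disconnected or very distant pairs keep the incidental
#' baseline epsilon.
#'
#' @param dist a `distance_summary` from [shortest_path_distances()].
#' @param params an [interaction_params()] object.
#' @return Symmetric N x N probability matrix with zero diagonal.
#' @export
interaction_probabilities <- function(dist, params = interaction_params()) {
  stopifnot(inherits(dist, "distance_summary"),
            inherits(params, "interaction_params"))
  d <- dist$distances
  shells <- dist$shell_counts
  n <- nrow(d)
  pi_m <- matrix(params$baseline, n, n)
  if (length(shells)) {
    dv <- as.integer(names(shells))
    if (any(shells == 0L))
      stop("internal error: empty shell with occupied distance", call. = FALSE)
    l1 <- if (any(dv == 1L)) shells[[match(1L, dv)]] else 0L
    # per-distance probability, integer-indexed lookup over finite entries
    lookup <- rep(params$baseline, max(dv))
    if (l1 > 0) {
      lookup[dv] <- pmax(params$baseline,
                         params$scale * (l1 / shells) *
                           exp(-(dv - 1) / params$decay_distance))
      lookup[1L] <- params$scale
    }
    fin <- is.finite(d) & d > 0
    pi_m[fin] <- lookup[d[fin]]
  }
  diag(pi_m) <- 0
  pi_m
}

#' Sample the interaction network
#'
#' Draws the fast interaction layer for one time step: every unordered agent
#' pair interacts independently with its entry of the interaction
#' probability matrix.
#'
#' @param probs symmetric probability matrix with zero diagonal.
#' @return An undirected simple `igraph` graph on the same agent set.
#' @export
sample_interaction_network <- function(probs) {
  adj <- sample_interaction_adjacency(probs)
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Matrix-level sampler used in the inner simulation loop (avoids building an
# igraph object when only the adjacency is needed).
sample_interaction_adjacency <- function(probs) {
  probs <- as.matrix(probs)
  n <- nrow(probs)
  adj <- matrix(FALSE, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- runif(sum(ut)) < probs[ut]
  adj | t(adj)
}
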