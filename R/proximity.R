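#' Time-dependent proximity matrix
#'
#' Social proximity mixes behavioural similarity with the static background:
#'   P_ij = alpha * 1\{s_i = s_j\} + (1 - alpha) * B_ij,
#' a convex combination weighting current behaviour co-occurrence by `alpha`
#' against the background proximity. With the default alpha = 0.2 a
#' behaviour match outweighs roughly one to two degrees of background social
#' distance, giving the network its typical mobility.
#'
#' @param background a `background_proximity` object or bare matrix B.
#' @param states 0/1 behaviour vector.
#' @param alpha behaviour weight in `[0, 1]` (default 0.2).
#' @return Symmetric N x N matrix with zero diagonal, entries in `[0, 1]`.
#' @export
proximity_matrix <- function(background, states, alpha = 0.2) {
  stopifnot(alpha >= 0, alpha <= 1)
  b <- proximity_values(background)
  match_m <- outer(states, states, "==") * 1
  p <- alpha * match_m + (1 - alpha) * b
  diag(p) <- 0
  p
}

#' Update the contact network by ranked reciprocal preference
#'
#' Each agent i ranks the union of its current contacts and this step's
#' interaction partners by descending social proximity P_ij (ties broken by
#' ascending agent index) and keeps the top q_i as its potential contact
#' list T_i. Contacts require reciprocity: the edge \{i, j\} exists after
#' the update iff j is in T_i and i is in T_j. Agents can therefore lose
#' contacts actively (dropping an alter) or passively (being dropped), and
#' new ties can only form between agents that interacted this step (only
#' those enter U_i). No "second best" refill is applied after the
#' reciprocity pruning; refinement happens implicitly over subsequent steps.
#'
#' @param previous contact network (`igraph` or logical adjacency matrix).
#' @param interaction interaction network of this step (same type).
#' @param P proximity matrix.
#' @param q integer vector of degree preferences.
#' @return Updated contact network, as an `igraph` graph if `previous` was
#'   one, otherwise as a logical adjacency matrix.
#' @export
update_contact_network <- function(previous, interaction, P, q) {
  as_graph <- igraph::is_igraph(previous)
  cadj <- if (as_graph)
    igraph::as_adjacency_matrix(previous, sparse = FALSE) > 0 else previous
  iadj <- if (igraph::is_igraph(interaction))
    igraph::as_adjacency_matrix(interaction, sparse = FALSE) > 0
  else interaction
  new_adj <- contact_update_adjacency(cadj, iadj, P, q)
  if (as_graph)
    igraph::graph_from_adjacency_matrix(new_adj, mode = "undirected")
  else new_adj
}

# Adjacency-level update used in the simulation loop.
contact_update_adjacency <- function(cadj, iadj, P, q) {
  n <- nrow(P)
  cand_m <- cadj | iadj
  tm <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    cand <- which(cand_m[i, ])
    if (!length(cand)) next
    ord <- cand[order(-P[i, cand], cand)]
    tm[i, ord[seq_len(min(q[i], length(ord)))]] <- TRUE
  }
  out <- tm & t(tm)
  diag(out) <- FALSE
  out
}

#' Initial contact network from a fully connected interaction round
#'
#' At initialisation every pair of agents is treated as having interacted, so
#' U_i contains all other agents; the ranked reciprocal update then yields
#' the initial contact network consistent with the initial proximities.
#'
#' @inheritParams update_contact_network
#' @return Logical adjacency matrix of the initial contact network.
#' @export
initial_contact_network <- function(P, q) {
  n <- nrow(P)
  full <- matrix(TRUE, n, n)
  diag(full) <- FALSE
  contact_update_adjacency(matrix(FALSE, n, n), full, P, q)
}
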