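#' Peer-influence parameters
#'
#' `switch_scale` (C) bounds the per-step switching probability and thereby
#' sets the amplitude of the equilibrium stochastic noise of the Ising-type
#' behaviour dynamics (default C = 0.1). `variant` selects the model
#' variant: `"coupled"` (full model), `"interaction"` (static contact
#' network), `"network"` (no peer influence; behaviour follows the
#' disposition threshold), `"mean_field"` (global instead of local peer
#' field).
#'
#' @param switch_scale switching probability scaling factor C in (0, 1].
#' @param variant one of `"coupled"`, `"network"`, `"interaction"`,
#'   `"mean_field"`.
#' @return A list of class `influence_params`.
#' @export
influence_params <- function(switch_scale = 0.1, variant = "coupled") {
  if (!(switch_scale > 0 && switch_scale <= 1))
    stop("`switch_scale` must lie in (0, 1]", call. = FALSE)
  variant <- match.arg(variant,
                       c("coupled", "network", "interaction", "mean_field"))
  structure(list(switch_scale = switch_scale, variant = variant),
            class = "influence_params")
}

#' Create an agent population
#'
#' Draws the per-agent properties: the degree preference q_i (upper bound on
#' the contact-network degree, discretised Gaussian with mean `mu` and sd
#' `sigma`, truncated to `[1, N - 1]`) and stores the dispositions and the
#' behaviour states initialised from them via the Heaviside rule
#' s_i = 1 iff gamma_i >= 0.5.
#'
#' @param dispositions numeric vector of smoking dispositions in `[0, 1]`.
#' @param mu,sigma mean and sd of the degree-preference distribution
#'   (defaults 10 and 3).
#' @param seed integer seed for the degree-preference draw.
#' @return A list of class `agent_population` with `degree_preference`,
#'   `disposition` and `smoking_state`.
#' @export
agent_population <- function(dispositions, mu = 10, sigma = 3, seed = 1L) {
  n <- length(dispositions)
  set.seed(seed)
  q <- pmin(pmax(round(rnorm(n, mu, sigma)), 1L), n - 1L)
  structure(list(degree_preference = as.integer(q),
                 disposition = dispositions,
                 smoking_state = initialise_behaviour(dispositions)),
            class = "agent_population")
}

#' Initialise behaviour from disposition
#'
#' The initial behaviour is consistent with the disposition through the
#' Heaviside function: s = Theta(gamma - 1/2), with the convention
#' Theta(0) = 1 so that gamma = 0.5 maps to smoking.
#'
#' @param disposition numeric vector with values in `[0, 1]`.
#' @return Integer vector of 0/1 states.
#' @export
initialise_behaviour <- function(disposition) {
  if (any(disposition < 0 | disposition > 1))
    stop("dispositions must lie in [0, 1]", call. = FALSE)
  as.integer(disposition >= 0.5)
}

#' Per-step probability of switching behaviour
#'
#' Ising-type switching: a non-smoker starts with probability
#' p = C * gamma * f and a smoker stops with probability
#' p = C * (1 - gamma) * (1 - f), where f is the smoking fraction among the
#' agent's interaction partners (or the global prevalence in the mean-field
#' variant). Both directions are bounded by C, vanish when the disposition
#' fully opposes the switch, and grow with the peer pressure toward it.
#'
#' @param state 0/1 behaviour state(s).
#' @param disposition smoking disposition(s) in `[0, 1]`.
#' @param peer_smoking_fraction smoking fraction f among peers, in `[0, 1]`.
#' @param C switching probability scaling factor.
#' @return Switching probability (vectorised), in `[0, C]`.
#' @export
switching_probability <- function(state, disposition, peer_smoking_fraction,
                                  C = 0.1) {
  n <- max(length(state), length(disposition),
           length(peer_smoking_fraction))
  state <- rep_len(state, n)
  disposition <- rep_len(disposition, n)
  f <- rep_len(peer_smoking_fraction, n)
  ifelse(state == 0L, C * disposition * f, C * (1 - disposition) * (1 - f))
}

#' Update all behaviour states for one time step
#'
#' Applies one synchronous social-influence step. For the `coupled` and
#' `interaction` variants the peer field f_i is the smoking fraction among
#' i's neighbours in the interaction network; agents without any interaction
#' this step keep their state. The `mean_field` variant replaces f_i by the
#' global prevalence S/N (the no-interaction rule still applies). The
#' `network` variant ignores peer influence entirely: s_i = 1 iff
#' gamma_i >= 0.5, deterministically. Switches are independent Bernoulli
#' draws with the probabilities of [switching_probability()].
#'
#' @param pop an [agent_population()].
#' @param interaction interaction network (`igraph` or logical adjacency
#'   matrix).
#' @param params an [influence_params()].
#' @return The population with updated `smoking_state`.
#' @export
update_behaviours <- function(pop, interaction, params = influence_params()) {
  stopifnot(inherits(pop, "agent_population"),
            inherits(params, "influence_params"))
  adj <- if (igraph::is_igraph(interaction)) {
    igraph::as_adjacency_matrix(interaction, sparse = FALSE) > 0
  } else interaction
  pop$smoking_state <- step_behaviours(pop$smoking_state, pop$disposition,
                                       adj, params)
  pop
}

# Vector-level behaviour step used in the simulation loop.
step_behaviours <- function(states, dispositions, adj, params) {
  if (params$variant == "network")
    return(as.integer(dispositions >= 0.5))
  n_int <- rowSums(adj)
  f <- if (params$variant == "mean_field") {
    rep(mean(states), length(states))
  } else {
    as.vector(adj %*% states) / pmax(n_int, 1)
  }
  p <- switching_probability(states, dispositions, f, params$switch_scale)
  flip <- (runif(length(states)) < p) & (n_int > 0)
  ifelse(flip, 1L - states, states)
}
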