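#' Configuration of a model run
#'
#' Collects every model parameter with the defaults of the smoking
#' experiment: a Watts-Strogatz substrate (z = 10, p_w = 0.03) behind the
#' background proximity, interaction kernel beta = 0.8, epsilon = 0.03,
#' delta = 2, switching scale C = 0.1, proximity weight alpha = 0.2, degree
#' preferences from N(10, 3^2), a parabolic disposition schedule C1 = 2.5
#' falling to C_f = 0.25 over 1000 forcing steps after 200 equilibration
#' steps, and an ensemble of 1000 runs.
#'
#' @param n_agents number of agents N (default 500).
#' @param mean_degree,rewiring_prob substrate parameters z, p_w.
#' @param decrement,noise_amp,proximity_floor background-proximity
#'   parameters. The defaults (0.2 each) put the homophily mobility --
#'   how many background degrees a behaviour match is worth,
#'   alpha / ((1 - alpha) * decrement) -- at 1.25, within the one-to-two
#'   degree range the proximity weighting is calibrated to.
#' @param beta,epsilon,delta interaction-kernel parameters.
#' @param C switching probability scaling factor.
#' @param variant model variant, see [influence_params()].
#' @param alpha behaviour weight of the proximity matrix.
#' @param degree_pref_mean,degree_pref_sd degree-preference distribution.
#' @param C1,C_f disposition-schedule endpoints.
#' @param forcing_steps,equilibration_steps protocol lengths.
#' @param step_scale,log_sd,ks_alpha,max_inner_iterations forcing-noise
#'   parameters, see [forcing_noise_params()].
#' @param cp_max_distance largest social distance tracked by the
#'   conditional-probability metric.
#' @param ensemble_size number of ensemble runs.
#' @param base_seed seed of the first ensemble run (run k uses
#'   `base_seed + k - 1`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_agents = 500L, mean_degree = 10L,
                       rewiring_prob = 0.03, decrement = 0.2,
                       noise_amp = 0.2, proximity_floor = 0.2,
                       beta = 0.8, epsilon = 0.03, delta = 2,
                       C = 0.1, variant = "coupled", alpha = 0.2,
                       degree_pref_mean = 10, degree_pref_sd = 3,
                       C1 = 2.5, C_f = 0.25, forcing_steps = 1000L,
                       equilibration_steps = 200L,
                       step_scale = 0.01, log_sd = 0.5, ks_alpha = 0.10,
                       max_inner_iterations = 500L,
                       cp_max_distance = 5L,
                       ensemble_size = 1000L, base_seed = 1L) {
  cfg <- list(n_agents = as.integer(n_agents),
              mean_degree = as.integer(mean_degree),
              rewiring_prob = rewiring_prob, decrement = decrement,
              noise_amp = noise_amp, proximity_floor = proximity_floor,
              beta = beta, epsilon = epsilon, delta = delta,
              C = C, variant = variant, alpha = alpha,
              degree_pref_mean = degree_pref_mean,
              degree_pref_sd = degree_pref_sd,
              C1 = C1, C_f = C_f, forcing_steps = as.integer(forcing_steps),
              equilibration_steps = as.integer(equilibration_steps),
              step_scale = step_scale, log_sd = log_sd, ks_alpha = ks_alpha,
              max_inner_iterations = as.integer(max_inner_iterations),
              cp_max_distance = as.integer(cp_max_distance),
              ensemble_size = as.integer(ensemble_size),
              base_seed = as.integer(base_seed))
  substrate_params(cfg$n_agents, cfg$mean_degree, cfg$rewiring_prob) # validate
  interaction_params(cfg$beta, cfg$epsilon, cfg$delta)
  influence_params(cfg$C, cfg$variant)
  stopifnot(cfg$ensemble_size >= 1, cfg$equilibration_steps >= 0,
            cfg$forcing_steps >= 0)
  class(cfg) <- "run_config"
  cfg
}

metric_names <- function(cfg) {
  c("prevalence", "evc_smokers", "evc_nonsmokers",
    paste0("cp_", seq_len(cfg$cp_max_distance)))
}

#' Run one model realisation
#'
#' Executes the full protocol for one seed: (i) draw the substrate,
#' background proximity, degree preferences and initial dispositions;
#' initialise behaviour by the Heaviside rule and build the initial contact
#' network from a fully connected interaction round; (ii) integrate without
#' forcing for `equilibration_steps`; (iii) integrate under the disposition
#' forcing for `forcing_steps`. Each step runs the cycle: interaction
#' probabilities from contact-network distances, stochastic interaction
#' network, behaviour update (per variant), proximity matrix, ranked
#' reciprocal contact update (skipped in the `interaction` variant), and the
#' forcing transformation of the dispositions.
#'
#' Structure (substrate, background noise, degree preferences), disposition
#' path and dynamics each consume separate random streams derived from
#' `seed`, so different variants run with the same seed share identical
#' background proximity and forcing realisations.
#'
#' @param config a [run_config()].
#' @param seed integer run seed.
#' @param keep_state also return the final model state (background matrix,
#'   contact adjacency, states, dispositions).
#' @return A list of class `coevo_trajectory` with `metrics` (one row per
#'   step), `baseline_step` (forcing onset), and `provenance`.
#' @export
run_simulation <- function(config, seed = config$base_seed,
                           keep_state = FALSE) {
  stopifnot(inherits(config, "run_config"))
  n <- config$n_agents
  infl <- influence_params(config$C, config$variant)
  ipar <- interaction_params(config$beta, config$epsilon, config$delta)

  # --- structure stream: substrate, background noise, degree preferences
  sp <- substrate_params(n, config$mean_degree, config$rewiring_prob,
                         seed = substream_seed(seed, "substrate"))
  substrate <- generate_ws_network(sp)
  bg <- build_background_proximity(substrate, config$decrement,
                                   config$noise_amp, config$proximity_floor,
                                   seed = substream_seed(seed,
                                                         "background_noise"))
  b <- bg$values
  set.seed(substream_seed(seed, "degree_pref"))
  q <- pmin(pmax(round(rnorm(n, config$degree_pref_mean,
                             config$degree_pref_sd)), 1L), n - 1L)

  # --- disposition stream: initial draw plus the whole forcing path
  schedule <- forcing_schedule(config$C1, config$C_f, config$forcing_steps)
  noise <- forcing_noise_params(config$step_scale, config$log_sd,
                                config$ks_alpha,
                                config$max_inner_iterations)
  gpath <- disposition_path(n, schedule, noise,
                            seed = substream_seed(seed, "disposition"))

  # --- initialisation (protocol step i)
  # The initial contact network is established before behaviour is
  # initialised, so its ranking reflects background proximity only (the
  # behaviour term of the proximity is constant across pairs at this point).
  gam <- gpath[1L, ]
  P0 <- proximity_matrix(b, integer(n), config$alpha)
  cadj <- initial_contact_network(P0, q)
  states <- initialise_behaviour(gam)
  g_contact <- igraph::graph_from_adjacency_matrix(cadj, mode = "undirected")
  dm <- igraph::distances(g_contact)

  n_steps <- config$equilibration_steps + config$forcing_steps
  met <- matrix(NA_real_, n_steps, length(metric_names(config)),
                dimnames = list(NULL, metric_names(config)))
  static_contact <- infl$variant == "interaction"
  evc_cache <- NULL

  set.seed(substream_seed(seed, "dynamics"))
  for (t in seq_len(n_steps)) {
    # Step 1-2: interaction probabilities on G^C(t-1), sample G^I(t)
    pim <- interaction_probabilities(.distance_summary(dm), ipar)
    iadj <- sample_interaction_adjacency(pim)

    # Step 3: behaviour update from gamma(t-1) and G^I(t)
    states <- step_behaviours(states, gam, iadj, infl)

    # Step 4-5: proximity and ranked reciprocal contact update
    if (!static_contact) {
      P <- proximity_matrix(b, states, config$alpha)
      cadj <- contact_update_adjacency(cadj, iadj, P, q)
      if (any(rowSums(cadj) > q))
        stop("degree bound violated at step ", t)
      g_contact <- igraph::graph_from_adjacency_matrix(cadj,
                                                       mode = "undirected")
      dm <- igraph::distances(g_contact)
      evc <- eigenvector_centrality(g_contact)
    } else {
      if (is.null(evc_cache)) evc_cache <- eigenvector_centrality(g_contact)
      evc <- evc_cache
    }

    # Step 6: forcing (active after equilibration); gamma path precomputed
    if (t > config$equilibration_steps)
      gam <- gpath[t - config$equilibration_steps + 1L, ]

    sm <- states == 1L
    met[t, ] <- c(prevalence(states),
                  if (any(sm)) mean(evc[sm]) else NA_real_,
                  if (any(!sm)) mean(evc[!sm]) else NA_real_,
                  cp_profile(dm, states, config$cp_max_distance))
  }

  out <- list(metrics = as.data.frame(cbind(step = seq_len(n_steps), met)),
              baseline_step = config$equilibration_steps,
              provenance = list(seed = as.integer(seed),
                                variant = infl$variant,
                                n_agents = n,
                                background_checksum = sum(b),
                                disposition_checksum = sum(gpath),
                                degree_pref_checksum = sum(q)))
  if (keep_state)
    out$state <- list(background = b, contact = cadj, states = states,
                      dispositions = gam, degree_preference = q,
                      disposition_path = gpath)
  class(out) <- "coevo_trajectory"
  out
}

#' @export
print.coevo_trajectory <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<coevo_trajectory> %s variant, %d agents, %d steps\n",
              x$provenance$variant, x$provenance$n_agents, nrow(m)))
  cat(sprintf("  prevalence: %.3f (baseline step %d) -> %.3f (final)\n",
              m$prevalence[max(x$baseline_step, 1L)], x$baseline_step,
              m$prevalence[nrow(m)]))
  invisible(x)
}

#' Run a seeded ensemble
#'
#' Runs `n_runs` independent realisations with seeds `base_seed + k - 1`
#' (each redrawing the background proximity and dispositions), and
#' aggregates every metric across runs: per-step ensemble mean and, when
#' `ci = TRUE`, percentile-bootstrap 95% and 99% bands. Metrics that are
#' undefined in a run (e.g. conditional probability with no smoking alters)
#' are excluded from the aggregation, with the number of contributing runs
#' reported.
#'
#' @param config a [run_config()].
#' @param n_runs number of runs (defaults to `config$ensemble_size`).
#' @param base_seed seed of the first run (defaults to `config$base_seed`).
#' @param ci compute bootstrap confidence bands (default TRUE).
#' @param ci_reps bootstrap resamples per step and metric.
#' @return A list of class `ensemble_summary` with `summary` (long-format
#'   data frame: step, metric, mean, n_runs and CI bounds), `metrics` (runs
#'   x steps x metrics array), `baseline_step`, `seeds`, `config`.
#' @export
run_ensemble <- function(config, n_runs = config$ensemble_size,
                         base_seed = config$base_seed, ci = TRUE,
                         ci_reps = 2000L) {
  stopifnot(inherits(config, "run_config"), n_runs >= 1)
  seeds <- base_seed + seq_len(n_runs) - 1L
  runs <- lapply(seeds, function(s) run_simulation(config, seed = s))
  n_steps <- nrow(runs[[1]]$metrics)
  mn <- metric_names(config)
  arr <- array(NA_real_, c(n_runs, n_steps, length(mn)),
               dimnames = list(NULL, NULL, mn))
  for (k in seq_len(n_runs))
    arr[k, , ] <- as.matrix(runs[[k]]$metrics[, mn])

  pieces <- lapply(mn, function(m) {
    x <- arr[, , m, drop = FALSE]
    dim(x) <- c(n_runs, n_steps)
    df <- data.frame(step = seq_len(n_steps), metric = m,
                     mean = colMeans(x, na.rm = TRUE),
                     n_runs = colSums(!is.na(x)))
    if (ci) {
      ciq <- ensemble_band(x, levels = c(0.95, 0.99), reps = ci_reps,
                           seed = substream_seed(base_seed, "bootstrap"))
      df <- cbind(df, ciq)
    }
    df
  })
  summary <- do.call(rbind, pieces)
  summary$mean[is.nan(summary$mean)] <- NA_real_
  structure(list(summary = summary, metrics = arr,
                 baseline_step = runs[[1]]$baseline_step,
                 seeds = seeds, config = config),
            class = "ensemble_summary")
}

# Percentile-bootstrap bands over runs, vectorised across steps. Shared
# resamples across levels keep the 99% band nested around the 95% band.
ensemble_band <- function(x, levels = c(0.95, 0.99), reps = 2000L,
                          seed = 1L) {
  n_runs <- nrow(x)
  set.seed(seed)
  w <- matrix(sample.int(n_runs, n_runs * reps, replace = TRUE), nrow = reps)
  counts <- matrix(0, reps, n_runs)
  for (r in seq_len(reps))
    counts[r, ] <- tabulate(w[r, ], nbins = n_runs)
  ok <- !is.na(x)
  x0 <- ifelse(ok, x, 0)
  num <- counts %*% x0          # reps x steps resampled sums
  den <- counts %*% ok          # contributing run counts per resample
  means <- num / ifelse(den > 0, den, NA_real_)
  out <- matrix(NA_real_, ncol(x), 2 * length(levels))
  cn <- character(0)
  for (li in seq_along(levels)) {
    l <- levels[li]
    qs <- apply(means, 2, quantile, probs = c((1 - l) / 2, 1 - (1 - l) / 2),
                na.rm = TRUE)
    out[, 2 * li - 1] <- qs[1, ]
    out[, 2 * li] <- qs[2, ]
    cn <- c(cn, paste0(c("lower_", "upper_"), l * 100))
  }
  colnames(out) <- cn
  as.data.frame(out)
}

#' @export
print.ensemble_summary <- function(x, ...) {
  prev <- x$summary[x$summary$metric == "prevalence", ]
  cat(sprintf("<ensemble_summary> %s variant, %d runs, %d steps\n",
              x$config$variant, length(x$seeds), max(prev$step)))
  b <- max(x$baseline_step, 1L)
  cat(sprintf("  mean prevalence: %.3f (forcing onset) -> %.3f (final)\n",
              prev$mean[b], prev$mean[nrow(prev)]))
  invisible(x)
}

#' Normalised metric series of an ensemble
#'
#' Divides each run's metric series by its own value at the forcing-onset
#' baseline step, then averages across runs (normalise-then-average), the
#' form in which centrality and conditional-probability changes are
#' reported. With `adjust_prevalence = TRUE` the per-run series is first
#' divided by the run's concurrent prevalence, turning a conditional
#' smoking probability into the distance-d *enrichment* (how much more
#' likely an ego is to smoke near a distance-d smoker than a random agent
#' is): the clustering measure that can rise while overall prevalence
#' collapses.
#'
#' @param ens an [run_ensemble()] result.
#' @param metric metric name, e.g. `"evc_smokers"` or `"cp_1"`.
#' @param adjust_prevalence divide by the run's prevalence series first.
#' @return Numeric vector over steps: mean across runs of the normalised
#'   series.
#' @export
normalised_series <- function(ens, metric, adjust_prevalence = FALSE) {
  x <- ens$metrics[, , metric, drop = FALSE]
  dim(x) <- dim(ens$metrics)[1:2]
  if (adjust_prevalence) {
    p <- ens$metrics[, , "prevalence", drop = FALSE]
    dim(p) <- dim(x)
    x <- x / p
  }
  base <- x[, max(ens$baseline_step, 1L)]
  colMeans(x / base, na.rm = TRUE)
}

#' Compare model variants on shared structure
#'
#' Runs one ensemble per variant with identical base seeds, so paired runs
#' share the background proximity, degree preferences and the full
#' disposition forcing path, and differ only in the behavioural/network
#' dynamics. Reports prevalence levels and drops (with ratios relative to
#' the `network` variant when present), normalised end-of-run eigenvector
#' centrality by behavioural group, and normalised conditional-probability
#' changes by distance.
#'
#' End-of-run values are averaged over the final `final_window` steps to
#' damp single-step sampling noise.
#'
#' @param config a [run_config()] (its `variant` field is ignored).
#' @param variants character vector of at least two variants.
#' @param n_runs ensemble size per variant.
#' @param base_seed shared first seed.
#' @param ci passed to [run_ensemble()].
#' @param final_window number of closing steps averaged for end-of-run
#'   values.
#' @return A list of class `variant_comparison` with `report` (one row per
#'   variant), `cp_change` (variant x distance matrix of relative changes),
#'   and `ensembles` (named list of [run_ensemble()] results).
#' @export
compare_variants <- function(config,
                             variants = c("coupled", "network",
                                          "interaction", "mean_field"),
                             n_runs = config$ensemble_size,
                             base_seed = config$base_seed, ci = FALSE,
                             final_window = 50L) {
  stopifnot(length(variants) >= 2)
  ensembles <- lapply(variants, function(v) {
    cfg <- config
    cfg$variant <- v
    run_ensemble(cfg, n_runs = n_runs, base_seed = base_seed, ci = ci)
  })
  names(ensembles) <- make.unique(variants)

  n_steps <- config$equilibration_steps + config$forcing_steps
  b <- max(config$equilibration_steps, 1L)
  fin <- seq(max(n_steps - final_window + 1L, 1L), n_steps)

  end_mean <- function(v) mean(v[fin], na.rm = TRUE)
  rows <- lapply(seq_along(ensembles), function(i) {
    e <- ensembles[[i]]
    prev <- e$summary$mean[e$summary$metric == "prevalence"]
    data.frame(variant = names(ensembles)[i],
               initial_prevalence = prev[b],
               final_prevalence = prev[n_steps],
               prevalence_drop = prev[b] - prev[n_steps],
               evc_smokers_change = end_mean(normalised_series(e,
                                                               "evc_smokers")) - 1,
               evc_nonsmokers_change = end_mean(normalised_series(e,
                                                                  "evc_nonsmokers")) - 1)
  })
  report <- do.call(rbind, rows)
  if ("network" %in% report$variant) {
    net_drop <- report$prevalence_drop[report$variant == "network"][1]
    report$drop_ratio_vs_network <- report$prevalence_drop / net_drop
  }

  dmax <- config$cp_max_distance
  cp_change <- t(vapply(ensembles, function(e)
    vapply(seq_len(dmax), function(d)
      end_mean(normalised_series(e, paste0("cp_", d))) - 1, numeric(1)),
    numeric(dmax)))
  colnames(cp_change) <- paste0("d", seq_len(dmax))
  cp_enrichment_change <- t(vapply(ensembles, function(e)
    vapply(seq_len(dmax), function(d)
      end_mean(normalised_series(e, paste0("cp_", d),
                                 adjust_prevalence = TRUE)) - 1, numeric(1)),
    numeric(dmax)))
  colnames(cp_enrichment_change) <- paste0("d", seq_len(dmax))

  structure(list(report = report, cp_change = cp_change,
                 cp_enrichment_change = cp_enrichment_change,
                 ensembles = ensembles, config = config,
                 final_window = as.integer(final_window)),
            class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("<variant_comparison>\n")
  enr <- x$cp_enrichment_change[, seq_len(min(3, ncol(x$cp_enrichment_change))),
                                drop = FALSE]
  colnames(enr) <- paste0("enrich_", colnames(enr))
  print(cbind(x$report[, c("variant", "initial_prevalence",
                           "final_prevalence", "prevalence_drop")],
              round(enr, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Write the metric series of an ensemble as tidy CSV
#'
#' Columns: run, step, metric, value.
#'
#' @param ens an [run_ensemble()] result.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_metrics_csv <- function(ens, path) {
  arr <- ens$metrics
  dn <- dimnames(arr)[[3]]
  long <- do.call(rbind, lapply(seq_along(dn), function(m)
    data.frame(run = rep(seq_len(dim(arr)[1]), times = dim(arr)[2]),
               step = rep(seq_len(dim(arr)[2]), each = dim(arr)[1]),
               metric = dn[m], value = as.vector(arr[, , m]))))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}
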