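# coevonet

Agent-based simulation of how a binary health behaviour (smoking) and a
social network restructure each other during a normative transition — and
of why the *remaining* minority ends up in marginalized clusters.

The package is aimed at computational social scientists and
epidemiological modellers who want a mechanistic, fully seeded sandbox for
behaviour–network co-evolution: every ingredient is generated internally
(no external data), every stage is an exported, individually testable
function, and partial-model variants isolate which mechanism produces
which observable.

## The model in brief

A closed population of `N` agents carries a binary state `s_i(t)`
(smoking / not smoking) on two network layers:

* a slow **contact network**: reciprocal ties, capped per agent by a
  degree preference `q_i ~ N(10, 3²)`, rewired each step by ranked
  homophilous preference on a proximity matrix
  `P_ij = α·1{s_i = s_j} + (1−α)·B_ij` (α = 0.2), where `B` is a fixed
  small-world background proximity built from a Watts–Strogatz substrate
  (`z = 10`, `p_w = 0.03`, floor 0.2);
* a fast **interaction network**, resampled every step with probability
  `β = 0.8` for direct contacts, decaying roughly exponentially with
  contact distance (`δ = 2`, shell-normalised), floored at `ε = 0.03` for
  incidental meetings.

Behaviour updates are Ising-type: a non-smoker starts with probability
`C·γ_i·f_i`, a smoker stops with `C·(1−γ_i)·(1−f_i)`, with `C = 0.1`,
`f_i` the smoking fraction among current interaction partners and `γ_i` an
exogenous disposition. A forcing schedule drags the disposition
distribution from symmetric-bimodal to quasi-unimodal over 1000 steps
(parabolic family `y(x) = a(b−x)² + c`, endpoints `C1 = 2.5 → C_f = 0.25`,
Kolmogorov–Smirnov-matched Markov noise), emulating changing social norms.

Model variants: `coupled` (everything), `interaction` (static contact
network), `network` (no peer influence, threshold behaviour), `mean_field`
(global instead of local peer field). Observables: prevalence `S(t)/N`,
eigenvector centrality by behavioural group, and the conditional
probability of smoking at contact distance `d` (plus its
prevalence-adjusted enrichment), with bootstrap confidence bands across
seeded ensembles.

## Worked example

```r
library(coevonet)

cfg <- run_config(n_agents = 200, ensemble_size = 5, base_seed = 1)
ens <- run_ensemble(cfg)
print(ens)
#> <ensemble_summary> coupled variant, 5 runs, 1200 steps
#>   mean prevalence: 0.505 (forcing onset) -> 0.205 (final)
```

Half the population smokes at the quasi-equilibrium reached after 200
burn-in steps; over the 1000 forcing steps the normative shift and peer
influence drive prevalence down to about a fifth. Comparing variants on
identical seeds (same background proximity, same disposition paths):

```r
cmp <- compare_variants(cfg, n_runs = 5)
print(cmp)
#> <variant_comparison>
#>      variant initial_prevalence final_prevalence prevalence_drop enrich_d1 enrich_d2 enrich_d3
#>      coupled              0.505            0.205           0.300     1.142     0.759     0.017
#>      network              0.496            0.290           0.206     0.579     0.418     0.046
#>  interaction              0.525            0.201           0.324     0.208     0.032    -0.004
#>   mean_field              0.510            0.181           0.329     1.373     0.808    -0.001
```

The `enrich_d1…d3` columns are end-of-run relative changes of the
distance-`d` smoking enrichment (conditional probability divided by
prevalence): behaviour clusters far more around surviving smokers when
the contact network co-evolves than on a static network (`interaction`),
and peer influence without network dynamics cannot produce it. The
influence variants also drop prevalence half again as much as the
disposition-threshold `network` variant. Smokers' mean eigenvector
centrality falls well below baseline wherever the network evolves
(`cmp$report$evc_smokers_change`: coupled −0.27, mean-field −0.40,
network −0.27, static-network +0.16), the clustered-marginalization
signature.

A thin command-line front-end wraps the same functions:

```sh
Rscript inst/scripts/coevonet.R ensemble --config my.yaml --runs 20 --out out/
```

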