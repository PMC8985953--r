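# chromem

Models of a gene's inner chromatin modification circuit and the epigenetic
memory it produces.

A gene's chromatin state is summarized by the modification status of its
`Dtot` nucleosomes: unmodified (`D`), activating marks such as H3K4me3/ac
(`DA`), DNA (CpG) methylation (`D1R`), repressive H3K9me3 (`D2R`), or both
repressive marks (`D12R`). Marks are established de novo, reinforced by
auto- and cross-catalysis among the repressive marks, opposed by the
activating mark through recruited erasure, and removed by slow basal
erasure at the dimensionless rate `eps`. When `eps` is small relative to the
recruited rates, the fully active and fully repressed configurations become
long-lived: the circuit stores a memory of past transcription-factor inputs.

The package provides three consistent views of one reaction network plus
composition operators for gene circuits:

- **Deterministic mean field** (`simulate_ode`, `find_equilibria`,
  `bifurcation_scan`, `stability_chart`, `hysteresis_sweep`): nucleosome
  fractions as ODEs; bistability, saddle-node points, input hysteresis.
- **Exact Markov chain** (`build_generator`, `exact_stationary`,
  `exact_mfpt`, `reduce_to_1d`, `limit_stationary`,
  `mfpt_scaling_check`): the full chemical master equation on the simplex
  of nucleosome counts, solved exactly; stationary laws, mean first-passage
  (memory) times, their scaling in `eps`, and a one-dimensional birth–death
  reduction.
- **Stochastic simulation** (`ssa_run`, `stationary_histogram`,
  `first_passage_sample`, `reactivation_experiment`): an exact Gillespie
  engine (C++ core) with event logging, stop conditions, and first-passage
  statistics.
- **Circuit composition** (`make_autoregulated`, `make_mutual_repression`,
  `apply_events`, `robustness_scan`, `pattern_census`, `pattern_survival`):
  TF-enabled positive autoregulation and mutual repression between two
  genes, with perturbation events (protein resets, overexpression, input
  steps).

## Quick start

```r
library(chromem)

p   <- chromatin_params(eps = 0.1, Dtot = 8L)   # dimensionless circuit parameters
net <- build_network(p)                          # the full reaction network

# Mean field: two stable states separated by a saddle
find_equilibria(net, n_starts = 40, seed = 1)
#> Equilibrium set: bistable ( 3 equilibria )
#>   [unstable, ...] D=0.2021 DA=0.6795 ... D12R=0.0134
#>   [stable,   ...] D=0.0042 DA=0.0002 ... D12R=0.8685
#>   [stable,   ...] D=0.1244 DA=0.8388 ... D12R=0.0024

# Exact Markov chain: stationary law and memory times
g  <- build_generator(net)
pi <- exact_stationary(g$Q)
sum(pi[g$states[, "D12R"] == 8])                       # P(fully repressed)
#> [1] 0.3237586
i_act <- which(g$states[, "DA"] == 8)
i_rep <- which(g$states[, "D12R"] == 8)
exact_mfpt(g$Q, i_act)[i_rep]                          # repressed -> active
#> [1] 39877300
exact_mfpt(g$Q, i_rep)[i_act]                          # active -> repressed
#> [1] 45.21627

# Stochastic simulation of the same network
run <- ssa_run(net, chromatin_state(net, "repressed"), tau_max = 200,
               seed = 1, sample_times = seq(0, 200, by = 50))
run$snapshots
#>   tau D DA D1R D2R D12R
#> 1   0 0  0   0   0    8
#> 2  50 0  0   1   0    7
#> ...
```

The asymmetry above (a repressed gene reactivates roughly six orders of
magnitude more slowly than an active gene is silenced, at these parameters)
is the central quantitative behaviour: DNA methylation (`D1R`/`D12R`)
recruits repressive histone methylation and vice versa, so the repressed
state is doubly protected, while the active state is maintained only by
its own auto-catalysis.

## Scenario configs and CLI

Reproducible experiments are described by small YAML/JSON configs
(`load_config`, `run_scenario`) with shipped presets
(`list_scenarios()`, `scenario_config("bistable_equilibria")`). A thin CLI
wraps them:

```sh
exec/chromem list-scenarios
exec/chromem run eps_bifurcation --out results/ --seed 1
exec/chromem validate my-config.yaml
```

Each run writes the resolved config, result CSVs, and a JSON run log with
a config fingerprint.

## Tests and acceptance run

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "chromem", load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The acceptance script recomputes the headline quantities (limit-law
masses, exact-vs-SSA agreement, memory-time scaling exponents, critical
inputs and hysteresis, autoregulation robustness, mutual-repression
pattern statistics, conservation drift) and writes them as a flat JSON
object.

## Vignette

`vignettes/chromatin-memory-methods.Rmd` documents the model, the
dimensionless parameterization, the propensity conventions, the numerical
methods (including the subtraction-free GTH solver used for extreme
metastability), and known limitations.
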