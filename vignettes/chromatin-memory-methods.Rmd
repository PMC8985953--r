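---
title: "Methods: chromatin modification circuits and epigenetic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin modification circuits and epigenetic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromem)
```

## The model

A gene carries `Dtot` modifiable nucleosomes, each in one of five states:

| Species | Meaning |
|---|---|
| `D`    | unmodified |
| `DA`   | activating marks (H3K4me3/ac) |
| `D1R`  | DNA (CpG) methylation only |
| `D2R`  | repressive histone methylation (H3K9me3) only |
| `D12R` | both repressive marks |

Counts satisfy the conservation law `D + DA + D1R + D2R + D12R = Dtot`.
The macroscopic observables are the activated count `nA = nDA` and the
repressed count `nR = n1R + n2R + n12R`.

Five classes of reactions interconvert the species; each reaction carries a
class tag used by downstream tooling:

- **de novo** writing of each mark, with strength `u0A + uA` for the
  activating mark and `u10R + u1R`, `u20R + u2R` for the repressive marks
  (basal plus TF-driven input);
- **auto-catalysis**: `DA` recruits writers of the activating mark, `D2R`
  and `D12R` recruit H3K9 writers (rate `alpha`);
- **cross-catalysis** between the repressive marks: CpG methylation
  (`D1R`, `D12R`) recruits H3K9 writers at rate `alpha_bar`, and H3K9me3
  (`D2R`, `D12R`) recruits CpG-methylation writers at rate `alpha_prime`;
- **basal erasure** at rate `eps` (scaled by `mu`, `mu_prime`, `b`, `beta`
  per mark), representing dilution and non-specific turnover;
- **recruited erasure** at rate `eps_prime`: the activating mark recruits
  erasers of the repressive marks and vice versa.

All rates are non-dimensionalized by the activating auto-catalysis rate
(`chromatin_params`, with `nondimensionalize`/`dimensionalize` mapping to
and from physical rate constants). Time `tau` is therefore measured in
units of the catalysis timescale.

### Propensity convention

Catalyzed reactions use mass-action kinetics in the substrate and a
*fraction* in the catalyst:

```
a = coeff * n_substrate * (sum of catalyst counts) / Dtot
```

so that the deterministic mean field is obtained by replacing counts with
fractions, independent of `Dtot`. The catalyst sets are `A = {DA}` for
activating recruitment, `K9 = {D2R, D12R}` for H3K9-mediated recruitment,
and `ME = {D1R, D12R}` for CpG-methylation-mediated recruitment.
`propensities()` exposes these values directly and is the single source of
truth for all three engines.

## Engines

### Deterministic mean field

`simulate_ode` integrates the fraction ODEs with `deSolve::lsoda`;
`mean_field_rhs` and `network_rhs` provide two independently derived
right-hand sides (closed-form and network-generated) that agree to
round-off, which is tested. `find_equilibria` multi-starts a damped Newton
solve on the simplex and classifies the phase portrait (`bistable`,
`monostable_repressed`, ...); `bifurcation_scan` tracks equilibria along a
parameter and reports saddle-node points, `stability_chart` maps regimes
over a 2-D parameter grid, and `hysteresis_sweep` performs quasi-static
up/down input sweeps. Small basal erasure makes the system stiff; `lsoda`
handles this, and conservation drift over `tau = 1e4` is held below
`1e-8` (asserted in the tests).

### Exact Markov chain

For moderate `Dtot` the chemical master equation is solved exactly on the
full state space of compositions of `Dtot` into five parts
(`choose(Dtot + 4, 4)` states; 495 for the default analysis size
`Dtot = 8`, chosen to keep exact solves interactive while preserving the
bistable phenomenology). `build_generator` assembles the sparse generator
`Q` from the same propensity function used by the SSA. `exact_stationary`
solves `pi Q = 0`; `exact_mfpt` computes mean first-passage times.

**Numerical note (GTH).** In the memory regime the chain is extremely
metastable: at `eps = 1e-4` first-passage times reach `1e13` and beyond,
and the linear system for hitting times has condition numbers far past
`1/.Machine$double.eps`, so LU-based solves return garbage (including
negative times). `exact_mfpt` therefore uses a Grassmann–Taksar–Heyman
style elimination that works entirely with non-negative rates and contains
no subtractions, making it entrywise accurate regardless of metastability.
It is validated against closed forms on small chains and against SSA
first-passage samples.

### Memory-time scaling

`mfpt_scaling_check` fits `log tau` against `log eps`. The closed-form
asymptotics — repressed-to-active time growing like
`1/(mu * mu_prime * eps^2)` with both repressive marks, versus `1/eps` for
the histone-only circuit — hold in the regime `eps << eps_prime << 1` with
order-one-but-moderate catalysis ratios. The default grid
(`eps` in `[1e-4, 1e-3]`, `eps_prime = 0.1`, `alpha = 0.2`) sits inside
that regime; at larger `eps` or `eps_prime ~ 1` the exact exponent is
visibly steeper (up to about −4) because nascent activating marks are
erased at order-one rate by the repressive background. This is a property
of the model, not of the solver, and is documented on the function.

### One-dimensional reduction

`reduce_to_1d` stochastically averages the fast species conditional on the
slow coordinate `x = n12R`, yielding a birth–death chain (`bd_stationary`,
`bd_mfpt`). The reduction reproduces the exact stationary repressed mass
and the qualitative memory structure (diverging repressed-escape time,
repressed/active asymmetry), but it is an asymptotic device: at finite
`eps` its mean first-passage times can be off by orders of magnitude, so
quantitative work should use `exact_mfpt`. `limit_stationary` provides the
closed-form `eps -> 0` two-point limit law.

### Stochastic simulation

`ssa_run` is a direct-method Gillespie implementation with the inner loop
in C++ (Rcpp). It supports snapshot grids, full event logs (reaction
labels and firing times), and stop conditions, and is deterministic given
a seed (replaying a seed reproduces the event log exactly).
`stationary_histogram` builds empirical stationary laws (compared to the
exact CME by total-variation distance in the tests: TV < 0.05 at 2000
replicates), `first_passage_sample` reports means, standard errors, and —
honestly — censoring counts, and `reactivation_experiment` measures the
latency distribution of reactivation under an activating input.

## Circuit composition

`make_autoregulated` couples the circuit to its own gene product: protein
`X` is produced at `px * gamma_x * nDA`, decays at `gamma_x`, and recruits
writers of the activating mark (`qss = TRUE` replaces `X` by its
quasi-steady-state mean `px * nDA`). `make_mutual_repression` builds two
complete gene copies (species suffixed `.X`, `.Z`) whose proteins recruit
repressive writers on the opposite gene. `apply_events` injects timed
perturbations (protein reset, overexpression, input steps) into any
engine; `robustness_scan` measures how autoregulation raises the
repressive-input threshold `uR*` needed to silence an active gene;
`pattern_census` and `pattern_survival` quantify the expression patterns
of the two-gene motif and their persistence under repeated protein resets
— with slow basal erasure the chromatin state itself, not the protein
levels, carries the pattern memory.

## Reproducibility

Experiments are described by validated YAML/JSON configs (`load_config`,
`run_scenario`) with shipped presets (`list_scenarios`). Every run writes
the resolved config, result tables, and a run log with a config
fingerprint. The `exec/chromem` CLI wraps these for shell use, and
`scripts/acceptance.R --seed <int> --out <path>` recomputes the package's
headline numbers into a flat JSON file.

## Limitations

- Exact CME analyses scale combinatorially in `Dtot`; beyond roughly
  `Dtot = 20` (10,626 states) use the SSA or the reduction.
- The 1-D reduction's first-passage times are qualitative at finite `eps`
  (see above).
- The published scaling exponents are asymptotic; outside
  `eps << eps_prime << 1` the exact exponents are steeper.
- Proteins in the composed circuits use linear production/decay without
  bursting or cooperativity; `px` and `gamma_x` summarize the expression
  machinery.
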