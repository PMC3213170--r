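# stpnet

Attractor networks that reorganize themselves through short-term synaptic
plasticity.

`stpnet` is for computational neuroscientists studying how prefrontal cortex
can switch, mid-task and without any external trigger, from holding a *goal*
in working memory to representing the *action* that achieves it.  The package
implements a minimal model of this **representational switching**: four
excitatory populations (A–D) and an inhibitory pool, in which goal assemblies
(A&B, C&D) are coupled by depressing synapses and action assemblies (A&D,
B&C) by facilitating ones.  Activating a goal assembly depresses its own
synapses while facilitating the cross-links, so the attractor landscape
itself is rebuilt on a timescale of seconds and the network state is handed
from the goal to an action.

The package provides:

* a conductance-based leaky integrate-and-fire **spiking network** (compiled
  core) with Tsodyks–Markram dynamic synapses,

  $$u \leftarrow u + U(1-u),\qquad s \leftarrow u\,x,\qquad x \leftarrow x - u\,x,$$

  depressing ($\tau_u = 20$, $\tau_x = 600$ ms) versus facilitating
  ($\tau_u = 600$, $\tau_x = 100$ ms) kinds, $U = 0.2$;
* a deterministic **mean-field reduction** with Naka–Rushton transfer
  functions $r = r_{\max}[g-\theta]_+^2/(h^2 + [g-\theta]_+^2)$ fitted to the
  spiking neurons;
* a **fast–slow stability analysis**: with the plasticity variables frozen as
  bifurcation parameters, Newton–Raphson equilibrium finding plus eigenvalue
  classification tracks how attractors are created and destroyed along a
  trial;
* the derived measures: PCA state-space projection, dummy-variable
  regression **selectivity time courses**, transition-time detection, batch
  statistics, and reproducible experiment protocols and parameter sweeps.

## A worked example

```r
library(stpnet)

cfg <- network_config("all_types")       # 200 neurons per population
eqs <- find_equilibria(config = cfg)     # attractors with plasticity at rest
eqs
#> stp_equilibria: 5 equilibria ( 3 stable )
```

The three stable equilibria are the resting state and the two goal states
(A&B active and C&D active, each at about 14 Hz) — the network starts out
able to discriminate goals but knows nothing of actions.

```r
b <- run_batch(cfg, n_trials = 8, seed = 1, goals = rep("G1", 8))
b$results[, c("goal", "action", "entry_ms", "transition_ms", "dwell_ms")]
#>   goal action entry_ms transition_ms dwell_ms
#> 1   G1     A1      574          1309      735
#> 2   G1     A2      584          1311      727
#> 3   G1     A1      577          1242      665
#> 4   G1     A1      577          1014      437
#> 5   G1     A2      730          1242      512
#> 6   G1     A2      569          1529      960
#> 7   G1     A2      576           807      231
#> 8   G1     A1      584          1361      777
median(b$results$dwell_ms) / 1000
#> [1] 0.696
```

Each trial ignites the cued goal assembly shortly after the display
(`entry_ms`: entry into the goal state, first principal component dominant),
dwells there for roughly a second, and then switches endogenously to one of
the two actions (`transition_ms`: second component dominant, sustained) —
well before the nominal Go cue at 3 s.  A balanced batch realizes all four
goal-by-action patterns.  `selectivity_timecourse(b)` turns such a batch
into normalized goal- and action-selectivity curves, and
`meanfield_stability_run(cfg)` reproduces the whole story deterministically:
three attractors before the display, destruction of the goal attractors and
emergence of two action attractors mid-delay.

A thin command-line interface over the same functions ships at
`inst/cli/stpnet` (subcommands `run`, `sweep`, `stability`, `fitrate`,
`analyze`), and the canonical parameter files for the three network variants
are under `inst/extdata/`.

## Layout

```
R/               configuration, network construction, spiking wrapper,
                 mean field, stability, analysis, experiments
src/             compiled spiking core (Rcpp)
inst/extdata/    canonical YAML parameter sets (three variants)
inst/cli/        command-line entry point
vignettes/       methods vignette: models, calibration, design choices
tests/testthat/  unit, property and acceptance suites (scalar event-driven
                 reference simulator included as an oracle)
scripts/         acceptance script
```
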