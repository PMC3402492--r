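# latchnet

Simulations of semantic priming with a two-layer latching attractor
network.

`latchnet` implements a lexical–semantic model of word recognition in
which a **lexical** attractor network (word forms) and a **semantic**
attractor network (concepts) are reciprocally coupled. Both layers store
sparse binary patterns with a Hopfield-style covariance rule; semantic
patterns are organized into neighborhoods of correlated concepts.
Short-term synaptic depression (Tsodyks–Markram dynamics) destabilizes
semantic attractors, so after a word ignites its concept the semantic
layer *latches*: it hops spontaneously from one concept to correlated
neighbors. Because latching preferentially visits related concepts,
top-down feedback to the lexical layer speeds recognition of related
target words — semantic priming.

Two conditions are built in:

- `"control"` — baseline utilization of synaptic resources;
- `"schizophrenic"` — utilization elevated by ~25 %, which accelerates
  depression, shortens attractor dwell times, and speeds the latching
  chain. This reproduces the qualitative clinical pattern: indirect
  (mediated) hyper-priming at short SOA and direct hypo-priming at long
  SOA, with faster spreading of the semantic activation wave.

## Quick start

```r
library(latchnet)

# one trial: prime word 1 for 100 ms, target word 2 at a 200 ms SOA
m    <- build_coupled_model("control", seed = 1)
spec <- trial_spec("related", soa = 200, prime = 1, target = 2, seed = 7)
rec  <- run_trial(m, spec)
rec$rt             # lexical recognition latency from target onset (ms)
rec$n_transitions  # semantic attractor transitions before recognition

# the two standard experiments (short / long SOA), reduced scale
models <- list(control       = build_coupled_model("control", seed = 1),
               schizophrenic = build_coupled_model("schizophrenic", seed = 1))
s1 <- simulate_sim1(trials_per_cell = 25, base_seed = 1000, models = models)
priming_effects(s1)          # direct / indirect priming per condition
transition_histogram(s1)     # latching statistics

# spreading-activation wave (trial-averaged correlation with probe concepts)
spreading_wave(models$control, n_trials = 20, base_seed = 1)
```

Config-driven runs:

```r
cfg <- make_config(condition = "schizophrenic", soa = 950,
                   trials_per_cell = 50)
save_config(cfg, "run.yaml")
trials <- run_config(load_config("run.yaml"))
```

## Package layout

| Module | Contents |
|---|---|
| `R/patterns.R` | relation graph, correlated semantic / disjoint lexical pattern generation, covariance weights |
| `R/dynamics.R` | transfer function, rate-equation reference stepper, gating, OU noise |
| `R/depression.R` | synaptic resource dynamics, plateau closed form, effective weights |
| `R/model.R` | coupled two-layer model, inter-layer projections |
| `R/trial.R` | trial protocol, sessions, the two experiment designs, transition counting |
| `R/analysis.R` | priming effects, transition histograms, spreading wave |
| `R/config.R` | YAML configs, fixtures |
| `src/sim.cpp` | compiled trial kernel (the R stepper is the cross-validation reference) |

`scripts/acceptance.R` reproduces the headline statistics as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results.json
```

The methods vignette (`vignettes/methods.Rmd`) documents the model
equations, parameter table, protocol, and the package's own modelling
decisions (regulation set points, transition-counting rule), along with
known quantitative deviations of the reduced-scale results.

## Tests

```r
testthat::test_dir("tests/testthat", package = "latchnet",
                   load_package = "installed")
```

`tests/testthat/test-acceptance.R` holds the acceptance criteria
(priming magnitudes, RT range, and a property suite) at the reduced
100-trials-per-cell scale.
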