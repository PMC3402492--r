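---
title: "Model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`latchnet` simulates semantic priming with two reciprocally coupled
attractor networks: a **lexical** layer storing word-form patterns and a
**semantic** layer storing concept patterns. This vignette documents the
mathematical model, the simulation protocol, and the modelling decisions
that are specific to this implementation.

## Stored patterns

Each layer stores 17 sparse binary patterns over `N = 500` rate neurons
(sparseness `p = 0.06` semantic, `p = 0.04` lexical; 30 and 20 active
neurons per pattern). Lexical patterns are mutually disjoint. Semantic
patterns are organized by a *relation graph* into four neighborhoods of
four concepts each, plus an unconnected *baseline* pattern (index 17)
used as the resting state:

- strongly related pairs share 3 active neurons (within-neighborhood
  pairs such as 1–2, and four cross-neighborhood links);
- typically related pairs share 2;
- all other pairs share 0.

`make_semantic_patterns()` realizes these overlaps exactly by
constructing shared neuron pools; `validate_pattern_set()` asserts the
active counts and every pairwise overlap. The graph also declares the
canonical prime–target pair lists used by the experiments: Type-I direct
pairs (strong, within-neighborhood), Type-II direct pairs (strong,
cross-neighborhood), mediated indirect pairs (e.g. 1 → 11 via 2), and
unrelated pairs (different, unlinked neighborhoods).

Connectivity within a layer follows the covariance rule with zero
diagonal,

$$J_{ij} = \frac{1}{N p (1-p)} \sum_{\mu} (\xi_i^\mu - p)(\xi_j^\mu - p),$$

so overlapping patterns are correlated attractors.

## Rate dynamics

Each neuron carries a local field $h_i$ with activity
$x_i = 1/(1+e^{-h_i/T})$ and evolves by Euler integration
(`dt = 0.66` ms):

$$\tau_n \dot h_i = -h_i + \sum_j J_{ij} r_j x_j
  - \lambda\left(\langle x\rangle - c\,p\right) - \theta
  + \left[I^{\mathrm{ext}}_i - \theta_{\mathrm{ext}}\right]_+ + \eta_i .$$

- $r_j$ is the depression variable (below); the recurrent drive is the
  weight matrix acting on the resource-scaled activity.
- The regulation term holds mean activity near a set point $c\,p$; see
  the next section for the choice of $c$.
- External drive (inter-layer plus stimulus input) is summed first and
  then gated through a rectified threshold $\theta_{\mathrm{ext}}$ —
  gating is applied jointly to the summed drive, not per source, because
  the top-down gain alone (0.21) is below the lexical gate (0.25):
  separate gating would silence feedback entirely.
- $\eta_i$ is Ornstein–Uhlenbeck noise with stationary standard
  deviation `eta_amp` and correlation time `tau_corr`.

Short-term depression follows resource dynamics

$$\dot r_j = \frac{1 - r_j}{\tau_r} - U\, x_{\max}\, x_j\, r_j,$$

with plateau $r^\ast = 1/(1 + U x_{\max} \tau_r)$ under sustained
activity (asserted to 1 % in the tests). Depression acts on semantic
recurrent synapses and on the lexical→semantic projection; lexical
recurrent and top-down synapses do not depress (`U = 0`).

### Parameter table

| parameter | semantic | lexical |
|---|---|---|
| `N`, `p` | 500, 0.06 | 500, 0.04 |
| `T`, `tau_n` (ms) | 0.05, 7 | 0.05, 13 |
| `theta`, `lambda` | 0.02, 14.75 | 0.17, 27.75 |
| `U` (control / schizophrenic) | 0.206 / 0.2615 | 0 |
| `tau_r` (ms), `x_max` (Hz) | 93, 100 | — |
| `theta_ext`, `eta_amp`, `tau_corr` (ms) | 1, 0.05, 17 | 0.25, 0.025, 17 |

Coupling: bottom-up gain 2 with depression `U_ls` 0.087 / 0.1104 and
`tau_r_ls = 1333` ms; top-down gain 0.21 (no depression); stimulus gain
0.56. Projections connect each word to its concept's active neurons,
normalized by the presynaptic active count; the baseline patterns have
no inter-layer connections. The *schizophrenic* condition differs from
control **only** in the two utilizations (`U`, `U_ls`), elevated ~25 %.

### Regulation set point (implementation decision)

The mean-activity regulation $-\lambda(\langle x\rangle - c\,p)$ needs a
set point below the single-pattern mean activity $p$, otherwise there is
no standing inhibition and mixture states of overlapping semantic
patterns become stable. This implementation uses a **per-layer**
fraction `reg_frac` ($c$ above):

- semantic: `c = 0.55`. The resulting standing inhibition suppresses
  two-pattern mixtures of strongly related concepts while keeping every
  stored pattern a stable fixed point (asserted in the tests) and
  producing the intended latching statistics.
- lexical: `c = 1` (no standing inhibition at baseline). Word patterns
  are disjoint, so there is no mixture risk, and any appreciable
  standing inhibition would block ignition by the gated stimulus drive
  (0.56 − 0.25 = 0.31).

The value `c = 0.55` was calibrated against the attractor-stability and
transition-statistics targets (control long-SOA transition mode 2–3,
schizophrenic mode far higher), not against the priming effects.

## Trial protocol

A trial starts with both layers clamped to their baseline patterns for a
50 ms burn-in. The prime word then drives the lexical layer for 100 ms;
after a blank gap the target word is presented at the SOA (200 ms short,
950 ms long) until the lexical layer converges on it. Convergence means
correlation ≥ 0.95 with one stored pattern and < 0.5 with all others,
checked every step; RT is the time from target onset to lexical
convergence on the target. Trials that do not converge within the
timeout are flagged and excluded from RT means but counted.

Semantic convergence events are logged with the same criterion, giving
the latching itinerary. `count_transitions()` turns it into a
transition count by dropping the leading baseline events and — when it
occurs at or after target onset — the final convergence onto the
target's own concept, which is the stimulus-driven recognition response
rather than a spontaneous transition (the semantic layer reliably
reaches the target concept a few milliseconds before the lexical layer
converges). A spontaneous jump onto the target *before* its onset does
count.

## Experiments and analysis

- `simulate_sim1()`: short SOA; related, indirect and unrelated pairs ×
  five Type-I prime ratios {0, .25, .5, .75, 1} × both conditions.
- `simulate_sim2()`: long SOA; related and unrelated pairs only.

Priming is `mean(unrelated RT) − mean(related RT)` within matched
condition × ratio cells (`priming_effects()`). `transition_histogram()`
summarizes latching; `spreading_wave()` measures the trial-averaged
correlation of the semantic state with probe concepts at increasing
semantic distance from the prime at fixed probe times.

Every trial derives its RNG stream from `base_seed + trial counter`, so
sessions are exactly reproducible; Type-I/Type-II allocation within a
cell is deterministic in the ratio.

## Calibration status and known deviations

At the reduced acceptance scale (100 trials/cell) the implementation
reproduces the qualitative phenomena robustly:

- control short-SOA trials mostly show zero semantic transitions while
  the schizophrenic network latches within the same window;
- schizophrenic ≫ control transition counts at both SOAs, control
  long-SOA mode at 2–3;
- indirect hyper-priming (schizophrenic > control, short SOA) and direct
  hypo-priming (control > schizophrenic, long SOA), both strict;
- direct priming exceeds indirect priming in every cell;
- the spreading-activation wave is broader for the schizophrenic network
  at 150 and 200 ms;
- priming vanishes when the top-down gain is set to 0 (feedback is the
  mechanism).

Quantitatively, this calibration undershoots the reference magnitudes
encoded in the acceptance suite (e.g. short-SOA direct priming ≈ 23 ms
control / 15 ms schizophrenic against reference values near 34 / 36 ms;
the schizophrenic long-SOA transition mode saturates at 6 rather than
7–8, and the schizophrenic-minus-control direct-priming difference rises
with the Type-I ratio but does not change sign). The gap traces to the
first latching hop: after an attractor collapses, the noise-driven
search from the near-empty state is only mildly biased toward the
prime's strong neighbor, whereas the larger reference effects require
strongly biased first transitions. The corresponding acceptance tests
encode the reference values unchanged and fail honestly rather than
being relaxed to the observed values.
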