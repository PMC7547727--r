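---
title: "Language models of discretized molecular trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Language models of discretized molecular trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`trajlm` treats a one-dimensional order-parameter time series
$\{\xi^{(t)}\}$ from a molecular system — the $x$-coordinate of a Langevin
trajectory, a torsion projection, a force-spectroscopy extension — as text.
The series is spatially discretized into $N$ "characters" (equal-width bins
with midpoint representative values), and a character-level recurrent
language model is fitted to the character stream:

1. **Embedding.** The one-hot character $s^{(t)} \in \{0,1\}^N$ is mapped to
   a dense vector $x^{(t)} = \Lambda s^{(t)} \in \mathbb{R}^M$.
2. **LSTM.** A single LSTM layer of $L$ units with the standard gate
   equations: input, forget and output gates through logistic sigmoids, a
   tanh candidate, cell update $c^{(t)} = f \circ c^{(t-1)} + i \circ
   \tilde c$, output $h^{(t)} = o \circ \tanh c^{(t)}$.
3. **Softmax readout.** $\hat y^{(t)} = \mathrm{softmax}(D h^{(t)} + b_d)$,
   the predicted distribution of the *next* character.

Training minimizes the teacher-forced cross-entropy
$J = -\sum_t s^{(t+1)} \cdot \ln \hat y^{(t)}$ (nats). Because the summed
cross-entropy over a long trajectory estimates the cross-entropy between the
true and modelled *path* distributions, its minimum is the path entropy of
the source, attained exactly when the learned conditional law equals the
true one. This is the operational contract of the package: the per-symbol
loss of a well-trained model should converge to the entropy rate of the
generating process, and sampling the learned conditionals should regenerate
both the stationary (Boltzmann) statistics and the transition kinetics of
the input. Both statements are tested against exact Markov-chain references
(`entropy_rate()`, `mfpt_commute()`) and against Langevin simulations.

A fitted model is generative: `sample_trajectory()` draws the next character
from $\hat y$ at temperature 1 and feeds it back, producing arbitrarily long
synthetic label series which are analyzed exactly like real ones.

# Parameters that matter

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `n_labels` (N) | 32 | alphabet size for model potentials. Published analyses of comparable systems used 20 (peptide torsions) and 34 (experimental extension traces); 32 resolves the three- and four-well landscapes well. |
| `embed_dim` (M) | 8 | embedding dimension for model potentials; 128 for biomolecular-scale data. |
| `hidden_dim` (L) | 64 | LSTM units for model potentials; 1024 for biomolecular-scale data. |
| `seq_len` | 100 | teacher-forcing window; hidden state resets to zero at each window start. |
| `batch_size` | 64 | windows per gradient step. |
| `epochs` | 20 | passes over the training windows. |
| `learning_rate` | 1e-3 | Adam step size. |
| `beta` | 9.5 / 9.0 | inverse temperature of the Langevin runs (9.0 for the triangular system). |
| `dt` | 0.01 | Langevin timestep. |
| `save_stride` | 10 | sampling stride of saved frames; one "sample" of the character stream is 10 integration steps. |

# Numerical and design choices

Where the underlying description is silent, the package makes these choices
(they are deliberate and documented rather than tuned):

* **Integrator.** Overdamped (Brownian) Euler–Maruyama with unit friction
  and unit mass: $x \leftarrow x - \nabla U\,dt + \sqrt{2dt/\beta}\,\eta$.
  Only $dt$ and $\beta$ are stated for the reference simulations; the
  overdamped integrator has the correct Boltzmann stationary law and no
  additional free parameter. Its $O(dt)$ bias is visible in the harmonic
  test (stationary variance $(1/\beta)/(1 - dt/2)$), well inside the
  tolerances used.
* **Trajectory length.** 5×10^6 steps at stride 10 (5×10^5 samples) by
  default: thousands of well-to-well transitions at desk scale.
  The default start is the deepest well center.
* **Binning.** Bins are fitted to `[min, max]` of the series, half-open with
  a closed last bin; out-of-range values clamp to the end bins so encoding
  is total on new data. Representative values are bin midpoints, so the
  decode error is at most half a bin width.
* **Optimizer.** Adam with learning rate 1e-3 by default; plain SGD is
  available (`optimizer = "sgd"`). Only "stochastic gradient descent" is
  stated for the reference results; at desk scale Adam reaches the entropy
  floor far faster, and the learned distribution — not the optimizer — is
  the contract. Gradients are clipped at global norm 5, the standard guard
  for recurrent nets. Softmax uses max-subtraction; the loss is computed by
  log-sum-exp, never as `log(softmax(...))`.
* **Windows.** Non-overlapping, reshuffled each epoch with the run seed;
  hidden state resets at window starts, which makes training
  order-independent and reproducible. Validation is the final 10% of the
  series, contiguous and unshuffled, to respect temporal structure.
* **Sampling.** Temperature fixed at 1 — the Boltzmann and kinetics claims
  are about the learned conditional law, so sampling must be unbiased. The
  default seed context is a stored training window; 1000 burn-in symbols are
  discarded to remove initial-state transients.
* **State assignment.** A label belongs to a state when its representative
  value lies within `radius` of the state's projected minimum (ties to the
  nearer minimum, exact ties to the lower id). Barrier labels stay
  unassigned and are *skipped* in kinetics: runs of consecutive identical
  states are formed after dropping unassigned samples, a run is committed
  when it is at least `commit_time` samples long, and transitions are
  counted between consecutive committed runs with different states.
  Whether brief uncommitted excursions should instead break committed runs
  is not determined by the source description; the run-length rule used here
  is oracle-tested against hand enumeration. One non-obvious consequence:
  as the commit time grows, a decommitting intermediate state *reroutes*
  its flanking transitions (A→B→C becomes A→C), so an individual pair's
  count can increase with commit time — only the total transition count is
  guaranteed non-increasing.
* **Commit-time grid.** 1–200 samples in steps of 1, spanning the decay
  region of the transition-count curves at the default stride.
* **Embedding kinetic distance.** The transition-probability ansatz
  $Q_{lm} = \exp(x_m \cdot x_l)/\sum_k \exp(x_k \cdot x_l)$ is defined per
  *label*, while kinetic states span several labels. By default each state
  is represented by its most-occupied label ("modal" aggregation), with
  $Q_l$ the model-generated occupancy of that label;
  occupancy-weighted aggregation over all in-state labels is available
  (`aggregation = "weighted"`). The interconversion rate is
  $k_{lm} = Q_l Q_{lm} + Q_m Q_{ml}$ and the kinetic time $t_{lm} = 1/k_{lm}$,
  compared against the counted commute time $\tau_{lm} = T/\langle N_{lm}
  \rangle$ with $N_{lm}$ summed over both directions and averaged over the
  commit-time grid. For cross-system comparisons both are min-max rescaled
  to $[0,1]$; the three-state comparison pools the linear and triangular
  systems before rescaling, since rescaling each system separately would
  force every system to span the full unit interval and destroy the
  contrast the comparison is about.
* **Counted commute time denominator.** $T$ is the total number of samples
  in the analyzed series (assigned or not), matching the definition of the
  transition time as total observation time per transition.
* **Training-trial averaging.** For multi-well Langevin systems the
  stationary law of a *single* trained model is noticeably variable: escape
  probabilities out of deep wells are tiny, so sampling noise in the data
  and in training propagates into the generated occupancies. The reference
  analyses average segments "from different trials of training"; the
  package's own closure checks do the same, pooling generated segments from
  several training seeds so segment standard errors include across-trial
  variability. A single trial reproduces conditional rows and commit-curve
  shapes but can misplace stationary weights by several segment standard
  errors; this is a property of the data size, not a code defect.

# What the synthetic-data generator does and does not emulate

The built-in world is: three 2-D model potentials (linear 3-state,
triangular 3-state with well placements `(-2,0),(0,0),(2,0)` for the linear
system and an equilateral triangle `(-2,-2/sqrt(3)), (2,-2/sqrt(3)),
(0,4/sqrt(3))` for the triangular one — the published figures show the
layouts but not the coordinates, so these are package choices, configurable;
the equilateral placement is forced by the triangular system's defining
property that all three well pairs are equally distant in 2-D while
projecting onto the same three x-positions as the linear system — and the
4-state potential with printed centers), Gaussian width 0.8, confinement weight
1e-4, overdamped Langevin at β = 9.5/9.0, plus exact stationary first-order
Markov chains for oracle tests. A green pipeline test establishes that the
model reproduces Boltzmann weights, commit-time kinetics and embedding
distances *for these dynamics at these sizes*. It does not establish
anything about underdamped or thermostatted MD, multidimensional order
parameters, experimental noise, or the data-hungry biomolecular-scale
configuration (M = 128, L = 1024), which the code supports but the test
suite does not exercise.

# Known limitations

* Single-layer LSTM only; no dropout, stacking, or GPU-scale training.
* **Embedding-distance variance.** The label-level ansatz matrix is a good
  object — its rows correlate strongly with the maximum-likelihood
  transition rows of the training data — but the *state-pair* quantities
  $t_{lm}$ depend on exponentials of dot products between embeddings of
  distant states, which at desk-scale data (≤ 5×10^5 samples) and a handful
  of training seeds fluctuate over orders of magnitude. Per-seed orderings
  of $t_{lm}$ are therefore unstable in all three aggregation rules, and
  the cross-system patterns (linear A–C separation, triangular uniformity,
  4-state rank agreement with counted commute times) do not emerge reliably
  from 3-seed medians; published analyses of this kind averaged over ~50
  independently trained trajectories. Treat `kinetic_distance_table()`
  output as exploratory unless it is averaged over many trials.
* The commit-run counting rule and the label-to-state aggregation of the
  embedding distance are declared conventions (see above); alternatives
  exist and may differ in detail from other implementations.
* Slowest-transition estimates inherit the sampling quality of the input:
  when the input trajectory itself has barely one or two direct transitions
  across the highest barrier (the 4-state diagonal pairs), the model cannot
  repair that, and forward/backward asymmetries appear exactly as in the
  underlying data.
* Test-suite runs scale the stated world down (shorter trajectories, fewer
  trials) to fit continuous-integration budgets; the defaults encode the
  full-scale protocol.
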