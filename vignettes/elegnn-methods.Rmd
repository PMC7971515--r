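---
title: "Decoding behavior and forecasting neural dynamics with edge-inferring graph networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding behavior and forecasting neural dynamics with edge-inferring graph networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elegnn)
```

## The problem

Whole-brain calcium imaging in *C. elegans* records the activity of tens of
identified neurons at about 3 Hz while the worm executes its stereotyped
motor sequence (forward crawling, reversal, turn, forward again — the
"pirouette"). Two analysis tasks recur in this literature:

* **Behavioral-state decoding** — read the worm's current motor state from a
  single timestep of neural activity.
* **Trajectory forecasting** — predict each neuron's activity a few seconds
  ahead.

Both tasks are complicated by *individual variability*: although every
worm's dynamics live on a similar low-dimensional cyclic manifold, the
mapping from that manifold to identified neurons differs between
individuals, so a decoder fit to one worm's neurons often fails on the next
worm. `elegnn` implements two models that address this and the protocols to
measure cross-individual generalization.

## The models

A recording is a temporal graph: nodes are neurons, the node features at
time $t$ are $x_{n,t} \in \mathbb{R}^2$ (normalized trace and derivative),
and the behavioral state is a graph-level feature. Both models are
universal approximators $f$ plugged into two heads:

* classification: $H_t = f(X_t)$, $p_t = \mathrm{softmax}(H_t)$,
  $\hat a_t = \arg\max p_t$;
* Markovian prediction: $\hat X_{t+1} = X_t + f(X_t)$, i.e. $f$ predicts the
  residual change $\Delta \hat X_t$; multi-step forecasts feed each
  prediction back as the next input.

**MLP (structure-agnostic baseline).** Node features are aggregated —
concatenated by default, summed optionally — and passed through a 2-layer
perceptron $g_\mathrm{graph}$.

**Edge-inferring GNN.** A per-node perceptron $g_\mathrm{node}$ embeds each
node's features ($V = g_\mathrm{node}(X)$); a perceptron $g_\mathrm{edge}$
scores every ordered pair via the concatenation $(v_i, v_j)$; a sigmoid maps
the scores to edge weights $A_{ij} \in (0,1)$, including self edges
($i = j$). Message passing is $M = AX$, followed by aggregation over nodes
and $g_\mathrm{graph}$. The ordered pair makes $A$ directed; no symmetry is
imposed. $A$ is an *inferred, functional* connectivity — a user-supplied
anatomical adjacency (e.g. connectome synapse counts, max-normalized to
$[0,1]$) can replace it (`edge_mode = "provided"`).

Edges come in two temporal flavors. In **dynamic** mode $A$ is re-inferred
at every timestep from that timestep's features. In **static** mode node
embeddings are averaged over all timesteps of the recording, giving one
adjacency per individual; on an unseen individual this average is computed
from its own recording, without labels — the edge encoder thereby *adapts*
to a new individual's mixing of the shared dynamics.

## Preprocessing and training protocol

* Each neuron's trace and derivative are mapped to $[0,1]$ over the **full
  recording**, never per window — relative magnitude carries graded
  behavioral information (e.g. crawl speed).
* Derivatives are central finite differences (one-sided at the ends) over
  `dt`; if a recording ships derivative columns, those are used instead. A
  regularized differentiator would also do; the $[0,1]$ normalization
  absorbs the scale, so the simple scheme suffices.
* Recordings are cut into non-overlapping 8-timestep windows (about 3 s, the
  time scale of a behavioral change); the trailing remainder is dropped so
  every window is fully observed. Windows are shuffled and dealt into 10
  folds for seen-population cross-validation. Plain shuffling is used; the
  folds are "representative" in expectation, and stratification by state is
  left as an option rather than a default.
* **Dataset enlargement**: with several training individuals, each epoch
  visits them one at a time and optimizes that individual's minibatches
  only. Feature-normalization layers (after the first linear layer of
  $g_\mathrm{node}$ and $g_\mathrm{graph}$) therefore always see
  single-individual statistics. At evaluation the statistics are recomputed
  from the evaluated recording itself — this per-individual renormalization
  is what lets a fixed network run on an individual it never saw.
* One optimization update draws 8 shuffled windows (64 timesteps).
  Timesteps are classified independently; mixing windows matters because a
  single 8-step window usually lies inside one behavioral state, and
  normalizing within one state would cancel exactly the between-state
  signal the classifier needs.
* Trajectory models minimize the MSE of multi-step rollouts inside each
  window, with **scheduled sampling**: at each step the fed-back input is
  the ground truth with probability $p$ and the model's own prediction
  otherwise, with $p$ decaying linearly from 1 at the first epoch to 0 at
  the last. Gradients are not propagated through fed-back predictions, as in
  the original scheduled-sampling curriculum. In static mode the per-update
  adjacency is computed from the minibatch's true timesteps (a stochastic
  approximation of the recording mean), so the edge encoder still receives
  gradients.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| hidden width | 64 | smallest round size that overfits one synthetic individual quickly on a CPU |
| node embedding | 16 | ample for 2-channel inputs |
| nonlinearity | ReLU | standard; no saturation issues with $[0,1]$ inputs |
| aggregation | concat | outperforms summation in our experiments; sum remains available |
| message steps | 1 | additional steps brought no improvement |
| optimizer | Adam, lr $10^{-3}$ | robust first-order default |
| epochs | 200 | enough to overfit a single individual; experiments below use fewer |
| edge mode | dynamic (classify), static (predict) | per-timestep decoding vs one functional graph per individual |

Argmax ties break toward the lowest state code, and every stochastic
ingredient (initialization, window shuffling, fold assignment,
scheduled-sampling coins) is driven by a single mandatory seed, so a fit is
bit-reproducible. Individuals are visited in their input order each epoch
(an option shuffles the order). A non-finite loss aborts training with a
diagnostic instead of continuing silently.

## The synthetic population

Real multi-worm recordings cannot ship with the package, so
`generate_population()` emulates their statistical structure:

* a **shared cyclic latent process**: a phase variable moves around a loop
  divided into contiguous arcs, one per behavioral state, visited in a fixed
  cyclic order (the pirouette sequence). Angular speed is state-dependent
  (arc length / mean dwell time — long forward runs, shorter reversals,
  brief turns) with lognormal fluctuations, so the phase never steps
  backwards and label transitions respect the cycle;
* **individual readouts**: traces are
  $\mathrm{smooth}(\mathrm{softplus}(R_\alpha z + b_\alpha)) + \varepsilon$
  with an individual-specific random $R_\alpha$ — individuals share
  dynamics and label statistics but mix them into neurons differently. The
  softplus keeps traces fluorescence-like (nonnegative, graded); smoothing
  is a first-order exponential kernel with a 1 s time constant, a crude
  calcium-indicator proxy;
* defaults: 15 neurons, 3200 timesteps at 1/3 s, 4 states, latent dimension
  3, observation noise sd 0.05.

The generator reproduces the dissociation the cross-individual claims rest
on: a linear decoder trained on one individual's *neurons* transfers poorly
to an individual with an independent readout, while a decoder on the shared
*latent* transfers well (see the test suite). It does **not** model
biophysical indicator kinetics, bleaching, real noise spectra, or
behavioral idiosyncrasies, so passing tests here show that the pipeline
recovers structure of this kind — not that any accuracy level carries over
to real worms.

For edge-level ground truth, `generate_coupled_system()` simulates
$X_{t+1} = X_t + \epsilon\,\tanh(W X_t) + \eta$ with a sparse directed $W$
(10% of off-diagonal pairs, $\epsilon = 0.1$, spectral radius of
$\epsilon W$ capped at 0.9), or the linear map $X_{t+1} = (I+\epsilon W)X_t$
with $W$ antisymmetrized into a lightly damped rotation — a decaying linear
system flattens out within a few hundred steps and carries no information
about its own map, whereas the rotational system keeps oscillating through
the whole recording. The retained $W$ scores edge recovery of the inferred
$A$ by ranking AUROC over off-diagonal pairs.

## Evaluation protocols

* **Seen population**: 10-fold cross-validation over shuffled windows; a
  fresh model per fold (no warm starts); accuracy averaged over folds with
  the spread reported as a standard deviation (the choice of sd over se is
  configurable — the convention is not fixed in this literature).
* **Unseen population**: the classifier runs separately on every timestep;
  per-individual accuracies are averaged with equal weight per individual
  regardless of recording length. Confusion matrices are row percentages of
  predicted against labeled states. A 7-state model is scored against
  4-state labels through an explicit overridable mapping (both forward
  states to forward, all three reversal states to reverse, turns kept);
  whether "forward slowing" belongs with forward cannot be settled from the
  sources, so the default is a config choice.
* **Trajectory**: evaluation windows start every `horizon` timesteps; the
  model receives the window's first timestep and predicts `horizon` steps
  (so a window spans `horizon + 1` timesteps and the reported MSE vector
  has length `horizon`, conventionally 16). The persistence baseline
  $\hat X_{t+s} = X_t$ over identical windows is the comparator a learned
  model must beat at step 1.

## Numerical choices and degenerate inputs

* Constant trace columns normalize to zero rather than NaN.
* Feature-normalization layers use variance $+10^{-5}$ under the square
  root; a single-row batch normalizes to zero (the layer's bias passes
  through).
* Softmax subtracts the row maximum before exponentiation; probabilities
  are clamped at $10^{-12}$ inside the cross-entropy.
* The edge encoder is bypassed (with an error on misuse) in provided mode.
* `windows_per_update` groups are formed after seeded shuffling; the last
  group of an epoch may be smaller.

## Problem sizes used in the shipped experiments

The packaged tests and the acceptance script run the full protocols at
reduced scale so the whole suite completes on one CPU in minutes: synthetic
recordings of 800–2000 timesteps instead of 3200, 5–10 master seeds per
stochastic comparison, classifiers trained 20 epochs and trajectory models
100 epochs (lr 5e-4) at these sizes, the overfit check at the 200-epoch
default. The suite asserts the qualitative structure: both models beat
4-state chance on unseen individuals, the static-edge GNN matches or
exceeds the MLP on average, training on three individuals is no worse than
one for both accuracy and 1-step error, and trajectory error grows with
horizon after smoothing. Two checks probe the limits of the approach and
are expected to sit at or beyond them on this generator — see the
limitations below.

## Known limitations

* No MAT-file reader: source-study archives must be converted to the CSV
  trace-table dialect first (`write_trace_table()` documents it).
* No recurrent (hidden-state) models: the predictor is strictly Markovian.
* No variational treatment of the inferred adjacency; $A$ is a
  deterministic function of the activity.
* Static-mode adjacencies on very short recordings (a few timesteps) are
  poorly averaged; dynamic mode is preferable there.
* **One-step error against persistence is at parity on this generator.**
  With observation noise sd 0.05, the persistence baseline's one-step error
  is dominated by twice the noise variance plus a tiny 1/3-second drift;
  beating it requires denoising the initial condition, and the denoising
  projection is individual-specific (it lives in the readout). A
  within-individual ridge fit beats persistence three-fold, so the data are
  predictable — the bottleneck is cross-individual transfer of the
  Markovian architecture, whose only individual-adaptive channels are the
  normalization statistics and the static adjacency. Across training sizes
  (1–5 individuals), lengths (15–200 epochs) and learning rates, unseen
  step-1 MSE lands at 0.98–1.07 times persistence. The suite asserts the
  strict inequality and documents that it is not reliably attained.
* **Inferred edges are functional, not structural, and their limits are
  sharp.** In static mode each node embedding is a time-average of that
  node's own feature embeddings, so an edge score is a function of the two
  units' *marginal* activity statistics — the joint (correlational)
  evidence that actually identifies a coupling never reaches the edge
  encoder, and the concatenation read-out can model couplings internally.
  On coupled systems with known ground truth the learned $A$ develops
  informative *column* structure (it down-weights driven, high-in-degree
  units as message sources) but does not rank true directed pairs above
  absent ones (AUROC near 0.5). Only rankings of inferred weights are ever
  interpretable, and pairwise recovery should not be expected from this
  architecture; a pairwise (trajectory-pair) edge encoder would be the
  remedy, at the cost of departing from the model equations implemented
  here.
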