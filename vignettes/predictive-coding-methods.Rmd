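---
title: "Predictive coding networks: model, conventions, and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictive coding networks: model, conventions, and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcnet)
```

## The model

A predictive coding network is a strictly sequential chain of layers
$f_1, \dots, f_L$ in which every layer carries two node populations: an
*activation* node $v_i$ and an *error* node $e_i$. The layer's *prediction* of
its own activity is $\hat v_i = f_i(v_{i-1}; \theta_i)$, and the error node
holds

$$ e_i = \hat v_i - v_i . $$

Learning minimizes the **variational free energy**, implemented here as

$$ F = \frac{1}{2n}\sum_{i=1}^{L} \lVert e_i \rVert^2 $$

for a minibatch of size $n$. Two relaxations drive everything:

* **Inference** (the backward phase) performs gradient descent on $F$ with
  respect to the hidden activations,
  $v_i \leftarrow v_i + \eta_v\,(e_i - J_{i+1}^\top e_{i+1})$, where
  $J_{i+1} = \partial \hat v_{i+1} / \partial v_i$. The input is always
  clamped; for the squared-error objective the output activation is clamped
  to the target, and for every other objective the output error node is set
  directly to the objective's gradient with respect to the prediction.
* **Learning** applies the local rule
  $\Delta\theta_i = -\eta_\theta\, e_i\, \partial f_i(v_{i-1};\theta_i)/\partial\theta_i$,
  which reads only the layer's own error node and its presynaptic input —
  no non-adjacent quantity is touched. The locality is asserted in the test
  suite by perturbing all other layers' error nodes and observing an
  unchanged gradient.

Under the **fixed prediction assumption** — predictions and Jacobians frozen
at their feedforward values during inference — the error nodes converge to
exactly the chain-rule deltas, so the equilibrium weight update equals the
backpropagation gradient of the same objective. The package exploits this in
both directions: `bp_gradient()` is the exact oracle against which
`pc_gradient()` is verified (relative error below $10^{-6}$ on random
networks for both squared-error and cross-entropy couplings), and
`bp_gradient()` itself is verified against central finite differences.

## Conventions and numerical choices

Several choices are deliberate and worth stating plainly:

* **The 1/2 energy convention.** The free energy is written with a factor
  $\tfrac12$ so that equilibrium updates match gradients of the standard
  half-squared-error loss without a factor-of-two mismatch. A formulation
  without the $\tfrac12$ only rescales $\eta_\theta$.
* **Error sign.** $e$ = prediction − actual, everywhere. All objective
  couplings are sign-aligned so that the squared-error coupling reproduces
  output clamping exactly.
* **Inference update.** The activation increment is
  $e_i - J_{i+1}^\top e_{i+1}$, the exact negative gradient of $F$ under the
  1/2 convention (a version without the child-error factor is not a descent
  direction on $F$).
* **Inference schedule.** Default $\eta_v = 0.1$ with a fixed budget of 20
  iterations and an optional tolerance-based early stop; a divergence guard
  aborts with a diagnostic naming $\eta_v$ and the iteration. The inference
  rate is a free parameter of the method; 0.1 is a stable default for
  fan-in-scaled initializations. With predictions re-evaluated each step
  (fixed predictions off), descent of $F$ is exactly monotone for small
  steps; at $\eta_v = 0.1$ a step can occasionally cross a ReLU kink and
  produce a rise of order $10^{-4}$ on roughly 1% of random instances, so
  the monotone-descent demonstrations in the acceptance material run at
  $\eta_v = 0.05$.
* **ReLU derivative at 0 is 0.** Dropout masks are drawn once per minibatch
  in the forward phase and frozen through all inference iterations (inverted
  dropout scaling). Batch statistics are likewise computed in the forward
  phase and reused during inference, so the loop is deterministic given the
  forward pass.
* **Batch normalization gradients** follow the full batch-norm backward
  (through the batch mean and variance). This is still layer-local and is
  required for the finite-difference oracle to agree; treating the statistics
  as constants leaves order-one relative errors. At evaluation time batch
  statistics of a fixed-size chunk are used (no running averages), which
  keeps evaluation deterministic; bank embeddings are computed after a fixed
  shuffle so that chunk composition is not correlated with class identity.
* **Two readings of the presynaptic factor.** `weight_gradient()` defaults to
  the frozen feedforward presynaptic activations (the form under which the
  fixed-prediction equilibrium equals backpropagation exactly);
  `use_relaxed = TRUE` evaluates it at the relaxed activations instead — the
  Hebbian reading of the update rule, which differs from backpropagation by
  an error-correlation term. Both were measured in the incremental suite and
  neither changes the ordering of the algorithm comparison there.
* **Composite layers.** A convolution block (convolution, optional batch
  norm, ReLU, max pooling) is a single predictive coding layer with one
  error node at its pooled output — the block-unit rule for architectures
  whose natural unit is larger than one affine map.
* **Rounding.** Reported accuracies round half away from zero to two
  decimals (`round_half_up()`); base R's round-half-even would print 86.395
  as 86.39. Published tables of this kind are not always internally
  consistent about this; one convention is used here throughout.

## The synthetic data generator

All pipelines run end-to-end on synthetic image classification data:
class templates are smooth low-frequency random fields (seeded white noise on
a coarse grid, bilinearly upsampled, unit RMS, minimum pairwise separation
enforced), and samples are templates plus additive Gaussian noise. The
generator is bit-reproducible under its seed, exposes per-class counts
directly (so long-tailed profiles are exact by construction), and ships a
nearest-template oracle (`difficulty_report()`) used once to calibrate noise
levels to a target difficulty.

What the generator emulates: multi-class image-like inputs with controllable
class count, per-class counts, and difficulty; a large bank of low-shot
character-like classes for episodic sampling. What it does not emulate:
feature sharing between classes (digit strokes, object parts), heavy-tailed
pixel statistics, or any spatial composition beyond smoothness. Passing tests
therefore demonstrate that the algorithms and pipelines are implemented
correctly and behave as documented under controlled conditions — not that
effect sizes measured here transfer to natural-image benchmarks. One place
this matters is noted below.

Study conditions fixed once for the synthetic suites:

* **Incremental suite:** 10 classes of 8×8 images, noise σ = 4 (calibrated
  with the oracle to ≈ 90% two-class accuracy, the single-task difficulty of
  the split scheme), 200 training and 50 test items per class, a 3-layer MLP
  with 100 hidden units, 10 epochs per task, batch 64. Weight learning rate
  0.1 for predictive coding and initial 0.05 for backpropagation, both under
  the reduce-on-plateau schedule (divide by 3 after 5 flat validation
  epochs, floor $10^{-4}$).
* **Long-tailed suite:** the same image world at σ = 1, head count
  $N_{max} = 200$, exponential profile
  $N_l = N_{max}\,\gamma^{-(l-1)/(L_c-1)}$ rounded to the nearest integer
  (minimum 1). The published protocol's rates (0.002 with weight decay
  $2\times10^{-4}$, batch 128, 100 epochs) remain the configuration defaults;
  the synthetic-scale checks use 30 epochs and a rate of 0.05 for predictive
  coding, since a rate tuned to a 60,000-sample benchmark undertrains a
  2,000-sample toy within the test budget.
* **Few-shot suite:** banks of 40 character classes × 20 variants of 16×16
  images at σ = 2 (σ = 3 for the training demonstrations, which leaves more
  headroom), the standard 4-block encoder (64 channels, batch norm, 2×2
  pooling) giving a 64-dimensional embedding, 15 queries per class, 1000
  evaluation episodes.

## Design choices in the task pipelines

**Incremental learning.** Tasks are trained strictly in order with no access
to earlier data (asserted by construction of the task index sets). A single
shared classifier head over all classes is trained throughout; per-task
accuracy is scored by argmax over the task's own classes. The restricted
scoring is the protocol under which published per-task tables of this kind
are mutually consistent — a plain-SGD row retaining high early-task accuracy
is impossible under all-class scoring — and it measures what the comparison
is about: whether features and head rows supporting an old task survive
later training. All-class scoring remains available
(`restrict_to_task = FALSE`). Both algorithms default to the cross-entropy
objective so the comparison isolates the learning algorithm; the
squared-error output clamp, which is how the backward phase is classically
written, is one configuration switch away. "Best model" within a task means
highest validation accuracy on the task's own seeded 10% split; tables use
it, learning curves use the current model each epoch.

A finding worth stating honestly: with an implementation whose
fixed-prediction equilibrium provably equals backpropagation, the only
systematic difference left at 20 iterations is a per-layer attenuation of
the hidden-layer updates (the error signal reaching layer $i$ after $T$
iterations is scaled by roughly $1-(1-\eta_v)^{T}$ per hop). On this
generator that behaves like a slightly smaller hidden learning rate: at
matched rates predictive coding forgets marginally less than
backpropagation, and at the published asymmetric rates (0.1 versus 0.05)
the smaller backpropagation rate retains more. The package reports both
quantities as measured; the acceptance material records the comparison at
the published rates.

**Consolidation.** Elastic weight consolidation estimates a diagonal Fisher
from squared per-sample objective gradients and adds
$\lambda\,F_k(\theta-\theta^*_k)$ to every layer's local increment — under
predictive coding this is simply added to each $\Delta\theta_i$, preserving
locality. The penalty is only stable when $\eta_\theta\,\lambda\,F$ is small;
on data noisy enough that training never converges, the Fisher stays large
and the usable $\lambda$ window closes. The consolidation demonstration
therefore runs at σ = 2, where task-1 training converges. Moment matching
merges per-task snapshots either unweighted (`mean`) or
Fisher-precision-weighted (`mode`).

**Long-tailed objectives.** Six objectives couple into the same output-error
node: cross-entropy, mixup (inputs and soft targets mixed before the forward
phase, one Beta-distributed coefficient per batch), focal
($-(1-p_t)^{\gamma_f}\log p_t$), class-balanced focal (per-sample weight
$(1-\beta)/(1-\beta^{n_y})$, unnormalized so that $n_y = 1$ always has
weight 1), label-distribution-aware margin (margin $C/n_j^{1/4}$ subtracted
from the true-class logit), and the balanced-softmax term
($\log n_j$ added to every logit; no meta-sampler). Each reduction identity
(focal→CE, CB→focal, LDAM→CE, balanced-softmax→CE) holds to machine
precision, and each coupling's equilibrium update matches the
backpropagation gradient of the same objective.

**Few-shot recognition.** Prototypes are class means of support embeddings;
episode scores are softmax over negative squared Euclidean distances; the
episode loss gradient with respect to both query and support embeddings is
analytic (verified by finite differences) and enters predictive coding as
the output error of the embedding layer. Evaluation embeds the whole bank
once and then samples seeded episodes, reporting mean accuracy with a
standard error.

The evaluator's chance calibration is checked against a *null of
uninformative labels*: independent pure-noise banks, in which episode
accuracy is exactly $100/N$% by exchangeability. An untrained (random-init)
convolutional encoder on a *class-informative* bank is emphatically not at
chance — random convolutional features preserve input distances, and the
measured untrained accuracy here runs from about 22% to 47% on 5-way
episodes depending on noise; the same is true of random encoders on real
character benchmarks. This is the clearest example of the generator-scope
caveat above: "untrained equals chance" is an idealization that holds only
when labels carry no signal, and the package tests exactly that statement.
The ordering properties — accuracy non-increasing in the number of ways,
non-decreasing in shots — are checked on the informative bank.

## Problem sizes

The synthetic suites are sized so the full test suite and the acceptance
script each run in minutes on one CPU: 2,000-sample training pools, width-100
MLPs, 10 epochs per task, 1,000-episode calibration runs (20 banks × 50
episodes), 300-episode ordering checks. These are the package's documented
study conditions; every number above is a config field and scales up
unchanged.

## Known limitations

* Strictly sequential chains only: no skip connections, recurrence,
  generative/unsupervised operation, or spiking dynamics.
* Predictive coding training costs roughly `pc_iters` Jacobian-transpose
  products per batch on top of the forward pass — about an order of
  magnitude more than backpropagation at the default 20 iterations.
* The simplified 3-block convolutional network and the 4-block encoder are
  the largest architectures exercised; nothing here is tuned for
  VGG/ResNet-scale networks.
* Effect sizes on the synthetic generator need not transfer to natural-image
  data (no shared features across classes); the incremental-comparison
  finding above is the case in point.
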