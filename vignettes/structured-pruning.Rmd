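---
title: "Multi-phase structured pruning for neural decoding models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-phase structured pruning for neural decoding models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Neural decoding maps recorded neural activity to behavior. Calcium imaging
now yields trace matrices over tens to hundreds of neurons per subject, and
dense or convolutional classifiers decode binary behavioral states from
them. Deployment contexts — closed-loop neuromodulation, brain–computer
interfaces — need compact models, so overparameterized decoders are pruned:
whole nodes (MLPs) or whole filters (CNNs) are removed together with every
weight that depends on them, leaving a dense, hardware-friendly network.

Greedy structured pruning with random intra-layer selection (GRS) removes
one unit at a time: at each step it builds one random single-unit-removal
candidate per layer, retrains and validates each candidate, and greedily
keeps the best, subject to an accuracy floor. This examines structure
carefully but retrains after *every* removal, which does not scale.

## The multi-phase schedule

Empirically, pruning passes through two regimes. While the network is far
from its final compact form (the *far phase*), accuracy is insensitive to
removals: surviving capacity re-absorbs the lost units under brief
retraining. Close to the final form (the *near phase*), each removal is
critical. The jump schedule (JGRS) exploits this by batching removals —
"jumping" over retraining — while the model is insensitive, and reverting
to per-unit greedy selection near the end.

For hidden layer $\lambda$ with current width $u_\lambda$ and minimum
allowed width $\mu_\lambda$, the *pruning midpoint* is

$$\mathrm{midpoint}(\lambda) = \max\!\left(\left\lfloor
\frac{u_\lambda - \mu_\lambda}{2} \right\rfloor, 1\right),$$

half the remaining distance to the floor. The schedule runs three stages,
distinguished by their *compression rate* (CR), the number of units removed
between successive retrain-and-validate events:

| Stage          | One retrain+validate per | CR |
|----------------|--------------------------|----|
| Far subphase 1 | sweep over all layers    | $\sum_\lambda \mathrm{midpoint}(\lambda)$ |
| Far subphase 2 | per-layer candidate      | $\mathrm{midpoint}(\lambda)$ |
| Near phase     | single unit              | 1  |

*Far subphase 1* cuts every still-prunable layer's midpoint in one sweep,
retrains once, validates once, and accepts the sweep iff validation
accuracy stays at or above the floor; the first rejection ends the
subphase, returning the last accepted model. *Far subphase 2* builds one
midpoint-cut candidate per layer, retrains each, and greedily accepts the
best. The *near phase* is GRS itself (CR = 1). The driver computes the
floor once from the input model,
$\mathrm{ValAcc}_{\min} = \mathcal{T} \cdot \mathrm{OriValAcc}$, and runs
each stage `attempts[k]` times, every attempt chaining on the current
model — re-attempting a stage after rejection gives the randomized
selection another draw.

The hard floor $\mu$ (the minimum unit-count vector, one entry per hidden
layer) is respected by every method; the returned model always satisfies
$u_\lambda \ge \mu_\lambda$.

### Baselines

* **RRS** (random inter-layer order, random selection) replaces the greedy
  choice with a uniformly random one and is used as a *sensitivity probe*:
  at each step it evaluates one single-unit candidate per layer (each
  retrained and validated several times to average retraining noise),
  records the mean accuracy across candidates, and walks to a random
  candidate until $\mu$ is reached. Its per-step accuracy curve exhibits
  the far/near phenomenon directly: flat early, collapsing near $\mu$. The
  walk is never truncated by the accuracy tolerance — the probe's loose
  default ($\mathcal{T} = 0.5$) exists to let it reach $\mu$, and steps
  whose chosen candidate falls below the floor are flagged, not dropped.
* **NWM** (natural order, weight magnitude) visits layers from the input
  side and repeatedly removes the half of a layer's units with the
  smallest L1 norm of incoming weights (floor when odd, clamped to
  $\mu$), retraining after each halving, until a round is rejected or the
  floor is reached. This is the structured adaptation of lower-half
  weight-magnitude pruning; the removal unit is a node/filter, not an
  individual weight, so the comparison with the schedule above stays
  like-for-like.

## Comparison metrics

For dataset $d$, with O the original model and G, J the GRS- and
JGRS-pruned models,

$$\mathrm{AL} = \frac{\mathrm{Acc}_G - \mathrm{Acc}_J}{\mathrm{Acc}_O},
\qquad
\mathrm{FCI}/\mathrm{PCI} = \frac{C_G - C_J}{C_O},
\qquad
\mathrm{Time\ ratio} = \frac{\mathrm{Runtime}_G}{\mathrm{Runtime}_J},$$

with $C$ a FLOP or parameter count. The differences are *signed* (summaries
report negative minima, so the enclosing bars in the defining sets are read
as set-builder notation, not absolute value): positive AL means JGRS lost
more accuracy; positive FCI/PCI means JGRS compressed further. Because
wall-clock ratios are hardware-bound, the package also counts every
`fine_tune()` call in a global tally — the retrain count is the portable
speed proxy, and the jump mechanism's speedup is measured as a reduction in
retrain calls. Per-model summary rows report "lost" percentages in relative
form, $(\mathrm{orig} - \mathrm{pruned})/\mathrm{orig}$, matching the ratio
form of the tolerance.

## Parameters that matter

* `mucv` ($\mu$) — per-layer floor, dimensionless unit counts. The probe
  experiments use $2 \times 2 \times 2$ on a $16 \times 16 \times 16$ MLP,
  which keeps all layers prunable for the same number of steps.
* `tolerance` ($\mathcal{T}$) — accuracy-drop tolerance in $(0, 1]$;
  default 0.985, i.e. the pruned model may lose at most 1.5% of the
  original validation accuracy. The sensitivity probe uses 0.5.
* `attempts` — per-stage attempt counts, default `c(3, 3, 3)`.
* `train_config()` — retraining is mini-batch Adam (default batch 128,
  learning rate 0.01). Defaults of 40 epochs for initial training and 6
  for each fine-tune were chosen so that a pruned decoder reliably
  re-converges on the package's decoding tasks in well under a second;
  fine-tuning warm-starts from the surviving weights, never
  re-initializes, because the far-phase argument rests on surviving
  capacity re-absorbing the removed units' role. With `seed = NULL` (the
  default) retraining draws its shuffling noise from the enclosing
  algorithm's seeded stream, so one seed reproduces a whole pruning run.

## Synthetic data: what it emulates, and what it does not

The decoding datasets the method targets are not publicly deposited, so
the package generates statistical stand-ins. All generators are seeded and
deterministic.

* `generate_msn_like()` emulates a single-subject calcium recording:
  3000 samples at 10 Hz (5 min), $\beta$ neurons, binary behavior labels
  forming a two-state Markov chain with 3 s mean bouts. Half the neurons
  are label-coupled, emitting Poisson events at 0.2 Hz (rest) vs 4 Hz
  (active) convolved with a single-exponential calcium kernel
  ($\tau = 0.5$ s, a fast-indicator value); the rest fire at a
  state-independent 0.5 Hz; Gaussian noise (SD 0.1) is added. These
  defaults were tuned empirically — the recordings they imitate are not
  characterized statistically in public sources — to put a
  $16 \times 16 \times 16$ decoder in the low-to-mid 0.9 accuracy range
  with a genuine far-phase plateau: removals from the overparameterized
  model retrain back above the 0.985 floor, while minimal structures lose
  accuracy. The generator does *not* model drift, neuropil contamination,
  correlated noise, or the behavior's speed signal itself (only the
  binarized label).
* `generate_embedding_like()` emulates balanced graph-embedding vectors:
  two unit-variance spherical Gaussians at separation $s$ along a random
  direction in 80 dimensions, 1600 samples, exactly 800 per class; Bayes
  accuracy is $\Phi(s/2)$, so difficulty is dialed directly.
* `generate_planted_subnetwork()` labels Gaussian inputs by the parity of
  the sign bits of the first $k = 3$ coordinates (pushed a margin away
  from the decision planes). Parity of $k$ bits cannot be recovered from
  any linear projection to fewer than $k$ dimensions, so no network with a
  hidden layer narrower than $k$ can represent the rule — minimal
  structures fail for capacity reasons, not optimization ones. This is
  the dataset on which the sensitivity probe shows its far/near collapse
  (observed first-quarter-minus-final-step drops of 0.2–0.5; the
  regression floor asserted in the tests is 0.05).

**Known leakage caveat.** Splitting is i.i.d. at sample level (8:1:1,
floor rule), which matches how the emulated experiments randomize — but
with temporally autocorrelated traces and persistent labels, a decoder can
exceed the majority share even with *zero* label-coupled neurons, by
matching validation samples to temporally adjacent training samples
through background-transient fingerprints. The null-signal test therefore
uses near-memoryless traces ($\tau = 0.05$ s, 0.5 s bouts). Conclusions
drawn from these synthetic tasks are about the pruning schedule, not about
decodability of any real recording.

## Numerical and design choices

* **Exact surgery.** Removing a unit deletes its incoming weights and
  bias, plus the next layer's matching input slices (input rows of a dense
  successor; input-channel slices of a conv successor; at the
  conv-to-dense boundary, the whole flattened block the filter feeds,
  under a channel-major flatten). Surviving weights are copied verbatim.
  Prediction uses a fixed left-to-right accumulation order
  (`colSums`-based) rather than BLAS matrix multiply, so removing a unit
  whose outgoing weights are exactly zero leaves logits *bitwise*
  unchanged — the package's core surgery identity, tested for MLPs and
  both CNN boundaries. Training uses BLAS for speed; only prediction needs
  order stability.
* **Cost conventions.** Parameters: every stored weight and bias (biases
  are removed with their unit). FLOPs: a dense layer with fan-in $n$ and
  $m$ units costs $(2n-1)m$ multiply–adds plus $m$ bias additions; a conv
  layer costs $(2 k_h k_w c_{\mathrm{in}} - 1)$ multiply–adds plus one
  bias addition per output position per filter, valid padding, stride 1;
  pooling and activations are excluded. Reference architectures for the
  original experiments are not published in textual form, so absolute
  table counts are not reproduction targets; both counters are verified
  against brute-force enumeration instead.
* **Tie-breaks.** Greedy selection takes the first argmax, i.e. the lowest
  candidate (layer) index, making traces deterministic under a fixed seed.
  Magnitude ranking in NWM uses a stable order, lowest unit index first.
* **Attempt chaining.** Attempts chain on the evolving model (not
  best-of-restarts), and the accuracy floor is computed once by the driver
  and passed down; sub-phases never recompute it.
* **Sweep bookkeeping.** Far subphase 1 re-copies the last accepted model
  at the top of each sweep, making accepted-state bookkeeping explicit
  even though the loop exits on first rejection.
* **Degenerate inputs.** A layer can never be cut below one unit; layers
  at $\mu$ are skipped by the prunable-layer predicate
  $u_\lambda > \mu_\lambda$; with all layers at $\mu$, candidate phases
  return the input unchanged; a zero-attempt driver run is the identity.
* **Converged models are fixed points.** With a saturated softmax the
  cross-entropy gradient is exactly zero, so fine-tuning a fully converged
  model leaves its weights untouched — relied on by the pinned-accuracy
  fixtures.
* **Pinned-accuracy fixtures** (used to check control flow and the
  midpoint descent $16 \to 9 \to 6 \to 4 \to 3 \to 2$) train a
  *linear-activation* MLP on widely separated clusters: ReLU layers cut to
  2 units can die under brief retraining, which is a ReLU pathology, not a
  property of the schedule under test.

## Problem sizes used by the test-suite and acceptance script

The shipped experiments are sized for a single CPU: calcium-like batteries
use $\beta = 60$ neurons, 3000 samples (2400/300/300 split), a
$16 \times 16 \times 16$ probe MLP pruned to $2 \times 2 \times 2$; the
contract battery runs 20 seeded repetitions; the acceptance script runs
six datasets and one 42-step sensitivity trace. These sizes reproduce the
qualitative findings — order-of-magnitude retrain-count savings with
near-zero accuracy difference and deeper compression than magnitude
pruning — in a few minutes.

## Limitations

* Only feed-forward dense/conv architectures; no recurrent or attention
  models, and no unstructured (weight-level) sparsity.
* No automated search over $\mu$.
* Runtime ratios are recorded but hardware-bound; cross-study speed claims
  should use the retrain-call counters.
* The synthetic generators target schema and learnability, not
  physiological realism; passing tests demonstrate properties of the
  pruning algorithms, not decoding performance on real recordings.
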