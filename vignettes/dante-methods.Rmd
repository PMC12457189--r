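---
title: "Surrogate-guided tree exploration for data-efficient black-box optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-guided tree exploration for data-efficient black-box optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Many design problems in materials science, engineering and protein
engineering share three properties: the objective is an expensive black box
(a simulation, a structure predictor, a wet-lab assay), labels arrive in
small batches, and the goal is the single best design rather than a
cumulative reward. `dante` implements a closed active-optimization loop for
this setting: train a deep surrogate on the labeled data collected so far,
search the discrete design space guided by that surrogate, label a small
batch of promising candidates, and repeat. The loop starts from roughly 200
random labels and adds at most 20 per iteration, so the entire run typically
consumes hundreds, not tens of thousands, of objective evaluations.

## The model

### Search spaces

Every dimension of the design space is a finite ordered set: a numeric grid
`lower + j * step` (benchmarks use the hypercube $[-5, 5]$ with step $0.1$,
i.e. 101 admissible values per dimension) or a categorical alphabet (20
amino acids for sequence design). Candidate identity is the vector of
integer grid indices, never the floating-point coordinates, which makes
visitation counting and dataset deduplication exact. Constraints are named
predicates enforced by rejection sampling with a retry cap (default 50):
there is no repair or projection operator, because none is well defined for
an arbitrary black-box constraint.

### The surrogate

The value model is a one-dimensional convolutional network. A candidate's
grid positions, scaled to $[0, 1]$ per dimension, form a single-channel
sequence of length $d$; six convolutional blocks (each block = convolution,
batch normalization, ReLU; 16, 16, 32, 32, 32, 32 channels by default) are
followed by global average pooling, dropout (0.05) and a dense head that
emits one value. The first five blocks use kernel width 1 (deep
positionwise features) and the last uses width 3 with replicate edge
padding, so the network is close to an additive model
$\sum_j g(x_{j-1}, x_j, x_{j+1})$ over small windows. That inductive bias
was the single most consequential architecture choice: with wider kernels
throughout, the network learned "similarity to the cluster of good
candidates" shortcuts and systematically mis-ranked true
single-coordinate refinements of the incumbent (measured directly on
stalled Rastrigin-20 states, where the wide-kernel model ranked 0 of 7
true coordinate fixes above the incumbent and the near-additive model 6
of 7), while neighbor interactions — the Rosenbrock coupling — remain
representable through the final width-3 layer. Labels are z-scored in the
internal maximization convention (minimization objectives are negated at
the adapter boundary, never inside the engine), and training uses Adam
(step size $10^{-2}$, decayed stepwise to $10^{-3}$) on mean-squared error
by default; mean absolute percentage error is available where relative
error is the natural loss.

Two numerical choices matter and were fixed after reference experiments on
toy targets (a linear function and the 20-dimensional Ackley benchmark at
n = 500):

* **Stopping.** Training stops on a *training-loss* plateau (patience 120
  epochs within a 400-epoch budget) and keeps the best-training-loss
  weights. A small validation split is still held out and reported as a
  diagnostic, but it does not gate training: with a 10% split of a few
  hundred points its minimum sits long before the network's *local*
  resolution — the ability to rank one-grid-step neighbors of the incumbent
  — stops improving, and early validation stopping measurably stalled the
  optimization loop.
* **Warm starts.** Within a run the surrogate is refit every iteration by
  continuing from the previous iteration's weights, after an exact linear
  rescaling of the output layer that compensates for the moved label
  z-scoring statistics. Each warm refit trains 80 epochs (scaled down as
  the dataset grows so the optimization-step budget stays roughly
  constant), so effective training accumulates across the run exactly
  where the data accumulates. A cold refit needs roughly 300 epochs per
  iteration for the same local resolution, which is severalfold more
  compute for no measurable gain in attainment. Every 10th iteration
  refits from scratch anyway (`cold_every`): long warm chains occasionally
  pin the network in a weight basin whose ranking of near-optimal
  candidates stops improving. `run_config(refit_cold = TRUE)` restores the
  full refit-from-scratch protocol.

Dropout defaults to 0.05: with global average pooling over 16–32 channels,
a rate of 0.1 noticeably degraded both fit and downstream convergence in
the reference runs. All randomness (initialization, shuffling, dropout) is
keyed off one seed; refits are bit-identical per machine.

### The tree search

One search call explores the space with repeated *rollouts* from restart
roots. Each rollout expands the current root into $d$ leaves, one per
dimension, each generated by one of three stochastic modes with equal
probability $1/3$: a one-step move (the smallest admissible change at one
position), a single mutation (one position resampled over its whole range),
and a scaled random mutation (a uniformly drawn 10–50% of positions
resampled). Sequence spaces use the two-strategy variant: point mutations
of 1–3 free positions, or an entirely fresh random sequence, with equal
probability; fixed (hotspot) positions are never mutated.

Root and leaves are scored with the data-driven upper confidence bound

$$\mathrm{DUCB} = v_{\mathrm{ML}} + c_0 \, c(\rho)\,
  \sqrt{\frac{2 \ln N}{n + 1}},$$

where $v_{\mathrm{ML}}$ is the surrogate's standardized prediction, $N$ the
root's visit count, $n$ the leaf's, $c_0 = 0.1$ (admissible range
$[0.01, 1]$), and $c(\rho)$ the maximum of the standardized observed
labels, floored at 1. The $+1$ in the denominator keeps the score finite
for unvisited leaves, so no first-visit sweep is ever needed. Using
*standardized* labels for $c(\rho)$ is an interpretive choice: the raw
label maximum is negative for negated minimization benchmarks, which would
flip the exploration term's sign; standardization restores the intended
positive scale and makes the bonus commensurate with the standardized
predictions. Because newly found high labels stretch the standardized
maximum, exploration strengthens right after improvements — the
adaptive-exploration mechanism.

*Conditional selection* keeps the current root unless some leaf's DUCB
strictly exceeds it (ties never move the root). *Local backpropagation*
then increments only the root's and the selected leaf's visit counts — no
value information is propagated and no path update occurs, because only the
single best state matters, not a trajectory. Repeated visits inflate the
incumbent's count while $\ln N$ grows, so a dwelling walk builds a local
gradient of exploration bonuses that eventually pushes it over ridges —
the escape mechanism that the two-armed recurrence test verifies directly.
Every mechanism has an ablation switch (`conditional_selection`,
`local_backprop`, `adaptive_exploration`, `top_visit`).

Choices the method description leaves open, fixed here once:

* **Stopping criterion per search call**: a fixed rollout budget,
  `rollouts_per_dim * d` rollouts (default 5·d, i.e. a leaf-evaluation
  budget of about $5 d^2$), split over restarts. The budget must scale with
  the leaf fan-out, which is $d$ by construction.
* **Restart policy**: restart roots are the current top-5 dataset
  candidates plus one uniformly random candidate, cycled in short
  restarts of about 40 rollouts each until the budget is spent. One long
  walk per root drifts away from the incumbent (the DUCB bonus always
  favors fresh leaves over a much-visited root), which starves most-visit
  sampling of incumbent-shell candidates; short cycled restarts keep the
  visit mass where refinements live.
* **Refinement phase**: after two consecutive iterations without a new
  best label the loop halves the rollout and warm-refit budgets until the
  next improvement — a stalled best means the search is polishing an
  incumbent, which needs less travel and less retraining per iteration.
* **Visit-count persistence**: the visitation table persists across loop
  iterations (counts are keyed by exact candidate identity). The
  ladder-escape mechanism requires memory of repeated visits; resetting
  each iteration would erase it. This is an interpretive choice.
* **$N$** is the current root's total visit count, not a per-(root, leaf)
  statistic.

### Batch selection

Top-visit sampling converts the search trace into the next labeling batch:
the $\lceil k/2 \rceil$ best-scored (by surrogate prediction, not DUCB —
the DUCB already governed the walk) and the $\lfloor k/2 \rfloor$
most-visited trace candidates, deduplicated and excluding already-labeled
points; deficits fill from the other list and then from uniform random
candidates, which stands in for the epsilon of the modified epsilon-greedy
scheme. The 50/50 split is a symmetric default; the method statement gives
no proportions. In instrumented runs the two halves play distinct roles:
best-scored picks probe optimistic extrapolations of the network (and
correct them when wrong), while most of the actual incumbent improvements
enter through the most-visited half — the walk dwells near the incumbent,
and its shell is exactly where refinements live.

### The outer loop

`run_dante()` draws `n_init = 200` distinct uniform random candidates,
labels them, and iterates train → search → sample → label until the
labeling budget is exhausted or the known optimum is attained within
absolute tolerance $10^{-6}$ (the attainment bookkeeping counts *all*
labeled points, including the initial 200). Every iteration's randomness
derives from the master seed, so a run is reproducible from
`(config, seed)` on one machine. A proposed candidate that is already
labeled is skipped (the batch shrinks) rather than relabeled, preserving
dataset-key uniqueness. The random-search baseline replaces the sampler
with uniform draws at identical batch accounting and trains no surrogate.

## The synthetic benchmarks and what they show

Shipped objectives: Ackley ($a = 20$, $b = 0.2$, $c = 2\pi$), Rosenbrock,
Rastrigin (implemented with the full index bound $i = 1..d$ so the optimum
at the origin is exactly 0), Griewank, Schwefel and Michalewicz. The first
three use $[-5, 5]$ with step 0.1; the last three use their standard
domains discretized to 101 values per dimension, and their on-grid optima
are not treated as exactly attainable (the continuous minimizers of
Schwefel and Michalewicz are off-grid). These functions are deterministic
and noise-free; they emulate the *shape* of hard design landscapes
(multimodality, curved valleys, deceptive gradients) but not label noise,
measurement drift, or constraint structure of real validation sources.
Passing the benchmark suite therefore demonstrates data-efficient
optimization of high-dimensional nonconvex landscapes, not robustness to
noisy labels.

The sequence-design application uses a synthetic binder-fitness oracle: a
hidden target sequence with per-position match weights and sparse pairwise
epistasis (2·L seeded random pairs, strong enough to create local optima,
verified by single-mutant enumeration at generation), mapped to a bounded
shape-complementarity-like factor in $[0,1]$ times a positive
interface-size factor, combined as `sc * dsasa / 100`. It reproduces the
multiplicative structure and scale of an interface-quality target and the
ruggedness of an epistatic fitness landscape; it does not model any
physical complex, and recovering its hidden optimum is a
parameter-recovery test, not a claim about real binders. External scoring
pipelines plug in through a FASTA-in / TSV-out adapter contract.

## Problem sizes used in the shipped checks

The package's own verification runs (test suite and the acceptance script)
use these scales, chosen as the package's reference workloads: the
benchmark reproduction runs Ackley at $d = 100$ (budget 2,800; five seeds
in the acceptance script, two in the test suite) and $d = 20$ (budget
1,600, five seeds) with the study conditions `n_init = 200`, `k = 20`;
the binder recovery uses $L = 10$ with a 2,000-label cap over five seeds,
against matched random-search baselines; Rastrigin runs at $d = 20$ with
budget 1,000 over three seeds; and the ablation comparisons run the five
search variants on Ackley-20 with budget 600 over three seeds, because
their full-scale versions multiply five variants by hundreds of surrogate
refits. Reduced-scale checks are qualitative: they assert orderings (full
pipeline at least as good, disabled mechanisms worse) rather than printed
values.

One check is expected to fail at its stated scale: Rastrigin-20 does not
reliably reach exactly 0 within 1,000 labels in this implementation (it
typically reaches single digits by 1,000 and 0-2 by 1,600, against a
random-search best of roughly 200). Crossing the last few +-1 basins
requires the surrogate to rank a ~1-unit improvement against a label
standard deviation of ~100, resolution it only reaches after roughly
1,200 labels.

## Known limitations

* Bit-exact reproducibility holds per machine (BLAS and libm details vary
  across builds); statistical behavior does not depend on the machine.
* The surrogate's extrapolations far from data are systematically
  optimistic on some landscapes; the loop self-corrects by labeling such
  candidates, at the price of part of each batch.
* Attainment counts have heavy right tails over seeds on high-dimensional
  multimodal objectives; single-seed results are not representative.
* Continuous (non-discretized) spaces, gradient-based moves, value
  backpropagation along paths, and diversity-promoting batch selection
  beyond deduplication are out of scope.
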