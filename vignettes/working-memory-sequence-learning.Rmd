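---
title: "Capacity-limited chunking models of motor sequence learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capacity-limited chunking models of motor sequence learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmseq)
```

## The problem

When people learn a long sequence of aimed movements — say, moving a cursor
from a central box to one of eight surrounding targets, thirty moves in a
fixed order — recall does not grow smoothly. It grows in jumps of a few
items at a time, and the jumps are smaller for people whose individual
movements are slower and less accurate (older adults, the non-preferred
hand, an awkwardly oriented mouse). `wmseq` implements a mechanistic
account of this: each movement element carries an informational load
determined by a speed–accuracy law, a limited-capacity working-memory
buffer can only hold a few elements' worth of load at once, and whatever
the buffer holds is written to long-term memory as one chunk per
study–test cycle.

## The movement-time law and informational load

A single aimed movement of amplitude $A$ (mm) to a target of width $W$
(mm) is modelled by the Welford formulation of the speed–accuracy
trade-off,

$$\mathrm{MT} = a + b \log_2 A + c \log_2 W,$$

with constants $a \ge 0$ (s), $b \ge 0$ (s/bit) and $c \le 0$ (s/bit) for
one individual, effector and condition. The sign constraint on $c$ is
enforced at construction: the formula is kept literal while making the
behavioural requirement — smaller targets must never speed movements —
testable. Degenerate parameter combinations can predict a negative
duration; `movement_time()` clamps at a configurable floor (default 0 s)
with a warning rather than erroring, so parameter sweeps over wide ranges
do not abort.

The informational load of one sequence element is the
information-dependent part of its movement time, rescaled:

$$e = \max\{e_{\min},\; k\,(\mathrm{MT} - a)\} .$$

Neither $k$ (buffer units per second, default 2) nor $e_{\min}$ (default
0.1) is an empirically fixed quantity — load has no canonical unit — so
both are explicit calibration parameters. The defaults place a skilled
young adult's element at just under one buffer unit for the default task
geometry, which is convenient but not load-bearing: every model prediction
tested is an ordering or an exact identity, not a fitted magnitude. The
load floor guarantees strictly positive loads, which the buffer model
requires.

## The buffer model

A buffer of capacity $C > 0$ stores elements in serial order while the
residual capacity $Q = C - \sum_i e_i$ stays non-negative. One learning
iteration takes the longest storable run of consecutive elements at the
current frontier of the unlearned sequence, writes it to long-term memory
as a chunk, and advances. For uniform loads $e$ every full chunk has
$\lfloor C/e \rfloor$ items, so capacity and difficulty trade off directly
against chunk size, recall per trial, and trials to completion.

Three numerical choices deserve note:

* **Oversized elements.** If a single element's load exceeds $C$, the
  literal storage condition stalls forever. By default
  (`force_progress = TRUE`) such an element is still learned one per
  iteration — matching the near one-item-per-trial growth seen in
  low-capacity/high-load regimes — while `force_progress = FALSE`
  reproduces the literal condition (useful in estimation, below).
* **Atomic chunks.** Chunks are contiguous, strictly sequential, and
  written atomically; there is no re-study of learned items and no
  forgetting between iterations. Partial-chunk survival after an
  interrupted iteration is not modelled.
* **Determinism.** The buffer model itself is deterministic; all
  stochasticity (trial-level recall noise, motor noise) belongs to the
  synthetic-cohort layer, so model properties can be tested exactly.

## The reinforcement-learning instantiation

The same capacity limit is expressed in a model-free learner. Each target
of the sequence (a *sub-goal*) is a deterministic grid world: states are
cells, actions move one cell N/E/S/W (moves off the grid leave the agent
in place), every action costs $-1$, and an episode ends at the target or
after a step cap. The default geometry is a 5×5 grid with the start at the
centre and compass targets at distance 2. Each sub-goal has its own
q-table (long-term memory), initialised uniformly at zero. The return is
an undiscounted sum ($\gamma = 1$; episodes are finite), and the learning
rate defaults to $\alpha = 1$, which is exact in a deterministic
environment.

During a training trial each transition proposes the standard Q-learning
increment $\alpha\,(r + \max_{a'} \hat q(s',a') - \hat q(s,a))$, computed
against the table as it stood at the start of the trial. Proposals enter a
**working-memory queue** only if the queue has free space and the
increment's magnitude exceeds a significance threshold $\theta$ (strict
inequality; default $10^{-6}$, i.e. any material change is significant).
The queue is flushed to the q-tables once at trial end; between flushes the
value function is frozen. Once a sub-goal's table has converged its
transitions generate zero-magnitude increments, are never admitted, and so
stop competing for queue space — later sub-goals then claim the capacity,
which is what produces strictly sequential, iterative learning of the
sequence.

Two design choices here were genuinely open:

* **Duplicate queue entries.** A repeated state–action pair within one
  trial replaces its pending update (a recency effect) rather than
  coexisting with it. With $\alpha = 1$ and trial-frozen proposals,
  *applying* two stale duplicates in sequence overshoots (two queued
  terminal-transition updates drive a value to $-2$, then two corrective
  $+1$s swing it back — a sustained oscillation that never settles), while
  replacement makes each flush an asynchronous value-iteration sweep over
  the visited pairs, which converges to the optimal values exactly. The
  coexisting variant remains available (`dedup = FALSE`) and is applied
  strictly in arrival order.
* **Behaviour policy.** Cued demonstrations (`policy = "teacher"`: greedy
  toward the cued cell with per-step error probability `p_err`) model the
  training-trial cue, but they only ever traverse near-optimal paths, so
  the optimistic zero initialisation of off-path actions is never
  corrected and greedy recall cannot emerge from demonstrations alone. The
  default experiment policy is therefore `"egreedy"`: greedy on the
  agent's own frozen q-table with probability $1 - p_{\mathrm{err}}$,
  random otherwise. With uniform optimistic initialisation this is
  optimism-driven exploration — the agent systematically tries untested
  actions, drives their values below the optimal ones, and recall emerges.

At test, recall follows the greedy policy with a fixed tie-break priority
N > E > S > W (reproducible by construction; seeded random tie-breaking
would add nothing tested). A sub-goal counts as recalled if the target is
reached within a step budget, and CR counts consecutive successes from the
start of the sequence — mirroring the prefix scoring of the behavioural
task.

## The behavioural task and outcome measures

The task layer encodes the 8-target layout (25 mm centre and target boxes;
centre-to-target distance is *not* a published quantity and defaults to
80 mm — every movement amplitude derives from this layout constant),
alternating training/test schedules (14 repetitions → 28 trials; 10 →
20), seeded irregular sequence generation (default constraint: no
immediate repeats, so each next token is uniform over the seven
alternatives), and participant-controlled termination (a centre dwell
strictly exceeding 4 s).

Recall scoring has two first-class modes, because the behavioural
definition is genuinely ambiguous: `prefix` (default) counts the longest
correct prefix, consistent with consecutive-order recall and with the
chunk-increment analysis; `positional` counts all positionally correct
moves without deducting errors. Prefix CR can never exceed positional CR;
both are bounded by the sequence length.

Chunk increments — the per-trial growth in CR — default to increments of
the running maximum, which is non-negative by construction; a raw
difference mode exists for sensitivity analysis. The first increment is
measured from zero, so a participant's trial-1 recall counts as their
first chunk. Reported percentages round half away from zero to integer
percent (26.67 → 27, 68.75 → 69, 81.25 → 81), and the hand drop-off is
expressed as a share of sequence length, the only convention under which a
2-item difference on a 16-move sequence is 12.5%.

## The synthetic cohort

The generator exists so that the whole analysis pipeline is exercisable
without any human data. It emulates: alternating training/test trials;
30-move (one design) and 16-move (two designs) sequences over the eight
compass targets; group structure (younger/older), hand
(preferred/non-preferred) and mouse orientation (regular/sideways)
conditions; recall that grows in chunks; and per-move cursor traces
(straight minimum-jerk segments of duration given by the movement-time
law, Poisson-count corrective out-and-back submovements each adding a
known arc length, Gaussian positional jitter, and a terminating centre
dwell on test trials). The minimum-jerk speed profile is a realism choice
only; no tested quantity depends on it.

Default group parameters are calibrated to the *qualitative* contrast
only: younger adults (a = 0.30 s, b = 0.15, c = −0.10, C = 4, λ = 0.2,
σ = 0.5 mm) store 3–5 items per early trial; older adults (a = 0.50 s,
b = 0.25, c = −0.15, C = 2, λ = 1.0, σ = 1.5 mm) store about one. The
non-preferred hand and the sideways mouse multiply $b$, $|c|$ and the
correction rate λ by 1.3, raising element loads through the same law
rather than through a separate mechanism. No distributional information
about human trial-level variability is available, so the
between-participant coefficient of variation (default 0.1) and the
trial-level recall noise (SD 0.75 items) are documented defaults, chosen
once as plausible for behavioural data of this kind. The generator is
deliberately *not* calibrated to published human group means: reproducing
those would make any downstream comparison circular.

What passing tests therefore show: the pipeline's arithmetic is correct,
its model predictions hold as orderings, and its estimator recovers known
ground truth from data generated under the model's own assumptions. What
they do not show: that real participants satisfy those assumptions —
straight-line submovements, engine-driven recall growth, or normally
distributed parameter variation.

## Capacity estimation

`fit_capacity()` recovers $C$ from an observed per-trial CR series by grid
search (default grid 0.5–8 in steps of 0.5), minimising squared deviation
between the observed series and the buffer model's predicted cumulative
recall. Two identifiability choices matter. First, predictions use the
literal storage condition (no forced progress): a candidate below the
single-element load predicts zero recall forever and is rejected by any
data showing learning, which separates candidates that forced progress
would make indistinguishable. Second, all capacities sharing a chunk size
predict identical curves — recall data can only identify the equivalence
class $\lfloor C/e \rfloor$ — so ties are broken toward the smallest
candidate and `summary()` reports the full class. On noise-free sessions
generated at the default group capacities (4 and 2 buffer units, which are
the smallest grid members of their classes under the default loads) the
fit is exact; with default noise the estimator is used for group
*ordering*, not point recovery.

## Problem sizes

The shipped tests and the acceptance script use: learning-curve grids over
$C \in \{1,2,4,8\}$ and uniform loads $\{0.5, 1, 2\}$ on 30-element
sequences; RL convergence runs of 250 trials on the default 5×5 geometry;
a capacity sweep of 100 paired seeds over capacities $\{1,2,4,8,\infty\}$
with an 800-trial cap; 200 replicates of 2-vs-2-participant noisy capacity
recovery; and cohorts of 8 + 8 for the chunk-increment contrast. These
sizes were chosen as the smallest at which the stochastic orderings are
stable across seeds.

## Known limitations

* Chunk boundaries are strictly sequential and contiguous; flexible
  boundary placement (e.g. inferred from inter-move pauses) is not
  modelled.
* The buffer has no forgetting and no partial-chunk survival; a decay hook
  exists but defaults off.
* The RL layer is tabular and deterministic; stochastic transition
  kernels and function approximation are out of scope.
* Inferential statistics on human data (ANOVAs, effect sizes) are
  deliberately excluded: the package computes descriptive summaries and
  model quantities only.
* Capacity is identified only up to a chunk-size equivalence class from
  recall curves alone; timing-based identification would require
  additional modelling.
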