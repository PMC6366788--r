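# wmseq

Models and simulation tools for **working-memory-limited motor sequence
learning** — for cognitive and motor neuroscientists who study how people
acquire sequences of aimed movements (e.g. older vs. younger adults learning
an 8-target cursor task), and who want a mechanistic, testable account of
why harder movements make sequences harder to memorise.

## The model

Two classical ingredients are combined into one learning mechanism.

**1. A speed–accuracy law for single movements** (Welford formulation).
A movement of amplitude *A* toward a target of width *W* (both mm) takes

    MT = a + b·log2(A) + c·log2(W)        [seconds]

with individual constants `a ≥ 0`, `b ≥ 0`, `c ≤ 0`: farther and smaller
targets carry more information (bits) and take longer. The
information-dependent part of MT, `k·(MT − a)`, is the **informational
load** *e* one sequence element places on working memory — higher for less
skilled performers and for harder task conditions.

**2. A limited-capacity working-memory buffer.** A buffer of capacity *C*
holds sequence elements in serial order only while the residual capacity

    Q = C − Σᵢ eᵢ   ≥ 0

remains non-negative. Each learning iteration fills the buffer from the
current position in the sequence, writes the stored run to long-term memory
as one **chunk**, and repeats. Chunk size for uniform loads is `floor(C/e)`:
a smaller capacity or a larger per-element load yields smaller chunks and
slower learning — the core behavioural prediction.

The same idea is also instantiated as a **model-free reinforcement
learner**: each sequence target is a deterministic grid world (−1 reward
per action) with its own tabular q-function, and proposed Q-learning
updates pass through a fixed-capacity, significance-gated working-memory
queue that is flushed to long-term memory once per trial. Queue capacity
plays the role of *C*; steps-to-target plays the role of difficulty.

The package also provides the behavioural task itself (8-target layout,
alternating training/test schedules, recall scoring, dwell-based trial
termination), the outcome measures (CR, MT_r, PL, MT_t, F5/L5 block means,
chunk increments, recall percentages), a synthetic cohort generator with
age / hand / mouse-orientation structure, and `fit_capacity()`, a
grid-search estimator of *C* from recall curves.

## Worked example

```r
library(wmseq)

## single-movement arithmetic for the default task geometry (80 mm reach,
## 25 mm targets) with young-adult skill parameters
p  <- skill_params(a = 0.3, b = 0.15, c = -0.1)
mv <- movement(A = 80, W = 25)
movement_time(mv, p)        # 0.7839036 s per move
element_load(mv, p, k = 2)  # 0.9678072 buffer units per element

## chunked learning of a 16-move sequence with capacity C = 4
simulate_learning(element_sequence(rep(0.97, 16)), buffer_config(4))
#> Chunk-learning trace: n = 16, C = 4, complete in 4 iterations
#>   chunk sizes:        4 4 4 4
#>   cumulative recall:  4 8 12 16

## a full synthetic session and capacity recovery from its recall curve
spec <- experiment_spec("exp2")                  # 16 moves, 10 repetitions
prof <- participant_profile("y01", "younger")
sess <- generate_session(prof, spec, seed = 8)
sess
#> Synthetic session: y01, exp2/regular hand preferred, 16-move sequence, 20 trials
#>   CR by test trial: 4 8 12 15 16 16 16 16 16 16

cr  <- sess$outcomes$CR[sess$outcomes$trial_type == "test"]
fit <- fit_capacity(cr, loads = sess$element_load, n = 16)
summary(fit)
#> Capacity fit over 10 trials, sequence length 16
#>   C-hat = 4   residual SD = 0.316 items
#>   equivalent capacities (identical predicted curve): 4, 4.5
#>   observed: 4 8 12 15 16 16 16 16 16 16
#>   fitted:   4 8 12 16 16 16 16 16 16 16
```

The recall curve climbs in chunks of four items per trial — the young-adult
pattern — and the estimator recovers the generating capacity (`C-hat = 4`;
capacities predicting the identical curve are reported as an equivalence
class). Recall percentages and drop-offs use the reporting convention of
the field: `proportion_recalled(8, 30)$percent` is `27`,
`hand_drop(14, 12, 16)` is `12.5`.

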