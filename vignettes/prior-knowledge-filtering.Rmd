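---
title: "Prior knowledge filtering for surgical phase traces: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prior knowledge filtering for surgical phase traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkfilter)
```

## The problem and the model

A phase classifier run over an operative video emits one probability
vector per second across a vocabulary of classes — here the nine-class
sleeve-gastrectomy vocabulary of `sleeve_gastrectomy_vocab()`: a background
"Not a phase" class plus eight surgical phases. Raw argmax labels flicker:
idle stretches, artifacts and visually ambiguous frames produce short
spurious phase predictions, fragmented segments, and phases predicted at
surgically impossible points of the procedure.

Prior knowledge filtering encodes three pieces of procedural knowledge as
hard constraints derived from training annotations:

* **Phase order.** Some phases are tied to a part of the procedure
  (exploration/inspection happens at the beginning). An order rule confines
  a phase to the fractional span of video time `[start_frac, end_frac]`
  where it was ever observed in training, widened by a margin
  (`margin_frac`, default 0.05); predictions wholly outside the span are
  relabeled background. Rules are derived only for phases the analyst
  lists: the prior is strong, and deriving it indiscriminately for phases
  that merely happened to cluster in the training data would relabel
  correct predictions.
* **Phase time.** The minimum phase time `T_i` (seconds) is the shortest
  annotated duration of phase *i* across training videos. It drives both
  the smoothing window `W_i = round(min(max(W_min, η·T_i), W_max))` and
  short-segment removal: an output segment strictly shorter than `T_i`
  cannot be that phase and becomes background.
* **Phase incidence.** The maximum incidence `I_i` is the largest
  per-video count of phase-*i* segments in training. Surplus output
  segments (beyond the `I_i` most confident) become background.

Filtering proceeds: order correction of raw labels; per phase, a sliding
window of `W_i` seconds marks second *t* as phase *i* when the count of
phase-*i* labels in the window strictly exceeds `J_i = μ_i·W_i`; maximal
marked runs become segments and runs separated by at most
`L_i = min(ν_i·T_i, L_max)` seconds are connected; overlapping claims by
different phases are settled by the mean in-interval confidence
`C_i = (1/(f−e+1)) Σ p_(t,i)`; finally short-segment removal and incidence
capping. The output is a sorted, non-overlapping segment list; uncovered
seconds are background.

## Parameters, units, defaults

| parameter | meaning | default |
|---|---|---|
| `w_min`, `w_max` | window clamp, seconds | 10, 60 |
| `eta` (η) | window weight on `T_i` | 0.2 |
| `mu` (μ) | in-window majority weight (scalar or per phase) | 0.5 |
| `nu` (ν) | connection weight on `T_i` (scalar or per phase) | 0.4 |
| `l_max` | connection clamp, seconds | 180 |
| `alpha`, `gamma` | focal loss balance / focusing | 4, 2 |
| `margin_frac` | order-rule widening | 0.05 |

The PKF defaults are the values selected by grid search on surgical
validation data; `grid_search_pkf()` sweeps η × μ × ν (default grid
0.1–0.5 / 0.3–0.7 / 0.2–0.6 at step 0.1, bracketing the defaults) against
mean frame accuracy, with the weighted Jaccard selectable. Window and
connection clamps are fixed-but-configurable rather than searched: they
bound the search space and their defaults already sit at the scale of the
shortest (10 s) and longest (3 min) plausible smoothing horizons at 1 Hz.

## Numerical choices and degenerate inputs

* **Time base.** Everything internal runs at 1 Hz on a 0-based, half-open
  seconds grid: second *t* is `[t, t+1)` and takes the label of the
  annotation segment containing `t + 0.5`. Traces must carry one row per
  second; how a clip-level classifier is aggregated to 1 Hz is the
  caller's concern.
* **Ties.** Argmax ties resolve to the lowest class index (background
  first, so ties favor background); equal-confidence overlap claims go to
  the lower class index; equal-confidence incidence surplus keeps the
  earlier segment.
* **Strictness.** The majority test is strictly greater than `J_i`;
  removal takes segments strictly shorter than `T_i` (a segment exactly at
  the minimum survives).
* **Edges.** The window is truncated at video boundaries and the threshold
  rescaled to `μ·|window|`, keeping majority semantics uniform; the
  "middle time step" of a window of size `W` is index `floor(W/2)`. With
  μ = 0.5 and clean labels this reproduces segment boundaries exactly.
* **Gap connection is transitive** (iterated to closure); a left-to-right
  sweep over sorted runs realizes the closure exactly, and the test suite
  checks it against a fixpoint oracle.
* **Row sums.** Trace rows deviating from 1 by ≤ 1e-3 are silently
  renormalized; larger deviations are validation errors.
* **Unobserved phases** get fallback priors `T = 10` s (= `w_min`) and
  `I = 1` with a warning instead of failing, keeping the pipeline total on
  cohorts where optional phases never occur.
* **Empty inputs.** An all-background trace yields an empty segment list;
  an empty training annotation set is an error (priors would be
  undefined).

## Focal loss and sampling plans

`focal_loss()` is the pure numeric form
`FL(p) = −α(1−p)^γ log(p)` (clipped below at 1e-12), with γ = 0 reducing
to α·cross-entropy; it is exposed so training code in any framework can be
checked against a reference. Sampling plans are emitted as data (tibbles /
JSON Lines manifests), not tensors, decoupling the sampling scheme from
any training framework:

* `asbs_plan()` — annotation-segment-balanced sampling: every annotation
  segment, background gaps included, contributes the same number of clips
  (default five 20-second clips) per epoch, so v videos with Σ(n+m)
  segments yield exactly 5·Σ(n+m) records per epoch. Frames are sampled at
  30 fps (configurable), 64 per clip, at a stride drawn uniformly from
  4–9 among strides that fit the clip (`64·a ≤` clip frames). For segments
  too short for any stride in range (< 256 frames), the stride is capped
  at the range minimum — the choice that minimizes padding — and indices
  wrap around the segment (loop-padding), flagged in the record: such
  clips over-represent their few frames rather than silently leaving the
  segment or being dropped.
* `balanced_plan()` — the class-balanced baseline: a fixed per-epoch total
  split evenly across classes with annotated time (remainder to the
  earliest classes), upsampling with replacement. This is segment-level
  resampling, not feature-space interpolation: no feature space exists
  before a network is trained, so class balancing over video clips is the
  faithful desk-scale analogue of oversampling pipelines.

## What the synthetic generator emulates — and what it does not

`workflow_template()` mimics the grammar of sleeve gastrectomy: phases in
procedure order, optional phases included with per-phase probabilities,
up to two repeats of the long mandatory phases, uniform durations
(short optional phases of minutes, mandatory phases of tens of minutes)
and background gaps of 30–300 s separating segments — reproducing the
strong class imbalance such procedures show. `noise_model()` corrupts the
rasterized truth: per-second label flips (default 0.1), bursts (a flip
extends with probability 0.2 into a geometric run of mean 5 s, emulating
multi-second confusions), boundary blur mixing probability mass between
adjacent labels near transitions (default 5 s), and a confidence model
putting ~0.7 on the emitted label.

The generator does **not** emulate: correlated long-range errors of a real
classifier (confusions that track visual similarity between specific phase
pairs), drift in confidence over a procedure, frame-rate-native timing, or
annotation error in the ground truth itself. Passing tests therefore
demonstrate the algorithmic correctness and the direction of the
improvement under the stated noise model — not the absolute accuracy
figures achievable on real surgical video.

`improvement_experiment()` derives priors from the generated cohort's own
annotations when none are supplied, playing the role of the training-set
derivation; this also guarantees the cohort satisfies its own minimum-time
and incidence priors, as a training set does by construction.

Problem sizes used by the shipped tests and acceptance script — chosen as
comfortable desk-scale cohorts — are 100 simulated videos (≈ 4000–6000 s
each) for the improvement experiment and structural-invariant checks, 200
random sequences (length ≤ 500) for the brute-force oracle comparisons,
and 10-video cohorts for sampling-plan accounting.

## Design choices where the design was open

* **Stage order.** Order rules are applied to raw labels first (they
  correct raw wrong predictions), then smoothing and connection per phase,
  then overlap resolution, then short-segment removal, then incidence
  capping. Connection before overlap resolution means confident fragments
  are consolidated before phases compete for time.
* **Short-segment and incidence corrections replace with background**
  rather than reselecting the next-best label by confidence; overlap
  resolution alone uses the mean-confidence competition. Reselection is a
  documented alternative but relabeling to background is the conservative
  choice: a wrong phase label is costlier in review workflows than an
  unlabeled stretch.
* **Order rules are generalized** to an allowed fractional interval per
  phase rather than a hard-coded "beginning of surgery" rule, with the
  single-phase beginning rule as the motivating instance.
* **Per-phase μ and ν** are supported in configuration but default to the
  single scalars that the grid search selects.

## Known limitations

* **Confident burst errors can invert the benefit.** Smoothing windows for
  short phases are small (down to `w_min` = 10 s), so a burst of ≥ 6
  consecutive confident wrong labels of a short phase survives smoothing
  as a small island inside a long segment. The island then wins its
  overlap interval on mean confidence, fragmenting the long segment — and
  fragments strictly shorter than the long phase's `T_i` are removed.
  Under the default burst noise model this cascade can make filtering
  *reduce* frame accuracy; under isolated flips it reliably improves it.
  This is inherent to the stage order and the hard `T_i` cutoff, and is
  the desk-scale analogue of the method's weakness on short phases
  (bougie, exploration) on real data.
* **Out-of-sample minimum times.** `T_i` is a training-set minimum; a test
  segment near that minimum, eroded by a few seconds of boundary noise,
  falls below the cutoff and is dropped wholesale. Large training cohorts
  soften this; small ones do not.
* **No streaming mode.** Filtering needs the full trace (windows and
  connections look both directions); the package is offline by design.
* **1 Hz only.** Sub-second phenomena and frame-rate-native pipelines are
  out of scope.
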