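# pkfilter

Prior knowledge filtering (PKF) for surgical phase recognition, in R.

Automatic surgical workflow recognition labels every second of an operative
video with the surgical phase in progress (or a background "Not a phase"
class covering transitions, idle time and out-of-body footage). Per-second
classifier outputs are noisy: idle stretches, artifacts and ambiguous frames
produce flickering, implausibly short or misplaced phase predictions.
`pkfilter` implements the prior-knowledge post-processor that turns a raw
per-second class-probability trace into a clean, surgically plausible
segmentation, together with everything needed to study it without video
data: the focal loss used to train phase classifiers on imbalanced
annotations, clip-sampling plans for training, frame-level evaluation
metrics, a grid-search driver, and a synthetic workflow/noise simulator.

It is aimed at surgical data-science groups post-processing the output of
any per-second phase classifier (3D CNNs, CNN–RNNs, transformers) and at
methods researchers who need a reproducible, data-free testbed for temporal
label-smoothing pipelines.

## The method

Phase priors are derived from training annotations: for each phase *i*, the
minimum phase time *T&#8342;* (shortest annotated duration) and the maximum
incidence *I&#8342;* (largest per-video segment count), plus optional order
rules confining a phase (e.g. exploration/inspection) to the fraction of
the procedure where it is ever observed. Filtering then proceeds in stages:

1. **Order correction** — raw argmax labels of a ruled phase lying outside
   its allowed span of video time are relabeled background.
2. **Per-phase sliding-window smoothing** — with window
   `W_i = round(min(max(W_min, η·T_i), W_max))` seconds, a second is
   smoothed to phase *i* when the count of phase-*i* predictions in its
   window strictly exceeds `J_i = μ_i·W_i`. Runs separated by gaps of at
   most `L_i = min(ν_i·T_i, L_max)` seconds are connected.
3. **Overlap resolution** — intervals claimed by several phases go to the
   phase with the highest mean confidence
   `C_i = (1/(f−e+1)) Σ_{t=e..f} p_(t,i)` over the interval.
4. **Short-segment removal and incidence capping** — segments strictly
   shorter than *T&#8342;* become background; a phase exceeding *I&#8342;*
   keeps only its *I&#8342;* most confident segments.

Defaults (`W_min = 10`, `W_max = 60`, `η = 0.2`, `μ = 0.5`, `ν = 0.4`,
`L_max = 180`; focal loss `α = 4`, `γ = 2`) are the grid-search-selected
values used for sleeve-gastrectomy phase recognition; `grid_search_pkf()`
re-selects them on any validation set.

## Worked example

Everything below is synthetic — no video data involved. Simulate 20
sleeve-gastrectomy-like procedures, corrupt the per-second traces with
isolated 10% label flips (plus boundary blur), derive priors from the
cohort's own annotations, and filter:

```r
library(pkfilter)

noise <- noise_model(flip_prob = 0.1, burst_prob = 0,
                     boundary_blur_s = 5, conf_jitter = 0.05)
ex <- improvement_experiment(workflow_template(), noise,
                             n_videos = 20, seed = 1)
ex$summary
#> # A tibble: 1 × 6
#>   raw_accuracy pkf_accuracy raw_jaccard pkf_jaccard improved_frac n_videos
#>          <dbl>        <dbl>       <dbl>       <dbl>         <dbl>    <dbl>
#> 1        0.901        0.965       0.855       0.942           0.9       20
```

Raw argmax labels are right about 90% of the time (1 − flip rate); prior
knowledge filtering lifts frame accuracy to 0.97 and the support-weighted
Jaccard from 0.86 to 0.94, improving 90% of the videos. On a single video
the pieces look like:

```r
vocab <- sleeve_gastrectomy_vocab()
wf <- generate_workflow(workflow_template(), "demo", seed = 3)
trace <- generate_trace(wf, noise, vocab, seed = 4)
res <- apply_pkf(trace, ex$priors)     # priors derived above
tidy(res)                              # segments with mean confidence
autoplot(res, truth = labels_from_annotation(wf$segments, wf$duration_s, vocab))
glance(evaluate_phases(res$labels,
                       labels_from_annotation(wf$segments, wf$duration_s, vocab),
                       vocab))
```

`tidy()` returns the filtered segment table (`video_id, phase, start_s,
end_s, mean_conf`), `autoplot()` draws the raw/filtered/truth ribbon bands,
and `evaluate_phases()` bundles frame accuracy, weighted Jaccard, per-phase
precision/recall/F1 and the confusion matrix.

A command-line front end over the same functions ships at
`inst/cli/pkf.R` with subcommands `derive-priors`, `smooth`, `evaluate`,
`simulate`, `gridsearch`, `sample-plan` and `ribbon`.

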