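---
title: "Methods: single-vesicle content-mixing trace analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-vesicle content-mixing trace analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svfusion)
```

## The measurement model

A single diffraction-limited spot in the content-dye channel reports one
SV–PM vesicle pair. Its intensity trace is piecewise constant plus noise:

- baseline $b$ before association;
- $b + h$ after the association step (an SV vesicle docking onto the
  immobilized PM vesicle brings its content dye into the evanescent
  field);
- $(b + h)\,f$ after fusion, with $f > 1$ the dequenching factor: the
  content dye is loaded at a self-quenching concentration, so dilution
  into the fused volume raises its quantum yield. Fusion is therefore
  modeled as *multiplicative* on the post-association level rather than
  additive — the dequenching relief scales with the dye already present.

Acquisition covers three 1-min periods (association, spontaneous,
Ca²⁺-triggered) separated by 5-s buffer exchanges during which no frames
are recorded. The time axis is continuous experiment time in seconds;
the gaps simply contain no samples. The Cy5 channel is flat until the
injection time and elevated afterwards, for every spot, since the
injected Cy5 is a solution dye filling the whole field.

## Kinetic model of the generator

Per spot, with one RNG stream per experiment (a single integer seed;
per-spot values are drawn in a fixed documented order, so output is
bit-reproducible):

- association occurs with probability `p_assoc`, at a time uniform over
  period 1 — vesicle arrival in the flow chamber is approximately a
  homogeneous process over the 1-min loading window;
- spontaneous fusion is a constant-hazard process: a latency is drawn
  from Exponential(`k_spont`) and kept only if it falls inside the 60-s
  spontaneous period, which reproduces the closed-form fusion fraction
  $1 - e^{-k \cdot 60}$; a draw beyond the period means no event, and
  the vesicle remains available for triggering;
- triggered fusion occurs with probability `p_trig` (conditional on being
  associated and not spontaneously fused), with latency drawn from an
  Exponential(`lambda_trig`) *truncated* to the triggered period by
  inverse-CDF sampling. The two periods use different truncation
  conventions deliberately: for the spontaneous hazard the physically
  meaningful parameter is the rate, so censoring is the honest model; for
  triggering the meaningful parameter is the total fusion probability, so
  `p_trig` is imposed exactly and the latency shape is conditioned on
  fusing within the period.

Default kinetic parameters describe a strongly clamped, sharply
synchronized condition: `k_spont` = 2×10⁻⁴ s⁻¹, `lambda_trig` = 0.43 s⁻¹,
and `p_trig` chosen so that the expected first 1-s bin holds 1.7% of
associated vesicles (`p_trig = 0.017 (1-e^{-0.43\cdot 60})/(1-e^{-0.43})
≈ 0.0486`).

Signal defaults are declared, not inferred from any instrument: frame
interval 0.1 s (1-s histogram bins need several frames per bin; 10 Hz is
typical of EMCCD TIRF acquisition), baseline 100 a.u., association step
300 a.u., dequenching factor 1.8, noise SD 20 a.u. — a ~15σ association
step, i.e. clean traces of the kind retained after manual checking in
real experiments. Photobleaching is off by default (3-min content traces
show sustained plateaus at these illumination levels) but a single
exponential bleach rate is available.

## Step detection

Real analyses of this assay use automated step detection with manual
verification; the program typically used is not described in a form that
can be reimplemented exactly, so the package uses a transparent detector
validated against an exhaustive oracle: a sliding two-window
mean-difference statistic
$d_i = \mathrm{mean}(x_{i..i+w-1}) - \mathrm{mean}(x_{i-w..i-1})$,
thresholded at $\max(k\,\hat\sigma, \text{min\_amplitude})$ with
$\hat\sigma$ the scaled median absolute deviation of within-period first
differences (robust to the steps themselves). Local maxima of $d$ above
threshold are accepted greedily with a minimum separation of $w$ frames.
Defaults: $w$ = 10 frames, $k$ = 4, `min_amplitude` = 0.

Conventions and consequences:

- `t_step` is the **first frame at the elevated level** (half-open
  convention).
- The windows slide over the *concatenated* frames: fluorescence levels
  persist across the unsampled buffer-exchange gaps, so the pre-step
  window of an event early in a period validly ends in the previous
  period. Without this, every event in the first $w$ frames after an
  injection would be undetectable — exactly the first 1-s bin that
  carries the burst amplitude. A level change occurring *during* a gap is
  attributed to the first frame of the following period; step times are
  therefore always sampled frames, never gap times.
- The detector is blind to events in the first $w$ frames of the
  experiment and the last $w$ frames of the final period, and cannot
  resolve two steps closer than $w$ frames. At 10 Hz these are 1-s
  margins on a 180-s trace (≲2% of uniformly distributed event times);
  affected traces are excluded by the exactly-one-association-step rule
  rather than misclassified. The test suite verifies exact fate recovery
  on noiseless data outside these margins.
- Downward steps (bleaching, undocking) are detected internally and flag
  the trace for exclusion, but are never returned as events — the
  analysis uses only clean single-increase traces.
- On ≤300-frame traces with ≤2 planted steps of amplitude ≥5σ the
  detected change points match an exhaustive least-squares two-change
  segmentation oracle within ±2 frames; at the default 4σ threshold a
  5σ step sits only ~2 noise-SD above threshold, so the equivalence
  property is exercised at a 3σ threshold where detection is
  essentially certain, while false positives on 1000 pure-noise traces
  stay below 0.01 per trace even at the default.

The Ca²⁺ arrival time is detected on the field-averaged Cy5 trace (the
injection is global, so averaging maximizes step SNR): the first frame
exceeding the pre-injection baseline mean + 4 SD with a sustained
elevation over the following 10 frames. A flat Cy5 channel (mock content
run without dye, failed injection) raises an explicit error.

## Classification cascade

Zero association-period steps → excluded ("no association"; includes SV
vesicles already associated during a previous acquisition round). Two or
more → excluded ("multiple association-period steps"). Exactly one →
associated; then the first spontaneous-period step marks spontaneous
fusion; otherwise the first triggered-period step at or after $t_{Ca}$
marks triggered fusion with latency $t_{step} - t_{Ca}$. A
triggered-period step *before* $t_{Ca}$ excludes the trace: spontaneous
statistics are defined over the spontaneous period only, and counting
such events in either class would distort both. At most one fusion event
is recorded per pair; later steps are tallied as anomalies
(`n_extra_steps`) and never observed on simulated data, matching the
single-pair interpretation of diffraction-limited spots. Every trace
receives exactly one fate, so excluded + no-fusion + spontaneous +
triggered partitions the input.

Mock injections (Cy5 step present, no Ca²⁺) are analyzed identically;
$t_{Ca}$ comes from the Cy5 channel and the triggered count is expected
to be zero, which the test suite verifies across 20 replicates.

## Histograms, fits and rates

Histograms use half-open 1-s bins from the time origin ($t_{Ca}$ for
triggered, the spontaneous-period start for spontaneous), normalized by
the number of associated vesicles of the merged table; the sum of
normalized bins equals events/associated exactly. The decay model
$n_k = A e^{-\lambda t_k}$ is fitted unweighted (no weighting is implied
by the two-parameter description of the published fits; Poisson
weighting is available behind a flag) at bin **left edges**, so $A$ is
directly the first-bin probability; bin centers are a documented switch.
There is no additive offset term. The fit uses a Levenberg–Marquardt
minimizer (`minpack.lm`) with tight tolerances — noiseless
model-generated histograms are recovered to ≤10⁻⁶ relative error — and
reports standard errors from the scaled inverse of the approximate
normal-equations matrix at the optimum. Initialization: $A_0$ from the
first/maximum bin, $\lambda_0$ from the reciprocal mean event time; the
fit requires ≥3 non-zero bins ("insufficient events" otherwise).

The spontaneous rate is emitted in two explicitly named forms — per
second (events / associated / 60 s) and per observation period — because
both appear in condition comparisons. The first-bin amplitude likewise
carries a per-associated-vesicle form and a per-fusion-event form
(first-bin count / total triggered events). The triggered/spontaneous
ratio is `first_bin / (spont_per_s × bin_width)`; with the defaults
(1.7% first bin, 0.02%/s spontaneous) it equals 85, and 6 for the
unclamped comparison values (0.6%, 0.1%/s).

Replicate comparisons operate on per-round values (`per_round_counts`),
not pooled counts, using the pooled-variance two-sample Student's *t*
with a p < 0.01 significance flag; the type-I error rate at that
threshold is calibrated within binomial error in the test suite.
Degenerate zero-variance groups are handled explicitly (equal constants
→ t = 0, p = 1).

## What the simulator does and does not emulate

It emulates: stepwise association and dequenching signals on a shared
schedule, constant-hazard spontaneous fusion, exponentially distributed
triggered latencies, a global Cy5 injection step, additive Gaussian
camera noise, optional bleaching, and (via the movie layer) Gaussian-PSF
spot images with conserved integrated intensities.

It does not emulate: molecular mechanism (SNARE zippering, Ca²⁺
binding — rates are phenomenological), lipid-mixing signals (the assay
modeled here is content-only), intensity heterogeneity between vesicles,
correlated or multiplicative camera noise, stage drift, or spot overlap
beyond the placement constraint. Passing tests therefore demonstrate
correctness of the detection–classification–summary chain under the
stated noise model, not robustness to every artifact of real recordings
— which is why real analyses retain a manual-check step.

## Numerical and design choices

- Problem sizes in the test suite: fate-frequency and latency checks at
  10⁴ spots; end-to-end amplitude/rate recovery at 5000 associated
  vesicles (matching the scale at which first-bin counts have ~10%
  relative binomial error); 10⁴-case partition and calibration suites.
- Tolerances on stochastic checks are 3 binomial/standard errors of the
  quantity under its generating model.
- Event times are continuous; a fusion exactly at a bin edge goes to the
  right bin (half-open bins), and an event exactly at $t_{Ca}$ is bin 0.
- Movie rendering normalizes each discrete PSF kernel to unit sum so a
  spot's pixel sum equals its trace value exactly; aperture photometry
  with radius $3.5\sigma_{PSF}$ captures ≥99.8% of that mass, keeping
  round-trip error below 1% when spots are spaced at least two aperture
  radii apart. Overlapping apertures flag both spots for exclusion.
- The trace table, truth sidecar, config and report formats are plain
  delimited text / JSON throughout; reports embed the exact config and
  seed and are byte-identical on reruns.

## Known limitations

Windowed detection imposes a one-window (1 s at defaults) resolution
limit and blind margins discussed above; sub-frame latencies are
quantized to the frame interval (0.1 s), which biases fitted decay rates
negligibly for bursts slower than ~2 s⁻¹. The unweighted histogram fit
under-uses sparse tails; its standard errors are approximate for low
event counts (the parameter-recovery tests quantify coverage at the
simulated scales). Association-period docking is modeled as at most one
SV vesicle per spot; crowded fields where multiple vesicles dock at one
spot are excluded by the cascade rule rather than deconvolved.
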