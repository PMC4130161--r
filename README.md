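# svfusion

Analysis of single vesicle–vesicle content-mixing fusion experiments from
dual-channel TIRF fluorescence time traces, with a fully ground-truthed
synthetic-data generator.

## The assay and the analysis problem

In the reconstituted single-vesicle fusion assay, vesicles mimicking the
plasma membrane (PM vesicles) are immobilized on a passivated surface and
vesicles mimicking synaptic vesicles (SV vesicles), loaded with a
self-quenched content dye, are flowed in. Acquisition covers three 1-min
periods separated by 5-s buffer exchanges:

1. **Association** — an SV vesicle docking onto a PM vesicle produces a
   stepwise increase of the spot's content fluorescence.
2. **Spontaneous fusion** — Ca²⁺-free observation; full fusion dequenches
   the content dye, producing a second stepwise increase.
3. **Ca²⁺-triggered fusion** — Ca²⁺ is injected together with soluble Cy5
   dye; the Cy5 channel reports the arrival time *t*₍Ca₎, and
   triggered-fusion latencies are measured from it.

Only spots with **exactly one** step during the association period are
analyzed, and at most one fusion event is recorded per associated pair.
The kinetic summaries are:

- the 1-s binned fusion histogram *n*ₖ, normalized by the number of
  associated vesicles, fitted with a single exponential
  *n*ₖ = *A*·exp(−λ·*t*ₖ) (Levenberg–Marquardt, standard errors from the
  fit covariance matrix) — *A* is the first-bin fusion probability per
  associated vesicle and λ the burst decay rate (s⁻¹);
- the spontaneous fusion probability per associated vesicle per second,
  *n*_spont / (*n*_assoc · 60 s);
- the triggered/spontaneous probability ratio *A* / (*k*_spont · 1 s);
- pooled-variance Student's *t* comparisons of per-replicate values across
  conditions (significance at p < 0.01).

Because raw traces of published experiments are generally not deposited,
the package ships a trace-level simulator with exact ground truth —
association steps, constant-hazard spontaneous fusion, single-exponential
triggered bursts, multiplicative dequenching, a Cy5 injection step and
additive camera noise — so every pipeline stage is testable end to end.

## Worked example

```r
library(svfusion)

truth <- ground_truth(n_spots = 5000, p_assoc = 1, k_spont = 2e-4, seed = 1)
ex    <- simulate_experiment(truth, acquisition_schedule())
tab   <- analyze_experiment(ex, condition = "with-cpx")
tab
#> Event table: condition 'with-cpx', 1 round(s)
#>   traces 5000 | associated 4978 | spontaneous 62 | triggered 234 | excluded 22

fit <- fit_exponential_decay(fusion_histogram(tab, "triggered"))
fit
#> Single-exponential decay fit: y = A * exp(-lambda * t)
#>   A      = 0.01741  (se 0.000223)   [first-bin probability]
#>   lambda = 0.4669  (se 0.0105) 1/s   [decay rate]
#>   rss = 3.41e-06 over 60 bins

sr  <- spontaneous_rate(tab)
amp <- first_bin_amplitude(fusion_histogram(tab, "triggered"))$per_associated
sr$percent_per_second                         # 0.0208  (% per s)
triggered_to_spontaneous_ratio(amp, sr$per_second)   # 85
```

The simulated condition has a spontaneous hazard of 2×10⁻⁴ s⁻¹ (0.02% per
second), a triggered burst decaying at 0.43 s⁻¹ and an expected first-bin
probability of 1.7%; the pipeline recovers all three from the raw traces
within sampling error, and the ~85-fold triggered/spontaneous ratio
follows. The 22 excluded traces are spots whose association step fell too
close to a period edge for the windowed detector, or which showed
multiple association-period steps.

A thin command-line surface (`inst/scripts/svfusion.R`) wraps the same
functions as `simulate` / `analyze` / `report` subcommands driven by a
flat key-value config file.

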