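# photospike

Quantification pipeline for photopharmacology experiments on ventral
tegmental area (VTA) dopamine neurons, where nicotinic acetylcholine
receptors are reversibly antagonized by a tethered azobenzene
photoswitch: ~390 nm light drives the switch to its antagonizing *cis*
form, ~520 nm light relieves antagonism, and the *cis* state persists
in darkness with a half-life of tens of minutes. The package is for
electrophysiologists and behavioural neuroscientists analysing such
experiments: it takes sorted spike times, light schedules, injection
tables, evoked-current amplitudes and arena trajectories, and returns
the standard read-outs of this paradigm.

## What it computes

* **Burst metrics** — bursts by the two-criterion ISI rule (onset ISI
  < 80 ms, closure ISI > 160 ms), percent spikes-within-bursts (%SWB),
  sliding 60 s / 15 s-step rate and %SWB series, and event-aligned
  rasters / peri-stimulus time histograms (250 ms bins).
* **Photoswitching analysis** — pooled per-wavelength firing
  frequencies and the photoswitching index

  `index = 100 × (Freq_520 − Freq_390) / Freq_390`,

  a control-derived responder threshold (the |index| quantile excluding
  95% of control neurons; fixed 15% available), classification into
  type 1 (firing reduced under 390 nm, index > 0) / type 2 (increased,
  index < 0) / non-responders, SWB frequency per wavelength, and cohort
  comparison by Kolmogorov–Smirnov test.
* **Pharmacology** — photo-inhibition of evoked currents,
  `100 × (1 − I_380/I_525)`; nicotine i.v. response magnitude (largest
  |percent variation| from baseline among windows starting within 200 s
  of the injection, sign kept) and normalization to the dark response.
* **Place preference** — per-zone occupancy from 20 frames/s
  trajectories, preference score `ps = test − pretest` seconds on the
  nicotine-paired side, bias-balanced group assignment, group
  summaries.
* **Statistics** — the normality-gated decision tree (Shapiro → pooled
  / Welch t-test or rank tests) with a full gate audit trail, and
  Holm–Bonferroni correction.
* **Synthetic data** — a generator for every input above: bistable
  photoswitch-state kinetics (74 min dark half-life, sub-second
  relief), light-gated gamma-renewal bursting spike trains, nicotine
  transients, occupancy-conditioned CPP trajectories, paired current
  amplitudes. Defaults mirror the reported class composition
  (28 controls; 93 transduced: 60 non-responders, 24 type 1, 9 type 2)
  and group means (type 1: 3.41 → 1.85 Hz; type 2: 3.48 → 5.25 Hz).

All times are seconds; all intervals are half-open `[on, off)`.

## Worked example

Simulate a small cohort under the standard protocol (200 s dark
baseline, then 20 cycles of alternating 5 s 390/520 nm flashes), derive
a responder threshold from the controls, and classify the transduced
neurons:

```r
library(photospike)

sched <- default_schedule(n_cycles = 20)
coh <- simulate_cohort(n_control = 10, n_nonresponder = 10,
                       n_type1 = 5, n_type2 = 2, seed = 42)

ctrl <- names(coh$trains)[coh$truth$cohort == "control"]
ctrl_abs <- sapply(coh$trains[ctrl], function(tr) {
  f <- epoch_frequencies(tr, sched)
  abs(photoswitching_index(f[["f_520"]], f[["f_390"]]))
})
thr <- control_threshold(ctrl_abs, exclusion_fraction = 0.95)
thr
#> <threshold_spec> 5.55% absolute photoswitching (control_quantile, exclusion 0.95)

trans <- names(coh$trains)[coh$truth$cohort == "transduced"]
tab <- photoswitch_table(coh$trains[trans], sched, thr)
head(tab[order(-tab$abs_index),
         c("neuron_id", "f_390", "f_520", "index", "label")], 7)
#>    neuron_id f_390 f_520 index label
#> 14 type1_004  1.82  3.43  88.5 type1
#> 11 type1_001  1.80  3.19  77.2 type1
#> 12 type1_002  1.96  3.44  75.5 type1
#> 13 type1_003  1.94  3.39  74.7 type1
#> 15 type1_005  2.11  3.31  56.9 type1
#> 16 type2_001  5.46  3.52 -35.5 type2
#> 17 type2_002  5.57  3.78 -32.1 type2
```

The type 1 neurons fire ~1.8–2.1 Hz under 390 nm (receptor antagonized)
versus ~3.2–3.4 Hz under 520 nm — a positive index well above the
threshold — while type 2 neurons show the opposite profile; true
non-responders (not shown) sit below the threshold. Burst metrics and
the cohort contrast:

```r
tr <- coh$trains$type1_001
b <- detect_bursts(tr)          # 80/160 ms ISI rule
b
#> <burst_set> type1_001: 5 burst(s), 29/1200 spikes within bursts (2.4%)

cmp <- cohort_compare(ctrl_abs, tab$abs_index, thr)
cmp$summary
#>       cohort  n mean_abs_index sem_abs_index responder_fraction
#> 1    control 10           3.59          0.49              0.100
#> 2 transduced 17          27.29          8.14              0.471
cmp$ks
#> <test_result> two-sample Kolmogorov-Smirnov: statistic = 0.4706, p = 0.123
```

Transduced neurons photoswitch (mean |index| 27.3% vs 3.6% in
controls); at this toy cohort size the KS test is underpowered, which
is the expected behaviour — the shipped tests run the full 121-neuron
composition.

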