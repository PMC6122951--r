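---
title: "Quantifying light-controlled nicotinic signalling: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying light-controlled nicotinic signalling: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photospike)
```

## The experimental system

photospike quantifies experiments in which nicotinic acetylcholine
receptors (nAChRs) carrying a cysteine-substituted β2 subunit are
conjugated to a tethered azobenzene photoswitch. Under ~390 nm light the
photoswitch isomerizes to its *cis* form and antagonizes the receptor;
under ~520 nm light it relaxes to *trans* and antagonism is relieved.
Because the *cis* form is thermally bistable (its dark half-life is tens
of minutes), brief light flashes toggle receptor function without
continuous illumination. Applied to ventral tegmental area (VTA)
dopamine neurons, this gives optical control over the endogenous
cholinergic drive that shapes their tonic firing and their bursting, and
over the response to systemic nicotine.

The package implements the full read-out chain for such experiments:
spike-train metrics, per-wavelength firing statistics and responder
classification, evoked-current and nicotine-response pharmacology,
conditioned place preference (CPP) scoring, and the statistical decision
tree tying group summaries together. A synthetic-data generator
produces every input with the statistical structure the analyses
assume, so the whole chain is testable at desk scale.

## Conventions

* **Units.** Seconds internally, everywhere. File columns carry unit
  suffixes (`time_s`, `half_ap_width_ms`) and are converted on load.
* **Intervals.** All intervals — light epochs, sliding windows, session
  phases, histogram bins — are half-open `[on, off)`. A spike sitting
  exactly on a boundary belongs to the later interval, so nothing is
  double-counted.
* **Putative dopamine neurons.** The electrophysiological filter
  (`is_putative_da`) requires a mean rate in [1, 10] Hz, an action
  potential half-width above 1.1 ms, and regular firing. No standard
  numeric criterion for "regular" exists, so it is operationalized as an
  ISI coefficient of variation at or below a configurable cut-off
  (default 1.0); the cut-off travels with any result that used it.

## Burst detection

Bursts are detected by the standard two-criterion extracellular rule: a
burst opens at two consecutive spikes with an inter-spike interval (ISI)
strictly below 80 ms, and closes at the first ISI strictly above 160 ms.
Design points that the rule's usual verbal statement leaves open:

* An ISI of exactly 80 ms does **not** open a burst, and an ISI of
  exactly 160 ms does **not** close one — both thresholds are read
  strictly, in both directions.
* Both spikes of the opening pair belong to the burst, so every burst
  has at least two spikes.
* Scanning resumes at the spike after the burst's last spike, so bursts
  are disjoint and ordered.

Amplitude-based burst features (decrementing spike height, lengthening
intra-burst ISI) are not operational here: the inputs are sorted spike
times, and only the two ISI criteria are enforced. `swb_fraction` gives
the percentage of spikes within bursts (%SWB); over short (5 s) light
epochs, bursting is instead reported as an SWB *frequency*
(`swb_frequency_by_epoch`), because a percentage over a handful of
spikes is unstable.

The test suite checks the detector against an independent brute-force
oracle that enumerates every contiguous spike range and keeps the ranges
satisfying the burst invariants, on 1,000 randomized trains that mix
Poisson-like ISIs, injected sub-80 ms runs, and ISIs pinned exactly to
the 80/160 ms boundaries.

## Sliding windows and event alignment

Firing rate and %SWB time courses use 60 s windows advanced in 15 s
steps (a 45 s overlap). Windows are anchored at the recording start and
a truncated final window is dropped, so every value is an average over
exactly one window length. Event-aligned analysis (`aligned_histogram`)
bins spike offsets around alignment events — typically 390 nm flash
onsets — into uniform bins (default 250 ms) and normalizes by
`n_events × bin width` to give a peri-stimulus time histogram in Hz;
the per-event offsets are kept for raster display. All transitions of a
schedule are kept as alignment events; no post-transition blanking is
applied by default (none is part of the published protocol, and a
configurable blanking would change PSTH edge bins only).

## Photoswitching index and classification

For each neuron the pooled per-wavelength frequency is
`f_λ = (spikes in all λ epochs) / (total λ epoch duration)`, and the
photoswitching index is

$$ \mathrm{index} = 100 \times \frac{f_{520} - f_{390}}{f_{390}} . $$

Pooling over all epochs (rather than averaging per-transition ratios)
was chosen because a 5 s epoch at 2–5 Hz holds 10–25 spikes, and
per-epoch ratios at such counts are dominated by shot noise; a
per-transition variant (`per_transition_index`) is provided for
sensitivity analysis. The sign convention puts firing-reduced-under-390
(direct antagonism of an excitatory nicotinic drive, "type 1") at
positive indices and firing-increased-under-390 ("type 2", consistent
with antagonism of an inhibitory drive through the local circuit) at
negative indices.

The responder threshold is derived from control neurons: the empirical
0.95 quantile of their absolute indices (linear interpolation between
order statistics), i.e. the level that excludes 95% of controls. The
conventional fixed 15% threshold is available as `method = "fixed"`.
Neurons exactly at the threshold count as responders (a ≥ rule), so a
fixed threshold yields a deterministic partition. `cohort_compare`
contrasts cohorts by mean ± SEM of the absolute index, responder
fractions, and a two-sample Kolmogorov–Smirnov test on the
absolute-index distributions.

## Pharmacology

`photoinhibition_index` is `100 × (1 − I_380/I_525)` for agonist-evoked
currents measured under the two wavelengths; it is invariant to
rescaling both amplitudes and rejects sign-discordant pairs as
artifactual. Nicotine responses are quantified on the sliding rate
series: the baseline is the mean of windows ending within 180 s before
the injection (the protocol guarantees ≥ 5 min of baseline; the last
180 s of it balances stability against drift), and the response is the
percent variation of largest absolute magnitude among windows starting
within 200 s after the injection, sign preserved — accommodating both
nicotine-evoked excitations and inhibitions. Light-condition responses
are expressed relative to the same neuron's dark response
(`normalize_to_dark`). Successive injections are analysed
independently, with a warning when the baseline has not returned to
within 20% of the previous one. %SWB responses follow the same
extremum contract; neurons without baseline bursting are flagged and
excluded rather than scored.

## Conditioned place preference

Occupancy credits each inter-sample interval (20 frames/s nominal) to
the zone of its leading sample; the central compartment is tracked but
never enters the preference score, which is

`ps = (test-phase seconds on the nicotine-paired side) − (pretest seconds on that side)`,

matching the two-chamber subtraction score. A side-difference variant
sits behind `mode = "difference"`. Group assignment after the pretest
(`balance_groups`) minimizes the largest absolute group-mean bias —
exhaustively up to 16 animals (group sizes of 6–8 are typical), by a
seeded randomized-swap descent beyond. `cpp_summary` reports mean ± SEM
per group with a normality-gated one-sample test against zero.

## The statistical decision tree

`compare_two_groups` reproduces the analysis policy as one auditable
entry point: Shapiro–Wilk on both groups at α = 0.05; if both pass, an
F-test of variance homogeneity (also α = 0.05 — the policy's "Welch if
needed" does not state a level, so the gate and its level are recorded
in every result) selects the pooled or Welch t-test; if either fails,
the rank test (signed-rank when paired, Mann–Whitney otherwise). All
gate p-values ride along in the `test_result`. Families of comparisons
are Holm–Bonferroni corrected (`holm_bonferroni`, a step-down with
monotonicity enforcement and capping at 1); which comparisons form a
family is the caller's decision. The primitive statistics are delegated
to base R's tested routines; what this module owns is the gating, the
branch bookkeeping and the audit trail. A simulation test confirms that
the gated tree holds its nominal 5% type-I error under both Gaussian
and log-normal nulls — gating on the same data used for testing can
inflate error, so this is checked rather than assumed.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions, not tuning knobs.

**Photoswitch state.** `photoswitch_state` models the *cis* fraction:
driven to 1 instantaneously at 390 nm epoch onset (antagonism appears
within the flash), relaxed toward 0 under 520 nm with a 0.5 s time
constant (relief is complete within well under a second), and decaying
thermally in darkness with a 74 min half-life. The dark decay matches
the closed form $0.5^{\Delta t/t_{1/2}}$ to numerical precision, which
the tests verify at 10 and 74 min.

**Spike trains.** `simulate_train` is a two-state point process: tonic
gamma-renewal firing (shape 10 by default, ISI CV ≈ 0.32 — the regular
pacemaker mode of dopamine neurons) via time rescaling of the cumulative
intensity, plus bursts entered as a Poisson process (1.5/min default)
emitting 3–6 spikes with 25–70 ms intra-burst ISIs. Receptor state
couples to rate as a binary multiplicative gate: when the *cis* fraction
exceeds 0.5, both the tonic and the burst-entry rates are multiplied by
`m_390`. This is deliberately the minimal phenomenological coupling — no
conductance-based dynamics, no desensitization, no network simulation;
type 2 behaviour is generated simply as `m_390 > 1`. Gating the
burst-entry rate by the same factor keeps the photoswitching index
invariant to burst superposition. A 2 ms absolute refractory period is
enforced after merging. The default class effect sizes are traceable to
the reported in vivo group means: type 1 fires 3.41 Hz under 520 nm with
multiplier 1.85/3.41 ≈ 0.54; type 2 fires 3.48 Hz with multiplier
5.25/3.48 ≈ 1.51. The default cohort composition is 28 controls and 93
transduced neurons (60 non-responders, 24 type 1, 9 type 2). A rebound
transient after relief (seen in some type 1 neurons) has no published
kinetics; it is available (`rebound_amp`, `rebound_tau_s`) but off by
default.

Because the 520 nm epochs spend their first ~0.35 s still antagonized
(relief is fast but not instantaneous), the measured index of a type 1
neuron over 5 s alternating epochs sits a few points below the
idealized construction value `100 × (1 − m)/m`; the recovery tests
compare against that construction with a tolerance that covers this
modelled physics plus sampling noise.

**Nicotine transients.** `simulate_nicotine_session` multiplies the
rate by a double-exponential kernel after each injection: 10 s onset
latency, 10 s rise, 300 s decay, peak multiplier `g` (so the peak
percent variation is `100 × (g − 1)`). With these constants the
transient peaks ≈ 45 s post-injection — within the 200 s analysis
horizon — and is broad relative to the 60 s analysis window, as the
slow systemic transients in such recordings are; a narrow kernel would
be systematically underestimated by a 60 s window average, which is a
property of the measurement, not a defect of the estimator. Under the
*cis* state the excursion `g − 1` is scaled by the kernel's antagonism
factor, so an antagonism of 0.4 yields a dark-normalized response of
≈ 40%.

**CPP trajectories.** `simulate_cpp_cohort` builds dwell-block walks
over the two-chamber arena at 20 frames/s. Per-animal pretest bias and
test-session noise are Gaussian; the test-phase paired-side occupancy
equals the pretest occupancy plus the conditioning shift plus noise.
Dwell blocks are quantized to the frame period and rescaled so the
per-zone frame counts realize those occupancies *exactly*, i.e. the
walk is conditioned on its occupancy — so the conditioning shift is the
exact expected preference score and recovery tests are sharp to the
frame period (50 ms). What the generator does not emulate: real
locomotion statistics (path curvature, speed), partial zone entries, or
tracking noise; tests passing on it certify the scoring arithmetic and
pipeline plumbing, not robustness to video-tracking artifacts.

**Currents.** `simulate_current_pairs` draws paired amplitudes whose
expected photo-inhibition index equals the generating fraction, with
mean-one multiplicative noise.

All randomness descends from one explicit seed; cohort generators draw
per-element sub-seeds once from the master stream, so any single neuron
or animal is reproducible in isolation.

## Problem sizes and tolerances

The shipped tests run at the composition above (121-neuron cohorts,
50-neuron recovery groups, 20-seed nicotine recoveries, 2,000-replicate
type-I error checks, 1,000 oracle trains) — sizes at which the checked
quantities have standard errors several times smaller than their
tolerances while the whole suite stays interactive. Closed-form checks
(cis decay, Holm step-down, fixture preference scores) use exact or
near-machine tolerances; stochastic recoveries use 3-standard-error
bands or the stated construction tolerances.

## Known limitations

* Inputs are sorted spike times; nothing upstream of sorting (waveform
  processing, unit isolation quality) is assessed.
* The generator's receptor→rate gate is phenomenological; it cannot be
  used to study kinetic questions (desensitization, rebound mechanism).
* `balance_groups` beyond 16 animals is a heuristic and only guarantees
  improvement over its random start, not the global optimum.
* The per-transition index drops transitions with a silent 390 nm
  flank, which biases it at very low rates; the pooled default does not
  have this failure mode.
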