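---
title: "Analysing spike propagation and stimulus-evoked calcium responses in channel-guided two-node networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing spike propagation and stimulus-evoked calcium responses in channel-guided two-node networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikechannel)
library(dplyr)
```

## The experimental system

`spikechannel` analyses *in vitro* two-node neuronal networks: a source
spheroid (for example retinal) and a target spheroid (for example thalamic)
seeded into the wells of a PDMS microstructure and connected by a single
axon guidance microchannel that runs over a row of MEA electrodes (500 µm
pitch, 30 µm electrode diameter, 25 kHz sampling). Because every spike in
the channel comes from axons of the same bundle, per-electrode spike trains
carry enough information to reconstruct the direction and speed of each
propagating spike without spike sorting. The target spheroid can in
addition express a genetically encoded calcium indicator, so electrical
stimulation of the bundle can be read out optically as a dF/F0 response
that is cleanly separated from presynaptic electrical activity.

The package covers five analysis stages — spike detection, propagation
analysis, network-integrity metrics, calcium response metrics, and Sholl
neurite-outgrowth analysis — plus a synthetic-data module that generates
recordings with known ground truth so that every stage is testable without
access to laboratory data.

## Spike detection

Raw voltage traces are high-pass filtered with a causal second-order
Butterworth filter, cut-off 200 Hz (−3 dB, the usual convention). We apply
the identical single-pass filter to every electrode: each trace then has
the same group delay, so inter-electrode spike latencies — the quantity all
propagation analysis rests on — are unaffected by the (unspecified) phase
behaviour of the filter.

Per-electrode noise is estimated robustly as `σ = 1.4826 × MAD`, which is
consistent for Gaussian noise and nearly insensitive to the spikes riding
on it. We compute σ on the *filtered* trace: the filter removes the slow
drift that would otherwise inflate the MAD, and the detection threshold is
defined on the same signal it is applied to. A spike is a local minimum
below `−5σ`; scanning in time order, any qualifying peak within 3 ms of the
previously accepted spike is discarded, keeping the earliest peak. Two
tie-break rules are fixed deliberately: plateau minima resolve to their
earliest sample, and the dead time is inclusive (a peak at exactly 3 ms is
still merged). Sample indices are 0-based internally; all public interfaces
report seconds.

A degenerate case worth documenting: on a noiseless trace the MAD is 0 and
a 0 threshold would accept everything, so `detect_spikes()` refuses
`sigma = 0` on a non-constant trace. Noise-free fixtures therefore pass an
explicit σ.

## Propagation events, directionality, speed, fidelity

Spikes are grouped into propagation events by greedy, time-ordered
chaining: each yet-unassigned spike starts a chain that is extended
electrode by electrode towards the target end, always taking the earliest
unassigned spike within a 5 ms pairing window of the chain's last spike;
electrodes without a match are skipped, which tolerates per-electrode
dropout. Chains of at least two electrodes become forward events; a mirror
pass over the remaining spikes builds backward events. With 500 µm pitch
the 5 ms window implies a 0.1 m/s minimum speed, matching the slow end of
unmyelinated axonal conduction. Chains with zero time span have no
defensible direction and are labelled ambiguous; they are excluded from the
forward percentage. The greedy scheme is exact when events do not overlap
within the pairing window; overlapping events are resolved
first-come-first-served, which is why the exactness tests use sparse event
rates and denser traffic is only checked statistically.

Conduction velocity is the absolute least-squares slope of electrode
position against spike time over the event's electrodes — with more than
two electrodes this averages timing quantisation better than adjacent-pair
lags — and the per-network speed is the mean over valid events. Events with
zero time span would have infinite speed and are flagged invalid. Channels
with a single in-channel electrode yield no velocity at all, which is why
speeds are only reported for channels of 1 mm and longer.

Conduction fidelity asks how many spikes at the most proximal electrode
reach the most distal one. With expected delay `T = distance / mean speed`,
a proximal spike is conducted if an unmatched distal spike falls within
`[0.5 T, 2 T]` after it (multiplicative rather than additive bounds, so the
window scales with channel length); each distal spike matches at most one
proximal spike, earliest first. The mean speed is taken from the same
recording's event velocities, with a 0.8 m/s fallback when none is
estimable.

The spike-time-triggered histogram (`build_stth()`) shows the same
structure non-parametrically: lags of all other electrodes' spikes within
±5 ms of each trigger spike, binned at 0.2 ms.

Whether a forward percentage should weight events or their constituent
spikes is a genuine choice; we report event-weighted by default and expose
`weight = "spike"`.

## Network integrity

Five visual-inspection criteria gate every network before analysis (the
spheroids stayed in their wells, the bundle stayed in the channel, the
channel covers the electrodes, no growth towards another network, the
bundle reached the first electrode); `apply_inclusion()` reports every
violated criterion and refuses missing flags rather than defaulting them.

An electrode is *active* when its rate is strictly above 1 Hz ("above"
read strictly; exactly 1 Hz is inactive), a network *functionally intact*
when at least 75 % of its electrodes are active (inclusive boundary — both
boundary readings are configurable), and *morphologically intact* when
labelled axons reach the target well. The cohort-level morphological
percentage divides by all networks containing a source spheroid, not only
those passing the inclusion screen. The mean firing rate averages active
electrodes only. Electrode–axon intersection uses the most permissive disk
rule: any mask-positive pixel within the 30 µm electrode disk counts.

## Calcium responses

dF/F0 is `(F − F0)/F0` with `F0` the mean fluorescence over the protocol's
pre-stimulus window, computed per cycle (continuous protocol: the 15 s
spontaneous phase; burst protocol: the 200 ms pre-train window). The peak
evoked response (PER) is the maximum dF/F0 within 5 s of onset (continuous)
or 1 s (burst, inside the 3 s recovery — the protocol leaves this window
open and 1 s comfortably contains the kernel peak). The sustain slope *m*
is the least-squares slope from the PER frame to the end of stimulation,
averaged over cycles; responses with `m ≥ −0.005 s⁻¹` are classified
sustained ("close to zero", made operational as a configurable threshold).
Transmission fidelity is the percentage of cycles whose PER exceeds the
pooled baseline mean by five MAD-derived standard deviations; pooling the
baseline across cycles (rather than per cycle) stabilises the MAD at the
short 200 ms burst baselines. If the baseline is exactly constant the
robust SD is 0 and any PER above the baseline mean counts as detectable.

Stimulation frequency is reported as `1000 / ISI(ms)`; the 32 ms ISI
condition is 31.25 Hz, which presentations round to either 31 or 32 Hz.

## The synthetic-data generators

The generators define the study conditions the tests run under.

**Recordings.** Sixty-second, 25 kHz recordings of channels with electrodes
at 500 µm pitch. Propagation events are a Poisson process (bundle-level
events; no refractory period is modelled), each travelling at a per-event
speed drawn with 5 % jitter around the configured truth and covering the
0.1–2 m/s range the hardware geometry supports. Each non-dropped arrival
injects a 1.2 ms biphasic (negative-then-positive) template whose unique
negative peak lands on the rounded arrival sample, at 8× the noise SD —
spike amplitudes and SNR are not constrained by published values, so the
default is chosen to make default detection near-certain while keeping a
realistic-looking waveform. Electrode noise is white Gaussian (5 µV SD by
default). Per-electrode dropout deletes an event's template from an
electrode with configured probability. All randomness flows through a
single mandatory seed, and identical seeds give bit-identical output.

**Calcium traces.** Fluorescence is a baseline plus per-pulse kernel
responses plus Gaussian noise. The kernel rises with a 50 ms time constant
and decays with 1.5 s, matching fast genetically encoded indicators at the
10 ms frame interval used. Per-pulse efficacy follows a single-pool
depression model: after each pulse the pool loses a fraction *u* and
recovers towards 1 with a 3 s time constant, with utilisation engaging only
above the cutoff frequency, `u(f) = u_max · max(0, 1 − cutoff/f)` and
`cutoff = 32 Hz`. Below the cutoff every pulse acts at full efficacy and
the response plateaus (sustained); above it the pool depletes within
seconds and the response collapses towards baseline after an initial
transient. This is the simplest mechanism that reproduces the
sustained/transient dichotomy with an exact boundary at the cutoff; it is
phenomenological and makes no claim about the biophysical site of the
depression (presynaptic vesicle pools, sodium-channel refractoriness and
indicator saturation would all look similar at this resolution).

**Masks and cohorts.** Neurite masks are a filled disk plus 1-px radial
rays rasterised by rounding densely sampled points of the continuous ray —
the same convention the Sholl shells use, so a shell crossing a ray is
guaranteed to share a pixel with it. Cohorts realise configured
morphological/functional fractions exactly (`round(fraction × n)` networks
get the property), with active electrodes firing at 14 Hz and inactive ones
at 0.2 Hz.

What the generators do *not* emulate — bursting and correlated firing,
electrode-specific noise spectra, stimulation artefacts, waveform variation
across the bundle, indicator saturation, real neurite tortuosity — bounds
what passing tests show: they demonstrate that the estimators recover the
quantities they define under the stated statistical structure, not that
this structure exhausts real recordings.

## Sholl analysis

Concentric shells are drawn from the spheroid edge outwards at 25 µm
intervals; each shell is rasterised (dense angular sampling, consecutive
duplicates removed) and intersections are counted as maximal connected runs
of mask-positive pixels along the ring, with circular wrap-around. Shells
leaving the image truncate the profile with a warning. The summary value is
the maximum count over shells strictly beyond 300 µm from the edge, which
suppresses false positives from dendritic outgrowth near the soma; the
cutoff distance is measured from the spheroid edge, like the shells
themselves. Group comparisons divide each spheroid's maximum by the mean of
the reference-size group within the same experimental repetition, after
removing wall-adherent and multi-spheroid wells. Spheroid centres and edge
radii are taken from annotations; automated spheroid segmentation is out of
scope.

## A worked example

```{r example}
layout <- standard_layout(2) # 2 mm channel, 4 electrodes
spec <- sim_spec(duration_s = 30, event_rate_hz = 3,
                 true_velocity_mps = 0.8, forward_fraction = 0.9,
                 noise_sigma_uv = 5, seed = 7)
sim <- simulate_recording(layout, spec)
trains <- detect_recording(sim$recording)
prop <- analyze_propagation(trains, layout, duration_s = 30)
glance(prop)
```

```{r calcium-example}
p <- stim_protocol("continuous", isi_ms = 32)
sim_ca <- simulate_calcium(calcium_sim_spec(p, seed = 7))
glance(analyze_calcium(sim_ca$trace, p, n_average = 10))
```

## Numerical choices and problem sizes

Detection works on 0-based sample indices and converts to seconds at the
API boundary; the dead time and pairing windows are inclusive at their
upper edge. Velocity regressions use `lsfit`; events with zero time span
are excluded rather than propagating infinities. The calcium kernel is
normalised by its continuous-time peak, so a single pulse of configured
peak 0.3 tops out at 0.3 exactly (up to frame sampling). The test-suite
fixtures use 30–60 s recordings at a few events per second for exactness
checks, and train-level simulations of a few thousand events for the
statistical recovery checks (forward fraction, conduction fidelity) —
large enough that binomial error is well inside the asserted tolerances,
small enough to run comfortably on one core.

## Limitations

The event grouper is greedy and first-come-first-served under overlapping
traffic; it does not model per-axon identity (the hardware cannot resolve
it either). Morphological integrity consumes an annotation flag; the
package does not trace axons into the target well. ROI extraction from
calcium movies and spike inference from calcium are out of scope. The
statistical hypothesis tests used for cohort comparisons (ANOVA, Kruskal–
Wallis, Friedman and post-hoc procedures) are deliberately left to base R
and standard packages.
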