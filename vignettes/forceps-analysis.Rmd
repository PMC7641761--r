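---
title: "Analyzing DNA-forceps synapsis assays with dnaforceps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing DNA-forceps synapsis assays with dnaforceps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnaforceps)
```

## The assay and its observables

Non-homologous end joining (NHEJ) repairs a DNA double-strand break by
physically bridging the two broken ends — *synapsis* — before ligation.
The molecular-forceps assay probes this step one molecule at a time: two
1.5 kbp dsDNA arms face each other tip-to-tip, mimicking a break, and are
held by a dsDNA bridge (6 kbp or 610 bp) covalently anchored 57 bp from
each tip. One side is tethered to a glass surface and the other to a
magnetic bead through 1 kbp handles. The force protocol alternates a low
force (~0.01 pN, letting the tips meet in the presence of NHEJ factors)
with a 1.4 pN test force per pulling cycle.

If the tips are synapsed when the force rises, the tension path shortcuts
through the joined tips and the bridge loops out of the tether: the bead
sits *below* its open-construct position by an extension deficit
$\Delta l$ until the synapse ruptures. Each rupture event is characterized
by its amplitude $\Delta l$ and its dwell time at high force,
$t_\mathrm{synapsis}$.

## Worm-like-chain expectation for the rip amplitude

The expected amplitude at force $F$ follows from the worm-like chain.
We use the Marko–Siggia interpolation for the fractional extension
$x = \ell/L_0$:

$$\frac{F P}{k_B T} = x + \frac{1}{4 (1 - x)^2} - \frac{1}{4},$$

inverted by bracketed bisection on $[0, 1)$ to an interval width of
$10^{-9}$ (the left side is strictly increasing, so the root is unique
and bisection is unconditionally convergent and deterministic). The
interpolation is a few percent accurate around 1.4 pN, which is all the
3σ amplitude classifier needs. Defaults are conventional dsDNA values —
persistence length $P = 50$ nm, rise 0.34 nm/bp, $k_B T = 4.11$ pN·nm
(room temperature) — all configurable, since the temperature and $P$
behind any particular instrument calibration are rarely reported.

The amplitude model counts only the bridge bypass,
$\Delta l = x(F)\, r\, (L_\mathrm{bridge} - 2 d_\mathrm{anchor})$:
nick/gap elasticity at the tips and handle compliance are ignored, which
matches the magnitude of measured amplitudes.

```{r wlc}
wlc_relative_extension(1.4)
expected_amplitude(forceps_construct(bridge_length = 6000), 1.4)  # nm
expected_amplitude(forceps_construct(bridge_length = 610), 1.4)   # nm
```

The 6 kbp prediction (~1754 nm) sits a few percent above the ~1700 nm
scale observed for that construct; the 610 bp prediction (~148 nm) falls
inside the 123–159 nm range measured across the short-bridge conditions.

## What the synthetic traces emulate — and what they do not

`simulate_trace()` generates traces under the study conditions with
planted ground truth, so every downstream stage is testable without
instrument data:

* **Per-cycle events.** At force-up, a cycle carries at most one event:
  specific synapsis with probability `p_specific` (amplitude
  $\mathcal{N}(\Delta l_\mathrm{expected}, \sigma_\mathrm{sp})$, lifetime
  $\mathrm{Exp}(\tau)$) or a surface-proximal nonspecific interaction with
  probability `p_nonspecific` (its own amplitude peak, default
  387 ± 54 nm, and lifetime law, exponential with 2 s mean — only the
  amplitudes of this class are ever analyzed). One event per cycle
  matches the per-cycle accounting of the assay.
* **Condition presets.** `condition_presets()` ships the seven standard
  condition mixes with generative values transcribed from the measured
  per-cycle rates, fitted lifetimes and peak widths. These are inputs for
  recovery tests, not measurements. One condition reports more synaptic
  events (356) than total events (350) in its source counts — an apparent
  transcription slip — so its preset uses the synaptic count with no
  nonspecific channel, and the count invariant is enforced on all
  pipeline output.
* **Censoring.** An event whose drawn lifetime exceeds the high phase is
  planted censored: the deficit persists to the end of the cycle with no
  rupture step. In the simulator the next cycle starts open, whereas a
  real censored synapse ruptures in a later cycle; this simplification
  does not touch the detection or bookkeeping contract.
* **Noise.** Additive Gaussian per sample (defaults 15 nm at high force,
  60 nm at low force — bead tracking is not quantified in the source
  assay, so these are plausible camera-tracking figures), plus optional
  linear drift. Sampling defaults to 30 Hz, typical of camera-based
  tracking.
* **Low force.** The low-force level is the open-construct WLC extension
  at 0.01 pN with larger noise; events are latent at low force and appear
  only as a deficit at force-up, since only the high-force phase is
  analyzed. (The source protocol states the low force variously as 1 fN
  and 0.01 pN; 0.01 pN is the default and it is configurable.)

Not emulated: Brownian bead dynamics, camera blur, multiple tethers,
sub-second kinetic substates, and ligation chemistry (a ligated construct
is representable as a permanently censored event, nothing more). Passing
recovery tests on these traces therefore demonstrates that the analysis
is correct *given* the event model — not that the event model captures
every artifact of real bead data, whose reproduction is out of scope.

## Event detection

`segment_cycles()` splits the force channel into high phases and
estimates the open-state baseline as the median of the top quartile of
high-force extension samples — robust even when ~20% of cycles carry
events. Note that on noisy data this estimator sits ~1.15 noise-SD above
the true open level (it is an 87.5th percentile); measured amplitudes
inherit that small offset, which is negligible against the 3σ
classification windows.

`detect_events()` declares an event when the smoothed extension at
force-up starts below `baseline − k_detect × noise_sd` and locates the
rupture at the first recovery that stays above threshold for at least
`dwell_min` samples. Numerical choices, since the source analysis does
not state its smoothing, threshold or rupture localization:

* **Smoothing**: centered moving median over 0.5 s within each high
  phase (robust to single-sample outliers, preserves step edges), with
  raw values kept at the phase boundaries — so a synapse that ruptures
  within one smoothing window of force-up still registers, and short
  dwell times are not truncated away.
* **Threshold**: `k_detect = 5` noise-SD with `dwell_min = 3` samples of
  hysteresis, controlling false positives over 120 s phases.
* **Rupture time**: midpoint between the last bound and first recovered
  sample, making the reported duration unbiased with respect to the
  sampling grid (error at most half a sample interval); on noiseless
  traces durations are exact to one sample and amplitudes to < 1 nm.
* **Multiple apparent steps** in one cycle end at the first durable
  recovery; partial intermediate recoveries are ignored (cycles, not
  sub-events, are counted).
* **Baseline** is per-molecule by default; a per-cycle option exists for
  drifting traces.

`classify_events()` applies the specificity rule: an event is specific
synapsis iff $|\Delta l - \Delta l_\mathrm{expected}| \le 3\sigma$. The
source of $\sigma$ is the pipeline's most consequential hidden parameter:
`run_pipeline()` takes it from the specific component of the amplitude
mixture fit when at least 50 candidate events support one, otherwise from
the condition preset, and records the choice in the run log.

## Distribution fits

**Amplitude mixture.** `fit_double_gaussian()` fits a two-component
Gaussian mixture by EM on the raw amplitudes — the binning behind any
histogram display is immaterial to the estimate (a histogram least-squares
mode exists for visual parity with binned figures). Initialization is
deterministic: ten quantile-split restarts, best log-likelihood kept,
ties broken by the smaller sum of component SDs. Component counts are
rounded posterior-responsibility sums; peaks are reported in descending
mean order so the specific (WLC-scale) peak comes first. Degenerate
all-equal input collapses both components onto that value.

**Lifetimes.** `fit_exponential_lifetime()` is the exponential MLE over
uncensored specific events: mean of the dwell times, with
$\mathrm{SEM} = \hat\tau/\sqrt{n}$. Censored events are excluded
outright — their lifetime is unknown — matching how the assay's summary
statistics treat them. (Printed SEMs in the source tables are not
internally consistent with any single estimator we could identify, so
this package defines its estimator explicitly.) A censoring-aware option
adds censored observation times to the numerator only (total time at
risk), the censored-exponential MLE; it is never used by the condition
summaries.

**Binding curves.** `fit_binding()` fits
$\theta(L) = L^h / (K_d^h + L^h)$ ($h \equiv 1$ for single-site) by
bounded Levenberg–Marquardt with $K_d$ on a log scale. Because
thermophoresis titrations are normalized fraction-bound, the plateaus
default to 0 and 1; with the standard 16-point dilution series from
93 μM only a couple of points sit below 20% saturation, so freeing the
lower plateau mostly trades baseline against Hill slope and widens the
spread of $\hat h$ by half again. `baselines = "free"` fits both plateaus
for un-normalized signals. A fit whose signal range is under three
residual SDs is rejected as unidentifiable.

## Condition summaries

`summarize_condition()` reproduces the per-condition accounting:
efficiency $= 100 \times$ synaptic events / pulling cycles, printed with
one decimal below 10% and as an integer above (the rounding that
reproduces the reported values from their raw counts); AMP from the
specific mixture component and DUR from the lifetime fit when at least
50 synaptic events exist, arithmetic averages otherwise; censored events
count toward efficiency but never toward DUR, so the lifetime point count
can be smaller than the synaptic count. `compare_conditions()` is plain
arithmetic on two rows (lifetime and efficiency ratios), refusing
cross-construct comparisons.

## A small end-to-end run

```{r pipeline}
cfg <- default_config()
cfg$conditions <- c("DPK+LINP1_0.6kbp", "DPK+PAXX_0.6kbp")
cfg$protocol$sampling_rate <- 5
summ <- run_pipeline(cfg, seed = 42,
                     n_cycles_override = c("DPK+LINP1_0.6kbp" = 400L,
                                           "DPK+PAXX_0.6kbp" = 400L))
summ[, c("condition", "n_cycles", "n_events", "n_synaptic",
         "efficiency", "dur_mean", "dur_sem")]
compare_conditions(summ[1, ], summ[2, ])
```

## Problem sizes and reproducibility

Everything that draws random numbers takes an explicit seed and is
byte-reproducible from it; `run_pipeline()` derives one sub-seed per
condition. Full-scale traces (thousands of 240 s cycles) are simulated at
reduced sampling rates where full camera rate would only add memory: the
calibration suite runs 20 seeded replicates per condition at 4 Hz, and
the reproduction script samples at 10 Hz — lifetimes of seconds are
resolved to 0.1 s, and the midpoint rupture convention keeps the
estimate unbiased at any rate. The sampling rate is a configuration key
like any other.

## Known limitations

* The amplitude model ignores tip and handle elasticity; the WLC
  interpolation itself is only a few-percent accurate at 1.4 pN.
* Detection assumes the two-level force protocol; free-form force ramps
  are not segmented.
* The mixture fit is strictly two-component; conditions with more
  amplitude classes would need an extended model.
* Simulated censored events end with their cycle, so cross-cycle rupture
  statistics cannot be studied on synthetic data.
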