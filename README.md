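# dnaforceps

Analysis of single-molecule "molecular forceps" assays of DNA
double-strand-break end synapsis by non-homologous end joining (NHEJ),
for biophysicists running (or reanalyzing) magnetic-tweezer experiments
on forceps-style DNA constructs.

The forceps construct mimics a double-strand break: two 1.5 kbp dsDNA
arms face each other tip-to-tip, held by a dsDNA bridge (6 kbp or 610 bp)
anchored 57 bp from each tip, with 1 kbp handles tethering the assembly
between a glass surface and a magnetic bead. Pulling cycles alternate a
low force (~0.01 pN, the ends may meet in the presence of NHEJ factors)
with a 1.4 pN test force. A synapsed construct shows an extension deficit
Δl at force-up that vanishes when the synapse ruptures after a dwell time
t_synapsis.

The package covers the complete analysis chain:

* **Worm-like-chain amplitude prediction** — the Marko–Siggia
  interpolation `F·P/kBT = x + 1/(4(1−x)²) − 1/4`, inverted by bisection,
  gives the expected rip amplitude
  `Δl = x(F) · 0.34 nm/bp · (bridge − 2·57 bp)`.
* **Synthetic traces with planted ground truth** (`simulate_trace()`):
  per-cycle exponential-lifetime events, a surface-proximal nonspecific
  amplitude class, censoring, Gaussian tracking noise, all seeded and
  byte-reproducible; presets for the seven standard condition mixes.
* **Event detection and classification** (`segment_cycles()`,
  `detect_events()`, `classify_events()`): robust baseline, median
  smoothing, 5σ detection with hysteresis, and the 3σ amplitude rule
  separating specific synapsis from surface-proximal events.
* **Fits** (`fit_double_gaussian()`, `fit_exponential_lifetime()`,
  `fit_binding()`): two-component Gaussian EM deconvolution of rupture
  amplitudes, censoring-aware exponential lifetimes, and single-site /
  Hill binding fits for thermophoresis titrations.
* **Condition summaries** (`run_pipeline()`, `summarize_condition()`,
  `compare_conditions()`): synaptic efficiency (synaptic events /
  pulling cycles), AMP and DUR statistics with the small-n arithmetic
  fallback, YAML-configurable end-to-end runs with CSV/JSON artifacts.

## Worked example

```r
library(dnaforceps)

# WLC expectation for the 6 kbp-bridge construct at 1.4 pN
expected_amplitude(forceps_construct(bridge_length = 6000), 1.4)
#> [1] 1754.193

# end-to-end on two short-bridge conditions (scaled down to 400 cycles)
cfg <- default_config()
cfg$conditions <- c("DPK+LINP1_0.6kbp", "DPK+PAXX_0.6kbp")
cfg$protocol$sampling_rate <- 5
summ <- run_pipeline(cfg, seed = 42,
                     n_cycles_override = c("DPK+LINP1_0.6kbp" = 400L,
                                           "DPK+PAXX_0.6kbp" = 400L))
summ[, c("condition", "n_cycles", "n_events", "n_synaptic",
         "efficiency", "dur_mean", "dur_sem")]
#>          condition n_cycles n_events n_synaptic efficiency dur_mean dur_sem
#> 1 DPK+LINP1_0.6kbp      400       47         26        6.5    6.008   1.018
#> 2  DPK+PAXX_0.6kbp      400       93         76       19.0    2.789   0.320

compare_conditions(summ[1, ], summ[2, ])
#> $lifetime_ratio   [1] 2.154
#> $efficiency_ratio [1] 0.342
#> $longer_lifetime  [1] "DPK+LINP1_0.6kbp"
```

Read: with the 610 bp bridge, the LINP1 condition synapses in 6.5% of
cycles versus 19% for PAXX at this scale, but each synapse survives about
twice as long (6.0 s vs 2.8 s here; the generative lifetimes are 4.8 s
and 2.3 s, and these 26- and 76-event estimates carry SEMs of ~1.0 s and
~0.3 s) — the lifetime ordering, not the efficiency, is what
distinguishes the RNA-stabilized synapse.

A binding titration:

```r
bc <- simulate_binding_curve("hill", kd = 19e-9, hill_h = 1.75,
                             noise_frac = 0.02, seed = 7)
fit_binding(bc, "hill")
#> Hill binding fit (n = 16): Kd = 1.98e-08 M, h = 1.71
```

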