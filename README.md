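# chronicsense

Analyses for **chronic neural sensing with fully implanted DBS
stimulation-and-recording systems** in the limbic (Papez) circuit —
hippocampus (HC), fornix (FX) and anterior nucleus of the thalamus (AN).
The package is aimed at electrophysiologists and device researchers who
need the standard longitudinal sensing readouts as tested, reproducible
code:

* **Evoked potentials (EPs)** — stimulus-artifact-triggered epoch
  averaging with artifact blanking and optional peak alignment; main-peak
  latency/amplitude/polarity metrics (hippocampal EPs to thalamic
  stimulation carry a 35–40 ms main peak).
* **LFP spectra** — Welch/Hann power spectral density reported as
  amplitude spectral density in uV/sqrt(Hz), spectrograms on a 40 dB
  logarithmic scale, band power, and peak frequency (theta-dominant
  hippocampal LFP peaks at 4–5 Hz).
* **Directional lead analysis** — the canonical 15-bipolar-pair sensing
  montage of 1-3-3-1 leads, per-segment band-power ranking, per-minute
  post-stimulation suppression profiles against a 20 s baseline, and
  rank concordance (R² with signed r).
* **Burst-response classification** — post- vs pre-burst power ratios
  label each stimulus burst `none` / `suppression` / `after_discharge`
  and estimate the inhibitory (0.6 V) and after-discharge (1 V)
  thresholds of an amplitude ramp.
* **Network coupling** — spike-event detection and event-matched
  cross-correlation lag: HC sharp waves arrive in AN 30–40 ms later
  (propagated), while sleep K-complexes are zero-lag, small-amplitude
  far-field events at the HC site.
* **Device health** — |Z| = |V/I| impedance from the constant-current
  test pulse, longitudinal stabilization/level trending, stimulated vs
  sense-only contact ratio (2–3x), and breakage flagging.
* **A seeded synthetic cohort generator** (`gen_params`, `generate_lfp`,
  `generate_stim_session`, `generate_cohort_timeline`) that emulates all
  of the above so every stage is testable without any data download.

## Worked example

```r
library(chronicsense)

p <- gen_params(seed = 42)

# spontaneous theta-state LFP and its spectrum
rec <- generate_lfp(p, 30, state = "theta")
psd <- power_spectral_density(rec, "HC_E0-E3")
peak_frequency(psd, c(2, 12))
#> theta peak: 4.5 Hz

# evoked potentials from a 5 Hz / 30 s / 4 V thalamic train
ses  <- generate_stim_session(p, stim_setting(4, "V", 5, 120, 30), "ep_train")
trig <- detect_stim_artifacts(ses$recording, "HC_E0-E3")
average_epochs(ses$recording, trig, "HC_E0-E3", align_to_peak = TRUE)
#> <evoked_potential> 150 epoch(s); main peak 45.6 uV (+) at 36.8 ms

# amplitude-ramp burst responses (0.4 / 0.6 / 0.8 / 1.0 V)
br  <- generate_stim_session(p, stim_setting(1, "V", 50, 120, 10), "burst_ramp")
cls <- classify_burst_responses(br$recording, br$events)
cls$responses
#>   burst_amplitude           label post_pre_power_ratio   ad_ratio
#> 1             0.4            none            1.0231563  1.0215569
#> 2             0.6     suppression            0.2605863  0.2587583
#> 3             0.8     suppression            0.2509618  0.2511197
#> 4             1.0 after_discharge           11.0475543 11.0334727
c(cls$theta_inh, cls$theta_ad)
#> inhibitory threshold: 0.6 V; after-discharge threshold: 1 V

# hippocampo-thalamic propagation lag from a sharp-wave session
net <- generate_lfp(gen_params(seed = 7), 120, state = "sharp_wave")
ev  <- detect_spike_events(net, "HC_E0-E3")
estimate_lag(net, "HC_E0-E3", "AN_E0-E3", ev$time)
#> <coupling_estimate> HC_E0-E3 -> AN_E0-E3: lag 36.1 ms, ratio 0.60, propagated (57 events)
```

Read: the 150-epoch average recovers the EP main peak at 36.8 ms (the
generator planted 37 ms); the burst ramp shows no effect at 0.4 V,
~4x power suppression at 0.6–0.8 V, and a large after-discharge at
1.0 V, so the estimated thresholds are 0.6 V and 1.0 V; sharp-wave
events reach the thalamus a median 36.1 ms after the hippocampus at
0.60 relative amplitude — a propagated, not far-field, pattern.

The end-to-end pipeline (`run_pipeline(list(seed = 11), out_dir = "out")`)
chains all stages and writes tidy CSVs, `summary.json` and a log;
re-running the same config reproduces every numeric output bit-for-bit.
A command-line wrapper lives at `exec/chronicsense`
(`simulate | spectra | ep | rank | suppress | couple | impedance | run`).

## Documentation

The methods vignette
(`vignettes/chronic-sensing-methods.Rmd`) describes the signal model,
every declared default and tolerance, and what green tests do and do not
establish.
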