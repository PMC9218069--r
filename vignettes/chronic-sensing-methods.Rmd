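---
title: "Methods: chronic DBS sensing analyses and their synthetic test bed"
author: "chronicsense"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chronic DBS sensing analyses and their synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronicsense)
```

## Scope and model

`chronicsense` implements the analysis chain used with fully implanted
DBS stimulation-and-recording systems sensing in the limbic (Papez)
circuit — hippocampus (HC), fornix (FX) and anterior nucleus of the
thalamus (AN): evoked-potential (EP) extraction triggered on the stimulus
artifact, Welch/Hann spectral quantification of local field potentials
(LFPs), ranking of segmented contacts on directional (1-3-3-1) leads,
stimulation-induced suppression and after-discharge classification,
cross-site event-lag estimation, and electrode impedance trending.

Because chronic in-vivo recordings of this kind are not publicly
deposited, the package ships a first-class seeded generator that emulates
the statistical structure those analyses assume. The generator is a
*stated world*: its defaults encode the physiologic ranges the analyses
are designed around, and the test suite measures whether the analysis
chain recovers them. A green test therefore establishes that the
*procedures* behave as specified on signals with the right structure — it
does not re-establish any in-vivo result, and the in-vivo concordance
values (R² of 0.1–0.8 between power rank and suppression rank) are
explicitly out of scope because they depend on the unavailable animal
data.

## The signal model

All channels are bipolar contact pairs in microvolts at a default 250 Hz
sampling rate (the device family records at 200–800 Hz with 0.5 Hz
high-pass and 100 Hz low-pass hardware filters; the generator applies the
same band edges, and channel labels follow the `LEAD_Ex-Ey` dialect).

The hippocampal-like source alternates among three behavioural states
under a Markov process with exponential dwell (default mean 20 s each):

* **theta** — a narrowband oscillation at `theta_f0` (default 4.5 Hz,
  constrained to the 4–5 Hz interval in which the dominant peak is
  observed), amplitude 40 uV, amplitude-modulated at depth 0.3 so the
  line is not unrealistically pure, over 1/f background noise
  (`noise_sd` = 10 uV, slope alpha = 1, realised by frequency-domain
  shaping of white Gaussian noise);
* **sharp wave** — biexponential transients (5 ms rise, 40 ms decay),
  Poisson rate 0.5/s, lognormal amplitude jitter (median 150 uV,
  sdlog 0.3). Each event reappears on the thalamic channel `net_lag` ms
  later (default 36 ms, constrained to 30–40 ms) at amplitude ratio 0.6;
* **sleep** — K-complexes: ~0.7 s biphasic waves local to the thalamic
  site (200 uV, Poisson 0.1/s), with a *zero-lag* far-field copy at the
  hippocampal site at ratio 0.15.

Directional-lead channels are scaled by the mean gain of their two
contacts (`segment_gains`, ring contacts fixed at 1; default gains make
E2b the strongest direction). Channel noise of 3 uV white is added per
channel.

Stimulation sessions add, depending on protocol: one-sample biphasic
stimulus artifacts at 10x the theta amplitude (so artifact detection is
unambiguous at default SNR); EP templates on hippocampal channels with a
Gaussian main peak at `ep_latency` (default 37 ms, the observed 35–40 ms
range) whose amplitude is sigmoidal in stimulation voltage with half-max
at `ep_threshold` (3 V within the 1–7 V train range); post-burst power
suppression by factor `supp_factor` (0.25) above the inhibitory threshold
(`theta_supp` = 0.6 V) with duration growing with amplitude; and a 4 s
large 2–8 Hz after-discharge above `theta_ad` (1 V). The directional
sweep stimulates each segmented contact once (seeded random order,
monopolar 1 mA / 100 Hz / 300 us / 10 s, 20 s baseline) and suppresses
the lead's ongoing LFP with depth proportional to the stimulated
contact's gain. Suppression depth, after-discharge duration and spectral
content are declared generator defaults — the source material describes
these effects qualitatively only — and sweep blocks are sized so one
step's suppression and 60 s recovery ramp never contaminate the next
step's baseline.

Impedance per contact stabilizes exponentially (time constant 1.5 months,
i.e. ~6 weeks) from 1.8x toward a plateau of 1200 Ohm for sense-only
contacts and 1200/2.5 Ohm for chronically stimulated ones (the reported
long-term factor is 2–3), with 3% lognormal measurement noise. A
scheduled breakage sets the contact to open circuit (1 MOhm, above the
50 kOhm ceiling) and every channel containing it to flat amplifier noise.

Everything is driven by a single integer seed; identical seed and
parameters give bit-identical output. Per-stage seeds are derived
deterministically so pipeline stages are independently reproducible.

## Analysis conventions and numerical choices

* **Spectra.** Welch-averaged periodograms with a Hann window, 4 s
  segments and 50% overlap (df = 0.25 Hz, enough to resolve a 4–5 Hz
  peak; the original processing names only the window, so segment length
  and overlap are declared here). The canonical stored quantity is the
  *amplitude* spectral density in uV/sqrt(Hz), the field's axis
  convention; band power integrates the squared density by the
  trapezoidal rule with exact interpolated band edges, so adjacent bands
  tile additively. Spectrogram values are 10·log10 of power density re
  1 uV²/Hz, display-clipped to a 40 dB dynamic range; a hard floor of
  1e-12 keeps all-zero input finite. Peak frequency ties break toward
  the lower frequency.
* **Evoked potentials.** Triggers are threshold crossings of the
  differentiated signal at 8x its MAD with a 50 ms refractory period
  (pulses closer than that merge — a documented limitation). Epochs use a
  −10 to +100 ms window; 0–5 ms after the trigger is blanked by linear
  interpolation (the artifact itself is the trigger, and its shape should
  not enter the average). Optional peak alignment shifts each epoch up to
  ±5 ms to maximise correlation with the plain average. The main peak is
  the largest-|value| extremum in the search window; its latency is
  refined by three-point quadratic interpolation because the 4 ms sample
  grid at 250 Hz is coarser than the ±1 ms recovery the latency metric
  is held to. Burst responses compare 5 s post- vs pre-burst band power:
  a 2–8 Hz excursion above 3x baseline is an after-discharge (takes
  precedence); a ratio strictly below 0.7 is suppression; the numeric
  criteria are declared defaults, as the source describes the effects
  only qualitatively.
* **Directional analysis.** The 15-pair montage is fixed (ring-to-E1
  segments, within-level angular pairs, corresponding segments,
  E2-segments-to-ring), recorded as three 5-pair groups of 40 s. Power is
  attributed to a segmented contact as the *mean band power over all
  montage pairs containing it* — no canonical attribution exists, so the
  referencing scheme is declared; ranking uses 3–8 Hz by default
  (capturing the theta peak), ties break by contact name and are flagged.
  Suppression profiles take the median band power over 2 s sub-windows
  (30 per minute) of the 20 s baseline and of each post-stimulation
  minute; dispersion is the s.d. across sub-windows (the across-sub-window
  reading of the ambiguous "median (avg/s.d.)" convention). Concordance
  between two rankings is the squared Pearson correlation of rank vectors
  (= squared Spearman without ties); because R² is direction-blind, the
  signed correlation is reported alongside.
* **Network coupling.** Spike events are MAD-thresholded (6x) on the
  1–30 Hz band-limited trace with a 200 ms refractory period; amplitudes
  are read from the raw trace at the detected index so the detection
  filter does not attenuate them. Per event, the lag is the argmax of the
  normalized cross-correlation between windows on the two channels
  (default ±100 ms), refined to sub-sample precision by quadratic
  interpolation of the correlation peak; the summary lag is the median
  across events. Classification: propagated when the median lag reaches
  the 8 ms simultaneity bound (two samples at 250 Hz) with amplitude
  ratio ≥ 0.4; far-field when |lag| is below the bound with ratio < 0.4;
  uncoupled otherwise, *and* whenever the interquartile range of
  per-event lags exceeds 30 ms — consistent timing across events is what
  evidences coupling, and band-limited noise correlates too strongly for
  a correlation-magnitude gate to separate chance alignment. For slow
  (~0.7 s) K-complexes the correlation window should be matched to the
  event duration (0.3 s is used in the pipeline); the default 100 ms
  window sees only a locally smooth segment and yields a flat correlation
  peak with tens of milliseconds of argmax jitter.
* **Impedance.** |Z| = |V/I| from the constant-current test pulse
  (100 Hz, 80 us). Trend stabilization is the first month after which
  every rolling relative change of a 3-point rolling median stays below
  10%; breakage is an excursion above 50 kOhm or a month-over-month step
  beyond 5x (both declared, as only qualitative patterns are reported).

## Design decisions that were genuinely open

* No EDF library exists in the supported dependency set, so the
  interchange format is the documented plain-text CSV bundle
  (`manifest.json`, `samples.csv`, `events.csv`); EDF support was dropped
  rather than hand-rolling a binary writer.
* The V-vs-mA amplitude mode is carried explicitly and never converted;
  response thresholds are defined in the mode they were measured in.
* The generator treats fornix leads as hippocampal-like sources; the
  device-to-channel mapping is configuration, never inference.
* Sham stimulation (amplitude 0) is representable so null-protocol tests
  can compare a "stimulated" session with the identical spontaneous
  background.

## Known limitations

* The generator is phenomenological: no conductance-based dynamics, no
  behavioural-state covariates, no electrode drift, and the 1/f
  background is stationary within a state. Recovery rates measured here
  will overestimate in-vivo performance; in particular the gain-driven
  power/suppression concordance (R² ≥ 0.8 in expectation) reflects
  noiseless coupling in the generator, deliberately stronger than any
  reported in-vivo value.
* Trigger detection merges pulses within the refractory period and the
  latency metric inherits a few milliseconds of absolute uncertainty from
  using the artifact as the trigger, mirroring the real constraint.
* Impedance values are generator defaults informed by the cited
  literature; absolute levels are not analysis targets, only their
  temporal pattern and ratios.
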