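# ppghrv

Offline detection of heartbeat-to-heartbeat (RR) intervals in
photoplethysmography (PPG) signals — including smartphone-camera
recordings — with built-in identification of corrupted signal parts, and
estimation of the basic heart-rate-variability (HRV) metrics SDNN and
RMSSD from the intervals that survive.

It is intended for anyone extracting resting HRV from raw PPG traces:
wearable/ mHealth researchers, physiological-signal engineers, and
students of biomedical signal processing. It is **not** suitable for
exercise recordings, where PPG peak-to-peak intervals stop tracking ECG
RR intervals.

## Method in brief

For a uniformly resampled, cleaned signal `x_n` (100 Hz):

* **Heart-rate curve.** The STFT spectrogram
  `S[k, j] = |Σ_n x_n e^{-2πi f_k t_n} Δt|²` (5 s rectangular window,
  stride 0.5 s, 80 frequencies on [0.5, 3.3] Hz) is convolved with a fan
  kernel that highlights curves with bounded slope; the heart-rate
  frequency `hrf(t)` is traced along column local maxima with
  exponential-smoothing re-initialisation.
* **Beats as wavelet ridge lines.** The scalogram
  `W[k, n] = Σ_m x_m a_k^{-1/2} ψ((t_m − t_n)/a_k) Δt` with the Mexican
  hat `ψ(t) ∝ (1 − t²) e^{-t²/2}` is computed on 50 geometric scales
  `a_k = 0.05·1.0376^{k−1}` s. Per-scale local maxima (*ridge points*)
  are linked across scales into *ridge lines*; lines persisting from
  scale ≥ 0.244 s up to ≤ 0.069 s are beats, and shorter lines are added
  greedily when they increase the log-normal likelihood
  `−(1/k) Σ (log rr_i − log(1000/hrf_i))²` of the interval set. Beat
  positions are the line tops at the smallest scale.
* **Quality filtration.** Each interval is scored by
  `q = q_sim · q_cwt`: self-similarity of neighbouring intervals
  (correlation × amplitude-ratio sigmoid) times the stability of the
  bounding ridge lines' separation across scales. Intervals below an
  adaptive threshold (`argmax_i i·q'_i` over the descending qualities
  above 0.8) or flagged by interval-length outlier rules are discarded;
  `discarded ratio = n_discarded / n_total` summarises signal quality.
* **Output choice.** The pipeline runs on every channel and both signal
  polarities; the result with the smallest discarded ratio wins.

SDNN is the population standard deviation of the kept intervals; RMSSD
is the RMS of successive differences (differences never span a discarded
gap).

## Worked example

```r
library(ppghrv)

# 120 s synthetic smartphone record (30 fps, SNR 20 dB) with known truth
sr  <- synth_record(synth_spec(seed = 1))
res <- analyze_recording(sr$record)
res
#> ppg_analysis: best channel G, polarity pos
#> rr_analysis: 136 intervals detected, 136 kept (discarded ratio 0.000)
#>   SDNN 39.12 ms, RMSSD 33.82 ms

evaluate_against_reference(res$best, sr$truth$rr_ms)
#> $rr_mae_ms    9.99
#> $sdnn_ae_ms   1.28
#> $rmssd_ae_ms  7.19
#> $n_matched    137
#> $n_detected   137
#> $n_reference  139
```

The clean green channel wins at positive polarity with nothing
discarded; detected intervals reproduce the ground-truth SDNN to ~1 ms
and individual intervals to ~10 ms — the residual comes from the 30 fps
capture and the injected 20 dB noise, not from missed beats (137 of 139
reference beats matched; the two missing ones sit in the boundary margin
at the very edges of the recording).

A command-line front end is installed as `exec/ppg-hrv`:

```sh
ppg-hrv synth --spec spec.json --out record.json --truth truth.json
ppg-hrv analyze record.json --out json          # summary + intervals
ppg-hrv analyze record.json --out csv           # per-interval qualities
ppg-hrv evaluate detected.json reference.csv
```

Welltory-style records (JSON or CSV with `Time`, `R`, `G`, `B`, and
optional reference `RR` arrays) and generic two-column
`time_ms,value` CSVs are read natively.

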