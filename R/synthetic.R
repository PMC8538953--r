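# Synthetic PPG with known ground truth: log-normal AR(1) RR intervals,
# a two-Gaussian pulse template, baseline drift, additive noise and
# controllable corruption segments.

#' Specification of a synthetic PPG recording
#'
#' Defaults emulate a ~2 minute resting smartphone measurement: beats
#' around 850 ms with SDNN 50 ms and RMSSD 30 ms, an asymmetric pulse with
#' a dicrotic wave, slow baseline wander, 20 dB additive noise, captured
#' at 30 frames per second in the (0, 255) colour range.
#'
#' @param duration_s recording length in seconds.
#' @param capture_hz camera frame rate of the emitted record.
#' @param mean_ms,sdnn_ms,rmssd_ms targets of the log-normal AR(1)
#'   interval model.
#' @param pulse_width_s Gaussian width (sd) of the systolic upstroke; the
#'   downstroke decays with twice this width, giving the sharp-peak /
#'   slow-decay asymmetry of a real pulse wave.
#' @param dicrotic_delay_s,dicrotic_amp,dicrotic_width_s delayed smaller
#'   Gaussian modelling the dicrotic wave (amplitude relative to the
#'   systolic peak).
#' @param noise_snr_db signal-to-noise ratio of the additive Gaussian
#'   noise, in dB relative to the pulse train.
#' @param drift_amp baseline wander amplitude relative to the pulse
#'   amplitude.
#' @param drift_freq_hz baseline wander frequency.
#' @param corruption list of corruption segments, each
#'   `list(start_s=, end_s=, kind=)` with kind one of `"white_noise"`,
#'   `"constant"`, `"step"`.
#' @param seed integer seed; the generator is deterministic given the
#'   spec.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(duration_s = 120, capture_hz = 30, mean_ms = 850,
                       sdnn_ms = 50, rmssd_ms = 30, pulse_width_s = 0.08,
                       dicrotic_delay_s = 0.25, dicrotic_amp = 0.35,
                       dicrotic_width_s = 0.1, noise_snr_db = 20,
                       drift_amp = 0.5, drift_freq_hz = 0.1,
                       corruption = list(), seed = 1L) {
  spec <- structure(as.list(environment()), class = "synth_spec")
  for (seg in corruption) {
    stopifnot(seg$start_s >= 0, seg$end_s <= duration_s,
              seg$kind %in% c("white_noise", "constant", "step"))
  }
  spec
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a ground-truth RR interval sequence
#'
#' First-order autoregressive process on log-RR, tuned so that the
#' realised SDNN and RMSSD approach the spec's targets: with
#' `s = sdnn/mean` the log-sd and `phi = 1 - rmssd^2 / (2 sdnn^2)` the
#' lag-1 autocorrelation, the stationary process has sd(rr) ~ sdnn and
#' rms successive difference ~ rmssd. Deterministic given the seed.
#' Intervals are clipped to the physiological range \[300, 2000\] ms.
#'
#' @param spec a [synth_spec()].
#' @return RR intervals in ms covering the spec duration.
#' @export
generate_rr <- function(spec) {
  n <- ceiling(spec$duration_s * 1000 / spec$mean_ms) + 2L
  if (spec$sdnn_ms == 0) return(rep(spec$mean_ms, n))
  s <- spec$sdnn_ms / spec$mean_ms
  phi <- 1 - spec$rmssd_ms^2 / (2 * spec$sdnn_ms^2)
  if (phi < -1) {
    stop("infeasible targets: rmssd too large relative to sdnn", call. = FALSE)
  }
  z <- with_seed(spec$seed, {
    e <- stats::rnorm(n)
    z <- numeric(n)
    z[1L] <- e[1L] * s
    innov_sd <- s * sqrt(max(1 - phi^2, 0))
    for (i in seq_len(n - 1L)) z[i + 1L] <- phi * z[i] + innov_sd * e[i + 1L]
    z
  })
  mu <- log(spec$mean_ms) - s^2 / 2
  pmin(pmax(exp(mu + z), 300), 2000)
}

#' Render a synthetic PPG channel from an RR sequence
#'
#' Superimposes the two-Gaussian pulse template at the cumulative beat
#' times, adds baseline drift and Gaussian noise at the spec's SNR,
#' applies the corruption segments, and emits the channel at the capture
#' rate, rescaled into (0, 255).
#'
#' @param rr RR intervals in ms (e.g. from [generate_rr()]).
#' @param spec a [synth_spec()].
#' @return list with `times_ms`, `values` (the raw channel) and `truth`
#'   (list with `beat_times_s`, `rr_ms`, `corruption` segments, and
#'   `corruption_mask` per emitted sample).
#' @export
render_ppg <- function(rr, spec) {
  stopifnot(length(rr) > 0L)
  beat_times <- 0.5 + cumsum(c(0, rr)) / 1000
  beat_times <- beat_times[beat_times < spec$duration_s - 0.5]
  t <- seq(0, spec$duration_s, by = 1 / spec$capture_hz)
  pulse <- rep(0, length(t))
  w_up <- spec$pulse_width_s
  w_down <- 2 * spec$pulse_width_s
  for (tb in beat_times) {
    # template support of a few widths around the beat keeps this O(n_beats)
    lo <- tb - 4 * w_up
    hi <- tb + spec$dicrotic_delay_s + 4 * spec$dicrotic_width_s
    idx <- which(t >= lo & t <= hi)
    dtb <- t[idx] - tb
    w <- ifelse(dtb < 0, w_up, w_down)   # fast upstroke, slow decay
    pulse[idx] <- pulse[idx] +
      exp(-dtb^2 / (2 * w^2)) +
      spec$dicrotic_amp *
        exp(-(dtb - spec$dicrotic_delay_s)^2 / (2 * spec$dicrotic_width_s^2))
  }
  x <- with_seed(spec$seed + 1L, {
    drift <- spec$drift_amp * sin(2 * pi * spec$drift_freq_hz * t +
                                    stats::runif(1, 0, 2 * pi))
    noise_sd <- stats::sd(pulse) * 10^(-spec$noise_snr_db / 20)
    x <- pulse + drift + stats::rnorm(length(t), sd = noise_sd)
    for (seg in spec$corruption) {
      idx <- which(t >= seg$start_s & t < seg$end_s)
      if (length(idx) == 0L) next
      if (seg$kind == "white_noise") {
        x[idx] <- mean(x) + stats::rnorm(length(idx), sd = stats::sd(pulse))
      } else if (seg$kind == "constant") {
        x[idx] <- x[idx[1L]]
      } else if (seg$kind == "step") {
        x[idx] <- x[idx] + 4 * (max(pulse) - min(pulse))
      }
    }
    x
  })
  corruption_mask <- rep(FALSE, length(t))
  for (seg in spec$corruption) {
    corruption_mask[t >= seg$start_s & t < seg$end_s] <- TRUE
  }
  values <- 20 + (x - min(x)) / (max(x) - min(x)) * 215
  list(times_ms = t * 1000, values = values,
       truth = list(beat_times_s = beat_times,
                    rr_ms = diff(beat_times) * 1000,
                    corruption = spec$corruption,
                    corruption_mask = corruption_mask))
}

#' Generate a full synthetic multi-channel record
#'
#' Renders the spec's channel into `G`, with `R` and `B` attenuated
#' (and slightly noisier) copies, in the Time/R/G/B/RR record layout.
#'
#' @param spec a [synth_spec()].
#' @return list with `record` (Time/R/G/B/RR) and `truth` (see
#'   [render_ppg()]).
#' @export
synth_record <- function(spec) {
  rr <- generate_rr(spec)
  ch <- render_ppg(rr, spec)
  degraded <- function(att, seed_off) {
    with_seed(spec$seed + seed_off, {
      v <- 127.5 + (ch$values - 127.5) * att +
        stats::rnorm(length(ch$values), sd = stats::sd(ch$values) * 0.05)
      pmin(pmax(v, 0), 255)
    })
  }
  record <- list(Time = ch$times_ms, R = degraded(0.5, 2L), G = ch$values,
                 B = degraded(0.3, 3L), RR = ch$truth$rr_ms)
  list(record = record, truth = ch$truth)
}
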