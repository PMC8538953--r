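# Fixtures built in code: uniform-signal constructor, noiseless pulse
# trains and hand-made ridge lines / heart-rate curves.

make_sig <- function(x, f = 100) {
  structure(list(samples = x, f = f, valid = rep(TRUE, length(x)),
                 chunks = cbind(start = 1L, end = length(x))),
            class = "uniform_signal")
}

# noiseless Gaussian pulse train at exact beat times (seconds), directly at
# the analysis rate; returns the signal vector
render_train <- function(beat_times_s, dur_s, f = 100, width_s = 0.06,
                         amp = 1) {
  tt <- (0:(round(dur_s * f) - 1)) / f
  x <- rep(0, length(tt))
  for (tb in beat_times_s) {
    x <- x + amp * exp(-(tt - tb)^2 / (2 * width_s^2))
  }
  x
}

# hand-made ridge line spanning scale rows k_lo..k_hi at constant sample n
make_line <- function(n, k_lo = 1L, k_hi = 50L) {
  sc <- scale_grid()
  ks <- k_lo:k_hi
  structure(list(k = ks, n = rep(n, length(ks)), top = n,
                 top_scale = sc[k_lo], bottom_scale = sc[k_hi]),
            class = "ridge_line")
}

# constant heart-rate curve covering a signal of n samples at f Hz
make_hr_curve <- function(hrf_hz, n, f = 100) {
  centers <- seq(2.5, n / f - 2.5, by = 0.5)
  if (length(centers) == 0L) centers <- n / f / 2
  structure(list(hrf = rep(hrf_hz, length(centers)), center_s = centers,
                 valid = rep(TRUE, length(centers))),
            class = "hr_curve")
}

# minimal stand-in for an rr_analysis, for evaluation tests
fake_result <- function(peak_times_ms, f = 100, kept = NULL) {
  rr <- diff(peak_times_ms)
  if (is.null(kept)) kept <- rep(TRUE, length(rr))
  list(peaks = peak_times_ms / 1000 * f + 1, f = f,
       intervals = data.frame(rr_ms = rr, kept = kept))
}
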