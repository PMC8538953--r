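# Preprocessing: raw (timestamp, value) channel -> clean uniformly sampled
# signal split into contiguous valid chunks.

#' Resample a raw channel to a uniform sampling grid
#'
#' Linearly interpolates an irregularly timestamped channel (e.g. a 30 fps
#' smartphone-camera colour trace) onto a uniform grid, by default 100 Hz.
#' Upsampling to 100 Hz is required for millisecond-accurate interval
#' estimation downstream.
#'
#' @param times_ms capture instants in milliseconds from start; strictly
#'   increasing, length >= 2.
#' @param values per-frame mean intensity values, same length as `times_ms`.
#' @param f target sampling frequency in Hz.
#' @return list with `samples` (numeric vector at times
#'   `t0_ms + (n-1) * 1000/f`), `f`, and `t0_ms` (first timestamp).
#' @export
resample_uniform <- function(times_ms, values, f = 100) {
  if (length(times_ms) < 2L || length(values) != length(times_ms)) {
    stop("need at least 2 (time, value) points of equal length", call. = FALSE)
  }
  if (any(diff(times_ms) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (f <= 0) stop("sampling frequency must be positive", call. = FALSE)
  dur_s <- (times_ms[length(times_ms)] - times_ms[1L]) / 1000
  n_out <- floor(dur_s * f) + 1L
  t_out <- times_ms[1L] + (seq_len(n_out) - 1) * 1000 / f
  samples <- stats::approx(times_ms, values, xout = t_out)$y
  list(samples = samples, f = f, t0_ms = times_ms[1L])
}

#' Rescale a signal onto the standard (0, 255) intensity range
#'
#' Affinely maps the observed range onto \[0, 255\], the standard camera
#' colour range that the downstream amplitude thresholds assume.
#' A constant signal cannot be rescaled; it is returned as all zeros with
#' attribute `constant = TRUE`.
#'
#' @param samples numeric vector.
#' @param observed_range length-2 numeric `(min, max)`; defaults to the
#'   observed range of `samples`.
#' @return rescaled numeric vector with attribute `constant` (logical).
#' @export
rescale_to_standard <- function(samples, observed_range = range(samples)) {
  lo <- observed_range[1L]
  hi <- observed_range[2L]
  if (hi <= lo) {
    out <- rep(0, length(samples))
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (samples - lo) / (hi - lo) * 255
  attr(out, "constant") <- FALSE
  out
}

# centred truncated running mean, vectorised via cumulative sums
running_mean <- function(x, width) {
  n <- length(x)
  h <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Running amplitude of a signal
#'
#' Per-sample max minus min over a centred window (default 1 s), truncated
#' at the signal edges. Used to detect abrupt steps and constant dropouts.
#'
#' @param samples numeric vector.
#' @param f sampling frequency in Hz.
#' @param window_s window length in seconds.
#' @return numeric vector of the same length as `samples`.
#' @export
running_amplitude <- function(samples, f, window_s = 1.0) {
  h <- floor(window_s * f / 2)
  if (2 * h < 1L) stop("window too short for running amplitude", call. = FALSE)
  width <- 2L * h + 1L
  mx <- zoo::rollapply(samples, width = width, FUN = max, partial = TRUE,
                       align = "center")
  mn <- zoo::rollapply(samples, width = width, FUN = min, partial = TRUE,
                       align = "center")
  as.numeric(mx - mn)
}

#' Detect abrupt steps in a signal
#'
#' A step (finger removed from / reapplied to the camera) makes the 1 s
#' running amplitude exceed 4 times its median. Every sample whose
#' surrounding 1 s window produced an exceeding amplitude is flagged, so
#' the full contaminated window is excluded.
#'
#' @inheritParams running_amplitude
#' @return logical mask, `TRUE` where a step contaminates the signal.
#' @export
detect_steps <- function(samples, f, window_s = 1.0) {
  amp <- running_amplitude(samples, f, window_s)
  med <- stats::median(amp)
  if (med == 0) return(rep(FALSE, length(samples)))  # degenerate constant input
  core <- amp > 4 * med
  dilate_mask(core, floor(window_s * f / 2))
}

#' Detect constant (dropped-out) signal parts
#'
#' After rescaling to (0, 255), a running amplitude below 0.1 marks a
#' constant signal: a colour-rendering failure or no finger on the camera.
#'
#' @inheritParams running_amplitude
#' @return logical mask, `TRUE` where the signal is effectively constant.
#' @export
detect_constant <- function(samples, f, window_s = 1.0) {
  running_amplitude(samples, f, window_s) < 0.1
}

dilate_mask <- function(mask, h) {
  if (!any(mask) || h < 1L) return(mask)
  n <- length(mask)
  out <- rep(FALSE, n)
  idx <- which(mask)
  starts <- pmax(idx - h, 1L)
  ends <- pmin(idx + h, n)
  # mark via difference array
  d <- integer(n + 1L)
  for (i in seq_along(starts)) {
    d[starts[i]] <- d[starts[i]] + 1L
    d[ends[i] + 1L] <- d[ends[i] + 1L] - 1L
  }
  cumsum(d[seq_len(n)]) > 0L
}

#' Zero flagged parts, split into chunks, detrend and low-pass filter
#'
#' Flagged samples are set to zero; the remaining signal is split into
#' contiguous runs and runs shorter than 2 s are zeroed as well. Each
#' surviving chunk is detrended by subtracting a centred 2 s running mean
#' and low-pass filtered at 10 Hz (4th-order Butterworth applied
#' forward-backward, so peak positions are not phase-shifted).
#'
#' @param samples numeric vector (rescaled to (0, 255)).
#' @param f sampling frequency in Hz.
#' @param flags logical mask of corrupted samples, e.g. the union of
#'   [detect_steps()] and [detect_constant()].
#' @return a `uniform_signal`: list with `samples` (cleaned, zero outside
#'   chunks), `f`, `valid` (logical mask), and `chunks` (integer matrix
#'   with columns `start`, `end`; 1-based closed sample ranges).
#' @export
chunk_and_clean <- function(samples, f, flags = rep(FALSE, length(samples))) {
  n <- length(samples)
  stopifnot(length(flags) == n)
  valid <- !flags
  min_len <- ceiling(2 * f)
  runs <- valid_runs(valid)
  keep <- runs[, 2L] - runs[, 1L] + 1L >= min_len
  chunks <- runs[keep, , drop = FALSE]
  out <- rep(0, n)
  new_valid <- rep(FALSE, n)
  if (nrow(chunks) > 0L) {
    bf <- signal::butter(4, 10 / (f / 2), type = "low")
    for (i in seq_len(nrow(chunks))) {
      a <- chunks[i, 1L]; b <- chunks[i, 2L]
      x <- samples[a:b]
      x <- x - running_mean(x, floor(2 * f))
      x <- signal::filtfilt(bf, x)
      out[a:b] <- x
      new_valid[a:b] <- TRUE
    }
  }
  structure(list(samples = out, f = f, valid = new_valid, chunks = chunks),
            class = "uniform_signal")
}

valid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  sel <- r$values
  cbind(start = starts[sel], end = ends[sel])
}

#' Full preprocessing of one raw channel
#'
#' Resamples to a uniform grid, rescales to (0, 255), detects steps and
#' constant dropouts, and produces the cleaned chunked signal.
#'
#' @inheritParams resample_uniform
#' @return a `uniform_signal` (see [chunk_and_clean()]) with an extra
#'   `t0_ms` element recording the first raw timestamp.
#' @export
preprocess_channel <- function(times_ms, values, f = 100) {
  rs <- resample_uniform(times_ms, values, f)
  x <- rescale_to_standard(rs$samples)
  if (isTRUE(attr(x, "constant"))) {
    sig <- structure(list(samples = rep(0, length(x)), f = f,
                          valid = rep(FALSE, length(x)),
                          chunks = cbind(start = integer(0), end = integer(0))),
                     class = "uniform_signal")
    sig$t0_ms <- rs$t0_ms
    return(sig)
  }
  flags <- detect_steps(x, f) | detect_constant(x, f)
  sig <- chunk_and_clean(as.numeric(x), f, flags)
  sig$t0_ms <- rs$t0_ms
  sig
}

#' @export
print.uniform_signal <- function(x, ...) {
  dur <- length(x$samples) / x$f
  cat(sprintf("uniform_signal: %.1f s at %g Hz, %d chunk(s), %.1f%% valid\n",
              dur, x$f, nrow(x$chunks), 100 * mean(x$valid)))
  invisible(x)
}
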