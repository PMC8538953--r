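# Heart-rate estimation: STFT spectrogram, continuity filter, rough
# peak/zero-crossing estimate and the smoothed heart-rate frequency curve.

SPEC_N_FREQ <- 80L
SPEC_F_MIN <- 0.5
SPEC_F_MAX <- 3.3
SPEC_WINDOW_S <- 5.0
SPEC_STRIDE_S <- 0.5

#' Sliding-window STFT spectrogram of a PPG signal
#'
#' Squared magnitude of the short-time Fourier transform over a sliding
#' rectangular (Dirichlet) window of 5 s, stride 0.5 s, evaluated at 80
#' frequencies uniformly spaced on \[0.5, 3.3\] Hz — the plausible
#' heart-rate band. Column j covers the `5f` samples starting at
#' `s_j = 0.5 f (j-1) + 1`:
#' `power[k, j] = |sum_n x_n exp(-2 pi i f_k t_n) dt|^2`, `t_n = (n-1)/f`.
#'
#' Columns whose window overlaps invalid (zeroed) samples are marked
#' invalid; the heart-rate curve carries its last value across them.
#'
#' @param sig a `uniform_signal` from [preprocess_channel()] or
#'   [chunk_and_clean()].
#' @return a `ppg_spectrogram`: list with `power` (80 x n_windows matrix),
#'   `freqs`, `window_s`, `stride_s`, `start_index` (1-based first sample
#'   of each window), `center_s` (window-centre times), `valid` (per
#'   column), `f`.
#' @export
compute_spectrogram <- function(sig) {
  f <- sig$f
  x <- sig$samples
  n <- length(x)
  wlen <- round(SPEC_WINDOW_S * f)          # window spans wlen samples
  stride <- round(SPEC_STRIDE_S * f)
  if (n < wlen) stop("signal shorter than the 5 s analysis window", call. = FALSE)
  n_win <- floor((n - wlen) / stride) + 1L
  starts <- (seq_len(n_win) - 1L) * stride + 1L
  freqs <- seq(SPEC_F_MIN, SPEC_F_MAX, length.out = SPEC_N_FREQ)
  dt <- 1 / f
  # window sample matrix [wlen x n_win] and phase matrix [n_freq x wlen]
  idx <- outer(0:(wlen - 1L), starts, "+")
  X <- matrix(x[idx], nrow = wlen)
  # phases depend on absolute time; factor exp(-2pi i f t) = exp(-2pi i f t_start) * exp(-2pi i f tau)
  tau <- (0:(wlen - 1L)) * dt
  E <- exp(-2i * pi * outer(freqs, tau))     # n_freq x (wlen+1)
  S <- E %*% X                               # n_freq x n_win, missing start-phase factor
  t_start <- (starts - 1) * dt
  phase0 <- exp(-2i * pi * outer(freqs, t_start))
  power <- Mod(S * phase0)^2 * dt^2
  valid <- vapply(seq_len(n_win), function(j) {
    all(sig$valid[starts[j]:(starts[j] + wlen - 1L)])
  }, logical(1))
  structure(list(power = power, freqs = freqs, window_s = SPEC_WINDOW_S,
                 stride_s = SPEC_STRIDE_S, start_index = starts,
                 center_s = t_start + SPEC_WINDOW_S / 2, valid = valid, f = f),
            class = "ppg_spectrogram")
}

#' Continuity filter: highlight slowly evolving spectrogram curves
#'
#' Convolves the spectrogram with a fan-shaped kernel: the union of
#' straight lines through the kernel centre with |slope| at most
#' 0.3 Hz per 10 s, spanning 10 s horizontally (20 columns) and 0.3 Hz
#' vertically in total. A genuine heart-rate trace, which drifts slowly,
#' is reinforced along its direction of travel, while isolated artifact
#' speckle is spread out and suppressed.
#'
#' @param spec a `ppg_spectrogram`.
#' @return the spectrogram with `power` replaced by the filtered matrix
#'   (same shape, zero-padded edges).
#' @export
continuity_filter <- function(spec) {
  df <- diff(spec$freqs[1:2])
  half_h <- round((10 / spec$stride_s) / 2)          # 10 columns
  half_v <- max(1L, round((0.3 / 2) / df))           # ~0.15 Hz in bins
  kern <- fan_kernel(half_v, half_h)
  spec$power <- conv2_same(spec$power, kern)
  spec
}

# binary fan of one-pixel-wide rasterized lines through the centre,
# normalized to unit sum
fan_kernel <- function(half_v, half_h) {
  K <- matrix(0, nrow = 2L * half_v + 1L, ncol = 2L * half_h + 1L)
  for (dy in (-half_v):half_v) {
    xs <- (-half_h):half_h
    ys <- round(dy / half_h * xs)
    K[cbind(ys + half_v + 1L, xs + half_h + 1L)] <- 1
  }
  K / sum(K)
}

# 2-D convolution, same shape, zero padding; shift-and-add over nonzero
# kernel cells (kernels here have ~100 nonzero cells)
conv2_same <- function(A, K) {
  nr <- nrow(A); nc <- ncol(A)
  cy <- (nrow(K) + 1L) %/% 2L
  cx <- (ncol(K) + 1L) %/% 2L
  out <- matrix(0, nr, nc)
  nz <- which(K != 0, arr.ind = TRUE)
  for (i in seq_len(nrow(nz))) {
    dy <- nz[i, 1L] - cy
    dx <- nz[i, 2L] - cx
    w <- K[nz[i, 1L], nz[i, 2L]]
    # out[r, c] += w * A[r - dy, c - dx]
    r_dst <- max(1L, 1L + dy):min(nr, nr + dy)
    c_dst <- max(1L, 1L + dx):min(nc, nc + dx)
    out[r_dst, c_dst] <- out[r_dst, c_dst] + w * A[r_dst - dy, c_dst - dx]
  }
  out
}

# local maxima of one spectrogram column; plateau ties toward lower frequency
column_peaks <- function(col) local_maxima(col, plateau = "first")

# frequencies of the (up to) 3 highest column peaks
top_peak_freqs <- function(spec, j, n_top = 3L) {
  col <- spec$power[, j]
  pk <- column_peaks(col)
  if (length(pk) == 0L) return(numeric(0))
  pk <- pk[order(col[pk], decreasing = TRUE)]
  spec$freqs[utils::head(pk, n_top)]
}

#' Rough heart-rate estimate for one spectrogram column
#'
#' Band-pass filters the signal segment starting at the column's window
#' (up to 10 s) with an adaptive upper cutoff chosen from the column's
#' argmax frequency (above 2 Hz: 2.5; below 1 Hz: 1.5; else 2 Hz), counts
#' local maxima and zero crossings of the filtered segment, averages the
#' two implied rates, and returns the frequency among the column's three
#' highest peaks closest to that estimate.
#'
#' @param sig the `uniform_signal` the spectrogram was computed from.
#' @param j column index (1-based).
#' @param spec the (typically continuity-filtered) `ppg_spectrogram`.
#' @return heart-rate frequency estimate in Hz.
#' @export
rough_hr_estimate <- function(sig, j, spec) {
  f <- sig$f
  col <- spec$power[, j]
  f_max <- spec$freqs[which.max(col)]
  threshold <- if (f_max > 2) 2.5 else if (f_max < 1) 1.5 else 2
  s0 <- spec$start_index[j]
  n_avail <- length(sig$samples) - s0 + 1L
  test_len <- min(10, n_avail / f)
  x <- sig$samples[s0:(s0 + round(test_len * f) - 1L)]
  bp <- signal::butter(2, c(0.1, threshold) / (f / 2), type = "pass")
  xf <- signal::filtfilt(bp, x)
  n_zero_cross <- count_zero_crossings(xf)
  n_loc_max <- length(local_maxima(xf))
  upper <- n_loc_max / test_len
  lower <- 0.5 * n_zero_cross / test_len
  estimate <- 0.5 * (lower + upper)
  cand <- top_peak_freqs(spec, j)
  if (length(cand) == 0L) return(f_max)
  cand[which.min(abs(cand - estimate))]
}

#' Construct the heart-rate frequency curve
#'
#' Starting from the rough estimate for the first valid column, follows
#' column local maxima continuously: among the three largest local maxima
#' of each column, the frequency nearest the previous value is accepted if
#' within 0.1 Hz; otherwise the curve is re-initialised by exponential
#' smoothing towards the rough estimate,
#' `hrf[i] = 0.95 hrf[i-1] + 0.05 f_next`. Invalid columns (windows
#' overlapping zeroed samples) carry the last valid value forward.
#'
#' @param spec a continuity-filtered `ppg_spectrogram`.
#' @param sig the underlying `uniform_signal`.
#' @return a `hr_curve`: list with `hrf` (Hz per column), `center_s`,
#'   `valid` (copied from the spectrogram).
#' @export
build_hr_curve <- function(spec, sig) {
  n <- ncol(spec$power)
  hrf <- numeric(n)
  vld <- spec$valid
  if (!any(vld)) stop("no spectrogram column lies fully inside a valid chunk", call. = FALSE)
  j0 <- which(vld)[1L]
  hrf[j0] <- rough_hr_estimate(sig, j0, spec)
  if (j0 > 1L) hrf[seq_len(j0 - 1L)] <- hrf[j0]
  if (j0 < n) {
    for (j in (j0 + 1L):n) {
      if (!vld[j]) {
        hrf[j] <- hrf[j - 1L]
        next
      }
      cand <- top_peak_freqs(spec, j)
      if (length(cand) == 0L) {
        hrf[j] <- hrf[j - 1L]
        next
      }
      fcl <- cand[which.min(abs(cand - hrf[j - 1L]))]
      if (abs(fcl - hrf[j - 1L]) < 0.1) {
        hrf[j] <- fcl
      } else {
        fnext <- rough_hr_estimate(sig, j, spec)
        hrf[j] <- 0.95 * hrf[j - 1L] + 0.05 * fnext
      }
    }
  }
  structure(list(hrf = hrf, center_s = spec$center_s, valid = vld),
            class = "hr_curve")
}

# heart-rate frequency at given sample indices: value of the curve at the
# column whose window centre is nearest
hrf_at_samples <- function(curve, sample_idx, f) {
  t_s <- (sample_idx - 1) / f
  j <- vapply(t_s, function(t) which.min(abs(curve$center_s - t)), integer(1))
  curve$hrf[j]
}
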