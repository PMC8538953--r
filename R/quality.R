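# Per-interval quality: signal self-similarity between neighbouring
# intervals, ridge-line shape stability, adaptive threshold filtration and
# interval-length outlier rules.

sigmoid <- function(x) 1 / (1 + exp(-x))

# linear resampling of a chunk to `m` points over its index range
resample_to <- function(x, m = 50L) {
  n <- length(x)
  if (n == m) return(x)
  stats::approx(seq_len(n), x, xout = seq(1, n, length.out = m))$y
}

#' Correlation similarity of two signal chunks
#'
#' Both chunks are resampled to 50 points; the Pearson correlation of the
#' resampled chunks, clipped at 0 from below. A constant chunk has
#' undefined correlation and yields 0.
#'
#' @param x,y numeric signal chunks (length >= 2).
#' @return similarity in \[0, 1\].
#' @export
correlation_similarity <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) return(0)
  xr <- resample_to(x)
  yr <- resample_to(y)
  if (stats::sd(xr) == 0 || stats::sd(yr) == 0) return(0)
  max(stats::cor(xr, yr), 0)
}

#' Amplitude similarity of two signal chunks
#'
#' With `r_amp` the ratio of the larger to the smaller peak-to-peak
#' amplitude, returns `sigmoid(2 * (3.5 - r_amp))`: near 1 for equal
#' amplitudes, 0.5 at a ratio of 3.5, and small once amplitudes differ by
#' 4 times or more.
#'
#' @param x,y numeric signal chunks.
#' @return similarity in (0, 1); 0 if either amplitude is zero.
#' @export
amplitude_similarity <- function(x, y) {
  ax <- max(x) - min(x)
  ay <- max(y) - min(y)
  if (ax <= 0 || ay <= 0) return(0)
  r_amp <- max(ax, ay) / min(ax, ay)
  sigmoid(2 * (3.5 - r_amp))
}

# similarity score between two chunks: geometric mean of correlation and
# amplitude similarity
similarity_score <- function(x, y) {
  sqrt(correlation_similarity(x, y) * amplitude_similarity(x, y))
}

#' Similarity-based quality of each RR interval
#'
#' `s_i` is the similarity score between the signal inside interval
#' `i - 1` and interval `i`; the quality of an interior interval is the
#' geometric mean `sqrt(s_i * s_{i+1})`, and edge intervals use their
#' single available neighbour. With a single interval no neighbour
#' comparison exists and the quality is 0 (conservative).
#'
#' @param samples the cleaned signal (one chunk).
#' @param peaks sample indices of detected peaks within `samples`,
#'   sorted increasing (length `n + 1` for `n` intervals).
#' @return numeric vector of per-interval `q_sim` in \[0, 1\].
#' @export
similarity_quality <- function(samples, peaks) {
  n_int <- length(peaks) - 1L
  if (n_int < 1L) return(numeric(0))
  if (n_int == 1L) return(0)
  seg <- function(i) samples[peaks[i]:peaks[i + 1L]]
  s <- c(NA_real_, vapply(2:n_int, function(i) {
    similarity_score(seg(i - 1L), seg(i))
  }, numeric(1)))
  q <- numeric(n_int)
  q[1L] <- s[2L]
  q[n_int] <- s[n_int]
  if (n_int > 2L) {
    for (i in 2:(n_int - 1L)) q[i] <- sqrt(s[i] * s[i + 1L])
  }
  q
}

#' Ridge-shape (CWT-based) quality of an interval
#'
#' The two ridge lines bounding an interval should stay roughly parallel
#' across scales for a genuine pair of heartbeats. `rr_std` is the
#' standard deviation, over the scale rows both lines share, of the
#' distance between them, in ms. The default quality
#' `sigmoid((50 - rr_std)/5)` is near 1 for parallel lines and drops to
#' 0.5 at 50 ms; `eq18_as_printed = TRUE` evaluates the reversed form
#' `sigmoid((rr_std - 50)/5)` instead.
#'
#' @param line1,line2 `ridge_line`s bounding the interval.
#' @param f sampling frequency in Hz.
#' @param eq18_as_printed use the reversed (unstable-rewarding) form.
#' @return quality in (0, 1); 0 if the lines share fewer than 2 scale rows.
#' @export
cwt_quality <- function(line1, line2, f, eq18_as_printed = FALSE) {
  shared <- intersect(line1$k, line2$k)
  if (length(shared) < 2L) return(0)
  d <- abs(line1$n[match(shared, line1$k)] - line2$n[match(shared, line2$k)])
  rr_std <- stats::sd(d) / f * 1000
  if (eq18_as_printed) sigmoid((rr_std - 50) / 5) else sigmoid((50 - rr_std) / 5)
}

#' Adaptive quality threshold filtration
#'
#' Intervals with quality above the rigid pre-filter 0.8 survive; their
#' qualities sorted descending `q'_1 >= ... >= q'_n'` define the cutoff
#' `q'_{i0}` with `i0 = argmax_i i * q'_i` (ties towards larger `i`, which
#' keeps more intervals). Kept intervals have `q > 0.8` and `q >= cutoff`.
#'
#' @param qualities numeric vector of interval qualities.
#' @return list with `kept` (logical) and `cutoff` (NA if nothing
#'   survives the pre-filter).
#' @export
adaptive_threshold_filter <- function(qualities) {
  pre <- qualities > 0.8
  if (!any(pre)) {
    return(list(kept = rep(FALSE, length(qualities)), cutoff = NA_real_))
  }
  qs <- sort(qualities[pre], decreasing = TRUE)
  prod <- seq_along(qs) * qs
  i0 <- max(which(prod == max(prod)))
  cutoff <- qs[i0]
  list(kept = pre & qualities >= cutoff, cutoff = cutoff)
}

#' Interval-length outlier detection
#'
#' Flags implausible intervals from their lengths alone, using robust
#' statistics of a running window of up to 27 intervals
#' (`rr[i-13] .. rr[i+13]`, truncated at the edges): `m` the median,
#' `p10`/`p90` the deciles, `amp = p90 - p10`. Four rules:
#' a short/long adjacent pair straddling the window spread (a split or
#' shifted beat), an adjacent pair both below `0.7 m` whose sum is
#' ordinary (one beat detected as two), a single interval above `1.6 m`
#' (missed beat), and a single interval below `min(0.7 m, p10)`.
#'
#' @param rr RR intervals in ms.
#' @return logical vector, `TRUE` where an interval is an outlier.
#' @export
outlier_filter <- function(rr) {
  n <- length(rr)
  if (n < 2L) return(rep(FALSE, n))
  out <- rep(FALSE, n)
  for (i in seq_len(n)) {
    w <- rr[max(1L, i - 13L):min(n, i + 13L)]
    p <- stats::quantile(w, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
    p10 <- p[1L]; m <- p[2L]; p90 <- p[3L]
    amp <- p90 - p10
    if (i < n) {
      rr_max <- max(rr[i], rr[i + 1L])
      rr_min <- min(rr[i], rr[i + 1L])
      if (rr_min < min(m - 50, p10 - 0.2 * amp) &&
          rr_max > max(m + 50, p90 + 0.2 * amp) &&
          p10 < (rr_max + rr_min) / 2 && (rr_max + rr_min) / 2 < p90) {
        out[i] <- TRUE
        out[i + 1L] <- TRUE
      }
      if (rr[i] < 0.7 * m && rr[i + 1L] < 0.7 * m &&
          p10 < rr[i] + rr[i + 1L] && rr[i] + rr[i + 1L] < p90) {
        out[i] <- TRUE
        out[i + 1L] <- TRUE
      }
    }
    if (rr[i] > 1.6 * m) out[i] <- TRUE
    if (rr[i] < min(0.7 * m, p10)) out[i] <- TRUE
  }
  out
}

#' Score, threshold and outlier-filter the detected intervals
#'
#' Combines the similarity and ridge-shape qualities into
#' `q = q_sim * q_cwt` per interval, applies the adaptive threshold over
#' all intervals of the signal, and then runs the interval-length outlier
#' rules on the sequence of threshold-surviving intervals. An interval is
#' kept when it passes the threshold and is not an outlier.
#'
#' @param sig the cleaned `uniform_signal`.
#' @param selection per-chunk selections as returned by the internal
#'   pipeline: list of lists with `chosen` (ridge lines sorted by top)
#'   and `chunk` (chunk row index).
#' @param eq18_as_printed passed to [cwt_quality()].
#' @return data.frame with one row per interval: `chunk`, `peak_index`
#'   (sample of the interval's left peak), `peak_time_ms`, `rr_ms`,
#'   `q_sim`, `q_cwt`, `q`, `kept`, `outlier`; plus attribute `cutoff`.
#' @export
assess_intervals <- function(sig, selection, eq18_as_printed = FALSE) {
  f <- sig$f
  rows <- list()
  for (s in selection) {
    chosen <- s$chosen
    if (length(chosen) < 2L) next
    pk <- peaks_from_lines(chosen, f)
    peaks <- pk$peaks
    n_int <- length(peaks) - 1L
    q_sim <- similarity_quality(sig$samples, peaks)
    q_cwt <- vapply(seq_len(n_int), function(i) {
      cwt_quality(chosen[[i]], chosen[[i + 1L]], f, eq18_as_printed)
    }, numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      chunk = s$chunk,
      peak_index = peaks[seq_len(n_int)],
      peak_time_ms = (peaks[seq_len(n_int)] - 1) / f * 1000,
      rr_ms = pk$rr_ms,
      q_sim = q_sim,
      q_cwt = q_cwt,
      q = q_sim * q_cwt
    )
  }
  if (length(rows) == 0L) {
    res <- data.frame(chunk = integer(0), peak_index = numeric(0),
                      peak_time_ms = numeric(0), rr_ms = numeric(0),
                      q_sim = numeric(0), q_cwt = numeric(0), q = numeric(0),
                      kept = logical(0), outlier = logical(0))
    attr(res, "cutoff") <- NA_real_
    return(res)
  }
  res <- do.call(rbind, rows)
  thr <- adaptive_threshold_filter(res$q)
  res$kept <- thr$kept
  res$outlier <- FALSE
  surv <- which(res$kept)
  if (length(surv) > 0L) {
    out <- outlier_filter(res$rr_ms[surv])
    res$outlier[surv] <- out
    res$kept[surv[out]] <- FALSE
  }
  rownames(res) <- NULL
  attr(res, "cutoff") <- thr$cutoff
  res
}
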