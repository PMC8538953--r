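# Orchestration: full per-polarity pipeline, per-channel and per-record
# analysis with best-result selection, and evaluation against reference
# RR intervals.

# run the detection pipeline on one cleaned signal (one polarity).
# Returns an rr_analysis object.
run_rr_pipeline <- function(sig, eq18_as_printed = FALSE) {
  empty <- function() {
    structure(list(
      intervals = assess_intervals(sig, list()),
      peaks = numeric(0), rr_ms = numeric(0),
      hrv = hrv_summary(numeric(0)), hr_curve = NULL,
      analyzable = FALSE, f = sig$f), class = "rr_analysis")
  }
  f <- sig$f
  wlen <- round(5 * f)
  if (nrow(sig$chunks) == 0L ||
      max(sig$chunks[, 2L] - sig$chunks[, 1L] + 1L) < wlen) {
    return(empty())
  }
  spec <- compute_spectrogram(sig)
  if (!any(spec$valid)) return(empty())
  spec_f <- continuity_filter(spec)
  curve <- build_hr_curve(spec_f, sig)
  scal <- compute_scalogram(sig)
  rp <- find_ridge_points(scal)
  lines <- link_ridge_lines(rp, scal$scales, f)
  tops <- vapply(lines, function(l) l$top, numeric(1))
  # scalogram coefficients within half the largest wavelet support of a
  # chunk boundary are dominated by the step from the zero padding into
  # the chunk; ridge tops there are boundary artifacts, not beats
  margin <- ceiling(2.5 * max(scal$scales) * f)
  selection <- list()
  for (ci in seq_len(nrow(sig$chunks))) {
    a <- sig$chunks[ci, 1L] + margin; b <- sig$chunks[ci, 2L] - margin
    in_chunk <- lines[tops >= a & tops <= b]
    chosen <- select_ridge_lines(in_chunk, curve, f)
    selection[[length(selection) + 1L]] <- list(chosen = chosen, chunk = ci)
  }
  intervals <- assess_intervals(sig, selection, eq18_as_printed)
  hrv <- hrv_summary(intervals$rr_ms, intervals$kept, intervals$chunk)
  peaks <- sort(unlist(lapply(selection, function(s) {
    vapply(s$chosen, function(l) l$top, numeric(1))
  })))
  structure(list(intervals = intervals, peaks = peaks,
                 rr_ms = intervals$rr_ms, hrv = hrv, hr_curve = curve,
                 analyzable = nrow(intervals) > 0L, f = f),
            class = "rr_analysis")
}

#' Analyze one raw PPG channel at both polarities
#'
#' Runs the full pipeline on the preprocessed signal and on its negative
#' (valleys can be easier to locate than peaks; negation is applied after
#' detrending). The polarity with the smaller discarded ratio wins; ties
#' are broken towards more kept intervals, then towards positive.
#'
#' @inheritParams resample_uniform
#' @param eq18_as_printed use the as-printed (reversed) ridge-shape
#'   quality; see [cwt_quality()].
#' @return a `channel_analysis`: list with `pos`, `neg` (both
#'   `rr_analysis`), `best_polarity`, `best` (the winning `rr_analysis`),
#'   `analyzable`.
#' @export
analyze_channel <- function(times_ms, values, f = 100, eq18_as_printed = FALSE) {
  sig <- preprocess_channel(times_ms, values, f)
  neg_sig <- sig
  neg_sig$samples <- -sig$samples
  pos <- run_rr_pipeline(sig, eq18_as_printed)
  neg <- run_rr_pipeline(neg_sig, eq18_as_printed)
  pick <- compare_results(list(pos = pos, neg = neg), c("pos", "neg"))
  structure(list(pos = pos, neg = neg, best_polarity = pick,
                 best = if (is.na(pick)) NULL else list(pos = pos, neg = neg)[[pick]],
                 analyzable = !is.na(pick)),
            class = "channel_analysis")
}

# order candidate results by (discarded ratio asc, mean kept quality desc,
# kept desc, stated order); unanalyzable results never win unless all are.
# Mean kept quality discriminates between polarities that both discard
# nothing: the broader, harder-to-localise morphology scores lower even
# when every interval survives. Returns the winning name or NA.
compare_results <- function(results, order_names) {
  ok <- vapply(results, function(r) isTRUE(r$analyzable), logical(1))
  if (!any(ok)) return(NA_character_)
  ratio <- vapply(results, function(r) r$hrv$discarded_ratio, numeric(1))
  kept <- vapply(results, function(r) r$hrv$n_kept, numeric(1))
  mq <- vapply(results, function(r) {
    k <- r$intervals$kept
    if (any(k)) mean(r$intervals$q[k]) else 0
  }, numeric(1))
  ratio[!ok] <- Inf
  best <- order(ratio, -mq, -kept, seq_along(results))[1L]
  order_names[best]
}

#' Analyze a multi-channel PPG recording
#'
#' Runs [analyze_channel()] on every channel; the overall result is the
#' (channel, polarity) pair with the global minimum discarded ratio, ties
#' broken by more kept intervals and then by channel order (R, G, B).
#'
#' @param record list with `Time` (ms) and one or more channel vectors
#'   (e.g. `R`, `G`, `B`), as returned by [read_welltory_record()].
#' @param channels which channels to analyze; defaults to all of
#'   R, G, B present in the record.
#' @param f sampling frequency in Hz.
#' @param eq18_as_printed see [cwt_quality()].
#' @return a `ppg_analysis`: list with `channels` (named
#'   `channel_analysis` list), `best_channel`, `best_polarity`, `best`
#'   (the winning `rr_analysis`), `analyzable`.
#' @export
analyze_recording <- function(record, channels = NULL, f = 100,
                              eq18_as_printed = FALSE) {
  if (is.null(channels)) {
    channels <- intersect(c("R", "G", "B"), names(record))
  }
  if (length(channels) == 0L) stop("no PPG channels found in record", call. = FALSE)
  per_channel <- lapply(channels, function(ch) {
    analyze_channel(record$Time, record[[ch]], f, eq18_as_printed)
  })
  names(per_channel) <- channels
  flat <- list()
  nm <- character(0)
  for (ch in channels) {
    for (pol in c("pos", "neg")) {
      flat[[length(flat) + 1L]] <- per_channel[[ch]][[pol]]
      nm <- c(nm, paste(ch, pol, sep = "/"))
    }
  }
  pick <- compare_results(flat, nm)
  if (is.na(pick)) {
    best_channel <- NA_character_; best_polarity <- NA_character_; best <- NULL
  } else {
    parts <- strsplit(pick, "/", fixed = TRUE)[[1L]]
    best_channel <- parts[1L]; best_polarity <- parts[2L]
    best <- per_channel[[best_channel]][[best_polarity]]
  }
  structure(list(channels = per_channel, best_channel = best_channel,
                 best_polarity = best_polarity, best = best,
                 analyzable = !is.na(pick)),
            class = "ppg_analysis")
}

#' Compare detected intervals with a reference RR sequence
#'
#' Reference peak times are reconstructed by cumulative summation of the
#' reference intervals, anchored at the first detected peak; since the
#' detection may miss leading beats, the anchor is chosen among the first
#' few reference beats (the alignment with the most matches, then the
#' smallest mean distance, wins). Detected peaks are matched one-to-one
#' to reference peaks greedily by time distance with a 250 ms gate.
#' `rr_mae_ms` is the mean absolute
#' difference between a detected interval and the matched reference
#' interval (over pairs of consecutive matched peaks on both sides);
#' `sdnn_ae_ms` / `rmssd_ae_ms` compare the metrics of the kept detected
#' intervals with the reference metrics.
#'
#' @param result an `rr_analysis` (e.g. the `best` element of
#'   [analyze_recording()]).
#' @param reference_rr_ms reference RR intervals in ms.
#' @param gate_ms matching gate.
#' @return list with `rr_mae_ms`, `sdnn_ae_ms`, `rmssd_ae_ms`,
#'   `n_matched`, `n_detected`, `n_reference`. NA metrics when undefined.
#' @export
evaluate_against_reference <- function(result, reference_rr_ms, gate_ms = 250) {
  det_peaks_ms <- (result$peaks - 1) / result$f * 1000
  n_ref <- length(reference_rr_ms) + 1L
  if (length(det_peaks_ms) < 2L) {
    return(list(rr_mae_ms = NA_real_, sdnn_ae_ms = NA_real_,
                rmssd_ae_ms = NA_real_, n_matched = 0L,
                n_detected = length(det_peaks_ms), n_reference = n_ref))
  }
  ref_cum <- cumsum(c(0, reference_rr_ms))
  best_match <- NULL
  best_key <- c(-Inf, Inf)
  for (lag in 0:min(10L, length(ref_cum) - 1L)) {
    ref_peaks_ms <- det_peaks_ms[1L] - ref_cum[lag + 1L] + ref_cum
    mr <- match_peaks(det_peaks_ms, ref_peaks_ms, gate_ms)
    got <- which(!is.na(mr))
    md <- if (length(got) > 0L) {
      mean(abs(det_peaks_ms[got] - ref_peaks_ms[mr[got]]))
    } else Inf
    if (length(got) > best_key[1L] ||
        (length(got) == best_key[1L] && md < best_key[2L])) {
      best_key <- c(length(got), md)
      best_match <- mr
    }
  }
  match_ref <- best_match
  matched <- which(!is.na(match_ref))
  # interval pairs: consecutive detected peaks both matched to consecutive refs
  rr_err <- numeric(0)
  if (length(matched) >= 2L) {
    for (i in utils::head(matched, -1)) {
      if ((i + 1L) %in% matched && match_ref[i + 1L] == match_ref[i] + 1L) {
        det_rr <- det_peaks_ms[i + 1L] - det_peaks_ms[i]
        ref_rr <- reference_rr_ms[match_ref[i]]
        rr_err <- c(rr_err, abs(det_rr - ref_rr))
      }
    }
  }
  kept_rr <- result$intervals$rr_ms[result$intervals$kept]
  sdnn_ae <- if (length(kept_rr) >= 2L && length(reference_rr_ms) >= 2L) {
    abs(sdnn(kept_rr) - sdnn(reference_rr_ms))
  } else NA_real_
  rmssd_ae <- if (length(kept_rr) >= 2L && length(reference_rr_ms) >= 2L) {
    abs(rmssd(kept_rr) - rmssd(reference_rr_ms))
  } else NA_real_
  list(rr_mae_ms = if (length(rr_err) > 0L) mean(rr_err) else NA_real_,
       sdnn_ae_ms = sdnn_ae, rmssd_ae_ms = rmssd_ae,
       n_matched = length(matched), n_detected = length(det_peaks_ms),
       n_reference = n_ref)
}

# greedy one-to-one matching of detected to reference peak times by
# increasing time distance, gated
match_peaks <- function(det, ref, gate_ms) {
  pairs <- expand.grid(d = seq_along(det), r = seq_along(ref))
  pairs$dist <- abs(det[pairs$d] - ref[pairs$r])
  pairs <- pairs[pairs$dist <= gate_ms, , drop = FALSE]
  pairs <- pairs[order(pairs$dist), , drop = FALSE]
  match_ref <- rep(NA_integer_, length(det))
  used_ref <- rep(FALSE, length(ref))
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$d[i]; r <- pairs$r[i]
    if (is.na(match_ref[d]) && !used_ref[r]) {
      match_ref[d] <- r
      used_ref[r] <- TRUE
    }
  }
  match_ref
}

#' @export
print.rr_analysis <- function(x, ...) {
  h <- x$hrv
  cat(sprintf(paste0("rr_analysis: %d intervals detected, %d kept ",
                     "(discarded ratio %.3f)\n"),
              h$n_total, h$n_kept, h$discarded_ratio))
  cat(sprintf("  SDNN %.2f ms, RMSSD %.2f ms\n", h$sdnn_ms, h$rmssd_ms))
  invisible(x)
}

#' @export
print.ppg_analysis <- function(x, ...) {
  if (!x$analyzable) {
    cat("ppg_analysis: no analyzable channel\n")
    return(invisible(x))
  }
  cat(sprintf("ppg_analysis: best channel %s, polarity %s\n",
              x$best_channel, x$best_polarity))
  print(x$best)
  invisible(x)
}

#' JSON-ready summary of an analysis result
#'
#' @param x a `ppg_analysis` or `channel_analysis`.
#' @return list with `sdnn_ms`, `rmssd_ms`, `discarded_ratio`, `n_total`,
#'   `n_kept`, `channel`, `polarity`.
#' @export
analysis_summary <- function(x) {
  if (inherits(x, "ppg_analysis")) {
    ch <- x$best_channel
    pol <- x$best_polarity
    r <- x$best
  } else if (inherits(x, "channel_analysis")) {
    ch <- NA_character_
    pol <- x$best_polarity
    r <- x$best
  } else {
    stop("unsupported object", call. = FALSE)
  }
  if (is.null(r)) {
    return(list(sdnn_ms = NA_real_, rmssd_ms = NA_real_,
                discarded_ratio = NA_real_, n_total = 0L, n_kept = 0L,
                channel = ch, polarity = pol))
  }
  h <- r$hrv
  list(sdnn_ms = h$sdnn_ms, rmssd_ms = h$rmssd_ms,
       discarded_ratio = h$discarded_ratio, n_total = h$n_total,
       n_kept = h$n_kept, channel = ch, polarity = pol)
}
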