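# Time-domain HRV metrics and the discarded-ratio signal-quality summary.

#' SDNN: standard deviation of RR intervals
#'
#' Population standard deviation (divisor `n`) of the interval lengths.
#' Invariant under permutation and under adding a constant.
#'
#' @param rr RR intervals in ms, length >= 2.
#' @return SDNN in ms.
#' @export
sdnn <- function(rr) {
  if (length(rr) < 2L) stop("SDNN needs at least 2 intervals", call. = FALSE)
  sqrt(mean((rr - mean(rr))^2))
}

#' RMSSD: root mean square of successive RR differences
#'
#' `sqrt(sum(diff(rr)^2) / (n - 1))`. Sensitive to the ordering of the
#' intervals, unlike SDNN.
#'
#' @param rr RR intervals in ms, length >= 2.
#' @return RMSSD in ms.
#' @export
rmssd <- function(rr) {
  if (length(rr) < 2L) stop("RMSSD needs at least 2 intervals", call. = FALSE)
  sqrt(mean(diff(rr)^2))
}

#' Discarded ratio: fraction of detected intervals rejected
#'
#' The per-signal quality summary: discarded over total detected
#' intervals. Zero by convention for an empty detection.
#'
#' @param n_discarded,n_total non-negative counts,
#'   `n_discarded <= n_total`.
#' @return fraction in \[0, 1\].
#' @export
discarded_ratio <- function(n_discarded, n_total) {
  if (n_discarded > n_total || n_discarded < 0) {
    stop("invalid counts: need 0 <= n_discarded <= n_total", call. = FALSE)
  }
  if (n_total == 0) return(0)
  n_discarded / n_total
}

#' HRV summary of a filtered interval sequence
#'
#' SDNN is computed over the kept intervals. RMSSD uses only successive
#' differences between intervals that are adjacent both in the kept
#' sequence and in the originally detected sequence (and in the same
#' chunk): a discarded interval breaks the difference chain, since the
#' difference across a gap is not a successive one.
#'
#' @param rr all detected RR intervals in ms, in temporal order.
#' @param kept logical, which intervals were kept.
#' @param chunk optional integer chunk id per interval; differences never
#'   span chunks.
#' @return list with `sdnn_ms`, `rmssd_ms` (NA when undefined),
#'   `discarded_ratio`, `n_total`, `n_kept`, `n_discarded`.
#' @export
hrv_summary <- function(rr, kept = rep(TRUE, length(rr)),
                        chunk = rep(1L, length(rr))) {
  n_total <- length(rr)
  n_kept <- sum(kept)
  rr_kept <- rr[kept]
  s <- if (n_kept >= 2L) sdnn(rr_kept) else NA_real_
  idx <- which(kept)
  dpairs <- idx[-length(idx)][diff(idx) == 1L &
                              chunk[idx[-length(idx)]] == chunk[idx[-1L]]]
  diffs <- if (length(idx) >= 2L) rr[dpairs + 1L] - rr[dpairs] else numeric(0)
  r <- if (length(diffs) >= 1L) sqrt(mean(diffs^2)) else NA_real_
  list(sdnn_ms = s, rmssd_ms = r,
       discarded_ratio = discarded_ratio(n_total - n_kept, n_total),
       n_total = n_total, n_kept = n_kept, n_discarded = n_total - n_kept)
}
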