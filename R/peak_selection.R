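# Choosing the ridge lines that correspond to heartbeats: persistence
# thresholds plus a log-normal RR likelihood under the estimated
# heart-rate curve.

# scale-value thresholds on a line's extremes (compared inclusively);
# full-height lines reach >= 0.244 s at the bottom and <= 0.069 s at the top
SEL_BOTTOM_SCALE <- 0.244
SEL_TOP_SCALE <- 0.069

#' Average log-likelihood score of an RR interval set
#'
#' Logarithms of RR intervals are modelled as normally distributed around
#' the log of the expected interval implied by the heart rate:
#' `-(1/k) * sum (log rr_i - log(1000/hrf_i))^2` with `rr` in ms and
#' `hrf` in Hz. Zero for an empty set by convention.
#'
#' @param rr RR intervals in ms (positive).
#' @param hrf expected heart-rate frequency in Hz during each interval.
#' @return a score `<= 0`; larger (closer to 0) is more plausible.
#' @export
estimated_likelihood <- function(rr, hrf) {
  if (length(rr) == 0L) return(0)
  stopifnot(length(rr) == length(hrf))
  if (any(rr <= 0) || any(hrf <= 0)) return(-Inf)
  expected <- 1000 / hrf
  -mean((log(rr) - log(expected))^2)
}

#' Select the ridge lines corresponding to heartbeats
#'
#' Lines spanning the scalogram's full persistence range (bottom scale at
#' least 0.244 s and top scale at most 0.069 s) are accepted outright.
#' Lines whose bottom lies between those levels (and whose top still
#' reaches at most 0.069 s) become candidates, swept from the
#' deepest-reaching downwards: a candidate is added if and only if the
#' RR-likelihood of the merged set under the heart-rate curve strictly
#' increases.
#'
#' @param lines list of `ridge_line`s (one chunk's worth).
#' @param hr_curve a `hr_curve` from [build_hr_curve()].
#' @param f sampling frequency in Hz.
#' @return list of chosen `ridge_line`s sorted by top position.
#' @export
select_ridge_lines <- function(lines, hr_curve, f) {
  if (length(lines) == 0L) return(list())
  bottom <- vapply(lines, function(l) l$bottom_scale, numeric(1))
  top <- vapply(lines, function(l) l$top_scale, numeric(1))
  tops_ok <- top <= SEL_TOP_SCALE
  chosen_idx <- which(bottom >= SEL_BOTTOM_SCALE & tops_ok)
  cand_idx <- which(bottom < SEL_BOTTOM_SCALE & bottom > SEL_TOP_SCALE & tops_ok)
  cand_idx <- cand_idx[order(bottom[cand_idx], decreasing = TRUE)]
  chosen_tops <- sort(vapply(lines[chosen_idx], function(l) l$top, numeric(1)))
  chosen <- lines[chosen_idx]
  score <- selection_score(chosen_tops, hr_curve, f)
  for (ci in cand_idx) {
    t_new <- lines[[ci]]$top
    prop_tops <- sort(c(chosen_tops, t_new))
    prop_score <- selection_score(prop_tops, hr_curve, f)
    if (prop_score > score) {
      chosen_tops <- prop_tops
      chosen <- c(chosen, lines[ci])
      score <- prop_score
    }
  }
  chosen[order(vapply(chosen, function(l) l$top, numeric(1)))]
}

selection_score <- function(tops, hr_curve, f) {
  if (length(tops) < 2L) return(0)
  rr <- diff(tops) / f * 1000
  if (any(rr <= 0)) return(-Inf)
  mid <- (utils::head(tops, -1) + utils::tail(tops, -1)) / 2
  hrf <- hrf_at_samples(hr_curve, mid, f)
  estimated_likelihood(rr, hrf)
}

#' Peaks and RR intervals from chosen ridge lines
#'
#' Beat (R peak) locations are the top points of the chosen ridge lines at
#' the smallest scale reached; RR intervals are their successive
#' differences in milliseconds.
#'
#' @param chosen list of chosen `ridge_line`s.
#' @param f sampling frequency in Hz.
#' @return list with `peaks` (sorted sample indices) and `rr_ms`.
#' @export
peaks_from_lines <- function(chosen, f) {
  peaks <- sort(vapply(chosen, function(l) l$top, numeric(1)))
  rr <- if (length(peaks) >= 2L) diff(peaks) / f * 1000 else numeric(0)
  list(peaks = peaks, rr_ms = rr)
}
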