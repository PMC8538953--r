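# Mexican-hat CWT scalogram on 50 geometric scales, ridge points and
# ridge-line linking.

N_SCALES <- 50L
SCALE_BASE <- 0.05
SCALE_RATIO <- 1.0376
WAVELET_SUPPORT <- 5  # truncate at |t| <= 5a; psi < 2e-5 beyond

#' Mexican hat (Ricker) mother wavelet
#'
#' `psi(t) = (2/sqrt(3)) * pi^(-1/4) * (1 - t^2) * exp(-t^2/2)`,
#' proportional to the negative second derivative of a Gaussian. Zero-mean
#' and even, with a single positive central lobe that matches the shape of
#' a PPG pulse peak.
#'
#' @param t time in seconds (vectorised).
#' @return wavelet values.
#' @export
mexican_hat <- function(t) {
  (2 / sqrt(3)) * pi^(-1 / 4) * (1 - t^2) * exp(-t^2 / 2)
}

#' Geometric grid of analysis scales
#'
#' Fifty scales `a_k = 0.05 * 1.0376^(k-1)` seconds, evenly spaced on a
#' log axis from 0.05 to about 0.3 s. The smallest scale localises pulse
#' peaks sharply; the largest smooths away everything but the beat rhythm.
#'
#' @return numeric vector of 50 scales in seconds.
#' @export
scale_grid <- function() {
  SCALE_BASE * SCALE_RATIO^(seq_len(N_SCALES) - 1)
}

#' Mexican-hat CWT scalogram of a signal
#'
#' Finite-sum approximation to the continuous wavelet transform:
#' `coef[k, n] = sum_m x_m a_k^(-1/2) psi((t_m - t_n)/a_k) dt`,
#' with the wavelet truncated at `|t| <= 5 a_k` and zero padding at the
#' boundaries. Computed per scale by FFT correlation.
#'
#' @param sig a `uniform_signal` (or any list with `samples` and `f`).
#' @return a `ppg_scalogram`: list with `coef` (50 x N matrix), `scales`,
#'   `f`.
#' @export
compute_scalogram <- function(sig) {
  x <- sig$samples
  f <- sig$f
  n <- length(x)
  scales <- scale_grid()
  coef <- matrix(0, nrow = N_SCALES, ncol = n)
  if (n > 0L) {
    dt <- 1 / f
    l_max <- ceiling(WAVELET_SUPPORT * scales[N_SCALES] * f)
    m <- stats::nextn(n + 2L * l_max + 2L)
    xp <- c(x, rep(0, m - n))
    fx <- stats::fft(xp)
    for (k in seq_len(N_SCALES)) {
      a <- scales[k]
      l <- ceiling(WAVELET_SUPPORT * a * f)
      j <- (-l):l
      w <- mexican_hat(j / (f * a)) / sqrt(a) * dt
      # place w_j at wrapped positions so that ifft gives sum_j x_{n+j} w_j
      wfull <- rep(0, m)
      wfull[((j + m) %% m) + 1L] <- w
      y <- Re(stats::fft(fx * Conj(stats::fft(wfull)), inverse = TRUE)) / m
      coef[k, ] <- y[seq_len(n)]
    }
  }
  structure(list(coef = coef, scales = scales, f = f), class = "ppg_scalogram")
}

#' Ridge points: per-scale local maxima of the scalogram
#'
#' A point `(a_k, t_n)` is a ridge point if the scalogram row at scale
#' `a_k` has a local maximum at sample `n` — the instant where the signal
#' most resembles a peak of width `a_k`. Flat-topped maxima are reported
#' at their midpoints.
#'
#' @param scal a `ppg_scalogram`.
#' @return list of 50 integer vectors, the ridge-point sample indices per
#'   scale row.
#' @export
find_ridge_points <- function(scal) {
  lapply(seq_len(nrow(scal$coef)), function(k) {
    local_maxima(scal$coef[k, ], plateau = "midpoint")
  })
}

#' Link ridge points into ridge lines
#'
#' Greedy nearest-neighbour linking from the largest scale downward: every
#' ridge point at the largest scale starts a line; a line whose current
#' point sits at scale row `k` connects to the nearest ridge point at row
#' `k - 1` within `0.5 * a_k * f` samples (peak drift across scales is
#' proportional to scale). Conflicts are resolved by smallest distance;
#' unmatched points start new lines; every ridge point joins exactly one
#' line.
#'
#' @param ridge_points output of [find_ridge_points()].
#' @param scales the scale grid (seconds).
#' @param f sampling frequency in Hz.
#' @return list of `ridge_line`s, each a list with `k` (increasing scale
#'   indices, contiguous), `n` (sample index per scale), `top` (sample at
#'   the smallest scale reached), `top_scale`, `bottom_scale`.
#' @export
link_ridge_lines <- function(ridge_points, scales = scale_grid(), f) {
  n_rows <- length(ridge_points)
  lines_k <- list()   # per line: vector of scale rows (descending while built)
  lines_n <- list()
  active <- integer(0)          # line ids
  active_pos <- numeric(0)      # their current sample positions
  next_id <- 1L
  start_lines <- function(pts) {
    ids <- seq.int(next_id, length.out = length(pts))
    for (i in seq_along(pts)) {
      lines_k[[ids[i]]] <<- n_rows_cur
      lines_n[[ids[i]]] <<- pts[i]
    }
    next_id <<- next_id + length(pts)
    ids
  }
  n_rows_cur <- n_rows
  ids <- if (length(ridge_points[[n_rows]]) > 0L) start_lines(ridge_points[[n_rows]]) else integer(0)
  active <- ids
  active_pos <- as.numeric(ridge_points[[n_rows]])
  for (k in seq(n_rows, 2L)) {
    pts <- ridge_points[[k - 1L]]
    tol <- 0.5 * scales[k] * f
    matched_line <- integer(0)
    matched_pt <- integer(0)
    if (length(active) > 0L && length(pts) > 0L) {
      # nearest candidate point for each active line
      nearest <- findInterval(active_pos, pts)
      cand_lo <- pmax(nearest, 1L)
      cand_hi <- pmin(nearest + 1L, length(pts))
      d_lo <- abs(active_pos - pts[cand_lo])
      d_hi <- abs(active_pos - pts[cand_hi])
      # build pair table (both neighbours, dedup later via greedy)
      pair_line <- c(seq_along(active), seq_along(active))
      pair_pt <- c(cand_lo, cand_hi)
      pair_d <- c(d_lo, d_hi)
      ok <- pair_d <= tol
      pair_line <- pair_line[ok]; pair_pt <- pair_pt[ok]; pair_d <- pair_d[ok]
      if (length(pair_d) > 0L) {
        ord <- order(pair_d)
        used_line <- rep(FALSE, length(active))
        used_pt <- rep(FALSE, length(pts))
        for (i in ord) {
          li <- pair_line[i]; pi <- pair_pt[i]
          if (!used_line[li] && !used_pt[pi]) {
            used_line[li] <- TRUE
            used_pt[pi] <- TRUE
            matched_line <- c(matched_line, li)
            matched_pt <- c(matched_pt, pi)
          }
        }
      }
    }
    # extend matched lines
    new_active <- integer(0)
    new_pos <- numeric(0)
    if (length(matched_line) > 0L) {
      for (i in seq_along(matched_line)) {
        id <- active[matched_line[i]]
        lines_k[[id]] <- c(lines_k[[id]], k - 1L)
        lines_n[[id]] <- c(lines_n[[id]], pts[matched_pt[i]])
      }
      new_active <- active[matched_line]
      new_pos <- as.numeric(pts[matched_pt])
    }
    # unmatched points start new lines
    un_pts <- if (length(matched_pt) > 0L) pts[-matched_pt] else pts
    if (length(un_pts) > 0L) {
      n_rows_cur <- k - 1L
      ids <- start_lines(un_pts)
      new_active <- c(new_active, ids)
      new_pos <- c(new_pos, as.numeric(un_pts))
    }
    active <- new_active
    active_pos <- new_pos
  }
  lapply(seq_len(next_id - 1L), function(id) {
    ks <- rev(lines_k[[id]])
    ns <- rev(lines_n[[id]])
    structure(list(k = ks, n = ns, top = ns[1L],
                   top_scale = scales[ks[1L]],
                   bottom_scale = scales[ks[length(ks)]]),
              class = "ridge_line")
  })
}
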