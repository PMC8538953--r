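test_that("resampling interpolates linearly onto the uniform grid", {
  r <- resample_uniform(c(0, 1000), c(0, 100), f = 100)
  expect_length(r$samples, 101L)
  expect_equal(r$samples, seq(0, 100, length.out = 101))

  # intermediate collinear points change nothing
  r2 <- resample_uniform(c(0, 500, 1000), c(0, 50, 100), f = 100)
  expect_equal(r2$samples, r$samples)

  # sample count is floor(duration * f) + 1 for arbitrary input
  set.seed(1)
  tms <- cumsum(runif(40, 20, 45))
  r3 <- resample_uniform(tms, rnorm(40), f = 100)
  expect_length(r3$samples,
                floor((tms[40] - tms[1]) / 1000 * 100) + 1)

  expect_error(resample_uniform(0, 1), "at least 2")
  expect_error(resample_uniform(c(0, 0, 10), c(1, 2, 3)), "increasing")
})

test_that("rescaling maps the observed range onto (0, 255)", {
  expect_equal(as.numeric(rescale_to_standard(c(0, 0.5, 1), c(0, 1))),
               c(0, 127.5, 255))
  x <- c(0, 100, 255)
  expect_equal(as.numeric(rescale_to_standard(x, c(0, 255))), x)
  expect_equal(as.numeric(rescale_to_standard(0, c(-1, 1))), 127.5)
  cst <- rescale_to_standard(rep(7, 5))
  expect_true(attr(cst, "constant"))
  expect_equal(as.numeric(cst), rep(0, 5))
})

test_that("running amplitude is the sliding max-min", {
  f <- 100
  expect_equal(running_amplitude(rep(3, 300), f), rep(0, 300))

  tt <- (0:499) / f
  x <- sin(2 * pi * 2 * tt)
  amp <- running_amplitude(x, f)
  expect_true(all(abs(amp[100:400] - 2) < 0.01))

  spike <- rep(0, 300); spike[150] <- 4
  amp2 <- running_amplitude(spike, f)
  expect_equal(max(amp2), 4)
  expect_equal(amp2[150], 4)

  # agrees with a naive sliding window
  set.seed(2)
  y <- rnorm(120)
  naive <- sapply(seq_along(y), function(i) {
    w <- y[max(1, i - 50):min(120, i + 50)]
    max(w) - min(w)
  })
  expect_equal(running_amplitude(y, f), naive)
})

test_that("step detection flags the window around an amplitude burst", {
  f <- 100
  tt <- (0:5999) / f
  x <- sin(2 * pi * 1.3 * tt)
  expect_false(any(detect_steps(x, f)))

  x2 <- x
  x2[3000:6000] <- x2[3000:6000] + 10       # abrupt 10x step
  mask <- detect_steps(x2, f)
  expect_true(any(mask[2950:3050]))
  # flags stay local to the step (within the 1 s dilation window)
  expect_false(any(mask[1:2850]))
  expect_false(any(mask[3200:6000]))

  # oracle: direct threshold on the sliding amplitude, dilated
  amp <- running_amplitude(x2, f)
  core <- amp > 4 * median(amp)
  expect_true(all(which(core) %in% which(mask)))

  expect_false(any(detect_steps(rep(5, 1000), f)))  # median-0 guard
})

test_that("constant detection flags dropouts on the (0,255) scale", {
  f <- 100
  expect_true(all(detect_constant(rep(128, 500), f)))
  tt <- (0:1999) / f
  x <- 127.5 + 100 * sin(2 * pi * 1.3 * tt)
  expect_false(any(detect_constant(x, f)))
  x[800:1100] <- x[800]                       # 3 s plateau
  mask <- detect_constant(x, f)
  expect_true(all(mask[870:1030]))            # plateau interior
  expect_false(any(mask[1:700]))
})

test_that("chunking drops short runs, detrends and low-pass filters", {
  f <- 100
  tt <- (0:5999) / f
  x <- 127 + 50 * sin(2 * pi * 1.2 * tt)
  sig <- chunk_and_clean(x, f)
  expect_equal(nrow(sig$chunks), 1L)
  expect_equal(unname(sig$chunks[1, ]), c(1L, 6000L))

  # a 1.5 s run between flags does not survive; the 30 s one does
  flags <- rep(FALSE, 6000)
  flags[1:2000] <- TRUE
  flags[2151:3000] <- TRUE                    # leaves 1.5 s then 30 s
  sig2 <- chunk_and_clean(x, f, flags)
  expect_equal(nrow(sig2$chunks), 1L)
  expect_equal(unname(sig2$chunks[1, ]), c(3001L, 6000L))
  expect_true(all(sig2$samples[1:3000] == 0))

  # detrending: for a constant + 1 Hz tone (a whole number of cycles per
  # 2 s window) the interior running mean of the cleaned chunk vanishes
  x1 <- 100 + 40 * sin(2 * pi * 1.0 * tt)
  y <- chunk_and_clean(x1, f)$samples
  rm2 <- ppghrv:::running_mean(y, 200)
  interior <- 300:5700
  expect_lt(max(abs(rm2[interior])), 0.01 * (max(y) - min(y)))

  # all-flagged input yields an empty signal
  sig3 <- chunk_and_clean(x, f, rep(TRUE, 6000))
  expect_equal(nrow(sig3$chunks), 0L)
  expect_true(all(sig3$samples == 0))
})

test_that("cleaning passes the heart-rate band and kills 20 Hz", {
  f <- 100
  tt <- (0:5999) / f
  idx <- 500:5500
  fit_amp <- function(y, freq) {
    ts <- tt[idx]
    co <- coef(lm(y ~ sin(2 * pi * freq * ts) + cos(2 * pi * freq * ts)))
    sqrt(co[2]^2 + co[3]^2)
  }
  x <- 127 + 40 * sin(2 * pi * 1.5 * tt) + 10 * sin(2 * pi * 20 * tt)
  sig <- chunk_and_clean(x, f)
  a15 <- fit_amp(sig$samples[idx], 1.5)
  a20 <- fit_amp(sig$samples[idx], 20)
  expect_gt(20 * log10(40 / a15), -1)   # < 1 dB change at 1.5 Hz
  expect_lt(20 * log10(40 / a15), 1)
  expect_gt(20 * log10(10 / a20), 20)   # >= 20 dB attenuation at 20 Hz
})

test_that("cleaning an already-clean signal keeps chunk boundaries", {
  f <- 100
  tt <- (0:5999) / f
  x <- 127 + 50 * sin(2 * pi * 1.2 * tt)
  flags <- rep(FALSE, 6000); flags[2500:2700] <- TRUE
  sig <- chunk_and_clean(x, f, flags)
  again <- chunk_and_clean(sig$samples, f, !sig$valid)
  expect_equal(again$chunks, sig$chunks)
})
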