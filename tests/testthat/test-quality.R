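test_that("correlation similarity is shape-based and clipped at zero", {
  x <- sin(seq(0, 2 * pi, length.out = 80))
  expect_equal(correlation_similarity(x, x), 1.0)
  expect_equal(correlation_similarity(x, -x), 0.0)
  # same shape, different lengths: resampling makes them near-identical
  y <- sin(seq(0, 2 * pi, length.out = 130))
  expect_gt(correlation_similarity(x, y), 0.999)
  expect_equal(correlation_similarity(rep(1, 50), x), 0)
})

test_that("amplitude similarity follows the calibrated sigmoid", {
  x <- c(0, 1)
  expect_equal(amplitude_similarity(x, x), 1 / (1 + exp(-5)))
  expect_equal(amplitude_similarity(x, 3.5 * x), 0.5)
  expect_equal(amplitude_similarity(5 * x, x), 1 / (1 + exp(3)))
  expect_equal(amplitude_similarity(x, c(2, 2)), 0)
})

test_that("similarity quality combines neighbour similarities geometrically", {
  f <- 100
  # identical repeated pulses: every interval scores sqrt(1 * sigmoid(5))
  beats <- seq(1, 9, by = 0.8)
  x <- render_train(beats, 10, f)
  peaks <- round(beats * f) + 1
  q <- similarity_quality(x, peaks)
  expect_length(q, length(peaks) - 1L)
  expect_equal(q, rep(sqrt(1 / (1 + exp(-5))), length(q)), tolerance = 1e-3)

  # an uncorrelated middle interval scores 0 and edges use one neighbour
  set.seed(4)
  x2 <- x
  a <- peaks[4]; b <- peaks[5]
  x2[a:b] <- -x2[a:b] + rnorm(b - a + 1, sd = 1e-3)
  q2 <- similarity_quality(x2, peaks)
  expect_equal(q2[4], 0)
  expect_equal(q2[1], ppghrv:::similarity_score(x2[peaks[1]:peaks[2]],
                                                x2[peaks[2]:peaks[3]]))
  expect_equal(similarity_quality(x, peaks[1:2]), 0)  # single interval
})

test_that("ridge-shape quality reflects the spread of line separation", {
  f <- 100
  l1 <- make_line(100)
  l2 <- make_line(180)
  expect_equal(cwt_quality(l1, l2, f), 1 / (1 + exp(-10)))

  # diverging lines: separation grows by 200 ms across scales; quality is
  # low and equals the oracle composition (std of distances, then sigmoid)
  l3 <- make_line(180)
  l3$n <- l3$n + round(seq(0, 0.2 * f, length.out = 50))
  div_std <- sd(abs(l1$n - l3$n)) / f * 1000
  expect_equal(cwt_quality(l1, l3, f), 1 / (1 + exp(-(50 - div_std) / 5)))
  expect_lt(cwt_quality(l1, l3, f), 0.2)

  # sd of 50 ms maps to exactly 0.5 under the corrected sign; the
  # as-printed variant is its mirror image
  l4 <- make_line(180)
  d <- rep(c(-5, 5), 25)                      # sd = 5 samples = 50 ms
  l4$n <- l4$n + d - round(mean(d))
  q <- cwt_quality(l1, l4, f)
  qp <- cwt_quality(l1, l4, f, eq18_as_printed = TRUE)
  rr_std <- sd(abs(l1$n - l4$n)) / f * 1000
  expect_equal(q, 1 / (1 + exp(-(50 - rr_std) / 5)))
  expect_equal(qp, 1 - q)

  l5 <- make_line(300, k_lo = 1L, k_hi = 1L)
  expect_equal(cwt_quality(l1, l5, f), 0)     # < 2 shared levels
})

test_that("adaptive threshold reproduces the worked examples and the
           exhaustive argmax on random vectors", {
  r1 <- adaptive_threshold_filter(c(0.9, 0.9, 0.9))
  expect_equal(r1$cutoff, 0.9)
  expect_true(all(r1$kept))

  r2 <- adaptive_threshold_filter(c(1.0, 0.85))
  expect_equal(r2$cutoff, 0.85)
  expect_true(all(r2$kept))

  r3 <- adaptive_threshold_filter(c(0.99, 0.99, 0.81))
  expect_equal(r3$cutoff, 0.81)
  expect_true(all(r3$kept))

  expect_false(any(adaptive_threshold_filter(c(0.5, 0.79))$kept))

  # oracle: evaluate the objective over every candidate cutoff directly
  set.seed(99)
  for (trial in 1:200) {
    q <- round(runif(sample(1:40, 1), 0.5, 1), 3)
    got <- adaptive_threshold_filter(q)
    want <- threshold_oracle(q)
    expect_identical(got$kept, want$kept)
    expect_identical(got$cutoff, want$cutoff)
  }
})

test_that("outlier rules flag spikes, splits and extremes, matching an
           independent transcription", {
  expect_false(any(outlier_filter(rep(800, 30))))

  rr <- rep(800, 30); rr[15] <- 1400
  expect_true(outlier_filter(rr)[15])          # > 1.6 * median

  # a 400/1200 adjacent pair amid ordinary variability trips the
  # spike-pair rule and flags both
  set.seed(55)
  rr2 <- rnorm(30, 800, 60); rr2[15] <- 400; rr2[16] <- 1200
  fl <- outlier_filter(rr2)
  expect_true(fl[15] && fl[16])

  expect_length(outlier_filter(800), 1L)
  expect_false(outlier_filter(800))

  set.seed(123)
  for (trial in 1:200) {
    rr <- random_rr(sample(2:60, 1))
    expect_identical(outlier_filter(rr), outlier_oracle(rr))
  }
})

test_that("interval assessment multiplies the qualities and localizes
           corruption", {
  sr <- synth_record(synth_spec(
    seed = 1, corruption = list(list(start_s = 40, end_s = 80,
                                     kind = "white_noise"))))
  res <- analyze_channel(sr$record$Time, sr$record$G)
  iv <- res$best$intervals
  expect_true(all(iv$q <= pmin(iv$q_sim, iv$q_cwt) + 1e-12))
  expect_true(all(iv$q >= 0 & iv$q <= 1))
  expect_true(all(iv$kept == (iv$q > 0.8 & !iv$outlier &
                              iv$q >= attr(iv, "cutoff"))))
  t0 <- iv$peak_time_ms / 1000
  t1 <- t0 + iv$rr_ms / 1000
  corrupted <- t1 > 40 & t0 < 80
  expect_gte(mean(!iv$kept[corrupted]), 0.8)
  expect_lte(mean(!iv$kept[!corrupted]), 0.1)

  # a zero ridge-shape quality forces the interval out
  expect_false(any(iv$kept[iv$q_cwt == 0]))
})

test_that("weakening one interval's correlation never raises its quality", {
  f <- 100
  beats <- seq(1, 14.6, by = 0.8)
  x <- render_train(beats, 16, f)
  peaks <- round(beats * f) + 1
  base_q <- similarity_quality(x, peaks)
  target <- 9L
  set.seed(8)
  noise <- rnorm(peaks[target + 1] - peaks[target] + 1)
  for (w in c(0.2, 0.5, 1.0, 2.0)) {
    x2 <- x
    idx <- peaks[target]:peaks[target + 1]
    x2[idx] <- x2[idx] + w * noise
    q2 <- similarity_quality(x2, peaks)
    expect_lte(q2[target], base_q[target] + 1e-9)
  }
})
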