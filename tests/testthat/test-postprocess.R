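# Time-course post-processing

test_that("motion QC applies the printed thresholds as strict bounds", {
  expect_false(as.logical(qc_exclude_subject(0.1, 0.1)))
  ex1 <- qc_exclude_subject(0.31, 0.1)
  expect_true(as.logical(ex1))
  expect_equal(attr(ex1, "reason"), "max_displacement")
  ex2 <- qc_exclude_subject(0.1, 3.01)
  expect_true(as.logical(ex2))
  expect_equal(attr(ex2, "reason"), "mean_fd")
  expect_false(as.logical(qc_exclude_subject(0.3, 3.0)))   # at threshold: keep
  expect_error(qc_exclude_subject(-0.1, 0.1), "non-negative")
})

test_that("initial-volume discard drops exactly the leading rows", {
  X <- matrix(seq_len(788 * 2), 788, 2)
  out <- discard_initial_volumes(X, 18)
  expect_equal(nrow(out), 770)
  expect_equal(out[1, ], X[19, ])
  expect_identical(discard_initial_volumes(X, 0), X)
  expect_error(discard_initial_volumes(X[1:10, ], 10), "smaller than T")
})

test_that("polynomial detrend annihilates cubics and keeps in-band signal", {
  t <- seq_len(770)
  cubic <- 2 + t - 0.5 * t^2 + 0.01 * t^3
  out <- polynomial_detrend(cbind(cubic, 0))
  expect_lt(max(abs(out)), 1e-7 * max(abs(cubic)))
  expect_equal(out[, 2], rep(0, 770))

  # oracle: residual by explicit normal equations must match, and the
  # sinusoid must survive detrending nearly intact
  sinus <- sin(2 * pi * 0.05 * t * 0.72)
  y <- cubic + sinus
  ts <- t / length(t)
  B <- cbind(1, ts, ts^2, ts^3)
  resid_oracle <- y - B %*% solve(crossprod(B), crossprod(B, y))
  out2 <- polynomial_detrend(cbind(y))
  expect_equal(as.numeric(out2), as.numeric(resid_oracle), tolerance = 1e-6)
  expect_gt(cor(as.numeric(out2), sinus), 0.99)
})

test_that("despiking replaces only flagged points, by neighbour interpolation", {
  set.seed(42)
  x <- rnorm(500)
  x_clean <- x[abs(x - median(x)) / mad(x) <= 4]
  expect_equal(despike(cbind(x_clean)), cbind(x_clean), ignore_attr = TRUE)

  x2 <- x
  x2[100] <- 50
  out <- despike(cbind(x2))
  expect_equal(attr(out, "n_replaced"), 1L)
  expect_lt(abs(out[100, 1]), 4)
  expect_identical(unname(out[-100, 1]), x2[-100])
  # interpolation oracle: midpoint of the flanking clean samples
  expect_equal(unname(out[100, 1]), (x2[99] + x2[101]) / 2)

  const <- matrix(1, 100, 1)
  expect_identical(despike(const)[, 1], const[, 1])
})

test_that("Butterworth filter matches its analytic magnitude response", {
  TR <- 0.72
  t <- (0:2047) * TR
  # DC gain 1 (away from the short edge-padding transient)
  const <- matrix(5, 2048, 1)
  yc <- butterworth_lowpass(const, TR = TR)
  expect_equal(yc[100:1948, 1], const[100:1948, 1], tolerance = 1e-8)

  # -3 dB at the cutoff for a single forward pass
  s15 <- matrix(sin(2 * pi * 0.15 * t), ncol = 1)
  y <- butterworth_lowpass(s15, zero_phase = FALSE, TR = TR)
  amp <- fitted_amplitude(y[, 1], 0.15, TR)
  expect_equal(amp, 2^(-1 / 2), tolerance = 0.02)

  # order-5 stopband: > 20 dB down at 0.5 Hz
  s50 <- matrix(sin(2 * pi * 0.5 * t), ncol = 1)
  y2 <- butterworth_lowpass(s50, zero_phase = FALSE, TR = TR)
  expect_lt(fitted_amplitude(y2[, 1], 0.5, TR), 10^(-20 / 20))

  expect_error(butterworth_lowpass(s15, cutoff_hz = 0.7, TR = TR), "Nyquist")
})

test_that("nuisance regression orthogonalises against the regressors", {
  set.seed(7)
  n <- 300
  motion <- matrix(rnorm(n * 6), n, 6)
  signal <- rnorm(n)
  y <- 0.7 * motion[, 1] + signal
  out <- regress_nuisance(cbind(y), motion)
  for (r in seq_len(6)) {
    expect_lt(abs(sum(out[, 1] * motion[, r])) /
                (sqrt(sum(out^2)) * sqrt(sum(motion[, r]^2))), 1e-6)
  }
  # oracle: residual via explicit normal equations
  D <- cbind(1, motion)
  resid_oracle <- y - D %*% solve(crossprod(D), crossprod(D, y))
  expect_equal(out[, 1], as.numeric(resid_oracle), tolerance = 1e-8)

  # regressing a column on itself leaves ~nothing
  self <- regress_nuisance(cbind(y), cbind(y))
  expect_lt(max(abs(self)), 1e-8 * sd(y))

  # orthogonal regressor changes the column only by mean removal
  z <- rnorm(n)
  z_orth <- qr.resid(qr(cbind(1, y)), z)
  kept <- regress_nuisance(cbind(y), cbind(z_orth))
  expect_equal(kept[, 1], y - mean(y), tolerance = 1e-8)

  expect_warning(regress_nuisance(cbind(y), cbind(motion[, 1], motion[, 1])),
                 "collinear")
})

test_that("low-frequency power ratio concentrates where the signal lives", {
  TR <- 0.72
  t <- (0:1023) * TR
  slow <- sin(2 * pi * 0.05 * t)
  fast <- sin(2 * pi * 0.4 * t)
  r <- low_freq_power_ratio(cbind(slow, fast), band_edge_hz = 0.15, TR = TR)
  expect_gt(r[1], 10)
  expect_lt(r[2], 0.1)

  # white noise: ratio ~ bandwidth ratio below/above the edge
  set.seed(1)
  noise <- matrix(rnorm(4096 * 20), 4096, 20)
  rn <- low_freq_power_ratio(noise, band_edge_hz = 0.15, TR = TR)
  nyq <- 1 / (2 * TR)
  expect_equal(mean(rn), 0.15 / (nyq - 0.15), tolerance = 0.2)
})

test_that("pipeline preserves shape and projection stages are idempotent", {
  co <- small_two_state_cohort(C = 4, T_points = 200, n_per_group = 1)
  tc <- co$subjects[[1]]
  out <- postprocess_timecourses(tc, n_discard = 0)
  expect_s3_class(out, "component_timecourses")
  expect_equal(dim(out$data), dim(tc$data))
  expect_identical(out$subject_id, tc$subject_id)
  expect_true(all(is.finite(out$data)))

  # detrend and regression are projections: applying twice changes nothing
  dd <- polynomial_detrend(polynomial_detrend(tc))
  expect_equal(dd$data, polynomial_detrend(tc)$data, tolerance = 1e-9)
  reg <- matrix(rnorm(200 * 2), 200, 2)
  r1 <- regress_nuisance(tc, reg)
  r2 <- regress_nuisance(r1, reg)
  expect_lt(sqrt(mean((r2$data - r1$data)^2)), 1e-6)
})

test_that("despike changes exactly as many entries as it flags", {
  set.seed(9)
  X <- matrix(rnorm(300 * 3), 300, 3)
  X[c(10, 200), 1] <- c(30, -25)
  X[50, 3] <- 40
  out <- despike(X)
  changed <- sum(out != X)
  expect_equal(changed, sum(attr(out, "n_replaced")))
  expect_equal(attr(out, "n_replaced"), c(2L, 0L, 1L))
})
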