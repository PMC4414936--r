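# EMG pre-processing chain: filters, activation dynamics, nonlinearity,
# MVC normalization and the dead-band value rectification.

test_that("high-pass filter removes DC and passes the signal band", {
  fs <- 1000
  # constant input: the final second must be driven to (near) zero
  const <- emg_trace(rep(5, 10 * fs), fs)
  out <- highpass_filter(const, 10, 4)
  expect_equal(nrow(out), 10 * fs)
  expect_lt(abs(mean(tail(out$emg, fs))), 1e-3)

  # 100 Hz sinusoid, one decade above cutoff: steady-state amplitude
  # within 1% (4th-order Butterworth magnitude at f/fc = 10 is ~1)
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  s100 <- emg_trace(sin(2 * pi * 100 * t), fs)
  out100 <- highpass_filter(s100, 10, 4)
  amp <- max(abs(tail(out100$emg, fs)))
  expect_lt(abs(amp - 1), 0.01)

  # 1 Hz sinusoid, one decade below cutoff: >= 70 dB attenuation
  # (80 dB/decade roll-off of a 4th-order filter)
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  s1 <- emg_trace(sin(2 * pi * 1 * t), fs)
  out1 <- highpass_filter(s1, 10, 4)
  amp1 <- max(abs(tail(out1$emg, 2 * fs)))
  expect_lt(20 * log10(amp1), -70)

  expect_error(highpass_filter(emg_trace(rnorm(10), fs), 600), "Nyquist")
})

test_that("rectification is the absolute value and is idempotent", {
  tr <- emg_trace(c(-1, 2, -3), 1000, stage = "highpassed")
  expect_equal(rectify(tr)$emg, c(1, 2, 3))
  z <- emg_trace(rep(0, 5), 1000, stage = "highpassed")
  expect_equal(rectify(z)$emg, rep(0, 5))
  nn <- emg_trace(c(0.5, 1, 2), 1000, stage = "highpassed")
  expect_equal(rectify(rectify(nn))$emg, c(0.5, 1, 2))
})

test_that("filter coefficients satisfy the second-order constraints", {
  c0 <- make_filter_coefficients(0, 0, 0)
  expect_equal(c0$alpha, 1)
  expect_equal(c0$beta1, 0)
  expect_equal(c0$beta2, 0)

  c1 <- make_filter_coefficients(-0.5, -0.5, 0)
  expect_equal(c1$beta1, -1)
  expect_equal(c1$beta2, 0.25)
  expect_equal(c1$alpha, 0.25)
  # alpha - beta1 - beta2 = 1 for any valid poles
  for (g in list(c(-0.9, 0.3), c(0.2, 0.7), c(-0.99, -0.99))) {
    cc <- make_filter_coefficients(g[1], g[2])
    expect_equal(cc$alpha - cc$beta1 - cc$beta2, 1)
  }
  expect_error(make_filter_coefficients(0.9, 1.1), "Unstable")
  expect_error(make_filter_coefficients(-0.5, -0.5, -3), "integer")
})

test_that("activation dynamics match a brute-force difference-equation loop", {
  # independent oracle: evaluate u(t) = alpha e(t-d) - b1 u(t-1) - b2 u(t-2)
  # sample by sample
  oracle <- function(e, cf) {
    n <- length(e)
    u <- numeric(n)
    for (t in seq_len(n)) {
      ed <- if (t - cf$delay_samples >= 1) e[t - cf$delay_samples] else 0
      u1 <- if (t >= 2) u[t - 1] else 0
      u2 <- if (t >= 3) u[t - 2] else 0
      u[t] <- cf$alpha * ed - cf$beta1 * u1 - cf$beta2 * u2
    }
    u
  }
  withr::with_seed(11, {
    for (g in list(c(-0.5, -0.5, 0L), c(-0.3, 0.4, 10L), c(0.6, -0.8, 3L))) {
      cf <- make_filter_coefficients(g[1], g[2], g[3])
      e <- emg_trace(abs(rnorm(500)), 1000, stage = "rectified")
      got <- activation_dynamics(e, cf)$emg
      expect_equal(got, oracle(e$emg, cf), tolerance = 1e-12)
    }
  })
})

test_that("activation dynamics have unity DC gain and delay property", {
  fs <- 1000
  step <- emg_trace(rep(1, 3 * fs), fs, stage = "rectified")
  cf <- make_filter_coefficients(-0.5, -0.5, 0)
  out <- activation_dynamics(step, cf)
  expect_equal(tail(out$emg, 1), 1, tolerance = 1e-6)

  # unity DC gain for arbitrary stable poles (steady state = input level)
  withr::with_seed(3, {
    for (k in 1:10) {
      g <- runif(2, -0.95, 0.95)
      cf <- make_filter_coefficients(g[1], g[2])
      lvl <- runif(1, 0.1, 1)
      con <- emg_trace(rep(lvl, 4 * fs), fs, stage = "rectified")
      out <- activation_dynamics(con, cf)
      expect_equal(tail(out$emg, 1), lvl, tolerance = 1e-6)
    }
  })

  z <- activation_dynamics(emg_trace(rep(0, 100), fs, stage = "rectified"), cf)
  expect_equal(z$emg, rep(0, 100))

  imp <- emg_trace(c(1, rep(0, 99)), fs, stage = "rectified")
  cfd <- make_filter_coefficients(-0.5, -0.5, 10)
  got <- activation_dynamics(imp, cfd)$emg
  expect_equal(got[1:10], rep(0, 10))
  expect_gt(got[11], 0)
})

test_that("low-pass smoothing has unity DC gain and kills fast ripple", {
  fs <- 1000
  con <- emg_trace(rep(0.5, 30 * fs), fs, stage = "excitation")
  out <- lowpass_smooth(con, 1, 2)
  expect_equal(tail(out$emg, 1), 0.5, tolerance = 1e-3)

  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  rip <- emg_trace(0.5 + 0.1 * sin(2 * pi * 50 * t), fs, stage = "excitation")
  outr <- lowpass_smooth(rip, 1, 2)
  resid <- tail(outr$emg, 5 * fs) - 0.5
  expect_lt(max(abs(resid)), 1e-3)

  z <- lowpass_smooth(emg_trace(rep(0, 100), fs, stage = "excitation"), 1)
  expect_equal(z$emg, rep(0, 100))
})

test_that("activation nonlinearity matches its closed form and is monotone", {
  fs <- 1000
  u <- emg_trace(c(0, 1, 0.999999), fs, stage = "excitation")
  a <- activation_nonlinearity(u, A = 2, R = 0.5)
  expect_equal(a$activation[1], 0)
  expect_equal(a$activation[2], 1, tolerance = 1e-9)  # u = R*A endpoint

  a2 <- activation_nonlinearity(emg_trace(1, fs, stage = "excitation"),
                                A = 2, R = 1)
  expect_equal(a2$activation, (exp(1) - 1) / (exp(2) - 1), tolerance = 1e-9)
  expect_equal(a2$activation, 0.2689414, tolerance = 1e-6)

  grid <- emg_trace(seq(0, 1, length.out = 200), fs, stage = "excitation")
  av <- activation_nonlinearity(grid, A = 2, R = 0.5)$activation
  expect_true(all(diff(av) > 0))
  expect_error(
    activation_nonlinearity(grid, A = 0),
    "Degenerate"
  )
})

test_that("MVC computation and normalization behave as specified", {
  cfg <- emg_config()
  withr::with_seed(21, {
    sub <- synthetic_subject(envelope_jitter = 0)
    tr <- envelope_to_raw_emg(rep(1, 3000), sub, 1000, seed = 9)
    m1 <- compute_mvc(tr, cfg)
    m5 <- compute_mvc(rep(list(tr), 5), cfg)
    expect_gt(m1, 0)
    expect_equal(m1, m5)  # identical trials -> same maximum
    # scaling a trial scales its envelope peak
    tr2 <- emg_trace(0.5 * tr$emg, 1000)
    expect_equal(compute_mvc(list(tr, tr2), cfg), m1)
  })
  expect_error(compute_mvc(list(), cfg), "at least one")
  z <- emg_trace(rep(0, 2000), 1000)
  expect_error(compute_mvc(z, cfg), "Degenerate MVC")

  u <- emg_trace(c(0.45, 0.9), 1000, stage = "excitation")
  expect_equal(normalize_mvc(u, 0.9)$emg, c(0.5, 1.0))
  expect_equal(normalize_mvc(emg_trace(1.2, 1000, stage = "excitation"),
                             1.0)$emg, 1.0)
  expect_error(normalize_mvc(u, 0), "positive")
})

test_that("dead-band rectification has staircase semantics", {
  # jitter inside the band is suppressed entirely
  withr::with_seed(2, {
    x <- 0.5 * (1 + runif(500, -0.005, 0.005))
    y <- dead_band_rectify(x, 0.02)
    expect_equal(y[-1], rep(x[1], 499))
  })
  # a step far outside the band passes through within one sample
  stp <- c(rep(0, 10), rep(0.5, 10))
  ys <- dead_band_rectify(stp, 0.02)
  expect_equal(ys[11:20], rep(0.5, 10))

  # monotone ramp: output is a staircase lagging by at most the band,
  # checked against a brute-force staircase oracle
  ramp <- seq(0, 1, by = 1e-4)
  yr <- dead_band_rectify(ramp, 0.01)
  held <- ramp[1]
  oracle <- numeric(length(ramp))
  oracle[1] <- held
  for (i in 2:length(ramp)) {
    band <- if (abs(held) < 0.01) 0.01 else 0.01 * abs(held)
    if (abs(ramp[i] - held) > band) held <- ramp[i]
    oracle[i] <- held
  }
  expect_equal(yr, oracle)
  expect_true(all(abs(yr - ramp) <= pmax(0.01, 0.01 * ramp) + 1e-12))

  # idempotence: the staircase is a fixed point of the operator
  expect_equal(dead_band_rectify(yr, 0.01), yr)
  expect_error(dead_band_rectify(ramp, 0.05), "0.01")
})

test_that("the full chain maps bounded signals into [0, 1]", {
  cfg <- emg_config()
  fs <- 500
  ok <- withr::with_seed(7, {
    vapply(seq_len(1000), function(i) {
      n <- 300
      x <- runif(1, 0.1, 5) * rnorm(n) * runif(1)
      tr <- emg_trace(x, fs)
      a <- process_emg(tibble::tibble(time_s = tr$time_s, emg = tr$emg),
                       mvc_value = runif(1, 0.05, 2), config = cfg)
      all(a$activation >= 0) && all(a$activation <= 1)
    }, logical(1))
  })
  expect_true(all(ok))
})
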