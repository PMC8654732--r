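test_that("background estimate recovers the envelope central value of pure noise", {
  # oracle: for N(0, sigma) noise the rectified-mean envelope concentrates at
  # sigma * sqrt(2/pi)
  theo <- sqrt(2 / pi)
  for (seed in 1:20) {
    tr <- simulateEEG(data.frame(onset_min = numeric(0), duration_s = numeric(0)),
                      EEGSimParams(), span_min = 10, seed = seed)
    expect_lt(abs(estimateBackground(tr) - theo) / theo, 0.10)
  }
})

test_that("a constant trace yields a degenerate background that detection refuses", {
  tr <- EEGTrace(samples = rep(0, 250 * 120), sampling_rate = 250)
  expect_identical(estimateBackground(tr), 0)
  expect_error(detectDischarges(tr), "degenerate")
})

test_that("a discharge occupying a small fraction of the trace barely moves the background", {
  for (seed in 1:5) {
    noise <- simulateEEG(data.frame(onset_min = numeric(0), duration_s = numeric(0)),
                         EEGSimParams(), span_min = 12, seed = seed)
    with_d <- simulateEEG(data.frame(onset_min = 5, duration_s = 30),
                          EEGSimParams(), span_min = 12, seed = seed)
    b0 <- estimateBackground(noise)
    b1 <- estimateBackground(with_d)
    expect_lt(abs(b1 - b0) / b0, 0.10)
  }
})

test_that("a rendered 30-s discharge is detected once with accurate duration and suppression", {
  tr <- simulateEEG(data.frame(onset_min = 2, duration_s = 30), EEGSimParams(),
                    span_min = 6, seed = 7)
  d <- detectDischarges(tr)
  expect_identical(nrow(d), 1L)
  expect_lt(abs(d$duration_s - 30), 2)
  expect_true(d$has_suppression)
  # detected onset lags the low-voltage fast onset by roughly the lead-in
  truth <- eegTruth(tr)
  expect_lt(abs(d$onset_s - truth$spike_onset_s), 1)
  # without a rendered suppression component the flag stays off
  p_nosupp <- EEGSimParams(suppression_seconds = 0)
  tr2 <- simulateEEG(data.frame(onset_min = 2, duration_s = 30), p_nosupp,
                     span_min = 6, seed = 7)
  d2 <- detectDischarges(tr2)
  expect_identical(nrow(d2), 1L)
  expect_false(d2$has_suppression)
})

test_that("sub-minimum bursts and pure noise yield no detections", {
  t8 <- simulateEEG(data.frame(onset_min = 2, duration_s = 8), EEGSimParams(),
                    span_min = 5, seed = 3)
  expect_identical(nrow(detectDischarges(t8)), 0L)
  for (seed in 1:5) {
    tn <- simulateEEG(data.frame(onset_min = numeric(0), duration_s = numeric(0)),
                      EEGSimParams(), span_min = 60, seed = seed)
    expect_identical(nrow(detectDischarges(tn)), 0L)
  }
})

test_that("every reported discharge satisfies the duration and amplitude criteria", {
  p <- DetectionParams()
  set.seed(31)
  on <- cumsum(2 + runif(5, 1, 3))
  tr <- simulateEEG(data.frame(onset_min = on, duration_s = runif(5, 12, 60)),
                    EEGSimParams(), span_min = max(on) + 3, seed = 31)
  d <- detectDischarges(tr, p)
  expect_gt(nrow(d), 0)
  expect_true(all(d$duration_s >= p@min_duration_s))
  expect_true(all(d$peak_amp_ratio >= p@amp_factor))
  expect_true(all(d$offset_s > d$onset_s))
  expect_true(all(diff(d$onset_s) > 0))
})

test_that("detection is invariant to positive rescaling of the trace", {
  tr <- simulateEEG(data.frame(onset_min = c(2, 4), duration_s = c(20, 35)),
                    EEGSimParams(), span_min = 8, seed = 13)
  d1 <- detectDischarges(tr)
  for (k in c(0.01, 3, 1000)) {
    tr_k <- EEGTrace(samples = samples(tr) * k, sampling_rate = samplingRate(tr))
    d2 <- detectDischarges(tr_k)
    expect_equal(d2$onset_s, d1$onset_s)
    expect_equal(d2$duration_s, d1$duration_s)
    expect_equal(d2$peak_amp_ratio, d1$peak_amp_ratio, tolerance = 1e-9)
  }
})

test_that("raising the amplitude threshold never adds detections", {
  tr <- simulateEEG(data.frame(onset_min = c(2, 5, 8), duration_s = c(15, 40, 25)),
                    EEGSimParams(), span_min = 12, seed = 17)
  n_prev <- Inf
  for (af in c(1.5, 2, 2.5, 3, 3.5)) {
    n <- nrow(detectDischarges(tr, DetectionParams(amp_factor = af)))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("quiet renderings are rejected at construction", {
  expect_error(EEGSimParams(discharge_amp_factor = 1.0), "exceed 2")
  expect_error(simulateEEG(data.frame(onset_min = c(2, 2.1), duration_s = c(30, 30)),
                           EEGSimParams(), span_min = 6), "overlap")
  expect_error(simulateEEG(data.frame(onset_min = 5.8, duration_s = 30),
                           EEGSimParams(), span_min = 6), "span")
})

test_that("detection matching agrees with an exhaustive assignment oracle", {
  # identical lists
  m <- matchDetections(c(10, 50, 90), data.frame(onset_s = c(10, 50, 90)), tol_s = 5)
  expect_identical(m$sensitivity, 1)
  expect_identical(m$precision, 1)
  # nothing detected
  m0 <- matchDetections(c(10, 50), data.frame(onset_s = numeric(0)), tol_s = 5)
  expect_identical(m0$sensitivity, 0)
  expect_true(is.na(m0$precision))
  # jitter within tol/2 keeps sensitivity 1, verified against the oracle
  set.seed(41)
  for (rep in 1:20) {
    truth <- sort(runif(6, 0, 600))
    det <- truth + runif(6, -2.5, 2.5)
    m <- matchDetections(truth, det, tol_s = 5)
    expect_identical(m$sensitivity, 1)
    expect_identical(nrow(m$pairs), oracleMaxMatching(truth, det, 5))
  }
  # greedy pairing never exceeds the exhaustive optimum and is one-to-one
  for (rep in 1:20) {
    truth <- sort(runif(5, 0, 300))
    det <- sort(runif(4, 0, 300))
    m <- matchDetections(truth, det, tol_s = 10)
    expect_lte(nrow(m$pairs), oracleMaxMatching(truth, det, 10))
    expect_false(anyDuplicated(m$pairs$truth_idx) > 0)
    expect_false(anyDuplicated(m$pairs$det_idx) > 0)
  }
})
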