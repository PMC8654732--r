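test_that("the consecutive-seizure worked example yields the expected intervals", {
  isis <- computeISIs(fig2Session())
  expect_equal(isis$interval_min, c(195, 3, 4, 4, 4, 5, 5))
  expect_identical(isis$next_idx, 2:8)
  # attribution: each interval belongs to the following event
  expect_identical(isis$prev_idx, 1:7)
})

test_that("sessions with fewer than two events yield no intervals", {
  expect_identical(nrow(computeISIs(makeSession(100))), 0L)
  s0 <- MonitoringSession(events = data.frame(onset_min = numeric(0),
                                              duration_s = numeric(0),
                                              score = integer(0)),
                          duration_days = 1L)
  expect_identical(nrow(computeISIs(s0)), 0L)
})

test_that("intervals equal a brute-force successive-difference oracle", {
  set.seed(51)
  t <- sort(runif(100, 0, 5 * 1440))
  isis <- computeISIs(makeSession(t))
  oracle <- vapply(2:100, function(i) t[i] - t[i - 1], 0)
  expect_equal(isis$interval_min, oracle)
  expect_identical(nrow(isis), 99L)
})

test_that("intervals crossing recording gaps are flagged and droppable", {
  s <- makeSession(c(590, 640, 700), gaps = matrix(c(600, 620), ncol = 2))
  isis <- computeISIs(s)
  expect_identical(isis$spans_gap, c(TRUE, FALSE))
  strictly <- computeISIs(s, strict = TRUE)
  expect_identical(nrow(strictly), 1L)
  expect_equal(strictly$interval_min, 60)
})

test_that("histogram counts match exhaustive per-value bin assignment", {
  set.seed(52)
  iv <- runif(500, 0.5, 700)
  h <- isiHistogram(iv, bin_width_min = 60)
  oracle <- vapply(seq_len(length(h$breaks) - 1), function(k)
    sum(iv > h$breaks[k] & iv <= h$breaks[k + 1]), 0L)
  expect_identical(h$counts, oracle)
  expect_identical(sum(h$counts), length(iv))
  expect_equal(sum(h$percent), 100)
  # boundary values fall in the lower bin: (a, b] convention
  hb <- isiHistogram(c(60, 60.0001), bin_width_min = 60)
  expect_identical(hb$counts[1:2], c(1L, 1L))
})

test_that("degenerate histogram inputs are handled", {
  h0 <- isiHistogram(numeric(0))
  expect_true(all(h0$counts == 0L))
  expect_error(isiHistogram(c(10, 20), bin_width_min = 0), "positive")
  expect_error(isiHistogram(c(-1, 10)), "positive")
})

test_that("the 10-min fine histogram nests exactly inside the 60-min bin", {
  set.seed(53)
  iv <- runif(400, 0.1, 600)
  coarse <- isiHistogram(iv, bin_width_min = 60)
  short <- iv[iv <= 60]
  fine <- fineHistogram(short)
  expect_length(fine$counts, 6)
  expect_identical(sum(fine$counts), coarse$counts[1])
  expect_error(fineHistogram(c(10, 65)), "<= 60")
  all5 <- fineHistogram(rep(5, 20))
  expect_identical(all5$counts, c(20L, 0L, 0L, 0L, 0L, 0L))
})

test_that("near-uniform short intervals spread across the fine bins", {
  set.seed(54)
  for (rep in 1:20) {
    iv <- runif(300, 0, 60)
    iv <- iv[iv > 0]
    fine <- fineHistogram(iv)
    # multinomial with p = 1/6: counts stay within a wide central band
    expect_true(all(fine$counts >= 20 & fine$counts <= 85))
  }
})

test_that("duration-ISI correlation handles exact and degenerate relationships", {
  # duration exactly 2 x preceding ISI: r = 1
  t <- cumsum(c(0, 5, 12, 30, 8, 50, 3))
  ev <- data.frame(onset_min = t, duration_s = c(10, 2 * diff(t)), score = 3L)
  s <- MonitoringSession(events = ev, duration_days = 1L)
  ct <- correlateDurationISI(s)
  expect_equal(ct$r, 1)
  expect_identical(ct$n, 6L)
  # constant duration: undefined, flagged
  ev$duration_s <- 40
  s2 <- MonitoringSession(events = ev, duration_days = 1L)
  ct2 <- correlateDurationISI(s2)
  expect_true(is.na(ct2$r))
  expect_true(ct2$degenerate)
})

test_that("score stratification reports per-stratum n, mean, SEM and an omnibus p", {
  # identical scores everywhere: equal means, no detectable difference
  t <- sort(c(runif(30, 0, 59), runif(30, 61, 119), runif(30, 125, 2000)))
  ev <- data.frame(onset_min = t, duration_s = 40, score = 3L)
  st <- stratifyScoresByISI(MonitoringSession(events = ev, duration_days = 2L))
  expect_true(all(st$summary$mean_score == 3))
  expect_equal(st$p, 1)
  # missing scores are excluded pairwise: stratum ns sum to scored intervals
  ev$score[c(3, 10, 40)] <- NA
  st2 <- stratifyScoresByISI(MonitoringSession(events = ev, duration_days = 2L))
  n_scored_with_isi <- sum(!is.na(ev$score[-1]))
  expect_identical(sum(st2$summary$n), n_scored_with_isi)
})

test_that("score distributions shifted between strata are detected with high power", {
  set.seed(55)
  # construct events whose stratum fully determines the score distribution
  gaps <- c(runif(100, 1, 59), runif(100, 61, 119), runif(100, 125, 400))
  scores <- c(sample(0:2, 100, TRUE), sample(2:4, 100, TRUE), sample(3:5, 100, TRUE))
  ord <- sample(300)  # interleave strata along the session
  t <- cumsum(c(0, gaps[ord]))
  ev <- data.frame(onset_min = t, duration_s = 40,
                   score = c(3L, scores[ord]))
  s <- MonitoringSession(events = ev, duration_days = as.integer(ceiling(max(t) / 1440)))
  st <- stratifyScoresByISI(s)
  expect_lt(st$p, 0.001)
})

test_that("sparse strata skip the omnibus test with a warning", {
  t <- c(0, 10, 20, 30, 200)   # nothing in (60, 120]
  ev <- data.frame(onset_min = t, duration_s = 40, score = c(1L, 2L, 3L, 2L, 4L))
  s <- MonitoringSession(events = ev, duration_days = 1L)
  expect_warning(st <- stratifyScoresByISI(s), "skipped")
  expect_true(is.na(st$p))
})
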