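test_that("the worked example segments into one 7-event cluster", {
  s <- fig2Session()
  cl <- detectClusters(s)
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_events, 7L)
  expect_identical(cl$first_idx, 2L)
  expect_identical(cl$last_idx, 8L)
  asg <- attr(cl, "assignment")
  expect_true(is.na(asg[1]))          # the first event stays unclustered
  expect_true(all(asg[2:8] == 1L))
})

test_that("the size and boundary rules behave as stated", {
  # three events with short gaps: a run of 3 is below the minimum size
  expect_identical(nrow(detectClusters(makeSession(c(0, 5, 10)))), 0L)
  # gaps exactly at the bound are inclusive
  cl <- detectClusters(makeSession(c(0, 120, 240, 360)))
  expect_identical(nrow(cl), 1L)
  expect_identical(cl$n_events, 4L)
  # a hair over the bound breaks the run
  expect_identical(nrow(detectClusters(makeSession(c(0, 120.01, 240, 360)))), 0L)
  # empty input
  s0 <- MonitoringSession(duration_days = 1L)
  expect_identical(nrow(detectClusters(s0)), 0L)
})

test_that("cluster segmentation matches the exhaustive maximal-run oracle", {
  set.seed(61)
  for (rep in 1:300) {
    n <- sample(0:50, 1)
    # gap scale chosen so runs straddle the 120-min bound often
    t <- cumsum(c(0, rexp(max(0, n - 1), rate = 1 / 90)))[seq_len(n)]
    if (n == 0) t <- numeric(0)
    s <- MonitoringSession(events = data.frame(onset_min = t,
                                               duration_s = rep(40, n),
                                               score = rep(3L, n)),
                           duration_days = max(1L, as.integer(ceiling(max(c(t, 1)) / 1440))))
    cl <- detectClusters(s)
    asg <- attr(cl, "assignment")
    expect_identical(canonicalLabels(asg), canonicalLabels(oracleClusters(t)))
    if (nrow(cl)) {
      expect_true(all(cl$n_events >= 4))
      expect_true(all(cl$max_intra_isi <= 120))
    }
  }
})

test_that("clusters are maximal: boundary gaps exceed the bound", {
  set.seed(62)
  for (rep in 1:50) {
    t <- cumsum(c(0, rexp(39, rate = 1 / 90)))
    s <- makeSession(t)
    cl <- detectClusters(s)
    for (i in seq_len(nrow(cl))) {
      if (cl$first_idx[i] > 1)
        expect_gt(t[cl$first_idx[i]] - t[cl$first_idx[i] - 1], 120)
      if (cl$last_idx[i] < length(t))
        expect_gt(t[cl$last_idx[i] + 1] - t[cl$last_idx[i]], 120)
    }
    # no event belongs to two clusters
    asg <- attr(cl, "assignment")
    expect_true(all(table(asg[!is.na(asg)]) ==
                      cl$n_events[order(cl$cluster_id)]))
  }
})

test_that("detected clusters reproduce the simulator's qualifying ground truth", {
  for (seed in 1:10) {
    s <- simulateEventStream(SimParams(), sessionSkeleton(duration_days = 7L), seed = seed)
    ev <- events(s)
    cl <- detectClusters(s)
    asg <- attr(cl, "assignment")
    # truth restricted to clusters that meet the size rule
    truth <- ev$cluster_id
    keep <- table(truth[!is.na(truth)])
    truth[!is.na(truth) & truth %in% as.integer(names(keep)[keep < 4])] <- NA
    expect_identical(canonicalLabels(asg), canonicalLabels(truth))
  }
  # with all sizes >= 4 the agreement is a full partition match (ARI = 1)
  p4 <- SimParams(cluster_size_probs = c(0, 0, 0.3, 0.3, 0.2, 0.1, 0.1, 0, 0, 0, 0))
  for (seed in 1:5) {
    s <- simulateEventStream(p4, sessionSkeleton(duration_days = 7L), seed = seed)
    cl <- detectClusters(s)
    expect_identical(canonicalLabels(attr(cl, "assignment")),
                     canonicalLabels(events(s)$cluster_id))
  }
})

test_that("intra-cluster ISI medians are recoverable from detected clusters", {
  p <- SimParams()
  intra <- numeric(0)
  j <- 0; n_clusters <- 0
  while (n_clusters < 50) {
    j <- j + 1
    s <- simulateEventStream(p, sessionSkeleton(mouse_id = sprintf("m%d", j),
                                                duration_days = 7L), seed = 600)
    cl <- detectClusters(s)
    n_clusters <- n_clusters + nrow(cl)
    ev <- events(s)
    for (k in seq_len(nrow(cl)))
      intra <- c(intra, diff(ev$onset_min[cl$first_idx[k]:cl$last_idx[k]]))
  }
  target <- exp(p@intra_isi_meanlog)
  expect_lt(abs(median(intra) - target) / target, 0.15)
})

test_that("cluster grouping chains by the inter-cluster gap threshold", {
  mk <- function(starts) {
    # four events 10 min apart from each start: each a cluster
    t <- sort(unlist(lapply(starts, function(s0) s0 + c(0, 10, 20, 30))))
    makeSession(t)
  }
  # two clusters 2.5 h apart (end-to-start): one group of 2
  s <- mk(c(0, 180))
  gr <- detectClusterGroups(detectClusters(s))
  expect_identical(nrow(gr$groups), 1L)
  expect_identical(gr$groups$n_clusters, 2L)
  expect_length(gr$singleton_clusters, 0)
  # two clusters 26 h apart: two separate units
  s2 <- mk(c(0, 26 * 60 + 30))
  gr2 <- detectClusterGroups(detectClusters(s2))
  expect_identical(nrow(gr2$groups), 0L)
  expect_identical(gr2$singleton_clusters, c(1L, 2L))
  # empty cluster list
  gr0 <- detectClusterGroups(detectClusters(MonitoringSession(duration_days = 1L)))
  expect_identical(nrow(gr0$groups), 0L)
})

test_that("grouping agrees with a brute-force chaining oracle", {
  set.seed(63)
  for (rep in 1:50) {
    k <- sample(2:8, 1)
    starts <- cumsum(c(0, runif(k - 1, 60, 8 * 60)))
    t <- sort(unlist(lapply(starts, function(s0) s0 + c(0, 5, 10, 15))))
    cl <- detectClusters(makeSession(t))
    gr <- detectClusterGroups(cl, group_max_gap_h = 3)
    # oracle: chain cluster i+1 to i when start - end <= 180 min
    sep <- cl$start_min[-1] - cl$end_min[-nrow(cl)]
    links <- sep <= 180
    runs <- rle(links)
    n_groups_oracle <- sum(runs$values)
    in_group <- rep(FALSE, nrow(cl))
    for (i in seq_along(links)) if (links[i]) in_group[c(i, i + 1)] <- TRUE
    expect_identical(nrow(gr$groups), n_groups_oracle)
    expect_identical(sort(gr$singleton_clusters), cl$cluster_id[!in_group])
  }
})

test_that("balanced cluster expression yields no circadian preference", {
  # same imbalance-free pattern every day: two clusters per phase per day
  day_starts <- (0:3) * 1440
  t <- sort(unlist(lapply(day_starts, function(d)
    d + c(60, 70, 80, 90, 700, 710, 720, 730))))  # 09:00 (on) and ~19:40 (off)
  s <- makeSession(t, start_clock = 8, duration_days = 4L)
  cl <- detectClusters(s)
  cs <- circadianSummary(cl, s)
  expect_identical(cs$preference, "none")
  expect_equal(cs$mean_on, cs$mean_off)
  # fewer than 2 monitored days: counts reported, test skipped
  s1 <- makeSession(c(60, 70, 80, 90), duration_days = 1L)
  cs1 <- circadianSummary(detectClusters(s1), s1)
  expect_identical(cs1$test, "skipped")
  expect_true(is.na(cs1$p))
})

test_that("a strong light-on modulation is flagged as a light-on preference", {
  # 2-3 light-on clusters per day (09:00, 12:00, odd days 15:00) against one
  # light-off cluster (21:00); all separations exceed the 120-min bound
  t <- c()
  for (d in 0:5) {
    base <- d * 1440
    starts <- base + c(60, 240, if (d %% 2 == 1) 420, 780)
    t <- c(t, unlist(lapply(starts, function(s0) s0 + c(0, 8, 16, 24))))
  }
  s <- makeSession(sort(t), start_clock = 8, duration_days = 6L)
  cl <- detectClusters(s)
  cs <- circadianSummary(cl, s, AnalysisParams())
  expect_identical(cs$preference, "light_on")
  expect_lt(cs$p, 0.05)
})

test_that("intra-cluster trends recover perfect monotone ISI sequences", {
  t <- cumsum(c(0, 2, 5, 9, 14))
  s <- makeSession(t, duration_s = c(40, 45, 38, 44, 41), score = c(3L, 3L, 4L, 3L, 4L))
  cl <- detectClusters(s)
  expect_true(cl$is_tight)
  tr <- intraClusterTrend(s, cl)
  expect_equal(tr$rho[tr$metric == "isi"], 1)
  expect_identical(tr$verdict[tr$metric == "isi"], "increase")
})

test_that("degenerate metrics and non-tight clusters are refused or flagged", {
  t <- cumsum(c(0, 2, 5, 9, 14))
  s <- makeSession(t, duration_s = 40, score = c(3L, NA, NA, NA, 3L))
  cl <- detectClusters(s)
  tr <- intraClusterTrend(s, cl)
  expect_identical(tr$verdict[tr$metric == "duration"], "undefined")  # constant
  expect_identical(tr$verdict[tr$metric == "score"], "undefined")     # < 3 scored
  # non-tight cluster: caller must filter
  s2 <- makeSession(cumsum(c(0, 30, 40, 50)))
  cl2 <- detectClusters(s2)
  expect_false(cl2$is_tight)
  expect_error(intraClusterTrend(s2, cl2), "tight")
})

test_that("exchangeable marks give the nominal trend false-positive rate", {
  set.seed(65)
  verdicts <- 0L; n_tested <- 0L
  sizes <- sample(4:7, 400, replace = TRUE)
  for (n in sizes) {
    t <- cumsum(c(0, runif(n - 1, 2, 18)))
    s <- makeSession(t, duration_s = rlnorm(n, log(40), 0.4),
                     score = sample(0:5, n, TRUE, prob = c(.01, .03, .1, .45, .31, .1)))
    cl <- detectClusters(s)
    tr <- intraClusterTrend(s, cl)
    row <- tr[tr$metric == "duration", ]
    if (row$verdict != "undefined") {
      n_tested <- n_tested + 1L
      if (row$verdict != "none") verdicts <- verdicts + 1L
    }
  }
  rate <- verdicts / n_tested
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)
})

test_that("cluster occupancy splits at midnight and conserves total minutes", {
  # cluster spanning 23:50-00:10 clock: two rows, one per day
  s <- makeSession(c(950, 955, 960, 970), start_clock = 8, duration_days = 2L)
  cl <- detectClusters(s)
  occ <- clusterRaster(s, cl)
  expect_identical(nrow(occ), 2L)
  expect_identical(occ$day, c(1L, 2L))
  expect_equal(occ$clock_start_min[1], 1430)  # 23:50
  expect_equal(occ$clock_end_min[1], 1440)
  expect_equal(occ$clock_start_min[2], 0)
  expect_equal(occ$clock_end_min[2], 10)     # 00:10
  # conservation over random sessions
  set.seed(66)
  for (rep in 1:20) {
    t <- cumsum(c(0, rexp(59, 1 / 90)))
    s2 <- makeSession(t, start_clock = runif(1, 0, 24))
    cl2 <- detectClusters(s2)
    occ2 <- clusterRaster(s2, cl2)
    expect_equal(sum(occ2$clock_end_min - occ2$clock_start_min),
                 sum(cl2$end_min - cl2$start_min))
  }
  # no clusters: empty table
  expect_identical(nrow(clusterRaster(s, detectClusters(makeSession(c(1, 400, 800))))), 0L)
})
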