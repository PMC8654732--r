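# Shared fixtures and independent oracles, all built in code.

# Event stream honoring the published consecutive-seizure example: a long
# first interval (~195 min) followed by seven seizures 2-6 min apart.
fig2Session <- function() {
  ev <- data.frame(onset_min = c(0, 195, 198, 202, 206, 210, 215, 220),
                   duration_s = c(42, 38, 35, 40, 44, 39, 41, 37),
                   score = c(3L, 3L, 4L, 3L, NA, 4L, 3L, 3L))
  MonitoringSession(mouse_id = "h1", session_index = 1L, start_clock = 8,
                    duration_days = 1L, events = ev)
}

makeSession <- function(onsets, duration_s = 40, score = 3L, start_clock = 8,
                        duration_days = NULL, gaps = matrix(numeric(0), ncol = 2),
                        mouse_id = "m1", session_index = 1L) {
  if (is.null(duration_days))
    duration_days <- max(1L, as.integer(ceiling(max(c(onsets, 1)) / 1440)))
  ev <- data.frame(onset_min = onsets,
                   duration_s = rep_len(duration_s, length(onsets)),
                   score = rep_len(score, length(onsets)))
  MonitoringSession(mouse_id = mouse_id, session_index = session_index,
                    start_clock = start_clock, duration_days = duration_days,
                    events = ev, recording_gaps = gaps)
}

# Exhaustive maximal-run oracle for the cluster rule: walk every event,
# extend the current run while the successive gap stays within the bound,
# and keep runs reaching the minimum size. Independent of detectClusters.
oracleClusters <- function(onsets, max_isi = 120, min_size = 4L) {
  n <- length(onsets)
  assignment <- rep(NA_integer_, n)
  if (n == 0) return(assignment)
  id <- 0L
  run_start <- 1L
  for (i in seq_len(n)) {
    at_end <- i == n || (onsets[i + 1] - onsets[i]) > max_isi
    if (at_end) {
      if (i - run_start + 1L >= min_size) {
        id <- id + 1L
        assignment[run_start:i] <- id
      }
      run_start <- i + 1L
    }
  }
  assignment
}

# Canonical relabeling by first occurrence, so two partitions can be
# compared for exact equality regardless of label values.
canonicalLabels <- function(x) {
  out <- rep(NA_integer_, length(x))
  seen <- integer(0)
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    k <- match(x[i], seen)
    if (is.na(k)) { seen <- c(seen, x[i]); k <- length(seen) }
    out[i] <- k
  }
  out
}

# Exhaustive assignment oracle for detection matching: try every injective
# truth->detected mapping within tolerance and return the maximum number of
# pairs. Feasible only for small lists.
oracleMaxMatching <- function(truth, detected, tol) {
  nt <- length(truth); nd <- length(detected)
  if (nt == 0 || nd == 0) return(0L)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (nt - i + 1) <= best) return()
    if (i > nt) { best <<- max(best, count); return() }
    for (j in seq_len(nd)) {
      if (!used[j] && abs(truth[i] - detected[j]) <= tol) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
    recurse(i + 1L, used, count)
  }
  recurse(1L, rep(FALSE, nd), 0L)
  best
}
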