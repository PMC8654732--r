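#' Inter-seizure intervals of a session
#'
#' Successive differences of the sorted onset times, attributed to the
#' *following* event (an event's ISI is the time since its preceding
#' seizure). No interval crosses a session boundary; for a contiguous
#' session of `n` events there are exactly `n - 1` intervals. Intervals
#' containing a recording gap (the daily 10-30 min care pauses) are flagged
#' `spans_gap`; they are retained by default and dropped in `strict` mode.
#'
#' @param session a [MonitoringSession].
#' @param strict drop intervals flagged `spans_gap` (default `FALSE`:
#'   monitoring is treated as continuous).
#' @return data.frame with columns `interval_min`, `prev_idx`, `next_idx`
#'   (row indices into `events(session)`), `spans_gap`. Empty when the
#'   session holds fewer than two events.
#' @examples
#' ev <- data.frame(onset_min = c(0, 195, 198, 202), duration_s = 40, score = 3L)
#' computeISIs(MonitoringSession(events = ev, duration_days = 1L))
#' @export
computeISIs <- function(session, strict = FALSE) {
  ev <- events(session)
  empty <- data.frame(interval_min = numeric(0), prev_idx = integer(0),
                      next_idx = integer(0), spans_gap = logical(0))
  if (nrow(ev) < 2) return(empty)
  t <- ev$onset_min
  iv <- diff(t)
  g <- recordingGaps(session)
  spans <- rep(FALSE, length(iv))
  if (nrow(g)) {
    for (k in seq_len(nrow(g)))
      spans <- spans | (t[-length(t)] < g[k, 2] & t[-1] > g[k, 1])
  }
  out <- data.frame(interval_min = iv,
                    prev_idx = seq_len(length(iv)),
                    next_idx = seq_len(length(iv)) + 1L,
                    spans_gap = spans)
  if (strict) out <- out[!out$spans_gap, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pool ISI records across sessions
#' @noRd
pooledISIs <- function(sessions, strict = FALSE) {
  if (is(sessions, "MonitoringSession")) sessions <- list(sessions)
  do.call(rbind, lapply(seq_along(sessions), function(i) {
    r <- computeISIs(sessions[[i]], strict = strict)
    if (nrow(r)) r$session <- i
    r
  }))
}

#' ISI histogram with left-open/right-closed bins
#'
#' Bins intervals into `(0, w], (w, 2w], ...` so that "ISIs <= 60 min" and
#' "60-120 min" partition the axis without double counting. Percentages are
#' computed from the unrounded count ratios; the print method reports them
#' to the nearest integer.
#'
#' @param isis positive numeric intervals in minutes (or a data.frame from
#'   [computeISIs()], whose `interval_min` column is used).
#' @param bin_width_min bin width in minutes (default 60).
#' @param range_max right edge of the last bin; defaults to the smallest
#'   multiple of the bin width covering the data.
#' @return An object of class `isi_histogram`: a list with `bin_width_min`,
#'   `breaks`, `counts`, `percent` (full precision), and `n`.
#' @examples
#' h <- isiHistogram(c(5, 30, 70, 130, 500))
#' h$counts
#' @export
isiHistogram <- function(isis, bin_width_min = 60, range_max = NULL) {
  if (is.data.frame(isis)) isis <- isis$interval_min
  if (bin_width_min <= 0) stopf("bin width must be positive")
  if (any(isis <= 0)) stopf("all intervals must be positive")
  if (is.null(range_max))
    range_max <- if (length(isis)) ceiling(max(isis) / bin_width_min) * bin_width_min
                 else bin_width_min
  if (length(isis) && max(isis) > range_max)
    stopf("interval %.1f exceeds range_max = %.1f", max(isis), range_max)
  breaks <- seq(0, range_max, by = bin_width_min)
  counts <- if (length(isis))
    as.integer(table(cut(isis, breaks = breaks, right = TRUE)))
  else integer(length(breaks) - 1L)
  n <- length(isis)
  structure(list(bin_width_min = bin_width_min, breaks = breaks,
                 counts = counts,
                 percent = if (n) 100 * counts / n else rep(0, length(counts)),
                 n = n),
            class = "isi_histogram")
}

#' @export
print.isi_histogram <- function(x, ...) {
  cat(sprintf("ISI histogram: %d intervals, %g-min bins\n", x$n, x$bin_width_min))
  lab <- sprintf("(%g,%g]", head(x$breaks, -1), x$breaks[-1])
  df <- data.frame(bin = lab, count = x$counts, percent = round(x$percent))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Fine 10-min histogram of the short intervals
#'
#' Re-bins the intervals of the first coarse bin (ISIs at most 60 min by
#' default) at 10-min resolution; the fine counts sum exactly to the parent
#' coarse bin.
#'
#' @param isis intervals in minutes, all within `(0, range_max]`.
#' @param bin_width_min fine bin width (default 10).
#' @param range_max upper limit (default 60); out-of-range input is an error.
#' @return An `isi_histogram` (see [isiHistogram()]).
#' @export
fineHistogram <- function(isis, bin_width_min = 10, range_max = 60) {
  if (is.data.frame(isis)) isis <- isis$interval_min
  if (length(isis) && max(isis) > range_max)
    stopf("fine histogram input must be <= %g min (got %.1f)", range_max, max(isis))
  isiHistogram(isis, bin_width_min = bin_width_min, range_max = range_max)
}

#' Pearson correlation of discharge duration against preceding ISI
#'
#' For every event with a defined preceding interval, pairs that interval
#' with the event's discharge duration and computes the product-moment
#' correlation. With zero variance in either variable, `r` is undefined and
#' reported missing.
#'
#' @param sessions a [MonitoringSession] or list of them.
#' @param strict passed to [computeISIs()].
#' @return list with `r`, `p`, `n`, and `degenerate` (TRUE when a variable
#'   had zero variance).
#' @export
correlateDurationISI <- function(sessions, strict = FALSE) {
  pr <- isiDurationPairs(sessions, strict)
  if (nrow(pr) < 3)
    return(list(r = NA_real_, p = NA_real_, n = nrow(pr), degenerate = FALSE))
  if (sd(pr$interval_min) == 0 || sd(pr$duration_s) == 0)
    return(list(r = NA_real_, p = NA_real_, n = nrow(pr), degenerate = TRUE))
  ct <- cor.test(pr$interval_min, pr$duration_s, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(pr), degenerate = FALSE)
}

#' (preceding ISI, duration) pairs pooled over sessions
#' @noRd
isiDurationPairs <- function(sessions, strict = FALSE) {
  if (is(sessions, "MonitoringSession")) sessions <- list(sessions)
  do.call(rbind, lapply(sessions, function(s) {
    r <- computeISIs(s, strict = strict)
    if (!nrow(r)) return(NULL)
    ev <- events(s)
    data.frame(interval_min = r$interval_min,
               duration_s = ev$duration_s[r$next_idx],
               score = ev$score[r$next_idx])
  }))
}

#' Racine-score summaries across ISI strata
#'
#' Each event with a defined preceding interval is assigned to an ISI
#' stratum — `(0, 60]`, `(60, 120]`, `(120, Inf)` minutes by default —
#' and per-stratum mean and SEM of the Racine score are reported together
#' with a Kruskal-Wallis omnibus test across strata. Events with missing
#' scores are excluded pairwise, so the stratum `n`s sum to the number of
#' *scored* events with a preceding interval, not to the total ISI count.
#'
#' @param sessions a [MonitoringSession] or list of them.
#' @param strata_edges increasing interior edges in minutes (default
#'   `c(60, 120)`).
#' @param strict passed to [computeISIs()].
#' @return list with `summary` (data.frame: `stratum`, `n`, `mean_score`,
#'   `sem_score`), `p` (Kruskal-Wallis; `NA` with a warning when any
#'   stratum has fewer than 2 scored events), `n_scored`.
#' @export
stratifyScoresByISI <- function(sessions, strata_edges = c(60, 120),
                                strict = FALSE) {
  if (is.unsorted(strata_edges, strictly = TRUE) || any(strata_edges <= 0))
    stopf("strata edges must be positive and strictly increasing")
  pr <- isiDurationPairs(sessions, strict)
  breaks <- c(0, strata_edges, Inf)
  labs <- c(sprintf("<=%g", strata_edges[1]),
            if (length(strata_edges) > 1)
              sprintf("%g-%g", head(strata_edges, -1), strata_edges[-1]),
            sprintf(">%g", strata_edges[length(strata_edges)]))
  if (is.null(pr) || !nrow(pr)) {
    return(list(summary = data.frame(stratum = labs, n = 0L,
                                     mean_score = NA_real_, sem_score = NA_real_),
                p = NA_real_, n_scored = 0L))
  }
  pr$stratum <- cut(pr$interval_min, breaks = breaks, right = TRUE, labels = labs)
  scored <- pr[!is.na(pr$score), , drop = FALSE]
  summ <- do.call(rbind, lapply(labs, function(l) {
    sc <- scored$score[scored$stratum == l]
    data.frame(stratum = l, n = length(sc),
               mean_score = if (length(sc)) mean(sc) else NA_real_,
               sem_score = if (length(sc) > 1) sd(sc) / sqrt(length(sc)) else NA_real_)
  }))
  p <- NA_real_
  if (all(summ$n >= 2)) {
    if (length(unique(scored$score)) > 1) {
      kw <- suppressWarnings(kruskal.test(score ~ stratum, data = scored))
      p <- kw$p.value
    } else p <- 1  # no rank variation: trivially no stratum difference
  } else {
    warnf("a stratum has fewer than 2 scored events; omnibus test skipped")
  }
  list(summary = summ, p = p, n_scored = nrow(scored))
}
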