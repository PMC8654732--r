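#' Segment a session's seizures into clusters
#'
#' Applies the run-based cluster rule: events are partitioned into maximal
#' runs of consecutive seizures in which every successive inter-seizure
#' interval is at most `cluster_max_isi` (120 min by default; the bound is
#' inclusive), and runs of at least `cluster_min_size` (4) events become
#' clusters. All other events are unclustered. By maximality, the gap from
#' the event preceding a run's first member and to the event following its
#' last member each exceed the bound, so clusters are disjoint and
#' time-ordered. Clusters whose intra-cluster ISIs are all at most
#' `tight_max_isi` (20 min) are flagged `is_tight`.
#'
#' @param session a [MonitoringSession].
#' @param params an [AnalysisParams].
#' @return data.frame with one row per cluster: `cluster_id`, `first_idx`,
#'   `last_idx` (members are the consecutive event rows
#'   `first_idx:last_idx`), `n_events`, `start_min`, `end_min`,
#'   `max_intra_isi`, `is_tight`, `phase` (circadian phase of the cluster
#'   start). The `"assignment"` attribute maps every event row to its
#'   cluster id (`NA` = unclustered).
#' @examples
#' ev <- data.frame(onset_min = c(0, 195, 198, 202, 206, 210, 215, 220),
#'                  duration_s = 40, score = 3L)
#' s <- MonitoringSession(events = ev, duration_days = 1L)
#' detectClusters(s)   # one 7-event cluster; the first event unclustered
#' @export
detectClusters <- function(session, params = AnalysisParams()) {
  validObject(params)
  ev <- events(session)
  empty <- data.frame(cluster_id = integer(0), first_idx = integer(0),
                      last_idx = integer(0), n_events = integer(0),
                      start_min = numeric(0), end_min = numeric(0),
                      max_intra_isi = numeric(0), is_tight = logical(0),
                      phase = character(0))
  n <- nrow(ev)
  assignment <- rep(NA_integer_, n)
  if (n == 0) {
    attr(empty, "assignment") <- assignment
    return(empty)
  }
  gaps <- diff(ev$onset_min)
  # maximal runs: break wherever the successive gap exceeds the bound
  brk <- c(0L, which(gaps > params@cluster_max_isi), n)
  rows <- list(); id <- 0L
  for (k in seq_len(length(brk) - 1L)) {
    a <- brk[k] + 1L; b <- brk[k + 1L]
    if (b - a + 1L < params@cluster_min_size) next
    id <- id + 1L
    intra <- gaps[seq(a, b - 1L)]
    assignment[a:b] <- id
    rows[[id]] <- data.frame(
      cluster_id = id, first_idx = a, last_idx = b, n_events = b - a + 1L,
      start_min = ev$onset_min[a], end_min = ev$onset_min[b],
      max_intra_isi = max(intra),
      is_tight = all(intra <= params@tight_max_isi),
      phase = phaseOf(ev$onset_min[a], startClock(session), lightCycle(session)))
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "assignment") <- assignment
  out
}

#' Chain clusters into groups
#'
#' Single-linkage chaining in time: consecutive clusters whose end-to-start
#' separation is at most `group_max_gap_h` belong to one group. Groups
#' require at least two clusters; clusters chained to nothing are reported
#' apart as singletons. The default 3 h threshold is the lower end of the
#' observed 3-26 h inter-group separation.
#'
#' @param clusters data.frame from [detectClusters()] (time-ordered).
#' @param group_max_gap_h maximum chaining gap in hours (default 3).
#' @return list with `groups` (data.frame: `group_id`, `n_clusters`,
#'   `start_min`, `end_min`, `cluster_ids` comma-joined) and
#'   `singleton_clusters` (integer cluster ids).
#' @export
detectClusterGroups <- function(clusters, group_max_gap_h = 3) {
  empty <- data.frame(group_id = integer(0), n_clusters = integer(0),
                      start_min = numeric(0), end_min = numeric(0),
                      cluster_ids = character(0))
  if (!nrow(clusters)) return(list(groups = empty, singleton_clusters = integer(0)))
  gap_min <- group_max_gap_h * MIN_PER_HOUR
  sep <- clusters$start_min[-1] - clusters$end_min[-nrow(clusters)]
  brk <- c(0, which(sep > gap_min), nrow(clusters))
  groups <- list(); singles <- integer(0); gid <- 0L
  for (k in seq_len(length(brk) - 1L)) {
    idx <- seq(brk[k] + 1L, brk[k + 1L])
    if (length(idx) < 2L) {
      singles <- c(singles, clusters$cluster_id[idx])
      next
    }
    gid <- gid + 1L
    groups[[gid]] <- data.frame(
      group_id = gid, n_clusters = length(idx),
      start_min = clusters$start_min[idx[1]],
      end_min = clusters$end_min[idx[length(idx)]],
      cluster_ids = paste(clusters$cluster_id[idx], collapse = ","))
  }
  list(groups = if (length(groups)) do.call(rbind, groups) else empty,
       singleton_clusters = singles)
}

#' Circadian expression summary of seizure clusters
#'
#' Assigns each cluster to the light phase containing its *start* time
#' (clusters may straddle the lights-on/off boundary), counts clustered
#' seizures and clusters per monitored day and phase, and compares the
#' per-day clustered-seizure counts between phases with a two-sided paired
#' test across days: a paired t-test when the day-to-day differences look
#' normal, falling back to a Wilcoxon signed-rank test when a Shapiro test
#' rejects normality (p < 0.05). A phase preference is declared only when
#' the paired test is significant at `alpha`, with direction given by the
#' larger mean.
#'
#' @param clusters data.frame from [detectClusters()].
#' @param session the [MonitoringSession] the clusters came from.
#' @param params an [AnalysisParams] (supplies `alpha`).
#' @return list with `per_day` (counts per day and phase, both clustered
#'   events and clusters), `mean_on`, `sem_on`, `mean_off`, `sem_off`
#'   (clustered events per day), `p`, `test` (`"paired t"`, `"wilcoxon"`, or
#'   `"skipped"`), `preference` (`"light_on"`, `"light_off"`, or `"none"`).
#' @export
circadianSummary <- function(clusters, session, params = AnalysisParams()) {
  nd <- durationDays(session)
  per_day <- data.frame(day = seq_len(nd),
                        events_light_on = 0, events_light_off = 0,
                        clusters_light_on = 0L, clusters_light_off = 0L)
  if (nrow(clusters)) {
    day <- pmin(nd, as.integer(clusters$start_min %/% MIN_PER_DAY + 1L))
    for (i in seq_len(nrow(clusters))) {
      if (clusters$phase[i] == "light_on") {
        per_day$events_light_on[day[i]] <- per_day$events_light_on[day[i]] + clusters$n_events[i]
        per_day$clusters_light_on[day[i]] <- per_day$clusters_light_on[day[i]] + 1L
      } else {
        per_day$events_light_off[day[i]] <- per_day$events_light_off[day[i]] + clusters$n_events[i]
        per_day$clusters_light_off[day[i]] <- per_day$clusters_light_off[day[i]] + 1L
      }
    }
  }
  on <- per_day$events_light_on; off <- per_day$events_light_off
  res <- list(per_day = per_day,
              mean_on = mean(on), sem_on = sd(on) / sqrt(nd),
              mean_off = mean(off), sem_off = sd(off) / sqrt(nd),
              p = NA_real_, test = "skipped", preference = "none")
  if (nd < 2) return(res)
  d <- on - off
  if (sd(d) == 0) {
    # identical per-day imbalance every day: no within-pair variation to test
    res$p <- if (all(d == 0)) 1 else NA_real_
    res$test <- "degenerate"
    return(res)
  }
  use_wilcox <- FALSE
  if (nd >= 3) {
    sh <- tryCatch(shapiro.test(d), error = function(e) NULL)
    if (!is.null(sh) && is.finite(sh$p.value) && sh$p.value < 0.05) use_wilcox <- TRUE
  }
  if (use_wilcox) {
    ht <- suppressWarnings(wilcox.test(on, off, paired = TRUE))
    res$test <- "wilcoxon"
  } else {
    ht <- t.test(on, off, paired = TRUE)
    res$test <- "paired t"
  }
  res$p <- ht$p.value
  if (is.finite(res$p) && res$p < params@alpha)
    res$preference <- if (mean(on) > mean(off)) "light_on" else "light_off"
  res
}

#' Trends within a tight cluster
#'
#' Spearman rank correlation of each within-cluster metric against seizure
#' position: intra-cluster ISI (positions 1..n-1), discharge duration and
#' Racine score (positions 1..n, missing scores excluded pairwise). Average
#' ranks handle the heavy ties in integer scores, and p-values use the t
#' approximation. A metric with fewer than 3 valid points or zero rank
#' variance is reported `"undefined"`; otherwise the verdict is
#' `"increase"` or `"decrease"` when the trend is significant at `alpha`
#' with the corresponding sign, else `"none"`.
#'
#' @param session the [MonitoringSession].
#' @param cluster one row of the [detectClusters()] output; must be tight
#'   (callers filter on `is_tight`) with at least 4 events.
#' @param params an [AnalysisParams].
#' @return data.frame with one row per metric (`isi`, `duration`, `score`):
#'   `rho`, `p`, `n`, `verdict`.
#' @export
intraClusterTrend <- function(session, cluster, params = AnalysisParams()) {
  if (nrow(cluster) != 1) stopf("pass exactly one cluster row")
  if (!cluster$is_tight)
    stopf("intra-cluster trends are defined for tight clusters only (all ISIs <= %g min)",
          params@tight_max_isi)
  if (cluster$n_events < 4) stopf("trend analysis needs >= 4 events per cluster")
  ev <- events(session)[cluster$first_idx:cluster$last_idx, , drop = FALSE]
  n <- nrow(ev)
  metricRow <- function(metric, pos, vals) {
    keep <- !is.na(vals)
    pos <- pos[keep]; vals <- vals[keep]
    if (length(vals) < 3 || length(unique(vals)) < 2)
      return(data.frame(metric = metric, rho = NA_real_, p = NA_real_,
                        n = length(vals), verdict = "undefined"))
    ct <- suppressWarnings(cor.test(pos, vals, method = "spearman", exact = FALSE))
    rho <- unname(ct$estimate); p <- ct$p.value
    verdict <- if (is.finite(p) && p < params@alpha)
      if (rho > 0) "increase" else "decrease"
    else "none"
    data.frame(metric = metric, rho = rho, p = p, n = length(vals),
               verdict = verdict)
  }
  rbind(metricRow("isi", seq_len(n - 1), diff(ev$onset_min)),
        metricRow("duration", seq_len(n), ev$duration_s),
        metricRow("score", seq_len(n), as.numeric(ev$score)))
}

#' Day-by-clock-time occupancy of clusters
#'
#' Projects each cluster span onto the 24-h clock: occupancy rows give, for
#' each calendar day of the recording, the clock-minute interval a cluster
#' occupies; a cluster straddling midnight contributes a row to each day.
#' Total occupancy minutes equal the summed cluster spans.
#'
#' @param session a [MonitoringSession].
#' @param clusters data.frame from [detectClusters()].
#' @return data.frame with columns `day`, `clock_start_min`,
#'   `clock_end_min`, `cluster_id`, suitable for raster rendering.
#' @export
clusterRaster <- function(session, clusters) {
  empty <- data.frame(day = integer(0), clock_start_min = numeric(0),
                      clock_end_min = numeric(0), cluster_id = integer(0))
  if (!nrow(clusters)) return(empty)
  off <- startClock(session) * MIN_PER_HOUR  # clock minutes at session t = 0
  rows <- list()
  for (i in seq_len(nrow(clusters))) {
    a <- clusters$start_min[i] + off
    b <- clusters$end_min[i] + off
    if (b == a) b <- a + 1e-9  # degenerate span still drawn
    first_bound <- ceiling(a / MIN_PER_DAY) * MIN_PER_DAY
    bounds <- if (first_bound < b) seq(first_bound, b, by = MIN_PER_DAY) else numeric(0)
    cuts <- sort(unique(c(a, bounds[bounds > a & bounds < b], b)))
    for (k in seq_len(length(cuts) - 1L)) {
      lo <- cuts[k]; hi <- cuts[k + 1L]
      start_clock_min <- lo %% MIN_PER_DAY
      rows[[length(rows) + 1L]] <- data.frame(
        day = as.integer(lo %/% MIN_PER_DAY + 1L),
        clock_start_min = start_clock_min,
        # end as start + length keeps occupancy conservation exact
        clock_end_min = start_clock_min + (hi - lo),
        cluster_id = clusters$cluster_id[i])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Raster plot of cluster expression across days
#'
#' Base-graphics rendering of the [clusterRaster()] table: one row per
#' recording day, black bars marking cluster spans, the light-on period
#' shaded gray.
#'
#' @param session a [MonitoringSession].
#' @param clusters data.frame from [detectClusters()].
#' @param main plot title.
#' @return The occupancy table, invisibly.
#' @export
plotClusterRaster <- function(session, clusters,
                              main = sprintf("mouse %s, session %d",
                                             mouseId(session), sessionIndex(session))) {
  occ <- clusterRaster(session, clusters)
  nd <- durationDays(session)
  lc <- lightCycle(session)
  graphics::plot(NULL, xlim = c(0, 24), ylim = c(nd + 0.5, 0.5),
                 xlab = "clock time (h)", ylab = "recording day",
                 main = main, yaxt = "n", xaxs = "i")
  graphics::axis(2, at = seq_len(nd))
  on0 <- lc@light_on_start; on1 <- on0 + lc@light_on_hours
  graphics::rect(on0, nd + 0.5, min(on1, 24), 0.5,
                 col = grDevices::adjustcolor("gray80", 0.5), border = NA)
  if (on1 > 24)
    graphics::rect(0, nd + 0.5, on1 - 24, 0.5,
                   col = grDevices::adjustcolor("gray80", 0.5), border = NA)
  if (nrow(occ))
    graphics::segments(occ$clock_start_min / 60, occ$day,
                       occ$clock_end_min / 60, occ$day, lwd = 6)
  invisible(occ)
}
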