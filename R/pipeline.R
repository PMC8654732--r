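PIPELINE_MODES <- c("simulate", "from_events", "from_eeg")

#' Build a parameter object from a config list block
#' @noRd
paramsFromList <- function(constructor, lst) {
  if (is.null(lst)) return(constructor())
  do.call(constructor, lst)
}

#' Read a pipeline configuration file
#'
#' YAML with top-level keys `mode` (`simulate`, `from_events`, or
#' `from_eeg`), `seed`, optional parameter blocks `sim`, `eeg_sim`,
#' `detection`, `analysis` (fields as in [SimParams], [EEGSimParams],
#' [DetectionParams], [AnalysisParams]), `sessions` (simulate mode: list of
#' session skeleton specs), `events_path` / `manifest_path` (from_events),
#' `trace_paths` (from_eeg), and `strict_gaps`.
#'
#' @param path YAML file path.
#' @return The config list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  yaml::read_yaml(path)
}

#' Validate a pipeline configuration
#'
#' Checks the mode, every parameter block against its class invariants,
#' and the presence of required inputs; returns the violations rather than
#' stopping, so a CLI can report all of them at once.
#'
#' @param config a config list (see [readPipelineConfig()]).
#' @return Character vector of violation messages; empty when the config
#'   is valid.
#' @examples
#' validateConfig(list(mode = "simulate", seed = 1))       # character(0)
#' validateConfig(list(mode = "simulate", seed = 1,
#'                     analysis = list(cluster_min_size = 1)))
#' @export
validateConfig <- function(config) {
  v <- character(0)
  mode <- config$mode
  if (is.null(mode) || length(mode) != 1 || !mode %in% PIPELINE_MODES)
    v <- c(v, sprintf("mode must be exactly one of: %s",
                      paste(PIPELINE_MODES, collapse = ", ")))
  tryBlock <- function(constructor, lst, label) {
    err <- tryCatch({ validObject(paramsFromList(constructor, lst)); NULL },
                    error = function(e) conditionMessage(e))
    if (!is.null(err)) sprintf("%s block invalid: %s", label, err) else NULL
  }
  v <- c(v,
         tryBlock(SimParams, config$sim, "sim"),
         tryBlock(EEGSimParams, config$eeg_sim, "eeg_sim"),
         tryBlock(DetectionParams, config$detection, "detection"),
         tryBlock(AnalysisParams, config$analysis, "analysis"))
  if (identical(mode, "from_events") && is.null(config$events_path))
    v <- c(v, "from_events mode requires events_path")
  if (identical(mode, "from_eeg") && is.null(config$trace_paths))
    v <- c(v, "from_eeg mode requires trace_paths")
  if (!is.null(config$seed) && (length(config$seed) != 1 || is.na(config$seed)))
    v <- c(v, "seed must be a single integer")
  v
}

#' Run every analysis stage on a set of sessions
#'
#' The common analysis core behind [runPipeline()]: pooled ISIs, the 60-min
#' histogram with a 10-min fine view of the first bin, duration-vs-ISI
#' correlation, score stratification, per-session cluster detection,
#' cluster grouping, circadian summaries, and intra-cluster trends on tight
#' clusters.
#'
#' @param sessions list of [MonitoringSession] objects.
#' @param params an [AnalysisParams].
#' @param strict drop gap-spanning ISIs (see [computeISIs()]).
#' @return list of result tables (see [runPipeline()] for the layout).
#' @export
analyzeSessions <- function(sessions, params = AnalysisParams(), strict = FALSE) {
  if (is(sessions, "MonitoringSession")) sessions <- list(sessions)
  isi <- pooledISIs(sessions, strict = strict)
  iv <- if (is.null(isi)) numeric(0) else isi$interval_min
  hist_main <- isiHistogram(iv, bin_width_min = params@isi_bin_main)
  hist_fine <- fineHistogram(iv[iv <= params@isi_bin_main],
                             bin_width_min = params@isi_bin_fine,
                             range_max = params@isi_bin_main)
  correlation <- correlateDurationISI(sessions, strict = strict)
  strata <- stratifyScoresByISI(sessions, strata_edges = params@score_strata_edges,
                                strict = strict)

  clus_rows <- list(); circ_rows <- list(); grp_rows <- list(); trend_rows <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    cl <- detectClusters(s, params)
    if (nrow(cl)) {
      cl2 <- cbind(mouse_id = mouseId(s), session_index = sessionIndex(s), cl)
      clus_rows[[length(clus_rows) + 1L]] <- cl2
    }
    gr <- detectClusterGroups(cl, group_max_gap_h = params@group_max_gap)
    if (nrow(gr$groups))
      grp_rows[[length(grp_rows) + 1L]] <-
        cbind(mouse_id = mouseId(s), session_index = sessionIndex(s), gr$groups)
    cs <- circadianSummary(cl, s, params)
    circ_rows[[length(circ_rows) + 1L]] <- data.frame(
      mouse_id = mouseId(s), session_index = sessionIndex(s),
      mean_on = cs$mean_on, sem_on = cs$sem_on,
      mean_off = cs$mean_off, sem_off = cs$sem_off,
      p = cs$p, test = cs$test, preference = cs$preference)
    tight <- cl[cl$is_tight & cl$n_events >= 4, , drop = FALSE]
    for (k in seq_len(nrow(tight))) {
      tr <- tryCatch(intraClusterTrend(s, tight[k, , drop = FALSE], params),
                     error = function(e) NULL)  # optional stage: record, not fatal
      if (!is.null(tr))
        trend_rows[[length(trend_rows) + 1L]] <-
          cbind(mouse_id = mouseId(s), session_index = sessionIndex(s),
                cluster_id = tight$cluster_id[k], tr)
    }
  }
  bindOrEmpty <- function(rows) if (length(rows)) do.call(rbind, rows) else NULL
  list(isi = isi, histogram = hist_main, fine_histogram = hist_fine,
       correlation = correlation, strata = strata,
       clusters = bindOrEmpty(clus_rows), groups = bindOrEmpty(grp_rows),
       circadian = bindOrEmpty(circ_rows), trends = bindOrEmpty(trend_rows))
}

#' Run the end-to-end seizure-cluster pipeline
#'
#' Executes the configured input stage (simulate an event stream, read an
#' event table, or detect discharges in EEG traces) and then every analysis
#' stage, returning a report bundle whose tables are byte-identical for
#' identical config and seed. A failed optional stage (e.g. trends with no
#' tight clusters) is recorded in the log, not fatal.
#'
#' @param config config list; see [readPipelineConfig()] and
#'   [validateConfig()].
#' @return An object of class `ReportBundle`: a list with `meta` (config
#'   hash, seed, mode, package version), `sessions`, the [analyzeSessions()]
#'   tables, optional `detection` metrics, and a stage `log` of event
#'   counts.
#' @export
runPipeline <- function(config) {
  v <- validateConfig(config)
  if (length(v)) stopf("invalid config:\n  - %s", paste(v, collapse = "\n  - "))
  seed <- as.integer(config$seed %||% 1L)
  ana <- paramsFromList(AnalysisParams, config$analysis)
  strict <- isTRUE(config$strict_gaps)
  log <- list()
  detection <- NULL

  if (config$mode == "simulate") {
    sim <- paramsFromList(SimParams, config$sim)
    specs <- config$sessions %||% list(list(mouse_id = "sim1", session_index = 1,
                                            duration_days = 7))
    sessions <- lapply(specs, function(sp) {
      simulateEventStream(sim, sessionSkeleton(
        mouse_id = sp$mouse_id %||% "sim1",
        session_index = as.integer(sp$session_index %||% 1L),
        start_clock = sp$start_clock %||% 8,
        duration_days = as.integer(sp$duration_days %||% 7L)),
        seed = seed, analysis = ana)
    })
    log$simulate <- sum(vapply(sessions, nEvents, 0L))
  } else if (config$mode == "from_events") {
    if (!file.exists(config$events_path))
      stopf("events_path does not exist: %s", config$events_path)
    sessions <- readEventTable(config$events_path, manifest = config$manifest_path)
    log$read_events <- sum(vapply(sessions, nEvents, 0L))
  } else {  # from_eeg
    det <- paramsFromList(DetectionParams, config$detection)
    missing_tr <- config$trace_paths[!file.exists(unlist(config$trace_paths))]
    if (length(missing_tr)) stopf("trace path does not exist: %s", missing_tr[[1]])
    sessions <- list(); n_det <- 0L
    for (i in seq_along(config$trace_paths)) {
      trace <- readTrace(config$trace_paths[[i]],
                         epoch_start = config$trace_epoch_start %||% 8)
      dd <- detectDischarges(trace, det)
      n_det <- n_det + nrow(dd)
      span_min <- length(samples(trace)) / samplingRate(trace) / 60
      ev <- data.frame(onset_min = dd$onset_s / 60, duration_s = dd$duration_s,
                       score = NA_integer_)
      sessions[[i]] <- MonitoringSession(
        mouse_id = sprintf("trace%d", i), session_index = 1L,
        start_clock = epochStart(trace),
        duration_days = max(1L, as.integer(ceiling(span_min / MIN_PER_DAY))),
        events = ev)
    }
    log$detect <- n_det
    if (!is.null(config$truth_path)) {
      truth <- read.table(config$truth_path, header = TRUE, sep = ",")
      m <- matchDetections(truth$spike_onset_s,
                           do.call(rbind, lapply(sessions, function(s) {
                             data.frame(onset_s = events(s)$onset_min * 60)
                           })),
                           tol_s = config$match_tol_s %||% 5)
      detection <- list(sensitivity = m$sensitivity, precision = m$precision,
                        n_truth = nrow(truth))
    }
  }

  results <- analyzeSessions(sessions, ana, strict = strict)
  log$isis <- if (is.null(results$isi)) 0L else nrow(results$isi)
  log$clusters <- if (is.null(results$clusters)) 0L else nrow(results$clusters)

  # hash only semantically meaningful fields
  sem <- config[setdiff(names(config), c("log_level", "out"))]
  bundle <- c(list(meta = list(config_hash = rlang::hash(sem), seed = seed,
                               mode = config$mode,
                               version = as.character(utils::packageVersion("srsclust"))),
                   sessions = sessions, detection = detection, log = log),
              results)
  class(bundle) <- "ReportBundle"
  bundle
}

#' @export
print.ReportBundle <- function(x, ...) {
  cat(sprintf("ReportBundle (mode %s, seed %d, config %s)\n",
              x$meta$mode, x$meta$seed, substr(x$meta$config_hash, 1, 8)))
  cat(sprintf("  %d session(s), %d ISI(s), %d cluster(s)\n",
              length(x$sessions), x$log$isis %||% 0L, x$log$clusters %||% 0L))
  invisible(x)
}

#' Write a report bundle as diff-able text tables
#'
#' Emits one CSV per result table plus `summary.json` (run metadata,
#' histogram, correlation, strata, detection metrics) and the event tables
#' the statistics came from, so every reported number is traceable to a
#' shipped input.
#'
#' @param bundle a `ReportBundle` from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEventTable(bundle$sessions, file.path(dir, "events.csv"))
  wt <- function(df, name) {
    if (!is.null(df) && nrow(df))
      write.table(df, file.path(dir, name), sep = ",", quote = FALSE,
                  row.names = FALSE, na = "")
  }
  wt(bundle$isi, "isis.csv")
  wt(bundle$clusters, "clusters.csv")
  wt(bundle$groups, "groups.csv")
  wt(bundle$circadian, "circadian.csv")
  wt(bundle$trends, "trends.csv")
  wt(bundle$strata$summary, "strata.csv")
  h <- bundle$histogram; hf <- bundle$fine_histogram
  summary <- list(
    meta = bundle$meta,
    log = bundle$log,
    isi_histogram = list(bin_width_min = h$bin_width_min, breaks = h$breaks,
                         counts = h$counts, percent = h$percent, n = h$n),
    isi_fine_histogram = list(bin_width_min = hf$bin_width_min,
                              breaks = hf$breaks, counts = hf$counts,
                              percent = hf$percent, n = hf$n),
    correlation = bundle$correlation,
    strata_p = bundle$strata$p,
    detection = bundle$detection)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}
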