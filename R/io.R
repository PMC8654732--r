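EVENT_COLS <- c("mouse_id", "session_index", "day_index",
                "onset_time_min", "discharge_duration_s", "motor_score")

#' Read a seizure event table into monitoring sessions
#'
#' The event table is delimited text (comma or tab; sniffed from the header
#' line unless `delim` is given) with header columns `mouse_id`,
#' `session_index`, `day_index`, `onset_time_min`, `discharge_duration_s`,
#' `motor_score`. Empty `motor_score` cells are preserved as missing —
#' seizures whose motor component could not be scored from video stay in
#' the EEG-based analyses. Rows are grouped by `(mouse_id, session_index)`
#' into one [MonitoringSession] each; events are sorted by onset (with a
#' warning if the file was unsorted). Negative onset times and
#' non-numeric cells are errors naming the offending row.
#'
#' @param path path to the delimited event table.
#' @param manifest optional session manifest: either a YAML file path or a
#'   list as returned by [readSessionManifest()], supplying per-session
#'   `start_clock`, `duration_days`, recording `gaps`, and light cycle.
#'   Without it, sessions start at clock 8.0 and span the smallest whole
#'   number of days covering the last event.
#' @param delim field delimiter; `NULL` (default) sniffs `,` vs tab.
#' @return A list of [MonitoringSession] objects, ordered by
#'   `(mouse_id, session_index)`.
#' @seealso [writeEventTable()]
#' @export
readEventTable <- function(path, manifest = NULL, delim = NULL) {
  if (!file.exists(path)) stopf("event table not found: %s", path)
  header <- readLines(path, n = 1L)
  if (is.null(delim))
    delim <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = delim,
                   colClasses = "character", na.strings = "",
                   strip.white = TRUE, fill = FALSE)
  missing_cols <- setdiff(EVENT_COLS, names(df))
  if (length(missing_cols))
    stopf("event table missing column(s): %s", paste(missing_cols, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stopf("malformed %s in row %d: '%s'", col, bad[1], df[[col]][bad[1]])
    v
  }
  onset <- num("onset_time_min")
  dur <- num("discharge_duration_s")
  score <- num("motor_score")
  day <- num("day_index")
  sess <- num("session_index")
  neg <- which(!is.na(onset) & onset < 0)
  if (length(neg)) stopf("negative onset_time_min in row %d", neg[1])
  if (any(is.na(onset))) stopf("missing onset_time_min in row %d", which(is.na(onset))[1])

  manifest <- resolveManifest(manifest)
  key <- paste(df$mouse_id, sess, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    ev <- data.frame(onset_min = onset[idx], duration_s = dur[idx],
                     score = as.integer(score[idx]),
                     day_index = as.integer(day[idx]))
    mid <- df$mouse_id[idx[1]]
    si <- as.integer(sess[idx[1]])
    spec <- manifestEntry(manifest, mid, si)
    dd <- spec$duration_days
    if (is.null(dd)) dd <- max(1L, as.integer(ceiling(max(ev$onset_min) / MIN_PER_DAY)))
    gaps <- spec$gaps
    if (is.null(gaps)) gaps <- matrix(numeric(0), ncol = 2)
    MonitoringSession(mouse_id = mid, session_index = si,
                      start_clock = spec$start_clock %||% 8,
                      duration_days = dd, events = ev,
                      recording_gaps = gaps,
                      light_cycle = spec$light_cycle %||% LightCycle())
  })
  ord <- order(vapply(out, mouseId, ""), vapply(out, sessionIndex, 0L))
  unname(out[ord])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
resolveManifest <- function(manifest) {
  if (is.null(manifest)) return(NULL)
  if (is.character(manifest)) return(readSessionManifest(manifest))
  manifest
}

#' @noRd
manifestEntry <- function(manifest, mouse_id, session_index) {
  if (is.null(manifest)) return(list())
  for (s in manifest) {
    if (identical(as.character(s$mouse_id), mouse_id) &&
        identical(as.integer(s$session_index %||% 1L), session_index))
      return(s)
  }
  list()
}

#' Read a YAML session manifest
#'
#' Each entry under `sessions:` carries `mouse_id`, `session_index`,
#' `start_clock` (clock hour), `duration_days`, optional `gaps` (list of
#' `[start_min, end_min]` pairs for the daily 10-30 min animal-care pauses)
#' and optional `light_on_start` / `light_on_hours`.
#'
#' @param path YAML file path.
#' @return A list of per-session spec lists consumable by [readEventTable()].
#' @export
readSessionManifest <- function(path) {
  y <- yaml::read_yaml(path)
  entries <- y$sessions %||% y
  lapply(entries, function(s) {
    if (!is.null(s$gaps) && length(s$gaps))
      s$gaps <- do.call(rbind, lapply(s$gaps, as.numeric))
    if (!is.null(s$light_on_start) || !is.null(s$light_on_hours))
      s$light_cycle <- LightCycle(light_on_start = s$light_on_start %||% 6,
                                  light_on_hours = s$light_on_hours %||% 12)
    s
  })
}

#' Write monitoring sessions as a delimited event table
#'
#' Inverse of [readEventTable()]: numeric fields are written at full
#' precision so that a read-back reproduces every field bit-exactly, and
#' missing Racine scores become empty cells. An empty session list writes a
#' header-only file.
#'
#' @param sessions a [MonitoringSession] or list of them.
#' @param path output file path.
#' @param delim field delimiter (default `","`; use `"\t"` for TSV).
#' @return `path`, invisibly.
#' @export
writeEventTable <- function(sessions, path, delim = ",") {
  if (is(sessions, "MonitoringSession")) sessions <- list(sessions)
  rows <- lapply(sessions, function(s) {
    ev <- events(s)
    if (!nrow(ev)) return(NULL)
    data.frame(mouse_id = mouseId(s),
               session_index = sessionIndex(s),
               day_index = ev$day_index,
               onset_time_min = fmtFull(ev$onset_min),
               discharge_duration_s = fmtFull(ev$duration_s),
               motor_score = ifelse(is.na(ev$score), "", as.character(ev$score)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- as.data.frame(setNames(rep(list(character(0)), length(EVENT_COLS)),
                                 EVENT_COLS))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(df, con, sep = delim, quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a two-column delimited EEG trace
#'
#' Expects header columns `time_s` and `amplitude` with uniform sampling;
#' the sampling rate is inferred from the median time step and checked for
#' uniformity.
#'
#' @param path file path.
#' @param epoch_start clock hour-of-day of the first sample.
#' @param channel_label channel name.
#' @return An [EEGTrace].
#' @export
readTrace <- function(path, epoch_start = 8, channel_label = "hpc") {
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- read.table(path, header = TRUE, sep = delim)
  if (!all(c("time_s", "amplitude") %in% names(df)))
    stopf("trace file must have columns time_s, amplitude: %s", path)
  dt <- diff(df$time_s)
  if (length(dt)) {
    step <- median(dt)
    if (step <= 0 || any(abs(dt - step) > step * 1e-3))
      stopf("trace is not uniformly sampled: %s", path)
    fs <- 1 / step
  } else fs <- 250
  EEGTrace(samples = df$amplitude, sampling_rate = fs,
           epoch_start = epoch_start, channel_label = channel_label)
}

#' Write an EEG trace as two-column delimited text
#'
#' @param trace an [EEGTrace].
#' @param path output path.
#' @param delim delimiter (default comma).
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path, delim = ",") {
  n <- length(samples(trace))
  df <- data.frame(time_s = (seq_len(n) - 1) / samplingRate(trace),
                   amplitude = samples(trace))
  write.table(df, path, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}
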