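#' @import methods
NULL

# ---- LightCycle --------------------------------------------------------------

#' Vivarium light cycle
#'
#' Describes the daily illumination schedule used as the circadian proxy.
#' The default is the standard 12 h/12 h cycle with lights on at 06:00.
#' The light-on interval is half-open: a time falling exactly at lights-off
#' (18:00 under the default) is classified as light-off.
#'
#' @slot light_on_start clock hour at which lights turn on (0-24).
#' @slot light_on_hours duration of the light-on phase in hours.
#'
#' @param light_on_start clock hour at which lights turn on (default 6).
#' @param light_on_hours light-on duration in hours (default 12).
#' @return A `LightCycle` object.
#' @examples
#' LightCycle()               # lights on 06:00-18:00
#' LightCycle(7, 10)          # lights on 07:00-17:00
#' @export LightCycle
#' @exportClass LightCycle
LightCycle <- setClass("LightCycle",
  representation(light_on_start = "numeric", light_on_hours = "numeric"),
  prototype(light_on_start = 6, light_on_hours = 12))

setValidity("LightCycle", function(object) {
  msg <- character()
  if (length(object@light_on_start) != 1 || is.na(object@light_on_start) ||
      object@light_on_start < 0 || object@light_on_start >= 24)
    msg <- c(msg, "light_on_start must be a single hour in [0, 24)")
  if (length(object@light_on_hours) != 1 || is.na(object@light_on_hours) ||
      object@light_on_hours <= 0 || object@light_on_hours >= 24)
    msg <- c(msg, "light_on_hours must lie strictly between 0 and 24")
  if (length(msg)) msg else TRUE
})

# ---- MonitoringSession -------------------------------------------------------

#' One continuous multi-day EEG monitoring session for one mouse
#'
#' Holds the seizure event table for a contiguous recording block (4-7 days
#' in the included data), together with the wall-clock time at which the
#' recording epoch started (so circadian phase is recoverable from event
#' times in minutes-since-epoch), the daily animal-care recording gaps, and
#' the vivarium light cycle.
#'
#' The `events` data.frame uses the canonical columns
#' `onset_min` (minutes since epoch start, strictly increasing),
#' `duration_s` (EEG discharge duration in seconds, measured from low-voltage
#' fast onset to spike cessation), `score` (Racine stage 0-5, `NA` when the
#' motor seizure could not be scored), `day_index` (1-based recording day),
#' and optionally `cluster_id` (simulator ground-truth label, `NA` for
#' isolated events).
#'
#' @slot mouse_id opaque animal label.
#' @slot session_index 1-based monitoring session number (1-3 in the data
#'   the model emulates).
#' @slot start_clock clock hour-of-day at which minute 0 of the session falls.
#' @slot duration_days number of monitored 24-h days.
#' @slot events seizure event data.frame (see Details).
#' @slot recording_gaps two-column matrix of (start_min, end_min) pauses.
#' @slot light_cycle a [LightCycle].
#'
#' @param mouse_id,session_index,start_clock,duration_days,events,recording_gaps,light_cycle
#'   see slot descriptions.
#' @return A `MonitoringSession`.
#' @examples
#' ev <- data.frame(onset_min = c(0, 195, 198), duration_s = c(40, 35, 50),
#'                  score = c(3L, NA, 4L))
#' MonitoringSession(mouse_id = "h1", events = ev, duration_days = 1L)
#' @export MonitoringSession
#' @exportClass MonitoringSession
MonitoringSession <- function(mouse_id = "m1", session_index = 1L,
                              start_clock = 8, duration_days = 7L,
                              events = emptyEvents(),
                              recording_gaps = matrix(numeric(0), ncol = 2),
                              light_cycle = LightCycle()) {
  events <- normalizeEvents(events, duration_days)
  new("MonitoringSession", mouse_id = as.character(mouse_id),
      session_index = as.integer(session_index),
      start_clock = as.numeric(start_clock),
      duration_days = as.integer(duration_days),
      events = events,
      recording_gaps = matrix(as.numeric(recording_gaps), ncol = 2,
                              dimnames = list(NULL, c("start_min", "end_min"))),
      light_cycle = light_cycle)
}

setClass("MonitoringSession",
  representation(mouse_id = "character", session_index = "integer",
                 start_clock = "numeric", duration_days = "integer",
                 events = "data.frame", recording_gaps = "matrix",
                 light_cycle = "LightCycle"))

setValidity("MonitoringSession", function(object) {
  msg <- character()
  ev <- object@events
  need <- c("onset_min", "duration_s", "score")
  if (!all(need %in% names(ev)))
    msg <- c(msg, paste("events must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(ev)) {
      if (any(is.na(ev$onset_min)) || any(ev$onset_min < 0))
        msg <- c(msg, "event onset_min must be non-negative and non-missing")
      if (is.unsorted(ev$onset_min, strictly = TRUE))
        msg <- c(msg, "event onset_min must be strictly increasing")
      if (any(!is.na(ev$duration_s) & ev$duration_s <= 0))
        msg <- c(msg, "discharge duration_s must be positive")
      sc <- ev$score[!is.na(ev$score)]
      if (length(sc) && !all(sc %in% 0:5))
        msg <- c(msg, "Racine score must be an integer stage in 0..5 (or NA)")
    }
  }
  if (object@duration_days < 1L)
    msg <- c(msg, "duration_days must be >= 1")
  if (object@session_index < 1L)
    msg <- c(msg, "session_index must be >= 1")
  g <- object@recording_gaps
  if (nrow(g)) {
    if (any(g[, 2] <= g[, 1]))
      msg <- c(msg, "recording gaps must have end > start")
    if (any(g[, 1] < 0) || any(g[, 2] > object@duration_days * MIN_PER_DAY))
      msg <- c(msg, "recording gaps must lie within the session span")
    o <- order(g[, 1])
    if (nrow(g) > 1 && any(g[o, 1][-1] < g[o, 2][-nrow(g)]))
      msg <- c(msg, "recording gaps must not overlap")
  }
  if (length(msg)) msg else TRUE
})

#' @noRd
emptyEvents <- function() {
  data.frame(onset_min = numeric(0), duration_s = numeric(0),
             score = integer(0), day_index = integer(0))
}

#' Sort events, coerce column types, derive day_index when absent
#' @noRd
normalizeEvents <- function(events, duration_days = NULL) {
  events <- as.data.frame(events)
  if (!nrow(events)) return(emptyEvents())
  if (is.null(events$score)) events$score <- NA_integer_
  events$score <- suppressWarnings(as.integer(events$score))
  events$onset_min <- as.numeric(events$onset_min)
  events$duration_s <- as.numeric(events$duration_s)
  if (is.unsorted(events$onset_min)) {
    warnf("events were not sorted by onset time; sorting")
    events <- events[order(events$onset_min), , drop = FALSE]
  }
  if (is.null(events$day_index))
    events$day_index <- as.integer(events$onset_min %/% MIN_PER_DAY + 1)
  rownames(events) <- NULL
  events
}

# ---- EEGTrace ----------------------------------------------------------------

#' Uniformly sampled single-channel EEG trace
#'
#' @slot sampling_rate sampling frequency in Hz.
#' @slot samples numeric amplitude vector (arbitrary units).
#' @slot epoch_start clock hour-of-day of the first sample.
#' @slot channel_label free-text channel name.
#'
#' @param samples,sampling_rate,epoch_start,channel_label see slots.
#' @return An `EEGTrace`.
#' @examples
#' EEGTrace(rnorm(2500), sampling_rate = 250)
#' @export EEGTrace
#' @exportClass EEGTrace
EEGTrace <- setClass("EEGTrace",
  representation(sampling_rate = "numeric", samples = "numeric",
                 epoch_start = "numeric", channel_label = "character"),
  prototype(sampling_rate = 250, samples = numeric(0), epoch_start = 8,
            channel_label = "hpc"))

setValidity("EEGTrace", function(object) {
  msg <- character()
  if (length(object@sampling_rate) != 1 || object@sampling_rate <= 0)
    msg <- c(msg, "sampling_rate must be a single positive number")
  if (length(object@samples) && any(!is.finite(object@samples)))
    msg <- c(msg, "samples must be finite")
  if (length(msg)) msg else TRUE
})

# ---- Parameter blocks --------------------------------------------------------

#' Analysis parameters for ISI, cluster, and trend analyses
#'
#' Defaults follow the study conditions the model emulates: clusters are
#' at least `cluster_min_size` (4) consecutive seizures whose successive
#' ISIs are all at most `cluster_max_isi` (120 min); tight clusters further
#' require every intra-cluster ISI at most `tight_max_isi` (20 min); the
#' main ISI histogram uses 60-min bins with a 10-min fine view of the first
#' bin; Racine scores are stratified at 60 and 120 min; neighboring clusters
#' separated by at most `group_max_gap` (3 h) chain into groups.
#'
#' @slot cluster_max_isi minutes; maximum intra-cluster ISI.
#' @slot cluster_min_size minimum events per cluster.
#' @slot tight_max_isi minutes; intra-cluster ISI bound for "tight" clusters.
#' @slot isi_bin_main,isi_bin_fine histogram bin widths in minutes.
#' @slot score_strata_edges ISI stratum edges in minutes.
#' @slot alpha two-sided significance level.
#' @slot group_max_gap hours; maximum gap chaining clusters into a group.
#'
#' @param cluster_max_isi,cluster_min_size,tight_max_isi,isi_bin_main,isi_bin_fine,score_strata_edges,alpha,group_max_gap
#'   see slots.
#' @return An `AnalysisParams`.
#' @export AnalysisParams
#' @exportClass AnalysisParams
AnalysisParams <- setClass("AnalysisParams",
  representation(cluster_max_isi = "numeric", cluster_min_size = "integer",
                 tight_max_isi = "numeric", isi_bin_main = "numeric",
                 isi_bin_fine = "numeric", score_strata_edges = "numeric",
                 alpha = "numeric", group_max_gap = "numeric"),
  prototype(cluster_max_isi = 120, cluster_min_size = 4L, tight_max_isi = 20,
            isi_bin_main = 60, isi_bin_fine = 10,
            score_strata_edges = c(60, 120), alpha = 0.05, group_max_gap = 3))

setValidity("AnalysisParams", function(object) {
  msg <- character()
  pos <- c(cluster_max_isi = object@cluster_max_isi,
           tight_max_isi = object@tight_max_isi,
           isi_bin_main = object@isi_bin_main,
           isi_bin_fine = object@isi_bin_fine,
           alpha = object@alpha, group_max_gap = object@group_max_gap)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad)) msg <- c(msg, paste("must be > 0:", paste(bad, collapse = ", ")))
  if (object@cluster_min_size < 2L)
    msg <- c(msg, "cluster_min_size must be >= 2")
  e <- object@score_strata_edges
  if (length(e) < 1 || is.unsorted(e, strictly = TRUE) || any(e <= 0))
    msg <- c(msg, "score_strata_edges must be positive and strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Detection parameters for the envelope-threshold discharge detector
#'
#' Operationalizes the discharge criteria: repetitive spikes with envelope
#' amplitude at least `amp_factor` (2) times the robust background and
#' duration at least `min_duration_s` (10 s). The background is a robust
#' central value of the smoothed rectified envelope, taken as the median
#' across `background_window_s` windows so that the discharge minority does
#' not inflate it. Sub-threshold lulls up to `merge_gap_s` are merged into
#' one event; post-ictal suppression is declared when the envelope drops
#' below `suppression_factor` times background for at least
#' `suppression_min_s` within 10 s of the offset.
#'
#' @slot amp_factor threshold in background multiples.
#' @slot min_duration_s minimum discharge duration, seconds.
#' @slot background_window_s window length for background estimation, seconds.
#' @slot merge_gap_s maximum merged sub-threshold gap, seconds.
#' @slot envelope_window_s rectified-signal smoothing window, seconds.
#' @slot suppression_factor,suppression_min_s post-ictal suppression criteria.
#'
#' @param amp_factor,min_duration_s,background_window_s,merge_gap_s,envelope_window_s,suppression_factor,suppression_min_s
#'   see slots.
#' @return A `DetectionParams`.
#' @export DetectionParams
#' @exportClass DetectionParams
DetectionParams <- setClass("DetectionParams",
  representation(amp_factor = "numeric", min_duration_s = "numeric",
                 background_window_s = "numeric", merge_gap_s = "numeric",
                 envelope_window_s = "numeric", suppression_factor = "numeric",
                 suppression_min_s = "numeric"),
  prototype(amp_factor = 2, min_duration_s = 10, background_window_s = 60,
            merge_gap_s = 5, envelope_window_s = 0.5,
            suppression_factor = 0.5, suppression_min_s = 2))

setValidity("DetectionParams", function(object) {
  msg <- character()
  if (object@amp_factor < 1) msg <- c(msg, "amp_factor must be >= 1")
  if (object@min_duration_s <= 0) msg <- c(msg, "min_duration_s must be > 0")
  if (object@merge_gap_s >= object@min_duration_s)
    msg <- c(msg, paste("merge_gap_s must be smaller than min_duration_s:",
                        "otherwise two distinct sub-minimum bursts could be",
                        "merged into a spurious qualifying discharge"))
  if (object@background_window_s <= 0 || object@envelope_window_s <= 0 ||
      object@suppression_min_s <= 0)
    msg <- c(msg, "window and suppression durations must be > 0")
  if (object@suppression_factor <= 0 || object@suppression_factor >= 1)
    msg <- c(msg, "suppression_factor must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Generative parameters of the clustered, circadian-modulated SRS process
#'
#' A Neyman-Scott-style doubly stochastic process: cluster initiations arrive
#' as an inhomogeneous Poisson process with rate `cluster_rate_base` per hour,
#' multiplied by `circadian_ratio` during the light-on phase, thinned so that
#' successive clusters are separated by more than the intra-cluster ISI bound
#' (clusters never chain together); each cluster draws its size from
#' `cluster_size_probs` (over sizes 2-12; the sub-threshold 2-3 tail creates
#' runs that must NOT be called clusters) and size-1 within-cluster ISIs from
#' a log-normal truncated at the cluster ISI bound; isolated seizures arrive
#' as an independent homogeneous Poisson process and are rejected when within
#' that bound of any cluster member. Discharge durations and Racine scores
#' are drawn independently of the ISIs (matching the null relationships the
#' analysis tests), unless `mark_coupling` is set for power studies.
#'
#' @slot cluster_rate_base cluster initiations per hour (default 0.15).
#' @slot circadian_ratio initiation-rate multiplier during light-on
#'   (1 = no circadian preference; > 1 prefers light-on).
#' @slot cluster_size_probs probability vector over cluster sizes 2..12.
#' @slot intra_isi_meanlog,intra_isi_sdlog log-normal parameters of
#'   within-cluster ISIs in log-minutes (default median 8 min, sd 0.6).
#' @slot isolated_rate isolated seizures per hour (default 0.05).
#' @slot duration_meanlog,duration_sdlog log-normal discharge-duration
#'   parameters in log-seconds (default median 40 s).
#' @slot score_probs probability vector over Racine stages 0..5
#'   (default mean ~ 3.3).
#' @slot mark_coupling slope coupling marks to log-ISI (0 = independent).
#' @slot truncate_intra_isis truncate within-cluster ISIs at the cluster
#'   ISI bound (TRUE; FALSE studies rule/truth mismatch).
#'
#' @param cluster_rate_base,circadian_ratio,cluster_size_probs,intra_isi_meanlog,intra_isi_sdlog,isolated_rate,duration_meanlog,duration_sdlog,score_probs,mark_coupling,truncate_intra_isis
#'   see slots.
#' @return A `SimParams`.
#' @export SimParams
#' @exportClass SimParams
SimParams <- setClass("SimParams",
  representation(cluster_rate_base = "numeric", circadian_ratio = "numeric",
                 cluster_size_probs = "numeric",
                 intra_isi_meanlog = "numeric", intra_isi_sdlog = "numeric",
                 isolated_rate = "numeric",
                 duration_meanlog = "numeric", duration_sdlog = "numeric",
                 score_probs = "numeric", mark_coupling = "numeric",
                 truncate_intra_isis = "logical"),
  prototype(cluster_rate_base = 0.15, circadian_ratio = 1,
            cluster_size_probs = c(`2` = 0.05, `3` = 0.07, `4` = 0.18,
                                   `5` = 0.20, `6` = 0.18, `7` = 0.12,
                                   `8` = 0.08, `9` = 0.05, `10` = 0.03,
                                   `11` = 0.02, `12` = 0.02),
            intra_isi_meanlog = log(8), intra_isi_sdlog = 0.6,
            isolated_rate = 0.05,
            duration_meanlog = log(40), duration_sdlog = 0.4,
            score_probs = c(`0` = 0.01, `1` = 0.03, `2` = 0.10, `3` = 0.45,
                            `4` = 0.31, `5` = 0.10),
            mark_coupling = 0, truncate_intra_isis = TRUE))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@cluster_rate_base < 0 || object@isolated_rate < 0)
    msg <- c(msg, "rates must be >= 0")
  if (object@circadian_ratio <= 0)
    msg <- c(msg, "circadian_ratio must be > 0")
  if (length(object@cluster_size_probs) != 11 ||
      any(object@cluster_size_probs < 0) ||
      abs(sum(object@cluster_size_probs) - 1) > 1e-8)
    msg <- c(msg, "cluster_size_probs must be 11 non-negative values over sizes 2..12 summing to 1")
  if (length(object@score_probs) != 6 || any(object@score_probs < 0) ||
      abs(sum(object@score_probs) - 1) > 1e-8)
    msg <- c(msg, "score_probs must be 6 non-negative values over stages 0..5 summing to 1")
  if (object@intra_isi_sdlog <= 0 || object@duration_sdlog <= 0)
    msg <- c(msg, "log-normal sd parameters must be > 0")
  if (length(msg)) msg else TRUE
})

#' Synthetic-EEG rendering parameters
#'
#' Renders each seizure as the discharge morphology the detector criteria
#' describe: a short low-voltage fast lead-in, then repetitive biphasic
#' spikes at `spike_rate_hz` with peak amplitude `discharge_amp_factor`
#' times the background noise scale for the discharge duration, then a
#' post-ictal suppression period in which the background is attenuated by
#' `suppression_factor`. The amplitude factor must exceed 2 because the
#' detection criterion itself is a 2-fold background threshold: a quieter
#' discharge is not a valid rendering of the detectable morphology.
#'
#' @slot background_sigma background noise amplitude scale.
#' @slot discharge_amp_factor spike peak in background multiples (> 2).
#' @slot spike_rate_hz intra-discharge spike repetition rate.
#' @slot onset_lvf_seconds low-voltage fast lead-in length.
#' @slot suppression_seconds post-ictal suppression length.
#' @slot suppression_factor amplitude multiplier during suppression.
#' @slot sampling_rate Hz.
#'
#' @param background_sigma,discharge_amp_factor,spike_rate_hz,onset_lvf_seconds,suppression_seconds,suppression_factor,sampling_rate
#'   see slots.
#' @return An `EEGSimParams`.
#' @export EEGSimParams
#' @exportClass EEGSimParams
EEGSimParams <- setClass("EEGSimParams",
  representation(background_sigma = "numeric", discharge_amp_factor = "numeric",
                 spike_rate_hz = "numeric", onset_lvf_seconds = "numeric",
                 suppression_seconds = "numeric", suppression_factor = "numeric",
                 sampling_rate = "numeric"),
  prototype(background_sigma = 1, discharge_amp_factor = 4, spike_rate_hz = 5,
            onset_lvf_seconds = 1.5, suppression_seconds = 5,
            suppression_factor = 0.3, sampling_rate = 250))

setValidity("EEGSimParams", function(object) {
  msg <- character()
  if (object@discharge_amp_factor <= 2)
    msg <- c(msg, "discharge_amp_factor must exceed 2 (the detection criterion is a 2-fold background threshold)")
  if (object@background_sigma <= 0) msg <- c(msg, "background_sigma must be > 0")
  if (object@spike_rate_hz <= 0 || object@sampling_rate <= 0)
    msg <- c(msg, "spike_rate_hz and sampling_rate must be > 0")
  if (object@onset_lvf_seconds < 0 || object@suppression_seconds < 0)
    msg <- c(msg, "lead-in and suppression durations must be >= 0")
  if (object@suppression_factor < 0 || object@suppression_factor >= 1)
    msg <- c(msg, "suppression_factor must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})
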