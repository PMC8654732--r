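#' @rdname srsclust-generics
#' @aliases events,MonitoringSession-method
setMethod("events", "MonitoringSession", function(x) x@events)

#' @rdname srsclust-generics
setReplaceMethod("events", "MonitoringSession", function(x, value) {
  x@events <- normalizeEvents(value, x@duration_days)
  validObject(x)
  x
})

#' @rdname srsclust-generics
setMethod("mouseId", "MonitoringSession", function(x) x@mouse_id)

#' @rdname srsclust-generics
setMethod("sessionIndex", "MonitoringSession", function(x) x@session_index)

#' @rdname srsclust-generics
setMethod("startClock", "MonitoringSession", function(x) x@start_clock)

#' @rdname srsclust-generics
setMethod("durationDays", "MonitoringSession", function(x) x@duration_days)

#' @rdname srsclust-generics
setMethod("recordingGaps", "MonitoringSession", function(x) x@recording_gaps)

#' @rdname srsclust-generics
setMethod("lightCycle", "MonitoringSession", function(x) x@light_cycle)

#' @rdname srsclust-generics
setMethod("nEvents", "MonitoringSession", function(x) nrow(x@events))

#' @rdname srsclust-generics
setMethod("samplingRate", "EEGTrace", function(x) x@sampling_rate)

#' @rdname srsclust-generics
setMethod("samples", "EEGTrace", function(x) x@samples)

#' @rdname srsclust-generics
setMethod("epochStart", "EEGTrace", function(x) x@epoch_start)

setMethod("show", "MonitoringSession", function(object) {
  ev <- object@events
  cat(sprintf("MonitoringSession: mouse %s, session %d\n",
              object@mouse_id, object@session_index))
  cat(sprintf("  %d days starting at clock %05.2f h; %d seizure events\n",
              object@duration_days, object@start_clock, nrow(ev)))
  if (nrow(ev)) {
    cat(sprintf("  onsets %.1f-%.1f min; %d events unscored\n",
                min(ev$onset_min), max(ev$onset_min), sum(is.na(ev$score))))
  }
  lc <- object@light_cycle
  cat(sprintf("  light-on %.1f-%.1f h; %d recording gap(s)\n",
              lc@light_on_start, lc@light_on_start + lc@light_on_hours,
              nrow(object@recording_gaps)))
  invisible(NULL)
})

setMethod("show", "EEGTrace", function(object) {
  cat(sprintf("EEGTrace '%s': %d samples @ %g Hz (%.1f s), epoch start %05.2f h\n",
              object@channel_label, length(object@samples),
              object@sampling_rate,
              length(object@samples) / object@sampling_rate,
              object@epoch_start))
  invisible(NULL)
})

setMethod("show", "LightCycle", function(object) {
  cat(sprintf("LightCycle: light-on [%g, %g) h\n", object@light_on_start,
              object@light_on_start + object@light_on_hours))
  invisible(NULL)
})
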