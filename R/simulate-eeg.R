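#' Render a synthetic EEG trace containing ictal discharges
#'
#' Builds a single-channel trace of Gaussian background noise and, for each
#' seizure event, the canonical ictal morphology: a low-voltage fast
#' lead-in (low-amplitude 40 Hz oscillation for `onset_lvf_seconds`), then
#' repetitive biphasic spikes at `spike_rate_hz` with peak amplitude
#' `discharge_amp_factor * background_sigma` lasting the event's discharge
#' duration, then post-ictal suppression in which the background is
#' attenuated by `suppression_factor` for `suppression_seconds`.
#'
#' @param events data.frame with columns `onset_min` (spike onset, minutes
#'   within the trace) and `duration_s` (spiking duration, seconds), e.g.
#'   `events(session)` from [simulateEventStream()].
#' @param eeg_params an [EEGSimParams].
#' @param span_min trace length in minutes.
#' @param seed optional integer seed for the noise stream.
#' @param epoch_start clock hour of the first sample.
#' @return An [EEGTrace]; its `"truth"` attribute is a data.frame of ground
#'   truth per event (`lvf_onset_s`, `spike_onset_s`, `offset_s`,
#'   `duration_s`), retrievable with [eegTruth()].
#' @examples
#' ev <- data.frame(onset_min = 2, duration_s = 30)
#' tr <- simulateEEG(ev, EEGSimParams(), span_min = 5, seed = 1)
#' eegTruth(tr)
#' @export
simulateEEG <- function(events, eeg_params = EEGSimParams(), span_min = 10,
                        seed = NULL, epoch_start = 8) {
  validObject(eeg_params)
  events <- as.data.frame(events)
  fs <- eeg_params@sampling_rate
  span_s <- span_min * 60
  n <- as.integer(round(span_s * fs))
  if (nrow(events)) {
    on_s <- events$onset_min * 60
    dur <- events$duration_s
    if (any(on_s - eeg_params@onset_lvf_seconds < 0) ||
        any(on_s + dur + eeg_params@suppression_seconds > span_s))
      stopf("event discharge windows (incl. lead-in and suppression) must lie within the %g-min span", span_min)
    win <- cbind(on_s - eeg_params@onset_lvf_seconds,
                 on_s + dur + eeg_params@suppression_seconds)
    o <- order(win[, 1])
    if (nrow(win) > 1 && any(win[o, 1][-1] < win[o, 2][-nrow(win)]))
      stopf("discharge windows overlap; events are too close for a single-channel rendering")
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  sigma <- eeg_params@background_sigma
  x <- rnorm(n, 0, sigma)
  # 1-based sample indices covering [t0, t1) seconds, clipped to the trace
  idxRange <- function(t0, t1) {
    a <- max(1L, as.integer(floor(t0 * fs)) + 1L)
    b <- min(n, as.integer(ceiling(t1 * fs)))
    if (a > b) integer(0) else a:b
  }
  truth <- data.frame(event = integer(0), lvf_onset_s = numeric(0),
                      spike_onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0))
  if (nrow(events)) {
    amp <- eeg_params@discharge_amp_factor * sigma
    spike_period <- 1 / eeg_params@spike_rate_hz
    spike_width <- 0.6 * spike_period     # biphasic deflection, 60% duty
    for (i in seq_len(nrow(events))) {
      t_on <- events$onset_min[i] * 60
      dur <- events$duration_s[i]
      # low-voltage fast lead-in: sub-threshold 40 Hz oscillation
      if (eeg_params@onset_lvf_seconds > 0) {
        idx <- idxRange(t_on - eeg_params@onset_lvf_seconds, t_on)
        tt <- (idx - 1) / fs
        x[idx] <- 0.3 * sigma * sin(2 * pi * 40 * tt) + rnorm(length(idx), 0, 0.3 * sigma)
      }
      # repetitive biphasic spikes: one sine cycle per spike, silence between
      idx <- idxRange(t_on, t_on + dur)
      tt <- (idx - 1) / fs - t_on
      ph <- (tt %% spike_period) / spike_width
      spike <- ifelse(ph < 1, amp * sin(2 * pi * ph), 0)
      x[idx] <- x[idx] + spike
      # post-ictal suppression: attenuated background
      if (eeg_params@suppression_seconds > 0) {
        idx <- idxRange(t_on + dur, t_on + dur + eeg_params@suppression_seconds)
        x[idx] <- x[idx] * eeg_params@suppression_factor
      }
      truth <- rbind(truth, data.frame(
        event = i, lvf_onset_s = t_on - eeg_params@onset_lvf_seconds,
        spike_onset_s = t_on, offset_s = t_on + dur, duration_s = dur))
    }
  }
  tr <- EEGTrace(samples = x, sampling_rate = fs, epoch_start = epoch_start,
                 channel_label = "sim")
  attr(tr, "truth") <- truth
  tr
}

#' Ground-truth discharge times of a synthetic trace
#'
#' @param trace an [EEGTrace] produced by [simulateEEG()].
#' @return The ground-truth data.frame, or an empty one for foreign traces.
#' @export
eegTruth <- function(trace) {
  tr <- attr(trace, "truth")
  if (is.null(tr))
    tr <- data.frame(event = integer(0), lvf_onset_s = numeric(0),
                     spike_onset_s = numeric(0), offset_s = numeric(0),
                     duration_s = numeric(0))
  tr
}
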