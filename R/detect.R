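#' Rectified, smoothed amplitude envelope of a trace
#' @noRd
traceEnvelope <- function(trace, params) {
  n_win <- max(1L, as.integer(round(params@envelope_window_s * samplingRate(trace))))
  movingMean(abs(samples(trace)), n_win)
}

#' Robust background amplitude of an EEG trace
#'
#' The background is the central value of the smoothed rectified envelope,
#' estimated robustly so that the ictal minority does not inflate it: the
#' envelope is cut into `background_window_s` windows, each window
#' contributes its median envelope level, and the estimate is the median
#' across windows. Discharge epochs occupying a minority of windows shift
#' at most their own windows' medians, leaving the across-window median
#' essentially unchanged.
#'
#' @param trace an [EEGTrace].
#' @param params a [DetectionParams].
#' @return Background amplitude in sample units; `0` for a degenerate
#'   (constant-zero envelope) trace, which downstream detection rejects.
#' @export
estimateBackground <- function(trace, params = DetectionParams()) {
  fs <- samplingRate(trace)
  if (length(samples(trace)) < params@background_window_s * fs)
    stopf("trace shorter than one background window (%g s)", params@background_window_s)
  env <- traceEnvelope(trace, params)
  wlen <- as.integer(round(params@background_window_s * fs))
  idx <- (seq_along(env) - 1L) %/% wlen
  med_by_win <- tapply(env, idx, median)
  as.numeric(median(med_by_win))
}

#' Detect ictal discharges by envelope thresholding
#'
#' Implements the discharge criteria on the smoothed rectified envelope:
#' samples whose envelope reaches `amp_factor` (default 2) times the robust
#' background are supra-threshold; supra-threshold segments separated by
#' sub-threshold gaps of at most `merge_gap_s` are merged (brief intra-ictal
#' lulls must not split one discharge); merged segments lasting at least
#' `min_duration_s` (default 10 s) are reported. The onset is the first
#' supra-threshold sample of the merged segment and the offset the last —
#' the low-voltage fast lead-in is sub-threshold by definition, so detected
#' onsets lag the morphological onset by roughly the lead-in length.
#' `has_suppression` flags events whose envelope falls below
#' `suppression_factor` times background for at least `suppression_min_s`
#' within 10 s of the offset. Because the threshold is background-relative,
#' detection is invariant to rescaling the whole trace by any positive
#' constant.
#'
#' @param trace an [EEGTrace].
#' @param params a [DetectionParams].
#' @return data.frame with one row per discharge: `onset_s`, `offset_s`,
#'   `duration_s`, `peak_amp_ratio`, `has_suppression`; sorted and
#'   non-overlapping.
#' @export
detectDischarges <- function(trace, params = DetectionParams()) {
  validObject(params)
  fs <- samplingRate(trace)
  bg <- estimateBackground(trace, params)
  if (bg <= 0) stopf("degenerate background (robust envelope scale is 0)")
  env <- traceEnvelope(trace, params)
  runs <- maskRuns(env >= params@amp_factor * bg)
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      duration_s = numeric(0), peak_amp_ratio = numeric(0),
                      has_suppression = logical(0))
  if (!nrow(runs)) return(empty)
  # merge across sub-threshold gaps <= merge_gap_s
  gap_n <- params@merge_gap_s * fs
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      if (runs[i, "start"] - merged[nrow(merged), "end"] - 1L <= gap_n)
        merged[nrow(merged), "end"] <- runs[i, "end"]
      else
        merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  dur_s <- (merged[, "end"] - merged[, "start"] + 1L) / fs
  keep <- dur_s >= params@min_duration_s
  merged <- merged[keep, , drop = FALSE]
  if (!nrow(merged)) return(empty)
  out <- lapply(seq_len(nrow(merged)), function(i) {
    a <- merged[i, "start"]; b <- merged[i, "end"]
    post <- env[seq(b + 1L, min(length(env), b + as.integer(10 * fs)))]
    supp_runs <- maskRuns(post < params@suppression_factor * bg)
    has_supp <- nrow(supp_runs) > 0 &&
      any((supp_runs[, "end"] - supp_runs[, "start"] + 1L) / fs >= params@suppression_min_s)
    data.frame(onset_s = (a - 1L) / fs, offset_s = (b - 1L) / fs,
               duration_s = (b - a + 1L) / fs,
               peak_amp_ratio = max(env[a:b]) / bg,
               has_suppression = has_supp)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Match detected discharges to ground-truth events
#'
#' Greedy one-to-one pairing by onset proximity: truth/detection pairs are
#' considered in order of increasing onset distance and accepted while both
#' members are unpaired and the distance is at most `tol_s`. Sensitivity is
#' `paired / n_truth`; precision is `paired / n_detected` (`NA` when nothing
#' was detected).
#'
#' @param truth_onsets_s numeric vector of true onset times (seconds).
#' @param detected data.frame from [detectDischarges()] (or a numeric vector
#'   of onset seconds).
#' @param tol_s pairing tolerance in seconds (default 5).
#' @return list with `sensitivity`, `precision`, and `pairs` (data.frame of
#'   `truth_idx`, `det_idx`, `delta_s`).
#' @export
matchDetections <- function(truth_onsets_s, detected, tol_s = 5) {
  det_onsets <- if (is.data.frame(detected)) detected$onset_s else as.numeric(detected)
  nt <- length(truth_onsets_s); nd <- length(det_onsets)
  pairs <- data.frame(truth_idx = integer(0), det_idx = integer(0),
                      delta_s = numeric(0))
  if (nt && nd) {
    d <- abs(outer(truth_onsets_s, det_onsets, "-"))
    cand <- which(d <= tol_s, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_t <- logical(nt); used_d <- logical(nd)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!used_t[i] && !used_d[j]) {
          used_t[i] <- TRUE; used_d[j] <- TRUE
          pairs <- rbind(pairs, data.frame(truth_idx = i, det_idx = j,
                                           delta_s = det_onsets[j] - truth_onsets_s[i]))
        }
      }
    }
  }
  list(sensitivity = if (nt) nrow(pairs) / nt else NA_real_,
       precision = if (nd) nrow(pairs) / nd else NA_real_,
       pairs = pairs)
}
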