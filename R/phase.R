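#' Circadian phase of a session time
#'
#' Maps a time in minutes since the session epoch to the light-on or
#' light-off phase of the vivarium light cycle. The clock time is
#' `(start_clock + t / 60) mod 24` hours; light-on is the half-open
#' interval `[light_on_start, light_on_start + light_on_hours)`, so a time
#' falling exactly at lights-off is classified `"light_off"`. The mapping
#' is periodic with period 24 h.
#'
#' @param t_min time(s) in minutes since the session epoch start (>= 0).
#' @param start_clock clock hour-of-day of the epoch start.
#' @param light_cycle a [LightCycle].
#' @return Character vector, `"light_on"` or `"light_off"` per element.
#' @examples
#' phaseOf(240, start_clock = 8)    # 12:00 -> light_on
#' phaseOf(0,  start_clock = 3)     # 03:00 -> light_off
#' @export
phaseOf <- function(t_min, start_clock = 8, light_cycle = LightCycle()) {
  stopifnot(is.numeric(t_min), all(t_min >= 0))
  clock_h <- (start_clock + t_min / MIN_PER_HOUR) %% 24
  on0 <- light_cycle@light_on_start
  on1 <- on0 + light_cycle@light_on_hours
  if (on1 <= 24) {
    on <- clock_h >= on0 & clock_h < on1
  } else {
    # light-on wraps midnight
    on <- clock_h >= on0 | clock_h < (on1 - 24)
  }
  ifelse(on, "light_on", "light_off")
}

#' Clock hour-of-day for a session time
#' @noRd
clockHour <- function(t_min, start_clock) (start_clock + t_min / MIN_PER_HOUR) %% 24
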