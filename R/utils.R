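#' @importFrom stats median sd rpois runif rlnorm rnorm cor.test kruskal.test
#'   t.test wilcox.test shapiro.test quantile complete.cases setNames
#' @importFrom utils read.table write.table head tail
NULL

MIN_PER_DAY <- 1440
MIN_PER_HOUR <- 60

#' Centered moving mean with truncated edge windows
#'
#' Cumulative-sum implementation; windows shrink at the trace edges rather
#' than emitting NA, so the envelope is defined over the whole trace.
#' @noRd
movingMean <- function(x, n) {
  n <- max(1L, as.integer(n))
  if (n == 1L) return(x)
  N <- length(x)
  cs <- cumsum(c(0, x))
  half <- n %/% 2L
  lo <- pmax(seq_len(N) - half, 1L)
  hi <- pmin(seq_len(N) + (n - half - 1L), N)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Runs of TRUE in a logical mask, as (start, end) index pairs
#' @noRd
maskRuns <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  cbind(start = starts[keep], end = ends[keep])
}

#' Deterministic per-session seed derived from (global seed, mouse, session)
#'
#' Keeps the derived value inside the 32-bit integer range.
#' @noRd
sessionSeed <- function(seed, mouse_id, session_index) {
  h <- 0
  for (ch in utf8ToInt(as.character(mouse_id))) h <- (h * 31 + ch) %% 1e7
  as.integer((as.numeric(seed) %% 1e6 * 1009 + h * 97 +
                as.numeric(session_index)) %% 2147483647)
}

#' Format numeric columns at full precision for bit-exact round trips
#' @noRd
fmtFull <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    s <- sprintf("%.17g", v)
    # prefer the shortest representation that survives the round trip
    for (d in 1:16) {
      c2 <- sprintf("%.*g", d, v)
      if (as.numeric(c2) == v) return(c2)
    }
    s
  }, character(1))
  out
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
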