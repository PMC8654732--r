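#' Session skeleton for simulation
#'
#' Convenience constructor for an event-free [MonitoringSession] describing
#' the recording layout (mouse, session number, start clock, monitored days,
#' daily care gaps, light cycle) into which [simulateEventStream()] places
#' simulated seizures.
#'
#' @inheritParams MonitoringSession
#' @return A [MonitoringSession] with zero events.
#' @export
sessionSkeleton <- function(mouse_id = "sim1", session_index = 1L,
                            start_clock = 8, duration_days = 7L,
                            recording_gaps = matrix(numeric(0), ncol = 2),
                            light_cycle = LightCycle()) {
  MonitoringSession(mouse_id = mouse_id, session_index = session_index,
                    start_clock = start_clock, duration_days = duration_days,
                    events = emptyEvents(), recording_gaps = recording_gaps,
                    light_cycle = light_cycle)
}

#' Simulate a clustered, circadian-modulated seizure event stream
#'
#' Draws one session of spontaneous recurrent seizures from the
#' Neyman-Scott-style generative model described in [SimParams]:
#'
#' 1. Cluster initiations arrive as an inhomogeneous Poisson process with
#'    rate `cluster_rate_base * circadian_ratio` per hour during light-on
#'    and `cluster_rate_base` otherwise (simulated by thinning a
#'    constant-rate proposal process), then thinned again so that each
#'    accepted cluster starts more than `cluster_max_isi` after the
#'    previous cluster's last event — clusters never chain.
#' 2. Each cluster draws a size from the size distribution (2-12; sizes
#'    below `cluster_min_size` create sub-threshold runs on purpose) and
#'    `size - 1` within-cluster ISIs from the truncated log-normal.
#' 3. Isolated seizures arrive as a homogeneous Poisson process and are
#'    rejected when within `cluster_max_isi` of any cluster member.
#' 4. Every event receives an independent discharge duration and Racine
#'    score mark (optionally coupled to its preceding ISI through
#'    `mark_coupling`).
#'
#' The RNG is a single per-session stream seeded deterministically from
#' `(seed, mouse_id, session_index)`, so a given skeleton and seed always
#' reproduce the identical stream.
#'
#' @param params a [SimParams].
#' @param session_spec a [MonitoringSession] skeleton (see
#'   [sessionSkeleton()]); any events it carries are discarded.
#' @param seed global integer seed.
#' @param analysis an [AnalysisParams]; supplies `cluster_max_isi` and the
#'   sub-threshold size boundary.
#' @return The session with simulated `events`, including a ground-truth
#'   `cluster_id` column (`NA` marks isolated events).
#' @examples
#' s <- simulateEventStream(SimParams(), sessionSkeleton(duration_days = 3L), seed = 1)
#' nEvents(s)
#' @export
simulateEventStream <- function(params = SimParams(),
                                session_spec = sessionSkeleton(),
                                seed = 1L,
                                analysis = AnalysisParams()) {
  validObject(params)
  T_min <- session_spec@duration_days * MIN_PER_DAY
  max_isi <- analysis@cluster_max_isi
  lc <- session_spec@light_cycle

  sizes <- 2:12
  mean_size <- sum(sizes * params@cluster_size_probs)
  frac_on <- lc@light_on_hours / 24
  mean_rate <- params@cluster_rate_base *
    (frac_on * params@circadian_ratio + (1 - frac_on))
  # expected realized rate under non-overlap thinning (renewal approximation:
  # each accepted cluster blocks its own span plus the enforced separation)
  block_h <- ((mean_size - 1) * exp(params@intra_isi_meanlog +
                                      params@intra_isi_sdlog^2 / 2) +
                max_isi) / MIN_PER_HOUR
  rate_eff <- if (mean_rate > 0) mean_rate / (1 + mean_rate * block_h) else 0
  expected_per_day <- rate_eff * 24 * mean_size + params@isolated_rate * 24
  if (expected_per_day > 50)
    stopf(paste("parameters imply an expected %.1f events/day (> 50), an",
                "unrealistic regime for this model"), expected_per_day)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(sessionSeed(seed, session_spec@mouse_id, session_spec@session_index))

  # -- cluster initiations: thinned constant-rate proposals ------------------
  rate_max <- params@cluster_rate_base * max(1, params@circadian_ratio) / MIN_PER_HOUR
  cand <- numeric(0)
  if (rate_max > 0) {
    n_prop <- rpois(1, rate_max * T_min)
    prop <- sort(runif(n_prop, 0, T_min))
    if (length(prop)) {
      on_phase <- phaseOf(prop, session_spec@start_clock, lc) == "light_on"
      rate_t <- params@cluster_rate_base *
        ifelse(on_phase, params@circadian_ratio, 1) / MIN_PER_HOUR
      cand <- prop[runif(length(prop)) < rate_t / rate_max]
    }
  }

  onset <- numeric(0); cid <- integer(0)
  last_end <- -Inf; next_id <- 0L
  for (t0 in cand) {
    if (t0 <= last_end + max_isi) next     # non-overlap thinning
    size <- sample(sizes, 1, prob = params@cluster_size_probs)
    gaps <- rTruncLnorm(size - 1L, params@intra_isi_meanlog,
                        params@intra_isi_sdlog,
                        upper = if (params@truncate_intra_isis) max_isi else Inf)
    times <- t0 + cumsum(c(0, gaps))
    times <- times[times < T_min]          # cluster truncated at session end
    if (!length(times)) next
    next_id <- next_id + 1L
    onset <- c(onset, times)
    cid <- c(cid, rep(next_id, length(times)))
    last_end <- times[length(times)]
  }

  # -- isolated seizures, rejected near any cluster member -------------------
  n_iso <- rpois(1, params@isolated_rate / MIN_PER_HOUR * T_min)
  iso <- sort(runif(n_iso, 0, T_min))
  if (length(iso) && length(onset)) {
    keep <- vapply(iso, function(t) min(abs(t - onset)) > max_isi, logical(1))
    iso <- iso[keep]
  }
  onset <- c(onset, iso)
  cid <- c(cid, rep(NA_integer_, length(iso)))
  o <- order(onset)
  onset <- onset[o]; cid <- cid[o]
  # de-duplicate pathological exact ties (continuous draws; effectively never)
  if (anyDuplicated(onset)) {
    keep <- !duplicated(onset)
    onset <- onset[keep]; cid <- cid[keep]
  }

  n <- length(onset)
  isi_prev <- c(NA, diff(onset))
  coup <- params@mark_coupling
  dur <- rlnorm(n, params@duration_meanlog +
                  coup * ifelse(is.na(isi_prev), 0, log(pmax(isi_prev, 0.1)) - log(8)),
                params@duration_sdlog)
  score <- sample(0:5, n, replace = TRUE, prob = params@score_probs)
  if (coup != 0 && n) {
    shift <- round(coup * (log(pmax(ifelse(is.na(isi_prev), 8, isi_prev), 0.1)) - log(8)))
    score <- pmin(5L, pmax(0L, as.integer(score + shift)))
  }

  ev <- data.frame(onset_min = onset, duration_s = dur,
                   score = as.integer(score),
                   day_index = as.integer(onset %/% MIN_PER_DAY + 1),
                   cluster_id = cid)
  out <- session_spec
  out@events <- ev
  validObject(out)
  out
}

#' Truncated log-normal sampler (rejection; upper tail mass is small here)
#' @noRd
rTruncLnorm <- function(n, meanlog, sdlog, upper = Inf) {
  if (n <= 0) return(numeric(0))
  x <- rlnorm(n, meanlog, sdlog)
  bad <- which(x > upper)
  guard <- 0L
  while (length(bad)) {
    x[bad] <- rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[x[bad] > upper]
    guard <- guard + 1L
    if (guard > 1000L) { x[bad] <- upper; break }
  }
  x
}

#' Tabulate simulator ground truth
#'
#' Deterministic recount of the simulator's cluster labels: one row per
#' true cluster (id, size, span, circadian phase of the first event) plus
#' the isolated-event count as an attribute.
#'
#' @param session a simulated [MonitoringSession] whose events carry a
#'   `cluster_id` column.
#' @return A data.frame with columns `cluster_id`, `n_events`, `start_min`,
#'   `end_min`, `phase`; attribute `n_isolated` carries the isolated count.
#' @export
groundTruthSummary <- function(session) {
  ev <- events(session)
  if (!nrow(ev) || is.null(ev$cluster_id)) {
    out <- data.frame(cluster_id = integer(0), n_events = integer(0),
                      start_min = numeric(0), end_min = numeric(0),
                      phase = character(0))
    attr(out, "n_isolated") <- if (is.null(ev$cluster_id)) nrow(ev) else 0L
    return(out)
  }
  lab <- ev$cluster_id
  ids <- sort(unique(lab[!is.na(lab)]))
  rows <- lapply(ids, function(id) {
    t <- ev$onset_min[!is.na(lab) & lab == id]
    data.frame(cluster_id = id, n_events = length(t),
               start_min = min(t), end_min = max(t),
               phase = phaseOf(min(t), startClock(session), lightCycle(session)))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = integer(0), n_events = integer(0),
               start_min = numeric(0), end_min = numeric(0), phase = character(0))
  attr(out, "n_isolated") <- sum(is.na(lab))
  out
}
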