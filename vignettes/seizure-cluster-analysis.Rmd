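---
title: "Detecting and characterizing spontaneous seizure clusters from chronic EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing spontaneous seizure clusters from chronic EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsclust)
```

## The problem

After extended hippocampal kindling (months of twice-daily electrical
stimulation of CA3), mice develop spontaneous recurrent seizures (SRS) that
can be followed for days with continuous single-channel EEG-video
monitoring. A striking feature of these seizures is that they arrive in
*clusters*: runs of several seizures a few minutes to two hours apart,
separated by much longer seizure-sparse gaps, with day-to-day and
light-phase structure that varies across animals. `srsclust` implements the
full analysis chain for this kind of data:

1. **Discharge detection.** Ictal discharges are found in the EEG as runs
   of repetitive spikes whose rectified, smoothed envelope reaches at least
   2× a robust background estimate for at least 10 s.
2. **Inter-seizure intervals (ISIs).** Successive onset differences within
   a session, the 60-min histogram with a 10-min fine view of the short
   intervals, and severity-versus-ISI analyses (Pearson correlation of
   discharge duration with the preceding ISI; Kruskal–Wallis comparison of
   Racine motor scores across ISI strata).
3. **Cluster segmentation.** A seizure cluster is a maximal run of at
   least 4 consecutive seizures in which every successive ISI is at most
   120 min; "tight" clusters further restrict every intra-cluster ISI to
   at most 20 min. Clusters chain into groups when separated by at most
   3 h, are assigned a circadian phase, and tight clusters are screened
   for within-cluster trends.
4. **Simulation.** A clustered, circadian-modulated point-process
   generator plus a synthetic EEG renderer make every stage testable and
   allow calibration studies without any recordings.

## Time and phase conventions

Event times are real-valued **minutes since the session epoch start**; the
session carries the epoch's clock hour (`start_clock`), so circadian phase
is always recoverable as `(start_clock + t/60) mod 24`. The vivarium light
cycle defaults to lights-on 06:00–18:00; the light-on interval is half-open
`[06:00, 18:00)` so that a time falling exactly at lights-off is
deterministically light-off. ISIs are never computed across session
boundaries, and an event's ISI is the interval *from its preceding
seizure*, which is how the severity analyses attribute intervals to events.

Daily 10–30 min animal-care pauses are carried as recording gaps. ISIs
containing a gap are flagged (`spans_gap`) but retained by default, since
monitoring is treated as effectively continuous; a `strict` mode excludes
them for sensitivity analyses.

## Binning and strata conventions

Histogram bins and ISI strata are left-open/right-closed, `(a, b]`, so
that "≤ 60 min", "60–120 min", and "> 120 min" partition the axis without
double counting; an ISI of exactly 120 min is intra-cluster. Percentages
are computed from unrounded ratios and reported to the nearest integer.
The 10-min fine histogram of the short intervals nests exactly inside the
first 60-min bin. Stratum sample sizes count only *scored* events with a
defined preceding interval, so they sum to less than the total ISI count
whenever motor scores are missing — missing scores (video failures) are
preserved as `NA` end to end and excluded pairwise.

## The discharge detector

The published criteria are morphological: repetitive spikes with
amplitudes at least 2-fold the background and durations at least 10 s,
low-voltage fast (LVF) activity at onset, and post-ictal suppression after
spike cessation. The detector operationalizes them as follows.

* **Envelope, not raw samples.** Spikes are biphasic, so amplitude is
  compared on the rectified signal smoothed over 0.5 s. A one-sided
  threshold on raw samples would miss half of each deflection.
* **Robust background.** No background estimator is part of the published
  criteria, so the package defines one: the envelope is cut into 60-s
  windows, each contributes its median envelope level, and the background
  is the median across windows. Because discharges occupy a minority of
  windows, they perturb only their own windows' medians and leave the
  across-window median essentially unchanged. A constant trace gives a
  zero background, which detection refuses as degenerate. Since the
  threshold is background-relative, detection is invariant to rescaling
  the trace by any positive constant.
* **Merging and duration.** Supra-threshold segments separated by
  sub-threshold lulls of at most 5 s merge into one event; 5 s is far
  below both the 10-s minimum duration (so two distinct sub-minimum
  bursts cannot merge into a spurious qualifying event — this is enforced
  as a parameter invariant) and the shortest observed ISIs (~2 min).
* **Onset convention and known bias.** The LVF lead-in is sub-threshold
  by definition, and the published onset convention is morphological and
  manual. The detector does not attempt a spectral LVF onset; the onset
  is the first supra-threshold sample, so detected onsets systematically
  lag morphological onsets by roughly the lead-in length (1.5 s in the
  default rendering) and detected durations under-measure LVF-inclusive
  durations by the same amount.
* **Suppression.** An event `has_suppression` when the envelope falls
  below 0.5× background for at least 2 s within 10 s of the offset.

## The synthetic seizure process

The generator is a Neyman–Scott-style doubly stochastic cluster process —
clusters are parameterized directly, rather than emerging from a
self-exciting intensity, because the cluster is the descriptive unit of
the downstream analysis and direct parameterization keeps parameter
recovery well-posed.

* Cluster initiations arrive as an inhomogeneous Poisson process at
  `cluster_rate_base` (0.15/h) scaled by `circadian_ratio` during
  light-on, and are thinned so that each accepted cluster starts more
  than 120 min after the previous cluster's last event. The separation
  guarantee is what makes ground-truth labels and the rule-based detector
  agree: without it, adjacent true clusters frequently sit within 120 min
  of each other and the run-based rule correctly merges them, so labels
  and detections could not be compared.
* Cluster sizes are categorical over 2–12 with most mass on 4–8 and a
  deliberate sub-threshold tail at 2–3, producing runs the cluster rule
  must *not* call clusters. Within-cluster ISIs are log-normal (median
  8 min, log-sd 0.6) truncated at 120 min; an untruncated mode exists to
  study rule/truth mismatch.
* Isolated seizures arrive as an independent homogeneous Poisson process
  (0.05/h) and are rejected within 120 min of any cluster member.
* Discharge durations (log-normal, median 40 s) and Racine scores
  (categorical over 0–5, mean ≈ 3.3) are drawn independently of the ISIs,
  matching the null relationships the analysis is designed to test; a
  `mark_coupling` knob couples them for power studies.
* Each session uses a single RNG stream seeded deterministically from
  `(seed, mouse_id, session_index)`: identical inputs reproduce
  bit-identical streams, and different mice are independent under one
  global seed.

At the defaults this yields roughly 10–20 seizures per monitored day —
the upper range of chronic kindled-mouse monitoring — with occasional
near-empty days, ISIs from a couple of minutes to many hours, and a
mixture of qualifying clusters, sub-threshold runs, and isolated events.
A guard refuses parameter combinations whose *expected realized* rate
(under a renewal approximation of the non-overlap thinning) exceeds 50
events/day, an unrealistic regime for this model.

The EEG renderer places, for each event, a 1.5-s low-amplitude 40 Hz LVF
lead-in, biphasic spikes at 5 Hz with peak 4× the background noise scale
for the discharge duration, and 5 s of attenuated background afterwards.
A rendering with peak amplitude at or below 2× background is rejected at
construction, because it would not be a valid instance of the detectable
morphology. What the renderer does **not** emulate: movement and chewing
artifacts, electrode drift, state-dependent background (sleep spindles,
theta), or evolving spike frequency within a discharge. Passing detection
tests therefore demonstrate correctness of the criteria's implementation,
not robustness to real-world artifact burden.

## Statistical choices

* **Circadian comparison.** A cluster belongs to the phase containing its
  *start* (clusters may straddle the boundary, and assignment by start is
  the deterministic convention). Clustered-seizure counts per day and
  phase are compared with a two-sided paired test across days: a paired
  t-test by default, switching to a Wilcoxon signed-rank test when a
  Shapiro test rejects normality of the day differences — mirroring the
  normal/non-normal test policy of the source analysis style. A
  preference is declared only at p < 0.05. Both clustered-event and
  cluster counters are reported, since "events per phase" and "clusters
  per phase" are both used in this literature. Note that with few
  monitored days the signed-rank test cannot reach p < 0.05 at all
  (its minimum two-sided p at n = 5 is 0.0625), and day-paired designs
  over 5 days have limited power for even substantial rate modulations:
  under the generator's conditions a 4-fold initiation-rate modulation
  compresses (through the non-overlap thinning) to about a 2-fold
  realized difference, which a 5-day paired design detects in well under
  half of sessions. This is an information limit of the design, not of
  the implementation.
* **Within-cluster trends.** Tight clusters are screened with Spearman
  rank correlations of ISI, discharge duration, and motor score against
  within-cluster position, with average ranks for the heavy ties in
  integer scores. P-values use the t approximation rather than the exact
  permutation null: tight clusters are small (4–7 seizures), where the
  exact two-sided null cannot fall below 0.083 at n = 4, which would make
  a 5%-level trend verdict structurally impossible; the approximation
  yields the intended nominal behavior, and its small-sample
  anti-conservatism at |rho| = 1 is acceptable for a screening verdict.
  Metrics with fewer than 3 valid points or zero rank variance are
  reported "undefined" rather than tested.
* **Calibration strata.** The Kruskal–Wallis stratum analysis defaults to
  the 60/120-min edges used for reporting. Under the generator's
  defaults, however, within-cluster ISIs put essentially no mass in
  (60, 120] while between-cluster ISIs all exceed 120 min, so the middle
  stratum is empty and the omnibus test is (correctly) skipped. The
  package's calibration studies therefore exercise the same operation at
  edges where the generated ISI distribution has mass (5 and 15 min);
  the operation and its defaults are unchanged.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run entirely on generated
data: 1,000 random event streams of up to 50 events against an exhaustive
maximal-run oracle; 20 rendered multi-discharge traces plus 20 one-hour
noise traces at 250 Hz for detection recovery; 100 replicates of ~1,000
events for the correlation null; 100 three-session replicates for the
Kruskal–Wallis null; 200 seven-day sessions for the circadian
false-positive rate; and 100 five-day sessions at a 4-fold modulation for
parameter recovery and power. These sizes give Monte-Carlo standard
errors of 1.5–2 percentage points on the calibration rates while keeping
the default run to well under a minute per study.

## Worked example

```{r example, eval = FALSE}
library(srsclust)

# simulate one 7-day session and analyze it
s  <- simulateEventStream(SimParams(), sessionSkeleton(duration_days = 7L), seed = 1)
cl <- detectClusters(s)
circadianSummary(cl, s)

# or run the whole pipeline from a config
bundle <- runPipeline(list(mode = "simulate", seed = 1,
                           sessions = list(list(mouse_id = "m1", duration_days = 7))))
writeReportBundle(bundle, "report")
```

## Known limitations

* Trace input is two-column delimited text; EDF and other binary
  acquisition formats are out of scope, as are multi-channel montages and
  any use of the video stream (Racine scores enter as data).
* The detector has no artifact rejection beyond the robust background;
  on real recordings, high-amplitude movement artifact would require
  upstream cleaning.
* Only circadian (24-h) structure is modeled and analyzed; multidien and
  longer rhythms are not.
* Cluster-group boundaries use a single configurable gap threshold (3 h
  by default, the lower end of the observed 3–26 h inter-group range);
  no model-based changepoint detection is attempted.
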