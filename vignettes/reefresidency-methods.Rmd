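---
title: "Methods: residency, space use and partial migration from acoustic detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residency, space use and partial migration from acoustic detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefresidency)
```

This vignette is the package's own account of the methods it implements:
the models and conventions behind each metric, the tunable parameters and
their defaults, what the synthetic-data generator emulates (and what it
does not), and the design choices made where the underlying study design
left the details open.

## Data model and day boundaries

Four tables drive the pipeline: detections (one row per decoded
transmission: UTC timestamp, receiver, transmitter, optional sensor
depth), receiver deployments (station, reef/site, array, WGS84 position,
active interval, detection radius), tagging metadata (sex, fork length,
tagging date and reef, home array) and a daily environmental station
series. Timestamps are stored in UTC; every *day-level* statistic uses
local calendar days under a configurable offset (`tz_offset_hours`,
default UTC+10 — Queensland has no daylight saving). Detections are
matched to the deployment active on their local day; detections at
unknown receivers or outside every active interval are routed to a
rejects table with a reason, never silently dropped, so
`|joined| + |rejects|` always equals the input count.

## Daily presence

An animal is present in an array on a day when at least two detections on
any receivers of that array fall within `hour_window_s` (default 3600 s)
of each other on that local day. The window is *rolling* (any pair within
3600 s qualifies, regardless of clock alignment) and is pooled at the
*array* level, because presence is a statement about the array, not one
station. A qualifying pair that spans local midnight confers presence on
neither day: the rule anchors the pair to a single calendar day. Both
choices are conventions — per-receiver pooling and clock-aligned windows
are defensible alternatives — and both are parameters rather than
constants. Satellite arrays far from the focal array are often sparse
(down to six receivers over a large area), so migration-related analyses
count *any* detection day there (`rule = "any_detection"`); the
two-detection rule is reserved for the focal residency metrics.

## Residency metrics

The residency index is `RI = DD / DM`: days detected in the home array
over days monitored. Days monitored run from the tagging date to a single
study-end date, *both endpoints inclusive*. The inclusive convention was
chosen because it is the only one under which an animal detected on every
monitored day — including the tagging day, which real datasets do count —
satisfies `DD ≤ DM` exactly, with `RI = 1` attainable. Against the
package's reference table this convention reproduces every printed
(tagging date, DM) pair with a study end of 2014-10-14.

Animals detected on fewer than `min_detection_days` (default 2) home-array
days are excluded from population residency summaries — a transient that
left on its tagging day tells us nothing about residency — but are
retained for migration analysis, where a single distant detection is
informative.

Residency groups use fixed cutpoints {0.09, 0.20, 0.50}: group I above
0.50, II in [0.20, 0.50], III in [0.09, 0.20), IV below 0.09. The band
(0.40, 0.50], which published group *ranges* (data-driven, not rule
defined) leave unoccupied, is assigned to group II, the closed
neighbouring class. A generic single-linkage hierarchical clustering of
the RI column is exposed (`residency_clusters()`) for comparison, with a
caveat worth stating plainly: on the reference table the two disagree.
Single linkage cuts at the largest gaps of the RI distribution, and the
two widest gaps both lie *inside* the high-residency tail (between 0.37
and 0.51, and between 0.52 and 0.64), so a four-cluster cut splits the
four most resident animals into two pairs and merges the low and very-low
groups (sizes 26/2/2/2). A dendrogram may still *suggest* the four
published classes to an analyst reading it jointly with the cutpoints, but
no unconstrained four-cluster single-linkage cut reproduces them; the
package therefore treats the cutpoints as the operative definition and the
clustering as an exploratory display.

`max_consecutive_days()` is the longest run of strictly consecutive
presence dates; it is validated in the test suite against an exhaustive
sub-range scan on 1,000 random date sets.

## Space use

Hourly centre-of-activity (COA) positions are detection-count-weighted
mean receiver positions, computed on the projected plane within
clock-aligned local hours (the hour definition is a convention; "hourly"
alone does not fix the bin edges). Each COA necessarily lies in the convex
hull of its contributing receivers, a property the test suite checks on
every simulated track via per-bin bounding boxes. Consecutive COAs give
minimum linear dispersal (straight-line km — a lower bound on the path
actually swum) and elapsed hours.

Coordinates are projected to UTM zone 55 south (WGS84) with an in-package
transverse Mercator implementation (standard series expansions; the
forward/inverse round trip is accurate to well under a metre in-zone, and
projected northings are tested against an independent geodesic
computation). Distances are planar on that single zone even for
inter-array spans, matching the convention of converting to UTM before
measuring; a geodesic alternative (`geodesic = TRUE`) is available for
spans where planar distortion matters (the most distant satellite array
sits near a zone boundary, where the planar error is a few km over
~1,400 km).

The roaming index `RoI = reefs visited / reefs monitored` counts a reef as
visited on *any* detection there, deliberately more permissive than the
day-level presence rule: in the reference table, reefs-visited counts of
low-residency animals exceed what day-level presence could produce, so
visit counting cannot be presence-gated. The rule is a parameter.

Movement matrices collapse each animal's time-sorted detections into runs
per site (or array) and count a directed transition for each consecutive
pair of distinct units. Default mode counts distinct *individuals* per
ordered pair over the period (the connectivity-plot quantity); `"moves"`
mode counts raw transitions and feeds the inner/outer shelf 2×2 frequency
table, whose percentages always redistribute exactly the matrix total.

Acoustic coverage per reef is `min(1, Σ π r² / A)` — summed detection-range
disc areas over reef area, with no overlap correction, capped at 100%. It
is a potential-coverage bound, not a measurement. (The ratio is stated in
this orientation because it is the only one that can produce coverage
*percentages* bounded by 100.)

## Broad-scale migration

Migration events are contiguous *away-episodes* in the day-level calendar:
an episode opens at the first detection at a non-home array (after at
least one home detection, or after tagging for animals never seen at home)
and closes — `returned = TRUE` — at the next home detection. Within an
episode each distinct array visited is one *leg* carrying its origin
(home for the first leg, the previous array after), so travel-time
summaries can include only legs that actually departed the home array:
the time from a last home detection to a first detection two arrays down
an itinerary does not measure either hop. Travel time is last-origin to
first-destination detection in days — the only definition available at
detection resolution, and a lower bound on true transit plus an unknown
residence slack on both ends. Day-resolution ties (home and away
detections on one day) are resolved home-first; zero-day legs are excluded
from travel-time summaries as unresolvable.

The population classification is per animal: *moved* if any episode
exists, *returned* if every episode that opened also closed. Monthly
array occupancy counts distinct animals with a counted presence day per
array × month × sex; monthly depth summaries average transmitter sensor
depths per animal × array × month.

## Covariates

Daily array-wide environment is the unweighted mean across stations
reporting that day (stations sit a few km apart on the same reef group;
nothing in the data supports weighting). The daily model table emits one
row per date × sex with the count of distinct animals present — zero rows
included, since absence days carry the signal in presence models — joined
to the covariates, ready for `glm`/`glmer`-style fitting outside this
package. The monthly residency table (days detected, days at liberty —
prorated in the tagging month — per animal × month) is the binomial-model
response analogue.

## The synthetic-data generator

The generator's defaults *are* the emulated study conditions: 17 focal
reefs 5–15 km apart holding 56 receivers; nine satellite arrays at their
real along-coast distances (−310 to +1,400 km) and receiver counts (a 298
receiver network); 33 animals, female-biased 25:8, fork lengths
N(201.8, 25.2) cm; a 2012-10-08 to 2014-10-14 window; transmitter pings
with independent uniform 50–100 s gaps; detection radii 250–350 m.
Where the study design does not pin a value, the default was chosen once
on field-realism grounds and not revisited:

* **Residency heterogeneity.** True per-animal residency is Beta(0.62,
  2.64) — the moment match to the observed population mean and SD
  (0.19, 0.19). A two-state daily Markov chain (leave hazard
  `c·(1−r)`, re-entry hazard `c·r`, `c = movement_speed = 0.1`) makes the
  long-run focal occupancy equal the drawn residency, with multi-day
  absence bouts like real animals.
* **Migration.** Migrants (probability 0.55 for females, 0.35 for males,
  giving the observed female bias among migrants) schedule one or two
  excursions departing in the austral summer window; travel days are
  `1 + Poisson(distance/40 km)`, away dwell `1 + Poisson(3)` days (short
  visits, as observed), and return probability 15/16. A returned
  excursion ends with the animal physically back at a home reef on its
  return day — without that, a "return" by a near-zero-residency animal
  would be undetectable in principle and the truth label meaningless.
* **Detection.** Within-day position is constant at one reef (all metrics
  here are day-level; continuous-space movement would add realism no
  metric consumes). Detection is a step function of range by default
  (probability `detection_prob` inside the radius), with an optional
  logistic range decay; receivers sit within ~200 m of their reef centre,
  inside every nominal radius.

Ground truth — per-day occupancy, scheduled excursions, true residency —
is emitted alongside the CSVs, and identical seeds yield byte-identical
files (a fixed RNG call order per stage, seeded at `seed`, `seed+1`, …).

What the simulator does **not** emulate: range variability with sea state
(beyond the optional wind coefficient), within-day movement between
reefs, receiver outages and biofouling, tag collisions and false
detections, or behavioural depth structure. Passing recovery tests
therefore show the *pipeline* is correct under a faithful rendering of
the study's sampling design — not that the metrics are unbiased under
every field condition; in particular, real presence days can be missed
when an animal skirts coverage, which the step-function geometry here
cannot produce.

## Numerical conventions and test scale

Report-table rounding is half-up at the printed precision
(`round_half_up()`; base R rounds half-to-even), SDs use the n−1
denominator and are `NA` for single-animal strata, and degenerate inputs
fail loudly: zero monitored days, empty movement matrices and unlabelled
shelf sites are errors, while empty ledgers, all-missing depths and
no-event destinations return typed empties or explicit signals.

The test suite exercises the pipeline at three scales, chosen as the
package's own trade-off between coverage and turnaround: hand-built
micro-fixtures for every contract; a six-animal, nine-month simulated
study for track-level properties; and a 30-animal, 500-day study at four
receivers per reef and detection probability 0.5 — the boundary of the
stated recovery conditions — for parameter recovery, where pipeline
residency matches truth within 0.05 mean absolute error and scheduled
excursions with at least two away days are recovered with correct return
flags at ≥ 95%.

## Known limitations

* Presence conventions (window width, pooling level, midnight rule) shift
  `DD` for animals detected near day boundaries; all are parameters, and
  cross-study comparisons should fix them explicitly.
* Planar UTM distances degrade far outside zone 55; use the geodesic
  option for coast-scale dispersal figures.
* Coverage ignores receiver-disc overlap and so overstates coverage on
  densely instrumented reefs (it is capped at 1).
* Migration travel times are detection-bounded and right-censored by the
  study end; an animal departing near the end of monitoring can be
  misclassified as not-returned.
* Statistical modelling (GLMs of daily counts, binomial mixed models of
  monthly residency) is intentionally out of scope: the package builds
  the model-ready tables and stops.
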