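---
title: "Methods: GPS life-space indicators, environmental exposures, and the day-level Poisson mixed model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GPS life-space indicators, environmental exposures, and the day-level Poisson mixed model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifespace)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults,
what the synthetic-data generators do and do not emulate, and the
numerical choices made where the methodology left the design open.

## 1. The measurement problem

Life-space mobility — how much of the out-of-home environment a person
actually uses — is a sensitive marker of healthy ageing. GPS recording
over about a week gives a day-resolved, objective view of it. The package
operationalizes two standard indicators per *mobility day*:

- **Time out of home (TOH)**, minutes per day beyond a buffer around the
  home coordinate (buffer default 50 m), and
- **Convex hull (CHull)**, the km² area of the smallest convex polygon
  containing all of the day's fixes.

A mobility day runs from 03:00 to 02:59 local wall-clock time so that an
evening that stretches past midnight is attributed to the day it started.
A day is **valid** when at least 8 hours of it carry GPS data; only valid
days enter the models (indicators are still computed and flagged for
invalid days, for debugging).

### Interpretation choices ("8 h", gaps, boundaries)

Several micro-decisions are not fixed by the verbal definitions above and
are therefore explicit, configurable conventions here:

- *"8 hours of data"* defaults to **8 distinct clock hours containing at
  least one fix**, which is robust to differences in fix rate; a
  cumulative-covered-time rule (`coverage_hours(..., rule = "cumulative")`,
  gap-capped) is available as a switch.
- *TOH accumulation*: an inter-fix interval counts when **both endpoint
  fixes are out of home** and the interval is at most `max_gap_min`
  (default 10 min). Recording holes longer than the cap contribute
  nothing — a deliberately conservative treatment of missing data; no
  interpolation across holes is attempted.
- *Buffer boundary*: a fix at exactly the buffer distance counts as at
  home (strict `>` for "out", with a nanometre tolerance absorbing
  floating-point noise). A fixed convention makes boundary behaviour
  testable.
- *Timezone*: one study timezone (default `Europe/Berlin`); DST is
  resolved by wall clock, so one day a year has 23 h and one 25 h.
- *Duplicate timestamps* keep the first occurrence — deterministic and
  order-stable re-reading.

### Geometry

All geodesic distances use the haversine formula on a sphere of mean
radius 6 371 008.8 m; at the 50 m buffer scale, ellipsoidal corrections
(sub-metre) are irrelevant. Hull areas need a *projection*, which the
indicator definition leaves unnamed; because the output unit is km², the
package uses a **Lambert azimuthal equal-area** projection centred at the
day's fix centroid — equal-area is the property that matters for an area
statistic, and distortion stays below 0.1 % within 50 km of the origin.
Points farther than 200 km from the projection origin are rejected rather
than projected, so a single corrupt fix cannot silently inflate a daily
hull. The hull itself is Andrew's monotone chain with strict turns
(collinear boundary points excluded, giving a canonical vertex list);
correctness is defined — and tested — against a brute-force edge-
enumeration oracle, not against the algorithm.

The stop/trip segmentation (`segment_stops_trips()`) is a
**reconstruction** of a dwell-based classifier: maximal fix runs within
50 m of their medoid lasting at least 5 min become stops, the spans
between them trips. The published classifier this emulates was optimized
on study data with parameters not available here; ours are honest
defaults, exposed as arguments, and the segmentation feeds no downstream
model.

## 2. Environmental exposures

All exposures are *home-centred disc queries* in the same equal-area
plane:

| exposure | radius | definition | default |
|---|---|---|---|
| intersection density | 1500 m | nodes where ≥ 3 walkable way-directions meet (graph degree ≥ 3) | snap tolerance 1 m |
| green share | 500 m | % of disc covered by the union of green polygons | grid pitch radius/200 |
| transit / health reach | 15 min × gait speed | POIs of the category set within the straight-line walkable radius | speed 1.0 m/s |

Decisions worth recording:

- **Area, not count, for green share.** The verbal definition could be
  read as counting green *attributes*; the stated "proportion of green to
  other area" and the scale of reported values support an area
  percentage. The union is computed so overlapping polygons never count
  twice.
- **Numerical integration for the union.** No polygon-clipping library is
  available in the supported environment, so the union ∩ disc area is
  evaluated by deterministic grid sampling in the projected plane
  (even-odd point-in-polygon; pitch radius/200 ≈ 2.5 m). For smooth
  boundaries the error is ≈ 0.3 % of the disc — comfortably within the
  0.5 % tolerance the half-disc test demands — and the estimate is exact
  for the empty and full scenes. The pitch is a resolution knob
  (`grid_n`), not a fitted constant.
- **Straight-line reach.** The 15-minute walkable reach uses a geodesic
  radius (speed × 900 s), matching a radius-based definition; street-
  network isochrones are a declared non-goal. The cohort's mean gait
  speed is a config value (default 1.0 m/s — a typical mean gait speed in
  community-dwelling adults over 75), since the study value is not
  published.
- **Node identification.** Intersections exist where ways share vertices;
  endpoints within 1 m are snapped (quantization grid), since real map
  extracts rarely share coordinates exactly. Both transit categories
  (bus stops, rail stations) count with weight 1.

The questionnaire-derived scores use the published codings: utilization
of seven outpatient services coded 0/1/2/3 (never / monthly / weekly /
more often), mean over answered services; subjective accessibility as the
mean of two 0–3 items (either may be missing); sidewalk quality as the
observed 0–3 rating, entered numerically.

## 3. The day-level model

For person $i$, day $j$:

$$ y_{ij} \sim \mathrm{Poisson}(\lambda_{ij}), \quad
   \log \lambda_{ij} = \mathbf{x}_{ij}^\top \boldsymbol\beta + b_i, \quad
   b_i \sim N(0, \tau_{00}) $$

The response is the **rounded** indicator (TOH minutes or CHull km²) —
a Poisson model needs integers and the indicators are treated as count
variables; the rounding convention is logged and configurable. Continuous
covariates are grand-mean centred (so the intercept is the expected log
count at the covariate means); binary covariates stay 0/1; the day
counter 1…7 enters as a (centred) fixed effect; persons with any missing
covariate are dropped listwise with a logged count.

### Estimation

The marginal likelihood integrates over $b_i$; with one scalar random
intercept per person the Laplace approximation is separable:

$$ \ell \approx \sum_i \Big[ h_i(\hat b_i) - \tfrac12 \log\big(1 + \tau_{00} S_i(\hat b_i)\big) \Big] - \sum_{ij} \log y_{ij}! $$

where $h_i(b) = \sum_j (y_{ij}\eta_{ij} - e^{\eta_{ij}}) - b^2/2\tau_{00}$
and $S_i = \sum_j e^{\eta_{ij}}$. The inner modes $\hat b_i$ are found by
a damped Newton iteration vectorized over persons (each step costs one
pass over the data); the outer problem maximizes over
$(\boldsymbol\beta, \log \tau_{00})$ by BFGS. Optimizing $\log \tau_{00}$
enforces non-negativity; estimates collapsing below $10^{-3}$ are flagged
as boundary. At $\tau_{00} = 0$ the expression reduces *exactly* to the
ordinary Poisson GLM log-likelihood — the package exploits this as an
oracle: `fit_poisson_glmm(..., fix_tau = 0)` is fitted by Newton scoring
and must match `glm()` to $10^{-6}$ in both coefficients and standard
errors (an acceptance criterion). On mixed designs the fit agrees with
`lme4::glmer` to three-plus decimals (cross-checked in the suite).

Standard errors come from the observed information (numerical Hessian of
the Laplace log-likelihood at the optimum, including the $\tau_{00}$
block); p-values are two-sided Wald with a normal reference, matching a
z-value reporting convention. Degenerate inputs fail loudly: rank-deficient
designs name the collinear columns, non-integer or negative responses are
rejected, and non-convergence is flagged on the result rather than
silently ignored.

### Variance decomposition

The latent-scale residual variance of a Poisson-log model is taken from
the **lognormal approximation**
$\sigma^2_d = \ln(1 + 1/\bar\lambda)$ with
$\bar\lambda = \exp(\beta_0 + \tau_{00}/2)$ evaluated on the centred
design — the standard choice for ICC and $R^2$ denominators in this model
family (how any given published table computed its rows is usually
software-specific and unstated; this package documents its own choice and
tests its closed form, e.g. $\sigma^2_d = \ln 2$ at $\bar\lambda = 1$).
Then

$$ \mathrm{ICC} = \frac{\tau_{00}}{\tau_{00} + \sigma^2_d}, \qquad
   R^2_m = \frac{\sigma^2_f}{\sigma^2_f + \tau_{00} + \sigma^2_d}, \qquad
   R^2_c = \frac{\sigma^2_f + \tau_{00}}{\sigma^2_f + \tau_{00} + \sigma^2_d} $$

with $\sigma^2_f = \mathrm{var}(\mathbf{x}^\top \hat{\boldsymbol\beta})$
over the fitted rows. $R^2_c \ge R^2_m$ by construction.

## 4. The synthetic world

The generators state one fixed world; their defaults are the published
cohort marginals (age 81.5 (4.1) truncated at 75; 56.1 % women; 57.1 %
cohabiting; 88.2 % active drivers; education tiers 5:85:122; health
literacy 40.6 (5.8) on 0–50; physical/mental HRQoL 43.9 (11.3) /
58.4 (4.9); social-network satisfaction 9.6 (1.0) on 0–10), seven days
per person, a 60 s fix interval (the true device rate is unpublished),
5 m GPS jitter, and a gridded town (9 streets per direction, 500 m
spacing) with parks and POIs at configurable densities.

Two generator decisions deserve explanation:

- **Mean-matched truncation.** Drawing age from $N(81.5, 4.1)$ truncated
  at 75 would give a mean near 82.0 — the truncation and the published
  marginal mean are jointly unsatisfiable with a naive draw. The
  generator therefore solves (once, numerically) for the location of the
  underlying normal such that the *truncated* distribution has the
  published mean, and applies the same rule to every bounded score
  (material for satisfaction 9.6 (1.0) on 0–10, negligible elsewhere).
  The SD is left as specified; matching both moments under truncation
  would distort the published SD's meaning more than it would help.
- **Closed-loop trajectories.** `simulate_trajectory()` builds a fix
  sequence whose *recomputed* TOH lands within two fix intervals of the
  requested target: a home dwell from 04:00, an excursion block whose
  out-of-home fix span equals the target, waypoints 400–4000 m out
  confined to a 120° cone (so legs between waypoints can never cut
  through the home buffer), and enough recorded span (≥ 12 h) to pass
  the validity filter. Jitter (SD 5 m) cannot flip fixes across the 50 m
  boundary from either the home (0 m) or the excursion (≥ 400 m) side.

What the synthetic world does **not** emulate: correlated covariates (the
published marginals carry no correlation matrix; a hook exists but
defaults to independence), road-snapped movement, realistic activity
scheduling, device dropout (a green recovery test therefore establishes
estimator correctness under the stated model, not robustness to
behavioural realism), and the real study geography.

## 5. What the tests establish

- Geometry: hull/area code equals brute-force oracles; the projection is
  equal-area to 0.1 % at 50 km; round trips are exact to $10^{-6}$°.
- Indicators: hand-computed TOH values (clean outing, gap-capped hole,
  exact-boundary fixes) are reproduced exactly; hull areas are invariant
  to fix order, duplication and interior points; TOH is monotone in the
  buffer and bounded by recorded span.
- Model: GLM oracle equivalence at $\tau_{00} = 0$; `lme4` agreement on
  mixed designs; boundary recovery ($\hat\tau_{00} < 0.02$ when the truth
  is 0); and a 50-replicate recovery study at study scale (200 × 7,
  $\beta = (2, 0.5, -0.3, 0.1)$, $\tau_{00} = 0.8$) with ≥ 90 % Wald-CI
  coverage and mean absolute bias < 0.05 per coefficient.
- Published-table arithmetic: the ICC row (3.44, 0.13 → 0.96) and the
  descriptive percentages (119/212 → 56.1 %, 187/212 → 88.2 %) are
  reproduced by the package's own functions.

Day-level regression coefficients estimated from real participant data
are *not* reproduction targets: no such data ships with the package. The
package's claim is that the pipeline that would produce such a table is
correct on worlds where the truth is known.

## 6. Known limitations

- TOH depends on the gap cap under heavy signal loss; sensitivity to
  `max_gap_min` should be reported alongside results on real data.
- Straight-line reach overestimates access where barriers (rivers, rail)
  sever the street network.
- The Laplace approximation is biased for very small counts per person;
  with 7 days per person and count responses in the hundreds this is
  negligible, but CHull models with many zero days deserve a check
  against adaptive quadrature in other software.
- Grid sampling caps green-share precision at ≈ 0.3 %; raise `grid_n`
  for finer work.
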