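---
title: "Methods: axial growth analysis for hemianamorphic arthropod ontogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: axial growth analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trilogrowth)
```

## The data model

A specimen is one fossil with axial part lengths in mm along the sagittal
line: frontal area (FAL), pre-occipital glabella (PGL), occipital ring (ORL),
thoracic segments (LTS1..LTS13) and pygidium (PYL). Meraspid specimens carry
a *degree* `s` (number of articulated thoracic segments, 0–12, one added per
moult); holaspides have the full complement of 13 and no degree. Composite
lengths are always derived, never measured: cephalic length
`CEL = FAL + PGL + ORL`, trunk length `TRL = sum(LTS) + PYL`, body length
`BOL = CEL + TRL`. This makes the additive identities exact by construction
— a deliberate choice that also governs the synthetic generator (below).
Relative quantities are per-trunk: segment shares `RLS_i = LTS_i/TRL`,
posterior boundary positions `RPS_i = cumsum(LTS)_i/TRL`, pygidial share
`RPYL = PYL/TRL`, so `sum(RLS) + RPYL = 1` to round-off for any complete
specimen.

Because specimens are cross-sectional (no individual is tracked between
moults), stage-level quantities are means: part means are arithmetic; the
relative quantities are averaged as **means of per-specimen ratios** by
default, since the ratios themselves are the modelled response downstream.
The alternative (ratios of stage-mean lengths) is available via
`stage_summaries(ratio_rule = "ratio-of-means")`; with roughly symmetric
size scatter the two differ little, but the choice is exposed rather than
silently fixed because the literature is not explicit about it. The
per-stage trunk growth rate `TRG_s = meanTRL(s+1)/meanTRL(s)` uses the ratio
of stage means for the same cross-sectional reason.

## Two-phase allometry

Part-vs-region relationships are modelled on the natural-log scale as a
continuous hinge, `ln y = β0 + β1 ln x + β2 (ln x − τ)₊`. For fixed τ the
model is linear, so the Gaussian maximum-likelihood threshold is found by
exhaustive search: every observed `ln x` leaving at least 10% of points
strictly on each side is a candidate, and the residual-sum-of-squares
minimizer wins (ties broken toward the smaller threshold). Change points are
reported back-transformed to mm. Numerical notes:

* the 10% trimming fraction keeps thresholds identifiable at the margins;
  the exact trimming dialect in threshold-regression software varies, and
  point estimates are robust to it while CI widths are not, so the fraction
  is an explicit argument;
* a fitted `|β2| < 1e-8` is flagged `no_change`: the threshold location is
  then arbitrary and the fit reduces to a single line;
* confidence intervals are pairs-bootstrap percentile intervals (1000
  replicates by default, seeded); more refined bootstrap variants exist, but
  with the threshold estimated by grid search the percentile interval is the
  least fragile choice. Replicates whose resample leaves fewer than two
  admissible candidates are dropped; more than 20% failures is an error.

Change points estimated on a part scale (e.g. CEL) are re-expressed on the
body-length scale by evaluating a reference hinge fit of `ln BOL` on that
part at the change point; extrapolation outside the reference fit's observed
range is refused. Stage assignment reports every stage whose observed size
range contains the change point — overlapping ranges legitimately yield
multi-stage answers (`"D8-10"`), and a broad holaspid size range can overlap
late meraspid stages.

Per-segment allometric coefficient profiles use **major-axis** regression
(first principal axis of the log–log scatter), appropriate when both
variables carry comparable measurement error; the slope equals the
eigenvector slope of the 2×2 covariance matrix, which the test suite checks
by independent eigendecomposition.

## Growth-gradient models

Stage-mean relative segment lengths `RLS(i, s)` (segment `i`, stage `s`,
`1 ≤ i ≤ s ≤ 12`; 78 observations when complete) are confronted with four
models. All share a geometric release-size law — the newly released
segment's share declines with its release stage — because released-segment
length shows an exponential decrease relative to trunk length in the taxa
this package targets; the exact published functional forms live in
supplementary material we deliberately do not copy, so the parameterizations
here are declared stand-ins with the canonical parameter counts (3 for SG, 4
for TG).

* **SG-R** (`A, B, r`): after release at share `A·B^(i−1)`, a segment's share
  changes by the constant factor `r` per stage — a constant ratio of segment
  to trunk growth rates.
* **SG-A** (`A, B, k`): a segment's length keeps a constant allometric
  coefficient `k` with respect to the trunk: `RLS` scales as
  `(TRL_s/TRL_i)^(k−1)`. `k = 1` is isometry.
* **TG-T / TG-D** (`c0, c1, q0, q1`): segment boundaries are material
  landmarks in a continuous growth field along relative trunk position `p`.
  A log-linear field `g(p) ∝ exp(b·p)` maps a boundary at `p` to
  `φ_b(p) = (e^{bp} − 1)/(e^b − 1)` after one moult (identity at `b = 0`;
  endpoints conserved). The field is not printed in the primary literature;
  log-linear is the standard choice in the trunk-gradient tradition and is
  the unique form with this closed-form map. The per-moult steepness is
  `b_s = c0 + c1·ln TRG_s` (TG-T: size as driver) or `b_s = c0 + c1·s`
  (TG-D: stage as driver) — the minimal two-parameter links consistent with
  the stated drivers and parameter counts. Boundaries are released at
  `RPS(i,i) = 1 − q0·q1^i`; `RLS` follows by differencing. With `b_s ≥ 0`
  (anteriorward relative drift, the observed polarity) release order is
  provably preserved; parameter points that produce boundary crossings
  (negative segment lengths) are treated as inadmissible during fitting.

SG models are defined for the RLS response only; TG models also predict RPS
directly, which is their natural response. Fitting minimizes squared error
with a damped Gauss–Newton (Levenberg–Marquardt) iteration implemented in
the package (no suitable optimizer with step rejection on inadmissible
parameter points was available among the declared dependencies). Positive
parameters are optimized on the log scale. Starting values are data-driven
and deterministic: `RLS(i,i)` identifies `(A, B)` by log-linear regression,
and the per-stage pygidial complement identifies `(q0, q1)`; small grids
over the remaining parameters plus fixed fallbacks guard against degenerate
data. Convergence uses a relative RSS-improvement tolerance of 1e-13 with an
absolute floor of 1e-28, tight enough that zero-noise recovery tests reach
machine precision.

Model comparison uses the least-squares AICc,
`n ln(RSS/n) + 2K + 2K(K+1)/(n−K−1)` with `K` counting the residual variance
alongside the model parameters (`K = p + 1`) — the standard convention;
absolute AICc values depend on it, so cross-study comparisons should compare
differences, not levels. Akaike weights, evidence ratios and
percent-variance-explained are derived from the scores. Comparing fits with
different responses is refused: their likelihoods are not commensurable.

The pygidial stasis test is a specimen-level OLS of PYL on degree with a
two-sided t-test on the slope. The stage window is a required argument —
including or excluding the epimorphic stages materially changes the answer —
and exactly constant PYL (zero residual variance) reports p = 1 by
convention rather than NaN.

## The synthetic world

`simulate_ontogeny()` emits specimen tables with the structure the analyses
assume. Defaults (all changeable through `default_sim_config()`):

| parameter | default | meaning |
|---|---|---|
| counts | 2; 7,3,8,7,4,8,16,11,7,6,14,6 | meraspides per degree D0; D1–D12 (97 in D1–D12, 99 total) |
| `n_holaspides` | 135 | holaspid sample (234 specimens in total) |
| `trl0`, `gamma`, `delta` | 0.9 mm, 0.35, 0.12 | trunk schedule `T_s` with per-moult rate `TRG_s = 1 + γe^{−δs}`, strictly decreasing (contra Dyar's rule) |
| `p0`, `rho` | 0.55 mm, 0.9 | pygidial length, constant through D0–D10, then ×ρ per stage (epimorphic phase from D10) |
| `model`, `model_par` | SG-A, (A 0.4205, B 0.75, k 0.315, k_slope 0.06) | generating thoracic share field; `k_slope` adds a posterior-increasing per-segment gradient `k_i = k + k_slope(i−1)` |
| cephalic hinges | see `default_sim_config()` | `ln CEL` vs `ln TRL`, and `ln FAL`, `ln PGL` vs `ln CEL`, each two-phase; ORL is the residual and must stay positive |
| `holaspid` | lognormal(ln 12, 0.25) on BOL; pygidial share 0.07 | adult size distribution; fixed part shares make holaspid thoracic growth exactly isometric |
| `sigma_size`, `sigma_part` | 0.08, 0.04 | lognormal sigmas: whole-specimen scatter and independent per-part measurement scatter |

Specimen values are stage means × one whole-specimen lognormal factor ×
independent per-part lognormal factors. A single seeded RNG stream makes
datasets reproducible; the whole-specimen factor cancels exactly in all
relative quantities.

**The world is over-determined, and the generator says so.** An exactly
constant pygidium, an exact trunk growth schedule, and specimen shares that
exactly equal the generating gradient model cannot hold simultaneously (for
TG models, for instance, the release law forces `PYL_s = TRL_s·q0·q1^s`,
which is incompatible with constant PYL under a decreasing TRG). Rather than
quietly compromising everything a little, the generator has two bookkeeping
modes:

* `"schedule"` (default): trunk and pygidium schedules hold exactly; the
  gradient model contributes only the relative thoracic share profile,
  renormalized to fill `TRL − PYL`. Use for threshold, profile and stasis
  analyses. The generating model's parameters are then recoverable only up
  to a smooth stage-dependent factor.
* `"exact-model"`: thoracic shares equal the generating model exactly and
  the pygidium absorbs the remainder of the scheduled trunk. Use for
  parameter-recovery and model-selection studies; pygidial stasis is then
  only approximate.

The default share-field parameters were calibrated once, by deterministic
least squares, so that the summed thoracic share tracks its pygidium
complement `1 − PYL_s/T_s` while per-segment shares stay realistic
(anterior-longest segments throughout, geometrically declining release
shares); they were frozen before any downstream test was run and are not
tuned thereafter. The scalar-`k` configuration used in recovery and
selection studies (`A = 0.3, B = 0.72, k = 0.85`) was likewise chosen once,
for admissibility (thoracic shares must sum below 1 at every stage).

Two stated defaults conflict at D0: a trunk anchor of 0.9 mm and a pygidium
of 0.55 mm cannot both hold when the D0 trunk *is* the pygidium. The 0.9 mm
anchors the schedule for stages ≥ 1; the realized D0 trunk equals the
pygidium, and monotonicity statements about TRG are made over D1–D12.

What the generator does **not** emulate: covariance among parts beyond the
shared size factor (real measurement errors on adjacent landmarks are
correlated), taphonomic missingness (simulated specimens are complete),
multi-instar D0 morphotypes, and any attempt to reproduce a particular
empirical dataset's values. A green test therefore establishes that the
machinery recovers the structure it assumes — not that any fossil dataset
satisfies those assumptions.

## Known limitations, and one honest failure

* Single threshold only: relationships with two change points will be
  summarized by whichever dominates the likelihood.
* The bootstrap CI inherits the granularity of the candidate grid; with few
  distinct sizes the interval can collapse to a grid cell.
* AICc levels depend on the `K = p + 1` convention (above).
* **TG-T selection under noise.** With measurement noise, the TG-T covariate
  (observed TRG) is itself noisy while TG-D's covariate (stage) is exact;
  and under the smooth default schedule `ln TRG_s` is nearly linear in `s`,
  so the two links are near-collinear. Consequently, data generated from
  TG-T at realistic noise are routinely attributed to TG-D, and the
  model-selection consistency criterion for TG-T fails in this synthetic
  world (the SG-A criterion passes, and zero-noise TG-T recovery and
  separation are exact to machine precision). This is an identifiability
  property of any world with a smooth stage–size relationship, not of the
  fitter; empirical TRG sequences, which are not smooth functions of stage,
  are what make the two trunk-gradient drivers distinguishable in practice.
  The corresponding acceptance test is left failing rather than weakened.
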