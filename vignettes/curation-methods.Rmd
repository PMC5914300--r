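---
title: "Curating century-long individual-tree measurement series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating century-long individual-tree measurement series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroclean)
```

## The problem

A permanent spacing trial observes every tree of a stand repeatedly over a
rotation — here the setting is a Norway spruce trial planted in the 1890s at
four spacings (1×1, 1.5×1.5, 1×2 and 2×2 m), measured roughly twenty times
between stand ages 35 and 109. Three facts shape the curation problem:

1. **The truth is monotone.** Diameter at breast height never decreases;
   spruce crown bases only recede upward; height decreases only when the
   top breaks (snow, wind), and such breaks were recorded as crown-quality
   codes.
2. **The errors are structured.** Instruments and observers changed between
   campaigns, so whole campaigns are biased together ("era effects");
   individual readings carry rounding, digit heaping (preference for
   terminal 0 and 5) and occasional gross errors; many campaigns measured
   heights only on subsamples.
3. **An internal reference exists.** Stem analysis of felled trees — discs
   cut at known heights, rings counted and measured — reconstructs each
   disc tree's diameter and height growth inside bark over its whole life,
   independent of the field campaigns.

The pipeline exploits all three: era effects are levelled against the disc
references, gross errors are filtered by increment rules, monotonicity is
enforced by isotonic regression, and gaps are filled by monotone
interpolation, so that the output series satisfy the biological constraints
exactly while deviating from the observations as little as possible.

## Pipeline stages and their rationale

### Diameters

Crosswise calliper campaigns yield two orthogonal readings, averaged
arithmetically. Disc radii (four directions) are averaged in basal-area
space — the equivalent diameter is `2 * sqrt(mean(r^2))` — because the mean
of the per-radius circle areas approximates the true cross-section better
than the mean radius. Disc diameters are inside bark and shrunk; they are
scaled by 1.070 to outside-bark unshrunk size before comparison. A ring
accrues linearly between May 1 and August 31 (123 days), so a mid-season
measurement is compared against a partially grown ring.

Era levelling works on the **relative basal-area difference**
`(BA_meas − BA_ref) / BA_ref`: for each campaign × plot group the median
over reference trees is subtracted in basal-area space. The median (not the
mean) makes the correction robust to the handful of gross errors that
survive to this stage, and by construction leaves the group median of the
reference trees at exactly zero. Groups without references keep factor 1
and are flagged rather than guessed.

Outlier rules fire on increments: below −10 mm in total, below −5.4 mm/yr,
or above +10 mm/yr relative to the previous kept observation. The two
negative thresholds are combined with OR (either triggers), the conservative
reading toward cleaning. Flagged points are removed only if at least three
observations survive (the published rule says "if there are enough other
measurements" without a number; three is the smallest count that still
leaves an interior point, and it is a parameter).

Monotonization uses isotonic least squares (pool-adjacent-violators, via
`stats::isoreg`) over decimal years, followed by linear interpolation across
interior flat runs: several campaigns with identical diameter are a
measurement artefact, and spreading the increment linearly between the
strict neighbours is the least-informative repair. Gap filling interpolates
**basal area** (not diameter) over **decimal years** (not campaign index),
because basal-area increment is closer to linear in time and the campaign
intervals range from 1 to 6 years.

The per-tree order is: level → filter → isotonic fit → gap fill →
re-check → flat-run interpolation, mirroring the narrative order of the
original curation.

### Monotone interpolation

Gap filling and the disc height–age splines use monotone cubic Hermite
interpolation with the Fritsch–Carlson tangent filter: knot tangents start
from secant means (zero at local extrema) and tangent/secant ratios are
projected onto the circle of radius 3, which guarantees a monotone
interpolant through monotone data. The filter is implemented directly in
`monotone_interp` because the stock `splinefun(method = "monoH.FC")`
evaluator was observed to violate monotonicity by ~2·10⁻⁴ on some knot
sets, which would break the pipeline's hard non-decrease guarantee; on
well-behaved data the two agree closely (a test asserts this).
Extrapolation is refused — only interior gaps between a tree's first and
last observation are ever filled.

### Heights

Heights measured as angles and distances are triangulated; legacy punch
cards store angles as three digits in tenths of a degree, first digit 9
flagging a downslope (negative) angle. The decode assumes the remaining two
digits carry |angle|·10; this is the only arithmetic consistent with a
3-character field and the (−90°, 90°) physical domain. A consequence worth
noting: positive angles of 90.0–99.9° cannot be represented, which is
irrelevant for sight angles.

After increment filtering (a decrease > 1 m is kept only when a crown break
or damage was recorded at that observation; a rise > 1 m/yr is never kept),
campaigns are levelled by the median of (disc-derived height / measured
height) per plot × campaign. Each disc pins the age at which the stem tip
passed the disc height — the calendar year of its innermost ring minus half
a year, since the height is reached mid vegetation period.

The height–age curve `h = c0 * log(1 + exp(c2) * age^c3)^c1` is fitted by
Levenberg–Marquardt least squares from a 27-point multi-start grid over the
shape parameters, on unbroken trees that reached the final stand age. The
four parameters are only weakly identified from ages 35–109 — different
parameter vectors produce nearly identical curves on that range — so the
package treats the **fitted curve**, not the coefficients, as the estimand;
tests and acceptance checks assert recovery of h(100), not of c₀…c₃.

Smoothing then models the ratio h_mon / h_curve(age) with penalized
additive splines over age and diameter (plus a thin-plate smooth over the
stem position for spruce) and a per-tree random intercept, realized as
`mgcv::gam` with `s(tree, bs = "re")`; trees with fewer than three height
observations share a per-species intercept instead. This is deliberately a
penalized-regression reading of "GAMM with random intercept on tree or
species": the structure (splines + shrunken grouped offsets) is what
matters, and `mgcv`'s REML estimation provides exactly the required
shrinkage, with a GCV fallback for degenerate (noise-free) responses. The
smoothed curve is projected to be non-decreasing per tree, then anchored
multiplicatively onto the monotone measured heights: the multiplier
observed/smooth is linearly interpolated in decimal years between
observation dates and held constant outside them, so every measured height
is reproduced exactly. Anchoring is done twice — once with all
observations, once only with those before the first crown break — yielding
`h` (decreases only across recorded breaks) and `h_nobreak` (globally
monotone, used downstream as crown-base covariate). Final flat runs are
resolved by placing the run value at the run's mean date.

### Crown base

Crown-base observations are clipped to the concurrent height, monotonized,
and modelled twice: directly, and as the crown ratio hCr/h times the
break-free height (the ratio model keeps predictions inside [0, h] by
clipping the ratio to [0, 1]). The unweighted average of the two estimates
(the published procedure says "average" without weights) is monotonized,
anchored onto the monotone observations with the same multiplier scheme as
heights — symmetric by design, the original only states "adjusted to hit" —
and finally clipped under the tree height. A clip that would force the
crown base to descend is an error, not a silent repair.

### Stand statistics

Digit preference is tested by Pearson's chi-square on the counts of value
mod 10 against uniformity (df = 9). Stand summaries define dg as the
quadratic mean diameter, hg as the basal-area-weighted mean height, and
d50/h50 as the diameter/height of the 50th strongest/tallest tree **per
hectare** — on a plot of area A ha the rank used is ⌈50·A⌉, a rule the
published definition leaves open. Increments are computed on total
production (standing + cumulatively removed basal area) over exact
decimal-year spans; mean annual increment divides total production by stand
age. Only trees inside the corner polygon enter the per-area values.

### Spatial reconstruction

The raster fit alternates nearest-node assignment with a linear
least-squares update of an affine node→plane map, from which spacing and
orientation are read off. Two departures from a literal "adjust the
inter-tree distances" are deliberate: a small orientation angle is fitted
(mapped coordinates live in a national projection, and without rotation the
nearest-node assignment is ill-posed on long plots), and the fit is
restarted from a 5×5 grid of spacing scale factors (0.9–1.1) because the
alternating scheme can lock onto a wrong lattice when the initial spacing
is off by ~7%. The node frame is normalized (axes along +x/+y, lower-left
occupied node at (0,0)) so that serpentine tree numbers map onto node
indices deterministically. Numbers that fit the serpentine path go to their
implied node; the rest are placed uniformly at random on the remaining
vacant nodes under a caller-supplied seed.

## The synthetic generator

`simulate_stand` emulates the trial's structure at configurable extent:
four plots at the historical spacings, campaigns 1923–1997 at 1–6 year
intervals, calliper (crosswise, two readings) until 1973 and tape from
1978. Height truth follows the four-parameter curve with a lognormal
per-tree multiplier (default sd 0.06); the defaults c₀ = 100.58, c₁ = 1.1,
c₂ = −6.578, c₃ = 2.0 (dm scale) were calibrated once so that the stand
passes 10 m around age 35 and 32 m around age 109 — the published
trajectory — and then frozen. Diameter truth is allometric,
d = 0.32·h^1.2 mm with its own lognormal multiplier; the crown ratio
drifts from ~0.2 to 0.7 with age. Within a year, growth accrues linearly
over the May–August season, so the simulated ring tables are consistent
with the measurement model to the rounding unit: the cumulative ring sum at
each season's end equals the inside-bark radius (truth / 1.070) exactly.

Observations apply a per-campaign era bias (sd 2% for diameters, 3% for
heights; tape reads +1.2% vs calliper, reflecting non-circular stems),
multiplicative reading noise (1.5% / 3%), rounding to the published units,
and digit heaping: with probability 0.286 a diameter is rounded to the
nearest 5 mm, which makes terminal digits 0 and 5 three times as frequent
as the others. Thinning removes 10% of standing trees per campaign with
coded reasons; crown breaks hit 8% of trees once, dropping height by 15%
with slow recovery; two trees per plot are felled late for stem analysis.

What the generator does **not** emulate: competition-driven growth (tree
effects are independent of spacing and neighbours), spatial autocorrelation,
bark-thickness trends with size, observer-specific (as opposed to
campaign-specific) effects, and partial height subsampling rules tied to
tree rank. Recovery results on synthetic stands therefore demonstrate that
the pipeline inverts the error model it targets — era bias, noise,
rounding, gaps, breaks — not that it removes every artefact of the
historical data.

## Numerical choices and degenerate inputs

* Internal time is decimal years (year + day-of-year/365.25); units stay as
  published (mm, dm, m, 1/100 mm), converted only inside computations.
* Isotonic fits use unit weights; ties in time share a fitted level.
* The outlier filters compare each observation to the last **kept** one, so
  a single bad point does not cascade.
* Penalized smooths default to basis dimension 6 per term, reduced
  automatically when a covariate has too few distinct values; REML falls
  back to GCV on degenerate responses.
* Trees with a single observation pass through unchanged; trees without
  any height observation get the model prediction with a species-level
  intercept; empty reference groups level with factor 1, flagged.
* Problem sizes in tests and the acceptance script — stands of 2 plots ×
  36 trees over 19 campaigns, 100-seed recovery loops for the scalar
  properties — were chosen so the full verification runs in about a minute
  while keeping every rate estimate at its specified sample size.

## Known limitations

* The serpentine numbering model assumes a constant row length per plot;
  historical renumbering or irregular row ends will push trees into the
  random-placement branch (flagged, never silently misplaced).
* The ±1.070 bark factor is a single constant; no species- or
  size-dependent bark model is attempted (the discs are conifers only).
* d50/h50 area scaling and the "at least 3 survivors" outlier rule are
  conventions where the published procedure is silent; both are parameters.
* The GAMM realization shrinks per-tree intercepts but does not propagate
  their uncertainty into the final series; the output is a point
  reconstruction, not a posterior.
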