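---
title: "Reconstructing and mapping fishing fleet capacity and effort: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing and mapping fishing fleet capacity and effort: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`effortr` rebuilds complete, spatially explicit fishing-effort series from
the kind of patchy national records that fisheries yearbooks provide, and
maps them onto a half-degree grid by prorating against catch. This vignette
documents the models behind each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical choices a maintainer would want to know about.

## The reconstruction model

National vessel counts per sector (industrial `I`, artisanal powered `APW`,
artisanal unpowered `UP`) are modelled as carrying-capacity-limited growth,

$$NV(t) = \frac{K}{1 + e^{-r (t - t_0)}},$$

with carrying capacity $K$ (vessels), growth rate $r$ (1/yr) and midpoint
$t_0$. Fleets grow roughly exponentially while profitable and saturate as
grounds, licences and markets fill up, which is why a sigmoid rather than a
spline is the default shape. `fit_logistic_series()` fits the three
parameters by Levenberg–Marquardt nonlinear least squares
(`minpack.lm::nlsLM`), initialized at $K = 1.2\,\max(\mathrm{obs})$,
$r = 0.1$/yr, $t_0$ at the year closest to half the observed maximum. The
default error family is multiplicative — the fit minimizes squared error on
the log scale — because count observations of fleets spanning orders of
magnitude carry relative, not additive, noise; a series containing zero
counts falls back to the additive-scale fit, since the log-likelihood is
undefined there. When
the NLS stalls the fallback is a straight-line fit on the logit of
$NV/\hat K$ with $\hat K = 1.05\,\max(\mathrm{obs})$, and the last resort is
monotone linear interpolation, flagged in the fit record. A zero-variance
segment short-circuits to a constant. Countries whose fleet was destroyed
and rebuilt (war, cyclone) are handled by splitting the series at supplied
disruption years; segments are fitted independently and a discontinuity at
the split is deliberate, because those events are discontinuities.

Observed years always keep their observed value and an `"observed"`
provenance flag; only missing years receive fitted values. A segment with
fewer than three observed points cannot identify a sigmoid and triggers the
population-proxy fallback: $NV_y = NV_a \cdot \mathrm{pop}_y /
\mathrm{pop}_a$ chained from the nearest observed anchor $a$, ties broken
toward the earlier year so the rule is deterministic.

### The unmotorized fleet

Unmotorized fleets rise and then fall, so a logistic cannot represent them.
Instead they follow two regimes joined continuously at the peak year
$Y_{max}$: before the peak, counts scale with population from the nearest
observation; after it, the count changes at the motorized artisanal fleet's
relative growth rate multiplied by a coupling coefficient, default $-1$.
The sign matters: motorization *replaces* unmotorized craft, so a fleet
past its stated maximum must decline when motorization grows — a positive
coupling would contradict $Y_{max}$ being a maximum. The coupling is
configurable for sensitivity work.

Where no interior peak is observed, $Y_{max}$ is predicted from the weakly
linear relation between peak year and GDP per capita at the peak, fitted by
ordinary least squares across the countries with an observed peak
(`fit_ymax_gdp_relation()`), and solved against the country's GDP
trajectory by minimizing $|y - (b + m\,\mathrm{gdp}(y))|$ over candidate
years. With fewer than three informative countries the observed maximum is
used as-is. Whether the relation should be used predictively or only
descriptively is genuinely open; here it is predictive only for countries
without an interior observed peak, which keeps it out of the data-rich
fits entirely.

## Compositions, capacity attributes

Length-class and gear compositions are observed in a handful of years and
must cover every year while remaining on the simplex. Each composition is
mapped to additive log-ratios against the class with the largest mean
share, interpolated linearly in time (flat beyond the first and last
observation), inverted and renormalized. With the 2–6 observation years
typical of these records a penalized spline is not identifiable, which is
why interpolation on the ALR scale stands in for a smoother; with denser
data the transform, not the interpolator, is the load-bearing choice.
Structural zeros — a class never observed in a country — are exempted from
the transform and stay exactly zero, so the smoother cannot invent a fleet
segment. Data-poor countries borrow the unweighted per-year mean of
configured donor countries, renormalized for compositional attributes;
"similar countries" is not defined algorithmically anywhere we could follow,
so the donor map is explicit configuration.

Integer vessel counts are apportioned across classes, then across gears,
with largest-remainder rounding at both levels. This makes the conservation
property exact and testable: segment counts sum to the (rounded) national
total, every year, with no drift from naive rounding.

Mean engine power per vessel varies in time (linear interpolation between
observations, flat outside), while gross tonnage depends only on hull
geometry and is held constant within configurable periods. Totals are
always `mean × NV`.

## Effort

The unmotorized fleet needs a kW equivalent for oar and sail. During early
motorization the catch per kW of the whole artisanal fleet is taken as
stable, so total artisanal catch is proportional to
$NV_{unmotor} \cdot PPV_{eq} + P_{motor}$. The proportionality is resolved
as the minimal identifiable estimator: a two-coefficient no-intercept least
squares $C_y = a\,NV_y + b\,P_y$ with $PPV_{eq} = a/b$, which cancels the
unknown catchability. Only years in which the unmotorized fleet makes up
20–80% of the artisanal vessel count enter the fit — newly motorized
vessels are over-used early ("novelty effect"), and obsolete unmotorized
craft under-used late. Both window endpoints are inclusive, for
determinism. The estimator is exactly correct on noise-free inputs and
unbiased in the median under multiplicative catch noise; its per-replicate
precision is limited by the collinearity of the two regressors, which is a
property of the problem, not of the implementation.

Nominal effort is the product $Eff_{nom} = P \times DAS \times R_{act}$
(kW·days): total engine power, days at sea, and the ratio of active vessels
to capacity. Days at sea come from a segment table with a fixed
key-relaxation order when a segment is missing — drop year, drop gear, drop
country — with provenance recording which fallback fired. Countries without
activity data receive the fleet-wide mean activity ratio of 0.72.

Technological creep — the biomass-independent annual increase in
catchability — converts nominal to effective effort. The estimator is
$c = e^{\beta} - 1$ from regressing log CPUE on year, optionally with log
biomass as a covariate to purge stock effects; without a biomass index the
raw trend is used and labelled as such (no stock-assessment reconstruction
is attempted). Sector defaults apply when estimation is impossible:
1.4%/yr industrial, 5%/yr artisanal (around a 3.5%/yr fleet-wide mean).
Effective effort compounds geometrically from the 1949 baseline,
$Eff_y = Nom_y \prod_{k=1950}^{y}(1+c_k)$, so effective equals nominal in
1949 exactly. Compounding is multiplicative, not linear, because a
catchability *rate* acting on a baseline implies a cumulative factor.

## Mapping

Effort concentrates where the targeted stocks are, and the mapped catch
already encodes habitat, depth and stock location — so relative catch is
the spatial template. Each (year, country, sector, length class, gear)
segment is matched to catch through a total cascade: the identical gear if
the catch data has it; otherwise all catch gears of the same family (nets,
trawls, lines, …, shipped as an editable table because only the family
concept, not the full mapping, is fixed); otherwise all catch of the
country and year. A segment is never silently dropped: if no catch matches
at all, its effort spreads uniformly over the country's cells under an
`"Unknown"` functional group, because losing effort would break
conservation.

Within a match, effort splits across functional groups by the catch
composition (times gross-tonnage shares when several vessel categories
share a gear — vessels are assumed to fish in proportion to capacity), and
across cells by relative catch. Constraint masks then zero disallowed
cells — trawl-family gears in ban cells, the unpowered sector outside
coastal cells — and redistribute proportionally over the segment's allowed
cells. Finally a 2-D Gaussian kernel (σ = 1 cell, truncated at 3σ) spreads
each segment to avoid single-cell hotspots; mass falling off-grid or into
banned cells is folded back by renormalizing the segment to its original
total, so smoothing conserves effort and cannot re-enter a banned cell.
The kernel width is configuration: the spreading is named by the method,
its width is not, and σ = 1 is the smallest width that removes single-cell
artefacts. The final conservation renormalization implements the
"standardize so mapped effort sums to the total" requirement once, at the
end, rather than twice.

Cell centres sit at odd multiples of 0.25° (0.5° spacing); records store
centre coordinates. Years are mapped independently, so long runs are
processed in year blocks (default 8) purely to bound peak memory; results
are identical to a single pass.

## Comparison metrics

Mapped grids are compared with three statistics. Cell-wise Spearman rank
correlation (ties mid-ranked) over the union of nonzero supports — zeros
kept as zeros, because coverage gaps in AIS-like data are informative; the
rule can be switched to intersection. V-measure treats each grid's cells as
a partition: cells are classed into deciles of log(effort + ε) per grid
(scale-free, so multiplying one grid by a constant changes nothing),
homogeneity is $1 - H(A|B)/H(A)$, completeness $1 - H(B|A)/H(B)$, and V is
their harmonic mean; a single-class partition has zero entropy and scores 1
on its own term by convention. The decile binning is a documented choice —
the map-comparison literature does not fix one. Cosine similarity of the
latitude and longitude marginals measures agreement at a coarser scale that
forgives small spatial offsets. Self-comparison identities (all three equal
1) and scalar invariance are enforced by tests.

## The synthetic world

Every stage is exercised against `generate_world()`, which fabricates
countries with known ground truth: logistic fleet growth per sector;
an unmotorized fleet that rises with population to a GDP-linked peak year
and then declines at the motorized growth rate (coupling −1); drifting
compositions; power/tonnage tables; days-at-sea records with activity data
for about a quarter of countries; and catch fields concentrated near a
stylized coastline (westernmost columns; intensity decays exponentially
with cell distance, e-folding two cells) with a stable lognormal texture
per functional group. Observation gaps remove 30% of years uniformly
(always keeping the first and last year, so reconstruction is
interpolation-dominated), and observation noise is multiplicative lognormal
with 5% CV, rounded to integer counts — counts are positive and a CV is
interpretable, which is why the noise is lognormal; nothing is known about
the real yearbooks' error structure, so this is a stand-in, not an
inference.

Parameter realism drove the fleet design: motorized artisanal fleets are
restricted to the two classes under 12 m with small mean engine powers
(10 and 30 kW — outboard-scale), motorization grows at 4–12%/yr (decadal
transitions), and the motorized logistic midpoint falls shortly after the
unmotorized peak, because motorization is what ends the unmotorized
fleet's growth. These choices also make the engine-power equivalence
identifiable: the unmotorized power term is a material share of artisanal
catch in the selection window, and the two regressors are not collinear
there. Artisanal catch is generated exactly as
$q\,(NV_{unmotor} PPV_{eq} + P_{motor})$ times noise, so the equivalence
estimator can be validated against truth.

What the generator does **not** emulate: real coastlines or bathymetry,
reporting biases that correlate across countries, sector misclassification,
regime shifts other than explicit disruption years, and any real country's
magnitudes. Passing tests therefore demonstrate that the algorithms recover
known structure under realistic noise and gaps — not that real yearbook
data satisfies these models.

## Problem sizes and numerical choices

The test suite and the reproduction script use 1–20 synthetic countries
over 1950–2017 with a 2×10-cell band per country: large enough that every
code path (gear cascade levels, fallbacks, masks, smoothing) is exercised,
small enough to run in minutes on one CPU. Tolerances: conservation and
effort-equation identities are asserted at 10⁻⁶ relative (accumulated
floating-point error is ~10⁻¹⁵); share closure at 10⁻⁹; creep recovery on
exact geometric series at 10⁻⁹. Ties: nearest-anchor ties go to the earlier
year; largest-remainder ties to the earlier class. Degenerate inputs:
single-cell grids, year ranges under three years, gap fractions of 1,
all-disallowed segments, zero marginal vectors and empty donor sets all
raise immediate, specific errors rather than propagating NaNs.

## Known limitations

- A logistic cannot represent fleets that grew, collapsed and regrew
  without an explicit disruption year; undetected disruptions bias $K$.
- The engine-power equivalence has wide per-country uncertainty whenever
  motorization was fast (few years in the 20–80% window); the pipeline
  widens the window to 10–90% and then borrows the cross-country median,
  which shrinks variance at the cost of country specificity.
- Creep without a biomass index conflates technology with long-run biomass
  trends; the estimate is labelled accordingly.
- Catch-prorated mapping inherits every bias of the underlying catch maps;
  where catch is misplaced, effort follows it.
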