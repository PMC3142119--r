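---
title: "Likelihood envelopes for the unmeasured intervals of sparse time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likelihood envelopes for the unmeasured intervals of sparse time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interpuq)
```

## The problem and the constraint

A gene expression time course with six or ten time points says nothing, by
itself, about what happened between the samples. `interpuq` quantifies that
gap uncertainty under one biological assumption: *no regulatory event occurs
in an unmeasured interval unless the measurements themselves imply it*. The
assumption is operationalized on piecewise-linear paths through the ordered
points. Writing $g_i$ for the gradient of segment $i$, the second
differences $g_{i+1} - g_i$ form a sign sequence; an **inflexion point** is
an adjacent sign alternation in that sequence, and each alternation stands
for one switch between acceleration and deceleration of expression — a
regulatory event the data force on every curve through them. A candidate
path through the measured points plus hypothetical **guide points** is
*plausible* when its inflexion count does not exceed the count of the
measured path alone.

Two remarks on this definition:

* Gradient changes with magnitude at or below a tolerance (`tol`, default
  `1e-12`) are transparent — a flat kink is neither positive nor negative
  curvature. Without this rule, exactly-collinear fixtures would count
  spurious events from floating-point jitter.
* The acceptance rule is `<=` (an insertion may *reduce* apparent
  curvature but never add events). The narrative of the source method is
  ambiguous between "not exceeding" and "the same as"; `acceptance = "eq"`
  is available for the strict-equality reading. For single insertions the
  two agree in practice because one extra point cannot remove an
  alternation forced by the measurements.

The curve family is deliberately piecewise-linear. The constraint is purely
combinatorial (a count of sign alternations), and any smooth curve
honouring a given alternation pattern can be approximated by a polyline
with the same pattern; splines would add smoothness assumptions the
constraint does not need.

## Plausible bounds

At any interior position $x$, the **plausible interval** is the set of
values $y$ such that inserting $(x, y)$ alone keeps the path plausible.
Empirically (and intuitively — moving $y$ monotonically toward the
interpolated path removes violations) this set is an interval containing
the path value at $x$, which justifies locating its edges by bisection: a
coarse scan of `grid_n = 64` candidates brackets each edge and bisection
refines it to `tol_y = 1e-8`. The test suite checks the interval property
on random fixtures and checks the bisection output against an exhaustive
scan oracle at $\Delta y = 10^{-4}$.

Candidates are clipped to $[\min y - cR,\ \max y + cR]$ with $R$ the
measured range and $c$ = `clip_factor` (default 1). Clipping matters
because with two measured points — or near the ends of longer series — a
single insertion is unconstrained and the mathematical bound is infinite;
an unbounded envelope is useless downstream, and one dynamic range beyond
the data is already an extreme excursion for a log-scale expression
series.

Measurement error widens the bounds. Each measurement's replicates give a
t-based confidence interval at `conf = 0.99`, and with $n$ points every
assignment of each measurement to its lower or upper limit defines a
corner shape, $2^n$ in all. The extended bounds are the pointwise union of
the per-corner bounds plus the all-means shape (which guarantees the union
contains the zero-error bounds). Each corner uses its own reference
inflexion count — corners are alternative hypotheses about the measured
shape, and judging a corner's insertions against a different shape's
budget would mix hypotheses. Beyond `corner_cap = 12` points exact
enumeration gives way to 4096 random corners plus the means, with a
logged message.

## Column distributions: Monte Carlo and direct

Two guide points per interval, at the trisection points, probe the
unmeasured regions. The **Monte Carlo route** draws every guide value
uniformly within the bounds at its column and accepts the configuration
iff the merged path is plausible; accepted guide values, histogrammed per
column, approximate the likelihood distribution of plausible
interpolations. The acceptance rate collapses as measured points are
added (about $2 \times 10^{-2}$ for 3 points, below $10^{-2}$ at 4, and
falling roughly geometrically — the suite asserts the monotone trend), so
Monte Carlo is retained mainly as a validation oracle.

The **direct route** discretizes each column's envelope span into `V`
equal-width cells represented by their midpoints and computes three
probability vectors per column by dynamic programming:

* a *left pass*: the leftmost column is uniform (nothing constrains it
  from the left); sweeping right, each midpoint accumulates the
  probability of the previous column's midpoints with which it forms a
  plausible pair (both inserted into the measured path), then the column
  is normalized;
* a *right pass*, the mirror image;
* a *joint combination*: end columns take their inward-conditional
  vectors; an interior column's midpoint $b$ sums
  $p_\mathrm{left}(a)\, p_\mathrm{right}(c)$ over neighbour midpoints
  $(a, c)$ forming a plausible triple with $b$.

`V = 40` by default: the triple loop is $O(V^3)$ per interior column
(64,000 plausibility checks, milliseconds in the compiled core), and at 40
cells the midpoint rule's discretization error against the continuous
ensemble is below the Monte Carlo noise floor at 10,000 samples (total
variation ~0.04; it scales roughly as $1/V$, so 8 cells would leave
~0.15 — useful only for enumeration-oracle comparisons).

A column whose weights are all zero needs care. With zero-error input
this is rare, but under the error model it happens routinely: the grid
spans the shared corner-union envelope, which is much wider than any one
realization's plausible band, and when that band is thinner than a grid
cell every midpoint can miss it. The band is never actually empty — it
always contains the realization path's own interpolated value — so the
column falls back to a point mass on the bin nearest that value (a thin
band is, at grid resolution, a spike). A uniform fallback was tried first
and rejected: with realistic replicate noise it fired on a majority of
realization-columns and flooded the aggregated field with envelope-wide
uniform mass, inflating the 95% bands to nearly the full plausible
envelope — replacing the thinnest, most informative distributions with
the least informative ones. `estimate_field()` reports the total fallback
count in one consolidated warning.

`enumerate_joint_oracle()` is the exactness reference: it enumerates every
combination of one midpoint per column (up to `cap`, default $10^6$) and
returns the exact marginals under the global constraint. On 3-measured-
point fixtures the DP reproduces it to machine precision; with more
points the joint combination, which conditions on *adjacent* columns
only, deviates where long-range constraints bind (total variation up to
~0.2 on a 4-point monotone fixture). This locality is the method's main
approximation and is why the enumeration oracle ships as a first-class
function.

## Measurement error in the distributions

Each measurement's CI is cut into `m = 20` sub-intervals of equal
probability under the t sampling distribution of the mean: boundaries at
quantile levels $(1-\gamma)/2 + j\gamma/m$, $j = 0..m$ (inverse t), each
sub-interval represented by the arithmetic midpoint of its boundaries.
The equal-mass property is enforced exactly and verified by numerical
integration to $10^{-6}$ for $df \ge 1$ and $m \le 50$.

Running the DP over all $m^n$ combinations of representatives is
hopeless, so a Latin Hypercube scheme samples them: each measurement's
midpoint indices are permuted independently (Fisher–Yates, via R's
`sample.int`), and cycle $k$ of `cycles = 20` takes the $k$-th-ranked
midpoint of every measurement. Each realization carries its own reference
inflexion count, for the same self-consistency reason as the envelope
corners. All realizations share one corner-union envelope (so their
column grids coincide), and because equal-mass strata make every
realization equally probable, the per-realization joint vectors are
combined as an equal-weight mixture and renormalized. As CIs shrink to
zero the aggregated field provably collapses onto the zero-error field
(asserted on fixtures).

## Envelopes, withholding and coverage

For levels 0.20 / 0.75 / 0.95 the envelope takes, at each guide column,
the central (equal-tailed) interval of the discrete joint distribution —
cumulative points $(1 \pm q)/2$ with linear interpolation inside cells —
and, at each measured point, the t-based central CI at level $q$;
vertices are joined by straight lines. Central intervals are the default
because they are unique and order-preserving (nesting across levels is
then automatic); highest-density intervals, which can be narrower for
skewed columns but are not unique under ties, sit behind
`type = "hdi"`.

Predictive evaluation withholds time points (`every_other`,
`every_third`, or an explicit index list; endpoints must stay — the
method interpolates, never extrapolates) and scores the fraction of
withheld measurement *means* inside each level's interpolated band. The
area or quantile range of an envelope between two measured points can be
read directly off the returned polylines when ranking candidate next
measurements; the iterative advisor itself is out of scope.

## The synthetic generator and calibration

`simulate_series()` emulates the targeted data class: 6–16 evenly spaced
time points, 2–3 replicates, normal replicate noise. Families: a logistic
rise/fall (at most one sampled inflexion), a single Gaussian peak (one
inflexion pair), and a damped oscillation (alternations growing with the
sampled span). Amplitude defaults to 2 — think log2 fold change of a
responsive gene — and `noise_sd = 0.2`, a tenth of that dynamic range,
typical of well-behaved RT-PCR or array replicates. Normal noise is the
default because the t-interval machinery is then exact; a heavy-tailed
option would only exercise robustness, not the contract.

Calibration draws the ground truth from the model itself:
`simulate_truth_from_plausible_set()` returns one accepted guide
configuration (uniform over the plausible set of the retained means) as a
piecewise-linear path. The calibration experiment
(`calibrate_coverage()`: 200 series of 7 points, every-other withholding,
direct method at `V = 40`, retained means treated as exact to match the
truth generator) pools 600 withheld points; empirical coverage lands
within three binomial standard errors of 20/75/95%.

Two things this does and does not show. It does show the whole chain —
bounds, DP, quantile inversion, interpolation — is internally consistent.
It does not show real biology obeys the no-new-inflexion assumption:
truths are drawn from the constrained set by construction, so a system
with an unobserved regulatory event between samples will be covered less
often than nominal. Separately, a small structural over-coverage
(~+0.01–0.03) exists at withheld positions *between* guide columns: the
straight-line band between two columns over-covers the path's
interpolated value whenever adjacent guide values are positively but
imperfectly correlated (measured $r \approx 0.75$), because averaging
quantiles ignores the variance reduction in averaging values. It is a
property of the polyline band construction, visible with exact marginals,
and worth remembering when reading coverage numbers near the nominal
level.

## Genome-wide matrices

For a complete genes × (time, replicate) matrix, `pc1_series()` performs
mean-centered PCA across the gene dimension, projects every sample onto
the first component and returns the scores as an ordinary series with
replicates plus PC1's variance fraction. The component sign is fixed by
making the largest-magnitude loading positive so repeated runs and
gene-order permutations agree. Imputation of missing cells is explicitly
out of scope — the tool consumes preprocessed expression tables.

## Numerical and scale choices, in one place

| quantity | default | why |
|---|---|---|
| `tol` (zero gradient change) | 1e-12 | float jitter on collinear data |
| `tol_y` (bisection) | 1e-8 | envelope edges far below data scale |
| `grid_n` (edge scan) | 64 | brackets both edges; bisection does the rest |
| `clip_factor` | 1 | one dynamic range beyond the data |
| `conf` | 0.99 | wide CIs for few replicates |
| `V` | 40 | midpoint-rule error < MC noise at 10k samples |
| `m` | 20 | one stratum per Latin Hypercube cycle |
| `cycles` | 20 | LHS cycles; one per stratum up to `m` |
| corner cap | 12 (2^12 corners) | exact enumeration at desk scale |
| oracle cap | 1e6 combinations | enumeration is a test instrument |
| MC attempt cap | 1e7 | fail loudly on pathological bounds |

Test and validation problem sizes (3-point oracle fixtures at V = 8 and
40, 200-series calibration at 7 points, 500-gene PCA matrix) were chosen
so every check enumerates or samples its reference exhaustively at desk
scale; they are stated in the tests themselves.

## Known limitations

* The joint DP conditions on adjacent columns only; long-range
  constraints (4+ measured points with tight monotone structure) are
  approximated. Use `enumerate_joint_oracle()` when the fixture is small
  enough to check.
* Coverage statements inherit the no-new-inflexion assumption; widely
  spaced measurements make it less credible, and the method cannot warn
  about events it is built to exclude.
* Bands between columns over-cover slightly (previous section).
* No extrapolation beyond the measured range, no spline smoothness, no
  missing-value imputation, no upstream expression preprocessing.
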