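---
title: "Methods: thermal performance curves and feeding-suitability projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermal performance curves and feeding-suitability projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermshift)
```

## The model

Feeding-related traits of ectotherms (ingestion rate, foraging rate, prey
capture efficiency) respond unimodally to temperature.  thermshift fits this
relationship — the thermal performance curve (TPC) — per species, and turns
the fitted curve into a spatial index of relative feeding suitability:

$$\mathrm{THS}(T) \;=\; \frac{FR_T}{FR_{opt}} \in [0, 1],$$

where $FR_T$ is the predicted feeding rate at temperature $T$ and
$FR_{opt}$ the predicted rate at the thermal optimum $T_{opt}$.  Because the
index is normalized per species, it compares temperature-dependent feeding
performance across species with different absolute rates; it deliberately
does not capture absolute metabolic demand, prey availability, or any
non-thermal driver.  THS is computed per grid cell for each of twelve
monthly temperature layers and averaged to an annual mean, for a baseline
and a future (uniformly warmer) scenario; the two annual surfaces are then
compared class-wise.

## Curve fitting and model selection

No single functional form fits all traits and taxa, so 22 published TPC
forms are scored per species (`tpc_forms()`): quadratic, Gaussian, modified
Gaussian, Brière 1 and 2, Lactin-2, Ratkowsky, the three Sharpe–Schoolfield
variants, Weibull, Thomas 2012, Logan-6, Rezende, O'Neill, Johnson–Lewin,
Flinn, Jöhnk, Boatman, Spain, Deutsch, and a two-term Arrhenius
(Hinshelwood) form.  Each carries its literature citation, parameter bounds
and a start-value heuristic.  The Hinshelwood form is re-centered at a 20 °C
reference temperature (its pre-exponential factors are absorbed into rates
at that temperature) so that in-bounds parameters can never overflow double
precision; the O'Neill form is evaluated in log space for the same reason.
Forms that go negative outside their thermal window (quadratic, Brière,
Thomas, Deutsch, …) are evaluated raw during fitting — clamping at zero is a
projection-stage rule — so least squares sees the true functional shape.

Each form is fitted by bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) from 10 seeded starts: the heuristic initials plus
jittered copies (±20% of each value), keeping the converged run with the
lowest residual sum of squares.  Model selection minimizes the small-sample
information criterion

$$\mathrm{AICc} = n\,\ln(\mathrm{RSS}/n) + 2k + \frac{2k(k+1)}{n-k-1},
\qquad k = \text{n\_params} + 1,$$

counting the residual variance as a parameter.  AICc is the default (the
small samples typical of feeding trials make the correction material); raw
AIC is available via the `correction`/`aic` options.  A form with
$n - k - 1 \le 0$ has no defined criterion and is treated as non-converged.
Ties within $10^{-9}$ are broken by fewer parameters, then by the fixed
registry order — which is why the registry order is versioned.

Species are excluded when no form converges (`no_convergence`), when fewer
than four distinct test temperatures survive quality filtering
(`insufficient_data` — four points cannot identify a four-parameter form),
or when the best fit is implausible (`implausible_parameters`): peak rate
$\le 0$, optimum more than 10 °C outside the observed temperature span, or a
thermal window $CT_{max}-CT_{min}$ wider than 80 °C.  These numeric
plausibility cutoffs are this package's explicit operationalization of
"unrealistic parameter estimates"; they are deliberately loose, intended to
catch degenerate fits rather than to police biology.

## Derived thermal parameters

From the selected curve, `derive_parameters()` extracts $T_{opt}$ by a
0.01 °C grid scan over the window extending 25 °C beyond the observed
temperature span, refined locally; $r_{max}$ is the curve value at the
refined optimum (so the THS peak is exactly 1 by construction).  $CT_{min}$
and $CT_{max}$ are the nearest zero-crossings of the fitted curve below and
above the optimum, located by bisection, and are reported undefined when the
curve never reaches zero inside the window (e.g. a Gaussian).  The ±25 °C
pad lets limits fall somewhat outside the experimental design without
chasing the asymptotes of exponential-tailed forms.  $Q_{10}$ is defined on
the rising limb as $r_{max} / f(T_{opt} - 10)$, undefined when the rate
10 °C below the optimum is non-positive.  This is the conventional
one-number summary of temperature sensitivity on the rising limb; the
interval choice is documented here because conventions differ.

## Uncertainty

Uncertainty is quantified by a residual bootstrap: centered residuals are
resampled with replacement, added to the fitted values, truncated below at
zero (rates are non-negative), and the selected form only is refitted from
the point estimates; percentile intervals at the 95% nominal level summarize
the derived parameters.  A residual (rather than case) bootstrap preserves
the sparse, structured temperature design of feeding trials.  Refits that
fail are dropped and counted, with a warning flag above 50% failures.
Intervals quantify fitting uncertainty but are *not* propagated into the
spatial projections: maps reflect the best-supported curve only.

With 20 temperatures and 5% noise, empirical coverage of the $T_{opt}$
intervals sits a little below nominal (≈91–93% at the 95% level in the
package's own 200-dataset simulation) — the familiar mild undercoverage of
percentile intervals in small nonlinear samples.

## Projection rules

`predict_rate()` clamps negative raw predictions to zero and, when both
thermal limits are defined, forces the rate to zero outside
$[CT_{min}, CT_{max}]$.  Both rules are applied: forms with genuine zero
crossings are truncated exactly at them, and forms that decay without
crossing zero simply decay.  THS is clipped into $[0, 1]$ to absorb
grid-refinement rounding at the peak (raw ratios can exceed 1 by at most
~1e-9, asserted in the tests).  The annual mean is a per-cell arithmetic
mean over months, with strict nodata propagation (any missing month makes
the cell missing) — the conservative reading of a twelve-month average.
Realm masking restricts marine species to sea cells and freshwater and
terrestrial species to land; masks must be exactly aligned with the grid
(no implicit resampling anywhere — alignment is a preprocessing concern).

Area computations weight cells by the cosine of the cell-center latitude on
a spherical Earth (radius 6371 km), reported in km² with raw cell counts
alongside; class extents therefore partition the total unmasked area to
within 1e-6 relative tolerance.

## Classification and priorities

Annual THS surfaces are cut into five equal classes — Minimal [0, 0.2),
Minor [0.2, 0.4), Moderate [0.4, 0.6), Major [0.6, 0.8), Massive [0.8, 1] —
left-closed with a closed top class, a convention fixed here because
interval notation at shared endpoints is otherwise ambiguous.  A species is
*range-expanding* when the area-weighted extent of THS ≥ 0.6 strictly
increases from baseline to future.  The monitoring priority screens the
sign-preserving percent change $r$ of that qualifying extent:
$|r| \ge 20\%$ → Priority, $5\% \le |r| < 20\%$ → Surveillance, else
NoIssue; a species whose qualifying extent appears from a zero baseline is
Priority ($r = +\infty$), and a class absent at baseline has an undefined
("new") percent change rather than a number.  The 5%/20% cutoffs are
invented screening defaults — the underlying concern matrix is qualitative —
so they are configurable and every reported category carries the thresholds
used.

## What the synthetic data emulate — and what they do not

The generator exists so that every stage is testable without external data.
Trait observations are drawn from a known registry curve at evenly spaced
temperatures with additive Gaussian noise (sd = `noise_cv` × true peak
rate), truncated at zero.  Additive truncated noise was chosen over
multiplicative lognormal noise for transparent parameter-recovery
tolerances; the true noise structure of empirical feeding-rate data is
unknown, and the generator is a stand-in, not a claim about it.  Climate
worlds combine a linear equator-to-pole gradient (27 °C to −20 °C by
default), an 8 °C seasonal sinusoid whose phase flips across the equator,
0.5 °C cell-level noise, a random 30% land mask, and a uniform +2 °C future
offset — a mid-century high-emissions-scenario magnitude.  Default grids are
36 × 72 (5°) for desk-scale work; the generator supports finer grids but the
tests do not require them.  The default study composition is 28 species
(4 freshwater, 16 marine, 8 terrestrial) with realm-typical optima
(freshwater 12–24 °C, marine 8–26 °C, terrestrial 22–36 °C), peak rates
log-uniform on [0.5, 20], curve widths 4–9 °C, twelve test temperatures and
two replicates at 5% noise.

The synthetic world has no continents, no ocean–land thermal contrast, no
ENSO-like variability, no spatially correlated warming, and its species are
drawn from the same family of curves the registry can fit.  Passing tests
therefore demonstrate that the *pipeline machinery* is correct — recovery of
known parameters, exact normalization, partition identities, monotone
responses — not that any real species' projection is right.

## Numerical choices and degenerate inputs

* Grid scans at 0.01 °C bound the optimum/limit location error below the
  0.01 °C oracle tolerance; bisection then refines to 1e-8.
* Seeds: every stochastic step (jittered starts, noise, bootstrap, masks)
  takes an explicit integer seed, and derived sub-seeds stay below 2^31.
* Degenerate designs: four collinear points fail every form's AICc degrees
  of freedom and exit as `no_convergence`; a flat curve fails the
  `rmax > 0` plausibility rule; temperatures must be finite, and non-finite
  grid cells project to nodata.
* Floating-point outputs are written with six significant digits so
  identical configurations and seeds reproduce byte-identical files.

## Problem sizes

The package's own simulations use desk-scale sizes chosen to exercise every
code path with comfortable statistical resolution: 200 datasets × 500
bootstrap resamples for the coverage study, 100 seeded datasets for
parameter recovery, a 36 × 72 climate world, and a 28-species study fixture.

## Known limitations

The 22-form registry is a documented choice among many published forms;
registry composition and order affect AICc tie-breaks.  Percentile bootstrap
intervals mildly undercover in small samples (see above).  Q10 depends on
the interval convention.  The index is relative: two species with identical
THS maps can differ arbitrarily in absolute feeding pressure.  Scenario
comparison assumes baseline and future grids are already on a common grid
and mask; the package refuses, rather than resamples, anything else.
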