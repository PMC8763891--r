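---
title: "Models and methods behind weldfume"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind weldfume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

weldfume reconstructs and rates long-term exposure of shipyard welders to
the metals carried in welding fume (Cr, Fe, Mn, Ni, Pb). This vignette is
the package's own account of the models it implements, the parameters
that matter, the numerical choices made, and what the tests do and do not
demonstrate. Units are fixed at mg, m<sup>3</sup> and min throughout the
package; any conversion happens at the I/O boundary.

## 1. Chamber mass balance and emission-rate estimation

A welding arc inside a test chamber of effective volume $V$ obeys the
single-compartment mass balance

$$\frac{dC_{in}}{dt} = p \cdot AER \cdot C_{out} + \frac{Q_s}{V}
  - (AER + k)\, C_{in},$$

with $AER$ the air exchange rate (1/min), $k$ the particle deposition
rate (1/min), $p$ the penetration efficiency of make-up air particles and
$Q_s$ the source strength (mg/min), equal to the emission rate ER while
the arc is on and zero afterwards. The removal term carries a negative
sign: air exchange and deposition can only reduce the in-chamber
concentration (with a positive sign the equation diverges and no
peak-based estimator could be derived from it). `simulate_chamber_series()`
solves this equation analytically on each piecewise-constant source
segment (exponential relaxation towards the segment equilibrium) rather
than by stepping, so simulated traces are exact up to the output sampling
grid.

`estimate_emission_rate()` inverts the balance from a measured trace:

$$ER = V\left[\frac{C_{in}}{\Delta t}
  + (\overline{AER + k})\,\bar{C}_{in}\right],$$

where $C_{in}$ is the peak concentration, $\Delta t$ the time from the
series start to the peak, and $\bar{C}_{in}$ the trapezoidal mean
concentration over $[0, \text{peak}]$. This is the integral of the mass
balance over the rise interval with the initial-concentration terms
dropped; the `method = "full"` variant retains them
($(C_{in} - C_{in,0})/\Delta t$ and $-AER \cdot C_{in,0}$) and should be
used when the trace does not start clean. With a clean trace the
estimator is an exact integral identity, so its residual error is the
trapezoidal discretization of $\bar{C}_{in}$, which shrinks quadratically
with the sampling interval; the test suite freezes a 15% round-trip
tolerance across a parameter sweep, which holds with two orders of
magnitude of margin at 0.01-min sampling.

Numerical conventions: the peak is the global maximum with ties broken by
the earliest time, except the series origin itself, which is never
accepted as a peak (a strictly decaying trace is a degenerate input); an
all-zero trace returns ER = 0 with a warning flag rather than an error;
the combined removal rate $AER + k$ is taken from the series metadata,
with $k = 0$ as the default when unknown, and `fit_removal_rate()`
estimates $AER + k$ by log-linear regression on the post-peak decay for
users who did not measure it.

## 2. The two-zone (near-field/far-field) dispersion model

The workplace is split into a near field — the hemisphere of radius
0.6 m around the arc, $V_N = \tfrac{2}{3}\pi (0.6)^3 \approx 0.452$
m<sup>3</sup>, containing the welder's breathing zone — and the far field
(the rest of the hall, volume $V_F$). Supply air enters and leaves the
far field at rate $Q$ (m<sup>3</sup>/min); a bidirectional interzonal
flow $\beta$ (m<sup>3</sup>/min) couples the zones; the source emits ER
(mg/min) into the near field:

$$V_N \frac{dC_N}{dt} = ER + \beta (C_F - C_N), \qquad
  V_F \frac{dC_F}{dt} = \beta C_N - \beta C_F - Q C_F.$$

`tz_concentration()` evaluates the closed-form solution for zero initial
concentrations, whose two exponential rates $\lambda_1 > \lambda_2$ (both
negative for any positive parameters) are the roots of

$$\lambda^2 + \frac{\beta V_F + V_N(\beta + Q)}{V_N V_F}\lambda
  + \frac{\beta Q}{V_N V_F} = 0.$$

The quadratic is solved in the numerically stable form (large-magnitude
root from the $-(b + \sqrt{b^2-4c})/2$ branch, the other via the product
identity), and a repeated-root L'Hôpital form guards the near-degenerate
regime $|\lambda_1 - \lambda_2| < 10^{-9}|\lambda_2|$, which is
unreachable for strictly positive parameters but can be approached under
extreme rounding. Steady states are $C_F = ER/Q$ and
$C_N = ER/Q + ER/\beta$; as $\beta \to \infty$ the model collapses to
the one-zone well-mixed room, which the tests verify at
$\beta = 10^3 Q$.

`tz_numeric_oracle()` integrates the same balance numerically (deSolve;
adaptive lsoda at rtol $10^{-10}$ by default, fixed-step RK4 with an
explicit stability refusal when a step is forced). It exists so that the
closed form is validated against an independent integration path — the
tests require agreement within $10^{-6}$ relative on a thousand
randomized parameter sets — and is never used in production runs.

**Mapping model output to an 8-h TWA.** Field samples are 8-h
time-weighted averages, while the model describes a continuously emitting
arc. `tz_tw_average()` uses the duty-cycle approximation: steady state
times the arc-on fraction of the shift. It is accurate when the slow
relaxation time $1/|\lambda_1|$ is short against the arc-on duration,
which holds for hall-scale parameters ($1/|\lambda_1|$ of minutes against
hours of cumulative arc time); the approximation ignores the build-up and
decay transients, which bias it slightly low for very short arcs.

**On deriving β from wind speed.** The textbook estimate
$\beta = \tfrac{1}{2} s \cdot 2\pi r^2$ over the near-field hemisphere
gives ~37 m<sup>3</sup>/min at 0.54 m/s, several-fold above the 5.11–11.1
m<sup>3</sup>/min range that anemometer-based field characterization
yields for these halls. Because the discrepancy cannot be resolved from
first principles, β is treated as a direct input everywhere;
`beta_from_windspeed()` is provided but never used by default.

## 3. Long-term Monte-Carlo reconstruction

`predict_longterm()` resamples daily operation records (process, wire,
current, $Q$, β, volumes, duty cycle) with replacement, perturbs each
draw's $Q$ and β by an independent uniform factor of ±20% (the
`flow_uncertainty` default; the stochastic inputs of the original
spreadsheet-based simulation are not recoverable, so the band is an
explicit, configurable choice), looks up the emission rate for the day's
condition, and evaluates the duty-cycle TWA. The pooled draws per metal
and zone are summarized as GM/GSD with natural logs and the n−1
denominator. The reported `n` is the number of operation-log days (the
effective observational support), not the iteration count: it is what the
Bayesian layer should treat as the weight of this evidence. The
study-scale iteration count is 100,000, which the analysis scripts use;
tests use 2,000–100,000 depending on what they assert, and a
repeated-seed check bounds the Monte-Carlo error of GM/GSD at 1% for
$10^5$ iterations.

Left-censored observations (below the LOQ) are substituted at
LOQ/$\sqrt 2$ before log-summaries — the standard industrial-hygiene
convention — and the synthetic generator retains the true values of
censored draws so recovery tests can quantify the substitution error.

## 4. Validation statistics

`fit_linear()` is ordinary least squares of measured on predicted
concentrations (stats::lm) with the two-sided slope t-test;
`fit_table()` reports every requested grouping because the natural
grouping (per metal, per zone, or per metal×zone) is a design choice the
data cannot arbitrate. `spearman_cor()` ranks with average ties — the
measured tables contain many tied values at the reporting resolution, so
tie handling materially affects ρ — and uses the t approximation for the
p-value; the implementation is cross-checked against stats::cor.test in
the tests.

## 5. Bayesian decision analysis on the (GM, GSD) grid

Exposure ratings are five ordered bands in fractions of the OEL
(ER0 ≤ 0.005, ER1 ≤ 0.05, ER2 ≤ 0.25, ER3 ≤ 0.5, ER4 > 0.5), each tied
to a recommended control; one-half the OEL is the action level. Band
upper edges are inclusive, exactly as the band definitions print. The
rating statistic is the lognormal 95th percentile
$X_{95} = GM \cdot GSD^{1.645}$, the convention of decision-chart
frameworks; the arithmetic mean is exposed as a configurable alternative
so the choice stays auditable.

The parameter space is a geometric grid over GM (OEL·10<sup>−3</sup> to
OEL·10<sup>2</sup>, 401 nodes) and GSD (1.01 to 4.5, 201 nodes), wide
enough to hold all packaged statistics with margin; doubling the
resolution moves no band probability by more than 0.005 (tested). On the
log scale the lognormal likelihood of a sample is fully determined by its
sufficient statistics $(m, s, n)$:

$$\ell(\mu, \sigma) = -n\ln\sigma
  - \frac{(n-1)s^2 + n(m-\mu)^2}{2\sigma^2} + \text{const},$$

which the tests verify node-wise against a brute-force per-observation
summation. Posterior weights are prior × likelihood with log-sum-exp
normalization; band probabilities are the weight totals over nodes whose
$X_{95}$ falls in each band; a multinomial sampling oracle re-derives the
same chart draw-by-draw as an independent path through the band logic.

**Prior encoding.** How a model-predicted exposure distribution should
enter the grid prior is genuinely open; two encodings are implemented:

* *suffstat* (default): prior weights proportional to the likelihood of
  the predicted GM/GSD treated as $n$ days of observation. It uses the
  predicted distribution's full shape and weights it by its
  observational support, making sequential updating exact (posterior
  from pooled statistics equals sequential posteriors, which is tested).
* *category*: prior and likelihood are first reduced to their five-band
  charts, and the posterior chart is their band-wise product,
  renormalized. This discards within-band information but mirrors how
  chart-level judgments are sometimes combined in practice.

`bda_sensitivity()` reports both side by side; dominant bands flip for
several metals between encodings, which is exactly why the report is
emitted with every analysis.

A degenerate predicted GSD of exactly 1 (a zero-spread prediction) makes
the σ-likelihood improper; the prior then degrades to a ridge in μ and
the result is flagged. The likelihood chart always uses a uniform prior,
so a flat prior reproduces it to machine precision (tested at
$10^{-12}$).

One property deserves a caveat: increasing the field GM cannot decrease
the posterior $P(\text{ER4})$ in the continuum (monotone likelihood
ratio in μ), but on the discrete grid the σ-mixing can introduce
sub-$10^{-4}$ wobble at the flat ends, and the test asserts monotonicity
at that tolerance.

## 6. The synthetic-data generators

`gen_operation_records()` emulates a shipyard operation log: FCAW/GMAW
with the correct wire pairing (KFX wires ⇒ FCAW, KM wires ⇒ GMAW),
currents in {120, 220, 300} A, and interzonal flows drawn within the
per-process field ranges (FCAW 6.78–11.1, GMAW 5.11–9.08
m<sup>3</sup>/min). Where the field characterization reports no value,
the defaults are stated choices for a naturally ventilated welding bay:
supply air $Q$ uniform on 20–60 m<sup>3</sup>/min, far-field volume
100–1000 m<sup>3</sup>, arc duty cycle uniform on 0.25–0.75 of the
shift, and an FCAW share of 2/3 matching the 12:6 split of the field
campaign. Draws are independent uniform within range (triangular
available); real operation logs are autocorrelated across days and
correlated across parameters, which the generator deliberately does not
model.

`gen_lognormal_sample()` draws exposure values at a requested GM/GSD
with optional left-censoring at a stated LOQ and stores the generating
truth. Passing tests on these generators therefore demonstrate correct
propagation of *assumed* lognormal, independent inputs — they cannot
validate the lognormality or independence of real shipyard exposures.

## 7. Problem sizes and reproducibility

Every stochastic routine takes an explicit integer seed and is
byte-reproducible under it. The test suite runs the closed-form/ODE
comparison on 1,000 randomized parameter sets (steady-state identities)
plus 120 full integrations, the chart sampling oracle at $10^6$ draws,
and the band-recovery study at 200 replicates of n = 100 samples across
all five bands; these sizes hold the whole suite to well under a minute
of BDA time while keeping Monte-Carlo error far below the asserted
tolerances. The analysis scripts run the long-term reconstruction at the
study-scale 100,000 iterations.

## 8. Known limitations

* The duty-cycle TWA mapping ignores transients; it is not suitable for
  arcs shorter than a few multiples of $1/|\lambda_1|$.
* Censoring is handled by LOQ/$\sqrt 2$ substitution, not maximum
  likelihood; at high censored fractions the GM is biased upward.
* The BDA treats predicted and field statistics as exchangeable
  lognormal evidence; systematic model error (e.g. a biased β) is not
  separately represented and will propagate into the posterior.
* The packaged chamber emission rates, predicted long-term statistics
  and field statistics are transcribed campaign summaries: the raw
  traces and logs behind them are not available, so the package can
  propagate but not re-derive them.
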