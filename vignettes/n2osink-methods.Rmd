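---
title: "Models and methods behind n2osink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind n2osink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(n2osink)
```

`n2osink` implements the computational chain used to evaluate
N2O-respiring bacteria (NRB) as biological sinks for soil nitrous oxide:
laboratory batch-vial respirometry, a bet-hedging population model, field
chamber-flux statistics, qPCR-based inoculant tracking, and
inventory-scale extrapolation. This vignette documents the models, the
parameters that matter, the numerical choices, and the limits of what the
synthetic-data tests can show.

## 1. Vial respirometry

A stirred batch culture (typically 50 ml liquid under a 70 ml He
headspace in a 120 ml serum vial) is sampled repeatedly by a gas
chromatograph. Two measurement artefacts must be undone before any
kinetics can be read off the headspace series:

* **Sampling loss.** Each sampling withdraws `sample_volume` ml of
  headspace, replaced by inert gas, diluting every gas by
  $1 - v_s/v_h$. The model books the reading at a sampling time *before*
  the withdrawal — that is what the instrument reports — and applies the
  dilution multiplicatively at the event time.
* **Leakage.** Septum leakage is first-order exchange towards an ambient
  composition (zero for He-atmosphere vials). Assuming the biological
  rate $r$ constant within an interval, $dA/dt = r - L(A - A_\mathrm{amb})$
  has a closed form that `interval_rates()` inverts exactly; $L = 0$
  reduces to plain difference quotients.

**The dissolved pool.** For a soluble gas such as N2O the liquid holds a
substantial share of the vial inventory (about one third at 50/70 ml).
`interval_rates(include_dissolved = TRUE)` therefore adds the change of
the dissolved pool, estimated by the quasi-steady-state (QSS) transfer
balance

$$C_\mathrm{liq} = C_\mathrm{eq} - \frac{r}{k_La \, V_\mathrm{liq}},$$

iterated twice because the offset term itself depends on the rate being
estimated. The first reading is taken at plain Henry equilibrium: the
vial is dosed and mixed before time zero, so no transfer gradient has
developed yet. Without this correction the rebuilt cell trajectories miss
the dissolved drawdown and mass balances cannot close; with it they
reproduce the simulator's biomass to better than 1 %. The QSS form
matches the per-interval spreadsheet style of processing such data; the
fully dynamic two-compartment description is available in the simulator
(section 2), so both interpretations of the liquid-phase routine are
provided.

**Solubility.** All Henry conversions use Weiss-form freshwater fits
$\ln K_0 = a_1 + a_2(100/T) + a_3 \ln(T/100)$ at zero salinity:
Weiss & Price (1980) for N2O, Weiss (1970) Bunsen coefficients for O2 and
N2, Weiss (1974) for CO2, tabulated in one internal registry. At 15 °C
this maps 12.9 µM dissolved N2O to ≈382 ppmv; published values around
389 ppmv correspond to slightly different solubility sources, a ~2 %
spread that users should keep in mind when comparing across papers.

**Biokinetics.** Cell numbers follow
$N(t) = N_\mathrm{ini} + Y_{O_2}\,\mathrm{cumO_2}(t) + Y_{N_2O}\,\mathrm{cumN_2O}(t)$;
cell-specific rates divide interval rates by interval-mean cells.
`fit_growth_rate()` fits $r(t) = r_0 e^{\mu t}$ by Levenberg–Marquardt
least squares (log-linear start values, response normalised by its
maximum for conditioning, convergence tolerances 1e-12); the fitting
window is user-set or auto-selected as the longest contiguous span whose
log-rate is linear at $R^2 \ge$ `r2_min` (default 0.98; ties resolved
towards the earliest window). Note that 0.98 tolerates a point or two of
saturation at the window edge — raise `r2_min` for strictly exponential
spans. `fit_michaelis_menten()` fits $v = V_\mathrm{max} C/(K_m + C)$
with starts $V_\mathrm{max} = \max v$, $K_m = C$ at half-max; flat rate
data are reported as a $K_m \to 0$ boundary, not a numeric estimate.
Electron conversions use 4 e⁻ per O2 and 2 e⁻ per N2O throughout.

**O2-onset detection.** `o2_onset_threshold()` reports the dissolved O2
at which net N2O consumption first exceeds a noise floor. Because the
consumption begins mid-interval, the onset time is back-extrapolated
within the first consuming interval using the (near-constant) rate of the
following interval. With sampling-dilution events the headspace-only N2O
rate is masked by post-sampling outgassing from the liquid; use
dissolved-corrected rates (or the `n2o_dissolved` argument) in that case.

## 2. The bet-hedging simulator

`simulate_bethedge()` implements a deliberately simple deterministic
two-subpopulation model: a fraction `f_nosz` of cells expresses N2O
reductase; all cells grow aerobically with Michaelis–Menten kinetics in
dissolved O2; once dissolved O2 falls below `o2_switch` (default 2 µM,
within the 1–2 µM onset band of aerobically raised cells) the expressing
subpopulation additionally grows by N2O respiration, while non-expressing
cells simply run out of electron acceptor. Stochastic per-cell expression
dynamics are intentionally out of scope; the two-subpopulation form is
the model's key declared assumption, as is the absence of late
recruitment of non-expressing cells.

States are headspace and dissolved amounts (mol) of O2, N2O and N2, the
two subpopulations, and running cumulated consumptions. Gas exchange is
$k_La V_\mathrm{liq}(C_\mathrm{eq} - C_\mathrm{liq})$ per gas. The stiff
`lsodar` integrator (absolute tolerance 1e-12 mol, relative 1e-9) runs
piecewise between sampling times; the O2 switch is located by
root-finding, and each sampling multiplies the headspace states by the
dilution factor, with the removed gas logged so that mole balances can be
audited including losses (they close to 1e-6 relative; N2 produced equals
N2O consumed mol-per-mol). Reported trajectories show the pre-removal
state at sampling times, which is what a GC reading gives.

`fit_fnosz()` estimates the expressing fraction by least squares on
observed headspace O2 and N2O, each gas's residuals normalised by its
data range. The loss is scanned on the fixed multistart grid
{0.01, 0.05, 0.2, 0.8} and the best bracket refined by 1-D bounded
minimisation; a flat loss surface (no O2-to-N2O transition in the data)
returns an explicit "unidentifiable" result instead of a number.
Recovery on noisy synthetic vials (2 % multiplicative noise) is within
20 % across `f_nosz` from 0.01 to 1.

## 3. Chamber fluxes and emission-reduction inference

Fluxes come from the dynamic-chamber equation
$q = 10^{-6} a h p / (RT)$ with $a$ the OLS slope (ppm s⁻¹) of the
enclosure concentration ramp after a deadband (default 15 s — robot
settling; configurable, as no published rule exists). Emissions are
cumulated by the trapezoidal rule (exact for linear flux, additive over
closed-open period splits). Visualisation uses a Nadaraya–Watson smoother
with Gaussian weights; the bandwidth (default 4 h, chosen to span a few
measurement cycles while preserving diurnal structure) is a display
parameter only and never enters the statistics.

Reduction inference distinguishes the two field designs:

* **Unpaired** (independent buckets): the estimand is the *ratio of
  means*. The Fieller interval solves the quadratic
  $(\bar X - \rho \bar Y)^2 = t^2(v_{11} + \rho^2 v_{22})$ on Welch
  degrees of freedom; when $g = t^2 v_{22}/\bar Y^2 \ge 1$ the interval
  is the whole line, flagged rather than thrown.
* **Paired** (matched plots): the estimand is the *mean of ratios*
  $\tfrac1n \sum X_i/Y_i$ with a Student-t interval, plus a
  covariance-aware Fieller interval and a pair-resampling bootstrap for
  comparison; the three agree in width within tens of percent on
  realistic noise.

Percentage reductions map interval endpoints through the monotone
transform $(1-\rho) \cdot 100$. The bootstrap is a simple nonparametric
percentile bootstrap (default 10,000 resamples, vectorised, seed
required). Its known small-sample behaviour matters here: at $n = 6$
chambers per arm with lognormal chamber noise its empirical coverage is
~89–90 % against a nominal 95 %, an $O(1/n)$ effect that bias-corrected
variants do not repair, while the Fieller and t intervals hold 94–97 %.
`calibrate_coverage()` implements the standard remedy — simulate, measure
coverage, and bisect for the nominal level that achieves the target —
which is also the appropriate check that calibration leaves well-behaved
intervals essentially unchanged.

## 4. qPCR tracking and survival decay

Absolute quantification uses the exponential detection model

$$N = \frac{N_T}{(2e)^{C_q}},$$

with $N_T$ the amplicons needed for signal detection and $e$ the
amplification efficiency. Calibration is linear least squares of
$\log N$ on $C_q$ (slope $-\log 2e$), exact on noiseless standards.
Fitted parameters are carried at full precision everywhere downstream:
the model is steeply exponential in $C_q$, so evaluating it with
two-digit rounded parameters at $C_q = 40$ shifts the implied detection
limit from ~34 to ~46 templates per tube — `qpcr_lod()` reports what the
supplied calibration actually gives, and rounded published parameters are
never substituted internally. Quantities beyond the $C_q$ trust limit
(default 40 cycles) are flagged below-LOD, never zeroed or imputed.

Inhibition screening compares measured $C_q$ of a spiked dilution series
with the model prediction; a dilution passes if its offset is at most
`delta_cq_max` (default 1 cycle, inclusive), and the least-diluted
passing extract defines the minimum safe dilution. Survival series are
fitted as first-order decay $N_t = N_0 e^{-dt}$ on the log scale within
user-specified day windows; two-phase laboratory series are handled by
fitting each window separately (breakpoints are not auto-detected — the
phases are described qualitatively, so their boundaries are analyst
input). Every fit satisfies $T_{1/2} \, d = \ln 2$ by construction.

## 5. Inventory extrapolation

`apply_scenario()` multiplies selected source categories of a per-region
emission inventory by $1 - f$ (default $f = 0.6$, the conservative
uniform reduction factor for NRB treatment of liquid manure) and
recomputes totals. The package ships no country table: published
national-scale percentages depend on an external model's values, so the
module consumes any CSV in the documented long schema and the tests use
generated inventories.

## 6. Synthetic data: what it does and does not show

Each generator is a pure function of its mandatory seed and serialises
its ground truth:

* `gen_incubation()` samples the simulator at a GC-like cadence (default
  45 min) with multiplicative lognormal reading noise (default CV 2 %, a
  typical GC precision).
* `gen_field()` builds a control flux path = baseline + sinusoidal
  diurnal forcing (peak at 14:00) + exponential-decay event pulses
  (rain/re-fertilisation analogues), multiplies it by the true treatment
  ratio for the treated arm, and gives each chamber an independent
  lognormal factor (default CV 0.25, a conservative chamber-to-chamber
  spread). Enclosure ramps are generated by inverting the chamber-flux
  equation, so flux computation recovers the truth exactly at zero noise.
* `gen_qpcr()` mirrors the six-decade standard design
  ($2.4\times10^1$–$2.4\times10^6$ templates per tube) with additive
  Gaussian $C_q$ noise; an optional inhibition variant offsets the
  least-diluted extracts.
* `gen_survival()` draws piecewise-exponential abundances (default: a
  fast phase, $d = 0.5$ d⁻¹ for 5 days, then $d = 0.02$ d⁻¹) with
  lognormal noise.

The generators emulate the statistical structure the estimators assume —
which is exactly why passing tests certify the *computational chain*, not
the biology: real soils add temperature-dependent kinetics, spatial
heterogeneity beyond a single lognormal factor, non-instant chamber
mixing, matrix-dependent DNA extraction efficiency, and N2O production
co-occurring with consumption. None of these are modelled, and claims
about real field performance cannot be derived from these tests.

## 7. Problem sizes and numerical conventions

Test and acceptance runs use: 200–500 Monte-Carlo replicates for
estimator-bias checks, 600–1000 synthetic campaigns for interval
coverage, three seeds per generating value for expressing-fraction
recovery, and bootstrap sizes of 500–1000 inside simulation loops (the
default 10,000 is for one-shot analyses). These sizes give Monte-Carlo
standard errors comfortably inside the asserted bands. Internal
computation is in mol, litre, hour and Kelvin with a single boundary
conversion layer to the field's customary units (ml, h, µM, fmol, ppmv);
temperatures are accepted in 0–40 °C where solubility fits are valid.
Degenerate inputs follow one rule: scientifically meaningful emptiness
(no N2O consumption, flat loss surface, unbounded Fieller set, nothing
above LOD) is a typed result, while malformed input (non-monotone times,
negative amounts, unknown gases) is an error.
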