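---
title: "Models and conventions behind pamkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind pamkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamkit)
```

pamkit analyzes pulse-amplitude-modulated (PAM) chlorophyll fluorometry
experiments on factorial plant designs — here, four *Ranunculus*-type
cytotypes (2x, 4x, 6x_29, 6x_35) crossed with two photoperiods (10 h
control, 16.5 h extended-light treatment). This vignette explains the
generative models of the simulator, the extraction and coefficient
conventions, the statistical machinery, and the design decisions taken
where more than one defensible convention exists.

## Why a simulator comes first

The group-comparison questions this pipeline answers (does a cytotype show
depressed quantum yield? elevated non-photochemical quenching?) are only
testable end-to-end if traces with *known* ground truth exist. The
`synthetic` module therefore generates complete studies — one light-curve
(LC), one Kautsky (KC) and one fast-transient (OJIP) trace per plant —
from per-cell true parameter values, and every downstream stage is
verified against those closed forms. The shipped preset
(`default_sim_params()`) mimics a qualitative pattern of interest (6x_35
with lower maximal yield; 4x and 6x_35 with higher steady-state NPQ; a
small NPQ increase under the long photoperiod). It is deliberately
synthetic: no group value was estimated from measured data, and within-
group variance is a free parameter (`noise_cv`) because no published
variance estimates exist to calibrate it against.

## Instrument protocols

The default protocols follow a FluorPen-class instrument: measuring light
0.09, saturating/super pulses 2400 and OJIP excitation
3000 µmol photons m⁻² s⁻¹.

* **KC** — after dark adaptation, one super pulse in darkness (F0, FM),
  then 60 s of actinic light at 300 µmol m⁻² s⁻¹ with five super pulses
  (first at 7 s, then every 12 s: 7, 19, 31, 43, 55 s), then 88 s of
  darkness with three pulses (first at 11 s, then every 26 s: 11, 37,
  63 s).
* **LC** — a dark super pulse, then saturating pulses at actinic steps of
  10, 20, 50, 100, 300, 500 µmol m⁻² s⁻¹.
* **OJIP** — a single continuous 3000 µmol m⁻² s⁻¹ pulse, sampled
  log-uniformly from 10 µs to 2 s.

Sampling grids: KC/LC run at 10 Hz between pulses and 1 kHz inside the
0.8 s pulse windows — enough to hold the pre-pulse `F(t)` median window
and the pulse maxima; OJIP uses 80 log-spaced points so that the 0.3 ms
sample needed by the initial-slope statistic M0 is resolved.

## Generative models

**OJIP.** A three-phase exponential rise
$F(t) = F_0 + F_V \sum_k w_k (1 - e^{-t/\tau_k})$, with weights $w_k \ge 0$
summing to one and strictly increasing time constants (defaults 0.9, 12,
200 ms, giving the J inflection near 2 ms and I near 30 ms). Setting
$F_V = F_0\,\varphi_{max}/(1-\varphi_{max})$ makes the asymptote satisfy
$(F_M - F_0)/F_M = \varphi_{max}$ exactly. No electron-transport ODE model
is attempted; the sum of exponentials is the simplest strictly monotone
form with the right inflection structure.

**Kautsky.** First-order kinetics for both quenching processes: under
actinic light NPQ rises toward `npq_ss` with time constant
$\tau_N = 10$ s, and in darkness relaxes with the same $\tau_N$ toward
`npq_ss * qi_frac` — the sustained, photoinhibitory floor. The quenched
maximum is $F_M'(t) = F_M / (1 + \mathrm{NPQ}(t))$ (Stern–Volmer). The
closed-center fraction $c(t)$ rises toward `closed_frac_ss` with
$\tau_c = 3$ s in light and decays to zero in darkness. Measuring-light
fluorescence interpolates $F(t) = F_0'(t) + (F_M'(t) - F_0'(t))\,c(t)$,
where $F_0'(t)$ is computed with the *same* estimator the analysis uses
(see below), so simulation and analysis agree by construction rather than
by numerical accident. During pulse windows the emitted signal is
$F_M'(t)$.

With the 60 s actinic phase and $\tau_N = 10$ s, the last light pulse at
55 s sees $1 - e^{-5.5} \approx 99.6\%$ of `npq_ss`, and the last dark
pulse at 63 s sees the relaxable component decayed by $e^{-6.3}$; the
"true" coefficient values recorded in the ground-truth table are the
targets (`npq_ss`, `npq_ss * qi_frac`), and the sub-percent kinetic
shortfalls are part of the documented 2 % end-to-end recovery budget.

**Light curve.** The steady-state response is the exponential saturating
curve $rETR(I) = rETR_{max}(1 - e^{-\alpha I / rETR_{max}})$; each step
emits a constant $(F(t), F_M')$ pair consistent with
$\phi(I) = rETR(I)/(f\,I)$, where $f$ is the photosystem partition factor.
The constraint $\alpha \le f\,\varphi_{max}$ guarantees
$\phi(I) \to \varphi_{max}$ as $I \to 0$. `fit_light_curve()` refits this
two-parameter model to recovered points; it exists to close the
simulation→analysis loop (noise-free recovery of `retr_max` to well below
1 %), not as a reported coefficient.

**Noise.** Multiplicative log-normal with unit mean and coefficient of
variation `noise_cv` (default 0.02), because fluorescence is strictly
positive — additive Gaussian noise can produce negative signal. One RNG
stream per (plant, protocol) is derived by stable string hashing of the
study seed and plant id, so per-plant traces are reproducible and
insensitive to generation order.

What the simulator does *not* emulate: instrument drift and detector
saturation, leaf optics and spectral effects, within-leaf heterogeneity,
day-to-day environmental variation, or any realistic correlation
structure between a plant's three traces. Passing recovery tests on
simulated data therefore demonstrates that the pipeline computes its
coefficients correctly, not that those coefficients are unbiased on any
real leaf.

## Landmark extraction conventions

* `F0`: median of dark measuring-light samples before the first pulse;
  `FM`, `FM'`, `FM''`: the *maximum* within each pulse window (saturation
  plateaus can be short; a mean would bias low).
* `F(t)`: median over the 0.5 s immediately before each pulse — robust to
  measuring-light noise; window configurable.
* `F0''`: the *minimum* measuring-light sample of the dark-recovery phase
  (the signal drifts downward as quenching relaxes, so a median would
  overestimate the minimum).
* OJIP landmarks are read by linear interpolation in log-time; `FP` is
  the trace maximum; `F300` (0.3 ms) is always extracted for M0.
* The O point defaults to 50 µs, the common JIP-test origin. Some
  instruments report O at 0.5 ms; that convention is available
  (`timepoints_ms`, config `o_point_ms`) but never silently assumed,
  because on a rising transient the two choices give different FO and
  hence different VJ and flux values.

## Coefficient conventions

All definitions are fixed to the standard PAM literature forms and
recorded in output metadata:
$\varphi_{max} = (F_M - F_0)/F_M$;
$\varphi_{PSII} = (F_M' - F(t))/F_M'$;
$rETR = f\,\varphi_{PSII}\,I$ with $f = 0.5$ by default (even
partition between photosystems; "relative" means no absorptance term);
$\mathrm{NPQ} = (F_M - F_M')/F_M'$;
$q_I = (F_M - F_M'')/F_M''$ at the *last* dark pulse (63 s of
relaxation); $q_E = \mathrm{NPQ} - q_I$, so the decomposition
$\mathrm{NPQ} = q_E + q_I$ holds exactly by construction;
$F_0' = F_0/(F_V/F_M + F_0/F_M')$;
$q_P = (F_M' - F(t))/(F_M' - F_0')$;
$q_L = q_P\,F_0'/F(t)$.

Steady-state quenching coefficients use the last actinic-phase pulse
(55 s) — the closest the 60 s induction comes to steady state; averaging
earlier pulses would mix induction kinetics into a steady-state quantity.
The pulse index is configurable.

**PQ.** A summary "photochemical quenching" coefficient is reported as
`PQ = 1 - qP` (the closed-center fraction, so that lower values mean more
open centers / higher efficiency). Since distinct conventions exist for
such a summary, the choice is exposed (`pq_convention`) and stamped into
the result metadata; no further biological interpretation is attached.

**Negative values.** Noisy traces can give $F_M' > F_M$ (negative NPQ) or
incomplete-relaxation patterns (negative $q_E$). These are retained with
classed warnings and tallied in the run manifest rather than clipped —
clipping at zero would bias group means upward.

**JIP-test.** From (FO, F300, FJ, FP):
$F_V = F_P - F_O$, $\varphi_{P0} = F_V/F_P$, $V_J = (F_J - F_O)/F_V$,
$\psi_0 = 1 - V_J$, $M_0 = 4(F_{300} - F_O)/F_V$ per ms, and the specific
fluxes $TR_0/RC = M_0/V_J$, $ABS/RC = (TR_0/RC)/\varphi_{P0}$,
$ET_0/RC = (TR_0/RC)\psi_0$, $DI_0/RC = ABS/RC - TR_0/RC$, and
$PI_{ABS} = \frac{\varphi_{P0} V_J}{M_0}
\frac{\varphi_{P0}}{1-\varphi_{P0}} \frac{\psi_0}{1-\psi_0}$.
All are ratios, hence scale-invariant, and $ABS/RC = TR_0/RC + DI_0/RC$
holds to machine precision by construction (kept as a regression
tripwire). Degenerate transients ($V_J \in \{0, 1\}$, no initial rise)
raise classed errors instead of dividing by zero. FI (30 ms) is extracted
and reported but enters no implemented formula.

## Group statistics

Each coefficient is compared across the eight cytotype × photoperiod
cells with a fixed-effects two-way ANOVA with interaction. Sums of
squares are **Type II** by default: the designs of interest are unbalanced
(3–11 plants per cell) and both main effects and the interaction are
reported; Type III is available via config. Degenerate inputs (empty
cells, zero residual df, zero residual variance) raise errors naming the
offending cell.

Post-hoc comparisons run by default on the eight *cell* means with the
pooled residual mean square — that is what per-box letters display;
factor-marginal comparisons are provided as an option. Whether a given
published figure used cells or marginals, or which SS type, is often
unstated; these defaults are declared, not inferred.

* **Tukey HSD** uses the Tukey–Kramer criterion for unequal cell sizes:
  $|m_i - m_j| > q_{1-\alpha;k,\nu}\sqrt{\mathrm{MSE}/2\,(1/n_i+1/n_j)}$.
* **Duncan's multiple range test** sorts the means and tests a span of
  $p$ ordered means at the protection level
  $\alpha_p = 1-(1-\alpha)^{p-1}$ with $q_{1-\alpha_p;p,\nu}$, stepping
  down with the classical blocking rule (no pair inside a span already
  found non-significant is declared significant). For $p = 2$,
  $\alpha_2 = \alpha$ and the test coincides with Tukey's; its critical
  values never exceed Tukey's, so Duncan rejects at least as often.
  Duncan yields decisions rather than exact p-values; results report the
  span and protection level instead of a p-value.
* The **studentized range distribution** needed by both is computed by
  Gauss–Legendre quadrature of its double-integral CDF (the chi scale
  factor integrated in probability scale, 160 nodes; the normal-range
  inner integral on [-9, 9], 100 nodes), with quantiles by root-finding
  and a per-(p, k, df) cache. Agreement with an independent
  implementation is at the 1e-5 level and the quantile↔CDF round-trip is
  tight to the 1e-10 root tolerance.
* The **compact letter display** uses the insert-and-absorb algorithm.
  Its output always satisfies the display contract — two cells share a
  letter iff they are not significantly different — which is checked
  programmatically on every output; minimal letter count is attempted by
  absorption but not guaranteed.

The default method mapping follows common practice for these panels:
Tukey for the quantum yields, Duncan for light-curve, quenching and
JIP-flux panels; both are available everywhere. No multiplicity
correction is applied *across* coefficients, and the output metadata says
so.

## Numerical and degenerate-input choices

* Trace I/O writes 17 significant digits so TSV round-trips are exact;
  readers validate monotone time, positive fluorescence and the column
  set, and always report the first offending line rather than coercing.
* Daily light integral: $DLI = I \cdot h \cdot 3600 \cdot 10^{-6}$
  mol m⁻² d⁻¹; at the growth irradiance of 250 µmol m⁻² s⁻¹ this gives
  9.0 (10 h) and 14.85, printed 14.8 (16.5 h).
* The light-curve fit uses `nls` with a `scaleOffset` so zero-residual
  (noise-free) data converge cleanly.
* Ties in log-time interpolation are impossible on the strictly
  increasing grids enforced at construction.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script are sized to run on one CPU in a
few minutes: recovery checks use one noise-free plant per cell (8
plants); the Duncan-vs-Tukey containment property uses 500 simulated
coefficient tables; the letter-display null and alternative rates use 200
replicates of 8 plants per cell each. These sizes put the Monte-Carlo
standard errors comfortably inside the bands being checked (about 1.5
percentage points for the 200-replicate rates).

## Known limitations

* The simulator's phenomenology (first-order NPQ, single closed-fraction
  pool, exponential light response) cannot generate data that violate the
  analysis' structural assumptions — it validates computation, not
  biology.
* `qE`/`qI` splitting by dark relaxation attributes everything unrelaxed
  at 63 s to photoinhibition; slowly-relaxing zeaxanthin-dependent
  quenching would be misattributed on real material.
* The Duncan letters inherit the test's known anticonservatism; they are
  provided because such panels are conventionally reported, with Tukey as
  the default for yields.
* No vendor binary formats are parsed; the TSV dialect is this package's
  own documented export format.
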