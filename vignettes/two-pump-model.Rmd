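---
title: "Modeling the mosquito two-pump drinking system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the mosquito two-pump drinking system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mozpump)
```

## The system and the model

Mosquitoes drink through two muscular pumps in the head — the small
cibarial pump (CP) fed directly by the food canal, and the larger
pharyngeal pump (PP) that passes fluid onward to the esophagus and gut.
X-ray video of live drinking reveals two distinct behaviors: a
*continuous* mode of rapid (~4 Hz), small-stroke, phase-offset
reciprocation, and an intermittent *burst* mode consisting of a single,
much larger stroke of both pumps, dominated by a massive expansion of the
pharyngeal pump.

`mozpump` implements a lumped-parameter model of this system. Each tube
segment (food canal, pharynx, esophagus) is a Hagen–Poiseuille impedance

$$\kappa(L, D) = \frac{128\,\mu L}{\pi D^4},$$

valid because the flow is strongly laminar (Re ≈ 0.1 at the fastest
reported canal velocities) and quasi-steady (Womersley number α < 0.1 in
every tube at the continuous-mode period — see
`dimensionless_report()`). Each pump is a prolate spheroid of fixed
semi-major axis $b = L_\beta/2$ and oscillating semi-minor axis
$a_\beta(t)$, with volume $V_\beta = \tfrac{4\pi}{3} a_\beta^2 b$. Mass
conservation in each pump,
$\dot V_\beta = Q_{\mathrm{in}} - Q_{\mathrm{out}}$, together with the
linear pressure–flow law $\Delta p_i = K_i Q_i$ in each tube, closes a
five-unknown linear system per instant
($Q_1, Q_2, Q_3, p_{CP}, p_{PP}$) with a closed-form solution.

Two check valves make the system piecewise linear: the pharyngeal valve
constricts a 20 µm section of the pharynx to 5 µm the instant the
pharynx flow reverses, and the esophageal valve multiplies the
esophageal impedance by $10^6$ under backflow — a finite stand-in for a
no-backflow condition that keeps every instant solve well posed. The
solver enumerates the four possible (sign $Q_2$, sign $Q_3$) valve
branches in a fixed, forward-first order and accepts the first branch
whose solution reproduces its assumed signs; zero flow counts as
forward. This is deterministic, exhaustive, and reports an error rather
than guessing if no branch is self-consistent (no such input has been
found for this network). If two branches were consistent at a crossing
instant, the forward-most would be taken — a reproducibility choice, not
a hysteresis model.

## Kinematics and parameters

The pump wall motion is prescribed, not solved. In the continuous mode

$$a_\beta(t) = \tfrac12 H_{\min}
  + \tfrac14\,(H_{\max,C} - H_{\min})\,
  \bigl\{1 - \cos[\omega_C (t - \tau_\beta)]\bigr\},$$

with period $T_C$ = 233.5 ms and pump delays $\tau_{CP}$ = 0,
$\tau_{PP}$ = 83.5 ms. The burst mode is one isolated $1-\cos$ hump per
pump within a 703 ms period (CP stroke 0.4–662 ms, PP stroke
153–646 ms), value- and slope-continuous at its edges. Volume rates are
closed-form derivatives — the flow solution is linear in $\dot V_\beta$,
so finite-difference noise would contaminate the narrow burst pressure
peaks.

All geometry and fluid parameters live in a single strict configuration
(`default_config()`, serialized in
`inst/extdata/paper_default.json`): canal 1560 × 25 µm, pharynx
200 × 25 µm, esophagus 100 × 50 µm, pump lengths 232/326 µm, resting
heights 38/44 µm, continuous maxima 50/50 µm, burst maxima 63/256 µm,
ρ = 1100 kg/m³, μ = 3.0 mPa·s, σ = 0.077 N/m, and all boundary
pressures atmospheric (zero gut backpressure). Unknown or missing fields
in a config file are errors — with ~25 parameters, silently ignored
typos are the main failure mode. Internally everything is SI; nL/s,
kPa, and nW appear only at I/O boundaries.

```{r headline}
cfg <- default_config()
tim <- default_timing()
sim_c <- simulate_mode("continuous", cfg, tim)
sim_b <- simulate_mode("burst", cfg, tim)
sim_c
sim_b
mode_comparison(mode_summary(sim_c), mode_summary(sim_b))
```

One period is simulated with no spin-up: the kinematics are periodic and
the quasi-steady system is memoryless, so the solution is periodic by
construction. The default grid is 2000 steps per period; halving or
doubling it changes the averaged flow and peak pressure drop by less
than 0.1% (asserted in the tests), comfortably inside the 2-significant-
figure resolution of the reference results. Time averages use the
trapezoidal rule on the closed periodic grid.

## Power accounting

The net power a pump delivers to the fluid is
$P_\beta = -(p_\beta - p_{\mathrm{hemo}})\,\dot V_\beta$, with the
hemolymph pressure a configurable boundary value (atmospheric by
default). Since muscle cannot absorb work back from the fluid, the
cycle-average input power rectifies each pump's power at zero before
averaging; on the default configuration rectification changes the
average by under 3%. The same total appears step by step as the summed
viscous dissipation $\sum_i Q_i \Delta p_i$ in the three tubes — an
identity the test suite enforces to $10^{-6}$ relative at every step.
The "effectiveness" of a mode is its average flow per unit average
power; defining it instead as flow per energy-per-cycle would rescale
both modes by their periods but barely moves the ratio, which stays
above 40 in favor of the continuous mode.

## Virtual knockouts

`simulate_knockout()` replaces one pump by a static tube of its length
and resting height, $\kappa(L_\beta, H_{\min})$. With the pharyngeal
pump removed the pharynx, knockout tube, and esophagus carry a single
series flow, so one sign selects both valve branches at once. Percentage
changes are reported against the two-pump baseline on identical grids.
On the defaults: cibarial-only continuous drinking loses 18% of average
flow and 14% of power while peak canal flow rises 12%; pharyngeal-only
burst drinking changes flow by under 2% and power by under 1% — the two
pumps dominate different modes.

## Capillarity threshold

If air enters the food canal, the meniscus resists being drawn up with a
Laplace pressure $\Delta p_m = 2\sigma/R$. The package's default
$R$ = 25 µm reproduces the reference threshold of 6.2 kPa; note the
convention tension here — the value printed alongside the source's text
equals $2\sigma/D_1$ even though the text defines $R = D_1/2$ (which
would give 12.3 kPa). $R$ is configurable; with the 6.2 kPa default only
the burst mode drives $p_{CP} - p_{\mathrm{atm}}$ below $-\Delta p_m$,
so only a burst can re-prime the canal.

## Known data inconsistencies carried, not hidden

* The published pump-volume table lists the pharyngeal burst maximum as
  7.96 nL, but the spheroid formula at the measured 256 µm height gives
  11.19 nL — and only the larger value is consistent with the 16 nL/s
  burst average flow. `volume_table()` uses the formula throughout; the
  7.96 nL cell is treated as a suspected transcription inconsistency and
  deliberately not reproduced.
* The same table's cibarial burst/continuous change ratio of 2.5 holds
  only for the two-decimal rounded volumes; the exact geometry gives
  2.39. Tests assert within the band the printed precision implies.
* The published continuous-mode timing summary is internally
  inconsistent (total cycle 319 ms and −44 ms to the next cycle imply a
  275 ms repeat, yet the printed frequency is 4.0 Hz). The
  measured-means trace recipe adopts the printed 4.0 Hz (250 ms repeat)
  with the printed stroke durations and offsets; its implied
  time-to-next-cycle is then −67 ms.

## Trace analysis and the synthetic generator

The kinematics pipeline starts from two-channel ROI-intensity series
(default 30 fps): a 3-point moving average (shrunken at the ends),
per-bout min–max normalization, extremum-based stroke detection with a
prominence filter (default 0.1 normalized units — chosen to sit well
above the smoothed noise at the emulated noise scale while passing all
genuine strokes), amplitude-based burst classification (default 3× the
median continuous amplitude, with an absolute fallback of half the
channel range when fewer than three events give no continuous context),
and a per-cycle timing table. Timing-table frequency is the reciprocal
of the interval between successive cibarial starts; per-specimen means
are taken before the grand mean ± SD when multiple specimens are
supplied. Bout boundaries are user-supplied or default to the whole
trace.

Two detection details go beyond the basic sketch and matter in
practice. First, a stroke boundary that falls in a rest plateau is
positionally arbitrary (the samples tie numerically), so boundaries
snap across near-ties — within 2% of the event amplitude — toward the
peak, landing on the plateau edge. Second, when bursts dwarf the
continuous oscillation, the surviving flanking minima of a burst can
lie far from it; the burst span used for masking is therefore re-found
by walking out from the peak to a 10%-of-amplitude threshold crossing.
Detection is then two-pass: bursts found on the bout-normalized trace
are masked, the remainder is re-normalized, and continuous strokes are
re-detected at full sensitivity.

The synthetic generator (`trace_recipe()`, `generate_trace()`) emulates
what the x-ray recordings measure: intensity as an affine image of pump
volume, plus linear drift and additive Gaussian noise (default SD 5% of
the continuous stroke amplitude — the real recordings' noise process is
uncharacterized, so this is a free parameter). It does **not** emulate
detector physics, motion blur, occlusion, ROI misregistration, or
non-Gaussian artifacts, so passing recovery tests demonstrate the
pipeline's correctness on the assumed signal model, not robustness to
every pathology of real video. Every generation requires an explicit
seed and is bit-reproducible.

```{r recovery}
g <- generate_trace(default_trace_recipe(pp_burst_volume_factor = 17),
                    seed = 1)
res <- analyze_trace(g$trace)
table(res$pp_events$mode)
subset(res$timing, variable %in% c("total_cycle_ms", "frequency_hz"))
```

Validation problem sizes were chosen to exercise the estimators without
waste: 20-cycle recordings, 50 seeded replicates for the stochastic
recovery properties, and 100 Hz sampling for the 2–12 Hz
frequency-recovery sweep — at 30 fps, cycles above roughly 8 Hz fall
under four samples per period and are unresolvable by any detector,
which is a property of the sampling, not of the pipeline.

## Limitations

The model is quasi-steady and lumped: no fluid inertia, no pressure
gradients inside a pump lumen, no elastic wall mechanics, no bubble or
free-surface dynamics inside the simulation (capillarity enters only as
a threshold), and Newtonian rheology only — blood feeding is outside its
scope. The resting pharyngeal height rests on a single specimen and is
treated as exact. Knockouts are pure parameter substitutions, with no
morphological re-optimization of the remaining pump. The power estimate
is a lower bound on metabolic cost: losses in the pumps and muscles are
not modeled.
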