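---
title: "The dynaclamp model: simulated I_K1 injection into a virtual iPSC-derived cardiomyocyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dynaclamp model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynaclamp)
```

## Why a virtual dynamic-clamp rig

Human iPSC-derived cardiomyocytes (iPSC-CMs) barely express the
inward-rectifier potassium current I_K1, so in isolation they rest
depolarised (0 to -15 mV) and fire short, triangular action potentials
with little Na+ channel availability.  A dynamic-clamp rig fixes this by
closing a loop around the cell: the amplifier measures the membrane
potential, a real-time computer evaluates an I_K1 channel model at that
potential, and the resulting current is injected back -- a hybrid of a
living cell and a simulated conductance, updated here at 20 kHz on up to
four parallel channels.

`dynaclamp` reproduces that system entirely in software.  The living
cell is replaced by a calibrated surrogate whose measurable properties
are anchored to automated-patch-clamp measurements of suspended
iPSC-CMs: capacitance 37 pF, peak Na+ current -5.4 nA at the -30 mV
step, peak L-type Ca2+ current -157 pA at the +10 mV step, activation
midpoints -46 mV (Na+) and -5.8 mV (Ca2+), a depolarised rest, and a
-180 pA holding current for a -94 mV diastolic potential.  Every stage
of the workflow -- voltage-clamp quality control, stimulus optimisation,
I_K1 engagement, conductance titration, L-type pharmacology -- can then
be exercised and tested at desk scale.

## The I_K1 model

The injected current follows the time-dependent Kir2.1 formulation of
the Ishihara model family: strong inward rectification arises from
voltage-dependent block of the pore by intracellular Mg2+ and spermine,
with spermine acting in two modes.  Writing $\Delta V = V - E_K$:

* **Mg2+ block** is equilibrated instantaneously.  Each channel carries
  three equivalent sites with opening/closing rates
  $a = 12\,e^{-0.025\,\Delta V}$ and
  $b = 0.28\,[\mathrm{Mg}^{2+}]_i\,e^{0.025\,\Delta V}$; only channels
  with all sites free conduct, giving a factor $(a/(a+b))^3$.
* **Mode-1 spermine block** (fast, low affinity) is also instantaneous,
  with $K_d(\Delta V) = 0.04\,e^{-\Delta V / 9.1}$ mmol/L.
* **Mode-2 spermine block** (slow, high affinity) is the single state
  variable $y$, the fraction of mode-2 channels free of spermine, with
  voltage-dependent rates on the seconds-to-tens-of-milliseconds scale
  (see `R/ik1-constants.R` for the full table).

The current density is
$$ I_{K1} = G_{K1}\,(K_o/4)^{0.4}\,(V - E_K)\;p_{Mg}(V)\,
   \bigl[\,0.9\,f_1(V) + 0.1\,y\,\bigr] \quad [\mathrm{pA/pF}], $$
with $G_{K1}$ in pS/pF defined at the experimental $K_o$ = 4 mmol/L so
that the user-facing density is not silently rescaled, and $E_K$ fixed
at -95 mV by convention for the simulated channels (a Nernst-derived
$E_K$ is available via `ik1_params(EK = NULL)`).  Because every block
factor is multiplicative, the current reverses exactly at $E_K$ for any
state -- the basis of the reversal test.

The structure of the model (three-site Mg2+ block, two spermine modes,
single slow gate, $\Delta V$-dependence, $K_o^{0.4}$ conductance
scaling, mode-1 fraction 0.9) follows the published formulation; the
numerical rate coefficients in the constants table are this package's
calibration, chosen once to reproduce the documented phenomenology:
reversal at $E_K$, an outward hump peaking ~17 mV above $E_K$, outward
current at -40 mV only ~5% of that peak (the model passes little
outward current at depolarised potentials, which is why engagement
needs a kick-start), inward current exceeding the hump for matched
displacements, and slow-gate relaxation times of tens to hundreds of
milliseconds.  All quantitative package-level checks are insensitive to
the exact coefficients, which is verified by the property tests.

Integration uses the closed-form exponential update
$y \leftarrow y_\infty + (y - y_\infty) e^{-\Delta t/\tau_y}$
(Rush--Larsen style), unconditionally stable at any step, with a
fine-step explicit-Euler oracle kept in the tests only.

```{r ik1-iv, fig.width = 5, fig.height = 3.5}
p <- ik1_params()
iv <- ik1_iv(p, seq(-120, 0, by = 0.5))
plot(iv$V, iv$I, type = "l", xlab = "V (mV)", ylab = "I_K1 (pA/pF)")
abline(h = 0, v = p$EK, lty = 3)
```

## The virtual cell

The surrogate is a single-compartment Hodgkin--Huxley membrane,
$C_m \dot V = -(I_{leak} + I_{Na} + I_{CaL} + I_{Kr} + I_{K1,endo}) +
I_{inj}$, with single-gate currents $I = g\,x_{act}\,x_{inact}(V - E)$
and fixed gate time constants.  Parameters that the measurements pin
down are calibrated at construction time; because each current is
linear in its conductance, one pilot run of the corresponding IV
protocol fixes the conductance exactly:

* `g_Na` so the isolated Na+ peak at the -30 mV step is -5.4 nA;
  activation (-46, 6) mV with $E_{Na}$ = +66.7 mV (Nernst of the
  140/10 mmol/L solutions) places the IV minimum at -30 mV.
* `g_CaL` so the isolated L-type peak at the +10 mV step is -157 pA;
  activation (-5.8, 10) mV with an ohmic surrogate reversal of +70 mV
  (not a GHK flux; sufficient for peak placement) puts the minimum at
  +10 mV.
* `g_leak` so that the complete cell -- including the small Na+/Ca2+
  window currents at -94 mV -- draws exactly -180 pA of holding current
  there; the leak reversal of -10 mV reproduces the depolarised rest.

Free kinetic choices (the measurements constrain none of these
directly) are: $\tau_m$ = 1 ms and $\tau_h$ = 7 ms, which land the
upstroke velocity in the tens of V/s measured for iPSC-CMs rather than
the hundreds typical of adult myocytes; a steep Na+ inactivation curve
(midpoint -85 mV, slope 1 mV) so that availability is negligible at the
depolarised rest (h < 0.01 above -15 mV, the reason suspended iPSC-CMs
cannot fire), saturated across the -92 to -95 mV hybrid diastolic
range, and free of a window current that would otherwise trap the final
repolarisation around -55 mV; and Ca2+ inactivation (-35, 5) mV with
$\tau_f$ = 150 ms, which shapes the plateau.

### The repolarising delayed-rectifier surrogate

With only leak (reversing at -10 mV), Na+, Ca2+ and injected I_K1, no
current in the surrogate is outward between -40 and -10 mV: after an
action potential the membrane would park at the depolarised rest
forever, because the I_K1 model -- correctly -- passes almost nothing
above -40 mV.  Real iPSC-CMs repolarise through a small rapid delayed
rectifier (hERG); at the tens of pA a 37 pF cell needs, such a current
is invisible next to the nA-scale step currents (hence "negligible" in
voltage-clamp surveys) yet decisive for the action potential.  The
surrogate therefore includes a minimal hERG-like term
$I_{Kr} = g_{Kr}\, x_r\, R(V)\,(V - E_K^{sol})$ with slow activation
($V_{1/2}$ = +10 mV, $\tau$ = 300 ms), instantaneous inward
rectification $R(V)$ falling off above -50 mV, and the Nernst reversal
of the recording solutions (-85.9 mV).  Its placement makes it vanish
in every calibrated quantity: at the depolarised rest its steady
current is a fraction of a pA (the rest range is preserved), and below
-80 mV the activation gate is closed (the -180 pA holding current and
the hybrid -94 mV rest are untouched).  It activates during the plateau
and, deactivating slowly, carries the descent from the plateau to about
-55 mV, where the injected I_K1 takes over the final repolarisation.
This is a deliberate minimal surrogate for the cell's residual
repolarisation reserve, not a hERG channel model.

## The clamp loop

Each tick (default 20 kHz): read the membrane potential, one tick old
under the default one-tick loop latency (latency 0 is reserved for
oracle comparisons); advance the slow I_K1 gate with the closed-form
update; compute the whole-cell current from the conductance density and
the set capacitance; hold that injection constant over the tick
(zero-order hold, the DAC behaviour of a real loop) while the cell
integrates in 4 substeps of explicit Euler for $V$ with exponential
gate updates.  Runtime commands (conductance density, set capacitance,
external K+, holding current) apply atomically at tick boundaries, as
with the digital remote control of the hardware.

Numerical accuracy is established two ways.  A dt-halving study shows
first-order self-convergence of the paced trajectory, and the full loop
at 20 kHz/latency 0 stays within 0.5 mV (maximum over a 2 s paced
episode) of a monolithic joint integration of cell + channel at 1 µs --
an oracle with no zero-order hold, no latency and a different
integration scheme.  The one-tick latency itself perturbs the
trajectory by < 0.3 mV.

Engagement follows the operational recipe: at the depolarised rest the
rectifier passes no current, so a -500 pA pulse first brings the
potential below -70 mV; if the conductance density is sufficient
(roughly > 35 pS/pF for fixture B's 0.15 nS leak; more for leakier
cells) the outward hump then holds the potential near $E_K$ after the
pulse is removed, otherwise the run is flagged.

## Protocols and analysis definitions

The three step protocols are single-sourced constructors: Na+ (hold
-100 mV; -80..+40 mV, 20 ms, 10 mV, 2 s intervals; 13 sweeps), Ca2+
(100 ms pre-pulse to -40 mV; -40..+40 mV, 200 ms, 5 s intervals; 9
sweeps), I_K1 (hold -40 mV; -120..+30 mV, 1200 ms; 16 sweeps).
Inter-sweep intervals are honoured as reset-to-holding periods of equal
simulated duration, preserving recovery from inactivation.  The clamp
is ideal (no series-resistance error), and sweeps carry the current
components alongside their sum -- the in-silico counterpart of the
ionic/pharmacological isolation used on the rig (Cs+ replacement,
pre-pulse inactivation); peak-current analyses of a single current use
the isolated component, since e.g. fixture A's 2.1 nS leak alone
contributes +42 pA at the +10 mV step.

Analysis definitions, declared rather than inferred: RMP is the mean
potential over the 100 ms before the stimulus; dV/dt_max is the maximal
forward-difference slope within 10 ms of pulse onset, excluding the
1 ms pulse itself so the injection artifact is not read as upstroke;
APD90 runs from the dV/dt_max instant (robust to stimulus width) to the
first return below RMP + 0.1 x amplitude; a plateau is flagged when the
potential stays above RMP + 0.5 x amplitude for at least 20% of the
APD90 after the first 5 ms.  "Reliably paced" means three consecutive
0.5 Hz pulses each eliciting an overshooting action potential (peak
> 0 mV); the stimulus optimiser returns the smallest amplitude on the
0.6--3 nA, 0.2 nA grid that achieves this.  Concentration-response
normalisation divides by the largest observed block, and the Hill fit
carries a free amplitude so that a one-site block family is recovered
exactly despite that normalisation.

## The cohort generator

`generate_cohort()` draws capacitance and peak Na+/Ca2+ currents from
normal distributions with the measured population means and SDs
recovered from the reported standard errors (SD = sem x sqrt(n): 31.7
pF, 4.0 nA, 101.8 pA).  Rejection bounds are placed symmetrically about
each mean -- capacitance in (5, 69) pF, currents in (2 x mean, 0) -- so
the sign constraints cannot bias the population means the table
reports.  Conductances are then calibrated per cell by linear scaling;
leak and delayed-rectifier conductances scale with capacitance
(constant density).  The generator emulates the marginal variability of
the measured population, not its correlation structure (currents and
capacitance are drawn independently), nor cell-quality covariates such
as seal resistance; passing tests therefore show that the pipeline
handles realistic parameter spread, not that it predicts any individual
cell.  The drug study screens generated cells with the same quality
control a rig operator applies (the channel engages and a stimulated
beat repolarises, in every drug condition), mirroring the fact that
reported drug cohorts are cells that completed the full protocol.

## Known limitations

* The surrogate has no calcium handling, no GHK fluxes and no
  rate-dependence; with $\tau_f$ = 150 ms its plateau is long (APD90
  ~800-900 ms on fixture B), so action-potential durations are
  qualitatively, not quantitatively, comparable to recorded cells.
  Absolute APD values from real cells are accordingly never asserted.
* Upstroke-velocity ordering across a conductance titration is a
  near-cancellation: deeper diastolic potentials make the fixed-charge
  stimulus land lower (faster takeoff), while more I_K1 opposes the
  foot of the upstroke.  With fixture B's parameters the opposition
  wins everywhere except the 200 to 400 pS/pF pair, where the measured
  upstroke rises by 0.2% -- a real property of the surrogate, exposed
  by the corresponding test.
* Constant-current holding at -94 mV is not a stable equilibrium for
  the low-leak fixture B (the Na+ window current has a steeper negative
  slope than its 0.15 nS leak); level 0 of a titration is therefore
  only meaningful on leakier cells such as fixture A, which is also the
  paper-typical case (-180 pA holding).
* Problem sizes used throughout (5 s runs at 20 kHz, 3-beat pacing,
  6-cell drug cohorts, 10^4-draw cohort summaries, 100-replicate fit
  Monte Carlo) were chosen as the smallest that make every quantity of
  interest measurable with comfortable margin; they are the package's
  test conditions, not recommendations for production studies.

## A worked run

```{r worked, eval = FALSE}
cell <- make_fixture("B")
ik1  <- ik1_params(gK1_density = 400)
eng  <- engage_ik1(cell, ik1)
tr   <- run_current_clamp(cell, ik1, duration = 5, state0 = eng$state)
mean(tr$V_mV[tr$time_s >= 4])        # about -93.3 mV
tab  <- run_titration(cell, gk1_titration_schedule(c(200, 400, 800)))
tab[, c("gk1_density", "RMP_mV", "APD90_ms", "dVdt_max_V_s")]
```
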