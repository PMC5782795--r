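# dynaclamp

An in-silico dynamic-clamp rig for iPSC-derived cardiomyocytes.

iPSC-derived cardiomyocytes (iPSC-CMs) lack the inward-rectifier
potassium current I_K1 and therefore rest depolarised (0 to −15 mV),
which inactivates their Na⁺ channels and cripples their action
potentials — a core obstacle to using them in safety-pharmacology
assays.  Dynamic clamp restores the missing conductance in real time: a
fixed-tick loop (20 kHz, up to four parallel channels) measures the
membrane potential V, evaluates a Kir2.1-type channel model at V, and
injects the resulting current back into the cell.  `dynaclamp`
reproduces that closed loop entirely in software, replacing the living
cell with a virtual iPSC-CM surrogate calibrated to
automated-patch-clamp measurements, so every stage of the workflow can
be run, tested and extended at the desk.

The injected current is a time-dependent inward-rectifier model with
instantaneous Mg²⁺ block, two modes of spermine block and a single slow
gate *y* (fraction of channels free of slow spermine block):

    I_K1 = G_K1 · (K_o/4)^0.4 · (V − E_K) · p_Mg(V) · [0.9·f₁(V) + 0.1·y],

in pA/pF with G_K1 in pS/pF and E_K = −95 mV; the slow gate relaxes as
dy/dt = (y∞(V) − y)/τ_y(V) and is integrated by closed-form exponential
(Rush–Larsen) updates, unconditionally stable at the loop tick.  The
virtual cell is a Hodgkin–Huxley surrogate (leak, fast Na⁺, L-type
Ca²⁺, a minimal repolarising delayed rectifier, optional endogenous
I_K1) whose conductances are calibrated so that the simulated step
protocols reproduce the measured phenotype: peak I_Na = −5.4 nA at the
−30 mV step, peak I_CaL = −157 pA at +10 mV, activation midpoints
−46 mV and −5.8 mV, 37 pF, and −180 pA of holding current for a −94 mV
diastolic potential.  The analysis layer provides peak-current I-V
curves, Ba²⁺-subtraction, Boltzmann activation fits, Hill
concentration-response fits and action-potential features (RMP,
amplitude, APD90, dV/dt_max, plateau detection).

See `vignettes/dynamic-clamp-model.Rmd` for the model description and
all numerical choices.

## Worked example

```r
library(dynaclamp)

cell <- make_fixture("B")                 # low-leak virtual iPSC-CM
ik1  <- ik1_params(gK1_density = 400)     # simulated I_K1, 400 pS/pF

ik1_reversal(ik1)                         # -95  (zero-current crossing, mV)
find_holding_current(make_fixture("A"), -94)
                                          # -179.996  (pA, the constant
                                          #  current that replaces I_K1 at -94 mV)

eng <- engage_ik1(cell, ik1)              # hyperpolarising kick-start
tr  <- run_current_clamp(cell, ik1, duration = 5, state0 = eng$state)
mean(tr$V_mV[tr$time_s >= 4])             # -93.32  (hybrid diastolic mV,
                                          #  no holding current)

tab <- run_titration(cell, gk1_titration_schedule(c(200, 400, 800, 1200, 2000)))
tab$APD90_ms                              # 915.8 894.8 876.0 865.8 853.8
                                          #  (shortens as G_K1 rises)

bc  <- nifedipine_block_curve(make_fixture("A"))
hill_fit(bc$conc_nM, bc$block_norm)$IC50  # 252  (nmol/L, recovered potency)
```

The titration shows the physiology the hybrid model restores: a stable
diastolic potential near E_K, overshooting action potentials with a
plateau, APD90 shortening and upstroke velocity falling as the
simulated conductance is raised, and restored sensitivity of the
plateau to L-type Ca²⁺ drugs (BayK-8644 prolongs, nifedipine shortens,
in that order on every cohort cell — `drug_ap_study()`).

A thin command-line wrapper over the same functions is installed at
`inst/scripts/dynaclamp` with subcommands `simulate-ap`, `iv`,
`titrate-gk1`, `drug-response`, `cohort` and `full-experiment`; see
`dynaclamp_cli()`.

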