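# Calibrated surrogate for the patched iPSC-CM: a passive leak plus fast
# Na+ and L-type Ca2+ currents with single-gate Hodgkin-Huxley kinetics
# (I = g * act * inact * (V - E)), a small repolarising delayed-rectifier
# surrogate, and an optional small endogenous I_K1 reusing the
# injected-channel model at low density.
#
# The delayed-rectifier surrogate carries the final descent of the action
# potential from the plateau into the range where the injected I_K1 takes
# over.  Without it no current in the surrogate is outward between the
# depolarised leak reversal (-10 mV) and -40 mV, so a paced cell would
# park near -10 mV forever -- whereas the cells this surrogate emulates
# repolarise fully.  Its conductance is small enough (~1 nS scale, tens of
# pA) that the voltage-step protocols read it as negligible, and its
# activation gate is fully closed below -80 mV, so it does not disturb
# the depolarised rest range, the holding-current calibration or the
# hybrid resting potential.  Its activation sits high (+10 mV) so that at
# the depolarised rest its steady current is a fraction of a pA; it
# activates during the plateau and its slow deactivation keeps it
# conducting through the descent until the injected I_K1 takes over
# below about -55 mV.

# Pharmacology of the L-type Ca2+ channel surrogate.  Nifedipine block is
# a one-site Hill curve at the potency measured on these cells; BayK-8644
# is modelled as saturable conductance scaling.
.drug_constants <- list(
  nifedipine_ic50 = 252,    # nmol/L
  nifedipine_h    = 1,
  bayk_amax       = 1.6,    # maximal conductance scale factor
  bayk_ec50       = 100     # nmol/L
)

#' Parameters of the virtual cardiomyocyte surrogate
#'
#' @param Cm membrane capacitance (pF).
#' @param g_leak,E_leak leak conductance (nS) and reversal (mV).  The
#'   depolarised leak reversal reproduces the resting potentials of
#'   suspended iPSC-CMs (0 to -15 mV).
#' @param g_Na,E_Na maximal Na+ conductance (nS) and reversal (mV).
#' @param V_half_m,k_m,tau_m Na+ activation: Boltzmann midpoint (mV),
#'   slope (mV) and time constant (ms).
#' @param V_half_h,k_h,tau_h Na+ inactivation (midpoint mV, slope mV,
#'   time constant ms).
#' @param g_CaL,E_Ca maximal L-type Ca2+ conductance (nS) and the ohmic
#'   surrogate reversal (mV).
#' @param V_half_d,k_d,tau_d Ca2+ activation parameters.
#' @param V_half_f,k_f,tau_f Ca2+ inactivation parameters.
#' @param g_Kr,E_Kr repolarising delayed-rectifier surrogate: conductance
#'   (nS) and reversal (mV, the K+ Nernst potential of the solutions).
#' @param V_half_xr,k_xr,tau_xr its activation gate (slow, hERG-like).
#' @param V_half_r,k_r its instantaneous inward-rectification factor
#'   (conduction falls off at depolarised potentials).
#' @param g_K1_endo endogenous inward-rectifier density (pS/pF), 0 for
#'   cells without measurable I_K1.
#' @param ba_block fraction of the endogenous I_K1 blocked by 10 umol/L
#'   Ba2+.
#' @param id optional fixture label carried into traces and reports.
#' @return an object of class `cell_params`.
#' @export
cell_params <- function(Cm = 37,
                        g_leak = 2, E_leak = -10,
                        g_Na = 60, E_Na = 66.7,
                        V_half_m = -46, k_m = 6, tau_m = 1,
                        V_half_h = -85, k_h = 1, tau_h = 7,
                        g_CaL = 4, E_Ca = 70,
                        V_half_d = -5.8, k_d = 10, tau_d = 2,
                        V_half_f = -35, k_f = 5, tau_f = 150,
                        g_Kr = 3, E_Kr = -85.9,
                        V_half_xr = 10, k_xr = 6, tau_xr = 300,
                        V_half_r = -50, k_r = 18,
                        g_K1_endo = 0, ba_block = 1,
                        id = NULL) {
  p <- list(Cm = Cm, g_leak = g_leak, E_leak = E_leak,
            g_Na = g_Na, E_Na = E_Na,
            V_half_m = V_half_m, k_m = k_m, tau_m = tau_m,
            V_half_h = V_half_h, k_h = k_h, tau_h = tau_h,
            g_CaL = g_CaL, E_Ca = E_Ca,
            V_half_d = V_half_d, k_d = k_d, tau_d = tau_d,
            V_half_f = V_half_f, k_f = k_f, tau_f = tau_f,
            g_Kr = g_Kr, E_Kr = E_Kr,
            V_half_xr = V_half_xr, k_xr = k_xr, tau_xr = tau_xr,
            V_half_r = V_half_r, k_r = k_r,
            g_K1_endo = g_K1_endo, ba_block = ba_block,
            id = id)
  validate_cell_params(p)
  structure(p, class = "cell_params")
}

validate_cell_params <- function(p) {
  stopifnot(p$Cm > 0,
            p$g_leak >= 0, p$g_Na >= 0, p$g_CaL >= 0, p$g_Kr >= 0,
            p$g_K1_endo >= 0,
            p$k_m != 0, p$k_h != 0, p$k_d != 0, p$k_f != 0, p$k_xr != 0,
            p$k_r != 0,
            p$tau_m > 0, p$tau_h > 0, p$tau_d > 0, p$tau_f > 0, p$tau_xr > 0,
            p$ba_block >= 0, p$ba_block <= 1)
  invisible(p)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Virtual iPSC-CM surrogate",
      if (!is.null(x$id)) paste0("(fixture ", x$id, ")"), "\n")
  cat(sprintf("  Cm = %.1f pF, leak %.4g nS -> %.1f mV\n",
              x$Cm, x$g_leak, x$E_leak))
  cat(sprintf("  g_Na = %.4g nS (act %.1f/%.1f mV), g_CaL = %.4g nS (act %.1f/%.1f mV)\n",
              x$g_Na, x$V_half_m, x$k_m, x$g_CaL, x$V_half_d, x$k_d))
  if (x$g_K1_endo > 0) {
    cat(sprintf("  endogenous I_K1: %.1f pS/pF (Ba2+ block %.0f%%)\n",
                x$g_K1_endo, 100 * x$ba_block))
  }
  invisible(x)
}

# Gate steady states.  Activation gates rise with depolarisation,
# inactivation gates fall; slope factors are stored positive.
gate_inf <- function(V, p) {
  list(m = 1 / (1 + exp(-(V - p$V_half_m) / p$k_m)),
       h = 1 / (1 + exp((V - p$V_half_h) / p$k_h)),
       d = 1 / (1 + exp(-(V - p$V_half_d) / p$k_d)),
       f = 1 / (1 + exp((V - p$V_half_f) / p$k_f)),
       xr = 1 / (1 + exp(-(V - p$V_half_xr) / p$k_xr)))
}

# Instantaneous rectification of the delayed-rectifier surrogate.
kr_rect <- function(V, p) 1 / (1 + exp((V - p$V_half_r) / p$k_r))

# Parameters of the endogenous inward-rectifier component (if any),
# optionally under 10 umol/L Ba2+.
endo_ik1_params <- function(p, ba = FALSE) {
  dens <- p$g_K1_endo * if (ba) 1 - p$ba_block else 1
  ik1_params(gK1_density = dens)
}

# Membrane currents (pA) at potential V with the given gate values.
cell_currents <- function(V, gates, p, ba = FALSE) {
  I_leak <- p$g_leak * (V - p$E_leak)
  I_Na   <- p$g_Na * gates$m * gates$h * (V - p$E_Na)
  I_CaL  <- p$g_CaL * gates$d * gates$f * (V - p$E_Ca)
  I_Kr   <- p$g_Kr * gates$xr * kr_rect(V, p) * (V - p$E_Kr)
  I_K1e  <- if (p$g_K1_endo > 0) {
    ik1_cell_current(
      ik1_density_current(V, gates$y_endo, endo_ik1_params(p, ba)), p$Cm)
  } else 0
  list(I_leak = I_leak, I_Na = I_Na, I_CaL = I_CaL, I_Kr = I_Kr,
       I_K1_endo = I_K1e,
       I_total = I_leak + I_Na + I_CaL + I_Kr + I_K1e)
}

#' Initialise the cell state
#'
#' Gates are set to their steady-state values at `V`; the endogenous
#' inward-rectifier gate (if present) likewise.
#'
#' @param V membrane potential (mV).
#' @param params a [cell_params()] object.
#' @return an object of class `cell_state`.
#' @export
cell_init_state <- function(V, params) {
  g <- gate_inf(V, params)
  y <- if (params$g_K1_endo > 0) {
    ik1_init_state(V, endo_ik1_params(params))$y
  } else 1
  structure(list(V = V, m = g$m, h = g$h, d = g$d, f = g$f, xr = g$xr,
                 y_endo = y),
            class = "cell_state")
}

#' Advance the cell by one time step (reference implementation)
#'
#' Gates are updated by closed-form exponential relaxation toward their
#' steady states, then the membrane potential by an explicit Euler step of
#' Cm dV/dt = -(I_leak + I_Na + I_CaL + I_K1,endo) + injected.  This pure-R
#' step is the reference against which the compiled engine is checked; the
#' clamp loop itself runs the compiled version.
#'
#' @param state a [cell_init_state()] object.
#' @param injected injected current (pA), constant over the step.
#' @param dt step duration (s), positive.
#' @param params a [cell_params()] object.
#' @param ba simulate 10 umol/L Ba2+ (blocks the endogenous I_K1 only)?
#' @return the updated `cell_state`.
#' @export
cell_step <- function(state, injected, dt, params, ba = FALSE) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  p <- params
  dtm <- dt * 1e3                       # gate time constants are in ms
  gi <- gate_inf(state$V, p)
  st <- state
  st$m <- gi$m + (state$m - gi$m) * exp(-dtm / p$tau_m)
  st$h <- gi$h + (state$h - gi$h) * exp(-dtm / p$tau_h)
  st$d <- gi$d + (state$d - gi$d) * exp(-dtm / p$tau_d)
  st$f <- gi$f + (state$f - gi$f) * exp(-dtm / p$tau_f)
  st$xr <- gi$xr + (state$xr - gi$xr) * exp(-dtm / p$tau_xr)
  if (p$g_K1_endo > 0) {
    ek <- endo_ik1_params(p, ba)
    gg <- ik1_gating(state$V, ek)
    st$y_endo <- gg$y_inf + (state$y_endo - gg$y_inf) * exp(-dt / gg$tau_y)
  }
  cur <- cell_currents(state$V, st, p, ba)
  st$V <- state$V + dt * 1e3 * (-cur$I_total + injected) / p$Cm
  st
}

#' Reference cell fixtures calibrated to the measured iPSC-CM phenotype
#'
#' Three virtual cells anchored to automated-patch-clamp measurements of
#' suspended iPSC-CMs:
#'
#' * `"A"` -- the workhorse: Cm = 37 pF, depolarised rest near -10 mV,
#'   Na+ conductance calibrated so the peak current at the -30 mV step of
#'   the Na I-V protocol is -5.4 nA, Ca2+ conductance calibrated so the
#'   peak at the +10 mV step of the Ca I-V protocol is -157 pA, and leak
#'   conductance calibrated so that a constant -180 pA holds the cell at
#'   -94 mV.  No endogenous I_K1.
#' * `"B"` -- as A but with a small leak (0.15 nS) such that coupling to
#'   the simulated I_K1 at 400 pS/pF rests within 1 mV of -94 mV without
#'   any holding current.
#' * `"C"` -- as A plus a small, weakly rectifying endogenous I_K1
#'   (20 pS/pF) that is fully blocked by 10 umol/L Ba2+.
#'
#' Calibration is performed at construction time by running the simulated
#' voltage-clamp protocols (currents are linear in their conductances, so
#' a single pilot run fixes each conductance exactly).
#'
#' @param id fixture identifier, one of `"A"`, `"B"`, `"C"`.
#' @return a [cell_params()] object.
#' @export
make_fixture <- function(id = c("A", "B", "C")) {
  id <- match.arg(id)
  base <- fixture_a_cached()
  out <- switch(id,
    A = base,
    B = { b <- base; b$g_leak <- 0.15; b },
    C = { c0 <- base; c0$g_K1_endo <- 20; c0$ba_block <- 1; c0 })
  out$id <- id
  validate_cell_params(out)
  structure(out, class = "cell_params")
}

# Fixture A is used everywhere; calibrate once per session.
fixture_a_cached <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- calibrate_fixture_a()
    cached
  }
})

# Peak-current calibration.  Pilot conductances of 1 nS give the peak
# current per nS for the isolated component; target peaks then fix the
# conductances (currents are exactly linear in g).  The leak is set last
# so that the full cell, including the small Na+/Ca2+ window currents at
# -94 mV, draws exactly -180 pA of holding current there.
calibrate_fixture_a <- function() {
  p <- cell_params(g_Na = 1, g_CaL = 1, g_leak = 0, id = "A")
  na <- run_voltage_clamp(p, protocol_na_iv())
  pk_na <- peak_currents(na, current = "I_Na_pA")
  p$g_Na <- -5400 / pk_na$I[pk_na$V == -30]
  ca <- run_voltage_clamp(p, protocol_ca_iv())
  pk_ca <- peak_currents(ca, current = "I_CaL_pA")
  p$g_CaL <- -157 / pk_ca$I[pk_ca$V == 10]
  gi <- gate_inf(-94, p)
  window <- p$g_Na * gi$m * gi$h * (-94 - p$E_Na) +
    p$g_CaL * gi$d * gi$f * (-94 - p$E_Ca) +
    p$g_Kr * gi$xr * kr_rect(-94, p) * (-94 - p$E_Kr)
  p$g_leak <- (-180 - window) / (-94 - p$E_leak)
  validate_cell_params(p)
  structure(p, class = "cell_params")
}

#' Constant holding current that maintains a target potential
#'
#' Bisection on a constant injected current: each candidate is applied for
#' 2 s of simulated time from the cell's unclamped rest and the final
#' potential compared with the target, until the settled potential is
#' within 0.1 mV.
#'
#' @param params a [cell_params()] object.
#' @param target_V target membrane potential (mV).
#' @param bracket current search interval (pA).
#' @param settle_s settling time per evaluation (s).
#' @return holding current in pA.
#' @export
find_holding_current <- function(params, target_V,
                                 bracket = c(-5000, 5000), settle_s = 2) {
  settle_v <- function(I) {
    settle_cell(params, injected = I, duration = settle_s)$V
  }
  lo <- bracket[1]; hi <- bracket[2]
  # settled V is monotone increasing in the injected current
  if (settle_v(lo) > target_V || settle_v(hi) < target_V) {
    stop("target potential not bracketed by currents in the search interval")
  }
  while (hi - lo > 0.05) {
    mid <- (lo + hi) / 2
    if (settle_v(mid) < target_V) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  if (abs(settle_v(mid) - target_V) > 0.1) {
    warning("settled potential differs from target by more than 0.1 mV",
            call. = FALSE)
  }
  mid
}

#' Apply an L-type Ca2+ channel drug to a cell
#'
#' Nifedipine scales the Ca2+ conductance by `1 / (1 + (conc/IC50)^h)`
#' (IC50 252 nmol/L, h = 1, the potency calibrated on these cells);
#' BayK-8644 scales it by `1 + (A_max - 1) * conc / (conc + EC50)` with
#' A_max = 1.6 and EC50 = 100 nmol/L.  Repeated application composes
#' multiplicatively; all other parameters are untouched.
#'
#' @param params a [cell_params()] object.
#' @param drug `"nifedipine"` or `"bayk8644"`.
#' @param conc concentration in nmol/L (non-negative).
#' @return the modified `cell_params`.
#' @export
apply_drug <- function(params, drug = c("nifedipine", "bayk8644"), conc) {
  drug <- match.arg(drug)
  if (!is.numeric(conc) || conc < 0) stop("concentration must be >= 0")
  k <- .drug_constants
  fac <- switch(drug,
    nifedipine = 1 / (1 + (conc / k$nifedipine_ic50)^k$nifedipine_h),
    bayk8644   = 1 + (k$bayk_amax - 1) * conc / (conc + k$bayk_ec50))
  params$g_CaL <- params$g_CaL * fac
  params
}

#' Apply 10 umol/L Ba2+ to a cell
#'
#' Blocks the `ba_block` fraction of the endogenous inward-rectifier
#' conductance; the injected (simulated) I_K1 is unaffected, as on the
#' rig, where Ba2+ in the bath cannot reach a virtual channel.
#'
#' @param params a [cell_params()] object.
#' @return the modified `cell_params`.
#' @export
apply_barium <- function(params) {
  params$g_K1_endo <- params$g_K1_endo * (1 - params$ba_block)
  params
}

# Population statistics used by the cohort generator: mean, s.e.m. and n
# as measured on suspended iPSC-CMs (capacitance pF, peak Na+ current nA
# at the -30 mV step, peak L-type Ca2+ current pA at the +10 mV step).
.cohort_constants <- list(
  Cm  = list(mean = 37,   sem = 6,   n = 28),
  INa = list(mean = -5.4, sem = 1.5, n = 7),
  ICa = list(mean = -157, sem = 24,  n = 18)
)

#' Generate a cohort of virtual cells with population variability
#'
#' Samples membrane capacitance and peak Na+/Ca2+ currents from normal
#' distributions whose means are the measured population means and whose
#' SDs are recovered from the reported s.e.m. values (SD = s.e.m. * sqrt(n)).
#' Samples are rejected outside physiological bounds placed symmetrically
#' about each mean (capacitance in (5, 69) pF; currents in (2*mean, 0)),
#' which enforces the sign constraints without biasing the means.
#' Conductances are then calibrated per cell by linear scaling from
#' fixture A; leak conductance scales with capacitance (constant leak
#' density).
#'
#' @param n number of cells (>= 1).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param base template [cell_params()] providing everything the
#'   population table does not constrain.  The default (fixture A) gives
#'   cells that need a holding current, like the average recorded cell;
#'   use fixture B for a cohort of cells whose seal quality admits a
#'   hybrid resting potential near E_K.
#' @return list of [cell_params()] objects.
#' @export
generate_cohort <- function(n, seed = 1, base = make_fixture("A")) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  k <- .cohort_constants
  rtrunc <- function(n, mean, sd, lower, upper) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- stats::rnorm(2 * (n - length(out)) + 8, mean, sd)
      out <- c(out, x[x > lower & x < upper])
    }
    out[seq_len(n)]
  }
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  cm  <- rtrunc(n, k$Cm$mean, k$Cm$sem * sqrt(k$Cm$n),
                5, 2 * k$Cm$mean - 5)
  ina <- rtrunc(n, k$INa$mean, k$INa$sem * sqrt(k$INa$n),
                2 * k$INa$mean, 0)
  ica <- rtrunc(n, k$ICa$mean, k$ICa$sem * sqrt(k$ICa$n),
                2 * k$ICa$mean, 0)
  lapply(seq_len(n), function(i) {
    p <- base
    p$Cm <- cm[i]
    p$g_Na <- base$g_Na * ina[i] / k$INa$mean
    p$g_CaL <- base$g_CaL * ica[i] / k$ICa$mean
    p$g_leak <- base$g_leak * cm[i] / base$Cm
    p$g_Kr <- base$g_Kr * cm[i] / base$Cm
    p$id <- sprintf("cohort-%s-%03d",
                    if (is.null(base$id)) "X" else base$id, i)
    structure(p, class = "cell_params")
  })
}

#' Tabulate a cohort as a data frame
#'
#' One row per cell, columns the [cell_params()] fields, suitable for CSV
#' export.
#'
#' @param cohort list of `cell_params` from [generate_cohort()].
#' @return a data.frame.
#' @export
cohort_table <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    d <- p[setdiff(names(p), "id")]
    cbind(data.frame(id = if (is.null(p$id)) NA_character_ else p$id),
          as.data.frame(d))
  }))
}
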