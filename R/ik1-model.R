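#' Parameters of the simulated inward-rectifier current
#'
#' Builds the parameter set of the time-dependent I_K1 model that the
#' dynamic-clamp loop injects into the virtual cell: a conductance density,
#' the K+ reversal potential, the intracellular blockers (Mg2+ and
#' spermine) responsible for inward rectification, and the split between
#' the two spermine-block modes.
#'
#' The reversal potential defaults to -95 mV, set explicitly rather than
#' computed from the solutions, matching the convention that the simulated
#' channels use a fixed E_K; pass `EK = NULL` to derive it from the Nernst
#' equation at the given K+ concentrations and temperature.
#'
#' @param gK1_density conductance density in pS/pF.  Values used on real
#'   cells span roughly 200--2000 pS/pF; densities outside that range
#'   trigger a warning (not an error) when `warn_range` is `TRUE`.
#' @param EK K+ reversal potential (mV), or `NULL` for the Nernst value.
#' @param Ko,Ki extracellular / intracellular K+ (mmol/L).
#' @param temperature bath temperature (degrees C); only used for the
#'   Nernst computation.
#' @param Mg_i intracellular free Mg2+ (mmol/L).
#' @param SPM_i intracellular free spermine (umol/L).
#' @param mode1_fraction fraction of current carried by the fast
#'   (instantaneous) spermine-block mode, in [0, 1].  The remainder is
#'   gated by the slow spermine gate.
#' @param rate_constants named list of block/unblock coefficients; the
#'   package default is the single documented constants table.
#' @param warn_range emit the soft out-of-range warning on
#'   `gK1_density`?
#' @return an object of class `ik1_params`.
#' @examples
#' p <- ik1_params()
#' ik1_steady_state(p$EK, p)   # zero at the reversal potential
#' @export
ik1_params <- function(gK1_density = 400, EK = -95, Ko = 4, Ki = 120,
                       temperature = 20, Mg_i = 1.0, SPM_i = 5,
                       mode1_fraction = 0.9,
                       rate_constants = .ik1_constants,
                       warn_range = FALSE) {
  stopifnot(is.numeric(gK1_density), length(gK1_density) == 1,
            gK1_density >= 0, Ko > 0, Ki > 0, Mg_i >= 0, SPM_i >= 0,
            mode1_fraction >= 0, mode1_fraction <= 1)
  if (is.null(EK)) {
    EK <- rtf_mv(temperature) * log(Ko / Ki)
  }
  if (warn_range && gK1_density > 0 &&
      (gK1_density < 200 || gK1_density > 2000)) {
    warning("gK1_density ", gK1_density,
            " pS/pF is outside the 200-2000 pS/pF range used on real cells",
            call. = FALSE)
  }
  structure(list(gK1_density = gK1_density, EK = EK, Ko = Ko, Ki = Ki,
                 temperature = temperature, Mg_i = Mg_i, SPM_i = SPM_i,
                 mode1_fraction = mode1_fraction,
                 rate_constants = rate_constants),
            class = "ik1_params")
}

#' @export
print.ik1_params <- function(x, ...) {
  cat("Simulated I_K1 parameters\n")
  cat(sprintf("  gK1_density: %g pS/pF   EK: %.2f mV   Ko: %g mmol/L\n",
              x$gK1_density, x$EK, x$Ko))
  cat(sprintf("  [Mg2+]i: %g mmol/L   [SPM]i: %g umol/L   mode-1 fraction: %g\n",
              x$Mg_i, x$SPM_i, x$mode1_fraction))
  invisible(x)
}

# Instantaneous block factors and slow-gate kinetics, vectorised over V.
# Returns p_mg (conducting fraction under Mg2+ block), f1 (conducting
# fraction under mode-1 spermine block), y_inf and tau_y (s).
ik1_gating <- function(V, params) {
  k  <- params$rate_constants
  dv <- V - params$EK
  a_mg <- k$mg_alpha * exp(k$mg_alpha_slope * dv)
  b_mg <- k$mg_beta * params$Mg_i * exp(k$mg_beta_slope * dv)
  p_mg <- (a_mg / (a_mg + b_mg))^k$mg_sites
  kd1  <- k$spm1_kd0 * exp(-dv * k$spm1_kd_slope)
  f1   <- kd1 / (kd1 + params$SPM_i * 1e-3)   # SPM umol/L -> mmol/L
  u    <- dv + k$spm2_mg_shift * params$Mg_i
  a_y  <- k$spm2_alpha * exp(-k$spm2_alpha_slope * u) /
    (1 + 0.01 * exp(k$spm2_alpha_sat * u))
  b_y  <- k$spm2_beta * params$SPM_i * exp(k$spm2_beta_slope * u) /
    (1 + 0.01 * exp(k$spm2_beta_sat * u))
  list(p_mg = p_mg, f1 = f1,
       y_inf = a_y / (a_y + b_y), tau_y = 1 / (a_y + b_y))
}

# Current density (pA/pF) at potential V with slow gate at y.
# pS/pF * mV = 1e-3 pA/pF, hence the unit factor.
ik1_density_current <- function(V, y, params) {
  g <- ik1_gating(V, params)
  k <- params$rate_constants
  scale <- (params$Ko / k$ko_ref)^k$ko_exponent
  params$gK1_density * 1e-3 * scale * (V - params$EK) * g$p_mg *
    (params$mode1_fraction * g$f1 + (1 - params$mode1_fraction) * y)
}

#' Initialise the slow spermine gate at its steady state
#'
#' @param V membrane potential (mV).
#' @param params an [ik1_params()] object.
#' @return an object of class `ik1_state` with field `y`, the fraction of
#'   mode-2 channels free of slow spermine block.
#' @export
ik1_init_state <- function(V, params) {
  stopifnot(inherits(params, "ik1_params"), is.finite(V))
  structure(list(y = ik1_gating(V, params)$y_inf), class = "ik1_state")
}

#' Steady-state I_K1 current density
#'
#' Evaluates the model with the slow gate at its steady-state value and all
#' instantaneous block factors at the given potential.  Inward current is
#' negative, outward positive.
#'
#' @inheritParams ik1_init_state
#' @return current density in pA/pF (vectorised over `V`).
#' @export
ik1_steady_state <- function(V, params) {
  stopifnot(inherits(params, "ik1_params"))
  ik1_density_current(V, ik1_gating(V, params)$y_inf, params)
}

#' Advance the slow gate one step and return the current
#'
#' The gate relaxes exponentially toward its voltage-dependent steady
#' state over `dt` (closed-form update, unconditionally stable for any
#' step size); the returned current density uses the updated gate.
#'
#' @param state an [ik1_init_state()] object.
#' @param V membrane potential (mV) held over the step.
#' @param dt step duration (s), must be positive.
#' @param params an [ik1_params()] object.
#' @return list with `state` (updated `ik1_state`) and `I` (pA/pF).
#' @export
ik1_step <- function(state, V, dt, params) {
  stopifnot(inherits(state, "ik1_state"), inherits(params, "ik1_params"))
  if (!is.numeric(dt) || dt <= 0) stop("dt must be positive")
  g <- ik1_gating(V, params)
  y <- g$y_inf + (state$y - g$y_inf) * exp(-dt / g$tau_y)
  y <- min(max(y, 0), 1)
  list(state = structure(list(y = y), class = "ik1_state"),
       I = ik1_density_current(V, y, params))
}

#' Steady-state current-voltage relation of the simulated I_K1
#'
#' @param params an [ik1_params()] object.
#' @param V_grid strictly increasing voltage grid (mV).
#' @return an [iv_curve()] with current density in pA/pF.
#' @export
ik1_iv <- function(params, V_grid) {
  stopifnot(inherits(params, "ik1_params"))
  if (length(V_grid) < 1) stop("empty voltage grid")
  if (is.unsorted(V_grid, strictly = TRUE)) {
    stop("voltage grid must be strictly increasing")
  }
  iv_curve(V_grid, ik1_steady_state(V_grid, params),
           units = "pA/pF", label = "I_K1 steady state")
}

#' Convert a current density to a whole-cell current
#'
#' @param density current density (pA/pF).
#' @param Cm membrane capacitance (pF), must be positive.
#' @return whole-cell current in pA.
#' @export
ik1_cell_current <- function(density, Cm) {
  if (!is.numeric(Cm) || Cm <= 0) stop("Cm must be positive")
  density * Cm
}

#' Locate the zero crossing of the steady-state I_K1 relation
#'
#' Scans a fine voltage grid for the unique sign change of the
#' steady-state current and refines it by bisection.  With multiplicative
#' block factors the crossing sits exactly at the reversal potential.
#'
#' @param params an [ik1_params()] object.
#' @param lower,upper search interval (mV).
#' @param grid_step scan resolution (mV).
#' @return the crossing voltage (mV).
#' @export
ik1_reversal <- function(params, lower = -120, upper = 0, grid_step = 0.01) {
  v <- seq(lower, upper, by = grid_step)
  i <- ik1_steady_state(v, params)
  s <- which(i[-length(i)] < 0 & i[-1] >= 0)
  if (length(s) != 1) stop("expected exactly one sign change on the grid")
  if (i[s + 1] == 0) return(v[s + 1])
  stats::uniroot(function(x) ik1_steady_state(x, params),
                 c(v[s], v[s + 1]), tol = 1e-10)$root
}
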