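# Ideal voltage clamp.  With the command potential piecewise constant and
# every gate relaxing exponentially with a fixed time constant, the gate
# trajectories have closed forms within each segment, so sweeps are
# computed exactly at the sample times (no integration error).  Series
# resistance is not simulated.

# Advance all gates over a constant-V segment of dur_ms; returns end state.
vc_advance <- function(state, V, dur_ms, p, ba = FALSE) {
  gi <- gate_inf(V, p)
  st <- state
  st$m <- gi$m + (state$m - gi$m) * exp(-dur_ms / p$tau_m)
  st$h <- gi$h + (state$h - gi$h) * exp(-dur_ms / p$tau_h)
  st$d <- gi$d + (state$d - gi$d) * exp(-dur_ms / p$tau_d)
  st$f <- gi$f + (state$f - gi$f) * exp(-dur_ms / p$tau_f)
  st$xr <- gi$xr + (state$xr - gi$xr) * exp(-dur_ms / p$tau_xr)
  if (p$g_K1_endo > 0) {
    ek <- endo_ik1_params(p, ba)
    gg <- ik1_gating(V, ek)
    st$y_endo <- gg$y_inf + (state$y_endo - gg$y_inf) *
      exp(-dur_ms * 1e-3 / gg$tau_y)
  }
  st$V <- V
  st
}

# Sample membrane currents over a constant-V segment at times tms (ms,
# measured from segment onset, may include 0).  Returns the current table
# and the segment end state.
vc_sample <- function(state, V, tms, dur_ms, p, ba = FALSE) {
  gi <- gate_inf(V, p)
  m <- gi$m + (state$m - gi$m) * exp(-tms / p$tau_m)
  h <- gi$h + (state$h - gi$h) * exp(-tms / p$tau_h)
  d <- gi$d + (state$d - gi$d) * exp(-tms / p$tau_d)
  f <- gi$f + (state$f - gi$f) * exp(-tms / p$tau_f)
  xr <- gi$xr + (state$xr - gi$xr) * exp(-tms / p$tau_xr)
  I_leak <- rep(p$g_leak * (V - p$E_leak), length(tms))
  I_Na <- p$g_Na * m * h * (V - p$E_Na)
  I_CaL <- p$g_CaL * d * f * (V - p$E_Ca)
  I_Kr <- p$g_Kr * xr * kr_rect(V, p) * (V - p$E_Kr)
  if (p$g_K1_endo > 0) {
    ek <- endo_ik1_params(p, ba)
    gg <- ik1_gating(V, ek)
    y <- gg$y_inf + (state$y_endo - gg$y_inf) * exp(-tms * 1e-3 / gg$tau_y)
    I_K1e <- ik1_cell_current(ik1_density_current(V, y, ek), p$Cm)
  } else {
    I_K1e <- rep(0, length(tms))
  }
  list(table = data.frame(time_ms = tms, V_mV = V,
                          I_pA = I_leak + I_Na + I_CaL + I_Kr + I_K1e,
                          I_leak_pA = I_leak, I_Na_pA = I_Na,
                          I_CaL_pA = I_CaL, I_Kr_pA = I_Kr,
                          I_K1endo_pA = I_K1e),
       end = vc_advance(state, V, dur_ms, p, ba))
}

#' Run a voltage-clamp step protocol on a virtual cell
#'
#' The command potential is imposed exactly (ideal clamp) and the summed
#' membrane current is recorded during each step, together with its
#' components -- the in-silico equivalent of the ionic/pharmacological
#' isolation used on the rig.  Sweeps are simulated back-to-back with the
#' protocol's inter-sweep interval honoured as a reset-to-holding period
#' of equal simulated duration, which preserves recovery from
#' inactivation between sweeps.
#'
#' @param cell a [cell_params()] object.
#' @param protocol a [protocol()] object.
#' @param dt sample interval (s).
#' @param ba simulate 10 umol/L Ba2+ in the bath (blocks the endogenous
#'   inward rectifier only)?
#' @return a data.frame of class `sweep_set`: columns `sweep`,
#'   `step_V_mV`, `time_ms` (from step onset), `V_mV`, `I_pA` and the
#'   per-current component columns.
#' @export
run_voltage_clamp <- function(cell, protocol, dt = 5e-5, ba = FALSE) {
  stopifnot(inherits(cell, "cell_params"), inherits(protocol, "vc_protocol"))
  steps <- protocol_steps(protocol)
  dtms <- dt * 1e3
  tms <- seq(0, protocol$step_duration, by = dtms)
  st <- cell_init_state(protocol$holding_V, cell)
  out <- vector("list", length(steps))
  for (i in seq_along(steps)) {
    st <- vc_advance(st, protocol$holding_V,
                     protocol$inter_sweep_interval * 1e3, cell, ba)
    if (!is.null(protocol$pre_pulse)) {
      st <- vc_advance(st, protocol$pre_pulse[1], protocol$pre_pulse[2],
                       cell, ba)
    }
    smp <- vc_sample(st, steps[i], tms, protocol$step_duration, cell, ba)
    st <- smp$end
    out[[i]] <- cbind(data.frame(sweep = i, step_V_mV = steps[i]), smp$table)
  }
  structure(do.call(rbind, out), protocol = protocol,
            class = c("sweep_set", "data.frame"))
}

#' @export
print.sweep_set <- function(x, ...) {
  pr <- attr(x, "protocol")
  cat(sprintf("Voltage-clamp sweeps ('%s'): %d sweeps x %d samples\n",
              pr$label, length(unique(x$sweep)),
              sum(x$sweep == x$sweep[1])))
  invisible(x)
}
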