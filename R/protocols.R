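# Declarative descriptions of the voltage-clamp step protocols and the
# current-clamp pacing used on the rig.  All protocol constants live in
# the three canonical constructors; nothing else in the package repeats
# them.

#' Voltage-step protocol description
#'
#' @param holding_V holding potential (mV).
#' @param step_range `c(start, stop, increment)` in mV; increment non-zero.
#' @param step_duration step length (ms).
#' @param inter_sweep_interval time between sweeps (s), honoured as a
#'   reset-to-holding period of equal simulated duration.
#' @param pre_pulse optional `c(V_mV, duration_ms)` conditioning pulse.
#' @param label protocol name.
#' @return an object of class `vc_protocol`.
#' @export
protocol <- function(holding_V, step_range, step_duration,
                     inter_sweep_interval, pre_pulse = NULL, label = "") {
  stopifnot(length(step_range) == 3, step_range[3] != 0,
            step_duration > 0, inter_sweep_interval > 0)
  if (!is.null(pre_pulse)) stopifnot(length(pre_pulse) == 2, pre_pulse[2] > 0)
  structure(list(holding_V = holding_V, step_range = step_range,
                 step_duration = step_duration,
                 inter_sweep_interval = inter_sweep_interval,
                 pre_pulse = pre_pulse, label = label),
            class = "vc_protocol")
}

#' @export
print.vc_protocol <- function(x, ...) {
  cat(sprintf("Voltage-clamp protocol '%s'\n", x$label))
  cat(sprintf("  hold %g mV; steps %g to %g mV by %g mV (%d steps), %g ms each\n",
              x$holding_V, x$step_range[1], x$step_range[2], x$step_range[3],
              length(protocol_steps(x)), x$step_duration))
  if (!is.null(x$pre_pulse)) {
    cat(sprintf("  pre-pulse %g mV for %g ms\n", x$pre_pulse[1], x$pre_pulse[2]))
  }
  cat(sprintf("  inter-sweep interval %g s\n", x$inter_sweep_interval))
  invisible(x)
}

#' Enumerate the step potentials of a protocol
#'
#' @param p a [protocol()] object.
#' @return numeric vector of step potentials (mV).
#' @export
protocol_steps <- function(p) {
  seq(p$step_range[1], p$step_range[2], by = p$step_range[3])
}

#' The Na+ current I-V protocol
#'
#' From a holding potential of -100 mV, 20 ms steps from -80 to +40 mV in
#' 10 mV increments at 2 s intervals (13 sweeps).
#' @return a [protocol()] object.
#' @export
protocol_na_iv <- function() {
  protocol(holding_V = -100, step_range = c(-80, 40, 10),
           step_duration = 20, inter_sweep_interval = 2, label = "na_iv")
}

#' The L-type Ca2+ current I-V protocol
#'
#' From a holding potential of -100 mV, a 100 ms pre-pulse to -40 mV (to
#' inactivate the Na+ current) followed by 200 ms steps from -40 to
#' +40 mV in 10 mV increments at 5 s intervals (9 sweeps).
#' @return a [protocol()] object.
#' @export
protocol_ca_iv <- function() {
  protocol(holding_V = -100, step_range = c(-40, 40, 10),
           step_duration = 200, inter_sweep_interval = 5,
           pre_pulse = c(-40, 100), label = "ca_iv")
}

#' The inward-rectifier (I_K1) I-V protocol
#'
#' From a holding potential of -40 mV, 1200 ms steps from -120 to +30 mV
#' in 10 mV increments (16 sweeps).  Run in control solution and under
#' 10 umol/L Ba2+ to extract the Ba2+-sensitive steady-state current.
#' @return a [protocol()] object.
#' @export
protocol_ik1 <- function() {
  protocol(holding_V = -40, step_range = c(-120, 30, 10),
           step_duration = 1200, inter_sweep_interval = 5, label = "ik1_iv")
}

#' Current-clamp stimulus train
#'
#' @param rate pacing rate (Hz).
#' @param pulse_width stimulus width (ms).
#' @param amplitude stimulus amplitude (nA); amplitudes outside the
#'   0.6--3 nA operating range of the rig trigger a warning.
#' @param count number of pulses.
#' @param holding_current constant holding current (pA).
#' @param warn_range emit the operating-range warning?
#' @return an object of class `stimulus_train`.
#' @export
stimulus_train <- function(rate = 0.5, pulse_width = 1, amplitude = 1,
                           count = 3, holding_current = 0,
                           warn_range = TRUE) {
  stopifnot(rate > 0, pulse_width > 0, count >= 0)
  if (warn_range && count > 0 && (amplitude < 0.6 || amplitude > 3)) {
    warning("stimulus amplitude ", amplitude,
            " nA is outside the 0.6-3 nA operating range", call. = FALSE)
  }
  structure(list(rate = rate, pulse_width = pulse_width,
                 amplitude = amplitude, count = count,
                 holding_current = holding_current),
            class = "stimulus_train")
}

# Per-tick injected stimulus (pA) over `n_ticks` ticks of length dt.
# Pulses start at t = first_at (s) and repeat at the pacing rate; the
# holding current is added everywhere.
stim_vector <- function(stim, n_ticks, dt, first_at = 0.1) {
  out <- rep(stim$holding_current, n_ticks)
  if (is.null(stim) || stim$count == 0) return(out)
  amp_pa <- stim$amplitude * 1e3
  width_ticks <- max(1L, round(stim$pulse_width * 1e-3 / dt))
  starts <- first_at + (seq_len(stim$count) - 1) / stim$rate
  for (s in starts) {
    i0 <- round(s / dt) + 1
    if (i0 > n_ticks) next
    i1 <- min(n_ticks, i0 + width_ticks - 1)
    out[i0:i1] <- out[i0:i1] + amp_pa
  }
  out
}

# Stimulus onset times (s) implied by a train.
stim_onsets <- function(stim, first_at = 0.1) {
  first_at + (seq_len(stim$count) - 1) / stim$rate
}

#' Find the smallest stimulus that reliably paces a cell
#'
#' Scans stimulus amplitudes from 0.6 to 3 nA in 0.2 nA increments and
#' returns the smallest for which three consecutive 1 ms pulses at 0.5 Hz
#' each elicit an action potential (peak above 0 mV).  The search runs in
#' the dynamic-clamp loop with the given simulated I_K1 (use density 0
#' plus a holding current for the constant-current condition).
#'
#' @param cell a [cell_params()] object.
#' @param ik1 an [ik1_params()] object.
#' @param cfg a [clamp_config()] object.
#' @param holding_current constant current (pA) added throughout.
#' @param state0 optional starting [cell_init_state()]; defaults to the
#'   settled state under the holding current (with I_K1 engaged first if
#'   its density is positive).
#' @return list with `amplitude` (nA, `NA` on failure), `success`, and
#'   the per-amplitude pass table `tried`.
#' @export
optimize_stimulus <- function(cell, ik1, cfg = clamp_config(),
                              holding_current = 0, state0 = NULL) {
  grid <- seq(0.6, 3, by = 0.2)
  if (is.null(state0)) {
    state0 <- engaged_or_held_state(cell, ik1, cfg, holding_current)
  }
  passed <- logical(length(grid))
  for (i in seq_along(grid)) {
    stim <- stimulus_train(rate = 0.5, pulse_width = 1, amplitude = grid[i],
                           count = 3, holding_current = holding_current,
                           warn_range = FALSE)
    tr <- run_current_clamp(cell, ik1, cfg, stim,
                            duration = 0.1 + 3 / stim$rate, state0 = state0)
    passed[i] <- all(beat_peaks(tr, stim_onsets(stim), 1 / stim$rate) > 0)
    if (passed[i]) break
  }
  idx <- which(passed)[1]
  list(amplitude = if (is.na(idx)) NA_real_ else grid[idx],
       success = !is.na(idx),
       tried = data.frame(amplitude = grid[seq_len(max(idx, 1, na.rm = TRUE))],
                          passed = passed[seq_len(max(idx, 1, na.rm = TRUE))]))
}

# Peak V within each beat window following a stimulus onset.
beat_peaks <- function(trace, onsets, window_s) {
  vapply(onsets, function(s) {
    sel <- trace$time_s >= s & trace$time_s < s + window_s
    if (!any(sel)) return(-Inf)
    max(trace$V_mV[sel])
  }, numeric(1))
}

# Settled starting state for pacing: engage the simulated I_K1 if its
# density is positive, otherwise settle under the holding current alone.
engaged_or_held_state <- function(cell, ik1, cfg, holding_current) {
  if (ik1$gK1_density > 0) {
    eng <- engage_ik1(cell, ik1, cfg)
    if (!eng$success) {
      warning("I_K1 engagement failed; starting from the depolarised rest",
              call. = FALSE)
    }
    eng$state
  } else {
    settle_cell(cell, injected = holding_current, duration = 2,
                dt = 1 / cfg$tick_rate, substeps = cfg$substeps)
  }
}

#' Build an I_K1 conductance titration schedule
#'
#' @param levels conductance densities (pS/pF); level 0 denotes the
#'   constant-current baseline.  The given order is preserved.
#' @return a data.frame of class `gk1_schedule` with columns `order` and
#'   `gk1_density`.
#' @export
gk1_titration_schedule <- function(levels = c(0, 200, 400, 800, 1200, 2000)) {
  if (length(levels) < 1) stop("at least one conductance level is required")
  structure(data.frame(order = seq_along(levels), gk1_density = levels),
            class = c("gk1_schedule", "data.frame"))
}
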