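# R-side surface of the compiled dynamic-clamp loop: parameter packing,
# loop configuration, runtime commands, the engagement manoeuvre and the
# multi-channel runner.

# -- parameter packing (order must match src/engine.cpp) ------------------

pack_cell <- function(p) {
  c(p$Cm, p$g_leak, p$E_leak,
    p$g_Na, p$E_Na, p$V_half_m, p$k_m, p$tau_m, p$V_half_h, p$k_h, p$tau_h,
    p$g_CaL, p$E_Ca, p$V_half_d, p$k_d, p$tau_d, p$V_half_f, p$k_f, p$tau_f,
    p$g_Kr, p$E_Kr, p$V_half_xr, p$k_xr, p$tau_xr, p$V_half_r, p$k_r,
    p$g_K1_endo)
}

pack_ik1 <- function(ik1, Cm_inj) {
  k <- ik1$rate_constants
  c(ik1$gK1_density, ik1$EK, ik1$Ko, ik1$Mg_i, ik1$SPM_i,
    ik1$mode1_fraction, Cm_inj,
    k$mg_alpha, k$mg_alpha_slope, k$mg_beta, k$mg_beta_slope, k$mg_sites,
    k$spm1_kd0, k$spm1_kd_slope,
    k$spm2_alpha, k$spm2_alpha_slope, k$spm2_alpha_sat,
    k$spm2_beta, k$spm2_beta_slope, k$spm2_beta_sat, k$spm2_mg_shift,
    k$ko_ref, k$ko_exponent)
}

pack_state <- function(st, y_ik1 = 1) {
  c(st$V, st$m, st$h, st$d, st$f, st$xr, st$y_endo, y_ik1, st$V)
}

unpack_state <- function(v) {
  st <- structure(list(V = v[["V"]], m = v[["m"]], h = v[["h"]],
                       d = v[["d"]], f = v[["f"]], xr = v[["xr"]],
                       y_endo = v[["y_endo"]]),
                  class = "cell_state")
  attr(st, "y_ik1") <- v[["y_ik1"]]
  st
}

ik1_off <- function() ik1_params(gK1_density = 0)

# Settle a cell under constant injection; returns the settled cell_state.
settle_cell <- function(params, injected = 0, duration = 2, V0 = NULL,
                        dt = 5e-5, substeps = 4) {
  if (is.null(V0)) V0 <- params$E_leak
  st <- cell_init_state(V0, params)
  res <- run_clamp_cpp(pack_cell(params),
                       pack_ik1(endo_ik1_params(params), params$Cm),
                       pack_ik1(ik1_off(), params$Cm),
                       pack_state(st),
                       rep(injected, round(duration / dt)),
                       dt, as.integer(substeps), 0L, record = FALSE)
  unpack_state(res$state)
}

# -- configuration and commands -------------------------------------------

#' Dynamic-clamp loop configuration
#'
#' @param tick_rate loop frequency (Hz); the rig value is 20 kHz.
#' @param latency_ticks delay (in ticks, 0 or 1) between the measured
#'   potential and the current computed from it.  One tick mirrors a real
#'   acquisition loop; 0 is used for oracle comparisons.
#' @param n_channels number of parallel channels (1--4).
#' @param substeps internal cell-integration substeps per tick.
#' @return an object of class `clamp_config`.
#' @export
clamp_config <- function(tick_rate = 20000, latency_ticks = 1,
                         n_channels = 1, substeps = 4) {
  stopifnot(tick_rate > 0, latency_ticks %in% c(0, 1),
            n_channels >= 1, n_channels <= 4, substeps >= 1)
  structure(list(tick_rate = tick_rate,
                 latency_ticks = as.integer(latency_ticks),
                 n_channels = as.integer(n_channels),
                 substeps = as.integer(substeps)),
            class = "clamp_config")
}

#' Runtime parameter-change command
#'
#' Mirrors the remote control of the rig: a time-stamped message changing
#' a model parameter while the loop runs.  Commands are applied atomically
#' at tick boundaries.
#'
#' @param at_time application time (s, >= 0).
#' @param target one of `"gK1_density"`, `"Cm"`, `"Ko"`,
#'   `"holding_current"`.
#' @param value new value in the parameter's units.
#' @return an object of class `clamp_command`.
#' @export
clamp_command <- function(at_time, target, value) {
  targets <- c("gK1_density", "Cm", "Ko", "holding_current")
  if (!target %in% targets) {
    stop("unknown command target '", target, "'; must be one of ",
         paste(targets, collapse = ", "))
  }
  stopifnot(at_time >= 0, is.numeric(value))
  structure(list(at_time = at_time, target = target, value = value),
            class = "clamp_command")
}

# -- the loop --------------------------------------------------------------

#' Run the dynamic-clamp loop in current-clamp mode
#'
#' Per tick the loop reads the membrane potential (one tick old under the
#' default latency), advances the slow gate of the simulated I_K1,
#' computes the whole-cell I_K1 from the conductance density and the set
#' membrane capacitance, and holds the resulting injection constant
#' (zero-order hold) while the cell integrates.  Stimulus and holding
#' currents are summed onto the same injection line.  With
#' `gK1_density = 0` the loop reduces exactly to the cell-only
#' simulation.
#'
#' @param cell a [cell_params()] object.
#' @param ik1 an [ik1_params()] object.
#' @param cfg a [clamp_config()] object.
#' @param stim a [stimulus_train()] or `NULL` for an unpaced run.
#' @param commands list of [clamp_command()] objects.
#' @param duration run length (s), positive.
#' @param state0 starting [cell_init_state()]; default is the cell's
#'   instantaneous rest at its leak reversal.
#' @param first_stim_at onset of the first stimulus pulse (s).
#' @param channel channel id recorded in the metadata.
#' @param ba simulate 10 umol/L Ba2+ (endogenous channel only)?
#' @return a trace of class `clamp_trace` (columns `time_s`, `V_mV`,
#'   `I_k1_pA`, `I_stim_pA`) with the final state in
#'   `attr(, "final_state")`.
#' @export
run_current_clamp <- function(cell, ik1, cfg = clamp_config(), stim = NULL,
                              commands = list(), duration,
                              state0 = NULL, first_stim_at = 0.1,
                              channel = 1, ba = FALSE) {
  stopifnot(inherits(cell, "cell_params"), inherits(ik1, "ik1_params"))
  if (!is.numeric(duration) || duration <= 0) stop("duration must be > 0")
  dt <- 1 / cfg$tick_rate
  n_ticks <- round(duration / dt)
  if (is.null(stim)) stim <- stimulus_train(count = 0, warn_range = FALSE)
  inj <- stim_vector(stim, n_ticks, dt, first_at = first_stim_at)
  if (is.null(state0)) state0 <- cell_init_state(cell$E_leak, cell)
  y0 <- attr(state0, "y_ik1")
  if (is.null(y0)) y0 <- ik1_init_state(state0$V, ik1)$y

  # commands partition the run into segments with constant parameters
  for (cmd in commands) {
    if (!inherits(cmd, "clamp_command")) stop("commands must be clamp_command objects")
  }
  cmd_ticks <- vapply(commands, function(cmd) round(cmd$at_time / dt), 0)
  ord <- order(cmd_ticks)
  commands <- commands[ord]; cmd_ticks <- cmd_ticks[ord]
  bounds <- unique(c(0, pmin(pmax(cmd_ticks, 0), n_ticks), n_ticks))

  Cm_inj <- cell$Cm
  extra_hold <- 0
  statev <- pack_state(state0, y0)
  rows <- vector("list", length(bounds) - 1)
  endov <- pack_ik1(endo_ik1_params(cell, ba), cell$Cm)
  for (seg in seq_len(length(bounds) - 1)) {
    if (seg > 1) {
      for (j in which(cmd_ticks == bounds[seg])) {
        cmd <- commands[[j]]
        switch(cmd$target,
               gK1_density = { ik1$gK1_density <- cmd$value },
               Ko = { ik1$Ko <- cmd$value },
               Cm = { Cm_inj <- cmd$value },
               holding_current = { extra_hold <- cmd$value })
      }
    }
    idx <- (bounds[seg] + 1):bounds[seg + 1]
    if (bounds[seg + 1] <= bounds[seg]) next
    res <- run_clamp_cpp(pack_cell(cell), endov, pack_ik1(ik1, Cm_inj),
                         statev, inj[idx] + extra_hold, dt,
                         cfg$substeps, cfg$latency_ticks, record = TRUE)
    statev <- res$state
    rows[[seg]] <- res$trace
  }
  tr <- do.call(rbind, rows)
  out <- new_trace(time_s = (seq_len(n_ticks) - 1) * dt,
                   V_mV = tr[, 1], I_k1_pA = tr[, 2], I_stim_pA = tr[, 3],
                   metadata = list(config = unclass(cfg),
                                   gk1_density = ik1$gK1_density,
                                   EK = ik1$EK,
                                   fixture = cell$id, channel = channel,
                                   stim = unclass(stim),
                                   first_stim_at = first_stim_at))
  attr(out, "final_state") <- unpack_state(statev)
  attr(attr(out, "final_state"), "y_ik1") <- statev[["y_ik1"]]
  out
}

#' Engage the simulated I_K1 with a hyperpolarising kick-start
#'
#' At the depolarised rest of a suspended cell the inward-rectifier model
#' passes almost no current, so switching it on has no immediate effect.
#' A brief hyperpolarising pulse (default -500 pA) brings the potential
#' into the range where the model generates substantial outward current;
#' if the conductance is sufficient the potential then stays near the K+
#' reversal after the pulse is removed.
#'
#' @param cell a [cell_params()] object.
#' @param ik1 an [ik1_params()] object with positive density.
#' @param cfg a [clamp_config()] object.
#' @param pulse_pA kick-start current (pA, negative).
#' @param threshold_mV potential that must be reached (and then held).
#' @param timeout_s maximum pulse duration before flagging failure.
#' @param hold_s post-pulse observation window; success requires the
#'   potential to stay below the threshold throughout.
#' @param state0 starting state; default is the cell's settled rest.
#' @return list with `state` (for subsequent pacing), `success`,
#'   `reason` (`"ok"`, `"timeout"` or `"not_held"`) and `trace`.
#' @export
engage_ik1 <- function(cell, ik1, cfg = clamp_config(), pulse_pA = -500,
                       threshold_mV = -70, timeout_s = 0.5, hold_s = 1,
                       state0 = NULL) {
  if (is.null(state0)) {
    state0 <- settle_cell(cell, 0, duration = 1, dt = 1 / cfg$tick_rate,
                          substeps = cfg$substeps)
  }
  dt <- 1 / cfg$tick_rate
  chunk <- round(0.01 / dt)                 # 10 ms probe chunks
  endov <- pack_ik1(endo_ik1_params(cell), cell$Cm)
  ik1v <- pack_ik1(ik1, cell$Cm)
  cellv <- pack_cell(cell)
  y0 <- attr(state0, "y_ik1")
  if (is.null(y0)) y0 <- ik1_init_state(state0$V, ik1)$y
  statev <- pack_state(state0, y0)

  pieces <- list()
  elapsed <- 0
  reached <- FALSE
  while (elapsed < timeout_s) {
    res <- run_clamp_cpp(cellv, endov, ik1v, statev,
                         rep(pulse_pA, chunk), dt, cfg$substeps,
                         cfg$latency_ticks, record = TRUE)
    statev <- res$state
    pieces[[length(pieces) + 1]] <- res$trace
    elapsed <- elapsed + chunk * dt
    if (statev[["V"]] < threshold_mV) { reached <- TRUE; break }
  }
  if (reached) {
    res <- run_clamp_cpp(cellv, endov, ik1v, statev,
                         rep(0, round(hold_s / dt)), dt, cfg$substeps,
                         cfg$latency_ticks, record = TRUE)
    statev <- res$state
    pieces[[length(pieces) + 1]] <- res$trace
    held <- all(res$trace[, 1] < threshold_mV)
  } else {
    held <- FALSE
  }
  tr <- do.call(rbind, pieces)
  trace <- new_trace((seq_len(nrow(tr)) - 1) * dt, tr[, 1], tr[, 2], tr[, 3],
                     metadata = list(config = unclass(cfg),
                                     gk1_density = ik1$gK1_density,
                                     fixture = cell$id,
                                     stage = "engage"))
  st <- unpack_state(statev)
  attr(st, "y_ik1") <- statev[["y_ik1"]]
  list(state = st, success = reached && held,
       reason = if (!reached) "timeout" else if (!held) "not_held" else "ok",
       trace = trace)
}

#' Run up to four clamp channels in parallel
#'
#' Channels share the loop clock but are otherwise independent: each
#' channel's output is identical to its single-channel run.
#'
#' @param channels list of channel descriptions, each a list with
#'   elements `cell`, `ik1`, and optionally `stim`, `state0`, `duration`.
#' @param cfg a [clamp_config()] object; `n_channels` must cover the
#'   channel count.
#' @param duration default run length (s) for channels that do not set
#'   their own.
#' @return list of `clamp_trace` objects, one per channel.
#' @export
run_parallel <- function(channels, cfg = clamp_config(n_channels = 4),
                         duration = 2) {
  if (length(channels) < 1 || length(channels) > 4) {
    stop("between 1 and 4 channels are supported")
  }
  if (length(channels) > cfg$n_channels) {
    stop("more channels than configured in clamp_config")
  }
  lapply(seq_along(channels), function(i) {
    ch <- channels[[i]]
    run_current_clamp(ch$cell, ch$ik1, cfg, stim = ch$stim,
                      duration = if (is.null(ch$duration)) duration else ch$duration,
                      state0 = ch$state0, channel = i)
  })
}
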