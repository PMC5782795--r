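# Feature extraction and curve fitting: action-potential parameters,
# peak-current I-V relations, Ba2+ subtraction, Boltzmann activation fits
# and Hill concentration-response fits.

#' Extract action-potential features from a paced trace
#'
#' Per stimulus: the resting (diastolic) potential is the mean over the
#' 100 ms preceding the pulse; the upstroke velocity is the maximal dV/dt
#' in the 10 ms after pulse onset, excluding the stimulus pulse itself
#' (so the artifact of the injection step is not read as upstroke); the
#' APD90 runs from the instant of maximal dV/dt until the potential first
#' falls below RMP + 0.1 x amplitude; a plateau is flagged when the
#' potential stays above RMP + 0.5 x amplitude for at least 20% of the
#' APD90 after the first 5 ms.  Beats whose peak stays at or below 0 mV
#' are flagged as undetected rather than raising an error.
#'
#' @param trace a `clamp_trace` (or any data.frame with `time_s`, `V_mV`
#'   on a uniform time base).
#' @param stim_times stimulus onset times (s), at least one.
#' @param pulse_width_ms stimulus width excluded from the upstroke
#'   window.
#' @return data.frame of class `ap_features`: one row per stimulus with
#'   columns `stim_time_s`, `detected`, `RMP_mV`, `peak_mV`,
#'   `amplitude_mV`, `dVdt_max_V_s`, `t_upstroke_s`, `APD90_ms`,
#'   `has_plateau`.
#' @export
ap_features <- function(trace, stim_times, pulse_width_ms = 1) {
  stopifnot(length(stim_times) >= 1, nrow(trace) > 2)
  t <- trace$time_s; V <- trace$V_mV
  dt <- t[2] - t[1]
  if (max(abs(diff(t) - dt)) > dt * 1e-6) stop("trace time base not uniform")
  dVdt <- c(diff(V), NA) / dt / 1e3            # forward difference, V/s
  beat_end <- c(stim_times[-1], max(t) + dt)
  rows <- lapply(seq_along(stim_times), function(i) {
    s <- stim_times[i]
    pre <- V[t >= s - 0.1 & t < s]
    rmp <- if (length(pre)) mean(pre) else NA_real_
    win <- t >= s & t < beat_end[i]
    peak <- max(V[win])
    amp <- peak - rmp
    up_win <- which(t > s + pulse_width_ms * 1e-3 & t <= s + 0.010)
    detected <- is.finite(peak) && peak > 0
    if (!detected || length(up_win) == 0) {
      return(data.frame(stim_time_s = s, detected = detected, RMP_mV = rmp,
                        peak_mV = peak, amplitude_mV = amp,
                        dVdt_max_V_s = NA_real_, t_upstroke_s = NA_real_,
                        APD90_ms = NA_real_, has_plateau = NA))
    }
    iu <- up_win[which.max(dVdt[up_win])]
    v90 <- rmp + 0.1 * amp
    after <- which(t > t[iu] & t < beat_end[i] & V < v90)
    apd90 <- if (length(after)) (t[after[1]] - t[iu]) * 1e3 else NA_real_
    plateau <- NA
    if (!is.na(apd90)) {
      sel <- t > t[iu] + 0.005 & t <= t[iu] + apd90 * 1e-3
      plateau <- mean(V[sel] > rmp + 0.5 * amp) >= 0.2
    }
    data.frame(stim_time_s = s, detected = TRUE, RMP_mV = rmp,
               peak_mV = peak, amplitude_mV = amp,
               dVdt_max_V_s = max(dVdt[up_win]), t_upstroke_s = t[iu],
               APD90_ms = apd90, has_plateau = plateau)
  })
  structure(do.call(rbind, rows), class = c("ap_features", "data.frame"))
}

#' Peak currents of a voltage-clamp sweep family
#'
#' Per sweep, the extremum of the chosen current during the step (the
#' most negative sample for inward protocols; earliest sample on ties,
#' which is how `which.min` resolves them).
#'
#' @param sweeps a [run_voltage_clamp()] result.
#' @param current column to analyse; the default is the summed membrane
#'   current, the component columns (`"I_Na_pA"`, `"I_CaL_pA"`, ...) give
#'   the isolated currents.
#' @param direction `"inward"` (minimum) or `"outward"` (maximum).
#' @return an [iv_curve()] of peak current (pA) vs step potential.
#' @export
peak_currents <- function(sweeps, current = "I_pA",
                          direction = c("inward", "outward")) {
  direction <- match.arg(direction)
  stopifnot(current %in% names(sweeps))
  vs <- unique(sweeps$step_V_mV)
  pk <- vapply(vs, function(v) {
    x <- sweeps[[current]][sweeps$step_V_mV == v]
    if (direction == "inward") min(x) else max(x)
  }, numeric(1))
  iv_curve(vs, pk, units = "pA",
           label = paste("peak", current,
                         attr(sweeps, "protocol")$label))
}

#' Ba2+-sensitive steady-state current
#'
#' Steady-state current per sweep is the mean over the final 200 ms of
#' the step; the Ba2+-sensitive component is control minus Ba2+,
#' reported per step potential.
#'
#' @param control,ba [run_voltage_clamp()] results from the same
#'   protocol, in control solution and under 10 umol/L Ba2+.
#' @param window_ms width of the steady-state averaging window at the
#'   end of each step.
#' @param current column to analyse.
#' @return an [iv_curve()] (pA).
#' @export
ba_sensitive_current <- function(control, ba, window_ms = 200,
                                 current = "I_pA") {
  pc <- attr(control, "protocol"); pb <- attr(ba, "protocol")
  if (!isTRUE(all.equal(unclass(pc), unclass(pb)))) {
    stop("control and Ba2+ recordings use different protocols")
  }
  vs <- unique(control$step_V_mV)
  ss <- function(sw, v) {
    sel <- sw$step_V_mV == v & sw$time_ms > pc$step_duration - window_ms
    mean(sw[[current]][sel])
  }
  diffs <- vapply(vs, function(v) ss(control, v) - ss(ba, v), numeric(1))
  iv_curve(vs, diffs, units = "pA", label = "Ba2+-sensitive current")
}

#' Convert a peak-current curve to a conductance-voltage curve
#'
#' Chord conductance G = I / (V - E_rev); points too close to the
#' reversal potential are dropped.
#'
#' @param iv an [iv_curve()] of peak currents (pA).
#' @param E_rev reversal potential (mV).
#' @param min_drive minimal |V - E_rev| (mV) to keep a point.
#' @return data.frame with columns `V` and `G` (nS).
#' @export
conductance_curve <- function(iv, E_rev, min_drive = 5) {
  keep <- abs(iv$V - E_rev) >= min_drive
  data.frame(V = iv$V[keep], G = iv$I[keep] / (iv$V[keep] - E_rev))
}

#' Boltzmann fit of an activation curve
#'
#' Least-squares fit of G(V) = G_max / (1 + exp(-(V - V_half) / k)).
#'
#' @param gv data.frame with columns `V` (mV) and `G`, e.g. from
#'   [conductance_curve()].
#' @return object of class `boltzmann_fit`: list with `V_half`, `k`,
#'   `G_max`, `residual_norm`, `converged` and the underlying `fit`.
#'   Non-convergence is flagged, not thrown.
#' @export
boltzmann_fit <- function(gv) {
  stopifnot(all(c("V", "G") %in% names(gv)))
  if (nrow(gv) < 4) stop("at least 4 points are required")
  gmax0 <- max(gv$G)
  vh0 <- gv$V[which.min(abs(gv$G - gmax0 / 2))]
  k0 <- diff(range(gv$V)) / 10
  fit <- tryCatch(
    minpack.lm::nlsLM(G ~ Gmax / (1 + exp(-(V - Vh) / k)), data = gv,
                      start = list(Gmax = gmax0, Vh = vh0, k = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(V_half = NA_real_, k = NA_real_, G_max = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          message = conditionMessage(fit), fit = NULL),
                     class = "boltzmann_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(V_half = unname(cf["Vh"]), k = unname(cf["k"]),
                 G_max = unname(cf["Gmax"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = TRUE, fit = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Boltzmann fit: did not converge (", x$message, ")\n")
    return(invisible(x))
  }
  cat(sprintf("Boltzmann fit: V_half = %.2f mV, k = %.2f mV, G_max = %.4g\n",
              x$V_half, x$k, x$G_max))
  invisible(x)
}

#' Hill fit of a concentration-response curve
#'
#' Least-squares fit of B(c) = B_max c^h / (c^h + IC50^h) to normalised
#' block fractions.  The fitted amplitude absorbs the normalisation to
#' the maximum observed block, so a response family generated by a
#' one-site block is recovered exactly.
#'
#' @param conc concentrations (nmol/L), at least 4.
#' @param response normalised block fractions in [0, 1].
#' @param fix_h optionally fix the Hill coefficient.
#' @return object of class `hill_fit`: list with `IC50`, `h`, `B_max`,
#'   `residual_norm`, `converged`.
#' @export
hill_fit <- function(conc, response, fix_h = NULL) {
  stopifnot(length(conc) == length(response))
  if (length(conc) < 4) stop("at least 4 concentrations are required")
  if (all(response == 0)) stop("degenerate response: no block observed")
  dat <- data.frame(c = conc, r = response)
  ic0 <- conc[which.min(abs(response - 0.5))]
  fit <- tryCatch(
    if (is.null(fix_h)) {
      minpack.lm::nlsLM(r ~ Bmax * c^h / (c^h + ic50^h), data = dat,
                        start = list(Bmax = max(response), ic50 = ic0, h = 1),
                        lower = c(0, 1e-6, 0.1),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(r ~ Bmax * c^fix_h / (c^fix_h + ic50^fix_h),
                        data = dat,
                        start = list(Bmax = max(response), ic50 = ic0),
                        lower = c(0, 1e-6),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    },
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(IC50 = NA_real_, h = NA_real_, B_max = NA_real_,
                          residual_norm = NA_real_, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "hill_fit"))
  }
  cf <- stats::coef(fit)
  structure(list(IC50 = unname(cf["ic50"]),
                 h = if (is.null(fix_h)) unname(cf["h"]) else fix_h,
                 B_max = unname(cf["Bmax"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 converged = TRUE, fit = fit),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Hill fit: did not converge (", x$message, ")\n")
    return(invisible(x))
  }
  cat(sprintf("Hill fit: IC50 = %.1f nmol/L, h = %.2f, B_max = %.3f\n",
              x$IC50, x$h, x$B_max))
  invisible(x)
}

#' Mean, standard error and n
#'
#' @param values numeric vector.
#' @return list with `mean`, `sem` (`NA` with a flag for a single
#'   value) and `n`.
#' @export
summarize_sem <- function(values) {
  n <- length(values)
  list(mean = mean(values),
       sem = if (n > 1) stats::sd(values) / sqrt(n) else NA_real_,
       n = n,
       sem_defined = n > 1)
}
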