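#' Current-voltage curve container
#'
#' A thin data.frame wrapper holding one current value per test potential,
#' used for both simulated steady-state relations and peak-current I-V
#' plots.
#'
#' @param V test potentials (mV), strictly increasing.
#' @param I currents (pA or pA/pF, see `units`).
#' @param n optional number of cells averaged per point.
#' @param units unit string for `I`.
#' @param label free-text label.
#' @return a data.frame of class `iv_curve` with columns `V` and `I`.
#' @export
iv_curve <- function(V, I, n = NULL, units = "pA", label = "") {
  stopifnot(length(V) == length(I))
  if (length(V) > 1 && is.unsorted(V, strictly = TRUE)) {
    stop("V must be strictly increasing")
  }
  out <- data.frame(V = as.numeric(V), I = as.numeric(I))
  if (!is.null(n)) out$n <- n
  structure(out, units = units, label = label,
            class = c("iv_curve", "data.frame"))
}

#' @export
print.iv_curve <- function(x, ...) {
  lbl <- attr(x, "label")
  cat(sprintf("I-V curve%s: %d points, I in %s\n",
              if (nzchar(lbl)) paste0(" (", lbl, ")") else "",
              nrow(x), attr(x, "units")))
  print.data.frame(x, ...)
  invisible(x)
}

# Recorded time series from a clamp run.  Columns: time_s, V_mV, I_k1_pA,
# I_stim_pA.  Metadata (config echo, fixture id, channel, seed) is carried
# in attributes and round-trips through write_trace()/read_trace().
new_trace <- function(time_s, V_mV, I_k1_pA, I_stim_pA, metadata = list()) {
  out <- data.frame(time_s = time_s, V_mV = V_mV,
                    I_k1_pA = I_k1_pA, I_stim_pA = I_stim_pA)
  structure(out, metadata = metadata, class = c("clamp_trace", "data.frame"))
}

#' @export
print.clamp_trace <- function(x, ...) {
  md <- attr(x, "metadata")
  dt <- if (nrow(x) > 1) x$time_s[2] - x$time_s[1] else NA_real_
  cat(sprintf("Dynamic-clamp trace: %d samples, %.3f s at %.0f Hz\n",
              nrow(x), nrow(x) * dt, 1 / dt))
  if (!is.null(md$fixture)) cat("  fixture:", md$fixture, "\n")
  if (!is.null(md$channel)) cat("  channel:", md$channel, "\n")
  cat(sprintf("  V range: [%.1f, %.1f] mV\n", min(x$V_mV), max(x$V_mV)))
  invisible(x)
}

#' @export
plot.clamp_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$time_s, x$V_mV, type = "l", xlab = "time (s)",
       ylab = "V (mV)", ...)
  plot(x$time_s, x$I_k1_pA, type = "l", xlab = "time (s)",
       ylab = "injected I_K1 (pA)", col = "firebrick")
  invisible(x)
}

trace_metadata <- function(trace) attr(trace, "metadata")
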