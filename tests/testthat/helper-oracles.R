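# Shared fixtures and independent numerical oracles used across tests.

fix_A <- make_fixture("A")
fix_B <- make_fixture("B")
fix_C <- make_fixture("C")

# Forward-Euler integration of the slow spermine gate along a voltage
# trajectory: the brute-force oracle for the closed-form gate update.
# V_fun(t) gives the potential at time t (s); returns y at t_end.
euler_gate_oracle <- function(V_fun, params, y0, t_end, dt) {
  n <- round(t_end / dt)
  tt <- (seq_len(n) - 1) * dt
  g <- ik1_gating(V_fun(tt), params)   # vectorised rates along the path
  y <- y0
  for (i in seq_len(n)) {
    y <- y + dt * (g$y_inf[i] - y) / g$tau_y[i]
  }
  y
}

# testthat runs helpers in the package namespace only when load_package =
# "installed" exposes exported symbols; reach the internal gating helper
# explicitly.
ik1_gating <- dynaclamp:::ik1_gating

# Analytic trapezoid "action potential": baseline -> peak in rise_ms,
# plateau, linear fall back to baseline.  Returns a trace-like data.frame
# plus its analytic APD90 for a stimulus at t_on.
trapezoid_trace <- function(base = -90, peak = 40, rise_ms = 2,
                            plateau_ms = 200, fall_ms = 50,
                            t_on = 0.2, total_s = 1, dt = 5e-5) {
  t <- seq(0, total_s, by = dt)
  V <- rep(base, length(t))
  tr <- (t - t_on) * 1e3                    # ms since onset
  rise <- tr > 0 & tr <= rise_ms
  V[rise] <- base + (peak - base) * tr[rise] / rise_ms
  plat <- tr > rise_ms & tr <= rise_ms + plateau_ms
  V[plat] <- peak
  fall <- tr > rise_ms + plateau_ms & tr <= rise_ms + plateau_ms + fall_ms
  V[fall] <- peak - (peak - base) *
    (tr[fall] - rise_ms - plateau_ms) / fall_ms
  amp <- peak - base
  v90 <- base + 0.1 * amp
  # geometric crossing of the fall below the 90%-repolarisation level,
  # in ms after stimulus onset
  t_cross <- rise_ms + plateau_ms + fall_ms * (peak - v90) / (peak - base)
  list(trace = data.frame(time_s = t, V_mV = V,
                          I_k1_pA = 0, I_stim_pA = 0),
       t_cross_ms = t_cross, dt = dt)
}
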