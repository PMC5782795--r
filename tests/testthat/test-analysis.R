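# Feature extraction and curve fitting.

test_that("APD90 of a synthetic trapezoid matches its geometry", {
  tz <- trapezoid_trace()
  ft <- ap_features(tz$trace, stim_times = 0.2)
  expect_true(ft$detected)
  expect_equal(ft$RMP_mV, -90)
  expect_equal(ft$amplitude_mV, 130)
  # measured from the post-pulse upstroke sample to the 90% crossing
  expected <- tz$t_cross_ms - (1 + tz$dt * 1e3)
  expect_lt(abs(ft$APD90_ms - expected), 2 * tz$dt * 1e3)
  expect_true(ft$has_plateau)

  # resampling at a finer rate moves the repolarisation instant by at
  # most one coarse sample period, and APD90 by at most two
  tz2 <- trapezoid_trace(dt = 1 / 80000)
  ft2 <- ap_features(tz2$trace, stim_times = 0.2)
  cross1 <- ft$t_upstroke_s * 1e3 + ft$APD90_ms
  cross2 <- ft2$t_upstroke_s * 1e3 + ft2$APD90_ms
  expect_lte(abs(cross1 - cross2), tz$dt * 1e3)
  expect_lte(abs(ft$APD90_ms - ft2$APD90_ms), 2 * tz$dt * 1e3)
})

test_that("quiescent traces are flagged rather than throwing", {
  t <- seq(0, 1, by = 5e-5)
  flat <- data.frame(time_s = t, V_mV = rep(-94, length(t)),
                     I_k1_pA = 0, I_stim_pA = 0)
  ft <- ap_features(flat, stim_times = 0.5)
  expect_false(ft$detected)
  expect_equal(ft$RMP_mV, -94)
  expect_true(is.na(ft$APD90_ms))
})

test_that("peak extraction matches a brute-force scan of the sweeps", {
  sw <- run_voltage_clamp(fix_A, protocol_na_iv())
  pk <- peak_currents(sw, current = "I_Na_pA")
  brute <- vapply(unique(sw$step_V_mV), function(v) {
    min(sw$I_Na_pA[sw$step_V_mV == v])
  }, numeric(1))
  expect_identical(pk$I, brute)
  expect_identical(pk$V[which.min(pk$I)], -30)
})

test_that("Ba2+ subtraction recovers the endogenous rectifier", {
  ctrl <- run_voltage_clamp(fix_C, protocol_ik1())
  ba <- run_voltage_clamp(fix_C, protocol_ik1(), ba = TRUE)
  bs <- ba_sensitive_current(ctrl, ba)
  direct <- ik1_steady_state(bs$V, dynaclamp:::endo_ik1_params(fix_C)) *
    fix_C$Cm
  expect_lt(max(abs(bs$I - direct) / pmax(abs(direct), 0.01)), 0.01)

  # antisymmetry and the null result on a cell without the channel
  expect_equal(ba_sensitive_current(ba, ctrl)$I, -bs$I)
  expect_equal(ba_sensitive_current(ctrl, ctrl)$I, rep(0, nrow(bs)))
  bsA <- ba_sensitive_current(run_voltage_clamp(fix_A, protocol_ik1()),
                              run_voltage_clamp(fix_A, protocol_ik1(),
                                                ba = TRUE))
  expect_equal(max(abs(bsA$I)), 0)
  expect_error(ba_sensitive_current(ctrl,
                 run_voltage_clamp(fix_C, protocol_na_iv())), "protocol")
})

test_that("Boltzmann fits recover activation parameters", {
  v <- seq(-80, 40, by = 10)
  g <- 20 / (1 + exp(-(v + 46) / 6))
  fit <- boltzmann_fit(data.frame(V = v, G = g))
  expect_true(fit$converged)
  expect_lt(abs(fit$V_half - (-46)), 1e-6)
  expect_lt(abs(fit$k - 6), 1e-6)

  # from the simulated Na+ protocol on fixture A
  pk <- peak_currents(run_voltage_clamp(fix_A, protocol_na_iv()),
                      current = "I_Na_pA")
  fitA <- boltzmann_fit(conductance_curve(pk, fix_A$E_Na))
  expect_lt(abs(fitA$V_half - (-46)), 1)

  # unbiased in median under multiplicative noise
  set.seed(20)
  vhs <- replicate(100, {
    fit_n <- boltzmann_fit(data.frame(V = v, G = g * (1 + 0.05 * rnorm(length(v)))))
    fit_n$V_half
  })
  expect_lt(abs(stats::median(vhs) - (-46)), 1)
  expect_error(boltzmann_fit(data.frame(V = 1:3, G = 1:3)), "4")
})

test_that("Hill fits recover the concentration-response parameters", {
  conc <- 10^seq(1, 4, by = 0.5)
  r <- conc / (conc + 252)
  fit <- hill_fit(conc, r)
  expect_true(fit$converged)
  expect_lt(abs(fit$IC50 - 252), 1e-4)
  expect_lt(abs(fit$h - 1), 1e-6)
  expect_error(hill_fit(conc, rep(0, length(conc))), "degenerate")
  expect_error(hill_fit(conc[1:3], r[1:3]), "4")

  # end-to-end: simulated voltage-clamp block curve on fixture A
  bc <- nifedipine_block_curve(fix_A)
  fitA <- hill_fit(bc$conc_nM, bc$block_norm)
  expect_lt(abs(fitA$IC50 - 252), 5)
})

test_that("summary statistics follow the mean +/- s.e.m. convention", {
  s <- summarize_sem(c(1, 1, 1))
  expect_identical(s$mean, 1)
  expect_identical(s$sem, 0)
  expect_identical(s$n, 3L)
  s1 <- summarize_sem(5)
  expect_true(is.na(s1$sem))
  expect_false(s1$sem_defined)
  # a generated cohort summarises back to its population inputs
  coh <- cohort_table(generate_cohort(2000, seed = 3))
  s2 <- summarize_sem(coh$Cm)
  expect_lt(abs(s2$mean - 37), 2)
})

test_that("gates stay in [0, 1] through a paced hybrid run", {
  ik1 <- ik1_params(gK1_density = 800)
  eng <- engage_ik1(fix_B, ik1)
  stim <- stimulus_train(amplitude = 2, count = 1, warn_range = FALSE)
  tr <- run_current_clamp(fix_B, ik1, clamp_config(), stim,
                          duration = 2, state0 = eng$state)
  st <- attr(tr, "final_state")
  for (g in c("m", "h", "d", "f", "xr")) {
    expect_gte(st[[g]], 0); expect_lte(st[[g]], 1)
  }
  expect_gte(attr(st, "y_ik1"), 0)
  expect_lte(attr(st, "y_ik1"), 1)
})
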