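# The fixed-tick dynamic-clamp loop: no-op equivalence, latency,
# engagement, command semantics, parallel channels and the voltage clamp.

test_that("a zero-density loop reduces to the cell-only simulation", {
  st0 <- dynaclamp:::settle_cell(fix_B, 0, 1)
  tr <- run_current_clamp(fix_B, ik1_params(gK1_density = 0),
                          duration = 0.1, state0 = st0)
  expect_true(all(tr$I_k1_pA == 0))
  # tick-by-tick agreement with the reference R step (4 substeps per tick)
  st <- st0
  v_ref <- numeric(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    v_ref[i] <- st$V
    for (s in 1:4) st <- cell_step(st, 0, 5e-5 / 4, fix_B)
  }
  expect_equal(tr$V_mV, v_ref, tolerance = 1e-9)
})

test_that("kick-started fixture B at 400 pS/pF rests at -94 mV", {
  ik1 <- ik1_params(gK1_density = 400)
  eng <- engage_ik1(fix_B, ik1)
  expect_true(eng$success)
  expect_identical(eng$reason, "ok")
  tr <- run_current_clamp(fix_B, ik1, duration = 5, state0 = eng$state)
  expect_lt(abs(mean(tr$V_mV[tr$time_s >= 4]) - (-94)), 1)
})

test_that("engagement fails gracefully without sufficient conductance", {
  # no simulated channel: the pulse hyperpolarises, release relaxes back
  e0 <- engage_ik1(fix_B, ik1_params(gK1_density = 0))
  expect_false(e0$success)
  # with nothing to hold it, the cell leaves the hyperpolarised range
  # (possibly via spontaneous activity) instead of resting near E_K
  after <- run_current_clamp(fix_B, ik1_params(gK1_density = 0),
                             duration = 4, state0 = e0$state)
  expect_gt(mean(after$V_mV[after$time_s >= 3]), -70)
  expect_gt(max(after$V_mV), -20)
  # below the equilibrium threshold of leak + window currents vs the
  # outward hump, the potential cannot be held
  elo <- engage_ik1(fix_B, ik1_params(gK1_density = 30))
  expect_false(elo$success)
  expect_identical(elo$reason, "not_held")
  ehi <- engage_ik1(fix_B, ik1_params(gK1_density = 200))
  expect_true(ehi$success)
  expect_lt(ehi$state$V, -85)
})

test_that("loop latency of one tick barely perturbs the trajectory", {
  ik1 <- ik1_params(gK1_density = 400)
  eng <- engage_ik1(fix_B, ik1, clamp_config(latency_ticks = 0))
  stim <- stimulus_train(amplitude = 1.6, count = 1, warn_range = FALSE)
  tr0 <- run_current_clamp(fix_B, ik1, clamp_config(latency_ticks = 0),
                           stim, duration = 2, state0 = eng$state)
  tr1 <- run_current_clamp(fix_B, ik1, clamp_config(latency_ticks = 1),
                           stim, duration = 2, state0 = eng$state)
  expect_lt(max(abs(tr0$V_mV - tr1$V_mV)), 0.5)
})

test_that("commands apply atomically at their tick and not before", {
  st0 <- dynaclamp:::settle_cell(fix_B, 0, 1)
  base <- run_current_clamp(fix_B, ik1_params(gK1_density = 0),
                            duration = 1, state0 = st0)
  cmd <- clamp_command(0.5, "holding_current", -300)
  mod <- run_current_clamp(fix_B, ik1_params(gK1_density = 0),
                           commands = list(cmd),
                           duration = 1, state0 = st0)
  pre <- base$time_s < 0.5
  expect_identical(mod$V_mV[pre], base$V_mV[pre])
  expect_lt(mod$V_mV[length(mod$V_mV)], base$V_mV[length(base$V_mV)] - 5)
  expect_error(clamp_command(0.5, "g_nonsense", 1), "unknown")
  # doubling the set capacitance doubles the injected conductance and
  # pulls the resting potential closer to E_K
  eng <- engage_ik1(fix_B, ik1_params(gK1_density = 400))
  cm2 <- run_current_clamp(fix_B, ik1_params(gK1_density = 400),
                           commands = list(clamp_command(0.2, "Cm", 74)),
                           duration = 1, state0 = eng$state)
  v_pre <- mean(cm2$V_mV[cm2$time_s < 0.19])
  v_post <- mean(cm2$V_mV[cm2$time_s > 0.8])
  expect_lt(v_post, v_pre - 0.3)
})

test_that("runs are deterministic and channels are independent", {
  ik1 <- ik1_params(gK1_density = 400)
  eng <- engage_ik1(fix_B, ik1)
  stim <- stimulus_train(amplitude = 1.6, count = 1, warn_range = FALSE)
  ch <- list(cell = fix_B, ik1 = ik1, stim = stim, state0 = eng$state)
  solo <- run_current_clamp(fix_B, ik1, clamp_config(), stim,
                            duration = 2, state0 = eng$state)
  # identical channels give identical traces, invariant to ordering
  par3 <- run_parallel(list(ch, ch, ch), duration = 2)
  expect_identical(par3[[1]]$V_mV, solo$V_mV)
  expect_identical(par3[[2]]$V_mV, par3[[3]]$V_mV)
  # distinct densities equal their solo runs bit for bit
  chans <- lapply(c(200, 400, 800), function(g) {
    k <- ik1_params(gK1_density = g)
    list(cell = fix_B, ik1 = k, stim = stim, state0 = eng$state)
  })
  par <- run_parallel(chans, duration = 1)
  for (i in seq_along(chans)) {
    solo_i <- run_current_clamp(fix_B, chans[[i]]$ik1, clamp_config(),
                                stim, duration = 1, state0 = eng$state)
    expect_identical(par[[i]]$V_mV, solo_i$V_mV)
    expect_identical(par[[i]]$I_k1_pA, solo_i$I_k1_pA)
  }
  expect_error(run_parallel(rep(list(ch), 5)), "4")
  # determinism of a repeated run
  again <- run_current_clamp(fix_B, ik1, clamp_config(), stim,
                             duration = 2, state0 = eng$state)
  expect_identical(again$V_mV, solo$V_mV)
})

test_that("ideal voltage clamp records the imposed steps and currents", {
  p <- fix_A
  p$g_leak <- 0; p$g_Na <- 0; p$g_CaL <- 0; p$g_Kr <- 0
  sw <- run_voltage_clamp(p, protocol_na_iv())
  expect_true(all(sw$I_pA == 0))
  expect_identical(unique(sw$step_V_mV), seq(-80, 40, by = 10))

  sw_na <- run_voltage_clamp(fix_A, protocol_na_iv())
  pk <- peak_currents(sw_na, current = "I_Na_pA")
  expect_lt(abs(min(pk$I) - (-5400)) / 5400, 0.02)
  sw_ca <- run_voltage_clamp(fix_A, protocol_ca_iv())
  pkc <- peak_currents(sw_ca, current = "I_CaL_pA")
  expect_lt(abs(min(pkc$I) - (-157)) / 157, 0.02)
})

test_that("the staged experiment runs end to end on fixture A", {
  rep <- run_full_experiment(fix_A)
  expect_true(rep$success)
  expect_true(rep$iv_na$success)
  expect_gt(nrow(rep$titration$table), 0)
  # an IV-only plan produces no current-clamp artifacts
  iv_only <- run_full_experiment(fix_A, plan = list(stages = c("iv_na", "iv_ca")))
  expect_null(iv_only$titration)
  expect_null(iv_only$engage)
  expect_true(iv_only$success)
  # cohort mode counts per-cell successes at the configured failure rate
  rep2 <- run_full_experiment(fix_A,
    plan = list(cohort = generate_cohort(28, 2), failure_prob = 8 / 28,
                seed = 3))
  expect_identical(rep2$cohort$n, 28L)
  expect_identical(rep2$cohort$succeeded + rep2$cohort$failed, 28L)
  expect_gt(rep2$cohort$success_rate, 0.5)
})
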