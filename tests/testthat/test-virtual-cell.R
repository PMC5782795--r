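# The calibrated iPSC-CM surrogate: fixtures, resting behaviour,
# holding-current search, pharmacology and the population generator.

test_that("fixtures carry the measured phenotype", {
  expect_identical(fix_A$Cm, 37)
  expect_identical(fix_B$g_leak, 0.15)
  expect_identical(fix_C$g_K1_endo, 20)
  expect_error(make_fixture("D"))

  # depolarised rest without injection, for every fixture
  for (p in list(fix_A, fix_B, fix_C)) {
    rest <- dynaclamp:::settle_cell(p, 0, duration = 3)$V
    expect_gte(rest, -15); expect_lte(rest, 0)
  }
  # fixture B differs from A only in its leak: same leak reversal
  expect_identical(fix_B$E_leak, fix_A$E_leak)

  # Na+ channels are essentially unavailable at the depolarised rest
  expect_lt(dynaclamp:::gate_inf(-10, fix_A)$h, 0.01)
})

test_that("peak-current calibration round-trips through the protocols", {
  pk_na <- peak_currents(run_voltage_clamp(fix_A, protocol_na_iv()),
                         current = "I_Na_pA")
  expect_equal(min(pk_na$I), -5400, tolerance = 0.01)
  expect_identical(pk_na$V[which.min(pk_na$I)], -30)
  pk_ca <- peak_currents(run_voltage_clamp(fix_A, protocol_ca_iv()),
                         current = "I_CaL_pA")
  expect_equal(min(pk_ca$I), -157, tolerance = 0.01)
  expect_identical(pk_ca$V[which.min(pk_ca$I)], 10)
})

test_that("cell_step keeps a passive membrane constant and settles at -94
           under the Figure-4 holding current", {
  p <- fix_A
  p$g_leak <- 0; p$g_Na <- 0; p$g_CaL <- 0; p$g_Kr <- 0
  st <- cell_init_state(-37, p)
  for (i in 1:100) st <- cell_step(st, 0, 5e-5, p)
  expect_equal(st$V, -37)

  st <- dynaclamp:::settle_cell(fix_A, -180, duration = 2)
  expect_lt(abs(st$V - (-94)), 0.1)
})

test_that("reference R step and the compiled engine agree", {
  p <- fix_C                                 # exercises the endogenous gate
  st_r <- cell_init_state(p$E_leak, p)
  dt <- 5e-5
  inj <- -150
  res <- dynaclamp:::run_clamp_cpp(
    dynaclamp:::pack_cell(p),
    dynaclamp:::pack_ik1(dynaclamp:::endo_ik1_params(p), p$Cm),
    dynaclamp:::pack_ik1(dynaclamp:::ik1_off(), p$Cm),
    dynaclamp:::pack_state(st_r), rep(inj, 2000), dt, 1L, 0L)
  for (i in 1:2000) st_r <- cell_step(st_r, inj, dt, p)
  expect_equal(res$state[["V"]], st_r$V, tolerance = 1e-10)
  expect_equal(res$state[["y_endo"]], st_r$y_endo, tolerance = 1e-10)
})

test_that("membrane integration converges at first order in the step", {
  # paced beat; compare against a fine-substep reference
  stim <- stimulus_train(amplitude = 2, count = 1, warn_range = FALSE)
  run_at <- function(substeps) {
    cfg <- clamp_config(substeps = substeps)
    st0 <- dynaclamp:::settle_cell(fix_A, -180, 2)
    run_current_clamp(fix_A, ik1_params(gK1_density = 0), cfg, stim,
                      duration = 0.4, state0 = st0,
                      first_stim_at = 0.05)$V_mV
  }
  ref <- run_at(32)
  e1 <- max(abs(run_at(1) - ref))
  e2 <- max(abs(run_at(2) - ref))
  e4 <- max(abs(run_at(4) - ref))
  expect_gt(e1 / e2, 1.5)     # roughly halves with the step
  expect_gt(e2 / e4, 1.5)
})

test_that("holding-current search reproduces the printed value", {
  expect_lt(abs(find_holding_current(fix_A, -94) - (-180)), 1)
  expect_lt(abs(find_holding_current(fix_A, -10) - 0), 0.5)
  expect_error(find_holding_current(fix_A, -94, bracket = c(-10, 10)),
               "bracket")
})

test_that("drug scaling is calibrated, monotone and bounded", {
  expect_equal(apply_drug(fix_A, "nifedipine", 0)$g_CaL, fix_A$g_CaL)
  expect_equal(apply_drug(fix_A, "nifedipine", 252)$g_CaL, fix_A$g_CaL / 2)
  expect_lt(apply_drug(fix_A, "nifedipine", 30000)$g_CaL,
            0.01 * fix_A$g_CaL)
  expect_error(apply_drug(fix_A, "nifedipine", -1))
  expect_error(apply_drug(fix_A, "digoxin", 10))

  conc <- 10^seq(0, 5, by = 0.5)
  gnif <- vapply(conc, function(c) apply_drug(fix_A, "nifedipine", c)$g_CaL,
                 numeric(1))
  expect_true(all(diff(gnif) < 0))
  gbk <- vapply(conc, function(c) apply_drug(fix_A, "bayk8644", c)$g_CaL,
                numeric(1))
  expect_true(all(diff(gbk) > 0))
  expect_lte(max(gbk), 1.6 * fix_A$g_CaL)
  # composition is multiplicative
  both <- apply_drug(apply_drug(fix_A, "nifedipine", 252), "nifedipine", 252)
  expect_equal(both$g_CaL, fix_A$g_CaL / 4)
})

test_that("Ba2+ removes the endogenous inward rectifier only", {
  expect_identical(apply_barium(fix_C)$g_K1_endo, 0)
  expect_identical(apply_barium(fix_A)$g_K1_endo, 0)
  expect_identical(apply_barium(fix_C)$g_leak, fix_C$g_leak)
})

test_that("cohort generator matches the population table and is seeded", {
  expect_error(generate_cohort(0))
  c1 <- generate_cohort(1, seed = 99)
  c2 <- generate_cohort(1, seed = 99)
  expect_identical(cohort_table(c1), cohort_table(c2))

  coh <- generate_cohort(10000, seed = 1)
  tab <- cohort_table(coh)
  expect_lt(abs(mean(tab$Cm) - 37) / 37, 0.02)
  expect_true(all(tab$Cm > 5))
  # conductances back to implied peak currents via linear scaling
  ina <- tab$g_Na / fix_A$g_Na * -5.4
  ica <- tab$g_CaL / fix_A$g_CaL * -157
  expect_lt(abs(mean(ina) - (-5.4)) / 5.4, 0.05)
  expect_lt(abs(mean(ica) - (-157)) / 157, 0.05)
  expect_true(all(ina <= 0) && all(ica <= 0))
})
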