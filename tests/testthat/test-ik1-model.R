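# The time-dependent inward-rectifier model: gate algebra, steady-state
# rectification and the closed-form gate update against brute-force
# integration.

test_that("slow gate initialises at its steady state and stays there", {
  p <- ik1_params()
  st <- ik1_init_state(p$EK, p)
  for (i in 1:10) st <- ik1_step(st, p$EK, 5e-5, p)$state
  expect_lt(abs(st$y - ik1_init_state(p$EK, p)$y), 1e-12)

  # the closed-form steady state matches long Euler relaxation from y = 0
  for (V in c(-120, 30)) {
    g <- ik1_gating(V, p)
    y_bf <- euler_gate_oracle(function(t) rep(V, length(t)), p,
                              y0 = 0, t_end = 25 * g$tau_y,
                              dt = g$tau_y / 2000)
    expect_lt(abs(ik1_init_state(V, p)$y - y_bf), 1e-6)
  }
})

test_that("steady-state current reverses at EK and rectifies inward", {
  p <- ik1_params()
  expect_identical(ik1_steady_state(p$EK, p), 0)

  # little outward current at depolarised potentials
  v_out <- seq(p$EK + 0.5, -40, by = 0.5)
  i_out <- ik1_steady_state(v_out, p)
  expect_lte(ik1_steady_state(-40, p), 0.10 * max(i_out))

  # inward limb dominates the outward hump
  expect_gt(abs(ik1_steady_state(-120, p)), max(i_out))

  # strong rectification at matched distances from the reversal
  for (dv in seq(10, 40, by = 5)) {
    expect_gt(abs(ik1_steady_state(p$EK - dv, p)),
              abs(ik1_steady_state(p$EK + dv, p)))
  }

  # single outward maximum, then monotone decay up to +40 mV
  v <- seq(p$EK + 0.1, 40, by = 0.1)
  i <- ik1_steady_state(v, p)
  k <- which.max(i)
  expect_lt(v[k], -40)
  expect_true(all(diff(i[seq_len(k)]) > 0))
  expect_true(all(diff(i[k:length(i)]) < 0))
})

test_that("reversal is pinned to EK for any blocker configuration", {
  set.seed(11)
  for (i in 1:20) {
    p <- ik1_params(gK1_density = runif(1, 100, 2000),
                    EK = runif(1, -100, -80),
                    Ko = runif(1, 2, 8), Mg_i = runif(1, 0.2, 3),
                    SPM_i = runif(1, 1, 20),
                    mode1_fraction = runif(1))
    expect_identical(ik1_steady_state(p$EK, p), 0)
    y <- runif(1)
    expect_identical(dynaclamp:::ik1_density_current(p$EK, y, p), 0)
  }
})

test_that("gate update matches fine-step Euler integration along a ramp", {
  p <- ik1_params()
  t_end <- 0.1
  ramp <- function(t) -120 + 150 * t / t_end      # -120 -> +30 mV
  # coarse closed-form stepping at the loop tick
  dt <- 5e-5
  st <- ik1_init_state(ramp(0), p)
  y_coarse <- st$y
  n <- round(t_end / dt)
  for (i in seq_len(n)) {
    st <- ik1_step(st, ramp((i - 1) * dt), dt, p)$state
  }
  y_fine <- euler_gate_oracle(ramp, p, y0 = ik1_init_state(ramp(0), p)$y,
                              t_end = t_end, dt = 1e-7)
  expect_lt(abs(st$y - y_fine), 1e-4)
})

test_that("gate update is stable, bounded and contractive", {
  p <- ik1_params()
  # large steps cannot leave [0, 1]
  st <- ik1_init_state(-120, p)
  for (V in c(40, -140, 40, -140)) {
    st <- ik1_step(st, V, 10, p)$state     # 10 s steps
    expect_gte(st$y, 0); expect_lte(st$y, 1)
  }
  # relaxation limit: holding at constant V converges to y_inf
  st <- ik1_init_state(-40, p)
  g <- ik1_gating(-110, p)
  for (i in seq_len(ceiling(25 * g$tau_y / 5e-3))) {
    st <- ik1_step(st, -110, 5e-3, p)$state
  }
  expect_lt(abs(st$y - g$y_inf), 1e-9)
  # two states driven by the same voltage sequence converge
  set.seed(4)
  vs <- runif(400, -120, 40)
  a <- structure(list(y = 0), class = "ik1_state")
  b <- structure(list(y = 1), class = "ik1_state")
  gap0 <- 1
  for (V in vs) {
    a <- ik1_step(a, V, 5e-3, p)$state
    b <- ik1_step(b, V, 5e-3, p)$state
    expect_lte(abs(a$y - b$y), gap0)
    gap0 <- abs(a$y - b$y)
  }
  expect_lt(gap0, 1e-3)
  # vanishing dt leaves the state unchanged and the current instantaneous
  st <- ik1_init_state(-80, p)
  out <- ik1_step(st, -60, 1e-12, p)
  expect_equal(out$state$y, st$y, tolerance = 1e-9)
  expect_equal(out$I, dynaclamp:::ik1_density_current(-60, out$state$y, p))
  expect_error(ik1_step(st, -60, 0, p), "positive")
})

test_that("IV tabulation is linear in density and zero at the reversal", {
  p <- ik1_params()
  expect_equal(ik1_iv(p, p$EK)$I, 0)
  expect_error(ik1_iv(p, numeric(0)), "empty")
  expect_error(ik1_iv(p, c(-50, -60)), "increasing")
  grid <- seq(-120, 0, by = 1)
  iv1 <- ik1_iv(p, grid)
  p2 <- p; p2$gK1_density <- 2 * p$gK1_density
  expect_equal(ik1_iv(p2, grid)$I, 2 * iv1$I)
  # unique sign change located at the reversal on a fine grid
  expect_equal(ik1_reversal(p), p$EK, tolerance = 1e-6)
})

test_that("density converts to whole-cell current through capacitance", {
  expect_identical(ik1_cell_current(0, 37), 0)
  expect_identical(ik1_cell_current(-10, 37), -370)
  set.seed(2)
  x <- rnorm(20)
  expect_equal(ik1_cell_current(x, 52.1) / 52.1, x)
  expect_error(ik1_cell_current(1, 0), "positive")
})

test_that("reversal defaults to -95 mV with a Nernst alternative", {
  expect_identical(ik1_params()$EK, -95)
  p <- ik1_params(EK = NULL, Ko = 4, Ki = 120, temperature = 20)
  expect_equal(p$EK, dynaclamp:::rtf_mv(20) * log(4 / 120))
  expect_equal(p$EK, -85.9, tolerance = 0.01)
  expect_warning(ik1_params(gK1_density = 50, warn_range = TRUE), "range")
  expect_silent(ik1_params(gK1_density = 50))
})
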