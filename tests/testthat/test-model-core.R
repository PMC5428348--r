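test_that("CFTR current is the stated passive linear form", {
  expect_identical(cftr_current(-60, 0.100, -60), 0)
  expect_identical(cftr_current(123.4, 0, -60), 0)
  expect_equal(cftr_current(-100, 0.100, -60), -4)

  ## exact linearity: I(V1) + I(V2) = 2 I((V1 + V2)/2)
  set.seed(11)
  for (k in 1:50) {
    v <- stats::runif(2, -150, 150)
    expect_identical(cftr_current(v[1], 0.1) + cftr_current(v[2], 0.1),
                     2 * cftr_current(mean(v), 0.1))
  }
  expect_error(cftr_current(-60, -0.1), "non-negative")
})

test_that("rhs matches an independent transcription to machine precision", {
  set.seed(7)
  params_list <- list(
    alpha_cell_parameters(),
    alpha_cell_scenario("glucose6"),
    alpha_cell_parameters(g_CFTR = 0.3, V_Cl = -45, g_KATP = 0.1,
                          g_L = 0.2, V_L = -10, C_m = 7))
  for (p in params_list) {
    for (k in 1:20) {
      st <- random_state()
      expect_equal(alpha_cell_rhs(0, st, p)[[1]],
                   unname(oracle_rhs(st, p)),
                   tolerance = 1e-14, ignore_attr = TRUE)
    }
  }
  ## and at the reference initial condition
  st0 <- default_initial_state()
  expect_equal(alpha_cell_rhs(0, st0, alpha_cell_parameters())[[1]],
               unname(oracle_rhs(st0, alpha_cell_parameters())),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("currents are additive in g_CFTR: dV/dt differs by exactly -I_CFTR/C_m", {
  p0 <- alpha_cell_parameters(g_CFTR = 0)
  p1 <- alpha_cell_parameters(g_CFTR = 0.100)
  for (k in 1:10) {
    st <- random_state()
    d0 <- alpha_cell_rhs(0, st, p0)[[1]]
    d1 <- alpha_cell_rhs(0, st, p1)[[1]]
    expect_equal(unname(d1[1] - d0[1]),
                 -cftr_current(st[["V"]], 0.100, -60) / p0$C_m,
                 tolerance = 1e-12)
    expect_identical(d1[-1], d0[-1])  # gating untouched by the Cl- term
  }
})

test_that("all derivatives vanish at a true equilibrium", {
  ## the high-K_ATP scenario settles to a stable fixed point; polish it
  ## with a long relaxation and check the fixed-point definition
  p <- alpha_cell_scenario("glucose1_highkatp")
  sim <- simulate_alpha_cell(p, 20000, dt = 20)
  st <- c(V = sim$V[length(sim$V)], sim$gating[nrow(sim$gating), ])
  d <- alpha_cell_rhs(0, st, p)[[1]]
  expect_lt(max(abs(d)), 1e-8)
})

test_that("with g_CFTR = 0 the trajectory is bitwise independent of V_Cl", {
  pa <- alpha_cell_parameters(g_CFTR = 0, V_Cl = -60)
  pb <- alpha_cell_parameters(g_CFTR = 0, V_Cl = 55)
  sa <- simulate_alpha_cell(pa, 1500)
  sb <- simulate_alpha_cell(pb, 1500)
  expect_identical(sa$V, sb$V)
  expect_identical(sa$gating, sb$gating)
})

test_that("simulation is deterministic and respects the output grid", {
  p <- alpha_cell_scenario("glucose1")
  s1 <- simulate_alpha_cell(p, 800)
  s2 <- simulate_alpha_cell(p, 800)
  expect_identical(s1$V, s2$V)
  expect_identical(s1$currents, s2$currents)
  expect_equal(diff(s1$t), rep(0.1, length(s1$t) - 1), tolerance = 1e-12)
})

test_that("gating variables stay in [0, 1] along spiking trajectories", {
  for (scen in c("glucose6", "glucose1")) {
    sim <- simulate_alpha_cell(alpha_cell_scenario(scen), 2000)
    expect_gte(min(sim$gating), 0)
    expect_lte(max(sim$gating), 1)
  }
})

test_that("current bookkeeping: C_m dV/dt + sum(I) ~ 0 at interior points", {
  p <- alpha_cell_scenario("glucose1")
  sim <- simulate_alpha_cell(p, 200, dt = 0.01)
  n <- length(sim$V)
  dv <- (sim$V[3:n] - sim$V[1:(n - 2)]) / 0.02
  resid <- p$C_m * dv + rowSums(sim$currents)[2:(n - 1)]
  ## residual is dominated by the O(dt^2) finite-difference error on the
  ## spike upstroke; currents reach hundreds of pA
  expect_lt(stats::median(abs(resid)), 1e-4)
  expect_lt(max(abs(resid)), 0.01)
})

test_that("duration 0 returns only the (burned-in) initial state", {
  z <- simulate_alpha_cell(alpha_cell_scenario("glucose1"), 0)
  expect_length(z$t, 1)
  expect_identical(z$t, 0)
})

test_that("an event patching a parameter to its current value is a no-op", {
  p <- alpha_cell_scenario("glucose1")
  a <- simulate_alpha_cell(p, 600)
  b <- simulate_alpha_cell(p, 600,
                           events = list(list(time = 0,
                                              patch = list(g_CFTR = 0.100))))
  expect_identical(a$V, b$V)
  expect_identical(a$gating, b$gating)
})

test_that("solver convergence: halved tolerances preserve spikes; silent traces converge pointwise", {
  p <- alpha_cell_scenario("glucose1")
  s1 <- simulate_alpha_cell(p, 3000)
  s2 <- simulate_alpha_cell(p, 3000, rtol = 5e-9, atol = 5e-11)
  t1 <- spike_times(s1)$times
  t2 <- spike_times(s2)$times
  expect_identical(length(t1), length(t2))
  expect_lt(max(abs(t1 - t2)), 2)  # ms; spike phase is the sensitive part

  ps <- alpha_cell_scenario("glucose1_highkatp")
  q1 <- simulate_alpha_cell(ps, 3000)
  q2 <- simulate_alpha_cell(ps, 3000, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(q1$V - q2$V)), 1e-9)  # mV, phase-free comparison
})

test_that("parameter validation catches invalid configurations", {
  expect_error(alpha_cell_parameters(g_KATP = -0.1), "conductances")
  expect_error(alpha_cell_parameters(C_m = 0), "C_m")
  expect_error(alpha_cell_parameters(soc_enabled = TRUE), "soc_enabled")
  expect_error(
    alpha_cell_parameters(base_conductances = c(Na = 1, Kv = 2)),
    "named exactly")
  p <- alpha_cell_parameters()
  expect_error(cftralpha:::patch_parameters(p, list(g_unknown = 1)),
               "unknown parameter")
})

test_that("scenario JSON files round-trip through the constructor", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(lowglucose = list(g_KATP = 0.27, g_L = 0.15, g_CFTR = 0.1),
         highglucose = list(g_KATP = 0.2, g_L = 0.2, g_CFTR = 0.1)),
    path, auto_unbox = TRUE)
  sc <- read_scenarios_json(path)
  expect_named(sc, c("lowglucose", "highglucose"))
  expect_equal(sc$lowglucose$g_KATP, 0.27)
  expect_s3_class(sc$lowglucose, "alpha_cell_parameters")
})
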