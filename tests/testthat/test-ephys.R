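test_that("slope conductance: exact lines and degenerate cases", {
  ## exact line through (-100, -4) and (-50, 0): slope 0.080 nS
  rec <- ramp_recording(c(-100, -50), c(-4, 0), "control", C_m = 5)
  expect_equal(slope_conductance(rec, c(-100, -50)), 0.080,
               tolerance = 1e-12)

  V <- seq(-100, 100, by = 1)
  const <- ramp_recording(V, rep(3, length(V)), "control", C_m = 5)
  expect_equal(slope_conductance(const), 0, tolerance = 1e-12)

  expect_error(slope_conductance(rec, c(-200, -150)), "fewer than 2")
})

test_that("noiseless generator round-trip recovers conductance to >= 6 digits", {
  cfg <- generator_config(seed = 5,
                          ramp = list(noise_sd_pA = 0,
                                      conductance_jitter_sdlog = 0,
                                      share_sd_pct = 0, n_cells = 2))
  cells <- gen_ramp_triplets(cfg)
  for (cl in cells) {
    an <- analyze_ramp_triplet(cl$control, cl$forskolin,
                               cl$forskolin_inhibitor)
    expect_equal(an$slope_conductance, cl$truth$g_cftr_nS,
                 tolerance = 1e-9)
    expect_equal(an$conductance_density, cl$truth$density_pS_pF,
                 tolerance = 1e-9)
    expect_equal(an$reversal, cl$truth$reversal_mV, tolerance = 1e-7)
    expect_equal(as.numeric(an$cftr_fraction), cl$truth$share_pct,
                 tolerance = 1e-9)
  }
})

test_that("difference currents obey linear arithmetic", {
  V <- seq(-100, 100, by = 0.5)
  a <- ramp_recording(V, 0.3 * (V + 61), "forskolin", C_m = 5)
  b <- ramp_recording(V, 0.1 * (V + 61), "control", C_m = 5)
  d <- difference_current(a, b)
  expect_equal(slope_conductance(d, c(-100, -50)), 0.2, tolerance = 1e-12)
  expect_equal(reversal_potential(d), -61, tolerance = 1e-9)

  self <- difference_current(a, a)
  expect_true(all(self$I == 0))
})

test_that("difference currents resample mismatched grids and reject disjoint ones", {
  Va <- seq(-90, 90, by = 1)
  Vb <- seq(-100, 100, by = 0.7)
  a <- ramp_recording(Va, 0.2 * (Va + 50), "forskolin", C_m = 5)
  b <- ramp_recording(Vb, 0.1 * (Vb + 50), "control", C_m = 5)
  d <- difference_current(a, b)
  expect_equal(slope_conductance(d, c(-90, -40)), 0.1, tolerance = 1e-9)

  b_short <- ramp_recording(seq(-50, 50, by = 1), rnorm(101), "control",
                            C_m = 5)
  expect_error(difference_current(a, b_short), "overlap")
})

test_that("CFTR fraction from slopes: full block, no block, arithmetic", {
  V <- seq(-100, 100, by = 0.5)
  mk <- function(I, cond) ramp_recording(V, I, cond, C_m = 5)
  leak <- 0.1 * (V + 70)
  act <- 0.3 * (V + 50)
  ctrl <- mk(leak, "control")
  fsk <- mk(leak + act, "forskolin")

  expect_equal(cftr_fraction(ctrl, fsk, mk(leak, "forskolin_inhibitor")),
               100, tolerance = 1e-9)
  expect_equal(cftr_fraction(ctrl, fsk, mk(leak + act, "forskolin_inhibitor")),
               0, tolerance = 1e-9)
  ## activated slope 0.3, CFTR-dependent slope 0.225 -> 75%
  inh <- mk(leak + act - 0.225 * (V + 55), "forskolin_inhibitor")
  expect_equal(cftr_fraction(ctrl, fsk, inh), 75, tolerance = 1e-9)

  expect_error(cftr_fraction(ctrl, ctrl, ctrl), "floor")
})

test_that("reversal potential is voltage-offset equivariant; estimators current-scale equivariant", {
  V <- seq(-100, 100, by = 0.5)
  set.seed(21)
  I <- 0.1 * (V + 60) + rnorm(length(V), 0, 0.5)
  d0 <- structure(list(V = V, I = I), class = "ramp_difference")
  delta <- 7.5
  d1 <- structure(list(V = V + delta, I = I), class = "ramp_difference")
  expect_equal(reversal_potential(d1, c(-90 + delta, -30 + delta)),
               reversal_potential(d0) + delta, tolerance = 1e-9)

  ## current rescaling multiplies the slope, leaves the reversal fixed
  d2 <- structure(list(V = V, I = 3 * I), class = "ramp_difference")
  expect_equal(reversal_potential(d2), reversal_potential(d0),
               tolerance = 1e-9)
  r0 <- ramp_recording(V, I, "control", C_m = 5)
  r2 <- ramp_recording(V, 3 * I, "control", C_m = 5)
  expect_equal(slope_conductance(r2), 3 * slope_conductance(r0),
               tolerance = 1e-9)
})

test_that("slope and reversal estimators are unbiased over repeated noisy generation", {
  ## 200 independent single-cell generations, no biological jitter: the
  ## only variation is additive current noise, so estimator means must
  ## approach the programmed truth within Monte-Carlo error
  dens <- numeric(200)
  rev <- numeric(200)
  for (k in 1:200) {
    cfg <- generator_config(seed = 1000 + k,
                            ramp = list(n_cells = 1,
                                        conductance_jitter_sdlog = 0,
                                        share_sd_pct = 0))
    cl <- gen_ramp_triplets(cfg)[[1]]
    d <- difference_current(cl$forskolin, cl$forskolin_inhibitor)
    dens[k] <- 1000 * slope_conductance(d, c(-100, -50)) / 5
    rev[k] <- reversal_potential(d)
  }
  expect_lt(abs(mean(dens) - 61), 3 * stats::sd(dens) / sqrt(200))
  expect_lt(abs(mean(rev) - (-61)), 3 * stats::sd(rev) / sqrt(200))
})

test_that("idealization: constructed traces and degenerate cases", {
  ## flat noiseless trace: no openings, p_o = 0, amplitude undefined
  flat <- single_channel_trace(rep(0.02, 5000), sampling_khz = 10)
  ide0 <- idealize(flat, filter = FALSE)
  expect_identical(ide0$p_o, 0)
  expect_false(ide0$amplitude_defined)

  ## square trace open exactly 250 of 1000 ms at 0.7 pA
  n <- 10000
  I <- rep(0, n)
  I[2501:5000] <- -0.7
  sq <- single_channel_trace(I, sampling_khz = 10)
  ide <- idealize(sq, filter = FALSE)
  expect_equal(ide$p_o, 0.25, tolerance = 0.002)
  expect_equal(ide$amplitude, 0.7, tolerance = 0.02)
  expect_identical(ide$n_levels, 1L)
})

test_that("open probability converges to the stationary alpha/(alpha+beta)", {
  cfg <- generator_config(seed = 9,
                          single_channel = list(duration_s = 30))
  g <- gen_single_channel(cfg)
  ide <- idealize(g$trace)
  p <- g$truth$p_o_stationary
  a <- cfg$single_channel$open_rate_hz
  b <- cfg$single_channel$close_rate_hz
  ## occupancy variance of a stationary two-state chain over T seconds
  se <- sqrt(2 * p^2 * (1 - p)^2 * (1 / a + 1 / b) /
               cfg$single_channel$duration_s)
  expect_lt(abs(ide$p_o - p), 4 * se)
  ## the idealized path also matches the realized path occupancy closely
  expect_lt(abs(ide$p_o - g$truth$p_o_path), 0.02)
})

test_that("filtering is zero-phase: idealized transitions stay centred", {
  ## a single long opening; the filtered half-amplitude crossings must
  ## bracket the true edges symmetrically
  n <- 20000
  I <- rep(0, n)
  I[8001:12000] <- -0.7
  tr <- single_channel_trace(I, sampling_khz = 10)
  ide <- idealize(tr, filter = TRUE)
  on <- range(which(ide$states == 1L))
  expect_lt(abs((on[1] - 8001) + (on[2] - 12000)), 6)  # samples
})

test_that("capacitance sums: additivity is exact for arbitrary trains", {
  t1 <- capacitance_train(rep(10, 10))
  expect_identical(capacitance_sums(t1),
                   list(sum_all = 100, sum_1_2 = 20, sum_3_10 = 80))
  t0 <- capacitance_train(rep(0, 10))
  expect_identical(capacitance_sums(t0),
                   list(sum_all = 0, sum_1_2 = 0, sum_3_10 = 0))
  decl <- capacitance_train(seq(20, by = -1.5, length.out = 10))
  s <- capacitance_sums(decl)
  expect_identical(s$sum_all, s$sum_1_2 + s$sum_3_10)

  set.seed(3)
  for (k in 1:20) {
    s <- capacitance_sums(capacitance_train(rnorm(10, 10, 8)))
    expect_identical(s$sum_all, s$sum_1_2 + s$sum_3_10)
  }
  expect_error(capacitance_train(rep(1, 9)), "exactly 10")
})
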