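## Independent second transcription of the alpha-cell ODE system, written
## directly from the equation list without reusing any package internals.
## Serves as the two-pass transcription oracle for alpha_cell_rhs().

oracle_rhs <- function(state, p) {
  V <- state[["V"]]
  boltz <- function(vh, s) 1 / (1 + exp((vh - V) / s))

  i_na   <- p$base_conductances[["Na"]] * state[["mNa"]]^3 * state[["hNa"]] *
    (V - p$base_reversals[["Na"]])
  i_cat  <- p$base_conductances[["CaT"]] * state[["mCaT"]]^3 * state[["hCaT"]] *
    (V - p$base_reversals[["Ca"]])
  i_cal  <- p$base_conductances[["CaL"]] * state[["mCaL"]]^2 * state[["hCaL"]] *
    (V - p$base_reversals[["Ca"]])
  i_capq <- p$base_conductances[["CaPQ"]] * state[["mCaPQ"]] *
    (V - p$base_reversals[["Ca"]])
  i_k    <- p$base_conductances[["K"]] * state[["mK"]]^4 *
    (V - p$base_reversals[["K"]])
  i_ka   <- p$base_conductances[["KA"]] * state[["mKA"]] * state[["hKA"]] *
    (V - p$base_reversals[["K"]])
  i_katp <- p$g_KATP * (V - p$base_reversals[["K"]])
  i_leak <- p$g_L * (V - p$V_L)
  i_cftr <- p$g_CFTR * (V - p$V_Cl)

  dV <- -(i_na + i_cat + i_cal + i_capq + i_k + i_ka + i_katp + i_leak +
            i_cftr) / p$C_m

  ## gate kinetics: (vhalf, slope, tau) per variable
  kin <- list(mNa  = c(-30, 5, 0.15),  hNa  = c(-48, -7, 6),
              mCaT = c(-49, 4, 0.5),   hCaT = c(-52, -7, 80),
              mCaL = c(-25, 6, 1),     hCaL = c(-30, -6, 60),
              mCaPQ = c(0, 8, 1),      mK   = c(-22, 6, 4),
              mKA  = c(-45, 10, 0.15), hKA  = c(-68, -10, 10))
  dg <- vapply(names(kin), function(nm) {
    k <- kin[[nm]]
    (boltz(k[1], k[2]) - state[[nm]]) / k[3]
  }, numeric(1))
  c(V = dV, dg)
}

## random-but-valid model states for property checks
random_state <- function() {
  g <- stats::runif(10)
  names(g) <- c("mNa", "hNa", "mCaT", "hCaT", "mCaL", "hCaL", "mCaPQ",
                "mK", "mKA", "hKA")
  c(V = stats::runif(1, -90, 30), g)
}

## minimal simulation object wrapping a hand-built voltage trace, for
## spike-detection tests that need full control over the waveform
fake_sim <- function(t, V, ica = NULL) {
  cur <- matrix(0, nrow = length(t), ncol = 9,
                dimnames = list(NULL, alpha_cell_current_names()))
  if (!is.null(ica)) cur[, "CaL"] <- ica
  structure(list(t = t, V = V,
                 gating = matrix(0.5, length(t), 10),
                 currents = cur,
                 params_used = list(list(time = 0,
                                         params = alpha_cell_parameters()))),
            class = "alpha_cell_sim")
}

## a 1 s trace carrying n identical spike waveforms above the -20 mV
## threshold on a -60 mV baseline
spike_train_sim <- function(n_spikes, dt = 0.1, dur = 1000,
                            peak = 10, baseline = -60) {
  t <- seq(0, dur, by = dt)
  V <- rep(baseline, length(t))
  if (n_spikes > 0) {
    centers <- seq(dur / (2 * n_spikes), dur - dur / (2 * n_spikes),
                   length.out = n_spikes)
    for (ct in centers) {
      idx <- which(abs(t - ct) <= 2)           # 4 ms triangular spike
      V[idx] <- baseline + (peak - baseline) * (1 - abs(t[idx] - ct) / 2)
    }
  }
  fake_sim(t, V)
}
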