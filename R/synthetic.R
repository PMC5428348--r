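#' Synthetic-data generator configuration
#'
#' One configuration object drives every generator. Defaults are the
#' experimental point estimates the analyses are meant to recover: a
#' CFTR-dependent conductance density of 61 pS/pF reversing at -61 mV and
#' constituting 76% of the forskolin-activated current for ramp triplets; a
#' ~0.7 pA single-channel amplitude at a -50 mV holding potential; a 2-fold
#' forskolin stimulation of human glucagon secretion at low (2.8 mM)
#' glucose, 3-fold under 50 mM K+ depolarization, and a 30% increment by
#' CFTR inhibition (GlyH-101) over forskolin in mouse islets at 1 mM
#' glucose; and a membrane band twice as bright as the cytosol in stained
#' single cells. Dispersion settings (jitter, noise, replicate CV) are
#' package choices sized to give realistic spread around those estimates.
#'
#' The seed is mandatory: no generator draws from an implicit RNG state.
#'
#' @param seed Integer seed; required.
#' @param ramp,single_channel,capacitance,secretion,image Named lists of
#'   overrides for the corresponding generator's defaults (see the list
#'   below).
#' @return Object of class `generator_config`.
#' @section Defaults:
#' \describe{
#'   \item{ramp}{`C_m_pF = 5`, `cftr_density_pS_pF = 61`,
#'     `reversal_mV = -61`, `cftr_share_pct = 76`, `share_sd_pct = 5`,
#'     `conductance_jitter_sdlog = 0.25`, `leak_nS = 0.4`,
#'     `leak_reversal_mV = -75`, `activated_reversal_mV = -20`,
#'     `noise_sd_pA = 2`, `n_cells = 5`, `n_points = 401`}
#'   \item{single_channel}{`amplitude_pA = 0.7`, `open_rate_hz = 30`,
#'     `close_rate_hz = 70`, `noise_sd_pA = 0.2`, `duration_s = 60`,
#'     `sampling_khz = 10`, `holding_V = -50`}
#'   \item{capacitance}{`first_pulse_fF = 50`, `depression = 0.85`,
#'     `noise_sd_fF = 3`}
#'   \item{secretion}{`human_forskolin_fold = 2`,
#'     `human_forskolin_glyh_fold = 2.6`, `human_K_forskolin_fold = 3`,
#'     `mouse_forskolin_fold = 2.5`, `mouse_glyh_increment = 0.30`,
#'     `n_donors_human = 9`, `n_experiments_mouse = 4`,
#'     `n_replicates = 4`, `donor_sdlog = 0.4`, `effect_sdlog = 0.1`,
#'     `replicate_cv = 0.15`, `baseline_value = 10`}
#'   \item{image}{`radius_um = 6`, `band_width_um = 0.5`,
#'     `band_intensity_ratio = 2`, `interior_intensity = 100`,
#'     `pixel_size_um = 0.1`, `noise_sd = 0`}
#' }
#' @export
generator_config <- function(seed, ramp = list(), single_channel = list(),
                             capacitance = list(), secretion = list(),
                             image = list()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed))
    stop("an explicit integer seed is required")
  defaults <- list(
    ramp = list(C_m_pF = 5, cftr_density_pS_pF = 61, reversal_mV = -61,
                cftr_share_pct = 76, share_sd_pct = 5,
                conductance_jitter_sdlog = 0.25, leak_nS = 0.4,
                leak_reversal_mV = -75, activated_reversal_mV = -20,
                noise_sd_pA = 2, n_cells = 5, n_points = 401),
    single_channel = list(amplitude_pA = 0.7, open_rate_hz = 30,
                          close_rate_hz = 70, noise_sd_pA = 0.2,
                          duration_s = 60, sampling_khz = 10,
                          holding_V = -50),
    capacitance = list(first_pulse_fF = 50, depression = 0.85,
                       noise_sd_fF = 3),
    secretion = list(human_forskolin_fold = 2, human_forskolin_glyh_fold = 2.6,
                     human_K_forskolin_fold = 3, mouse_forskolin_fold = 2.5,
                     mouse_glyh_increment = 0.30, n_donors_human = 9,
                     n_experiments_mouse = 4, n_replicates = 4,
                     donor_sdlog = 0.4, effect_sdlog = 0.1,
                     replicate_cv = 0.15, baseline_value = 10),
    image = list(radius_um = 6, band_width_um = 0.5,
                 band_intensity_ratio = 2, interior_intensity = 100,
                 pixel_size_um = 0.1, noise_sd = 0))
  merge_one <- function(name, user) {
    bad <- setdiff(names(user), names(defaults[[name]]))
    if (length(bad))
      stop("unknown ", name, " setting(s): ", paste(bad, collapse = ", "))
    utils::modifyList(defaults[[name]], user)
  }
  cfg <- list(seed = as.integer(seed),
              ramp = merge_one("ramp", ramp),
              single_channel = merge_one("single_channel", single_channel),
              capacitance = merge_one("capacitance", capacitance),
              secretion = merge_one("secretion", secretion),
              image = merge_one("image", image))
  with(cfg$single_channel, {
    if (open_rate_hz < 0 || close_rate_hz <= 0 || duration_s <= 0 ||
        sampling_khz <= 0)
      stop("single-channel rates and durations must be positive")
  })
  structure(cfg, class = "generator_config")
}

## mean-corrected lognormal multiplier: E[jitter] = 1
lognormal_jitter <- function(n, sdlog) {
  if (sdlog == 0) return(rep(1, n))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Generate synthetic whole-cell ramp triplets
#'
#' For each cell, a (control, forskolin, forskolin+inhibitor) triplet on a
#' common -100 to +100 mV ramp. The control sweep is a leak line; forskolin
#' adds an activated conductance of which the CFTR share is a linear
#' component reversing at the configured chloride reversal; the inhibitor
#' condition removes exactly that CFTR component. Per-cell CFTR
#' conductances are jittered lognormally (mean-corrected) around the
#' default density, the CFTR share is jittered normally, and i.i.d.
#' Gaussian current noise is added to every sweep. Ramp nonlinearities
#' (e.g. voltage-dependent inhibitor block at positive potentials) are
#' deliberately not modelled; the analysis windows sit at negative
#' potentials where the linear description holds.
#'
#' @param cfg A [generator_config()].
#' @return List with one element per cell: `control`, `forskolin`,
#'   `forskolin_inhibitor` ([ramp_recording()]s) and `truth` (list of the
#'   cell's true `g_cftr_nS`, `density_pS_pF`, `reversal_mV`, `share_pct`,
#'   `g_activated_nS`).
#' @export
gen_ramp_triplets <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  r <- cfg$ramp
  V <- seq(-100, 100, length.out = r$n_points)
  lapply(seq_len(r$n_cells), function(i) {
    cid <- sprintf("cell%02d", i)
    g_cftr <- r$cftr_density_pS_pF / 1000 * r$C_m_pF *
      lognormal_jitter(1, r$conductance_jitter_sdlog)
    share <- min(99, max(20, r$cftr_share_pct +
                               stats::rnorm(1, 0, r$share_sd_pct)))
    g_act <- g_cftr / (share / 100)
    g_other <- g_act - g_cftr
    leak <- r$leak_nS * (V - r$leak_reversal_mV)
    i_cftr <- g_cftr * (V - r$reversal_mV)
    i_other <- g_other * (V - r$activated_reversal_mV)
    noisy <- function(I) I + stats::rnorm(length(V), 0, r$noise_sd_pA)
    list(control = ramp_recording(V, noisy(leak), "control",
                                  r$C_m_pF, cid),
         forskolin = ramp_recording(V, noisy(leak + i_cftr + i_other),
                                    "forskolin", r$C_m_pF, cid),
         forskolin_inhibitor = ramp_recording(V, noisy(leak + i_other),
                                              "forskolin_inhibitor",
                                              r$C_m_pF, cid),
         truth = list(g_cftr_nS = g_cftr,
                      density_pS_pF = 1000 * g_cftr / r$C_m_pF,
                      reversal_mV = r$reversal_mV,
                      share_pct = share,
                      g_activated_nS = g_act))
  })
}

#' Generate a synthetic two-state single-channel trace
#'
#' Samples a continuous-time two-state Markov chain (closed <-> open, with
#' opening rate alpha and closing rate beta, both per second) by exact
#' exponential dwell times, discretizes it on the sampling grid, adds the
#' open-level deflection (downward, -amplitude pA) and Gaussian noise. The
#' stationary open probability of the chain is alpha/(alpha+beta). The
#' ground-truth state path is returned for oracle tests.
#'
#' @param cfg A [generator_config()].
#' @return List: `trace` ([single_channel_trace()]), `truth` (list with
#'   `states` per sample, `p_o_stationary`, `p_o_path` = realized open
#'   fraction, `amplitude_pA`).
#' @export
gen_single_channel <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  s <- cfg$single_channel
  n <- round(s$duration_s * s$sampling_khz * 1000)
  dt_s <- 1 / (s$sampling_khz * 1000)
  states <- integer(n)
  if (s$open_rate_hz > 0) {
    t_cur <- 0; state <- 0L; k <- 1L
    while (t_cur < s$duration_s && k <= n) {
      rate <- if (state == 0L) s$open_rate_hz else s$close_rate_hz
      dwell <- stats::rexp(1, rate)
      k_end <- min(n, ceiling((t_cur + dwell) / dt_s))
      if (k_end >= k) states[k:k_end] <- state
      k <- k_end + 1L
      t_cur <- t_cur + dwell
      state <- 1L - state
    }
  }
  I <- -s$amplitude_pA * states +
    stats::rnorm(n, 0, s$noise_sd_pA)
  list(trace = single_channel_trace(I, s$sampling_khz, s$holding_V),
       truth = list(states = states,
                    p_o_stationary = s$open_rate_hz /
                      (s$open_rate_hz + s$close_rate_hz),
                    p_o_path = mean(states),
                    amplitude_pA = s$amplitude_pA))
}

#' Generate a synthetic capacitance train
#'
#' Ten per-pulse capacitance increments with geometric depression across
#' the train (pulse k carries `first_pulse * depression^(k-1)` fF) plus
#' Gaussian noise, emulating pool depletion over repeated depolarizations.
#'
#' @param cfg A [generator_config()].
#' @return List: `train` ([capacitance_train()]), `truth` (noise-free
#'   increments and their `sum_all`, `sum_1_2`, `sum_3_10`).
#' @export
gen_capacitance_train <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  cc <- cfg$capacitance
  clean <- cc$first_pulse_fF * cc$depression^(0:9)
  noisy <- clean + stats::rnorm(10, 0, cc$noise_sd_fF)
  list(train = capacitance_train(noisy),
       truth = list(dCm_fF = clean, sum_all = sum(clean),
                    sum_1_2 = sum(clean[1:2]), sum_3_10 = sum(clean[3:10])))
}

#' Generate a synthetic secretion table
#'
#' Emulates static batch-incubation designs: per-experiment lognormal
#' baselines, programmed condition folds (jittered lognormally per
#' experiment, mean-corrected), and lognormal technical-replicate noise in
#' quadruplicates. The human design covers a low-glucose block (baseline,
#' forskolin, forskolin+GlyH-101) and a 50 mM K+ depolarization block
#' (baseline, +forskolin); the mouse design covers a 1 mM glucose block
#' (baseline, forskolin, forskolin+GlyH-101) where GlyH-101 adds the
#' configured increment over forskolin.
#'
#' @param cfg A [generator_config()].
#' @param species `"human"`, `"mouse"` or both.
#' @return List: `table` ([secretion_table()]), `truth` (named list of the
#'   programmed folds per block/condition).
#' @export
gen_secretion_table <- function(cfg, species = c("human", "mouse")) {
  stopifnot(inherits(cfg, "generator_config"))
  species <- match.arg(species, several.ok = TRUE)
  set.seed(cfg$seed)
  sc <- cfg$secretion
  designs <- list()
  if ("human" %in% species) {
    designs <- c(designs, list(
      list(species = "human", glucose = 2.8, n = sc$n_donors_human,
           folds = c(baseline = 1,
                     forskolin = sc$human_forskolin_fold,
                     forskolin_glyh = sc$human_forskolin_glyh_fold)),
      list(species = "human", glucose = 1, n = sc$n_donors_human,
           ## 50 mM K+ depolarization block at 1 mM glucose
           folds = c(baseline = 1,
                     K50 = 1.5,
                     K50_forskolin = 1.5 * sc$human_K_forskolin_fold))))
  }
  if ("mouse" %in% species) {
    designs <- c(designs, list(
      list(species = "mouse", glucose = 1, n = sc$n_experiments_mouse,
           folds = c(baseline = 1,
                     forskolin = sc$mouse_forskolin_fold,
                     forskolin_glyh = sc$mouse_forskolin_fold *
                       (1 + sc$mouse_glyh_increment)))))
  }
  rows <- list()
  truth <- list()
  rep_sdlog <- sqrt(log(1 + sc$replicate_cv^2))
  for (d in designs) {
    block_key <- sprintf("%s_glucose%g", d$species, d$glucose)
    truth[[block_key]] <- d$folds
    for (e in seq_len(d$n)) {
      base_e <- sc$baseline_value * lognormal_jitter(1, sc$donor_sdlog)
      for (cond in names(d$folds)) {
        mu_e <- base_e * d$folds[[cond]] *
          (if (cond == "baseline") 1
           else lognormal_jitter(1, sc$effect_sdlog))
        vals <- mu_e * lognormal_jitter(sc$n_replicates, rep_sdlog)
        rows[[length(rows) + 1L]] <- data.frame(
          hormone = "glucagon", species = d$species,
          glucose_mM = d$glucose, condition = cond,
          experiment_id = sprintf("%s_exp%02d", d$species, e),
          replicate_id = seq_len(sc$n_replicates), value = vals)
      }
    }
  }
  list(table = secretion_table(do.call(rbind, rows)), truth = truth)
}

#' Generate a synthetic membrane-stained cell image
#'
#' A disk-shaped cell whose boundary band (the configured membrane width)
#' is brighter than the interior by the configured ratio, plus optional
#' Gaussian pixel noise — the geometry assumed by the membrane-to-cytosol
#' ratio measurement.
#'
#' @param cfg A [generator_config()].
#' @return List: `image` ([cell_image()]), `truth` (`ratio`).
#' @export
gen_membrane_image <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  im <- cfg$image
  r_px <- im$radius_um / im$pixel_size_um
  n <- 2L * ceiling(r_px) + 9L
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  mask <- (d <= r_px) * 1
  band <- mask > 0 & d > r_px - im$band_width_um / im$pixel_size_um
  intensity <- matrix(0, n, n)
  intensity[mask > 0] <- im$interior_intensity
  intensity[band] <- im$interior_intensity * im$band_intensity_ratio
  if (im$noise_sd > 0)
    intensity <- intensity + matrix(stats::rnorm(n * n, 0, im$noise_sd), n, n)
  list(image = cell_image(intensity, mask, im$pixel_size_um),
       truth = list(ratio = im$band_intensity_ratio))
}
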