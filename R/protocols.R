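#' Action-potential firing frequency
#'
#' Counts upward threshold crossings of the membrane-potential trace,
#' enforcing a refractory separation between accepted spikes, and divides by
#' the window length. Alpha-cell action potentials in this model overshoot
#' roughly 0 mV, so the default -20 mV threshold sits well above the
#' interspike baseline and well below the spike peak.
#'
#' @param sim An `alpha_cell_sim` object (from [simulate_alpha_cell()]).
#' @param window Analysis window `c(t_start, t_end)` in ms, or `NULL` for
#'   the whole trace.
#' @param threshold Spike detection threshold (mV). Default -20 mV.
#' @param refractory Minimum separation between accepted spikes (ms).
#'   Default 10 ms.
#' @return Firing frequency in Hz (>= 0).
#' @export
firing_frequency <- function(sim, window = NULL, threshold = -20,
                             refractory = 10) {
  st <- spike_times(sim, window, threshold, refractory)
  1000 * length(st$times) / st$window_ms
}

#' Spike times by threshold crossing
#'
#' @inheritParams firing_frequency
#' @return List with `times` (ms, accepted upward crossings) and
#'   `window_ms` (window length).
#' @export
spike_times <- function(sim, window = NULL, threshold = -20,
                        refractory = 10) {
  stopifnot(inherits(sim, "alpha_cell_sim"))
  t <- sim$t; V <- sim$V
  if (!is.null(window)) {
    if (length(window) != 2 || window[2] <= window[1])
      stop("window must be c(t_start, t_end) with t_end > t_start")
    keep <- t >= window[1] & t <= window[2]
    if (sum(keep) < 2) stop("window contains fewer than 2 samples")
    t <- t[keep]; V <- V[keep]
  }
  n <- length(V)
  up <- which(V[-1L] >= threshold & V[-n] < threshold) + 1L
  times <- numeric(0)
  last <- -Inf
  for (tt in t[up]) {
    if (tt - last >= refractory) {
      times <- c(times, tt)
      last <- tt
    }
  }
  list(times = times, window_ms = t[length(t)] - t[1L])
}

#' Classify a trace as silent or spiking
#'
#' A trace is `"silent"` on the window if and only if its firing frequency
#' there is zero.
#'
#' @inheritParams firing_frequency
#' @return `"silent"` or `"spiking"`.
#' @export
classify_regime <- function(sim, window = NULL, threshold = -20,
                            refractory = 10) {
  if (firing_frequency(sim, window, threshold, refractory) > 0)
    "spiking" else "silent"
}

#' CFTR-inhibition switch protocol
#'
#' Simulates a cell that runs with its CFTR conductance operating and then
#' has it removed instantaneously at `t_switch` (no inhibitor binding
#' kinetics are modelled). Firing frequency and regime are evaluated on the
#' final `window_len` ms of each phase; the post-switch window additionally
#' excludes a `settle` ms margin after the switch.
#'
#' @param params An [alpha_cell_parameters()] object (its `g_CFTR` is the
#'   pre-switch conductance).
#' @param t_switch Switch time (ms). Default 5000 ms.
#' @param total Total simulated time (ms). Default 10000 ms.
#' @param window_len Length of the pre- and post-switch analysis windows
#'   (ms). Default 2000 ms.
#' @param settle Settling margin after the switch excluded from analysis
#'   (ms). Default 200 ms.
#' @param scenario_name Optional label stored in the result.
#' @param threshold,refractory Spike detection settings, see
#'   [firing_frequency()].
#' @param ... Further arguments to [simulate_alpha_cell()].
#' @return An object of class `alpha_cell_protocol`: list with
#'   `scenario_name`, `pre_frequency`, `post_frequency` (Hz), `pre_regime`,
#'   `post_regime` (`"silent"`/`"spiking"`), and `trace`.
#' @examples
#' \donttest{
#' res <- cftr_inhibition_protocol(alpha_cell_scenario("glucose1"),
#'                                 t_switch = 2000, total = 4000,
#'                                 window_len = 1500)
#' res$post_frequency > res$pre_frequency
#' }
#' @export
cftr_inhibition_protocol <- function(params, t_switch = 5000, total = 10000,
                                     window_len = 2000, settle = 200,
                                     scenario_name = NULL,
                                     threshold = -20, refractory = 10, ...) {
  if (!(t_switch > 0 && t_switch < total))
    stop("t_switch must satisfy 0 < t_switch < total")
  if (window_len > t_switch)
    stop("window_len must not exceed t_switch")
  if (total - t_switch - settle < window_len)
    stop("post-switch phase too short for the analysis window plus settling margin")
  sim <- simulate_alpha_cell(params, duration = total,
                             events = list(list(time = t_switch,
                                                patch = list(g_CFTR = 0))),
                             ...)
  pre_w <- c(t_switch - window_len, t_switch)
  post_w <- c(total - window_len, total)
  pre_f <- firing_frequency(sim, pre_w, threshold, refractory)
  post_f <- firing_frequency(sim, post_w, threshold, refractory)
  structure(list(scenario_name = scenario_name,
                 pre_frequency = pre_f, post_frequency = post_f,
                 pre_regime = if (pre_f > 0) "spiking" else "silent",
                 post_regime = if (post_f > 0) "spiking" else "silent",
                 trace = sim),
            class = "alpha_cell_protocol")
}

#' @export
print.alpha_cell_protocol <- function(x, ...) {
  cat(sprintf("CFTR-inhibition protocol%s\n",
              if (!is.null(x$scenario_name)) paste0(" [", x$scenario_name, "]")
              else ""))
  cat(sprintf("  with CFTR:    %s, %.2f Hz\n", x$pre_regime, x$pre_frequency))
  cat(sprintf("  CFTR removed: %s, %.2f Hz\n", x$post_regime, x$post_frequency))
  invisible(x)
}

#' Secretion proxy from simulated electrical activity
#'
#' A deliberately simple scalar mapping electrical activity to a relative
#' secretion rate, used to make the bell-shaped dependence of glucagon
#' secretion on the K_ATP conductance testable. It is defined as the time
#' average over the window of a saturating (Hill) function of the total
#' calcium-current magnitude,
#' \deqn{proxy = \langle |I_{Ca}|^4 / (|I_{Ca}|^4 + K^4) \rangle,}
#' gated to exactly zero when the window contains no spikes. The Hill form
#' rewards the large calcium transients of full action potentials over
#' tonic window currents; the half-saturation `K` = 20 pA sits between the
#' two. No quantitative secretion claim is attached to this construction.
#'
#' @param sim An `alpha_cell_sim` object.
#' @param window Analysis window (ms) or `NULL` for the whole trace.
#' @param K Half-saturation calcium-current magnitude (pA). Default 20.
#' @param hill Hill exponent. Default 4.
#' @param threshold,refractory Spike detection settings used for gating.
#' @return Dimensionless rate in \[0, 1\]; 0 for silent traces.
#' @export
secretion_proxy <- function(sim, window = NULL, K = 20, hill = 4,
                            threshold = -20, refractory = 10) {
  stopifnot(inherits(sim, "alpha_cell_sim"))
  if (firing_frequency(sim, window, threshold, refractory) == 0)
    return(0)
  keep <- if (is.null(window)) rep(TRUE, length(sim$t))
          else sim$t >= window[1] & sim$t <= window[2]
  ica <- abs(rowSums(sim$currents[keep, c("CaT", "CaL", "CaPQ"),
                                  drop = FALSE]))
  mean(ica^hill / (ica^hill + K^hill))
}

#' Scan electrical activity across the K_ATP conductance
#'
#' Runs one steady-state simulation per grid point, with and/or without the
#' CFTR conductance, and reports firing frequency and secretion proxy. With
#' CFTR operating, the activity boundary (the largest `g_KATP` that still
#' yields spiking) is left-shifted: cells near the boundary are silenced by
#' the additional chloride shunt.
#'
#' @param base_params An [alpha_cell_parameters()] object; its `g_CFTR` is
#'   used for the CFTR-on arm.
#' @param grid Numeric vector of `g_KATP` values (nS), all >= 0.
#' @param cftr_on Logical; compute the CFTR-on arm (`TRUE`) or the arm with
#'   `g_CFTR = 0` (`FALSE`), or both when `cftr_on = c(TRUE, FALSE)`.
#' @param duration Simulated time per point (ms) after burn-in. The
#'   analysis window is the final `window_len` ms.
#' @param window_len Analysis window length (ms).
#' @param ... Passed to [simulate_alpha_cell()] and [secretion_proxy()].
#' @return An object of class `alpha_cell_scan`: data.frame with columns
#'   `g_katp_nS`, `cftr`, `freq_hz`, `proxy`.
#' @export
gkatp_scan <- function(base_params, grid, cftr_on = c(TRUE, FALSE),
                       duration = 4000, window_len = 2000, ...) {
  stopifnot(inherits(base_params, "alpha_cell_parameters"))
  if (!length(grid) || any(grid < 0))
    stop("grid must be a non-empty vector of non-negative conductances")
  rows <- list()
  for (on in cftr_on) {
    for (gk in grid) {
      p <- patch_parameters(base_params,
                            list(g_KATP = gk,
                                 g_CFTR = if (on) base_params$g_CFTR else 0))
      sim <- simulate_alpha_cell(p, duration = duration, ...)
      w <- c(duration - window_len, duration)
      rows[[length(rows) + 1L]] <-
        data.frame(g_katp_nS = gk, cftr = on,
                   freq_hz = firing_frequency(sim, w),
                   proxy = secretion_proxy(sim, w))
    }
  }
  structure(do.call(rbind, rows), class = c("alpha_cell_scan", "data.frame"))
}

#' Largest spiking K_ATP conductance in a scan
#'
#' @param scan An `alpha_cell_scan` object.
#' @param cftr Which arm to inspect (`TRUE` = CFTR on).
#' @return The largest `g_KATP` with nonzero frequency, or `NA` if none.
#' @export
activity_boundary <- function(scan, cftr = TRUE) {
  sub <- scan[scan$cftr == cftr & scan$freq_hz > 0, ]
  if (!nrow(sub)) return(NA_real_)
  max(sub$g_katp_nS)
}
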