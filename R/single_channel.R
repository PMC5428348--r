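#' Cell-attached single-channel trace
#'
#' Uniformly sampled current from a cell-attached patch, by convention held
#' at -50 mV; channel openings are downward (negative-going) deflections.
#'
#' @param I Current samples (pA).
#' @param sampling_khz Sampling rate (kHz). Default 10.
#' @param holding_V Holding potential (mV). Default -50.
#' @return Object of class `single_channel_trace` with `t` (ms), `I`,
#'   `sampling_khz`, `holding_V`.
#' @export
single_channel_trace <- function(I, sampling_khz = 10, holding_V = -50) {
  if (!is.numeric(I) || length(I) < 2) stop("I must be a numeric trace")
  if (sampling_khz <= 0) stop("sampling_khz must be > 0")
  structure(list(t = (seq_along(I) - 1) / sampling_khz, I = as.numeric(I),
                 sampling_khz = sampling_khz, holding_V = holding_V),
            class = "single_channel_trace")
}

#' Zero-phase low-pass filter for single-channel records
#'
#' Linear-phase FIR low-pass (Hamming window design via [signal::fir1()])
#' applied as a centered symmetric convolution, i.e. with zero net phase
#' delay, so that event times are not biased. Edges are handled by
#' reflection padding.
#'
#' @param I Current samples (pA).
#' @param sampling_khz Sampling rate (kHz).
#' @param cutoff_hz Cutoff frequency (Hz). Default 500, matching the
#'   conventional playback filter for CFTR single-channel analysis.
#' @param order FIR order (even). Default 64.
#' @return Filtered trace, same length as `I`.
#' @export
lowpass_filter <- function(I, sampling_khz, cutoff_hz = 500, order = 64) {
  nyq_hz <- sampling_khz * 1000 / 2
  if (cutoff_hz >= nyq_hz) return(I)
  b <- signal::fir1(order, cutoff_hz / nyq_hz)
  half <- order / 2
  padded <- c(rev(I[seq_len(half)]), I,
              rev(I[seq.int(length(I) - half + 1L, length(I))]))
  out <- stats::filter(padded, b, sides = 2)
  as.numeric(out[seq.int(half + 1L, half + length(I))])
}

#' Idealize a single-channel trace
#'
#' Two-level idealization of a cell-attached record:
#' \enumerate{
#'   \item the closed-channel baseline is the mode of the current
#'     amplitude histogram (kernel density peak);
#'   \item the open-channel level is the second density peak below the
#'     baseline (openings are downward), and the single-channel amplitude
#'     `i` is the peak separation, reported as a positive magnitude;
#'   \item samples are assigned open/closed by half-amplitude threshold
#'     crossing with hysteresis (a sample must cross beyond the half level
#'     by `hysteresis * i` to switch state);
#'   \item the open probability `p_o` is the fraction of open samples.
#' }
#' If the histogram has no second peak (no detectable openings) the trace
#' is idealized as always closed: `p_o = 0` with `amplitude = NA` and
#' `amplitude_defined = FALSE`, not an error.
#'
#' When more than one open level is detected, `n_levels > 1` is flagged and
#' `p_o` is reported as NPo (mean occupied level count), since the number
#' of channels in the patch is then not 1.
#'
#' @param trace A `single_channel_trace`.
#' @param filter Apply the 500 Hz zero-phase low-pass first? Default TRUE.
#' @param cutoff_hz Filter cutoff (Hz).
#' @param hysteresis Hysteresis as a fraction of the amplitude. Default 0.1.
#' @param min_peak_frac Minimum height of the open-level density peak,
#'   relative to the baseline peak, to count as detected. Default 0.02.
#' @return Object of class `sc_idealization`: `states` (integer per sample,
#'   0 = closed), `baseline` (pA), `amplitude` (pA, magnitude),
#'   `amplitude_defined`, `p_o`, `n_levels`, `filtered` trace.
#' @export
idealize <- function(trace, filter = TRUE, cutoff_hz = 500,
                     hysteresis = 0.1, min_peak_frac = 0.02) {
  stopifnot(inherits(trace, "single_channel_trace"))
  I <- if (filter) lowpass_filter(trace$I, trace$sampling_khz, cutoff_hz)
       else trace$I
  d <- stats::density(I, n = 1024)
  pk <- local_maxima(d$y)
  ## baseline = highest-density peak (closed state dominates or ties);
  ## open levels = remaining peaks BELOW baseline (downward openings)
  base_pk <- pk[which.max(d$y[pk])]
  baseline <- d$x[base_pk]
  open_pks <- pk[d$x[pk] < baseline - 3 * d$bw &
                   d$y[pk] >= min_peak_frac * d$y[base_pk]]
  if (!length(open_pks)) {
    return(structure(list(states = integer(length(I)), baseline = baseline,
                          amplitude = NA_real_, amplitude_defined = FALSE,
                          p_o = 0, n_levels = 0L, filtered = I),
                     class = "sc_idealization"))
  }
  ## principal open level: tallest peak below baseline
  main_open <- open_pks[which.max(d$y[open_pks])]
  amplitude <- baseline - d$x[main_open]
  n_levels <- length(open_pks)

  half <- baseline - amplitude / 2
  dh <- hysteresis * amplitude
  states <- hysteresis_threshold(I, lower = half - dh, upper = half + dh)
  p_o <- mean(states)
  if (n_levels > 1L) {
    ## NPo: occupancy weighted by level index relative to the unit amplitude
    lev <- pmax(0, round((baseline - I) / amplitude))
    lev[states == 0L] <- 0L
    p_o <- mean(lev)
  }
  structure(list(states = states, baseline = baseline,
                 amplitude = amplitude, amplitude_defined = TRUE,
                 p_o = p_o, n_levels = n_levels, filtered = I),
            class = "sc_idealization")
}

#' @export
print.sc_idealization <- function(x, ...) {
  if (x$amplitude_defined) {
    cat(sprintf("Single-channel idealization: i = %.3f pA, %s = %.3f, %d open level(s)\n",
                x$amplitude, if (x$n_levels > 1) "NPo" else "p_o",
                x$p_o, x$n_levels))
  } else {
    cat("Single-channel idealization: no detectable openings (p_o = 0)\n")
  }
  invisible(x)
}

local_maxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

## Two-state assignment with hysteresis: a sample switches closed -> open
## only when I < lower, and open -> closed only when I > upper.
hysteresis_threshold <- function(I, lower, upper) {
  states <- integer(length(I))
  open <- FALSE
  for (k in seq_along(I)) {
    if (!open && I[k] < lower) open <- TRUE
    else if (open && I[k] > upper) open <- FALSE
    states[k] <- as.integer(open)
  }
  states
}

#' Capacitance train from a depolarization protocol
#'
#' Per-pulse membrane-capacitance increments evoked by a train of ten
#' 500 ms depolarizations from -70 mV to 0 mV, the standard exocytosis
#' protocol.
#'
#' @param dCm_fF Numeric vector of exactly 10 capacitance increments (fF).
#' @param pulse_ms,from_mV,to_mV Protocol descriptor. Defaults 500, -70, 0.
#' @return Object of class `capacitance_train`.
#' @export
capacitance_train <- function(dCm_fF, pulse_ms = 500, from_mV = -70,
                              to_mV = 0) {
  if (length(dCm_fF) != 10)
    stop("a capacitance train has exactly 10 pulse increments")
  structure(list(dCm_fF = as.numeric(dCm_fF),
                 protocol = list(pulse_ms = pulse_ms, from_mV = from_mV,
                                 to_mV = to_mV)),
            class = "capacitance_train")
}

#' Train-summed capacitance increments
#'
#' The exocytotic response summaries of a 10-pulse train: the total
#' response (sum over all 10 pulses), the early component (pulses 1-2,
#' dominated by the readily releasable pool) and the late component
#' (pulses 3-10). By construction `sum_all = sum_1_2 + sum_3_10` exactly.
#'
#' @param train A `capacitance_train`.
#' @return Named list `sum_all`, `sum_1_2`, `sum_3_10` (fF).
#' @export
capacitance_sums <- function(train) {
  stopifnot(inherits(train, "capacitance_train"))
  d <- train$dCm_fF
  s12 <- sum(d[1:2])
  s310 <- sum(d[3:10])
  ## the total is defined as the sum of the two components so that the
  ## additivity identity holds exactly in floating point
  list(sum_all = s12 + s310, sum_1_2 = s12, sum_3_10 = s310)
}
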