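#' Whole-cell voltage-ramp recording
#'
#' One ramp sweep (nominally -100 mV to +100 mV) with its current trace,
#' the pharmacological condition and the cell's capacitance.
#'
#' @param V Voltage trace (mV), non-decreasing.
#' @param I Current trace (pA), same length as `V`.
#' @param condition One of `"control"`, `"forskolin"`,
#'   `"forskolin_inhibitor"`.
#' @param C_m Cell capacitance (pF), > 0.
#' @param cell_id Cell label.
#' @return An object of class `ramp_recording`.
#' @export
ramp_recording <- function(V, I,
                           condition = c("control", "forskolin",
                                         "forskolin_inhibitor"),
                           C_m, cell_id = "cell1") {
  condition <- match.arg(condition)
  if (length(V) != length(I)) stop("V and I must have equal length")
  if (length(V) < 2) stop("a ramp needs at least 2 samples")
  if (is.unsorted(V)) stop("V must be non-decreasing along the ramp")
  if (!is.finite(C_m) || C_m <= 0) stop("C_m must be > 0")
  structure(list(V = as.numeric(V), I = as.numeric(I), condition = condition,
                 C_m = C_m, cell_id = cell_id),
            class = "ramp_recording")
}

#' @export
print.ramp_recording <- function(x, ...) {
  cat(sprintf("Ramp recording [%s, %s]: %d samples, V in [%.0f, %.0f] mV, C_m = %g pF\n",
              x$cell_id, x$condition, length(x$V), min(x$V), max(x$V), x$C_m))
  invisible(x)
}

#' Slope conductance over a voltage window
#'
#' Least-squares slope of current versus voltage restricted to the window,
#' in nS (pA/mV). The default window, -100 to -50 mV, is the negative-
#' potential range over which membrane conductance is quantified.
#'
#' @param rec A `ramp_recording` (or a difference trace from
#'   [difference_current()]).
#' @param window Voltage window `c(V_lo, V_hi)` in mV.
#' @return Slope conductance (nS).
#' @export
slope_conductance <- function(rec, window = c(-100, -50)) {
  keep <- rec$V >= window[1] & rec$V <= window[2]
  if (sum(keep) < 2)
    stop("fewer than 2 samples inside the voltage window")
  unname(stats::coef(stats::lm(rec$I[keep] ~ rec$V[keep]))[2])
}

#' Condition-difference current
#'
#' Pointwise difference `I_a - I_b` on a common voltage grid: the
#' forskolin-minus-control difference isolates the forskolin-activated
#' current, forskolin-minus-inhibitor the CFTR-dependent current. If the
#' grids differ, `b` is linearly interpolated onto `a`'s grid; voltages of
#' `a` outside `b`'s range are an error.
#'
#' @param a,b `ramp_recording` objects from the same cell.
#' @return A list of class `ramp_difference` with `V`, `I`, `label`,
#'   `C_m`, `cell_id`.
#' @export
difference_current <- function(a, b) {
  stopifnot(inherits(a, "ramp_recording"), inherits(b, "ramp_recording"))
  if (!identical(a$cell_id, b$cell_id))
    stop("difference_current expects recordings from the same cell")
  if (length(a$V) == length(b$V) && max(abs(a$V - b$V)) < 1e-9) {
    Ib <- b$I
  } else {
    if (min(a$V) < min(b$V) || max(a$V) > max(b$V))
      stop("voltage grids do not overlap enough for interpolation")
    Ib <- stats::approx(b$V, b$I, xout = a$V, ties = mean)$y
  }
  structure(list(V = a$V, I = a$I - Ib,
                 label = paste(a$condition, "-", b$condition),
                 C_m = a$C_m, cell_id = a$cell_id),
            class = "ramp_difference")
}

#' CFTR-dependent fraction of the forskolin-activated current
#'
#' The fraction, in percent, of the forskolin-activated current at negative
#' potentials that is blocked by the CFTR inhibitor:
#' `100 * slope(forskolin - inhibitor) / slope(forskolin - control)`,
#' both slopes taken over the same window. The slope-based form is used
#' rather than pointwise current ratios, which blow up near the reversal
#' potential.
#'
#' @param ctrl,fsk,inh `ramp_recording`s of the three conditions for one
#'   cell.
#' @param window Voltage window (mV). Default `c(-100, -50)`.
#' @param floor Minimum forskolin-activated slope (nS) below which the
#'   fraction is undefined. Default 0.01 nS.
#' @return Fraction in percent. Values outside \[0, 150\] carry an
#'   attribute `flag = "outside_plausible_range"`.
#' @export
cftr_fraction <- function(ctrl, fsk, inh, window = c(-100, -50),
                          floor = 0.01) {
  activated <- slope_conductance(difference_current(fsk, ctrl), window)
  blocked <- slope_conductance(difference_current(fsk, inh), window)
  if (abs(activated) < floor)
    stop("forskolin-activated slope below floor; CFTR fraction undefined")
  out <- 100 * blocked / activated
  if (out < 0 || out > 150) attr(out, "flag") <- "outside_plausible_range"
  out
}

#' Reversal potential of a difference current
#'
#' X-intercept of the least-squares line fitted to the difference current
#' within `fit_window`. The default window, -90 to -30 mV, brackets the
#' chloride reversal potential while excluding positive potentials where
#' inhibitor block may be voltage dependent.
#'
#' @param diff A `ramp_difference` (or any list with `V` and `I`).
#' @param fit_window Voltage window (mV). Default `c(-90, -30)`.
#' @param floor Minimum |slope| (nS) for a defined intercept. Default
#'   1e-4 nS.
#' @return Reversal potential (mV).
#' @export
reversal_potential <- function(diff, fit_window = c(-90, -30),
                               floor = 1e-4) {
  keep <- diff$V >= fit_window[1] & diff$V <= fit_window[2]
  if (sum(keep) < 2)
    stop("fewer than 2 samples inside the fit window")
  co <- stats::coef(stats::lm(diff$I[keep] ~ diff$V[keep]))
  if (abs(co[2]) < floor)
    stop("slope below floor; reversal potential undefined")
  unname(-co[1] / co[2])
}

#' Full ramp-triplet analysis for one cell
#'
#' Computes, from the (control, forskolin, forskolin+inhibitor) triplet of
#' one cell: the CFTR-dependent slope conductance over the negative-
#' potential window, its density normalized to cell capacitance (pS/pF),
#' the chloride reversal potential from the CFTR-dependent difference
#' current, and the CFTR-dependent fraction of the forskolin-activated
#' current.
#'
#' @inheritParams cftr_fraction
#' @param reversal_window Fit window for the reversal potential (mV).
#' @return A list of class `ramp_analysis`: `slope_conductance` (nS),
#'   `conductance_density` (pS/pF), `reversal` (mV), `cftr_fraction` (%).
#' @export
analyze_ramp_triplet <- function(ctrl, fsk, inh, window = c(-100, -50),
                                 reversal_window = c(-90, -30)) {
  stopifnot(identical(ctrl$condition, "control"),
            identical(fsk$condition, "forskolin"),
            identical(inh$condition, "forskolin_inhibitor"))
  cftr_diff <- difference_current(fsk, inh)
  g <- slope_conductance(cftr_diff, window)
  structure(list(cell_id = ctrl$cell_id,
                 slope_conductance = g,
                 conductance_density = 1000 * g / ctrl$C_m,
                 reversal = reversal_potential(cftr_diff, reversal_window),
                 cftr_fraction = cftr_fraction(ctrl, fsk, inh, window)),
            class = "ramp_analysis")
}

#' @export
print.ramp_analysis <- function(x, ...) {
  cat(sprintf("Ramp analysis [%s]\n", x$cell_id))
  cat(sprintf("  CFTR-dependent conductance: %.4f nS (%.1f pS/pF)\n",
              x$slope_conductance, x$conductance_density))
  cat(sprintf("  reversal potential: %.1f mV\n", x$reversal))
  cat(sprintf("  CFTR fraction of activated current: %.1f%%\n",
              as.numeric(x$cftr_fraction)))
  invisible(x)
}

#' Summarize ramp analyses across cells
#'
#' Mean and standard error (over cells) of the per-cell ramp-analysis
#' quantities, the per-cell-then-average convention used for patch-clamp
#' summaries.
#'
#' @param analyses List of `ramp_analysis` objects.
#' @return data.frame with one row per quantity: `mean`, `sem`, `n`.
#' @export
summarize_ramp_analyses <- function(analyses) {
  pull <- function(field) vapply(analyses, function(a) as.numeric(a[[field]]),
                                 numeric(1))
  qty <- c("conductance_density", "reversal", "cftr_fraction",
           "slope_conductance")
  out <- do.call(rbind, lapply(qty, function(f) {
    v <- pull(f)
    data.frame(quantity = f, mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)), n = length(v))
  }))
  rownames(out) <- NULL
  out
}
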