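## Gating kinetics of the conductance-based alpha-cell model.
##
## Every gate x relaxes as dx/dt = (x_inf(V) - x)/tau_x with the Boltzmann
## steady state x_inf(V) = 1/(1 + exp((vhalf - V)/slope)); a negative slope
## encodes inactivation. Midpoints in mV, time constants in ms. The
## parameterization reproduces the hallmarks of alpha-cell excitability:
## large Na+/T-type-driven action potentials from a baseline near -50 mV at
## low glucose, smaller high-voltage-activated (CaL/CaPQ-driven) spikes from
## a depolarized baseline near -40 mV at 6 mM glucose, and silencing once
## the K_ATP conductance exceeds roughly 0.3 nS.
.alpha_gates <- data.frame(
  name  = c("mNa", "hNa", "mCaT", "hCaT", "mCaL", "hCaL", "mCaPQ",
            "mK", "mKA", "hKA"),
  vhalf = c(-30, -48, -49, -52, -25, -30, 0, -22, -45, -68),
  slope = c(5, -7, 4, -7, 6, -6, 8, 6, 10, -10),
  tau   = c(0.15, 6, 0.5, 80, 1, 60, 1, 4, 0.15, 10),
  stringsAsFactors = FALSE
)

#' Gating-variable steady states
#'
#' Boltzmann steady-state values of all gating variables at a membrane
#' potential `V`, in the model's gate order.
#'
#' @param V Membrane potential (mV), scalar.
#' @return Named numeric vector with one entry per gating variable, all in
#'   \[0, 1\].
#' @export
gate_steady_states <- function(V) {
  stats::setNames(1 / (1 + exp((.alpha_gates$vhalf - V) / .alpha_gates$slope)),
                  .alpha_gates$name)
}

#' Names of the model's membrane currents
#' @return Character vector of current labels as used in simulation output.
#' @export
alpha_cell_current_names <- function() {
  c("Na", "CaT", "CaL", "CaPQ", "K", "KA", "KATP", "L", "CFTR")
}

#' Passive CFTR chloride current
#'
#' The CFTR current is represented as a passive (ohmic) current
#' \eqn{I_{CFTR} = g_{CFTR}\,(V - V_{Cl})}: strictly linear in the membrane
#' potential, reversing at the chloride reversal potential. Units follow the
#' package convention nS x mV = pA.
#'
#' @param V Membrane potential (mV); may be a vector.
#' @param g_CFTR CFTR conductance (nS), must be >= 0.
#' @param V_Cl Chloride reversal potential (mV). Default -60 mV.
#' @return Current in pA (positive = outward for V > V_Cl).
#' @examples
#' cftr_current(-100, 0.100)  # -4 pA
#' cftr_current(-60, 0.100)   #  0 pA at the reversal potential
#' @export
cftr_current <- function(V, g_CFTR, V_Cl = -60) {
  if (!is.numeric(g_CFTR) || length(g_CFTR) != 1 || !is.finite(g_CFTR) ||
      g_CFTR < 0)
    stop("g_CFTR must be a single finite non-negative conductance (nS)")
  stopifnot(is.numeric(V), all(is.finite(V)), is.finite(V_Cl))
  g_CFTR * (V - V_Cl)
}

#' Membrane currents of the alpha-cell model
#'
#' Evaluate every ionic current (pA) at a given membrane potential and
#' gating state.
#'
#' @param V Membrane potential (mV), scalar.
#' @param gating Named vector of gating variables (see
#'   [gate_steady_states()] for the order).
#' @param params An [alpha_cell_parameters()] object.
#' @return Named numeric vector of currents in pA, positive = outward.
#' @export
alpha_cell_currents <- function(V, gating, params) {
  g <- params$base_conductances
  e <- params$base_reversals
  x <- gating
  c(Na   = unname(g["Na"]   * x[["mNa"]]^3  * x[["hNa"]]  * (V - e[["Na"]])),
    CaT  = unname(g["CaT"]  * x[["mCaT"]]^3 * x[["hCaT"]] * (V - e[["Ca"]])),
    CaL  = unname(g["CaL"]  * x[["mCaL"]]^2 * x[["hCaL"]] * (V - e[["Ca"]])),
    CaPQ = unname(g["CaPQ"] * x[["mCaPQ"]]               * (V - e[["Ca"]])),
    K    = unname(g["K"]    * x[["mK"]]^4                * (V - e[["K"]])),
    KA   = unname(g["KA"]   * x[["mKA"]] * x[["hKA"]]    * (V - e[["K"]])),
    KATP = params$g_KATP * (V - e[["K"]]),
    L    = params$g_L    * (V - params$V_L),
    CFTR = params$g_CFTR * (V - params$V_Cl))
}

#' Right-hand side of the alpha-cell ODE system
#'
#' State derivative of the full model:
#' \eqn{C_m\,dV/dt = -\sum_k I_k} over all ionic currents (including the
#' CFTR and leak terms), and \eqn{dx/dt = (x_\infty(V) - x)/\tau_x} for each
#' gating variable. The function has the signature expected by
#' [deSolve::ode()]. With `g_CFTR = 0` the system reduces exactly to the
#' base model: the chloride term vanishes identically and `V_Cl` has no
#' influence on any derivative.
#'
#' @param t Time (ms); unused (autonomous system) but part of the solver
#'   interface.
#' @param state Named state vector: `V` followed by the gating variables.
#' @param params An [alpha_cell_parameters()] object.
#' @return A list whose first element is the derivative vector.
#' @export
alpha_cell_rhs <- function(t, state, params) {
  V <- state[[1L]]
  gating <- state[-1L]
  I <- alpha_cell_currents(V, gating, params)
  dV <- -sum(I) / params$C_m
  dg <- (1 / (1 + exp((.alpha_gates$vhalf - V) / .alpha_gates$slope)) -
           gating) / .alpha_gates$tau
  list(c(dV, dg))
}

#' Default initial state
#'
#' The model's reference starting point: `V` = -60 mV with every gating
#' variable at its steady state for that potential. Analyses use this state
#' followed by a burn-in (see [simulate_alpha_cell()]) so that reported
#' traces describe steady behaviour, not the initial transient.
#'
#' @return Named state vector (`V` plus gating variables).
#' @export
default_initial_state <- function() {
  c(V = -60, gate_steady_states(-60))
}

#' Simulate the alpha-cell model
#'
#' Integrates the model with the stiff-capable adaptive solver
#' [deSolve::lsoda()] (relative tolerance 1e-8, absolute tolerance 1e-10,
#' maximum internal step 1 ms so that no action potential can be stepped
#' over) and returns the solution on a fixed 0.1 ms output grid,
#' independent of the internal steps, for reproducible spike detection.
#'
#' Parameter switches (for instance CFTR inhibition, modelled as an
#' instantaneous change `g_CFTR` to 0) are supplied as `events`: the
#' integration is restarted at each event time with the state carried over
#' continuously and the patched parameters in force from then on.
#'
#' @param params An [alpha_cell_parameters()] object.
#' @param duration Simulated time (ms) after burn-in; `duration = 0`
#'   returns only the initial state.
#' @param events Optional list of events, each a
#'   `list(time = <ms>, patch = list(<parameter> = <value>))`, sorted by
#'   time within `[0, duration]`.
#' @param initial `"default"` for the burned-in default state, or a named
#'   state vector (`V` plus gating variables) used as-is without burn-in.
#' @param burn_in Burn-in time (ms) preceding `t = 0` when
#'   `initial = "default"`; the burn-in segment is discarded. Default
#'   2000 ms.
#' @param dt Output sampling interval (ms). Default 0.1 ms.
#' @param rtol,atol Solver tolerances.
#' @return An object of class `alpha_cell_sim` with elements `t` (ms), `V`
#'   (mV), `gating` (matrix, one column per gate), `currents` (matrix in pA,
#'   one column per current including `CFTR`, `KATP`, `L`) and `params_used`
#'   (list of parameter snapshots with their start times).
#' @examples
#' p <- alpha_cell_scenario("glucose1")
#' sim <- simulate_alpha_cell(p, duration = 500)
#' range(sim$V)
#' @export
simulate_alpha_cell <- function(params, duration,
                                events = NULL,
                                initial = "default",
                                burn_in = 2000,
                                dt = 0.1,
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "alpha_cell_parameters"))
  if (!is.numeric(duration) || length(duration) != 1 || duration < 0)
    stop("duration must be a non-negative time in ms")
  if (!is.null(events)) {
    tt <- vapply(events, function(e) e$time, numeric(1))
    if (is.unsorted(tt, strictly = FALSE))
      stop("events must be sorted by time")
    if (any(tt < 0) || any(tt > duration))
      stop("event times must lie within [0, duration]")
  }

  y0 <- if (identical(initial, "default")) {
    state <- default_initial_state()
    if (burn_in > 0) {
      bi <- integrate_segment(state, c(0, burn_in), params, rtol, atol)
      state <- bi[nrow(bi), -1L]
    }
    state
  } else {
    check_state(initial)
    initial
  }

  if (duration == 0) {
    return(build_sim(t = 0, states = matrix(unlist(y0), nrow = 1,
                                            dimnames = list(NULL, names(y0))),
                     params_used = list(list(time = 0, params = params))))
  }

  ## piecewise integration across event times
  breaks <- c(0, vapply(events, function(e) e$time, numeric(1)), duration)
  plist <- vector("list", length(breaks) - 1L)
  plist[[1L]] <- params
  if (length(events))
    for (i in seq_along(events))
      plist[[i + 1L]] <- patch_parameters(plist[[i]], events[[i]]$patch)

  segs <- vector("list", length(plist))
  state <- y0
  for (i in seq_along(plist)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    if (t1 == t0) {
      ## zero-length segment (event at segment start): carry the state over
      segs[[i]] <- if (i == 1L)
        matrix(c(t0, state), nrow = 1,
               dimnames = list(NULL, c("time", names(state))))
      else NULL
      next
    }
    times <- seq(t0, t1, by = dt)
    if (times[length(times)] < t1) times <- c(times, t1)
    out <- integrate_segment(state, times, plist[[i]], rtol, atol)
    state <- out[nrow(out), -1L]
    segs[[i]] <- if (all(vapply(segs[seq_len(i - 1L)], is.null, logical(1))))
      out else out[-1L, , drop = FALSE]
  }
  sol <- do.call(rbind, segs)
  build_sim(t = sol[, 1L], states = sol[, -1L, drop = FALSE],
            params_used = Map(function(tm, p) list(time = tm, params = p),
                              breaks[-length(breaks)], plist))
}

integrate_segment <- function(state, times, params, rtol, atol) {
  out <- deSolve::ode(y = state, times = times, func = alpha_cell_rhs,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol, hmax = 1, maxsteps = 50000)
  if (nrow(out) < length(times)) {
    stop(sprintf(
      "integration failed (step-size underflow or excessive work) at t = %.3f ms",
      out[nrow(out), 1L]))
  }
  out
}

check_state <- function(state) {
  expected <- c("V", .alpha_gates$name)
  if (!is.numeric(state) || !identical(names(state), expected))
    stop("initial state must be a named numeric vector: ",
         paste(expected, collapse = ", "))
  g <- state[-1L]
  if (any(g < 0) || any(g > 1))
    stop("gating values must lie in [0, 1]")
  invisible(TRUE)
}

build_sim <- function(t, states, params_used) {
  V <- states[, "V"]
  gating <- states[, .alpha_gates$name, drop = FALSE]
  ## per-current decomposition under the parameters in force at each time
  cur <- matrix(NA_real_, nrow = length(t),
                ncol = length(alpha_cell_current_names()),
                dimnames = list(NULL, alpha_cell_current_names()))
  starts <- vapply(params_used, function(s) s$time, numeric(1))
  idx <- findInterval(t, starts)
  idx[idx < 1L] <- 1L
  for (k in unique(idx)) {
    rows <- which(idx == k)
    cur[rows, ] <- currents_matrix(V[rows], gating[rows, , drop = FALSE],
                                   params_used[[k]]$params)
  }
  structure(list(t = as.numeric(t), V = as.numeric(V), gating = gating,
                 currents = cur, params_used = params_used),
            class = "alpha_cell_sim")
}

## Vectorized current decomposition along a trajectory (rows = time points).
currents_matrix <- function(V, gating, params) {
  g <- params$base_conductances
  e <- params$base_reversals
  cbind(Na   = g[["Na"]]   * gating[, "mNa"]^3  * gating[, "hNa"]  * (V - e[["Na"]]),
        CaT  = g[["CaT"]]  * gating[, "mCaT"]^3 * gating[, "hCaT"] * (V - e[["Ca"]]),
        CaL  = g[["CaL"]]  * gating[, "mCaL"]^2 * gating[, "hCaL"] * (V - e[["Ca"]]),
        CaPQ = g[["CaPQ"]] * gating[, "mCaPQ"]                     * (V - e[["Ca"]]),
        K    = g[["K"]]    * gating[, "mK"]^4                      * (V - e[["K"]]),
        KA   = g[["KA"]]   * gating[, "mKA"] * gating[, "hKA"]     * (V - e[["K"]]),
        KATP = params$g_KATP * (V - e[["K"]]),
        L    = params$g_L    * (V - params$V_L),
        CFTR = params$g_CFTR * (V - params$V_Cl))
}

#' @export
print.alpha_cell_sim <- function(x, ...) {
  cat(sprintf("Alpha-cell simulation: %.1f ms, %d samples, V in [%.1f, %.1f] mV\n",
              max(x$t) - min(x$t), length(x$t), min(x$V), max(x$V)))
  if (length(x$params_used) > 1L)
    cat(sprintf("  parameter switches at: %s ms\n",
                paste(vapply(x$params_used[-1L], function(s) s$time,
                             numeric(1)), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.alpha_cell_sim <- function(x, ...) {
  cur <- as.data.frame(x$currents)
  names(cur) <- paste0("I_", names(cur), "_pA")
  cbind(data.frame(time_ms = x$t, V_mV = x$V), cur)
}

#' Write a simulated trace to CSV
#'
#' Columns: `time_ms`, `V_mV`, then one column per current in pA.
#'
#' @param sim An `alpha_cell_sim` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(sim, path) {
  stopifnot(inherits(sim, "alpha_cell_sim"))
  utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
  invisible(path)
}
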