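#' Alpha-cell model parameters
#'
#' Construct the parameter set of the conductance-based alpha-cell model:
#' the Watts--Sherman-type mouse alpha-cell formulation (the variant without
#' store-operated currents) extended with a passive CFTR chloride current
#' \eqn{I_{CFTR} = g_{CFTR}(V - V_{Cl})}.
#'
#' Units are mV, ms, pA, nS and pF throughout the package, so that
#' nS x mV = pA and pA / pF = mV / ms. These conventions are enforced here
#' and assumed everywhere else.
#'
#' The K_ATP conductance stands in for ambient glucose: roughly 0.200 nS at
#' 6 mM glucose and 0.270--0.300 nS at 1 mM glucose, with the leak
#' conductance 0.200 nS and 0.150 nS respectively (see
#' [alpha_cell_scenario()]).
#'
#' @param g_CFTR CFTR chloride conductance (nS). Default 0.100 nS.
#' @param V_Cl Chloride reversal potential (mV). Default -60 mV.
#' @param g_KATP ATP-sensitive K+ conductance (nS).
#' @param g_L Leak conductance (nS).
#' @param V_L Leak reversal potential (mV). Default 0 mV.
#' @param C_m Cell capacitance (pF). Default 5 pF.
#' @param base_conductances Named numeric vector of the base-model maximal
#'   conductances (nS) for currents `Na`, `CaT`, `CaL`, `CaPQ`, `K`, `KA`.
#' @param base_reversals Named numeric vector of reversal potentials (mV)
#'   for `Na`, `Ca`, `K`.
#' @param soc_enabled Must be `FALSE`; the store-operated current of the
#'   base model family is not part of this variant and cannot be switched on.
#'
#' @return An object of class `alpha_cell_parameters`.
#' @examples
#' p <- alpha_cell_parameters()
#' p$g_CFTR
#' @export
alpha_cell_parameters <- function(g_CFTR = 0.100,
                                  V_Cl = -60,
                                  g_KATP = 0.270,
                                  g_L = 0.150,
                                  V_L = 0,
                                  C_m = 5,
                                  base_conductances = c(Na = 10, CaT = 0.5,
                                                        CaL = 0.7, CaPQ = 0.6,
                                                        K = 7, KA = 1),
                                  base_reversals = c(Na = 70, Ca = 65, K = -75),
                                  soc_enabled = FALSE) {
  if (!identical(soc_enabled, FALSE))
    stop("soc_enabled must be FALSE: the store-operated current variant is not supported")
  gc <- c(g_CFTR = g_CFTR, g_KATP = g_KATP, g_L = g_L, base_conductances)
  if (any(!is.finite(gc)) || any(gc < 0))
    stop("all conductances must be finite and >= 0")
  if (!is.finite(C_m) || C_m <= 0) stop("C_m must be > 0")
  wanted <- c("Na", "CaT", "CaL", "CaPQ", "K", "KA")
  if (!setequal(names(base_conductances), wanted))
    stop("base_conductances must be named exactly: ", paste(wanted, collapse = ", "))
  if (!setequal(names(base_reversals), c("Na", "Ca", "K")))
    stop("base_reversals must be named exactly: Na, Ca, K")
  structure(list(g_CFTR = g_CFTR, V_Cl = V_Cl,
                 g_KATP = g_KATP, g_L = g_L, V_L = V_L,
                 base_conductances = base_conductances[wanted],
                 base_reversals = base_reversals[c("Na", "Ca", "K")],
                 C_m = C_m, soc_enabled = FALSE),
            class = "alpha_cell_parameters")
}

#' @export
print.alpha_cell_parameters <- function(x, ...) {
  cat("Alpha-cell model parameters (nS, mV, pF)\n")
  cat(sprintf("  g_CFTR = %.3f nS, V_Cl = %g mV\n", x$g_CFTR, x$V_Cl))
  cat(sprintf("  g_KATP = %.3f nS, g_L = %.3f nS, V_L = %g mV\n",
              x$g_KATP, x$g_L, x$V_L))
  cat(sprintf("  C_m = %g pF\n", x$C_m))
  cat("  base conductances:",
      paste(sprintf("%s=%.1f", names(x$base_conductances), x$base_conductances),
            collapse = " "), "\n")
  invisible(x)
}

#' Named simulation scenarios
#'
#' The glucose-to-K_ATP mapping is exposed only through these anchor
#' scenarios, not as a continuous function: 6 mM glucose corresponds to
#' `g_KATP` = 0.200 nS with `g_L` = 0.200 nS; 1 mM glucose to
#' `g_KATP` = 0.270 nS (or 0.300 nS at the upper end of the experimental
#' range) with `g_L` = 0.150 nS. All scenarios carry the CFTR conductance
#' `g_CFTR` = 0.100 nS.
#'
#' @param name One of `"glucose6"`, `"glucose1"`, `"glucose1_highkatp"`.
#' @param ... Overrides forwarded to [alpha_cell_parameters()].
#' @return An `alpha_cell_parameters` object.
#' @examples
#' alpha_cell_scenario("glucose6")
#' @export
alpha_cell_scenario <- function(name = c("glucose6", "glucose1",
                                         "glucose1_highkatp"), ...) {
  name <- match.arg(name)
  preset <- switch(name,
    glucose6          = list(g_KATP = 0.200, g_L = 0.200),
    glucose1          = list(g_KATP = 0.270, g_L = 0.150),
    glucose1_highkatp = list(g_KATP = 0.300, g_L = 0.150))
  args <- utils::modifyList(c(preset, list(g_CFTR = 0.100)), list(...))
  do.call(alpha_cell_parameters, args)
}

#' Read model scenarios from a JSON parameter file
#'
#' The file holds one object per named scenario, each with fields among
#' `g_KATP`, `g_L`, `g_CFTR`, `V_Cl`, `V_L`, `C_m`, e.g.
#' `{"lowglucose": {"g_KATP": 0.270, "g_L": 0.150, "g_CFTR": 0.100}}`.
#'
#' @param path Path to a JSON file.
#' @return A named list of `alpha_cell_parameters`.
#' @export
read_scenarios_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw) || is.null(names(raw)) || any(names(raw) == ""))
    stop("scenario file must be a JSON object of named scenarios")
  lapply(raw, function(entry) {
    allowed <- c("g_CFTR", "V_Cl", "g_KATP", "g_L", "V_L", "C_m")
    bad <- setdiff(names(entry), allowed)
    if (length(bad))
      stop("unknown parameter field(s) in scenario file: ",
           paste(bad, collapse = ", "))
    do.call(alpha_cell_parameters, as.list(entry))
  })
}

## Apply a named patch (e.g. list(g_CFTR = 0)) to a parameter object,
## re-validating through the constructor.
patch_parameters <- function(params, patch) {
  stopifnot(inherits(params, "alpha_cell_parameters"))
  fields <- list(g_CFTR = params$g_CFTR, V_Cl = params$V_Cl,
                 g_KATP = params$g_KATP, g_L = params$g_L, V_L = params$V_L,
                 C_m = params$C_m,
                 base_conductances = params$base_conductances,
                 base_reversals = params$base_reversals)
  known <- names(fields)
  for (nm in names(patch)) {
    if (nm %in% known) {
      fields[[nm]] <- patch[[nm]]
    } else if (nm %in% names(fields$base_conductances)) {
      fields$base_conductances[[nm]] <- patch[[nm]]
    } else {
      stop("unknown parameter in patch: ", nm)
    }
  }
  do.call(alpha_cell_parameters, fields)
}
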