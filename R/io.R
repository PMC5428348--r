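## CSV schemas used across the package. Every reader checks its schema and
## fails with named-column messages; validate_inputs() exposes the same
## checks without constructing objects.

#' Write / read a ramp recording as CSV
#'
#' Columns: `V_mV`, `I_pA`, plus constant metadata columns `condition`,
#' `C_m_pF`, `cell_id`.
#'
#' @param rec A [ramp_recording()].
#' @param path File path.
#' @return `path` (write) or a `ramp_recording` (read).
#' @export
write_ramp_csv <- function(rec, path) {
  stopifnot(inherits(rec, "ramp_recording"))
  utils::write.csv(data.frame(V_mV = rec$V, I_pA = rec$I,
                              condition = rec$condition,
                              C_m_pF = rec$C_m, cell_id = rec$cell_id),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ramp_csv
#' @export
read_ramp_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("V_mV", "I_pA", "condition", "C_m_pF", "cell_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("ramp CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  ramp_recording(df$V_mV, df$I_pA, unique(df$condition)[1],
                 unique(df$C_m_pF)[1], as.character(unique(df$cell_id)[1]))
}

#' Write / read a capacitance train as CSV
#'
#' Columns: `pulse_index` (1..10), `dCm_fF`.
#' @param train A [capacitance_train()].
#' @param path File path.
#' @export
write_capacitance_csv <- function(train, path) {
  stopifnot(inherits(train, "capacitance_train"))
  utils::write.csv(data.frame(pulse_index = 1:10, dCm_fF = train$dCm_fF),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_capacitance_csv
#' @export
read_capacitance_csv <- function(path) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("pulse_index", "dCm_fF"), names(df))
  if (length(miss)) stop("capacitance CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  capacitance_train(df$dCm_fF[order(df$pulse_index)])
}

#' Write / read a secretion table as CSV
#' @param table A [secretion_table()].
#' @param path File path.
#' @export
write_secretion_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_secretion_csv
#' @param baseline Baseline condition label for validation.
#' @export
read_secretion_csv <- function(path, baseline = "baseline") {
  secretion_table(utils::read.csv(path), baseline = baseline)
}

#' Read a single-channel trace from CSV
#'
#' Columns: `time_ms`, `I_pA` on a uniform grid.
#' @param path File path.
#' @param holding_V Holding potential (mV) recorded in the object.
#' @export
read_single_channel_csv <- function(path, holding_V = -50) {
  df <- utils::read.csv(path)
  miss <- setdiff(c("time_ms", "I_pA"), names(df))
  if (length(miss)) stop("single-channel CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  dt <- diff(df$time_ms)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-6 * dt[1]))
    stop("time grid is not uniform")
  single_channel_trace(df$I_pA, sampling_khz = 1 / dt[1],
                       holding_V = holding_V)
}

#' @export
#' @rdname read_single_channel_csv
#' @param trace A [single_channel_trace()].
write_single_channel_csv <- function(trace, path) {
  stopifnot(inherits(trace, "single_channel_trace"))
  utils::write.csv(data.frame(time_ms = trace$t, I_pA = trace$I),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write an intensity grid as headerless CSV
#' @param path File path.
#' @export
read_grid_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' @rdname read_grid_csv
#' @param m Numeric matrix.
#' @export
write_grid_csv <- function(m, path) {
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' @param x A named list (or object coercible to one).
#' @param path Output file.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Validate an input file against a named schema
#'
#' Checks structural requirements (required columns, non-empty, value
#' constraints) of the package's CSV formats without constructing analysis
#' objects. Intended for pre-flight checks in pipelines; the CLI maps the
#' result onto exit codes (0 = valid).
#'
#' @param path File to check.
#' @param schema One of `"ramp"`, `"trace"`, `"single_channel"`,
#'   `"capacitance"`, `"secretion"`, `"image"`.
#' @return List of class `validation_report`: `valid` (logical),
#'   `n_errors`, `errors` (character messages).
#' @export
validate_inputs <- function(path,
                            schema = c("ramp", "trace", "single_channel",
                                       "capacitance", "secretion", "image")) {
  schema <- match.arg(schema)
  errs <- character(0)
  if (!file.exists(path)) {
    errs <- sprintf("file not found: %s", path)
    return(validation_report(errs))
  }
  df <- tryCatch({
    if (schema == "image") utils::read.csv(path, header = FALSE)
    else utils::read.csv(path)
  }, error = function(e) e)
  if (inherits(df, "error"))
    return(validation_report(sprintf("unreadable file: %s",
                                     conditionMessage(df))))
  if (nrow(df) == 0)
    return(validation_report("no rows"))
  need <- switch(schema,
                 ramp = c("V_mV", "I_pA", "condition", "C_m_pF", "cell_id"),
                 trace = c("time_ms", "V_mV"),
                 single_channel = c("time_ms", "I_pA"),
                 capacitance = c("pulse_index", "dCm_fF"),
                 secretion = c("hormone", "species", "glucose_mM",
                               "condition", "experiment_id", "replicate_id",
                               "value"),
                 image = NULL)
  if (!is.null(need)) {
    for (col in setdiff(need, names(df)))
      errs <- c(errs, sprintf("missing column: %s", col))
  }
  if (!length(errs)) {
    errs <- c(errs, switch(schema,
      ramp = {
        e <- character(0)
        if (is.unsorted(df$V_mV))
          e <- c(e, "V_mV must be non-decreasing")
        if (any(df$C_m_pF <= 0))
          e <- c(e, "C_m_pF must be > 0")
        e
      },
      capacitance = if (nrow(df) != 10)
        sprintf("expected exactly 10 pulses, found %d rows", nrow(df))
        else character(0),
      secretion = {
        e <- character(0)
        bad <- which(!is.finite(df$value) | df$value < 0)
        if (length(bad))
          e <- c(e, sprintf("row %d: value must be finite and >= 0", bad))
        e
      },
      image = if (!all(vapply(df, is.numeric, logical(1))))
        "image grid must be entirely numeric" else character(0),
      character(0)))
  }
  validation_report(errs)
}

validation_report <- function(errs) {
  structure(list(valid = length(errs) == 0, n_errors = length(errs),
                 errors = errs),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$valid) cat("valid\n")
  else cat(sprintf("invalid (%d error%s):\n", x$n_errors,
                   if (x$n_errors == 1) "" else "s"),
           paste0("  - ", x$errors, collapse = "\n"), "\n")
  invisible(x)
}
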