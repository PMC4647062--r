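#' Recording metadata for a cell
#'
#' Describes where and from what a sweep was recorded. Voltages throughout the
#' package follow the whole-cell convention of *not* correcting for the liquid
#' junction potential; `ljp_corrected` records that convention explicitly and
#' must remain `FALSE` when features are compared against the calibrated
#' presets.
#'
#' @param cell_id character scalar identifying the cell.
#' @param genotype `"WT"` or `"KO"`.
#' @param projection_class `"PT"`, `"IT"` or `"unlabeled"`.
#' @param compartment `"soma"` or `"dendrite"`.
#' @param distance_um non-negative recording distance from the soma in
#'   micrometres (0 for somatic recordings; any positive value is allowed for
#'   dendritic sites).
#' @param temperature_C bath temperature, degrees Celsius.
#' @param holding_potential_mV holding potential, or `NA` if not held.
#' @param ljp_corrected logical; must be `FALSE` for preset comparisons.
#' @return An object of class `"recording_metadata"`.
#' @export
recording_metadata <- function(cell_id,
                               genotype = c("WT", "KO"),
                               projection_class = c("PT", "IT", "unlabeled"),
                               compartment = c("soma", "dendrite"),
                               distance_um = 0,
                               temperature_C = 33,
                               holding_potential_mV = NA_real_,
                               ljp_corrected = FALSE) {
  genotype <- match.arg(genotype)
  projection_class <- match.arg(projection_class)
  compartment <- match.arg(compartment)
  stopifnot(is.character(cell_id), length(cell_id) == 1L, nzchar(cell_id))
  if (!is.numeric(distance_um) || length(distance_um) != 1L || distance_um < 0)
    stop("distance_um must be a single non-negative number", call. = FALSE)
  if (!identical(ljp_corrected, FALSE) && !identical(ljp_corrected, TRUE))
    stop("ljp_corrected must be TRUE or FALSE", call. = FALSE)
  structure(
    list(cell_id = cell_id, genotype = genotype,
         projection_class = projection_class, compartment = compartment,
         distance_um = as.numeric(distance_um),
         temperature_C = as.numeric(temperature_C),
         holding_potential_mV = as.numeric(holding_potential_mV),
         ljp_corrected = ljp_corrected),
    class = "recording_metadata")
}

#' Protocol descriptor
#'
#' A tag plus free-form parameter record describing the stimulus protocol a
#' sweep belongs to. Parameter units follow the package convention: pA for
#' currents, mV for voltages, ms for durations of protocol segments, Hz for
#' frequencies (chirp duration is in seconds as `duration_s`).
#'
#' @param kind protocol kind; one of `step_family`, `chirp`, `brief_pulse`,
#'   `epsc_train`, `threshold_pulse`, `vc_activation`, `vc_prepulse`,
#'   `vc_sustained`, `vc_recovery`, `vc_ih_step`, `custom`.
#' @param ... named protocol parameters.
#' @return An object of class `"protocol_descriptor"`.
#' @export
protocol_descriptor <- function(kind = c("step_family", "chirp", "brief_pulse",
                                         "epsc_train", "threshold_pulse",
                                         "vc_activation", "vc_prepulse",
                                         "vc_sustained", "vc_recovery",
                                         "vc_ih_step", "custom"),
                                ...) {
  kind <- match.arg(kind)
  params <- list(...)
  required <- switch(kind,
    chirp = c("f_start_Hz", "f_end_Hz", "duration_s", "amplitude_pA"),
    step_family = c("duration_ms"),
    epsc_train = c("frequency_Hz", "n_events"),
    character(0))
  missing <- setdiff(required, names(params))
  if (length(missing))
    stop("protocol '", kind, "' requires parameters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  structure(list(kind = kind, parameters = params),
            class = "protocol_descriptor")
}

#' A single time-aligned stimulus/response sweep
#'
#' In current clamp the stimulus is in pA and the response in mV; in voltage
#' clamp the stimulus (command) is in mV and the response in pA. Units are
#' fixed by `mode` and never stored separately.
#'
#' @param stimulus,response numeric vectors of equal length (>= 2).
#' @param sampling_rate_Hz sampling rate, Hz.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param metadata a [recording_metadata()] object.
#' @param protocol a [protocol_descriptor()] object.
#' @param t0_s start time of the sweep, seconds.
#' @return An object of class `"sweep"`.
#' @export
sweep <- function(stimulus, response, sampling_rate_Hz,
                  mode = c("current_clamp", "voltage_clamp"),
                  metadata = recording_metadata("cell"),
                  protocol = protocol_descriptor("custom"),
                  t0_s = 0) {
  mode <- match.arg(mode)
  stimulus <- as.numeric(stimulus)
  response <- as.numeric(response)
  if (length(stimulus) != length(response) || length(stimulus) < 2L)
    stop("stimulus and response must have equal length >= 2", call. = FALSE)
  if (!is.numeric(sampling_rate_Hz) || sampling_rate_Hz <= 0)
    stop("sampling_rate_Hz must be positive", call. = FALSE)
  if (!inherits(metadata, "recording_metadata"))
    stop("metadata must be a recording_metadata object", call. = FALSE)
  if (!inherits(protocol, "protocol_descriptor"))
    stop("protocol must be a protocol_descriptor object", call. = FALSE)
  structure(
    list(stimulus = stimulus, response = response,
         sampling_rate_Hz = as.numeric(sampling_rate_Hz), mode = mode,
         t0_s = as.numeric(t0_s), metadata = metadata, protocol = protocol),
    class = "sweep")
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %s, %d samples @ %g kHz, cell %s (%s/%s %s)\n",
              x$mode, length(x$response), x$sampling_rate_Hz / 1000,
              x$metadata$cell_id, x$metadata$genotype,
              x$metadata$projection_class, x$metadata$compartment))
  invisible(x)
}

#' Time base of a sweep
#'
#' @param sw a [sweep()].
#' @return Numeric vector of sample times in seconds, starting at `t0_s`.
#' @export
sweep_time <- function(sw) {
  sw$t0_s + (seq_along(sw$response) - 1) / sw$sampling_rate_Hz
}

#' An ordered set of sweeps sharing a protocol
#'
#' @param sweeps list of [sweep()] objects; all must share `mode` and
#'   `sampling_rate_Hz`.
#' @param protocol_id character tag naming the shared protocol.
#' @return An object of class `"sweep_set"`.
#' @export
sweep_set <- function(sweeps, protocol_id = NULL) {
  if (!is.list(sweeps) || length(sweeps) == 0L)
    stop("a sweep_set must contain at least one sweep", call. = FALSE)
  ok <- vapply(sweeps, inherits, logical(1), what = "sweep")
  if (!all(ok))
    stop("element(s) ", paste(which(!ok), collapse = ", "),
         " are not sweep objects", call. = FALSE)
  modes <- vapply(sweeps, `[[`, character(1), "mode")
  rates <- vapply(sweeps, `[[`, numeric(1), "sampling_rate_Hz")
  if (length(unique(modes)) != 1L)
    stop("all sweeps in a set must share the same mode", call. = FALSE)
  if (length(unique(rates)) != 1L)
    stop("all sweeps in a set must share the same sampling rate", call. = FALSE)
  if (is.null(protocol_id)) protocol_id <- sweeps[[1]]$protocol$kind
  structure(list(sweeps = sweeps, protocol_id = protocol_id),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> protocol '%s', %d sweep(s), %s\n",
              x$protocol_id, length(x$sweeps), x$sweeps[[1]]$mode))
  invisible(x)
}

#' @export
length.sweep_set <- function(x) length(x$sweeps)

#' Build a per-cell feature table
#'
#' One row per (cell, feature). The fixed column order is
#' `cell_id, genotype, projection_class, compartment, distance_um, feature,
#' value, units` and rows are sorted lexicographically by cell then feature, so
#' a table built from the same features is byte-identical regardless of input
#' order.
#'
#' @param cell_id,genotype,projection_class,compartment,distance_um metadata
#'   columns (recycled if scalar).
#' @param feature,value,units feature name, numeric value and unit string.
#' @return A `data.frame` of class `"feature_table"`.
#' @export
feature_table <- function(cell_id, genotype, projection_class, compartment,
                          distance_um, feature, value, units) {
  df <- data.frame(cell_id = as.character(cell_id),
                   genotype = as.character(genotype),
                   projection_class = as.character(projection_class),
                   compartment = as.character(compartment),
                   distance_um = as.numeric(distance_um),
                   feature = as.character(feature),
                   value = as.numeric(value),
                   units = as.character(units),
                   stringsAsFactors = FALSE)
  if (any(!nzchar(df$units)))
    stop("every feature row needs a non-empty units string", call. = FALSE)
  key <- paste(df$cell_id, df$feature, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (cell_id, feature) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  df <- df[order(df$cell_id, df$feature, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("feature_table", "data.frame")
  df
}
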