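# Sweep container: a hierarchical directory container (schema "fxsephys-1").
# manifest.json carries the attribute tree (one group per cell, one entry per
# sweep); each sweep's arrays live in a two-column CSV written at %.17g, which
# round-trips IEEE-754 doubles bit-exactly. A flat per-sweep CSV fallback with
# '#key=value' header lines is also supported.

.fxs_schema <- "fxsephys-1"
.fxs_modes <- c("current_clamp", "voltage_clamp")

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# as.numeric("NA") warns; parse explicitly
.num_or_na <- function(s) {
  s[s == "NA"] <- NA_character_
  as.numeric(s)
}

.meta_to_list <- function(md) unclass(md)

.meta_from_list <- function(x) {
  required <- c("cell_id", "genotype", "projection_class", "compartment",
                "distance_um", "temperature_C", "holding_potential_mV",
                "ljp_corrected")
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("container metadata is missing required attribute(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  recording_metadata(cell_id = x$cell_id, genotype = x$genotype,
                     projection_class = x$projection_class,
                     compartment = x$compartment,
                     distance_um = x$distance_um,
                     temperature_C = x$temperature_C,
                     holding_potential_mV =
                       if (is.null(x$holding_potential_mV)) NA_real_
                       else as.numeric(x$holding_potential_mV),
                     ljp_corrected = isTRUE(x$ljp_corrected))
}

.check_mode <- function(mode) {
  if (length(mode) != 1L || !mode %in% .fxs_modes)
    stop("invalid sweep mode '", paste(mode, collapse = ","),
         "': must be one of ", paste(.fxs_modes, collapse = ", "),
         call. = FALSE)
  mode
}

#' Write sweep sets to a hierarchical container
#'
#' Writes a directory container (schema tag `fxsephys-1`): `manifest.json`
#' holds the group/attribute tree (a group per cell, an entry per sweep with
#' sampling rate, mode, units convention, serialized protocol and metadata),
#' and each sweep's stimulus/response arrays are stored as a two-column CSV in
#' full precision, so [read_container()] reproduces arrays bit-exactly.
#'
#' @param sweepsets a single [sweep_set()] or a list of them.
#' @param path directory to create (must not be an existing non-container
#'   file).
#' @return `path`, invisibly.
#' @export
write_container <- function(sweepsets, path) {
  if (inherits(sweepsets, "sweep_set")) sweepsets <- list(sweepsets)
  if (!is.list(sweepsets) || length(sweepsets) == 0L)
    stop("sweepsets must be a non-empty list of sweep_set objects",
         call. = FALSE)
  ok <- vapply(sweepsets, inherits, logical(1), what = "sweep_set")
  if (!all(ok))
    stop("sweepsets element(s) ", paste(which(!ok), collapse = ", "),
         " are not sweep_set objects", call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create container at ", path,
                              call. = FALSE)
  dir.create(file.path(path, "data"), showWarnings = FALSE)
  manifest <- list(schema = .fxs_schema, sweepsets = list())
  for (si in seq_along(sweepsets)) {
    ss <- sweepsets[[si]]
    entries <- vector("list", length(ss$sweeps))
    for (wi in seq_along(ss$sweeps)) {
      sw <- ss$sweeps[[wi]]
      rel <- sprintf("data/set%03d_sweep%03d.csv", si, wi)
      con <- file(file.path(path, rel), open = "wb")
      writeLines(c("stimulus,response",
                   paste(.fmt_num(sw$stimulus), .fmt_num(sw$response),
                         sep = ",")), con, sep = "\n")
      close(con)
      units <- if (sw$mode == "current_clamp") {
        list(stimulus = "pA", response = "mV")
      } else list(stimulus = "mV", response = "pA")
      entries[[wi]] <- list(
        file = rel, sampling_rate_Hz = sw$sampling_rate_Hz, mode = sw$mode,
        t0_s = sw$t0_s, units = units,
        protocol = list(kind = sw$protocol$kind,
                        parameters = sw$protocol$parameters),
        metadata = .meta_to_list(sw$metadata))
    }
    manifest$sweepsets[[si]] <- list(
      group = ss$sweeps[[1]]$metadata$cell_id,
      protocol_id = ss$protocol_id, sweeps = entries)
  }
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                           null = "null", na = "null", pretty = TRUE)
  writeLines(json, file.path(path, "manifest.json"))
  invisible(path)
}

.sweep_from_entry <- function(entry, path) {
  f <- file.path(path, entry$file)
  if (!file.exists(f)) stop("container data file missing: ", entry$file,
                            call. = FALSE)
  arr <- utils::read.csv(f, colClasses = "character")
  if (!identical(names(arr), c("stimulus", "response")))
    stop("corrupted sweep array file (bad columns): ", entry$file,
         call. = FALSE)
  stim <- as.numeric(arr$stimulus)
  resp <- as.numeric(arr$response)
  for (req in c("sampling_rate_Hz", "mode", "metadata"))
    if (is.null(entry[[req]]))
      stop("sweep entry missing required attribute '", req, "'",
           call. = FALSE)
  .check_mode(entry$mode)
  prot <- entry$protocol
  pd <- do.call(protocol_descriptor,
                c(list(kind = prot$kind), prot$parameters))
  sw <- sweep(stim, resp, sampling_rate_Hz = entry$sampling_rate_Hz,
              mode = entry$mode, metadata = .meta_from_list(entry$metadata),
              protocol = pd,
              t0_s = if (is.null(entry$t0_s)) 0 else entry$t0_s)
  known <- c("file", "sampling_rate_Hz", "mode", "t0_s", "units", "protocol",
             "metadata")
  extra <- entry[setdiff(names(entry), known)]
  if (length(extra)) attr(sw, "passthrough") <- extra
  sw
}

#' Read a sweep container
#'
#' Reads a directory container written by [write_container()], or, when
#' `path` contains no `manifest.json`, the documented flat CSV fallback
#' layout (one file per sweep; leading `#key=value` header lines followed by
#' `stimulus,response` columns; see [write_csv_fallback()]). Unknown sweep
#' attributes are preserved in a `"passthrough"` attribute.
#'
#' @param path container directory.
#' @return A list of [sweep_set()] objects.
#' @export
read_container <- function(path) {
  if (!dir.exists(path)) stop("no container at ", path, call. = FALSE)
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) return(.read_csv_fallback(path))
  manifest <- jsonlite::fromJSON(mf, simplifyVector = FALSE)
  if (!identical(manifest$schema, .fxs_schema))
    stop("unrecognised container schema: ",
         deparse(manifest$schema), call. = FALSE)
  lapply(manifest$sweepsets, function(ssent) {
    sweeps <- lapply(ssent$sweeps, .sweep_from_entry, path = path)
    sweep_set(sweeps, protocol_id = ssent$protocol_id)
  })
}

#' Write sweep sets in the flat CSV fallback layout
#'
#' One CSV per sweep: header lines `#key=value` (cell_id, genotype,
#' projection_class, compartment, distance_um, temperature_C,
#' holding_potential_mV, ljp_corrected, sampling_rate_Hz, mode, t0_s, set,
#' protocol_kind, protocol_json) followed by `stimulus,response` data lines
#' in full precision.
#'
#' @param sweepsets a [sweep_set()] or list of them.
#' @param path directory to write into.
#' @return `path`, invisibly.
#' @export
write_csv_fallback <- function(sweepsets, path) {
  if (inherits(sweepsets, "sweep_set")) sweepsets <- list(sweepsets)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (si in seq_along(sweepsets)) {
    ss <- sweepsets[[si]]
    for (wi in seq_along(ss$sweeps)) {
      sw <- ss$sweeps[[wi]]
      md <- sw$metadata
      hdr <- c(
        sprintf("#cell_id=%s", md$cell_id),
        sprintf("#genotype=%s", md$genotype),
        sprintf("#projection_class=%s", md$projection_class),
        sprintf("#compartment=%s", md$compartment),
        sprintf("#distance_um=%s", .fmt_num(md$distance_um)),
        sprintf("#temperature_C=%s", .fmt_num(md$temperature_C)),
        sprintf("#holding_potential_mV=%s", .fmt_num(md$holding_potential_mV)),
        sprintf("#ljp_corrected=%s", md$ljp_corrected),
        sprintf("#sampling_rate_Hz=%s", .fmt_num(sw$sampling_rate_Hz)),
        sprintf("#mode=%s", sw$mode),
        sprintf("#t0_s=%s", .fmt_num(sw$t0_s)),
        sprintf("#set=%03d", si),
        sprintf("#set_protocol_id=%s", ss$protocol_id),
        sprintf("#protocol_json=%s",
                jsonlite::toJSON(list(kind = sw$protocol$kind,
                                      parameters = sw$protocol$parameters),
                                 auto_unbox = TRUE, digits = NA)))
      f <- file.path(path, sprintf("set%03d_sweep%03d.csv", si, wi))
      con <- file(f, open = "wb")
      writeLines(c(hdr, "stimulus,response",
                   paste(.fmt_num(sw$stimulus), .fmt_num(sw$response),
                         sep = ",")), con, sep = "\n")
      close(con)
    }
  }
  invisible(path)
}

.read_csv_fallback <- function(path) {
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop("no container manifest and no CSV sweeps at ",
                           path, call. = FALSE)
  parsed <- lapply(files, function(f) {
    lines <- readLines(f)
    hdr_n <- which(!startsWith(lines, "#"))[1]
    kv <- lines[seq_len(hdr_n - 1L)]
    keys <- sub("^#([^=]+)=.*$", "\\1", kv)
    vals <- sub("^#[^=]+=", "", kv)
    names(vals) <- keys
    for (req in c("sampling_rate_Hz", "mode", "cell_id"))
      if (!req %in% keys)
        stop("CSV fallback sweep ", basename(f),
             " missing required attribute '", req, "'", call. = FALSE)
    .check_mode(unname(vals[["mode"]]))
    arr <- utils::read.csv(textConnection(lines[hdr_n:length(lines)]),
                           colClasses = "character")
    prot <- jsonlite::fromJSON(vals[["protocol_json"]],
                               simplifyVector = FALSE)
    md <- .meta_from_list(list(
      cell_id = vals[["cell_id"]], genotype = vals[["genotype"]],
      projection_class = vals[["projection_class"]],
      compartment = vals[["compartment"]],
      distance_um = .num_or_na(vals[["distance_um"]]),
      temperature_C = .num_or_na(vals[["temperature_C"]]),
      holding_potential_mV = .num_or_na(vals[["holding_potential_mV"]]),
      ljp_corrected = identical(vals[["ljp_corrected"]], "TRUE")))
    list(set = vals[["set"]], protocol_id = vals[["set_protocol_id"]],
         sweep = sweep(as.numeric(arr$stimulus), as.numeric(arr$response),
                       sampling_rate_Hz = .num_or_na(vals[["sampling_rate_Hz"]]),
                       mode = vals[["mode"]], metadata = md,
                       protocol = do.call(protocol_descriptor,
                                          c(list(kind = prot$kind),
                                            prot$parameters)),
                       t0_s = as.numeric(vals[["t0_s"]])))
  })
  sets <- split(parsed, vapply(parsed, `[[`, character(1), "set"))
  lapply(unname(sets), function(grp)
    sweep_set(lapply(grp, `[[`, "sweep"),
              protocol_id = grp[[1]]$protocol_id))
}

#' Write a feature table to CSV
#'
#' Fixed column order (`cell_id, genotype, projection_class, compartment,
#' distance_um, feature, value, units`) and deterministic row order (cell
#' then feature, lexicographic), so the same features always produce the same
#' bytes.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  if (!inherits(table, "feature_table"))
    table <- feature_table(table$cell_id, table$genotype,
                           table$projection_class, table$compartment,
                           table$distance_um, table$feature, table$value,
                           table$units)
  tab <- table[order(table$cell_id, table$feature, method = "radix"), ,
               drop = FALSE]
  lines <- c("cell_id,genotype,projection_class,compartment,distance_um,feature,value,units",
             paste(tab$cell_id, tab$genotype, tab$projection_class,
                   tab$compartment, .fmt_num(tab$distance_um), tab$feature,
                   .fmt_num(tab$value), tab$units, sep = ","))
  con <- file(path, open = "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV file path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c(
    cell_id = "character", genotype = "character",
    projection_class = "character", compartment = "character",
    distance_um = "character", feature = "character", value = "character",
    units = "character"))
  feature_table(df$cell_id, df$genotype, df$projection_class, df$compartment,
                as.numeric(df$distance_um), df$feature, as.numeric(df$value),
                df$units)
}
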