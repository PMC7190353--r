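# Delimited-text readers/writers and YAML configuration. All tabular I/O is
# tab-separated text with explicit headers; units are embedded in the
# column names (t_s, D_um, d_um, tension_nN, x_nm, ...).

.read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, check.names = FALSE)
  if (!nrow(df)) stop(sprintf("%s: no data rows", path))
  df
}

.check_numeric_cols <- function(df, cols, path) {
  for (cn in cols) {
    v <- df[[cn]]
    bad <- which(!is.finite(suppressWarnings(as.numeric(v))))
    if (length(bad))
      stop(sprintf("%s: malformed value in column '%s' at data line %d",
                   path, cn, bad[1]))
    df[[cn]] <- as.numeric(v)
  }
  df
}

.check_time <- function(t, path) {
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop(sprintf("%s: time not strictly increasing at data line %d",
                 path, bad[1] + 1L))
  invisible(t)
}

#' Write / read a force record
#'
#' Force records are tab-separated text with header `t_s, D_um, d_um`.
#' [read_force_record()] also auto-detects the pre-computed variant with
#' header `t_s, gamma, tension_nN` and returns a `tension_trace` in that
#' case (no geometry needed). Malformed rows and non-monotone times are
#' reported with their line numbers.
#'
#' @param record A [force_record()] object.
#' @param path File path.
#' @param geometry A [cantilever_geometry()], required for the raw
#'   `t_s, D_um, d_um` format.
#' @return `read_force_record()`: a [force_record()] or a `tension_trace`
#'   data frame depending on the detected format.
#' @export
write_force_record <- function(record, path) {
  stopifnot(inherits(record, "force_record"))
  df <- data.frame(t_s = record$t, D_um = record$D, d_um = record$d)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_force_record
#' @export
read_force_record <- function(path, geometry = NULL) {
  df <- .read_table(path)
  if (all(c("t_s", "D_um", "d_um") %in% names(df))) {
    df <- .check_numeric_cols(df, c("t_s", "D_um", "d_um"), path)
    .check_time(df$t_s, path)
    if (is.null(geometry))
      stop("geometry is required for a raw (t_s, D_um, d_um) record")
    return(force_record(df$t_s, df$D_um, df$d_um, geometry))
  }
  if (all(c("t_s", "gamma", "tension_nN") %in% names(df))) {
    df <- .check_numeric_cols(df, c("t_s", "gamma", "tension_nN"), path)
    .check_time(df$t_s, path)
    out <- data.frame(t = df$t_s, gamma = df$gamma,
                      tension_nN = df$tension_nN)
    return(structure(out, class = c("tension_trace", "data.frame"),
                     geometry = geometry))
  }
  stop(sprintf("%s: expected header (t_s, D_um, d_um) or (t_s, gamma, tension_nN)",
               path))
}

#' Write / read a tension trace
#'
#' Tab-separated text with header `t_s, gamma, tension_nN` plus one
#' `ell_<species>_nm` column per simulated species, if present.
#'
#' @param trace A `tension_trace` data frame.
#' @param path File path.
#' @export
write_tension_trace <- function(trace, path) {
  stopifnot(is.data.frame(trace),
            all(c("t", "gamma", "tension_nN") %in% names(trace)))
  df <- data.frame(t_s = trace$t, gamma = trace$gamma,
                   tension_nN = trace$tension_nN)
  ell <- grep("^ell_", names(trace), value = TRUE)
  for (cn in ell) df[[paste0(cn, "_nm")]] <- trace[[cn]]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tension_trace
#' @export
read_tension_trace <- function(path) {
  df <- .read_table(path)
  need <- c("t_s", "gamma", "tension_nN")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  df <- .check_numeric_cols(df, names(df), path)
  out <- data.frame(t = df$t_s, gamma = df$gamma, tension_nN = df$tension_nN)
  for (cn in grep("^ell_.*_nm$", names(df), value = TRUE))
    out[[sub("_nm$", "", cn)]] <- df[[cn]]
  structure(out, class = c("tension_trace", "data.frame"))
}

#' Write / read an intensity profile
#'
#' Tab-separated text with header `x_nm, intensity`.
#'
#' @param profile An [intensity_profile()] object.
#' @param path File path.
#' @export
write_intensity_profile <- function(profile, path) {
  stopifnot(inherits(profile, "intensity_profile"))
  utils::write.table(data.frame(x_nm = profile$x,
                                intensity = profile$intensity),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_intensity_profile
#' @export
read_intensity_profile <- function(path) {
  df <- .read_table(path)
  if (!all(c("x_nm", "intensity") %in% names(df)))
    stop(sprintf("%s: expected header (x_nm, intensity)", path))
  df <- .check_numeric_cols(df, c("x_nm", "intensity"), path)
  intensity_profile(df$x_nm, df$intensity)
}

# --- YAML configuration records ------------------------------------------

#' Write / read model, protocol, geometry and envelope configs as YAML
#'
#' Round-trip serialisation of the main parameter containers. A model file
#' holds a list of species records; a protocol file holds step times,
#' strains and end time; geometry and envelope files hold their scalar
#' fields.
#'
#' @param x The object to serialise.
#' @param path File path.
#' @name config_io
NULL

#' @rdname config_io
#' @export
write_model_config <- function(x, path) {
  stopifnot(inherits(x, "axon_model"))
  rec <- list(label = x$label, species = lapply(x$species, function(s)
    list(name = s$name, ell_f = s$ell_f, ell_u = s$ell_u, ell0p = s$ell0p,
         dx_fu = s$dx_fu, dx_uf = s$dx_uf, nu_u0 = s$nu_u0, nu_f0 = s$nu_f0,
         n = s$n, persistence_length = s$wlc$persistence_length,
         kBT = s$wlc$kBT)))
  yaml::write_yaml(rec, path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_model_config <- function(path) {
  rec <- yaml::read_yaml(path)
  if (is.null(rec$species)) stop(sprintf("%s: no species in model config", path))
  sp <- lapply(rec$species, function(s)
    crosslinker_species(s$name, s$ell_f, s$ell_u, s$ell0p, s$dx_fu, s$dx_uf,
                        s$nu_u0, s$nu_f0, n = s$n %||% 1,
                        wlc = wlc_params(s$persistence_length %||% 20,
                                         s$kBT %||% 4)))
  axon_model(sp, label = rec$label %||% "axon")
}

#' @rdname config_io
#' @export
write_protocol_config <- function(x, path) {
  stopifnot(inherits(x, "strain_protocol"))
  yaml::write_yaml(list(step_times = x$step_times, strains = x$strains,
                        end_time = x$end_time), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_protocol_config <- function(path) {
  rec <- yaml::read_yaml(path)
  strain_protocol(unlist(rec$step_times), unlist(rec$strains), rec$end_time)
}

#' @rdname config_io
#' @export
write_geometry_config <- function(x, path) {
  stopifnot(inherits(x, "cantilever_geometry"))
  yaml::write_yaml(list(k = x$k, L0 = x$L0, radius = x$radius), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_geometry_config <- function(path) {
  rec <- yaml::read_yaml(path)
  cantilever_geometry(rec$k, rec$L0, rec$radius)
}

#' @rdname config_io
#' @export
write_envelope_config <- function(x, path) {
  stopifnot(inherits(x, "axon_envelope"))
  yaml::write_yaml(unclass(x), path)
  invisible(path)
}

#' @rdname config_io
#' @export
read_envelope_config <- function(path) {
  do.call(axon_envelope, yaml::read_yaml(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
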