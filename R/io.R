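# File I/O: CSV traces and sweep tables with structured-text (YAML)
# sidecars carrying the configuration needed to regenerate them, and
# serialisation of cell fixtures and I_K1 parameter sets.

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Write / read a clamp trace
#'
#' The trace is written as CSV (`time_s`, `V_mV`, `I_k1_pA`,
#' `I_stim_pA`) at full precision, with a YAML sidecar
#' (`<path>.meta.yaml`) holding the metadata (configuration echo,
#' fixture id, seed, package version) so that any figure made from the
#' file can be regenerated from the file pair alone.
#'
#' @param trace a `clamp_trace`.
#' @param path CSV file path.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns
#'   the restored `clamp_trace`.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "clamp_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  md <- trace_metadata(trace)
  md$package_version <- as.character(utils::packageVersion("dynaclamp"))
  yaml::write_yaml(md, sidecar_path(path))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "V_mV", "I_k1_pA", "I_stim_pA")
  if (!all(need %in% names(df))) {
    stop("trace file is missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  md <- if (file.exists(sidecar_path(path))) {
    yaml::read_yaml(sidecar_path(path))
  } else list()
  new_trace(df$time_s, df$V_mV, df$I_k1_pA, df$I_stim_pA, metadata = md)
}

#' Write a voltage-clamp sweep family as CSV
#'
#' One row per sample with step-index and step-voltage columns; the
#' protocol is echoed into the YAML sidecar.
#'
#' @param sweeps a [run_voltage_clamp()] result.
#' @param path CSV file path.
#' @export
write_sweeps <- function(sweeps, path) {
  utils::write.csv(as.data.frame(sweeps), path, row.names = FALSE)
  pr <- attr(sweeps, "protocol")
  yaml::write_yaml(lapply(unclass(pr), function(x) x), sidecar_path(path))
  invisible(path)
}

#' Serialise cell parameters to / from structured text
#'
#' @param params a [cell_params()] object.
#' @param path YAML file path.
#' @export
write_cell <- function(params, path) {
  stopifnot(inherits(params, "cell_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' @rdname write_cell
#' @export
read_cell <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cell_params, vals[!vapply(vals, is.null, logical(1))])
}

#' Serialise I_K1 parameters to / from structured text
#'
#' The rate-constant table is written out in full so a file fully
#' determines the model.
#'
#' @param params an [ik1_params()] object.
#' @param path YAML file path.
#' @export
write_ik1 <- function(params, path) {
  stopifnot(inherits(params, "ik1_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' @rdname write_ik1
#' @export
read_ik1 <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(ik1_params, vals)
}

#' Write an I-V curve as two-column CSV
#'
#' @param iv an [iv_curve()].
#' @param path CSV file path.
#' @export
write_iv <- function(iv, path) {
  df <- data.frame(V_mV = iv$V, I = iv$I)
  names(df)[2] <- paste0("I_", gsub("[^A-Za-z0-9]", "_", attr(iv, "units")))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
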