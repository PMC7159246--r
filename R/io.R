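## CSV dialect: comma separator, dot decimal, UTF-8, header required.

trace_schema <- c("time_s", "force_N", "displacement_mm")

check_schema <- function(found, required, optional = character(0), path) {
  base <- found[seq_len(min(length(found), length(required)))]
  if (length(found) < length(required) || !identical(base, required))
    stop(sprintf("%s: expected header %s%s, found: %s", path,
                 paste(required, collapse = ","),
                 if (length(optional)) paste0("[,", paste(optional, collapse = ","), "]") else "",
                 paste(found, collapse = ",")))
  extra <- found[-seq_along(required)]
  if (length(extra) && !all(extra %in% optional))
    stop(sprintf("%s: unexpected column(s): %s", path,
                 paste(setdiff(extra, optional), collapse = ",")))
  invisible(TRUE)
}

check_numeric_col <- function(df, col, path) {
  v <- df[[col]]
  if (is.numeric(v)) return(as.numeric(v))
  coerced <- suppressWarnings(as.numeric(v))
  bad <- which(is.na(coerced) & !is.na(v))
  if (length(bad))
    stop(sprintf("%s: non-numeric value '%s' in column %s at data row %d",
                 path, v[bad[1]], col, bad[1]))
  coerced
}

#' Read a load-trace CSV
#'
#' Expects the dialect `time_s,force_N,displacement_mm[,phase]` (comma
#' separator, dot decimal, UTF-8, header required). Strictly increasing time
#' is enforced on read; schema and non-numeric violations are reported with
#' the offending column and row.
#'
#' @param path CSV path.
#' @return A [load_trace()].
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                          data.table = FALSE, encoding = "UTF-8")
  check_schema(names(dt), trace_schema, "phase", path)
  tm <- check_numeric_col(dt, "time_s", path)
  fo <- check_numeric_col(dt, "force_N", path)
  di <- check_numeric_col(dt, "displacement_mm", path)
  load_trace(tm, fo, di, phase = if ("phase" %in% names(dt)) dt$phase else NULL)
}

#' Write a load-trace CSV
#'
#' @param trace A [load_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  if (!inherits(trace, "load_trace")) stop("trace must be a load_trace")
  data.table::fwrite(as.data.frame(trace), path, sep = ",", dec = ".")
  invisible(path)
}

read_table_csv <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                          data.table = FALSE, encoding = "UTF-8")
  if (!all(required %in% names(dt)))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(setdiff(required, names(dt)), collapse = ",")))
  for (col in numeric_cols) dt[[col]] <- check_numeric_col(dt, col, path)
  dt
}

#' Read / write specimen metadata CSV (`specimen_id,group,csa_mm2`)
#'
#' @param path CSV path.
#' @return data.frame of specimen metadata.
#' @export
read_metadata_csv <- function(path) {
  dt <- read_table_csv(path, c("specimen_id", "group", "csa_mm2"), "csa_mm2")
  if (!all(dt$group %in% group_labels()))
    stop(path, ": unknown group label(s): ",
         paste(setdiff(unique(dt$group), group_labels()), collapse = ","))
  if (any(dt$csa_mm2 <= 0)) stop(path, ": csa_mm2 must be > 0")
  dt
}

#' @rdname read_metadata_csv
#' @param metadata data.frame with the metadata schema.
#' @export
write_metadata_csv <- function(metadata, path) {
  data.table::fwrite(metadata, path, sep = ",", dec = ".")
  invisible(path)
}

#' Read / write biopsy spectral CSV
#' (`specimen_id,group,distance_mm,dry_weight_mg,fluorescence_au,absorption_au`)
#'
#' @param path CSV path.
#' @return data.frame of spectral samples.
#' @export
read_spectral_csv <- function(path) {
  dt <- read_table_csv(path,
                       c("specimen_id", "group", "distance_mm", "dry_weight_mg",
                         "fluorescence_au", "absorption_au"),
                       c("distance_mm", "dry_weight_mg", "fluorescence_au", "absorption_au"))
  if (any(dt$dry_weight_mg <= 0)) stop(path, ": dry_weight_mg must be > 0")
  if (any(dt$distance_mm < 0)) stop(path, ": distance_mm must be >= 0")
  dt
}

#' @rdname read_spectral_csv
#' @param samples data.frame with the spectral schema.
#' @export
write_spectral_csv <- function(samples, path) {
  data.table::fwrite(samples, path, sep = ",", dec = ".")
  invisible(path)
}

#' Read / write calibration CSV
#' (`sample_id,concentration_mM,dry_weight_mg,fluorescence_au`)
#'
#' @param path CSV path.
#' @return data.frame of calibration samples.
#' @export
read_calibration_csv <- function(path) {
  dt <- read_table_csv(path,
                       c("sample_id", "concentration_mM", "dry_weight_mg", "fluorescence_au"),
                       c("concentration_mM", "dry_weight_mg", "fluorescence_au"))
  if (any(dt$concentration_mM < 0)) stop(path, ": concentration_mM must be >= 0")
  dt
}

#' @rdname read_calibration_csv
#' @param samples data.frame with the calibration schema.
#' @export
write_calibration_csv <- function(samples, path) {
  data.table::fwrite(samples, path, sep = ",", dec = ".")
  invisible(path)
}
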