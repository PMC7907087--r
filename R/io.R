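# File interfaces: CSV tables for chemicals, ratios and effect
# concentrations; YAML configs for cover parameters and well geometries;
# JSON run manifests.

#' Read a chemical descriptor CSV
#'
#' Expected header: `name,log_kow,log_hlc,mw,melting_point_c,
#' water_solubility` (comma-separated, UTF-8, decimal point). Empty cells
#' are missing values; a missing `log_kow` is a hard error naming the
#' offending row; unknown extra columns are dropped with a warning.
#'
#' @param path CSV file path.
#' @return A validated [chemicals] table.
#' @export
read_chemicals <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  extra <- setdiff(names(df), .chemical_columns)
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  if (!"log_kow" %in% names(df))
    stop("chemical table lacks required column(s): log_kow", call. = FALSE)
  blank <- !is.finite(suppressWarnings(as.numeric(df$log_kow)))
  if (any(blank))
    stop("row ", which(blank)[1], ": log_kow required", call. = FALSE)
  as_chemicals(df[, intersect(.chemical_columns, names(df)), drop = FALSE])
}

#' Write a chemical descriptor CSV
#' @param chems a [chemicals] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_chemicals <- function(chems, path) {
  chems <- as_chemicals(as.data.frame(chems))
  utils::write.csv(as.data.frame(chems), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read a measured-ratio CSV
#'
#' Expected header: `name,cover,medium_volume_ml,time_h,ratio,sd,n`
#' (plus optional `source`).
#'
#' @param path CSV file path.
#' @return A validated [as_ratio_records] table.
#' @export
read_ratio_records <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  as_ratio_records(utils::read.csv(path, stringsAsFactors = FALSE,
                                   na.strings = c("", "NA")))
}

#' Write a measured-ratio CSV
#' @param records a [as_ratio_records] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ratio_records <- function(records, path) {
  records <- as_ratio_records(as.data.frame(records))
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read loss-model parameters from YAML
#'
#' Expected keys: `cover`, `p1`..`p4`, optional `provenance` and
#' `n_calibration`.
#'
#' @param path YAML file path.
#' @return A [cover_params] object.
#' @export
read_cover_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  miss <- setdiff(c("p1", "p2", "p3", "p4"), names(y))
  if (length(miss))
    stop("cover parameter file lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cover_params(y$p1, y$p2, y$p3, y$p4, cover = y$cover %||% "custom",
               provenance = y$provenance,
               n_calibration = y$n_calibration)
}

#' Write loss-model parameters to YAML
#' @param params a [cover_params] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cover_params <- function(params, path) {
  stopifnot(inherits(params, "cover_params"))
  y <- list(cover = params$cover, p1 = params$p1, p2 = params$p2,
            p3 = params$p3, p4 = params$p4)
  if (!is.null(params$provenance)) y$provenance <- params$provenance
  if (!is.null(params$n_calibration))
    y$n_calibration <- params$n_calibration
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read a well geometry from YAML
#'
#' Expected keys: `well_diameter_mm`, `total_well_volume_ml`,
#' `medium_volume_ml`, optional `plate_format` and `biota` (a map with
#' `kind`, `count`, ...).
#'
#' @param path YAML file path.
#' @return A [well_geometry()] object.
#' @export
read_well_geometry <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  miss <- setdiff(c("well_diameter_mm", "total_well_volume_ml",
                    "medium_volume_ml"), names(y))
  if (length(miss))
    stop("geometry file lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  well_geometry(y$well_diameter_mm, y$total_well_volume_ml,
                y$medium_volume_ml,
                plate_format = y$plate_format %||% "custom",
                biota = y$biota)
}

#' Write a well geometry to YAML
#' @param geom a [well_geometry()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_well_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "well_geometry"))
  y <- list(plate_format = geom$plate_format,
            well_diameter_mm = geom$well_diameter_mm,
            total_well_volume_ml = geom$total_well_volume_ml,
            medium_volume_ml = geom$medium_volume_ml)
  if (!is.null(geom$biota)) y$biota <- geom$biota
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Read an EC50/LC50 comparison CSV
#'
#' Expected header: `name,ec50,lc50,unit,medium_volume_ml`. All
#' concentrations in one table must share the declared unit; no unit
#' conversion is attempted.
#'
#' @param path CSV file path.
#' @return data.frame with positive `ec50`/`lc50` columns.
#' @export
read_ec50_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  miss <- setdiff(c("name", "ec50"), names(df))
  if (length(miss))
    stop("EC50 table lacks: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$ec50)) || any(df$ec50 <= 0))
    stop("ec50 values must be > 0", call. = FALSE)
  if ("lc50" %in% names(df) &&
      any(!is.na(df$lc50) & df$lc50 <= 0))
    stop("lc50 values must be > 0", call. = FALSE)
  df
}

#' Write a JSON run manifest
#'
#' Records everything needed to reproduce a stochastic run: the inputs,
#' seed, parameter provenance and package version.
#'
#' @param path output path.
#' @param ... named fields to record.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, ...) {
  manifest <- c(list(package = "welldose",
                     version = as.character(
                       utils::packageVersion("welldose")),
                     timestamp = format(Sys.time(), tz = "UTC",
                                        usetz = TRUE)),
                list(...))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
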