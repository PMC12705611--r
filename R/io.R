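#' Write a study's plant and observation tables as CSV
#'
#' `plants.csv` carries plant_id, round_id, dose_uM, fw_root_g, fw_shoot_g,
#' excluded, reason; `observations.csv` carries plant_id, round_id, dose_uM,
#' day, modality, pixel_count, health_fraction, mean_ndvi.
#'
#' @param study An `ecobot_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$plants, file.path(dir, "plants.csv"), row.names = FALSE)
  write.csv(study$observations, file.path(dir, "observations.csv"),
            row.names = FALSE)
  invisible(dir)
}

plant_cols <- c("plant_id", "round_id", "dose_uM", "fw_root_g", "fw_shoot_g",
                "excluded", "reason")
obs_cols <- c("plant_id", "round_id", "dose_uM", "day", "modality",
              "pixel_count", "health_fraction", "mean_ndvi")

check_schema <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop(what, ": missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read plant / observation tables, validating the column schema
#'
#' @param path CSV file path.
#' @return A tibble; malformed files raise an error naming the missing
#'   columns.
#' @export
read_plant_table <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  check_schema(df, plant_cols, "read_plant_table")
  df$reason[is.na(df$reason)] <- ""
  df
}

#' @rdname read_plant_table
#' @export
read_observation_table <- function(path) {
  df <- tibble::as_tibble(read.csv(path))
  check_schema(df, obs_cols, "read_observation_table")
  df
}

#' Write a hyperspectral cube as band-sequential binary with a JSON sidecar
#'
#' The data file holds 32-bit little-endian floats in band-sequential order;
#' the sidecar lists dimensions, wavelengths (nm) and the flattened mask.
#'
#' @param cube An `hs_cube`.
#' @param path Path of the data file; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path) {
  dims <- dim(cube$cube)
  con <- file(path, "wb")
  on.exit(close(con))
  # BSQ: whole band planes in sequence, column-major within a plane
  writeBin(as.numeric(cube$cube), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(rows = dims[1], cols = dims[2], bands = dims[3],
         wavelengths = cube$wavelengths, interleave = "bsq",
         mask = as.vector(cube$mask)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a hyperspectral cube (JSON sidecar or ENVI-style header)
#'
#' Accepts either the sidecar written by [write_cube()] or a minimal
#' ENVI-style text header (`<path>.hdr` with samples/lines/bands, bsq
#' interleave, 32-bit float, and a wavelength list).
#'
#' @param path Path of the binary data file.
#' @return An `hs_cube`.
#' @export
read_cube <- function(path) {
  sidecar <- paste0(path, ".json")
  hdr <- paste0(path, ".hdr")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    rows <- meta$rows; cols <- meta$cols; bands <- meta$bands
    wl <- meta$wavelengths
    mask <- matrix(meta$mask, rows, cols)
  } else if (file.exists(hdr)) {
    meta <- parse_envi_header(hdr)
    rows <- meta$lines; cols <- meta$samples; bands <- meta$bands
    wl <- meta$wavelengths
    mask <- matrix(TRUE, rows, cols)
  } else {
    stop("read_cube: no sidecar (", sidecar, ") or ENVI header (", hdr,
         ") found", call. = FALSE)
  }
  n <- rows * cols * bands
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  structure(
    list(cube = array(vals, c(rows, cols, bands)), wavelengths = wl,
         mask = mask, w = NULL),
    class = "hs_cube"
  )
}

parse_envi_header <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  grab <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), txt))
    if (length(m) == 0) stop("read_cube: ENVI header missing `", key, "`",
                             call. = FALSE)
    as.integer(sub(".*=\\s*", "", m))
  }
  wl_m <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  wl <- if (length(wl_m) == 1) {
    as.numeric(strsplit(gsub(".*\\{|\\}", "", wl_m), ",")[[1]])
  } else {
    stop("read_cube: ENVI header missing `wavelength`", call. = FALSE)
  }
  list(samples = grab("samples"), lines = grab("lines"),
       bands = grab("bands"), wavelengths = wl)
}

#' Export an evaluation report as JSON
#'
#' Stores the per-split scores and the summary so reports can be compared
#' later (e.g. by the command-line `compare`).
#'
#' @param report A `pl_evaluation`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(report, path) {
  obj <- list(
    target = report$target,
    summary = as.list(glance(report)),
    splits = report$splits
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_evaluation
#' @export
read_evaluation_splits <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(target = obj$target, splits = tibble::as_tibble(obj$splits),
       summary = obj$summary)
}
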