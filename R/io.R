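# File I/O: multi-page TIFF volumes, YAML dose-model configuration, and
# atomic table/report writers (write to a temporary file in the target
# directory, then rename, so partial outputs never masquerade as complete).

#' Read / write a volume as multi-page TIFF
#'
#' Volumes are stored as 16-bit grayscale multi-page TIFF with one page per
#' z slice; gray values are assumed to lie in `[0, 65535]`.  TIFF carries no
#' 3D spacing, so the voxel size must be supplied on read.
#'
#' @param path File path.
#' @param voxel_size_um Isotropic voxel size in um (required on read).
#' @return `read_volume_tiff`: a [gray_volume()].
#' @export
read_volume_tiff <- function(path, voxel_size_um) {
  if (missing(voxel_size_um))
    stop("voxel_size_um must be supplied: TIFF carries no 3D spacing",
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(dim(pages[[1]])[1:2], length(pages))
  arr <- array(0, d)
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]][, , drop = TRUE]
  gray_volume(arr * 65535, voxel_size_um)
}

#' @rdname read_volume_tiff
#' @param volume A [gray_volume()] or [binary_volume()] (binary masks are
#'   written as 0/65535).
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, c("gray_volume", "binary_volume")))
  v <- if (inherits(volume, "binary_volume")) volume * 65535
       else pmin(pmax(as.double(volume), 0), 65535)
  v <- array(v, dim(volume)) / 65535
  pages <- lapply(seq_len(dim(v)[3]), function(k) v[, , k])
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tif")
  tiff::writeTIFF(pages, tmp, bits.per.sample = 16)
  file.rename(tmp, path)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

write_json_atomic <- function(obj, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(obj, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Build a dose model from a YAML configuration
#'
#' Expected structure (all dosimetry fields optional except the schedule):
#' ```yaml
#' nuclide: Ca-45            # preset name, or a block with
#'                           # name/half_life_days/mean_beta_energy_MeV/
#'                           # max_beta_energy_MeV/beta_yield_per_decay
#' schedule:
#'   - {age_weeks: 4, activity_concentration_Bq_per_g: 37000, body_mass_g: 20}
#'   - {age_weeks: 7, activity_concentration_Bq_per_g: 37000, body_mass_g: 20}
#' calibration: pinned_peak_rate
#' peak_dose_rate_mGy_per_day: 29
#' absorbed_fraction: 0.9
#' retention_fraction: 0.879
#' ddref: 1
#' # physical_mass mode instead:
#' # calibration: physical_mass
#' # source_mass_kg: 0.00088
#' # equilibrium_dose_constant: 1.233e-14   # optional override
#' ```
#'
#' @param path Path to the YAML file.
#' @return A calibrated [dose_model()].
#' @export
read_dose_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  nuc <- cfg$nuclide
  nuclide <- if (is.null(nuc)) {
    nuclide_ca45()
  } else if (is.character(nuc)) {
    switch(toupper(gsub("[^A-Z0-9]", "", toupper(nuc))),
           "CA45" = nuclide_ca45(),
           "SR89" = nuclide_sr89(),
           stop("unknown nuclide preset: ", nuc, call. = FALSE))
  } else {
    beta_nuclide(nuc$name, nuc$half_life_days, nuc$mean_beta_energy_MeV,
                 nuc$max_beta_energy_MeV,
                 yield = nuc$beta_yield_per_decay %||% 1)
  }
  if (is.null(cfg$schedule) || !length(cfg$schedule))
    stop("configuration error: schedule is required", call. = FALSE)
  schedule <- lapply(cfg$schedule, function(s)
    injection_event(s$age_weeks,
                    s$activity_concentration_Bq_per_g %||% 37000,
                    s$body_mass_g %||% 20))
  dose_model(nuclide = nuclide, schedule = schedule,
             calibration = cfg$calibration %||% "pinned_peak_rate",
             peak_dose_rate_mGy_per_day =
               cfg$peak_dose_rate_mGy_per_day %||% 29,
             source_mass_kg = cfg$source_mass_kg,
             absorbed_fraction = cfg$absorbed_fraction %||% 0.9,
             retention_fraction = cfg$retention_fraction %||% 0.879,
             delta = cfg$equilibrium_dose_constant,
             ddref = cfg$ddref %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
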