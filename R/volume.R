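#' Grayscale and binary 3D volumes
#'
#' Containers for microCT data: a `gray_volume` holds attenuation (or
#' density-calibrated gray) values on an isotropic voxel grid, a
#' `binary_volume` holds the segmented bone mask.  The voxel size is carried
#' in micrometres per side.
#'
#' @param voxels 3D numeric array of gray values.
#' @param voxel_size_um Isotropic voxel edge length in um (> 0).
#' @return A `gray_volume` or `binary_volume` object (a 3D array with a
#'   `voxel_size_um` attribute).
#' @export
gray_volume <- function(voxels, voxel_size_um) {
  stopifnot(is.numeric(voxels), length(dim(voxels)) == 3L,
            all(dim(voxels) >= 1L))
  if (!is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel size must be positive", call. = FALSE)
  structure(voxels, voxel_size_um = voxel_size_um,
            class = c("gray_volume", "array"))
}

#' @rdname gray_volume
#' @param mask 3D logical array; `TRUE` = bone.
#' @export
binary_volume <- function(mask, voxel_size_um) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, all(dim(mask) >= 1L))
  if (!is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("voxel size must be positive", call. = FALSE)
  structure(mask, voxel_size_um = voxel_size_um,
            class = c("binary_volume", "array"))
}

#' @rdname gray_volume
#' @param x A volume object.
#' @export
voxel_size_um <- function(x) {
  attr(x, "voxel_size_um")
}

#' @export
print.gray_volume <- function(x, ...) {
  cat(sprintf("<gray_volume> %s voxels @ %g um; range [%.4g, %.4g]\n",
              paste(dim(x), collapse = " x "), voxel_size_um(x),
              min(x), max(x)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume> %s voxels @ %g um; %.2f%% foreground\n",
              paste(dim(x), collapse = " x "), voxel_size_um(x),
              100 * mean(x)))
  invisible(x)
}

#' 3D median filter
#'
#' Replaces each voxel by the median of its cubic neighbourhood (default
#' 5 x 5 x 5), the standard denoising step before density thresholding of
#' microCT volumes.  Edges are padded by reflection.
#'
#' @param volume A [gray_volume()].
#' @param size Odd kernel edge length (default 5).
#' @return A filtered [gray_volume()].
#' @export
median_filter_3d <- function(volume, size = 5) {
  stopifnot(inherits(volume, "gray_volume"),
            size %% 2 == 1, size >= 1)
  d <- dim(volume)
  out <- cpp_median3(as.double(volume), as.integer(d), as.integer(size))
  gray_volume(array(out, d), voxel_size_um(volume))
}

#' Density calibration from phantom pairs
#'
#' Linear map from scanner gray values to hydroxyapatite-equivalent density
#' (mg/cm^3), fitted by least squares to phantom inserts of known density,
#' together with the minimum bone density used for segmentation.
#'
#' @param gray Gray values of the phantom inserts (>= 2 distinct values).
#' @param density_mg_cm3 Known densities of the inserts, mg/cm^3.
#' @param min_bone_density_mg_cm3 Segmentation threshold (default 334).
#' @return An object of class `density_calibration` with fields `slope`,
#'   `intercept`, `min_bone_density_mg_cm3`.
#' @export
#' @examples
#' cal <- density_calibration(c(100, 1100), c(0, 1000))
#' map_density(cal, 434)  # 334
density_calibration <- function(gray, density_mg_cm3,
                                min_bone_density_mg_cm3 = 334) {
  stopifnot(length(gray) == length(density_mg_cm3), length(gray) >= 2)
  if (length(unique(gray)) < 2)
    stop("calibration error: need >= 2 distinct phantom gray values",
         call. = FALSE)
  fit <- stats::lm(density_mg_cm3 ~ gray)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration error: fitted slope must be positive", call. = FALSE)
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 pairs = data.frame(gray = gray,
                                    density_mg_cm3 = density_mg_cm3),
                 min_bone_density_mg_cm3 = min_bone_density_mg_cm3),
            class = "density_calibration")
}

#' @rdname density_calibration
#' @param cal A `density_calibration`.
#' @param gray_values Gray values to map.
#' @return `map_density`: densities in mg/cm^3.
#' @export
map_density <- function(cal, gray_values) {
  stopifnot(inherits(cal, "density_calibration"))
  cal$intercept + cal$slope * gray_values
}

#' Segment bone by density threshold
#'
#' Maps gray values to density through the calibration and marks voxels at
#' or above the minimum bone density (inclusive, default 334 mg/cm^3) as
#' bone.
#'
#' @param volume A [gray_volume()].
#' @param cal A [density_calibration()].
#' @return A [binary_volume()].
#' @export
threshold_density <- function(volume, cal) {
  stopifnot(inherits(volume, "gray_volume"),
            inherits(cal, "density_calibration"))
  dens <- map_density(cal, as.double(volume))
  binary_volume(array(dens >= cal$min_bone_density_mg_cm3, dim(volume)),
                voxel_size_um(volume))
}

#' Volume-of-interest specification
#'
#' Defines either the trabecular metaphyseal VOI (a slab of `height_mm`
#' starting `offset_mm` from the growth-plate slice, toward the diaphysis)
#' or the cortical midshaft VOI (`n_slices` slices centred on the midshaft
#' slice).  Slices are counted along the third array axis.
#'
#' @param kind `"trabecular_metaphysis"` or `"cortical_midshaft"`.
#' @param growth_plate_slice Index of the growth-plate slice (trabecular).
#' @param offset_mm Gap between growth plate and VOI start, mm (default 0.5).
#' @param height_mm VOI height, mm (default 1.0).
#' @param direction +1 if the diaphysis lies at increasing slice index,
#'   -1 otherwise.
#' @param midshaft_center_slice Central slice of the cortical VOI.
#' @param n_slices Number of cortical slices (default 50).
#' @return An object of class `voi_spec`.
#' @export
voi_spec <- function(kind = c("trabecular_metaphysis", "cortical_midshaft"),
                     growth_plate_slice = NULL, offset_mm = 0.5,
                     height_mm = 1.0, direction = 1L,
                     midshaft_center_slice = NULL, n_slices = 50L) {
  kind <- match.arg(kind)
  if (kind == "trabecular_metaphysis") {
    stopifnot(!is.null(growth_plate_slice), offset_mm > 0, height_mm > 0,
              direction %in% c(-1L, 1L))
  } else {
    stopifnot(!is.null(midshaft_center_slice), n_slices >= 1)
  }
  structure(list(kind = kind, growth_plate_slice = growth_plate_slice,
                 offset_mm = offset_mm, height_mm = height_mm,
                 direction = as.integer(direction),
                 midshaft_center_slice = midshaft_center_slice,
                 n_slices = as.integer(n_slices)),
            class = "voi_spec")
}

#' Extract a volume of interest
#'
#' Crops the volume to the slices selected by a [voi_spec()].  For the
#' trabecular VOI the slab covers the half-open slice interval
#' `[gp + offset/v, gp + (offset + height)/v)` in the diaphysis direction
#' (voxel size `v`); the cortical VOI takes `n_slices` centred on the
#' midshaft slice.
#'
#' @param volume A [binary_volume()] or [gray_volume()].
#' @param spec A [voi_spec()].
#' @return The cropped volume (same class as the input).
#' @export
select_voi <- function(volume, spec) {
  stopifnot(inherits(volume, c("binary_volume", "gray_volume")),
            inherits(spec, "voi_spec"))
  nz <- dim(volume)[3]
  vox_mm <- voxel_size_um(volume) / 1000
  if (spec$kind == "trabecular_metaphysis") {
    off <- round(spec$offset_mm / vox_mm)
    h <- round(spec$height_mm / vox_mm)
    gp <- spec$growth_plate_slice
    if (spec$direction > 0) {
      lo <- gp + off
      hi <- gp + off + h - 1L
    } else {
      hi <- gp - off
      lo <- gp - off - h + 1L
    }
  } else {
    half_lo <- floor((spec$n_slices - 1) / 2)
    lo <- spec$midshaft_center_slice - half_lo
    hi <- lo + spec$n_slices - 1L
  }
  if (lo < 1L || hi > nz)
    stop(sprintf(
      "VOI slices %d..%d exceed volume slices 1..%d (overrun %d slice(s))",
      lo, hi, nz, max(1L - lo, hi - nz)), call. = FALSE)
  sub <- volume[, , lo:hi, drop = FALSE]
  if (inherits(volume, "binary_volume"))
    binary_volume(array(sub, dim(sub)), voxel_size_um(volume))
  else
    gray_volume(array(sub, dim(sub)), voxel_size_um(volume))
}
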