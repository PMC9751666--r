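# Analytic bone phantoms: deterministic voxelizations of geometries whose
# morphometric metrics have closed forms, used to validate the morphometry
# code.  All phantoms are generated programmatically; none are shipped as
# files.

#' Analytic bone phantoms with known metrics
#'
#' Voxelizes one of a family of test geometries and returns the binary
#' volume together with the closed-form ("truth") values of every metric the
#' geometry defines.  Feature sizes below 4 voxels are rejected as
#' unresolvable.
#'
#' Kinds and their parameters (all lengths in um):
#' * `plate_stack`: parallel plates of `thickness_um` on `pitch_um`
#'   (plates normal to the z axis, spanning x-y).  Truth: BV/TV, Tb.Th,
#'   Tb.Sp, Tb.N, SMI 0.
#' * `rod_lattice`: `n_rods` x `n_rods` parallel circular rods of
#'   `diameter_um` on a square lattice of `pitch_um`, along z.  Truth:
#'   BV/TV, Tb.Th, SMI 3, Euler characteristic `n_rods^2`.
#' * `ball`: solid sphere of `radius_um` padded by background.  Truth:
#'   thickness 2r, SMI 4, chi 1, Conn.D 0.
#' * `solid_torus`: torus of `major_radius_um`/`minor_radius_um` in a cubic
#'   domain of `domain_um`.  Truth: chi 0, Conn.D = 1/TV.
#' * `hollow_cylinder`: annular shaft of `outer_radius_um`,
#'   `inner_radius_um` spanning the full z extent (`n_slices` slices).
#'   Truth: Tt.Ar, Ct.Ar, Ct.Ar/Tt.Ar, Ct.Th.
#' * `loop_lattice`: planar grid of square-section struts with
#'   `n_bars_x` x `n_bars_y` bars, strut width `strut_um`, bar pitch
#'   `pitch_um`; carries `(n_bars_x-1)(n_bars_y-1)` independent loops.
#'   Truth: chi, Conn.D = loops/TV.
#' * `femur_like`: stylized long bone along z: a solid growth-plate slab,
#'   a metaphyseal plate stack (no cortical shell, plates span the cross
#'   section), and a midshaft hollow cylinder running to the end of the
#'   volume.  Truth: trabecular plate metrics for the standard trabecular
#'   VOI and annulus metrics for the midshaft VOI, plus the two
#'   [voi_spec()]s to use.
#'
#' @param kind Phantom kind (see Details).
#' @param voxel_size_um Isotropic voxel size (default 10 um).
#' @param ... Kind-specific geometry parameters, see Details.
#' @return A list with `volume` (a [binary_volume()]), `truth` (named list
#'   of closed-form metric values), and `spec` (the resolved parameters).
#' @export
#' @examples
#' ph <- make_phantom("plate_stack", thickness_um = 100, pitch_um = 500)
#' ph$truth$bv_tv  # 20
make_phantom <- function(kind = c("plate_stack", "rod_lattice", "ball",
                                  "solid_torus", "hollow_cylinder",
                                  "loop_lattice", "femur_like"),
                         voxel_size_um = 10, ...) {
  kind <- match.arg(kind)
  fun <- switch(kind,
                plate_stack = phantom_plate_stack,
                rod_lattice = phantom_rod_lattice,
                ball = phantom_ball,
                solid_torus = phantom_solid_torus,
                hollow_cylinder = phantom_hollow_cylinder,
                loop_lattice = phantom_loop_lattice,
                femur_like = phantom_femur_like)
  out <- fun(voxel_size_um = voxel_size_um, ...)
  out$spec <- c(list(kind = kind, voxel_size_um = voxel_size_um), out$spec)
  out
}

check_resolvable <- function(feature_um, voxel_size_um, what) {
  if (any(feature_um < 4 * voxel_size_um))
    stop(sprintf("%s (%g um) is below the 4-voxel resolvability limit at %g um voxels",
                 what, min(feature_um), voxel_size_um), call. = FALSE)
}

# voxel center coordinates (um) along one axis, first center at half a voxel
vox_centers <- function(n, voxel_size_um) {
  (seq_len(n) - 0.5) * voxel_size_um
}

phantom_plate_stack <- function(voxel_size_um, thickness_um = 100,
                                pitch_um = 500, n_periods = 4,
                                lateral_um = 640) {
  check_resolvable(thickness_um, voxel_size_um, "plate thickness")
  check_resolvable(pitch_um - thickness_um, voxel_size_um, "plate gap")
  t_vox <- round(thickness_um / voxel_size_um)
  p_vox <- round(pitch_um / voxel_size_um)
  nl <- round(lateral_um / voxel_size_um)
  nz <- n_periods * p_vox
  # phase-shift by half a plate so the stack starts and ends with a
  # half-plate: every gap is interior and the periodic 1-voxel tiling
  # (hence BV/TV = t/p) is preserved
  z_in_plate <- ((seq_len(nz) - 1 + t_vox %/% 2) %% p_vox) < t_vox
  mask <- array(rep(z_in_plate, each = nl * nl), dim = c(nl, nl, nz))
  t_mm <- t_vox * voxel_size_um / 1000
  p_mm <- p_vox * voxel_size_um / 1000
  list(volume = binary_volume(mask, voxel_size_um),
       truth = list(bv_tv = 100 * t_vox / p_vox, tb_th = t_mm,
                    tb_sp = p_mm - t_mm, tb_n = 1 / p_mm, smi = 0,
                    chi = n_periods + 1),
       spec = list(thickness_um = thickness_um, pitch_um = pitch_um,
                   n_periods = n_periods, lateral_um = lateral_um))
}

phantom_rod_lattice <- function(voxel_size_um, diameter_um = 160,
                                pitch_um = 480, n_rods = 2,
                                length_um = 640) {
  check_resolvable(diameter_um, voxel_size_um, "rod diameter")
  r_um <- diameter_um / 2
  lat_um <- n_rods * pitch_um
  nl <- round(lat_um / voxel_size_um)
  nz <- round(length_um / voxel_size_um)
  xy <- vox_centers(nl, voxel_size_um)
  centers <- (seq_len(n_rods) - 0.5) * pitch_um
  in_rod_1d <- outer(xy, centers, function(x, c) (x - c) ^ 2)
  # squared distance to the nearest rod axis, per (x, y)
  dx2 <- apply(in_rod_1d, 1, min)
  cross <- outer(dx2, dx2, `+`) <= r_um ^ 2
  mask <- array(rep(cross, nz), dim = c(nl, nl, nz))
  list(volume = binary_volume(mask, voxel_size_um),
       truth = list(bv_tv = 100 * pi * r_um ^ 2 / pitch_um ^ 2,
                    tb_th = diameter_um / 1000, smi = 3,
                    chi = n_rods ^ 2),
       spec = list(diameter_um = diameter_um, pitch_um = pitch_um,
                   n_rods = n_rods, length_um = length_um))
}

phantom_ball <- function(voxel_size_um, radius_um = 200, pad_vox = 18) {
  check_resolvable(2 * radius_um, voxel_size_um, "ball diameter")
  r_vox <- radius_um / voxel_size_um
  n <- 2 * ceiling(r_vox) + 1 + 2 * pad_vox
  ax <- seq_len(n) - (n + 1) / 2
  d2 <- outer(outer(ax ^ 2, ax ^ 2, `+`), ax ^ 2, `+`)
  mask <- array(d2 <= r_vox ^ 2, dim = c(n, n, n))
  list(volume = binary_volume(mask, voxel_size_um),
       truth = list(tb_th = 2 * radius_um / 1000, smi = 4, chi = 1,
                    conn_d = 0),
       spec = list(radius_um = radius_um, pad_vox = pad_vox))
}

phantom_solid_torus <- function(voxel_size_um, major_radius_um = 300,
                                minor_radius_um = 120, domain_um = 1000) {
  check_resolvable(2 * minor_radius_um, voxel_size_um, "torus tube diameter")
  n <- round(domain_um / voxel_size_um)
  ax <- vox_centers(n, voxel_size_um) - domain_um / 2
  rho <- sqrt(outer(ax ^ 2, ax ^ 2, `+`))   # distance to z axis in x-y plane
  ring2 <- (rho - major_radius_um) ^ 2
  mask <- array(FALSE, dim = c(n, n, n))
  for (k in seq_len(n))
    mask[, , k] <- ring2 + ax[k] ^ 2 <= minor_radius_um ^ 2
  tv_mm3 <- (n * voxel_size_um / 1000) ^ 3
  list(volume = binary_volume(mask, voxel_size_um),
       truth = list(chi = 0, conn_d = 1 / tv_mm3),
       spec = list(major_radius_um = major_radius_um,
                   minor_radius_um = minor_radius_um,
                   domain_um = domain_um))
}

phantom_hollow_cylinder <- function(voxel_size_um, outer_radius_um = 800,
                                    inner_radius_um = 500, n_slices = 50,
                                    margin_vox = 8) {
  check_resolvable(outer_radius_um - inner_radius_um, voxel_size_um,
                   "cortical shell thickness")
  nl <- 2 * ceiling(outer_radius_um / voxel_size_um) + 2 * margin_vox
  ax <- vox_centers(nl, voxel_size_um) - nl * voxel_size_um / 2
  rho2 <- outer(ax ^ 2, ax ^ 2, `+`)
  cross <- rho2 <= outer_radius_um ^ 2 & rho2 > inner_radius_um ^ 2
  mask <- array(rep(cross, n_slices), dim = c(nl, nl, n_slices))
  ro_mm <- outer_radius_um / 1000
  ri_mm <- inner_radius_um / 1000
  list(volume = binary_volume(mask, voxel_size_um),
       truth = list(tt_ar = pi * ro_mm ^ 2,
                    ct_ar = pi * (ro_mm ^ 2 - ri_mm ^ 2),
                    ct_ar_tt_ar = 100 * (ro_mm ^ 2 - ri_mm ^ 2) / ro_mm ^ 2,
                    ct_th = ro_mm - ri_mm),
       spec = list(outer_radius_um = outer_radius_um,
                   inner_radius_um = inner_radius_um,
                   n_slices = n_slices))
}

phantom_loop_lattice <- function(voxel_size_um, n_bars_x = 3, n_bars_y = 3,
                                 strut_um = 60, pitch_um = 300,
                                 pad_vox = 4) {
  check_resolvable(strut_um, voxel_size_um, "strut width")
  w <- round(strut_um / voxel_size_um)
  p <- round(pitch_um / voxel_size_um)
  span_x <- (n_bars_y - 1) * p + w   # bars along x cross bars along y
  span_y <- (n_bars_x - 1) * p + w
  nx <- span_x + 2 * pad_vox
  ny <- span_y + 2 * pad_vox
  nz <- w + 2 * pad_vox
  mask <- array(FALSE, dim = c(nx, ny, nz))
  zs <- pad_vox + seq_len(w)
  # bars along x at fixed y bands; bars along y at fixed x bands
  for (i in seq_len(n_bars_x)) {
    ys <- pad_vox + (i - 1) * p + seq_len(w)
    mask[pad_vox + seq_len(span_x), ys, zs] <- TRUE
  }
  for (j in seq_len(n_bars_y)) {
    xs <- pad_vox + (j - 1) * p + seq_len(w)
    mask[xs, pad_vox + seq_len(span_y), zs] <- TRUE
  }
  loops <- (n_bars_x - 1) * (n_bars_y - 1)
  tv_mm3 <- nx * ny * nz * (voxel_size_um / 1000) ^ 3
  list(volume = binary_volume(mask, voxel_size_um),
       truth = list(chi = 1 - loops, loops = loops,
                    conn_d = loops / tv_mm3),
       spec = list(n_bars_x = n_bars_x, n_bars_y = n_bars_y,
                   strut_um = strut_um, pitch_um = pitch_um))
}

phantom_femur_like <- function(voxel_size_um, lateral_um = 640,
                               plate_thickness_um = 100, pitch_um = 500,
                               growth_plate_um = 50,
                               outer_radius_um = 300,
                               inner_radius_um = 200) {
  check_resolvable(c(plate_thickness_um, growth_plate_um,
                     outer_radius_um - inner_radius_um),
                   voxel_size_um, "smallest feature")
  nl <- round(lateral_um / voxel_size_um)
  t_vox <- round(plate_thickness_um / voxel_size_um)
  p_vox <- round(pitch_um / voxel_size_um)
  gp_vox <- round(growth_plate_um / voxel_size_um)
  off_vox <- round(0.5 * 1000 / voxel_size_um)       # standard 0.5 mm offset
  h_vox <- round(1.0 * 1000 / voxel_size_um)         # standard 1.0 mm height
  pre <- 8                                            # epiphysis background
  gp_last <- pre + gp_vox                             # growth-plate slice
  meta_len <- off_vox + h_vox + p_vox                 # metaphyseal stack
  shaft_len <- 60
  nz <- gp_last + meta_len + shaft_len
  mask <- array(FALSE, dim = c(nl, nl, nz))
  mask[, , (pre + 1):gp_last] <- TRUE                 # growth plate slab
  # plate stack phased so the trabecular VOI tiles symmetrically:
  # half-gap, plate, gap, plate, half-gap (gaps at the VOI faces are then
  # half-width and bounded by the VOI boundary convention)
  j <- seq_len(meta_len) - 1
  phase <- (off_vox - 1 + (p_vox - t_vox) %/% 2) %% p_vox
  in_plate <- ((j - phase) %% p_vox) < t_vox
  for (s in which(in_plate)) mask[, , gp_last + s] <- TRUE
  # midshaft annulus to the end of the volume
  ax <- vox_centers(nl, voxel_size_um) - lateral_um / 2
  rho2 <- outer(ax ^ 2, ax ^ 2, `+`)
  ring <- rho2 <= outer_radius_um ^ 2 & rho2 > inner_radius_um ^ 2
  for (z in (gp_last + meta_len + 1):nz) mask[, , z] <- ring
  t_mm <- t_vox * voxel_size_um / 1000
  p_mm <- p_vox * voxel_size_um / 1000
  ro_mm <- outer_radius_um / 1000
  ri_mm <- inner_radius_um / 1000
  mid_center <- gp_last + meta_len + shaft_len - 25
  list(volume = binary_volume(mask, voxel_size_um),
       truth = list(
         trabecular = list(bv_tv = 100 * t_vox / p_vox, tb_th = t_mm,
                           tb_sp = p_mm - t_mm, tb_n = 1 / p_mm, smi = 0),
         cortical = list(tt_ar = pi * ro_mm ^ 2,
                         ct_ar = pi * (ro_mm ^ 2 - ri_mm ^ 2),
                         ct_ar_tt_ar = 100 * (ro_mm ^ 2 - ri_mm ^ 2) /
                           ro_mm ^ 2,
                         ct_th = ro_mm - ri_mm)),
       voi = list(
         trabecular = voi_spec("trabecular_metaphysis",
                               growth_plate_slice = gp_last),
         cortical = voi_spec("cortical_midshaft",
                             midshaft_center_slice = mid_center)),
       spec = list(lateral_um = lateral_um,
                   plate_thickness_um = plate_thickness_um,
                   pitch_um = pitch_um,
                   growth_plate_slice = gp_last,
                   midshaft_center_slice = mid_center,
                   outer_radius_um = outer_radius_um,
                   inner_radius_um = inner_radius_um))
}

#' Grayscale phantom with density calibration
#'
#' Converts a binary phantom into a grayscale volume through a linear
#' density-to-gray map with optional additive Gaussian noise, and returns
#' the matching [density_calibration()].  With zero noise,
#' [threshold_density()] recovers the binary phantom exactly.
#'
#' @param binary A [binary_volume()] (e.g. from [make_phantom()]).
#' @param bone_density_mg_cm3 Density assigned to bone voxels; must be at
#'   least the segmentation threshold (334 mg/cm^3).
#' @param background_density_mg_cm3 Density of non-bone voxels; must be
#'   below the threshold.
#' @param noise_sd Gaussian noise SD in density units (mg/cm^3).
#' @param seed Optional integer seed for the noise (reproducible).
#' @return A list with `volume` (a [gray_volume()]) and `calibration`.
#' @export
make_gray_phantom <- function(binary, bone_density_mg_cm3 = 800,
                              background_density_mg_cm3 = 100,
                              noise_sd = 0, seed = NULL) {
  stopifnot(inherits(binary, "binary_volume"))
  if (!(bone_density_mg_cm3 >= 334 &&
        background_density_mg_cm3 < 334))
    stop("need bone density >= 334 > background density", call. = FALSE)
  # gray = density/2 + 50: an arbitrary, invertible scanner map
  to_gray <- function(d) d / 2 + 50
  dens <- ifelse(binary, bone_density_mg_cm3, background_density_mg_cm3)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    dens <- dens + stats::rnorm(length(dens), sd = noise_sd)
  }
  vol <- gray_volume(array(to_gray(dens), dim(binary)),
                     voxel_size_um(binary))
  cal <- density_calibration(gray = to_gray(c(0, 500, 1000)),
                             density_mg_cm3 = c(0, 500, 1000))
  list(volume = vol, calibration = cal)
}
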