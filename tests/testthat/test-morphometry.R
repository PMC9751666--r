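# All tolerances below are in physical units: "1 voxel" at the default
# 10 um voxel size is 0.010 mm.

test_that("plate-stack phantom recovers all plate-model metrics", {
  ph <- make_phantom("plate_stack", thickness_um = 100, pitch_um = 500)
  v <- ph$volume
  expect_equal(bv_tv(v), ph$truth$bv_tv)                     # exact: 20%
  th <- local_thickness(v, "bone")
  sp <- local_thickness(v, "background")
  expect_equal(th, ph$truth$tb_th, tolerance = 0.010 / ph$truth$tb_th)
  expect_equal(sp, ph$truth$tb_sp, tolerance = 0.010 / ph$truth$tb_sp)
  expect_equal(tb_n(th, sp), ph$truth$tb_n, tolerance = 0.05)
  expect_equal(tb_n(0.1, 0.4), 2.0)
  expect_equal(tb_n(0.25, 0.25), 2.0)
  expect_error(tb_n(0, 0), "positive")
})

test_that("thickness recovers plate/ball/rod sizes across 4-20 voxels", {
  for (t_um in c(40, 80, 200)) {
    ph <- make_phantom("plate_stack", thickness_um = t_um,
                       pitch_um = t_um + 300, n_periods = 3,
                       lateral_um = 300)
    expect_equal(local_thickness(ph$volume, "bone"), t_um / 1000,
                 tolerance = 0.010 / (t_um / 1000))
  }
  b <- make_phantom("ball", radius_um = 200, pad_vox = 6)
  expect_equal(local_thickness(b$volume, "bone"), 0.400,
               tolerance = 0.010 / 0.4)
  r <- make_phantom("rod_lattice", diameter_um = 160, pitch_um = 480,
                    n_rods = 2, length_um = 480)
  expect_equal(local_thickness(r$volume, "bone"), 0.160,
               tolerance = 0.010 / 0.16)
  # a single voxel is one voxel thick
  single <- array(FALSE, c(7, 7, 7)); single[4, 4, 4] <- TRUE
  expect_equal(local_thickness(binary_volume(single, 10), "bone"), 0.010,
               tolerance = 1)
  expect_error(local_thickness(binary_volume(array(FALSE, c(3, 3, 3)), 10),
                               "bone"), "empty")
})

test_that("bv_tv covers the boundary cases", {
  allb <- binary_volume(array(TRUE, c(3, 3, 3)), 10)
  expect_equal(bv_tv(allb), 100)
  none <- binary_volume(array(FALSE, c(3, 3, 3)), 10)
  expect_equal(bv_tv(none), 0)
})

test_that("metrics are invariant under axis permutation and mirroring", {
  m <- random_blob(c(24, 20, 28), n_balls = 3, seed = 7)
  v <- binary_volume(m, 10)
  ref <- c(bv = bv_tv(v), cd = conn_d(v), th = local_thickness(v, "bone"))
  perms <- list(c(2, 1, 3), c(3, 2, 1), c(1, 3, 2))
  for (p in perms) {
    vp <- binary_volume(aperm(m, p), 10)
    expect_equal(bv_tv(vp), unname(ref["bv"]))
    expect_equal(conn_d(vp), unname(ref["cd"]))
    expect_equal(local_thickness(vp, "bone"), unname(ref["th"]),
                 tolerance = 1e-10)
  }
  mirror <- binary_volume(m[dim(m)[1]:1, , ], 10)
  expect_equal(bv_tv(mirror), unname(ref["bv"]))
  expect_equal(conn_d(mirror), unname(ref["cd"]))
  expect_equal(local_thickness(mirror, "bone"), unname(ref["th"]),
               tolerance = 1e-10)
  expect_equal(smi(binary_volume(aperm(m, c(2, 1, 3)), 10),
                   offsets_vox = seq(2, 6, 0.5)),
               smi(v, offsets_vox = seq(2, 6, 0.5)), tolerance = 1e-10)
})

test_that("cortical annulus metrics match the closed forms", {
  hc <- make_phantom("hollow_cylinder", outer_radius_um = 800,
                     inner_radius_um = 500)
  met <- cortical_metrics(hc$volume)
  # closed forms: Tt.Ar = pi 0.8^2 = 2.011, Ct.Ar = pi (0.64-0.25) = 1.225,
  # fraction 60.9%, Ct.Th = 0.300; 1-voxel slack on areas via the perimeter
  expect_equal(met$`Tt.Ar`, hc$truth$tt_ar, tolerance = 0.02)
  expect_equal(met$`Ct.Ar`, hc$truth$ct_ar, tolerance = 0.02)
  expect_equal(met$`Ct.Ar/Tt.Ar`, hc$truth$ct_ar_tt_ar, tolerance = 0.02)
  expect_equal(met$`Ct.Th`, hc$truth$ct_th, tolerance = 0.010 / 0.3)
})

test_that("solid cylinder degenerates to Ct.Ar = Tt.Ar", {
  nl <- 60
  ax <- (1:nl) - (nl + 1) / 2
  disc <- outer(ax^2, ax^2, `+`) <= 20^2
  vol <- binary_volume(array(rep(disc, 10), c(nl, nl, 10)), 10)
  met <- cortical_metrics(vol)
  expect_equal(met$`Ct.Ar`, met$`Tt.Ar`)
  expect_equal(met$`Ct.Ar/Tt.Ar`, 100)
})

test_that("a slice without bone is reported by index", {
  hc <- make_phantom("hollow_cylinder", n_slices = 10)
  v <- hc$volume
  v[, , 4] <- FALSE
  expect_error(cortical_metrics(binary_volume(array(v, dim(v)), 10)),
               "slice 4")
})

test_that("annulus metrics converge to closed form as voxels shrink", {
  errs <- sapply(c(20, 10, 5), function(vox) {
    hc <- make_phantom("hollow_cylinder", voxel_size_um = vox,
                       outer_radius_um = 800, inner_radius_um = 500,
                       n_slices = round(200 / vox))
    met <- cortical_metrics(hc$volume)
    abs(met$`Ct.Ar` - hc$truth$ct_ar) / hc$truth$ct_ar
  })
  expect_true(all(diff(errs) < 0))         # strictly shrinking error
  expect_lt(errs[3], 0.005)
  # doubling the voxel size changes areas by < 5%
  expect_lt(abs(errs[1] - errs[2]), 0.05)
})

test_that("relative metric ratio reports percent of means", {
  expect_equal(relative_metric_ratio(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(relative_metric_ratio(2.47, 1.0), 247)
  expect_equal(relative_metric_ratio(0, 5), 0)
  expect_error(relative_metric_ratio(1, 0), "zero")
  expect_error(relative_metric_ratio(numeric(0), 1), "non-empty")
})
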