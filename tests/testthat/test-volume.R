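test_that("median filter preserves constants and rejects impulses", {
  const <- gray_volume(array(7, c(8, 8, 8)), 10)
  expect_equal(as.double(median_filter_3d(const)), rep(7, 512))
  imp <- array(0, c(9, 9, 9))
  imp[5, 5, 5] <- 100
  out <- median_filter_3d(gray_volume(imp, 10))
  expect_equal(max(out), 0)
})

test_that("median filter matches a brute-force oracle with reflection", {
  set.seed(42)
  arr <- array(rnorm(6 * 7 * 5), c(6, 7, 5))
  got <- median_filter_3d(gray_volume(arr, 10), size = 3)
  expect_equal(as.double(got), as.double(oracle_median3(arr, 3)),
               tolerance = 1e-12)
  got5 <- median_filter_3d(gray_volume(arr, 10), size = 5)
  expect_equal(as.double(got5), as.double(oracle_median3(arr, 5)),
               tolerance = 1e-12)
})

test_that("density threshold maps gray to density and is inclusive", {
  # phantoms: gray 100 -> 0 mg/cm3, gray 1100 -> 1000 mg/cm3
  cal <- density_calibration(c(100, 1100), c(0, 1000))
  expect_equal(map_density(cal, 434), 334)
  vol <- gray_volume(array(c(433, 434, 435, 100), c(2, 2, 1)), 10)
  seg <- threshold_density(vol, cal)
  expect_equal(as.logical(seg), c(FALSE, TRUE, TRUE, FALSE))
  # all-air volume: empty mask
  air <- gray_volume(array(100, c(4, 4, 4)), 10)
  expect_equal(sum(threshold_density(air, cal)), 0)
  expect_error(density_calibration(c(100, 100), c(0, 1000)), "distinct")
  expect_error(density_calibration(c(1100, 100), c(0, 1000)), "slope")
})

test_that("trabecular VOI selects the offset slab toward the diaphysis", {
  vol <- binary_volume(array(FALSE, c(4, 4, 300)), 10)
  vol[, , 160:260] <- TRUE
  spec <- voi_spec("trabecular_metaphysis", growth_plate_slice = 100)
  voi <- select_voi(vol, spec)
  # 0.5 mm offset and 1.0 mm height at 10 um -> slices 150..249
  expect_equal(dim(voi)[3], 100)
  expect_equal(mean(voi[, , 1]), 0)    # slice 150: before the bone
  expect_equal(mean(voi[, , 11]), 1)   # slice 160: bone
  # reversed direction
  spec_dn <- voi_spec("trabecular_metaphysis", growth_plate_slice = 299,
                      direction = -1)
  voi_dn <- select_voi(vol, spec_dn)
  expect_equal(dim(voi_dn)[3], 100)
  # identity crop: offset + height spanning an aligned stack
  full <- select_voi(vol, voi_spec("trabecular_metaphysis",
                                   growth_plate_slice = 159,
                                   offset_mm = 0.01, height_mm = 1.0))
  expect_equal(dim(full)[3], 100)
  expect_true(all(full))
})

test_that("cortical VOI takes the midshaft slice block", {
  vol <- binary_volume(array(TRUE, c(4, 4, 200)), 10)
  voi <- select_voi(vol, voi_spec("cortical_midshaft",
                                  midshaft_center_slice = 100))
  expect_equal(dim(voi)[3], 50)   # 50 slices at 10 um = 0.5 mm of shaft
})

test_that("VOI overruns raise errors naming the overrun", {
  vol <- binary_volume(array(TRUE, c(4, 4, 60)), 10)
  expect_error(select_voi(vol, voi_spec("trabecular_metaphysis",
                                        growth_plate_slice = 20)),
               "exceed")
  expect_error(select_voi(vol, voi_spec("cortical_midshaft",
                                        midshaft_center_slice = 10)),
               "exceed")
})

test_that("volumes round-trip through multi-page TIFF", {
  ph <- make_phantom("loop_lattice")
  g <- make_gray_phantom(ph$volume, noise_sd = 20, seed = 1)
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume_tiff(g$volume, path)
  back <- read_volume_tiff(path, voxel_size_um = 10)
  expect_equal(dim(back), dim(g$volume))
  # 16-bit storage: values agree to one gray unit
  expect_lte(max(abs(as.double(back) - as.double(g$volume))), 1.0)
  expect_error(read_volume_tiff(path), "voxel_size_um")
})
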