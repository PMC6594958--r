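# Renders a single sphere at a known position for measurement tests.
render_sphere_volume <- function(center, radius, intensity = 0.8,
                                 shape = c(80, 80, 60),
                                 voxel = c(1, 1, 5)) {
  cfg <- volume_sim_config(volume_shape_um = shape, voxel_size_um = voxel,
                           noise_sd = 0, n_autofluor_blobs = 0,
                           n_nests_per_class = c(Bright = 0, Mid = 0),
                           n_singletons = 0)
  truth <- data.frame(x_um = center[1], y_um = center[2], z_um = center[3])
  arr <- array(0, dim = c(round(shape[2] / voxel[2]),
                          round(shape[1] / voxel[1]),
                          round(shape[3] / voxel[3])))
  xc <- (seq_len(dim(arr)[2]) - 0.5) * voxel[1]
  yc <- (seq_len(dim(arr)[1]) - 0.5) * voxel[2]
  zc <- (seq_len(dim(arr)[3]) - 0.5) * voxel[3]
  for (z in seq_along(zc)) {
    d2 <- outer((yc - center[2])^2, (xc - center[1])^2, "+") +
      (zc[z] - center[3])^2
    arr[, , z][d2 <= radius^2] <- intensity
  }
  image_volume(arr, voxel, "eGFP")
}

test_that("TIFF round trip preserves intensities and metadata", {
  cfg <- small_volume_config(volume_shape_um = c(150, 150, 60),
                             n_nests_per_class = c(Bright = 1, Mid = 0),
                             n_singletons = 0, n_autofluor_blobs = 0,
                             n_tubules = 1)
  sim <- simulate_testis_volume(cfg, seed = 9)
  path <- file.path(tempdir(), "roundtrip.tif")
  write_volume(sim$egfp, path)
  back <- read_volume(path)
  expect_identical(back$data, sim$egfp$data)
  expect_equal(back$voxel_size_um, sim$egfp$voxel_size_um)
  expect_equal(back$channel, "eGFP")
  # explicit voxel size overrides the sidecar
  v2 <- read_volume(path, voxel_size_um = c(2, 2, 10))
  expect_equal(v2$voxel_size_um, c(2, 2, 10))
  # no sidecar and no override is an error
  path2 <- file.path(tempdir(), "nosidecar.tif")
  file.copy(path, path2, overwrite = TRUE)
  unlink(paste0(path2, ".json"))
  expect_error(read_volume(path2), "voxel size")
  expect_s3_class(read_volume(path2, voxel_size_um = c(1, 1, 5)),
                  "image_volume")
})

test_that("a rendered 20 um sphere is measured near its analytic volume", {
  vol <- render_sphere_volume(center = c(40, 40, 30), radius = 10)
  obj <- segment_objects(vol, detection_config(threshold_method = 0.4,
                                               min_object_volume_um3 = 100))
  expect_equal(nrow(obj), 1)
  analytic <- 4 / 3 * pi * 10^3
  expect_lt(abs(obj$volume_um3 - analytic) / analytic, 0.15)
  expect_equal(obj$volume_um3, obj$voxel_count * 5)
  expect_lt(max(abs(c(obj$x_um - 40, obj$y_um - 40, obj$z_um - 30))), 5)
})

test_that("two separated spheres detect as two objects with accurate centroids", {
  cfg <- small_volume_config(
    volume_shape_um = c(200, 200, 100), n_tubules = 1,
    tubule_radius_um = 40,
    n_nests_per_class = c(Bright = 0, Mid = 0),
    n_singletons = 2, n_autofluor_blobs = 0, noise_sd = 0)
  sim <- simulate_testis_volume(cfg, seed = 21)
  # fixed threshold: with zero background noise, Otsu would split the two
  # reporter classes instead of background vs foreground
  obj <- segment_objects(sim$egfp,
                         detection_config(threshold_method = 0.1))
  expect_equal(nrow(obj), 2)
  tt <- sim$truth
  for (i in seq_len(2)) {
    d <- sqrt((obj$x_um - tt$x_um[i])^2 + (obj$y_um - tt$y_um[i])^2 +
                (obj$z_um - tt$z_um[i])^2)
    expect_lt(min(d), max(cfg$voxel_size_um))
  }
})

test_that("size filter and degenerate inputs behave", {
  vol <- render_sphere_volume(center = c(40, 40, 30), radius = 10)
  big_min <- detection_config(threshold_method = 0.4,
                              min_object_volume_um3 = 1e5)
  expect_equal(nrow(segment_objects(vol, big_min)), 0)
  zero <- image_volume(array(0, c(8, 8, 4)), c(1, 1, 5))
  expect_equal(nrow(segment_objects(zero, detection_config())), 0)
})

test_that("voxel count conservation against the thresholded mask", {
  cfg <- small_volume_config(noise_sd = 0)
  sim <- simulate_testis_volume(cfg, seed = 4)
  dc <- detection_config(threshold_method = 0.05,
                         min_object_volume_um3 = 0)
  obj <- segment_objects(sim$egfp, dc)
  expect_equal(sum(obj$voxel_count), sum(sim$egfp$data > 0.05))
})

test_that("otsu segmentation is invariant to intensity rescaling", {
  cfg <- small_volume_config(noise_sd = 0.01)
  sim <- simulate_testis_volume(cfg, seed = 8)
  obj1 <- segment_objects(sim$egfp, detection_config())
  half <- image_volume(sim$egfp$data / 2, sim$egfp$voxel_size_um, "eGFP")
  obj2 <- segment_objects(half, detection_config())
  expect_equal(nrow(obj1), nrow(obj2))
  expect_equal(obj1$voxel_count, obj2$voxel_count, tolerance = 0.02)
})

test_that("intensity classification bins with closed-left upper bins", {
  obj <- data.frame(mean_intensity = c(10, 55, 90, 40, 80))
  cls <- classify_intensity(obj, boundaries = c(40, 80))
  expect_equal(cls$class, c("below", "Mid", "Bright", "Mid", "Bright"))
  all_low <- classify_intensity(data.frame(mean_intensity = c(1, 2)),
                                c(40, 80))
  expect_true(all(all_low$class == "below"))
  expect_error(classify_intensity(obj, c(80, 40)))
})

test_that("cochannel filter removes autofluorescent objects", {
  cfg <- small_volume_config(n_autofluor_blobs = 3, noise_sd = 0.02)
  sim <- simulate_testis_volume(cfg, seed = 13)
  obj <- segment_objects(sim$egfp, detection_config())
  kept <- filter_by_cochannel(obj, sim$tdtomato)
  tt <- sim$truth
  blobs <- tt[tt$class == "autofluor", ]
  for (i in seq_len(nrow(blobs))) {
    d <- sqrt((kept$x_um - blobs$x_um[i])^2 + (kept$y_um - blobs$y_um[i])^2 +
                (kept$z_um - blobs$z_um[i])^2)
    expect_gt(min(d), blobs$radius_um[i])
  }
  expect_equal(nrow(kept), nrow(obj) - nrow(blobs))
})
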