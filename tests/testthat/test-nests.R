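sphere_objects <- function(centers, diameter = 20) {
  v <- 4 / 3 * pi * (diameter / 2)^3
  data.frame(id = seq_len(nrow(centers)), x_um = centers[, 1],
             y_um = centers[, 2], z_um = centers[, 3],
             volume_um3 = v)
}

test_that("border and center distances follow the sphere arithmetic", {
  obj <- sphere_objects(rbind(c(0, 0, 0), c(25, 0, 0)))
  expect_equal(pairwise_distances(obj, "border")[1, 2], 5)
  expect_equal(pairwise_distances(obj, "center")[1, 2], 25)
  # overlapping objects floor at zero
  close_obj <- sphere_objects(rbind(c(0, 0, 0), c(15, 0, 0)))
  expect_equal(pairwise_distances(close_obj, "border")[1, 2], 0)
  d <- pairwise_distances(obj, "border")
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(0, 0))
})

test_that("single-linkage chaining merges consecutive sub-cutoff gaps", {
  # three collinear cells, consecutive border gaps 9 um (ends 18 um apart)
  obj <- sphere_objects(rbind(c(0, 0, 0), c(29, 0, 0), c(58, 0, 0)))
  d <- pairwise_distances(obj, "border")
  res <- call_nests(d, nest_config(distance_mode = "border"))
  expect_equal(nrow(res$nests), 1)
  expect_equal(res$nests$cell_count, 3)
  expect_length(res$singleton_ids, 0)
})

test_that("pairs below the minimum nest size stay singletons", {
  obj <- sphere_objects(rbind(c(0, 0, 0), c(25, 0, 0)))
  res <- call_nests(pairwise_distances(obj, "border"),
                    nest_config(distance_mode = "border"))
  expect_equal(nrow(res$nests), 0)
  expect_equal(sort(res$singleton_ids), c(1, 2))
})

test_that("ties at exactly the cutoff are merged", {
  obj <- sphere_objects(rbind(c(0, 0, 0), c(30, 0, 0), c(60, 0, 0)))
  d <- pairwise_distances(obj, "border")  # consecutive gaps exactly 10
  res <- call_nests(d, nest_config(distance_mode = "border"))
  expect_equal(nrow(res$nests), 1)
})

test_that("nest partition equals brute-force components on random points", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 200
    pts <- cbind(runif(n, 0, 250), runif(n, 0, 250), runif(n, 0, 100))
    d <- as.matrix(dist(pts))
    res <- call_nests(d, nest_config(distance_mode = "center"))
    oracle <- brute_force_components(d, 10)
    expect_true(same_partition(res$membership, oracle))
  }
})

test_that("invalid distance matrices are rejected", {
  d <- matrix(c(0, 5, 6, 0), 2, 2)
  expect_error(call_nests(d, nest_config()), "asymmetric")
  d2 <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(call_nests(d2, nest_config()), "negative")
})

test_that("cell-count estimation rounds volumes against the 20 um sphere", {
  ref <- 4 / 3 * pi * 10^3
  expect_equal(estimate_cell_count(ref), 1L)
  expect_equal(estimate_cell_count(2 * ref), 2L)
  expect_equal(estimate_cell_count(100), 1L)  # clamp
  expect_equal(estimate_cell_count(c(4189, 8378)), c(1L, 2L))
  expect_error(estimate_cell_count(0))
})

test_that("nest summaries compute percent nested, size and counts", {
  # 8 nests of 4 cells plus 6 singletons, one class
  nests <- data.frame(nest_id = 1:8, cell_count = rep(4L, 8),
                      class = "Bright")
  objects <- data.frame(class = "Bright",
                        cell_count = c(rep(4L, 8), rep(1L, 6)))
  s <- summarize_nests(nests, objects)
  expect_equal(s$percent_in_nests, 100 * 32 / 38)
  expect_equal(s$average_nest_size, 4)
  expect_equal(s$total_nests, 8)

  none <- summarize_nests(nests[0, ], data.frame(class = "Bright",
                                                 cell_count = rep(1L, 5)))
  expect_equal(none$percent_in_nests, 0)
  expect_equal(none$total_nests, 0)

  all_in <- summarize_nests(
    data.frame(nest_id = 1, cell_count = 7L, class = "Mid"),
    data.frame(class = "Mid", cell_count = 7L))
  expect_equal(all_in$percent_in_nests, 100)

  empty_class <- summarize_nests(nests, objects, classes = c("Bright", "Mid"))
  expect_false(empty_class$defined[empty_class$class == "Mid"])
  expect_true(is.na(
    empty_class$percent_in_nests[empty_class$class == "Mid"]))
})

test_that("whole-organ scaling is linear with a full-imaging identity", {
  expect_equal(scale_total_nests(50, 400, 800), 100)
  expect_equal(scale_total_nests(37, 512, 512), 37)
  expect_warning(est <- scale_total_nests(10, 100, 80), "inconsistent")
  expect_equal(est, 8)
  expect_error(scale_total_nests(10, 0, 80))
})

test_that("nest membership grows monotonically with the cutoff", {
  set.seed(7)
  pts <- cbind(runif(80, 0, 200), runif(80, 0, 200), runif(80, 0, 80))
  d <- as.matrix(dist(pts))
  cfg10 <- nest_config(cutoff_um = 10, distance_mode = "center")
  sizes <- sapply(c(5, 10, 20, 40), function(h) {
    res <- call_nests(d, nest_config(cutoff_um = h,
                                     distance_mode = "center"))
    sum(res$nests$cell_count)
  })
  expect_true(all(diff(sizes) >= 0))
})

test_that("voxel-border distances agree with true gaps for rendered cells", {
  cfg <- small_volume_config(
    volume_shape_um = c(200, 200, 100), n_tubules = 1,
    tubule_radius_um = 40, n_nests_per_class = c(Bright = 1, Mid = 0),
    nest_size_sampler = function(n) rep(3L, n),
    n_singletons = 1, n_autofluor_blobs = 0, noise_sd = 0)
  sim <- simulate_testis_volume(cfg, seed = 31)
  obj <- segment_objects(sim$egfp, detection_config())
  d <- voxel_border_distances(obj, sim$egfp$voxel_size_um)
  expect_true(isSymmetric(d))
  # distances between objects of one nest stay below the cutoff, and the
  # singleton stays beyond it
  res <- call_nests(d, nest_config(),
                    cell_counts = estimate_cell_count(obj$volume_um3))
  expect_equal(nrow(res$nests), 1)
  expect_length(res$singleton_ids, nrow(obj) - res$nests$n_objects[1])
})
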