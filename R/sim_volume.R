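#' Configuration for the synthetic whole-testis volume generator
#'
#' Describes the geometry and photometry of a simulated two-channel
#' (eGFP reporter + tdTomato lineage label) confocal volume of a neonatal
#' testis: seminiferous tubules modelled as straight cylinders, germ-cell
#' nests placed along them, isolated single cells, and interstitial
#' autofluorescent blobs visible in the eGFP channel only.
#'
#' A configuration is "well separated" when the largest surface gap inside a
#' nest is below the nest-calling cutoff and the smallest gap between cells of
#' different nests (or singletons) is above it; this is validated at
#' construction via `cutoff_reference_um`.
#'
#' @param volume_shape_um numeric length-3, physical (x, y, z) extents in µm.
#' @param voxel_size_um numeric length-3, voxel pitch (x, y, z) in µm.
#'   The default 5 µm z pitch mirrors typical whole-testis optical sectioning.
#' @param n_tubules number of straight tubule tracks running along x.
#' @param tubule_radius_um tubule cylinder radius (µm).
#' @param n_nests_per_class named integer vector, nests per intensity class
#'   (`Bright`, `Mid`).
#' @param nest_size_sampler function(n) returning n integer nest sizes, all
#'   at least 3 cells.
#' @param intra_nest_gap_um maximum surface-to-surface gap (µm) between a nest
#'   cell and its attachment neighbour; must stay below the cutoff.
#' @param inter_nest_min_gap_um minimum surface gap (µm) between cells of
#'   different nests/singletons; must exceed the cutoff.
#' @param n_singletons isolated germ cells (assigned a class at random).
#' @param cell_diameter_um named numeric `c(mean=, sd=)`, germ-cell diameter.
#'   Germ cells in this system measure roughly 20 µm across.
#' @param intensity_params list with per-class log-normal eGFP intensity
#'   parameters (`Bright`, `Mid`, `autofluor`, each `c(meanlog=, sdlog=)`, on
#'   the normalised \[0, 1\] intensity scale) and a scalar `tdtomato` level
#'   shared by all germ cells.
#' @param n_autofluor_blobs interstitial autofluorescent objects (eGFP channel
#'   only, placed outside all tubules).
#' @param noise_sd additive Gaussian background noise (normalised intensity).
#' @param imaged_depth_fraction fraction of the z extent actually imaged
#'   (from z = 0); models depth-limited acquisition of large testes.
#' @param cutoff_reference_um nest-calling cutoff used to validate the
#'   well-separated invariant (default 10 µm).
#' @param max_placement_retries total rejection-sampling draws allowed before
#'   placement fails with an error naming the violated constraint.
#'
#' @return A validated list of class `volume_sim_config`.
#' @export
volume_sim_config <- function(volume_shape_um = c(400, 400, 200),
                              voxel_size_um = c(1, 1, 5),
                              n_tubules = 8,
                              tubule_radius_um = 35,
                              n_nests_per_class = c(Bright = 8, Mid = 3),
                              nest_size_sampler = function(n) sample(3:6, n, replace = TRUE),
                              intra_nest_gap_um = 6,
                              inter_nest_min_gap_um = 35,
                              n_singletons = 8,
                              cell_diameter_um = c(mean = 20, sd = 2),
                              intensity_params = list(
                                Bright = c(meanlog = log(0.80), sdlog = 0.04),
                                Mid = c(meanlog = log(0.40), sdlog = 0.04),
                                autofluor = c(meanlog = log(0.55), sdlog = 0.10),
                                tdtomato = 0.6),
                              n_autofluor_blobs = 3,
                              noise_sd = 0.02,
                              imaged_depth_fraction = 1,
                              cutoff_reference_um = 10,
                              max_placement_retries = 10000) {
  stopifnot(length(volume_shape_um) == 3, all(volume_shape_um > 0),
            length(voxel_size_um) == 3, all(voxel_size_um > 0),
            n_tubules >= 1, tubule_radius_um > 0,
            all(n_nests_per_class >= 0),
            all(c("Bright", "Mid") %in% names(n_nests_per_class)),
            is.function(nest_size_sampler),
            intra_nest_gap_um > 0, inter_nest_min_gap_um > 0,
            n_singletons >= 0, n_autofluor_blobs >= 0,
            cell_diameter_um[["mean"]] > 0, cell_diameter_um[["sd"]] >= 0,
            noise_sd >= 0,
            imaged_depth_fraction > 0, imaged_depth_fraction <= 1,
            max_placement_retries >= 1)
  if (!(intra_nest_gap_um < cutoff_reference_um &&
        cutoff_reference_um < inter_nest_min_gap_um)) {
    stop("well-separated invariant violated: need intra_nest_gap_um < ",
         cutoff_reference_um, " < inter_nest_min_gap_um")
  }
  structure(list(volume_shape_um = as.numeric(volume_shape_um),
                 voxel_size_um = as.numeric(voxel_size_um),
                 n_tubules = as.integer(n_tubules),
                 tubule_radius_um = tubule_radius_um,
                 n_nests_per_class = n_nests_per_class,
                 nest_size_sampler = nest_size_sampler,
                 intra_nest_gap_um = intra_nest_gap_um,
                 inter_nest_min_gap_um = inter_nest_min_gap_um,
                 n_singletons = as.integer(n_singletons),
                 cell_diameter_um = cell_diameter_um,
                 intensity_params = intensity_params,
                 n_autofluor_blobs = as.integer(n_autofluor_blobs),
                 noise_sd = noise_sd,
                 imaged_depth_fraction = imaged_depth_fraction,
                 cutoff_reference_um = cutoff_reference_um,
                 max_placement_retries = as.integer(max_placement_retries)),
            class = "volume_sim_config")
}

# surface gap between spheres (centres cx[i,], radii r): d - r_i - r_j
.surface_gaps <- function(point, radius, centers, radii) {
  if (nrow(centers) == 0L) return(numeric(0))
  d <- sqrt(colSums((t(centers) - point)^2))
  d - radii - radius
}

# Draw one candidate cell centre inside a random tubule, sphere fully inside
# the volume. Returns NULL when the tubule cannot host this radius.
.draw_in_tubule <- function(cfg, tubules, radius) {
  tb <- tubules[sample.int(nrow(tubules), 1L), ]
  ext <- cfg$volume_shape_um
  if (cfg$tubule_radius_um <= radius) return(NULL)
  x <- runif(1, radius, ext[1] - radius)
  rr <- sqrt(runif(1)) * (cfg$tubule_radius_um - radius)
  th <- runif(1, 0, 2 * pi)
  y <- tb$y + rr * cos(th)
  z <- tb$z + rr * sin(th)
  if (y < radius || y > ext[2] - radius || z < radius || z > ext[3] - radius)
    return(NULL)
  c(x, y, z)
}

#' Simulate a two-channel whole-testis image volume with ground truth
#'
#' Renders germ cells as solid spheres of class-specific eGFP intensity (all
#' germ cells share one tdTomato level), groups them into nests chained at
#' surface gaps below `intra_nest_gap_um`, keeps distinct groups separated by
#' more than `inter_nest_min_gap_um`, adds interstitial autofluorescent blobs
#' to the eGFP channel only, then samples the scene on the anisotropic voxel
#' grid, adds Gaussian background noise and quantises to 16 bits.
#'
#' Placement is rejection sampling with a global retry budget; an
#' unplaceable geometry raises an error naming the violated constraint.
#' Identical `config` + `seed` give bit-identical volumes and truth tables.
#'
#' @param config a [volume_sim_config()].
#' @param seed integer RNG seed.
#' @return list with `egfp` and `tdtomato` [image_volume()] objects (only the
#'   imaged slab `z <= imaged_depth_fraction * z extent` is rendered) and
#'   `truth`, a data.frame with one row per object: `cell_id`, `class`
#'   (`Bright`/`Mid`/`autofluor`), `nest_id` (NA for singletons and blobs),
#'   `x_um`, `y_um`, `z_um`, `radius_um`, `egfp_intensity`, `in_depth`.
#' @export
simulate_testis_volume <- function(config, seed) {
  stopifnot(inherits(config, "volume_sim_config"), is.numeric(seed))
  set.seed(as.integer(seed))
  cfg <- config
  ext <- cfg$volume_shape_um
  mean_r <- cfg$cell_diameter_um[["mean"]] / 2
  sd_r <- cfg$cell_diameter_um[["sd"]] / 2

  rt <- cfg$tubule_radius_um
  # tubule axes stay inside the volume; in extents below one diameter the
  # axis range collapses to the mid-plane
  rng <- function(extent) {
    lo <- min(rt, extent / 2); hi <- max(extent - rt, extent / 2)
    runif(cfg$n_tubules, lo, hi)
  }
  tubules <- data.frame(y = rng(ext[2]), z = rng(ext[3]))

  draws <- 0L
  budget <- cfg$max_placement_retries
  bump <- function(what) {
    draws <<- draws + 1L
    if (draws > budget)
      stop("placement failure: exceeded ", budget,
           " rejection-sampling draws while satisfying ", what)
  }

  centers <- matrix(numeric(0), ncol = 3)
  radii <- numeric(0)
  classes <- character(0)
  nest_ids <- integer(0)

  # Group radii are resampled until the summed cell volume rounds back to
  # the group's cell count against the reference (mean) diameter, with a
  # 0.3-cell margin: planted configurations stay recoverable by
  # volume-based cell counting even when touching cells merge into one
  # segmented object. Individual diameters still spread around the mean.
  draw_group_radii <- function(n) {
    for (try in seq_len(2000L)) {
      r <- pmax(2, rnorm(n, mean_r, sd_r))
      if (abs(sum((r / mean_r)^3) - n) <= 0.3) return(r)
    }
    stop("placement failure: could not draw a volume-consistent radius set")
  }

  place_group <- function(n_cells, class, nest_id) {
    # first cell anchors the group; later cells chain off a random member
    repeat {
      bump("inter_nest_min_gap_um")
      g_radii_draw <- draw_group_radii(n_cells)
      g_centers <- matrix(NA_real_, nrow = n_cells, ncol = 3)
      g_radii <- numeric(n_cells)
      ok <- TRUE
      for (i in seq_len(n_cells)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          bump("intra/inter nest gap constraints")
          r <- g_radii_draw[i]
          if (i == 1L) {
            p <- .draw_in_tubule(cfg, tubules, r)
            if (is.null(p)) next
          } else {
            j <- sample.int(i - 1L, 1L)
            gap <- runif(1, 0.25, 0.85) * cfg$intra_nest_gap_um
            dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
            p <- g_centers[j, ] + dir * (g_radii[j] + r + gap)
            if (any(p < r) || any(p > ext - r)) next
            # keep all members disjoint: overlapping spheres would lose
            # the intersection volume and break volume-based cell counting
            gg <- .surface_gaps(p, r, g_centers[seq_len(i - 1L), , drop = FALSE],
                                g_radii[seq_len(i - 1L)])
            if (any(gg < 0.5)) next
            if (min(gg) >= cfg$intra_nest_gap_um) next
          }
          if (any(.surface_gaps(p, r, centers, radii) <=
                  cfg$inter_nest_min_gap_um)) next
          g_centers[i, ] <- p
          g_radii[i] <- r
          placed <- TRUE
          break
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) break
    }
    centers <<- rbind(centers, g_centers)
    radii <<- c(radii, g_radii)
    classes <<- c(classes, rep(class, n_cells))
    nest_ids <<- c(nest_ids, rep(nest_id, n_cells))
  }

  nest_id <- 0L
  for (class in c("Bright", "Mid")) {
    n_nests <- cfg$n_nests_per_class[[class]]
    if (n_nests == 0) next
    sizes <- as.integer(cfg$nest_size_sampler(n_nests))
    if (any(sizes < 3))
      stop("nest_size_sampler returned a size below 3")
    for (s in sizes) {
      nest_id <- nest_id + 1L
      place_group(s, class, nest_id)
    }
  }
  for (k in seq_len(cfg$n_singletons)) {
    class <- sample(c("Bright", "Mid"), 1L)
    place_group(1L, class, NA_integer_)
  }

  # interstitial autofluorescent blobs: outside every tubule cylinder
  blob_centers <- matrix(numeric(0), ncol = 3)
  blob_radii <- numeric(0)
  for (k in seq_len(cfg$n_autofluor_blobs)) {
    repeat {
      bump("autofluorescent blob placement outside tubules")
      r <- runif(1, 5, 8)
      p <- c(runif(1, r, ext[1] - r), runif(1, r, ext[2] - r),
             runif(1, r, ext[3] - r))
      d_axis <- sqrt((tubules$y - p[2])^2 + (tubules$z - p[3])^2)
      # a 5 um clearance from germ cells and other blobs keeps blobs from
      # fusing with neighbouring objects during segmentation
      if (all(d_axis > rt + r) &&
          !any(.surface_gaps(p, r, centers, radii) <= 5) &&
          !any(.surface_gaps(p, r, blob_centers, blob_radii) <= 5)) {
        blob_centers <- rbind(blob_centers, p)
        blob_radii <- c(blob_radii, r)
        break
      }
    }
  }

  n_cells <- nrow(centers)
  ip <- cfg$intensity_params
  egfp_int <- numeric(n_cells)
  # nest members share independent draws from their class distribution
  for (class in c("Bright", "Mid")) {
    idx <- which(classes == class)
    p <- ip[[class]]
    egfp_int[idx] <- pmin(1, rlnorm(length(idx), p[["meanlog"]], p[["sdlog"]]))
  }
  blob_int <- if (length(blob_radii))
    pmin(1, rlnorm(length(blob_radii), ip$autofluor[["meanlog"]],
                   ip$autofluor[["sdlog"]])) else numeric(0)

  z_img <- cfg$imaged_depth_fraction * ext[3]

  truth <- data.frame(
    cell_id = seq_len(n_cells + length(blob_radii)),
    class = c(classes, rep("autofluor", length(blob_radii))),
    nest_id = c(nest_ids, rep(NA_integer_, length(blob_radii))),
    x_um = c(centers[, 1], blob_centers[, 1]),
    y_um = c(centers[, 2], blob_centers[, 2]),
    z_um = c(centers[, 3], blob_centers[, 3]),
    radius_um = c(radii, blob_radii),
    egfp_intensity = c(egfp_int, blob_int),
    in_depth = c(centers[, 3], blob_centers[, 3]) <= z_img,
    stringsAsFactors = FALSE)

  all_centers <- rbind(centers, blob_centers)
  all_radii <- c(radii, blob_radii)
  egfp <- .render_channel(all_centers, all_radii, c(egfp_int, blob_int),
                          cfg, z_img, "eGFP")
  td_lvl <- c(rep(ip$tdtomato, n_cells), rep(0, length(blob_radii)))
  tdt <- .render_channel(all_centers, all_radii, td_lvl, cfg, z_img,
                         "tdTomato")
  list(egfp = egfp, tdtomato = tdt, truth = truth)
}

# Rasterise spheres at voxel centres of the imaged slab, add noise, quantise.
.render_channel <- function(centers, radii, intensities, cfg, z_img, channel) {
  v <- cfg$voxel_size_um
  ext <- cfg$volume_shape_um
  nx <- max(1L, round(ext[1] / v[1]))
  ny <- max(1L, round(ext[2] / v[2]))
  nz <- max(1L, round(z_img / v[3]))
  arr <- array(0, dim = c(ny, nx, nz))
  xc <- (seq_len(nx) - 0.5) * v[1]
  yc <- (seq_len(ny) - 0.5) * v[2]
  zc <- (seq_len(nz) - 0.5) * v[3]
  for (i in seq_along(radii)) {
    if (intensities[i] <= 0) next
    cx <- centers[i, 1]; cy <- centers[i, 2]; cz <- centers[i, 3]
    r <- radii[i]
    ix <- which(xc >= cx - r & xc <= cx + r)
    iy <- which(yc >= cy - r & yc <= cy + r)
    iz <- which(zc >= cz - r & zc <= cz + r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (xc[ix] - cx)^2
    dy2 <- (yc[iy] - cy)^2
    dz2 <- (zc[iz] - cz)^2
    d2 <- outer(outer(dy2, dx2, "+"), dz2, "+")
    sub <- arr[iy, ix, iz, drop = FALSE]
    inside <- d2 <= r^2
    sub[inside] <- pmax(sub[inside], intensities[i])
    arr[iy, ix, iz] <- sub
  }
  if (cfg$noise_sd > 0)
    arr <- arr + rnorm(length(arr), 0, cfg$noise_sd)
  arr <- pmin(pmax(arr, 0), 1)
  arr <- round(arr * 65535) / 65535
  image_volume(arr, voxel_size_um = v, channel = channel)
}
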