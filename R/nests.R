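#' Nest-calling settings
#'
#' A nest is a group of three or more germ cells chained pairwise at no more
#' than `cutoff_um` apart. With ~20 µm cells, a 10 µm separation can only be
#' a surface-to-surface distance, so the default `distance_mode` is
#' `"border"` (centroid distance minus equivalent-sphere radii); centre-to-
#' centre distances remain available as `"center"`.
#'
#' @param cutoff_um single-linkage cut height, µm (default 10).
#' @param min_cells_per_nest minimum estimated cells for a reported nest
#'   (default 3; smaller groups are returned as sub-threshold singletons,
#'   since two cells can sit close together by chance).
#' @param distance_mode `"voxel_border"` (exact surface distance from the
#'   segmentation label map; falls back to `"border"` when no label map is
#'   available), `"border"` (equivalent-sphere surface distance) or
#'   `"center"`. Equivalent spheres underestimate the extent of merged
#'   multi-cell objects, so the voxel-accurate mode is the default.
#' @param reference_cell_diameter_um single-cell reference diameter used to
#'   convert object volumes to cell counts (default 20).
#' @return list of class `nest_config`.
#' @export
nest_config <- function(cutoff_um = 10,
                        min_cells_per_nest = 3L,
                        distance_mode = c("voxel_border", "border", "center"),
                        reference_cell_diameter_um = 20) {
  distance_mode <- match.arg(distance_mode)
  stopifnot(cutoff_um > 0, min_cells_per_nest >= 2,
            reference_cell_diameter_um > 0)
  structure(list(cutoff_um = cutoff_um,
                 min_cells_per_nest = as.integer(min_cells_per_nest),
                 distance_mode = distance_mode,
                 reference_cell_diameter_um = reference_cell_diameter_um),
            class = "nest_config")
}

#' Pairwise physical distances between detected objects
#'
#' `"center"` mode is the Euclidean centroid distance; `"border"` mode
#' subtracts the equivalent-sphere radii of both objects (radii derived from
#' object volumes) and floors the result at zero for overlapping objects.
#'
#' @param objects data.frame with `x_um`, `y_um`, `z_um` and (for border
#'   mode) `volume_um3`.
#' @param mode `"border"` or `"center"`.
#' @param reference_diameter_um unused in the distance itself; kept for
#'   interface symmetry with [nest_config()].
#' @return symmetric matrix of distances in µm with zero diagonal.
#' @export
pairwise_distances <- function(objects, mode = c("border", "center"),
                               reference_diameter_um = 20) {
  mode <- match.arg(mode)
  stopifnot(nrow(objects) >= 1)
  d <- as.matrix(dist(objects[, c("x_um", "y_um", "z_um")]))
  if (mode == "border") {
    r <- (3 * objects$volume_um3 / (4 * pi))^(1 / 3)
    d <- d - outer(r, r, "+")
    d <- pmax(d, 0)
    diag(d) <- 0
  }
  dimnames(d) <- NULL
  d
}

#' Call germ-cell nests by single-linkage clustering at a distance cutoff
#'
#' Cuts the single-linkage dendrogram of the supplied distance matrix at
#' `cutoff_um` (ties at exactly the cutoff are merged, honouring "no more
#' than"), which is equivalent to taking connected components of the
#' at-most-cutoff adjacency graph. Groups whose summed estimated cell count
#' reaches `min_cells_per_nest` are reported as nests; the rest are
#' singletons / sub-threshold groups. Nest ids are assigned in order of the
#' minimum member object id.
#'
#' @param dmat symmetric distance matrix (µm) with zero diagonal, e.g. from
#'   [pairwise_distances()].
#' @param config a [nest_config()].
#' @param cell_counts per-object cell counts (default 1 per object).
#'   Multi-cell merged objects contribute their full count. Fractional
#'   volume-equivalents (object volume over the reference single-cell
#'   volume) are accepted and preferred: group totals are rounded once at
#'   the group level, which avoids accumulating per-object rounding error
#'   when a nest splits across several merged objects.
#' @param intensities optional per-object mean eGFP intensities; when given,
#'   each nest carries its cell-count-weighted mean intensity, which
#'   downstream classification uses (the nest's average eGFP intensity
#'   determines its class).
#' @return list with `nests` (data.frame: `nest_id`, `n_objects`,
#'   `cell_count`, `mean_intensity`, `member_ids` as a list column),
#'   `singleton_ids` (object indices in sub-threshold groups), and
#'   `membership` (per-object group index before the size filter).
#' @export
call_nests <- function(dmat, config = nest_config(), cell_counts = NULL,
                       intensities = NULL) {
  stopifnot(inherits(config, "nest_config"), is.matrix(dmat),
            nrow(dmat) == ncol(dmat))
  if (any(dmat < 0)) stop("distance matrix has negative entries")
  if (max(abs(dmat - t(dmat))) > 1e-8) stop("distance matrix is asymmetric")
  n <- nrow(dmat)
  if (is.null(cell_counts)) cell_counts <- rep(1L, n)
  stopifnot(length(cell_counts) == n)

  groups <- if (n == 1L) 1L else {
    hc <- hclust(as.dist(dmat), method = "single")
    # ties at exactly the cutoff are merged ("no more than"); the epsilon
    # absorbs floating-point noise in computed border distances
    cutree(hc, h = config$cutoff_um * (1 + 1e-9))
  }

  ids <- seq_len(n)
  group_totals <- tapply(cell_counts, groups, sum)
  group_cells <- round(group_totals + 1e-9)
  group_min_id <- tapply(ids, groups, min)
  is_nest <- group_cells >= config$min_cells_per_nest
  nest_groups <- names(group_cells)[is_nest]
  # deterministic nest ids: ascending minimum member object id
  nest_groups <- nest_groups[order(group_min_id[nest_groups])]

  members <- lapply(nest_groups, function(g) ids[groups == as.integer(g)])
  mean_int <- if (is.null(intensities)) rep(NA_real_, length(nest_groups))
    else vapply(members, function(m)
      sum(intensities[m] * cell_counts[m]) / sum(cell_counts[m]), numeric(1))

  nests <- data.frame(
    nest_id = seq_along(nest_groups),
    n_objects = vapply(members, length, integer(1)),
    cell_count = as.integer(group_cells[nest_groups]),
    mean_intensity = mean_int)
  nests$member_ids <- members
  singleton_ids <- ids[!(groups %in% as.integer(nest_groups))]
  list(nests = nests, singleton_ids = singleton_ids, membership = groups)
}

#' Estimate the number of cells in a (possibly merged) object from its volume
#'
#' Touching same-class cells segment as one object; its volume divided by the
#' reference single-cell sphere volume, rounded and clamped to at least one,
#' estimates how many cells it holds.
#'
#' @param volume_um3 object volume(s), µm³ (must be positive).
#' @param reference_diameter_um single-cell diameter, µm (default 20).
#' @return integer vector of estimated cell counts, each ≥ 1.
#' @export
estimate_cell_count <- function(volume_um3, reference_diameter_um = 20) {
  if (any(volume_um3 <= 0)) stop("object volume must be positive")
  ref <- 4 / 3 * pi * (reference_diameter_um / 2)^3
  pmax(1L, as.integer(round(volume_um3 / ref)))
}

#' Per-class nest summary statistics
#'
#' For each intensity class: the percentage of cells found in nests, the
#' average nest size (estimated cells per nest) and the total nest count.
#' The denominator of the percentage is every detected cell of the class,
#' nested or not. A class with zero detected cells yields an
#' undefined-flagged row rather than NaN.
#'
#' @param nests data.frame from [call_nests()] with a `class` column added
#'   (classify the nest `mean_intensity`, e.g. via [classify_intensity()]).
#' @param objects data.frame of all detected objects with `class` and
#'   `cell_count` columns.
#' @param config a [nest_config()].
#' @param classes classes to report (default the classes present in
#'   `objects`).
#' @return data.frame with `class`, `n_cells`, `cells_in_nests`,
#'   `percent_in_nests`, `average_nest_size`, `total_nests`, `defined`.
#' @export
summarize_nests <- function(nests, objects, config = nest_config(),
                            classes = NULL) {
  stopifnot(!is.null(objects$class), !is.null(objects$cell_count))
  if (is.null(classes)) classes <- sort(unique(objects$class))
  rows <- lapply(classes, function(cl) {
    n_cells <- sum(objects$cell_count[objects$class == cl])
    sel <- nests[!is.na(nests$class) & nests$class == cl, , drop = FALSE]
    in_nests <- sum(sel$cell_count)
    data.frame(class = cl,
               n_cells = n_cells,
               cells_in_nests = in_nests,
               percent_in_nests = if (n_cells > 0) 100 * in_nests / n_cells
                                  else NA_real_,
               average_nest_size = if (nrow(sel)) mean(sel$cell_count)
                                   else NA_real_,
               total_nests = nrow(sel),
               defined = n_cells > 0)
  })
  do.call(rbind, rows)
}

#' Scale an observed nest count to a whole-organ estimate
#'
#' When imaging covers only part of the organ, the total nest number is
#' estimated by scaling the observed count by the ratio of the total cells
#' of that reporter subtype (quantified by flow-cytometric analysis) to the
#' cells captured by imaging.
#'
#' @param observed_nests nests counted in the imaged portion.
#' @param imaged_cells cells of the class captured by imaging (must be > 0).
#' @param fca_total_cells total cells of the class in the organ, from FCA.
#' @return scaled nest-count estimate (`observed * fca_total / imaged`);
#'   warns when `fca_total_cells < imaged_cells` (inconsistent inputs) but
#'   still returns the estimate.
#' @export
scale_total_nests <- function(observed_nests, imaged_cells, fca_total_cells) {
  stopifnot(imaged_cells > 0)
  if (fca_total_cells < imaged_cells)
    warning("fca_total_cells < imaged_cells: inconsistent inputs, ",
            "scaled estimate will shrink the observed count")
  observed_nests * fca_total_cells / imaged_cells
}

#' Exact voxel-surface distances between detected objects
#'
#' Minimum physical distance between the surface voxels of each object
#' pair, computed from the segmentation label map. This is the distance a
#' 3D ROI border-to-border measurement reports and stays accurate for
#' merged multi-cell objects, whose equivalent-sphere radius underestimates
#' their extent. Pairs whose centroids are farther apart than
#' `far_threshold_um` keep the cheap equivalent-sphere estimate (they are
#' far beyond any nest cutoff).
#'
#' @param objects data.frame from [segment_objects()] carrying its
#'   `label_array` attribute (or pass `label_array` explicitly).
#' @param voxel_size_um voxel pitch (x, y, z) in µm.
#' @param label_array integer 3D label array from segmentation.
#' @param far_threshold_um centroid-distance cutoff above which the
#'   equivalent-sphere estimate is kept (default 120).
#' @return symmetric distance matrix (µm), zero diagonal.
#' @export
voxel_border_distances <- function(objects, voxel_size_um,
                                   label_array = attr(objects, "label_array"),
                                   far_threshold_um = 120) {
  if (is.null(label_array))
    stop("no label array: rerun segment_objects() or pass label_array")
  n <- nrow(objects)
  d <- pairwise_distances(objects, mode = "border")
  if (n < 2) return(d)
  cen <- as.matrix(dist(objects[, c("x_um", "y_um", "z_um")]))
  near <- which(upper.tri(cen) & cen <= far_threshold_um, arr.ind = TRUE)
  if (nrow(near)) {
    pairs <- cbind(objects$label[near[, 1]], objects$label[near[, 2]])
    exact <- min_border_distances(as.integer(label_array), dim(label_array),
                                  as.numeric(voxel_size_um),
                                  matrix(as.integer(pairs), ncol = 2))
    d[near] <- exact
    d[near[, c(2, 1), drop = FALSE]] <- exact
  }
  d
}

#' End-to-end nest statistics from a two-channel volume
#'
#' Convenience wrapper running the full imaging arm: detect eGFP objects,
#' drop autofluorescent objects via the tdTomato co-channel, convert object
#' volumes to cell counts, classify object and nest intensities, call nests,
#' and summarise per class.
#'
#' @param egfp,tdtomato [image_volume()] objects (tdtomato may be NULL).
#' @param boundaries length-2 eGFP class boundaries for
#'   [classify_intensity()].
#' @param detection a [detection_config()].
#' @param nest_cfg a [nest_config()].
#' @param cochannel_threshold tdTomato threshold for autofluorescence
#'   exclusion.
#' @return list with `objects`, `nests`, `singleton_ids`, `summary`.
#' @export
nest_pipeline <- function(egfp, tdtomato = NULL, boundaries,
                          detection = detection_config(),
                          nest_cfg = nest_config(),
                          cochannel_threshold = 0.1) {
  obj <- segment_objects(egfp, detection)
  if (!is.null(tdtomato))
    obj <- filter_by_cochannel(obj, tdtomato, cochannel_threshold)
  if (!nrow(obj)) {
    return(list(objects = obj, nests = NULL, singleton_ids = integer(0),
                summary = NULL))
  }
  obj$cell_count <- estimate_cell_count(obj$volume_um3,
                                        nest_cfg$reference_cell_diameter_um)
  obj <- classify_intensity(obj, boundaries)
  dmat <- if (nest_cfg$distance_mode == "voxel_border" &&
              !is.null(attr(obj, "label_array")))
    voxel_border_distances(obj, egfp$voxel_size_um)
  else pairwise_distances(obj, mode = if (nest_cfg$distance_mode == "center")
    "center" else "border")
  ref_vol <- 4 / 3 * pi * (nest_cfg$reference_cell_diameter_um / 2)^3
  called <- call_nests(dmat, nest_cfg,
                       cell_counts = obj$volume_um3 / ref_vol,
                       intensities = obj$mean_intensity)
  nests <- called$nests
  if (nrow(nests)) nests <- classify_intensity(nests, boundaries)
  else nests$class <- character(0)
  summary <- summarize_nests(nests, obj, nest_cfg)
  list(objects = obj, nests = nests, singleton_ids = called$singleton_ids,
       summary = summary)
}
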