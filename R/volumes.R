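#' 3D image volume with physical voxel spacing
#'
#' A light container for one fluorescence channel of a confocal stack:
#' a numeric array `dim = c(ny, nx, nz)` of nonnegative intensities on the
#' normalised \[0, 1\] scale, plus the voxel pitch in µm.
#'
#' @param data numeric 3D array, `dim = c(ny, nx, nz)`.
#' @param voxel_size_um numeric length-3 voxel pitch (x, y, z) in µm.
#' @param channel channel name, e.g. `"eGFP"`.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size_um, channel = "unknown") {
  stopifnot(is.array(data), length(dim(data)) == 3, all(dim(data) > 0),
            length(voxel_size_um) == 3, all(voxel_size_um > 0),
            all(is.finite(data)), min(data) >= 0)
  structure(list(data = data,
                 voxel_size_um = as.numeric(voxel_size_um),
                 channel = as.character(channel)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> channel=%s  %d x %d x %d voxels (y,x,z), voxel %.3g x %.3g x %.3g um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

.sidecar_path <- function(path) paste0(path, ".json")

#' Write an image volume as a multi-page 16-bit TIFF with a JSON sidecar
#'
#' One TIFF page per z slice; voxel pitch and channel name go to
#' `<path>.json`. Intensities are stored at 16-bit depth, which round-trips
#' the generator's quantised values exactly.
#'
#' @param volume an [image_volume()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  pages <- lapply(seq_len(dim(volume$data)[3]),
                  function(z) volume$data[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(list(voxel_size_um = volume$voxel_size_um,
                            channel = volume$channel),
                       .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack into an image volume
#'
#' Voxel pitch is taken from the `<path>.json` sidecar when present;
#' a `voxel_size_um` argument overrides it. With neither, reading fails.
#'
#' @param path TIFF path.
#' @param voxel_size_um optional numeric length-3 voxel pitch (x, y, z), µm.
#' @param channel optional channel name override.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, voxel_size_um = NULL, channel = NULL) {
  stopifnot(file.exists(path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged TIFF stack: pages differ in size")
  side <- .sidecar_path(path)
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else NULL
  if (is.null(voxel_size_um)) {
    if (is.null(meta))
      stop("no voxel size metadata: sidecar ", side,
           " missing and voxel_size_um not supplied")
    voxel_size_um <- meta$voxel_size_um
  }
  if (is.null(channel))
    channel <- if (!is.null(meta)) meta$channel else "unknown"
  arr <- array(0, dim = c(dims[1, 1], dims[2, 1], length(pages)))
  for (z in seq_along(pages)) arr[, , z] <- pages[[z]]
  image_volume(arr, voxel_size_um = voxel_size_um, channel = channel)
}

#' Object-detection settings
#'
#' @param threshold_method `"otsu"` (Otsu's threshold computed on the nonzero
#'   voxels) or a fixed numeric threshold.
#' @param min_object_volume_um3 discard components below this physical volume.
#' @param connectivity 6 (faces) or 26 (faces + edges + corners); 26 merges
#'   diagonal voxel contacts, which matters at coarse z steps.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(threshold_method = "otsu",
                             min_object_volume_um3 = 250,
                             connectivity = 26L) {
  stopifnot(min_object_volume_um3 >= 0, connectivity %in% c(6L, 26L))
  if (!(identical(threshold_method, "otsu") ||
        (is.numeric(threshold_method) && length(threshold_method) == 1)))
    stop("threshold_method must be 'otsu' or a single numeric value")
  structure(list(threshold_method = threshold_method,
                 min_object_volume_um3 = min_object_volume_um3,
                 connectivity = as.integer(connectivity)),
            class = "detection_config")
}

.otsu_threshold <- function(values) {
  nz <- values[values > 0]
  if (!length(nz)) return(Inf)
  if (length(unique(nz)) == 1L) return(nz[1] / 2)
  img <- EBImage::Image(nz, dim = c(length(nz), 1L))
  EBImage::otsu(img, range = range(nz), levels = 256L)
}

#' Detect fluorescent objects in a 3D volume
#'
#' Thresholds the volume (Otsu on nonzero voxels by default), labels
#' connected components in 3D at the configured connectivity, discards
#' components below the minimum physical volume, and measures each surviving
#' object in µm: unweighted centroid of voxel centres, voxel count, physical
#' volume (`voxel_count` times the voxel volume) and mean intensity. Objects
#' are ordered by the (z, y, x) scan position of their first voxel.
#'
#' @param volume an [image_volume()].
#' @param config a [detection_config()].
#' @return data.frame with columns `id`, `x_um`, `y_um`, `z_um`,
#'   `volume_um3`, `mean_intensity`, `voxel_count`, `channel`; the threshold
#'   used is attached as attribute `"threshold"`. An all-zero volume yields
#'   zero rows.
#' @export
segment_objects <- function(volume, config = detection_config()) {
  stopifnot(inherits(volume, "image_volume"),
            inherits(config, "detection_config"))
  arr <- volume$data
  thr <- if (identical(config$threshold_method, "otsu"))
    .otsu_threshold(as.numeric(arr)) else config$threshold_method
  mask <- arr > thr
  empty <- data.frame(id = integer(0), x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), volume_um3 = numeric(0),
                      mean_intensity = numeric(0), voxel_count = integer(0),
                      channel = character(0), stringsAsFactors = FALSE)
  attr(empty, "threshold") <- thr
  if (!any(mask)) return(empty)

  labels <- label_components_3d(as.logical(mask), dim(arr),
                                config$connectivity)
  ncomp <- attr(labels, "n_components")
  keep <- labels > 0L
  lab <- labels[keep]
  idx <- which(keep)
  d <- dim(arr)
  ny <- d[1]; nx <- d[2]
  z <- (idx - 1L) %/% (ny * nx)
  rem <- (idx - 1L) %% (ny * nx)
  x <- rem %/% ny
  y <- rem %% ny
  v <- volume$voxel_size_um
  voxvol <- prod(v)

  counts <- tabulate(lab, nbins = ncomp)
  cx <- (tapply((x + 0.5) * v[1], lab, sum) / counts)
  cy <- (tapply((y + 0.5) * v[2], lab, sum) / counts)
  cz <- (tapply((z + 0.5) * v[3], lab, sum) / counts)
  mi <- tapply(arr[keep], lab, mean)
  # first voxel under (z, y, x)-major scan order, for deterministic ids
  zyx_rank <- z * (ny * nx) + y * nx + x
  first_rank <- tapply(zyx_rank, lab, min)

  obj <- data.frame(x_um = as.numeric(cx), y_um = as.numeric(cy),
                    z_um = as.numeric(cz),
                    volume_um3 = counts * voxvol,
                    mean_intensity = as.numeric(mi),
                    voxel_count = counts,
                    stringsAsFactors = FALSE)
  obj$label <- seq_len(nrow(obj))
  obj <- obj[obj$volume_um3 >= config$min_object_volume_um3, , drop = FALSE]
  ord <- order(first_rank[obj$label])
  obj <- obj[ord, , drop = FALSE]
  if (nrow(obj)) {
    obj <- cbind(id = seq_len(nrow(obj)), obj)
    obj$channel <- volume$channel
  } else {
    obj <- empty
  }
  rownames(obj) <- NULL
  attr(obj, "threshold") <- thr
  attr(obj, "label_array") <- array(as.integer(labels), dim = dim(arr))
  obj
}

#' Classify detected objects into reporter-intensity classes
#'
#' Bins `mean_intensity` at the supplied ordered boundaries into
#' `below` / `Mid` / `Bright`. Bins are closed on the left of the upper bin:
#' an intensity exactly at a boundary takes the higher class.
#'
#' @param objects data.frame from [segment_objects()].
#' @param boundaries strictly increasing numeric length-2 eGFP thresholds
#'   (below/Mid and Mid/Bright).
#' @return `objects` with an added `class` column.
#' @export
classify_intensity <- function(objects, boundaries) {
  stopifnot(length(boundaries) == 2, diff(boundaries) > 0)
  cls <- ifelse(objects$mean_intensity >= boundaries[2], "Bright",
                ifelse(objects$mean_intensity >= boundaries[1], "Mid",
                       "below"))
  objects$class <- cls
  objects
}

#' Drop eGFP objects lacking lineage-label signal
#'
#' Interstitial autofluorescent blobs show up in the eGFP channel but carry
#' no tdTomato lineage label; when a tdTomato volume is supplied they are
#' removed by requiring the object-mean tdTomato intensity (over the
#' object's own voxels) to exceed `threshold`. When the label map from
#' [segment_objects()] is unavailable, the tdTomato intensity at the
#' centroid voxel is used as a fallback.
#'
#' @param objects data.frame from [segment_objects()] on the eGFP channel.
#' @param tdtomato an [image_volume()] of the tdTomato channel (same grid).
#' @param threshold minimum mean tdTomato intensity.
#' @return filtered objects (ids preserved).
#' @export
filter_by_cochannel <- function(objects, tdtomato, threshold = 0.1) {
  stopifnot(inherits(tdtomato, "image_volume"))
  if (!nrow(objects)) return(objects)
  labels <- attr(objects, "label_array")
  if (!is.null(labels) && identical(dim(labels), dim(tdtomato$data))) {
    keep <- labels > 0L
    signal_by_label <- tapply(tdtomato$data[keep], labels[keep], mean)
    signal <- as.numeric(signal_by_label[as.character(objects$label)])
  } else {
    v <- tdtomato$voxel_size_um
    d <- dim(tdtomato$data)
    ix <- pmin(pmax(ceiling(objects$x_um / v[1]), 1L), d[2])
    iy <- pmin(pmax(ceiling(objects$y_um / v[2]), 1L), d[1])
    iz <- pmin(pmax(ceiling(objects$z_um / v[3]), 1L), d[3])
    signal <- tdtomato$data[cbind(iy, ix, iz)]
  }
  out <- objects[signal > threshold, , drop = FALSE]
  attr(out, "threshold") <- attr(objects, "threshold")
  attr(out, "label_array") <- attr(objects, "label_array")
  out
}
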