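# Islet delineation and per-marker stain detection: the thresholding
# protocols applied to smoothed 3D stacks, plus the voxel-level morphology
# they rely on (connected components, cavity filling, distance transform,
# watershed). All physical parameters are micrometres, converted per axis
# by the grid's voxel size.

#' Label connected components of a 3D binary mask
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (default) or 6 neighbourhood.
#' @return integer array of the same shape; 0 = background, components
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  stopifnot(length(dim(mask)) == 3)
  out <- .cc_label3d(as.logical(mask), dim(mask), as.integer(connectivity))
  array(out, dim(mask))
}

#' Fill internal cavities of a 3D binary mask
#'
#' Background voxels not 6-connected to the array border are enclosed by
#' foreground and are switched on.
#' @param mask logical 3D array.
#' @return logical array with cavities filled.
#' @export
fill_holes3d <- function(mask) {
  stopifnot(length(dim(mask)) == 3)
  reached <- array(.cc_border_reach3d(as.logical(mask), dim(mask)), dim(mask))
  mask | !reached
}

#' Euclidean distance to background, anisotropic voxels
#'
#' Exact Euclidean distance (um) from each foreground voxel to the nearest
#' background voxel; voxels beyond the array faces count as background.
#' @param mask logical 3D array.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return numeric array of distances in um (0 on background).
#' @export
distance_to_background <- function(mask, voxel_size) {
  stopifnot(length(dim(mask)) == 3)
  sqrt(array(.edt_sq3d(as.logical(mask), dim(mask), as.numeric(voxel_size)),
             dim(mask)))
}

new_islet_labeling <- function(labels, voxel_size, params = list()) {
  counts <- tabulate(labels[labels > 0L], nbins = max(labels, 0L))
  structure(
    list(labels = labels, voxel_counts = counts,
         voxel_size = as.numeric(voxel_size), params = params),
    class = "islet_labeling"
  )
}

#' @export
print.islet_labeling <- function(x, ...) {
  cat(sprintf("<islet_labeling> K=%d islet(s), dims %s\n",
              length(x$voxel_counts),
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

relabel_by_volume <- function(labels, min_voxels) {
  counts <- tabulate(labels[labels > 0L], nbins = max(labels, 0L))
  keep <- which(counts >= min_voxels)
  if (length(keep) == 0L) {
    labels[] <- 0L
    return(labels)
  }
  keep <- keep[order(counts[keep], decreasing = TRUE)]
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  labels
}

#' Delineate individual islets in 3D
#'
#' Mirrors the surface protocol used on cleared-islet stacks: the pixel
#' values of all channels are summed, smoothed with a Gaussian blur, and
#' thresholded; internal cavities (e.g., unstained necrotic cores) are
#' filled so islet volume is the enclosed volume; connected components are
#' labelled, components smaller than `min_islet_volume` dropped, and the
#' remainder relabelled `1..K` in decreasing volume order. An empty result
#' is a valid `K = 0` labelling, not an error.
#'
#' @param grid a [voxel_grid()].
#' @param params segmentation parameter list as in
#'   [default_config()]`$segmentation`; `islet_threshold = NULL` uses Otsu
#'   on the smoothed sum.
#' @return an `islet_labeling`.
#' @export
delineate_islets <- function(grid, params = default_config()$segmentation) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.finite(params$sigma_islet) || params$sigma_islet < 0) {
    stop("sigma_islet must be finite and nonnegative")
  }
  d <- dim(grid$data)
  total <- array(0, d[2:4])
  for (cc in seq_len(d[1])) total <- total + grid$data[cc, , , ]
  sm <- gaussian_blur3d(total, params$sigma_islet, grid$voxel_size)
  thr <- params$islet_threshold
  if (is.null(thr)) thr <- otsu_threshold(sm)
  if (!is.finite(thr) || thr < 0) stop("islet threshold must be finite and nonnegative")
  mask <- sm > thr
  mask <- fill_holes3d(mask)
  labels <- label_components(mask, params$connectivity)
  min_vox <- params$min_islet_volume / voxel_volume(grid$voxel_size)
  labels <- relabel_by_volume(labels, min_vox)
  new_islet_labeling(labels, grid$voxel_size,
                     params = c(params, list(islet_threshold_used = thr)))
}

#' Split touching islets by distance-transform watershed
#'
#' Islets that coexist in one acquisition can merge into a single
#' thresholded component. For each label, the Euclidean distance map to
#' background is smoothed and its high plateaus (above `marker_fraction`
#' of the per-object maximum) become watershed markers; if two or more
#' markers emerge, the object is flooded from them and the split is
#' accepted only when every resulting part exceeds `min_islet_volume`,
#' otherwise the original label is kept. A no-op when no candidate splits
#' exist.
#'
#' @param labeling an `islet_labeling`.
#' @param grid the source [voxel_grid()] (carried for interface symmetry;
#'   the split is geometric).
#' @param params segmentation parameters (uses `marker_fraction`,
#'   `min_islet_volume`, `connectivity`).
#' @return an `islet_labeling`, relabelled `1..K` by decreasing volume.
#' @export
split_touching <- function(labeling, grid = NULL,
                           params = default_config()$segmentation) {
  stopifnot(inherits(labeling, "islet_labeling"))
  labels <- labeling$labels
  vs <- labeling$voxel_size
  min_vox <- params$min_islet_volume / voxel_volume(vs)
  smooth_um <- 2 * max(vs)
  out <- array(0L, dim(labels))
  next_lab <- 0L
  for (k in seq_along(labeling$voxel_counts)) {
    obj <- labels == k
    dist <- distance_to_background(obj, vs)
    dist_s <- gaussian_blur3d(dist, smooth_um, vs)
    dist_s[!obj] <- 0
    dmax <- max(dist_s)
    markers <- label_components(dist_s >= params$marker_fraction * dmax &
                                  obj, 26L)
    n_mark <- max(markers)
    parts <- NULL
    if (n_mark >= 2L) {
      w <- array(.watershed3d(as.numeric(dist), as.integer(markers),
                              as.logical(obj), dim(labels), 26L),
                 dim(labels))
      sizes <- tabulate(w[w > 0L], nbins = n_mark)
      if (all(sizes >= min_vox)) parts <- w
    }
    if (is.null(parts)) {
      out[obj] <- next_lab + 1L
      next_lab <- next_lab + 1L
    } else {
      pos <- parts > 0L
      out[pos] <- next_lab + parts[pos]
      next_lab <- next_lab + n_mark
    }
  }
  out <- relabel_by_volume(out, min_vox)
  new_islet_labeling(out, vs, params = labeling$params)
}

new_stain_mask <- function(mask, marker, params) {
  structure(list(mask = mask, marker = marker, params = params),
            class = "stain_mask")
}

#' Detect stained volume for one marker channel
#'
#' The channel is Gaussian-filtered (`sigma`); in
#' `"background_subtracted"` mode a copy blurred with the much larger
#' `background_sigma` is subtracted first (negatives clamped to zero) to
#' remove slowly varying background; the result is binarised at
#' `threshold`. No morphological post-processing is applied, matching the
#' protocol the quantification mirrors.
#'
#' @param grid a [voxel_grid()].
#' @param marker marker name present in the channel map.
#' @param params list with `sigma` (um), `threshold` (AU; `NULL` = Otsu on
#'   the filtered channel), `mode`, `background_sigma` (um). Defaults from
#'   [default_config()] for that marker.
#' @return a `stain_mask` carrying the binary mask and the parameters that
#'   produced it.
#' @export
detect_stain <- function(grid, marker, params = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!marker %in% grid$channel_map$marker) {
    stop("unknown marker: '", marker, "' not in channel map")
  }
  if (is.null(params)) params <- default_config()$detection[[marker]]
  mode <- if (!is.null(params$mode)) params$mode else "absolute"
  v <- get_channel(grid, marker)
  f <- gaussian_blur3d(v, params$sigma, grid$voxel_size)
  if (mode == "background_subtracted") {
    if (params$background_sigma <= params$sigma) {
      stop("background_sigma must exceed sigma in background_subtracted mode")
    }
    bg <- gaussian_blur3d(v, params$background_sigma, grid$voxel_size)
    f <- pmax(f - bg, 0)
  } else if (mode != "absolute") {
    stop("unknown detection mode: ", mode)
  }
  thr <- params$threshold
  if (is.null(thr)) thr <- otsu_threshold(f)
  if (!is.finite(thr) || thr < 0) stop("threshold must be finite and nonnegative")
  new_stain_mask(f > thr, marker,
                 list(sigma = params$sigma, mode = mode, threshold = thr,
                      background_sigma = params$background_sigma))
}

#' Recompute a stain mask from its stored parameters
#'
#' Verifies the `stain_mask` invariant that the recorded parameters
#' reproduce the mask from the source grid.
#' @param stain a `stain_mask`.
#' @param grid the source [voxel_grid()].
#' @return `TRUE` if the recomputed mask is voxel-identical.
#' @export
verify_stain_mask <- function(stain, grid) {
  redo <- detect_stain(grid, stain$marker, stain$params)
  identical(redo$mask, stain$mask)
}
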