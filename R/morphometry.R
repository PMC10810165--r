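# Per-islet quantities: enclosed volume, stained volume fraction, laminin
# node counts, E-cadherin hole fraction, raw mean intensity, CA9 fraction
# and the 2D live/dead viability ratio.

islet_voxels <- function(labeling, islet_id) {
  stopifnot(inherits(labeling, "islet_labeling"))
  if (!is.numeric(islet_id) || islet_id < 1 ||
      islet_id > length(labeling$voxel_counts)) {
    stop("unknown islet id: ", islet_id)
  }
  labeling$labels == islet_id
}

#' Physical volume of one islet
#'
#' Voxel count times voxel volume, in cubic micrometres.
#' @param labeling an `islet_labeling`.
#' @param islet_id label of the islet.
#' @return volume in um^3.
#' @export
islet_volume <- function(labeling, islet_id) {
  sum(islet_voxels(labeling, islet_id)) * voxel_volume(labeling$voxel_size)
}

#' Stained volume fraction of an islet
#'
#' Percentage of the islet's voxels covered by the stain mask; stain
#' voxels outside the islet are ignored. This is the primary volumetric
#' readout (percentage of stained volume over islet volume).
#'
#' @param stain a `stain_mask` (or logical 3D array).
#' @param labeling an `islet_labeling` of the same shape.
#' @param islet_id islet label.
#' @return percentage in `[0, 100]`.
#' @export
volume_fraction <- function(stain, labeling, islet_id) {
  m <- if (inherits(stain, "stain_mask")) stain$mask else stain
  iv <- islet_voxels(labeling, islet_id)
  if (!identical(dim(m), dim(iv))) stop("stain and labeling shapes differ")
  n_islet <- sum(iv)
  if (n_islet == 0) stop("empty islet")
  100 * sum(m & iv) / n_islet
}

#' CA9-positive volume fraction
#'
#' Hypoxia-marker positivity expressed as a percentage of total islet
#' volume; a named delegate of [volume_fraction()].
#' @inheritParams volume_fraction
#' @export
ca9_fraction <- function(stain, labeling, islet_id) {
  volume_fraction(stain, labeling, islet_id)
}

#' Count laminin nodes inside an islet
#'
#' 26-connected components of the stain within the islet; components
#' smaller than `min_node_volume` are discarded as speckle. Zero nodes is
#' a valid result.
#'
#' @param stain the laminin `stain_mask` (or logical array).
#' @param labeling an `islet_labeling`.
#' @param islet_id islet label.
#' @param min_node_volume minimum node volume in um^3.
#' @return list with `node_count` and sorted `node_volumes` (um^3).
#' @export
count_nodes <- function(stain, labeling, islet_id,
                        min_node_volume = default_config()$morphometry$min_node_volume) {
  m <- if (inherits(stain, "stain_mask")) stain$mask else stain
  iv <- islet_voxels(labeling, islet_id)
  if (!identical(dim(m), dim(iv))) stop("stain and labeling shapes differ")
  comp <- label_components(m & iv, 26L)
  vv <- voxel_volume(labeling$voxel_size)
  sizes <- tabulate(comp[comp > 0L], nbins = max(comp, 0L)) * vv
  sizes <- sizes[sizes >= min_node_volume]
  list(node_count = length(sizes), node_volumes = sort(sizes))
}

#' Quantify enclosed unstained holes in the E-cadherin signal
#'
#' Within the islet, unstained voxels are labelled (26-connectivity);
#' components touching the islet's boundary shell (voxels within
#' `boundary_margin` of the islet surface) are open indentations, not
#' holes, and are excluded, as are components below `min_hole_volume`.
#' The hole fraction is the retained hole volume as a percentage of islet
#' volume. A fully stained islet yields 0.
#'
#' @param ecad the E-cadherin `stain_mask` (or logical array).
#' @param labeling an `islet_labeling`.
#' @param islet_id islet label.
#' @param min_hole_volume minimum hole volume, um^3.
#' @param boundary_margin boundary shell depth, um.
#' @return hole fraction in percent.
#' @export
quantify_holes <- function(ecad, labeling, islet_id,
                           min_hole_volume = default_config()$morphometry$min_hole_volume,
                           boundary_margin = default_config()$morphometry$boundary_margin) {
  m <- if (inherits(ecad, "stain_mask")) ecad$mask else ecad
  iv <- islet_voxels(labeling, islet_id)
  if (!identical(dim(m), dim(iv))) stop("stain and labeling shapes differ")
  n_islet <- sum(iv)
  if (n_islet == 0) stop("empty islet")
  unstained <- iv & !m
  if (!any(unstained)) return(0)
  shell <- iv & (distance_to_background(iv, labeling$voxel_size) <=
                   boundary_margin)
  comp <- label_components(unstained, 26L)
  ncomp <- max(comp)
  if (ncomp == 0L) return(0)
  touches <- unique(comp[shell & comp > 0L])
  sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
  vv <- voxel_volume(labeling$voxel_size)
  keep <- setdiff(which(sizes * vv >= min_hole_volume), touches)
  100 * sum(sizes[keep]) / n_islet
}

#' Mean raw intensity of a marker over an islet
#'
#' Arithmetic mean of the unfiltered channel over the islet's voxels, in
#' the acquisition's arbitrary units.
#' @param grid a [voxel_grid()].
#' @param marker marker name.
#' @param labeling an `islet_labeling`.
#' @param islet_id islet label.
#' @return mean intensity (AU).
#' @export
mean_intensity <- function(grid, marker, labeling, islet_id) {
  v <- get_channel(grid, marker)
  iv <- islet_voxels(labeling, islet_id)
  if (!identical(dim(v), dim(iv))) stop("grid and labeling shapes differ")
  if (!any(iv)) stop("empty islet")
  mean(v[iv])
}

#' Live/dead viability ratio from a 2-channel 2D image
#'
#' Each channel (green = fluorescein/viable, red = propidium
#' iodide/dead) is thresholded and viability is the green area over the
#' area of the combined channels, `|G| / |G union R|`. When nothing is
#' stained the ratio is undefined and the result carries status
#' `"no_stained_area"` with `viability = NA` rather than a number.
#'
#' @param image array `(2, y, x)` (green, red) or the list returned by
#'   [generate_viability_image()].
#' @param green_threshold,red_threshold intensity thresholds (AU);
#'   `NULL` = per-channel Otsu.
#' @param pixel_size optional um per pixel; when given, absolute areas in
#'   um^2 are reported too.
#' @return list: `viability`, `status` (`"ok"` or `"no_stained_area"`),
#'   `green_area_px`, `red_area_px`, `union_px`, thresholds used, and
#'   `*_area_um2` when `pixel_size` is known.
#' @export
viability_ratio <- function(image, green_threshold = NULL,
                            red_threshold = NULL, pixel_size = NULL) {
  if (is.list(image) && !is.null(image$image)) {
    if (is.null(pixel_size)) pixel_size <- image$pixel_size
    image <- image$image
  }
  if (length(dim(image)) != 3 || dim(image)[1] != 2) {
    stop("expected a 2-channel (green, red) 2D image")
  }
  g <- image[1, , ]; r <- image[2, , ]
  if (is.null(green_threshold)) green_threshold <- otsu_threshold(g)
  if (is.null(red_threshold)) red_threshold <- otsu_threshold(r)
  gm <- g > green_threshold
  rm_ <- r > red_threshold
  union_px <- sum(gm | rm_)
  out <- list(
    viability = NA_real_, status = "no_stained_area",
    green_area_px = sum(gm), red_area_px = sum(rm_), union_px = union_px,
    green_threshold = green_threshold, red_threshold = red_threshold
  )
  if (union_px > 0) {
    out$viability <- sum(gm) / union_px
    out$status <- "ok"
  }
  if (!is.null(pixel_size)) {
    out$green_area_um2 <- out$green_area_px * pixel_size^2
    out$red_area_um2 <- out$red_area_px * pixel_size^2
  }
  out
}

#' Full morphometry record for one islet
#'
#' Convenience wrapper assembling the tidy one-row-per-marker records the
#' pipeline reports: islet volume, per-marker volume fraction and mean
#' intensity, node count/volumes for laminin, hole fraction for
#' E-cadherin.
#'
#' @param grid a [voxel_grid()].
#' @param labeling an `islet_labeling`.
#' @param islet_id islet label.
#' @param stains named list of `stain_mask` objects (one per marker to
#'   quantify).
#' @param morpho morphometry parameter list (see [default_config()]).
#' @param condition optional condition label.
#' @return data frame, one row per marker.
#' @export
measure_islet <- function(grid, labeling, islet_id, stains,
                          morpho = default_config()$morphometry,
                          condition = NA_character_) {
  vol <- islet_volume(labeling, islet_id)
  rows <- lapply(names(stains), function(mk) {
    st <- stains[[mk]]
    vf <- volume_fraction(st, labeling, islet_id)
    nc <- NA_integer_; nv <- NA_real_; hf <- NA_real_
    if (mk == "laminin") {
      nd <- count_nodes(st, labeling, islet_id, morpho$min_node_volume)
      nc <- nd$node_count
      nv <- sum(nd$node_volumes)
    }
    if (mk == "ecadherin") {
      hf <- quantify_holes(st, labeling, islet_id, morpho$min_hole_volume,
                           morpho$boundary_margin)
    }
    data.frame(
      islet_id = islet_id, condition = condition, marker = mk,
      islet_volume_um3 = vol, volume_fraction_pct = vf,
      node_count = nc, node_volume_total_um3 = nv,
      hole_fraction_pct = hf,
      mean_intensity_au = mean_intensity(grid, mk, labeling, islet_id),
      viability = NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
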