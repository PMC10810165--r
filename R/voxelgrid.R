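#' Recognised marker names
#'
#' The fluorescence targets the pipeline knows how to quantify: a nuclear
#' counterstain, the two islet hormones, the hypoxia marker CA9, three
#' extracellular-matrix proteins, the adhesion protein E-cadherin, and the
#' two live/dead viability channels (fluorescein green, propidium iodide
#' red).
#' @export
MARKER_NAMES <- c(
  "nuclei", "insulin", "glucagon", "ca9",
  "collagen4", "fibronectin", "laminin", "ecadherin",
  "viability_green", "viability_red"
)

#' Build a channel map
#'
#' Associates each channel of an acquisition with a marker name and a
#' detection mode. Channels are numbered contiguously starting at 1
#' (R convention). A 3D stack must carry exactly one nuclei channel;
#' 2D viability images carry `viability_green` / `viability_red` instead.
#'
#' @param markers character vector of marker names, one per channel, in
#'   channel order; each must be one of [MARKER_NAMES].
#' @param modes detection mode per channel, `"absolute"` or
#'   `"background_subtracted"`; recycled if length 1.
#' @return a `channel_map`: a data frame with columns `channel`, `marker`,
#'   `mode`.
#' @export
channel_map <- function(markers, modes = "absolute") {
  if (length(markers) < 1) stop("channel map needs at least one channel")
  bad <- setdiff(markers, MARKER_NAMES)
  if (length(bad) > 0) {
    stop("unknown marker name(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(markers)) stop("duplicated marker in channel map")
  modes <- rep_len(modes, length(markers))
  if (!all(modes %in% c("absolute", "background_subtracted"))) {
    stop("detection mode must be 'absolute' or 'background_subtracted'")
  }
  cm <- data.frame(
    channel = seq_along(markers),
    marker = markers,
    mode = modes,
    stringsAsFactors = FALSE
  )
  class(cm) <- c("channel_map", "data.frame")
  cm
}

validate_channel_map <- function(cm, n_channels = NULL, require_nuclei = FALSE) {
  if (!inherits(cm, "channel_map")) stop("not a channel_map")
  if (!identical(cm$channel, seq_len(nrow(cm)))) {
    stop("channel indices must be unique and contiguous from 1")
  }
  if (!is.null(n_channels) && nrow(cm) != n_channels) {
    stop("channel map has ", nrow(cm), " entries but grid has ",
         n_channels, " channels")
  }
  if (require_nuclei && sum(cm$marker == "nuclei") != 1) {
    stop("a 3D stack requires exactly one nuclei channel")
  }
  invisible(cm)
}

#' Construct a multi-channel 3D voxel grid
#'
#' The pipeline's raw input: a 4D nonnegative-integer intensity array in
#' `(channel, z, y, x)` order together with the physical voxel size and a
#' channel map. Anisotropic voxels (`dz != dx`) are permitted — light-sheet
#' stacks typically have coarser axial sampling.
#'
#' @param data 4D numeric array, dimensions `(channel, z, y, x)`, values in
#'   `[0, 2^bit_depth - 1]`.
#' @param voxel_size numeric length-3, `(dz, dy, dx)` in micrometres, all
#'   strictly positive.
#' @param channel_map a [channel_map()] with one entry per channel.
#' @param bit_depth intensity bit depth, 8 or 16 (default). 8-bit data is
#'   accepted and promoted without rescaling.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size, channel_map, bit_depth = 16L) {
  if (length(dim(data)) != 4) stop("data must be a 4D (channel, z, y, x) array")
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (length(voxel_size) != 3 || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel_size must be three strictly positive values (dz, dy, dx)")
  }
  validate_channel_map(channel_map, n_channels = dim(data)[1])
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 2^bit_depth - 1) {
    stop("intensities outside [0, 2^bit_depth - 1]")
  }
  structure(
    list(
      data = data,
      voxel_size = as.numeric(voxel_size),
      channel_map = channel_map,
      bit_depth = as.integer(bit_depth)
    ),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid> %d channel(s) x %d x %d x %d (z,y,x), voxel %.3g x %.3g x %.3g um, %d-bit\n",
    d[1], d[2], d[3], d[4],
    x$voxel_size[1], x$voxel_size[2], x$voxel_size[3], x$bit_depth
  ))
  cat("channels:", paste(x$channel_map$marker, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one marker channel as a 3D array
#'
#' @param grid a [voxel_grid()].
#' @param marker marker name present in the grid's channel map.
#' @return 3D array `(z, y, x)`.
#' @export
get_channel <- function(grid, marker) {
  stopifnot(inherits(grid, "voxel_grid"))
  i <- match(marker, grid$channel_map$marker)
  if (is.na(i)) stop("marker '", marker, "' not present in channel map")
  d <- dim(grid$data)
  array(grid$data[i, , , ], dim = d[2:4])
}

#' Physical volume of one voxel in cubic micrometres
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @export
voxel_volume <- function(voxel_size) prod(voxel_size)
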