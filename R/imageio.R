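#' Write a voxel grid to a multi-page TIFF
#'
#' Pages are written plane-major by default (channel 1 plane 1, channel 2
#' plane 1, ...), the common export order of acquisition software;
#' channel-major (all planes of channel 1, then channel 2, ...) is also
#' supported. Intensities are stored losslessly at the grid's bit depth.
#' Voxel size, bit depth, interleave and channel map are recorded in a JSON
#' sidecar `<path>.json`, since baseline TIFF has no standard 3D voxel-size
#' tag.
#'
#' @param grid a [voxel_grid()].
#' @param path output file path (`.tif`).
#' @param interleave `"plane"` (default) or `"channel"` page order.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path, interleave = c("plane", "channel")) {
  stopifnot(inherits(grid, "voxel_grid"))
  interleave <- match.arg(interleave)
  d <- dim(grid$data)
  nc <- d[1]; nz <- d[2]
  scale <- 2^grid$bit_depth - 1
  pages <- vector("list", nc * nz)
  k <- 1L
  if (interleave == "plane") {
    for (z in seq_len(nz)) for (cc in seq_len(nc)) {
      pages[[k]] <- matrix(grid$data[cc, z, , ], d[3], d[4]) / scale
      k <- k + 1L
    }
  } else {
    for (cc in seq_len(nc)) for (z in seq_len(nz)) {
      pages[[k]] <- matrix(grid$data[cc, z, , ], d[3], d[4]) / scale
      k <- k + 1L
    }
  }
  ok <- tiff::writeTIFF(pages, path, bits.per.sample = grid$bit_depth,
                        compression = "LZW")
  if (ok != length(pages)) stop("failed to write all pages to ", path)
  meta <- list(
    voxel_size_um = grid$voxel_size,
    bit_depth = grid$bit_depth,
    interleave = interleave,
    n_channels = nc,
    markers = grid$channel_map$marker,
    modes = grid$channel_map$mode
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-channel 3D stack from a multi-page TIFF
#'
#' The page count must be divisible by the number of channels in
#' `channel_map`. Voxel size and page interleave are taken from the JSON
#' sidecar written by [write_stack()] when present; otherwise `voxel_size`
#' must be supplied. Intensities are read as stored — no rescaling or
#' normalisation is applied.
#'
#' @param path TIFF file path.
#' @param channel_map a [channel_map()] describing the channels.
#' @param voxel_size optional `(dz, dy, dx)` in micrometres, overriding (or
#'   supplying, when absent) the sidecar metadata.
#' @param interleave `"auto"` (sidecar, defaulting to plane-major),
#'   `"plane"` or `"channel"`.
#' @param bit_depth optional override of the stored bit depth.
#' @return a [voxel_grid()].
#' @export
read_stack <- function(path, channel_map, voxel_size = NULL,
                       interleave = c("auto", "plane", "channel"),
                       bit_depth = NULL) {
  interleave <- match.arg(interleave)
  if (!file.exists(path)) stop("file not found: ", path)
  validate_channel_map(channel_map)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  if (is.null(voxel_size)) voxel_size <- meta$voxel_size_um
  if (is.null(voxel_size)) {
    stop("missing voxel size: no sidecar metadata for ", path,
         " and no voxel_size override given")
  }
  if (interleave == "auto") {
    interleave <- if (!is.null(meta$interleave)) meta$interleave else "plane"
  }
  if (is.null(bit_depth)) {
    bit_depth <- if (!is.null(meta$bit_depth)) meta$bit_depth else 16L
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  nc <- nrow(channel_map)
  if (length(pages) %% nc != 0) {
    stop("page/channel mismatch: ", length(pages),
         " pages not divisible by ", nc, " channels")
  }
  nz <- length(pages) %/% nc
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, dim = c(nc, nz, ny, nx))
  k <- 1L
  if (interleave == "plane") {
    for (z in seq_len(nz)) for (cc in seq_len(nc)) {
      data[cc, z, , ] <- pages[[k]]
      k <- k + 1L
    }
  } else {
    for (cc in seq_len(nc)) for (z in seq_len(nz)) {
      data[cc, z, , ] <- pages[[k]]
      k <- k + 1L
    }
  }
  voxel_grid(data, voxel_size, channel_map, bit_depth = as.integer(bit_depth))
}

#' Default pipeline configuration
#'
#' All length parameters are physical (micrometres); they are converted to
#' voxels internally using each grid's voxel size. Detection thresholds
#' left `NULL` are initialised per channel by Otsu's method at run time.
#'
#' @return a `pipeline_config` list with components:
#' \describe{
#'   \item{segmentation}{`sigma_islet` (um, smoothing of the summed
#'     channels), `islet_threshold` (AU, `NULL` = Otsu),
#'     `min_islet_volume` (um^3), `connectivity` (6 or 26),
#'     `split_touching` (logical), `marker_fraction` (watershed marker
#'     height as fraction of the per-object distance maximum).}
#'   \item{detection}{named per-marker lists of `sigma` (um), `threshold`
#'     (AU or `NULL`), `mode`, `background_sigma` (um).}
#'   \item{morphometry}{`min_node_volume` (um^3), `min_hole_volume`
#'     (um^3), `boundary_margin` (um).}
#'   \item{stats}{`alpha`, `transform` (`"auto"`, `"none"` or `"log"`),
#'     `var_equal` (pooled-variance t test), `holm` (multiple-testing
#'     correction, off by default).}
#'   \item{exclude_islets}{character vector of `"<stack_id>:<label>"`.}
#'   \item{seed}{integer RNG seed.}
#' }
#' @export
default_config <- function() {
  det <- function(sigma = 1, threshold = NULL, mode = "absolute",
                  background_sigma = 20) {
    list(sigma = sigma, threshold = threshold, mode = mode,
         background_sigma = background_sigma)
  }
  cfg <- list(
    segmentation = list(
      sigma_islet = 3,
      islet_threshold = NULL,
      min_islet_volume = 4 / 3 * pi * 20^3,  # reject debris below ~ 20 um radius
      connectivity = 26L,
      split_touching = TRUE,
      marker_fraction = 0.6
    ),
    detection = list(
      nuclei = det(), insulin = det(), glucagon = det(), ca9 = det(),
      collagen4 = det(), fibronectin = det(), laminin = det(),
      ecadherin = det(),
      viability_green = det(), viability_red = det()
    ),
    morphometry = list(
      min_node_volume = 4 / 3 * pi * 3^3,   # a 3 um-radius sphere
      min_hole_volume = 4 / 3 * pi * 4^3,
      boundary_margin = 3
    ),
    stats = list(alpha = 0.05, transform = "auto", var_equal = FALSE,
                 holm = FALSE),
    exclude_islets = character(0),
    seed = 1L
  )
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  seg <- cfg$segmentation
  for (f in c("sigma_islet", "min_islet_volume")) {
    v <- seg[[f]]
    if (!is.numeric(v) || !is.finite(v) || v < 0) {
      stop("invalid config: segmentation.", f, " must be a nonnegative number")
    }
  }
  if (!is.null(seg$islet_threshold) &&
      (!is.finite(seg$islet_threshold) || seg$islet_threshold < 0)) {
    stop("invalid config: segmentation.islet_threshold must be nonnegative")
  }
  if (!seg$connectivity %in% c(6L, 26L)) {
    stop("invalid config: segmentation.connectivity must be 6 or 26")
  }
  bad <- setdiff(names(cfg$detection), MARKER_NAMES)
  if (length(bad) > 0) stop("unknown marker name in config: ",
                            paste(bad, collapse = ", "))
  for (m in names(cfg$detection)) {
    dd <- cfg$detection[[m]]
    if (!is.finite(dd$sigma) || dd$sigma < 0) {
      stop("invalid config: detection.", m, ".sigma must be nonnegative")
    }
    if (!dd$mode %in% c("absolute", "background_subtracted")) {
      stop("invalid config: detection.", m, ".mode unknown")
    }
    if (!is.finite(dd$background_sigma) || dd$background_sigma <= 0) {
      stop("invalid config: detection.", m, ".background_sigma must be positive")
    }
  }
  mo <- cfg$morphometry
  for (f in c("min_node_volume", "min_hole_volume", "boundary_margin")) {
    if (!is.finite(mo[[f]]) || mo[[f]] < 0) {
      stop("invalid config: morphometry.", f, " must be nonnegative")
    }
  }
  a <- cfg$stats$alpha
  if (!is.finite(a) || a <= 0 || a >= 1) {
    stop("invalid config: stats.alpha must lie in (0, 1)")
  }
  if (!cfg$stats$transform %in% c("auto", "none", "log")) {
    stop("invalid config: stats.transform must be auto, none or log")
  }
  invisible(cfg)
}

# recursively overlay user values on defaults
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from a YAML file
#'
#' Unspecified fields take the documented defaults of [default_config()];
#' the fully resolved configuration is validated and should be echoed into
#' every report for provenance (as [run_pipeline()] does).
#'
#' @param path YAML file path, or `NULL` for an all-default configuration.
#' @return a validated `pipeline_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) {
      if (!is.list(user)) stop("malformed config file: ", path)
      cfg2 <- merge_config(unclass(cfg), user)
      class(cfg2) <- "pipeline_config"
      cfg <- cfg2
    }
  }
  validate_config(cfg)
  cfg
}

#' Serialise the resolved configuration beside a run's outputs
#' @param cfg a `pipeline_config`.
#' @param path output YAML path.
#' @keywords internal
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
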