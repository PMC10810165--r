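# Seeded synthetic islet phantoms with full ground truth.
#
# The generator emulates the morphologies seen in cleared, light-sheet
# imaged islets cultured under normoxia (day 1 / day 5) or 1% O2 hypoxia
# (day 5): a roughly spherical islet (diameter 50-250 um), Hoechst-like
# nuclear blobs, membrane-associated E-cadherin with a central signal
# void ("hole") under stress, laminin as small scattered nodes in
# normoxia versus one or two large central condensations in hypoxia,
# collagen-4 vessel-like tubes, a fibronectin intercellular mesh, and a
# CA9-positive rim around the necrotic core. Structures are rasterised as
# geometric primitives at stated intensities, blurred with an anisotropic
# PSF (sigma_z > sigma_xy, the light-sheet axial-resolution penalty), and
# corrupted with signal-dependent Poisson noise plus additive Gaussian
# read noise. Ground truth (pre-blur, pre-noise masks and parameters) is
# returned with every phantom so downstream recovery is testable.

# Fixed substream offsets: reseeding per structure means adding or
# removing one structure never reshuffles the others.
.SUBSTREAM <- c(shape = 11L, nuclei = 23L, collagen4 = 37L,
                fibronectin = 41L, laminin = 53L, ca9 = 67L,
                noise = 79L, viability = 89L)

mix_seed <- function(seed, index = 0L, offset = 0L) {
  ((as.numeric(seed) %% 2147483647) * 69069 +
     as.numeric(index) * 2654435 + as.numeric(offset) * 97) %% 2147483647
}

reseed <- function(spec_seed, stream) {
  set.seed(as.integer(mix_seed(spec_seed, 0L, .SUBSTREAM[[stream]])))
}

#' Specify a synthetic islet phantom
#'
#' All lengths are micrometres, intensities arbitrary units (AU) on a
#' 16-bit scale. Defaults describe a normoxia-like islet on a 128^3
#' canvas at 1.5 um isotropic sampling.
#'
#' @param canvas integer length-3 voxel dimensions `(nz, ny, nx)`.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param islet_radius islet radius in um (diameter 50-250 um range).
#' @param shape_perturbation ellipsoidal perturbation amplitude as a
#'   fraction of the radius (0 = perfect sphere).
#' @param nuclei list: `count`, `radius` (um).
#' @param collagen4 list: `n_tubes`, `radius` (um) of vessel-like tubes.
#' @param fibronectin list: `mesh_thickness` (um), `n_seeds` of the
#'   Voronoi partition whose boundary network forms the mesh.
#' @param laminin list: `node_count`, `node_radius` (um),
#'   `well_separated` (enforce pairwise center distance
#'   >= 2 * (node_radius + blur sigma_xy)).
#' @param scar central condensed-scar radius (um); 0 = none. Drives the
#'   nuclei exclusion zone ("scarce nuclei") and the CA9 rim.
#' @param ecadherin list: `hole_radius` (um) of the central signal void.
#' @param ca9 list: `rim_thickness` (um) around the scar; `blob_count`,
#'   `blob_radius` (um) for sporadic positivity under normoxia.
#' @param intensity named list of per-structure intensities (AU) plus
#'   `baseline` (in-islet cytoplasmic level) and `outside`.
#' @param noise list: `gaussian_sd` (AU, read noise), `poisson_scale`
#'   (AU per photon; 0 disables shot noise).
#' @param blur list: `sigma_xy`, `sigma_z` PSF sigmas in um.
#' @param seed integer seed; identical spec + seed gives bit-identical
#'   phantoms.
#' @return a `phantom_spec`.
#' @export
phantom_spec <- function(canvas = c(128L, 128L, 128L),
                         voxel_size = c(1.5, 1.5, 1.5),
                         islet_radius = 60,
                         shape_perturbation = 0.08,
                         nuclei = list(count = 120L, radius = 3),
                         collagen4 = list(n_tubes = 3L, radius = 3),
                         fibronectin = list(mesh_thickness = 3, n_seeds = 12L),
                         laminin = list(node_count = 7L, node_radius = 5,
                                        well_separated = TRUE),
                         scar = 0,
                         ecadherin = list(hole_radius = 0),
                         ca9 = list(rim_thickness = 6, blob_count = 0L,
                                    blob_radius = 3.5),
                         intensity = list(nuclei = 6000, insulin = 4000,
                                          glucagon = 4000, ca9 = 5000,
                                          collagen4 = 3000, fibronectin = 3000,
                                          laminin = 4000, ecadherin = 8000,
                                          baseline = 300, outside = 50),
                         noise = list(gaussian_sd = 120, poisson_scale = 2),
                         blur = list(sigma_xy = 1.5, sigma_z = 3),
                         seed = 1L) {
  spec <- list(canvas = as.integer(canvas), voxel_size = as.numeric(voxel_size),
               islet_radius = islet_radius,
               shape_perturbation = shape_perturbation,
               nuclei = nuclei, collagen4 = collagen4,
               fibronectin = fibronectin, laminin = laminin, scar = scar,
               ecadherin = ecadherin, ca9 = ca9, intensity = intensity,
               noise = noise, blur = blur, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  r <- spec$islet_radius
  if (!is.finite(r) || r <= 0) stop("islet_radius must be positive")
  if (spec$scar > 0 && spec$scar + spec$ca9$rim_thickness >= r) {
    stop("scar radius + ca9 rim thickness must stay below the islet radius")
  }
  if (spec$ecadherin$hole_radius >= r) {
    stop("hole radius must stay below the islet radius")
  }
  if (spec$shape_perturbation < 0 || spec$shape_perturbation >= 0.5) {
    stop("shape_perturbation must lie in [0, 0.5)")
  }
  extent <- spec$canvas * spec$voxel_size
  if (2 * r * (1 + spec$shape_perturbation) > min(extent)) {
    stop("islet does not fit the canvas")
  }
  invisible(spec)
}

# voxel-center physical coordinates, canvas centred at 0
canvas_coords <- function(canvas, voxel_size) {
  lapply(1:3, function(i) {
    (seq_len(canvas[i]) - (canvas[i] + 1) / 2) * voxel_size[i]
  })
}

# A[z,y,x] = f_z[z] + f_y[y] + f_x[x], built by broadcasting
outer_sum3 <- function(fz, fy, fx) {
  nz <- length(fz); ny <- length(fy); nx <- length(fx)
  array(fz, c(nz, ny, nx)) +
    array(rep(fy, each = nz), c(nz, ny, nx)) +
    array(rep(fx, each = nz * ny), c(nz, ny, nx))
}

rasterize_ellipsoid <- function(canvas, coords, center, semi_axes) {
  outer_sum3(((coords[[1]] - center[1]) / semi_axes[1])^2,
             ((coords[[2]] - center[2]) / semi_axes[2])^2,
             ((coords[[3]] - center[3]) / semi_axes[3])^2) <= 1
}

# add a sphere to a mask, touching only its bounding box
add_sphere <- function(mask, coords, center, r) {
  ii <- lapply(1:3, function(a) {
    which(abs(coords[[a]] - center[a]) <= r + 1e-9)
  })
  if (any(lengths(ii) == 0)) return(mask)
  d2 <- outer_sum3((coords[[1]][ii[[1]]] - center[1])^2,
                   (coords[[2]][ii[[2]]] - center[2])^2,
                   (coords[[3]][ii[[3]]] - center[3])^2)
  sub <- mask[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
  mask[ii[[1]], ii[[2]], ii[[3]]] <- sub | array(d2 <= r^2, dim(d2))
  mask
}

add_tube <- function(mask, coords, p1, p2, r) {
  lo <- pmin(p1, p2) - r; hi <- pmax(p1, p2) + r
  ii <- lapply(1:3, function(a) {
    which(coords[[a]] >= lo[a] & coords[[a]] <= hi[a])
  })
  if (any(lengths(ii) == 0)) return(mask)
  g <- expand.grid(z = coords[[1]][ii[[1]]], y = coords[[2]][ii[[2]]],
                   x = coords[[3]][ii[[3]]])
  P <- as.matrix(g)
  v <- p2 - p1
  vv <- sum(v^2)
  t <- ((P[, 1] - p1[1]) * v[1] + (P[, 2] - p1[2]) * v[2] +
          (P[, 3] - p1[3]) * v[3]) / vv
  t <- pmin(pmax(t, 0), 1)
  d2 <- (P[, 1] - (p1[1] + t * v[1]))^2 + (P[, 2] - (p1[2] + t * v[2]))^2 +
    (P[, 3] - (p1[3] + t * v[3]))^2
  sub <- mask[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
  dims <- vapply(ii, length, 1L)
  mask[ii[[1]], ii[[2]], ii[[3]]] <- sub | array(d2 <= r^2, dims)
  mask
}

# Rejection-sample k points in the ellipsoid shrunk by `margin`, pairwise
# at least `min_sep` apart and at least `min_center_dist` from the origin.
# Mutual-separation constraints are handled by full-configuration
# restarts (sequential placement alone dead-ends when an early point
# lands centrally); the total attempt budget is bounded.
place_points <- function(k, semi_axes, margin, min_sep = 0,
                         min_center_dist = 0, max_attempts = 40000L,
                         constraint_name = "separation", sep_sigma = NULL,
                         sep_radius = 0) {
  if (k == 0L) return(matrix(numeric(0), 0, 3))
  ax <- pmax(semi_axes - margin, 1e-6)
  attempts <- 0L
  tries_per_point <- 200L
  while (attempts < max_attempts) {
    pts <- matrix(NA_real_, k, 3)
    done <- TRUE
    for (i in seq_len(k)) {
      placed <- FALSE
      for (t in seq_len(tries_per_point)) {
        attempts <- attempts + 1L
        u <- runif(3, -1, 1)
        if (sum(u^2) > 1) next
        p <- u * ax
        if (min_center_dist > 0 && sqrt(sum(p^2)) < min_center_dist) next
        if (i > 1 && (min_sep > 0 || !is.null(sep_sigma))) {
          dv <- pts[seq_len(i - 1), , drop = FALSE] -
            matrix(p, i - 1, 3, byrow = TRUE)
          dd <- sqrt(rowSums(dv^2))
          if (any(dd < min_sep)) next
          if (!is.null(sep_sigma)) {
            # direction-dependent PSF width: pairs displaced axially see
            # the broader sigma_z, so the bound follows the displacement
            seff <- sqrt((dv[, 1]^2 * sep_sigma[1]^2 +
                            (dv[, 2]^2 + dv[, 3]^2) * sep_sigma[2]^2)) /
              pmax(dd, 1e-12)
            if (any(dd < 2 * (sep_radius + seff))) next
          }
        }
        pts[i, ] <- p
        placed <- TRUE
        break
      }
      if (!placed) { done <- FALSE; break }
    }
    if (done) return(pts)
  }
  stop("could not place ", k, " structure(s) under the ",
       constraint_name, " constraint")
}

render_channel <- function(struct_mask, islet, intensity, baseline, outside,
                           blur, noise, voxel_size, bit_depth = 16L) {
  img <- array(outside, dim(islet))
  img[islet] <- baseline
  img[struct_mask] <- intensity
  sig <- c(blur$sigma_z, blur$sigma_xy, blur$sigma_xy)
  if (any(sig > 0)) img <- gaussian_blur3d(img, sig, voxel_size)
  n <- length(img)
  if (noise$poisson_scale > 0) {
    img <- array(rpois(n, pmax(img, 0) / noise$poisson_scale) *
                   noise$poisson_scale, dim(img))
  }
  if (noise$gaussian_sd > 0) {
    img <- img + array(rnorm(n, 0, noise$gaussian_sd), dim(img))
  }
  round(pmin(pmax(img, 0), 2^bit_depth - 1))
}

#' Generate one synthetic islet stack with ground truth
#'
#' Builds a `(1 + length(markers))`-channel stack (nuclei first) by
#' rasterising geometric structures at stated intensities, applying the
#' anisotropic PSF blur, and adding Poisson-Gaussian noise. The returned
#' truth carries the pre-blur, pre-noise masks, the planted node count and
#' node volumes, and the planted hole volume fraction (hole voxels /
#' islet voxels x 100, exact on the voxel grid).
#'
#' @param spec a [phantom_spec()].
#' @param markers up to three of `insulin`, `glucagon`, `ca9`,
#'   `collagen4`, `fibronectin`, `laminin`, `ecadherin`.
#' @return list with elements `grid` (a [voxel_grid()]) and `truth`
#'   (class `phantom_truth`).
#' @export
generate_islet_phantom <- function(spec,
                                   markers = c("laminin", "ecadherin", "ca9")) {
  validate_phantom_spec(spec)
  if (length(markers) < 1 || length(markers) > 3) {
    stop("choose one to three marker channels")
  }
  ok <- c("insulin", "glucagon", "ca9", "collagen4", "fibronectin",
          "laminin", "ecadherin")
  if (!all(markers %in% ok)) stop("unsupported marker for phantom rendering")
  coords <- canvas_coords(spec$canvas, spec$voxel_size)
  vs <- spec$voxel_size

  # islet body: volume-normalised random ellipsoid
  reseed(spec$seed, "shape")
  if (spec$shape_perturbation > 0) {
    u <- runif(3, 1 - spec$shape_perturbation, 1 + spec$shape_perturbation)
    u <- u / prod(u)^(1 / 3)
  } else {
    u <- c(1, 1, 1)
  }
  semi_axes <- spec$islet_radius * u
  islet <- rasterize_ellipsoid(spec$canvas, coords, c(0, 0, 0), semi_axes)
  islet_n <- sum(islet)
  interior <- distance_to_background(islet, vs) > max(vs)

  masks <- list()
  node_centers <- NULL

  # central cavity (E-cadherin hole); the scar occupies the same core
  hole_r <- spec$ecadherin$hole_radius
  cavity <- array(FALSE, spec$canvas)
  if (hole_r > 0) {
    cavity <- add_sphere(cavity, coords, c(0, 0, 0), hole_r) & islet
  }
  if ("ecadherin" %in% markers) masks$ecadherin <- islet & !cavity

  if ("laminin" %in% markers) {
    reseed(spec$seed, "laminin")
    lam <- spec$laminin
    well_sep <- isTRUE(lam$well_separated)
    min_sep <- if (well_sep) 2 * (lam$node_radius + spec$blur$sigma_xy) else 0
    node_centers <- place_points(
      lam$node_count, semi_axes,
      margin = lam$node_radius + max(vs) + spec$blur$sigma_xy,
      min_sep = min_sep, constraint_name = "node separation",
      sep_sigma = if (well_sep) c(spec$blur$sigma_z, spec$blur$sigma_xy),
      sep_radius = lam$node_radius
    )
    m <- array(FALSE, spec$canvas)
    for (i in seq_len(nrow(node_centers))) {
      m <- add_sphere(m, coords, node_centers[i, ], lam$node_radius)
    }
    masks$laminin <- m & islet
  }

  if ("ca9" %in% markers) {
    reseed(spec$seed, "ca9")
    m <- array(FALSE, spec$canvas)
    if (spec$scar > 0 && spec$ca9$rim_thickness > 0) {
      outer_m <- add_sphere(array(FALSE, spec$canvas), coords, c(0, 0, 0),
                            spec$scar + spec$ca9$rim_thickness)
      core <- add_sphere(array(FALSE, spec$canvas), coords, c(0, 0, 0),
                         spec$scar)
      m <- m | (outer_m & !core)
    }
    if (spec$ca9$blob_count > 0) {
      centers <- place_points(spec$ca9$blob_count, semi_axes,
                              margin = spec$ca9$blob_radius + max(vs),
                              min_sep = 2 * spec$ca9$blob_radius,
                              min_center_dist = spec$scar +
                                spec$ca9$rim_thickness +
                                spec$ca9$blob_radius,
                              constraint_name = "ca9 blob placement")
      for (i in seq_len(nrow(centers))) {
        m <- add_sphere(m, coords, centers[i, ], spec$ca9$blob_radius)
      }
    }
    masks$ca9 <- m & islet
  }

  if ("collagen4" %in% markers) {
    reseed(spec$seed, "collagen4")
    m <- array(FALSE, spec$canvas)
    for (i in seq_len(spec$collagen4$n_tubes)) {
      dir1 <- rnorm(3); dir1 <- dir1 / sqrt(sum(dir1^2))
      dir2 <- rnorm(3); dir2 <- dir2 / sqrt(sum(dir2^2))
      m <- add_tube(m, coords, dir1 * semi_axes * 0.95,
                    dir2 * semi_axes * 0.95, spec$collagen4$radius)
    }
    if (spec$scar > 0) m <- add_sphere(m, coords, c(0, 0, 0), spec$scar)
    masks$collagen4 <- m & islet
  }

  if ("fibronectin" %in% markers) {
    reseed(spec$seed, "fibronectin")
    seeds <- place_points(spec$fibronectin$n_seeds, semi_axes, margin = 2,
                          min_sep = 4, constraint_name = "mesh seed")
    idx <- which(islet)
    P <- cbind(coords[[1]][((idx - 1) %% spec$canvas[1]) + 1],
               coords[[2]][(((idx - 1) %/% spec$canvas[1]) %% spec$canvas[2]) + 1],
               coords[[3]][((idx - 1) %/% (spec$canvas[1] * spec$canvas[2])) + 1])
    d1 <- rep(Inf, nrow(P)); d2 <- rep(Inf, nrow(P))
    for (s in seq_len(nrow(seeds))) {
      dd <- sqrt((P[, 1] - seeds[s, 1])^2 + (P[, 2] - seeds[s, 2])^2 +
                   (P[, 3] - seeds[s, 3])^2)
      closer <- dd < d1
      d2 <- ifelse(closer, d1, pmin(d2, dd))
      d1 <- pmin(d1, dd)
    }
    m <- array(FALSE, spec$canvas)
    m[idx] <- (d2 - d1) < spec$fibronectin$mesh_thickness
    if (spec$scar > 0) {
      m <- add_sphere(m, coords, c(0, 0, 0), spec$scar) & islet
    }
    masks$fibronectin <- m
  }

  for (h in intersect(markers, c("insulin", "glucagon"))) {
    # cytoplasmic hormones, lost in the necrotic core
    m <- islet
    if (spec$scar > 0) {
      core <- add_sphere(array(FALSE, spec$canvas), coords, c(0, 0, 0),
                         spec$scar)
      m <- m & !core
    }
    masks[[h]] <- m
  }

  # nuclei: non-overlapping small spheres, strictly inside the islet and
  # excluded from the scar core ("scarce nuclei")
  reseed(spec$seed, "nuclei")
  nuc <- spec$nuclei
  centers <- place_points(nuc$count, semi_axes,
                          margin = nuc$radius + max(vs),
                          min_sep = 2 * nuc$radius,
                          min_center_dist = if (spec$scar > 0)
                            spec$scar + nuc$radius else 0,
                          constraint_name = "nuclei packing")
  m <- array(FALSE, spec$canvas)
  for (i in seq_len(nrow(centers))) {
    m <- add_sphere(m, coords, centers[i, ], nuc$radius)
  }
  masks <- c(list(nuclei = m & interior), masks)

  # render channels in map order: nuclei then the requested markers
  chan_names <- c("nuclei", markers)
  cm <- channel_map(chan_names)
  data <- array(0, c(length(chan_names), spec$canvas))
  reseed(spec$seed, "noise")
  for (i in seq_along(chan_names)) {
    data[i, , , ] <- render_channel(
      masks[[chan_names[i]]], islet,
      intensity = spec$intensity[[chan_names[i]]],
      baseline = spec$intensity$baseline,
      outside = spec$intensity$outside,
      blur = spec$blur, noise = spec$noise, voxel_size = vs
    )
  }
  grid <- voxel_grid(data, vs, cm, bit_depth = 16L)

  node_volumes <- if (!is.null(masks$laminin) && !is.null(node_centers) &&
                      nrow(node_centers) > 0) {
    rep(4 / 3 * pi * spec$laminin$node_radius^3, nrow(node_centers))
  } else numeric(0)
  truth <- structure(list(
    islet_mask = islet,
    masks = masks,
    node_count = if ("laminin" %in% markers) spec$laminin$node_count else NA_integer_,
    node_centers = node_centers,
    node_volumes = node_volumes,
    hole_fraction_pct = 100 * sum(cavity) / islet_n,
    viable_fraction = NA_real_,
    intensities = spec$intensity,
    semi_axes = semi_axes,
    islet_voxels = islet_n,
    spec = spec
  ), class = "phantom_truth")
  list(grid = grid, truth = truth)
}

#' Condition profiles: normoxia day 1/5 and hypoxia day 5
#'
#' Distributions over phantom parameters emulating the three experimental
#' groups. Normoxic profiles plant 5-9 small scattered laminin nodes,
#' little or no central scarring and sporadic CA9 blobs; the hypoxic
#' profile plants 1-2 large central laminin condensations, a necrotic
#' core with a CA9-positive rim, a larger E-cadherin hole fraction and a
#' higher E-cadherin intensity. Group hole-fraction and intensity means
#' follow the reported group statistics (hole % 2.5 / 3.1 / 8.6, E-cadherin
#' intensity 8598 / 6463 / 14805 AU for ND1 / ND5 / HD5). Islet radii are
#' drawn from a profile-independent stream so seed-paired cohorts share
#' identical size distributions.
#'
#' @param name `"ND1"`, `"ND5"` or `"HD5"`.
#' @return a `condition_profile`.
#' @export
condition_profile <- function(name) {
  name <- match.arg(name, c("ND1", "ND5", "HD5"))
  structure(list(name = name), class = "condition_profile")
}

# draw a phantom_spec from a profile; radius comes from a substream keyed
# only by (cohort_seed, index) so profiles are size-matched when paired
draw_spec <- function(profile, cohort_seed, index,
                      canvas = c(64L, 64L, 64L), voxel_size = c(2, 2, 2)) {
  set.seed(as.integer(mix_seed(cohort_seed, index, 1L)))
  r <- runif(1, 30, 48)
  set.seed(as.integer(mix_seed(cohort_seed, index, 2L)))
  trunc_norm <- function(mean, sd, lo, hi) {
    min(max(rnorm(1, mean, sd), lo), hi)
  }
  name <- profile$name
  if (name == "HD5") {
    node_count <- sample(1:2, 1)
    # total condensed volume comparable whether one or two scars
    node_radius <- runif(1, 0.25, 0.32) * r / node_count^(1 / 3)
    hole_pct <- trunc_norm(8.6, 4, 2.5, 18)
    ecad_int <- trunc_norm(14805, 1762, 9000, 22000)
    ca9_blobs <- 0L
    rim <- 6
  } else if (name == "ND5") {
    node_count <- sample(5:9, 1)
    node_radius <- runif(1, 4, 6)
    hole_pct <- trunc_norm(3.1, 1.3, 0.3, 8)
    ecad_int <- trunc_norm(6463, 657, 4000, 10000)
    ca9_blobs <- sample(1:2, 1)
    rim <- 0
  } else {
    node_count <- sample(5:9, 1)
    node_radius <- runif(1, 4, 6)
    hole_pct <- trunc_norm(2.5, 2.5, 0.2, 8)
    ecad_int <- trunc_norm(8598, 1318, 5500, 13000)
    ca9_blobs <- sample(0:1, 1)
    rim <- 0
  }
  hole_r <- r * (hole_pct / 100)^(1 / 3)
  scar <- if (name == "HD5") hole_r else 0
  intensity <- list(nuclei = 6000, insulin = 4000, glucagon = 4000,
                    ca9 = 5000, collagen4 = 3000, fibronectin = 3000,
                    laminin = 4000, ecadherin = ecad_int,
                    baseline = 300, outside = 50)
  phantom_spec(
    canvas = canvas, voxel_size = voxel_size, islet_radius = r,
    shape_perturbation = 0.06,
    nuclei = list(count = if (name == "HD5") 60L else 90L, radius = 3),
    laminin = list(node_count = node_count, node_radius = node_radius,
                   well_separated = TRUE),
    scar = scar,
    ecadherin = list(hole_radius = hole_r),
    ca9 = list(rim_thickness = rim, blob_count = ca9_blobs,
               blob_radius = 3.5),
    intensity = intensity,
    seed = as.integer(mix_seed(cohort_seed, index, 3L))
  )
}

#' Generate a seeded cohort of phantoms for one condition
#'
#' Per-islet seeds are derived deterministically from the cohort seed, so
#' the same `(profile, n, seed)` always reproduces the same cohort, and
#' cohorts of different profiles at the same seed are size-paired.
#'
#' @param profile a [condition_profile()] or profile name.
#' @param n number of phantoms (>= 1).
#' @param seed cohort seed.
#' @param markers marker channels, as in [generate_islet_phantom()].
#' @param canvas,voxel_size phantom canvas (defaults 64^3 at 2 um, a
#'   desk-scale setting that holds radius <= 48 um islets).
#' @return list of `list(grid, truth)` with a `summary` attribute (data
#'   frame of planted parameters per phantom).
#' @export
generate_cohort <- function(profile, n, seed = 1L,
                            markers = c("laminin", "ecadherin", "ca9"),
                            canvas = c(64L, 64L, 64L),
                            voxel_size = c(2, 2, 2)) {
  if (is.character(profile)) profile <- condition_profile(profile)
  stopifnot(inherits(profile, "condition_profile"))
  if (!is.numeric(n) || n < 1) stop("cohort size n must be >= 1")
  out <- vector("list", n)
  sm <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- draw_spec(profile, seed, i, canvas = canvas,
                      voxel_size = voxel_size)
    out[[i]] <- generate_islet_phantom(spec, markers = markers)
    tr <- out[[i]]$truth
    sm[[i]] <- data.frame(
      index = i, condition = profile$name,
      islet_radius_um = spec$islet_radius,
      planted_islet_voxels = tr$islet_voxels,
      planted_node_count = tr$node_count,
      planted_hole_fraction_pct = tr$hole_fraction_pct,
      ecadherin_intensity_au = spec$intensity$ecadherin,
      seed = spec$seed
    )
  }
  attr(out, "summary") <- do.call(rbind, sm)
  out
}

#' Generate a 2D live/dead viability image with ground truth
#'
#' Emulates fluorescein (green, viable) / propidium iodide (red, dead)
#' epifluorescence snapshots: non-overlapping islet silhouettes whose
#' stained area is partitioned into green and red sectors such that the
#' planted green / (green + red) area ratio equals `viable_fraction` to
#' within one pixel. Channels are blurred and noised like the 3D stacks.
#'
#' @param viable_fraction target viable fraction in `[0, 1]`.
#' @param n_islets_2d number of islet silhouettes.
#' @param seed integer seed.
#' @param canvas `(ny, nx)` pixels.
#' @param pixel_size um per pixel.
#' @param intensity stain intensity (AU); background and noise as in the
#'   3D generator.
#' @return list with `image` (array `(2, y, x)`: green, red), `truth`
#'   (planted ratio and masks), `pixel_size`.
#' @export
generate_viability_image <- function(viable_fraction, n_islets_2d = 5L,
                                     seed = 1L, canvas = c(192L, 192L),
                                     pixel_size = 2, intensity = 3000) {
  if (!is.finite(viable_fraction) || viable_fraction < 0 || viable_fraction > 1) {
    stop("viable_fraction must lie in [0, 1]")
  }
  set.seed(as.integer(mix_seed(seed, 0L, .SUBSTREAM[["viability"]])))
  ny <- canvas[1]; nx <- canvas[2]
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  centers <- matrix(NA_real_, n_islets_2d, 3)  # (y, x, r) in px
  for (i in seq_len(n_islets_2d)) {
    for (att in 1:500) {
      r <- runif(1, 14, 30)
      cy <- runif(1, r + 4, ny - r - 4)
      cx <- runif(1, r + 4, nx - r - 4)
      if (i > 1) {
        prev <- centers[seq_len(i - 1), , drop = FALSE]
        if (any(sqrt((prev[, 1] - cy)^2 + (prev[, 2] - cx)^2) <
                  prev[, 3] + r + 4)) next
      }
      centers[i, ] <- c(cy, cx, r)
      break
    }
    if (anyNA(centers[i, ])) stop("could not place islet silhouettes")
  }
  # global angular-sweep partition: per islet, pixels sorted by angle from
  # a random start; the greedy global split hits the target to one pixel
  green <- matrix(FALSE, ny, nx)
  red <- matrix(FALSE, ny, nx)
  pix <- list()
  for (i in seq_len(n_islets_2d)) {
    sel <- which((yy - centers[i, 1])^2 + (xx - centers[i, 2])^2 <=
                   centers[i, 3]^2)
    a0 <- runif(1, 0, 2 * pi)
    ang <- (atan2(yy[sel] - centers[i, 1], xx[sel] - centers[i, 2]) - a0) %%
      (2 * pi)
    pix[[i]] <- sel[order(ang)]
  }
  n_total <- sum(lengths(pix))
  n_green_target <- round(viable_fraction * n_total)
  taken <- 0L
  for (i in seq_len(n_islets_2d)) {
    p <- pix[[i]]
    want <- round(viable_fraction * length(p))
    want <- min(want, n_green_target - taken)
    if (i == n_islets_2d) want <- n_green_target - taken
    want <- min(max(want, 0L), length(p))
    if (want > 0) green[p[seq_len(want)]] <- TRUE
    if (want < length(p)) red[p[(want + 1):length(p)]] <- TRUE
    taken <- taken + want
  }
  planted <- sum(green) / (sum(green) + sum(red))
  render2d <- function(mask) {
    img <- matrix(50, ny, nx)
    img[mask] <- intensity
    img <- gaussian_blur2d(img, 1)
    img <- matrix(rpois(length(img), pmax(img, 0) / 2) * 2, ny, nx) +
      matrix(rnorm(length(img), 0, 80), ny, nx)
    round(pmin(pmax(img, 0), 65535))
  }
  image <- array(0, c(2, ny, nx))
  image[1, , ] <- render2d(green)
  image[2, , ] <- render2d(red)
  truth <- structure(list(
    viable_fraction = planted,
    target_fraction = viable_fraction,
    green_mask = green, red_mask = red
  ), class = "phantom_truth")
  list(image = image, truth = truth, pixel_size = pixel_size)
}
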