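# Independent brute-force oracles used to cross-check the package's
# morphology kernels. These deliberately share no code with the
# implementation: plain breadth-first searches over explicit neighbour
# offsets, and direct voxel counting.

oracle_offsets <- function(connectivity) {
  off <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  off <- off[!(off$dz == 0 & off$dy == 0 & off$dx == 0), ]
  if (connectivity == 6) {
    off <- off[abs(off$dz) + abs(off$dy) + abs(off$dx) == 1, ]
  }
  as.matrix(off)
}

# BFS connected-component labelling of a logical 3D array
oracle_label_cc <- function(mask, connectivity = 26) {
  d <- dim(mask)
  off <- oracle_offsets(connectivity)
  labels <- array(0L, d)
  nextlab <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    labels[start] <- nextlab
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ai <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        p <- ai + off[r, ]
        if (any(p < 1) || any(p > d)) next
        j <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
        if (mask[j] && labels[j] == 0L) {
          labels[j] <- nextlab
          queue <- c(queue, j)
        }
      }
    }
  }
  labels
}

# BFS flood of the background (6-connectivity) from all border voxels;
# returns the logical array of reached background voxels
oracle_flood_from_border <- function(mask) {
  d <- dim(mask)
  off <- oracle_offsets(6)
  reached <- array(FALSE, d)
  border <- which(slice.index(mask, 1) %in% c(1, d[1]) |
                    slice.index(mask, 2) %in% c(1, d[2]) |
                    slice.index(mask, 3) %in% c(1, d[3]))
  queue <- border[!mask[border]]
  reached[queue] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[length(queue)]
    queue <- queue[-length(queue)]
    ai <- arrayInd(cur, d)
    for (r in seq_len(nrow(off))) {
      p <- ai + off[r, ]
      if (any(p < 1) || any(p > d)) next
      j <- p[1] + d[1] * ((p[2] - 1) + d[2] * (p[3] - 1))
      if (!mask[j] && !reached[j]) {
        reached[j] <- TRUE
        queue <- c(queue, j)
      }
    }
  }
  reached
}

# do two labelings define the same partition of the foreground?
same_partition <- function(a, b) {
  fa <- a > 0; fb <- b > 0
  if (!identical(fa, fb)) return(FALSE)
  key <- paste(a[fa], b[fb])
  length(unique(key)) == max(a) && max(a) == max(b)
}

# random blobby logical array: union of a few random boxes/spheres
random_blob_mask <- function(dims, n_blobs = 4, p_noise = 0.02) {
  m <- array(runif(prod(dims)) < p_noise, dims)
  for (i in seq_len(n_blobs)) {
    c0 <- sapply(dims, function(n) runif(1, 1, n))
    r <- runif(1, 1.5, max(2.5, min(dims) / 3))
    g <- expand.grid(z = 1:dims[1], y = 1:dims[2], x = 1:dims[3])
    d2 <- (g$z - c0[1])^2 + (g$y - c0[2])^2 + (g$x - c0[3])^2
    m[d2 <= r^2] <- TRUE
  }
  m
}

# a simple centred-sphere voxel grid with one uniform foreground channel
sphere_grid <- function(radius_um, canvas, voxel_size, fg = 1000,
                        n_channels = 1, centers = NULL) {
  cs <- lapply(1:3, function(i) {
    (seq_len(canvas[i]) - (canvas[i] + 1) / 2) * voxel_size[i]
  })
  if (is.null(centers)) centers <- matrix(0, 1, 3)
  m <- array(FALSE, canvas)
  for (k in seq_len(nrow(centers))) {
    d2 <- outer(
      outer((cs[[1]] - centers[k, 1])^2, (cs[[2]] - centers[k, 2])^2, "+"),
      (cs[[3]] - centers[k, 3])^2, "+"
    )
    m <- m | (d2 <= radius_um^2)
  }
  data <- array(0, c(n_channels, canvas))
  for (cc in seq_len(n_channels)) data[cc, , , ] <- fg * m
  markers <- c("nuclei", "laminin", "ecadherin")[seq_len(n_channels)]
  list(grid = voxel_grid(data, voxel_size, channel_map(markers)), mask = m)
}
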