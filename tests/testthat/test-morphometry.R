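# A hand-built labeling: one islet of given voxel set
manual_labeling <- function(mask, voxel_size) {
  labels <- array(0L, dim(mask))
  labels[mask] <- 1L
  isletmorph:::new_islet_labeling(labels, voxel_size)
}

test_that("islet_volume is voxel count times voxel volume", {
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10][1:1000] <- TRUE
  expect_equal(islet_volume(manual_labeling(m, c(1, 1, 1)), 1), 1000)
  expect_equal(islet_volume(manual_labeling(m, c(2, 0.5, 0.5)), 1), 500)
  expect_error(islet_volume(manual_labeling(m, c(1, 1, 1)), 2), "unknown")
})

test_that("islet_volume of a phantom equals the brute-force truth count", {
  ph <- generate_islet_phantom(phantom_spec(
    canvas = c(40L, 40L, 40L), voxel_size = c(2, 1.5, 1.5), islet_radius = 25,
    nuclei = list(count = 20L, radius = 3),
    laminin = list(node_count = 3L, node_radius = 4, well_separated = TRUE),
    seed = 3L
  ))
  lab <- manual_labeling(ph$truth$islet_mask, c(2, 1.5, 1.5))
  expect_equal(islet_volume(lab, 1), sum(ph$truth$islet_mask) * 2 * 1.5 * 1.5)
})

test_that("volume_fraction counts stain inside the islet only", {
  m <- array(FALSE, c(25, 20, 20)); m[1:10000] <- TRUE  # 10000 islet voxels
  lab <- manual_labeling(m, c(1, 1, 1))
  st <- array(FALSE, c(25, 20, 20)); st[1:500] <- TRUE
  expect_equal(volume_fraction(st, lab, 1), 5.0)
  # stain covering everything (incl. outside): exactly 100
  expect_equal(volume_fraction(array(TRUE, dim(m)), lab, 1), 100.0)
  # random mask vs brute-force intersection ratio
  set.seed(7)
  rnd <- array(runif(prod(dim(m))) < 0.3, dim(m))
  expect_equal(volume_fraction(rnd, lab, 1),
               100 * sum(rnd & m) / sum(m))
  expect_equal(ca9_fraction(rnd, lab, 1), volume_fraction(rnd, lab, 1))
})

test_that("volume fractions are pure ratios while volumes scale with voxel size", {
  m <- array(FALSE, c(12, 12, 12)); m[3:9, 3:9, 3:9] <- TRUE
  st <- array(FALSE, dim(m)); st[4:6, 4:6, 4:6] <- TRUE
  f1 <- volume_fraction(st, manual_labeling(m, c(1, 1, 1)), 1)
  f2 <- volume_fraction(st, manual_labeling(m, c(3, 2, 0.5)), 1)
  expect_equal(f1, f2)
  v1 <- islet_volume(manual_labeling(m, c(1, 1, 1)), 1)
  v2 <- islet_volume(manual_labeling(m, c(3, 2, 0.5)), 1)
  expect_equal(v2, v1 * 3)
})

test_that("disjoint stains have fractions summing to at most 100", {
  set.seed(12)
  m <- random_blob_mask(c(15, 15, 15), 3, 0.05)
  lab <- manual_labeling(m, c(1, 1, 1))
  s1 <- array(runif(15^3) < 0.2, c(15, 15, 15))
  s2 <- array(runif(15^3) < 0.2, c(15, 15, 15)) & !s1
  s3 <- !(s1 | s2) & array(runif(15^3) < 0.5, c(15, 15, 15))
  tot <- volume_fraction(s1, lab, 1) + volume_fraction(s2, lab, 1) +
    volume_fraction(s3, lab, 1)
  expect_lte(tot, 100 + 1e-9)
})

test_that("count_nodes filters small components and merges adjacent ones", {
  m <- array(TRUE, c(30, 30, 30))
  lab <- manual_labeling(m, c(1, 1, 1))
  st <- array(FALSE, c(30, 30, 30))
  st[3:7, 3:7, 3:7] <- TRUE        # 125 voxels
  st[15:19, 15:19, 15:19] <- TRUE  # 125 voxels
  st[25, 25, 25] <- TRUE           # speckle
  nd <- count_nodes(st, lab, 1, min_node_volume = 50)
  expect_equal(nd$node_count, 2L)
  expect_equal(nd$node_volumes, c(125, 125))
  # empty stain: zero nodes
  expect_equal(count_nodes(array(FALSE, dim(m)), lab, 1, 50)$node_count, 0L)
  # two cubes sharing a single face-adjacent voxel pair: one component,
  # same as the BFS oracle
  st2 <- array(FALSE, c(30, 30, 30))
  st2[3:5, 3:5, 3:5] <- TRUE
  st2[6:8, 5, 5] <- TRUE  # touches the cube face at (5,5,5)-(6,5,5)
  nd2 <- count_nodes(st2, lab, 1, min_node_volume = 1)
  expect_equal(nd2$node_count, max(oracle_label_cc(st2, 26)))
  expect_equal(nd2$node_count, 1L)
})

test_that("count_nodes recovers planted nodes on a phantom", {
  sp <- phantom_spec(canvas = c(48L, 48L, 48L), voxel_size = c(2, 2, 2),
                     islet_radius = 34,
                     laminin = list(node_count = 7L, node_radius = 4.5,
                                    well_separated = TRUE),
                     nuclei = list(count = 40L, radius = 3), seed = 21L)
  ph <- generate_islet_phantom(sp)
  lab <- manual_labeling(ph$truth$islet_mask, sp$voxel_size)
  st <- detect_stain(ph$grid, "laminin",
                     list(sigma = 0, threshold = 2150, mode = "absolute",
                          background_sigma = 20))
  expect_equal(count_nodes(st, lab, 1)$node_count, 7L)
})

test_that("quantify_holes matches the analytic concentric-shell ratio", {
  # islet sphere r = 50 um fully stained except a central r = 20 um void
  cs <- (1:52 - 26.5) * 2  # 52^3 canvas at 2 um
  d2 <- outer(outer(cs^2, cs^2, "+"), cs^2, "+")
  islet <- d2 <= 50^2
  ecad <- islet & (d2 > 20^2)
  lab <- manual_labeling(islet, c(2, 2, 2))
  hf <- quantify_holes(ecad, lab, 1, min_hole_volume = 100,
                       boundary_margin = 3)
  expect_equal(hf, 100 * 20^3 / 50^3, tolerance = 0.02)  # 6.4, quantization
  # fully stained islet: zero
  expect_equal(quantify_holes(islet, lab, 1, 100, 3), 0)
})

test_that("open indentations are excluded; only enclosed cavities count", {
  cs <- (1:40 - 20.5) * 2
  d2 <- outer(outer(cs^2, cs^2, "+"), cs^2, "+")
  islet <- d2 <= 36^2
  ecad <- islet & (d2 > 12^2)           # enclosed central cavity
  # carve an unstained wedge open to the surface along +x
  wedge <- array(FALSE, c(40, 40, 40))
  wedge[18:23, 18:23, 28:40] <- TRUE
  ecad2 <- ecad & !wedge
  lab <- manual_labeling(islet, c(2, 2, 2))
  hf <- quantify_holes(ecad2, lab, 1, min_hole_volume = 100,
                       boundary_margin = 3)
  # oracle: flood unstained voxels from the islet boundary; what is
  # reached is open, the rest is the enclosed hole
  unstained <- islet & !ecad2
  # flood everything unstained (outside the islet and open voids) from the
  # array border, treating stained voxels as the obstacle
  outside_flood <- oracle_flood_from_border(ecad2)
  enclosed <- unstained & !outside_flood
  expect_equal(hf, 100 * sum(enclosed) / sum(islet), tolerance = 1e-9)
  # and the wedge itself contributed nothing beyond the central cavity
  expect_equal(hf, quantify_holes(ecad, lab, 1, 100, 3), tolerance = 1e-9)
})

test_that("mean_intensity is the raw mean over islet voxels", {
  m <- array(FALSE, c(12, 12, 12)); m[3:10, 3:10, 3:10] <- TRUE
  lab <- manual_labeling(m, c(1, 1, 1))
  mk_grid <- function(ch) {
    data <- array(0, c(1, dim(ch))); data[1, , , ] <- ch
    voxel_grid(data, c(1, 1, 1), channel_map("ecadherin"))
  }
  expect_equal(mean_intensity(mk_grid(array(100, c(12, 12, 12))),
                              "ecadherin", lab, 1), 100)
  half <- array(0, c(12, 12, 12)); half[, , 7:12] <- 200
  expect_equal(mean_intensity(mk_grid(half), "ecadherin", lab, 1), 100)
  set.seed(3)
  rnd <- array(sample(0:4000, 12^3, TRUE), c(12, 12, 12))
  expect_equal(mean_intensity(mk_grid(rnd), "ecadherin", lab, 1),
               sum(rnd[m]) / sum(m))
})

test_that("viability ratio follows the green-over-union definition", {
  img <- array(0, c(2, 40, 40))
  img[1, 1:11, 1:8] <- 1000   # green 88 px
  img[2, 30:35, 30:31] <- 1000  # red 12 px, disjoint
  v <- viability_ratio(img, green_threshold = 500, red_threshold = 500)
  expect_equal(v$viability, 0.88)
  expect_equal(v$status, "ok")
  # red empty: viability 1
  img2 <- img; img2[2, , ] <- 0
  expect_equal(viability_ratio(img2, 500, 500)$viability, 1.0)
  # nothing stained: distinct non-numeric outcome
  v0 <- viability_ratio(array(0, c(2, 10, 10)), 500, 500)
  expect_equal(v0$status, "no_stained_area")
  expect_true(is.na(v0$viability))
  # physical areas reported when pixel size is known
  va <- viability_ratio(img, 500, 500, pixel_size = 2)
  expect_equal(va$green_area_um2, 88 * 4)
})

test_that("viability recovery on rendered phantoms is within 0.03", {
  v <- generate_viability_image(0.62, n_islets_2d = 5, seed = 13L)
  r <- viability_ratio(v)  # Otsu thresholds
  expect_lt(abs(r$viability - v$truth$viable_fraction), 0.03)
})

test_that("ca9_fraction recovers a planted rim exactly on clean input", {
  sp <- phantom_spec(canvas = c(48L, 48L, 48L), voxel_size = c(2, 2, 2),
                     islet_radius = 32, scar = 10,
                     ca9 = list(rim_thickness = 6, blob_count = 0L,
                                blob_radius = 3),
                     noise = list(gaussian_sd = 0, poisson_scale = 0),
                     blur = list(sigma_xy = 0, sigma_z = 0),
                     nuclei = list(count = 30L, radius = 3), seed = 6L)
  ph <- generate_islet_phantom(sp)
  lab <- manual_labeling(ph$truth$islet_mask, sp$voxel_size)
  st <- detect_stain(ph$grid, "ca9",
                     list(sigma = 0, threshold = 2500, mode = "absolute",
                          background_sigma = 20))
  planted_pct <- 100 * sum(ph$truth$masks$ca9) / sum(ph$truth$islet_mask)
  expect_equal(ca9_fraction(st, lab, 1), planted_pct)
  expect_equal(ca9_fraction(array(FALSE, dim(lab$labels)), lab, 1), 0)
  expect_equal(ca9_fraction(ph$truth$islet_mask, lab, 1), 100)
})

test_that("measure_islet assembles one row per marker with the right fields", {
  ph <- generate_islet_phantom(phantom_spec(
    canvas = c(48L, 48L, 48L), voxel_size = c(2, 2, 2), islet_radius = 32,
    ecadherin = list(hole_radius = 10), scar = 10,
    nuclei = list(count = 40L, radius = 3), seed = 4L
  ))
  cfg <- default_config()
  lab <- manual_labeling(ph$truth$islet_mask, c(2, 2, 2))
  stains <- list(
    laminin = detect_stain(ph$grid, "laminin",
                           list(sigma = 1, threshold = 2150,
                                mode = "absolute", background_sigma = 20)),
    ecadherin = detect_stain(ph$grid, "ecadherin",
                             list(sigma = 1, threshold = 4150,
                                  mode = "absolute", background_sigma = 20))
  )
  rec <- measure_islet(ph$grid, lab, 1, stains, cfg$morphometry,
                       condition = "ND5")
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$marker, c("laminin", "ecadherin"))
  lam <- rec[rec$marker == "laminin", ]
  expect_false(is.na(lam$node_count))
  expect_true(is.na(lam$hole_fraction_pct))
  ec <- rec[rec$marker == "ecadherin", ]
  expect_false(is.na(ec$hole_fraction_pct))
  expect_true(all(rec$volume_fraction_pct >= 0 & rec$volume_fraction_pct <= 100))
  expect_true(all(rec$islet_volume_um3 > 0))
})
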