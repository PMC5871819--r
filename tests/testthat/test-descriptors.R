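test_that("height function is depth below the bounding-box top", {
  tr <- path_tree(seq(0, -10, by = -1))
  f <- height_function(tr)
  expect_equal(unname(f$values), 0:10)
  expect_equal(f$max_value, 10)
  tr2 <- tr
  tr2$nodes$x <- tr2$nodes$x + 100  # horizontal translation: no change
  expect_equal(height_function(tr2)$values, f$values)
})

test_that("upwards complexity counts upward trajectory changes", {
  expect_equal(upwards_complexity(path_tree(seq(0, -10, by = -1))), 0L)
  expect_equal(upwards_complexity(n_shape_tree()), 1L)
  # single node / degenerate trees return 0
  expect_equal(upwards_complexity(airway_tree(
    data.frame(id = 1, x = 0, y = 0, z = 0, parent = NA))), 0L)
})

test_that("upwards complexity equals local minima minus components", {
  for (seed in 31:36) {
    tr <- random_airway_tree(100, seed)
    f <- height_function(tr)
    expect_equal(upwards_complexity(tr),
                 count_local_minima(tr, f$values) - 1L)
  }
})

test_that("directional complexity generalizes the upwards count", {
  tr <- n_shape_tree()
  expect_equal(directional_complexity(tr, c(0, 0, 0)), upwards_complexity(tr))
  # 180 degrees about X counts downward turns; N shape has one interior
  # maximum and one interior minimum of height
  down <- directional_complexity(tr, c(180, 0, 0))
  expect_equal(upwards_complexity(tr) + down, 2L)
  # invariance under rotation about the vertical axis
  for (seed in 41:43) {
    rt <- random_airway_tree(80, seed)
    expect_equal(directional_complexity(rt, c(0, 0, 137)),
                 upwards_complexity(rt))
  }
})

test_that("interior height extrema split into up and down turns", {
  for (seed in 51:54) {
    tr <- random_airway_tree(90, seed)
    f <- height_function(tr)
    flip <- rotate_tree(tr, c(180, 0, 0))
    ff <- height_function(flip)
    up <- upwards_complexity(tr)
    down <- upwards_complexity(flip)
    minima <- count_local_minima(tr, f$values)
    maxima <- count_local_minima(flip, ff$values)
    expect_equal(up + down, minima + maxima - 2L)
  }
})

test_that("branch-to-branch proximity behaves per its geometric definition", {
  # straight branch: no loops
  expect_warning(p0 <- branch_to_branch_proximity(path_tree(c(0, -1, -2))),
                 "fewer than 4")
  expect_equal(p0, 0)
  straight <- path_tree(seq(0, -20, by = -0.5))
  expect_equal(branch_to_branch_proximity(straight), 0, tolerance = 1e-9)
  # hairpin: two parallel 20-node arms 1 mm apart, joined at one end
  z <- seq(0, -19)
  hp <- airway_tree(data.frame(id = 1:40, x = c(rep(0, 20), rep(1, 20)),
                               y = 0, z = c(z, rev(z)),
                               parent = c(NA, 1:39)))
  expect_gt(branch_to_branch_proximity(hp, 2), 0)
})

test_that("proximity equals degree-1 total persistence from brute reduction", {
  tr <- random_airway_tree(22, 61)
  pts <- unique(as.matrix(tr$nodes[, c("x", "y", "z")]))
  fc <- alpha_filtration(pts, jitter_seed = 7)
  want <- oracle_persistence(fc)[[2]]
  want <- want[want[, 2] > want[, 1], , drop = FALSE]
  expect_equal(branch_to_branch_proximity(tr, jitter_seed = 7),
               sum(want[, 2] - want[, 1]), tolerance = 1e-10)
})

test_that("proximity scales linearly with global coordinate scale", {
  tr <- random_airway_tree(60, 71)
  p1 <- branch_to_branch_proximity(tr, 3)
  tr3 <- tr
  tr3$nodes[, c("x", "y", "z")] <- tr3$nodes[, c("x", "y", "z")] * 2.5
  expect_equal(branch_to_branch_proximity(tr3, 3), 2.5 * p1,
               tolerance = 1e-3)
})

test_that("voxel point clouds, emphysema and lumen counts are exact", {
  g <- array(0L, c(3, 3, 2))
  g[1, 1, 1] <- 1L
  g[3, 2, 1] <- 1L
  v <- voxel_volume(g, spacing = 0.7, kind = "lumen_mask")
  pc <- voxel_to_pointcloud(v)
  expect_equal(unname(pc[order(pc[, 1]), ]),
               rbind(c(0, 0, 0), c(1.4, 0.7, 0)))
  expect_equal(lumen_volume(v), 2)
  expect_error(voxel_to_pointcloud(voxel_volume(array(0, c(2, 2, 2)))),
               "no 1-voxels")
  hu <- voxel_volume(array(c(rep(-960, 3), rep(-800, 7), rep(0, 2)),
                           c(3, 2, 2)), kind = "hu_attenuation")
  mask <- voxel_volume(array(c(rep(1, 10), 0, 0), c(3, 2, 2)),
                       kind = "lung_mask")
  expect_equal(emphysema_score(hu, mask), 30)
  allhi <- voxel_volume(array(-800, c(3, 2, 2)), kind = "hu_attenuation")
  expect_equal(emphysema_score(allhi, mask), 0)
  alllo <- voxel_volume(array(-1000, c(3, 2, 2)), kind = "hu_attenuation")
  expect_equal(emphysema_score(alllo, mask), 100)
  empty <- voxel_volume(array(0, c(3, 2, 2)), kind = "lung_mask")
  expect_error(emphysema_score(hu, empty), "empty lung mask")
})

test_that("NIfTI volumes round trip through disk", {
  ph <- generate_lung_phantom(phantom_params(lobe_semiaxes_mm = c(8, 7, 9),
                                             tube_radii_mm = 1.2, seed = 2))
  p <- withr::local_tempfile(fileext = ".nii")
  write_volume(ph$surface, p)
  back <- read_volume(p, "surface_labels")
  expect_equal(back$grid, ph$surface$grid, ignore_attr = TRUE)
  expect_equal(back$spacing, ph$surface$spacing, tolerance = 1e-6)
})

test_that("void barcode finds the cavity of a hollow sphere phantom", {
  ph <- generate_lung_phantom(phantom_params(hollow_sphere_radius_mm = 10,
                                             seed = 1))
  b2 <- void_barcode(ph$surface, jitter_seed = 2)
  i <- which.max(b2$bars[, 2] - b2$bars[, 1])
  expect_lt(abs(b2$bars[i, 2] - 10), 0.5)
  expect_equal(b2$degree, 2L)
  expect_equal(b2$units, "mm_radius")
  # identical phantoms: distance zero between their void barcodes
  b2b <- void_barcode(ph$surface, jitter_seed = 2)
  expect_equal(bottleneck_distance(b2, b2b), 0)
})

test_that("a solid cube has no void of more than voxel persistence", {
  g <- array(1L, c(9, 9, 9))
  vol <- voxel_volume(g, spacing = 0.7, kind = "surface_labels")
  b2 <- void_barcode(vol, jitter_seed = 4)
  if (nrow(b2$bars))
    expect_lt(max(b2$bars[, 2] - b2$bars[, 1]), 0.7)
})

test_that("normalization by height divides by metres and checks inputs", {
  m <- scan_meta("p1", "HNS", "inspiratory", body_height = 1.80)
  expect_equal(normalize_by_height(100, m), 55.5556, tolerance = 1e-4)
  m2 <- scan_meta("p2", "HS", "expiratory")
  expect_error(normalize_by_height(100, m2), "height")
  expect_error(scan_meta("p3", "Bad"), "arg")
})
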