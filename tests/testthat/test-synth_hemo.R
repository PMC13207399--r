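test_that("a depth-1 spec with no bend gives a single straight branch", {
  tree <- make_tube_tree(length_mm = 10, radius_mm = 1.5, spacing_mm = 1)
  expect_length(tree$branches, 1L)
  pts <- tree$branches[[1]]$points
  # collinearity: all points on the x-axis ray from the origin
  expect_equal(pts[, 2], rep(0, nrow(pts)))
  expect_equal(pts[, 3], rep(0, nrow(pts)))
  expect_equal(pts[, 1], seq(0, 10, by = 1))
})

test_that("tree generation is deterministic and respects Murray's law", {
  spec <- vessel_spec(n_levels = 2L, seed = 11L)
  t1 <- build_vessel_tree(spec)
  t2 <- build_vessel_tree(spec)
  expect_identical(tree_points(t1), tree_points(t2))
  expect_length(t1$branches, 3L)  # 2^2 - 1
  r_root <- t1$branches[[1]]$radius[1]
  r_children <- vapply(t1$branches[2:3], function(b) b$radius[1], numeric(1))
  expect_equal(r_root^3, sum(r_children^3), tolerance = 1e-9)
  # deeper tree has 2^n - 1 branches and children attached to parent tips
  t3 <- build_vessel_tree(vessel_spec(n_levels = 3L, seed = 5L))
  expect_length(t3$branches, 7L)
  for (b in t3$branches[-1]) {
    parent <- t3$branches[[b$parent]]
    expect_equal(unname(b$points[1, ]),
                 unname(parent$points[b$parent_point, ]))
  }
})

test_that("consecutive centerline spacing never exceeds twice the step", {
  for (seed in 1:3) {
    tree <- build_vessel_tree(vessel_spec(n_levels = 3L, seed = seed,
                                          point_spacing = 0.75))
    for (b in tree$branches) {
      d <- sqrt(rowSums(diff(b$points)^2))
      expect_true(all(d <= 2 * 0.75))
      expect_true(all(b$radius > 0))
    }
  }
})

test_that("full occlusions are rejected", {
  expect_error(vessel_spec(stenoses = data.frame(branch = 1, position = 0.5,
                                                 severity = 1, extent = 3)),
               "severity")
  expect_error(vessel_spec(root_radius = 0), "root_radius")
  expect_error(vessel_spec(point_spacing = 0), "point_spacing")
})

test_that("stenosis narrows the radius smoothly by (1 - severity)", {
  st <- data.frame(branch = 1, position = 0.5, severity = 0.6, extent = 4)
  tree <- build_vessel_tree(vessel_spec(n_levels = 1L, root_radius = 2,
                                        root_length = 20, bend_amplitude = 0,
                                        stenoses = st, point_spacing = 0.5))
  r <- tree$branches[[1]]$radius
  s <- tree$branches[[1]]$arc
  expect_equal(min(r), 2 * (1 - 0.6), tolerance = 1e-9)
  expect_equal(s[which.min(r)], 10)
  expect_equal(r[abs(s - 10) > 2], rep(2, sum(abs(s - 10) > 2)))
})

test_that("the no-flow limit keeps every point at inlet pressure", {
  tree <- build_vessel_tree(vessel_spec(n_levels = 2L, seed = 4L))
  sol <- solve_pressures(tree, hemo_params(outlet_resistance = Inf))
  expect_equal(unlist(sol$pressure),
               rep(100, length(unlist(sol$pressure))), tolerance = 1e-9)
  expect_equal(sol$inlet_flow, 0, tolerance = 1e-12)
})

test_that("a single tube matches the series-circuit hand solution", {
  # L = 1 cm, r = 0.2 cm, mu = 0.04: R = 8*0.04*1/(pi*0.2^4) dyn s/cm^5
  tree <- make_tube_tree(length_mm = 10, radius_mm = 2, spacing_mm = 1)
  prm <- hemo_params(inlet_pressure = 100, viscosity = 0.04,
                     outlet_resistance = 1333)
  sol <- solve_pressures(tree, prm)
  R_dyn <- 8 * 0.04 * 1 / (pi * 0.2^4)
  expect_equal(R_dyn, 63.66, tolerance = 1e-3)
  R <- R_dyn / 1333.22                    # mmHg s / cm^3
  R_out <- 1333 * 10 / 1333.22
  Q <- 100 / (R + R_out)
  expect_equal(sol$inlet_flow, Q, tolerance = 1e-9)
  outlet_p <- 100 - Q * R                 # = Q * R_out
  p <- sol$pressure[[1]]
  expect_equal(p[1], 100)
  expect_equal(p[length(p)], outlet_p, tolerance = 1e-9)
})

test_that("pressure drop strictly increases with stenosis severity", {
  drops <- vapply(c(0.3, 0.5, 0.7), function(sev) {
    st <- data.frame(branch = 1, position = 0.5, severity = sev, extent = 4)
    tree <- build_vessel_tree(vessel_spec(n_levels = 1L, root_radius = 2,
                                          root_length = 20,
                                          bend_amplitude = 0, stenoses = st,
                                          point_spacing = 0.5))
    p <- solve_pressures(tree)$pressure[[1]]
    p[1] - p[length(p)]
  }, numeric(1))
  base_tree <- build_vessel_tree(vessel_spec(n_levels = 1L, root_radius = 2,
                                             root_length = 20,
                                             bend_amplitude = 0,
                                             point_spacing = 0.5))
  p0 <- solve_pressures(base_tree)$pressure[[1]]
  drop0 <- p0[1] - p0[length(p0)]
  expect_true(all(diff(c(drop0, drops)) > 0))
})

test_that("flow is conserved at bifurcations and pressure is monotone", {
  tree <- build_vessel_tree(vessel_spec(n_levels = 3L, seed = 8L,
                                        stenoses = data.frame(
                                          branch = c(2, 5), position = 0.5,
                                          severity = c(0.5, 0.6),
                                          extent = 4)))
  sol <- solve_pressures(tree)
  # conservation: parent tip flow equals the sum of child first-segment flows
  for (b in seq_along(tree$branches)) {
    kids <- which(vapply(tree$branches, function(x)
      identical(x$parent, b), logical(1)))
    if (length(kids) == 0) next
    qp <- tail(sol$segment_flow[[b]], 1)
    qk <- sum(vapply(kids, function(k) sol$segment_flow[[k]][1], numeric(1)))
    expect_equal(qp, qk, tolerance = 1e-9 * abs(qp))
  }
  # monotone non-increasing along every root-to-leaf path
  for (b in seq_along(tree$branches))
    expect_true(all(diff(sol$pressure[[b]]) <= 1e-9))
  # child branch starts at the parent's tip pressure
  for (b in seq_along(tree$branches)[-1]) {
    par <- tree$branches[[b]]$parent
    expect_equal(sol$pressure[[b]][1],
                 tail(sol$pressure[[par]], 1))
  }
})

test_that("a severe stenosis lowers the distal pressure ratio (FFR)", {
  mk <- function(st) build_vessel_tree(
    vessel_spec(n_levels = 1L, root_radius = 1.8, root_length = 24,
                bend_amplitude = 0, stenoses = st, point_spacing = 0.5))
  p_open <- solve_pressures(mk(NULL))$pressure[[1]]
  p_sten <- solve_pressures(mk(data.frame(branch = 1, position = 0.5,
                                          severity = 0.7,
                                          extent = 5)))$pressure[[1]]
  ffr_open <- tail(p_open, 1) / 100
  ffr_sten <- tail(p_sten, 1) / 100
  expect_lt(ffr_sten, ffr_open)
})

test_that("disconnected trees are rejected", {
  tree <- make_tube_tree()
  tree$branches[[2]] <- tree$branches[[1]]
  tree$branches[[2]]$parent <- 5L  # forward reference: not reachable
  tree$branches[[2]]$parent_point <- 1L
  expect_error(solve_pressures(tree), "disconnected")
})

test_that("rasterization produces the expected lumen geometry", {
  # noise-free binary phantom: exactly two intensities
  tree <- make_tube_tree(length_mm = 20, radius_mm = 2, spacing_mm = 1)
  vol <- rasterize_volume(tree, spacing = 0.5, noise_sd = 0, blur_sd = 0)
  expect_setequal(unique(as.vector(vol$data)), c(0, 400))
  # cylinder voxel count close to pi r^2 L / voxel volume
  n_lumen <- sum(vol$data == 400)
  expected <- pi * 2^2 * 20 / 0.5^3
  expect_lt(abs(n_lumen - expected) / expected, 0.15)
  # every centerline point maps into a lumen voxel
  pts <- as.matrix(tree_points(tree)[, c("x", "y", "z")])
  idx <- round_voxel_index(world_to_local_voxel(pts, vol)) + 1L
  vals <- vol$data[idx]
  expect_true(all(vals == 400))
})

test_that("rasterization handles empty trees, determinism and fit errors", {
  empty <- structure(list(branches = list(), spec = NULL),
                     class = "centerline_tree")
  vol <- rasterize_volume(empty, dims = c(10, 10, 10), origin = c(0, 0, 0),
                          noise_sd = 0)
  expect_equal(unique(as.vector(vol$data)), 0)
  # with noise: uniform background + noise, deterministic given seed
  v1 <- rasterize_volume(empty, dims = c(8, 8, 8), origin = c(0, 0, 0),
                         noise_sd = 5, seed = 3)
  v2 <- rasterize_volume(empty, dims = c(8, 8, 8), origin = c(0, 0, 0),
                         noise_sd = 5, seed = 3)
  expect_identical(v1$data, v2$data)
  # a tree exceeding the volume extent names the offending branch
  tree <- make_tube_tree(length_mm = 30)
  expect_error(rasterize_volume(tree, dims = c(10, 10, 10),
                                origin = c(0, 0, 0)),
               "branch 1")
})

test_that("pressure clouds inherit pressures and expected densities", {
  tree <- make_tube_tree(length_mm = 20, radius_mm = 2, spacing_mm = 0.5)
  sol <- solve_pressures(tree)
  # jitter 0: every cloud point coincides with a centerline point
  cld <- scatter_pressure_cloud(tree, sol, density = 3, jitter_sd = 0,
                                seed = 2)
  pts <- as.matrix(tree_points(tree)[, c("x", "y", "z")])
  d2 <- apply(cld$points, 1, function(p)
    min(colSums((t(pts) - p)^2)))
  expect_true(all(d2 < 1e-18))
  # uniform (no-flow) pressures give zero cloud variance
  cld_u <- scatter_pressure_cloud(tree, uniform_pressures(tree),
                                  density = 3, jitter_sd = 0.2, seed = 2)
  expect_equal(var(cld_u$pressure), 0)
  # density 10/mm on a 20 mm tube: ~200 points, Poisson-consistent
  counts <- vapply(1:20, function(s)
    nrow(scatter_pressure_cloud(tree, sol, density = 10, jitter_sd = 0,
                                seed = s)$points), numeric(1))
  expect_lt(abs(mean(counts) - 200), 4 * sqrt(200 / 20))
  expect_error(scatter_pressure_cloud(tree, sol, density = 0), "density")
})

test_that("pascal to mmHg conversion matches the printed equivalence", {
  expect_equal(round(pa_to_mmhg(13330)), 100)
  expect_equal(pa_to_mmhg(0), 0)
  expect_equal(pa_to_mmhg(133322), 1000, tolerance = 1e-2 / 1000)
  expect_equal(mmhg_to_pa(pa_to_mmhg(250)), 250)
})

test_that("case sets are reproducible with per-case derived seeds", {
  cs1 <- generate_case_set(1, seed = 9,
                           spec_ranges = list(n_levels = 2L,
                                              point_spacing = 1.5))
  expect_length(cs1$cases, 1L)
  expect_length(cs1$manifest$cases, 1L)
  expect_equal(cs1$manifest$cases[[1]]$seed, 10L)  # master + index
  cs2 <- generate_case_set(1, seed = 9,
                           spec_ranges = list(n_levels = 2L,
                                              point_spacing = 1.5))
  expect_identical(jsonlite::toJSON(cs1$manifest, auto_unbox = TRUE,
                                    digits = NA),
                   jsonlite::toJSON(cs2$manifest, auto_unbox = TRUE,
                                    digits = NA))
})

test_that("case sets survive a write/read round trip", {
  cs <- tiny_case_set(2)
  dir <- tempfile("cases_")
  on.exit(unlink(dir, recursive = TRUE))
  write_case_set(cs, dir)
  back <- read_case_set(dir)
  expect_length(back$cases, 2L)
  for (i in 1:2) {
    a <- cs$cases[[i]]; b <- back$cases[[i]]
    expect_equal(tree_points(b$tree), tree_points(a$tree), tolerance = 1e-9)
    expect_equal(b$solution$pressure, a$solution$pressure,
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(b$cloud$points, a$cloud$points, tolerance = 1e-9)
    expect_equal(b$volume$origin, a$volume$origin, tolerance = 1e-4)
    expect_equal(b$volume$data, a$volume$data, tolerance = 1e-5,
                 ignore_attr = TRUE)
    expect_equal(b$tree$branches[[2]]$parent, a$tree$branches[[2]]$parent)
  }
  # a dataset built from the re-read cases matches the original
  ds1 <- build_dataset(cs, c("train", "train"), patch_size = 12L)
  ds2 <- build_dataset(back, c("train", "train"), patch_size = 12L)
  expect_equal(ds2$train$labels_mmhg, ds1$train$labels_mmhg,
               tolerance = 1e-9)
})

test_that("ordered split assignment matches scan-count protocols", {
  sp <- assign_splits(55, c(40, 5, 10))
  expect_equal(sum(sp == "train"), 40)
  expect_equal(sum(sp == "val"), 5)
  expect_equal(sum(sp == "test"), 10)
  expect_error(assign_splits(10, c(5, 2, 2)), "sum")
})
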