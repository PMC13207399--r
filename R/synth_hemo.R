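# Synthetic coronary phantoms: branching vessel-tree geometry, a steady-state
# Poiseuille resistance-network pressure solver, voxelized volumes and
# near-surface pressure point clouds. These stand in for the external
# CT + segmentation + transient CFD stage at desk scale while preserving the
# structure a pressure regressor must learn: ~100 mmHg at the inlet, monotone
# drops along flow, and severity-dependent gradients across stenoses.

#' Vessel tree specification
#'
#' Describes a full binary vessel tree: each of `n_levels` generations halves
#' into two children whose radii follow `child_ratio` (default Murray's law
#' for symmetric bifurcations, `2^(-1/3)`, so parent and child radii satisfy
#' `r_p^3 = 2 r_c^3`).
#'
#' @param n_levels Integer branching depth (1 = a single tube).
#' @param root_radius Root lumen radius, mm.
#' @param root_length Root branch length, mm.
#' @param child_ratio Radius decay per generation (dimensionless).
#' @param length_ratio Length decay per generation (dimensionless).
#' @param branch_angle Half-opening angle at bifurcations, degrees.
#' @param bend_amplitude Amplitude of the smooth in-plane bend of each branch,
#'   mm (0 gives straight branches).
#' @param stenoses Data frame (or list of lists) with columns `branch`
#'   (branch id), `position` (fraction 0-1 along the branch), `severity`
#'   (fractional radius reduction, in `[0, 1)`) and `extent` (mm).
#' @param point_spacing Centerline sampling step, mm.
#' @param seed Integer seed controlling the (small) random components:
#'   bifurcation-plane azimuths and bend phases.
#' @param azimuth Bifurcation-plane azimuth in degrees; `NULL` (default)
#'   draws one at random per bifurcation, a number fixes the skeleton (e.g.
#'   0 gives a planar tree), useful for controlled phantom studies.
#' @return An object of class `vessel_spec`.
#' @export
vessel_spec <- function(n_levels = 3L, root_radius = 1.8, root_length = 24,
                        child_ratio = 2^(-1 / 3), length_ratio = 0.75,
                        branch_angle = 35, bend_amplitude = 1.0,
                        stenoses = NULL, point_spacing = 0.75, seed = 1L,
                        azimuth = NULL) {
  if (root_radius <= 0) stop("root_radius must be > 0")
  if (point_spacing <= 0) stop("point_spacing must be > 0")
  if (n_levels < 1) stop("n_levels must be >= 1")
  if (child_ratio <= 0 || length_ratio <= 0)
    stop("child_ratio and length_ratio must be > 0")
  stenoses <- normalize_stenoses(stenoses)
  structure(list(n_levels = as.integer(n_levels), root_radius = root_radius,
                 root_length = root_length, child_ratio = child_ratio,
                 length_ratio = length_ratio, branch_angle = branch_angle,
                 bend_amplitude = bend_amplitude, stenoses = stenoses,
                 point_spacing = point_spacing, seed = as.integer(seed),
                 azimuth = azimuth),
            class = "vessel_spec")
}

normalize_stenoses <- function(stenoses) {
  if (is.null(stenoses) || (is.data.frame(stenoses) && nrow(stenoses) == 0L))
    return(data.frame(branch = integer(), position = numeric(),
                      severity = numeric(), extent = numeric()))
  if (!is.data.frame(stenoses))
    stenoses <- do.call(rbind.data.frame, lapply(stenoses, as.data.frame))
  need <- c("branch", "position", "severity", "extent")
  if (!all(need %in% names(stenoses)))
    stop("stenoses need columns: ", paste(need, collapse = ", "))
  if (any(stenoses$severity < 0 | stenoses$severity >= 1))
    stop("stenosis severity must lie in [0, 1): severity 1 is a full occlusion")
  if (any(stenoses$extent <= 0)) stop("stenosis extent must be > 0")
  if (any(stenoses$position < 0 | stenoses$position > 1))
    stop("stenosis position must lie in [0, 1]")
  stenoses[need]
}

# A unit vector orthogonal to `d`.
perp_vector <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * d) * d
  v / sqrt(sum(v^2))
}

#' Build a branching centerline tree
#'
#' Deterministic given `spec$seed`. A full binary tree of `n_levels`
#' generations has `2^n_levels - 1` branches; each branch is an ordered point
#' sequence (world mm) with per-point radii. A child's first point coincides
#' with its parent's tip. Stenoses narrow the radius by a factor that tapers
#' smoothly (raised-cosine) to `1 - severity` at the stenosis center over the
#' stated extent.
#'
#' @param spec A [vessel_spec()].
#' @return An object of class `centerline_tree` with elements `branches`
#'   (list of `points` matrix, `radius` vector, `parent` id, `parent_point`
#'   index, `level`) and `spec`.
#' @export
build_vessel_tree <- function(spec) {
  stopifnot(inherits(spec, "vessel_spec"))
  with_seed(spec$seed, {
    branches <- list()
    # Queue of branches to emit: (parent id, start point, direction, level).
    queue <- list(list(parent = NA_integer_, parent_point = NA_integer_,
                       start = c(0, 0, 0), dir = c(1, 0, 0), level = 1L))
    while (length(queue) > 0L) {
      job <- queue[[1L]]; queue <- queue[-1L]
      lev <- job$level
      len <- spec$root_length * spec$length_ratio^(lev - 1)
      rad <- spec$root_radius * spec$child_ratio^(lev - 1)
      s <- seq(0, len, by = spec$point_spacing)
      if (s[length(s)] < len) s <- c(s, len)
      d <- job$dir / sqrt(sum(job$dir^2))
      u <- perp_vector(d)
      v <- pracma_cross(d, u)
      phase <- runif(1, 0, 2 * pi)
      bend <- spec$bend_amplitude * sin(pi * s / len)
      pts <- outer(s, d) +
        outer(bend * cos(phase), u) + outer(bend * sin(phase), v)
      pts <- sweep(pts, 2, job$start, "+")
      id <- length(branches) + 1L
      branches[[id]] <- list(points = pts, radius = rep(rad, length(s)),
                             parent = job$parent,
                             parent_point = job$parent_point, level = lev,
                             arc = s)
      if (lev < spec$n_levels) {
        # Children leave the parent tip at +/- branch_angle in a randomly
        # oriented plane containing the parent direction.
        tip <- pts[nrow(pts), ]
        az <- if (is.null(spec$azimuth)) runif(1, 0, 2 * pi) else
          spec$azimuth * pi / 180
        w <- cos(az) * u + sin(az) * v
        a <- spec$branch_angle * pi / 180
        for (sgn in c(1, -1)) {
          cd <- cos(a) * d + sgn * sin(a) * w
          queue <- c(queue, list(list(parent = id,
                                      parent_point = nrow(pts),
                                      start = tip, dir = cd,
                                      level = lev + 1L)))
        }
      }
    }
    tree <- structure(list(branches = branches, spec = spec),
                      class = "centerline_tree")
    apply_stenoses(tree, spec$stenoses)
  })
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

apply_stenoses <- function(tree, stenoses) {
  if (nrow(stenoses) == 0L) return(tree)
  if (any(stenoses$branch < 1 | stenoses$branch > length(tree$branches)))
    stop("stenosis branch id out of range")
  for (row in seq_len(nrow(stenoses))) {
    st <- stenoses[row, ]
    b <- tree$branches[[st$branch]]
    s <- b$arc
    s0 <- st$position * s[length(s)]
    w <- abs(s - s0) <= st$extent / 2
    taper <- 0.5 * (1 + cos(2 * pi * (s[w] - s0) / st$extent))
    b$radius[w] <- b$radius[w] * (1 - st$severity * taper)
    tree$branches[[st$branch]] <- b
  }
  tree
}

#' Flatten a centerline tree to a point table
#'
#' @param tree A `centerline_tree`.
#' @return Data frame with columns `branch`, `point_index` (1-based within
#'   branch), `x`, `y`, `z` (mm) and `radius_mm`.
#' @export
tree_points <- function(tree) {
  stopifnot(inherits(tree, "centerline_tree"))
  do.call(rbind, lapply(seq_along(tree$branches), function(b) {
    br <- tree$branches[[b]]
    data.frame(branch = b, point_index = seq_len(nrow(br$points)),
               x = br$points[, 1], y = br$points[, 2], z = br$points[, 3],
               radius_mm = br$radius)
  }))
}

#' Centroid of all centerline points (mm)
#' @param tree A `centerline_tree`.
#' @return Length-3 numeric.
#' @export
tree_center <- function(tree) {
  pts <- tree_points(tree)
  c(mean(pts$x), mean(pts$y), mean(pts$z))
}

tree_bbox <- function(tree) {
  pts <- tree_points(tree)
  rbind(min = c(min(pts$x), min(pts$y), min(pts$z)),
        max = c(max(pts$x), max(pts$y), max(pts$z)))
}

#' Hemodynamic parameters for the resistance-network solver
#'
#' Defaults follow standard coronary simulation practice: 100 mmHg inlet
#' pressure (the mmHg equivalent of 13,330 Pa), blood viscosity 0.04 g/(cm s),
#' an outlet resistance of 1333 Pa s/cm^3 at every terminal branch, and blood
#' density 1.06 g/cm^3 (carried as metadata; the steady 1D solver does not use
#' inertia).
#'
#' @param inlet_pressure Inlet pressure, mmHg.
#' @param viscosity Dynamic viscosity, g/(cm s) (poise).
#' @param outlet_resistance Terminal resistance, Pa s/cm^3. May be `Inf` for
#'   the no-flow limit.
#' @param density Blood density, g/cm^3 (metadata only).
#' @return Object of class `hemo_params`.
#' @export
hemo_params <- function(inlet_pressure = 100, viscosity = 0.04,
                        outlet_resistance = 1333, density = 1.06) {
  if (inlet_pressure <= 0) stop("inlet_pressure must be > 0")
  if (viscosity <= 0) stop("viscosity must be > 0")
  if (outlet_resistance <= 0) stop("outlet_resistance must be > 0")
  structure(list(inlet_pressure = inlet_pressure, viscosity = viscosity,
                 outlet_resistance = outlet_resistance, density = density),
            class = "hemo_params")
}

# Assign one hydraulic node per centerline point, merging each child's first
# point with its parent's attachment point. Returns per-branch node-id vectors
# and the total node count.
tree_node_ids <- function(tree) {
  nb <- length(tree$branches)
  ids <- vector("list", nb)
  nxt <- 0L
  for (b in seq_len(nb)) {
    br <- tree$branches[[b]]
    n <- nrow(br$points)
    v <- integer(n)
    if (is.na(br$parent)) {
      v <- nxt + seq_len(n)
      nxt <- nxt + n
    } else {
      if (br$parent < 1 || br$parent >= b || is.null(ids[[br$parent]]))
        stop("disconnected tree: branch ", b, " has invalid parent")
      v[1] <- ids[[br$parent]][br$parent_point]
      v[-1] <- nxt + seq_len(n - 1L)
      nxt <- nxt + n - 1L
    }
    ids[[b]] <- v
  }
  list(ids = ids, n_nodes = nxt)
}

#' Solve steady pressures on a centerline tree
#'
#' Models each inter-point segment as a Poiseuille resistor,
#' `R = 8 mu L / (pi r^4)` (integrated with the trapezoid rule on `1/r^4`
#' between the endpoint radii), imposes the inlet pressure at the root's
#' first point, attaches `outlet_resistance` from every leaf tip to the zero
#' reference, and solves nodal flow conservation. All internal arithmetic is
#' in mmHg and cm^3/s; resistances are converted from dyn s/cm^5.
#'
#' @param tree A `centerline_tree` (positive radii, connected).
#' @param params A [hemo_params()].
#' @return Object of class `pressure_solution`: `pressure` (list of per-branch
#'   mmHg vectors aligned with the branch points), `node_pressure`,
#'   `segment_flow` (list of per-branch flows, cm^3/s, one per segment),
#'   `outlet_flow`, `inlet_flow`, and the node-id map.
#' @export
solve_pressures <- function(tree, params = hemo_params()) {
  stopifnot(inherits(tree, "centerline_tree"), inherits(params, "hemo_params"))
  for (b in seq_along(tree$branches))
    if (any(tree$branches[[b]]$radius <= 0))
      stop("non-positive radius on branch ", b)
  nodes <- tree_node_ids(tree)
  n <- nodes$n_nodes
  G <- matrix(0, n, n)
  seg_res <- vector("list", length(tree$branches))
  for (b in seq_along(tree$branches)) {
    br <- tree$branches[[b]]
    ids <- nodes$ids[[b]]
    np <- nrow(br$points)
    if (np < 2L) { seg_res[[b]] <- numeric(0); next }
    dl <- sqrt(rowSums((br$points[-1, , drop = FALSE] -
                        br$points[-np, , drop = FALSE])^2)) / 10  # mm -> cm
    r_cm <- br$radius / 10
    inv_r4 <- 0.5 * (1 / r_cm[-np]^4 + 1 / r_cm[-1]^4)
    R_dyn <- 8 * params$viscosity * dl * inv_r4 / pi      # dyn s / cm^5
    R <- R_dyn / DYN_PER_MMHG                             # mmHg s / cm^3
    seg_res[[b]] <- R
    for (k in seq_len(np - 1L)) {
      i <- ids[k]; j <- ids[k + 1L]; g <- 1 / R[k]
      G[i, i] <- G[i, i] + g; G[j, j] <- G[j, j] + g
      G[i, j] <- G[i, j] - g; G[j, i] <- G[j, i] - g
    }
  }
  # Terminal resistances to the zero-pressure reference at leaf tips.
  is_parent <- rep(FALSE, length(tree$branches))
  for (b in seq_along(tree$branches)) {
    p <- tree$branches[[b]]$parent
    if (!is.na(p)) is_parent[p] <- TRUE
  }
  leaves <- which(!is_parent)
  r_out <- params$outlet_resistance * 10 / DYN_PER_MMHG   # Pa s/cm^3 -> mmHg s/cm^3
  g_out <- if (is.finite(r_out)) 1 / r_out else 0
  outlet_nodes <- vapply(leaves, function(b) {
    ids <- nodes$ids[[b]]; ids[length(ids)]
  }, integer(1))
  for (nd in outlet_nodes) G[nd, nd] <- G[nd, nd] + g_out

  inlet_node <- nodes$ids[[1]][1]
  p <- numeric(n)
  p[inlet_node] <- params$inlet_pressure
  free <- setdiff(seq_len(n), inlet_node)
  if (length(free) > 0L) {
    rhs <- -G[free, inlet_node, drop = FALSE] * params$inlet_pressure
    p[free] <- solve(G[free, free, drop = FALSE], rhs)
  }

  pressure <- lapply(seq_along(tree$branches), function(b)
    p[nodes$ids[[b]]])
  segment_flow <- lapply(seq_along(tree$branches), function(b) {
    ids <- nodes$ids[[b]]
    np <- length(ids)
    if (np < 2L) return(numeric(0))
    (p[ids[-np]] - p[ids[-1]]) / seg_res[[b]]
  })
  outlet_flow <- p[outlet_nodes] * g_out
  inlet_flow <- if (length(segment_flow[[1]]) > 0L) segment_flow[[1]][1] else
    sum(outlet_flow)
  structure(list(pressure = pressure, node_pressure = p,
                 segment_flow = segment_flow, outlet_flow = outlet_flow,
                 inlet_flow = inlet_flow, node_ids = nodes$ids,
                 params = params),
            class = "pressure_solution")
}

#' Rasterize a centerline tree into a voxel volume
#'
#' Voxels whose centers lie within the local lumen radius of any centerline
#' point take `lumen_intensity`; the rest take `background_intensity`.
#' Optional Gaussian blur and additive Gaussian noise emulate partial-volume
#' effects and acquisition noise. Intensities are abstract units.
#'
#' @param tree A `centerline_tree` (may have zero branches for a pure
#'   background volume, in which case `dims` and `origin` are required).
#' @param dims Length-3 voxel counts; default fits the tree plus `margin`.
#' @param spacing Isotropic or length-3 voxel size, mm.
#' @param lumen_intensity,background_intensity Intensities, abstract units.
#' @param noise_sd Additive Gaussian noise SD (0 disables).
#' @param blur_sd Gaussian blur SD in mm (0 disables).
#' @param seed Integer seed for the noise draw.
#' @param origin Length-3 world position of voxel `(0,0,0)`; default derived
#'   from the tree bounding box and `margin`.
#' @param margin Margin around the tree when auto-sizing, mm.
#' @param partial_volume If `TRUE`, voxel intensities ramp linearly across
#'   the lumen boundary (coverage `0.5 - (d - r)/spacing`, clamped to
#'   `[0, 1]`), emulating CT partial-volume averaging so sub-voxel lumina
#'   remain visible; the default is a binary mask.
#' @return A [voxel_volume()] in the LPS frame.
#' @export
rasterize_volume <- function(tree, dims = NULL, spacing = 0.5,
                             lumen_intensity = 400, background_intensity = 0,
                             noise_sd = 20, blur_sd = 0, seed = 1L,
                             origin = NULL, margin = 8,
                             partial_volume = FALSE) {
  stopifnot(inherits(tree, "centerline_tree"))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  empty <- length(tree$branches) == 0L
  if (is.null(dims) || is.null(origin)) {
    if (empty) stop("dims and origin are required for an empty tree")
    bb <- tree_bbox(tree)
    if (is.null(origin)) origin <- bb["min", ] - margin
    if (is.null(dims))
      dims <- as.integer(ceiling((bb["max", ] - origin + margin) / spacing)) + 1L
  }
  dims <- as.integer(dims)
  vol <- array(background_intensity, dim = dims)
  if (!empty) {
    pts <- tree_points(tree)
    hi_world <- voxel_to_world(dims - 1, origin, spacing)
    for (b in unique(pts$branch)) {
      pb <- pts[pts$branch == b, ]
      out <- pb$x - pb$radius_mm < origin[1] | pb$x + pb$radius_mm > hi_world[1] |
             pb$y - pb$radius_mm < origin[2] | pb$y + pb$radius_mm > hi_world[2] |
             pb$z - pb$radius_mm < origin[3] | pb$z + pb$radius_mm > hi_world[3]
      if (any(out))
        stop("branch ", b, " exceeds the volume extent; enlarge dims/margin")
    }
    pv_pad <- if (partial_volume) 1L else 0L
    for (row in seq_len(nrow(pts))) {
      ctr <- c(pts$x[row], pts$y[row], pts$z[row])
      r <- pts$radius_mm[row]
      ci <- world_to_local_voxel(ctr, origin, spacing)
      lo <- pmax(floor(ci - r / spacing) + 1 - pv_pad, 1)  # 1-based index
      hi <- pmin(ceiling(ci + r / spacing) + 1 + pv_pad, dims)
      ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
      dx2 <- (origin[1] + (ii - 1) * spacing[1] - ctr[1])^2
      dy2 <- (origin[2] + (jj - 1) * spacing[2] - ctr[2])^2
      dz2 <- (origin[3] + (kk - 1) * spacing[3] - ctr[3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      sub <- vol[ii, jj, kk, drop = FALSE]
      if (partial_volume) {
        cov <- pmin(pmax(0.5 - (sqrt(d2) - r) / mean(spacing), 0), 1)
        val <- background_intensity +
          (lumen_intensity - background_intensity) * cov
        vol[ii, jj, kk] <- pmax(sub, val)
      } else {
        sub[d2 <= r^2] <- lumen_intensity
        vol[ii, jj, kk] <- sub
      }
    }
  }
  if (blur_sd > 0) vol <- gaussian_blur3(vol, blur_sd / spacing)
  if (noise_sd > 0)
    vol <- vol + with_seed(seed, array(rnorm(length(vol), 0, noise_sd),
                                       dim = dims))
  voxel_volume(vol, origin, spacing, "LPS")
}

# Separable Gaussian blur; sigma in voxels per axis.
gaussian_blur3 <- function(a, sigma) {
  d <- dim(a)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- dnorm(-half:half, sd = s)
    kern <- kern / sum(kern)
    out <- array(0, d)
    for (t in seq_along(kern)) {
      off <- t - half - 1L
      src <- pmin(pmax(seq_len(d[ax]) + off, 1L), d[ax])  # replicate edges
      idx <- switch(ax,
                    a[src, , , drop = FALSE],
                    a[, src, , drop = FALSE],
                    a[, , src, drop = FALSE])
      out <- out + kern[t] * idx
    }
    a <- out
  }
  a
}

#' Scatter a pressure point cloud around a centerline
#'
#' Emulates surface/mesh-node pressure samples: each centerline point emits a
#' Poisson-distributed number of cloud points (rate `density` per mm of local
#' centerline length), each inheriting the pressure of its generating
#' centerline point and jittered isotropically with SD `jitter_sd`.
#'
#' @param tree A `centerline_tree`.
#' @param pressures A [solve_pressures()] result, or a list of per-branch
#'   pressure vectors (one value per centerline point).
#' @param density Expected points per mm of centerline; must be > 0.
#' @param jitter_sd Isotropic jitter SD, mm (0 places points exactly on the
#'   centerline).
#' @param seed Integer seed.
#' @return Object of class `pressure_cloud`: `points` (n x 3 mm), `pressure`
#'   (mmHg), `field_name` (`"avg_pressure_mmHg"`).
#' @export
scatter_pressure_cloud <- function(tree, pressures, density = 5,
                                   jitter_sd = 0.3, seed = 1L) {
  stopifnot(inherits(tree, "centerline_tree"))
  if (density <= 0) stop("density must be > 0")
  if (inherits(pressures, "pressure_solution")) pressures <- pressures$pressure
  if (length(pressures) != length(tree$branches))
    stop("need one pressure vector per branch")
  with_seed(seed, {
    pts_out <- list(); prs_out <- list()
    for (b in seq_along(tree$branches)) {
      br <- tree$branches[[b]]
      np <- nrow(br$points)
      if (length(pressures[[b]]) != np)
        stop("branch ", b, ": need one pressure per centerline point")
      # Local length attributed to each point: half of adjacent segments.
      dl <- sqrt(rowSums((br$points[-1, , drop = FALSE] -
                          br$points[-np, , drop = FALSE])^2))
      wl <- c(dl / 2, 0) + c(0, dl / 2)
      counts <- rpois(np, density * wl)
      tot <- sum(counts)
      if (tot == 0L) next
      base <- br$points[rep(seq_len(np), counts), , drop = FALSE]
      jit <- if (jitter_sd > 0)
        matrix(rnorm(3 * tot, 0, jitter_sd), ncol = 3) else 0
      pts_out[[length(pts_out) + 1L]] <- base + jit
      prs_out[[length(prs_out) + 1L]] <- rep(pressures[[b]], counts)
    }
    points <- if (length(pts_out)) do.call(rbind, pts_out) else
      matrix(numeric(0), ncol = 3)
    pressure <- if (length(prs_out)) unlist(prs_out) else numeric(0)
    stopifnot(all(is.finite(pressure)))
    structure(list(points = unname(points), pressure = pressure,
                   field_name = "avg_pressure_mmHg"),
              class = "pressure_cloud")
  })
}

default_spec_ranges <- function() {
  list(n_levels = 3L, root_radius = c(1.6, 2.0), root_length = c(22, 26),
       length_ratio = 0.75, branch_angle = 35, bend_amplitude = c(0.5, 1.5),
       n_stenoses = c(1L, 2L), severity = c(0.35, 0.75), extent = c(3, 6),
       position = c(0.2, 0.8), point_spacing = 0.75, azimuth = NULL,
       index_branches = NULL, index_severity = NULL)
}

#' Generate a reproducible set of synthetic cases
#'
#' Draws one [vessel_spec()] per case from `spec_ranges`, builds the tree,
#' solves the pressure field, rasterizes the volume and scatters the pressure
#' cloud. Per-case seeds are `seed + case_index`, recorded in the manifest
#' together with every drawn specification, so the same master seed
#' reproduces the set exactly.
#'
#' @param n_cases Number of cases (>= 1).
#' @param spec_ranges Named list overriding entries of the default ranges:
#'   `n_levels`, `root_radius`, `root_length`, `bend_amplitude`,
#'   `n_stenoses`, `severity`, `extent`, `position` (ranges are
#'   `c(min, max)`), `point_spacing`.
#' @param seed Master integer seed.
#' @param hemo A [hemo_params()].
#' @param raster Named list of [rasterize_volume()] overrides (e.g.
#'   `spacing`, `noise_sd`).
#' @param cloud Named list of [scatter_pressure_cloud()] overrides.
#' @return Object of class `case_set`: `cases` (list of `case_id`, `seed`,
#'   `tree`, `solution`, `volume`, `cloud`) and `manifest`.
#' @export
generate_case_set <- function(n_cases, spec_ranges = list(), seed = 1L,
                              hemo = hemo_params(), raster = list(),
                              cloud = list()) {
  if (n_cases < 1) stop("n_cases must be >= 1")
  rng <- modifyList(default_spec_ranges(), spec_ranges)
  draw <- function(r) if (length(r) == 2L) runif(1, r[1], r[2]) else r
  cases <- vector("list", n_cases)
  manifest_cases <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    case_seed <- as.integer(seed + i)
    spec <- with_seed(case_seed, {
      n_st <- if (length(rng$n_stenoses) == 2L)
        sample(rng$n_stenoses[1]:rng$n_stenoses[2], 1L) else rng$n_stenoses
      n_branch <- 2^rng$n_levels - 1
      st <- if (n_st > 0) data.frame(
        branch = sample(seq_len(n_branch), n_st, replace = FALSE),
        position = runif(n_st, rng$position[1], rng$position[2]),
        severity = runif(n_st, rng$severity[1], rng$severity[2]),
        extent = runif(n_st, rng$extent[1], rng$extent[2])) else NULL
      # optional index lesion: every case carries one hemodynamically
      # significant proximal stenosis, as in cohorts enrolled on a minimum
      # stenosis grade
      if (!is.null(rng$index_severity)) {
        idx <- data.frame(
          branch = if (length(rng$index_branches) > 1L)
            sample(rng$index_branches, 1L) else rng$index_branches %||% 1L,
          position = runif(1, rng$position[1], rng$position[2]),
          severity = runif(1, rng$index_severity[1], rng$index_severity[2]),
          extent = runif(1, rng$extent[1], rng$extent[2]))
        st <- if (is.null(st)) idx else rbind(idx, st[st$branch != idx$branch,
                                                      , drop = FALSE])
      }
      vessel_spec(n_levels = rng$n_levels, root_radius = draw(rng$root_radius),
                  root_length = draw(rng$root_length),
                  length_ratio = draw(rng$length_ratio),
                  branch_angle = draw(rng$branch_angle),
                  bend_amplitude = draw(rng$bend_amplitude), stenoses = st,
                  point_spacing = rng$point_spacing, seed = case_seed,
                  azimuth = rng$azimuth)
    })
    tree <- build_vessel_tree(spec)
    sol <- solve_pressures(tree, hemo)
    vol <- do.call(rasterize_volume,
                   c(list(tree = tree, seed = case_seed), raster))
    cld <- do.call(scatter_pressure_cloud,
                   c(list(tree = tree, pressures = sol, seed = case_seed),
                     cloud))
    cases[[i]] <- list(case_id = sprintf("case_%03d", i), seed = case_seed,
                       tree = tree, solution = sol, volume = vol, cloud = cld)
    sp_list <- spec_to_list(spec)
    sp_list$seed <- NULL  # already recorded as the per-case seed
    manifest_cases[[i]] <- c(list(case_id = cases[[i]]$case_id,
                                  seed = case_seed), sp_list)
  }
  manifest <- list(master_seed = as.integer(seed), n_cases = n_cases,
                   hemo = unclass(hemo), cases = manifest_cases)
  structure(list(cases = cases, manifest = manifest), class = "case_set")
}

spec_to_list <- function(spec) {
  out <- unclass(spec)
  out$stenoses <- if (nrow(spec$stenoses)) spec$stenoses else NULL
  out
}

#' Assign ordered train/validation/test splits
#'
#' Cases are assigned in order: the first `counts[1]` to train, the next
#' `counts[2]` to validation, the remaining `counts[3]` to test (mirroring
#' ordered scan-count protocols such as 40/5/10).
#'
#' @param n_cases Number of cases.
#' @param counts Length-3 integer vector `c(train, val, test)`; must sum to
#'   `n_cases`.
#' @return Character vector of `"train"`, `"val"`, `"test"` per case.
#' @export
assign_splits <- function(n_cases, counts) {
  stopifnot(length(counts) == 3L)
  if (sum(counts) != n_cases)
    stop("split counts must sum to n_cases")
  rep(c("train", "val", "test"), times = counts)
}

#' Write a case set to disk
#'
#' Volumes as NIfTI, centerlines as CSV (`branch_id`, `point_index`, `x`,
#' `y`, `z`, `radius_mm`) with a JSON topology sidecar, pressure clouds as
#' CSV (`x`, `y`, `z`, `avg_pressure_mmHg`), and the manifest as JSON.
#'
#' @param case_set A [generate_case_set()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case_set <- function(case_set, dir) {
  stopifnot(inherits(case_set, "case_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cs in case_set$cases) {
    base <- file.path(dir, cs$case_id)
    write_volume_nifti(cs$volume, paste0(base, "_volume.nii.gz"))
    pts <- tree_points(cs$tree)
    names(pts)[1] <- "branch_id"
    pts$pressure_mmhg <- unlist(cs$solution$pressure)
    write.csv(pts, paste0(base, "_centerline.csv"), row.names = FALSE)
    topo <- lapply(cs$tree$branches, function(b)
      list(parent = if (is.na(b$parent)) NULL else b$parent,
           parent_point = if (is.na(b$parent)) NULL else b$parent_point,
           level = b$level))
    jsonlite::write_json(topo, paste0(base, "_topology.json"),
                         auto_unbox = TRUE, null = "null")
    cl <- data.frame(x = cs$cloud$points[, 1], y = cs$cloud$points[, 2],
                     z = cs$cloud$points[, 3])
    cl[[cs$cloud$field_name]] <- cs$cloud$pressure
    write.csv(cl, paste0(base, "_pressure_cloud.csv"), row.names = FALSE)
  }
  jsonlite::write_json(case_set$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12, null = "null")
  invisible(dir)
}

#' Read a case set written by [write_case_set()]
#'
#' Reconstructs volumes, centerline trees (with topology), pressure fields
#' and clouds from the on-disk NIfTI/CSV/JSON layout.
#'
#' @param dir Directory written by [write_case_set()].
#' @return A `case_set` (the `solution` carries only the per-point
#'   pressures, not flows).
#' @export
read_case_set <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ids <- vapply(manifest$cases, function(x) x$case_id, character(1))
  cases <- lapply(ids, function(id) {
    base <- file.path(dir, id)
    vol <- read_volume_nifti(paste0(base, "_volume.nii.gz"))
    ctl <- read.csv(paste0(base, "_centerline.csv"))
    topo <- jsonlite::read_json(paste0(base, "_topology.json"))
    branches <- lapply(seq_along(topo), function(b) {
      rows <- ctl[ctl$branch_id == b, ]
      pts <- as.matrix(rows[, c("x", "y", "z")])
      dimnames(pts) <- NULL
      s <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
      list(points = pts, radius = rows$radius_mm,
           parent = topo[[b]]$parent %||% NA_integer_,
           parent_point = topo[[b]]$parent_point %||% NA_integer_,
           level = topo[[b]]$level, arc = s)
    })
    tree <- structure(list(branches = branches, spec = NULL),
                      class = "centerline_tree")
    pressure <- lapply(seq_along(branches), function(b)
      ctl$pressure_mmhg[ctl$branch_id == b])
    cl <- read.csv(paste0(base, "_pressure_cloud.csv"))
    cloud <- structure(list(points = unname(as.matrix(cl[, c("x", "y", "z")])),
                            pressure = cl[[4]],
                            field_name = names(cl)[4]),
                       class = "pressure_cloud")
    list(case_id = id, tree = tree, volume = vol, cloud = cloud,
         solution = structure(list(pressure = pressure),
                              class = "pressure_solution"))
  })
  structure(list(cases = cases, manifest = manifest), class = "case_set")
}
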