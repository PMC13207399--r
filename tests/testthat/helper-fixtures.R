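# Shared fixtures, built in code.

# A hand-constructed single-branch straight tube along +x (no RNG involved).
make_tube_tree <- function(length_mm = 10, radius_mm = 2, spacing_mm = 1) {
  spec <- vessel_spec(n_levels = 1L, root_radius = radius_mm,
                      root_length = length_mm, bend_amplitude = 0,
                      point_spacing = spacing_mm, seed = 1L)
  build_vessel_tree(spec)
}

# Uniform pressure field matching a tree's point layout.
uniform_pressures <- function(tree, value = 100) {
  lapply(tree$branches, function(b) rep(value, nrow(b$points)))
}

# Small deterministic pressure cloud from explicit points.
as_pressure_cloud <- function(points, pressure) {
  structure(list(points = as.matrix(points), pressure = pressure,
                 field_name = "avg_pressure_mmHg"),
            class = "pressure_cloud")
}

# Independent triple-loop patch copy oracle (0-based center index).
patch_oracle <- function(vol, ctr, size = 28L, pad = 0) {
  half <- size %/% 2L
  out <- array(pad, rep(size, 3L))
  d <- dim(vol)
  for (a in 0:(size - 1L)) for (b in 0:(size - 1L)) for (cc in 0:(size - 1L)) {
    src <- c(ctr[1] - half + a, ctr[2] - half + b, ctr[3] - half + cc)
    if (all(src >= 0) && all(src < d))
      out[a + 1L, b + 1L, cc + 1L] <- vol[src[1] + 1L, src[2] + 1L,
                                          src[3] + 1L]
  }
  out
}

# Tiny case set reused by dataset/training tests (built once per test run).
tiny_case_set <- function(n = 2, seed = 77) {
  generate_case_set(n, spec_ranges = list(n_levels = 2L,
                                          point_spacing = 1.5,
                                          root_length = c(14, 16)),
                    seed = seed,
                    raster = list(spacing = 0.8, noise_sd = 10))
}

# Minimal trainable dataset: small patches via a shrunken patch size.
tiny_dataset <- function(n = 2, seed = 77, patch_size = 12L) {
  cs <- tiny_case_set(n, seed)
  splits <- if (n >= 3) c("train", "val", rep("test", n - 2)) else
    rep("train", n)
  build_dataset(cs, splits, patch_size = patch_size)
}
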