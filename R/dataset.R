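# Patch-based dataset construction: iterate along every centerline, extract a
# 28x28x28 patch centered at each point (via the world -> voxel transform) and
# label it with the average cloud pressure within a 5 mm radius of the point.

#' Extract a cubic patch centered on a voxel index
#'
#' The patch is positioned so the (rounded) center index sits at patch
#' position `size %/% 2` (0-based; `(14,14,14)` for the default size 28).
#' Voxels falling outside the volume are filled with `pad_value`.
#'
#' @param volume A [voxel_volume()] or a rank-3 array.
#' @param center_index Length-3 voxel index (0-based; continuous values are
#'   rounded with [round_voxel_index()]).
#' @param size Patch edge length in voxels.
#' @param pad_value Fill value for out-of-volume voxels.
#' @return A `size^3` array. Errors (class `coroflow_patch_error`) if the
#'   center itself lies outside the volume.
#' @export
extract_patch <- function(volume, center_index, size = 28L, pad_value = 0) {
  dat <- if (inherits(volume, "voxel_volume")) volume$data else volume
  stopifnot(is.array(dat), length(dim(dat)) == 3L, length(center_index) == 3L)
  d <- dim(dat)
  ctr <- round_voxel_index(as.numeric(center_index))
  if (any(ctr < 0) || any(ctr > d - 1))
    stop(structure(class = c("coroflow_patch_error", "error", "condition"),
                   list(message = sprintf(
                     "patch center (%s) outside volume of dims (%s)",
                     paste(ctr, collapse = ","), paste(d, collapse = ",")),
                     call = sys.call(-1))))
  half <- size %/% 2L
  lo <- ctr - half                # 0-based inclusive
  hi <- ctr + (size - half) - 1L
  patch <- array(pad_value, dim = rep(size, 3L))
  src_lo <- pmax(lo, 0L); src_hi <- pmin(hi, d - 1L)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - lo + 1L; dst_hi <- src_hi - lo + 1L
    patch[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      dat[(src_lo[1] + 1L):(src_hi[1] + 1L),
          (src_lo[2] + 1L):(src_hi[2] + 1L),
          (src_lo[3] + 1L):(src_hi[3] + 1L)]
  }
  patch
}

#' Average cloud pressure around a point
#'
#' Arithmetic mean of all cloud pressures within Euclidean distance `r`
#' (closed ball: a point at exactly `r` is included) of the query point. If no
#' cloud point lies within `r`, the mean of the `k_fallback` nearest points is
#' returned and the result is flagged via the `"fallback"` attribute.
#'
#' @param cloud A `pressure_cloud`.
#' @param center Length-3 world point (mm).
#' @param r Labeling radius, mm.
#' @param k_fallback Number of nearest neighbours for the empty-ball fallback.
#' @return The label in mmHg, with attribute `fallback` (logical).
#' @export
label_pressure <- function(cloud, center, r = 5, k_fallback = 5L) {
  stopifnot(inherits(cloud, "pressure_cloud"), length(center) == 3L, r > 0)
  n <- nrow(cloud$points)
  if (n == 0L) stop("pressure cloud is empty")
  d2 <- (cloud$points[, 1] - center[1])^2 +
        (cloud$points[, 2] - center[2])^2 +
        (cloud$points[, 3] - center[3])^2
  inside <- d2 <= r^2
  if (any(inside)) {
    structure(mean(cloud$pressure[inside]), fallback = FALSE)
  } else {
    k <- min(k_fallback, n)
    nn <- order(d2)[seq_len(k)]
    structure(mean(cloud$pressure[nn]), fallback = TRUE)
  }
}

#' Build a paired patch/pressure dataset from synthetic cases
#'
#' Iterates along every centerline of every case, extracts a patch centered
#' at each point (intensities windowed to `intensity_window` then scaled to
#' `[0, 1]`) and computes the pressure label with [label_pressure()]. Labels
#' are standardized (z-score) with the mean and SD of the *training* split
#' only; patch-center coordinates are standardized the same way. Both sets of
#' constants are stored in the manifest so predictions can be mapped back to
#' mmHg exactly.
#'
#' @param cases A `case_set` or a list of case lists (`volume`, `tree`,
#'   `cloud`, `case_id`).
#' @param splits Character vector (`"train"`/`"val"`/`"test"`) per case, e.g.
#'   from [assign_splits()].
#' @param r Labeling radius, mm.
#' @param intensity_window Length-2 intensity window mapped to `[0, 1]`.
#' @param seed Integer seed (recorded; the builder itself is deterministic).
#' @param patch_size Patch edge length, voxels.
#' @return Object of class `patch_dataset` with per-split containers
#'   (`patches` as a `(patch_size^3) x n` matrix, `labels_mmhg`,
#'   `labels_std`, `coords` `n x 3` mm, `coords_std`, `case`, `branch`,
#'   `point_index`, `fallback`), a `manifest`, and a `skipped` log.
#' @export
build_dataset <- function(cases, splits, r = 5, intensity_window = c(0, 500),
                          seed = 1L, patch_size = 28L) {
  if (inherits(cases, "case_set")) cases <- cases$cases
  if (length(splits) != length(cases))
    stop("need one split assignment per case")
  if (!all(splits %in% c("train", "val", "test")))
    stop("splits must be 'train', 'val' or 'test'")
  if (!any(splits == "train"))
    stop("configuration error: empty training split")
  w <- as.numeric(intensity_window)
  stopifnot(length(w) == 2L, w[2] > w[1])

  acc <- list(train = list(), val = list(), test = list())
  skipped <- list()
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    vol <- cs$volume
    pts <- tree_points(cs$tree)
    idx_cont <- world_to_local_voxel(as.matrix(pts[, c("x", "y", "z")]), vol)
    n_pts <- nrow(pts)
    pat <- matrix(NA_real_, patch_size^3, n_pts)
    lab <- numeric(n_pts); fb <- logical(n_pts); keep <- logical(n_pts)
    for (m in seq_len(n_pts)) {
      p <- tryCatch(
        extract_patch(vol, idx_cont[m, ], size = patch_size),
        coroflow_patch_error = function(e) e)
      if (inherits(p, "condition")) {
        skipped[[length(skipped) + 1L]] <- data.frame(
          case = cs$case_id, branch = pts$branch[m],
          point_index = pts$point_index[m], reason = conditionMessage(p))
        next
      }
      pw <- (pmin(pmax(p, w[1]), w[2]) - w[1]) / (w[2] - w[1])
      y <- label_pressure(cs$cloud, c(pts$x[m], pts$y[m], pts$z[m]), r = r)
      pat[, m] <- as.vector(pw)
      lab[m] <- as.numeric(y)
      fb[m] <- attr(y, "fallback")
      keep[m] <- TRUE
    }
    if (!any(keep)) next
    sp <- splits[ci]
    acc[[sp]][[length(acc[[sp]]) + 1L]] <- list(
      patches = pat[, keep, drop = FALSE], labels = lab[keep],
      coords = as.matrix(pts[keep, c("x", "y", "z")]),
      case = rep(cs$case_id, sum(keep)), branch = pts$branch[keep],
      point_index = pts$point_index[keep], fallback = fb[keep])
  }

  bind_split <- function(lst) {
    if (length(lst) == 0L)
      return(list(patches = matrix(numeric(0), patch_size^3, 0),
                  labels_mmhg = numeric(0),
                  coords = matrix(numeric(0), 0, 3), case = character(0),
                  branch = integer(0), point_index = integer(0),
                  fallback = logical(0)))
    list(patches = do.call(cbind, lapply(lst, `[[`, "patches")),
         labels_mmhg = unlist(lapply(lst, `[[`, "labels")),
         coords = do.call(rbind, lapply(lst, `[[`, "coords")),
         case = unlist(lapply(lst, `[[`, "case")),
         branch = unlist(lapply(lst, `[[`, "branch")),
         point_index = unlist(lapply(lst, `[[`, "point_index")),
         fallback = unlist(lapply(lst, `[[`, "fallback")))
  }
  out <- lapply(acc, bind_split)

  mu <- mean(out$train$labels_mmhg)
  sdv <- sd(out$train$labels_mmhg)
  if (!is.finite(sdv) || sdv < 1e-8) sdv <- 1  # sd floor: constant labels -> 0
  cmu <- colMeans(out$train$coords)
  csd <- apply(out$train$coords, 2, sd)
  csd[!is.finite(csd) | csd < 1e-8] <- 1
  for (sp in names(out)) {
    out[[sp]]$labels_std <- (out[[sp]]$labels_mmhg - mu) / sdv
    out[[sp]]$coords_std <-
      sweep(sweep(out[[sp]]$coords, 2, cmu), 2, csd, "/")
  }
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(case = character(), branch = integer(),
               point_index = integer(), reason = character())

  manifest <- list(r = r, patch_size = as.integer(patch_size),
                   intensity_window = w, seed = as.integer(seed),
                   label_mean = mu, label_sd = sdv,
                   coord_mean = as.numeric(cmu), coord_sd = as.numeric(csd),
                   splits = as.list(table(splits)),
                   n_samples = lapply(out, function(s) length(s$labels_mmhg)),
                   n_skipped = nrow(skipped))
  manifest$hash <- object_hash(manifest)
  structure(c(out, list(manifest = manifest, skipped = skipped)),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat("<patch_dataset> patch", x$manifest$patch_size, "^3, r =",
      x$manifest$r, "mm\n")
  for (sp in c("train", "val", "test"))
    cat(sprintf("  %-5s %d samples\n", sp, length(x[[sp]]$labels_mmhg)))
  if (nrow(x$skipped)) cat("  skipped:", nrow(x$skipped), "points\n")
  invisible(x)
}

#' Map standardized labels back to mmHg
#'
#' Inverts the z-score stored in the dataset manifest.
#' @param dataset A `patch_dataset`.
#' @param y Standardized values.
#' @return Values in mmHg.
#' @export
destandardize_labels <- function(dataset, y) {
  m <- dataset$manifest
  y * m$label_sd + m$label_mean
}

#' Save / load a patch dataset
#'
#' The dataset is written as one RDS container per split plus the JSON
#' manifest.
#' @param dataset A `patch_dataset`.
#' @param dir Output directory.
#' @return `dir` (save) or the `patch_dataset` (load).
#' @export
save_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "patch_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sp in c("train", "val", "test"))
    saveRDS(dataset[[sp]], file.path(dir, paste0(sp, ".rds")))
  saveRDS(dataset$skipped, file.path(dir, "skipped.rds"))
  jsonlite::write_json(dataset$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 12)
  invisible(dir)
}

#' @rdname save_dataset
#' @param dir Directory written by [save_dataset()].
#' @export
load_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out <- lapply(c(train = "train", val = "val", test = "test"),
                function(sp) readRDS(file.path(dir, paste0(sp, ".rds"))))
  out$manifest <- manifest
  out$skipped <- readRDS(file.path(dir, "skipped.rds"))
  structure(out, class = "patch_dataset")
}
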