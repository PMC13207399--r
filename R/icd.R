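# Inverted conditional diffusion: the scalar label (centerline pressure, in
# standardized units) is diffused with a forward Gaussian Markov chain, and a
# conditional denoiser — conditioned on fused imaging and coordinate
# embeddings — learns the reverse transitions used for regression at
# inference time.

#' Build a diffusion noise schedule
#'
#' Precomputes the per-step noise variances `beta_t`, `alpha_t = 1 - beta_t`,
#' the cumulative products `alpha_bar_t`, and the reverse-process posterior
#' variances `sigma_t^2 = (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) * beta_t`
#' (with `alpha_bar_0 = 1`, so `sigma_1^2 = 0`).
#'
#' @param T Number of diffusion steps, in `[1, 1000]`.
#' @param beta_start,beta_end Linear schedule endpoints, `0 < start <= end
#'   < 1`.
#' @param kind Schedule type; only `"linear"` is provided.
#' @return Object of class `noise_schedule` with fields `T`, `beta`, `alpha`,
#'   `alpha_bar`, `alpha_bar_prev`, `sigma2`.
#' @export
make_schedule <- function(T = 1000L, beta_start = 1e-4, beta_end = 0.02,
                          kind = "linear") {
  kind <- match.arg(kind, "linear")
  T <- as.integer(T)
  if (T < 1L || T > 1000L) stop("T must lie in [1, 1000]")
  if (!(beta_start > 0 && beta_start <= beta_end && beta_end < 1))
    stop("need 0 < beta_start <= beta_end < 1")
  beta <- if (T == 1L) beta_start else seq(beta_start, beta_end,
                                           length.out = T)
  alpha <- 1 - beta
  alpha_bar <- cumprod(alpha)
  alpha_bar_prev <- c(1, alpha_bar[-T])
  sigma2 <- (1 - alpha_bar_prev) / (1 - alpha_bar) * beta
  structure(list(T = T, beta = beta, alpha = alpha, alpha_bar = alpha_bar,
                 alpha_bar_prev = alpha_bar_prev, sigma2 = sigma2,
                 beta_start = beta_start, beta_end = beta_end, kind = kind),
            class = "noise_schedule")
}

check_t <- function(t, schedule) {
  if (any(t < 1L) || any(t > schedule$T))
    stop("t out of range [1, ", schedule$T, "]")
  as.integer(t)
}

#' Forward diffusion marginal
#'
#' Closed-form sample of the forward chain at step `t`:
#' `y_t = sqrt(alpha_bar_t) * y0 + sqrt(1 - alpha_bar_t) * eps`.
#'
#' @param y0 Clean values (standardized units).
#' @param t Step index (scalar or vector matching `y0`).
#' @param eps Standard-normal noise, same shape as `y0`.
#' @param schedule A [make_schedule()] result.
#' @return `y_t`, same shape as `y0`.
#' @export
forward_sample <- function(y0, t, eps, schedule) {
  t <- check_t(t, schedule)
  ab <- schedule$alpha_bar[t]
  sqrt(ab) * y0 + sqrt(1 - ab) * eps
}

#' Recover the injected noise from a forward sample
#'
#' Exactly inverts [forward_sample()]:
#' `eps = (y_t - sqrt(alpha_bar_t) * y0) / sqrt(1 - alpha_bar_t)` — the
#' quantity the denoising network is trained to predict.
#'
#' @inheritParams forward_sample
#' @param y_t Noised values at step `t`.
#' @return The noise `eps`.
#' @export
noise_target <- function(y0, y_t, t, schedule) {
  t <- check_t(t, schedule)
  ab <- schedule$alpha_bar[t]
  if (any(1 - ab <= .Machine$double.eps))
    stop("noise target undefined: alpha_bar is 1 at the requested step")
  (y_t - sqrt(ab) * y0) / sqrt(1 - ab)
}

#' Reverse-process posterior variance
#'
#' `sigma_t^2 = (1 - alpha_bar_{t-1}) / (1 - alpha_bar_t) * beta_t`, with
#' `alpha_bar_0 = 1` so `sigma_1^2 = 0`.
#' @inheritParams forward_sample
#' @return `sigma_t^2` for each requested step.
#' @export
posterior_variance <- function(t, schedule) {
  t <- check_t(t, schedule)
  schedule$sigma2[t]
}

#' One reverse diffusion step
#'
#' `y_{t-1} = (y_t - beta_t / sqrt(1 - alpha_bar_t) * eps_hat) /
#' sqrt(alpha_t) + sigma_t * z`. At `t = 1` the stochastic term must vanish
#' (`z = 0`); a nonzero `z` there is a contract violation.
#'
#' @inheritParams forward_sample
#' @param y_t Current state.
#' @param eps_hat Predicted noise.
#' @param z Standard-normal draw (0 at `t = 1`).
#' @return `y_{t-1}`.
#' @export
reverse_step <- function(y_t, t, eps_hat, z, schedule) {
  t <- check_t(t, schedule)
  if (length(t) != 1L) stop("reverse_step takes a single step index")
  if (t == 1L && any(z != 0))
    stop("contract violation: z must be 0 at t = 1")
  ab <- schedule$alpha_bar[t]
  (y_t - schedule$beta[t] / sqrt(1 - ab) * eps_hat) /
    sqrt(schedule$alpha[t]) + sqrt(schedule$sigma2[t]) * z
}

#' Run a full reverse chain with an arbitrary noise predictor
#'
#' Diagnostic utility: starts chains at `y_T` (drawn `N(0, 1)` unless given)
#' and applies [reverse_step()] from `t = T` down to 1, querying
#' `eps_fn(y_t, t)` for the noise estimate. With the analytic noise function
#' of a fixed `y0`, the chain terminates at exactly `y0` regardless of the
#' `z` draws, because the `t = 1` update cancels `y_1` algebraically.
#'
#' @param eps_fn Function `(y_t, t) -> eps_hat`, vectorized over `y_t`.
#' @param schedule A [make_schedule()] result.
#' @param n Number of chains.
#' @param seed Integer seed for `y_T` and the `z` draws.
#' @param y_T Optional starting values (length `n`).
#' @return Numeric vector of length `n`: the denoised samples.
#' @export
reverse_chain <- function(eps_fn, schedule, n = 1L, seed = 1L, y_T = NULL) {
  with_seed(seed, {
    y <- if (is.null(y_T)) rnorm(n) else rep_len(y_T, n)
    for (t in schedule$T:1) {
      z <- if (t > 1L) rnorm(n) else numeric(n)
      y <- reverse_step(y, t, eps_fn(y, t), z, schedule)
    }
    y
  })
}

#' Initialize an inverted conditional diffusion model
#'
#' The model couples a 3D convolutional patch encoder (three strided
#' conv + batch-norm + ReLU blocks projected to a 128-dimensional embedding),
#' a linear coordinate encoder (default 3 dimensions), and a denoising MLP
#' (two hidden ReLU layers, scalar linear head) that takes the noised label,
#' a sinusoidal timestep embedding and the fused condition.
#'
#' @param schedule A [make_schedule()] result.
#' @param patch_size Patch edge length, voxels.
#' @param channels Encoder channel widths (length 3).
#' @param image_emb_dim Patch embedding dimension.
#' @param coord_emb_dim Coordinate embedding dimension.
#' @param hidden_dim Denoiser hidden width.
#' @param time_emb_dim Sinusoidal timestep embedding dimension.
#' @param seed Integer seed for parameter initialization.
#' @return Object of class `icd_model` (untrained).
#' @export
icd_model <- function(schedule = make_schedule(), patch_size = 28L,
                      channels = c(8L, 16L, 32L), image_emb_dim = 128L,
                      coord_emb_dim = 3L, hidden_dim = 128L,
                      time_emb_dim = 64L, seed = 1L) {
  stopifnot(inherits(schedule, "noise_schedule"))
  with_seed(seed, {
    enc <- encoder_init(patch_size, as.integer(channels),
                        as.integer(image_emb_dim))
    params <- enc$params
    params[["coord.W"]] <- he_init(coord_emb_dim, 3L, 3L)
    params[["coord.b"]] <- numeric(coord_emb_dim)
    cond_dim <- image_emb_dim + coord_emb_dim
    in_dim <- 1L + time_emb_dim + cond_dim
    params <- c(params, mlp_init(c(in_dim, hidden_dim, hidden_dim, 1L),
                                 "den"))
    structure(list(
      schedule = schedule, params = params, running = enc$running,
      enc = enc[c("channels", "cin", "geom", "patch_size", "emb_dim")],
      temb = time_embedding_table(schedule$T, time_emb_dim),
      config = list(patch_size = as.integer(patch_size),
                    channels = as.integer(channels),
                    image_emb_dim = as.integer(image_emb_dim),
                    coord_emb_dim = as.integer(coord_emb_dim),
                    hidden_dim = as.integer(hidden_dim),
                    time_emb_dim = as.integer(time_emb_dim),
                    seed = as.integer(seed)),
      trained = FALSE), class = "icd_model")
  })
}

as_patch_matrix <- function(patches, patch_size) {
  if (is.matrix(patches)) {
    if (nrow(patches) != patch_size^3)
      stop("patch matrix must have patch_size^3 rows")
    return(patches)
  }
  d <- dim(patches)
  if (is.null(d) || !length(d) %in% c(3L, 4L) ||
      any(d[1:3] != patch_size))
    stop("patches must be ", patch_size, "^3 arrays")
  matrix(patches, nrow = patch_size^3)
}

#' Encode image patches
#'
#' Runs the convolutional encoder in evaluation mode (batch-norm uses running
#' statistics, so identical inputs give identical embeddings).
#'
#' @param model An `icd_model` (or `cm_model`).
#' @param patches A single `28^3` array, a `28 x 28 x 28 x n` array, or a
#'   `(28^3) x n` matrix.
#' @return `image_emb_dim x n` embedding matrix.
#' @export
encode_patch <- function(model, patches) {
  X <- as_patch_matrix(patches, model$enc$patch_size)
  encoder_forward(model$enc, model$params, model$running, X,
                  train = FALSE)$emb
}

#' Encode centerline coordinates
#'
#' Lightweight linear map of the (standardized) patch-center coordinates into
#' a low-dimensional geometric embedding.
#'
#' @param model An `icd_model`.
#' @param coords Length-3 vector or `3 x n` matrix (or `n x 3`, transposed
#'   automatically when unambiguous).
#' @return `coord_emb_dim x n` embedding matrix.
#' @export
encode_coords <- function(model, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, nrow = 3L)
  if (nrow(coords) != 3L && ncol(coords) == 3L) coords <- t(coords)
  stopifnot(all(is.finite(coords)), nrow(coords) == 3L)
  model$params[["coord.W"]] %*% coords +
    model$params[["coord.b"]]
}

#' Fuse image and coordinate embeddings into the condition
#'
#' Concatenates the two blocks, image block first; the fused length is
#' asserted to equal the sum of the parts.
#'
#' @param image_emb `d_img x n` matrix.
#' @param coord_emb `d_coord x n` matrix.
#' @return `(d_img + d_coord) x n` condition matrix.
#' @export
fuse_condition <- function(image_emb, coord_emb) {
  if (is.null(image_emb) || is.null(coord_emb))
    stop("both embeddings are required")
  image_emb <- as.matrix(image_emb)
  coord_emb <- as.matrix(coord_emb)
  if (ncol(image_emb) != ncol(coord_emb))
    stop("embedding batch sizes differ")
  out <- rbind(image_emb, coord_emb)
  stopifnot(nrow(out) == nrow(image_emb) + nrow(coord_emb))
  out
}

# Denoiser forward: y_t (length B), tvec (length B), cond (dim x B).
denoiser_forward <- function(model, y_t, tvec, cond) {
  X <- rbind(matrix(y_t, nrow = 1L), t(model$temb[tvec, , drop = FALSE]),
             cond)
  mlp_forward(model$params, "den", 3L, X)
}

#' Sample predictions from a trained ICD model
#'
#' Runs the learned reverse chain (Algorithm-style DDPM sampling) from
#' `y_T ~ N(0, 1)` for `n_chains` chains per condition and returns the
#' per-condition chain mean, in standardized label units.
#'
#' @param model A trained `icd_model`.
#' @param cond Condition matrix from [fuse_condition()] (`cond_dim x n`).
#' @param n_chains Number of reverse chains averaged per condition.
#' @param seed Integer seed; the whole procedure is reproducible.
#' @param clip_y0 Length-2 bounds on the implied clean label during
#'   sampling, in standardized units. At each step the denoised estimate
#'   `y0_hat = (y_t - sqrt(1 - ab_t) eps_hat) / sqrt(ab_t)` is clamped to
#'   this interval and the noise estimate recomputed — the standard
#'   clipped-denoised stabilization, preventing imperfect noise predictions
#'   from being amplified through the chain. `NULL` disables.
#' @return Numeric vector of length `n` (standardized units).
#' @export
icd_sample <- function(model, cond, n_chains = 10L, seed = 1L,
                       clip_y0 = c(-4, 4)) {
  stopifnot(inherits(model, "icd_model"))
  if (!isTRUE(model$trained))
    stop("model is untrained; fit it with train_icd() first")
  icd_reverse_mean(model, cond, n_chains, seed, clip_y0)
}

# Reverse-chain mean without the trained-flag guard (used during training
# for validation-based checkpoint selection).
icd_reverse_mean <- function(model, cond, n_chains, seed, clip_y0) {
  n <- ncol(cond)
  B <- n * n_chains
  cond_rep <- cond[, rep(seq_len(n), each = n_chains), drop = FALSE]
  sched <- model$schedule
  with_seed(seed, {
    y <- rnorm(B)
    for (t in sched$T:1) {
      eps_hat <- as.numeric(
        denoiser_forward(model, y, rep.int(t, B), cond_rep)$out)
      if (!is.null(clip_y0)) {
        ab <- sched$alpha_bar[t]
        y0_hat <- (y - sqrt(1 - ab) * eps_hat) / sqrt(ab)
        y0_hat <- pmin(pmax(y0_hat, clip_y0[1]), clip_y0[2])
        eps_hat <- (y - sqrt(ab) * y0_hat) / sqrt(1 - ab)
      }
      z <- if (t > 1L) rnorm(B) else numeric(B)
      y <- reverse_step(y, t, eps_hat, z, sched)
    }
    colMeans(matrix(y, nrow = n_chains))
  })
}
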