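# Internal neural-network plumbing: layer geometry for strided 3D
# convolutions (the heavy kernels live in src/convnet.cpp), dense layers,
# sinusoidal time embeddings and an Adam optimizer with decoupled weight
# decay. Parameters live in flat named lists of matrices/vectors so the
# optimizer can walk them generically.

# Neighbour table for a k^3 convolution: for each output position the 0-based
# input voxel id of each kernel tap, -1 for zero padding. Output dims follow
# floor((n + 2*pad - k) / stride) + 1.
conv_geometry <- function(dims_in, k = 3L, stride = 2L, pad = 1L) {
  dims_out <- (dims_in + 2L * pad - k) %/% stride + 1L
  K <- k^3
  off <- as.matrix(expand.grid(0:(k - 1), 0:(k - 1), 0:(k - 1)))
  pos <- as.matrix(expand.grid(0:(dims_out[1] - 1), 0:(dims_out[2] - 1),
                               0:(dims_out[3] - 1)))
  nbr <- matrix(-1L, K, nrow(pos))
  for (kk in seq_len(K)) {
    ijk <- sweep(pos * stride, 2, off[kk, ] - pad, "+")
    ok <- ijk[, 1] >= 0 & ijk[, 1] < dims_in[1] &
          ijk[, 2] >= 0 & ijk[, 2] < dims_in[2] &
          ijk[, 3] >= 0 & ijk[, 3] < dims_in[3]
    v <- ijk[, 1] + dims_in[1] * (ijk[, 2] + dims_in[2] * ijk[, 3])
    nbr[kk, ] <- ifelse(ok, as.integer(v), -1L)
  }
  list(dims_out = dims_out, nbr = nbr)
}

he_init <- function(nrow, ncol, fan_in) {
  matrix(rnorm(nrow * ncol, 0, sqrt(2 / fan_in)), nrow, ncol)
}

# 3D conv encoder: three conv(stride 2) + BN + ReLU blocks, then a dense
# projection to `emb_dim`. Geometry (neighbour tables) is precomputed once.
encoder_init <- function(patch_size = 28L, channels = c(8L, 16L, 32L),
                         emb_dim = 128L) {
  stopifnot(length(channels) == 3L)
  g1 <- conv_geometry(rep(patch_size, 3L))
  g2 <- conv_geometry(g1$dims_out)
  g3 <- conv_geometry(g2$dims_out)
  cin <- c(1L, channels[1], channels[2])
  params <- list()
  for (l in 1:3) {
    fan <- 27L * cin[l]
    params[[paste0("conv", l, ".W")]] <- he_init(channels[l], fan, fan)
    params[[paste0("conv", l, ".b")]] <- numeric(channels[l])
    params[[paste0("bn", l, ".gamma")]] <- rep(1, channels[l])
    params[[paste0("bn", l, ".beta")]] <- numeric(channels[l])
  }
  flat <- channels[3] * prod(g3$dims_out)
  params[["proj.W"]] <- he_init(emb_dim, flat, flat)
  params[["proj.b"]] <- numeric(emb_dim)
  running <- list()
  for (l in 1:3) {
    running[[paste0("bn", l, ".mean")]] <- numeric(channels[l])
    running[[paste0("bn", l, ".var")]] <- rep(1, channels[l])
  }
  list(params = params, running = running, channels = channels,
       cin = cin, geom = list(g1, g2, g3), patch_size = patch_size,
       emb_dim = emb_dim)
}

# X: (patch_size^3) x B matrix. Returns emb (emb_dim x B) and caches.
encoder_forward <- function(enc, params, running, X, train = TRUE,
                            bn_momentum = 0.1, bn_eps = 1e-5) {
  if (nrow(X) != enc$patch_size^3)
    stop("patch batch must have patch_size^3 rows")
  A <- X
  caches <- vector("list", 3L)
  for (l in 1:3) {
    W <- params[[paste0("conv", l, ".W")]]
    b <- params[[paste0("conv", l, ".b")]]
    Y <- cpp_conv3d_fwd(A, enc$geom[[l]]$nbr, W, b, enc$cin[l])
    C <- enc$channels[l]
    if (train) {
      bn <- cpp_bn_relu_fwd(Y, C, params[[paste0("bn", l, ".gamma")]],
                            params[[paste0("bn", l, ".beta")]],
                            numeric(C), numeric(C), FALSE, bn_eps)
      running[[paste0("bn", l, ".mean")]] <-
        (1 - bn_momentum) * running[[paste0("bn", l, ".mean")]] +
        bn_momentum * as.numeric(bn$mean)
      running[[paste0("bn", l, ".var")]] <-
        (1 - bn_momentum) * running[[paste0("bn", l, ".var")]] +
        bn_momentum * as.numeric(bn$var)
    } else {
      bn <- cpp_bn_relu_fwd(Y, C, params[[paste0("bn", l, ".gamma")]],
                            params[[paste0("bn", l, ".beta")]],
                            running[[paste0("bn", l, ".mean")]],
                            running[[paste0("bn", l, ".var")]], TRUE, bn_eps)
    }
    caches[[l]] <- list(A = A, out = bn$out, xhat = bn$xhat,
                        invstd = as.numeric(bn$invstd))
    A <- bn$out
  }
  emb <- params[["proj.W"]] %*% A + params[["proj.b"]]
  list(emb = emb, flat = A, caches = caches, running = running)
}

# dEmb: (emb_dim x B). Returns flat named gradient list (same names as params).
encoder_backward <- function(enc, params, fwd, dEmb) {
  grads <- list()
  grads[["proj.W"]] <- dEmb %*% t(fwd$flat)
  grads[["proj.b"]] <- rowSums(dEmb)
  dA <- crossprod(params[["proj.W"]], dEmb)
  for (l in 3:1) {
    cache <- fwd$caches[[l]]
    C <- enc$channels[l]
    bn <- cpp_bn_relu_bwd(dA, cache$out, cache$xhat,
                          params[[paste0("bn", l, ".gamma")]],
                          cache$invstd, C)
    grads[[paste0("bn", l, ".gamma")]] <- as.numeric(bn$dgamma)
    grads[[paste0("bn", l, ".beta")]] <- as.numeric(bn$dbeta)
    cv <- cpp_conv3d_bwd(cache$A, enc$geom[[l]]$nbr,
                         params[[paste0("conv", l, ".W")]], bn$dY,
                         enc$cin[l], l > 1L)
    grads[[paste0("conv", l, ".W")]] <- cv$dW
    grads[[paste0("conv", l, ".b")]] <- as.numeric(cv$db)
    if (l > 1L) dA <- cv$dA
  }
  grads
}

# Fully connected stack. `sizes` is c(in, hidden..., out); hidden layers get
# ReLU, the final layer is linear (scalar output head when out = 1).
mlp_init <- function(sizes, prefix) {
  params <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    params[[paste0(prefix, ".W", l)]] <-
      he_init(sizes[l + 1L], sizes[l], sizes[l])
    params[[paste0(prefix, ".b", l)]] <- numeric(sizes[l + 1L])
  }
  params
}

mlp_forward <- function(params, prefix, n_layers, X) {
  acts <- list(X)
  A <- X
  for (l in seq_len(n_layers)) {
    Z <- params[[paste0(prefix, ".W", l)]] %*% A +
      params[[paste0(prefix, ".b", l)]]
    A <- if (l < n_layers) pmax(Z, 0) else Z
    acts[[l + 1L]] <- A
  }
  list(out = A, acts = acts)
}

mlp_backward <- function(params, prefix, n_layers, fwd, dOut) {
  grads <- list()
  dZ <- dOut  # final layer is linear
  for (l in n_layers:1) {
    grads[[paste0(prefix, ".W", l)]] <- dZ %*% t(fwd$acts[[l]])
    grads[[paste0(prefix, ".b", l)]] <- rowSums(dZ)
    dA <- crossprod(params[[paste0(prefix, ".W", l)]], dZ)
    if (l > 1L) {
      dZ <- dA * (fwd$acts[[l]] > 0)  # ReLU mask of the previous hidden layer
    } else {
      grads[["dX"]] <- dA
    }
  }
  grads
}

# Sinusoidal timestep embedding table: row t (1..T) of dim `dim`.
time_embedding_table <- function(T, dim = 64L) {
  half <- dim %/% 2L
  freqs <- exp(-log(10000) * (seq_len(half) - 1L) / max(half - 1L, 1L))
  tt <- outer(seq_len(T), freqs)
  cbind(sin(tt), cos(tt))
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# Decoupled weight decay: decay applies to weight matrices only (not biases,
# batch-norm parameters or the step counter).
adamw_step <- function(params, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    decay <- if (weight_decay > 0 && grepl("\\.W", nm))
      weight_decay * params[[nm]] else 0
    params[[nm]] <- params[[nm]] - lr * (step + decay)
  }
  list(params = params, state = state)
}

# Merge gradient lists (summing nothing: names are disjoint by construction).
merge_grads <- function(...) {
  out <- list()
  for (g in list(...)) {
    g$dX <- NULL
    out[names(g)] <- g
  }
  out
}
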