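# Conditioning encoders and the compiled conv/batch-norm kernels.

# Direct (slow) reference conv for a small geometry, matching the kernel's
# layout contracts: channel-fastest activations, W of shape (Cout x K*Cin).
conv_oracle <- function(A, dims_in, dims_out, W, b, Cin, stride = 2L,
                        pad = 1L, k = 3L) {
  B <- ncol(A)
  Cout <- nrow(W)
  npos <- prod(dims_out)
  out <- matrix(0, Cout * npos, B)
  offs <- as.matrix(expand.grid(0:(k - 1), 0:(k - 1), 0:(k - 1)))
  pos <- as.matrix(expand.grid(0:(dims_out[1] - 1), 0:(dims_out[2] - 1),
                               0:(dims_out[3] - 1)))
  for (s in 1:B) for (p in 1:npos) {
    g <- numeric(27 * Cin)
    for (kk in 1:27) {
      ijk <- pos[p, ] * stride + offs[kk, ] - pad
      if (all(ijk >= 0) && all(ijk < dims_in)) {
        v <- ijk[1] + dims_in[1] * (ijk[2] + dims_in[2] * ijk[3])
        g[(kk - 1) * Cin + seq_len(Cin)] <- A[v * Cin + seq_len(Cin), s]
      }
    }
    out[(p - 1) * Cout + seq_len(Cout), s] <- W %*% g + b
  }
  out
}

test_that("the compiled conv kernel matches a direct reference", {
  set.seed(11)
  din <- c(5L, 4L, 6L); Cin <- 2L; Cout <- 3L
  geom <- coroflow:::conv_geometry(din)
  A <- matrix(rnorm(prod(din) * Cin * 4), , 4)
  W <- matrix(rnorm(Cout * 27 * Cin), Cout)
  b <- rnorm(Cout)
  got <- coroflow:::cpp_conv3d_fwd(A, geom$nbr, W, b, Cin)
  want <- conv_oracle(A, din, geom$dims_out, W, b, Cin)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("conv backward gradients agree with finite differences", {
  set.seed(12)
  din <- c(4L, 4L, 4L); Cin <- 2L; Cout <- 2L
  geom <- coroflow:::conv_geometry(din)
  A <- matrix(rnorm(prod(din) * Cin * 3), , 3)
  W <- matrix(rnorm(Cout * 27 * Cin), Cout)
  b <- rnorm(Cout)
  U <- matrix(rnorm(Cout * prod(geom$dims_out) * 3), , 3)  # random cotangent
  loss <- function(W., A.) sum(U * coroflow:::cpp_conv3d_fwd(A., geom$nbr,
                                                             W., b, Cin))
  g <- coroflow:::cpp_conv3d_bwd(A, geom$nbr, W, U, Cin, TRUE)
  eps <- 1e-6
  for (i in sample(length(W), 5)) {
    Wp <- W; Wp[i] <- Wp[i] + eps
    Wm <- W; Wm[i] <- Wm[i] - eps
    expect_equal(g$dW[i], (loss(Wp, A) - loss(Wm, A)) / (2 * eps),
                 tolerance = 1e-5)
  }
  for (i in sample(length(A), 5)) {
    Ap <- A; Ap[i] <- Ap[i] + eps
    Am <- A; Am[i] <- Am[i] - eps
    expect_equal(g$dA[i], (loss(W, Ap) - loss(W, Am)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("batch-norm + ReLU forward/backward are consistent", {
  set.seed(13)
  C <- 3L; npos <- 10L; B <- 6L
  Y <- matrix(rnorm(C * npos * B, sd = 2), C * npos, B)
  gamma <- runif(C, 0.5, 1.5); beta <- rnorm(C)
  f <- coroflow:::cpp_bn_relu_fwd(Y, C, gamma, beta, numeric(C), numeric(C),
                                  FALSE, 1e-5)
  # channel statistics: per-channel mean ~ 0, var ~ 1 of xhat
  xh <- matrix(f$xhat, C)  # C x (npos*B) view
  expect_equal(rowMeans(xh), numeric(C), tolerance = 1e-12)
  expect_equal(apply(xh, 1, function(r) mean(r^2)), rep(1, C),
               tolerance = 1e-3)
  expect_true(all(f$out >= 0))
  # backward vs finite differences through the full fwd map
  U <- matrix(rnorm(C * npos * B), C * npos, B)
  lossY <- function(Y.) {
    ff <- coroflow:::cpp_bn_relu_fwd(Y., C, gamma, beta, numeric(C),
                                     numeric(C), FALSE, 1e-5)
    sum(U * ff$out)
  }
  bw <- coroflow:::cpp_bn_relu_bwd(U, f$out, f$xhat, gamma,
                                   as.numeric(f$invstd), C)
  eps <- 1e-6
  for (i in sample(length(Y), 6)) {
    Yp <- Y; Yp[i] <- Yp[i] + eps
    Ym <- Y; Ym[i] <- Ym[i] - eps
    expect_equal(bw$dY[i], (lossY(Yp) - lossY(Ym)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("patch embeddings are deterministic, 128-dim and shape-checked", {
  model <- icd_model(make_schedule(10, 0.01, 0.02), channels = c(2, 3, 4),
                     seed = 3)
  set.seed(14)
  patch <- array(runif(28^3), c(28, 28, 28))
  e1 <- encode_patch(model, patch)
  e2 <- encode_patch(model, patch)
  expect_identical(e1, e2)  # eval mode: running statistics, no batch effects
  expect_equal(nrow(e1), 128L)
  expect_equal(ncol(e1), 1L)
  batch <- array(runif(28^3 * 3), c(28, 28, 28, 3))
  expect_equal(dim(encode_patch(model, batch)), c(128L, 3L))
  expect_error(encode_patch(model, array(0, c(14, 14, 14))), "28")
  # zero patch through a zeroed final projection gives a zero embedding
  model$params[["proj.W"]][] <- 0
  model$params[["proj.b"]][] <- 0
  expect_equal(as.numeric(encode_patch(model, array(0, c(28, 28, 28)))),
               numeric(128))
})

test_that("coordinate encoding is a linear map of default dimension 3", {
  model <- icd_model(make_schedule(10, 0.01, 0.02), channels = c(2, 3, 4),
                     seed = 3)
  expect_equal(nrow(encode_coords(model, c(1, 2, 3))), 3L)
  model$params[["coord.b"]][] <- 0
  a <- c(0.3, -1, 2); b <- c(1, 0.5, -2)
  expect_equal(encode_coords(model, a + b),
               encode_coords(model, a) + encode_coords(model, b),
               tolerance = 1e-12)
  expect_equal(as.numeric(encode_coords(model, c(0, 0, 0))), numeric(3))
})

test_that("condition fusion concatenates image first, coordinates second", {
  img <- matrix(seq_len(128 * 2) / 100, 128, 2)
  crd <- matrix(c(9, 8, 7, 6, 5, 4), 3, 2)
  fused <- fuse_condition(img, crd)
  expect_equal(nrow(fused), 131L)
  expect_equal(fused[1:128, ], img)
  expect_equal(fused[129:131, ], crd)
  expect_equal(fuse_condition(matrix(0, 4, 1), matrix(0, 2, 1)),
               matrix(0, 6, 1))
  expect_error(fuse_condition(NULL, crd), "required")
  expect_error(fuse_condition(img, crd[, 1, drop = FALSE]), "batch")
})

test_that("the denoiser outputs one scalar per sample for any batch size", {
  model <- icd_model(make_schedule(10, 0.01, 0.02), channels = c(2, 3, 4),
                     seed = 3)
  for (B in c(1L, 5L, 17L)) {
    cond <- matrix(rnorm(131 * B), 131, B)
    out <- coroflow:::denoiser_forward(model, rnorm(B),
                                       sample(10, B, TRUE), cond)$out
    expect_equal(dim(out), c(1L, B))
  }
})
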