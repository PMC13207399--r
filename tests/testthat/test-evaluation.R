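# Brute-force metric references, coded independently of the implementations.
r2_oracle <- function(y, p) {
  ss <- 0; st <- 0; m <- mean(y)
  for (i in seq_along(y)) {
    ss <- ss + (p[i] - y[i])^2
    st <- st + (m - y[i])^2
  }
  1 - ss / st
}
rmse_oracle <- function(y, p) {
  s <- 0
  for (i in seq_along(y)) s <- s + (p[i] - y[i])^2
  sqrt(s / length(y))
}

test_that("metrics match worked examples and brute-force references", {
  y <- c(1, 2, 3); p <- c(1, 2, 4)
  expect_equal(r2_score(y, p), 0.5)
  expect_equal(rmse(y, p), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(rmse(y, p), 0.5774, tolerance = 1e-4)
  expect_equal(nrmse(y, p), sqrt(1 / 3) / 2, tolerance = 1e-12)
  expect_equal(pearson(y, c(1, 3, 2)), 0.5)
  # perfect / mean / inverted predictions
  expect_equal(r2_score(y, y), 1)
  expect_equal(r2_score(y, rep(2, 3)), 0)
  expect_equal(pearson(y, 2 * y + 1), 1)
  expect_equal(pearson(y, -y), -1)
  expect_equal(rmse(y, y), 0)
  expect_equal(nrmse(y, y), 0)
  set.seed(16)
  for (i in 1:10) {
    y <- rnorm(30, 100, 8); p <- y + rnorm(30, 0, 3)
    expect_equal(r2_score(y, p), r2_oracle(y, p), tolerance = 1e-12)
    expect_equal(rmse(y, p), rmse_oracle(y, p), tolerance = 1e-12)
    expect_equal(nrmse(y, p) * mean(y), rmse(y, p), tolerance = 1e-12)
    expect_equal(pearson(y, p), cor(y, p), tolerance = 1e-12)
    # scale equivariance / invariance
    expect_equal(rmse(3 * y, 3 * p), 3 * rmse(y, p))
    expect_equal(nrmse(3 * y, 3 * p), nrmse(y, p))
    # pcc invariant to positive affine transforms of either argument
    expect_equal(pearson(y, 0.5 * p + 7), pearson(y, p), tolerance = 1e-12)
    expect_equal(pearson(2 * y - 3, p), pearson(y, p), tolerance = 1e-12)
  }
})

test_that("degenerate metric inputs raise errors", {
  expect_error(r2_score(c(2, 2, 2), c(1, 2, 3)), "constant")
  expect_error(pearson(c(1, 2, 3), c(5, 5, 5)), "constant")
  expect_error(nrmse(c(-1, 1), c(0, 0)), "zero")
  expect_error(r2_score(1, 1))
})

test_that("case-wise aggregation reproduces the published mean rows", {
  ref <- reference_casewise_table()
  # the two small-cohort tables print different case labels per metric pair,
  # so pivot each requested metric subset separately
  wide <- function(cohort, metrics = c("r2", "pcc", "rmse", "nrmse")) {
    d <- ref[ref$cohort == cohort & ref$metric %in% metrics, ]
    out <- reshape(d, idvar = c("model", "case"), timevar = "metric",
                   direction = "wide")
    names(out) <- sub("^value\\.", "", names(out))
    out
  }
  med <- casewise_report(wide("medium"))
  expect_equal(report_mean(med, "RD", "r2"), 64.42, tolerance = 0.005)
  expect_equal(report_mean(med, "RD", "pcc"), 84.978, tolerance = 0.0005)
  expect_equal(report_mean(med, "RD", "rmse"), 0.974, tolerance = 0.0005)
  expect_equal(report_mean(med, "RD", "nrmse"), 0.155, tolerance = 0.0005)
  expect_equal(report_mean(med, "CD", "r2"), 61.093, tolerance = 0.0005)
  expect_equal(report_mean(med, "CD", "rmse"), 0.984, tolerance = 0.0005)
  expect_equal(report_mean(med, "CD", "nrmse"), 0.157, tolerance = 0.0005)
  sml <- casewise_report(wide("small", c("r2", "pcc")))
  expect_equal(report_mean(sml, "RD", "r2"), 23.305, tolerance = 0.0005)
  expect_equal(report_mean(sml, "RD", "pcc"), 70.96, tolerance = 0.0005)
  # mean rows equal the arithmetic mean of per-case rows to 1e-9
  d <- wide("medium")
  for (m in unique(d$model))
    expect_equal(report_mean(med, m, "r2"),
                 mean(d$r2[d$model == m]), tolerance = 1e-9)
  # single case: the mean row equals that case
  one <- casewise_report(data.frame(model = "X", case = 1, r2 = 55.5))
  expect_equal(report_mean(one, "X", "r2"), 55.5)
})

test_that("improvement figures reproduce the published comparisons", {
  ref <- reference_casewise_table()
  mn <- function(model, metric)
    mean(ref$value[ref$cohort == "medium" & ref$model == model &
                     ref$metric == metric])
  expect_equal(improvement(mn("RD", "r2"), mn("RL", "r2"),
                           "absolute_points"), 19.78, tolerance = 0.005)
  expect_equal(improvement(mn("RD", "rmse"), mn("RL", "rmse"), "relative"),
               19.44, tolerance = 0.005)
  expect_equal(improvement(mn("RD", "nrmse"), mn("RL", "nrmse"), "relative"),
               18, tolerance = 0.5)
  expect_equal(improvement(5, 5, "absolute_points"), 0)
  expect_equal(improvement(5, 5, "relative"), 0)
  expect_error(improvement(1, 0, "relative"), "zero")
})

test_that("FFR ratios and significance flags follow the 0.80 rule", {
  f <- compute_ffr(c(100, 90, 70), 100)
  expect_equal(f$ffr, c(1.0, 0.9, 0.7))
  expect_equal(f$significant, c(FALSE, FALSE, TRUE))
  # boundary value is flagged (<= rule)
  expect_true(compute_ffr(80, 100)$significant)
  u <- compute_ffr(rep(95, 4), 95)
  expect_equal(u$ffr, rep(1, 4))
  expect_false(any(u$significant))
  expect_error(compute_ffr(c(90, 80), 0), "inlet")
})

test_that("error maps export and re-read consistently", {
  set.seed(17)
  pts <- matrix(rnorm(30), ncol = 3)
  y <- rnorm(10, 100, 5); p <- y + rnorm(10)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(c(path, sub("csv$", "vtk", path))))
  export_error_map(pts, y, p, path, vtk = TRUE)
  back <- read.csv(path)
  expect_equal(nrow(back), 10)
  expect_equal(back$abs_error, abs(back$label - back$prediction),
               tolerance = 1e-12)
  expect_equal(back$abs_error, abs(y - p), tolerance = 1e-6)
  # perfect predictions give an all-zero error column
  export_error_map(pts, y, y, path)
  expect_true(all(read.csv(path)$abs_error == 0))
  vtk <- readLines(sub("csv$", "vtk", path))
  expect_equal(vtk[4], "DATASET POLYDATA")
  expect_true(any(grepl("abs_error", vtk)))
})
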