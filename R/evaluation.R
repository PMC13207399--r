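# Case-wise evaluation: R2, Pearson correlation, RMSE and NRMSE per test
# case, aggregation to mean rows, between-model improvement figures, FFR
# significance flagging and error-map export.

#' Coefficient of determination
#'
#' `R2 = 1 - sum((y_hat - y)^2) / sum((mean(y) - y)^2)`: the proportion of
#' variance in the observed values explained by the predictions. May be
#' negative for predictions worse than the observed mean.
#'
#' @param y Observed values (length >= 2, non-constant).
#' @param y_hat Predicted values.
#' @return R2 as a fraction.
#' @export
r2_score <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L)
  sstot <- sum((mean(y) - y)^2)
  if (sstot <= 0) stop("R2 undefined for constant observations")
  1 - sum((y_hat - y)^2) / sstot
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation between predictions and observations; both
#' arguments must be non-constant.
#'
#' @inheritParams r2_score
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2L)
  dy <- y - mean(y)
  dp <- y_hat - mean(y_hat)
  den <- sqrt(sum(dp^2) * sum(dy^2))
  if (den <= 0) stop("correlation undefined for constant input")
  sum(dp * dy) / den
}

#' Root mean squared error
#' @inheritParams r2_score
#' @return RMSE, in the units of `y` (mmHg for pressures).
#' @export
rmse <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1L)
  sqrt(mean((y_hat - y)^2))
}

#' Normalized root mean squared error
#'
#' RMSE divided by the mean observed value, for scale-free comparison.
#' @inheritParams r2_score
#' @return Dimensionless NRMSE.
#' @export
nrmse <- function(y, y_hat) {
  obar <- mean(y)
  if (abs(obar) <= .Machine$double.eps)
    stop("NRMSE undefined: observed mean is zero")
  rmse(y, y_hat) / obar
}

#' All four metrics for one case
#'
#' R2 and PCC are reported on the percent scale (x100), matching case-wise
#' evaluation tables; RMSE stays in mmHg and NRMSE is dimensionless.
#'
#' @inheritParams r2_score
#' @param case Case identifier.
#' @return One-row data frame: `case`, `r2`, `pcc`, `rmse`, `nrmse`, `m`.
#' @export
case_metrics <- function(y, y_hat, case = "case") {
  data.frame(case = case, r2 = 100 * r2_score(y, y_hat),
             pcc = 100 * pearson(y, y_hat), rmse = rmse(y, y_hat),
             nrmse = nrmse(y, y_hat), m = length(y))
}

#' Aggregate per-case metrics into a case-wise report
#'
#' Appends, per model, a mean row equal to the arithmetic mean of the
#' unrounded per-case values (rounding is for display only).
#'
#' @param per_case Data frame with columns `model`, `case` and one column per
#'   metric (any of `r2`, `pcc`, `rmse`, `nrmse`).
#' @return Object of class `casewise_report`: `per_case` and `means` (one row
#'   per model).
#' @export
casewise_report <- function(per_case) {
  stopifnot(is.data.frame(per_case), all(c("model") %in% names(per_case)))
  metrics <- intersect(c("r2", "pcc", "rmse", "nrmse"), names(per_case))
  if (length(metrics) == 0L) stop("no metric columns found")
  if (nrow(per_case) == 0L) stop("need at least one case")
  means <- aggregate(per_case[metrics], by = list(model = per_case$model),
                     FUN = mean)
  structure(list(per_case = per_case, means = means,
                 metrics = metrics), class = "casewise_report")
}

#' @export
print.casewise_report <- function(x, digits = 3, ...) {
  cat("<casewise_report>", length(unique(x$per_case$model)), "models,",
      length(unique(x$per_case$case)), "cases\n")
  m <- x$means
  m[x$metrics] <- lapply(m[x$metrics], round, digits = digits)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Mean-row value for one model/metric
#' @param report A [casewise_report()].
#' @param model Model label.
#' @param metric Metric name.
#' @return Scalar mean.
#' @export
report_mean <- function(report, model, metric) {
  stopifnot(inherits(report, "casewise_report"))
  row <- report$means[report$means$model == model, ]
  if (nrow(row) != 1L) stop("model not found: ", model)
  row[[metric]]
}

#' Improvement of one model over another
#'
#' Two conventions coexist in case-wise evaluation summaries: differences of
#' percent-scale scores (R2) are reported in absolute percentage points
#' (`mean_a - mean_b`), while error reductions (RMSE, NRMSE) are relative,
#' `(mean_b - mean_a) / mean_b * 100`.
#'
#' @param mean_a Mean metric of the proposed model.
#' @param mean_b Mean metric of the comparator, same scale.
#' @param mode `"absolute_points"` or `"relative"`.
#' @return The improvement, in percentage points or percent.
#' @export
improvement <- function(mean_a, mean_b,
                        mode = c("absolute_points", "relative")) {
  mode <- match.arg(mode)
  if (mode == "absolute_points") return(mean_a - mean_b)
  if (mean_b == 0) stop("relative improvement undefined for zero baseline")
  (mean_b - mean_a) / mean_b * 100
}

#' Fractional flow reserve along a centerline
#'
#' `FFR_i = p_i / inlet_pressure`; values at or below 0.80 are flagged as
#' hemodynamically significant.
#'
#' @param pressures Pressures along the centerline, mmHg.
#' @param inlet_pressure Reference (proximal/aortic) pressure, mmHg (> 0).
#' @param threshold Significance threshold (default 0.80, inclusive).
#' @return Data frame with `pressure`, `ffr`, `significant`.
#' @export
compute_ffr <- function(pressures, inlet_pressure, threshold = 0.80) {
  if (inlet_pressure <= 0) stop("inlet_pressure must be > 0")
  ffr <- pressures / inlet_pressure
  data.frame(pressure = pressures, ffr = ffr,
             significant = ffr <= threshold)
}

#' Export a point-wise absolute-error map
#'
#' Writes a CSV of `(x, y, z, label, prediction, abs_error)` and optionally a
#' legacy-ASCII VTK polydata file with the absolute error as a point scalar,
#' for 3D inspection.
#'
#' @param points `n x 3` world coordinates (mm).
#' @param y Labels (mmHg).
#' @param y_hat Predictions (mmHg).
#' @param path Output CSV path.
#' @param vtk Also write `<path>.vtk` polydata.
#' @return `path`, invisibly.
#' @export
export_error_map <- function(points, y, y_hat, path, vtk = FALSE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3L, nrow(points) == length(y),
            length(y) == length(y_hat))
  df <- data.frame(x = points[, 1], y = points[, 2], z = points[, 3],
                   label = y, prediction = y_hat,
                   abs_error = abs(y - y_hat))
  write.csv(df, path, row.names = FALSE)
  if (vtk) {
    vp <- paste0(tools::file_path_sans_ext(path), ".vtk")
    con <- file(vp, "w")
    on.exit(close(con), add = TRUE)
    n <- nrow(df)
    writeLines(c("# vtk DataFile Version 3.0", "absolute error map", "ASCII",
                 "DATASET POLYDATA", paste("POINTS", n, "double")), con)
    write(t(points), con, ncolumns = 3)
    writeLines(c(paste("VERTICES", n, 2 * n)), con)
    write(t(cbind(1L, seq_len(n) - 1L)), con, ncolumns = 2)
    writeLines(c(paste("POINT_DATA", n), "SCALARS abs_error double 1",
                 "LOOKUP_TABLE default"), con)
    write(df$abs_error, con, ncolumns = 1)
  }
  invisible(path)
}

#' Bundled reference case-wise benchmark table
#'
#' Per-case R2, Pearson correlation (both percent scale), RMSE and NRMSE for
#' six pressure-prediction models on two published CCTA evaluation cohorts
#' (a medium ten-test-case cohort and a small two-test-case cohort), as
#' printed. Used to validate the aggregation and improvement operations
#' against known mean rows.
#'
#' @return Data frame with columns `cohort`, `model`, `case`, `r2`, `pcc`,
#'   `rmse`, `nrmse`.
#' @export
reference_casewise_table <- function() {
  path <- system.file("extdata", "casewise_reference.csv",
                      package = "coroflow", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
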