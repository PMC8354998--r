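#' Exact distance from points to a triangle mesh
#'
#' For each query point, finds the exact nearest point over all reference
#' triangles (interior, edge or vertex) and the Euclidean distance to it. The
#' signed distance takes the sign of the dot product between
#' (point - nearest) and the outward face normal at the nearest triangle:
#' positive means the point lies outside the reference surface. The default
#' uniform-grid accelerated search returns exactly the same distances as the
#' exhaustive all-triangle scan (`method = "exhaustive"`).
#'
#' @param points numeric matrix (n x 3) or data frame with `x`, `y`, `z`.
#' @param reference a [tri_mesh()] with at least one face.
#' @param method `"grid"` (accelerated, default) or `"exhaustive"`.
#' @return a tibble with columns `x`, `y`, `z`, `unsigned`, `signed`, `face`,
#'   `nx`, `ny`, `nz` (the nearest point).
#' @export
point_to_surface_distance <- function(points, reference,
                                      method = c("grid", "exhaustive")) {
  method <- match.arg(method)
  stopifnot(inherits(reference, "tri_mesh"))
  if (!nrow(reference$faces)) stop("reference mesh has no faces", call. = FALSE)
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y", "z")])
  points <- matrix(as.numeric(points), ncol = 3)
  res <- cpp_closest_on_mesh(points, reference$vertices, reference$faces,
                             method == "grid")
  d <- res$distance
  fn <- reference$face_normals[res$face, , drop = FALSE]
  sgn <- sign(rowSums((points - res$closest) * fn))
  sgn[sgn == 0] <- 1 # on-surface points count as outside (distance 0 anyway)
  tibble::tibble(
    x = points[, 1], y = points[, 2], z = points[, 3],
    unsigned = d, signed = sgn * d, face = res$face,
    nx = res$closest[, 1], ny = res$closest[, 2], nz = res$closest[, 3]
  )
}

#' Both-way surface-to-surface distance samples
#'
#' One distance sample per test vertex against the reference surface
#' (`test_to_ref`) and one per reference vertex against the test surface
#' (`ref_to_test`), so protrusions and missing parts are both detected.
#' Sampling at mesh vertices matches the density of marching-cubes output and
#' keeps the measurement deterministic.
#'
#' @param test,reference [tri_mesh()] objects.
#' @param method passed to [point_to_surface_distance()].
#' @return a tibble of distance samples with a `direction` column.
#' @export
both_way_distances <- function(test, reference,
                               method = c("grid", "exhaustive")) {
  method <- match.arg(method)
  fwd <- point_to_surface_distance(test$vertices, reference, method)
  bwd <- point_to_surface_distance(reference$vertices, test, method)
  fwd$direction <- "test_to_ref"
  bwd$direction <- "ref_to_test"
  dplyr::bind_rows(fwd, bwd)
}

#' Surface-distance accuracy report
#'
#' The evaluation statistics, pooled over both comparison directions:
#' ASSD (mean unsigned distance), AASD (mean signed distance, positive =
#' protrusion outside the reference), RMS (root mean squared unsigned
#' distance), maximum error, 95th percentile (linear interpolation between
#' order statistics), and the percentage of samples with an error strictly
#' below the tolerance (default 0.2 mm, the patient-specific-guide design
#' offset used as the clinically relevant cut-off).
#'
#' @param samples a tibble from [both_way_distances()] (needs `unsigned`,
#'   `signed` and optionally `direction` columns).
#' @param tolerance tolerance in mm for the percentage-below statistic.
#' @return an object of class `metrics_report`.
#' @export
compute_report <- function(samples, tolerance = 0.2) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0L) stop("no distance samples", call. = FALSE)
  u <- samples$unsigned
  s <- samples$signed
  n_each <- if ("direction" %in% names(samples)) {
    tab <- table(samples$direction)
    c(test_to_ref = unname(tab["test_to_ref"]),
      ref_to_test = unname(tab["ref_to_test"]))
  } else c(test_to_ref = NA_integer_, ref_to_test = NA_integer_)
  structure(list(
    assd = mean(u),
    aasd = mean(s),
    rms = sqrt(mean(u^2)),
    max_error = max(u),
    p95 = unname(stats::quantile(u, 0.95, type = 7)),
    pct_below_tolerance = 100 * mean(u < tolerance),
    tolerance = tolerance,
    n_samples_each_way = n_each
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  cat(sprintf("  ASSD  %8.4f mm    AASD %8.4f mm    RMS %8.4f mm\n",
              x$assd, x$aasd, x$rms))
  cat(sprintf("  max   %8.4f mm    p95  %8.4f mm    %5.1f%% < %g mm\n",
              x$max_error, x$p95, x$pct_below_tolerance, x$tolerance))
  invisible(x)
}

#' Tidy a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return a long tibble with `metric`, `value`, `unit` columns.
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::tibble(
    metric = c("assd", "aasd", "rms", "max_error", "p95",
               "pct_below_tolerance"),
    value = c(x$assd, x$aasd, x$rms, x$max_error, x$p95,
              x$pct_below_tolerance),
    unit = c(rep("mm", 5), "%")
  )
}

#' One-row summary of a metrics report
#'
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    assd = x$assd, aasd = x$aasd, rms = x$rms, max_error = x$max_error,
    p95 = x$p95, pct_below_tolerance = x$pct_below_tolerance,
    tolerance = x$tolerance,
    n_test_to_ref = x$n_samples_each_way[["test_to_ref"]],
    n_ref_to_test = x$n_samples_each_way[["ref_to_test"]]
  )
}

#' Cumulative error distribution curve
#'
#' Percentiles of the pooled unsigned distances: for each requested
#' percentile p, the distance below which p percent of the surface samples
#' fall. The curve is monotone non-decreasing and its value at 95 equals the
#' report's p95 (same linear-interpolation percentile rule).
#'
#' @param samples a tibble of distance samples (needs `unsigned`).
#' @param percentiles percentages in [0, 100].
#' @return a tibble of class `error_curve` with columns `percentile`,
#'   `distance_mm`.
#' @export
cumulative_error_curve <- function(samples, percentiles = 0:100) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0L) stop("no distance samples", call. = FALSE)
  if (any(percentiles < 0 | percentiles > 100))
    stop("percentiles must lie in [0, 100]", call. = FALSE)
  out <- tibble::tibble(
    percentile = as.numeric(percentiles),
    distance_mm = unname(stats::quantile(samples$unsigned,
                                         percentiles / 100, type = 7))
  )
  class(out) <- c("error_curve", class(out))
  out
}

#' Plot a cumulative error distribution curve
#'
#' @param object an `error_curve` from [cumulative_error_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.error_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$percentile, y = .data$distance_mm)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "percentile of surface samples (%)",
                  y = "surface distance (mm)",
                  title = "Cumulative error distribution") +
    ggplot2::theme_minimal()
}

#' Partition mesh vertices by a cutting plane
#'
#' Splits vertices into the two half-spaces of a plane (e.g. the vertical
#' plane midway through the pedicles separating anterior from posterior
#' vertebral substructures). Vertices exactly on the plane go to the positive
#' side.
#'
#' @param mesh a [tri_mesh()].
#' @param plane_point a point on the plane (length-3, mm).
#' @param plane_normal plane normal (length-3, nonzero).
#' @return a list with logical vertex masks `positive` and `negative`.
#' @export
partition_by_plane <- function(mesh, plane_point, plane_normal) {
  nrm <- sqrt(sum(plane_normal^2))
  if (nrm == 0) stop("plane normal must be nonzero", call. = FALSE)
  n <- plane_normal / nrm
  d <- sweep(mesh$vertices, 2, plane_point) %*% n
  list(positive = as.vector(d >= 0), negative = as.vector(d < 0))
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC from the
#' standard ANOVA decomposition: with n subjects, k raters, between-subject
#' mean square MSR, between-rater mean square MSC and residual mean square
#' MSE,
#' \deqn{ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).}
#'
#' @param ratings numeric matrix or data frame, subjects in rows, raters in
#'   columns, no missing cells.
#' @return an object of class `icc_fit` with elements `value`, `n_subjects`,
#'   `n_raters`, `msr`, `msc`, `mse`.
#' @export
icc <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings must have no missing cells", call. = FALSE)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 raters", call. = FALSE)
  grand <- mean(m)
  if (sum((m - grand)^2) == 0)
    stop("ICC undefined: zero total variance", call. = FALSE)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  value <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  structure(list(value = value, n_subjects = n, n_raters = k,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4f  (%d subjects, %d raters)\n",
              x$value, x$n_subjects, x$n_raters))
  invisible(x)
}

#' Tidy an ICC fit
#'
#' @param x an `icc_fit`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
tidy.icc_fit <- function(x, ...) {
  tibble::tibble(estimate = x$value, n_subjects = x$n_subjects,
                 n_raters = x$n_raters, msr = x$msr, msc = x$msc,
                 mse = x$mse)
}
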