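# Polynomial spinal profiles: fitting, fixed-interval resampling, plane
# parametric-curve curvature, and profile-to-profile distance metrics.

#' Fit a polynomial profile to a planar landmark series
#'
#' Ordinary least squares of a degree-7 (by default) polynomial in a
#' centred/scaled cephalo-caudal variable, mapping the fitted z range onto
#' [-1, 1] for numerical conditioning. The fit RMSE is the root-mean-square
#' residual against the input points.
#'
#' @param series Data frame with columns `z` and `v` (mm), e.g. from
#'   [project_to_plane()].
#' @param degree Polynomial degree, default 7.
#' @return An object of class `profile_model` with elements `coefficients`
#'   (ascending powers of the scaled variable), `z_center`, `z_scale`,
#'   `domain` (`c(z_min, z_max)`), `fit_rmse`, `degree`, `plane`, `source`
#'   and `n_points`.
#' @export
fit_profile <- function(series, degree = 7L) {
  if (!all(c("z", "v") %in% names(series))) {
    stop_input("series must have columns z and v")
  }
  z <- as.numeric(series$z)
  v <- as.numeric(series$v)
  if (anyDuplicated(z)) stop_input("duplicate z values in profile series")
  if (length(z) < degree + 2L) {
    stop_input(
      "need at least ", degree + 2L, " points for a degree-", degree,
      " profile fit, got ", length(z)
    )
  }
  z_center <- (max(z) + min(z)) / 2
  z_scale <- (max(z) - min(z)) / 2
  zs <- (z - z_center) / z_scale
  vand <- outer(zs, 0:degree, `^`)
  fit <- lm.fit(vand, v)
  rmse <- sqrt(mean(fit$residuals^2))
  structure(
    list(
      coefficients = unname(fit$coefficients),
      z_center = z_center,
      z_scale = z_scale,
      domain = c(min(z), max(z)),
      fit_rmse = rmse,
      degree = as.integer(degree),
      plane = attr(series, "plane"),
      source = attr(series, "source"),
      n_points = length(z)
    ),
    class = "profile_model"
  )
}

#' Evaluate a fitted profile
#'
#' @param object A `profile_model`.
#' @param newz z values (mm) at which to evaluate.
#' @param ... Unused.
#' @return Profile values v(z) in mm.
#' @export
predict.profile_model <- function(object, newz, ...) {
  zs <- (as.numeric(newz) - object$z_center) / object$z_scale
  # Horner evaluation, ascending coefficients
  co <- object$coefficients
  out <- rep(co[length(co)], length(zs))
  for (i in rev(seq_len(length(co) - 1L))) {
    out <- out * zs + co[i]
  }
  out
}

#' @export
print.profile_model <- function(x, ...) {
  cat(sprintf(
    "<profile_model> degree %d%s, domain [%.1f, %.1f] mm, fit RMSE %.4g mm\n",
    x$degree,
    if (!is.null(x$plane)) paste0(" (", x$plane, ")") else "",
    x$domain[1], x$domain[2], x$fit_rmse
  ))
  invisible(x)
}

# Station grid anchored at the most cephalad domain point, stepping caudally.
station_grid <- function(z_max, z_min, interval) {
  k <- floor((z_max - z_min) / interval + 1e-9)
  z_max - interval * (0:k)
}

#' Sample a profile at fixed cephalo-caudal intervals
#'
#' Stations are anchored at the most cephalad fitted point and step caudally
#' in `interval` increments while remaining inside the fitted domain.
#' Curvature at each station is computed from the sampled point sequence by
#' finite differences (see [line_curvature()]), or analytically from the
#' polynomial when `curvature = "analytic"`.
#'
#' @param model A `profile_model`.
#' @param interval Station spacing in mm, default 20.
#' @param curvature `"finite_diff"` (default) or `"analytic"`.
#' @param stations Optional explicit station vector (mm, descending) to use
#'   instead of the anchored grid, e.g. a grid shared between two profiles.
#' @return An object of class `sampled_profile`: data frame with columns
#'   `z` (stations, mm), `v` (mm) and `k` (curvature, 1/mm).
#' @export
sample_profile <- function(model, interval = 20,
                           curvature = c("finite_diff", "analytic"),
                           stations = NULL) {
  curvature <- match.arg(curvature)
  stopifnot(inherits(model, "profile_model"))
  if (interval <= 0) stop_input("interval must be positive")
  if (is.null(stations)) {
    if (diff(model$domain) < 2 * interval) {
      stop_input("fitted domain is shorter than two sampling intervals")
    }
    stations <- station_grid(model$domain[2], model$domain[1], interval)
  }
  v <- predict(model, stations)
  k <- if (curvature == "finite_diff") {
    line_curvature(stations, v)
  } else {
    curvature_analytic(model, stations)
  }
  out <- data.frame(z = stations, v = v, k = k)
  class(out) <- c("sampled_profile", "data.frame")
  attr(out, "plane") <- model$plane
  attr(out, "interval") <- interval
  attr(out, "fit_rmse") <- model$fit_rmse
  out
}

#' Curvature of a sampled plane curve
#'
#' Plane parametric-curve curvature
#' \deqn{k = |x' y'' - y' x''| / (x'^2 + y'^2)^{3/2}}
#' with derivatives taken with respect to the point index by finite
#' differences: central differences at interior points, one-sided stencils at
#' the two endpoints. The curvature of a parametric curve is independent of
#' the parameterisation, so the index parameterisation is exact up to the
#' finite-difference truncation error. Returns nonnegative values.
#'
#' @param x Cephalo-caudal coordinates of the points (mm).
#' @param y In-plane coordinates of the points (mm): antero-posterior in the
#'   sagittal plane, lateral in the coronal plane.
#' @return Curvature k at each point, in 1/mm.
#' @export
line_curvature <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop_input("x and y must have equal length")
  if (n < 3L) stop_input("curvature needs at least 3 points")
  d1 <- function(f) c(f[2] - f[1], (f[3:n] - f[1:(n - 2)]) / 2, f[n] - f[n - 1])
  d2 <- function(f) {
    mid <- f[1:(n - 2)] - 2 * f[2:(n - 1)] + f[3:n]
    c(mid[1], mid, mid[n - 2])
  }
  x1 <- d1(x)
  y1 <- d1(y)
  x2 <- d2(x)
  y2 <- d2(y)
  speed2 <- x1^2 + y1^2
  k <- abs(x1 * y2 - y1 * x2) / pmax(speed2^1.5, .Machine$double.eps)
  k
}

#' Analytic curvature of a fitted polynomial profile
#'
#' Exact curvature of the graph (z, v(z)) of the fitted polynomial,
#' \eqn{k = |v''| / (1 + v'^2)^{3/2}}, used as the high-precision reference
#' for the finite-difference routine.
#'
#' @param model A `profile_model`.
#' @param z Evaluation points (mm).
#' @return Curvature in 1/mm.
#' @export
curvature_analytic <- function(model, z) {
  co <- model$coefficients
  s <- model$z_scale
  zs <- (as.numeric(z) - model$z_center) / s
  deg <- length(co) - 1L
  d1co <- if (deg >= 1L) co[-1] * seq_len(deg) else 0
  d2co <- if (deg >= 2L) d1co[-1] * seq_len(deg - 1L) else 0
  horner <- function(cf, t) {
    out <- rep(cf[length(cf)], length(t))
    for (i in rev(seq_len(length(cf) - 1L))) out <- out * t + cf[i]
    out
  }
  vp <- horner(d1co, zs) / s
  vpp <- horner(d2co, zs) / s^2
  abs(vpp) / (1 + vp^2)^1.5
}

# Assign stations to spinal regions. Bounds are z ranges; the thoracic/lumbar
# boundary is the T12-L1 midpoint, and a station exactly on the boundary goes
# to the thoracic side (equidistant tie).
station_region_mask <- function(z, region, region_bounds) {
  if (region == "overall") return(rep(TRUE, length(z)))
  if (is.null(region_bounds)) {
    stop_input("region_bounds required for regional RMSD")
  }
  b <- region_bounds[[region]]
  if (is.null(b)) stop_input("region_bounds lacks entry '", region, "'")
  tol <- 1e-9
  if (region == "thoracic") {
    z >= b[1] & z <= b[2] + tol
  } else {
    z >= b[1] - tol & z < b[2]
  }
}

#' Regional z bounds from a spinous-process landmark set
#'
#' The thoracic region spans from the T12-L1 midpoint up to T1; the lumbar
#' region from L5 up to (excluding) the same midpoint.
#'
#' @param spine A `landmark_set` containing T1, T12, L1 and L5.
#' @return List with elements `thoracic` and `lumbar`, each `c(z_lo, z_hi)`.
#' @export
region_bounds_from_landmarks <- function(spine) {
  m <- landmark_coords(spine, c("T1", "T12", "L1", "L5"))
  mid <- (m["T12", "z"] + m["L1", "z"]) / 2
  list(
    thoracic = c(mid, m["T1", "z"]),
    lumbar = c(m["L5", "z"], mid)
  )
}

#' Root-mean-square distance between two sampled profiles
#'
#' Distances are matched-station differences of the profile value v at
#' identical stations z (not closest-point distances). Returns the RMSD
#' together with the mean and SD of the absolute point distances and, for
#' coronal profiles, the signed lateral statistics (positive = `b` left of
#' `a`; exact zeros do not count as left).
#'
#' @param a,b `sampled_profile` objects sharing stations (`a` is the
#'   reference, e.g. the spinous-process profile).
#' @param region `"overall"`, `"thoracic"` or `"lumbar"`.
#' @param region_bounds List from [region_bounds_from_landmarks()]; required
#'   for regional RMSD.
#' @param plane Plane tag; defaults to the profiles' plane attribute.
#' @return An object of class `distance_summary`: list with `rmsd`,
#'   `mean_distance`, `sd_distance`, `n_stations`, `region`, and for coronal
#'   input `signed_lateral_mean` and `left_lateral_fraction`.
#' @export
profile_rmsd <- function(a, b, region = c("overall", "thoracic", "lumbar"),
                         region_bounds = NULL, plane = NULL) {
  region <- match.arg(region)
  if (is.null(plane)) plane <- attr(a, "plane")
  idx <- match(round(a$z, 6), round(b$z, 6))
  common <- which(!is.na(idx))
  if (length(common) < 3L) {
    stop_input("profiles share fewer than 3 stations")
  }
  za <- a$z[common]
  keep <- station_region_mask(za, region, region_bounds)
  if (sum(keep) < 3L) {
    stop_input("fewer than 3 common stations in region '", region, "'")
  }
  diff_v <- b$v[idx[common]][keep] - a$v[common][keep]
  dist <- abs(diff_v)
  out <- list(
    rmsd = sqrt(mean(diff_v^2)),
    mean_distance = mean(dist),
    sd_distance = if (length(dist) > 1L) sd(dist) else 0,
    n_stations = length(dist),
    region = region,
    plane = plane
  )
  if (identical(plane, "coronal")) {
    out$signed_lateral_mean <- mean(diff_v)
    out$left_lateral_fraction <- mean(diff_v > 0)
  }
  structure(out, class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf(
    "<distance_summary> %s %s: RMSD %.3f mm (mu %.3f, sigma %.3f, n=%d)\n",
    x$plane %||% "", x$region, x$rmsd, x$mean_distance, x$sd_distance,
    x$n_stations
  ))
  if (!is.null(x$signed_lateral_mean)) {
    cat(sprintf(
      "  signed lateral mean %.3f mm, left fraction %.2f\n",
      x$signed_lateral_mean, x$left_lateral_fraction
    ))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-level signed lateral distances between matched marker series
#'
#' Signed lateral difference (fiducial minus spinous process; positive =
#' subject-left) at each matched vertebral label, with the summary mean, SD
#' and the fraction of labels displaced to the left (exact zeros count as
#' not-left).
#'
#' @param spine,fiducials Coronal planar series (data frames with `label`,
#'   `v`) covering identical label sets.
#' @return List with `per_level` (data frame label/lateral_mm), `mean`, `sd`,
#'   `left_fraction`.
#' @export
marker_pointwise_lateral <- function(spine, fiducials) {
  if (!setequal(spine$label, fiducials$label)) {
    stop_input("spine and fiducial series must cover the same labels")
  }
  idx <- match(spine$label, fiducials$label)
  d <- fiducials$v[idx] - spine$v
  list(
    per_level = data.frame(label = spine$label, lateral_mm = d),
    mean = mean(d),
    sd = if (length(d) > 1L) sd(d) else 0,
    left_fraction = mean(d > 0)
  )
}
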