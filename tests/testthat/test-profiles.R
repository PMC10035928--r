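# Polynomial profile fitting, 20 mm resampling, curvature and RMSD metrics.

test_that("profiles in the polynomial span are fitted exactly", {
  z <- seq(0, 460, length.out = 17)
  lin <- data.frame(z = z, v = 2 * z + 1)
  m <- fit_profile(lin)
  expect_lt(m$fit_rmse, 1e-8)
  probe <- seq(10, 450, by = 37)
  expect_lt(max(abs(predict(m, probe) - (2 * probe + 1))), 1e-8)
  expect_identical(m$degree, 7L)

  set.seed(5)
  co <- rnorm(8)
  zs <- (z - mean(range(z))) / (diff(range(z)) / 2)
  v7 <- as.numeric(outer(zs, 0:7, `^`) %*% co)
  m7 <- fit_profile(data.frame(z = z, v = v7))
  expect_lt(m7$fit_rmse, 1e-6)

  # conversely, a non-polynomial input leaves a nonzero residual
  m_sin <- fit_profile(data.frame(z = z, v = sin(z / 30)))
  expect_gt(m_sin$fit_rmse, 1e-4)
})

test_that("fit RMSE of a noisy sine arc matches a normal-equations oracle", {
  set.seed(8)
  z <- seq(0, 460, length.out = 17)
  v <- 20 * sin(pi * z / 460) + rnorm(17, 0, 0.5)
  m <- fit_profile(data.frame(z = z, v = v))
  # independent route: explicit normal equations on the same scaled basis
  zs <- (z - m$z_center) / m$z_scale
  vand <- outer(zs, 0:7, `^`)
  beta <- solve(crossprod(vand), crossprod(vand, v))
  rmse_oracle <- sqrt(mean((v - vand %*% beta)^2))
  expect_lt(abs(m$fit_rmse - rmse_oracle), 1e-9)
  expect_lt(max(abs(m$coefficients - as.numeric(beta))), 1e-7)
})

test_that("profile fitting rejects deficient input", {
  z <- seq(0, 100, length.out = 8)
  expect_error(fit_profile(data.frame(z = z, v = z)), class = "spinetopo_input_error")
  z17 <- seq(0, 460, length.out = 17)
  z17[2] <- z17[1]
  expect_error(fit_profile(data.frame(z = z17, v = z17)), class = "spinetopo_input_error")
})

test_that("station grids follow the anchoring and truncation rules", {
  m <- fit_profile(data.frame(z = seq(0, 400, length.out = 17),
                              v = seq(0, 400, length.out = 17)))
  s <- sample_profile(m, 20)
  expect_equal(s$z, seq(400, 0, by = -20))
  expect_equal(diff(s$z), rep(-20, 20))

  m2 <- fit_profile(data.frame(z = seq(0, 395, length.out = 17), v = rep(1, 17) + seq(0, 395, length.out = 17) * 0.01))
  s2 <- sample_profile(m2, 20)
  expect_equal(s2$z, seq(395, 15, by = -20))
  expect_false(0 %in% s2$z)

  const <- fit_profile(data.frame(z = seq(0, 400, length.out = 17), v = rep(3.5, 17)))
  s3 <- sample_profile(const, 20)
  expect_equal(s3$v, rep(3.5, 21), tolerance = 1e-10)

  short <- fit_profile(data.frame(z = seq(0, 30, length.out = 17), v = rep(1, 17)))
  expect_error(sample_profile(short, 20), class = "spinetopo_input_error")
})

test_that("finite-difference curvature matches analytic closed forms", {
  # straight line: zero curvature everywhere
  z <- seq(0, 400, by = 20)
  expect_lt(max(line_curvature(z, 2 * z + 1)), 1e-12)

  # circle of radius 200 mm spanning 60 degrees: interior k within 1% of 1/200
  r <- 200
  zc <- seq(-r * sin(pi / 6), r * sin(pi / 6), by = 20)
  yc <- sqrt(r^2 - zc^2)
  k <- line_curvature(zc, yc)
  interior <- k[2:(length(k) - 1)]
  expect_lt(max(abs(interior - 1 / r)) / (1 / r), 0.01)

  # parabola v = z^2 / (2 * 500): curvature at the apex is 1/500
  zp <- seq(-100, 100, by = 20)
  kp <- line_curvature(zp, zp^2 / 1000)
  expect_lt(abs(kp[zp == 0] - 0.002), 2e-5)

  expect_error(line_curvature(1:2, 1:2), class = "spinetopo_input_error")
})

test_that("curvature is invariant under translation/reflection and scales as 1/s", {
  set.seed(10)
  z <- seq(0, 460, by = 20)
  v <- 25 * sin(pi * z / 460) + 3 * cos(z / 50)
  k0 <- line_curvature(z, v)
  expect_equal(line_curvature(z, v + 17.3), k0, tolerance = 1e-12)
  expect_equal(line_curvature(z, -v), k0, tolerance = 1e-12)
  s <- 2.5
  expect_equal(line_curvature(s * z, s * v), k0 / s, tolerance = 1e-10)
})

test_that("finite-difference curvature tracks the analytic polynomial curvature", {
  # smooth synthetic profile: truncation error bound h^2/6 * max|v'''| on the
  # third-derivative term dominates; verify against the exact polynomial k
  cfg <- quiet_config()
  sp <- generate_spine_centerline(demo_row(), cfg, 1)
  series <- project_to_plane(sp, identity_frame(), "sagittal")
  m <- fit_profile(series)
  err_at <- function(h) {
    s_fd <- sample_profile(m, h, curvature = "finite_diff")
    s_an <- sample_profile(m, h, curvature = "analytic")
    interior <- 2:(nrow(s_fd) - 1)
    max(abs(s_fd$k[interior] - s_an$k[interior]))
  }
  e20 <- err_at(20)
  # truncation error is second order in the station spacing: small relative to
  # the curvature scale at 20 mm, and shrinking ~4x when the spacing halves
  expect_lt(e20, 0.05 * max(sample_profile(m, 20, curvature = "analytic")$k))
  expect_lt(err_at(10), e20 / 2.5)
})

test_that("profile RMSD reproduces closed forms and its invariants", {
  z <- seq(0, 400, length.out = 17)
  base <- fit_profile(data.frame(z = z, v = 10 * sin(pi * z / 400)))
  a <- sample_profile(base, 20)
  same <- profile_rmsd(a, a)
  expect_equal(same$rmsd, 0)
  expect_equal(same$mean_distance, 0)
  expect_equal(same$sd_distance, 0)

  shifted <- fit_profile(data.frame(z = z, v = 10 * sin(pi * z / 400) + 21.85))
  b <- sample_profile(shifted, 20)
  const <- profile_rmsd(a, b)
  expect_equal(const$rmsd, 21.85, tolerance = 1e-9)
  expect_equal(const$sd_distance, 0, tolerance = 1e-9)

  # two-station closed form sqrt((3^2 + 4^2)/2) on hand-built samples
  mk <- function(v) {
    out <- data.frame(z = c(40, 20, 0), v = v, k = 0)
    class(out) <- c("sampled_profile", "data.frame")
    out
  }
  d <- profile_rmsd(mk(c(0, 0, 0)), mk(c(3, 4, 0)))
  expect_equal(d$rmsd, sqrt((9 + 16 + 0) / 3))
  d2 <- profile_rmsd(mk(c(0, 0, 5)), mk(c(3, 4, 5)))
  expect_equal(sqrt(mean(c(3, 4)^2)), sqrt(12.5) / sqrt(1), tolerance = 1e-12)
  expect_equal(d2$rmsd, sqrt((9 + 16) / 3), tolerance = 1e-12)

  # symmetry and triangle inequality over matched stations
  set.seed(11)
  mk2 <- function() {
    out <- data.frame(z = seq(400, 0, -20), v = rnorm(21), k = 0)
    class(out) <- c("sampled_profile", "data.frame")
    out
  }
  for (i in 1:10) {
    pa <- mk2(); pb <- mk2(); pc <- mk2()
    dab <- profile_rmsd(pa, pb)$rmsd
    expect_equal(dab, profile_rmsd(pb, pa)$rmsd)
    expect_gte(dab, 0)
    expect_lte(profile_rmsd(pa, pc)$rmsd,
               dab + profile_rmsd(pb, pc)$rmsd + 1e-12)
  }
})

test_that("regional RMSD splits stations at the T12-L1 midpoint", {
  sp <- straight_spine()
  bounds <- region_bounds_from_landmarks(sp)
  zt12 <- sp$points$z[sp$points$label == "T12"]
  zl1 <- sp$points$z[sp$points$label == "L1"]
  expect_equal(bounds$thoracic[1], (zt12 + zl1) / 2)

  z <- sp$points$z
  base <- fit_profile(data.frame(z = z, v = 0.01 * z))
  # offset grows linearly toward caudal: thoracic and lumbar RMSD differ
  off <- fit_profile(data.frame(z = z, v = 0.01 * z + 5 + 0.01 * (max(z) - z)))
  a <- sample_profile(base, 20)
  b <- sample_profile(off, 20)
  r_th <- profile_rmsd(a, b, "thoracic", bounds)
  r_lu <- profile_rmsd(a, b, "lumbar", bounds)
  r_all <- profile_rmsd(a, b, "overall", bounds)
  expect_lt(r_th$rmsd, r_lu$rmsd)
  expect_equal(
    r_all$rmsd^2 * r_all$n_stations,
    r_th$rmsd^2 * r_th$n_stations + r_lu$rmsd^2 * r_lu$n_stations,
    tolerance = 1e-9
  )
  expect_equal(r_th$n_stations + r_lu$n_stations, r_all$n_stations)
})

test_that("rmsd^2 decomposes into mu^2 + sigma^2 (n-1)/n over absolute distances", {
  set.seed(13)
  mk <- function(v) {
    out <- data.frame(z = seq(400, 0, -20), v = v, k = 0)
    class(out) <- c("sampled_profile", "data.frame")
    out
  }
  a <- mk(rnorm(21)); b <- mk(rnorm(21, 3))
  d <- profile_rmsd(a, b)
  n <- d$n_stations
  expect_equal(d$rmsd^2,
               d$mean_distance^2 + d$sd_distance^2 * (n - 1) / n,
               tolerance = 1e-12)
  expect_gte(d$rmsd, d$mean_distance)
})

test_that("pointwise lateral offsets summarise sign and magnitude per level", {
  sp_series <- data.frame(label = vertebral_labels(), v = rep(0, 17))
  same <- marker_pointwise_lateral(sp_series, sp_series)
  expect_equal(same$mean, 0)
  expect_equal(same$left_fraction, 0) # exact zeros are not-left

  left5 <- sp_series
  left5$v <- left5$v + 5
  shifted <- marker_pointwise_lateral(sp_series, left5)
  expect_equal(shifted$mean, 5)
  expect_equal(shifted$sd, 0)
  expect_equal(shifted$left_fraction, 1)

  alt <- sp_series[1:16, ]
  alt$v <- rep(c(2, -2), 8)
  alt_base <- sp_series[1:16, ]
  res <- marker_pointwise_lateral(alt_base, alt)
  expect_equal(res$mean, 0)
  expect_equal(res$left_fraction, 0.5)

  expect_error(marker_pointwise_lateral(sp_series, sp_series[1:10, ]),
               class = "spinetopo_input_error")
})
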