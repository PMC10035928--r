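# Anatomical frames, rigid alignment, patch centroids, plane projection and
# the CSV round trip.

test_that("axis-aligned inputs give the identity frame", {
  fr <- build_frame(c(0, 0, 400), c(35, 0, -70), c(-35, 0, -70), c(0, 1, 0))
  expect_equal(fr$origin, c(0, 0, 400))
  expect_equal(fr$axes, diag(3), tolerance = 1e-12)
})

test_that("frame construction is equivariant under a known rotation", {
  set.seed(42)
  for (i in 1:5) {
    r <- random_rotation()
    l1 <- c(0, 0, 400)
    pl <- c(35, 0, -70)
    pr <- c(-35, 0, -70)
    fr <- build_frame(r %*% l1, r %*% pl, r %*% pr, r %*% c(0, 1, 0))
    expect_equal(fr$axes, r %*% diag(3), tolerance = 1e-9)
    expect_equal(fr$origin, as.numeric(r %*% l1), tolerance = 1e-9)
  }
})

test_that("degenerate frame geometry is rejected", {
  expect_error(
    build_frame(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0)),
    class = "spinetopo_geometry_error"
  )
  # L1-PSIS line parallel to the substrate normal
  expect_error(
    build_frame(c(0, 1, 0), c(0.1, 0, 0), c(-0.1, 0, 0), c(0, 1, 0)),
    class = "spinetopo_geometry_error"
  )
  # orthonormality is enforced on direct construction
  expect_error(anatomical_frame(c(0, 0, 0), diag(3) * 2),
               class = "spinetopo_geometry_error")
})

test_that("frame axes are orthonormal and right-handed for random geometries", {
  set.seed(7)
  for (i in 1:20) {
    l1 <- rnorm(3, sd = 100)
    mid <- rnorm(3, sd = 100)
    if (sqrt(sum((l1 - mid)^2)) < 1) next
    normal <- rnorm(3)
    spread <- rnorm(3, sd = 10)
    fr <- tryCatch(
      build_frame(l1, mid + spread, mid - spread, normal),
      spinetopo_geometry_error = function(e) NULL
    )
    if (is.null(fr)) next
    expect_equal(crossprod(fr$axes), diag(3), tolerance = 1e-9)
    expect_equal(det(fr$axes), 1, tolerance = 1e-9)
  }
})

test_that("rigid alignment recovers exact rigid motions to numerical precision", {
  sp <- straight_spine()
  f <- generate_fiducials(sp, demo_row(), quiet_config(lateral_bias_mm = 5,
                                                       lateral_sd_mm = 2), 3)
  coords <- landmark_coords(f)

  # identity case
  al0 <- align_scan_to_mri(offset_set(f, "SCAN_MARKER"), f)
  expect_lt(al0$rms_residual, 1e-9)
  expect_equal(al0$transform$rotation, diag(3), tolerance = 1e-9)

  set.seed(3)
  for (i in 1:10) {
    r <- random_rotation()
    tr <- rnorm(3, sd = 50)
    moved <- t(r %*% t(coords) + tr)
    pts <- f$points
    pts[, c("x", "y", "z")] <- moved
    scan <- landmark_set(f$subject_id, "SCAN_MARKER", pts, frame = "scan")
    al <- align_scan_to_mri(scan, f)
    expect_lt(al$rms_residual, 1e-9)
    # recovered transform is the inverse motion
    expect_equal(al$transform$rotation %*% r, diag(3), tolerance = 1e-8)
    # residual invariant when both sets undergo a common rigid motion
    r2 <- random_rotation()
    common <- function(s) {
      p <- s$points
      p[, c("x", "y", "z")] <- t(r2 %*% t(as.matrix(p[, c("x", "y", "z")])) + c(1, 2, 3))
      landmark_set(s$subject_id, s$source, p, frame = "scan")
    }
    al2 <- align_scan_to_mri(common(scan), common(f))
    expect_lt(abs(al2$rms_residual - al$rms_residual), 1e-9)
  }
})

test_that("alignment input validation: too few or collinear labels", {
  sp <- straight_spine()
  two <- landmark_set("S001", "SCAN_MARKER", sp$points[1:2, ])
  expect_error(align_scan_to_mri(two, sp), class = "spinetopo_input_error")
  # perfectly collinear shared labels trigger the degeneracy warning
  colin <- offset_set(sp, "SCAN_MARKER", dx = 1)
  expect_warning(align_scan_to_mri(colin, sp), "collinear")
})

test_that("patch centroid matches closed forms and a Monte-Carlo surface integral", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(patch_centroid(tri), c(1 / 3, 1 / 3, 0))
  expect_equal(patch_centroid(tri, rbind(c(1, 2, 3)), mode = "area_weighted"),
               c(1 / 3, 1 / 3, 0))

  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(
    patch_centroid(square, rbind(c(1, 2, 3), c(1, 3, 4)), mode = "area_weighted"),
    c(0.5, 0.5, 0)
  )

  # skewed mesh: one large, one tiny triangle; oracle = uniform sampling over
  # the surface
  verts <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0), c(10.2, 0.2, 0))
  tris <- rbind(c(1, 2, 3), c(2, 4, 3))
  got <- patch_centroid(verts, tris, mode = "area_weighted")
  set.seed(9)
  tri_area <- function(p, q, r) sqrt(sum(cross_oracle(q - p, r - p)^2)) / 2
  cross_oracle <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                                   a[3] * b[1] - a[1] * b[3],
                                   a[1] * b[2] - a[2] * b[1])
  areas <- c(tri_area(verts[1, ], verts[2, ], verts[3, ]),
             tri_area(verts[2, ], verts[4, ], verts[3, ]))
  n_mc <- 2e5
  pick <- sample(1:2, n_mc, replace = TRUE, prob = areas / sum(areas))
  u <- runif(n_mc); v <- runif(n_mc)
  flip <- u + v > 1
  u[flip] <- 1 - u[flip]; v[flip] <- 1 - v[flip]
  pts <- matrix(NA_real_, n_mc, 3)
  for (ti in 1:2) {
    sel <- pick == ti
    p <- verts[tris[ti, 1], ]; q <- verts[tris[ti, 2], ]; r <- verts[tris[ti, 3], ]
    pts[sel, ] <- t(p + outer(q - p, u[sel]) + outer(r - p, v[sel]))
  }
  expect_lt(max(abs(got - colMeans(pts))), 1e-2)

  # vertex-mean permutation invariance and translation equivariance
  set.seed(4)
  vm <- patch_centroid(verts)
  expect_equal(patch_centroid(verts[sample(4), ]), vm)
  expect_equal(patch_centroid(sweep(verts, 2, c(-1, 2, 5), `+`)), vm + c(-1, 2, 5))

  expect_error(patch_centroid(matrix(numeric(0), 0, 3)), class = "spinetopo_input_error")
  degenerate <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(patch_centroid(degenerate, rbind(c(1, 2, 3)), mode = "area_weighted"),
               class = "spinetopo_geometry_error")
})

test_that("surface patch reader round-trips a small ASCII mesh", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# patch", "v 0 0 0", "v 1 0 0", "v 0 1 0", "f 1 2 3"), path)
  patch <- read_surface_patch(path)
  expect_equal(patch$vertices, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(patch$triangles, matrix(c(1L, 2L, 3L), 1))
  expect_equal(patch_centroid(patch$vertices, patch$triangles, "area_weighted"),
               c(1 / 3, 1 / 3, 0))
})

test_that("plane projection extracts frame coordinates with cephalad ordering", {
  sp <- straight_spine()
  pts <- sp$points
  pts$x <- seq_len(17)
  pts$y <- 100 + seq_len(17)
  lm <- landmark_set("S001", "MRI_SPINOUS", pts)
  sag <- project_to_plane(lm, identity_frame(), "sagittal")
  corp <- project_to_plane(lm, identity_frame(), "coronal")
  expect_equal(sag$v, pts$y)
  expect_equal(corp$v, pts$x)
  expect_equal(sag$z, pts$z)
  expect_true(all(diff(sag$z) < 0))

  # translated frame shifts the projected components of the origin
  fr <- identity_frame(origin = c(5, -3, 10))
  sag2 <- project_to_plane(lm, fr, "sagittal")
  expect_equal(sag2$v, pts$y + 3)
  expect_equal(sag2$z, pts$z - 10)

  # rotated frame equals projecting counter-rotated points in the identity frame
  set.seed(12)
  r <- random_rotation()
  fr_rot <- anatomical_frame(c(0, 0, 0), r %*% diag(3))
  pts_rot <- pts
  pts_rot[, c("x", "y", "z")] <- t(r %*% t(as.matrix(pts[, c("x", "y", "z")])))
  lm_rot <- landmark_set("S001", "MRI_SPINOUS", pts_rot, frame = "scan")
  sag3 <- project_to_plane(lm_rot, fr_rot, "sagittal")
  expect_equal(sag3$v[match(sag$label, sag3$label)], sag$v, tolerance = 1e-9)
  expect_equal(sag3$z[match(sag$label, sag3$label)], sag$z, tolerance = 1e-9)
})

test_that("landmark CSV write/read round trip is lossless to 1e-9 mm", {
  coh <- generate_cohort(generator_config(n_subjects = 3, seed = 99))
  lpath <- withr::local_tempfile(fileext = ".csv")
  dpath <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(coh$landmarks, lpath)
  write_demographics(coh$demographics, dpath)
  back <- read_landmarks(lpath)
  expect_equal(length(back), length(coh$landmarks))
  key <- function(s) paste(s$subject_id, s$source, s$session)
  orig <- setNames(coh$landmarks, vapply(coh$landmarks, key, ""))
  for (s in back) {
    o <- orig[[key(s)]]
    expect_equal(landmark_coords(s, o$points$label),
                 landmark_coords(o), tolerance = 1e-9)
  }
  demo <- read_demographics(dpath)
  expect_equal(demo$bmi, coh$demographics$bmi, tolerance = 1e-9)
  expect_equal(as.character(demo$bmi_class), as.character(coh$demographics$bmi_class))
})

test_that("malformed landmark CSVs fail with row-level diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,source,session,label,x_mm,y_mm,z_mm",
    "S001,MRI_SPINOUS,1,T1,0,0,400",
    "S001,MRI_SPINOUS,1,T13,0,0,380"
  ), path)
  expect_error(read_landmarks(path), "T13.*row 3", class = "spinetopo_input_error")

  writeLines(c(
    "subject_id,source,session,label,x_mm,y_mm,z_mm",
    "S001,MRI_SPINOUS,1,T1,0,0,400",
    "S001,MRI_SPINOUS,1,T1,0,0,380"
  ), path)
  expect_error(read_landmarks(path), "duplicate", class = "spinetopo_input_error")

  writeLines(c("subject_id,source,label,x_mm,y_mm,z_mm",
               "S001,MRI_SPINOUS,T1,0,0,400"), path)
  expect_error(read_landmarks(path), "missing column", class = "spinetopo_input_error")
})

test_that("a scan set lacking L1 cannot seed frame construction downstream", {
  sp <- straight_spine()
  f <- generate_fiducials(sp, demo_row(), quiet_config(), 1)
  pts <- f$points[f$points$label != "L1", ]
  expect_error(
    landmark_coords(landmark_set("S001", "MRI_FIDUCIAL", pts), c("L1")),
    class = "spinetopo_input_error"
  )
})
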