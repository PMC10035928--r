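# Anatomical coordinate frames and rigid alignment.
#
# The frame follows the lateral-lying imaging setup: the sagittal plane is
# parallel to the substrate surface, the cephalo-caudal axis runs from the
# midpoint between the two posterior superior iliac spine (PSIS) markers
# toward the L1 marker (projected into the substrate plane), and the
# antero-posterior axis is the substrate normal (posterior positive).

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop_geometry("zero-length vector cannot be normalised")
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Construct an anatomical frame
#'
#' @param origin 3D point (mm), the L1 marker.
#' @param axes 3x3 matrix whose columns are the lateral (+x, subject-left),
#'   antero-posterior (+y, posterior) and cephalo-caudal (+z, cephalad) unit
#'   vectors. Must be orthonormal and right-handed.
#' @return An object of class `anatomical_frame`.
#' @export
anatomical_frame <- function(origin, axes) {
  origin <- as.numeric(origin)
  axes <- unname(as.matrix(axes))
  if (length(origin) != 3L || !all(dim(axes) == c(3L, 3L))) {
    stop_input("frame needs a 3D origin and a 3x3 axes matrix")
  }
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9) {
    stop_geometry("frame axes are not orthonormal")
  }
  if (abs(det(axes) - 1) > 1e-9) {
    stop_geometry("frame axes are not right-handed")
  }
  structure(list(origin = origin, axes = axes), class = "anatomical_frame")
}

#' The identity frame
#'
#' Frame whose axes coincide with the package coordinate convention.
#'
#' @param origin Frame origin, default the global origin.
#' @return An `anatomical_frame`.
#' @export
identity_frame <- function(origin = c(0, 0, 0)) {
  anatomical_frame(origin, diag(3))
}

#' Build the anatomical frame from L1 and PSIS markers
#'
#' The cephalo-caudal axis is the unit vector from the PSIS midpoint toward
#' the L1 marker, projected into the substrate plane; the antero-posterior
#' axis is the substrate normal (posterior positive); the lateral axis
#' completes the right-handed triad. The origin is the L1 marker.
#'
#' @param l1_marker,psis_left,psis_right 3D points (mm).
#' @param substrate_normal Unit vector normal to the substrate surface,
#'   pointing posteriorly; default `c(0, 1, 0)`.
#' @return An `anatomical_frame` with origin at the L1 marker.
#' @export
build_frame <- function(l1_marker, psis_left, psis_right,
                        substrate_normal = c(0, 1, 0)) {
  l1 <- as.numeric(l1_marker)
  mid <- (as.numeric(psis_left) + as.numeric(psis_right)) / 2
  d <- l1 - mid
  if (sqrt(sum(d^2)) < 1e-9) {
    stop_geometry("L1 marker coincides with the PSIS midpoint")
  }
  n <- unit(as.numeric(substrate_normal))
  proj <- d - sum(d * n) * n
  if (sqrt(sum(proj^2)) < 1e-9 * sqrt(sum(d^2))) {
    stop_geometry("L1-PSIS line is parallel to the substrate normal")
  }
  z_axis <- unit(proj)
  y_axis <- n
  x_axis <- cross3(y_axis, z_axis)
  anatomical_frame(l1, cbind(x_axis, y_axis, z_axis))
}

# Express world points (n x 3 matrix) in frame coordinates.
to_frame_coords <- function(points, frame) {
  stopifnot(inherits(frame, "anatomical_frame"))
  points <- rbind(points)
  sweep(points, 2, frame$origin) %*% frame$axes
}

#' @export
print.anatomical_frame <- function(x, ...) {
  cat("<anatomical_frame>\n  origin:", sprintf("%.3f", x$origin), "\n")
  cat("  axes (columns = lateral, posterior, cephalad):\n")
  print(round(x$axes, 6))
  invisible(x)
}

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix (det = +1, orthonormal).
#' @param translation 3-vector (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || length(translation) != 3L) {
    stop_input("rigid transform needs a 3x3 rotation and 3-vector translation")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop_geometry("rotation must be proper orthonormal (no scaling/shear)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to points or a landmark set
#'
#' @param x An n x 3 matrix of points, or a `landmark_set`.
#' @param transform A [rigid_transform()].
#' @param frame Frame tag given to a transformed `landmark_set`, default
#'   `"mri"` (the usual direction of alignment).
#' @return Object of the same kind with transformed coordinates.
#' @export
apply_rigid <- function(x, transform, frame = "mri") {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "landmark_set")) {
    m <- as.matrix(x$points[, c("x", "y", "z")])
    m2 <- t(transform$rotation %*% t(m) + transform$translation)
    pts <- x$points
    pts$x <- m2[, 1]
    pts$y <- m2[, 2]
    pts$z <- m2[, 3]
    return(landmark_set(x$subject_id, x$source, pts, session = x$session,
                        frame = frame))
  }
  t(transform$rotation %*% t(rbind(x)) + transform$translation)
}

# Minimal rotation carrying unit vector a onto unit vector b (Rodrigues).
rotation_between <- function(a, b) {
  v <- cross3(a, b)
  s <- sqrt(sum(v^2))
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # opposite directions: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) unit(cross3(a, c(1, 0, 0))) else unit(cross3(a, c(0, 1, 0)))
    k <- matrix(c(0, perp[3], -perp[2], -perp[3], 0, perp[1], perp[2], -perp[1], 0), 3, 3)
    return(diag(3) + 2 * k %*% k)
  }
  k <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + k + k %*% k * ((1 - c_) / s^2)
}

#' Rigidly align a scan-marker set to MRI fiducials
#'
#' Least-squares rigid superposition (orthogonal Procrustes without scaling,
#' Kabsch algorithm) over the labels shared by the two sets. The recovered
#' transform maps scan coordinates into the MRI frame. If the shared labels
#' are collinear the rotation about that line is unconstrained; the minimal
#' rotation carrying the scan line direction onto the reference direction is
#' used and a warning is raised.
#'
#' @param scan `landmark_set` of scan markers.
#' @param mri_fiducials Reference `landmark_set` in the MRI frame.
#' @return List with `transform` (a `rigid_transform`), `aligned` (the
#'   transformed scan `landmark_set`), `rms_residual` (mm) and `labels` used.
#' @export
align_scan_to_mri <- function(scan, mri_fiducials) {
  stopifnot(inherits(scan, "landmark_set"), inherits(mri_fiducials, "landmark_set"))
  shared <- intersect(scan$points$label, mri_fiducials$points$label)
  if (length(shared) < 3L) {
    stop_input("alignment needs at least 3 shared labels, found ", length(shared))
  }
  a <- landmark_coords(scan, shared)          # source
  b <- landmark_coords(mri_fiducials, shared) # target
  ca <- colMeans(a)
  cb <- colMeans(b)
  ac <- sweep(a, 2, ca)
  bc <- sweep(b, 2, cb)
  sv <- svd(crossprod(ac, bc)) # H = sum a_i b_i^T
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    warning("shared labels are (nearly) collinear; rotation about the line is unconstrained")
    dir_a <- svd(ac)$v[, 1]
    dir_b <- svd(bc)$v[, 1]
    if (sum(dir_a * dir_b) < 0) dir_b <- -dir_b
    rot <- rotation_between(unit(dir_a), unit(dir_b))
  } else {
    d <- sign(det(sv$v %*% t(sv$u)))
    rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  trans <- cb - as.numeric(rot %*% ca)
  tf <- rigid_transform(rot, trans)
  aligned <- apply_rigid(scan, tf, frame = mri_fiducials$frame)
  resid <- landmark_coords(aligned, shared) - b
  rms <- sqrt(mean(rowSums(resid^2)))
  list(transform = tf, aligned = aligned, rms_residual = rms, labels = shared)
}

#' Centroid of a selected surface patch
#'
#' Emulates selecting a marker's surface with a lasso tool and reducing it to
#' one point.
#'
#' @param vertices n x 3 matrix of patch vertex coordinates (mm).
#' @param triangles m x 3 integer matrix of vertex indices (1-based); required
#'   for `mode = "area_weighted"`.
#' @param mode `"vertex_mean"` (arithmetic mean of vertices) or
#'   `"area_weighted"` (area-weighted mean of triangle centroids, i.e. the
#'   surface-integral centroid of the triangulated patch).
#' @return 3D point.
#' @export
patch_centroid <- function(vertices, triangles = NULL,
                           mode = c("vertex_mean", "area_weighted")) {
  mode <- match.arg(mode)
  vertices <- rbind(vertices)
  if (nrow(vertices) == 0L) stop_input("empty patch")
  if (mode == "vertex_mean") {
    return(colMeans(vertices))
  }
  if (is.null(triangles) || nrow(rbind(triangles)) < 1L) {
    stop_input("area_weighted mode needs at least one triangle")
  }
  triangles <- rbind(triangles)
  if (any(triangles < 1L) || any(triangles > nrow(vertices))) {
    stop_input("triangle index out of range")
  }
  centroid <- c(0, 0, 0)
  total <- 0
  for (i in seq_len(nrow(triangles))) {
    p <- vertices[triangles[i, 1], ]
    q <- vertices[triangles[i, 2], ]
    r <- vertices[triangles[i, 3], ]
    area <- sqrt(sum(cross3(q - p, r - p)^2)) / 2
    centroid <- centroid + area * (p + q + r) / 3
    total <- total + area
  }
  if (total <= 0) stop_geometry("patch has zero total area")
  centroid / total
}

#' Read a minimal ASCII surface patch
#'
#' Plain-text mesh table with one element per line: `v x y z` for vertices
#' and `f i j k` for triangles (1-based indices), as in the OBJ subset.
#'
#' @param path File path.
#' @return List with `vertices` (n x 3) and `triangles` (m x 3).
#' @export
read_surface_patch <- function(path) {
  if (!file.exists(path)) stop_io("patch file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse_row <- function(l, n_fields, what) {
    parts <- strsplit(l, "[[:space:]]+")[[1]][-1]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) != n_fields || anyNA(vals)) {
      stop_input("malformed ", what, " line: '", l, "'")
    }
    vals
  }
  v <- t(vapply(lines[startsWith(lines, "v ")], parse_row, numeric(3), 3, "vertex"))
  f <- t(vapply(lines[startsWith(lines, "f ")], parse_row, numeric(3), 3, "face"))
  dimnames(v) <- NULL
  dimnames(f) <- NULL
  if (nrow(v) == 0L) stop_input("patch file contains no vertices")
  list(vertices = v, triangles = if (nrow(f)) matrix(as.integer(f), ncol = 3) else NULL)
}

#' Project landmarks onto an anatomical plane
#'
#' Expresses the landmarks in the frame and returns the planar series used
#' for profile fitting: the cephalo-caudal coordinate z paired with the
#' antero-posterior coordinate (sagittal plane) or the lateral coordinate
#' (coronal plane), both relative to the frame origin, ordered cephalad to
#' caudad.
#'
#' @param landmarks A `landmark_set`.
#' @param frame An `anatomical_frame` (default: identity frame, for landmark
#'   sets already expressed in the package convention).
#' @param plane `"sagittal"` or `"coronal"`.
#' @param labels Which labels to project; default the vertebral chain labels
#'   present in the set.
#' @return Data frame with columns `label`, `z`, `v`, ordered by decreasing z.
#' @export
project_to_plane <- function(landmarks, frame = identity_frame(),
                             plane = c("sagittal", "coronal"), labels = NULL) {
  plane <- match.arg(plane)
  stopifnot(inherits(landmarks, "landmark_set"))
  if (is.null(labels)) {
    labels <- intersect(vertebral_labels(), landmarks$points$label)
  }
  m <- to_frame_coords(landmark_coords(landmarks, labels), frame)
  v <- if (plane == "sagittal") m[, 2] else m[, 1]
  out <- data.frame(label = labels, z = m[, 3], v = v)
  out <- out[order(-out$z), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "plane") <- plane
  out
}
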