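# Labelled 3D landmark sets.
#
# Coordinate convention, fixed package-wide and enforced at I/O:
#   +z cephalad (toward the head), +y posterior, +x subject-left, millimetres.

#' Vertebral landmark labels in cephalo-caudal order
#'
#' The thoracolumbar chain used throughout the package: T1 (most cephalad)
#' through T12, then L1 through L5 (most caudad).
#'
#' @return Character vector of the 17 vertebral labels.
#' @export
vertebral_labels <- function() {
  c(paste0("T", 1:12), paste0("L", 1:5))
}

auxiliary_labels <- function() c("C7", "PSIS_L", "PSIS_R")

landmark_sources <- function() c("MRI_SPINOUS", "MRI_FIDUCIAL", "SCAN_MARKER")

#' Construct a labelled landmark set
#'
#' A landmark set holds the labelled 3D points of one subject, from one
#' measurement source, in one observer session. Points follow the package
#' coordinate convention: +z cephalad, +y posterior, +x subject-left, in
#' millimetres. Vertebral labels must be unique and strictly monotone in z
#' from T1 (largest z) down to L5; the auxiliary labels C7, PSIS_L and PSIS_R
#' (posterior superior iliac spines) are permitted alongside the chain.
#'
#' @param subject_id Subject identifier (single string).
#' @param source One of `"MRI_SPINOUS"` (spinous-process selections),
#'   `"MRI_FIDUCIAL"` (skin fiducial capsules seen in MRI) or `"SCAN_MARKER"`
#'   (surface-scan stickers).
#' @param points Data frame with columns `label`, `x`, `y`, `z` (mm).
#' @param session Observer selection session, default 1.
#' @param frame Frame identifier tag, default `"mri"`.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(subject_id, source, points, session = 1L, frame = "mri") {
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id)) {
    stop_input("subject_id must be a single string")
  }
  if (!source %in% landmark_sources()) {
    stop_input("unknown landmark source '", source, "'")
  }
  required <- c("label", "x", "y", "z")
  if (!is.data.frame(points) || !all(required %in% names(points))) {
    stop_input("points must be a data frame with columns label, x, y, z")
  }
  points <- points[, required]
  points$label <- as.character(points$label)
  for (col in c("x", "y", "z")) {
    if (!is.numeric(points[[col]]) || any(!is.finite(points[[col]]))) {
      stop_input("non-finite coordinate in column '", col, "'")
    }
  }
  known <- c(vertebral_labels(), auxiliary_labels())
  bad <- setdiff(points$label, known)
  if (length(bad)) {
    stop_input("unknown landmark label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(points$label)) {
    dup <- unique(points$label[duplicated(points$label)])
    stop_input("duplicate landmark label(s): ", paste(dup, collapse = ", "))
  }
  # canonical ordering: C7, T1..L5, PSIS pair
  ord <- match(points$label, c("C7", vertebral_labels(), "PSIS_L", "PSIS_R"))
  points <- points[order(ord), , drop = FALSE]
  rownames(points) <- NULL
  # the cephalo-caudal ordering is only meaningful once coordinates follow the
  # anatomical convention; raw scanner-frame sets may be arbitrarily oriented
  vert <- points[points$label %in% vertebral_labels(), ]
  if (identical(frame, "mri") && nrow(vert) >= 2L && any(diff(vert$z) >= 0)) {
    stop_input(
      "vertebral z coordinates must decrease strictly from T1 to L5 ",
      "(subject ", subject_id, ", source ", source, ")"
    )
  }
  structure(
    list(
      subject_id = subject_id,
      source = source,
      session = as.integer(session),
      frame = frame,
      points = points
    ),
    class = "landmark_set"
  )
}

#' Extract landmark coordinates as a matrix
#'
#' @param set A `landmark_set`.
#' @param labels Labels to extract, in this order; defaults to all labels in
#'   the set. Missing labels are an error.
#' @return Numeric matrix with one row per label (rownames = labels) and
#'   columns x, y, z.
#' @export
landmark_coords <- function(set, labels = NULL) {
  stopifnot(inherits(set, "landmark_set"))
  pts <- set$points
  if (is.null(labels)) labels <- pts$label
  idx <- match(labels, pts$label)
  if (anyNA(idx)) {
    stop_input(
      "missing landmark label(s): ",
      paste(labels[is.na(idx)], collapse = ", ")
    )
  }
  m <- as.matrix(pts[idx, c("x", "y", "z")])
  rownames(m) <- labels
  m
}

# TRUE when all 17 vertebral labels are present.
has_full_chain <- function(set) {
  all(vertebral_labels() %in% set$points$label)
}

assert_full_chain <- function(set, what = "landmark set") {
  missing <- setdiff(vertebral_labels(), set$points$label)
  if (length(missing)) {
    stop_input(
      what, " is missing vertebral label(s): ",
      paste(missing, collapse = ", ")
    )
  }
  invisible(set)
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf(
    "<landmark_set> subject %s, %s, session %d, frame '%s', %d points\n",
    x$subject_id, x$source, x$session, x$frame, nrow(x$points)
  ))
  vert <- x$points[x$points$label %in% vertebral_labels(), ]
  if (nrow(vert)) {
    cat(sprintf(
      "  vertebral span: %s (z=%.1f) .. %s (z=%.1f) mm\n",
      vert$label[1], vert$z[1], vert$label[nrow(vert)], vert$z[nrow(vert)]
    ))
  }
  invisible(x)
}
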