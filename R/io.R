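# CSV input/output for landmark sets and demographics.
#
# Landmark CSV dialect: comma-separated, header row, UTF-8, decimal point,
# columns subject_id,source,session,label,x_mm,y_mm,z_mm. Coordinates are in
# the package convention (+z cephalad, +y posterior, +x subject-left, mm).

#' Write landmark sets to a CSV file
#'
#' @param sets A single `landmark_set` or a list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(sets, path) {
  if (inherits(sets, "landmark_set")) sets <- list(sets)
  rows <- lapply(sets, function(s) {
    stopifnot(inherits(s, "landmark_set"))
    data.frame(
      subject_id = s$subject_id,
      source = s$source,
      session = s$session,
      label = s$points$label,
      x_mm = s$points$x,
      y_mm = s$points$y,
      z_mm = s$points$z
    )
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch(
    {
      write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) stop_io("cannot write landmark CSV: ", path)
  invisible(path)
}

#' Read landmark sets from a CSV file
#'
#' Validates labels, sources and uniqueness strictly; errors name the
#' offending row. The write/read round trip is lossless to better than
#' 1e-9 mm.
#'
#' @param path Landmark CSV path (schema in [write_landmarks()]).
#' @return List of `landmark_set`, one per (subject, source, session).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop_io("landmark file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "source", "session", "label", "x_mm", "y_mm", "z_mm")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_input("landmark CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  known <- c(vertebral_labels(), auxiliary_labels())
  bad <- which(!df$label %in% known)
  if (length(bad)) {
    stop_input(
      "unknown landmark label '", df$label[bad[1]], "' at row ", bad[1] + 1L,
      " of ", path
    )
  }
  bad_src <- which(!df$source %in% landmark_sources())
  if (length(bad_src)) {
    stop_input(
      "unknown source '", df$source[bad_src[1]], "' at row ", bad_src[1] + 1L,
      " of ", path
    )
  }
  key <- paste(df$subject_id, df$source, df$session, df$label, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_input(
      "duplicate (subject, source, session, label) at row ", dup[1] + 1L,
      " of ", path, ": ", gsub("\r", "/", key[dup[1]])
    )
  }
  groups <- split(df, paste(df$subject_id, df$source, df$session, sep = "\r"))
  sets <- lapply(groups, function(g) {
    landmark_set(
      g$subject_id[1], g$source[1],
      data.frame(label = g$label, x = g$x_mm, y = g$y_mm, z = g$z_mm),
      session = g$session[1]
    )
  })
  names(sets) <- NULL
  # stable ordering: subject, then source, then session
  ord <- order(
    vapply(sets, function(s) s$subject_id, ""),
    match(vapply(sets, function(s) s$source, ""), landmark_sources()),
    vapply(sets, function(s) s$session, 1L)
  )
  sets[ord]
}

#' Write subject demographics to a CSV file
#'
#' @param demographics Data frame with columns `subject_id`, `gender`, `age`,
#'   `height_m`, `weight_kg` (derived columns `bmi`, `bmi_class` are
#'   recomputed on read and not required).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_demographics <- function(demographics, path) {
  required <- c("subject_id", "gender", "age", "height_m", "weight_kg")
  missing <- setdiff(required, names(demographics))
  if (length(missing)) {
    stop_input("demographics missing column(s): ", paste(missing, collapse = ", "))
  }
  write.csv(demographics[, required], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read subject demographics from a CSV file
#'
#' Recomputes BMI (weight / height^2) and the BMI class (underweight < 18.5,
#' healthy 18.5-24.9, overweight >= 25).
#'
#' @param path Demographics CSV path.
#' @return Data frame with `subject_id`, `gender`, `age`, `height_m`,
#'   `weight_kg`, `bmi`, `bmi_class`.
#' @export
read_demographics <- function(path) {
  if (!file.exists(path)) stop_io("demographics file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "gender", "age", "height_m", "weight_kg")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop_input("demographics CSV missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(!df$gender %in% c("F", "M"))
  if (length(bad)) {
    stop_input("gender must be 'F' or 'M' at row ", bad[1] + 1L, " of ", path)
  }
  bad <- which(!(df$height_m > 0) | !(df$weight_kg > 0))
  if (length(bad)) {
    stop_input("nonpositive height or weight at row ", bad[1] + 1L, " of ", path)
  }
  if (anyDuplicated(df$subject_id)) {
    stop_input("duplicate subject_id in ", path)
  }
  res <- bmi_and_class(df$weight_kg, df$height_m)
  df$bmi <- res$bmi
  df$bmi_class <- res$bmi_class
  df
}
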