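# Per-subject and cohort-level orchestration of the two comparison phases:
# phase 1, spinous-process profile (SCP) vs MRI fiducial-marker profile (FMP);
# phase 2, FMP vs surface-scan marker profile (3MP).

pair_names <- function() c("SCP_vs_FMP", "FMP_vs_3MP")

# Shared station grid for a profile pair: anchored at the shared most
# cephalad domain point, stepping caudally while inside both domains.
common_stations <- function(model_a, model_b, interval) {
  z_max <- min(model_a$domain[2], model_b$domain[2])
  z_min <- max(model_a$domain[1], model_b$domain[1])
  if (z_max - z_min < 2 * interval) {
    stop_input("profile domains overlap by less than two sampling intervals")
  }
  station_grid(z_max, z_min, interval)
}

comparison_row <- function(subject_id, pair, plane, summary_overall,
                           rmsd_thoracic, rmsd_lumbar, ks, ks_type,
                           fit_rmse_ref, fit_rmse_cmp, align_residual = NA_real_) {
  data.frame(
    subject_id = subject_id,
    pair = pair,
    plane = plane,
    n_stations = summary_overall$n_stations,
    rmsd_overall = summary_overall$rmsd,
    rmsd_thoracic = rmsd_thoracic,
    rmsd_lumbar = rmsd_lumbar,
    mean_distance = summary_overall$mean_distance,
    sd_distance = summary_overall$sd_distance,
    signed_lateral_mean = summary_overall$signed_lateral_mean %||% NA_real_,
    left_lateral_fraction = summary_overall$left_lateral_fraction %||% NA_real_,
    ks_type = ks_type,
    ks_d = ks$d,
    ks_p = ks$p,
    ks_mode = ks$mode,
    ks_significant = ks$significant,
    fit_rmse_ref = fit_rmse_ref,
    fit_rmse_cmp = fit_rmse_cmp,
    align_residual = align_residual,
    stringsAsFactors = FALSE
  )
}

#' Analyse one subject's landmark sets
#'
#' Builds the anatomical frame (from the fiducial set's L1 and PSIS markers
#' when present, otherwise the identity frame), rigidly aligns the scan-marker
#' set to the MRI fiducials, projects all sets to the sagittal and coronal
#' planes, fits degree-`degree` polynomial profiles, samples them on shared
#' 20 mm station grids with curvature, and emits the two comparison phases:
#' SCP vs FMP (RMSD by region plus a KS test on the curvature samples) and
#' FMP vs 3MP (RMSD plus a KS test on the sampled coordinate values).
#'
#' @param spine `landmark_set` of MRI spinous-process selections (full T1-L5).
#' @param fiducials `landmark_set` of MRI skin fiducials (full T1-L5).
#' @param scan Optional `landmark_set` of surface-scan markers; when `NULL`
#'   only phase 1 is computed.
#' @param frame Optional `anatomical_frame` overriding frame construction.
#' @param interval Station spacing (mm), default 20.
#' @param degree Profile polynomial degree, default 7.
#' @param alpha KS significance level, default 0.05.
#' @param curvature Curvature mode passed to [sample_profile()].
#' @param ks_endpoints Include the two endpoint stations (one-sided curvature
#'   stencils) in the KS samples; default TRUE.
#' @return Data frame with one row per (pair, plane) comparison.
#' @export
analyze_subject <- function(spine, fiducials, scan = NULL, frame = NULL,
                            interval = 20, degree = 7L, alpha = 0.05,
                            curvature = c("finite_diff", "analytic"),
                            ks_endpoints = TRUE) {
  curvature <- match.arg(curvature)
  stopifnot(inherits(spine, "landmark_set"), inherits(fiducials, "landmark_set"))
  if (spine$source != "MRI_SPINOUS" || fiducials$source != "MRI_FIDUCIAL") {
    stop_input("expected MRI_SPINOUS and MRI_FIDUCIAL landmark sets")
  }
  assert_full_chain(spine, "spinous-process set")
  assert_full_chain(fiducials, "fiducial set")
  if (is.null(frame)) {
    aux <- c("L1", "PSIS_L", "PSIS_R")
    frame <- if (all(aux %in% fiducials$points$label)) {
      m <- landmark_coords(fiducials, aux)
      build_frame(m["L1", ], m["PSIS_L", ], m["PSIS_R", ])
    } else {
      identity_frame()
    }
  }
  align_res <- NULL
  if (!is.null(scan)) {
    stopifnot(inherits(scan, "landmark_set"))
    if (scan$source != "SCAN_MARKER") stop_input("scan set must have source SCAN_MARKER")
    align_res <- align_scan_to_mri(scan, fiducials)
    scan <- align_res$aligned
  }
  rows <- list()
  for (plane in c("sagittal", "coronal")) {
    p_spine <- project_to_plane(spine, frame, plane)
    p_fid <- project_to_plane(fiducials, frame, plane)
    bounds <- list(
      thoracic = {
        mid <- (p_spine$z[p_spine$label == "T12"] +
                  p_spine$z[p_spine$label == "L1"]) / 2
        c(mid, p_spine$z[p_spine$label == "T1"])
      },
      lumbar = c(
        p_spine$z[p_spine$label == "L5"],
        (p_spine$z[p_spine$label == "T12"] +
           p_spine$z[p_spine$label == "L1"]) / 2
      )
    )
    m_spine <- fit_profile(p_spine, degree)
    m_fid <- fit_profile(p_fid, degree)
    st <- common_stations(m_spine, m_fid, interval)
    s_spine <- sample_profile(m_spine, interval, curvature, stations = st)
    s_fid <- sample_profile(m_fid, interval, curvature, stations = st)
    attr(s_spine, "plane") <- plane
    attr(s_fid, "plane") <- plane
    overall <- profile_rmsd(s_spine, s_fid, "overall", bounds, plane = plane)
    ks_idx <- if (ks_endpoints) seq_along(st) else seq_along(st)[-c(1, length(st))]
    ks1 <- ks_two_sample(s_spine$k[ks_idx], s_fid$k[ks_idx], alpha = alpha)
    rows[[length(rows) + 1L]] <- comparison_row(
      spine$subject_id, "SCP_vs_FMP", plane, overall,
      profile_rmsd(s_spine, s_fid, "thoracic", bounds, plane = plane)$rmsd,
      profile_rmsd(s_spine, s_fid, "lumbar", bounds, plane = plane)$rmsd,
      ks1, "curvature", m_spine$fit_rmse, m_fid$fit_rmse
    )
    if (!is.null(scan)) {
      p_scan <- project_to_plane(scan, frame, plane)
      m_scan <- fit_profile(p_scan, degree)
      st2 <- common_stations(m_fid, m_scan, interval)
      s_fid2 <- sample_profile(m_fid, interval, curvature, stations = st2)
      s_scan <- sample_profile(m_scan, interval, curvature, stations = st2)
      attr(s_fid2, "plane") <- plane
      attr(s_scan, "plane") <- plane
      overall2 <- profile_rmsd(s_fid2, s_scan, "overall", bounds, plane = plane)
      ks2 <- ks_two_sample(s_fid2$v, s_scan$v, alpha = alpha)
      rows[[length(rows) + 1L]] <- comparison_row(
        spine$subject_id, "FMP_vs_3MP", plane, overall2,
        profile_rmsd(s_fid2, s_scan, "thoracic", bounds, plane = plane)$rmsd,
        profile_rmsd(s_fid2, s_scan, "lumbar", bounds, plane = plane)$rmsd,
        ks2, "coordinates", m_fid$fit_rmse, m_scan$fit_rmse,
        align_res$rms_residual
      )
    }
  }
  do.call(rbind, rows)
}

# Index a flat list of landmark sets by subject/source/session.
landmark_index <- function(landmarks) {
  keys <- vapply(
    landmarks,
    function(s) paste(s$subject_id, s$source, s$session, sep = "\r"),
    ""
  )
  if (anyDuplicated(keys)) {
    stop_input("duplicate (subject, source, session) landmark sets")
  }
  setNames(landmarks, keys)
}

lookup_set <- function(index, subject_id, source, session = 1L) {
  index[[paste(subject_id, source, session, sep = "\r")]]
}

#' Summarise per-subject comparisons at cohort level
#'
#' Builds the subject-level RMSD table (SCP vs FMP, both planes, three
#' regions), the Pearson correlation matrix against BMI, age and gender
#' (coded female = 1, male = 2), the KS non-significance fractions per pair,
#' plane and BMI class, and the underweight-to-overweight percent change of
#' the overall RMSDs.
#'
#' @param comparisons Data frame of rows from [analyze_subject()].
#' @param demographics Demographics data frame (with `bmi`, `bmi_class`,
#'   `age`, `gender`).
#' @param alpha KS significance level used when the fractions are recomputed,
#'   default 0.05.
#' @return List with `subject_table`, `correlations`, `ks_summary`,
#'   `percent_changes`.
#' @export
summarize_comparisons <- function(comparisons, demographics, alpha = 0.05) {
  scp <- comparisons[comparisons$pair == "SCP_vs_FMP", ]
  subj_ids <- unique(comparisons$subject_id)
  tab <- data.frame(subject_id = subj_ids, stringsAsFactors = FALSE)
  for (plane in c("sagittal", "coronal")) {
    sub <- scp[scp$plane == plane, ]
    idx <- match(tab$subject_id, sub$subject_id)
    tab[[paste0("rmsd_", plane, "_overall")]] <- sub$rmsd_overall[idx]
    tab[[paste0("rmsd_", plane, "_thoracic")]] <- sub$rmsd_thoracic[idx]
    tab[[paste0("rmsd_", plane, "_lumbar")]] <- sub$rmsd_lumbar[idx]
  }
  di <- match(tab$subject_id, demographics$subject_id)
  if (anyNA(di)) {
    stop_input(
      "demographics missing subject(s): ",
      paste(tab$subject_id[is.na(di)], collapse = ", ")
    )
  }
  tab$bmi <- demographics$bmi[di]
  tab$age <- as.numeric(demographics$age[di])
  tab$gender_code <- ifelse(demographics$gender[di] == "F", 1, 2)
  tab$bmi_class <- as.character(demographics$bmi_class[di])

  rmsd_vars <- grep("^rmsd_", names(tab), value = TRUE)
  correlations <- pearson_matrix(tab, c(rmsd_vars, "bmi", "age", "gender_code"))

  classes <- c("all", levels(bmi_class(numeric(0))))
  ks_rows <- list()
  for (pair in intersect(pair_names(), unique(comparisons$pair))) {
    for (plane in c("sagittal", "coronal")) {
      sub <- comparisons[comparisons$pair == pair & comparisons$plane == plane, ]
      cls <- tab$bmi_class[match(sub$subject_id, tab$subject_id)]
      for (cl in classes) {
        keep <- if (cl == "all") rep(TRUE, nrow(sub)) else cls == cl
        n <- sum(keep)
        ks_rows[[length(ks_rows) + 1L]] <- data.frame(
          pair = pair, plane = plane, bmi_class = cl, n_subjects = n,
          n_nonsignificant = sum(!sub$ks_significant[keep]),
          nonsig_fraction = if (n > 0) mean(!sub$ks_significant[keep]) else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  ks_summary <- do.call(rbind, ks_rows)

  pct <- lapply(c("rmsd_sagittal_overall", "rmsd_coronal_overall"), function(v) {
    value <- tryCatch(
      group_percent_change(tab[[v]], tab$bmi_class, "underweight", "overweight"),
      error = function(e) NA_real_
    )
    data.frame(metric = v, from = "underweight", to = "overweight",
               percent_change = value, stringsAsFactors = FALSE)
  })
  list(
    subject_table = tab,
    correlations = correlations,
    ks_summary = ks_summary,
    percent_changes = do.call(rbind, pct)
  )
}

#' Observer reliability between two selection sessions
#'
#' Pools the matched points of the supplied landmark-set pairs (matched by
#' source and label) and computes the single-measure two-way random-effects
#' ICC separately for the antero-posterior, lateral and cephalo-caudal
#' coordinates.
#'
#' @param session1,session2 A `landmark_set` or list of them; each set in
#'   `session1` must have a counterpart with the same subject and source in
#'   `session2`, covering identical labels.
#' @param type ICC form, see [icc_two_session()].
#' @return Data frame with one row per axis: `axis`, `icc`, `agreement`,
#'   `n_points`.
#' @export
run_reliability <- function(session1, session2, type = "agreement") {
  if (inherits(session1, "landmark_set")) session1 <- list(session1)
  if (inherits(session2, "landmark_set")) session2 <- list(session2)
  if (length(session1) != length(session2) || !length(session1)) {
    stop_input("sessions must supply the same nonempty number of landmark sets")
  }
  key <- function(s) paste(s$subject_id, s$source)
  k2 <- vapply(session2, key, "")
  m1 <- list()
  m2 <- list()
  for (s1 in session1) {
    j <- match(key(s1), k2)
    if (is.na(j)) stop_input("no session-2 counterpart for ", key(s1))
    s2 <- session2[[j]]
    if (!setequal(s1$points$label, s2$points$label)) {
      stop_input("label mismatch between sessions for ", key(s1))
    }
    labels <- s1$points$label
    m1[[length(m1) + 1L]] <- landmark_coords(s1, labels)
    m2[[length(m2) + 1L]] <- landmark_coords(s2, labels)
  }
  a <- do.call(rbind, m1)
  b <- do.call(rbind, m2)
  axes <- c(lateral = "x", `antero-posterior` = "y", `cephalo-caudal` = "z")
  rows <- lapply(names(axes), function(nm) {
    col <- axes[[nm]]
    res <- icc_two_session(a[, col], b[, col], type = type, axis = nm)
    data.frame(
      axis = nm, icc = res$icc, agreement = res$agreement,
      n_points = res$n, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Analyse a full cohort
#'
#' Runs [analyze_subject()] for every subject, aggregates the comparisons
#' with [summarize_comparisons()], computes the per-level lateral offset
#' statistics of the fiducials relative to the spinous processes, and the
#' reliability ICCs for subjects carrying duplicate-session MRI selections.
#' Subjects without a scan set are retained for phase 1 and excluded (with a
#' message) from phase 2.
#'
#' @param landmarks A `spine_cohort` from [generate_cohort()], or a list of
#'   `landmark_set` objects.
#' @param demographics Demographics data frame (ignored when `landmarks` is a
#'   `spine_cohort`).
#' @param alpha KS significance level, default 0.05.
#' @param interval Station spacing (mm), default 20.
#' @param degree Profile polynomial degree, default 7.
#' @param ... Further arguments passed to [analyze_subject()].
#' @return An object of class `cohort_results`: list with `comparisons`,
#'   `subject_table`, `correlations`, `ks_summary`, `percent_changes`,
#'   `lateral`, `reliability`, `counts`, `alpha`.
#' @export
analyze_cohort <- function(landmarks, demographics = NULL, alpha = 0.05,
                           interval = 20, degree = 7L, ...) {
  config <- NULL
  if (inherits(landmarks, "spine_cohort")) {
    demographics <- landmarks$demographics
    config <- landmarks$config
    landmarks <- landmarks$landmarks
  }
  if (is.null(demographics)) stop_input("demographics are required")
  index <- landmark_index(landmarks)
  comparisons <- list()
  lateral_levels <- list()
  subject_lateral <- numeric(0)
  n_missing_scan <- 0L
  for (i in seq_len(nrow(demographics))) {
    sid <- demographics$subject_id[i]
    spine <- lookup_set(index, sid, "MRI_SPINOUS")
    fid <- lookup_set(index, sid, "MRI_FIDUCIAL")
    if (is.null(spine) || is.null(fid)) {
      stop_input("subject ", sid, " is missing required MRI landmark sets")
    }
    scan <- lookup_set(index, sid, "SCAN_MARKER")
    if (is.null(scan)) n_missing_scan <- n_missing_scan + 1L
    comparisons[[i]] <- analyze_subject(
      spine, fid, scan,
      interval = interval, degree = degree, alpha = alpha, ...
    )
    lat <- marker_pointwise_lateral(
      project_to_plane(spine, plane = "coronal"),
      project_to_plane(fid, plane = "coronal",
                       labels = intersect(vertebral_labels(), fid$points$label))
    )
    lateral_levels[[i]] <- lat$per_level$lateral_mm
    subject_lateral[sid] <- lat$mean
  }
  if (n_missing_scan > 0L) {
    message(n_missing_scan, " subject(s) without scan sets excluded from phase 2")
  }
  comparisons <- do.call(rbind, comparisons)
  summaries <- summarize_comparisons(comparisons, demographics, alpha)
  pooled <- unlist(lateral_levels)
  lateral <- list(
    pooled_mean = mean(pooled),
    pooled_sd = sd(pooled),
    left_subject_fraction = mean(subject_lateral > 0),
    n_levels = length(pooled),
    n_subjects = length(subject_lateral)
  )
  # reliability from duplicate-session MRI selections, per subject
  rel_rows <- list()
  for (sid in demographics$subject_id) {
    s1 <- Filter(Negate(is.null), list(
      lookup_set(index, sid, "MRI_SPINOUS", 1L),
      lookup_set(index, sid, "MRI_FIDUCIAL", 1L)
    ))
    s2 <- Filter(Negate(is.null), list(
      lookup_set(index, sid, "MRI_SPINOUS", 2L),
      lookup_set(index, sid, "MRI_FIDUCIAL", 2L)
    ))
    if (length(s2) == length(s1) && length(s2) > 0L) {
      rel <- run_reliability(s1, s2)
      rel$subject_id <- sid
      rel_rows[[length(rel_rows) + 1L]] <- rel
    }
  }
  reliability <- if (length(rel_rows)) do.call(rbind, rel_rows) else NULL
  structure(
    c(
      list(comparisons = comparisons),
      summaries,
      list(
        lateral = lateral,
        reliability = reliability,
        counts = list(
          n_subjects = nrow(demographics),
          n_with_scan = nrow(demographics) - n_missing_scan,
          n_reliability = if (is.null(reliability)) 0L else length(unique(reliability$subject_id)),
          bmi_classes = table(demographics$bmi_class)
        ),
        alpha = alpha,
        config = config
      )
    ),
    class = "cohort_results"
  )
}

#' @export
print.cohort_results <- function(x, ...) {
  cat(sprintf(
    "<cohort_results> %d subjects (%d with scans)\n",
    x$counts$n_subjects, x$counts$n_with_scan
  ))
  scp <- x$comparisons[x$comparisons$pair == "SCP_vs_FMP", ]
  for (plane in c("sagittal", "coronal")) {
    v <- scp$rmsd_overall[scp$plane == plane]
    cat(sprintf(
      "  SCP vs FMP %s RMSD: %.2f +/- %.2f mm\n", plane, mean(v), sd(v)
    ))
  }
  ks_all <- x$ks_summary[x$ks_summary$bmi_class == "all", ]
  for (i in seq_len(nrow(ks_all))) {
    cat(sprintf(
      "  KS nonsignificant (%s, %s): %.0f%%\n",
      ks_all$pair[i], ks_all$plane[i], 100 * ks_all$nonsig_fraction[i]
    ))
  }
  invisible(x)
}

#' Write the cohort report files
#'
#' Writes the per-subject comparison CSV, the correlation CSV, the KS summary
#' CSV, and a JSON run manifest carrying the configuration, counts, lateral
#' statistics, percent changes and reliability ICCs.
#'
#' @param results A `cohort_results` object.
#' @param path Output directory (created if needed).
#' @return Character vector of the four file paths, invisibly.
#' @export
write_report <- function(results, path) {
  stopifnot(inherits(results, "cohort_results"))
  ok <- dir.exists(path) || dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_io("cannot create output directory: ", path)
  f_comp <- file.path(path, "per_subject_comparisons.csv")
  f_corr <- file.path(path, "correlations.csv")
  f_ks <- file.path(path, "ks_summary.csv")
  f_manifest <- file.path(path, "manifest.json")
  write.csv(results$comparisons, f_comp, row.names = FALSE)
  write.csv(results$correlations, f_corr, row.names = FALSE)
  write.csv(results$ks_summary, f_ks, row.names = FALSE)
  manifest <- list(
    package = "spinetopo",
    version = as.character(packageVersion("spinetopo")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    alpha = results$alpha,
    counts = list(
      n_subjects = results$counts$n_subjects,
      n_with_scan = results$counts$n_with_scan,
      n_reliability = results$counts$n_reliability,
      bmi_classes = as.list(results$counts$bmi_classes)
    ),
    lateral = results$lateral,
    percent_changes = results$percent_changes,
    reliability = results$reliability,
    config = if (!is.null(results$config)) unclass(results$config) else NULL
  )
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(f_comp, f_corr, f_ks, f_manifest))
}
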