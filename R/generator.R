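# Synthetic cohort generator.
#
# Emulates the measurement structure of a paired MRI / surface-scan study of
# healthy adults lying laterally: an internal spinous-process chain (T1-L5)
# with thoracic kyphosis and lumbar lordosis plus mild coronal deviation;
# skin fiducial capsules displaced posteriorly from the bone by a
# BMI-dependent adipose offset with a subject-left lateral bias; and
# surface-scan markers equal to the fiducials plus a smooth low-order
# posture-misalignment field and sub-millimetre repositioning noise.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe a 50-subject healthy adult cohort: BMI 22.82 +/- 3.22
#' kg/m2 truncated to 16-31 so all three BMI classes occur, age 23.48 +/- 2.79
#' years, an even gender split, a ~462 mm T1-L5 chain (27 mm thoracic / 33 mm
#' lumbar inter-level spacing), 25 mm thoracic kyphosis and 20 mm lumbar
#' lordosis amplitudes, a posterior adipose offset of 1.3 mm + 0.9 mm per BMI
#' unit, and a subject-left lateral marker bias of 5.17 +/- 2.83 mm. Posture
#' misalignment between modalities is a smooth quadratic field, 12 mm coronal /
#' 2 mm sagittal amplitude by default.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Master seed; every random draw derives from it through fixed
#'   per-subject streams, so adding a subject never perturbs earlier ones.
#' @param spacing_mm Inter-level gaps, cephalad to caudad (T1-T2 ... L4-L5);
#'   16 positive values.
#' @param kyphosis_mm,lordosis_mm Sagittal arc amplitudes (posterior thoracic
#'   bulge / anterior lumbar bulge), mm, >= 0.
#' @param inflection_level Vertebral level at whose caudal boundary the
#'   sagittal curve crosses zero (default "T12": thoracolumbar junction).
#' @param coronal_dev_mm Amplitude of the mild coronal deviation arc, mm.
#' @param shape_jitter_sd Relative SD of per-subject multiplicative variation
#'   of the three arc amplitudes (0 disables).
#' @param spine_noise_sd_mm Per-level SD of in-plane (x, y) irregularity of
#'   the spinous-process points around the smooth arcs, mm: anatomical
#'   level-to-level variation plus MRI voxel-selection error. Default 0.8, of
#'   the order of the profile fit RMSE reported in comparable MRI studies.
#' @param adipose_intercept_mm,adipose_slope_mm_per_bmi Posterior offset model
#'   intercept (mm) and slope (mm per BMI unit).
#' @param adipose_noise_sd_mm Per-level SD of the posterior offset, mm.
#' @param adipose_subject_sd_mm Between-subject SD of adipose thickness at
#'   equal BMI, mm.
#' @param lateral_bias_mm,lateral_sd_mm Mean (+ = subject-left) and SD of the
#'   per-level lateral fiducial offset, mm.
#' @param lateral_smooth_frac Fraction of the lateral offset variance carried
#'   by a smooth (degree <= 2) field along the chain, the remainder being
#'   independent per-level placement jitter; adipose distortion is spatially
#'   continuous, so most of the variance is smooth by default (0.95). Set to 0
#'   for independent per-level draws.
#' @param posture_coronal_mm,posture_sagittal_mm Amplitudes of the smooth
#'   (degree <= 2) posture-misalignment field between scan and MRI, mm.
#' @param reposition_sd_mm Isotropic scan-marker repositioning noise SD, mm.
#' @param observer_sd_mm Isotropic observer re-selection noise SD for
#'   duplicate-session landmark sets, mm.
#' @param n_reliability Number of leading subjects that receive duplicate
#'   (session 2) MRI selections for reliability analysis.
#' @param age_mean,age_sd,age_range Age distribution (years; truncated normal,
#'   rounded to integers).
#' @param bmi_mean,bmi_sd,bmi_range BMI distribution (kg/m2; truncated normal).
#' @param height_mean_f,height_mean_m,height_sd Height distribution by gender
#'   (metres); weight is derived from BMI and height.
#' @param female_fraction Fraction of female subjects (assigned
#'   deterministically, interleaved, so a 0.5 split is exact for even n).
#' @return A validated object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 50L,
                             seed = 1L,
                             spacing_mm = c(rep(27, 11), rep(33, 5)),
                             kyphosis_mm = 25,
                             lordosis_mm = 20,
                             inflection_level = "T12",
                             coronal_dev_mm = 3,
                             shape_jitter_sd = 0.1,
                             spine_noise_sd_mm = 0.8,
                             adipose_intercept_mm = 1.3,
                             adipose_slope_mm_per_bmi = 0.9,
                             adipose_noise_sd_mm = 0.5,
                             adipose_subject_sd_mm = 3.0,
                             lateral_bias_mm = 5.17,
                             lateral_sd_mm = 2.83,
                             lateral_smooth_frac = 0.95,
                             posture_coronal_mm = 12,
                             posture_sagittal_mm = 2,
                             reposition_sd_mm = 0.5,
                             observer_sd_mm = 0.5,
                             n_reliability = min(2L, n_subjects),
                             age_mean = 23.48,
                             age_sd = 2.79,
                             age_range = c(18, 30),
                             bmi_mean = 22.82,
                             bmi_sd = 3.22,
                             bmi_range = c(16, 31),
                             height_mean_f = 1.65,
                             height_mean_m = 1.78,
                             height_sd = 0.06,
                             female_fraction = 0.5) {
  cfg <- structure(
    list(
      n_subjects = as.integer(n_subjects),
      seed = as.integer(seed),
      spacing_mm = as.numeric(spacing_mm),
      kyphosis_mm = kyphosis_mm,
      lordosis_mm = lordosis_mm,
      inflection_level = inflection_level,
      coronal_dev_mm = coronal_dev_mm,
      shape_jitter_sd = shape_jitter_sd,
      spine_noise_sd_mm = spine_noise_sd_mm,
      adipose_intercept_mm = adipose_intercept_mm,
      adipose_slope_mm_per_bmi = adipose_slope_mm_per_bmi,
      adipose_noise_sd_mm = adipose_noise_sd_mm,
      adipose_subject_sd_mm = adipose_subject_sd_mm,
      lateral_bias_mm = lateral_bias_mm,
      lateral_sd_mm = lateral_sd_mm,
      lateral_smooth_frac = lateral_smooth_frac,
      posture_coronal_mm = posture_coronal_mm,
      posture_sagittal_mm = posture_sagittal_mm,
      reposition_sd_mm = reposition_sd_mm,
      observer_sd_mm = observer_sd_mm,
      n_reliability = as.integer(n_reliability),
      age_mean = age_mean, age_sd = age_sd, age_range = as.numeric(age_range),
      bmi_mean = bmi_mean, bmi_sd = bmi_sd, bmi_range = as.numeric(bmi_range),
      height_mean_f = height_mean_f, height_mean_m = height_mean_m,
      height_sd = height_sd,
      female_fraction = female_fraction
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 1L) stop_input("n_subjects must be >= 1")
  if (length(cfg$spacing_mm) != 16L || any(cfg$spacing_mm <= 0)) {
    stop_input("spacing_mm must hold 16 positive inter-level gaps (T1-T2 .. L4-L5)")
  }
  sds <- c(
    cfg$shape_jitter_sd, cfg$spine_noise_sd_mm,
    cfg$adipose_noise_sd_mm, cfg$adipose_subject_sd_mm,
    cfg$lateral_sd_mm, cfg$reposition_sd_mm, cfg$observer_sd_mm,
    cfg$age_sd, cfg$bmi_sd, cfg$height_sd
  )
  if (any(sds < 0)) stop_input("all standard deviations must be >= 0")
  if (cfg$kyphosis_mm < 0 || cfg$lordosis_mm < 0 || cfg$coronal_dev_mm < 0 ||
      cfg$posture_coronal_mm < 0 || cfg$posture_sagittal_mm < 0) {
    stop_input("amplitudes must be >= 0")
  }
  if (!cfg$inflection_level %in% vertebral_labels()[-17]) {
    stop_input("inflection_level must be a vertebral level above L5")
  }
  if (cfg$n_reliability < 0L || cfg$n_reliability > cfg$n_subjects) {
    stop_input("n_reliability must be between 0 and n_subjects")
  }
  if (cfg$female_fraction < 0 || cfg$female_fraction > 1) {
    stop_input("female_fraction must be in [0, 1]")
  }
  if (cfg$lateral_smooth_frac < 0 || cfg$lateral_smooth_frac > 1) {
    stop_input("lateral_smooth_frac must be in [0, 1]")
  }
  cfg
}

#' Read a generator configuration from a YAML file
#'
#' Keys are the argument names of [generator_config()]; unknown keys are an
#' error. Missing keys take the documented defaults.
#'
#' @param path Path to a YAML file.
#' @return A `generator_config`.
#' @export
load_generator_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: ", path)
  values <- yaml::read_yaml(path)
  if (is.null(values)) values <- list()
  known <- names(formals(generator_config))
  bad <- setdiff(names(values), known)
  if (length(bad)) {
    stop_input("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  do.call(generator_config, values)
}

# z station (mm) of each vertebral level, L5 = 0, T1 = total chain length.
spine_stations <- function(cfg) {
  z <- rev(cumsum(rev(c(cfg$spacing_mm, 0))))
  setNames(z, vertebral_labels())
}

# Normalised inflection position t0 in (0,1): midpoint between the inflection
# level and the next level down, as a fraction of chain length (t=1 at T1).
inflection_t0 <- function(cfg) {
  z <- spine_stations(cfg)
  i <- match(cfg$inflection_level, names(z))
  ((z[[i]] + z[[i + 1L]]) / 2) / z[["T1"]]
}

# Sagittal double-arc shape: a quartic polynomial in normalised position t
# (t=0 at L5, t=1 at T1),
#     y(t) = t (1-t) (t - t0) (a + b t),
# vanishing at both chain ends and at the thoracolumbar inflection t0. The
# two free coefficients are solved so that the continuous maximum over the
# thoracic lobe (t0,1) equals +kyphosis and the minimum over the lumbar lobe
# (0,t0) equals -lordosis exactly. Degree 4 keeps a degree-7 profile fit
# exact by construction.
sagittal_arc <- function(kyphosis, lordosis, t0) {
  base <- function(t) t * (1 - t) * (t - t0)
  if (kyphosis == 0 && lordosis == 0) {
    return(function(t) rep(0, length(t)))
  }
  if (kyphosis == 0 || lordosis == 0) {
    # exactly one lobe present: a single parabolic arc over the whole chain
    # with exact amplitude, signed posterior for kyphosis-only
    amp <- if (lordosis == 0) kyphosis else -lordosis
    return(function(t) amp * 4 * t * (1 - t))
  }
  a <- kyphosis / optimize(base, c(t0, 1), maximum = TRUE)$objective
  b <- 0
  tol <- .Machine$double.eps^0.5
  for (iter in 1:100) {
    f <- function(t) base(t) * (a + b * t)
    t_th <- optimize(f, c(t0, 1), maximum = TRUE, tol = tol)$maximum
    t_lu <- optimize(f, c(0, t0), tol = tol)$minimum
    m <- rbind(
      c(base(t_th), t_th * base(t_th)),
      c(base(t_lu), t_lu * base(t_lu))
    )
    sol <- solve(m, c(kyphosis, -lordosis))
    delta <- max(abs(sol - c(a, b)))
    a <- sol[1]
    b <- sol[2]
    if (delta < 1e-12 * max(1, abs(a), abs(b))) break
  }
  function(t) base(t) * (a + b * t)
}

# Coronal deviation: single parabolic arc, exact amplitude at mid-chain.
coronal_arc <- function(amplitude) {
  function(t) amplitude * 4 * t * (1 - t)
}

# Derived per-subject RNG stream seeds (double arithmetic, kept below 2^31).
subject_seed <- function(master, i, stream) {
  as.integer(((as.numeric(master) %% 1e5) * 19997 + i * 211 + stream * 7) %%
               2147483629) + 1L
}

#' Generate the spinous-process chain for one subject
#'
#' Places the 17 T1-L5 spinous-process landmarks on the configured double-arc
#' sagittal shape (thoracic kyphosis posterior, lumbar lordosis anterior) and
#' mild coronal deviation arc. The arc amplitudes receive per-subject
#' multiplicative jitter of relative SD `shape_jitter_sd`; all other
#' coordinates are deterministic functions of the configuration. Identical
#' `(subject, config, rng_seed)` yield bit-identical output.
#'
#' @param subject One row of a cohort demographics data frame (needs
#'   `subject_id`).
#' @param config A [generator_config()].
#' @param rng_seed Integer seed for this subject's shape jitter.
#' @return A `landmark_set` with source `"MRI_SPINOUS"`.
#' @export
generate_spine_centerline <- function(subject, config, rng_seed) {
  config <- validate_generator_config(config)
  z <- spine_stations(config)
  t <- z / z[["T1"]]
  draws <- withr::with_seed(rng_seed, {
    mult <- if (config$shape_jitter_sd > 0) {
      pmax(1 + rnorm(3, 0, config$shape_jitter_sd), 0.2)
    } else {
      c(1, 1, 1)
    }
    irregular <- if (config$spine_noise_sd_mm > 0) {
      matrix(rnorm(2 * length(z), 0, config$spine_noise_sd_mm), ncol = 2)
    } else {
      matrix(0, length(z), 2)
    }
    list(mult = mult, irregular = irregular)
  })
  mult <- draws$mult
  sag <- sagittal_arc(
    config$kyphosis_mm * mult[1], config$lordosis_mm * mult[2],
    inflection_t0(config)
  )
  corf <- coronal_arc(config$coronal_dev_mm * mult[3])
  pts <- data.frame(
    label = names(z),
    x = corf(t) + draws$irregular[, 1],
    y = sag(t) + draws$irregular[, 2],
    z = as.numeric(z)
  )
  landmark_set(subject$subject_id, "MRI_SPINOUS", pts)
}

#' Generate skin fiducial markers from a spinous-process chain
#'
#' Each fiducial sits posterior to its spinous process by a BMI-dependent
#' adipose offset (intercept + slope x BMI + between-subject term + per-level
#' Gaussian noise, floored just above zero so markers are always posterior)
#' and is displaced laterally by a per-level draw biased toward subject-left.
#' Posterior superior iliac spine markers (PSIS_L/PSIS_R) are appended for
#' frame construction.
#'
#' @param spine `landmark_set` with the full T1-L5 chain.
#' @param subject Demographics row with `subject_id` and `bmi`.
#' @param config A [generator_config()].
#' @param rng_seed Integer seed for this subject's offset draws.
#' @return A `landmark_set` with source `"MRI_FIDUCIAL"`.
#' @export
generate_fiducials <- function(spine, subject, config, rng_seed) {
  config <- validate_generator_config(config)
  assert_full_chain(spine, "spine centerline")
  sp <- landmark_coords(spine, vertebral_labels())
  n <- nrow(sp)
  # Lateral adipose distortion is spatially continuous: split its variance
  # into a smooth degree-<=2 field along the chain (fraction
  # lateral_smooth_frac) plus independent per-level placement jitter, with
  # average per-level variance equal to lateral_sd_mm^2.
  zr <- range(sp[, "z"])
  u <- (sp[, "z"] - mean(zr)) / (diff(zr) / 2)
  phi1 <- u
  phi2 <- 2 * u^2 - 1
  draws <- withr::with_seed(rng_seed, {
    c1 <- rnorm(1)
    c2 <- rnorm(1)
    rho <- config$lateral_smooth_frac
    smooth <- config$lateral_sd_mm * sqrt(rho) *
      (c1 * phi1 / sqrt(2 * mean(phi1^2)) + c2 * phi2 / sqrt(2 * mean(phi2^2)))
    jitter <- rnorm(n, 0, config$lateral_sd_mm * sqrt(1 - rho))
    list(
      subj = rnorm(1, 0, config$adipose_subject_sd_mm),
      post = rnorm(n, 0, config$adipose_noise_sd_mm),
      lat = config$lateral_bias_mm + smooth + jitter,
      psis = rnorm(4, 0, config$adipose_noise_sd_mm)
    )
  })
  base_off <- config$adipose_intercept_mm +
    config$adipose_slope_mm_per_bmi * subject$bmi + draws$subj
  post_off <- pmax(base_off + draws$post, 1e-6)
  pts <- data.frame(
    label = rownames(sp),
    x = sp[, "x"] + draws$lat,
    y = sp[, "y"] + post_off,
    z = sp[, "z"]
  )
  # PSIS skin markers near the sacrum, below L5, at skin depth
  l5 <- sp["L5", ]
  psis_y <- max(base_off, 1e-6)
  psis <- data.frame(
    label = c("PSIS_L", "PSIS_R"),
    x = c(35, -35) + draws$psis[1:2],
    y = l5[["y"]] + psis_y + draws$psis[3:4],
    z = l5[["z"]] - 70
  )
  landmark_set(spine$subject_id, "MRI_FIDUCIAL", rbind(pts, psis))
}

#' Generate surface-scan markers from fiducials
#'
#' Scan markers equal the fiducials plus a smooth posture-misalignment field
#' (a random polynomial of degree <= 2 in the cephalo-caudal coordinate,
#' normalised so its maximum absolute value over the vertebral chain equals
#' the configured amplitude, independently for the coronal and sagittal
#' components) plus isotropic repositioning noise. Zero amplitudes and zero
#' noise reproduce the fiducials exactly.
#'
#' @param fiducials `landmark_set` with the full T1-L5 chain.
#' @param config A [generator_config()].
#' @param rng_seed Integer seed for this subject's posture field and noise.
#' @return A `landmark_set` with source `"SCAN_MARKER"`.
#' @export
generate_scan_markers <- function(fiducials, config, rng_seed) {
  config <- validate_generator_config(config)
  assert_full_chain(fiducials, "fiducial set")
  pts <- fiducials$points
  vert <- pts$label %in% vertebral_labels()
  zr <- range(pts$z[vert])
  u <- (pts$z - mean(zr)) / (diff(zr) / 2) # [-1, 1] over the chain
  field <- function(amplitude, coefs) {
    if (amplitude == 0) return(rep(0, length(u)))
    g <- coefs[1] + coefs[2] * u + coefs[3] * (2 * u^2 - 1)
    m <- max(abs(g[vert]))
    if (m < 1e-12) return(rep(0, length(u)))
    amplitude * g / m
  }
  out <- withr::with_seed(rng_seed, {
    cx <- rnorm(3)
    cy <- rnorm(3)
    noise <- if (config$reposition_sd_mm > 0) {
      matrix(rnorm(3 * nrow(pts), 0, config$reposition_sd_mm), ncol = 3)
    } else {
      matrix(0, nrow(pts), 3)
    }
    list(cx = cx, cy = cy, noise = noise)
  })
  pts$x <- pts$x + field(config$posture_coronal_mm, out$cx) + out$noise[, 1]
  pts$y <- pts$y + field(config$posture_sagittal_mm, out$cy) + out$noise[, 2]
  pts$z <- pts$z + out$noise[, 3]
  landmark_set(fiducials$subject_id, "SCAN_MARKER", pts, frame = "scan")
}

# Truncated-normal sampling by rejection (deterministic under a seed).
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(n)
  filled <- 0L
  while (filled < n) {
    draw <- rnorm(n, mean, sd)
    keep <- draw[draw >= lo & draw <= hi]
    take <- min(length(keep), n - filled)
    if (take > 0L) {
      out[(filled + 1L):(filled + take)] <- keep[seq_len(take)]
      filled <- filled + take
    }
  }
  out
}

# Deterministic interleaved gender assignment with the exact configured split.
assign_gender <- function(n, female_fraction) {
  counts <- floor(seq_len(n) * female_fraction + 1e-9)
  ifelse(diff(c(0, counts)) == 1, "F", "M")
}

#' Generate a complete synthetic cohort
#'
#' Draws demographics (gender, age, height, BMI-derived weight) and, per
#' subject, the spinous-process chain, fiducial markers and scan markers.
#' The first `n_reliability` subjects additionally carry session-2 duplicates
#' of both MRI sources with isotropic observer re-selection noise. The
#' function is pure and deterministic: identical configurations produce
#' byte-identical cohorts, and every subject draws from its own derived seed
#' stream so earlier subjects are unaffected by `n_subjects`.
#'
#' @param config A [generator_config()].
#' @return An object of class `spine_cohort`: list with `demographics`
#'   (data frame: subject_id, gender, age, height_m, weight_kg, bmi,
#'   bmi_class), `landmarks` (list of `landmark_set`) and `config`.
#' @export
generate_cohort <- function(config) {
  config <- validate_generator_config(config)
  n <- config$n_subjects
  gender <- assign_gender(n, config$female_fraction)
  demo <- do.call(rbind, lapply(seq_len(n), function(i) {
    withr::with_seed(subject_seed(config$seed, i, 0L), {
      age <- round(rtrunc_norm(
        1, config$age_mean, config$age_sd,
        config$age_range[1], config$age_range[2]
      ))
      bmi <- rtrunc_norm(
        1, config$bmi_mean, config$bmi_sd,
        config$bmi_range[1], config$bmi_range[2]
      )
      hmean <- if (gender[i] == "F") config$height_mean_f else config$height_mean_m
      height <- rtrunc_norm(1, hmean, config$height_sd, 1.40, 2.10)
      data.frame(
        subject_id = sprintf("S%03d", i),
        gender = gender[i],
        age = as.integer(age),
        height_m = height,
        weight_kg = bmi * height^2,
        bmi = bmi
      )
    })
  }))
  demo$bmi_class <- bmi_class(demo$bmi)
  landmarks <- list()
  for (i in seq_len(n)) {
    subj <- demo[i, ]
    spine <- generate_spine_centerline(subj, config, subject_seed(config$seed, i, 1L))
    fid <- generate_fiducials(spine, subj, config, subject_seed(config$seed, i, 2L))
    scan <- generate_scan_markers(fid, config, subject_seed(config$seed, i, 3L))
    sets <- list(spine, fid, scan)
    if (i <= config$n_reliability) {
      sets <- c(sets, list(
        jitter_landmarks(spine, config$observer_sd_mm, subject_seed(config$seed, i, 4L)),
        jitter_landmarks(fid, config$observer_sd_mm, subject_seed(config$seed, i, 5L))
      ))
    }
    landmarks <- c(landmarks, sets)
  }
  structure(
    list(demographics = demo, landmarks = landmarks, config = config),
    class = "spine_cohort"
  )
}

# Session-2 duplicate of a landmark set: same anatomy, new observer selection
# with isotropic noise on every coordinate.
jitter_landmarks <- function(set, sd, rng_seed) {
  pts <- set$points
  noise <- withr::with_seed(rng_seed, {
    if (sd > 0) matrix(rnorm(3 * nrow(pts), 0, sd), ncol = 3) else matrix(0, nrow(pts), 3)
  })
  pts$x <- pts$x + noise[, 1]
  pts$y <- pts$y + noise[, 2]
  pts$z <- pts$z + noise[, 3]
  landmark_set(set$subject_id, set$source, pts, session = set$session + 1L,
               frame = set$frame)
}

#' @export
print.spine_cohort <- function(x, ...) {
  cat(sprintf(
    "<spine_cohort> %d subjects, %d landmark sets (seed %d)\n",
    nrow(x$demographics), length(x$landmarks), x$config$seed
  ))
  print(table(x$demographics$bmi_class))
  invisible(x)
}
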