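# Shared fixtures: small, fully deterministic configurations and hand-built
# landmark sets used across the module tests.

# Generator config with every stochastic term switched off, for closed-form
# checks of the deterministic generator skeleton.
quiet_config <- function(...) {
  base <- list(
    n_subjects = 1L,
    shape_jitter_sd = 0,
    spine_noise_sd_mm = 0,
    adipose_noise_sd_mm = 0,
    adipose_subject_sd_mm = 0,
    lateral_bias_mm = 0,
    lateral_sd_mm = 0,
    posture_coronal_mm = 0,
    posture_sagittal_mm = 0,
    reposition_sd_mm = 0,
    observer_sd_mm = 0,
    n_reliability = 0L
  )
  do.call(generator_config, utils::modifyList(base, list(...)))
}

demo_row <- function(subject_id = "S001", bmi = 22, gender = "F", age = 24,
                     height = 1.7) {
  data.frame(
    subject_id = subject_id, gender = gender, age = as.integer(age),
    height_m = height, weight_kg = bmi * height^2, bmi = bmi,
    bmi_class = bmi_class(bmi)
  )
}

# Straight vertical chain (all x = y = 0), convenient base for hand-built
# subjects with known offsets.
straight_spine <- function(subject_id = "S001") {
  z <- rev(cumsum(rev(c(rep(27, 11), rep(33, 5), 0))))
  landmark_set(
    subject_id, "MRI_SPINOUS",
    data.frame(label = vertebral_labels(), x = 0, y = 0, z = z)
  )
}

# Offset copy of a landmark set with a different source tag.
offset_set <- function(set, source, dx = 0, dy = 0, dz = 0) {
  pts <- set$points
  pts$x <- pts$x + dx
  pts$y <- pts$y + dy
  pts$z <- pts$z + dz
  landmark_set(set$subject_id, source, pts, session = set$session)
}

random_rotation <- function() {
  repeat {
    q <- rnorm(4)
    if (sqrt(sum(q^2)) > 1e-6) break
  }
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}
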