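# Seeded synthetic kinematics generator for the six advanced activities of
# daily living (AADLs), standing in for a motion-capture corpus. Each trial is
# a smooth humerus pose series (shoulder position + orientation quaternion)
# with a locked elbow. Trajectories are sums of 1-3 harmonically related
# sinusoids per rotation axis with per-trial randomized amplitude, phase and
# speed -- qualitative emulation of cyclic/ballistic shoulder motion, not
# marker-level realism.

ACTIVITIES <- c("jumping_jack", "jug_lift", "underhand_toss", "jogging",
                "internal_rotation", "briefcase_carry")

WEIGHTED_ACTIVITIES <- c("jug_lift", "briefcase_carry")

DEFAULT_HANDHELD <- c(briefcase_carry = 4.5, jug_lift = 3.8)

#' Activities known to the generator
#' @export
activity_names <- function() ACTIVITIES

#' Per-activity kinematic template
#'
#' Means and inter-subject SDs of the angular amplitudes (rad) about the
#' abduction (x), flexion (y) and axial-rotation (z) axes, the fundamental
#' frequency (Hz), baseline posture, locked elbow angle, shoulder translation
#' amplitudes (m) and the handheld mass (kg, weighted activities only).
#' Defaults qualitatively match the activity descriptions: jumping jack is
#' ab/adduction-dominant and fast; rapid internal rotation is axial-rotation
#' dominant; briefcase carry is a near-vertical arm with small oscillation and
#' a handheld weight; jug lift is a slower elevation arc with the elbow
#' straight and a handheld jug.
#'
#' @param activity one of [activity_names()].
#' @param duration trial duration, s.
#' @param sample_rate Hz.
#' @param handheld_masses named overrides for the briefcase / jug masses, kg.
#' @return object of class `activity_params`.
#' @export
activity_params <- function(activity, duration = 5, sample_rate = 100,
                            handheld_masses = DEFAULT_HANDHELD) {
  if (!activity %in% ACTIVITIES) {
    stop("unknown activity: ", activity, call. = FALSE)
  }
  stopifnot(duration > 0, sample_rate > 0)
  tpl <- switch(activity,
    jumping_jack = list(
      freq = 1.0, mean = c(0.9, 0.1, 0.0), amp = c(1.05, 0.15, 0.20),
      amp_sd = c(0.15, 0.05, 0.05), harmonics = 2L,
      trans_amp = c(0, 0, 0.05), trans_freq = 2.0, elbow = pi / 2),
    jug_lift = list(
      freq = 0.35, mean = c(0.1, 0.8, 0.0), amp = c(0.10, 0.70, 0.10),
      amp_sd = c(0.03, 0.10, 0.03), harmonics = 2L,
      trans_amp = c(0, 0.02, 0.02), trans_freq = 0.35, elbow = 0),
    underhand_toss = list(
      freq = 0.8, mean = c(0.1, 0.3, 0.0), amp = c(0.15, 0.90, 0.15),
      amp_sd = c(0.05, 0.15, 0.05), harmonics = 3L,
      trans_amp = c(0, 0.03, 0.02), trans_freq = 0.8, elbow = pi / 2),
    jogging = list(
      freq = 1.4, mean = c(0.05, 0.1, 0.0), amp = c(0.08, 0.35, 0.10),
      amp_sd = c(0.02, 0.05, 0.03), harmonics = 2L,
      trans_amp = c(0, 0.02, 0.04), trans_freq = 2.8, elbow = pi / 2),
    internal_rotation = list(
      freq = 1.5, mean = c(0.15, 0.1, 0.0), amp = c(0.10, 0.10, 1.20),
      amp_sd = c(0.03, 0.03, 0.15), harmonics = 2L,
      trans_amp = c(0, 0, 0), trans_freq = 1.5, elbow = pi / 2),
    briefcase_carry = list(
      freq = 1.0, mean = c(0.05, 0.05, 0.0), amp = c(0.08, 0.08, 0.05),
      amp_sd = c(0.02, 0.02, 0.02), harmonics = 2L,
      trans_amp = c(0, 0.03, 0.02), trans_freq = 2.0, elbow = 0)
  )
  handheld <- if (activity %in% WEIGHTED_ACTIVITIES) {
    unname(handheld_masses[[activity]])
  } else 0
  structure(
    c(list(activity = activity, duration = duration,
           sample_rate = sample_rate, handheld_mass = handheld,
           speed_sd = 0.08, omega_cap = 20), tpl),
    class = "activity_params"
  )
}

#' Draw a synthetic subject
#'
#' Stature uniform between 1.6 and 1.9 m; body mass between 44.1 and
#' 123.7 kg,
#' positively correlated with stature (a stature-driven component plus an
#' independent uniform component). Segment lengths scale with stature
#' (upper arm 0.186 x stature by default); joint widths scale mildly with
#' stature. Draws consume the current R random stream, so results are a pure
#' function of the seed.
#'
#' @param id subject identifier (metadata).
#' @param upper_arm_fraction upper-arm length as a fraction of stature.
#' @return a [subject_anthropometry()] with a `subject_id` attribute.
#' @export
sample_subject <- function(id = 1L, upper_arm_fraction = 0.186) {
  stature <- stats::runif(1, 1.6, 1.9)
  us <- (stature - 1.6) / 0.3
  mass <- 44.1 + (123.7 - 44.1) * (0.6 * us + 0.4 * stats::runif(1))
  subj <- subject_anthropometry(
    body_mass = mass, stature = stature,
    upper_arm_length = upper_arm_fraction * stature,
    elbow_width = 0.060 + 0.012 * us,
    wrist_width = 0.050 + 0.010 * us,
    sex_label = if (stats::runif(1) < 0.5) "F" else "M"
  )
  attr(subj, "subject_id") <- id
  subj
}

#' Motion trial container
#'
#' @param activity activity label.
#' @param time strictly increasing, uniformly sampled time vector, s.
#' @param position n x 3 shoulder position, m, gravity-aligned z-up frame.
#' @param quaternion n x 4 unit humerus orientation (w, x, y, z).
#' @param elbow_flexion locked elbow flexion angle, rad (constant).
#' @param handheld_mass kg (> 0 only for weighted activities).
#' @param sample_rate Hz.
#' @param subject_id,trial_index,seed metadata.
#' @export
motion_trial <- function(activity, time, position, quaternion, elbow_flexion,
                         handheld_mass = 0, sample_rate = 1 / diff(time[1:2]),
                         subject_id = NA, trial_index = NA, seed = NA) {
  position <- as.matrix(position)
  quaternion <- as.matrix(quaternion)
  n <- length(time)
  stopifnot(nrow(position) == n, ncol(position) == 3,
            nrow(quaternion) == n, ncol(quaternion) == 4,
            length(elbow_flexion) == 1L)
  if (n >= 2 && any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (quat_norm_error(quaternion) > 1e-6) {
    stop("quaternion norm drift exceeds 1e-6", call. = FALSE)
  }
  if (handheld_mass > 0 && !activity %in% WEIGHTED_ACTIVITIES) {
    stop("handheld mass only allowed for ",
         paste(WEIGHTED_ACTIVITIES, collapse = ", "), call. = FALSE)
  }
  structure(
    list(activity = activity, time = time, position = position,
         quaternion = quat_normalize(quaternion),
         elbow_flexion = elbow_flexion, handheld_mass = handheld_mass,
         sample_rate = sample_rate, subject_id = subject_id,
         trial_index = trial_index, seed = seed),
    class = "motion_trial"
  )
}

# decaying-harmonic angle series: mean + sum_j (A/j^2) sin(2 pi f j t + phi_j)
harmonic_angle <- function(t, mean, amp, freq, harmonics, phases) {
  th <- rep(mean, length(t))
  for (j in seq_len(harmonics)) {
    th <- th + amp / j^2 * sin(2 * pi * freq * j * t + phases[j])
  }
  th
}

#' Generate one synthetic motion trial
#'
#' Humerus orientation is composed as intrinsic rotations
#' `Rx(abduction) Ry(flexion) Rz(axial)`; each angle is a smooth sum of
#' decaying harmonics whose base amplitude is drawn once per trial from the
#' template's normal law (truncated at zero), with a per-trial speed factor.
#' Trials whose peak angular speed exceeds the plausibility cap (default
#' 20 rad/s) are redrawn. Draws consume the current R random stream.
#'
#' @param activity one of [activity_names()].
#' @param subject a [subject_anthropometry()] (metadata; trials are poses).
#' @param params an [activity_params()]; defaults to the activity template.
#' @param subject_id,trial_index,seed metadata stamped on the trial.
#' @return a [motion_trial()].
#' @export
generate_trial <- function(activity, subject = NULL,
                           params = activity_params(activity),
                           subject_id = NA, trial_index = NA, seed = NA) {
  if (!activity %in% ACTIVITIES) {
    stop("unknown activity: ", activity, call. = FALSE)
  }
  n <- round(params$duration * params$sample_rate) + 1L
  t <- seq(0, params$duration, length.out = n)
  dt <- t[2] - t[1]
  for (attempt in 1:20) {
    speed <- max(0.5, 1 + stats::rnorm(1, 0, params$speed_sd))
    f <- params$freq * speed
    amps <- pmax(0, stats::rnorm(3, params$amp, params$amp_sd))
    phases <- matrix(stats::runif(3 * params$harmonics, 0, 2 * pi), 3)
    th_x <- harmonic_angle(t, params$mean[1], amps[1], f, params$harmonics,
                           phases[1, ])
    th_y <- harmonic_angle(t, params$mean[2], amps[2], f, params$harmonics,
                           phases[2, ])
    th_z <- harmonic_angle(t, params$mean[3], amps[3], f, params$harmonics,
                           phases[3, ])
    q <- quat_multiply(
      quat_multiply(quat_from_axis_angle(c(1, 0, 0), th_x),
                    quat_from_axis_angle(c(0, 1, 0), th_y)),
      quat_from_axis_angle(c(0, 0, 1), th_z))
    # plausibility gate on raw finite-difference angular speed
    R9 <- quat_to_rotmat9(q)
    Rd <- fdiff(R9, dt)
    w2 <- (Rd[, 7] * R9[, 4] + Rd[, 8] * R9[, 5] + Rd[, 9] * R9[, 6])^2 +
      (Rd[, 1] * R9[, 7] + Rd[, 2] * R9[, 8] + Rd[, 3] * R9[, 9])^2 +
      (Rd[, 4] * R9[, 1] + Rd[, 5] * R9[, 2] + Rd[, 6] * R9[, 3])^2
    if (sqrt(max(w2)) <= params$omega_cap) break
    if (attempt == 20) {
      stop("could not generate a trial under the angular-velocity cap",
           call. = FALSE)
    }
  }
  tf <- params$trans_freq * speed
  tphase <- stats::runif(3, 0, 2 * pi)
  pos <- cbind(
    params$trans_amp[1] * sin(2 * pi * tf * t + tphase[1]),
    params$trans_amp[2] * sin(2 * pi * tf * t + tphase[2]),
    params$trans_amp[3] * sin(2 * pi * tf * t + tphase[3])
  )
  motion_trial(activity, t, pos, q, params$elbow,
               handheld_mass = params$handheld_mass,
               sample_rate = params$sample_rate,
               subject_id = if (!is.null(subject) &&
                                !is.null(attr(subject, "subject_id"))) {
                 attr(subject, "subject_id")
               } else subject_id,
               trial_index = trial_index, seed = seed)
}

#' Write / read a motion trial as CSV
#'
#' Lossless full-precision round trip. Metadata travel in `# key: value`
#' header lines; data columns are
#' `time, px, py, pz, qw, qx, qy, qz, elbow_flexion, handheld_mass`.
#'
#' @param trial a [motion_trial()].
#' @param path file path.
#' @export
write_trial_csv <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(activity = trial$activity, sample_rate = trial$sample_rate,
            subject_id = trial$subject_id, trial_index = trial$trial_index,
            seed = trial$seed)
  writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  df <- data.frame(time = trial$time,
                   px = trial$position[, 1], py = trial$position[, 2],
                   pz = trial$position[, 3],
                   qw = trial$quaternion[, 1], qx = trial$quaternion[, 2],
                   qy = trial$quaternion[, 3], qz = trial$quaternion[, 4],
                   elbow_flexion = trial$elbow_flexion,
                   handheld_mass = trial$handheld_mass)
  writeLines(paste(names(df), collapse = ","), con)
  writeLines(do.call(paste, c(lapply(df, function(x) sprintf("%.17g", x)),
                              sep = ",")), con)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_lines]) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    meta[[trimws(key)]] <- trimws(sub("^[^:]*:\\s*", "", kv))
  }
  body_start <- if (length(meta_lines)) max(meta_lines) + 1L else 1L
  header <- strsplit(lines[body_start], ",")[[1]]
  expected <- c("time", "px", "py", "pz", "qw", "qx", "qy", "qz",
                "elbow_flexion", "handheld_mass")
  missing <- setdiff(expected, header)
  if (length(missing)) {
    stop("parse error at line ", body_start, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  rows <- lines[(body_start + 1L):length(lines)]
  rows <- rows[nzchar(rows)]
  parsed <- strsplit(rows, ",")
  nfield <- lengths(parsed)
  if (any(nfield != length(header))) {
    bad <- which(nfield != length(header))[1]
    stop("parse error at line ", body_start + bad,
         ": expected ", length(header), " fields, found ", nfield[bad],
         call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(parsed))),
              ncol = length(header), byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("parse error at line ", body_start + bad, ": non-numeric field",
         call. = FALSE)
  }
  colnames(m) <- header
  strip <- function(x) { dimnames(x) <- NULL; x }
  q <- strip(m[, c("qw", "qx", "qy", "qz"), drop = FALSE])
  if (quat_norm_error(q) > 1e-6) {
    stop("validation error: quaternion norm drift exceeds 1e-6", call. = FALSE)
  }
  num_or_na <- function(x) if (is.null(x) || x == "NA") NA else as.numeric(x)
  motion_trial(
    activity = meta$activity %||% "unknown",
    time = unname(m[, "time"]),
    position = strip(m[, c("px", "py", "pz"), drop = FALSE]),
    quaternion = q, elbow_flexion = unname(m[1, "elbow_flexion"]),
    handheld_mass = unname(m[1, "handheld_mass"]),
    sample_rate = as.numeric(meta$sample_rate %||% (1 / diff(m[1:2, "time"]))),
    subject_id = num_or_na(meta$subject_id),
    trial_index = num_or_na(meta$trial_index),
    seed = num_or_na(meta$seed)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
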