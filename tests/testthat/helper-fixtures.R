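# Shared fixtures: all built in code, no stored data.

test_subject <- function(body_mass = 70, stature = 1.75) {
  subject_anthropometry(body_mass, stature)
}

# prosthetic model at a given level, defaulting to study connector settings
prosthetic_model <- function(category = "advanced", level = 0.25,
                             subject = test_subject(),
                             pylon_linear_density = 1.0, adapter_mass = 0.10,
                             rod_inertia = FALSE) {
  cfg <- amputation_config(level, pylon_linear_density = pylon_linear_density,
                           adapter_mass = adapter_mass)
  m <- attach_prosthesis(
    apply_virtual_amputation(build_intact_model(subject), cfg),
    prosthesis_preset(category), cfg)
  if (rod_inertia) m$segments$transverse_radius <- 0
  m
}

# constant-pose trial (statics fixture)
static_trial <- function(quat = c(1, 0, 0, 0), elbow = 0, n = 201,
                         duration = 2, activity = "jogging",
                         handheld_mass = 0, position = c(0, 0, 0)) {
  t <- seq(0, duration, length.out = n)
  motion_trial(activity, t, matrix(position, n, 3, byrow = TRUE),
               matrix(quat / sqrt(sum(quat^2)), n, 4, byrow = TRUE),
               elbow, handheld_mass = handheld_mass)
}

# relative load-series discrepancy, scaled by the peak force / moment norms
# (straight-elbow poses make torsion ~ 0, so per-component ratios are 0/0)
load_rel_err <- function(a, b) {
  Fn <- max(sqrt(b$Fx^2 + b$Fy^2 + b$Fz^2))
  Mn <- max(sqrt(b$Mx^2 + b$My^2 + b$Mz^2))
  max(
    max(abs(a$Fx - b$Fx), abs(a$Fy - b$Fy), abs(a$Fz - b$Fz),
        abs(a$axial - b$axial)) / Fn,
    max(abs(a$Mx - b$Mx), abs(a$My - b$My), abs(a$Mz - b$Mz),
        abs(a$bending - b$bending), abs(a$torsion - b$torsion)) / Mn
  )
}

# long-format synthetic peak table with a known multiplicative variant effect
simulate_peak_table <- function(n_subjects, ratio, sigma_log,
                                trials = 3, subject_sd = 0.2,
                                baseline = c(bending = 25, torsion = 15,
                                             axial = 100)) {
  rows <- list()
  for (s in seq_len(n_subjects)) {
    b_s <- stats::rnorm(1, 0, subject_sd)
    for (variant in c("intact", "prosthetic")) {
      eff <- if (variant == "intact") 0 else log(ratio)
      for (tr in seq_len(trials)) {
        noise <- stats::rnorm(3, 0, sigma_log)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = s, model_variant = variant, trial_index = tr,
          bending_peak = exp(log(baseline[["bending"]]) + b_s + eff + noise[1]),
          torsion_peak = exp(log(baseline[["torsion"]]) + b_s + eff + noise[2]),
          axial_peak = exp(log(baseline[["axial"]]) + b_s + eff + noise[3]))
      }
    }
  }
  do.call(rbind, rows)
}

reference_peaks <- function() {
  utils::read.csv(system.file("extdata", "reference_peak_loads.csv",
                              package = "oiload", mustWork = TRUE))
}
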