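test_that("zero-phase filter preserves constants and trends, removes noise", {
  x <- rep(3.7, 200)
  expect_equal(filter_lowpass(x, 6, 100), x, tolerance = 1e-9)
  tr <- seq(0, 5, length.out = 200)
  expect_equal(filter_lowpass(tr, 6, 100), tr, tolerance = 1e-6)
  set.seed(1)
  noisy <- sin(2 * pi * 1 * seq(0, 2, by = 0.01)) # 1 Hz signal
  hf <- 0.5 * sin(2 * pi * 40 * seq(0, 2, by = 0.01)) # 40 Hz noise
  y <- filter_lowpass(noisy + hf, 6, 100)
  expect_lt(max(abs(y - noisy)[20:180]), 0.02)
})

test_that("constant pose differentiates to exact zeros", {
  model <- prosthetic_model("advanced", 0.25)
  kin <- differentiate_poses(static_trial(elbow = pi / 2), model, 6)
  expect_lt(max(abs(kin$omega)), 1e-9)
  expect_lt(max(abs(kin$alpha)), 1e-9)
  expect_lt(max(abs(kin$a_sh)), 1e-9)
  for (s in kin$segments) expect_lt(max(abs(s$acc)), 1e-9)
})

test_that("uniform rotation recovers the closed-form angular speed", {
  n <- 501
  t <- seq(0, 5, length.out = n)
  Om <- 2
  q <- cbind(cos(Om * t / 2), 0, 0, sin(Om * t / 2))
  tr <- motion_trial("jogging", t, matrix(0, n, 3), q, pi / 2)
  kin <- differentiate_poses(tr, prosthetic_model(), 6)
  speed <- sqrt(rowSums(kin$omega^2))
  expect_lt(max(abs(speed[25:475] - Om)) / Om, 1e-3)
})

test_that("parabolic translation recovers the constant acceleration", {
  n <- 501
  t <- seq(0, 5, length.out = n)
  a <- c(0.3, -0.2, 0.5)
  tr <- motion_trial("jogging", t, 0.5 * outer(t^2, a),
                     matrix(rep(c(1, 0, 0, 0), each = n), n, 4), pi / 2)
  kin <- differentiate_poses(tr, prosthetic_model(), 6)
  err <- abs(sweep(kin$a_sh[50:450, ], 2, a))
  expect_lt(max(err) / max(abs(a)), 1e-3)
})

test_that("short or non-uniform trials are rejected", {
  model <- prosthetic_model()
  expect_error(differentiate_poses(static_trial(n = 4), model), "5 samples")
  t <- c(0, 0.01, 0.025, 0.04, 0.06, 0.09)
  tr <- motion_trial("jogging", t, matrix(0, 6, 3),
                     matrix(rep(c(1, 0, 0, 0), each = 6), 6, 4), 0)
  expect_error(differentiate_poses(tr, model), "uniform")
})

test_that("static vertical hang matches closed-form statics", {
  # advanced prosthesis at 75%: no pylon, adapter 0.1 kg + 1.875 + 1.525 kg
  model <- prosthetic_model("advanced", 0.75)
  kin <- differentiate_poses(static_trial(elbow = 0), model, 6)
  loads <- interface_loads(model, kin)
  expect_equal(loads$axial, rep((0.1 + 1.875 + 1.525) * 9.81, kin$n),
               tolerance = 1e-9)
  expect_lt(max(loads$bending), 1e-9)
  expect_lt(max(loads$torsion), 1e-9)
})

test_that("static horizontal arm matches the hand-computed moment sum", {
  subj <- test_subject()
  model <- prosthetic_model("myoelectric_hand", 0.5, subject = subj)
  # rotate arm to horizontal: body distal (0,0,-1) -> world (0,1,0)
  q <- quat_from_axis_angle(c(1, 0, 0), pi / 2)
  kin <- differentiate_poses(static_trial(quat = q, elbow = 0), model, 6)
  loads <- interface_loads(model, kin)

  segs <- model$segments
  plane <- model$interface_position
  distal <- segs[segs$branch == "forearm" |
                   (segs$branch == "humerus" & segs$attach >= plane - 1e-12), ]
  arc <- ifelse(distal$branch == "humerus",
                distal$attach + distal$com_offset * distal$length,
                model$upper_arm_length + distal$attach +
                  distal$com_offset * distal$length)
  expected_bending <- 9.81 * sum(distal$mass * (arc - plane))
  expect_equal(loads$bending, rep(expected_bending, kin$n), tolerance = 1e-9)
  expect_lt(max(abs(loads$axial)), 1e-9)
})

test_that("zero-mass chain with a handheld mass reduces to the point mass", {
  model <- prosthetic_model("advanced", 0.25)
  model$segments$mass <- 0
  model <- set_handheld_mass(model, 1)
  tr <- static_trial(activity = "briefcase_carry", elbow = 0,
                     handheld_mass = 0)
  kin <- differentiate_poses(tr, model, 6)
  loads <- interface_loads(model, kin, handheld_mass = 1)
  expect_equal(loads$axial, rep(9.81, kin$n), tolerance = 1e-9)
  d <- sqrt(sum((kin$handheld_pos[1, ] - kin$p_interface[1, ])^2))
  expect_lt(max(loads$bending), 1e-9) # point mass on the long axis

  # with zero handheld too, everything vanishes
  zero <- interface_loads(model, kin, handheld_mass = 0)
  expect_lt(max(abs(as.matrix(zero[, -1]))), 1e-12)
  orc <- point_mass_oracle(model, kin, 50, handheld_mass = 0)
  expect_lt(max(abs(as.matrix(orc[, -1]))), 1e-12)
})

test_that("resolve_components obeys the stated decompositions", {
  r <- resolve_components(c(0, 0, -10), c(0, 0, 0), c(0, 0, 1))
  expect_equal(r$axial, -10) # compressive
  r <- resolve_components(c(0, 0, 0), c(3, 4, 0), c(0, 0, 1))
  expect_equal(r$bending, 5)
  expect_equal(r$torsion, 0)
  r <- resolve_components(c(0, 0, 0), c(0, 0, 7), c(0, 0, 1))
  expect_equal(r$torsion, 7)
  expect_equal(r$bending, 0)
  expect_error(resolve_components(c(1, 0, 0), c(0, 0, 0), c(0, 0, 2)),
               "unit")
  # invariant: bending^2 + torsion^2 = |M|^2
  set.seed(3)
  M <- matrix(rnorm(30), 10, 3)
  u <- c(1, 2, 2) / 3
  r <- resolve_components(matrix(0, 10, 3), M, u)
  expect_equal(r$bending^2 + r$torsion^2, rowSums(M^2), tolerance = 1e-12)
})

test_that("point-mass oracle agrees with Newton-Euler loads", {
  set.seed(21)
  subj <- test_subject()
  # statics at random orientations: 1e-9
  for (i in 1:5) {
    model <- prosthetic_model(sample(prosthesis_categories(), 1),
                              sample(c(0.25, 0.5, 0.75), 1),
                              subject = subj, rod_inertia = TRUE)
    ax <- stats::rnorm(3)
    q <- quat_from_axis_angle(ax / sqrt(sum(ax^2)), stats::runif(1, 0, pi))
    kin <- differentiate_poses(static_trial(quat = q, elbow = pi / 3), model, 6)
    expect_lt(load_rel_err(interface_loads(model, kin),
                           point_mass_oracle(model, kin, 200)), 1e-9)
  }
  # dynamics on generated trials
  for (i in 1:3) {
    act <- sample(activity_names(), 1)
    model <- prosthetic_model(sample(prosthesis_categories(), 1),
                              sample(c(0.25, 0.5, 0.75), 1),
                              subject = subj, rod_inertia = TRUE)
    tr <- generate_trial(act, subj, activity_params(act, duration = 2))
    kin <- differentiate_poses(tr, model, 6)
    expect_lt(load_rel_err(interface_loads(model, kin),
                           point_mass_oracle(model, kin, 1000)), 1e-3)
  }
})

test_that("oracle discretization converges with n_points", {
  set.seed(8)
  subj <- test_subject()
  model <- prosthetic_model("advanced", 0.25, subject = subj,
                            rod_inertia = TRUE)
  tr <- generate_trial("jumping_jack", subj,
                       activity_params("jumping_jack", duration = 2))
  kin <- differentiate_poses(tr, model, 6)
  ref <- interface_loads(model, kin)
  errs <- vapply(c(10, 40, 160), function(np) {
    load_rel_err(point_mass_oracle(model, kin, np), ref)
  }, numeric(1))
  expect_true(all(diff(errs) < 0)) # monotone refinement
  expect_lt(errs[3] / errs[1], 1 / 50) # ~ O(1/n^2)
})

test_that("loads are frame-invariant under a global rotation", {
  set.seed(13)
  subj <- test_subject()
  model <- prosthetic_model("myoelectric_hook", 0.25, subject = subj)
  tr <- generate_trial("jumping_jack", subj,
                       activity_params("jumping_jack", duration = 2))
  kin <- differentiate_poses(tr, model, 6)
  base <- interface_loads(model, kin)

  ax <- c(1, -2, 0.5); ax <- ax / sqrt(sum(ax^2))
  qQ <- quat_from_axis_angle(ax, 1.1)
  Q <- matrix(quat_to_rotmat9(qQ), 3, 3, byrow = TRUE)
  tr2 <- tr
  tr2$position <- tr$position %*% t(Q)
  tr2$quaternion <- quat_multiply(
    matrix(qQ, nrow(tr$quaternion), 4, byrow = TRUE), tr$quaternion)
  kin2 <- differentiate_poses(tr2, model, 6)
  rot <- interface_loads(model, kin2, gravity = drop(Q %*% c(0, 0, -9.81)))
  expect_equal(rot$bending, base$bending, tolerance = 1e-9)
  expect_equal(rot$torsion, base$torsion, tolerance = 1e-9)
  expect_equal(rot$axial, base$axial, tolerance = 1e-9)
})

test_that("torsion is invariant across amputation levels for on-axis connectors", {
  set.seed(17)
  subj <- test_subject()
  tr <- generate_trial("internal_rotation", subj)
  torsions <- lapply(c(0.25, 0.5, 0.75), function(level) {
    model <- prosthetic_model("advanced", level, subject = subj,
                              rod_inertia = TRUE)
    interface_loads(model, differentiate_poses(tr, model, 6))$torsion
  })
  scale <- max(torsions[[1]])
  expect_lt(max(abs(torsions[[1]] - torsions[[2]])) / scale, 1e-10)
  expect_lt(max(abs(torsions[[1]] - torsions[[3]])) / scale, 1e-10)
})

test_that("per-sample linearity holds when every distal mass scales", {
  set.seed(19)
  subj <- test_subject()
  model <- prosthetic_model("myoelectric_hand", 0.5, subject = subj)
  tr <- generate_trial("jug_lift", subj)
  model <- set_handheld_mass(model, tr$handheld_mass)
  kin <- differentiate_poses(tr, model, 6)
  base <- interface_loads(model, kin)
  for (k in c(0.5, 1.5)) {
    scaled <- scale_distal_masses(model, k, include_handheld = TRUE,
                                  include_connectors = TRUE)
    kin_s <- differentiate_poses(tr, scaled, 6)
    ls <- interface_loads(scaled, kin_s, handheld_mass = k * tr$handheld_mass)
    for (cl in c("Fx", "Fy", "Fz", "Mx", "My", "Mz", "bending", "torsion",
                 "axial")) {
      # absolute comparison on a per-column scale (torsion can be ~ 0 for
      # straight-elbow activities, making relative comparison meaningless)
      expect_lt(max(abs(ls[[cl]] - k * base[[cl]])),
                1e-12 * max(abs(base[[cl]]), 1))
    }
  }
})

test_that("NaN kinematics abort with a located error", {
  model <- prosthetic_model()
  tr <- static_trial(elbow = 0)
  tr$position[7, 2] <- NaN
  kin <- differentiate_poses(tr, model, 6)
  expect_error(interface_loads(model, kin), "NaN in kinematics at sample")
})

test_that("load series CSV export has the documented columns", {
  model <- prosthetic_model("advanced", 0.75)
  kin <- differentiate_poses(static_trial(elbow = 0), model, 6)
  loads <- interface_loads(model, kin)
  path <- withr::local_tempfile(fileext = ".csv")
  write_loads_csv(loads, path)
  back <- utils::read.csv(path)
  expect_identical(names(back),
                   c("time", "Fx", "Fy", "Fz", "Mx", "My", "Mz",
                     "bending", "torsion", "axial"))
  expect_equal(back$axial, loads$axial, tolerance = 1e-12)
})
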