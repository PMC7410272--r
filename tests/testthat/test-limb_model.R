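test_that("anthropometric segment masses reproduce the fixed fractions", {
  m <- anthropometric_segment_masses(44.1)
  expect_equal(round(m[["forearm"]], 2), 0.71)
  expect_equal(round(m[["hand"]], 2), 0.26)
  m <- anthropometric_segment_masses(123.7)
  expect_equal(round(m[["forearm"]], 2), 1.98)
  expect_equal(round(m[["hand"]], 2), 0.74)
  m <- anthropometric_segment_masses(100)
  expect_equal(m[["forearm"]], 1.60)
  expect_equal(m[["hand"]], 0.60)
  expect_equal(m[["upper_arm"]], 2.80)

  expect_error(anthropometric_segment_masses(0), "positive")
  expect_error(anthropometric_segment_masses(-3), "positive")
  expect_error(anthropometric_segment_masses(c(1, 2)), "positive|single")
})

test_that("intact model carries conserved anthropometric masses", {
  m <- build_intact_model(test_subject(70))
  expect_equal(m$segments$mass[m$segments$name == "upper_arm"], 1.96)
  expect_equal(sum(m$segments$mass), sum(anthropometric_segment_masses(70)))
  expect_identical(m$variant, "intact")

  m2 <- build_intact_model(test_subject(44.1, 1.6))
  fh <- sum(m2$segments$mass[m2$segments$name %in% c("forearm", "hand")])
  expect_equal(round(fh, 2), 0.97)

  expect_error(subject_anthropometry(-1, 1.7), "positive")
  expect_error(subject_anthropometry(70, 1.7, upper_arm_length = 1.8),
               "smaller than")
})

test_that("prosthesis presets are bit-exact and round-trip", {
  expected <- list(
    body_powered = c(0.0635, 0.555, 0.0381, 0.027, 0.1016),
    myoelectric_hook = c(0.0762, 1.013, 0.0540, 0.416, 0.1524),
    myoelectric_hand = c(0.0825, 1.040, 0.0635, 0.500, 0.2159),
    advanced = c(0.0773, 1.875, 0.0635, 1.525, 0.1950))
  for (catg in names(expected)) {
    p <- prosthesis_preset(catg)
    expect_identical(
      c(p$elbow_width, p$forearm_mass, p$wrist_width, p$hand_mass,
        p$hand_length),
      expected[[catg]], info = catg)
    expect_true(p$forearm_com_offset >= 0 && p$forearm_com_offset <= 1)
  }
  expect_error(prosthesis_preset("hook_of_unknown_make"), "unknown")
  expect_error(prosthesis_spec("x", 0.06, -1, 0.05, 0.5, 0.2), "positive")
  expect_error(prosthesis_spec("x", 0.06, 1, 0.05, 0.5, 0.2,
                               hand_com_offset = 1.2), "\\[0, 1\\]")
})

test_that("virtual amputation conserves mass and splits quarters", {
  intact <- build_intact_model(test_subject(70))
  ua_mass <- intact$segments$mass[intact$segments$name == "upper_arm"]
  for (level in c(0.25, 0.5, 0.75)) {
    amp <- apply_virtual_amputation(intact, amputation_config(level))
    q <- amp$segments[amp$segments$role == "humerus_quarter", ]
    expect_equal(nrow(q), 4)
    expect_equal(unique(q$mass), ua_mass / 4)
    expect_equal(sum(q$mass), ua_mass) # conservation to machine precision
    residual <- sum(q$mass[q$attach < amp$interface_position - 1e-12])
    expect_equal(residual, level * ua_mass)
    expect_equal(amp$interface_position, level * intact$upper_arm_length)
  }
  amp25 <- apply_virtual_amputation(intact, amputation_config(0.25))
  expect_equal(
    sum(amp25$segments$mass[amp25$segments$role == "humerus_quarter"][1]),
    0.49)
  expect_error(apply_virtual_amputation(amp25, amputation_config(0.5)),
               "intact")
  expect_error(amputation_config(0), "\\(0, 1\\)")
  expect_error(amputation_config(1.2), "\\(0, 1\\)")
  expect_error(amputation_config(0.3), "restricted")
  expect_s3_class(amputation_config(0.3, allow_nonstandard = TRUE),
                  "amputation_config")
})

test_that("prosthesis attachment builds pylon / adapter / components", {
  subj <- subject_anthropometry(70, 1.75, upper_arm_length = 0.30)
  intact <- build_intact_model(subj)

  cfg <- amputation_config(0.25)
  pro <- attach_prosthesis(apply_virtual_amputation(intact, cfg),
                           prosthesis_preset("body_powered"), cfg)
  pylon <- pro$segments[pro$segments$role == "pylon", ]
  expect_equal(pylon$length, 0.225) # (1 - 0.25) x 0.30
  expect_equal(pylon$mass, 1.0 * 0.225)
  fh <- sum(pro$segments$mass[pro$segments$role %in% c("forearm", "hand")])
  expect_equal(fh, 0.582) # 0.555 + 0.027
  expect_identical(pro$variant, "prosthetic")
  expect_equal(pro$elbow_width, 0.0635)
  expect_equal(pro$wrist_width, 0.0381)

  cfg75 <- amputation_config(0.75)
  pro75 <- attach_prosthesis(apply_virtual_amputation(intact, cfg75),
                             prosthesis_preset("advanced"), cfg75)
  expect_false("pylon" %in% pro75$segments$role)
  expect_equal(sort(setdiff(unique(pro75$segments$role), "humerus_quarter")),
               c("adapter", "forearm", "hand"))
  expect_equal(distal_mass(pro75), 0.10 + 1.875 + 1.525)

  expect_error(attach_prosthesis(intact, prosthesis_preset("advanced"), cfg),
               "interface plane")
})

test_that("distal mass ordering follows terminal-device complexity", {
  for (level in c(0.25, 0.5, 0.75)) {
    dm <- vapply(prosthesis_categories(), function(catg) {
      distal_mass(prosthetic_model(catg, level))
    }, numeric(1))
    expect_true(all(diff(dm[c("body_powered", "myoelectric_hook",
                               "myoelectric_hand", "advanced")]) > 0),
                info = paste("level", level))
  }
})

test_that("model JSON serialization round-trips", {
  pro <- prosthetic_model("myoelectric_hook", 0.5)
  pro <- set_handheld_mass(pro, 3.8, offset = 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(pro, path)
  back <- read_model_json(path)
  expect_equal(back$segments, pro$segments)
  expect_equal(back$interface_position, pro$interface_position)
  expect_equal(back$handheld_mass, 3.8)
  expect_equal(back$subject$body_mass, pro$subject$body_mass)
  expect_identical(back$prosthesis, "myoelectric_hook")
})
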