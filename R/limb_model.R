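# Subject-scaled rigid-body models of the upper limb, virtual amputation at
# fractional humeral lengths, and substitution of prosthesis mass-distribution
# models attached through a pylon / pyramid adapter.
#
# Geometry convention: the humeral long axis runs shoulder -> elbow; arc-length
# positions ("attach") are measured from the branch origin (shoulder for the
# humeral branch, elbow for the forearm branch). In the body frame the distal
# direction is (0, 0, -1), so with an identity orientation the arm hangs
# straight down in the z-up global frame. The unit long-axis direction used to
# resolve loads points proximally (distal -> proximal).

#' Segment mass fractions of body mass (Dempster-style)
#'
#' Fractions of total body mass assigned to the upper arm, forearm and hand of
#' the intact model.
#' @export
SEGMENT_MASS_FRACTIONS <- c(upper_arm = 0.028, forearm = 0.016, hand = 0.006)

#' Anthropometric segment masses
#'
#' Upper-arm, forearm and hand masses of the intact model as fixed fractions
#' of body mass (0.028 / 0.016 / 0.006).
#'
#' @param body_mass body mass, kg (> 0).
#' @return named numeric vector `c(upper_arm, forearm, hand)`, kg.
#' @examples
#' anthropometric_segment_masses(44.1) # forearm 0.71, hand 0.26 (2 dp)
#' @export
anthropometric_segment_masses <- function(body_mass) {
  if (!is.numeric(body_mass) || length(body_mass) != 1L ||
      !is.finite(body_mass) || body_mass <= 0) {
    stop("`body_mass` must be a single positive number", call. = FALSE)
  }
  SEGMENT_MASS_FRACTIONS * body_mass
}

#' Subject anthropometry
#'
#' @param body_mass kg.
#' @param stature m.
#' @param upper_arm_length shoulder joint centre to elbow joint centre, m;
#'   default `0.186 * stature`.
#' @param forearm_length elbow to wrist, m; default `0.146 * stature`.
#' @param elbow_width,wrist_width joint widths, m (set segment cylinder radii).
#' @param hand_length m; default `0.108 * stature`.
#' @param sex_label metadata only.
#' @return object of class `subject_anthropometry`.
#' @export
subject_anthropometry <- function(body_mass, stature,
                                  upper_arm_length = 0.186 * stature,
                                  forearm_length = 0.146 * stature,
                                  elbow_width = 0.066,
                                  wrist_width = 0.055,
                                  hand_length = 0.108 * stature,
                                  sex_label = NA_character_) {
  vals <- c(body_mass = body_mass, stature = stature,
            upper_arm_length = upper_arm_length,
            forearm_length = forearm_length,
            elbow_width = elbow_width, wrist_width = wrist_width,
            hand_length = hand_length)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all anthropometric masses and lengths must be strictly positive",
         call. = FALSE)
  }
  if (upper_arm_length >= stature) {
    stop("`upper_arm_length` must be smaller than `stature`", call. = FALSE)
  }
  structure(
    list(body_mass = body_mass, stature = stature,
         upper_arm_length = upper_arm_length,
         forearm_length = forearm_length,
         elbow_width = elbow_width, wrist_width = wrist_width,
         hand_length = hand_length, sex_label = sex_label),
    class = "subject_anthropometry"
  )
}

#' Prosthesis mass-distribution preset
#'
#' Representative component metrics for the four terminal-device classes
#' (body-powered hook, myoelectric hook, myoelectric hand, advanced
#' multi-degree-of-freedom limb), loaded from the shipped preset file.
#' Forearm mass includes the integrated elbow components.
#'
#' @param category one of `"body_powered"`, `"myoelectric_hook"`,
#'   `"myoelectric_hand"`, `"advanced"`.
#' @return object of class `prosthesis_spec`.
#' @export
prosthesis_preset <- function(category) {
  presets <- .oiload_presets()
  if (!is.character(category) || length(category) != 1L ||
      !category %in% names(presets)) {
    stop("unknown prosthesis category: ", paste(category, collapse = ", "),
         " (expected one of ", paste(names(presets), collapse = ", "), ")",
         call. = FALSE)
  }
  p <- presets[[category]]
  prosthesis_spec(
    category = category,
    elbow_width = p$elbow_width_m, forearm_mass = p$forearm_mass_kg,
    wrist_width = p$wrist_width_m, hand_mass = p$hand_mass_kg,
    hand_length = p$hand_length_m,
    forearm_com_offset = p$forearm_com_offset,
    hand_com_offset = p$hand_com_offset
  )
}

#' @rdname prosthesis_preset
#' @export
prosthesis_categories <- function() names(.oiload_presets())

.oiload_presets <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "prosthesis_presets.json",
                          package = "oiload", mustWork = TRUE)
      cache <<- jsonlite::fromJSON(path)$presets
    }
    cache
  }
})

#' Prosthesis specification
#'
#' @param category device class label.
#' @param elbow_width,wrist_width m.
#' @param forearm_mass,hand_mass kg.
#' @param hand_length m.
#' @param forearm_com_offset,hand_com_offset COM position as a fraction of
#'   segment length from the proximal end, in `[0, 1]`.
#' @export
prosthesis_spec <- function(category, elbow_width, forearm_mass, wrist_width,
                            hand_mass, hand_length,
                            forearm_com_offset = 0.45, hand_com_offset = 0.45) {
  vals <- c(elbow_width, forearm_mass, wrist_width, hand_mass, hand_length)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("prosthesis masses, widths and lengths must be strictly positive",
         call. = FALSE)
  }
  offs <- c(forearm_com_offset, hand_com_offset)
  if (any(offs < 0 | offs > 1)) {
    stop("COM offsets must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(category = category, elbow_width = elbow_width,
         forearm_mass = forearm_mass, wrist_width = wrist_width,
         hand_mass = hand_mass, hand_length = hand_length,
         forearm_com_offset = forearm_com_offset,
         hand_com_offset = hand_com_offset),
    class = "prosthesis_spec"
  )
}

#' Amputation configuration
#'
#' @param level fraction of upper-arm length from the shoulder at which the
#'   humerus is cut; study levels are 0.25 (proximal, short residual), 0.50
#'   and 0.75 (distal). Other values in (0, 1) are allowed with
#'   `allow_nonstandard = TRUE`.
#' @param pylon_linear_density kg/m of the connecting pylon.
#' @param adapter_mass pyramid-adapter mass, kg, placed at the interface.
#' @param pylon_radius pylon cylinder radius, m (inertia model).
#' @param allow_nonstandard allow levels outside \{0.25, 0.5, 0.75\}.
#' @export
amputation_config <- function(level, pylon_linear_density = 1.0,
                              adapter_mass = 0.10, pylon_radius = 0.015,
                              allow_nonstandard = FALSE) {
  if (!is.numeric(level) || length(level) != 1L || !is.finite(level) ||
      level <= 0 || level >= 1) {
    stop("`level` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!allow_nonstandard && !isTRUE(any(abs(level - c(0.25, 0.5, 0.75)) < 1e-9))) {
    stop("`level` restricted to 0.25, 0.50, 0.75 unless ",
         "`allow_nonstandard = TRUE`", call. = FALSE)
  }
  if (pylon_linear_density < 0 || adapter_mass < 0 || pylon_radius < 0) {
    stop("pylon density, adapter mass and radius must be >= 0", call. = FALSE)
  }
  structure(
    list(level = level, pylon_linear_density = pylon_linear_density,
         adapter_mass = adapter_mass, pylon_radius = pylon_radius),
    class = "amputation_config"
  )
}

new_segment <- function(name, role, branch, mass, length, com_offset,
                        transverse_radius, attach, on_axis) {
  data.frame(name = name, role = role, branch = branch, mass = mass,
             length = length, com_offset = com_offset,
             transverse_radius = transverse_radius, attach = attach,
             on_axis = on_axis, stringsAsFactors = FALSE)
}

#' Build the intact limb model
#'
#' Three-segment chain (upper arm, forearm, hand) with Dempster-style masses,
#' COMs at the configured offsets and uniform-cylinder inertias.
#'
#' @param subject a [subject_anthropometry()].
#' @param com_offsets named list of COM offsets (fractions from the proximal
#'   end) for `upper_arm`, `forearm`, `hand`.
#' @return object of class `limb_model`, `variant = "intact"`.
#' @export
build_intact_model <- function(subject,
                               com_offsets = list(upper_arm = 0.43,
                                                  forearm = 0.43,
                                                  hand = 0.50)) {
  stopifnot(inherits(subject, "subject_anthropometry"))
  m <- anthropometric_segment_masses(subject$body_mass)
  segs <- rbind(
    new_segment("upper_arm", "upper_arm", "humerus", m[["upper_arm"]],
                subject$upper_arm_length, com_offsets$upper_arm,
                subject$elbow_width / 2, 0, FALSE),
    new_segment("forearm", "forearm", "forearm", m[["forearm"]],
                subject$forearm_length, com_offsets$forearm,
                (subject$elbow_width + subject$wrist_width) / 4, 0, FALSE),
    new_segment("hand", "hand", "forearm", m[["hand"]],
                subject$hand_length, com_offsets$hand,
                subject$wrist_width / 2, subject$forearm_length, FALSE)
  )
  structure(
    list(variant = "intact", subject = subject, segments = segs,
         interface_position = NA_real_, level = NA_real_,
         upper_arm_length = subject$upper_arm_length,
         forearm_length = subject$forearm_length,
         hand_length = subject$hand_length,
         elbow_width = subject$elbow_width,
         wrist_width = subject$wrist_width,
         prosthesis = NULL, handheld_mass = 0, handheld_offset = 0),
    class = "limb_model"
  )
}

#' Virtual amputation of the intact model
#'
#' Replaces the upper arm by four contiguous quarter-segments of equal mass
#' (uniform density) and records the interface plane at
#' `level * upper_arm_length` from the shoulder. All segments distal to the
#' plane are retained, so the returned model is the intact-comparison model
#' evaluated at the amputation plane; [attach_prosthesis()] removes them.
#'
#' @param model an intact `limb_model`.
#' @param cfg an [amputation_config()].
#' @return `limb_model` with `variant = "amputated"`.
#' @export
apply_virtual_amputation <- function(model, cfg) {
  stopifnot(inherits(model, "limb_model"), inherits(cfg, "amputation_config"))
  if (model$variant != "intact") {
    stop("virtual amputation requires an intact model", call. = FALSE)
  }
  ua <- model$segments[model$segments$role == "upper_arm", ]
  L <- ua$length
  qlen <- L / 4
  quarters <- do.call(rbind, lapply(1:4, function(i) {
    new_segment(sprintf("humerus_q%d", i), "humerus_quarter", "humerus",
                ua$mass / 4, qlen, 0.5, ua$transverse_radius,
                (i - 1) * qlen, TRUE)
  }))
  segs <- rbind(quarters,
                model$segments[model$segments$role != "upper_arm", ])
  rownames(segs) <- NULL
  model$segments <- segs
  model$variant <- "amputated"
  model$level <- cfg$level
  model$interface_position <- cfg$level * L
  model$amputation <- cfg
  model
}

#' Attach a prosthesis model at the interface plane
#'
#' Removes native segments distal to the interface plane and appends the
#' connector and prosthetic segments: a pylon spanning interface plane to
#' elbow (omitted at the 75% level, where the limb joins through the pyramid
#' adapter alone), the adapter point mass at the plane, and the prosthetic
#' forearm and hand with preset masses and geometry. Elbow and wrist widths
#' are replaced by the component widths. Prosthetic forearm length equals the
#' subject's forearm length (components sized to the subject's arm).
#'
#' @param amputated `limb_model` from [apply_virtual_amputation()].
#' @param spec a [prosthesis_spec()].
#' @param cfg the [amputation_config()] (defaults to the one recorded at
#'   amputation).
#' @return `limb_model` with `variant = "prosthetic"`.
#' @export
attach_prosthesis <- function(amputated, spec, cfg = amputated$amputation) {
  stopifnot(inherits(amputated, "limb_model"), inherits(spec, "prosthesis_spec"))
  if (!is.finite(amputated$interface_position)) {
    stop("model has no interface plane; run apply_virtual_amputation() first",
         call. = FALSE)
  }
  L <- amputated$upper_arm_length
  level <- amputated$level
  plane <- amputated$interface_position
  segs <- amputated$segments
  keep <- segs$branch == "humerus" & segs$attach < plane - 1e-12
  segs <- segs[keep, , drop = FALSE]

  no_pylon <- isTRUE(abs(level - 0.75) < 1e-9)
  if (!no_pylon) {
    plen <- (1 - level) * L
    segs <- rbind(segs, new_segment(
      "pylon", "pylon", "humerus", cfg$pylon_linear_density * plen, plen,
      0.5, cfg$pylon_radius, plane, TRUE))
  }
  segs <- rbind(segs,
    new_segment("adapter", "adapter", "humerus", cfg$adapter_mass, 0, 0.5,
                0, plane, TRUE),
    new_segment("prosthetic_forearm", "forearm", "forearm", spec$forearm_mass,
                amputated$forearm_length, spec$forearm_com_offset,
                (spec$elbow_width + spec$wrist_width) / 4, 0, FALSE),
    new_segment("prosthetic_hand", "hand", "forearm", spec$hand_mass,
                spec$hand_length, spec$hand_com_offset,
                spec$wrist_width / 2, amputated$forearm_length, FALSE))

  rownames(segs) <- NULL
  amputated$segments <- segs
  amputated$variant <- "prosthetic"
  amputated$prosthesis <- spec$category
  amputated$elbow_width <- spec$elbow_width
  amputated$wrist_width <- spec$wrist_width
  amputated$hand_length <- spec$hand_length
  amputated
}

#' Set the handheld mass carried in the hand
#'
#' Modelled as a point mass at the hand COM, optionally offset distally along
#' the forearm axis (e.g. a jug held beyond the palm).
#'
#' @param model a `limb_model`.
#' @param mass kg (>= 0).
#' @param offset distance distal to the hand COM along the forearm axis, m.
#' @export
set_handheld_mass <- function(model, mass, offset = 0) {
  stopifnot(inherits(model, "limb_model"), mass >= 0)
  model$handheld_mass <- mass
  model$handheld_offset <- offset
  model
}

# Segments distal to the interface plane (the load-bearing set).
distal_segments <- function(model) {
  if (!is.finite(model$interface_position)) {
    stop("model has no interface plane", call. = FALSE)
  }
  segs <- model$segments
  distal <- segs$branch == "forearm" |
    (segs$branch == "humerus" & segs$attach >= model$interface_position - 1e-12)
  segs[distal, , drop = FALSE]
}

#' Total mass distal to the interface plane
#'
#' @param model a `limb_model` with an interface plane.
#' @param include_handheld include the handheld point mass.
#' @export
distal_mass <- function(model, include_handheld = FALSE) {
  m <- sum(distal_segments(model)$mass)
  if (include_handheld) m <- m + model$handheld_mass
  m
}

#' Serialize / restore a limb model
#'
#' JSON round-trip preserving all numeric fields at full precision.
#' @param model a `limb_model`.
#' @param path file path.
#' @export
write_model_json <- function(model, path) {
  obj <- unclass(model)
  obj$subject <- unclass(obj$subject)
  if (!is.null(obj$amputation)) obj$amputation <- unclass(obj$amputation)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  obj$segments <- as.data.frame(obj$segments)
  rownames(obj$segments) <- NULL
  obj$subject <- structure(obj$subject, class = "subject_anthropometry")
  if (!is.null(obj$amputation)) {
    obj$amputation <- structure(obj$amputation, class = "amputation_config")
  }
  if (is.null(obj$prosthesis)) obj$prosthesis <- NULL
  if (is.null(obj$interface_position)) obj$interface_position <- NA_real_
  structure(obj, class = "limb_model")
}

#' @export
print.limb_model <- function(x, ...) {
  cat(sprintf("<limb_model: %s%s>\n", x$variant,
              if (!is.null(x$prosthesis)) paste0(" / ", x$prosthesis) else ""))
  if (is.finite(x$interface_position)) {
    cat(sprintf("  interface at %.1f%% of upper arm (%.3f m from shoulder)\n",
                100 * x$level, x$interface_position))
    cat(sprintf("  distal mass %.3f kg (+ %.2f kg handheld)\n",
                distal_mass(x), x$handheld_mass))
  }
  print(x$segments[, c("name", "mass", "length", "com_offset", "attach")],
        row.names = FALSE)
  invisible(x)
}
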