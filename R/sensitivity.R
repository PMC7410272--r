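# Single-trial sensitivity analysis: scale forearm/hand masses and shift
# their COMs, re-run the load pipeline on identical kinematics, and report
# peak-load ratios against the unperturbed baseline.

#' Scale the distal (forearm + hand) masses
#'
#' Multiplies the forearm and hand segment masses by `k`. The pylon and
#' pyramid adapter are untouched by default; `include_connectors = TRUE`
#' scales them too (the exact-linearity configuration). The handheld mass is
#' scaled by default so that weighted activities scale coherently.
#'
#' @param model a `limb_model`.
#' @param k positive scale factor.
#' @param include_handheld scale the handheld point mass.
#' @param include_connectors also scale pylon, adapter and residual humerus
#'   segments (everything distal of the interface).
#' @return perturbed `limb_model`.
#' @export
scale_distal_masses <- function(model, k, include_handheld = TRUE,
                                include_connectors = FALSE) {
  stopifnot(inherits(model, "limb_model"))
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0) {
    stop("`k` must be a single positive number", call. = FALSE)
  }
  roles <- c("forearm", "hand")
  if (include_connectors) {
    roles <- c(roles, "pylon", "adapter", "humerus_quarter", "upper_arm")
  }
  sel <- model$segments$role %in% roles
  model$segments$mass[sel] <- model$segments$mass[sel] * k
  if (include_handheld) model$handheld_mass <- model$handheld_mass * k
  model
}

#' Shift forearm and hand COMs along their segments
#'
#' Each COM offset (fraction of segment length from the proximal end) is
#' multiplied by `1 + s`: `s = +0.5` moves the COM 50% of its current
#' proximal-joint distance distally, `s = -0.5` proximally. This
#' interpretation ("percent of the COM's distance from the proximal joint")
#' makes proximal shifts smaller in absolute terms for COMs proximal of
#' mid-segment. The alternative reading, a shift of half the segment length,
#' is available as `mode = "segment_fraction"` (`com_offset + s * 0.5`).
#'
#' @param model a `limb_model`.
#' @param s signed shift fraction (distal positive).
#' @param mode `"of_offset"` (default, multiply the offset) or
#'   `"segment_fraction"` (add `s * 0.5` of the segment length).
#' @return perturbed `limb_model`; errors if any offset leaves `[0, 1]`.
#' @export
shift_coms <- function(model, s, mode = c("of_offset", "segment_fraction")) {
  stopifnot(inherits(model, "limb_model"))
  mode <- match.arg(mode)
  sel <- model$segments$role %in% c("forearm", "hand")
  off <- model$segments$com_offset[sel]
  new_off <- switch(mode,
                    of_offset = off * (1 + s),
                    segment_fraction = off + s * 0.5)
  if (any(new_off < 0 | new_off > 1)) {
    stop("shifted COM offset leaves [0, 1]: ",
         paste(sprintf("%.3f", new_off), collapse = ", "), call. = FALSE)
  }
  model$segments$com_offset[sel] <- new_off
  model
}

#' Sensitivity report over mass and COM perturbations
#'
#' Re-runs differentiation and interface-load computation on identical trial
#' kinematics for every perturbation and reports per-modality peak ratios
#' (perturbed / baseline).
#'
#' @param trial a [motion_trial()].
#' @param model the baseline `limb_model` (with interface plane).
#' @param mass_scales numeric vector of mass scale factors `k`.
#' @param com_shifts numeric vector of signed COM shift fractions `s`.
#' @param filter_cutoff passed to [differentiate_poses()].
#' @param ... passed to [scale_distal_masses()].
#' @return data.frame `perturbation, value, modality, peak_ratio`.
#' @export
sensitivity_report <- function(trial, model, mass_scales = c(0.5, 1.5),
                               com_shifts = c(-0.5, 0.5),
                               filter_cutoff = 6, ...) {
  peaks_of <- function(m) {
    kin <- differentiate_poses(trial, m, filter_cutoff)
    extract_peaks(interface_loads(m, kin, handheld_mass = m$handheld_mass))
  }
  model$handheld_mass <- trial$handheld_mass
  base <- peaks_of(model)
  rows <- list()
  add <- function(kind, value, pk) {
    for (mod in names(MODALITY_COLS)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        perturbation = kind, value = value, modality = mod,
        peak_ratio = pk[[MODALITY_COLS[[mod]]]] / base[[MODALITY_COLS[[mod]]]])
    }
  }
  for (k in mass_scales) add("mass_scale", k,
                             peaks_of(scale_distal_masses(model, k, ...)))
  for (s in com_shifts) add("com_shift", s, peaks_of(shift_coms(model, s)))
  do.call(rbind, rows)
}
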