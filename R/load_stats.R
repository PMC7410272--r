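# Peak extraction, trial aggregation, percent-of-intact comparisons,
# log-scale mixed-effects contrasts and one-sample signed-rank threshold
# tests for interface load series.

#' Extract per-modality peak loads from a load series
#'
#' Bending and torsion peaks are maxima of the (non-negative) resolved
#' moments; the axial peak is the tensile (pullout) maximum under the default
#' convention, or the maximum absolute value with
#' `axial_convention = "absolute"`.
#'
#' @param loads a `load_series` from [interface_loads()].
#' @param meta named list/vector of identifying metadata (subject_id,
#'   activity, model_variant, level, trial_index) copied onto the row.
#' @param axial_convention `"tensile"` (default) or `"absolute"`.
#' @return one-row data.frame with `bending_peak`, `torsion_peak`,
#'   `axial_peak` plus metadata columns.
#' @export
extract_peaks <- function(loads, meta = list(),
                          axial_convention = c("tensile", "absolute")) {
  if (is.null(nrow(loads)) || nrow(loads) == 0L) {
    stop("empty load series", call. = FALSE)
  }
  axial_convention <- match.arg(axial_convention)
  axial <- switch(axial_convention,
                  tensile = max(loads$axial),
                  absolute = max(abs(loads$axial)))
  out <- data.frame(bending_peak = max(loads$bending),
                    torsion_peak = max(loads$torsion),
                    axial_peak = axial)
  for (nm in names(meta)) out[[nm]] <- meta[[nm]]
  out
}

MODALITY_COLS <- c(bending = "bending_peak", torsion = "torsion_peak",
                   axial = "axial_peak")

#' Average peak loads over repeated trials
#'
#' Arithmetic mean of the per-trial peaks (mean-of-peaks, never
#' peak-of-means). All rows must share subject, activity, model variant and
#' level; three trials are expected unless `allow_partial = TRUE`.
#'
#' @param peaks data.frame of [extract_peaks()] rows.
#' @param n_trials expected trial count (default 3).
#' @param allow_partial accept fewer than `n_trials` rows.
#' @return one-row data.frame of averaged peaks with the shared metadata.
#' @export
aggregate_trials <- function(peaks, n_trials = 3, allow_partial = FALSE) {
  stopifnot(is.data.frame(peaks), nrow(peaks) >= 1)
  keys <- intersect(c("subject_id", "activity", "model_variant", "level"),
                    names(peaks))
  for (k in keys) {
    if (length(unique(peaks[[k]])) != 1L) {
      stop("mixed metadata in `", k, "`: trials must share ",
           "subject/activity/model/level", call. = FALSE)
    }
  }
  if (nrow(peaks) != n_trials && !allow_partial) {
    stop("expected ", n_trials, " trials, got ", nrow(peaks),
         " (set `allow_partial = TRUE` to accept)", call. = FALSE)
  }
  out <- peaks[1, , drop = FALSE]
  for (cl in MODALITY_COLS) out[[cl]] <- mean(peaks[[cl]])
  out$trial_index <- NULL
  rownames(out) <- NULL
  out
}

#' Prosthetic load as a percent of the intact reference
#'
#' @param prosthetic_mean,intact_mean mean peak loads (same modality/units).
#' @return percent of the intact model (100 = equal).
#' @export
percent_vs_intact <- function(prosthetic_mean, intact_mean) {
  if (any(intact_mean <= 0)) {
    stop("intact mean must be positive (undefined ratio)", call. = FALSE)
  }
  100 * prosthetic_mean / intact_mean
}

#' Log-scale linear mixed model of peak loads
#'
#' Per-modality linear mixed model on `log(peak)` with fixed effects
#' `model_variant * level * activity` (factors with a single observed level
#' are dropped) and a subject random intercept, fitted with
#' \code{lme4::lmer}. For every prosthetic variant and observed
#' level/activity cell, the contrast against the intact model in the same
#' cell is exponentiated to a percent difference with a Wald confidence
#' interval and p-value. A singular or failed mixed fit falls back to a
#' fixed-effects-only `lm` with a warning.
#'
#' @param peak_table long-format data.frame with columns `subject_id`,
#'   `model_variant` (containing `"intact"`), optional `level`, `activity`,
#'   and the three `*_peak` columns.
#' @param modalities subset of `c("bending", "torsion", "axial")`.
#' @param conf_level confidence level for the Wald interval.
#' @return data.frame with `modality, model_variant, level, activity,
#'   percent_estimate, conf_lo, conf_hi, p_value` (empty if no prosthetic
#'   rows are present).
#' @export
fit_log_mixed_model <- function(peak_table,
                                modalities = c("bending", "torsion", "axial"),
                                conf_level = 0.95) {
  stopifnot(is.data.frame(peak_table))
  if (length(unique(peak_table$subject_id)) < 2) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  variants <- unique(peak_table$model_variant)
  prosthetic <- setdiff(variants, "intact")
  if (!length(prosthetic)) {
    return(data.frame(modality = character(), model_variant = character(),
                      level = numeric(), activity = character(),
                      percent_estimate = numeric(), conf_lo = numeric(),
                      conf_hi = numeric(), p_value = numeric()))
  }
  df <- peak_table
  df$model_variant <- stats::relevel(factor(df$model_variant), ref = "intact")
  df$subject_id <- factor(df$subject_id)
  has_level <- "level" %in% names(df) && length(unique(df$level)) > 1
  has_act <- "activity" %in% names(df) && length(unique(df$activity)) > 1
  if (has_level) df$level <- factor(df$level)
  if (has_act) df$activity <- factor(df$activity)
  rhs <- paste(c("model_variant",
                 if (has_level) "level",
                 if (has_act) "activity"), collapse = " * ")

  levels_obs <- if (has_level) levels(df$level) else NA
  acts_obs <- if (has_act) levels(df$activity) else NA
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  out <- list()
  for (mod in modalities) {
    df$.y <- log(df[[MODALITY_COLS[[mod]]]])
    form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | subject_id)"))
    fit <- tryCatch(
      lme4::lmer(form, data = df,
                 control = lme4::lmerControl(calc.derivs = FALSE)),
      error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit)) {
      warning("singular or failed mixed fit for ", mod,
              "; falling back to fixed effects only", call. = FALSE)
      fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = df)
      beta <- stats::coef(fit)
      beta <- beta[!is.na(beta)] # drop aliased terms in unbalanced fallbacks
      V <- stats::vcov(fit)
    } else {
      beta <- lme4::fixef(fit)
      V <- as.matrix(stats::vcov(fit))
    }
    tt <- stats::delete.response(stats::terms(
      stats::as.formula(paste("~", rhs))))
    grid <- expand.grid(model_variant = prosthetic,
                        level = levels_obs, activity = acts_obs,
                        stringsAsFactors = FALSE)
    for (i in seq_len(nrow(grid))) {
      nd <- data.frame(model_variant =
                         factor(c(grid$model_variant[i], "intact"),
                                levels = levels(df$model_variant)))
      if (has_level) nd$level <- factor(grid$level[i], levels = levels_obs)
      if (has_act) nd$activity <- factor(grid$activity[i], levels = acts_obs)
      X <- stats::model.matrix(tt, nd)
      cvec <- X[1, names(beta)] - X[2, names(beta)]
      est <- sum(cvec * beta)
      se <- sqrt(drop(t(cvec) %*% V %*% cvec))
      out[[length(out) + 1L]] <- data.frame(
        modality = mod,
        model_variant = grid$model_variant[i],
        level = if (has_level) as.numeric(as.character(grid$level[i])) else NA,
        activity = if (has_act) grid$activity[i] else NA,
        percent_estimate = 100 * exp(est),
        conf_lo = 100 * exp(est - z * se),
        conf_hi = 100 * exp(est + z * se),
        p_value = 2 * stats::pnorm(-abs(est / se))
      )
    }
  }
  do.call(rbind, out)
}

#' One-sided one-sample Wilcoxon signed-rank test against a threshold
#'
#' Exact null distribution for n <= 25, normal approximation with continuity
#' correction beyond.
#'
#' @param values observed loads.
#' @param threshold reference load value.
#' @param direction `"greater"` tests median > threshold, `"less"` the
#'   reverse.
#' @return the p-value.
#' @export
wilcoxon_vs_threshold <- function(values, threshold,
                                  direction = c("greater", "less")) {
  direction <- match.arg(direction)
  values <- values[is.finite(values)]
  if (length(values) < 5) stop("need at least 5 values", call. = FALSE)
  d <- values - threshold
  if (all(d == 0) || stats::sd(d) == 0) {
    stop("degenerate data: zero variance after differencing", call. = FALSE)
  }
  res <- suppressWarnings(stats::wilcox.test(
    values, mu = threshold, alternative = direction,
    exact = length(values) <= 25, correct = TRUE))
  unname(res$p.value)
}
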