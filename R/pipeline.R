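# End-to-end study orchestration: synthetic cohort -> inverse dynamics ->
# peak statistics -> failure comparison, reproducible from one master seed.

#' Study configuration
#'
#' Defaults reproduce the study design: 40 subjects, 3 trials per condition,
#' six activities, four prosthesis categories plus the intact reference, and
#' amputation levels 25/50/75%.
#'
#' @param master_seed integer master seed; the whole run is a pure function
#'   of it.
#' @param n_subjects cohort size.
#' @param trials_per_condition repeated trials per subject x activity.
#' @param activities activity subset.
#' @param categories prosthesis categories ("none" for an intact-only run is
#'   expressed by `character(0)`).
#' @param levels amputation levels (fractions).
#' @param pylon_linear_density,adapter_mass,pylon_radius connector
#'   parameters.
#' @param handheld_masses named briefcase/jug masses, kg.
#' @param filter_cutoff low-pass cutoff, Hz.
#' @param axial_convention `"tensile"` or `"absolute"` peak convention.
#' @param sample_rate,duration trial sampling.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @export
study_config <- function(master_seed = 1L, n_subjects = 40L,
                         trials_per_condition = 3L,
                         activities = activity_names(),
                         categories = prosthesis_categories(),
                         levels = c(0.25, 0.50, 0.75),
                         pylon_linear_density = 1.0, adapter_mass = 0.10,
                         pylon_radius = 0.015,
                         handheld_masses = DEFAULT_HANDHELD,
                         filter_cutoff = 6, axial_convention = "tensile",
                         sample_rate = 100, duration = 5, out_dir = NULL) {
  stopifnot(n_subjects >= 1, trials_per_condition >= 1,
            all(activities %in% activity_names()),
            all(categories %in% prosthesis_categories()),
            all(levels > 0 & levels < 1))
  structure(
    list(master_seed = as.integer(master_seed), n_subjects = n_subjects,
         trials_per_condition = trials_per_condition, activities = activities,
         categories = categories, levels = levels,
         pylon_linear_density = pylon_linear_density,
         adapter_mass = adapter_mass, pylon_radius = pylon_radius,
         handheld_masses = handheld_masses, filter_cutoff = filter_cutoff,
         axial_convention = axial_convention, sample_rate = sample_rate,
         duration = duration, out_dir = out_dir),
    class = "study_config"
  )
}

#' Read a study configuration from YAML
#'
#' Any field of [study_config()] may appear; missing fields keep their
#' defaults.
#' @param path YAML file.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(y$handheld_masses)) y$handheld_masses <- unlist(y$handheld_masses)
  do.call(study_config, y)
}

# models evaluated at one level for one subject: intact-comparison model plus
# one prosthetic model per category, all sharing the amputation config.
build_condition_models <- function(subject, level, config) {
  cfg <- amputation_config(level,
                           pylon_linear_density = config$pylon_linear_density,
                           adapter_mass = config$adapter_mass,
                           pylon_radius = config$pylon_radius,
                           allow_nonstandard = TRUE)
  amp <- apply_virtual_amputation(build_intact_model(subject), cfg)
  models <- c(list(intact = amp),
              stats::setNames(lapply(config$categories, function(cat) {
                attach_prosthesis(amp, prosthesis_preset(cat), cfg)
              }), config$categories))
  models
}

#' Run the full simulated study
#'
#' Draws the synthetic cohort, generates `trials_per_condition` trials per
#' subject x activity, evaluates interface loads for the intact-comparison
#' model and every prosthesis category at every amputation level on the
#' *same* trial kinematics, extracts and trial-averages peaks, and summarizes
#' peak tables, percent-of-intact ranges and failure exceedance.
#'
#' @param config a [study_config()].
#' @param verbose log one line per pipeline stage.
#' @return list with `config`, `subjects`, `peaks` (per-trial long table),
#'   `aggregated` (trial-averaged), `table2` (max-over-activities summary),
#'   `percent_table` (percent-of-intact ranges, weighted/unweighted),
#'   `exceedance` (flags at 25/75% levels). Written as CSV/JSON under
#'   `config$out_dir` when set.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  set.seed(config$master_seed)
  say("stage=cohort seed=%d n_subjects=%d", config$master_seed,
      config$n_subjects)

  subjects <- lapply(seq_len(config$n_subjects), sample_subject)
  subj_df <- do.call(rbind, lapply(subjects, function(s) {
    data.frame(subject_id = attr(s, "subject_id"), body_mass = s$body_mass,
               stature = s$stature, upper_arm_length = s$upper_arm_length)
  }))

  say("stage=simulate+dynamics activities=%d levels=%d categories=%d",
      length(config$activities), length(config$levels),
      length(config$categories))
  rows <- vector("list", 0L)
  for (si in seq_along(subjects)) {
    subj <- subjects[[si]]
    models_by_level <- lapply(config$levels, build_condition_models,
                              subject = subj, config = config)
    for (act in config$activities) {
      params <- activity_params(act, duration = config$duration,
                                sample_rate = config$sample_rate,
                                handheld_masses = config$handheld_masses)
      for (tr in seq_len(config$trials_per_condition)) {
        trial <- tryCatch(
          generate_trial(act, subj, params, trial_index = tr),
          error = function(e) {
            stop("trial generation failed for subject ", si, ", activity ",
                 act, ", trial ", tr, ": ", conditionMessage(e),
                 call. = FALSE)
          })
        for (li in seq_along(config$levels)) {
          for (variant in names(models_by_level[[li]])) {
            model <- models_by_level[[li]][[variant]]
            kin <- differentiate_poses(trial, model, config$filter_cutoff)
            loads <- interface_loads(model, kin)
            rows[[length(rows) + 1L]] <- extract_peaks(
              loads,
              meta = list(subject_id = si, activity = act,
                          model_variant = variant,
                          level = config$levels[li], trial_index = tr),
              axial_convention = config$axial_convention)
          }
        }
      }
    }
  }
  peaks <- do.call(rbind, rows)

  say("stage=aggregate rows=%d", nrow(peaks))
  agg <- stats::aggregate(
    peaks[, MODALITY_COLS],
    by = peaks[, c("subject_id", "activity", "model_variant", "level")],
    FUN = mean)

  table2 <- summarize_table2(agg)
  percent <- summarize_percent_table(agg)
  exc <- exceedance_from_table2(table2)

  bundle <- list(config = config, subjects = subj_df, peaks = peaks,
                 aggregated = agg, table2 = table2, percent_table = percent,
                 exceedance = exc)
  if (!is.null(config$out_dir)) write_study_outputs(bundle, config$out_dir)
  say("stage=done")
  bundle
}

#' Peak-load summary in the published table shape
#'
#' Per model variant x amputation level x modality: the activity with the
#' largest cohort mean of the trial-averaged peaks, with that mean and its
#' between-subject SD.
#'
#' @param agg trial-averaged peak table (from [run_study()]'s `aggregated`).
#' @return data.frame `model_variant, level, modality, activity, mean, sd`.
#' @export
summarize_table2 <- function(agg) {
  if (is.null(agg) || nrow(agg) == 0L) stop("empty peak table", call. = FALSE)
  out <- list()
  for (variant in unique(agg$model_variant)) {
    for (lev in sort(unique(agg$level))) {
      sub <- agg[agg$model_variant == variant & agg$level == lev, ]
      for (mod in names(MODALITY_COLS)) {
        cl <- MODALITY_COLS[[mod]]
        st <- stats::aggregate(sub[[cl]], by = list(activity = sub$activity),
                               FUN = function(x) c(mean = mean(x), sd = stats::sd(x)))
        means <- st$x[, "mean"]
        i <- which.max(means)
        out[[length(out) + 1L]] <- data.frame(
          model_variant = variant, level = lev, modality = mod,
          activity = st$activity[i], mean = means[i],
          sd = unname(st$x[i, "sd"]))
      }
    }
  }
  do.call(rbind, out)
}

#' Percent-of-intact summary ranges
#'
#' Percent of the intact model (100%) per prosthetic variant x level x
#' activity (ratio of cohort mean peaks), then min-max ranges per variant x
#' modality split into unweighted and weighted activities.
#'
#' @param agg trial-averaged peak table.
#' @return list with `cells` (per-cell percents) and `ranges`.
#' @export
summarize_percent_table <- function(agg) {
  prosthetic <- setdiff(unique(agg$model_variant), "intact")
  if (!length(prosthetic)) {
    return(list(cells = data.frame(), ranges = data.frame()))
  }
  cells <- list()
  for (variant in prosthetic) {
    for (lev in unique(agg$level)) {
      for (act in unique(agg$activity)) {
        for (mod in names(MODALITY_COLS)) {
          cl <- MODALITY_COLS[[mod]]
          pro <- agg[[cl]][agg$model_variant == variant & agg$level == lev &
                             agg$activity == act]
          int <- agg[[cl]][agg$model_variant == "intact" & agg$level == lev &
                             agg$activity == act]
          if (!length(pro) || !length(int)) next
          cells[[length(cells) + 1L]] <- data.frame(
            model_variant = variant, level = lev, activity = act,
            modality = mod,
            weighted = act %in% WEIGHTED_ACTIVITIES,
            percent = percent_vs_intact(mean(pro), mean(int)))
        }
      }
    }
  }
  cells <- do.call(rbind, cells)
  ranges <- stats::aggregate(
    cells$percent,
    by = cells[, c("model_variant", "modality", "weighted")],
    FUN = function(x) c(lo = min(x), hi = max(x)))
  ranges <- cbind(ranges[, 1:3], lo = ranges$x[, "lo"], hi = ranges$x[, "hi"])
  list(cells = cells, ranges = ranges)
}

# Exceedance flags for the summary peaks at the levels with anatomical
# counterparts (25% -> proximal, 75% -> distal).
exceedance_from_table2 <- function(table2, env = load_envelope_presets(),
                                   ...) {
  t2 <- table2[table2$level %in% c(0.25, 0.75), ]
  if (!nrow(t2)) return(data.frame())
  peaks <- data.frame(modality = t2$modality, value = t2$mean,
                      level = t2$level, model_variant = t2$model_variant,
                      activity = t2$activity)
  exceedance(peaks, env, ...)
}

write_study_outputs <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- bundle$config
  manifest <- list(
    master_seed = cfg$master_seed,
    config = unclass(cfg[setdiff(names(cfg), "out_dir")]),
    config_hash = config_hash(cfg),
    n_subjects = nrow(bundle$subjects),
    package_version = as.character(utils::packageVersion("oiload")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(bundle$subjects, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$peaks, file.path(out_dir, "peaks.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$aggregated, file.path(out_dir, "peaks_aggregated.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$table2, file.path(out_dir, "summary_peaks.csv"),
                   row.names = FALSE)
  if (nrow(bundle$percent_table$ranges)) {
    utils::write.csv(bundle$percent_table$ranges,
                     file.path(out_dir, "percent_of_intact.csv"),
                     row.names = FALSE)
  }
  if (nrow(bundle$exceedance)) {
    utils::write.csv(bundle$exceedance,
                     file.path(out_dir, "exceedance.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

# order-independent hash of the config values (no digest dependency)
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(x) paste(format(x, digits = 17),
                                                       collapse = "|"),
                                character(1)),
             sep = "=", collapse = ";")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 2^31
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (cohort + trials + loads + tables), `analyze`
#' (mixed-model contrasts on a peak table CSV), `failure` (exceedance from a
#' summary CSV), `sensitivity`, `all`. Options: `--config <yaml>`,
#' `--seed <int>`, `--out <dir>`. Exit status 0 ok, 1 invalid input,
#' 2 internal error.
#'
#' @param args character vector of CLI arguments.
#' @return exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) {
      stop("usage: oiload <simulate|analyze|failure|sensitivity|all> ",
           "[--config file.yaml] [--seed N] [--out dir]", call. = FALSE)
    }
    cmd <- args[1]
    opt <- list(config = NULL, seed = NULL, out = "oiload_out", input = NULL)
    i <- 2
    while (i <= length(args)) {
      key <- sub("^--", "", args[i])
      if (!key %in% names(opt)) stop("unknown option --", key, call. = FALSE)
      opt[[key]] <- args[i + 1]
      i <- i + 2
    }
    cfg <- if (!is.null(opt$config)) read_study_config(opt$config)
           else study_config()
    if (!is.null(opt$seed)) cfg$master_seed <- as.integer(opt$seed)
    cfg$out_dir <- opt$out

    if (cmd %in% c("simulate", "all")) {
      bundle <- run_study(cfg, verbose = TRUE)
      if (cmd == "all") {
        res <- fit_log_mixed_model(bundle$aggregated)
        utils::write.csv(res, file.path(opt$out, "contrasts.csv"),
                         row.names = FALSE)
      }
    } else if (cmd == "analyze") {
      if (is.null(opt$input)) stop("--input peaks CSV required", call. = FALSE)
      agg <- utils::read.csv(opt$input)
      res <- fit_log_mixed_model(agg)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(res, file.path(opt$out, "contrasts.csv"),
                       row.names = FALSE)
    } else if (cmd == "failure") {
      if (is.null(opt$input)) stop("--input summary CSV required",
                                   call. = FALSE)
      t2 <- utils::read.csv(opt$input)
      res <- exceedance_from_table2(t2)
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(res, file.path(opt$out, "exceedance.csv"),
                       row.names = FALSE)
    } else if (cmd == "sensitivity") {
      set.seed(cfg$master_seed)
      subj <- sample_subject()
      rows <- list()
      for (act in cfg$activities) {
        trial <- generate_trial(act, subj,
                                activity_params(act,
                                                duration = cfg$duration,
                                                sample_rate = cfg$sample_rate))
        models <- build_condition_models(subj, cfg$levels[1], cfg)
        for (variant in setdiff(names(models), "intact")) {
          rep <- sensitivity_report(trial, models[[variant]],
                                    filter_cutoff = cfg$filter_cutoff)
          rep$activity <- act
          rep$model_variant <- variant
          rows[[length(rows) + 1L]] <- rep
        }
      }
      dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(do.call(rbind, rows),
                       file.path(opt$out, "sensitivity.csv"),
                       row.names = FALSE)
    } else {
      stop("unknown subcommand: ", cmd, call. = FALSE)
    }
    0L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("usage:|unknown|required|invalid|restricted", conditionMessage(e))) 1L else 2L
  })
  invisible(status)
}
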