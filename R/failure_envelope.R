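# Published time-zero cadaveric failure thresholds of the bone-implant
# interface (yield = onset of interface micromotion; ultimate = fracture of
# the interface), and exceedance flagging of peak activity loads against them.

#' Load the shipped failure-envelope presets
#'
#' Yield and ultimate failure mean ranges per loading modality, anatomical
#' level counterpart (proximal ~ 30% amputation, distal ~ 65%) and
#' stabilizing-screw condition, read from the versioned preset file. Bound
#' ordering (`yield_lo <= yield_hi`, `yield_lo <= ultimate_lo`,
#' `yield_hi <= ultimate_hi`) is validated at load.
#'
#' @param path preset file; defaults to the shipped constants.
#' @return data.frame of class `failure_envelope` with columns `modality,
#'   level, screws, yield_lo, yield_hi, ultimate_lo, ultimate_hi, source`.
#' @export
load_envelope_presets <- function(path = system.file(
    "extdata", "failure_envelopes.json", package = "oiload", mustWork = TRUE)) {
  env <- jsonlite::fromJSON(path)$envelopes
  num <- function(x) ifelse(vapply(x, is.null, logical(1)), NA_real_,
                            as.numeric(x))
  for (cl in c("yield_lo", "yield_hi", "ultimate_lo", "ultimate_hi")) {
    env[[cl]] <- as.numeric(env[[cl]])
  }
  for (i in seq_len(nrow(env))) {
    r <- env[i, ]
    if (!is.na(r$yield_lo)) {
      if (!(r$yield_lo > 0 && r$yield_lo <= r$yield_hi &&
            r$yield_hi <= r$ultimate_hi && r$yield_lo <= r$ultimate_lo)) {
        stop("envelope preset ", i, " violates bound ordering", call. = FALSE)
      }
    }
    if (!(r$ultimate_lo > 0 && r$ultimate_lo <= r$ultimate_hi)) {
      stop("envelope preset ", i, " violates bound ordering", call. = FALSE)
    }
  }
  class(env) <- c("failure_envelope", "data.frame")
  env
}

#' Map a modelled amputation level to its anatomical test counterpart
#'
#' The cadaveric failure tests were run at proximal (30%) and distal (65%)
#' amputation levels; modelled 25% and 75% levels map to those. The 50% level
#' has no counterpart and errors.
#'
#' @param model_level 0.25 or 0.75.
#' @return `"proximal"` or `"distal"`.
#' @export
map_level <- function(model_level) {
  if (isTRUE(abs(model_level - 0.25) < 1e-9)) return("proximal")
  if (isTRUE(abs(model_level - 0.75) < 1e-9)) return("distal")
  stop("no anatomical counterpart for level ", model_level,
       " (only 0.25 and 0.75 were tested)", call. = FALSE)
}

pick_envelope <- function(env, modality, level, screws) {
  cand <- env[env$modality == modality &
                (env$screws == screws |
                   (screws == "unspecified" & env$screws == "unspecified")), ]
  if (screws != "unspecified" && !nrow(cand)) {
    cand <- env[env$modality == modality & env$screws == "unspecified", ]
  }
  exact <- cand[cand$level == level, ]
  if (nrow(exact)) return(exact[1, ])
  anyrow <- cand[cand$level == "any", ]
  if (nrow(anyrow)) return(anyrow[1, ])
  stop("no failure envelope configured for modality=", modality,
       ", level=", level, ", screws=", screws, call. = FALSE)
}

#' Flag loading conditions that exceed the failure envelope
#'
#' Compares peak loads against yield and ultimate thresholds. The default
#' policy is conservative for the patient: it uses the lower bound of each
#' published mean range (`bound = "lo"`); `bound = "hi"` compares against the
#' upper bound. `margin` is threshold / load (how many times the observed
#' peak fits under the threshold).
#'
#' @param peaks data.frame with columns `modality`, `value` and `level`
#'   (0.25/0.75 or "proximal"/"distal"), plus any identifying columns
#'   (activity, model_variant) which are carried through.
#' @param env a `failure_envelope` from [load_envelope_presets()].
#' @param bound `"lo"` (conservative, default) or `"hi"`.
#' @param screws screw condition to compare against: `"unspecified"`
#'   (aggregate), `"with"`, or `"without"`.
#' @return data.frame with `exceeds_yield`, `exceeds_ultimate`,
#'   `yield_margin`, `ultimate_margin` appended.
#' @export
exceedance <- function(peaks, env = load_envelope_presets(),
                       bound = c("lo", "hi"),
                       screws = c("unspecified", "with", "without")) {
  bound <- match.arg(bound)
  screws <- match.arg(screws)
  stopifnot(all(c("modality", "value", "level") %in% names(peaks)))
  out <- peaks
  out$exceeds_yield <- NA
  out$exceeds_ultimate <- NA
  out$yield_margin <- NA_real_
  out$ultimate_margin <- NA_real_
  for (i in seq_len(nrow(peaks))) {
    lev <- peaks$level[i]
    if (!lev %in% c("proximal", "distal")) lev <- map_level(as.numeric(lev))
    e <- pick_envelope(env, peaks$modality[i], lev, screws)
    yield <- e[[paste0("yield_", bound)]]
    ult <- e[[paste0("ultimate_", bound)]]
    v <- peaks$value[i]
    if (!is.na(yield)) {
      out$exceeds_yield[i] <- v > yield
      out$yield_margin[i] <- yield / v
    }
    out$exceeds_ultimate[i] <- v > ult
    out$ultimate_margin[i] <- ult / v
  }
  out
}
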