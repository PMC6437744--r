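# Virtual subjects: a generative model of preferred-amplitude curves and
# of calibration behavior, so engine and metrics code can be exercised
# end-to-end without human data. A subject is a stable "true" preferred
# curve; each session's target is that curve under multiplicative
# session-to-session noise; the responder answers ramp and fine-tune
# queries truthfully with a configurable reaction overshoot.

#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Virtual-subject generator configuration
#'
#' Parameter bands for [make_profile()]. The defaults emulate the
#' reference cohort: preferred amplitudes around 1.5--2.5 mA with a
#' convex circumferential profile (volar middle pads least intense, end
#' pads most), per-pad idiosyncratic offsets that give each subject a
#' stable fingerprint, session-to-session multiplicative noise with CV in
#' the 13--27% band, and a small reaction overshoot of 0--2 ramp steps.
#'
#' @param n_pads array size (default 16).
#' @param a0_range base amplitude level band in mA.
#' @param a1_range modulation depth band in mA (half the volar-to-dorsal
#'   swing).
#' @param center_jitter max deviation of the sensitivity center from the
#'   array middle, in pads.
#' @param offset_sd_mA SD of the per-pad idiosyncratic offsets.
#' @param session_cv_range session noise CV band, percent.
#' @param overshoot_choices candidate reaction overshoots, in 0.1 mA ramp
#'   steps.
#' @param satisfaction_tol_mA fine-tuning stops when every pad is within
#'   this of the session target.
#' @param cv_pad_multiplier optional length-`n_pads` multiplier on the
#'   session CV, for modeling extra variability in the volar/dorsal
#'   transition zone; `NULL` (off) by default.
#' @return A named list of class `vs_config`.
#' @export
vs_config <- function(n_pads = 16, a0_range = c(1.5, 2.5),
                      a1_range = c(0.2, 0.8), center_jitter = 0.5,
                      offset_sd_mA = 0.15, session_cv_range = c(13, 27),
                      overshoot_choices = c(0L, 1L, 2L),
                      satisfaction_tol_mA = 0.05,
                      cv_pad_multiplier = NULL) {
  stopifnot(n_pads >= 2, length(a0_range) == 2, length(a1_range) == 2,
            a0_range[1] <= a0_range[2], a1_range[1] <= a1_range[2],
            offset_sd_mA >= 0, length(session_cv_range) == 2,
            session_cv_range[1] >= 0,
            session_cv_range[1] <= session_cv_range[2],
            all(overshoot_choices >= 0), satisfaction_tol_mA >= 0)
  if (!is.null(cv_pad_multiplier)) stopifnot(length(cv_pad_multiplier) == n_pads,
                                             all(cv_pad_multiplier > 0))
  structure(list(n_pads = as.integer(n_pads), a0_range = a0_range,
                 a1_range = a1_range, center_jitter = center_jitter,
                 offset_sd_mA = offset_sd_mA,
                 session_cv_range = session_cv_range,
                 overshoot_choices = as.integer(overshoot_choices),
                 satisfaction_tol_mA = satisfaction_tol_mA,
                 cv_pad_multiplier = cv_pad_multiplier),
            class = "vs_config")
}

#' Draw a virtual-subject profile
#'
#' The subject's true preferred curve is
#' `A0 - A1 * cos(2*pi*(pad - center)/n_pads) + offset(pad)`:
#' lowest at the array middle (the sensitive volar pads need the least
#' current) and highest at the end pads near the dorsal junction, giving
#' the convex cross-array shape. Offsets are per-pad Gaussian draws that
#' persist across the subject's sessions. Draws are deterministic in
#' `rng_seed` and the caller's RNG state is left untouched.
#'
#' @param rng_seed integer seed.
#' @param config a [vs_config()].
#' @param max_tries redraws of the offsets allowed before giving up when
#'   the curve leaves the open interval (0.1, 5.0) mA.
#' @return An object of class `virtual_subject_profile` with fields
#'   `base_level_mA`, `modulation_depth_mA`, `center_pad`,
#'   `idiosyncratic_offsets`, `true_curve`, `session_cv`,
#'   `overshoot_steps`, `satisfaction_tol_mA`, `n_pads`, `rng_seed`.
#' @export
make_profile <- function(rng_seed, config = vs_config(), max_tries = 100L) {
  with_local_seed(rng_seed, {
    n <- config$n_pads
    pads <- seq_len(n)
    a0 <- stats::runif(1, config$a0_range[1], config$a0_range[2])
    a1 <- stats::runif(1, config$a1_range[1], config$a1_range[2])
    center <- (n + 1) / 2 +
      stats::runif(1, -config$center_jitter, config$center_jitter)
    lim <- device_limits()
    true_curve <- NULL
    for (i in seq_len(max_tries)) {
      offsets <- stats::rnorm(n, 0, config$offset_sd_mA)
      cand <- a0 - a1 * cos(2 * pi * (pads - center) / n) + offsets
      if (all(cand > lim$min_mA) && all(cand < lim$max_mA)) {
        true_curve <- cand
        break
      }
    }
    if (is.null(true_curve)) {
      stop("generator configuration produces curves outside (0.1, 5.0) mA",
           call. = FALSE)
    }
    cv <- stats::runif(1, config$session_cv_range[1], config$session_cv_range[2])
    ov <- config$overshoot_choices[sample.int(length(config$overshoot_choices), 1)]
    structure(list(base_level_mA = a0, modulation_depth_mA = a1,
                   center_pad = center, idiosyncratic_offsets = offsets,
                   true_curve = true_curve, session_cv = cv,
                   overshoot_steps = ov,
                   satisfaction_tol_mA = config$satisfaction_tol_mA,
                   cv_pad_multiplier = config$cv_pad_multiplier,
                   n_pads = n, rng_seed = as.integer(rng_seed)),
              class = "virtual_subject_profile")
  })
}

#' Draw one session's target curve
#'
#' The session target is the profile's true curve under multiplicative
#' truncated-Gaussian noise, `true * (1 + e)` with
#' `e ~ N(0, session_cv/100)` per pad, clamped to the device range and
#' floored to the 0.1 mA grid. Multiplicative noise is the minimal model
#' consistent with variability reported as CVs.
#'
#' @param profile a [make_profile()] result.
#' @param rng_seed optional seed; by default the current RNG stream is
#'   consumed (as [simulate_cohort()] does).
#' @return A grid-valid [amplitude_curve()].
#' @export
sample_session_target <- function(profile, rng_seed = NULL) {
  with_local_seed(rng_seed, {
    n <- profile$n_pads
    sdv <- rep(profile$session_cv / 100, n)
    if (!is.null(profile$cv_pad_multiplier)) sdv <- sdv * profile$cv_pad_multiplier
    eps <- stats::rnorm(n, 0, sdv)
    lim <- device_limits()
    raw <- pmin(pmax(profile$true_curve * (1 + eps), lim$min_mA), lim$max_mA)
    amplitude_curve(to_grid(raw, "floor"))
  })
}

#' Truthful responder for a session target
#'
#' Builds the [subject_responder()] a profile implies for one session:
#' the ramp is stopped at the first amplitude at or above the target plus
#' the profile's reaction overshoot (so an overshoot of 1 leaves the
#' baseline 0.1 mA high, corrected later by one down-click); fine-tune
#' responses move the active pad one click toward the session target and
#' accept when it is reached; the subject is satisfied when every pad is
#' within the satisfaction tolerance of the target. Fully deterministic
#' given the target.
#'
#' @param profile a [make_profile()] result.
#' @param session_target a grid-valid [amplitude_curve()] from
#'   [sample_session_target()].
#' @return A [subject_responder()].
#' @export
make_responder <- function(profile, session_target) {
  tgt_t <- as_tenths(curve_values(session_target))
  stop_t <- tgt_t + profile$overshoot_steps
  tol <- profile$satisfaction_tol_mA
  target <- as.numeric(session_target)
  subject_responder(
    stop_ramp = function(pad, amplitude_mA) {
      round(amplitude_mA * 10) >= stop_t[pad]
    },
    adjust = function(pad, current_mA) {
      cur_t <- round(current_mA * 10)
      if (cur_t > tgt_t[pad]) "down"
      else if (cur_t < tgt_t[pad]) "up"
      else "accept"
    },
    satisfied = function(curve) {
      all(abs(as.numeric(curve) - target) <= tol + .grid_tol)
    })
}

#' Simulate a calibration cohort
#'
#' Draws `n_subjects` profiles, plays `n_sessions` full calibration
#' sessions each through the engine, and returns the final selected
#' curves as a [calibration_dataset()] (the complete [session_record()]s
#' are attached as attribute `"records"`, the profiles as `"profiles"`).
#' The default 9 x 10 shape matches the reference experiment. All
#' randomness derives from `rng_seed`, so the cohort is reproducible.
#'
#' @param n_subjects,n_sessions cohort shape (defaults 9 and 10).
#' @param procedure `"standard"` or `"streamlined"`.
#' @param config a [vs_config()].
#' @param rng_seed integer seed.
#' @param baseline grid-valid [amplitude_curve()]; required for the
#'   streamlined procedure.
#' @param timing a [timing_model()].
#' @param logger optional `function(event)` receiving every stimulus and
#'   click event from the engine.
#' @return A [calibration_dataset()] with attributes `records` and
#'   `profiles`.
#' @export
#' @examples
#' ds <- simulate_cohort(n_subjects = 2, n_sessions = 3, rng_seed = 7)
#' n_curves(ds) # 6
simulate_cohort <- function(n_subjects = 9, n_sessions = 10,
                            procedure = c("standard", "streamlined"),
                            config = vs_config(), rng_seed = 1L,
                            baseline = NULL, timing = timing_model(),
                            logger = NULL) {
  procedure <- match.arg(procedure)
  stopifnot(n_subjects >= 1, n_sessions >= 1)
  if (procedure == "streamlined") {
    if (is.null(baseline)) {
      stop("streamlined cohorts need a baseline curve", call. = FALSE)
    }
    stopifnot(isTRUE(attr(baseline, "grid")))
  }
  layout <- electrode_layout(config$n_pads)
  with_local_seed(rng_seed, {
    subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
    records <- vector("list", n_subjects * n_sessions)
    profiles <- vector("list", n_subjects)
    idx <- 0L
    for (i in seq_len(n_subjects)) {
      profile <- make_profile(subj_seeds[i], config)
      profiles[[i]] <- profile
      for (j in seq_len(n_sessions)) {
        target <- sample_session_target(profile)
        responder <- make_responder(profile, target)
        idx <- idx + 1L
        records[[idx]] <- if (procedure == "standard") {
          run_standard_session(responder, layout, timing,
                               subject_id = paste0("S", i), session_id = j,
                               rng_seed = subj_seeds[i], logger = logger)
        } else {
          run_streamlined_session(baseline, responder, layout, timing,
                                  subject_id = paste0("S", i), session_id = j,
                                  rng_seed = subj_seeds[i], logger = logger)
        }
      }
    }
    ds <- sessions_to_dataset(records)
    attr(ds, "records") <- records
    attr(ds, "profiles") <- profiles
    ds
  })
}
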