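# Calibration engine: plays the stimulation schedules against a
# responder (real or simulated) and does the action/time accounting. The
# engine never talks to hardware; amplitudes are tracked on the integer-
# tenths grid and "delivering" a stimulus means invoking the responder.

#' Subject responder contract
#'
#' A responder supplies the three behaviors the engine needs from a
#' subject:
#' * `stop_ramp(pad, amplitude_mA)` -> `TRUE` when the current ramp
#'   amplitude feels distinct but pleasant (the STOP click);
#' * `adjust(pad, current_mA)` -> one of `"up"`, `"down"`, `"accept"`
#'   while the pad is active during fine-tuning;
#' * `satisfied(curve)` -> `TRUE` when the whole curve feels even and the
#'   fine-tune pass need not be repeated.
#'
#' The engine guards against non-terminating responders: a ramp that is
#' never stopped ends at the device ceiling with the pad flagged as a
#' non-response, a pad that is never accepted stops adjusting after
#' `max_clicks` per activation, and passes stop after `max_passes`.
#'
#' @param stop_ramp,adjust,satisfied functions as described above.
#' @return An object of class `subject_responder`.
#' @export
subject_responder <- function(stop_ramp, adjust, satisfied) {
  stopifnot(is.function(stop_ramp), is.function(adjust), is.function(satisfied))
  structure(list(stop_ramp = stop_ramp, adjust = adjust,
                 satisfied = satisfied),
            class = "subject_responder")
}

#' Session timing model
#'
#' Dwell times used to convert action counts into modeled elapsed
#' seconds. The fine-tune and fast-scan dwells (2.0 s and 0.2 s) are the
#' procedure's stated values; the phase-1 per-step dwell has no stated
#' value and defaults to 1.0 s, which puts baseline acquisition near
#' three minutes for typical preferred amplitudes around 2 mA.
#'
#' @param phase1_step_dwell_s seconds per ramp step (default 1.0).
#' @param finetune_dwell_s seconds per fine-tune activation (default 2.0).
#' @param fastscan_dwell_s seconds per fast-scan pad (default 0.2).
#' @return An object of class `timing_model`.
#' @export
timing_model <- function(phase1_step_dwell_s = 1.0, finetune_dwell_s = 2.0,
                         fastscan_dwell_s = 0.2) {
  stopifnot(phase1_step_dwell_s > 0, finetune_dwell_s > 0,
            fastscan_dwell_s > 0)
  structure(list(phase1_step_dwell_s = phase1_step_dwell_s,
                 finetune_dwell_s = finetune_dwell_s,
                 fastscan_dwell_s = fastscan_dwell_s),
            class = "timing_model")
}

#' @keywords internal
#' @noRd
log_event <- function(logger, ...) {
  if (!is.null(logger)) logger(list(...))
  invisible(NULL)
}

#' Run phase 1: the method-of-limits amplitude ramp
#'
#' For each pad in order 1..n, the amplitude ramps up from `start` in
#' `step` increments until the responder stops it; the stopping amplitude
#' becomes that pad's baseline. A pad whose ramp reaches the device
#' ceiling without a stop keeps the ceiling value and is flagged as a
#' non-response rather than raising an error.
#'
#' @param responder a [subject_responder()].
#' @param layout an [electrode_layout()].
#' @param timing a [timing_model()].
#' @param start,step ramp parameters in mA (defaults 1.0 and 0.1).
#' @param logger optional `function(event)` receiving every stimulus
#'   event.
#' @return A list with `curve` (the baseline [amplitude_curve()]),
#'   `steps` (ramp steps delivered per pad), `nonresponse` (logical per
#'   pad) and `elapsed_s` (total steps times the phase-1 dwell).
#' @export
run_phase1 <- function(responder, layout = electrode_layout(),
                       timing = timing_model(), start = 1.0, step = 0.1,
                       logger = NULL) {
  n <- layout$n_pads
  ramp <- build_phase1_ramp(start, step)
  baseline <- numeric(n)
  steps <- integer(n)
  nonresponse <- logical(n)
  for (pad in seq_len(n)) {
    stopped_at <- NA_real_
    for (amp in ramp) {
      steps[pad] <- steps[pad] + 1L
      log_event(logger, type = "stimulus", phase = 1L, pad = pad,
                amplitude_mA = amp)
      if (isTRUE(responder$stop_ramp(pad, amp))) {
        stopped_at <- amp
        log_event(logger, type = "stop", pad = pad, amplitude_mA = amp)
        break
      }
    }
    if (is.na(stopped_at)) {
      nonresponse[pad] <- TRUE
      stopped_at <- ramp[length(ramp)]
    }
    baseline[pad] <- stopped_at
  }
  list(curve = amplitude_curve(baseline, layout = layout),
       steps = steps, nonresponse = nonresponse,
       elapsed_s = sum(steps) * timing$phase1_step_dwell_s)
}

#' Run phase 2: fine-tuning passes
#'
#' Plays the fine-tune sequence, letting the responder nudge the active
#' pad by 0.1 mA per click while it is active. A click that would leave
#' the device range is clamped at the limit and counted separately rather
#' than raising an error. After each full pass the responder's
#' `satisfied` is consulted; passes repeat until it returns `TRUE` or
#' `max_passes` is reached (the record is then flagged). Elapsed time is
#' passes times the sequence duration — clicks themselves are modeled as
#' instantaneous within an activation dwell.
#'
#' @param responder a [subject_responder()].
#' @param start_curve grid-valid starting [amplitude_curve()].
#' @param layout an [electrode_layout()].
#' @param timing a [timing_model()].
#' @param max_passes pass guard (default 10).
#' @param max_clicks per-activation click guard (default 100).
#' @param logger optional event callback.
#' @return A list with `curve` (final [amplitude_curve()]), `actions`
#'   (up/down clicks per pad), `elapsed_s`, `passes`, `guard_exceeded`
#'   and `clamped` (count of clicks swallowed at a device limit).
#' @export
run_finetune <- function(responder, start_curve,
                         layout = electrode_layout(attr(start_curve, "n_pads")),
                         timing = timing_model(), max_passes = 10L,
                         max_clicks = 100L, logger = NULL) {
  n <- layout$n_pads
  cur <- as_tenths(curve_values(start_curve))
  actions <- integer(n)
  clamped <- 0L
  seq_df <- build_finetune_sequence(n, timing$finetune_dwell_s)
  passes <- 0L
  guard_exceeded <- FALSE
  repeat {
    passes <- passes + 1L
    for (i in seq_len(nrow(seq_df))) {
      pad <- seq_df$pad[i]
      log_event(logger, type = "stimulus", phase = 2L, pad = pad,
                amplitude_mA = from_tenths(cur[pad]))
      clicks <- 0L
      repeat {
        r <- responder$adjust(pad, from_tenths(cur[pad]))
        if (identical(r, "accept")) break
        if (!r %in% c("up", "down")) {
          stop(sprintf("responder returned '%s'; expected up/down/accept", r),
               call. = FALSE)
        }
        clicks <- clicks + 1L
        delta <- if (identical(r, "up")) 1L else -1L
        nxt <- cur[pad] + delta
        if (nxt < 1L || nxt > 50L) {
          clamped <- clamped + 1L
          log_event(logger, type = "click_clamped", pad = pad,
                    direction = r, amplitude_mA = from_tenths(cur[pad]))
        } else {
          cur[pad] <- nxt
          actions[pad] <- actions[pad] + 1L
          log_event(logger, type = "click", pad = pad, direction = r,
                    amplitude_mA = from_tenths(cur[pad]))
        }
        if (clicks >= max_clicks) break
      }
    }
    if (isTRUE(responder$satisfied(amplitude_curve(from_tenths(cur),
                                                   layout = layout)))) break
    if (passes >= max_passes) {
      guard_exceeded <- TRUE
      break
    }
  }
  list(curve = amplitude_curve(from_tenths(cur), layout = layout),
       actions = actions,
       elapsed_s = passes * sequence_duration(seq_df),
       passes = passes, guard_exceeded = guard_exceeded, clamped = clamped)
}

#' Run a standard calibration session
#'
#' The full two-phase procedure: a method-of-limits ramp on every pad
#' (phase 1), one fast scan to review the baseline, then fine-tuning
#' passes until the responder is satisfied. Elapsed time is the sum of
#' the three parts.
#'
#' @inheritParams run_finetune
#' @param subject_id,session_id identifiers stored in the record.
#' @param start,step phase-1 ramp parameters.
#' @param rng_seed optional seed recorded for provenance.
#' @return A [session_record()] with `procedure = "standard"`.
#' @export
run_standard_session <- function(responder, layout = electrode_layout(),
                                 timing = timing_model(),
                                 subject_id = "S1", session_id = "1",
                                 start = 1.0, step = 0.1,
                                 max_passes = 10L, max_clicks = 100L,
                                 rng_seed = NULL, logger = NULL) {
  p1 <- run_phase1(responder, layout, timing, start, step, logger)
  scan_s <- sequence_duration(build_fast_scan(layout$n_pads,
                                              timing$fastscan_dwell_s))
  ft <- run_finetune(responder, p1$curve, layout, timing,
                     max_passes, max_clicks, logger)
  session_record(subject_id, session_id, "standard",
                 baseline_curve = p1$curve, final_curve = ft$curve,
                 phase1_steps = p1$steps, finetune_actions = ft$actions,
                 elapsed_s = p1$elapsed_s + scan_s + ft$elapsed_s,
                 nonresponse = p1$nonresponse, passes = ft$passes,
                 guard_exceeded = ft$guard_exceeded, rng_seed = rng_seed)
}

#' Run a streamlined calibration session
#'
#' Phase 2 only: fine-tuning starts from an a-priori baseline curve (in
#' practice the cohort 25th-percentile curve floored to the device grid)
#' instead of a per-pad ramp, so the theoretical minimum duration is one
#' fine-tune pass — 92 s for 16 pads at the default dwell.
#'
#' @inheritParams run_finetune
#' @param baseline grid-valid starting [amplitude_curve()].
#' @param subject_id,session_id identifiers stored in the record.
#' @param rng_seed optional seed recorded for provenance.
#' @return A [session_record()] with `procedure = "streamlined"` and all
#'   `phase1_steps` zero.
#' @export
run_streamlined_session <- function(baseline, responder,
                                    layout = electrode_layout(attr(baseline, "n_pads")),
                                    timing = timing_model(),
                                    subject_id = "S1", session_id = "1",
                                    max_passes = 10L, max_clicks = 100L,
                                    rng_seed = NULL, logger = NULL) {
  ft <- run_finetune(responder, baseline, layout, timing,
                     max_passes, max_clicks, logger)
  session_record(subject_id, session_id, "streamlined",
                 baseline_curve = baseline, final_curve = ft$curve,
                 phase1_steps = rep(0L, layout$n_pads),
                 finetune_actions = ft$actions,
                 elapsed_s = ft$elapsed_s,
                 passes = ft$passes, guard_exceeded = ft$guard_exceeded,
                 rng_seed = rng_seed)
}
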