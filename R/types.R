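# Domain types: pulse parameters, electrode layout, amplitude curves,
# session records and calibration datasets. All constructors validate on
# construction; downstream code can assume the invariants.

#' Stimulation pulse parameters
#'
#' Parameter triple for one biphasic current-controlled pulse train, with
#' the stimulation unit's hard limits enforced: pulse width 50--1000 us in
#' 10 us steps, pulse rate 1--400 Hz in 1 Hz steps, amplitude 0.1--5.0 mA
#' in 0.1 mA steps.
#'
#' @param pulse_width_us pulse width in microseconds.
#' @param rate_hz pulse rate in hertz.
#' @param amplitude_mA amplitude in milliamps, on the device grid.
#' @return An object of class `stim_pulse_params`.
#' @export
#' @examples
#' stim_pulse_params(300, 100, 1.8)
stim_pulse_params <- function(pulse_width_us, rate_hz, amplitude_mA) {
  if (length(pulse_width_us) != 1 || pulse_width_us < 50 || pulse_width_us > 1000 ||
      pulse_width_us %% 10 != 0) {
    stop("pulse_width_us must be in [50, 1000] and a multiple of 10", call. = FALSE)
  }
  if (length(rate_hz) != 1 || rate_hz < 1 || rate_hz > 400 || rate_hz %% 1 != 0) {
    stop("rate_hz must be an integer in [1, 400]", call. = FALSE)
  }
  if (length(amplitude_mA) != 1 || !is_on_grid(amplitude_mA)) {
    stop("amplitude_mA must be a multiple of 0.1 in [0.1, 5.0]", call. = FALSE)
  }
  structure(
    list(pulse_width_us = as.integer(pulse_width_us),
         rate_hz = as.integer(rate_hz),
         amplitude_mA = amplitude_mA),
    class = "stim_pulse_params")
}

#' Electrode array layout
#'
#' Describes the multipad array: `n_pads` circular cathodes labelled
#' 1..n_pads. Although the physical electrode wraps the forearm, pad
#' adjacency is linear (non-wrapping): pads i and j are adjacent iff
#' |i - j| = 1. The fine-tuning sequence relies on this strip ordering.
#'
#' @param n_pads number of pads (default 16).
#' @return An object of class `electrode_layout`.
#' @export
electrode_layout <- function(n_pads = 16) {
  if (length(n_pads) != 1 || n_pads < 2 || n_pads %% 1 != 0) {
    stop("n_pads must be an integer >= 2", call. = FALSE)
  }
  structure(
    list(n_pads = as.integer(n_pads), pad_labels = seq_len(n_pads)),
    class = "electrode_layout")
}

#' Are two pads adjacent?
#'
#' @param layout an [electrode_layout()].
#' @param i,j pad labels.
#' @return Logical.
#' @export
pads_adjacent <- function(layout, i, j) {
  abs(i - j) == 1
}

#' Per-pad amplitude curve
#'
#' The vector of per-pad stimulation amplitudes (mA) that is the unit of
#' all analysis. Grid-constrained curves (everything actually delivered to
#' the subject) are exact multiples of 0.1 mA in [0.1, 5.0]; analysis-only
#' curves (means, percentiles) may sit off-grid but must stay in (0, 5.0].
#'
#' @param amplitudes numeric vector of amplitudes in mA, one per pad.
#' @param grid if `TRUE` (default) the curve must be grid-exact.
#' @param layout optional [electrode_layout()]; defaults to one sized to
#'   the input.
#' @return A numeric vector of class `amplitude_curve` with attributes
#'   `grid` and `n_pads`.
#' @export
#' @examples
#' amplitude_curve(rep(1.8, 16))
amplitude_curve <- function(amplitudes, grid = TRUE, layout = NULL) {
  amplitudes <- as.numeric(amplitudes)
  if (is.null(layout)) layout <- electrode_layout(length(amplitudes))
  if (length(amplitudes) != layout$n_pads) {
    stop(sprintf("curve has %d values but the layout has %d pads",
                 length(amplitudes), layout$n_pads), call. = FALSE)
  }
  lim <- device_limits()
  if (grid) {
    if (!all(is_on_grid(amplitudes))) {
      bad <- which(!is_on_grid(amplitudes))[1]
      stop(sprintf(
        "pad %d: amplitude %.6g mA is not a multiple of %.1f in [%.1f, %.1f]",
        bad, amplitudes[bad], lim$step_mA, lim$min_mA, lim$max_mA), call. = FALSE)
    }
  } else {
    if (any(amplitudes <= 0) || any(amplitudes > lim$max_mA + .grid_tol)) {
      stop(sprintf("analysis curves must stay in (0, %.1f] mA", lim$max_mA),
           call. = FALSE)
    }
  }
  structure(amplitudes, class = "amplitude_curve",
            grid = grid, n_pads = layout$n_pads)
}

#' @export
print.amplitude_curve <- function(x, ...) {
  kind <- if (isTRUE(attr(x, "grid"))) "grid" else "analysis"
  cat(sprintf("<amplitude_curve: %d pads, %s>\n", attr(x, "n_pads"), kind))
  print(stats::setNames(as.numeric(x), paste0("pad", seq_along(x))))
  invisible(x)
}

#' @keywords internal
#' @noRd
curve_values <- function(x) as.numeric(x)

#' One calibration session record
#'
#' Bundles the outcome of a calibration run: the procedure kind, the
#' baseline curve from which fine-tuning started, the final selected
#' curve, per-pad action accounting and the modeled elapsed time.
#' Streamlined sessions skip phase 1, so their `phase1_steps` are all
#' zero.
#'
#' @param subject_id,session_id identifiers (coerced to character).
#' @param procedure `"standard"` or `"streamlined"`.
#' @param baseline_curve,final_curve grid-valid [amplitude_curve()]s.
#' @param phase1_steps integer vector: ramp steps delivered per pad.
#' @param finetune_actions integer vector: up/down clicks per pad.
#' @param elapsed_s modeled session duration in seconds.
#' @param nonresponse logical vector: pads where the ramp hit the device
#'   ceiling without a stop response. Default all `FALSE`.
#' @param passes number of fine-tune passes played.
#' @param guard_exceeded `TRUE` when the fine-tune pass guard tripped.
#' @param rng_seed integer seed used to simulate the session, or `NULL`.
#' @return An object of class `session_record`.
#' @export
session_record <- function(subject_id, session_id,
                           procedure = c("standard", "streamlined"),
                           baseline_curve, final_curve,
                           phase1_steps, finetune_actions, elapsed_s,
                           nonresponse = NULL, passes = 1L,
                           guard_exceeded = FALSE, rng_seed = NULL) {
  procedure <- match.arg(procedure)
  n <- attr(baseline_curve, "n_pads")
  stopifnot(inherits(baseline_curve, "amplitude_curve"),
            inherits(final_curve, "amplitude_curve"),
            attr(final_curve, "n_pads") == n,
            length(phase1_steps) == n, length(finetune_actions) == n,
            all(phase1_steps >= 0), all(finetune_actions >= 0),
            elapsed_s >= 0)
  if (procedure == "streamlined" && any(phase1_steps != 0)) {
    stop("streamlined sessions have no phase 1: phase1_steps must all be zero",
         call. = FALSE)
  }
  if (is.null(nonresponse)) nonresponse <- rep(FALSE, n)
  structure(
    list(subject_id = as.character(subject_id),
         session_id = as.character(session_id),
         procedure = procedure,
         baseline_curve = baseline_curve,
         final_curve = final_curve,
         phase1_steps = as.integer(phase1_steps),
         finetune_actions = as.integer(finetune_actions),
         elapsed_s = as.numeric(elapsed_s),
         nonresponse = as.logical(nonresponse),
         passes = as.integer(passes),
         guard_exceeded = isTRUE(guard_exceeded),
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
    class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat(sprintf("<session_record %s/%s: %s, %d pads, %.1f s, %d clicks>\n",
              x$subject_id, x$session_id, x$procedure,
              attr(x$final_curve, "n_pads"), x$elapsed_s,
              sum(x$finetune_actions)))
  invisible(x)
}

#' Check the action-distance identity of a session record
#'
#' With a responder that only ever moves a pad toward its target, every
#' up/down click changes the pad by exactly 0.1 mA, so per pad
#' `finetune_actions * 0.1 == |final - baseline|` holds exactly in integer
#' tenths. Non-monotone click histories (a subject who overshoots and
#' corrects within a pass) legitimately break the identity, so it is a
#' diagnostic rather than a constructor invariant.
#'
#' @param record a [session_record()].
#' @return `TRUE` if the identity holds at every pad.
#' @export
action_distance_identity <- function(record) {
  d <- abs(as_tenths(curve_values(record$final_curve)) -
             as_tenths(curve_values(record$baseline_curve)))
  all(d == record$finetune_actions)
}

#' Calibration dataset of per-session amplitude curves
#'
#' A long-format table of curves keyed by subject and session: columns
#' `subject_id`, `session_id`, `procedure`, `pad`, `amplitude_mA`. Every
#' (subject, session) pair must carry exactly one amplitude for each pad
#' of a shared layout, and pairs must be unique.
#'
#' @param df a data.frame with the columns above.
#' @param n_pads expected layout size; inferred from the data when `NULL`.
#' @return `df` with class `calibration_dataset` and attribute `n_pads`.
#' @export
calibration_dataset <- function(df, n_pads = NULL) {
  req <- c("subject_id", "session_id", "procedure", "pad", "amplitude_mA")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  df$subject_id <- as.character(df$subject_id)
  df$session_id <- as.character(df$session_id)
  df$procedure <- as.character(df$procedure)
  df$pad <- as.integer(df$pad)
  df$amplitude_mA <- as.numeric(df$amplitude_mA)

  lim <- device_limits()
  bad <- which(!is.finite(df$amplitude_mA) |
                 df$amplitude_mA < lim$min_mA - .grid_tol |
                 df$amplitude_mA > lim$max_mA + .grid_tol)
  if (length(bad)) {
    stop(sprintf("row %d: amplitude %.6g mA outside device range [%.1f, %.1f]",
                 bad[1], df$amplitude_mA[bad[1]], lim$min_mA, lim$max_mA),
         call. = FALSE)
  }
  bad_proc <- which(!df$procedure %in% c("standard", "streamlined"))
  if (length(bad_proc)) {
    stop(sprintf("row %d: unknown procedure '%s'",
                 bad_proc[1], df$procedure[bad_proc[1]]), call. = FALSE)
  }

  key <- paste(df$subject_id, df$session_id, sep = "\r")
  if (anyDuplicated(paste(key, df$pad))) {
    stop("duplicate (subject_id, session_id, pad) rows", call. = FALSE)
  }
  pads_by_key <- split(df$pad, key)
  if (is.null(n_pads)) n_pads <- if (nrow(df)) max(df$pad) else 16L
  for (k in names(pads_by_key)) {
    p <- sort(pads_by_key[[k]])
    if (!identical(p, seq_len(n_pads))) {
      id <- strsplit(k, "\r", fixed = TRUE)[[1]]
      stop(sprintf(
        "subject '%s' session '%s': expected one amplitude for each of pads 1..%d",
        id[1], id[2], n_pads), call. = FALSE)
    }
  }
  df <- df[order(match(key, unique(key)), df$pad), req, drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("calibration_dataset", "data.frame"),
            n_pads = as.integer(n_pads))
}

#' Assemble a dataset from a list of curves
#'
#' @param curves list of [amplitude_curve()]s (or bare numeric vectors).
#' @param subject_id,session_id character vectors, one entry per curve.
#' @param procedure recycled over curves.
#' @return A [calibration_dataset()].
#' @export
dataset_from_curves <- function(curves, subject_id, session_id,
                                procedure = "standard") {
  stopifnot(length(curves) == length(subject_id),
            length(curves) == length(session_id))
  procedure <- rep_len(procedure, length(curves))
  n <- if (length(curves)) length(curves[[1]]) else 16L
  rows <- lapply(seq_along(curves), function(i) {
    data.frame(subject_id = subject_id[i], session_id = session_id[i],
               procedure = procedure[i], pad = seq_len(n),
               amplitude_mA = as.numeric(curves[[i]]))
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject_id = character(), session_id = character(),
               procedure = character(), pad = integer(),
               amplitude_mA = numeric())
  calibration_dataset(df, n_pads = n)
}

#' Curves of a dataset as a matrix
#'
#' @param dataset a [calibration_dataset()].
#' @return A numeric matrix, one row per (subject, session) curve and one
#'   column per pad, with attributes `subject_id` and `session_id` giving
#'   the row keys.
#' @export
curve_matrix <- function(dataset) {
  n <- attr(dataset, "n_pads")
  key <- paste(dataset$subject_id, dataset$session_id, sep = "\r")
  ukey <- unique(key)
  m <- matrix(NA_real_, nrow = length(ukey), ncol = n,
              dimnames = list(NULL, paste0("pad", seq_len(n))))
  for (i in seq_along(ukey)) {
    rows <- dataset[key == ukey[i], ]
    m[i, rows$pad] <- rows$amplitude_mA
  }
  ids <- do.call(rbind, strsplit(ukey, "\r", fixed = TRUE))
  attr(m, "subject_id") <- ids[, 1]
  attr(m, "session_id") <- ids[, 2]
  m
}

#' Number of curves in a dataset
#' @param dataset a [calibration_dataset()].
#' @return Integer count of (subject, session) curves.
#' @export
n_curves <- function(dataset) {
  length(unique(paste(dataset$subject_id, dataset$session_id, sep = "\r")))
}
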