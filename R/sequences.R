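# Stimulation schedules. Three deterministic constructions drive a
# session: the phase-1 amplitude ramp, the phase-2 fine-tuning activation
# sequence, and the fast scan used to review a curve.

#' Phase-1 amplitude ramp
#'
#' The method-of-limits ramp: amplitudes start at `start` and rise by
#' `step` until the subject stops the ramp or `ceiling` is reached. The
#' defaults (1.0 mA start, 0.1 mA step, 5.0 mA ceiling) are the device's
#' standard phase-1 schedule.
#'
#' @param start,step,ceiling grid amplitudes in mA; `step > 0`,
#'   `start <= ceiling`.
#' @return Numeric vector of grid amplitudes: `start, start+step, ...`,
#'   truncated at `ceiling`.
#' @export
#' @examples
#' build_phase1_ramp(1.0, 0.1, 2.0) # 11 amplitudes
build_phase1_ramp <- function(start = 1.0, step = 0.1,
                              ceiling = device_limits()$max_mA) {
  ts <- as_tenths(start); tp <- as_tenths(step); tc <- as_tenths(ceiling)
  if (tp <= 0) stop("step must be positive", call. = FALSE)
  if (ts > tc) stop("start exceeds ceiling", call. = FALSE)
  from_tenths(seq.int(ts, tc, by = tp))
}

#' @keywords internal
#' @noRd
validate_finetune_sequence <- function(seq_df, n_pads) {
  pads <- seq_df$pad
  stopifnot(all(pads >= 1), all(pads <= n_pads),
            all(abs(diff(pads)) == 1),
            length(pads) == 3 * n_pads - 2)
  counts <- tabulate(pads, nbins = n_pads)
  stopifnot(counts[1] == 2, counts[n_pads] == 2,
            all(counts[setdiff(seq_len(n_pads), c(1, n_pads))] == 3))
  invisible(seq_df)
}

#' Phase-2 fine-tuning activation sequence
#'
#' Builds the ordered pad-activation plan used while the subject equalizes
#' perceived intensity: each pad is felt before and after each of its
#' neighbours, so subtle differences between adjacent pads stand out. The
#' construction chains triads (k, k+1, k) for k = 1..n-1 and closes with a
#' single activation of pad n; for n = 16 this gives the order
#' 1,2,1, 2,3,2, ..., 15,16,15, 16. Every interior pad is activated
#' exactly 3 times and the two end pads twice, for 3n - 2 activations in
#' total — 46 activations, 92 s at the 2 s default dwell, for a 16-pad
#' array.
#'
#' @param n_pads number of pads (>= 2).
#' @param dwell_s activation dwell per step in seconds (default 2.0).
#' @return A data.frame of class `finetune_sequence` with columns `pad`
#'   and `dwell_s`, one row per activation.
#' @export
#' @examples
#' fs <- build_finetune_sequence(16)
#' nrow(fs)               # 46
#' sequence_duration(fs)  # 92
build_finetune_sequence <- function(n_pads = 16, dwell_s = 2.0) {
  if (length(n_pads) != 1 || n_pads < 2 || n_pads %% 1 != 0) {
    stop("n_pads must be an integer >= 2", call. = FALSE)
  }
  if (dwell_s <= 0) stop("dwell_s must be positive", call. = FALSE)
  k <- seq_len(n_pads - 1)
  pads <- c(rbind(k, k + 1, k), n_pads)
  out <- structure(
    data.frame(pad = as.integer(pads), dwell_s = dwell_s),
    class = c("finetune_sequence", "data.frame"))
  validate_finetune_sequence(out, n_pads)
}

#' Fast-scan schedule
#'
#' Activates each pad once, in ascending order, for a short dwell. Used
#' after phase 1 (and in the improvised fast-review loop) to let the
#' subject sweep across all pads and judge whether the sensations feel
#' even.
#'
#' @param n_pads number of pads (>= 1).
#' @param dwell_s dwell per pad in seconds (default 0.2).
#' @return A data.frame with columns `pad` and `dwell_s`.
#' @export
#' @examples
#' sequence_duration(build_fast_scan(16)) # 3.2
build_fast_scan <- function(n_pads = 16, dwell_s = 0.2) {
  if (length(n_pads) != 1 || n_pads < 1 || n_pads %% 1 != 0) {
    stop("n_pads must be an integer >= 1", call. = FALSE)
  }
  if (dwell_s <= 0) stop("dwell_s must be positive", call. = FALSE)
  data.frame(pad = seq_len(n_pads), dwell_s = dwell_s)
}

#' Total duration of a schedule
#'
#' @param seq a schedule with a `dwell_s` column ([build_finetune_sequence()]
#'   or [build_fast_scan()] output).
#' @return Sum of dwell times in seconds.
#' @export
sequence_duration <- function(seq) {
  if (is.null(seq$dwell_s)) stop("not a schedule: no dwell_s column", call. = FALSE)
  sum(seq$dwell_s)
}
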