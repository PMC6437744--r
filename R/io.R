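# File formats: long-format curve CSV, curve/session JSON, and the run
# configuration file (YAML or JSON). Grid amplitudes serialize with one
# decimal so files are stable under round trips.

#' @keywords internal
#' @noRd
format_amplitude <- function(x) {
  ifelse(abs(x * 10 - round(x * 10)) <= .grid_tol,
         sprintf("%.1f", x),
         format(x, digits = 15, scientific = FALSE, trim = TRUE))
}

#' Read calibration curves
#'
#' Reads a long-format curve file into a validated
#' [calibration_dataset()]. CSV files carry the columns
#' `subject_id,session_id,procedure,pad,amplitude_mA`; JSON files carry an
#' array of objects with `subject_id`, `session_id`, `procedure` and an
#' `amplitudes` array (one value per pad).
#'
#' @param path file to read.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   missing.
#' @param n_pads expected layout size (`NULL` to infer).
#' @return A [calibration_dataset()]; row order of the file is preserved.
#' @export
read_curves <- function(path, format = c("auto", "csv", "json"), n_pads = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    rows <- lapply(recs, function(r) {
      data.frame(subject_id = r$subject_id, session_id = r$session_id,
                 procedure = r$procedure,
                 pad = seq_along(r$amplitudes),
                 amplitude_mA = as.numeric(unlist(r$amplitudes)))
    })
    df <- if (length(rows)) do.call(rbind, rows) else
      data.frame(subject_id = character(), session_id = character(),
                 procedure = character(), pad = integer(),
                 amplitude_mA = numeric())
  }
  calibration_dataset(df, n_pads = n_pads)
}

#' Write calibration curves
#'
#' Inverse of [read_curves()]: `read_curves(write_curves(d, p), p)`
#' returns a dataset equal to `d`. Grid amplitudes are written with one
#' decimal.
#'
#' @param dataset a [calibration_dataset()].
#' @param path output file.
#' @param format `"csv"` or `"json"`; inferred from the extension when
#'   missing.
#' @return `path`, invisibly.
#' @export
write_curves <- function(dataset, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    out <- data.frame(subject_id = dataset$subject_id,
                      session_id = dataset$session_id,
                      procedure = dataset$procedure,
                      pad = dataset$pad,
                      amplitude_mA = format_amplitude(dataset$amplitude_mA),
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    m <- curve_matrix(dataset)
    key <- paste(dataset$subject_id, dataset$session_id, sep = "\r")
    proc <- tapply(dataset$procedure, key, function(p) p[1])
    ukey <- unique(key)
    recs <- lapply(seq_len(nrow(m)), function(i) {
      list(subject_id = attr(m, "subject_id")[i],
           session_id = attr(m, "session_id")[i],
           procedure = unname(proc[ukey[i]]),
           amplitudes = as.numeric(m[i, ]))
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @keywords internal
#' @noRd
record_to_list <- function(r) {
  list(subject_id = r$subject_id, session_id = r$session_id,
       procedure = r$procedure,
       baseline_curve = as.numeric(r$baseline_curve),
       final_curve = as.numeric(r$final_curve),
       phase1_steps = r$phase1_steps,
       finetune_actions = r$finetune_actions,
       elapsed_s = r$elapsed_s,
       nonresponse = r$nonresponse,
       passes = r$passes,
       guard_exceeded = r$guard_exceeded,
       rng_seed = r$rng_seed)
}

#' Write session records to JSON
#'
#' @param records a list of [session_record()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sessions <- function(records, path) {
  jsonlite::write_json(lapply(records, record_to_list), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read session records from JSON
#'
#' @param path file written by [write_sessions()].
#' @return A list of [session_record()]s.
#' @export
read_sessions <- function(path) {
  recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(recs, function(r) {
    session_record(
      subject_id = r$subject_id, session_id = r$session_id,
      procedure = r$procedure,
      baseline_curve = amplitude_curve(unlist(r$baseline_curve)),
      final_curve = amplitude_curve(unlist(r$final_curve)),
      phase1_steps = unlist(r$phase1_steps),
      finetune_actions = unlist(r$finetune_actions),
      elapsed_s = r$elapsed_s,
      nonresponse = unlist(r$nonresponse),
      passes = r$passes,
      guard_exceeded = r$guard_exceeded,
      rng_seed = r$rng_seed)
  })
}

#' Datasets from session records
#'
#' Extracts the final selected curves of a list of session records as a
#' [calibration_dataset()].
#'
#' @param records list of [session_record()]s.
#' @return A [calibration_dataset()] of the final curves.
#' @export
sessions_to_dataset <- function(records) {
  dataset_from_curves(
    lapply(records, function(r) as.numeric(r$final_curve)),
    subject_id = vapply(records, function(r) r$subject_id, character(1)),
    session_id = vapply(records, function(r) r$session_id, character(1)),
    procedure = vapply(records, function(r) r$procedure, character(1)))
}

#' Default run configuration
#'
#' Bundles every knob of a simulated calibration experiment: layout size,
#' device limits, timing constants, virtual-subject generator parameters,
#' the baseline strategies to compare, and the RNG seed. The defaults
#' reproduce the reference experiment shape: 9 subjects by 10 sessions on
#' a 16-pad array.
#'
#' @param seed RNG seed stored in the config.
#' @return A named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    n_pads = 16L,
    device = device_limits(),
    timing = list(phase1_step_dwell_s = 1.0, finetune_dwell_s = 2.0,
                  fastscan_dwell_s = 0.2),
    generator = vs_config(),
    n_subjects = 9L,
    n_sessions = 10L,
    strategies = list(
      list(kind = "constant", constant_mA = 1.0),
      list(kind = "optimal_constant"),
      list(kind = "mean_curve")),
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration file
#'
#' YAML or JSON, decided by extension. Fields missing from the file keep
#' their defaults, so a config file only needs to state what it changes.
#'
#' @param path config file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  cfg <- default_run_config()
  merge_in <- function(base, upd) {
    for (nm in names(upd)) {
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) && nm != "strategies") {
        base[[nm]] <- merge_in(base[[nm]], upd[[nm]])
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  out <- merge_in(unclass(cfg), raw)
  out$n_pads <- as.integer(out$n_pads)
  out$n_subjects <- as.integer(out$n_subjects)
  out$n_sessions <- as.integer(out$n_sessions)
  out$seed <- as.integer(out$seed)
  structure(out, class = "run_config")
}

#' Write a run configuration file
#'
#' @param config a `run_config` list.
#' @param path output file (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  strip <- function(x) if (is.list(x)) lapply(x, strip) else x
  x <- strip(unclass(config))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
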