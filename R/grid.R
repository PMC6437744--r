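# Device amplitude grid: the stimulation unit delivers 0.1 to 5.0 mA in
# 0.1 mA steps. All grid arithmetic is done on integer tenths of a mA so
# that membership checks are exact integer comparisons rather than
# binary-fraction comparisons.

#' Device amplitude limits
#'
#' The stimulation unit delivers current-controlled pulses with amplitude
#' between 0.1 and 5.0 mA on a 0.1 mA grid. These constants are used by all
#' validation and grid-snapping code.
#'
#' @return A list with elements `min_mA`, `max_mA` and `step_mA`.
#' @export
#' @examples
#' device_limits()
device_limits <- function() {
  list(min_mA = 0.1, max_mA = 5.0, step_mA = 0.1)
}

# tolerance on |10*x - round(10*x)| when deciding grid membership
.grid_tol <- 1e-9

#' @keywords internal
#' @noRd
as_tenths <- function(x) {
  t <- x * 10
  r <- round(t)
  if (any(abs(t - r) > .grid_tol)) {
    off <- x[abs(t - r) > .grid_tol][1]
    stop(sprintf("amplitude %.6g mA is not on the 0.1 mA device grid", off),
         call. = FALSE)
  }
  as.integer(r)
}

#' @keywords internal
#' @noRd
from_tenths <- function(t) as.numeric(t) / 10

#' Test grid membership
#'
#' @param x numeric vector of amplitudes in mA.
#' @return Logical vector: `TRUE` where the value is an exact multiple of
#'   0.1 mA within [0.1, 5.0].
#' @export
is_on_grid <- function(x) {
  t <- x * 10
  abs(t - round(t)) <= .grid_tol & round(t) >= 1L & round(t) <= 50L
}

#' Snap an amplitude to the 0.1 mA device grid
#'
#' Converts an analysis value (for example a mean or percentile amplitude)
#' into a deliverable stimulation amplitude. `floor` truncates to the grid
#' step below and is the default when a continuous curve seeds a
#' stimulation baseline: approaching the preferred value from below avoids
#' uncomfortable overshoot and delays habituation. `nearest` rounds half
#' away from zero.
#'
#' @param value numeric vector of amplitudes in mA, each in (0, 5.0].
#' @param mode `"floor"` or `"nearest"`.
#' @return Numeric vector of grid amplitudes in [0.1, 5.0]; `floor` never
#'   exceeds its input.
#' @export
#' @examples
#' to_grid(1.84, "floor")   # 1.8
#' to_grid(1.85, "nearest") # 1.9
to_grid <- function(value, mode = c("floor", "nearest")) {
  mode <- match.arg(mode)
  lim <- device_limits()
  if (any(!is.finite(value)) || any(value <= 0) || any(value > lim$max_mA + .grid_tol)) {
    stop(sprintf(
      "amplitude out of device range: values must lie in (0, %.1f] mA", lim$max_mA),
      call. = FALSE)
  }
  t <- value * 10
  ti <- switch(mode,
    floor   = floor(t + .grid_tol),
    nearest = floor(t + 0.5)
  )
  if (any(ti < 1)) {
    stop(sprintf(
      "amplitude below the %.1f mA device minimum after snapping to the grid",
      lim$min_mA), call. = FALSE)
  }
  ti <- pmin(ti, 50)
  from_tenths(as.integer(ti))
}

#' @keywords internal
#' @noRd
clamp_tenths <- function(t) pmin(pmax(t, 1L), 50L)
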