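#' Display geometry of the stimulus monitor
#'
#' Physical and pixel dimensions of the display plus the subject's viewing
#' distance and the refresh rate. These are the quantities needed to convert
#' gaze angles (degrees of visual angle) into pixel offsets on the screen and
#' to quantize stimulus-onset times to frame boundaries. Anisotropic pixels
#' are allowed: the cm and px aspect ratios need not match.
#'
#' @param width_cm,height_cm physical display size in cm.
#' @param res_x,res_y display resolution in pixels.
#' @param distance_cm eye-to-screen distance in cm. The default is the
#'   48-inch viewing distance of a head-fixed primate rig (121.92 cm).
#' @param refresh_hz display refresh rate in Hz (default 60).
#' @return an object of class `display_geometry`.
#' @examples
#' geom <- display_geometry(121, 68, 1920, 1080)
#' deg_to_px(geom, 5, 0)
#' @export
display_geometry <- function(width_cm, height_cm, res_x, res_y,
                             distance_cm = 121.92, refresh_hz = 60) {
  vals <- c(width_cm = width_cm, height_cm = height_cm, res_x = res_x,
            res_y = res_y, distance_cm = distance_cm, refresh_hz = refresh_hz)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all display_geometry fields must be finite and strictly positive")
  if (refresh_hz < 1) stop("refresh_hz must be >= 1")
  structure(as.list(vals), class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf("<display_geometry> %gx%g cm, %gx%g px, distance %g cm, %g Hz\n",
              x$width_cm, x$height_cm, x$res_x, x$res_y,
              x$distance_cm, x$refresh_hz))
  invisible(x)
}

#' Eye-position DAC calibration
#'
#' Linear map between gaze angle in degrees and the integer
#' digital-to-analog-converter (DAC) counts in which the real-time sequencer
#' expresses its forgiveness-window edges. The map is
#' `counts = round(gain * deg + offset)`. Conversions that fall outside
#' `range` raise an error rather than clamping: a silently clamped window
#' edge would corrupt window-containment decisions.
#'
#' Defaults (100 counts/degree, offset at the mid-range of a 12-bit DAC)
#' match a typical eye-coil rig and keep worked examples exact integers;
#' every field is configurable.
#'
#' @param gain_x,gain_y counts per degree; must be nonzero.
#' @param offset_x,offset_y counts at gaze angle 0.
#' @param range length-2 integer vector of representable counts.
#' @return an object of class `dac_calibration`.
#' @export
dac_calibration <- function(gain_x = 100, gain_y = 100,
                            offset_x = 2048, offset_y = 2048,
                            range = c(0L, 4095L)) {
  if (gain_x == 0 || gain_y == 0) stop("DAC gain must be nonzero")
  if (length(range) != 2 || range[1] >= range[2])
    stop("range must be c(lo, hi) with lo < hi")
  structure(list(gain_x = gain_x, gain_y = gain_y,
                 offset_x = offset_x, offset_y = offset_y,
                 range = range),
            class = "dac_calibration")
}

#' Sequencer time base
#'
#' The real-time sequencer runs on its own clock (1 microsecond ticks by
#' default) and counts time in integer steps. User-facing durations in
#' milliseconds are converted to steps at `steps_per_ms` steps per
#' millisecond. With the default 1 us tick each step maps 1:1 to a tick
#' (1000 steps/ms); real acquisition sequencers may step slower, hence the
#' parameter.
#'
#' @param tick_us clock tick in microseconds (default 1).
#' @param steps_per_ms conversion rate in steps per millisecond (default 1000).
#' @return an object of class `time_base`.
#' @export
time_base <- function(tick_us = 1, steps_per_ms = 1000) {
  if (tick_us <= 0) stop("tick_us must be > 0")
  if (steps_per_ms <= 0) stop("steps_per_ms must be > 0")
  structure(list(tick_us = tick_us, steps_per_ms = steps_per_ms),
            class = "time_base")
}

#' Convert gaze angle to pixel offset from screen center
#'
#' Exact tangent projection: `offset_cm = distance_cm * tan(angle)` scaled by
#' the pixel pitch. No small-angle approximation is used, so large
#' eccentricities remain correct. Degrees are signed, right/up positive,
#' origin at straight-ahead gaze.
#'
#' @param geom a [display_geometry()].
#' @param angle_x,angle_y gaze angles in degrees; must satisfy |angle| < 90.
#' @return numeric vector `c(x, y)` of pixel offsets from screen center.
#' @seealso [px_to_deg()] for the inverse.
#' @export
deg_to_px <- function(geom, angle_x, angle_y) {
  stopifnot(inherits(geom, "display_geometry"))
  if (any(abs(c(angle_x, angle_y)) >= 90))
    stop("gaze angle must satisfy |angle| < 90 degrees")
  x <- geom$distance_cm * tan(angle_x * pi / 180) * (geom$res_x / geom$width_cm)
  y <- geom$distance_cm * tan(angle_y * pi / 180) * (geom$res_y / geom$height_cm)
  c(x = unname(x), y = unname(y))
}

#' Convert pixel offset to gaze angle
#'
#' @param geom a [display_geometry()].
#' @param px_x,px_y pixel offsets from screen center.
#' @return numeric vector `c(x, y)` of gaze angles in degrees.
#' @export
px_to_deg <- function(geom, px_x, px_y) {
  stopifnot(inherits(geom, "display_geometry"))
  x <- atan2(px_x * (geom$width_cm / geom$res_x), geom$distance_cm) * 180 / pi
  y <- atan2(px_y * (geom$height_cm / geom$res_y), geom$distance_cm) * 180 / pi
  c(x = unname(x), y = unname(y))
}

#' Convert gaze angle to DAC counts
#'
#' Linear map with rounding to integer counts. Out-of-range results are an
#' error, never clamped.
#'
#' @param cal a [dac_calibration()].
#' @param x,y gaze angles in degrees (finite).
#' @return integer vector `c(x, y)` of DAC counts.
#' @seealso [dac_to_deg()]
#' @export
deg_to_dac <- function(cal, x, y) {
  stopifnot(inherits(cal, "dac_calibration"))
  if (any(!is.finite(c(x, y)))) stop("gaze angles must be finite")
  cx <- round(cal$gain_x * x + cal$offset_x)
  cy <- round(cal$gain_y * y + cal$offset_y)
  if (any(c(cx, cy) < cal$range[1]) || any(c(cx, cy) > cal$range[2]))
    stop(sprintf("DAC result (%d, %d) outside range [%d, %d]",
                 cx, cy, cal$range[1], cal$range[2]))
  c(x = as.integer(cx), y = as.integer(cy))
}

#' Convert DAC counts to gaze angle
#'
#' Inverts [deg_to_dac()] to within half a count of quantization error.
#'
#' @param cal a [dac_calibration()].
#' @param x,y DAC counts.
#' @return numeric vector `c(x, y)` in degrees.
#' @export
dac_to_deg <- function(cal, x, y) {
  stopifnot(inherits(cal, "dac_calibration"))
  c(x = unname((x - cal$offset_x) / cal$gain_x),
    y = unname((y - cal$offset_y) / cal$gain_y))
}

#' Convert milliseconds to sequencer steps
#'
#' @param tb a [time_base()].
#' @param dur_ms nonnegative duration in milliseconds.
#' @return integer number of steps, `round(dur_ms * steps_per_ms)`.
#' @export
ms_to_steps <- function(tb, dur_ms) {
  stopifnot(inherits(tb, "time_base"))
  if (any(!is.finite(dur_ms)) || any(dur_ms < 0))
    stop("duration must be finite and >= 0 ms")
  as.integer(round(dur_ms * tb$steps_per_ms))
}

#' Convert sequencer steps to milliseconds
#'
#' Inverts [ms_to_steps()] to within one step.
#'
#' @param tb a [time_base()].
#' @param steps step count.
#' @return duration in milliseconds.
#' @export
steps_to_ms <- function(tb, steps) {
  stopifnot(inherits(tb, "time_base"))
  steps / tb$steps_per_ms
}

# steps -> microseconds on the session clock (internal)
steps_to_us <- function(tb, steps) steps_to_ms(tb, steps) * 1000

#' Construct a gaze-sample stream
#'
#' A gaze stream is a data frame with columns `t_us` (session-clock time in
#' microseconds, nondecreasing), `x` and `y` (degrees). Helper used by the
#' virtual rig and accepted by the sequencer after DAC conversion.
#'
#' @param t_us times in microseconds, nondecreasing.
#' @param x,y gaze position in degrees (NA allowed: signal dropout).
#' @return data.frame of class `gaze_stream`.
#' @export
gaze_stream <- function(t_us, x, y) {
  if (length(t_us) != length(x) || length(x) != length(y))
    stop("t_us, x, y must have equal length")
  if (is.unsorted(t_us)) stop("gaze timestamps must be nondecreasing")
  structure(data.frame(t_us = t_us, x = x, y = y),
            class = c("gaze_stream", "data.frame"))
}
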