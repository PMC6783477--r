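# Arena tracking: digitized head positions -> per-second lab-frame bearings,
# with the acclimation/observation window protocol.

.arena_radius_cm <- 20   # 40-cm diameter circular chamber

#' Construct an arena track
#'
#' One animal's digitized positions in the circular arena, with the metadata
#' needed to place its test in the magnetic and tidal frames.
#'
#' @param eel_id Identifier.
#' @param estuary Recruitment-estuary name.
#' @param condition Magnetic condition: geographic heading of the imposed
#'   magnetic north (0, 90, 180 or 270).
#' @param test_start POSIXct start time of the recording.
#' @param elapsed_s Elapsed seconds of each sample, strictly increasing
#'   (nominal 1 Hz).
#' @param x,y Head position in cm relative to the arena center (x to the
#'   image right, y to the image top); must lie within the 20-cm arena radius.
#' @param compass_offset Arena-frame angle (degrees) at which the lab-frame
#'   north mark of the analog compass appears; the single knob reconciling
#'   camera orientation with the lab frame.
#' @return A list of class `eel_track`.
#' @export
eel_track <- function(eel_id, estuary, condition, test_start,
                      elapsed_s, x, y, compass_offset = 0) {
  if (any(diff(elapsed_s) <= 0))
    stop("elapsed_s must be strictly increasing (eel ", eel_id, ")",
         call. = FALSE)
  if (length(x) != length(elapsed_s) || length(y) != length(elapsed_s))
    stop("positions and times must have equal length", call. = FALSE)
  rr <- sqrt(x^2 + y^2)
  if (any(rr > .arena_radius_cm + 1e-6))
    stop("positions outside the 20-cm arena radius (eel ", eel_id, ")",
         call. = FALSE)
  structure(
    list(eel_id = as.character(eel_id), estuary = as.character(estuary),
         condition = as.numeric(condition), test_start = test_start,
         samples = data.frame(elapsed_s = as.numeric(elapsed_s),
                              x = as.numeric(x), y = as.numeric(y)),
         compass_offset = as.numeric(compass_offset)),
    class = "eel_track"
  )
}

#' Convert an arena position to a lab-frame compass bearing
#'
#' The bearing of the head as seen from the arena center, clockwise from the
#' lab-frame north. The raw arena angle (clockwise from the image-top +y
#' axis) is corrected by `compass_offset`, the arena angle at which lab north
#' appears. Points at the exact center have no bearing and return `NA`.
#'
#' @param x,y Position relative to the arena center (any length unit).
#' @param compass_offset Degrees; see [eel_track()].
#' @return Bearing(s) in `[0, 360)`; `NA` for center points (within 1e-9 of
#'   the origin).
#' @examples
#' position_to_bearing(0, 1)        # 0 (due "north")
#' position_to_bearing(1, 0)        # 90 (due east)
#' position_to_bearing(1, 0, 90)    # 0
#' @export
position_to_bearing <- function(x, y, compass_offset = 0) {
  at_center <- sqrt(x^2 + y^2) < 1e-9
  b <- normalize_angle(rad2deg(atan2(x, y)) - compass_offset)
  b[at_center] <- NA_real_
  b
}

#' Trim the acclimation period and extract per-second bearings
#'
#' Retains samples in the observation window
#' `[acclimation_s, acclimation_s + duration_s)` — by default minutes 5-15 of
#' a 15-minute recording — and converts each retained position to a lab-frame
#' bearing. Center points (no defined bearing) are dropped with a warning.
#' Fewer than 90 percent of the expected `duration_s` bearings makes the
#' track unusable (error); between 90 and 100 percent proceeds with a
#' warning.
#'
#' @param track An [eel_track()].
#' @param acclimation_s Acclimation period in seconds (default 300).
#' @param duration_s Observation window in seconds (default 600).
#' @return A list of class `bearing_track`: `eel_id`, `estuary`, `condition`,
#'   `test_start`, `bearings` (lab-frame degrees), `n_expected`,
#'   `n_retained`.
#' @export
trim_acclimation <- function(track, acclimation_s = 300, duration_s = 600) {
  s <- track$samples
  if (max(s$elapsed_s) < acclimation_s)
    stop("track shorter than the acclimation period (eel ", track$eel_id, ")",
         call. = FALSE)
  keep <- s$elapsed_s >= acclimation_s & s$elapsed_s < acclimation_s + duration_s
  w <- s[keep, , drop = FALSE]
  b <- position_to_bearing(w$x, w$y, track$compass_offset)
  n_center <- sum(is.na(b))
  if (n_center > 0) {
    warning(n_center, " center-point sample(s) dropped (eel ",
            track$eel_id, ")", call. = FALSE)
    b <- b[!is.na(b)]
  }
  n_exp <- duration_s   # 1 Hz nominal cadence
  if (length(b) < 0.9 * n_exp)
    stop("track unusable: only ", length(b), "/", n_exp,
         " bearings retained (eel ", track$eel_id, ")", call. = FALSE)
  if (length(b) < n_exp)
    warning("short track: ", length(b), "/", n_exp, " bearings (eel ",
            track$eel_id, ")", call. = FALSE)
  structure(
    list(eel_id = track$eel_id, estuary = track$estuary,
         condition = track$condition, test_start = track$test_start,
         bearings = b, n_expected = n_exp, n_retained = length(b)),
    class = "bearing_track"
  )
}

#' Construct a bearing track directly from pre-digitized bearings
#'
#' For data already expressed as lab-frame bearings (the bearings-only file
#' dialect), bypassing [position_to_bearing()].
#'
#' @inheritParams eel_track
#' @param bearings Lab-frame bearings in degrees.
#' @param n_expected Nominal number of bearings (default 600).
#' @return A `bearing_track`.
#' @export
bearing_track <- function(eel_id, estuary, condition, test_start, bearings,
                          n_expected = 600) {
  structure(
    list(eel_id = as.character(eel_id), estuary = as.character(estuary),
         condition = as.numeric(condition), test_start = test_start,
         bearings = normalize_angle(bearings), n_expected = n_expected,
         n_retained = length(bearings)),
    class = "bearing_track"
  )
}
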