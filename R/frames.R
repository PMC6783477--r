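# Reference frames and tides: estuary configuration, ebb/flood classification
# from tide tables, and rotations between laboratory, magnetic, and tidal-flow
# frames.

#' Estuary configuration
#'
#' An estuary is described by the magnetic heading of its downstream
#' (freshwater-to-sea) flow. The ebb current flows seaward along this heading;
#' the flood current flows landward, 180 degrees opposed.
#'
#' @param name Character vector of estuary names (unique).
#' @param downstream_heading Magnetic degrees in `[0, 360)` of the
#'   freshwater-to-sea flow direction, one per estuary.
#' @return A data.frame of class `estuary_config` with columns `name` and
#'   `downstream_heading`.
#' @seealso [default_estuaries()] for the Austevoll study sites.
#' @export
estuary_config <- function(name, downstream_heading) {
  if (length(name) != length(downstream_heading))
    stop("'name' and 'downstream_heading' lengths differ", call. = FALSE)
  if (anyDuplicated(name)) stop("estuary names must be unique", call. = FALSE)
  if (any(!is.finite(downstream_heading) | downstream_heading < 0 |
            downstream_heading >= 360))
    stop("headings must lie in [0, 360)", call. = FALSE)
  structure(
    data.frame(name = as.character(name),
               downstream_heading = as.numeric(downstream_heading),
               stringsAsFactors = FALSE),
    class = c("estuary_config", "data.frame")
  )
}

#' Default estuary configuration (Austevoll study sites)
#'
#' The four Norwegian recruitment estuaries and the magnetic cardinal
#' directions toward which they flow: Vasseide north (0), Torvesund
#' southeast (135), Vinnesvag south (180), Stolmen northwest (315).
#'
#' @return An [estuary_config()] with four rows.
#' @export
default_estuaries <- function() {
  estuary_config(
    name = c("Vasseide", "Torvesund", "Vinnesvag", "Stolmen"),
    downstream_heading = c(0, 135, 180, 315)
  )
}

.estuary_heading <- function(estuaries, name) {
  i <- match(name, estuaries$name)
  if (any(is.na(i)))
    stop("unknown estuary: ", paste(unique(name[is.na(i)]), collapse = ", "),
         call. = FALSE)
  estuaries$downstream_heading[i]
}

#' Tide table of high/low water extrema
#'
#' @param time POSIXct vector of extremum times, strictly increasing.
#' @param type Character vector, each `"high"` or `"low"`, strictly
#'   alternating.
#' @return A data.frame of class `tide_table` with columns `time` and `type`.
#' @export
tide_table <- function(time, type) {
  if (!inherits(time, "POSIXct")) stop("'time' must be POSIXct", call. = FALSE)
  if (length(time) != length(type))
    stop("'time' and 'type' lengths differ", call. = FALSE)
  if (length(time) < 2) stop("tide table needs at least 2 extrema", call. = FALSE)
  if (any(diff(as.numeric(time)) <= 0))
    stop("tide times must be strictly increasing", call. = FALSE)
  type <- match.arg(as.character(type), c("high", "low"), several.ok = TRUE)
  if (any(type[-1] == type[-length(type)]))
    stop("tide types must strictly alternate high/low", call. = FALSE)
  structure(data.frame(time = time, type = type, stringsAsFactors = FALSE),
            class = c("tide_table", "data.frame"))
}

#' Classify an instant as ebb or flood
#'
#' An instant in a (high to low) interval is ebb (falling tide, seaward
#' current); in a (low to high) interval it is flood. An instant exactly at an
#' extremum belongs to the interval that follows it.
#'
#' @param t POSIXct time(s), strictly inside the table's span.
#' @param table A [tide_table()].
#' @return Character vector, `"ebb"` or `"flood"`.
#' @export
classify_tide_phase <- function(t, table) {
  if (!inherits(table, "tide_table")) table <- tide_table(table$time, table$type)
  if (!inherits(t, "POSIXct")) stop("'t' must be POSIXct", call. = FALSE)
  tn <- as.numeric(t)
  ex <- as.numeric(table$time)
  if (any(tn < ex[1] | tn >= ex[length(ex)]))
    stop("time outside tide-table span", call. = FALSE)
  i <- findInterval(tn, ex)   # extremum instants fall in the following interval
  ifelse(table$type[i] == "high", "ebb", "flood")
}

#' Magnetic direction of the tidal current
#'
#' The direction the water flows: during ebb, seaward along the estuary's
#' downstream heading; during flood, landward (downstream heading + 180).
#'
#' @param estuaries An [estuary_config()].
#' @param name Estuary name(s).
#' @param phase `"ebb"` or `"flood"` (vectorized with `name`).
#' @return Magnetic degrees in `[0, 360)`.
#' @export
current_direction <- function(estuaries, name, phase) {
  phase <- match.arg(phase, c("ebb", "flood"), several.ok = TRUE)
  h <- .estuary_heading(estuaries, name)
  normalize_angle(ifelse(phase == "ebb", h, h + 180))
}

#' Upstream direction of the tidal current
#'
#' The heading of a fish swimming against the prevailing current:
#' `current_direction + 180`. This is the 0-degree reference of the flow frame
#' under the default (upstream) convention.
#'
#' @inheritParams current_direction
#' @return Magnetic degrees in `[0, 360)`.
#' @export
upstream_direction <- function(estuaries, name, phase) {
  normalize_angle(current_direction(estuaries, name, phase) + 180)
}

#' Magnetic-condition constructor
#'
#' The coil system rotates magnetic north to one of the four geographic
#' cardinal headings; each animal is tested under exactly one condition.
#'
#' @param lab_north_heading Geographic degrees toward which the imposed
#'   magnetic north points; one of 0, 90, 180, 270.
#' @return Numeric of class `magnetic_condition`.
#' @export
magnetic_condition <- function(lab_north_heading) {
  if (!all(lab_north_heading %in% c(0, 90, 180, 270)))
    stop("lab_north_heading must be one of 0, 90, 180, 270", call. = FALSE)
  structure(as.numeric(lab_north_heading), class = "magnetic_condition")
}

#' Rotate a laboratory-frame bearing into the magnetic frame
#'
#' Expresses a bearing relative to the magnetic north the animal experienced:
#' `(bearing_lab - lab_north_heading) mod 360`.
#'
#' @param bearing_lab Bearing(s) in lab-frame degrees.
#' @param condition A [magnetic_condition()] or a heading in
#'   `{0, 90, 180, 270}`.
#' @return Magnetic-frame degrees in `[0, 360)`.
#' @export
lab_to_magnetic <- function(bearing_lab, condition) {
  cond <- as.numeric(condition)
  if (!all(cond %in% c(0, 90, 180, 270)))
    stop("condition must be one of 0, 90, 180, 270", call. = FALSE)
  normalize_angle(bearing_lab - cond)
}

#' Rotate a magnetic-frame bearing into the tidal-flow frame
#'
#' Signed angular difference between a magnetic bearing and the flow
#' reference direction (by default the upstream direction of the prevailing
#' current): 0 means heading straight into the current.
#'
#' @param bearing_magnetic Magnetic degrees in `[0, 360)`.
#' @param ref Flow reference direction in magnetic degrees.
#' @return Signed degrees in `(-180, 180]`.
#' @export
to_flow_frame <- function(bearing_magnetic, ref) {
  angular_difference(bearing_magnetic, ref)
}

#' Flow-frame reference direction for an estuary, phase, and convention
#'
#' Under the `"upstream"` convention (default) the reference is the direction
#' a fish heads when swimming against the prevailing current; under
#' `"downstream"` it is the direction the water flows. The two differ by
#' exactly 180 degrees.
#'
#' @inheritParams current_direction
#' @param convention `"upstream"` or `"downstream"`.
#' @return Magnetic degrees in `[0, 360)`.
#' @export
flow_reference <- function(estuaries, name, phase,
                           convention = c("upstream", "downstream")) {
  convention <- match.arg(convention)
  if (convention == "upstream") upstream_direction(estuaries, name, phase)
  else current_direction(estuaries, name, phase)
}
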