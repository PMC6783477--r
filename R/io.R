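# File I/O: delimited-text dialects for tracks, metadata, tide tables,
# estuary configs, and results. All files are UTF-8 CSV with a header row;
# lines starting with '#' are comment headers carrying provenance (seed,
# convention, package version).

.time_fmt <- "%Y-%m-%dT%H:%M:%S"

.fmt_time <- function(t) format(t, .time_fmt, tz = "UTC")
.parse_time <- function(s) {
  t <- as.POSIXct(s, format = .time_fmt, tz = "UTC")
  if (any(is.na(t))) stop("unparseable ISO-8601 timestamp", call. = FALSE)
  t
}

.write_csv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
}

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

.provenance <- function(seed = NULL, convention = NULL) {
  c(sprintf("generated-by: eelcompass %s",
            as.character(utils::packageVersion("eelcompass"))),
    if (!is.null(seed)) sprintf("seed: %d", as.integer(seed)),
    if (!is.null(convention)) sprintf("convention: %s", convention))
}

#' Write and read estuary configuration files
#'
#' Two-column CSV: `name`, `downstream_heading` (magnetic degrees).
#'
#' @param estuaries An [estuary_config()].
#' @param path File path.
#' @return `read_estuaries` returns an [estuary_config()].
#' @export
write_estuaries <- function(estuaries, path) {
  .write_csv(as.data.frame(estuaries), path, .provenance())
  invisible(path)
}

#' @rdname write_estuaries
#' @export
read_estuaries <- function(path) {
  d <- .read_csv(path)
  if (!all(c("name", "downstream_heading") %in% names(d)))
    stop("estuary config needs columns name, downstream_heading",
         call. = FALSE)
  estuary_config(d$name, d$downstream_heading)
}

#' Write and read tide tables
#'
#' Two-column CSV: ISO-8601 UTC `time`, `type` (`high`/`low`).
#'
#' @param tides A [tide_table()].
#' @param path File path.
#' @return `read_tide_table` returns a [tide_table()].
#' @export
write_tide_table <- function(tides, path) {
  .write_csv(data.frame(time = .fmt_time(tides$time), type = tides$type),
             path, .provenance())
  invisible(path)
}

#' @rdname write_tide_table
#' @export
read_tide_table <- function(path) {
  d <- .read_csv(path)
  if (!all(c("time", "type") %in% names(d)))
    stop("tide table needs columns time, type", call. = FALSE)
  tide_table(.parse_time(d$time), d$type)
}

#' Write and read per-animal test metadata
#'
#' Columns: `eel_id`, `estuary`, `condition`, `test_start` (ISO-8601 UTC),
#' `compass_offset`. One row per animal; duplicate ids are an error on read.
#'
#' @param meta Data.frame of metadata.
#' @param path File path.
#' @param seed,convention Optional provenance recorded in the file header.
#' @return `read_metadata` returns the metadata data.frame with parsed times.
#' @export
write_metadata <- function(meta, path, seed = NULL, convention = NULL) {
  out <- meta
  out$test_start <- .fmt_time(out$test_start)
  .write_csv(out, path, .provenance(seed, convention))
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  d <- .read_csv(path)
  need <- c("eel_id", "estuary", "condition", "test_start")
  if (!all(need %in% names(d)))
    stop("metadata needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(d$eel_id))
    stop("duplicate eel_id in metadata: ",
         paste(unique(d$eel_id[duplicated(d$eel_id)]), collapse = ", "),
         call. = FALSE)
  if (is.null(d$compass_offset)) d$compass_offset <- 0
  d$test_start <- .parse_time(d$test_start)
  d
}

#' Write tracks to a delimited file
#'
#' Positions dialect (`eel_id, elapsed_s, x_cm, y_cm`) for arena tracks, or
#' bearings-only dialect (`eel_id, elapsed_s, bearing_deg`) for pre-digitized
#' data.
#'
#' @param tracks List of `eel_track` or `bearing_track` objects (one dialect
#'   per file).
#' @param path File path.
#' @param seed,convention Optional provenance recorded in the file header.
#' @return The path, invisibly.
#' @export
write_tracks <- function(tracks, path, seed = NULL, convention = NULL) {
  if (all(vapply(tracks, inherits, logical(1), "eel_track"))) {
    rows <- lapply(tracks, function(tr) {
      data.frame(eel_id = tr$eel_id, elapsed_s = tr$samples$elapsed_s,
                 x_cm = sprintf("%.6f", tr$samples$x),
                 y_cm = sprintf("%.6f", tr$samples$y),
                 stringsAsFactors = FALSE)
    })
  } else if (all(vapply(tracks, inherits, logical(1), "bearing_track"))) {
    rows <- lapply(tracks, function(tr) {
      data.frame(eel_id = tr$eel_id,
                 elapsed_s = seq_along(tr$bearings) - 1,
                 bearing_deg = sprintf("%.6f", tr$bearings),
                 stringsAsFactors = FALSE)
    })
  } else {
    stop("tracks must be all eel_track or all bearing_track", call. = FALSE)
  }
  .write_csv(do.call(rbind, rows), path, .provenance(seed, convention))
  invisible(path)
}

#' Read tracks from a delimited file
#'
#' Accepts the positions dialect (`eel_id, elapsed_s, x_cm, y_cm`), yielding
#' `eel_track` objects to be digitized by [trim_acclimation()], or the
#' bearings-only dialect (`eel_id, elapsed_s, bearing_deg`), yielding
#' `bearing_track` objects that bypass [position_to_bearing()]. Metadata
#' supplies estuary, condition, test time, and compass offset per animal.
#'
#' @param path Track file path.
#' @param meta Metadata data.frame (see [read_metadata()]).
#' @return List of `eel_track` or `bearing_track` objects.
#' @export
read_tracks <- function(path, meta) {
  d <- .read_csv(path)
  pos_dialect <- all(c("eel_id", "elapsed_s", "x_cm", "y_cm") %in% names(d))
  brg_dialect <- all(c("eel_id", "elapsed_s", "bearing_deg") %in% names(d))
  if (!pos_dialect && !brg_dialect)
    stop("unknown track dialect in ", path,
         " (need x_cm,y_cm or bearing_deg)", call. = FALSE)
  ids <- unique(d$eel_id)
  miss <- setdiff(ids, meta$eel_id)
  if (length(miss) > 0)
    stop("no metadata for eel_id: ", paste(miss, collapse = ", "),
         call. = FALSE)
  sp <- split(d, d$eel_id)[ids]
  lapply(ids, function(id) {
    rows <- sp[[id]]
    if (any(diff(rows$elapsed_s) <= 0))
      stop("non-monotone elapsed_s for eel ", id, " in ", path,
           call. = FALSE)
    m <- meta[match(id, meta$eel_id), ]
    if (pos_dialect)
      eel_track(id, m$estuary, m$condition, m$test_start,
                rows$elapsed_s, rows$x_cm, rows$y_cm, m$compass_offset)
    else
      bearing_track(id, m$estuary, m$condition, m$test_start,
                    rows$bearing_deg)
  })
}

#' Write individual results and a group summary
#'
#' `write_individuals` writes the per-animal results table as CSV.
#' `write_group_summary` writes the group result as key-value lines.
#'
#' @param individuals Data.frame of individual results.
#' @param group A `group_result`.
#' @param path File path.
#' @param seed,convention Provenance recorded in the header.
#' @return The path, invisibly.
#' @export
write_individuals <- function(individuals, path, seed = NULL,
                              convention = NULL) {
  out <- individuals
  out$test_start <- NULL
  .write_csv(out, path, .provenance(seed, convention))
  invisible(path)
}

#' @rdname write_individuals
#' @export
write_group_summary <- function(group, path, seed = NULL, convention = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in .provenance(seed, convention)) writeLines(paste0("# ", cm), con)
  kv <- c(n_total = group$n_total, n_oriented = group$n_oriented,
          proportion_oriented = group$proportion_oriented,
          mean_direction_deg = group$mean_direction,
          resultant_length = group$r, rayleigh_p = group$p,
          ci_lower_deg = group$ci95[["lower"]],
          ci_upper_deg = group$ci95[["upper"]])
  writeLines(sprintf("%s: %s", names(kv), format(kv, digits = 15,
                                                 scientific = FALSE)), con)
  invisible(path)
}

#' Read a group summary written by [write_group_summary()]
#'
#' @param path File path.
#' @return Named numeric vector.
#' @export
read_group_summary <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, ": ", fixed = TRUE)
  stats::setNames(as.numeric(trimws(vapply(parts, `[`, "", 2))),
                  vapply(parts, `[`, "", 1))
}
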