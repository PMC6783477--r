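# Synthetic experiments: semidiurnal tide tables, test schedules, and
# von Mises arena tracks with the statistical structure the analysis assumes.

#' Design of a synthetic orientation experiment
#'
#' Defaults reproduce the study design of the Austevoll glass-eel data set:
#' 222 animals split 49/36/24/113 across four estuaries, a 70 percent
#' orienting phenotype fraction, and a population spread of preferred
#' flow-frame headings giving an expected group resultant length of 0.2
#' around the upstream flow direction.
#'
#' @param n_per_estuary Named integer vector: animals per estuary. Names must
#'   appear in `estuaries`.
#' @param p_orient Probability an animal is an orienting phenotype (default
#'   0.70).
#' @param group_resultant_target Expected resultant length of the orienting
#'   animals' preferred flow-frame headings (default 0.2); converted to a
#'   population von Mises concentration via [vonmises_kappa_from_r()].
#' @param kappa_track Within-track von Mises concentration of the per-second
#'   bearings (default 2.0, at which a 600-point individual Rayleigh filter
#'   passes with probability > 0.99).
#' @param rho_track Lag-1 circular mixing weight in `[0, 1)` (default 0:
#'   independent per-second bearings). Positive values stress-test the
#'   independence assumption of the individual Rayleigh test.
#' @param conditions Magnetic-north rotations assigned round-robin (default
#'   0, 90, 180, 270).
#' @param estuaries An [estuary_config()].
#' @param convention Flow-frame convention used to place preferred headings.
#' @param seed Master seed; all randomness (phenotypes, headings, schedule,
#'   tracks) flows from it through named substreams.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n_per_estuary = c(Vasseide = 49, Vinnesvag = 36,
                                                Torvesund = 24, Stolmen = 113),
                              p_orient = 0.70,
                              group_resultant_target = 0.2,
                              kappa_track = 2.0, rho_track = 0,
                              conditions = c(0, 90, 180, 270),
                              estuaries = default_estuaries(),
                              convention = c("upstream", "downstream"),
                              seed = 1L) {
  convention <- match.arg(convention)
  if (is.null(names(n_per_estuary)) ||
      !all(names(n_per_estuary) %in% estuaries$name))
    stop("'n_per_estuary' must be named with known estuaries", call. = FALSE)
  if (any(n_per_estuary < 0)) stop("sample sizes must be >= 0", call. = FALSE)
  if (p_orient < 0 || p_orient > 1) stop("'p_orient' in [0, 1]", call. = FALSE)
  if (group_resultant_target < 0 || group_resultant_target >= 1)
    stop("'group_resultant_target' in [0, 1)", call. = FALSE)
  if (rho_track < 0 || rho_track >= 1)
    stop("'rho_track' in [0, 1)", call. = FALSE)
  structure(
    list(n_per_estuary = n_per_estuary, p_orient = p_orient,
         group_resultant_target = group_resultant_target,
         kappa_pop = vonmises_kappa_from_r(group_resultant_target),
         kappa_track = kappa_track, rho_track = rho_track,
         conditions = conditions, estuaries = estuaries,
         convention = convention, seed = as.integer(seed)),
    class = "simulation_design"
  )
}

# named substreams derived from the master seed (kept below 2^31)
.sub_seed <- function(seed, stream, i = 0L) {
  offs <- c(phenotype = 11L, headings = 23L, schedule = 37L, tracks = 53L)
  (as.integer(seed) + offs[[stream]] + 104729L * as.integer(i)) %%
    .Machine$integer.max
}

#' Simulate a semidiurnal tide table
#'
#' Alternating high/low water extrema spaced half a tidal period apart
#' (default period 12.42 h, the principal lunar semidiurnal constituent).
#'
#' @param t0 POSIXct origin.
#' @param n_days Number of days to cover, `>= 1`.
#' @param period_h Tidal period in hours (default 12.42).
#' @param first_high_offset_h Hours after `t0` of the first high water
#'   (default 0).
#' @return A [tide_table()].
#' @export
simulate_tide_table <- function(t0, n_days, period_h = 12.42,
                                first_high_offset_h = 0) {
  if (n_days < 1) stop("'n_days' must be >= 1", call. = FALSE)
  half <- period_h * 3600 / 2
  n_ext <- ceiling(n_days * 86400 / half) + 1
  times <- t0 + first_high_offset_h * 3600 + (seq_len(n_ext) - 1) * half
  types <- rep(c("high", "low"), length.out = n_ext)
  tide_table(times, types)
}

# circular interpolation used for lag-1 mixing: direction of
# rho * unit(prev) + (1 - rho) * unit(new)
.circ_mix <- function(prev, new, rho) {
  p <- deg2rad(prev); q <- deg2rad(new)
  rad2deg(atan2(rho * sin(p) + (1 - rho) * sin(q),
                rho * cos(p) + (1 - rho) * cos(q)))
}

#' Simulate one animal's arena track
#'
#' An orienting animal holds a preferred flow-frame heading: the heading is
#' mapped to the lab frame by inverting the flow-frame and coil corrections
#' for the animal's estuary, the tidal phase at its test time, and its
#' magnetic condition; per-second bearings are von Mises around that lab
#' target with concentration `kappa_track` and optional lag-1 circular mixing
#' `rho_track`. A non-orienting animal's bearings are uniform. Head positions
#' are placed at the simulated bearing at a radius uniform in (5, 19) cm, so
#' [position_to_bearing()] recovers the bearing exactly. 900 samples at 1 Hz
#' (15 min including the 5-min acclimation window).
#'
#' @param eel One-row data.frame (or list) with `eel_id`, `estuary`,
#'   `phenotype` (`"orienting"`/`"non_orienting"`), `true_relative_heading`
#'   (degrees, orienting only), `condition`, `test_start`, `compass_offset`.
#' @param design A [simulation_design()].
#' @param tides A [tide_table()] spanning `test_start`.
#' @param seed Integer seed for this track.
#' @return An [eel_track()].
#' @export
simulate_eel_track <- function(eel, design, tides, seed) {
  n <- 900L
  with_seed(seed, {
    if (identical(eel$phenotype, "orienting")) {
      phase <- classify_tide_phase(eel$test_start, tides)
      ref <- flow_reference(design$estuaries, eel$estuary, phase,
                            design$convention)
      # invert to_flow_frame then lab_to_magnetic
      lab_target <- normalize_angle(ref + eel$true_relative_heading +
                                      eel$condition)
      b <- rvonmises(n, lab_target, design$kappa_track)
      if (design$rho_track > 0) {
        for (t in 2:n) b[t] <- .circ_mix(b[t - 1], b[t], design$rho_track)
        b <- normalize_angle(b)
      }
    } else {
      b <- normalize_angle(runif(n, 0, 360))
    }
    radius <- runif(n, 5, 19)
    arena <- deg2rad(b + eel$compass_offset)
    eel_track(eel$eel_id, eel$estuary, eel$condition, eel$test_start,
              elapsed_s = 0:(n - 1),
              x = radius * sin(arena), y = radius * cos(arena),
              compass_offset = eel$compass_offset)
  })
}

#' Simulate a complete orientation experiment
#'
#' Generates a tide table, a test schedule spreading animals over both ebb
#' and flood windows, round-robin magnetic-condition assignment, phenotype
#' and preferred-heading draws, and one arena track per animal. The manifest
#' records every true parameter for recovery tests. Fully reproducible from
#' the design's master seed.
#'
#' @param design A [simulation_design()].
#' @param t0 POSIXct origin of the tide table (default 2016-05-01 00:00 UTC).
#' @return A list: `tracks` (list of [eel_track()]), `metadata` (data.frame
#'   of per-animal test metadata), `tides` (a [tide_table()]), `manifest`
#'   (data.frame of true per-animal parameters plus the design as an
#'   attribute).
#' @export
simulate_experiment <- function(design,
                                t0 = as.POSIXct("2016-05-01 00:00:00",
                                                tz = "UTC")) {
  stopifnot(inherits(design, "simulation_design"))
  n_total <- sum(design$n_per_estuary)
  if (n_total < 1) stop("design has no animals", call. = FALSE)
  # enough semidiurnal windows to spread tests over ebb and flood
  n_days <- ceiling(n_total / 3) + 2
  tides <- simulate_tide_table(t0, n_days)
  n_int <- nrow(tides) - 1

  estuary <- rep(names(design$n_per_estuary), design$n_per_estuary)
  eel_id <- sprintf("eel%03d", seq_len(n_total))
  condition <- design$conditions[(seq_len(n_total) - 1) %%
                                   length(design$conditions) + 1]

  phenotype <- with_seed(.sub_seed(design$seed, "phenotype"), {
    ifelse(runif(n_total) < design$p_orient, "orienting", "non_orienting")
  })
  true_heading <- with_seed(.sub_seed(design$seed, "headings"), {
    h <- rvonmises(n_total, 0, design$kappa_pop)
    ifelse(phenotype == "orienting", h, NA_real_)
  })
  sched <- with_seed(.sub_seed(design$seed, "schedule"), {
    interval <- (seq_len(n_total) - 1) %% n_int + 1
    lo <- as.numeric(tides$time[interval])
    hi <- as.numeric(tides$time[interval + 1])
    start <- lo + (0.25 + 0.5 * runif(n_total)) * (hi - lo)
    list(test_start = as.POSIXct(start, origin = "1970-01-01", tz = "UTC"),
         compass_offset = floor(runif(n_total, 0, 360)))
  })

  meta <- data.frame(
    eel_id = eel_id, estuary = estuary, condition = condition,
    test_start = sched$test_start, compass_offset = sched$compass_offset,
    stringsAsFactors = FALSE
  )
  manifest <- cbind(meta,
                    data.frame(phenotype = phenotype,
                               true_relative_heading = true_heading,
                               phase = classify_tide_phase(sched$test_start,
                                                           tides),
                               stringsAsFactors = FALSE))
  attr(manifest, "design") <- design

  tracks <- lapply(seq_len(n_total), function(i) {
    simulate_eel_track(
      list(eel_id = eel_id[i], estuary = estuary[i],
           phenotype = phenotype[i],
           true_relative_heading = true_heading[i],
           condition = condition[i], test_start = sched$test_start[i],
           compass_offset = sched$compass_offset[i]),
      design, tides, seed = .sub_seed(design$seed, "tracks", i))
  })
  list(tracks = tracks, metadata = meta, tides = tides, manifest = manifest)
}
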