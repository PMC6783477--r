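# The orientation analysis: per-individual circular statistics, frame
# corrections, and group-level inference, wrapped as a classed model fit.

#' Analyze one individual's bearing track
#'
#' Runs the per-animal inference chain: the Rayleigh test on the raw
#' lab-frame bearings decides whether the animal is oriented; the circular
#' mean bearing is rotated from the lab frame into the magnetic frame (coil
#' correction) and then into the tidal-flow frame of the animal's estuary,
#' using the tidal phase prevailing at its test time. Rotations leave r and
#' the Rayleigh p unchanged, so the oriented filter commutes with the frame
#' corrections.
#'
#' @param bt A `bearing_track` (see [trim_acclimation()], [bearing_track()]).
#' @param estuaries An [estuary_config()].
#' @param tides A [tide_table()] spanning the test time.
#' @param alpha Individual significance level (default 0.05).
#' @param convention Flow-frame reference convention; see [flow_reference()].
#' @return One-row data.frame: `eel_id`, `estuary`, `phase`,
#'   `mean_bearing_lab`, `mean_bearing_magnetic`, `relative_bearing`, `r`,
#'   `p`, `oriented`, `n_bearings`.
#' @export
analyze_individual <- function(bt, estuaries, tides, alpha = 0.05,
                               convention = c("upstream", "downstream")) {
  convention <- match.arg(convention)
  s <- circ_mean(bt$bearings)
  rt <- rayleigh_test(s)
  phase <- classify_tide_phase(bt$test_start, tides)
  ref <- flow_reference(estuaries, bt$estuary, phase, convention)
  mu_lab <- if (s$mean_defined) s$mean_direction else NA_real_
  mu_mag <- if (s$mean_defined) lab_to_magnetic(mu_lab, bt$condition) else NA_real_
  rel <- if (s$mean_defined) to_flow_frame(mu_mag, ref) else NA_real_
  data.frame(
    eel_id = bt$eel_id, estuary = bt$estuary, phase = phase,
    mean_bearing_lab = mu_lab, mean_bearing_magnetic = mu_mag,
    relative_bearing = rel, r = s$resultant_length, p = rt$p_value,
    oriented = rt$p_value < alpha, n_bearings = s$n,
    stringsAsFactors = FALSE
  )
}

#' Group-level circular inference over oriented individuals
#'
#' Takes one flow-frame bearing per oriented animal (its mean relative
#' bearing) and runs the Rayleigh test of uniformity on them, with a
#' percentile-bootstrap confidence interval for the group mean direction.
#' Non-oriented animals contribute to `n_total` only.
#'
#' @param individuals A data.frame of individual results
#'   (rows from [analyze_individual()]).
#' @param level Confidence level for the CI (default 0.95).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param seed Integer seed for the bootstrap (mandatory).
#' @return A list of class `group_result`: `n_total`, `n_oriented`,
#'   `proportion_oriented`, `mean_direction` (degrees, `[0, 360)`), `r`, `p`,
#'   `ci95` (lower/upper degrees).
#' @export
analyze_group <- function(individuals, level = 0.95, n_boot = 2000, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  or <- individuals[individuals$oriented, , drop = FALSE]
  if (nrow(or) < 2)
    stop("need at least 2 oriented individuals for group inference",
         call. = FALSE)
  b <- normalize_angle(or$relative_bearing)
  s <- circ_mean(b)
  rt <- rayleigh_test(s)
  ci <- if (s$mean_defined) circ_ci_mean(b, level = level, n_boot = n_boot,
                                         seed = seed)
        else c(lower = NA_real_, upper = NA_real_)
  structure(
    list(n_total = nrow(individuals), n_oriented = nrow(or),
         proportion_oriented = nrow(or) / nrow(individuals),
         mean_direction = s$mean_direction, r = s$resultant_length,
         p = rt$p_value, ci95 = ci, level = level),
    class = "group_result"
  )
}

#' @export
print.group_result <- function(x, ...) {
  cat(sprintf(
    "Group orientation: N = %d oriented of %d tested (%.0f%%)\n",
    x$n_oriented, x$n_total, 100 * x$proportion_oriented))
  cat(sprintf(
    "  mean direction %.0f deg, r = %.2f, Rayleigh p = %.4g, %d%% CI [%.1f, %.1f] deg\n",
    x$mean_direction, x$r, x$p, round(100 * x$level),
    x$ci95[["lower"]], x$ci95[["upper"]]))
  invisible(x)
}

#' Per-estuary orientation counts
#'
#' Counts tested and oriented animals per estuary, with a Total row.
#' Proportions are kept at full precision; `percent` is the display rounding
#' to whole percent.
#'
#' @param individuals Data.frame of individual results.
#' @return Data.frame with columns `estuary`, `n`, `n_oriented`,
#'   `proportion`, `percent`; last row is `Total`. Estuaries with no tested
#'   animals do not appear.
#' @export
summarize_by_estuary <- function(individuals) {
  if (nrow(individuals) == 0) stop("no individual results", call. = FALSE)
  sp <- split(individuals, individuals$estuary)
  rows <- lapply(names(sp), function(e) {
    d <- sp[[e]]
    data.frame(estuary = e, n = nrow(d), n_oriented = sum(d$oriented),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, data.frame(estuary = "Total", n = sum(tab$n),
                               n_oriented = sum(tab$n_oriented),
                               stringsAsFactors = FALSE))
  tab$proportion <- tab$n_oriented / tab$n
  tab$percent <- round(100 * tab$proportion)
  tab
}

#' Bin bearings for circular display
#'
#' Half-open bins `[k*width, (k+1)*width)` after mapping bearings to
#' `[0, 360)`. Display only — statistics always use the unbinned values.
#'
#' @param bearings Degrees (signed or unsigned).
#' @param width Bin width in degrees; must divide 360 (default 5).
#' @return Data.frame `bin_start`, `count` (one row per bin, counts sum to
#'   the number of bearings).
#' @export
bin_bearings <- function(bearings, width = 5) {
  if (360 %% width != 0) stop("'width' must divide 360", call. = FALSE)
  b <- normalize_angle(bearings)
  starts <- seq(0, 360 - width, by = width)
  idx <- floor(b / width)
  data.frame(bin_start = starts,
             count = tabulate(idx + 1, nbins = length(starts)))
}

#' Fit the tidal-flow orientation model to a set of tracks
#'
#' The main entry point. Each track is reduced to its observation-window
#' bearings (arena tracks are trimmed and digitized via [trim_acclimation()];
#' `bearing_track` objects are used as-is), tested individually for
#' directionality, rotated into the tidal-flow frame of its estuary, and the
#' oriented animals are pooled for group-level circular inference.
#'
#' @param tracks List of `eel_track` and/or `bearing_track` objects.
#' @param tides A [tide_table()] spanning all test times.
#' @param estuaries An [estuary_config()]; defaults to the four Austevoll
#'   study estuaries.
#' @param alpha Significance level for the individual and group Rayleigh
#'   tests (default 0.05).
#' @param convention Flow-frame reference convention (`"upstream"` heads into
#'   the prevailing current; `"downstream"` with it).
#' @param n_boot Bootstrap resamples for the group CI (default 2000).
#' @param seed Integer seed for the bootstrap (mandatory).
#' @return An object of class `orient_fit` with components `individuals`
#'   (data.frame), `group` (a `group_result`), `by_estuary` (summary table),
#'   `alpha`, `convention`, `seed`, `call`. Methods: `print`, `summary`,
#'   `coef`, `plot`, `residuals`, `predict`, `simulate`.
#' @examples
#' design <- simulation_design(n_per_estuary = c(Vasseide = 8, Stolmen = 8),
#'                             seed = 1)
#' ex <- simulate_experiment(design)
#' fit <- fit_orientation(ex$tracks, ex$tides, seed = 1)
#' fit
#' @export
fit_orientation <- function(tracks, tides, estuaries = default_estuaries(),
                            alpha = 0.05,
                            convention = c("upstream", "downstream"),
                            n_boot = 2000, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  convention <- match.arg(convention)
  bts <- lapply(tracks, function(tr) {
    if (inherits(tr, "bearing_track")) tr
    else if (inherits(tr, "eel_track")) trim_acclimation(tr)
    else stop("tracks must be eel_track or bearing_track objects",
              call. = FALSE)
  })
  ind <- do.call(rbind, lapply(bts, analyze_individual, estuaries = estuaries,
                               tides = tides, alpha = alpha,
                               convention = convention))
  grp <- analyze_group(ind, n_boot = n_boot, seed = seed)
  structure(
    list(individuals = ind, group = grp,
         by_estuary = summarize_by_estuary(ind), alpha = alpha,
         convention = convention, n_boot = n_boot, seed = seed,
         estuaries = estuaries, call = match.call()),
    class = "orient_fit"
  )
}

#' @export
print.orient_fit <- function(x, ...) {
  cat("Tidal-flow magnetic orientation fit\n")
  cat(sprintf("  %d animals, %d estuaries, flow reference: %s current\n",
              x$group$n_total, nrow(x$by_estuary) - 1, x$convention))
  print(x$group)
  invisible(x)
}

#' @describeIn fit_orientation Per-estuary table and group statistics.
#' @param object,x An `orient_fit`.
#' @param ... Unused.
#' @export
summary.orient_fit <- function(object, ...) {
  structure(list(by_estuary = object$by_estuary, group = object$group,
                 alpha = object$alpha, convention = object$convention),
            class = "summary.orient_fit")
}

#' @export
print.summary.orient_fit <- function(x, ...) {
  cat("Proportion of animals with significant individual orientation",
      sprintf("(Rayleigh p < %.2g):\n", x$alpha))
  tab <- x$by_estuary
  tab$percent <- paste0(tab$percent, "%")
  print(tab[, c("estuary", "n", "n_oriented", "percent")], row.names = FALSE)
  cat("\n")
  print(x$group)
  invisible(x)
}

#' @describeIn fit_orientation Group mean direction (degrees) and resultant
#'   length.
#' @export
coef.orient_fit <- function(object, ...) {
  c(mean_direction = object$group$mean_direction,
    resultant_length = object$group$r)
}

#' @describeIn fit_orientation Signed angular deviations (degrees) of the
#'   oriented animals' flow-frame bearings from the group mean direction.
#' @export
residuals.orient_fit <- function(object, ...) {
  or <- object$individuals[object$individuals$oriented, , drop = FALSE]
  angular_difference(normalize_angle(or$relative_bearing),
                     object$group$mean_direction)
}

#' @describeIn fit_orientation Predicted magnetic heading of an oriented
#'   animal at a given estuary and tidal phase: the flow reference rotated by
#'   the fitted group mean direction.
#' @param estuary,phase Estuary name(s) and `"ebb"`/`"flood"`.
#' @export
predict.orient_fit <- function(object, estuary, phase, ...) {
  ref <- flow_reference(object$estuaries, estuary, phase, object$convention)
  normalize_angle(ref + object$group$mean_direction)
}

#' @describeIn fit_orientation Simulate new experiments from the fitted
#'   orienting proportion, group spread, and per-estuary sample sizes.
#'   Returns a list of `nsim` experiments (see [simulate_experiment()]).
#' @param nsim Number of simulated experiments.
#' @param seed Integer seed.
#' @export
simulate.orient_fit <- function(object, nsim = 1, seed, ...) {
  if (missing(seed)) seed <- object$seed
  ind <- object$individuals
  n_per <- table(ind$estuary)
  lapply(seq_len(nsim), function(i) {
    design <- simulation_design(
      n_per_estuary = stats::setNames(as.integer(n_per), names(n_per)),
      p_orient = object$group$proportion_oriented,
      group_resultant_target = min(object$group$r, 0.99),
      estuaries = object$estuaries,
      seed = (seed + 7919L * i) %% .Machine$integer.max
    )
    simulate_experiment(design)
  })
}
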