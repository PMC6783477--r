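# Core circular statistics on compass bearings.
#
# Convention at every interface: bearings are degrees, clockwise from the
# reference north, in [0, 360).  Radians appear only inside deg2rad/rad2deg.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# resultant length below this is treated as zero (mean direction undefined)
.zero_resultant_tol <- 1e-12

#' Normalize an angle in degrees
#'
#' Reduces an angle to the canonical compass range. In unsigned mode the
#' result lies in `[0, 360)`; in signed mode in `(-180, 180]`, the range used
#' for bearings expressed relative to a reference direction.
#'
#' @param a Numeric vector of angles in degrees. Must be finite.
#' @param signed Logical; if `TRUE` return values in `(-180, 180]`, otherwise
#'   in `[0, 360)`.
#' @return Numeric vector of normalized angles.
#' @examples
#' normalize_angle(360)            # 0
#' normalize_angle(-1)             # 359
#' normalize_angle(359, signed = TRUE)  # -1
#' @export
normalize_angle <- function(a, signed = FALSE) {
  if (!is.numeric(a) || any(!is.finite(a)))
    stop("'a' must be finite numeric", call. = FALSE)
  x <- a %% 360
  x[x >= 360] <- 0   # a tiny negative input can round %% up to exactly 360
  if (signed) {
    x <- ifelse(x > 180, x - 360, x)
  }
  x
}

#' Construct a set of compass bearings
#'
#' Validates a vector of bearings (degrees clockwise from north) and returns
#' it normalized to `[0, 360)`.
#'
#' @param values Numeric vector of bearings in degrees; must be non-empty and
#'   finite.
#' @return Numeric vector of class `bearing_set`, values in `[0, 360)`.
#' @export
bearing_set <- function(values) {
  if (length(values) == 0) stop("bearing set must be non-empty", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("bearings must be finite numeric", call. = FALSE)
  structure(normalize_angle(values), class = "bearing_set")
}

#' Circular mean and resultant length
#'
#' Computes the mean direction and resultant length of a set of compass
#' bearings: unit vectors are laid at each bearing, summed, and the direction
#' and (length / n) of the sum are returned. The mean direction is undefined
#' (NA, with `mean_defined = FALSE`) when the resultant vanishes, e.g. for
#' antipodally balanced bearings.
#'
#' @param b Numeric vector of bearings in degrees (a `bearing_set` or any
#'   non-empty finite numeric vector).
#' @return A list of class `circ_summary` with elements `mean_direction`
#'   (degrees in `[0, 360)`, `NA` if undefined), `resultant_length` (`r` in
#'   `[0, 1]`), `n`, and `mean_defined`.
#' @examples
#' circ_mean(c(10, 350))  # mean 0, r = cos(10 deg)
#' @export
circ_mean <- function(b) {
  if (length(b) == 0) stop("bearing set must be non-empty", call. = FALSE)
  if (!is.numeric(b) || any(!is.finite(b)))
    stop("bearings must be finite numeric", call. = FALSE)
  th <- deg2rad(as.numeric(b))
  C <- sum(cos(th)) / length(th)
  S <- sum(sin(th)) / length(th)
  r <- min(sqrt(C^2 + S^2), 1)
  defined <- r >= .zero_resultant_tol
  mu <- if (defined) normalize_angle(rad2deg(atan2(S, C))) else NA_real_
  structure(
    list(mean_direction = mu, resultant_length = r, n = length(th),
         mean_defined = defined),
    class = "circ_summary"
  )
}

#' @export
print.circ_summary <- function(x, ...) {
  mu <- if (x$mean_defined) sprintf("%.2f deg", x$mean_direction) else "undefined"
  cat(sprintf("Circular summary: n = %d, mean direction = %s, r = %.4f\n",
              x$n, mu, x$resultant_length))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether bearings depart from uniformity on the circle using the
#' statistic Z = n * r^2 and the standard series approximation to its p-value,
#' p = exp(-Z) * \[1 + (2Z - Z^2)/(4n) - (24Z - 132Z^2 + 76Z^3 - 9Z^4)/(288n^2)\],
#' clamped to `[0, 1]`. A small p indicates a preferred direction.
#'
#' @param x Either a `circ_summary` (from [circ_mean()]) or a numeric vector
#'   of bearings in degrees.
#' @return A list of class `rayleigh_test` with `z_statistic`, `p_value`, `n`,
#'   and `r`.
#' @examples
#' rayleigh_test(c(355, 0, 5, 10, 350, 2, 358))
#' @export
rayleigh_test <- function(x) {
  if (inherits(x, "circ_summary")) s <- x else s <- circ_mean(x)
  if (s$n < 2) stop("Rayleigh test requires n >= 2", call. = FALSE)
  p <- rayleigh_p(s$n, s$resultant_length)
  structure(
    list(z_statistic = s$n * s$resultant_length^2, p_value = p, n = s$n,
         r = s$resultant_length),
    class = "rayleigh_test"
  )
}

#' Rayleigh p-value from n and resultant length
#'
#' Vectorized series approximation used by [rayleigh_test()]; exposed so the
#' p-value can be computed directly from summary statistics (e.g. for a
#' published n and r).
#'
#' @param n Sample size(s), `>= 2`.
#' @param r Resultant length(s) in `[0, 1]`.
#' @return p-value(s) in `[0, 1]`.
#' @export
rayleigh_p <- function(n, r) {
  if (any(n < 2)) stop("Rayleigh test requires n >= 2", call. = FALSE)
  if (any(r < 0 | r > 1)) stop("'r' must lie in [0, 1]", call. = FALSE)
  Z <- n * r^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  pmin(pmax(p, 0), 1)
}

#' @export
print.rayleigh_test <- function(x, ...) {
  cat(sprintf("Rayleigh test: n = %d, r = %.4f, Z = %.4f, p = %.4g\n",
              x$n, x$r, x$z_statistic, x$p_value))
  invisible(x)
}

#' Monte Carlo p-value for the Rayleigh test
#'
#' Simulation oracle for the series approximation: draws `reps` samples of `n`
#' independent uniform bearings and reports the fraction whose resultant
#' length is at least `r_obs`. Several observed resultants can be evaluated
#' against the same null draws by passing a vector `r_obs`.
#'
#' @param n Sample size, `>= 2`.
#' @param r_obs Observed resultant length(s).
#' @param reps Number of Monte Carlo replicates, `>= 1000`.
#' @param seed Integer seed (mandatory; results are reproducible).
#' @return Numeric vector of p-values, one per element of `r_obs`.
#' @export
rayleigh_p_montecarlo <- function(n, r_obs, reps = 1e5, seed) {
  if (n < 2) stop("'n' must be >= 2", call. = FALSE)
  if (reps < 1000) stop("'reps' must be >= 1000", call. = FALSE)
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  r_null <- with_seed(seed, {
    out <- numeric(reps)
    done <- 0
    chunk <- max(1, floor(2e6 / n))   # bound the working matrix
    while (done < reps) {
      k <- min(chunk, reps - done)
      th <- matrix(runif(n * k, 0, 2 * pi), nrow = n)
      out[(done + 1):(done + k)] <-
        sqrt(colSums(cos(th))^2 + colSums(sin(th))^2) / n
      done <- done + k
    }
    out
  })
  vapply(r_obs, function(r) mean(r_null >= r), numeric(1))
}

#' Bootstrap confidence interval for a circular mean direction
#'
#' Percentile bootstrap: bearings are resampled with replacement `n_boot`
#' times, the circular mean of each resample is taken, and the central
#' `level` arc around the observed mean is reported. Endpoints are in
#' `[0, 360)`; an interval straddling north has `lower > upper`.
#'
#' @param b Numeric vector of bearings in degrees with strictly positive
#'   resultant.
#' @param level Confidence level in (0, 1); default 0.95.
#' @param n_boot Number of bootstrap resamples; default 2000.
#' @param seed Integer seed (mandatory).
#' @return Named numeric vector `c(lower, upper)` in degrees.
#' @export
circ_ci_mean <- function(b, level = 0.95, n_boot = 2000, seed) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)", call. = FALSE)
  s <- circ_mean(b)
  if (!s$mean_defined)
    stop("mean direction undefined (zero resultant); no CI", call. = FALSE)
  th <- as.numeric(b)
  n <- length(th)
  boot_mu <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    rad <- deg2rad(th)
    C <- colSums(matrix(cos(rad)[idx], nrow = n))
    S <- colSums(matrix(sin(rad)[idx], nrow = n))
    rad2deg(atan2(S, C))
  })
  # center on the observed mean so quantiles are taken on a linear scale
  dev <- normalize_angle(boot_mu - s$mean_direction, signed = TRUE)
  qs <- stats::quantile(dev, probs = c((1 - level) / 2, (1 + level) / 2),
                        names = FALSE, type = 7)
  c(lower = normalize_angle(s$mean_direction + qs[1]),
    upper = normalize_angle(s$mean_direction + qs[2]))
}

#' Signed angular difference between two bearings
#'
#' Returns `a - ref` reduced to `(-180, 180]`: the rotation taking the
#' reference direction onto `a`, positive clockwise. Used to express a bearing
#' relative to a reference direction such as the upstream tidal flow.
#'
#' @param a,ref Bearings in degrees (finite; vectorized).
#' @return Signed degrees in `(-180, 180]`.
#' @examples
#' angular_difference(359, 0)   # -1
#' angular_difference(0, 180)   # 180
#' @export
angular_difference <- function(a, ref) {
  normalize_angle(a - ref, signed = TRUE)
}

#' von Mises concentration from a target resultant length
#'
#' Solves A1(kappa) = r, where A1 = I1/I0 is the ratio of modified Bessel
#' functions, by bracketed root finding. This is the concentration at which a
#' von Mises population has expected resultant length `r`; used to calibrate
#' simulations.
#'
#' @param r Target resultant length in `[0, 1)`.
#' @return Concentration `kappa >= 0` with `A1(kappa) = r` to relative
#'   tolerance 1e-8.
#' @export
vonmises_kappa_from_r <- function(r) {
  if (!is.finite(r) || r < 0 || r >= 1)
    stop("'r' must lie in [0, 1)", call. = FALSE)
  if (r < 1e-12) return(0)
  A1 <- function(k) besselI(k, 1, expon.scaled = TRUE) /
    besselI(k, 0, expon.scaled = TRUE)
  # A1 is increasing; bracket upward from a small kappa
  hi <- 1
  while (A1(hi) < r) hi <- hi * 2
  stats::uniroot(function(k) A1(k) - r, c(1e-12, hi), tol = 1e-12)$root
}

#' A1 Bessel-function ratio
#'
#' `I1(kappa)/I0(kappa)`, the expected resultant length of a von Mises sample
#' with concentration `kappa`. Inverse of [vonmises_kappa_from_r()].
#'
#' @param kappa Concentration, `>= 0`.
#' @return Expected resultant length in `[0, 1)`.
#' @export
vonmises_r_from_kappa <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

#' Draw von Mises bearings
#'
#' Samples compass bearings (degrees) from a von Mises distribution with mean
#' direction `mu` and concentration `kappa`, using the Best-Fisher rejection
#' algorithm. `kappa = 0` gives the circular uniform distribution.
#'
#' @param n Number of draws.
#' @param mu Mean direction in degrees.
#' @param kappa Concentration, `>= 0`.
#' @return Numeric vector of bearings in `[0, 360)`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (kappa < 0) stop("'kappa' must be >= 0", call. = FALSE)
  if (kappa < 1e-10) return(normalize_angle(runif(n, 0, 360)))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  Rb <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  filled <- 0
  while (filled < n) {
    m <- n - filled
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + Rb * z) / (Rb + z)
    cc <- kappa * (Rb - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(f[ok])
    k <- length(th)
    if (k > 0) {
      out[(filled + 1):(filled + k)] <- th
      filled <- filled + k
    }
  }
  normalize_angle(mu + rad2deg(out))
}

# Run an expression under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
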