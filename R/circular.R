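#' Wrap angles into (-180, 180]
#'
#' Maps any finite angle in degrees onto the half-open interval
#' \eqn{(-180, 180]}. This is the package-wide convention for report errors
#' and target--flanker orientation differences: positive values are
#' clockwise of the reference orientation. The function is idempotent and
#' preserves congruence modulo 360.
#'
#' @param angle numeric vector of angles in degrees.
#' @return numeric vector of the same length, each element in (-180, 180].
#' @examples
#' wrap_deg(c(190, -180, 540, 0))  # -170, 180, 180, 0
#' @export
wrap_deg <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric")
  }
  out <- angle %% 360
  out[out > 180] <- out[out > 180] - 360
  # boundary convention: -180 maps to +180 (the modulo above already does
  # this because -180 %% 360 == 180)
  out
}

#' Wrap angles into [0, 360)
#'
#' Companion to [wrap_deg()] for absolute orientations (target, flanker gap
#' and report orientations are stored on \eqn{[0, 360)}).
#'
#' @param angle numeric vector of angles in degrees.
#' @return numeric vector with elements in [0, 360).
#' @export
wrap360 <- function(angle) {
  if (!is.numeric(angle) || any(!is.finite(angle))) {
    stop("`angle` must be finite numeric")
  }
  angle %% 360
}

# mean resultant length of a sample of angles in degrees
resultant_length <- function(angles) {
  th <- angles * pi / 180
  sqrt(mean(cos(th))^2 + mean(sin(th))^2)
}

#' Circular standard deviation
#'
#' Computes the circular standard deviation \eqn{\sqrt{-2 \ln R}} (in
#' degrees), where \eqn{R} is the mean resultant length of the angles
#' treated as unit vectors. This is the "perceptual error" measure used to
#' summarise report-error dispersion in unflanked and no-gap flanker
#' conditions, and follows the Circular Statistics Toolbox convention
#' rather than the angular-deviation variant \eqn{\sqrt{2(1-R)}}; the two
#' diverge for dispersed samples.
#'
#' The statistic is unbounded as \eqn{R \to 0}: for a perfectly uniform
#' sample `Inf` is returned with a warning.
#'
#' @param angles numeric vector of angles in degrees (any range; wrapping
#'   does not affect the result).
#' @return circular standard deviation in degrees (scalar).
#' @examples
#' circular_sd(c(60, -60))          # 67.46 degrees
#' circular_sd(rep(45, 10))         # 0
#' @export
circular_sd <- function(angles) {
  if (length(angles) == 0L) stop("`angles` must be non-empty")
  if (!is.numeric(angles) || any(!is.finite(angles))) {
    stop("`angles` must be finite numeric")
  }
  R <- resultant_length(angles)
  # guard machine-precision noise at both ends of the resultant length
  if (R < 1e-12) {
    warning("zero resultant length; circular SD is infinite")
    return(Inf)
  }
  if (R >= 1 - 1e-12) return(0)
  sqrt(-2 * log(R)) * 180 / pi
}

#' Circular mean
#'
#' Direction of the mean resultant vector, in degrees wrapped to
#' (-180, 180]. Unlike the arithmetic mean this is wrap-aware:
#' `circular_mean(c(170, -170))` is 180, not 0.
#'
#' @param angles numeric vector of angles in degrees.
#' @return circular mean in degrees, in (-180, 180].
#' @export
circular_mean <- function(angles) {
  if (length(angles) == 0L) stop("`angles` must be non-empty")
  if (!is.numeric(angles) || any(!is.finite(angles))) {
    stop("`angles` must be finite numeric")
  }
  th <- angles * pi / 180
  s <- mean(sin(th)); c <- mean(cos(th))
  if (sqrt(s^2 + c^2) < .Machine$double.eps^0.5) {
    stop("zero resultant length; circular mean is undefined")
  }
  wrap_deg(atan2(s, c) * 180 / pi)
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric percentile bootstrap for an arbitrary statistic of a
#' sample. Resampling is with replacement at the level of individual
#' elements (trials), `n_boot` times, and the interval is taken from the
#' empirical quantiles of the resampled statistic.
#'
#' @param data vector (or list) of observations; the resampling unit.
#' @param statistic function mapping a sample like `data` to a scalar.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level confidence level in (0, 1) (default 0.95).
#' @param seed optional integer seed for reproducibility.
#' @return an object of class `"bootstrap_ci"`: a list with elements
#'   `point`, `lower`, `upper`, `level`, `n_boot`, `seed`.
#' @examples
#' x <- rnorm(50)
#' bootstrap_ci(x, mean, n_boot = 500, seed = 1)
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000, level = 0.95,
                         seed = NULL) {
  if (length(data) == 0L) stop("`data` must be non-empty")
  stopifnot(is.function(statistic), level > 0, level < 1, n_boot >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(data)
  point <- statistic(data)
  boot <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    res <- tryCatch(statistic(data[sample.int(n, n, replace = TRUE)]),
                    error = function(e) {
                      stop("statistic failed on resample ", b, ": ",
                           conditionMessage(e))
                    })
    boot[b] <- res
  }
  alpha <- (1 - level) / 2
  qs <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE,
                        na.rm = TRUE)
  structure(list(point = point, lower = qs[1], upper = qs[2],
                 level = level, n_boot = n_boot, seed = seed),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, digits = 4, ...) {
  cat(sprintf("%.*g  [%.*g, %.*g]  (%g%% percentile bootstrap, %d resamples)\n",
              digits, x$point, digits, x$lower, digits, x$upper,
              100 * x$level, x$n_boot))
  invisible(x)
}

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis that a sample of angles is uniformly
#' distributed on the circle, using the mean resultant length statistic
#' with the standard finite-sample corrected p-value approximation.
#'
#' @param angles numeric vector of angles in degrees.
#' @return list with `R_bar` (mean resultant length), `statistic`
#'   (\eqn{Z = n \bar R^2}) and `p_value`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 2L) stop("need at least 2 angles")
  Rbar <- resultant_length(angles)
  Z <- n * Rbar^2
  # Zar's approximation
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(R_bar = Rbar, statistic = Z, p_value = max(0, min(1, p)))
}

# --- von Mises utilities (degree parameterisation, full 360-degree circle) ---

#' von Mises density on the 360-degree circle
#'
#' Density of the von Mises distribution parameterised in degrees on the
#' full circle (period 360): the Landolt-C gap position is unique on the
#' circle, so the 180-degree grating convention does not apply.
#'
#' @param x angles in degrees (deviations from the mean direction).
#' @param kappa concentration parameter (>= 0); `kappa = 0` is the uniform
#'   density 1/360.
#' @return density values (per degree).
#' @export
dvonmises_deg <- function(x, kappa) {
  stopifnot(kappa >= 0)
  th <- x * pi / 180
  # exponentially scaled Bessel keeps this finite for large kappa
  exp(kappa * (cos(th) - 1)) / (360 * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Sample from a von Mises distribution (degrees)
#'
#' Best--Fisher (1979) rejection sampler, parameterised in degrees on the
#' 360-degree circle.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration (>= 0); 0 gives uniform draws.
#' @return numeric vector of `n` angles in [0, 360).
#' @export
rvonmises_deg <- function(n, mu_deg = 0, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  th <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    k <- sum(ok)
    if (k > 0L) {
      th[(got + 1L):(got + k)] <- sign(u3[ok] - 0.5) * acos(f[ok])
      got <- got + k
    }
  }
  wrap360(mu_deg + th * 180 / pi)
}

#' Convert von Mises concentration to circular SD (degrees)
#'
#' The circular SD implied by concentration \eqn{\kappa} is
#' \eqn{\sqrt{-2\ln R(\kappa)}} with \eqn{R(\kappa) = I_1(\kappa)/I_0(\kappa)}
#' the mean resultant length. Strictly decreasing in \eqn{\kappa};
#' \eqn{\kappa = 0} maps to `Inf`.
#'
#' @param kappa concentration (>= 0); vectorised.
#' @return circular SD in degrees.
#' @seealso [circ_sd_to_kappa()]
#' @export
kappa_to_circ_sd <- function(kappa) {
  stopifnot(all(kappa >= 0))
  R <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  out <- rep(Inf, length(kappa))
  pos <- R > 0
  out[pos] <- sqrt(-2 * log(R[pos])) * 180 / pi
  out[kappa == Inf] <- 0
  out
}

#' Convert circular SD (degrees) to von Mises concentration
#'
#' Inverse of [kappa_to_circ_sd()] by monotone root-finding. Concentrations
#' are confined to \eqn{[0.01, 500]}; an `sd_deg` below the floor
#' representable at the upper bound is clamped there with a warning.
#'
#' @param sd_deg circular SD in degrees (> 0); vectorised.
#' @param kappa_bounds length-2 numeric search interval.
#' @return concentration parameter kappa.
#' @export
circ_sd_to_kappa <- function(sd_deg, kappa_bounds = c(0.01, 500)) {
  stopifnot(all(sd_deg > 0), length(kappa_bounds) == 2)
  vapply(sd_deg, function(s) {
    lo <- kappa_bounds[1]; hi <- kappa_bounds[2]
    if (s >= kappa_to_circ_sd(lo)) return(lo)
    if (s <= kappa_to_circ_sd(hi)) {
      warning("circular SD below representable floor; kappa clamped to ",
              hi)
      return(hi)
    }
    stats::uniroot(function(k) kappa_to_circ_sd(k) - s,
                   lower = lo, upper = hi, tol = 1e-10)$root
  }, numeric(1))
}

#' Two-sample Kuiper statistic
#'
#' Rotation-invariant analogue of the Kolmogorov--Smirnov statistic for
#' circular data: \eqn{V = \max(F_1 - F_2) + \max(F_2 - F_1)} over the
#' pooled sample. Used as the distance score by the grid-search simulation
#' estimator, where a rotation-invariant comparison is appropriate because
#' report errors live on the circle.
#'
#' @param x,y numeric vectors of angles in degrees.
#' @return the Kuiper statistic V (scalar in [0, 2]).
#' @export
kuiper_stat <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  x <- wrap_deg(x); y <- wrap_deg(y)
  pts <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(pts)
  Fy <- stats::ecdf(y)(pts)
  d <- Fx - Fy
  max(d, 0) + max(-d, 0)
}
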