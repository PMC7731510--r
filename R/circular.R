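#' von Mises sampling and axial dispersion
#'
#' `rvonmises` draws from the von Mises distribution VM(mu, kappa) on the
#' circle using the Best–Fisher rejection algorithm; `raxial_vonmises` draws
#' axial orientations on `[0, pi)` by sampling the doubled angle from
#' VM(2*mu, kappa) and halving — the standard axial-data construction, under
#' which the population directional variance has the closed form
#' `1 - I1(kappa)/I0(kappa)` returned by [axial_dispersion_expected()].
#'
#' @param n number of draws.
#' @param mu mean direction, radians.
#' @param kappa concentration, `>= 0`; `kappa = 0` is the uniform circle.
#' @return numeric vector of angles in radians (`rvonmises`: on the circle;
#'   `raxial_vonmises`: in `[0, pi)`).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0, is.finite(kappa))
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-9) return((mu + stats::runif(n, 0, 2 * pi)) %% (2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(n - length(out), 16L)
    m <- ceiling(m * 1.3)          # over-draw; acceptance rate is high
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    ccc <- kappa * (r - f)
    keep <- (ccc * (2 - ccc) - u2 > 0) | (log(ccc / u2) + 1 - ccc >= 0)
    th <- sign(u3[keep] - 0.5) * acos(pmin(pmax(f[keep], -1), 1))
    out <- c(out, th)
  }
  (mu + out[seq_len(n)]) %% (2 * pi)
}

#' @rdname rvonmises
#' @export
raxial_vonmises <- function(n, mu = 0, kappa = 1) {
  (rvonmises(n, 2 * mu, kappa) / 2) %% pi
}

#' @rdname rvonmises
#' @export
axial_dispersion_expected <- function(kappa) {
  stopifnot(all(kappa >= 0))
  # exponentially scaled Bessel ratio for numerical stability at large kappa
  1 - besselI(kappa, 1, expon.scaled = TRUE) /
      besselI(kappa, 0, expon.scaled = TRUE)
}

#' Circular variance of axial orientations
#'
#' `1 - |mean(exp(2i*phi))|` for a set of axial orientations `phi` (radians,
#' modulo pi): 0 for perfectly aligned fibers, 1 when doubled orientation
#' vectors cancel (e.g. equal populations 90 degrees apart).
#'
#' @param phi orientations in radians.
#' @return variance in `[0, 1]`; `NaN` for empty input.
#' @export
axial_variance <- function(phi) {
  if (length(phi) == 0L) return(NaN)
  1 - Mod(mean(exp(2i * phi)))
}
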