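#' Wrap angles into (-pi, pi]
#' @param theta numeric vector of angles (rad).
#' @return wrapped angles.
#' @export
wrap_angle <- function(theta) {
  w <- (theta + pi) %% (2 * pi) - pi
  # map the -pi representative to +pi so the range is (-pi, pi]
  w[w == -pi] <- pi
  w
}

#' Draw from a von Mises distribution
#'
#' Best & Fisher (1979) rejection sampler. `kappa = 0` returns uniform angles;
#' very large concentrations are capped so the sampler stays numerically sane
#' (the draw is then effectively the mean direction).
#'
#' @param n number of draws.
#' @param mu mean direction (rad).
#' @param kappa concentration (>= 0).
#' @return angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("`kappa` must be >= 0", call. = FALSE)
  if (kappa == 0) return(wrap_angle(stats::runif(n, -pi, pi)))
  kappa <- min(kappa, 1e6)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1L])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2L] > 0 || log(c0 / u[2L]) + 1 - c0 >= 0) break
    }
    out[i] <- sign(u[3L] - 0.5) * acos(f)
  }
  wrap_angle(out + mu)
}

#' Circular mean direction and resultant length
#'
#' The mean direction is the argument of the mean resultant vector
#' `sum(exp(i * theta)) / n` and `R` is its modulus. When the resultant is
#' numerically zero (antipodal or uniform angles) the direction is undefined
#' and returned as `NA` with `R = 0`.
#'
#' @param angles numeric vector of angles (rad), length >= 1.
#' @return list with `direction` (rad, `NA` if undefined) and `R` in `[0, 1]`.
#' @export
circular_mean <- function(angles) {
  if (length(angles) < 1L) stop("need at least one angle", call. = FALSE)
  v <- mean(exp(1i * angles))
  R <- Mod(v)
  if (R < 1e-12) return(list(direction = NA_real_, R = 0))
  list(direction = Arg(v), R = R)
}

#' Rayleigh test of circular uniformity
#'
#' Uses the standard approximation to the tail probability
#' (Zar 1999, eq. 27.4) which is accurate for n >= 10.
#'
#' @param angles numeric vector of angles (rad).
#' @return list with `R`, `z = n R^2` and `p`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  R <- circular_mean(angles)$R
  Rn <- n * R
  z <- Rn^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - Rn^2)) - (1 + 2 * n))
  list(R = R, z = z, p = min(max(p, 0), 1))
}
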