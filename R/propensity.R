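#' Characteristic-curve specification
#'
#' @param theta time constant of the vascular smooth muscle state
#'   (minutes, >= 0).
#' @param p,q nonnegative loop gains of the two delayed negative
#'   feedbacks (ANP loop; grouped AVP loops).
#' @param tau1,tau2 loop delays in minutes (> 0).
#' @return a [CharSpec-class].
#' @export
charSpec <- function(theta, p, q, tau1, tau2)
  new("CharSpec", theta = theta, p = p, q = q, tau1 = tau1, tau2 = tau2)

setMethod("show", "CharSpec", function(object) {
  cat(sprintf("CharSpec: theta = %.3g, p = %.3g, q = %.3g, tau = (%.3g, %.3g)\n",
              object@theta, object@p, object@q, object@tau1, object@tau2))
})

#' Characteristic function of the delayed double feedback
#'
#' Value of
#' \eqn{j\omega\Theta + 1 + p e^{j\tau_1\omega} + q e^{j\tau_2\omega}}
#' at pulsation `omega` (rad/min).  A zero of this function at some
#' `omega > 0` is the critical condition for the onset of sustained
#' oscillations of the linearised loop; `omega = 2*pi*f` with `f` the
#' oscillation frequency.
#'
#' @param omega nonnegative pulsation(s), rad/min (vectorised).
#' @param spec a [CharSpec-class].
#' @return complex vector of characteristic values.
#' @examples
#' sp <- charSpec(0, 0.5, 0.5, 3, 3)
#' Mod(charValue(pi / 3, sp)) < 1e-15   # root at omega = pi/tau
#' @export
charValue <- function(omega, spec) {
  if (any(omega < 0)) stop("omega must be nonnegative")
  1i * omega * spec@theta + 1 +
    spec@p * exp(1i * spec@tau1 * omega) +
    spec@q * exp(1i * spec@tau2 * omega)
}

#' Oscillation propensity from the distance to instability
#'
#' The characteristic curve traced by [charValue()] over
#' `omega in (0, omegaMax]` is scanned on a dense grid; every local
#' minimum of its modulus is refined by golden-section/parabolic search
#' and the smallest value is the distance `rho` of the curve from the
#' origin of the complex plane.  The oscillation-propensity index is
#' `J* = 1/rho`; `rho` at numerical zero (a root of the characteristic
#' equation) gives `J* = Inf`.  The larger `J*`, the closer the loop is
#' to the onset of sustained oscillations.
#'
#' @param spec a [CharSpec-class].
#' @param omegaMax upper end of the pulsation range (default
#'   `20*pi/min(tau1, tau2)`, covering ten fundamental periods of the
#'   fastest delay).
#' @param nGrid number of grid points (>= 100).
#' @param zeroTol modulus below which `rho` counts as an exact root.
#' @return a [PropensityResult-class].
#' @examples
#' jstar(oscillationPropensity(charSpec(0, 0.5, 0.5, 3, 3)))  # Inf
#' rho(oscillationPropensity(charSpec(0.5, 0, 0, 3, 3)))      # 1
#' @export
oscillationPropensity <- function(spec, omegaMax = NULL, nGrid = 1e5,
                                  zeroTol = 1e-8) {
  if (nGrid < 100) stop("nGrid too coarse to bracket a minimum")
  omegaMax <- omegaMax %||% (20 * pi / min(spec@tau1, spec@tau2))
  w <- seq(omegaMax / nGrid, omegaMax, length.out = nGrid)
  m <- Mod(charValue(w, spec))
  ## candidate brackets: all strict local minima plus both ends
  n <- length(m)
  locmin <- which(m[2:(n - 1)] <= m[1:(n - 2)] & m[2:(n - 1)] <= m[3:n]) + 1L
  cand <- unique(c(1L, locmin, n))
  best <- c(rho = Inf, omega = NA_real_)
  f <- function(x) Mod(charValue(x, spec))
  for (i in cand) {
    lo <- if (i == 1L) w[1] / 2 else w[i - 1L]
    hi <- if (i == n) w[n] else w[i + 1L]
    opt <- stats::optimize(f, c(lo, hi), tol = 1e-12)
    if (opt$objective < best[["rho"]])
      best <- c(rho = opt$objective, omega = opt$minimum)
  }
  rho <- best[["rho"]]
  new("PropensityResult", rho = rho,
      jstar = if (rho < zeroTol) Inf else 1 / rho,
      omegaStar = best[["omega"]], spec = spec)
}

#' @rdname accessors
#' @export
setMethod("rho", "PropensityResult", function(object) object@rho)

#' @rdname accessors
#' @export
setMethod("jstar", "PropensityResult", function(object) object@jstar)

#' @rdname accessors
#' @export
setMethod("omegaStar", "PropensityResult", function(object)
  object@omegaStar)

setMethod("show", "PropensityResult", function(object) {
  cat(sprintf("PropensityResult: rho = %.6g, J* = %.6g at omega = %.6g rad/min\n",
              object@rho, object@jstar, object@omegaStar))
})

#' Critical total loop gain for the onset of oscillations
#'
#' Smallest total gain `s` (split as `p = ratio*s`,
#' `q = (1-ratio)*s`) at which the characteristic equation acquires a
#' root at some pulsation `omega > 0`.  A root at gain s requires
#' \deqn{s\,D(\omega) = -(1 + j\omega\Theta), \quad
#'       D(\omega) = r\,e^{j\tau_1\omega} + (1-r)\,e^{j\tau_2\omega},}
#' i.e. \eqn{c(\omega) = -(1+j\omega\Theta)/D(\omega)} real and
#' positive; the zeros of `Im c` are bracketed on a pulsation grid,
#' refined by bisection, and the smallest positive `Re c` over the
#' crossings is the critical gain.  Because `|D| <= 1` and
#' `|1 + j omega Theta| >= 1`, the critical gain is always at least 1;
#' it equals 1 exactly when `theta = 0` and the delays are equal (root
#' at `omega = pi/tau`), and exceeds 1 otherwise — a necessary total
#' gain `p + q >= 1` for oscillation onset.
#'
#' @param theta time constant (minutes, >= 0).
#' @param tau1,tau2 delays (minutes, > 0).
#' @param ratio gain split `p/(p+q)` in `[0, 1]`.
#' @param tol absolute tolerance on the returned gain.
#' @param cap gain cap; if no crossing yields a gain below `cap` the
#'   cap is returned with `capped = TRUE`.
#' @param nGrid pulsation grid size for bracketing.
#' @return list with `gain` (the critical total gain `s*`), `omega`
#'   (the crossing pulsation) and `capped`.
#' @examples
#' criticalGain(0, 3, 3)$gain        # 1
#' criticalGain(0.5, 3, 3)$gain > 1  # TRUE
#' @export
criticalGain <- function(theta, tau1, tau2, ratio = 0.5, tol = 1e-6,
                         cap = 50, nGrid = 2e4) {
  if (tol <= 0) stop("tol must be positive")
  if (ratio < 0 || ratio > 1) stop("ratio must lie in [0, 1]")
  omegaMax <- 20 * pi / min(tau1, tau2)
  w <- seq(omegaMax / nGrid, omegaMax, length.out = nGrid)
  D <- ratio * exp(1i * tau1 * w) + (1 - ratio) * exp(1i * tau2 * w)
  valid <- Mod(D) > 1e-9
  cw <- -(1 + 1i * w * theta) / D
  im <- Im(cw)
  re <- Re(cw)
  cfun <- function(x) {
    Dx <- ratio * exp(1i * tau1 * x) + (1 - ratio) * exp(1i * tau2 * x)
    -(1 + 1i * x * theta) / Dx
  }
  best <- Inf
  bestOmega <- NA_real_
  consider <- function(s, omg) {
    if (is.finite(s) && s > 1e-9 && s < best) {
      best <<- s
      bestOmega <<- omg
    }
  }
  nW <- length(w)
  exact <- which(valid & im == 0)
  for (i in exact) consider(re[i], w[i])
  cross <- which(valid[-nW] & valid[-1L] & im[-nW] * im[-1L] < 0)
  for (i in cross) {
    rt <- stats::uniroot(function(x) Im(cfun(x)), c(w[i], w[i + 1L]),
                         tol = min(tol, 1e-9))$root
    consider(Re(cfun(rt)), rt)
  }
  if (!is.finite(best) || best > cap)
    list(gain = cap, omega = NA_real_, capped = TRUE)
  else
    list(gain = best, omega = bestOmega, capped = FALSE)
}

#' Oscillation-propensity surface over loop-delay pairs
#'
#' Evaluates `J*` on an `n x n` grid of delay pairs
#' `(tau1, tau2) in tauRange^2` for fixed time constant and gains
#' (normalised to `p + q = 1` for the canonical analysis).  The surface
#' is symmetric under delay swap when `p = q`, attains its maximum on
#' the diagonal of equal delays, and decays as the delays move apart —
#' homogeneous loop delays maximise oscillation propensity.
#'
#' @param theta time constant (minutes).
#' @param p,q loop gains.
#' @param tauRange `c(min, max)` delay range in minutes.
#' @param n grid size per axis (>= 2).
#' @param nGrid pulsation grid for each propensity evaluation.
#' @return a [PropensitySurface-class].
#' @examples
#' s <- propensitySurface(0.5, 0.5, 0.5, n = 5, nGrid = 5e3)
#' which(s@jstar == max(s@jstar), arr.ind = TRUE)  # on the diagonal
#' @export
propensitySurface <- function(theta, p, q, tauRange = c(2, 4), n = 41,
                              nGrid = 2e4) {
  if (n < 2) stop("n must be at least 2")
  tau <- seq(tauRange[1], tauRange[2], length.out = n)
  J <- matrix(NA_real_, n, n, dimnames = list(tau1 = NULL, tau2 = NULL))
  R <- J
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      pr <- oscillationPropensity(charSpec(theta, p, q, tau[i], tau[j]),
                                  nGrid = nGrid)
      J[i, j] <- pr@jstar
      R[i, j] <- pr@rho
    }
  }
  new("PropensitySurface", tau = tau, jstar = J, rhoMat = R,
      theta = theta, p = p, q = q)
}

#' @rdname accessors
#' @export
setMethod("jstar", "PropensitySurface", function(object) object@jstar)

#' @rdname accessors
#' @export
setMethod("rho", "PropensitySurface", function(object) object@rhoMat)

setMethod("show", "PropensitySurface", function(object) {
  cat(sprintf(
    "PropensitySurface: %d x %d grid over [%.3g, %.3g] min, theta = %.3g, p = %.3g, q = %.3g\n",
    length(object@tau), length(object@tau), min(object@tau),
    max(object@tau), object@theta, object@p, object@q))
  cat(sprintf("  J* range: [%.4g, %.4g]\n", min(object@jstar),
              max(object@jstar)))
})

#' Export / plot a propensity surface
#'
#' `writeSurfaceCSV` writes the long-format table with columns `tau1`,
#' `tau2`, `rho`, `J_star`; `plotSurface` draws a filled-contour map of
#' `J*` (values clipped at `clip` for display).
#'
#' @param surface a [PropensitySurface-class].
#' @param path output file.
#' @export
writeSurfaceCSV <- function(surface, path) {
  tau <- surface@tau
  grid <- expand.grid(tau1 = tau, tau2 = tau)
  out <- data.frame(tau1 = grid$tau1, tau2 = grid$tau2,
                    rho = as.vector(surface@rhoMat),
                    J_star = as.vector(surface@jstar))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param clip display ceiling for `J*`.
#' @param ... passed to [graphics::filled.contour()].
#' @rdname writeSurfaceCSV
#' @export
plotSurface <- function(surface, clip = 1e3, ...) {
  J <- pmin(surface@jstar, clip)
  graphics::filled.contour(
    surface@tau, surface@tau, J,
    xlab = expression(tau[1] ~ "(min)"), ylab = expression(tau[2] ~ "(min)"),
    main = sprintf("J* (theta = %.2g, p = %.2g, q = %.2g)",
                   surface@theta, surface@p, surface@q), ...)
  invisible(surface)
}
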