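# SRTM dynamic-PET simulator: frame schedule, reference curve, forward model,
# frame integration and the frame-weighted Gaussian noise model.

#' Build the 54-frame acquisition schedule
#'
#' Fixed dynamic framing used throughout: 6 x 10 s, 8 x 15 s, 6 x 30 s,
#' 8 x 60 s, 8 x 120 s and 18 x 300 s, i.e. N = 54 frames covering a total of
#' T = 7200 s (120 min).
#'
#' @return a [FrameSchedule-class]
#' @examples
#' sched <- buildFrameSchedule()
#' nFrames(sched)        # 54
#' totalDuration(sched)  # 7200
#' @export
buildFrameSchedule <- function() {
  dur <- rep(c(10, 15, 30, 60, 120, 300), c(6, 8, 6, 8, 8, 18))
  new("FrameSchedule", frameEnd = cumsum(dur), frameDuration = dur)
}

#' Default reference-curve shape parameters
#'
#' Feng-style tracer input shape for the reference region (cerebellum grey):
#' a gamma-variate bolus term `A*t*exp(-t/tau)` plus a slow-washout
#' bi-exponential term `B*(exp(-t/tau2) - exp(-t/tau1))`. The amplitude pair
#' (A, B) sets the absolute activity scale of the simulation, a free
#' calibration of the framework (activity units are arbitrary); the defaults
#' put the curve peak near t = 140 s and give frame-integral signal-to-noise
#' comparable to regional TACs from clinical dynamic acquisitions under the
#' default noise scale.
#'
#' @return named list with elements A, tau, B, tau1, tau2 (seconds and
#'   arbitrary activity units)
#' @export
referenceCurveDefaults <- function() {
  list(A = 0.03, tau = 120, B = 0.6, tau1 = 120, tau2 = 2400)
}

#' Make the deterministic reference-region curve
#'
#' @param gridStep grid spacing in seconds (default 1 s)
#' @param pars shape parameters, see [referenceCurveDefaults()]
#' @param totalTime end of the grid in seconds (default the 7200 s scan)
#' @return a [ReferenceCurve-class] on the grid `seq(0, totalTime, gridStep)`
#' @export
makeReferenceCurve <- function(gridStep = 1,
                               pars = referenceCurveDefaults(),
                               totalTime = 7200) {
  if (gridStep <= 0) stop("gridStep must be positive")
  pars <- utils::modifyList(referenceCurveDefaults(), pars)
  t <- seq(0, totalTime, by = gridStep)
  cr <- pars$A * t * exp(-t / pars$tau) +
    pars$B * (exp(-t / pars$tau2) - exp(-t / pars$tau1))
  new("ReferenceCurve", time = t, activity = cr, pars = pars)
}

#' SRTM forward model: continuous target-region curve
#'
#' Computes the analytic SRTM solution
#' \deqn{C_T(t) = R_1 C_R(t) + (k_2 - R_1 k_2 / DVR)\,
#'   [C_R \otimes e^{-(k_2/DVR) t}](t)}
#' on the reference curve's grid. The causal convolution is evaluated by a
#' trapezoidal recursion that is exact for the exponential kernel between
#' grid nodes up to quadrature order. `k2` is given in min^-1 and converted
#' to s^-1 internally; the time grid is in seconds.
#'
#' @param params named numeric (DVR, k2, R1); k2 in min^-1
#' @param ref a [ReferenceCurve-class]
#' @return numeric vector, \eqn{C_T} on `curveTime(ref)`
#' @export
srtmTargetCurve <- function(params, ref) {
  p <- checkParams(params)
  t <- ref@time
  cr <- ref@activity
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9)) stop("reference grid must be regular")
  h <- dt[1]
  k2s <- p["k2"] / 60                      # min^-1 -> s^-1
  lambda <- k2s / p["DVR"]
  a <- exp(-lambda * h)
  # I_i = a I_{i-1} + h/2 (cr_i + a cr_{i-1}) (trapezoid on the convolution)
  u <- (h / 2) * (cr[-1] + a * cr[-length(cr)])
  conv <- c(0, stats::filter(u, a, method = "recursive"))
  w <- k2s - p["R1"] * k2s / p["DVR"]
  unname(p["R1"] * cr + w * conv)
}

#' @noRd
checkParams <- function(params) {
  p <- unlist(params)
  if (is.null(names(p)) || !all(c("DVR", "k2", "R1") %in% names(p)))
    p <- stats::setNames(p[1:3], c("DVR", "k2", "R1"))
  p <- p[c("DVR", "k2", "R1")]
  if (!all(is.finite(p))) stop("kinetic parameters must be finite")
  if (p["DVR"] <= 0) stop("DVR must be positive (the model divides by DVR)")
  if (p["k2"] < 0) stop("k2 must be non-negative")
  if (p["R1"] <= 0) stop("R1 must be positive")
  p
}

#' Integrate a continuous curve over the acquisition frames
#'
#' \eqn{y_n = \int_{t_{n-1}}^{t_n} C_T(t)\,dt} by trapezoidal quadrature on
#' the curve's grid. Frame boundaries must lie on the grid.
#'
#' @param curve numeric curve values on `time`, or a [ReferenceCurve-class]
#' @param schedule a [FrameSchedule-class]
#' @param time time grid (s); defaults to the curve's own grid when `curve`
#'   is a `ReferenceCurve`
#' @return a clean [Tac-class] (sigma = NA)
#' @export
integrateFrames <- function(curve, schedule, time = NULL) {
  if (is(curve, "ReferenceCurve")) {
    time <- curve@time
    curve <- curve@activity
  }
  if (is.null(time)) stop("a time grid is required")
  h <- diff(time)
  if (any(h <= 0)) stop("time grid must be increasing")
  if (max(h) > min(frameDurations(schedule)))
    stop("grid is coarser than the shortest frame")
  if (max(time) < totalDuration(schedule) - 1e-9)
    stop("grid does not cover the full scan")
  idx <- match(round(frameEnds(schedule), 9), round(time, 9))
  if (anyNA(idx)) stop("frame boundaries must lie on the time grid")
  ct <- cumTrapz(time, curve)
  y <- diff(c(0, ct[idx]))
  new("Tac", values = y, schedule = schedule, sigma = NA_real_)
}

#' Draw a TAC noise scale
#'
#' The per-TAC noise scale follows \eqn{\sigma \sim 10^{-4}\,\Gamma(1, 1)}
#' (an exponential with mean 1e-4).
#'
#' @param n number of draws
#' @param sigmaScale multiplier, default 1e-4
#' @return numeric vector of positive noise scales
#' @export
sampleNoiseSigma <- function(n = 1, sigmaScale = 1e-4) {
  sigmaScale * stats::rgamma(n, shape = 1, scale = 1)
}

#' Add frame-weighted Gaussian noise to a clean TAC
#'
#' \eqn{y_n^{noisy} = y_n + \epsilon_n}, with independent
#' \eqn{\epsilon_n \sim N(0, (\sigma (\Delta t_n / T)^{q})^2)} and q = 1/2 by
#' default, so the noise standard deviation grows with the square root of the
#' frame's share of the total scan time, as for counting statistics on frame
#' integrals. The exponent `q` is exposed for sensitivity analyses.
#'
#' @param tac a clean [Tac-class]
#' @param sigma positive noise scale (see [sampleNoiseSigma()])
#' @param exponent q, default 0.5
#' @return a noisy [Tac-class] carrying the realized `sigma`
#' @export
addNoise <- function(tac, sigma, exponent = 0.5) {
  stopifnot(is(tac, "Tac"), sigma > 0)
  sched <- tac@schedule
  sd <- sigma * (frameDurations(sched) / totalDuration(sched))^exponent
  new("Tac", values = tac@values + stats::rnorm(nFrames(sched), 0, sd),
      schedule = sched, sigma = sigma)
}

#' Per-frame noise standard deviations for a given noise scale
#'
#' @inheritParams addNoise
#' @param schedule a [FrameSchedule-class]
#' @return numeric vector of per-frame standard deviations
#' @export
noiseSd <- function(sigma, schedule, exponent = 0.5) {
  sigma * (frameDurations(schedule) / totalDuration(schedule))^exponent
}

#' Simulate one noisy TAC from kinetic parameters
#'
#' Convenience wrapper: SRTM forward curve, frame integration, then noise.
#' With `sigma = NULL` a fresh noise scale is drawn; with `sigma = 0` the
#' clean TAC is returned.
#'
#' @inheritParams srtmTargetCurve
#' @param schedule a [FrameSchedule-class]
#' @param sigma noise scale; NULL draws one from [sampleNoiseSigma()]
#' @param sigmaScale passed to [sampleNoiseSigma()]
#' @param exponent noise exponent, see [addNoise()]
#' @return a [Tac-class]
#' @export
simulateTac <- function(params, ref, schedule, sigma = NULL,
                        sigmaScale = 1e-4, exponent = 0.5) {
  clean <- integrateFrames(srtmTargetCurve(params, ref), schedule,
                           time = ref@time)
  if (is.null(sigma)) sigma <- sampleNoiseSigma(1, sigmaScale)
  if (sigma == 0) return(clean)
  addNoise(clean, sigma, exponent)
}
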