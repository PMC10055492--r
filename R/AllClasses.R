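#' @import methods
NULL

#' Acquisition frame schedule
#'
#' Holds the dynamic-PET framing: frame end times, frame durations and the
#' total scan duration, all in seconds. The default schedule produced by
#' [buildFrameSchedule()] has 54 frames covering 7200 s.
#'
#' @slot frameEnd numeric, strictly increasing frame end times (s)
#' @slot frameDuration numeric, per-frame durations (s)
#' @export
setClass("FrameSchedule",
  representation(frameEnd = "numeric", frameDuration = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@frameEnd) != length(object@frameDuration))
      msg <- c(msg, "frameEnd and frameDuration lengths differ")
    if (any(object@frameDuration <= 0))
      msg <- c(msg, "frame durations must be positive")
    starts <- object@frameEnd - object@frameDuration
    if (any(abs(starts - c(0, object@frameEnd[-length(object@frameEnd)])) > 1e-9))
      msg <- c(msg, "frames must tile [0, T] contiguously")
    if (is.null(msg)) TRUE else msg
  })

#' Reference-region input curve
#'
#' A deterministic reference-region activity curve \eqn{C_R(t)} sampled on a
#' dense regular grid, starting at zero activity at injection with a single
#' early peak followed by monotone washout.
#'
#' @slot time numeric time grid (s), starting at 0
#' @slot activity numeric activity concentrations (arbitrary units)
#' @slot pars list of shape parameters used to build the curve
#' @export
setClass("ReferenceCurve",
  representation(time = "numeric", activity = "numeric", pars = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@time) != length(object@activity))
      msg <- c(msg, "time/activity lengths differ")
    if (object@time[1] != 0) msg <- c(msg, "grid must start at t = 0")
    if (abs(object@activity[1]) > 1e-12) msg <- c(msg, "C_R(0) must be 0")
    if (any(object@activity < -1e-12)) msg <- c(msg, "C_R must be non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' A single time-activity curve (TAC)
#'
#' Frame-integrated activity \eqn{y_n = \int_{t_{n-1}}^{t_n} C_T(t)\,dt}
#' for one region, optionally with frame-weighted Gaussian noise added.
#'
#' @slot values numeric, one value per frame
#' @slot schedule the [FrameSchedule-class] the values refer to
#' @slot sigma realized noise scale (NA for clean TACs)
#' @export
setClass("Tac",
  representation(values = "numeric", schedule = "FrameSchedule",
                 sigma = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@values) != length(object@schedule@frameEnd))
      msg <- c(msg, "TAC length must equal the number of frames")
    if (length(object@sigma) != 1) msg <- c(msg, "sigma must be length 1")
    if (is.null(msg)) TRUE else msg
  })

#' Gaussian prior specification for the kinetic parameters
#'
#' Independent Gaussian priors on DVR, k2 (min^-1) and R1, truncated at
#' sampling time to the physically valid region DVR > 0, k2 >= 0, R1 > 0.
#' Four settings are supported: setting 1 is the base prior; settings 2-4
#' scale its means, variances or both by 20%.
#'
#' @slot location named numeric (DVR, k2, R1) prior means
#' @slot scale named numeric prior standard deviations
#' @slot setting integer in 1..4
#' @export
setClass("PriorSpec",
  representation(location = "numeric", scale = "numeric", setting = "integer"),
  validity = function(object) {
    msg <- NULL
    nm <- c("DVR", "k2", "R1")
    if (!identical(names(object@location), nm) ||
        !identical(names(object@scale), nm))
      msg <- c(msg, "location/scale must be named DVR, k2, R1")
    if (any(object@scale <= 0)) msg <- c(msg, "scales must be positive")
    if (!(object@setting %in% 1:4)) msg <- c(msg, "setting must be in 1..4")
    if (is.null(msg)) TRUE else msg
  })

#' Posterior samples of the kinetic parameters
#'
#' A draws-by-3 matrix of (DVR, k2, R1) samples representing a posterior
#' p(x | y), produced either by the Metropolis-Hastings reference sampler or
#' by a trained CVAE.
#'
#' @slot draws numeric matrix with columns DVR, k2, R1
#' @slot source character, "mcmc" or "cvae-<variant>"
#' @slot acceptanceRate post-burn-in MH acceptance rate (NA for CVAE)
#' @slot provenance list of seeds/config recorded at sampling time
#' @export
setClass("PosteriorSamples",
  representation(draws = "matrix", source = "character",
                 acceptanceRate = "numeric", provenance = "list"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@draws) < 1) msg <- c(msg, "need at least one draw")
    if (!identical(colnames(object@draws), c("DVR", "k2", "R1")))
      msg <- c(msg, "draws must have columns DVR, k2, R1")
    if (any(!is.finite(object@draws))) msg <- c(msg, "draws must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' A trained (or initialized) conditional VAE posterior estimator
#'
#' @slot variant one of "dual_encoder", "dual_decoder", "vanilla"
#' @slot nets list of network parameter stacks (phi, theta, and, depending on
#'   the variant, phiPrime or thetaPrime)
#' @slot standardization list with x/y means and standard deviations computed
#'   from the training set
#' @slot config training configuration actually used
#' @slot log per-epoch mean loss components (data.frame)
#' @slot trained logical
#' @export
setClass("CvaeModel",
  representation(variant = "character", nets = "list",
                 standardization = "list", config = "list",
                 log = "data.frame", trained = "logical"),
  validity = function(object) {
    if (!object@variant %in% c("dual_encoder", "dual_decoder", "vanilla"))
      return("unknown variant")
    TRUE
  })
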