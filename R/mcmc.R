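# Random-walk Metropolis-Hastings reference sampler for p(x | y) under the
# SRTM forward model, plus proposal tuning and the segment-mean convergence
# diagnostic.

#' Unnormalized log posterior of kinetic parameters given a noisy TAC
#'
#' Gaussian log likelihood of the measured frame integrals under the SRTM
#' forward model with known per-frame noise standard deviations
#' \eqn{\sigma (\Delta t_n/T)^{q}}, plus the truncated Gaussian log prior.
#' Returns -Inf (not an error) outside the truncated support.
#'
#' @param x named numeric (DVR, k2, R1), k2 in min^-1
#' @param y a noisy [Tac-class] (or numeric vector of frame values)
#' @param sigma the noise scale used when y was generated
#' @param prior a [PriorSpec-class]
#' @param ref reference curve (default [makeReferenceCurve()])
#' @param schedule frame schedule; defaults to the TAC's own schedule
#' @param exponent noise exponent q (default 0.5)
#' @return scalar log density (up to an additive constant)
#' @export
logPosterior <- function(x, y, sigma, prior, ref = makeReferenceCurve(),
                         schedule = NULL, exponent = 0.5) {
  stopifnot(sigma > 0)
  if (is(y, "Tac")) {
    if (is.null(schedule)) schedule <- tacSchedule(y)
    y <- tacValues(y)
  }
  if (is.null(schedule)) schedule <- buildFrameSchedule()
  p <- checkSupport(x)
  if (is.null(p)) return(-Inf)
  clean <- tacValues(integrateFrames(srtmTargetCurve(p, ref), schedule,
                                     time = ref@time))
  sd <- noiseSd(sigma, schedule, exponent)
  sum(stats::dnorm(y, clean, sd, log = TRUE)) + logPrior(p, prior)
}

#' Generic random-walk Metropolis-Hastings chain
#'
#' Low-level engine: symmetric Gaussian proposals with diagonal covariance,
#' acceptance probability min(1, exp(delta log target)). Optional
#' Robbins-Monro adaptation of a global proposal scale factor (and of the
#' per-coordinate scale profile from the running chain spread) during the
#' first `adaptUntil` iterations only, so retained draws come from a fixed
#' kernel.
#'
#' @param logTarget function(x) -> scalar unnormalized log density
#' @param init numeric start point (must have finite log target)
#' @param scales positive per-coordinate proposal standard deviations
#' @param nIter total iterations
#' @param adaptUntil adapt during iterations 1..adaptUntil (0 = no
#'   adaptation)
#' @param targetAcceptance mid-point of the acceptance band (default 0.3)
#' @param seed optional integer seed
#' @return list with `chain` (nIter x d matrix), `acceptanceRate` (over the
#'   post-adaptation part), `scales` (final per-coordinate scales)
#' @export
metropolisChain <- function(logTarget, init, scales, nIter,
                            adaptUntil = 0, targetAcceptance = 0.3,
                            seed = NULL) {
  stopifnot(all(scales > 0), nIter >= 1, adaptUntil < nIter)
  withSeed(seed, {
    d <- length(init)
    x <- as.numeric(init)
    lp <- logTarget(x)
    if (!is.finite(lp)) stop("initialization point has zero target density")
    chain <- matrix(NA_real_, nIter, d)
    sc <- as.numeric(scales)
    fac <- 1
    accWin <- 0L; winLen <- 100L
    accPost <- 0L; nPost <- 0L
    for (i in seq_len(nIter)) {
      prop <- x + stats::rnorm(d) * (fac * sc)
      lpProp <- logTarget(prop)
      if (is.finite(lpProp) && log(stats::runif(1)) < lpProp - lp) {
        x <- prop; lp <- lpProp
        accWin <- accWin + 1L
        if (i > adaptUntil) accPost <- accPost + 1L
      }
      if (i > adaptUntil) nPost <- nPost + 1L
      chain[i, ] <- x
      if (adaptUntil > 0 && i <= adaptUntil && i %% winLen == 0L) {
        rate <- accWin / winLen
        fac <- fac * exp(rate - targetAcceptance)
        accWin <- 0L
        # refresh the per-coordinate profile from the recent chain spread,
        # early enough that the global factor can re-control the acceptance
        # rate before the kernel freezes
        marks <- floor(adaptUntil * c(0.3, 0.6)) %/% winLen * winLen
        if (i %in% pmax(marks, winLen)) {
          sds <- apply(chain[max(1, i - 3000):i, , drop = FALSE], 2,
                       stats::sd)
          if (all(is.finite(sds)) && all(sds > 0)) {
            sc <- sds * 2.4 / sqrt(d) / fac
          }
        }
      }
    }
    list(chain = chain, acceptanceRate = if (nPost > 0) accPost / nPost else NA,
         scales = fac * sc)
  })
}

#' Default MCMC configuration
#'
#' 60,000 random-walk iterations with 15,000 burn-in steps (45,000 retained
#' draws); adaptation confined to the burn-in.
#'
#' @param nIterations total iterations
#' @param nBurnIn burn-in steps
#' @param proposalScales initial per-parameter proposal standard deviations
#'   (DVR, k2 in min^-1, R1)
#' @param targetAcceptance acceptance mid-point used during adaptation
#' @return list configuration
#' @export
mcmcConfig <- function(nIterations = 60000, nBurnIn = 15000,
                       proposalScales = c(DVR = 0.01, k2 = 3e-5, R1 = 0.01),
                       targetAcceptance = 0.3) {
  stopifnot(nBurnIn < nIterations, all(proposalScales > 0))
  list(nIterations = nIterations, nBurnIn = nBurnIn,
       proposalScales = proposalScales,
       targetAcceptance = targetAcceptance)
}

#' Sample the reference posterior with random-walk Metropolis-Hastings
#'
#' Runs the MH chain on [logPosterior()], starting from the prior location
#' vector, adapting the proposal during burn-in only, and discarding the
#' burn-in. At the defaults this retains 45,000 draws.
#'
#' By default the sampler receives the noise scale realized when the TAC
#' was generated (the amortized estimators instead marginalize over it
#' implicitly). With `inferSigma = TRUE`, `sigma` is treated as unknown:
#' it joins the chain state with its 1e-4 * Gamma(1, 1) prior, and the
#' returned draws carry a fourth `sigma` column — a sensitivity-analysis
#' mode.
#'
#' @param y a noisy [Tac-class]
#' @param sigma noise scale realized when `y` was generated (used as the
#'   chain's starting value when `inferSigma = TRUE`)
#' @param prior a [PriorSpec-class]
#' @param config see [mcmcConfig()]
#' @param ref reference curve (default [makeReferenceCurve()])
#' @param exponent noise exponent (default 0.5)
#' @param inferSigma add sigma to the sampled state (default FALSE)
#' @param sigmaScale scale of the sigma prior (default 1e-4)
#' @param seed optional integer seed
#' @return a [PosteriorSamples-class]; the full (pre-burn-in) chain is kept
#'   in `provenance$chain` for convergence diagnostics
#' @export
runMH <- function(y, sigma, prior, config = mcmcConfig(),
                  ref = makeReferenceCurve(), exponent = 0.5,
                  inferSigma = FALSE, sigmaScale = 1e-4, seed = NULL) {
  stopifnot(is(y, "Tac"), sigma > 0)
  schedule <- tacSchedule(y)
  lt <- makeLogTarget(y, sigma, prior, ref, schedule, exponent,
                      inferSigma = inferSigma, sigmaScale = sigmaScale)
  init <- priorLocation(prior)
  scales <- config$proposalScales
  if (inferSigma) {
    init <- c(init, sigma = sigma)
    scales <- c(scales, sigma = sigmaScale / 4)
  }
  res <- metropolisChain(lt, init, scales,
                         nIter = config$nIterations,
                         adaptUntil = config$nBurnIn,
                         targetAcceptance = config$targetAcceptance,
                         seed = seed)
  cols <- c("DVR", "k2", "R1", if (inferSigma) "sigma")
  kept <- res$chain[(config$nBurnIn + 1):config$nIterations, , drop = FALSE]
  colnames(kept) <- cols
  colnames(res$chain) <- cols
  samples <- new("PosteriorSamples",
                 draws = kept[, c("DVR", "k2", "R1"), drop = FALSE],
                 source = "mcmc", acceptanceRate = res$acceptanceRate,
                 provenance = list(seed = if (is.null(seed)) NA else seed,
                                   nIterations = config$nIterations,
                                   nBurnIn = config$nBurnIn,
                                   sigma = sigma,
                                   inferSigma = inferSigma,
                                   setting = priorSetting(prior),
                                   scales = res$scales, chain = res$chain))
  if (inferSigma) samples@provenance$sigmaDraws <- kept[, "sigma"]
  samples
}

# Fast closure over precomputed quantities for repeated likelihood
# evaluations inside the chain.
#' @noRd
makeLogTarget <- function(y, sigma, prior, ref, schedule, exponent,
                          inferSigma = FALSE, sigmaScale = 1e-4) {
  yv <- tacValues(y)
  t <- ref@time
  cr <- ref@activity
  h <- t[2] - t[1]
  n <- length(cr)
  idx <- match(round(frameEnds(schedule), 9), round(t, 9))
  if (anyNA(idx)) stop("frame boundaries must lie on the reference grid")
  share <- (frameDurations(schedule) / totalDuration(schedule))^exponent
  sd0 <- sigma * share
  iv0 <- 1 / (2 * sd0^2)
  loc <- prior@location; sc <- prior@scale
  crHead <- cr[-n]; crTail <- cr[-1]
  function(x) {
    dvr <- x[1]; k2 <- x[2]; r1 <- x[3]
    if (!is.finite(dvr) || dvr <= 0 || k2 < 0 || r1 <= 0) return(-Inf)
    k2s <- k2 / 60
    a <- exp(-k2s / dvr * h)
    u <- (h / 2) * (crTail + a * crHead)
    conv <- c(0, stats::filter(u, a, method = "recursive"))
    ct <- r1 * cr + (k2s - r1 * k2s / dvr) * conv
    cum <- c(0, cumsum((h / 2) * (ct[-n] + ct[-1])))
    yn <- diff(c(0, cum[idx]))
    lpx <- -0.5 * sum(((x[1:3] - loc) / sc)^2)
    if (!inferSigma) return(-sum((yv - yn)^2 * iv0) + lpx)
    s <- x[4]
    if (!is.finite(s) || s <= 0) return(-Inf)
    sdn <- s * share
    sum(stats::dnorm(yv, yn, sdn, log = TRUE)) + lpx - s / sigmaScale
  }
}

#' Tune the proposal scales with a pilot chain
#'
#' Runs a short fully-adaptive pilot chain and returns the per-parameter
#' proposal standard deviations it settles on, together with the acceptance
#' rate achieved over the last third of the pilot. Warns (and returns the
#' best found scales) if the acceptance rate is outside the target band.
#'
#' The pilot first runs a fully adaptive chain from the prior location (this
#' phase also travels towards the posterior mode), then repeats short
#' re-adaptation rounds from the chain's end state until the frozen-kernel
#' acceptance lands in the band or `maxRounds` is exhausted.
#'
#' @inheritParams runMH
#' @param pilotLength pilot iterations (>= 1000)
#' @param band target acceptance band (default c(0.2, 0.5))
#' @param maxRounds re-adaptation rounds after the initial pilot
#' @return list with `scales` and `acceptance`
#' @export
tuneProposal <- function(y, sigma, prior, pilotLength = 10000,
                         band = c(0.2, 0.5), maxRounds = 6,
                         ref = makeReferenceCurve(), exponent = 0.5,
                         seed = NULL) {
  stopifnot(pilotLength >= 1000)
  lt <- makeLogTarget(y, sigma, prior, ref, tacSchedule(y), exponent)
  withSeed(seed, {
    res <- metropolisChain(lt, priorLocation(prior),
                           mcmcConfig()$proposalScales, nIter = pilotLength,
                           adaptUntil = floor(pilotLength * 0.85),
                           targetAcceptance = mean(band))
    round <- 0
    while ((res$acceptanceRate < band[1] || res$acceptanceRate > band[2]) &&
           round < maxRounds) {
      state <- res$chain[nrow(res$chain), ]
      res <- metropolisChain(lt, state, res$scales, nIter = 4000,
                             adaptUntil = 3000,
                             targetAcceptance = mean(band))
      round <- round + 1
    }
    if (res$acceptanceRate < band[1] || res$acceptanceRate > band[2])
      warning(sprintf("pilot acceptance %.2f outside [%.2f, %.2f]",
                      res$acceptanceRate, band[1], band[2]))
    list(scales = res$scales, acceptance = res$acceptanceRate)
  })
}

#' Segment-mean convergence diagnostic
#'
#' For each parameter trace, compares the mean of the first 10% of the
#' post-burn-in samples with the mean of the last 50%; the chain is flagged
#' as converged when the absolute gap is below the threshold (default
#' 0.001) for every parameter.
#'
#' @param chain a [PosteriorSamples-class] from [runMH()] (its full chain and
#'   burn-in are used), or a draws matrix
#' @param burnIn burn-in rows to drop when `chain` is a matrix (default 0)
#' @param threshold pass threshold on the absolute gap (default 0.001)
#' @return data.frame with columns `parameter`, `gap`, `pass`
#' @export
convergenceCheck <- function(chain, burnIn = 0, threshold = 0.001) {
  if (is(chain, "PosteriorSamples")) {
    full <- chain@provenance$chain
    if (!is.null(full)) {
      burnIn <- chain@provenance$nBurnIn
      chain <- full
    } else {
      chain <- posteriorDraws(chain)
      burnIn <- 0
    }
  }
  chain <- as.matrix(chain)
  if (burnIn >= nrow(chain)) stop("burnIn must be smaller than chain length")
  post <- chain[(burnIn + 1):nrow(chain), , drop = FALSE]
  n <- nrow(post)
  n1 <- max(1, floor(0.1 * n))
  n2 <- max(1, floor(0.5 * n))
  gap <- abs(colMeans(post[seq_len(n1), , drop = FALSE]) -
               colMeans(post[(n - n2 + 1):n, , drop = FALSE]))
  data.frame(parameter = colnames(post) %||% paste0("x", seq_along(gap)),
             gap = as.numeric(gap), pass = as.numeric(gap) < threshold,
             row.names = NULL)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
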