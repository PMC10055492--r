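# Metropolis-Hastings engine, SRTM posterior, proposal tuning and the
# convergence diagnostic.

test_that("log posterior matches an independent density sum and truncates", {
  ref <- refCurve(); s <- schedule54()
  prior <- makePrior(1)
  y <- defaultTestTac()
  x <- c(DVR = 1.05, k2 = 0.0007, R1 = 0.72)
  # independent re-implementation: per-frame normal log densities + prior
  clean <- tacValues(integrateFrames(srtmTargetCurve(x, ref), s,
                                     curveTime(ref)))
  sd <- 1e-4 * sqrt(frameDurations(s) / totalDuration(s))
  oracle <- sum(dnorm(tacValues(y), clean, sd, log = TRUE)) +
    sum(dnorm(x, priorLocation(prior), priorScale(prior), log = TRUE))
  expect_equal(logPosterior(x, y, 1e-4, prior, ref), oracle)
  expect_identical(logPosterior(c(DVR = -0.1, k2 = 0.1, R1 = 1), y, 1e-4,
                                prior, ref), -Inf)
})

test_that("noiseless likelihood peaks at the generating parameters", {
  ref <- refCurve(); s <- schedule54()
  prior <- makePrior(1)
  clean <- integrateFrames(srtmTargetCurve(defaultParams, ref), s,
                           curveTime(ref))
  at <- function(x) logPosterior(x, clean, 1e-4, prior, ref)
  l0 <- at(defaultParams)
  for (shift in list(c(0.05, 0, 0), c(-0.05, 0, 0), c(0, 1e-4, 0),
                     c(0, 0, 0.01), c(0, 0, -0.01)))
    expect_lt(at(defaultParams + shift), l0)
})

test_that("the chain recovers a standard normal target", {
  res <- metropolisChain(function(x) -0.5 * x^2, init = 0, scales = 2.4,
                         nIter = 60000, adaptUntil = 0, seed = 4)
  draws <- res$chain[15001:60000, 1]
  expect_lt(abs(mean(draws)), 0.02)
  expect_lt(abs(sd(draws) - 1), 0.02)
})

test_that("the chain recovers a conjugate linear-Gaussian posterior", {
  # x ~ N(0, I2), y = A x + e, e ~ N(0, 0.3^2 I3): Gaussian posterior in
  # closed form
  A <- matrix(c(1, 0.5, -0.3, 0.2, 1.1, 0.7), 3, 2)
  xTrue <- c(0.4, -0.2)
  y <- withr_seed(5, as.numeric(A %*% xTrue + rnorm(3, 0, 0.3)))
  Prec <- diag(2) + crossprod(A) / 0.3^2
  Sig <- solve(Prec)
  mu <- as.numeric(Sig %*% (crossprod(A, y) / 0.3^2))
  lt <- function(x) -0.5 * sum(x^2) - sum((y - A %*% x)^2) / (2 * 0.3^2)
  res <- metropolisChain(lt, init = c(0, 0), scales = c(0.3, 0.3),
                         nIter = 60000, adaptUntil = 10000, seed = 6)
  draws <- res$chain[15001:60000, ]
  # Monte-Carlo s.e. inflated by the autocorrelation time
  iact <- function(v) {
    ac <- acf(v, lag.max = 200, plot = FALSE)$acf[-1]
    1 + 2 * sum(ac[ac > 0.05])
  }
  for (j in 1:2) {
    se <- sd(draws[, j]) * sqrt(iact(draws[, j]) / nrow(draws))
    expect_lt(abs(mean(draws[, j]) - mu[j]), 3 * se)
    expect_lt(abs(sd(draws[, j]) - sqrt(Sig[j, j])) / sqrt(Sig[j, j]), 0.05)
  }
})

test_that("proposal scale extremes drive the acceptance rate to 0 or 1", {
  lt <- function(x) -0.5 * sum(x^2)
  hot <- metropolisChain(lt, 0, scales = 1e6, nIter = 3000, seed = 7)
  cold <- metropolisChain(lt, 0, scales = 1e-6, nIter = 3000, seed = 7)
  expect_lt(hot$acceptanceRate, 0.01)
  expect_gt(cold$acceptanceRate, 0.99)
})

test_that("pilot tuning lands in the target acceptance band", {
  prior <- makePrior(1)
  for (i in 1:3) {
    x <- selectTestSet(prior, M = 1, seed = 20 + i)
    sig <- withr_seed(30 + i, sampleNoiseSigma(1))
    y <- withr_seed(40 + i, simulateTac(x[1, ], refCurve(), schedule54(),
                                        sigma = sig))
    tp <- tuneProposal(y, sig, prior, pilotLength = 4000, seed = i)
    expect_gte(tp$acceptance, 0.2)
    expect_lte(tp$acceptance, 0.5)
  }
})

test_that("the SRTM chain keeps its support, length and reproducibility", {
  prior <- makePrior(1)
  y <- defaultTestTac()
  cfg <- mcmcConfig(4000, 1000)
  p1 <- runMH(y, 1e-4, prior, cfg, refCurve(), seed = 9)
  p2 <- runMH(y, 1e-4, prior, cfg, refCurve(), seed = 9)
  d <- posteriorDraws(p1)
  expect_equal(nrow(d), 3000)
  expect_true(all(d[, "DVR"] > 0 & d[, "k2"] >= 0 & d[, "R1"] > 0))
  expect_identical(d, posteriorDraws(p2))
  expect_equal(sampleSource(p1), "mcmc")
})

test_that("posterior means recover the truth for nearly noiseless TACs", {
  # The likelihood concentrates at the generating parameters as the noise
  # vanishes; R1 (identified by the early frames) is recovered to well
  # under 2%. DVR and k2 lie along a near-degenerate likelihood ridge that
  # the diagonal random-walk kernel traverses slowly, so for them the check
  # is strong contraction towards the truth from the prior-location start
  # plus a percent-level error bound, not exact recovery.
  prior <- makePrior(1)
  init <- priorLocation(prior)
  xs <- selectTestSet(prior, M = 6, seed = 55)
  d0 <- matrix(NA_real_, 6, 3); d1 <- matrix(NA_real_, 6, 3)
  for (i in 1:6) {
    y <- withr_seed(60 + i, simulateTac(xs[i, ], refCurve(), schedule54(),
                                        sigma = 1e-6))
    post <- runMH(y, 1e-6, prior, mcmcConfig(60000, 15000), refCurve(),
                  seed = 70 + i)
    mu <- colMeans(posteriorDraws(post))
    expect_lt(abs(mu["R1"] - xs[i, "R1"]) / xs[i, "R1"], 0.02)
    expect_true(all(abs(mu - xs[i, ]) / xs[i, ] < 0.10))
    d0[i, ] <- abs(init - xs[i, ]); d1[i, ] <- abs(mu - xs[i, ])
  }
  contraction <- colMeans(d1) / colMeans(d0)
  expect_true(all(contraction < 0.35))
})

test_that("the sigma-inference mode samples a positive noise scale", {
  prior <- makePrior(1)
  y <- defaultTestTac()
  post <- runMH(y, 1e-4, prior, mcmcConfig(4000, 1000), refCurve(),
                inferSigma = TRUE, seed = 14)
  sig <- post@provenance$sigmaDraws
  expect_equal(length(sig), 3000)
  expect_true(all(sig > 0))
  expect_equal(ncol(posteriorDraws(post)), 3)   # kinetic draws unchanged
})

test_that("segment-mean convergence gaps follow their definition", {
  const <- matrix(2, 1000, 2, dimnames = list(NULL, c("a", "b")))
  cc <- convergenceCheck(const)
  expect_equal(cc$gap, c(0, 0))
  expect_true(all(cc$pass))
  ramp <- matrix(seq(0, 1, length.out = 10000), ncol = 1)
  cc2 <- convergenceCheck(ramp)
  expect_equal(cc2$gap, 0.70, tolerance = 1e-3)
  expect_false(cc2$pass)
  expect_error(convergenceCheck(ramp, burnIn = 10000), "burnIn")
})

test_that("long-run histogram matches a discretized 1D target", {
  # detailed-balance sanity on a bimodal mixture target
  lt <- function(x) log(0.3 * dnorm(x, -1.5, 0.5) + 0.7 * dnorm(x, 1, 0.8))
  res <- metropolisChain(lt, 0, scales = 1.5, nIter = 80000, seed = 13)
  draws <- res$chain[20001:80000, 1]
  brk <- seq(-4, 4, length.out = 21)
  obs <- tabulate(findInterval(pmin(pmax(draws, -3.99), 3.99), brk),
                  nbins = 20)
  pr <- diff(0.3 * pnorm(brk, -1.5, 0.5) + 0.7 * pnorm(brk, 1, 0.8))
  pr <- pr / sum(pr)
  # effective sample size after autocorrelation
  ac <- acf(draws, lag.max = 500, plot = FALSE)$acf[-1]
  neff <- length(draws) / (1 + 2 * sum(ac[ac > 0.05]))
  chi2 <- sum((obs / length(draws) - pr)^2 / pr) * neff
  expect_lt(chi2, qchisq(0.99, df = 19))
})
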