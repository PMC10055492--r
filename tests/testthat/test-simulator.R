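# Frame schedule, reference curve, SRTM forward model, frame integration
# and the noise model.

test_that("frame schedule tiles the two-hour scan in 54 frames", {
  s <- schedule54()
  expect_equal(nFrames(s), 54)
  expect_equal(totalDuration(s), 7200)
  expect_equal(frameDurations(s)[1], 10)
  expect_equal(frameDurations(s)[54], 300)
  expect_true(all(diff(frameEnds(s)) > 0))
  expect_equal(frameStarts(s)[1], 0)
})

test_that("reference curve starts at zero, peaks early, then washes out", {
  ref <- refCurve()
  cr <- curveActivity(ref)
  t <- curveTime(ref)
  expect_identical(cr[1], 0)
  expect_true(all(cr >= 0))
  pk <- which.max(cr)
  expect_lt(t[pk], 600)          # peak within the first 10 minutes
  expect_true(all(diff(cr[pk:length(cr)]) <= 0))
  expect_identical(cr, curveActivity(makeReferenceCurve()))  # deterministic
  expect_error(makeReferenceCurve(gridStep = 0), "positive")
})

test_that("SRTM degenerate cases collapse to the reference curve", {
  ref <- refCurve()
  # DVR = 1, R1 = 1: the convolution weight vanishes for any k2
  expect_equal(srtmTargetCurve(c(DVR = 1, k2 = 0.3, R1 = 1), ref),
               curveActivity(ref))
  # k2 = 0: pure scaling by R1
  expect_equal(srtmTargetCurve(c(DVR = 2, k2 = 0, R1 = 0.6), ref),
               0.6 * curveActivity(ref))
  expect_error(srtmTargetCurve(c(DVR = 0, k2 = 0.1, R1 = 1), ref), "DVR")
})

test_that("SRTM convolution solution matches ODE integration", {
  skip_if_not_installed("deSolve")
  ref <- refCurve()
  pars <- ref@pars
  # analytic derivative of the reference-curve expression (independent of
  # the package's convolution path)
  dCR <- function(t) {
    pars$A * exp(-t / pars$tau) * (1 - t / pars$tau) +
      pars$B * (-exp(-t / pars$tau2) / pars$tau2 +
                  exp(-t / pars$tau1) / pars$tau1)
  }
  crFun <- approxfun(curveTime(ref), curveActivity(ref), rule = 2)
  for (x in list(c(DVR = 1.0, k2 = 0.0006, R1 = 0.74),
                 c(DVR = 2.5, k2 = 0.02, R1 = 1.1),
                 c(DVR = 0.6, k2 = 0.005, R1 = 0.4))) {
    rhs <- function(t, y, p) {
      list(x[["R1"]] * dCR(t) + (x[["k2"]] / 60) * crFun(t) -
             (x[["k2"]] / 60) / x[["DVR"]] * y)
    }
    ode <- deSolve::lsoda(y = 0, times = curveTime(ref), func = rhs,
                          parms = NULL, rtol = 1e-9, atol = 1e-12)
    ct <- srtmTargetCurve(x, ref)
    expect_lt(max(abs(ct - ode[, 2])) / max(abs(ode[, 2])), 1e-3)
  }
})

test_that("frame integration is exact for constants and stable under grid refinement", {
  s <- schedule54()
  t <- seq(0, 7200, 1)
  const <- integrateFrames(rep(3.5, length(t)), s, t)
  expect_equal(tacValues(const), 3.5 * frameDurations(s))
  expect_equal(sum(tacValues(const)), 3.5 * totalDuration(s))
  # 10x finer grid as quadrature oracle on the same smooth curve
  f <- function(t) 0.03 * t * exp(-t / 120) + 0.6 * (exp(-t / 2400) -
                                                       exp(-t / 120))
  t1 <- seq(0, 7200, 1); t10 <- seq(0, 7200, 0.1)
  y1 <- tacValues(integrateFrames(f(t1), s, t1))
  y10 <- tacValues(integrateFrames(f(t10), s, t10))
  # composite trapezoid at the default 1 s grid: below the 0.1% quadrature
  # tolerance (measured ~1.5e-4, driven by the curvature in the first frame)
  expect_lt(max(abs(y1 - y10) / abs(y10)), 1e-3)
  expect_error(integrateFrames(rep(1, 100), s, seq(0, 7200, length.out = 100)),
               "coarser")
})

test_that("noise scale prior has the exponential moments", {
  draws <- withr_seed(1, sampleNoiseSigma(1e6))
  expect_true(all(draws > 0))
  # sigma ~ 1e-4 * Gamma(1,1): mean 1e-4, variance 1e-8
  expect_lt(abs(mean(draws) - 1e-4), 3 * 1e-4 / sqrt(1e6))
  seVar <- stats::sd((draws - mean(draws))^2) / sqrt(1e6)
  expect_lt(abs(stats::var(draws) - 1e-8), 3 * seVar)
})

test_that("frame noise follows the square-root frame-share law", {
  s <- schedule54()
  sd <- noiseSd(2e-4, s)
  expect_equal(sd, 2e-4 * sqrt(frameDurations(s) / 7200))
  # equal durations, equal noise; sd non-decreasing with duration
  expect_true(all(diff(sd[order(frameDurations(s))]) >= 0))
  # empirical per-frame standard deviation over replicates
  clean <- integrateFrames(srtmTargetCurve(defaultParams, refCurve()), s,
                           curveTime(refCurve()))
  reps <- withr_seed(2, replicate(2e4, tacValues(addNoise(clean, 2e-4)))) -
    tacValues(clean)
  emp <- apply(reps, 1, stats::sd)
  se <- sd / sqrt(2 * (2e4 - 1))
  expect_true(all(abs(emp - sd) < 4 * se))
  # degenerate noise limit
  tiny <- addNoise(clean, 1e-30)
  expect_equal(tacValues(tiny), tacValues(clean), tolerance = 1e-12)
})

test_that("dataset generation is replayable bit-exactly", {
  prior <- makePrior(1)
  d1 <- makeDataset(prior, 8, seed = 99)
  d2 <- makeDataset(prior, 8, seed = 99)
  expect_identical(SummarizedExperiment::assay(d1, "tac"),
                   SummarizedExperiment::assay(d2, "tac"))
  expect_identical(as.data.frame(SummarizedExperiment::colData(d1)),
                   as.data.frame(SummarizedExperiment::colData(d2)))
  f1 <- tempfile(); f2 <- tempfile()
  writeTacTable(d1, f1); writeTacTable(d2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
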