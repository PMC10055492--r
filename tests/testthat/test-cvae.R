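# CVAE losses, gradients, training and posterior sampling.

test_that("reparameterization is exact in its degenerate and moment limits", {
  mu <- c(0.3, -1, 2); lv <- c(0, log(4), log(0.25))
  expect_equal(reparameterize(mu, lv, c(0, 0, 0)), mu)
  expect_equal(reparameterize(mu, rep(-1e10, 3), c(3, -2, 1)), mu)
  expect_error(reparameterize(mu, lv, c(0, 0)), "length")
  draws <- withr_seed(1, t(replicate(1e5, reparameterize(mu, lv, rnorm(3)))))
  sd <- exp(0.5 * lv)
  expect_true(all(abs(colMeans(draws) - mu) < 3 * sd / sqrt(1e5)))
  expect_true(all(abs(apply(draws, 2, sd) - sd) < 3 * sd / sqrt(1e5)))
})

test_that("diagonal-Gaussian KL terms hit their analytic identities", {
  mu <- c(0.5, -0.2); lv <- c(0.3, -0.4)
  expect_equal(klPair(mu, lv, mu, lv), 0)
  expect_equal(klPair(1, 0, 0, 0), 0.5)            # pure mean shift
  expect_equal(klToStandard(0, 0), 0)
  expect_equal(klToStandard(2, 0), 2.0)
  expect_equal(klToStandard(mu, lv), klPair(mu, lv, c(0, 0), c(0, 0)))
  # non-negativity over random inputs
  for (i in 1:200) {
    a <- rnorm(5); la <- rnorm(5); b <- rnorm(5); lb <- rnorm(5)
    expect_gte(klPair(a, la, b, lb), 0)
    expect_gte(klToStandard(a, la), 0)
  }
  expect_error(klPair(NA, 0, 0, 0), "finite")
})

test_that("reconstruction losses are half squared distances", {
  expect_equal(reconstructionLoss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(reconstructionLoss(c(1, 0, 0), c(0, 0, 0)), 0.5)
  x <- rnorm(3); xh <- rnorm(3)
  expect_equal(reconstructionLoss(x, xh), 0.5 * sum((x - xh)^2))
  y <- rnorm(54); yh <- rnorm(54)
  expect_equal(measurementLoss(y, yh), 0.5 * sum((y - yh)^2))
  expect_equal(measurementLoss(y, y), 0)
  expect_error(reconstructionLoss(c(1, 2), c(1, 2, 3)), "mismatch")
})

# small nets + batch used by several blocks below
tinySetup <- function(variant, seed = 42) {
  withr_seed(seed, {
    spec <- cvaeSpec(variant, K = 3, nParams = 3, nFrames = 6)
    spec$encWidths <- c(7, 5); spec$decWidths <- c(6, 3)
    spec$auxDecWidths <- c(4, 6)
    # data drawn before the nets so that phi/theta (initialized first, from
    # the same stream) and the batch coincide across variants
    xs <- matrix(rnorm(12), 4, 3); ys <- matrix(rnorm(24), 4, 6)
    eps <- matrix(rnorm(12), 4, 3)
    nets <- srtmcvae:::initCvaeNets(spec)
    list(spec = spec, nets = nets, xs = xs, ys = ys, eps = eps)
  })
}

test_that("analytic gradients match finite differences for all variants", {
  for (variant in c("vanilla", "dual_decoder", "dual_encoder")) {
    s <- tinySetup(variant)
    fw <- srtmcvae:::cvaeForward(variant, s$nets, s$xs, s$ys, s$eps, 0.7, 1.3)
    gr <- srtmcvae:::cvaeBackward(variant, s$nets, fw, s$xs, s$ys, s$eps,
                                  0.7, 1.3)
    f <- function(nets)
      srtmcvae:::cvaeForward(variant, nets, s$xs, s$ys, s$eps, 0.7, 1.3)$total
    h <- 1e-6
    checkEntry <- function(get, set, g, k) {
      w <- get(s$nets)
      up <- s$nets; dn <- s$nets
      wp <- w; wp[k] <- wp[k] + h
      wm <- w; wm[k] <- wm[k] - h
      num <- (f(set(up, wp)) - f(set(dn, wm))) / (2 * h)
      expect_equal(g[k], num, tolerance = 1e-4)
    }
    withr_seed(7, {
      for (nm in names(gr)) {
        if (!is.null(s$nets[[nm]]$trunk)) {
          for (l in seq_along(s$nets[[nm]]$trunk$layers))
            checkEntry(function(n) n[[nm]]$trunk$layers[[l]]$W,
                       function(n, w) { n[[nm]]$trunk$layers[[l]]$W <- w; n },
                       gr[[nm]]$trunk[[l]]$W,
                       sample(length(gr[[nm]]$trunk[[l]]$W), 1))
          checkEntry(function(n) n[[nm]]$muHead$W,
                     function(n, w) { n[[nm]]$muHead$W <- w; n },
                     gr[[nm]]$muHead$W, sample(length(gr[[nm]]$muHead$W), 1))
          checkEntry(function(n) n[[nm]]$lvHead$b,
                     function(n, w) { n[[nm]]$lvHead$b <- w; n },
                     gr[[nm]]$lvHead$b, sample(length(gr[[nm]]$lvHead$b), 1))
        } else {
          for (l in seq_along(s$nets[[nm]]$layers))
            checkEntry(function(n) n[[nm]]$layers[[l]]$W,
                       function(n, w) { n[[nm]]$layers[[l]]$W <- w; n },
                       gr[[nm]][[l]]$W, sample(length(gr[[nm]][[l]]$W), 1))
        }
      }
    })
  }
})

test_that("the vanilla loss is the dual variants' structural restriction", {
  # same seed => identical phi and theta weights across variants
  sV <- tinySetup("vanilla"); sD <- tinySetup("dual_decoder")
  sE <- tinySetup("dual_encoder")
  fwV <- srtmcvae:::cvaeForward("vanilla", sV$nets, sV$xs, sV$ys, sV$eps,
                                1, 1)
  # dual-decoder with lambda = 0 has the same total loss
  fwD <- srtmcvae:::cvaeForward("dual_decoder", sD$nets, sD$xs, sD$ys,
                                sD$eps, 1, 0)
  expect_equal(fwV$recon + fwV$kl, fwD$recon + fwD$kl)
  expect_equal(fwD$total, fwV$total - 0)   # lambda*meas contributes nothing
  # dual-encoder with phi' pinned to the standard normal reduces to vanilla
  netsE <- sE$nets
  for (h in c("muHead", "lvHead")) {
    netsE$phiPrime[[h]]$W <- netsE$phiPrime[[h]]$W * 0
    netsE$phiPrime[[h]]$b <- netsE$phiPrime[[h]]$b * 0
  }
  fwE <- srtmcvae:::cvaeForward("dual_encoder", netsE, sE$xs, sE$ys, sE$eps,
                                1, 1)
  expect_equal(fwE$kl, fwV$kl)
  expect_equal(fwE$total, fwV$total)
  # beta = lambda = 0 leaves the reconstruction term only
  fw0 <- srtmcvae:::cvaeForward("dual_decoder", sD$nets, sD$xs, sD$ys,
                                sD$eps, 0, 0)
  expect_equal(fw0$total, fw0$recon)
})

test_that("training descends, is reproducible, and aborts on empty data", {
  # 1024 pairs / 15 epochs: enough steps for the slow auxiliary-decoder
  # term of the dual-decoder loss to come down too
  xy <- deskSubset(1024)
  for (variant in c("vanilla", "dual_decoder", "dual_encoder")) {
    cfg <- trainConfig(epochs = 15, seed = 5)
    m1 <- trainCvae(xy, variant, cfg)
    expect_lt(m1@log$total[15], m1@log$total[1])
    expect_true(all(is.finite(m1@log$val)))    # diagnostic holdout loss
    m2 <- trainCvae(xy, variant, cfg)
    expect_identical(m1@nets, m2@nets)
  }
  expect_error(trainCvae(list(x = matrix(0, 0, 3), y = matrix(0, 0, 54)),
                         "vanilla"), "empty")
})

test_that("posterior sampling uses the inference path deterministically", {
  xy <- deskSubset(256)
  y <- defaultTestTac()
  for (variant in c("vanilla", "dual_encoder")) {
    m <- trainCvae(xy, variant, trainConfig(epochs = 3, seed = 2))
    ps <- samplePosterior(m, y, nDraws = 1234, seed = 3)
    expect_equal(nrow(posteriorDraws(ps)), 1234)
    expect_equal(sampleSource(ps), paste0("cvae-", variant))
    expect_identical(posteriorDraws(ps),
                     posteriorDraws(samplePosterior(m, y, 1234, seed = 3)))
    expect_true(all(is.finite(posteriorDraws(ps))))
  }
  mUn <- new("CvaeModel", variant = "vanilla", nets = list(),
             standardization = list(), config = list(),
             log = data.frame(), trained = FALSE)
  expect_error(samplePosterior(mUn, y, 10), "untrained")
})

test_that("total loss evaluates finitely and respects weight degeneracy", {
  xy <- deskSubset(128)
  m <- trainCvae(xy, "dual_decoder", trainConfig(epochs = 2, seed = 9))
  eps <- matrix(0, 16, 10)
  l <- totalLoss(m, xy$x[1:16, ], xy$y[1:16, ], eps = eps)
  expect_true(is.finite(l$total))
  expect_equal(l$total, l$recon + l$kl + l$meas)
})
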