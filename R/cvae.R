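# The three conditional-VAE posterior estimators: losses, architectures,
# training loop and variant-specific posterior sampling.
#
# All three variants share an encoder phi([x, y] -> z) and a decoder
# theta([y, z] -> x~). The dual-encoder variant adds an auxiliary encoder
# phi'(y -> z~) whose Gaussian is the KL target of phi; the dual-decoder
# variant adds an auxiliary decoder theta'(z -> y~) and pulls the latent
# towards the standard normal; the vanilla variant keeps only the standard
# normal pull. Losses are computed in standardized (z-scored) space.

CVAE_VARIANTS <- c("dual_encoder", "dual_decoder", "vanilla")

#' Architecture specification for a CVAE variant
#'
#' Defaults: latent dimension K = 10; encoder trunks of widths
#' 128/100/50/20 with rectified-linear units and two linear K-node heads
#' (mean and log-variance); decoder 128/100/50 hidden plus a linear 3-node
#' output; auxiliary decoder 16/16/32 hidden plus a linear 54-node output.
#'
#' @param variant one of `"dual_encoder"`, `"dual_decoder"`, `"vanilla"`
#' @param K latent dimension
#' @param nParams dimension of x (3 kinetic parameters)
#' @param nFrames dimension of y (54 frames)
#' @return a list describing the networks the variant needs
#' @export
cvaeSpec <- function(variant = CVAE_VARIANTS, K = 10, nParams = 3,
                     nFrames = 54) {
  variant <- match.arg(variant)
  list(variant = variant, K = K, nParams = nParams, nFrames = nFrames,
       encWidths = c(128, 100, 50, 20),
       decWidths = c(128, 100, 50, nParams),
       auxDecWidths = c(16, 16, 32, nFrames))
}

#' Training configuration
#'
#' Defaults follow the study setup: learning rate 1e-4, plain SGD with
#' momentum 0.9, 200 epochs, loss weights beta = lambda = 1. The batch size
#' (64) is a framework choice.
#'
#' @param epochs training epochs
#' @param lr learning rate
#' @param momentum SGD momentum
#' @param batchSize mini-batch size
#' @param beta weight of the KL term
#' @param lambda weight of the measurement-reconstruction term
#'   (dual-decoder only)
#' @param seed integer seed for init, shuffling and latent draws
#' @return list configuration
#' @export
trainConfig <- function(epochs = 200, lr = 1e-4, momentum = 0.9,
                        batchSize = 64, beta = 1, lambda = 1, seed = 1) {
  stopifnot(beta > 0 || beta == 0, lambda >= 0, epochs >= 1, batchSize >= 1)
  list(epochs = epochs, lr = lr, momentum = momentum, batchSize = batchSize,
       beta = beta, lambda = lambda, seed = seed)
}

# ---- loss primitives (operate on plain vectors, standardized space) ------

#' Reparameterization trick
#'
#' z = mu + sigma * eps with sigma = exp(log-variance / 2).
#'
#' @param mu latent mean vector
#' @param logvar latent log-variance vector
#' @param eps standard-normal perturbation, same length
#' @return latent draw z
#' @export
reparameterize <- function(mu, logvar, eps) {
  if (length(mu) != length(logvar) || length(mu) != length(eps))
    stop("mu, logvar and eps must have equal length")
  mu + exp(0.5 * logvar) * eps
}

#' KL divergence between two diagonal Gaussians
#'
#' \deqn{KL(N(\mu, \sigma^2) \| N(\mu', \sigma'^2)) = -\tfrac12 \sum_k
#'  [1 + \log(\sigma_k^2/\sigma_k'^2) - \sigma_k^2/\sigma_k'^2 -
#'   (\mu_k - \mu_k')^2/\sigma_k'^2]}
#' This is the latent alignment term of the dual-encoder loss.
#'
#' @param muA,logvarA mean / log-variance of the first Gaussian
#' @param muB,logvarB mean / log-variance of the second Gaussian
#' @return scalar KL divergence (nats), non-negative
#' @export
klPair <- function(muA, logvarA, muB, logvarB) {
  if (!all(is.finite(c(muA, logvarA, muB, logvarB))))
    stop("non-finite latent parameters")
  if (length(muA) != length(muB)) stop("latent dimensions differ")
  -0.5 * sum(1 + logvarA - logvarB - exp(logvarA - logvarB) -
               (muA - muB)^2 / exp(logvarB))
}

#' KL divergence from a diagonal Gaussian to the standard normal
#'
#' \deqn{-\tfrac12 \sum_k (1 + \log\sigma_k^2 - \sigma_k^2 - \mu_k^2)}
#' The latent regularization term of the dual-decoder and vanilla losses.
#'
#' @param mu,logvar mean / log-variance vectors
#' @return scalar KL divergence (nats), non-negative
#' @export
klToStandard <- function(mu, logvar) {
  if (!all(is.finite(c(mu, logvar)))) stop("non-finite latent parameters")
  -0.5 * sum(1 + logvar - exp(logvar) - mu^2)
}

#' Parameter-reconstruction loss
#'
#' Half squared Euclidean distance between the (standardized) kinetic
#' parameters and their reconstruction.
#'
#' @param x,xhat length-3 vectors
#' @return scalar loss
#' @export
reconstructionLoss <- function(x, xhat) {
  if (length(x) != length(xhat)) stop("length mismatch")
  0.5 * sum((x - xhat)^2)
}

#' Measurement-reconstruction loss
#'
#' Half squared Euclidean distance between the (standardized) TAC and the
#' auxiliary decoder's reconstruction (dual-decoder variant).
#'
#' @param y,yhat length-N vectors
#' @return scalar loss
#' @export
measurementLoss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  0.5 * sum((y - yhat)^2)
}

# ---- model construction --------------------------------------------------

#' @noRd
initCvaeNets <- function(spec) {
  nx <- spec$nParams; ny <- spec$nFrames; K <- spec$K
  nets <- list(
    phi = initEncoder(nx + ny, spec$encWidths, K),
    theta = initStack(ny + K, spec$decWidths,
                      nAct = length(spec$decWidths) - 1))
  if (spec$variant == "dual_encoder")
    nets$phiPrime <- initEncoder(ny, spec$encWidths, K)
  if (spec$variant == "dual_decoder")
    nets$thetaPrime <- initStack(K, spec$auxDecWidths,
                                 nAct = length(spec$auxDecWidths) - 1)
  nets
}

# Forward pass over a standardized batch; returns caches and per-batch mean
# loss components. eps is a (batch x K) matrix of standard normals.
#' @noRd
cvaeForward <- function(variant, nets, xs, ys, eps, beta, lambda) {
  B <- nrow(xs)
  enc <- encoderForward(nets$phi, cbind(xs, ys))
  sigma <- exp(0.5 * enc$lv)
  z <- enc$mu + sigma * eps
  dec <- stackForward(nets$theta, cbind(ys, z))
  recon <- 0.5 * sum((xs - dec$out)^2) / B
  out <- list(enc = enc, sigma = sigma, z = z, dec = dec, recon = recon,
              meas = 0)
  if (variant == "dual_encoder") {
    encP <- encoderForward(nets$phiPrime, ys)
    out$encP <- encP
    out$kl <- -0.5 * sum(1 + enc$lv - encP$lv - exp(enc$lv - encP$lv) -
                           (enc$mu - encP$mu)^2 / exp(encP$lv)) / B
  } else {
    out$kl <- -0.5 * sum(1 + enc$lv - exp(enc$lv) - enc$mu^2) / B
  }
  if (variant == "dual_decoder") {
    decP <- stackForward(nets$thetaPrime, z)
    out$decP <- decP
    out$meas <- 0.5 * sum((ys - decP$out)^2) / B
  }
  out$total <- out$recon + beta * out$kl + lambda * out$meas
  out
}

# Backward pass matching cvaeForward; returns gradients per network.
#' @noRd
cvaeBackward <- function(variant, nets, fw, xs, ys, eps, beta, lambda) {
  B <- nrow(xs)
  K <- ncol(fw$z)
  dXhat <- (fw$dec$out - xs) / B
  tb <- stackBackward(nets$theta, fw$dec, dXhat)
  dZ <- tb$dX[, ncol(ys) + seq_len(K), drop = FALSE]
  grads <- list(theta = tb$grads)
  if (variant == "dual_decoder") {
    dYhat <- lambda * (fw$decP$out - ys) / B
    tbP <- stackBackward(nets$thetaPrime, fw$decP, dYhat)
    grads$thetaPrime <- tbP$grads
    dZ <- dZ + tbP$dX
  }
  dMu <- dZ
  dLv <- dZ * (0.5 * fw$sigma * eps)
  if (variant == "dual_encoder") {
    s2r <- exp(fw$enc$lv - fw$encP$lv)       # sigma^2 / sigma'^2
    dmu <- (fw$enc$mu - fw$encP$mu) / exp(fw$encP$lv)
    dMu <- dMu + beta * dmu / B
    dLv <- dLv + beta * 0.5 * (s2r - 1) / B
    dMuP <- -beta * dmu / B
    dLvP <- beta * 0.5 * (1 - s2r - (fw$enc$mu - fw$encP$mu)^2 /
                            exp(fw$encP$lv)) / B
    grads$phiPrime <- encoderBackward(nets$phiPrime, fw$encP, dMuP, dLvP)
    grads$phiPrime$dX <- NULL
  } else {
    dMu <- dMu + beta * fw$enc$mu / B
    dLv <- dLv + beta * 0.5 * (exp(fw$enc$lv) - 1) / B
  }
  grads$phi <- encoderBackward(nets$phi, fw$enc, dMu, dLv)
  grads$phi$dX <- NULL
  grads
}

#' Total training loss of a CVAE on a batch
#'
#' Evaluates the variant's loss (batch mean) on standardized inputs:
#' reconstruction + beta * KL (+ lambda * measurement reconstruction for the
#' dual-decoder). With beta = lambda = 0 the total reduces to the
#' reconstruction term alone. Supplying `eps` makes the evaluation
#' deterministic.
#'
#' @param model a [CvaeModel-class]
#' @param x matrix (batch x 3) of kinetic parameters, native units
#' @param y matrix (batch x 54) of TAC values, native units
#' @param eps optional (batch x K) standard-normal matrix
#' @param standardized set TRUE if x and y are already standardized
#' @return list with components `total`, `recon`, `kl`, `meas`
#' @export
totalLoss <- function(model, x, y, eps = NULL, standardized = FALSE) {
  stopifnot(is(model, "CvaeModel"))
  x <- rbind(x); y <- rbind(y)
  if (!standardized) {
    st <- model@standardization
    x <- sweep(sweep(x, 2, st$xMean), 2, st$xSd, "/")
    y <- sweep(sweep(y, 2, st$yMean), 2, st$ySd, "/")
  }
  K <- model@config$spec$K
  if (is.null(eps)) eps <- matrix(stats::rnorm(nrow(x) * K), nrow(x), K)
  fw <- cvaeForward(model@variant, model@nets, x, y, eps,
                    model@config$train$beta, model@config$train$lambda)
  fw[c("total", "recon", "kl", "meas")]
}

# ---- training ------------------------------------------------------------

#' Train a CVAE posterior estimator
#'
#' Mini-batch SGD with momentum on the variant's loss, computed in z-scored
#' space (per-parameter for x, per-frame for y) with statistics taken from
#' the training set only. Per-epoch mean loss components are logged. Fixed
#' seeds make the whole run reproducible.
#'
#' A `valFraction` holdout (default 10%) is carved off before training and
#' its loss logged per epoch purely as a diagnostic — training always runs
#' the configured number of epochs, never early-stops, and the holdout
#' never influences the standardization statistics or the gradients.
#'
#' @param dataset a `SummarizedExperiment` from [makeDataset()], or a list
#'   with elements `x` (n x 3) and `y` (n x 54)
#' @param variant one of `"dual_encoder"`, `"dual_decoder"`, `"vanilla"`
#' @param config see [trainConfig()]
#' @param spec see [cvaeSpec()]; its variant is overridden by `variant`
#' @param valFraction diagnostic holdout fraction (0 disables it)
#' @return a trained [CvaeModel-class]
#' @export
trainCvae <- function(dataset, variant = CVAE_VARIANTS,
                      config = trainConfig(), spec = NULL,
                      valFraction = 0.1) {
  variant <- match.arg(variant)
  if (is(dataset, "SummarizedExperiment")) dataset <- datasetXY(dataset)
  x <- as.matrix(dataset$x); y <- as.matrix(dataset$y)
  if (nrow(x) == 0) stop("empty dataset")
  if (nrow(x) != nrow(y)) stop("x and y must have the same number of rows")
  if (is.null(spec)) spec <- cvaeSpec(variant, nFrames = ncol(y),
                                      nParams = ncol(x))
  spec$variant <- variant
  withSeed(config$seed, {
    nVal <- floor(nrow(x) * valFraction)
    if (nVal >= 1 && nrow(x) - nVal >= config$batchSize) {
      holdout <- sample.int(nrow(x), nVal)
      xv <- x[holdout, , drop = FALSE]; yv <- y[holdout, , drop = FALSE]
      x <- x[-holdout, , drop = FALSE]; y <- y[-holdout, , drop = FALSE]
    } else {
      xv <- NULL
    }
    st <- list(xMean = colMeans(x), xSd = apply(x, 2, stats::sd),
               yMean = colMeans(y), ySd = apply(y, 2, stats::sd))
    st$xSd[st$xSd == 0] <- 1
    st$ySd[st$ySd == 0] <- 1
    xs <- sweep(sweep(x, 2, st$xMean), 2, st$xSd, "/")
    ys <- sweep(sweep(y, 2, st$yMean), 2, st$ySd, "/")
    if (!is.null(xv)) {
      xvs <- sweep(sweep(xv, 2, st$xMean), 2, st$xSd, "/")
      yvs <- sweep(sweep(yv, 2, st$yMean), 2, st$ySd, "/")
    }
    n <- nrow(xs); K <- spec$K
    nets <- initCvaeNets(spec)
    vel <- lapply(nets, function(net)
      if (!is.null(net$trunk)) zeroGradEncoder(net) else zeroGradStack(net))
    log <- data.frame()
    for (epoch in seq_len(config$epochs)) {
      perm <- sample.int(n)
      tot <- c(total = 0, recon = 0, kl = 0, meas = 0)
      nb <- 0
      for (start in seq(1, n, by = config$batchSize)) {
        ii <- perm[start:min(start + config$batchSize - 1, n)]
        eps <- matrix(stats::rnorm(length(ii) * K), length(ii), K)
        fw <- cvaeForward(variant, nets, xs[ii, , drop = FALSE],
                          ys[ii, , drop = FALSE], eps,
                          config$beta, config$lambda)
        if (!is.finite(fw$total))
          stop(sprintf("non-finite loss at epoch %d (total=%g)", epoch,
                       fw$total))
        gr <- cvaeBackward(variant, nets, fw, xs[ii, , drop = FALSE],
                           ys[ii, , drop = FALSE], eps,
                           config$beta, config$lambda)
        for (nm in names(gr)) {
          u <- if (!is.null(nets[[nm]]$trunk))
            updateEncoder(nets[[nm]], gr[[nm]], vel[[nm]],
                          config$lr, config$momentum)
          else updateStack(nets[[nm]], gr[[nm]], vel[[nm]],
                           config$lr, config$momentum)
          nets[[nm]] <- u$net
          vel[[nm]] <- u$v
        }
        tot <- tot + c(fw$total, fw$recon, fw$kl, fw$meas)
        nb <- nb + 1
      }
      valTotal <- if (!is.null(xv)) {
        epsV <- matrix(stats::rnorm(nrow(xvs) * K), nrow(xvs), K)
        cvaeForward(variant, nets, xvs, yvs, epsV, config$beta,
                    config$lambda)$total
      } else NA_real_
      log <- rbind(log, data.frame(epoch = epoch, total = tot[1] / nb,
                                   recon = tot[2] / nb, kl = tot[3] / nb,
                                   meas = tot[4] / nb, val = valTotal))
    }
    new("CvaeModel", variant = variant, nets = nets, standardization = st,
        config = list(spec = spec, train = config), log = log,
        trained = TRUE)
  })
}

# ---- posterior sampling --------------------------------------------------

#' Sample an amortized posterior from a trained CVAE
#'
#' Inference uses only the variant's inference path: the dual-encoder draws
#' the latent from the auxiliary encoder phi'(y*); the dual-decoder and
#' vanilla variants draw z ~ N(0, I). The decoder theta maps (y*, z) to
#' parameter draws, which are de-standardized back to native units.
#'
#' @param model a trained [CvaeModel-class]
#' @param y a [Tac-class] or numeric vector of 54 frame values (native units)
#' @param nDraws number of posterior draws (study default 45,000)
#' @param seed optional integer seed
#' @return a [PosteriorSamples-class]
#' @export
samplePosterior <- function(model, y, nDraws = 45000, seed = NULL) {
  stopifnot(is(model, "CvaeModel"), nDraws >= 1)
  if (!model@trained) stop("model is untrained")
  if (is(y, "Tac")) y <- tacValues(y)
  st <- model@standardization
  ys <- (y - st$yMean) / st$ySd
  K <- model@config$spec$K
  withSeed(seed, {
    eps <- matrix(stats::rnorm(nDraws * K), nDraws, K)
    z <- if (model@variant == "dual_encoder") {
      encP <- encoderForward(model@nets$phiPrime, rbind(ys))
      sweep(sweep(eps, 2, as.numeric(exp(0.5 * encP$lv)), "*"), 2,
            as.numeric(encP$mu), "+")
    } else eps
    Y <- matrix(ys, nDraws, length(ys), byrow = TRUE)
    xhat <- stackForward(model@nets$theta, cbind(Y, z))$out
    draws <- sweep(sweep(xhat, 2, st$xSd, "*"), 2, st$xMean, "+")
    colnames(draws) <- c("DVR", "k2", "R1")
    new("PosteriorSamples", draws = draws,
        source = paste0("cvae-", model@variant),
        acceptanceRate = NA_real_,
        provenance = list(seed = if (is.null(seed)) NA else seed,
                          nDraws = nDraws))
  })
}
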