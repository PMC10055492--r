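# Experiment drivers: the Tables-1-3 comparison and the hyperparameter,
# training-size and data-shift sweeps. All of them evaluate CVAE posteriors
# against MCMC reference posteriors on a shared evaluation context so the
# expensive MCMC runs are computed once per test TAC.

#' Build an evaluation context (test TACs + MCMC reference posteriors)
#'
#' Draws the alpha-filtered test set, simulates one noisy TAC per test
#' triple (fresh noise scale each), runs the MH reference sampler on every
#' TAC and fits Gaussians to the MCMC marginals. Every random stream is
#' derived from `rootSeed` by name.
#'
#' @param prior a [PriorSpec-class]
#' @param M number of test cases
#' @param mcmc MCMC configuration, see [mcmcConfig()]
#' @param rootSeed integer root seed
#' @param alpha test-set filter half-width (default 0.26)
#' @param ref reference curve
#' @param schedule frame schedule
#' @param nKeep MCMC draws kept per case for KL estimation (thinned
#'   uniformly if the chain retains more); default keeps all
#' @param xTest optional explicit matrix of test triples (bypasses the
#'   alpha filter; used by the data-shift sweep)
#' @return list with test parameters, TACs, noise scales, MCMC draws and
#'   Gaussian fits
#' @export
makeEvalContext <- function(prior, M, mcmc = mcmcConfig(), rootSeed = 1,
                            alpha = 0.26, ref = makeReferenceCurve(),
                            schedule = buildFrameSchedule(), nKeep = NULL,
                            xTest = NULL) {
  if (is.null(xTest))
    xTest <- selectTestSet(prior, alpha = alpha, M = M,
                           seed = seedStream(rootSeed, "test-x"))
  M <- nrow(xTest)
  sigmas <- withSeed(seedStream(rootSeed, "test-sigma"),
                     sampleNoiseSigma(M))
  tacs <- vector("list", M)
  mcmcDraws <- vector("list", M)
  fits <- vector("list", M)
  for (i in seq_len(M)) {
    tacs[[i]] <- withSeed(seedStream(rootSeed, paste0("test-tac-", i)),
                          simulateTac(xTest[i, ], ref, schedule,
                                      sigma = sigmas[i]))
    post <- runMH(tacs[[i]], sigmas[i], prior, mcmc, ref,
                  seed = seedStream(rootSeed, paste0("mcmc-", i)))
    d <- posteriorDraws(post)
    if (!is.null(nKeep) && nrow(d) > nKeep)
      d <- d[round(seq(1, nrow(d), length.out = nKeep)), , drop = FALSE]
    mcmcDraws[[i]] <- d
    fits[[i]] <- cbind(case = i, fitPosteriorGaussians(d))
  }
  list(prior = prior, xTest = xTest, sigmas = sigmas, tacs = tacs,
       mcmcDraws = mcmcDraws, mcmcFits = do.call(rbind, fits),
       ref = ref, schedule = schedule, rootSeed = rootSeed)
}

# Evaluate one trained model on every context case; returns per-case fits
# and per-case per-parameter KL values.
#' @noRd
evalModelOnContext <- function(model, ctx, nDraws, seedTag = "infer") {
  M <- length(ctx$tacs)
  fits <- vector("list", M)
  kls <- matrix(NA_real_, M, 3, dimnames = list(NULL, c("DVR", "k2", "R1")))
  for (i in seq_len(M)) {
    ps <- samplePosterior(model, ctx$tacs[[i]], nDraws,
                          seed = seedStream(ctx$rootSeed,
                                            paste0(seedTag, "-", i)))
    d <- posteriorDraws(ps)
    fits[[i]] <- cbind(case = i, fitPosteriorGaussians(d))
    kls[i, ] <- klMetric(ctx$mcmcDraws[[i]], d)
  }
  list(fits = do.call(rbind, fits), kl = kls)
}

#' Run the full CVAE-versus-MCMC comparison for one prior setting
#'
#' Trains each requested variant (for each training seed) on a fresh
#' simulated dataset, evaluates all trained models against the MCMC
#' reference posteriors of the alpha-filtered test set, and reports
#' per-parameter averaged relative mean/width differences (percent) and
#' averaged KL divergences, in the shape of the study's summary tables.
#'
#' @param setting prior setting 1..4
#' @param variants CVAE variants to include
#' @param M test-set size
#' @param trainN training pairs
#' @param epochs training epochs
#' @param seeds training seeds (one trained model per variant per seed)
#' @param mcmc MCMC configuration
#' @param nDraws posterior draws per CVAE evaluation
#' @param rootSeed root seed for all derived streams
#' @param context optional precomputed [makeEvalContext()] result
#' @param dataset optional precomputed training dataset
#' @return list with `report` (per variant x parameter x seed), `aggregate`
#'   (averaged over seeds), `perCase` KL values, and the `context` used
#' @export
runTableExperiment <- function(setting = 1, variants = CVAE_VARIANTS,
                               M = 20, trainN = 2000, epochs = 50,
                               seeds = 1:3, mcmc = mcmcConfig(20000, 5000),
                               nDraws = 15000, rootSeed = 1,
                               context = NULL, dataset = NULL) {
  prior <- makePrior(setting)
  if (is.null(context))
    context <- makeEvalContext(prior, M, mcmc, rootSeed)
  if (is.null(dataset))
    dataset <- makeDataset(prior, trainN,
                           ref = context$ref, schedule = context$schedule,
                           seed = seedStream(rootSeed, "train-data"))
  rows <- list()
  perCase <- list()
  for (v in variants) {
    for (s in seeds) {
      cfg <- trainConfig(epochs = epochs,
                         seed = seedStream(rootSeed,
                                           paste0("train-", v, "-", s)))
      model <- trainCvae(dataset, v, cfg)
      ev <- evalModelOnContext(model, context, nDraws,
                               seedTag = paste0("infer-", v, "-", s))
      rd <- relDiffMetrics(context$mcmcFits, ev$fits)
      rows[[length(rows) + 1]] <- data.frame(
        setting = setting, variant = v, seed = s,
        parameter = rd$parameter, delta_mu = rd$delta_mu,
        delta_sigma = rd$delta_sigma, D = colMeans(ev$kl)[rd$parameter])
      perCase[[paste(v, s, sep = "-")]] <- ev$kl
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  agg <- stats::aggregate(cbind(delta_mu, delta_sigma, D) ~
                            setting + variant + parameter,
                          data = report, FUN = mean)
  list(report = report, aggregate = agg, perCase = perCase,
       context = context, dataset = dataset)
}

#' Sweep a loss hyperparameter and track the averaged KL divergence
#'
#' Retrains the variant at each hyperparameter value (for each seed) and
#' reports the KL divergence to the MCMC reference averaged over parameters
#' and test cases, plus its across-training-run (seed) dispersion.
#'
#' @param values hyperparameter grid (positive; study range 0.6..1.8)
#' @param variant `"dual_encoder"` (sweeps beta) or `"dual_decoder"`
#'   (sweeps beta or lambda)
#' @param which `"beta"` or `"lambda"` (lambda only for the dual decoder)
#' @param seeds training seeds per grid point
#' @param context evaluation context (built at desk scale if missing)
#' @param dataset training dataset (built if missing)
#' @inheritParams runTableExperiment
#' @return data.frame with one row per (value, seed) and columns `value`,
#'   `seed`, `D`; aggregate mean/sd per value in `attr(, "summary")`
#' @export
runHyperparameterSweep <- function(values, variant = c("dual_encoder",
                                                       "dual_decoder"),
                                   which = c("beta", "lambda"), seeds = 1:3,
                                   setting = 1, M = 20, trainN = 2000,
                                   epochs = 50, mcmc = mcmcConfig(20000, 5000),
                                   nDraws = 15000, rootSeed = 1,
                                   context = NULL, dataset = NULL) {
  variant <- match.arg(variant)
  which <- match.arg(which)
  if (any(values <= 0)) stop("hyperparameter values must be positive")
  if (which == "lambda" && variant != "dual_decoder")
    stop("lambda only applies to the dual-decoder variant")
  prior <- makePrior(setting)
  if (is.null(context)) context <- makeEvalContext(prior, M, mcmc, rootSeed)
  if (is.null(dataset))
    dataset <- makeDataset(prior, trainN, ref = context$ref,
                           schedule = context$schedule,
                           seed = seedStream(rootSeed, "train-data"))
  rows <- list()
  for (val in values) {
    for (s in seeds) {
      cfg <- trainConfig(epochs = epochs,
                         seed = seedStream(rootSeed,
                                           paste0("sweep-", which, "-", s)))
      cfg[[which]] <- val
      model <- trainCvae(dataset, variant, cfg)
      ev <- evalModelOnContext(model, context, nDraws,
                               seedTag = sprintf("sw-%s-%g-%d", which, val, s))
      rows[[length(rows) + 1]] <- data.frame(value = val, seed = s,
                                             D = mean(ev$kl))
    }
  }
  out <- do.call(rbind, rows)
  summ <- stats::aggregate(D ~ value, data = out,
                           FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  attr(out, "summary") <- do.call(data.frame,
                                  c(list(value = summ$value), as.data.frame(summ$D)))
  out
}

#' Sweep the number of training samples
#'
#' Trains the variant at each training-set size (subsets of one generated
#' dataset) and reports the averaged KL divergence and its across-test-case
#' dispersion.
#'
#' @param sizes increasing training-set sizes
#' @inheritParams runHyperparameterSweep
#' @return data.frame with columns `size`, `D` (mean over cases and
#'   parameters) and `D_sd_cases` (across-case dispersion)
#' @export
runTrainingSizeSweep <- function(sizes, variant = "dual_decoder",
                                 setting = 1, M = 20, epochs = 50,
                                 mcmc = mcmcConfig(20000, 5000),
                                 nDraws = 15000, rootSeed = 1,
                                 context = NULL, dataset = NULL) {
  if (is.unsorted(sizes)) stop("sizes must be increasing")
  prior <- makePrior(setting)
  if (is.null(context)) context <- makeEvalContext(prior, M, mcmc, rootSeed)
  if (is.null(dataset))
    dataset <- makeDataset(prior, max(sizes), ref = context$ref,
                           schedule = context$schedule,
                           seed = seedStream(rootSeed, "train-data"))
  xy <- if (is(dataset, "SummarizedExperiment")) datasetXY(dataset)
        else dataset
  rows <- list()
  for (n in sizes) {
    if (n > nrow(xy$x)) stop("size exceeds the generated dataset")
    cfg <- trainConfig(epochs = epochs,
                       seed = seedStream(rootSeed, paste0("size-", n)))
    model <- trainCvae(list(x = xy$x[seq_len(n), , drop = FALSE],
                            y = xy$y[seq_len(n), , drop = FALSE]),
                       variant, cfg)
    ev <- evalModelOnContext(model, context, nDraws,
                             seedTag = paste0("size-", n))
    perCaseD <- rowMeans(ev$kl)
    rows[[length(rows) + 1]] <- data.frame(size = n, D = mean(perCaseD),
                                           D_sd_cases = stats::sd(perCaseD))
  }
  do.call(rbind, rows)
}

#' Sweep the DVR used to generate test measurements (data shift)
#'
#' With a model trained under the setting-1 prior, generates test TACs at
#' each requested DVR* (k2 and R1 held at the prior locations), runs fresh
#' MCMC on each, and reports the averaged KL divergence. The output records
#' the in-distribution boundary DVR = 3.35 (prior mean 1 plus the FWHM 2.35
#' of the N(1,1) prior) in its `"referenceThreshold"` attribute.
#'
#' @param dvrStar DVR values used to generate the shifted measurements
#' @param nPer noisy TACs per DVR* value
#' @param model optional pre-trained [CvaeModel-class] (trained at desk
#'   scale if missing)
#' @inheritParams runHyperparameterSweep
#' @return data.frame with columns `dvr_star` and `D`
#' @export
runDataShiftSweep <- function(dvrStar, nPer = 5, model = NULL,
                              variant = "dual_decoder", trainN = 2000,
                              epochs = 50, mcmc = mcmcConfig(20000, 5000),
                              nDraws = 15000, rootSeed = 1,
                              dataset = NULL) {
  if (any(dvrStar <= 0)) stop("DVR* must be positive")
  prior <- makePrior(1)
  ref <- makeReferenceCurve()
  schedule <- buildFrameSchedule()
  if (is.null(model)) {
    if (is.null(dataset))
      dataset <- makeDataset(prior, trainN, ref = ref, schedule = schedule,
                             seed = seedStream(rootSeed, "train-data"))
    model <- trainCvae(dataset, variant,
                       trainConfig(epochs = epochs,
                                   seed = seedStream(rootSeed, "shift-train")))
  }
  loc <- priorLocation(prior)
  rows <- list()
  for (v in dvrStar) {
    x <- matrix(rep(c(v, loc["k2"], loc["R1"]), nPer), nPer, 3, byrow = TRUE,
                dimnames = list(NULL, c("DVR", "k2", "R1")))
    ctx <- makeEvalContext(prior, nPer, mcmc,
                           rootSeed = seedStream(rootSeed,
                                                 paste0("shift-", v)),
                           ref = ref, schedule = schedule, xTest = x)
    ev <- evalModelOnContext(model, ctx, nDraws,
                             seedTag = paste0("shift-", v))
    rows[[length(rows) + 1]] <- data.frame(dvr_star = v, D = mean(ev$kl))
  }
  out <- do.call(rbind, rows)
  attr(out, "referenceThreshold") <- 1 + 2.35
  out
}
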