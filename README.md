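# srtmcvae

Posterior estimation for kinetic parameters in dynamic brain PET, by
Markov-chain Monte Carlo and by amortized deep variational inference —
entirely simulation-based, so the two can be compared against each other.

## What problem this solves

A dynamic PET acquisition summarizes a brain region as a time-activity
curve (TAC): here, 54 frame integrals over a two-hour scan. Under the
simplified reference tissue model (SRTM), the target-region curve is

    C_T(t) = R1 * C_R(t) + (k2 - R1*k2/DVR) * [C_R (x) exp(-(k2/DVR) t)](t)

with parameters x = (DVR, k2, R1) and a fixed reference-region curve
C_R. The measurement is y_n = integral of C_T over frame n plus Gaussian
noise with per-frame standard deviation sigma * sqrt(dt_n / T),
sigma ~ 1e-4 * Gamma(1,1). The object of interest is the full posterior
p(x | y) — parameter uncertainty, not just a point estimate.

The package provides:

* **Simulator** — frame schedule, reference curve, SRTM forward model,
  noise model, Gaussian priors (four settings), training datasets and the
  alpha-filtered test set (`buildFrameSchedule`, `makeReferenceCurve`,
  `simulateTac`, `makeDataset`, `makePrior`, `selectTestSet`).
* **Reference sampler** — random-walk Metropolis-Hastings on the exact
  posterior with burn-in-only adaptation and a segment-mean convergence
  diagnostic (`runMH`, `tuneProposal`, `convergenceCheck`).
* **Amortized estimators** — three conditional-VAE variants
  (dual-encoder, dual-decoder, vanilla) with hand-verified gradients,
  trained by SGD with momentum on simulated pairs; a trained network emits
  45,000 posterior draws for a new TAC in under a second
  (`trainCvae`, `samplePosterior`).
* **Evaluation** — Gaussian fits of posterior marginals, averaged relative
  mean/width differences (percent) and per-marginal histogram KL
  divergence against the MCMC reference, plus experiment drivers for the
  variant comparison and the hyperparameter / training-size / data-shift
  sweeps (`fitGaussian`, `relDiffMetrics`, `klMetric`,
  `runTableExperiment`, `runHyperparameterSweep`, `runTrainingSizeSweep`,
  `runDataShiftSweep`).
* **CLI** — `inst/scripts/srtmcvae-cli` with `simulate`, `mcmc`, `train`,
  `infer`, `evaluate`, `sweep` and `reproduce-tables` subcommands, all
  writing TSV artifacts plus a JSON run manifest.

## Worked example

Simulate a noisy TAC at the default parameters, sample its reference
posterior, and compare with an amortized estimator:

```r
library(srtmcvae)

ref   <- makeReferenceCurve()
sched <- buildFrameSchedule()
prior <- makePrior(1)

# one noisy measurement at DVR = 1.0, k2 = 0.0006 min^-1, R1 = 0.74
set.seed(7)
tac <- simulateTac(c(DVR = 1.0, k2 = 0.0006, R1 = 0.74), ref, sched)

# reference posterior: 60,000 MH iterations, 15,000 burn-in
post <- runMH(tac, tacSigma(tac), prior, mcmcConfig(), ref, seed = 1)
post
#> PosteriorSamples: 45000 draws from mcmc
#>   acceptance rate: 0.278
#>   DVR mean 1.0003, sd 0.00036
#>   k2  mean 0.00059942, sd 6.44e-07
#>   R1  mean 0.74, sd 1.61e-07
convergenceCheck(post)
#>   parameter          gap pass
#> 1       DVR 2.477135e-05 TRUE
#> 2        k2 4.380629e-08 TRUE
#> 3        R1 3.476853e-08 TRUE

# amortized posterior from a (desk-scale) trained CVAE
ds    <- makeDataset(prior, 2000, seed = 11)
model <- trainCvae(ds, "dual_decoder", trainConfig(epochs = 50, seed = 2))
samplePosterior(model, tac, nDraws = 15000, seed = 3)
#> PosteriorSamples: 15000 draws from cvae-dual_decoder
#>   DVR mean 1.1079, sd 0.0235
#>   k2  mean 0.0085713, sd 8.16e-05
#>   R1  mean 0.78718, sd 0.0373
```

The MH posterior recovers the generating parameters and is extremely sharp
(the simulation's high-amplitude calibration; see the methods vignette);
its convergence gaps sit well below the 0.001 threshold. The desk-scale
CVAE (50 epochs on 2,000 pairs) places its mass in the right region but
with visible bias and far wider spread — amortized approximation error
plus implicit marginalization over the noise scale, which is exactly the
kind of discrepancy the evaluation metrics quantify.

The background and every modelling choice (priors, noise model,
standardization, adaptation schedule, metric estimators, known
limitations) are documented in `vignettes/posterior-estimation.Rmd`.

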