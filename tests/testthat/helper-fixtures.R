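# Shared fixtures. Heavy objects (reference curve, desk-scale evaluation
# context, desk-scale table run) are built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

refCurve <- function() fixture("ref", makeReferenceCurve())
schedule54 <- function() fixture("sched", buildFrameSchedule())

defaultParams <- c(DVR = 1.0, k2 = 0.0006, R1 = 0.74)

# One noisy TAC at the default parameters, fixed noise scale.
defaultTestTac <- function(sigma = 1e-4, seed = 42) {
  fixture(paste0("tac-", sigma, "-", seed), withr_seed(seed, {
    addNoise(integrateFrames(srtmTargetCurve(defaultParams, refCurve()),
                             schedule54(), curveTime(refCurve())), sigma)
  }))
}

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Desk-scale evaluation context (20 alpha-filtered test TACs + MCMC at
# 20,000/5,000) shared by the table experiment and the sweeps.
deskContext <- function() {
  fixture("deskContext",
          makeEvalContext(makePrior(1), M = 20, mcmcConfig(20000, 5000),
                          rootSeed = 1))
}

deskDataset <- function() {
  ctx <- deskContext()
  fixture("deskDataset",
          makeDataset(makePrior(1), 4000, ref = ctx$ref,
                      schedule = ctx$schedule, seed = seedStream(1, "train-data")))
}

deskSubset <- function(n) {
  xy <- list(x = as.matrix(SummarizedExperiment::colData(deskDataset())[, c("DVR", "k2", "R1")]),
             y = t(SummarizedExperiment::assay(deskDataset(), "tac")))
  list(x = xy$x[seq_len(n), , drop = FALSE], y = xy$y[seq_len(n), , drop = FALSE])
}

# Desk-scale table experiment (train_n = 2000, 50 epochs, M = 20, 3
# training seeds, all three variants).
deskTableRun <- function() {
  fixture("deskTable",
          runTableExperiment(setting = 1, M = 20, trainN = 2000, epochs = 50,
                             seeds = 1:3, mcmc = mcmcConfig(20000, 5000),
                             nDraws = 15000, rootSeed = 1,
                             context = deskContext(),
                             dataset = deskSubset(2000)))
}
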