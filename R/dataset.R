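# Training/test dataset generation and plain-text TAC I/O.

#' Generate a paired (parameters, noisy TAC) dataset
#'
#' Draws `n` kinetic-parameter triples from the truncated prior, simulates
#' each one's clean target TAC through the SRTM forward model, draws one
#' noise scale per TAC and adds frame-weighted Gaussian noise. The result is
#' the training material for the CVAE estimators and is fully replayable
#' from the seed.
#'
#' @param prior a [PriorSpec-class]
#' @param n number of pairs
#' @param ref reference curve (default [makeReferenceCurve()])
#' @param schedule frame schedule (default [buildFrameSchedule()])
#' @param seed optional integer seed; recorded in the metadata
#' @param sigmaScale noise scale multiplier (default 1e-4)
#' @param exponent noise exponent (default 0.5)
#' @param noiseless if TRUE, no noise is added (sigma column is 0)
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay `tac`
#'   (frames x samples), colData columns DVR, k2, R1, sigma, and the frame
#'   schedule in rowData
#' @export
makeDataset <- function(prior, n, ref = makeReferenceCurve(),
                        schedule = buildFrameSchedule(), seed = NULL,
                        sigmaScale = 1e-4, exponent = 0.5,
                        noiseless = FALSE) {
  stopifnot(n >= 1)
  withSeed(seed, {
    x <- samplePrior(prior, n)
    sig <- if (noiseless) rep(0, n) else sampleNoiseSigma(n, sigmaScale)
    y <- matrix(NA_real_, nFrames(schedule), n)
    for (i in seq_len(n)) {
      y[, i] <- tacValues(simulateTac(x[i, ], ref, schedule, sigma = sig[i],
                                      exponent = exponent))
    }
    rownames(y) <- sprintf("frame%02d", seq_len(nFrames(schedule)))
    colnames(y) <- sprintf("tac%05d", seq_len(n))
    SummarizedExperiment::SummarizedExperiment(
      assays = list(tac = y),
      rowData = S4Vectors::DataFrame(
        t_start_s = frameStarts(schedule),
        t_end_s = frameEnds(schedule),
        dt_s = frameDurations(schedule)),
      colData = S4Vectors::DataFrame(DVR = x[, "DVR"], k2 = x[, "k2"],
                                     R1 = x[, "R1"], sigma = sig),
      metadata = list(setting = priorSetting(prior), n = n,
                      seed = if (is.null(seed)) NA else seed,
                      sigmaScale = sigmaScale, noiseExponent = exponent,
                      referenceCurve = ref@pars))
  })
}

#' @noRd
datasetXY <- function(se) {
  list(x = as.matrix(SummarizedExperiment::colData(se)[, c("DVR", "k2", "R1")]),
       y = t(SummarizedExperiment::assay(se, "tac")))
}

#' Write / read a TAC table
#'
#' Tab-separated long format with columns `tac_id`, `frame_index`,
#' `t_start_s`, `t_end_s`, `value`, one row per frame.
#'
#' @param tac a [Tac-class] or a dataset from [makeDataset()]
#' @param path output file
#' @return `writeTacTable` returns `path` invisibly; `readTacTable` returns
#'   a list of [Tac-class] objects (noise scales are not stored in the table
#'   and read back as NA)
#' @export
writeTacTable <- function(tac, path) {
  if (is(tac, "Tac")) {
    sched <- tacSchedule(tac)
    df <- data.frame(tac_id = "tac1",
                     frame_index = seq_len(nFrames(sched)),
                     t_start_s = frameStarts(sched),
                     t_end_s = frameEnds(sched),
                     value = tacValues(tac))
  } else {
    y <- SummarizedExperiment::assay(tac, "tac")
    rd <- SummarizedExperiment::rowData(tac)
    df <- data.frame(tac_id = rep(colnames(y), each = nrow(y)),
                     frame_index = rep(seq_len(nrow(y)), ncol(y)),
                     t_start_s = rep(rd$t_start_s, ncol(y)),
                     t_end_s = rep(rd$t_end_s, ncol(y)),
                     value = as.vector(y))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTacTable
#' @export
readTacTable <- function(path) {
  df <- utils::read.delim(path)
  need <- c("tac_id", "frame_index", "t_start_s", "t_end_s", "value")
  if (!all(need %in% names(df))) stop("malformed TAC table")
  lapply(split(df, df$tac_id), function(d) {
    d <- d[order(d$frame_index), ]
    sched <- new("FrameSchedule", frameEnd = d$t_end_s,
                 frameDuration = d$t_end_s - d$t_start_s)
    new("Tac", values = d$value, schedule = sched, sigma = NA_real_)
  })
}

#' Write posterior samples to a TSV table
#'
#' Columns `draw_index`, `DVR`, `k2_per_min`, `R1`; header metadata (source,
#' seed) is stored in comment lines starting with `#`.
#'
#' @param samples a [PosteriorSamples-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
writePosteriorTable <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source: %s", sampleSource(samples)), con)
  prov <- Filter(function(v) is.atomic(v) && length(v) <= 10,
                 samples@provenance)
  if (length(prov))
    writeLines(sprintf("# %s: %s", names(prov),
                       vapply(prov, function(v) paste(format(v), collapse = ","),
                              character(1))), con)
  d <- posteriorDraws(samples)
  df <- data.frame(draw_index = seq_len(nrow(d)), DVR = d[, "DVR"],
                   k2_per_min = d[, "k2"], R1 = d[, "R1"])
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
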