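# Posterior-comparison metrics: Gaussian fits of marginals, relative
# mean/width differences, and per-marginal histogram KL divergence.

#' Fit a Gaussian to a one-parameter marginal sample
#'
#' Histograms the draws and least-squares fits a Gaussian bell
#' `a * exp(-(x - mu)^2 / (2 s^2))` to the bin counts. If the nonlinear fit
#' fails to converge the fit falls back to moment matching; the method used
#' is recorded.
#'
#' @param draws numeric vector of marginal posterior draws (>= 100)
#' @param bins number of histogram bins (default `sqrt(n)` capped at 200)
#' @return data.frame with columns `mu`, `sigma`, `method`
#' @export
fitGaussian <- function(draws, bins = NULL) {
  draws <- as.numeric(draws)
  if (length(draws) < 100) stop("need at least 100 draws")
  s0 <- stats::sd(draws)
  if (!is.finite(s0) || s0 == 0) stop("degenerate (zero-variance) samples")
  if (is.null(bins)) bins <- max(20, min(200, floor(sqrt(length(draws)))))
  h <- graphics::hist(draws, breaks = seq(min(draws), max(draws),
                                          length.out = bins + 1),
                      plot = FALSE)
  df <- data.frame(xc = h$mids, ct = h$counts)
  fit <- tryCatch({
    f <- minpack.lm::nlsLM(ct ~ a * exp(-(xc - mu)^2 / (2 * s^2)), data = df,
                           start = list(a = max(df$ct), mu = mean(draws),
                                        s = s0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(f)
    if (!is.finite(cf["mu"]) || !is.finite(cf["s"]) || cf["s"] == 0)
      stop("bad fit")
    data.frame(mu = unname(cf["mu"]), sigma = abs(unname(cf["s"])),
               method = "histogram-ls")
  }, error = function(e) NULL)
  if (is.null(fit))
    fit <- data.frame(mu = mean(draws), sigma = s0, method = "moments")
  fit
}

#' Fit Gaussians to all three parameter marginals
#'
#' @param samples a [PosteriorSamples-class] or a draws matrix
#' @return data.frame with columns `parameter`, `mu`, `sigma`, `method`
#' @export
fitPosteriorGaussians <- function(samples) {
  d <- if (is(samples, "PosteriorSamples")) posteriorDraws(samples)
       else as.matrix(samples)
  do.call(rbind, lapply(colnames(d), function(p) {
    f <- fitGaussian(d[, p])
    cbind(parameter = p, f)
  }))
}

#' Test-set-averaged relative differences of posterior mean and width
#'
#' \deqn{\bar\delta_\mu = \frac{1}{M} \sum_m
#'   \frac{|\mu_m^{MCMC} - \mu_m^{DL}|}{\mu_m^{MCMC}}}
#' and analogously for the fitted standard deviations; both reported in
#' percent, per kinetic parameter. Signed per-case values are retained in
#' the `"cases"` attribute for dispersion diagnostics.
#'
#' @param fitsMcmc,fitsDl data.frames with columns `case`, `parameter`,
#'   `mu`, `sigma`, paired by (case, parameter)
#' @return data.frame with columns `parameter`, `delta_mu`, `delta_sigma`
#'   (percent); per-case signed values in `attr(, "cases")`
#' @export
relDiffMetrics <- function(fitsMcmc, fitsDl) {
  m <- merge(fitsMcmc, fitsDl, by = c("case", "parameter"),
             suffixes = c("_mcmc", "_dl"))
  if (nrow(m) != nrow(fitsMcmc)) stop("fits are not fully paired")
  if (any(m$mu_mcmc == 0)) stop("MCMC fitted mean of zero")
  m$dmu <- 100 * (m$mu_mcmc - m$mu_dl) / m$mu_mcmc
  m$dsigma <- 100 * (m$sigma_mcmc - m$sigma_dl) / m$sigma_mcmc
  out <- do.call(rbind, lapply(split(m, m$parameter), function(d)
    data.frame(parameter = d$parameter[1],
               delta_mu = mean(abs(d$dmu)),
               delta_sigma = mean(abs(d$dsigma)))))
  rownames(out) <- NULL
  attr(out, "cases") <- m[, c("case", "parameter", "dmu", "dsigma")]
  out
}

#' Histogram KL divergence between two sample-represented marginals
#'
#' Estimates \eqn{D_{KL}(p \| q)} per one-dimensional marginal by binning
#' both sample sets on a shared grid spanning the pooled 0.1-99.9 percentile
#' range (draws outside are clamped into the edge bins), with additive
#' smoothing of `smooth` pseudo-counts per bin. `method = "gaussian"`
#' instead uses the closed-form KL between moment-matched Gaussians, as a
#' sensitivity alternative.
#'
#' @param p,q numeric vectors, or draws matrices / [PosteriorSamples-class]
#'   (then a named per-parameter vector is returned); p is the reference
#'   (MCMC) side
#' @param bins number of bins (default `sqrt(min(n_p, n_q))` capped at 200)
#' @param smooth pseudo-counts per bin (default 0.5)
#' @param method `"histogram"` (default) or `"gaussian"`
#' @return scalar KL divergence in nats, or a named vector per parameter
#' @export
klMetric <- function(p, q, bins = NULL, smooth = 0.5,
                     method = c("histogram", "gaussian")) {
  method <- match.arg(method)
  if (is(p, "PosteriorSamples")) p <- posteriorDraws(p)
  if (is(q, "PosteriorSamples")) q <- posteriorDraws(q)
  if (is.matrix(p) || is.matrix(q)) {
    p <- as.matrix(p); q <- as.matrix(q)
    return(vapply(colnames(p), function(j)
      klMetric(p[, j], q[, j], bins = bins, smooth = smooth,
               method = method), numeric(1)))
  }
  if (length(p) < 1000 || length(q) < 1000)
    stop("need at least 1000 draws on each side")
  if (method == "gaussian") {
    mA <- mean(p); sA <- stats::sd(p); mB <- mean(q); sB <- stats::sd(q)
    return(log(sB / sA) + (sA^2 + (mA - mB)^2) / (2 * sB^2) - 0.5)
  }
  if (is.null(bins))
    bins <- max(10, min(200, floor(sqrt(min(length(p), length(q))))))
  rng <- stats::quantile(c(p, q), c(0.001, 0.999), names = FALSE)
  if (rng[1] == rng[2]) stop("degenerate pooled range")
  brk <- seq(rng[1], rng[2], length.out = bins + 1)
  cp <- tabulate(findInterval(pmin(pmax(p, rng[1]), rng[2]), brk,
                              rightmost.closed = TRUE, all.inside = TRUE),
                 nbins = bins)
  cq <- tabulate(findInterval(pmin(pmax(q, rng[1]), rng[2]), brk,
                              rightmost.closed = TRUE, all.inside = TRUE),
                 nbins = bins)
  pp <- (cp + smooth) / sum(cp + smooth)
  qq <- (cq + smooth) / sum(cq + smooth)
  sum(pp * log(pp / qq))
}
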