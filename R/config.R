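# Declarative experiment configuration, presets, and run manifests.

#' Default experiment configuration
#'
#' The `"paper"` preset pins the full-scale study values (10,000 training
#' pairs, 200 epochs, M = 200 test cases, 60,000/15,000 MCMC iterations,
#' 45,000 posterior draws). The `"desk"` preset is a scaled-down profile
#' (2,000 pairs, 50 epochs, M = 20, 20,000/5,000 iterations, 15,000 draws)
#' that preserves the qualitative orderings while finishing on one CPU in
#' tens of minutes.
#'
#' @param scale `"paper"` or `"desk"`
#' @return nested configuration list
#' @export
defaultConfig <- function(scale = c("paper", "desk")) {
  scale <- match.arg(scale)
  desk <- scale == "desk"
  list(
    scale = scale,
    setting = 1L,
    alpha = 0.26,
    M = if (desk) 20L else 200L,
    trainN = if (desk) 2000L else 10000L,
    nDraws = if (desk) 15000L else 45000L,
    noise = list(sigmaScale = 1e-4, exponent = 0.5),
    referenceCurve = c(referenceCurveDefaults(),
                       list(gridStep = 1, totalTime = 7200)),
    mcmc = list(nIterations = if (desk) 20000L else 60000L,
                nBurnIn = if (desk) 5000L else 15000L,
                targetAcceptance = 0.3),
    train = list(epochs = if (desk) 50L else 200L, lr = 1e-4,
                 momentum = 0.9, batchSize = 64L, beta = 1, lambda = 1),
    cvae = list(K = 10L),
    seed = 1L)
}

#' @noRd
validateConfig <- function(cfg) {
  template <- defaultConfig(if (identical(cfg$scale, "desk")) "desk"
                            else "paper")
  checkKeys <- function(x, tpl, path = "") {
    unknown <- setdiff(names(x), names(tpl))
    if (length(unknown))
      stop(sprintf("unknown config key%s: %s", if (length(unknown) > 1) "s"
                   else "", paste0(path, unknown, collapse = ", ")))
    for (nm in names(x))
      if (is.list(tpl[[nm]]) && !is.null(names(tpl[[nm]])))
        checkKeys(x[[nm]], tpl[[nm]], paste0(path, nm, "."))
  }
  checkKeys(cfg, template)
  cfg <- utils::modifyList(template, cfg)
  if (!cfg$scale %in% c("paper", "desk")) stop("scale must be paper or desk")
  if (!cfg$setting %in% 1:4) stop("setting must be one of 1, 2, 3, 4")
  if (cfg$alpha <= 0) stop("alpha must be positive")
  if (cfg$mcmc$nBurnIn >= cfg$mcmc$nIterations)
    stop("nBurnIn must be smaller than nIterations")
  if (cfg$noise$sigmaScale <= 0) stop("sigmaScale must be positive")
  if (cfg$train$beta < 0 || cfg$train$lambda < 0)
    stop("loss weights must be non-negative")
  cfg
}

#' Load / save an experiment configuration
#'
#' YAML key-value files validated against the configuration schema: unknown
#' keys are rejected with a field-level message, missing keys are filled
#' with the preset defaults (an empty file yields the full `"paper"`
#' preset).
#'
#' @param path file path
#' @return `loadConfig`: validated configuration list; `saveConfig`: `path`,
#'   invisibly
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validateConfig(cfg)
}

#' @rdname loadConfig
#' @param config configuration list to write
#' @export
saveConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, the named seed streams derived from
#' the root seed, package version and timestamp next to a run's artifacts,
#' so any artifact can be replayed bit-exactly.
#'
#' @param path output JSON path
#' @param config configuration list
#' @param streams character vector of stream names to record
#' @param extra named list of additional fields (e.g. output file names)
#' @return `path`, invisibly
#' @export
writeManifest <- function(path, config, streams = character(), extra = list()) {
  manifest <- c(list(
    package = "srtmcvae",
    version = as.character(utils::packageVersion("srtmcvae")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = stats::setNames(
      lapply(streams, function(s) seedStream(config$seed, s)), streams)),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
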