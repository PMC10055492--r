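# Accessor generics, methods and show() methods for the S4 classes.

#' @rdname FrameSchedule-class
#' @param object a `FrameSchedule`
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))

#' @rdname FrameSchedule-class
#' @export
setMethod("nFrames", "FrameSchedule", function(object) length(object@frameEnd))

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameEnds", function(object) standardGeneric("frameEnds"))

#' @rdname FrameSchedule-class
#' @export
setMethod("frameEnds", "FrameSchedule", function(object) object@frameEnd)

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameStarts", function(object) standardGeneric("frameStarts"))

#' @rdname FrameSchedule-class
#' @export
setMethod("frameStarts", "FrameSchedule",
          function(object) object@frameEnd - object@frameDuration)

#' @rdname FrameSchedule-class
#' @export
setGeneric("frameDurations", function(object) standardGeneric("frameDurations"))

#' @rdname FrameSchedule-class
#' @export
setMethod("frameDurations", "FrameSchedule",
          function(object) object@frameDuration)

#' @rdname FrameSchedule-class
#' @export
setGeneric("totalDuration", function(object) standardGeneric("totalDuration"))

#' @rdname FrameSchedule-class
#' @export
setMethod("totalDuration", "FrameSchedule",
          function(object) sum(object@frameDuration))

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, total %g s\n", nFrames(object),
              totalDuration(object)))
  cat("  durations:", paste(rle(object@frameDuration)$lengths, "x",
                            rle(object@frameDuration)$values, "s",
                            collapse = ", "), "\n")
})

#' @rdname ReferenceCurve-class
#' @param object a `ReferenceCurve`
#' @export
setGeneric("curveTime", function(object) standardGeneric("curveTime"))

#' @rdname ReferenceCurve-class
#' @export
setMethod("curveTime", "ReferenceCurve", function(object) object@time)

#' @rdname ReferenceCurve-class
#' @export
setGeneric("curveActivity", function(object) standardGeneric("curveActivity"))

#' @rdname ReferenceCurve-class
#' @export
setMethod("curveActivity", "ReferenceCurve", function(object) object@activity)

setMethod("show", "ReferenceCurve", function(object) {
  pk <- which.max(object@activity)
  cat(sprintf(
    "ReferenceCurve: %d grid points over [0, %g] s; peak %.3g at t = %g s\n",
    length(object@time), max(object@time), object@activity[pk],
    object@time[pk]))
})

#' @rdname Tac-class
#' @param object a `Tac`
#' @export
setGeneric("tacValues", function(object) standardGeneric("tacValues"))

#' @rdname Tac-class
#' @export
setMethod("tacValues", "Tac", function(object) object@values)

#' @rdname Tac-class
#' @export
setGeneric("tacSigma", function(object) standardGeneric("tacSigma"))

#' @rdname Tac-class
#' @export
setMethod("tacSigma", "Tac", function(object) object@sigma)

#' @rdname Tac-class
#' @export
setGeneric("tacSchedule", function(object) standardGeneric("tacSchedule"))

#' @rdname Tac-class
#' @export
setMethod("tacSchedule", "Tac", function(object) object@schedule)

setMethod("show", "Tac", function(object) {
  cat(sprintf("Tac: %d frames, %s, range [%.3g, %.3g]\n",
              length(object@values),
              if (is.na(object@sigma)) "clean"
              else sprintf("noisy (sigma = %.3g)", object@sigma),
              min(object@values), max(object@values)))
})

#' @rdname PriorSpec-class
#' @param object a `PriorSpec`
#' @export
setGeneric("priorLocation", function(object) standardGeneric("priorLocation"))

#' @rdname PriorSpec-class
#' @export
setMethod("priorLocation", "PriorSpec", function(object) object@location)

#' @rdname PriorSpec-class
#' @export
setGeneric("priorScale", function(object) standardGeneric("priorScale"))

#' @rdname PriorSpec-class
#' @export
setMethod("priorScale", "PriorSpec", function(object) object@scale)

#' @rdname PriorSpec-class
#' @export
setGeneric("priorSetting", function(object) standardGeneric("priorSetting"))

#' @rdname PriorSpec-class
#' @export
setMethod("priorSetting", "PriorSpec", function(object) object@setting)

setMethod("show", "PriorSpec", function(object) {
  cat(sprintf("PriorSpec (setting %d):\n", object@setting))
  for (nm in names(object@location))
    cat(sprintf("  %-3s ~ N(%g, sd %g), truncated to %s\n", nm,
                object@location[nm], object@scale[nm],
                if (nm == "k2") ">= 0" else "> 0"))
})

#' @rdname PosteriorSamples-class
#' @param object a `PosteriorSamples`
#' @export
setGeneric("posteriorDraws", function(object) standardGeneric("posteriorDraws"))

#' @rdname PosteriorSamples-class
#' @export
setMethod("posteriorDraws", "PosteriorSamples", function(object) object@draws)

#' @rdname PosteriorSamples-class
#' @export
setGeneric("sampleSource", function(object) standardGeneric("sampleSource"))

#' @rdname PosteriorSamples-class
#' @export
setMethod("sampleSource", "PosteriorSamples", function(object) object@source)

#' @rdname PosteriorSamples-class
#' @export
setGeneric("acceptanceRate", function(object) standardGeneric("acceptanceRate"))

#' @rdname PosteriorSamples-class
#' @export
setMethod("acceptanceRate", "PosteriorSamples",
          function(object) object@acceptanceRate)

setMethod("show", "PosteriorSamples", function(object) {
  cat(sprintf("PosteriorSamples: %d draws from %s\n", nrow(object@draws),
              object@source))
  if (!is.na(object@acceptanceRate))
    cat(sprintf("  acceptance rate: %.3f\n", object@acceptanceRate))
  mu <- colMeans(object@draws)
  sd <- apply(object@draws, 2, stats::sd)
  for (j in colnames(object@draws))
    cat(sprintf("  %-3s mean %.5g, sd %.3g\n", j, mu[j], sd[j]))
})

setMethod("show", "CvaeModel", function(object) {
  cat(sprintf("CvaeModel: variant %s, %s\n", object@variant,
              if (object@trained) sprintf("trained (%d epochs)",
                                          nrow(object@log))
              else "untrained"))
})
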