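## Accessor generics. Slot access from user code goes through these.

#' @name accessors
#' @title Accessors for NanoSiMPull classes
#' @description Small accessor generics: `frames()`, `pixelSize()`,
#'   `frameInterval()`, `channelLabel()`, `nFrames()`, `fieldArea()`,
#'   `spots()`, `nSpots()`, `intensity()`, `intervals()`, `durations()`,
#'   `kOff()`, `nSteps()`, `adjustedCount()`, `thresholdValue()`,
#'   `isBound()`.
#' @param object an object of the documented class.
#' @return The corresponding slot value (see each method).
NULL

#' @rdname accessors
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(object) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("channelLabel", function(object) standardGeneric("channelLabel"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("fieldArea", function(object) standardGeneric("fieldArea"))
#' @rdname accessors
#' @export
setGeneric("spots", function(object) standardGeneric("spots"))
#' @rdname accessors
#' @export
setGeneric("nSpots", function(object) standardGeneric("nSpots"))
#' @rdname accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setGeneric("intervals", function(object) standardGeneric("intervals"))
#' @rdname accessors
#' @export
setGeneric("durations", function(object) standardGeneric("durations"))
#' @rdname accessors
#' @export
setGeneric("kOff", function(object) standardGeneric("kOff"))
#' @rdname accessors
#' @export
setGeneric("nSteps", function(object) standardGeneric("nSteps"))
#' @rdname accessors
#' @export
setGeneric("adjustedCount", function(object) standardGeneric("adjustedCount"))
#' @rdname accessors
#' @export
setGeneric("thresholdValue", function(object) standardGeneric("thresholdValue"))
#' @rdname accessors
#' @export
setGeneric("isBound", function(object) standardGeneric("isBound"))

#' @rdname accessors
setMethod("frames", "MovieStack", function(object) object@frames)
#' @rdname accessors
setMethod("pixelSize", "MovieStack", function(object) object@pixelSize)
#' @rdname accessors
setMethod("frameInterval", "MovieStack", function(object) object@frameInterval)
#' @rdname accessors
setMethod("channelLabel", "MovieStack", function(object) object@channel)
#' @rdname accessors
setMethod("nFrames", "MovieStack", function(object) dim(object@frames)[3])
#' @rdname accessors
setMethod("fieldArea", "MovieStack", function(object) {
  d <- dim(object@frames)
  prod(d[1:2]) * (object@pixelSize / 1000)^2  # um^2
})

#' @rdname accessors
setMethod("spots", "SpotSet", function(object) object@spots)
#' @rdname accessors
setMethod("nSpots", "SpotSet", function(object) nrow(object@spots))
#' @rdname accessors
setMethod("channelLabel", "SpotSet", function(object) object@channel)
#' @rdname accessors
setMethod("fieldArea", "SpotSet", function(object)
  prod(object@fieldDim) * (object@pixelSize / 1000)^2)

#' @rdname accessors
setMethod("intensity", "Trace", function(object) object@intensity)
#' @rdname accessors
setMethod("frameInterval", "Trace", function(object) object@frameInterval)
#' @rdname accessors
setMethod("nFrames", "Trace", function(object) length(object@intensity))

#' @rdname accessors
setMethod("intervals", "IntervalSet", function(object) object@intervals)
#' @rdname accessors
setMethod("frameInterval", "IntervalSet", function(object) object@frameInterval)

#' @rdname accessors
setMethod("durations", "DwellTimeSet", function(object) object@durations)
#' @rdname accessors
setMethod("frameInterval", "DwellTimeSet", function(object) object@frameInterval)

#' @rdname accessors
setMethod("kOff", "ExpFit", function(object) object@kOff)
#' @rdname accessors
setMethod("nSteps", "StepFit", function(object) object@nSteps)
#' @rdname accessors
setMethod("adjustedCount", "FieldCount", function(object) object@adjustedCount)
#' @rdname accessors
setMethod("thresholdValue", "BindingThreshold", function(object) object@value)
#' @rdname accessors
setMethod("isBound", "BindingCall", function(object) object@bound)

#' @describeIn accessors maximized log-likelihood of an exponential fit.
#' @importFrom stats logLik
#' @export
setMethod("logLik", "ExpFit", function(object, ...) {
  structure(object@logLik, df = 1L, nobs = object@n, class = "logLik")
})

#' @describeIn accessors 95% confidence interval of the dissociation rate.
#' @param parm,level,... ignored (the interval is always the stored 95% one).
#' @importFrom stats confint
#' @export
setMethod("confint", "ExpFit", function(object, parm, level = 0.95, ...) {
  matrix(object@ci95, nrow = 1,
         dimnames = list("kOff", c("2.5 %", "97.5 %")))
})

## show methods -------------------------------------------------------------

setMethod("show", "MovieStack", function(object) {
  d <- dim(object@frames)
  cat(sprintf("MovieStack [%s]: %d x %d px, %d frames, %.0f nm/px, %.3g s/frame (%.0f um^2)\n",
              object@channel, d[1], d[2], d[3], object@pixelSize,
              object@frameInterval, fieldArea(object)))
})

setMethod("show", "SpotSet", function(object) {
  cat(sprintf("SpotSet [%s]: %d spots in %d x %d px field (%.0f um^2)\n",
              object@channel, nrow(object@spots), object@fieldDim[1],
              object@fieldDim[2], fieldArea(object)))
})

setMethod("show", "FieldCount", function(object) {
  cat(sprintf("FieldCount: raw %g - background %g = adjusted %g spots per %.0f um^2\n",
              object@rawCount, object@backgroundCount, object@adjustedCount,
              object@area))
})

setMethod("show", "Trace", function(object) {
  cat(sprintf("Trace '%s': %d frames at %.3g s/frame, range [%.3g, %.3g] counts\n",
              object@spotId, length(object@intensity), object@frameInterval,
              min(object@intensity), max(object@intensity)))
})

setMethod("show", "IntervalSet", function(object) {
  iv <- object@intervals
  cat(sprintf("IntervalSet '%s': %d on / %d off intervals (%d censored)\n",
              object@spotId, sum(iv$state == "on"), sum(iv$state == "off"),
              sum(iv$censored)))
})

setMethod("show", "StepFit", function(object) {
  if (object@nSteps == 0L)
    cat(sprintf("StepFit: unclassifiable (%s)\n", object@reason))
  else
    cat(sprintf("StepFit: %d photobleaching step(s) at %s s; levels %s\n",
                object@nSteps,
                paste(signif(object@stepTimes, 3), collapse = ", "),
                paste(signif(object@levels, 3), collapse = " > ")))
})

setMethod("show", "StepDistribution", function(object) {
  cat(sprintf("StepDistribution [%s]: n = %d classified (+%d unclassifiable)\n",
              object@condition, object@nClassified, object@nUnclassified))
  print(object@table, row.names = FALSE)
})

setMethod("show", "DwellTimeSet", function(object) {
  cat(sprintf("DwellTimeSet: %d dwells, mean %.3g s%s\n",
              length(object@durations), mean(object@durations),
              if (object@frameInterval > 0)
                sprintf(" (frame interval %.3g s)", object@frameInterval)
              else " (continuous)"))
})

setMethod("show", "ExpFit", function(object) {
  cat(sprintf("ExpFit (%s): k_off = %.4g 1/s (SE %.3g), 95%% CI [%.4g, %.4g], n = %d, logL = %.4g\n",
              object@method, object@kOff, object@se, object@ci95[1],
              object@ci95[2], object@n, object@logLik))
})

setMethod("show", "LRTResult", function(object) {
  cat(sprintf("LRT: statistic = %.4g on %d df, p = %.3g (rates %.4g vs %.4g; pooled %.4g 1/s)\n",
              object@statistic, object@df, object@pValue, object@rateA,
              object@rateB, object@ratePooled))
})

setMethod("show", "RebindSummary", function(object) {
  cat(sprintf("RebindSummary: %.1f%% of %d spots display rebinding",
              object@percent, object@nSpots))
  if (!is.na(object@sem))
    cat(sprintf(" (per-experiment mean %.1f%% +/- %.1f%% SEM, %d experiments)",
                object@mean, object@sem, nrow(object@perExperiment)))
  cat("\n")
})

setMethod("show", "BindingThreshold", function(object) {
  cat(sprintf("BindingThreshold: %.4g adjusted spots/field (mean %.4g + 2 x SD %.4g over %d nonbinder assays)\n",
              object@value, object@meanCount, object@sdCount, object@n))
})

setMethod("show", "BindingCall", function(object) {
  cat(sprintf("BindingCall [%s]: %s (mean %.4g vs threshold %.4g; t = %.3g, df = %g, one-tailed p = %.3g)\n",
              object@label, if (object@bound) "BOUND" else "not bound",
              mean(object@assayMeans), object@threshold, object@tStat,
              object@df, object@pValue))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d discs, %d binding intervals, %d nonspecific spots, movie %.3g s\n",
              nrow(object@discPositions), nrow(object@bindingIntervals),
              nrow(object@nonspecificPositions), object@movieLength))
})

setMethod("show", "DiscSpec", function(object) {
  cat(sprintf("DiscSpec: %g lipids/leaflet x %g leaflets, %.0f%% anionic, %.0f%% PIP, %.2f nm^2/lipid\n",
              object@lipidsPerLeaflet, object@leaflets,
              100 * object@anionicFraction, 100 * object@pipFraction,
              object@areaPerLipid))
})
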