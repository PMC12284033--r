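#' @import methods
#' @importFrom stats rexp rpois rnorm runif pnorm median mad sd qnorm
#'   pchisq t.test
#' @importFrom utils head tail write.csv
NULL

## ---------------------------------------------------------------------------
## Raw data containers
## ---------------------------------------------------------------------------

#' MovieStack: a time-ordered stack of intensity frames
#'
#' Container for a single-channel TIRF movie: an `H x W x T` array of pixel
#' intensities (camera counts) together with the pixel size and frame
#' interval needed to interpret it physically.
#'
#' @slot frames numeric array, `H x W x T` (rows x columns x frames).
#' @slot pixelSize numeric(1), nm per pixel.
#' @slot frameInterval numeric(1), seconds per frame.
#' @slot channel character(1) label, e.g. `"disc"` (638 nm excitation of the
#'   DiD-labelled Nanodiscs) or `"protein"` (488 nm excitation of EGFP).
#' @exportClass MovieStack
setClass("MovieStack",
  representation(frames = "array", pixelSize = "numeric",
                 frameInterval = "numeric", channel = "character"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@frames)
    if (length(d) != 3L) msg <- c(msg, "frames must be an H x W x T array")
    else if (d[3] < 1L) msg <- c(msg, "at least one frame is required")
    if (!all(is.finite(object@frames)))
      msg <- c(msg, "frame intensities must be finite")
    if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive value (nm)")
    if (length(object@frameInterval) != 1L || object@frameInterval <= 0)
      msg <- c(msg, "frameInterval must be a single positive value (s)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a MovieStack
#'
#' @param frames numeric `H x W x T` array of camera counts.
#' @param pixelSize nm per pixel (default 160 nm: 100x objective with a
#'   16 um EMCCD pixel).
#' @param frameInterval seconds per frame (default 0.1 s, i.e. 10 frames/s).
#' @param channel channel label.
#' @return A [MovieStack-class] object.
#' @examples
#' mv <- movieStack(array(0, c(16, 16, 5)))
#' nFrames(mv)
#' @export
movieStack <- function(frames, pixelSize = 160, frameInterval = 0.1,
                       channel = "unspecified") {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  new("MovieStack", frames = frames, pixelSize = pixelSize,
      frameInterval = frameInterval, channel = channel)
}

#' SpotSet: detected diffraction-limited spots in one field
#'
#' @slot spots data.frame with columns `x`, `y` (subpixel positions, pixel
#'   units), `amplitude` (fitted peak amplitude, counts) and `sigma`
#'   (PSF width, pixels).
#' @slot channel character(1) source channel label.
#' @slot fieldDim integer(2), field size in pixels (rows, columns).
#' @slot pixelSize numeric(1), nm per pixel.
#' @exportClass SpotSet
setClass("SpotSet",
  representation(spots = "data.frame", channel = "character",
                 fieldDim = "integer", pixelSize = "numeric"),
  validity = function(object) {
    msg <- NULL
    need <- c("x", "y", "amplitude", "sigma")
    if (!all(need %in% names(object@spots)))
      msg <- c(msg, paste("spots needs columns:", paste(need, collapse = ", ")))
    else if (nrow(object@spots)) {
      if (any(object@spots$x < 0.5 | object@spots$x > object@fieldDim[2] + 0.5) ||
          any(object@spots$y < 0.5 | object@spots$y > object@fieldDim[1] + 0.5))
        msg <- c(msg, "spot positions must lie within the field")
      if (any(object@spots$amplitude <= 0))
        msg <- c(msg, "spot amplitudes must be positive")
    }
    if (length(object@fieldDim) != 2L)
      msg <- c(msg, "fieldDim must have length 2")
    if (is.null(msg)) TRUE else msg
  })

spotSet <- function(spots, channel, fieldDim, pixelSize) {
  new("SpotSet", spots = spots, channel = channel,
      fieldDim = as.integer(fieldDim), pixelSize = pixelSize)
}

#' FieldCount: adjusted spot count for one imaging field
#'
#' Holds the raw (post-lysate) count, the pre-lysate background count and
#' their difference, the adjusted count, for one field of known area.
#' A negative adjusted count is preserved, never clipped.
#'
#' @slot rawCount numeric(1) spots per field after lysate.
#' @slot backgroundCount numeric(1) spots per field before lysate.
#' @slot adjustedCount numeric(1), `rawCount - backgroundCount`.
#' @slot area numeric(1), field area in um^2.
#' @exportClass FieldCount
setClass("FieldCount",
  representation(rawCount = "numeric", backgroundCount = "numeric",
                 adjustedCount = "numeric", area = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!isTRUE(all.equal(object@adjustedCount,
                          object@rawCount - object@backgroundCount)))
      msg <- c(msg, "adjustedCount must equal rawCount - backgroundCount")
    if (object@area <= 0) msg <- c(msg, "area must be positive (um^2)")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Traces and intervals
## ---------------------------------------------------------------------------

#' Trace: per-spot intensity time series
#'
#' Aperture-summed, local-background-subtracted intensity of one spot over
#' the frames of a movie.
#'
#' @slot spotId character(1) identifier.
#' @slot intensity numeric vector, one value per frame (counts).
#' @slot frameInterval numeric(1), seconds per frame.
#' @slot metadata list of optional provenance (e.g. simulation ground truth).
#' @exportClass Trace
setClass("Trace",
  representation(spotId = "character", intensity = "numeric",
                 frameInterval = "numeric", metadata = "list"),
  validity = function(object) {
    msg <- NULL
    if (!length(object@intensity)) msg <- c(msg, "empty intensity vector")
    if (!all(is.finite(object@intensity)))
      msg <- c(msg, "intensities must be finite")
    if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a Trace
#' @param intensity numeric per-frame intensities.
#' @param frameInterval seconds per frame.
#' @param spotId identifier.
#' @param metadata optional list.
#' @return A [Trace-class] object.
#' @export
trace <- function(intensity, frameInterval = 0.1, spotId = "spot",
                  metadata = list()) {
  new("Trace", spotId = spotId, intensity = as.numeric(intensity),
      frameInterval = frameInterval, metadata = metadata)
}

#' IntervalSet: alternating bound/unbound intervals of one spot
#'
#' @slot intervals data.frame with columns `state` ("on"/"off"), `start`,
#'   `end` (seconds) and `censored` (logical: interval touches movie start
#'   or end, so its true duration is unknown).
#' @slot frameInterval numeric(1) seconds per frame.
#' @slot spotId character(1).
#' @slot experiment character(1) experiment label for pooling.
#' @exportClass IntervalSet
setClass("IntervalSet",
  representation(intervals = "data.frame", frameInterval = "numeric",
                 spotId = "character", experiment = "character"),
  validity = function(object) {
    msg <- NULL
    iv <- object@intervals
    need <- c("state", "start", "end", "censored")
    if (!all(need %in% names(iv)))
      msg <- c(msg, paste("intervals needs columns:",
                          paste(need, collapse = ", ")))
    else if (nrow(iv)) {
      if (any(iv$end <= iv$start)) msg <- c(msg, "intervals must have end > start")
      if (nrow(iv) > 1L &&
          any(abs(iv$start[-1L] - iv$end[-nrow(iv)]) > 1e-9))
        msg <- c(msg, "intervals must tile the movie without gaps or overlap")
      if (!all(iv$state %in% c("on", "off")))
        msg <- c(msg, "state must be 'on' or 'off'")
    }
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Photobleaching step fits
## ---------------------------------------------------------------------------

#' StepFit: piecewise-constant photobleaching model of one trace
#'
#' @slot nSteps integer(1): number of downward photobleaching steps, 1-4;
#'   0 means the trace was unclassifiable (non-monotone levels, too few
#'   steps resolved, or final level above background).
#' @slot stepTimes numeric, step times in seconds (length `nSteps`).
#' @slot levels numeric, fitted segment levels (length `nSteps + 1`),
#'   non-increasing for a classified trace.
#' @slot score numeric(1), BIC of the selected model (lower is better).
#' @slot sigma numeric(1), robust per-frame noise estimate.
#' @slot reason character(1), why a trace was left unclassified ("" if
#'   classified).
#' @exportClass StepFit
setClass("StepFit",
  representation(nSteps = "integer", stepTimes = "numeric",
                 levels = "numeric", score = "numeric", sigma = "numeric",
                 reason = "character"))

#' StepDistribution: per-class photobleaching step percentages
#'
#' @slot table data.frame with columns `steps` (1-4), `percent` and, when
#'   per-assay grouping was requested, `sem` across assays.
#' @slot nClassified integer(1) number of classified traces.
#' @slot nUnclassified integer(1) traces excluded from percentages.
#' @slot condition character(1) label.
#' @exportClass StepDistribution
setClass("StepDistribution",
  representation(table = "data.frame", nClassified = "integer",
                 nUnclassified = "integer", condition = "character"),
  validity = function(object) {
    tot <- sum(object@table$percent)
    if (object@nClassified > 0L && abs(tot - 100) > 1e-6)
      "percentages over classified traces must sum to 100" else TRUE
  })

## ---------------------------------------------------------------------------
## Dwell-time kinetics
## ---------------------------------------------------------------------------

#' DwellTimeSet: pooled bound-state dwell times
#'
#' @slot durations numeric, dwell times in seconds (each >= one frame when
#'   frame-discretized).
#' @slot frameInterval numeric(1): seconds per frame used to record the
#'   dwells; 0 means continuous (un-discretized) durations.
#' @slot censored logical, one flag per dwell; `TRUE` marks an interval
#'   that touched the movie start or end (only present when censored
#'   intervals were deliberately retained).
#' @slot source data.frame with one row per dwell (`spot`, `experiment`)
#'   retaining provenance, or 0 rows if unknown.
#' @exportClass DwellTimeSet
setClass("DwellTimeSet",
  representation(durations = "numeric", frameInterval = "numeric",
                 censored = "logical", source = "data.frame"),
  validity = function(object) {
    msg <- NULL
    if (!length(object@durations)) msg <- c(msg, "at least one dwell required")
    if (any(object@durations <= 0)) msg <- c(msg, "durations must be positive")
    if (object@frameInterval < 0) msg <- c(msg, "frameInterval must be >= 0")
    if (object@frameInterval > 0 &&
        any(object@durations < object@frameInterval - 1e-9))
      msg <- c(msg, "durations cannot be shorter than one frame")
    if (length(object@censored) != length(object@durations))
      msg <- c(msg, "censored must have one flag per dwell")
    if (nrow(object@source) &&
        nrow(object@source) != length(object@durations))
      msg <- c(msg, "source must have one row per dwell")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a DwellTimeSet
#' @param durations dwell times (s).
#' @param frameInterval seconds per frame (0 = continuous).
#' @param source optional data.frame (`spot`, `experiment`), one row per dwell.
#' @param censored optional logical flags, one per dwell (default: all
#'   uncensored).
#' @return A [DwellTimeSet-class] object.
#' @export
dwellTimeSet <- function(durations, frameInterval = 0,
                         source = data.frame(), censored = NULL) {
  if (is.null(censored)) censored <- rep(FALSE, length(durations))
  new("DwellTimeSet", durations = as.numeric(durations),
      frameInterval = frameInterval, censored = censored, source = source)
}

#' ExpFit: exponential dwell-time fit
#'
#' Maximum-likelihood fit of a single, uncensored exponential decay to a
#' set of dwell times: the dissociation rate constant with its standard
#' error and 95% confidence interval.
#'
#' @slot kOff numeric(1) dissociation rate, 1/s.
#' @slot se numeric(1) standard error of `kOff`, 1/s.
#' @slot ci95 numeric(2) 95% confidence interval (log-scale Wald), 1/s.
#' @slot logLik numeric(1) maximized log-likelihood.
#' @slot n integer(1) number of dwells.
#' @slot frameInterval numeric(1) discretization used (0 = continuous).
#' @slot method character(1) likelihood used: "continuous" or
#'   "frame-discretized".
#' @exportClass ExpFit
setClass("ExpFit",
  representation(kOff = "numeric", se = "numeric", ci95 = "numeric",
                 logLik = "numeric", n = "integer",
                 frameInterval = "numeric", method = "character"),
  validity = function(object) {
    msg <- NULL
    if (object@kOff <= 0) msg <- c(msg, "kOff must be positive")
    if (length(object@ci95) != 2L ||
        object@ci95[1] > object@kOff || object@ci95[2] < object@kOff)
      msg <- c(msg, "confidence interval must contain the estimate")
    if (is.null(msg)) TRUE else msg
  })

#' LRTResult: likelihood-ratio comparison of two dissociation rates
#'
#' @slot statistic numeric(1) LRT statistic, >= 0.
#' @slot df integer(1) degrees of freedom (1).
#' @slot pValue numeric(1) upper-tail chi-square p-value.
#' @slot rateA,rateB numeric(1) separate ML rates (1/s).
#' @slot ratePooled numeric(1) pooled (null) ML rate (1/s).
#' @exportClass LRTResult
setClass("LRTResult",
  representation(statistic = "numeric", df = "integer", pValue = "numeric",
                 rateA = "numeric", rateB = "numeric", ratePooled = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@statistic < -1e-8) msg <- c(msg, "statistic must be >= 0")
    if (object@pValue <= 0 || object@pValue > 1)
      msg <- c(msg, "p-value must be in (0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' RebindSummary: fraction of spots showing rebinding
#'
#' A spot "displays rebinding" when its movie contains two or more distinct
#' bound intervals (dissociation followed by renewed binding).
#'
#' @slot percent numeric(1) overall percentage of spots with rebinding.
#' @slot nSpots integer(1) spots considered.
#' @slot perExperiment data.frame (`experiment`, `percent`, `nSpots`).
#' @slot mean,sem numeric(1) mean and SEM of per-experiment percentages
#'   (`NA` when fewer than 2 experiments).
#' @exportClass RebindSummary
setClass("RebindSummary",
  representation(percent = "numeric", nSpots = "integer",
                 perExperiment = "data.frame", mean = "numeric",
                 sem = "numeric"),
  validity = function(object) {
    if (object@percent < 0 || object@percent > 100)
      "percent must be in [0, 100]" else TRUE
  })

## ---------------------------------------------------------------------------
## Binding calls
## ---------------------------------------------------------------------------

#' BindingThreshold: mean + 2 SD nonbinder threshold
#'
#' @slot value numeric(1): adjusted spots per field; equals
#'   `meanCount + 2 * sdCount`.
#' @slot meanCount,sdCount numeric(1) mean and sample SD of the pooled
#'   nonbinder adjusted counts.
#' @slot n integer(1) number of nonbinder assays pooled.
#' @exportClass BindingThreshold
setClass("BindingThreshold",
  representation(value = "numeric", meanCount = "numeric",
                 sdCount = "numeric", n = "integer"),
  validity = function(object) {
    if (!isTRUE(all.equal(object@value,
                          object@meanCount + 2 * object@sdCount)))
      "value must equal meanCount + 2 * sdCount" else TRUE
  })

#' BindingCall: binary binding decision for one protein-lipid pair
#'
#' @slot label character(1) pair label, e.g. `"AKT-PH / PI(3,4,5)P3"`.
#' @slot assayMeans numeric, per-assay mean adjusted counts (>= 3 assays).
#' @slot threshold numeric(1) threshold value used.
#' @slot tStat numeric(1) one-sample t statistic against the threshold.
#' @slot df numeric(1) degrees of freedom.
#' @slot pValue numeric(1) one-tailed (upper) p-value.
#' @slot bound logical(1): `TRUE` iff the mean exceeds the threshold AND
#'   p < 0.05.
#' @exportClass BindingCall
setClass("BindingCall",
  representation(label = "character", assayMeans = "numeric",
                 threshold = "numeric", tStat = "numeric", df = "numeric",
                 pValue = "numeric", bound = "logical"),
  validity = function(object) {
    ok <- mean(object@assayMeans) > object@threshold && object@pValue < 0.05
    if (!identical(object@bound, ok))
      "call must be bound iff mean > threshold and p < 0.05" else TRUE
  })

## ---------------------------------------------------------------------------
## Stoichiometry specifications
## ---------------------------------------------------------------------------

#' DiscSpec: lipid composition and geometry of a Nanodisc
#'
#' @slot lipidsPerLeaflet numeric(1) total lipids per leaflet (~80 for an
#'   MSP1D1 disc).
#' @slot anionicFraction numeric(1) mole fraction of anionic lipid (e.g.
#'   DMPS) in \[0, 1\].
#' @slot pipFraction numeric(1) mole fraction of phosphoinositide in \[0, 1\].
#' @slot areaPerLipid numeric(1) nm^2 per lipid headgroup.
#' @slot leaflets numeric(1) number of leaflets (2 for a bilayer disc).
#' @exportClass DiscSpec
setClass("DiscSpec",
  representation(lipidsPerLeaflet = "numeric", anionicFraction = "numeric",
                 pipFraction = "numeric", areaPerLipid = "numeric",
                 leaflets = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@lipidsPerLeaflet < 1) msg <- c(msg, "lipidsPerLeaflet must be >= 1")
    if (object@anionicFraction < 0 || object@anionicFraction > 1)
      msg <- c(msg, "anionicFraction must be in [0, 1]")
    if (object@pipFraction < 0 || object@pipFraction > 1)
      msg <- c(msg, "pipFraction must be in [0, 1]")
    if (object@anionicFraction + object@pipFraction > 1)
      msg <- c(msg, "anionicFraction + pipFraction must be <= 1")
    if (object@areaPerLipid <= 0) msg <- c(msg, "areaPerLipid must be > 0")
    if (object@leaflets < 1) msg <- c(msg, "leaflets must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' VesicleSpec: geometry and composition of a small unilamellar vesicle
#'
#' @slot diameter numeric(1) outer diameter, nm.
#' @slot areaPerLipid numeric(1) nm^2 per lipid headgroup.
#' @slot pipFraction numeric(1) phosphoinositide mole fraction in \[0, 1\].
#' @exportClass VesicleSpec
setClass("VesicleSpec",
  representation(diameter = "numeric", areaPerLipid = "numeric",
                 pipFraction = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@diameter <= 0) msg <- c(msg, "diameter must be positive (nm)")
    if (object@areaPerLipid <= 0) msg <- c(msg, "areaPerLipid must be > 0")
    if (object@pipFraction < 0 || object@pipFraction > 1)
      msg <- c(msg, "pipFraction must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' MassModel: mass inventory of a dye-labelled Nanodisc
#'
#' @slot nDye,nScaffold,nLipids numeric(1) molecule counts (>= 0).
#' @slot dyeMw,scaffoldMw,lipidMw numeric(1) molecular weights, Da (> 0).
#' @exportClass MassModel
setClass("MassModel",
  representation(nDye = "numeric", dyeMw = "numeric", nScaffold = "numeric",
                 scaffoldMw = "numeric", nLipids = "numeric",
                 lipidMw = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@nDye, object@nScaffold, object@nLipids) < 0))
      msg <- c(msg, "counts must be >= 0")
    if (any(c(object@dyeMw, object@scaffoldMw, object@lipidMw) <= 0))
      msg <- c(msg, "molecular weights must be positive (Da)")
    if (object@nScaffold + object@nLipids == 0)
      msg <- c(msg, "a disc must contain scaffold or lipid mass")
    if (is.null(msg)) TRUE else msg
  })

## ---------------------------------------------------------------------------
## Simulation configuration and ground truth
## ---------------------------------------------------------------------------

#' ImagingModel: camera and optics parameters of the simulator
#'
#' @slot pixelSize numeric(1) nm per pixel.
#' @slot fieldEdge integer(1) field edge in pixels (square field).
#' @slot psfSigma numeric(1) Gaussian PSF width, pixels.
#' @slot frameInterval numeric(1) seconds per frame.
#' @slot cameraGain numeric(1) counts per photoelectron.
#' @slot readNoiseSd numeric(1) Gaussian read noise SD, counts.
#' @slot baselineOffset numeric(1) constant camera offset, counts.
#' @slot photonsPerFluor numeric(1) detected photons per fluorophore per
#'   frame.
#' @slot shotNoise logical(1) apply Poisson shot noise.
#' @exportClass ImagingModel
setClass("ImagingModel",
  representation(pixelSize = "numeric", fieldEdge = "integer",
                 psfSigma = "numeric", frameInterval = "numeric",
                 cameraGain = "numeric", readNoiseSd = "numeric",
                 baselineOffset = "numeric", photonsPerFluor = "numeric",
                 shotNoise = "logical"),
  validity = function(object) {
    msg <- NULL
    if (object@psfSigma <= 0) msg <- c(msg, "psfSigma must be > 0")
    if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
    if (object@fieldEdge < 8L) msg <- c(msg, "fieldEdge must be >= 8 pixels")
    if (object@readNoiseSd < 0) msg <- c(msg, "readNoiseSd must be >= 0")
    if (object@photonsPerFluor <= 0) msg <- c(msg, "photonsPerFluor must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' KineticsConfig: binding and bleaching rates of the simulator
#'
#' @slot kOff numeric(1) dissociation rate, 1/s.
#' @slot kOnPseudo numeric(1) per-disc pseudo-first-order rebinding rate at
#'   the fixed lysate concentration, 1/s.
#' @slot stableFraction numeric(1) fraction of binders that never dissociate
#'   within the movie.
#' @slot bleachRate numeric(1) per-fluorophore photobleaching rate under
#'   excitation, 1/s.
#' @slot fluorsPerBinder integer(1) fluorophores per bound protein
#'   (1 monomer, 2 dimer).
#' @slot dyesPerDisc integer(1) DiD dyes per Nanodisc (2 under the standard
#'   labelling).
#' @exportClass KineticsConfig
setClass("KineticsConfig",
  representation(kOff = "numeric", kOnPseudo = "numeric",
                 stableFraction = "numeric", bleachRate = "numeric",
                 fluorsPerBinder = "integer", dyesPerDisc = "integer"),
  validity = function(object) {
    msg <- NULL
    if (any(c(object@kOff, object@kOnPseudo, object@bleachRate) < 0))
      msg <- c(msg, "rates must be >= 0")
    if (object@stableFraction < 0 || object@stableFraction > 1)
      msg <- c(msg, "stableFraction must be in [0, 1]")
    if (object@fluorsPerBinder < 1L) msg <- c(msg, "fluorsPerBinder must be >= 1")
    if (object@dyesPerDisc < 1L) msg <- c(msg, "dyesPerDisc must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' SimConfig: full configuration of one simulated field
#'
#' @slot imaging an [ImagingModel-class].
#' @slot kinetics a [KineticsConfig-class].
#' @slot discDensity numeric(1) Nanodiscs per field.
#' @slot binderOccupancy numeric(1) fraction of discs visited by a binder.
#' @slot nonspecificDensity numeric(1) protein-channel spots per field not
#'   on discs (surface-stuck molecules).
#' @slot nFrames integer(1) protein-channel movie length, frames.
#' @slot discFrames integer(1) disc-channel movie length, frames (the disc
#'   channel is acquired first and briefly).
#' @slot minSeparation numeric(1) minimum spot separation, pixels.
#' @slot rngSeed numeric(1) seed (NA = leave RNG state alone).
#' @exportClass SimConfig
setClass("SimConfig",
  representation(imaging = "ImagingModel", kinetics = "KineticsConfig",
                 discDensity = "numeric", binderOccupancy = "numeric",
                 nonspecificDensity = "numeric", nFrames = "integer",
                 discFrames = "integer", minSeparation = "numeric",
                 rngSeed = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@discDensity < 0 || object@nonspecificDensity < 0)
      msg <- c(msg, "densities must be >= 0")
    if (object@binderOccupancy < 0 || object@binderOccupancy > 1)
      msg <- c(msg, "binderOccupancy must be in [0, 1]")
    if (object@nFrames < 1L || object@discFrames < 1L)
      msg <- c(msg, "movies need at least one frame")
    if (object@minSeparation < 0) msg <- c(msg, "minSeparation must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' GroundTruth: generative truth of one simulated field
#'
#' @slot discPositions data.frame (`spot`, `x`, `y`): subpixel disc
#'   positions.
#' @slot bindingIntervals data.frame (`spot`, `start`, `end`,
#'   `visibleEnd`): true binding intervals in seconds; `visibleEnd` may
#'   precede `end` when the fluorophore bleaches while bound.
#' @slot discFluors data.frame (`spot`, `bleachTime`): per-dye bleach times
#'   in the disc channel.
#' @slot nonspecificPositions data.frame (`x`, `y`, `bleachTime`).
#' @slot movieLength numeric(1) protein-channel movie length, seconds.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(discPositions = "data.frame",
                 bindingIntervals = "data.frame",
                 discFluors = "data.frame",
                 nonspecificPositions = "data.frame",
                 movieLength = "numeric"),
  validity = function(object) {
    bi <- object@bindingIntervals
    msg <- NULL
    if (nrow(bi)) {
      if (any(bi$start < -1e-9) || any(bi$end > object@movieLength + 1e-9))
        msg <- c(msg, "binding intervals must lie within the movie")
      ## single-molecule regime: one binder at a time per disc
      bad <- vapply(split(bi, bi$spot), function(d) {
        d <- d[order(d$start), , drop = FALSE]
        nrow(d) > 1L && any(d$start[-1L] < d$end[-nrow(d)] - 1e-9)
      }, logical(1))
      if (any(bad))
        msg <- c(msg, "a disc cannot carry two simultaneous binders")
    }
    if (is.null(msg)) TRUE else msg
  })
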