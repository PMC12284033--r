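## Forward model: two-channel TIRF movies of surface-tethered Nanodiscs
## with transiently binding fluorescent proteins, plus stand-alone
## generators for dwell-time samples and photobleaching traces. Every
## simulated object carries its full ground truth so downstream stages can
## be tested against known answers.

#' Imaging model for the simulator
#'
#' Defaults describe a typical single-molecule TIRF setup: 100x objective
#' with a 16-um-pixel EMCCD giving 160 nm/pixel, a 250 x 250 px field
#' (1,600 um^2), 10 frames/s, and an EMCCD modelled as Poisson shot noise
#' -> gain -> Gaussian read noise -> constant offset (the EM excess-noise
#' factor is omitted).
#'
#' @param pixelSize nm per pixel.
#' @param fieldEdge field edge, pixels (square field).
#' @param psfSigma Gaussian PSF width, pixels.
#' @param frameInterval seconds per frame.
#' @param cameraGain counts per photoelectron.
#' @param readNoiseSd Gaussian read noise SD, counts.
#' @param baselineOffset constant camera offset, counts.
#' @param photonsPerFluor detected photons per fluorophore per frame;
#'   the default puts a single fluorophore at peak-pixel SNR ~11 against
#'   the read noise.
#' @param shotNoise logical, apply Poisson shot noise.
#' @return An [ImagingModel-class].
#' @export
imagingModel <- function(pixelSize = 160, fieldEdge = 250, psfSigma = 1.0,
                         frameInterval = 0.1, cameraGain = 1,
                         readNoiseSd = 8, baselineOffset = 100,
                         photonsPerFluor = 600, shotNoise = TRUE) {
  new("ImagingModel", pixelSize = pixelSize,
      fieldEdge = as.integer(fieldEdge), psfSigma = psfSigma,
      frameInterval = frameInterval, cameraGain = cameraGain,
      readNoiseSd = readNoiseSd, baselineOffset = baselineOffset,
      photonsPerFluor = photonsPerFluor, shotNoise = shotNoise)
}

#' Kinetic model for the simulator
#'
#' Binding at each occupied disc is an alternating renewal process:
#' unbound waits are exponential with rate `kOnPseudo` (pseudo-first-order
#' at the fixed lysate concentration), bound dwells exponential with rate
#' `kOff`. A `stableFraction` of binders never dissociates within the
#' movie. Each bound protein carries `fluorsPerBinder` fluorophores
#' (1 monomer, 2 dimer); each disc carries `dyesPerDisc` DiD dyes.
#'
#' @param kOff dissociation rate, 1/s.
#' @param kOnPseudo per-disc rebinding rate, 1/s; 0 means occupied discs
#'   are bound from the movie start (pre-equilibrated stable binding).
#' @param stableFraction fraction of binders with no dissociation.
#' @param bleachRate per-fluorophore photobleaching rate, 1/s.
#' @param fluorsPerBinder fluorophores per bound protein.
#' @param dyesPerDisc DiD dyes per disc.
#' @return A [KineticsConfig-class].
#' @export
kineticsConfig <- function(kOff = 0.55, kOnPseudo = 0.2,
                           stableFraction = 0, bleachRate = 0.05,
                           fluorsPerBinder = 1, dyesPerDisc = 2) {
  new("KineticsConfig", kOff = kOff, kOnPseudo = kOnPseudo,
      stableFraction = stableFraction, bleachRate = bleachRate,
      fluorsPerBinder = as.integer(fluorsPerBinder),
      dyesPerDisc = as.integer(dyesPerDisc))
}

#' Full simulation configuration
#'
#' Defaults emulate the standard assay geometry: ~700 discs per
#' 1,600 um^2 field, a short 20-frame disc-channel acquisition followed by
#' a 35-s (350-frame) protein-channel movie at 10 frames/s.
#'
#' @param imaging an [ImagingModel-class].
#' @param kinetics a [KineticsConfig-class].
#' @param discDensity discs per field.
#' @param binderOccupancy fraction of discs visited by a binder.
#' @param nonspecificDensity protein-channel spots per field that are not
#'   on discs.
#' @param nFrames protein-channel frames.
#' @param discFrames disc-channel frames.
#' @param minSeparation minimum spot separation, pixels.
#' @param rngSeed integer seed (NA = use current RNG state).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(imaging = imagingModel(), kinetics = kineticsConfig(),
                      discDensity = 700, binderOccupancy = 0.7,
                      nonspecificDensity = 30, nFrames = 350,
                      discFrames = 20, minSeparation = 4, rngSeed = NA) {
  new("SimConfig", imaging = imaging, kinetics = kinetics,
      discDensity = discDensity, binderOccupancy = binderOccupancy,
      nonspecificDensity = nonspecificDensity,
      nFrames = as.integer(nFrames), discFrames = as.integer(discFrames),
      minSeparation = minSeparation, rngSeed = as.numeric(rngSeed))
}

## Uniform positions with a minimum pairwise separation, by rejection.
samplePositions <- function(n, edge, minSep) {
  if (n == 0L) return(data.frame(x = numeric(), y = numeric()))
  if (n * pi * (minSep / 2)^2 > 0.7 * edge^2)
    stop("field too small for ", n, " spots at minimum separation ",
         minSep, " px")
  x <- numeric(n); y <- numeric(n)
  kept <- 0L
  tries <- 0L
  maxTries <- 500L * n
  while (kept < n) {
    if ((tries <- tries + 1L) > maxTries)
      stop("could not place ", n, " spots at minimum separation ", minSep,
           " px")
    cx <- runif(1, 0.5, edge + 0.5)
    cy <- runif(1, 0.5, edge + 0.5)
    if (kept == 0L ||
        min((x[seq_len(kept)] - cx)^2 + (y[seq_len(kept)] - cy)^2) >=
          minSep^2) {
      kept <- kept + 1L
      x[kept] <- cx; y[kept] <- cy
    }
  }
  data.frame(x = x, y = y)
}

## Linear indices and values of one emitter's photon contribution to an
## H x W x T array. Frames with zero flux are skipped; the caller adds the
## values in place (arr[idx] <- arr[idx] + vals) to avoid copying the
## whole stack per emitter.
emitterContribution <- function(x, y, sigma, flux, dims) {
  H <- dims[1]; W <- dims[2]; T <- dims[3]
  flux <- rep_len(flux, T)
  fr <- which(flux > 0)
  if (!length(fr)) return(NULL)
  rows <- max(1L, floor(y - 5 * sigma)):min(H, ceiling(y + 5 * sigma))
  cols <- max(1L, floor(x - 5 * sigma)):min(W, ceiling(x + 5 * sigma))
  patch <- psfPatch(x, y, sigma, rows, cols)
  base <- outer(rows, (cols - 1L) * H, "+")
  list(idx = as.vector(outer(as.vector(base), (fr - 1L) * (H * W), "+")),
       vals = as.vector(outer(as.vector(patch), flux[fr])))
}

## Fraction of each frame (1..T, interval dt) overlapped by [a, b).
frameOverlap <- function(a, b, T, dt) {
  f <- seq_len(T)
  lo <- (f - 1) * dt
  hi <- f * dt
  pmax(0, pmin(hi, b) - pmax(lo, a)) / dt
}

## Camera model: photons -> Poisson -> gain -> read noise -> offset.
applyCamera <- function(phot, im) {
  counts <- if (im@shotNoise)
    array(rpois(length(phot), phot), dim(phot)) else phot
  counts <- counts * im@cameraGain
  if (im@readNoiseSd > 0)
    counts <- counts + array(rnorm(length(phot), 0, im@readNoiseSd),
                             dim(phot))
  counts + im@baselineOffset
}

#' Simulate one two-channel field
#'
#' Generates the disc-channel movie (static DiD spots with stepwise
#' bleaching), the protein-channel movie (spots lighting up during bound
#' intervals, plus surface-stuck nonspecific spots), and the complete
#' ground truth. Each occupied disc hosts at most one binder at a time
#' (single-molecule regime); each bound interval represents a fresh
#' molecule with fresh fluorophores. Pixel formation is Gaussian-PSF
#' photon integration, then Poisson shot noise, camera gain, Gaussian read
#' noise and a constant offset. Identical seeds give identical output.
#'
#' @param config a [SimConfig-class].
#' @param channels which channels to render (subset of
#'   `c("disc", "protein")`); ground truth is always complete.
#' @return A list with elements `disc` and `protein`
#'   ([MovieStack-class] or `NULL` when not rendered) and `truth`
#'   (a [GroundTruth-class]).
#' @examples
#' cfg <- simConfig(imaging = imagingModel(fieldEdge = 64),
#'                  discDensity = 20, nFrames = 20, rngSeed = 1)
#' field <- simulateField(cfg)
#' field$truth
#' @export
simulateField <- function(config, channels = c("disc", "protein")) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(config@rngSeed, {
    im <- config@imaging
    kin <- config@kinetics
    edge <- im@fieldEdge
    dt <- im@frameInterval
    Tp <- config@nFrames
    Td <- config@discFrames
    movieLen <- Tp * dt

    nDisc <- as.integer(round(config@discDensity))
    nNon <- as.integer(round(config@nonspecificDensity))
    pos <- samplePositions(nDisc + nNon, edge, config@minSeparation)
    discPos <- if (nDisc)
      data.frame(spot = seq_len(nDisc), x = pos$x[seq_len(nDisc)],
                 y = pos$y[seq_len(nDisc)])
      else data.frame(spot = integer(), x = numeric(), y = numeric())
    nonPos <- pos[nDisc + seq_len(nNon), , drop = FALSE]

    ## disc-channel dyes and their bleach times
    discFluors <- if (nDisc)
      data.frame(spot = rep(seq_len(nDisc), each = kin@dyesPerDisc),
                 bleachTime = if (kin@bleachRate > 0)
                   rexp(nDisc * kin@dyesPerDisc, kin@bleachRate)
                 else rep(Inf, nDisc * kin@dyesPerDisc))
      else data.frame(spot = integer(), bleachTime = numeric())

    ## binding intervals per occupied disc (alternating renewal)
    bindRows <- list()
    if (nDisc) {
      occupied <- which(runif(nDisc) < config@binderOccupancy)
      for (s in occupied) {
        stable <- runif(1) < kin@stableFraction
        t0 <- 0
        repeat {
          start <- if (kin@kOnPseudo > 0) t0 + rexp(1, kin@kOnPseudo) else t0
          if (start >= movieLen) break
          dwell <- if (stable || kin@kOff == 0) Inf else rexp(1, kin@kOff)
          end <- min(start + dwell, movieLen)
          bleach <- if (kin@bleachRate > 0)
            max(rexp(kin@fluorsPerBinder, kin@bleachRate)) else Inf
          visibleEnd <- min(start + bleach, end)
          bindRows[[length(bindRows) + 1L]] <-
            data.frame(spot = s, start = start, end = end,
                       visibleEnd = visibleEnd)
          if (!is.finite(dwell)) break
          t0 <- start + dwell
          if (t0 >= movieLen) break
          if (kin@kOnPseudo == 0) break
        }
      }
    }
    bindingIntervals <- if (length(bindRows)) do.call(rbind, bindRows)
      else data.frame(spot = integer(), start = numeric(), end = numeric(),
                      visibleEnd = numeric())

    nonspecific <- if (nNon)
      data.frame(x = nonPos$x, y = nonPos$y,
                 bleachTime = if (kin@bleachRate > 0)
                   rexp(nNon, kin@bleachRate) else rep(Inf, nNon))
      else data.frame(x = numeric(), y = numeric(), bleachTime = numeric())

    truth <- new("GroundTruth", discPositions = discPos,
                 bindingIntervals = bindingIntervals,
                 discFluors = discFluors,
                 nonspecificPositions = nonspecific,
                 movieLength = movieLen)

    discStack <- NULL
    if ("disc" %in% channels) {
      dims <- c(edge, edge, Td)
      phot <- array(0, dims)
      for (s in seq_len(nDisc)) {
        bt <- discFluors$bleachTime[discFluors$spot == s]
        ## each dye is alive from 0 until its bleach time
        flux <- im@photonsPerFluor *
          Reduce(`+`, lapply(bt, function(b) frameOverlap(0, b, Td, dt)))
        ct <- emitterContribution(discPos$x[s], discPos$y[s],
                                  im@psfSigma, flux, dims)
        if (!is.null(ct)) phot[ct$idx] <- phot[ct$idx] + ct$vals
      }
      discStack <- movieStack(applyCamera(phot, im), im@pixelSize, dt,
                              "disc")
    }

    protStack <- NULL
    if ("protein" %in% channels) {
      dims <- c(edge, edge, Tp)
      phot <- array(0, dims)
      if (nrow(bindingIntervals)) {
        perFluor <- im@photonsPerFluor
        for (i in seq_len(nrow(bindingIntervals))) {
          b <- bindingIntervals[i, ]
          ## all fluorophores of the binder share the interval; bleaching
          ## of individual fluorophores within the interval is resolved at
          ## the step level only for the longest-lived one (visibleEnd)
          flux <- perFluor * kin@fluorsPerBinder *
            frameOverlap(b$start, b$visibleEnd, Tp, dt)
          ct <- emitterContribution(discPos$x[b$spot], discPos$y[b$spot],
                                    im@psfSigma, flux, dims)
          if (!is.null(ct)) phot[ct$idx] <- phot[ct$idx] + ct$vals
        }
      }
      for (i in seq_len(nrow(nonspecific))) {
        flux <- im@photonsPerFluor *
          frameOverlap(0, nonspecific$bleachTime[i], Tp, dt)
        ct <- emitterContribution(nonspecific$x[i], nonspecific$y[i],
                                  im@psfSigma, flux, dims)
        if (!is.null(ct)) phot[ct$idx] <- phot[ct$idx] + ct$vals
      }
      protStack <- movieStack(applyCamera(phot, im), im@pixelSize, dt,
                              "protein")
    }

    list(disc = discStack, protein = protStack, truth = truth)
  })
}

#' Simulate a set of dwell times
#'
#' Draws `n` bound-state durations from an exponential law with rate
#' `kOff`, then discretizes them to integer multiples of the frame
#' interval by the ceiling rule (an event shorter than one frame is
#' recorded as one frame), matching how dwell times are read off a movie.
#' `frameInterval = 0` keeps the continuous durations.
#'
#' @param kOff dissociation rate, 1/s (> 0).
#' @param n number of dwells (>= 1).
#' @param frameInterval seconds per frame; 0 for continuous durations.
#' @param rngSeed integer seed (NA = use current RNG state).
#' @return A [DwellTimeSet-class].
#' @examples
#' d <- simulateDwellTimes(0.5, 1000, frameInterval = 0.1, rngSeed = 1)
#' mean(durations(d))  # ~ 1/0.5 + discretization
#' @export
simulateDwellTimes <- function(kOff, n, frameInterval = 0, rngSeed = NA) {
  if (kOff <= 0) stop("kOff must be positive")
  if (n < 1) stop("n must be >= 1")
  withSeed(rngSeed, {
    t <- rexp(n, kOff)
    if (frameInterval > 0) t <- pmax(ceiling(t / frameInterval), 1) *
        frameInterval
    dwellTimeSet(t, frameInterval = frameInterval)
  })
}

#' Simulate a photobleaching trace
#'
#' A spot carrying `nFluors` fluorophores (1-4) loses them one at a time
#' at independent exponential times, producing a descending
#' piecewise-constant intensity trace, optionally with Gaussian noise.
#' A fluorophore contributes to a frame when it is still fluorescent at
#' the frame midpoint, so the noiseless trace is exactly piecewise
#' constant. The returned trace's `metadata` holds the ground truth:
#' `bleachTimes` (s) and `visibleSteps`, the number of distinct downward
#' transitions actually present in the noiseless trace (bleach events in
#' the same frame merge; events after the movie end are not visible).
#'
#' @param nFluors fluorophores on the spot, 1-4.
#' @param bleachRate per-fluorophore bleach rate, 1/s (> 0).
#' @param levelPerFluor intensity per fluorophore, counts.
#' @param nFrames movie length, frames.
#' @param frameInterval seconds per frame.
#' @param noiseSd Gaussian noise SD, counts.
#' @param rngSeed integer seed (NA = use current RNG state).
#' @return A [Trace-class] with ground truth in `metadata`.
#' @examples
#' tr <- simulateBleachTrace(2, 0.2, nFrames = 200, rngSeed = 1)
#' tr@metadata$visibleSteps
#' @export
simulateBleachTrace <- function(nFluors, bleachRate, levelPerFluor = 100,
                                nFrames = 400, frameInterval = 0.1,
                                noiseSd = 0, rngSeed = NA) {
  if (nFluors < 1 || nFluors > 4)
    stop("nFluors must be between 1 and 4 (the classification range)")
  if (bleachRate <= 0) stop("bleachRate must be positive")
  withSeed(rngSeed, {
    bleach <- rexp(nFluors, bleachRate)
    mids <- (seq_len(nFrames) - 0.5) * frameInterval
    level <- levelPerFluor *
      colSums(outer(bleach, mids, ">"))
    visibleSteps <- sum(diff(level) < 0)
    y <- level
    if (noiseSd > 0) y <- y + rnorm(nFrames, 0, noiseSd)
    trace(y, frameInterval, spotId = "simulated",
          metadata = list(bleachTimes = sort(bleach),
                          nFluors = as.integer(nFluors),
                          visibleSteps = as.integer(visibleSteps),
                          levelPerFluor = levelPerFluor,
                          noiseSd = noiseSd))
  })
}

#' Simulate a panel of nonbinder assay counts
#'
#' Adjusted (background-subtracted) spot counts of nonbinding
#' protein-lipid pairs, modelled as Gaussian around a nonspecific mean.
#' The defaults (mean 40, SD 20 adjusted spots per 1,600 um^2 field) are
#' consistent with a mean + 2 SD detection threshold of 80.
#'
#' @param nAssays number of assays.
#' @param meanCount mean adjusted count per assay.
#' @param sdCount SD of adjusted counts across assays.
#' @param rngSeed integer seed (NA = use current RNG state).
#' @return Numeric vector of adjusted counts (may be negative, as real
#'   adjusted counts can be).
#' @export
simulateNonbinderPanel <- function(nAssays, meanCount = 40, sdCount = 20,
                                   rngSeed = NA) {
  if (nAssays < 1) stop("nAssays must be >= 1")
  withSeed(rngSeed, rnorm(nAssays, meanCount, sdCount))
}
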