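## Independent oracles used across tests.

## Grid-search argmax of the exponential dwell log-likelihood, independent
## of the closed form: three zoom stages of a dense multiplicative grid.
gridSearchRate <- function(durations, nGrid = 2001) {
  logl <- function(k) length(durations) * log(k) - k * sum(durations)
  lo <- 0.01 / mean(durations)
  hi <- 100 / mean(durations)
  for (stage in 1:3) {
    ks <- exp(seq(log(lo), log(hi), length.out = nGrid))
    best <- ks[which.max(logl(ks))]
    span <- (log(hi) - log(lo)) / (nGrid - 1)
    lo <- exp(log(best) - 2 * span)
    hi <- exp(log(best) + 2 * span)
  }
  best
}

## Closed-form log-likelihood of an exponential sample at its MLE.
expLogLikAtMLE <- function(n, sumT) n * log(n / sumT) - n

## Build a noiseless square-wave trace: value `level` on the given frame
## ranges (1-based, inclusive), 0 elsewhere.
squareTrace <- function(nFrames, onRanges, level = 100, dt = 0.1) {
  y <- numeric(nFrames)
  for (r in onRanges) y[r[1]:r[2]] <- level
  trace(y, frameInterval = dt)
}

## A tiny simulated field configuration used by several tests.
smallFieldConfig <- function(seed, nDiscs = 50, edge = 128, nFrames = 20,
                             kinetics = kineticsConfig(bleachRate = 0),
                             nonspecific = 0) {
  simConfig(imaging = imagingModel(fieldEdge = edge),
            kinetics = kinetics, discDensity = nDiscs,
            binderOccupancy = 0, nonspecificDensity = nonspecific,
            nFrames = nFrames, discFrames = nFrames, rngSeed = seed)
}
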