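## Photobleaching step counting.
##
## Each trace from a static spot is fitted with piecewise-constant models
## of 0..maxSteps downward steps. The change points for each model order
## are found by exact dynamic programming (globally optimal segmented
## least squares; see src/segment_dp.cpp) and the order is selected by
## BIC on Gaussian residuals. Photobleaching only goes down, so a
## selected model with an upward step, a step below the noise floor, or a
## final level above background disqualifies the trace.

#' Fit photobleaching steps to a trace
#'
#' @param trc a [Trace-class] from a static (disc or stably bound) spot.
#' @param maxSteps maximum number of steps considered (default 4, the
#'   classification range).
#' @param minStepSigma minimum step height, in units of the robust
#'   per-frame noise SD, for a step to count as real (default 2).
#' @param baselineTol tolerance, in noise SDs, for "final level is at
#'   background" (default 3).
#' @return A [StepFit-class]; `nSteps` is 0 with a `reason` when the trace
#'   is unclassifiable.
#' @examples
#' tr <- simulateBleachTrace(3, 0.2, noiseSd = 20, rngSeed = 2)
#' fitSteps(tr)
#' @export
fitSteps <- function(trc, maxSteps = 4, minStepSigma = 2,
                     baselineTol = 3) {
  stopifnot(is(trc, "Trace"))
  if (maxSteps < 1 || maxSteps > 4)
    stop("maxSteps must be between 1 and 4")
  y <- intensity(trc)
  n <- length(y)
  if (n < 2 * (maxSteps + 1))
    stop("trace too short to resolve ", maxSteps, " steps")
  dt <- frameInterval(trc)

  sigma <- mad(diff(y)) / sqrt(2)
  dp <- .segmentDP(y, as.integer(maxSteps))
  rss <- pmax(dp$rss, n * (1e-8 * max(abs(y), 1))^2)
  bic <- n * log(rss / n) + (2 * (0:maxSteps) + 1) * log(n)

  segLevels <- function(cps) {
    bounds <- c(0L, cps, n)
    vapply(seq_len(length(cps) + 1L), function(i)
      mean(y[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  }
  tolBase <- max(baselineTol * sigma, 1e-8 * max(abs(y), 1))
  ## why a candidate model is inadmissible as a photobleaching staircase
  violation <- function(levels) {
    if (length(levels) == 1L) return("")
    drops <- -diff(levels)
    if (any(drops <= 0)) return("non-monotone levels (upward step)")
    if (any(drops < minStepSigma * sigma)) return("step below noise floor")
    if (abs(levels[length(levels)]) > tolBase)
      return("final level above background")
    ""
  }

  ## model selection over the admissible class: the best-BIC
  ## piecewise-constant model whose steps all go down by more than the
  ## noise floor and that ends at background
  lv <- lapply(dp$changepoints, segLevels)
  bad <- vapply(lv, violation, character(1))
  admissible <- which(bad == "")
  if (!length(admissible)) {
    kBest <- which.min(bic)
    return(new("StepFit", nSteps = 0L, stepTimes = numeric(),
               levels = lv[[kBest]], score = bic[kBest], sigma = sigma,
               reason = bad[kBest]))
  }
  kBest <- admissible[which.min(bic[admissible])]  # index = k + 1
  k <- kBest - 1L
  if (k == 0L) {
    ## flat is the best admissible model; if an inadmissible step model
    ## fits decisively better, report its violation instead
    reason <- if (which.min(bic) > 1L) bad[which.min(bic)]
              else "no step detected"
    return(new("StepFit", nSteps = 0L, stepTimes = numeric(),
               levels = lv[[1L]], score = bic[1L], sigma = sigma,
               reason = reason))
  }
  new("StepFit", nSteps = k, stepTimes = dp$changepoints[[kBest]] * dt,
      levels = lv[[kBest]], score = bic[kBest], sigma = sigma,
      reason = "")
}

#' Distribution of photobleaching step counts
#'
#' Percentage of classified traces in each step class (1-4). With assay
#' labels, percentages are computed per assay and reported as mean with
#' SEM across assays.
#'
#' @param fits list of [StepFit-class] objects.
#' @param assay optional vector of assay labels, one per fit, for
#'   mean +/- SEM reporting across independent assays.
#' @param condition condition label carried on the result.
#' @return A [StepDistribution-class].
#' @examples
#' fits <- lapply(1:20, function(i)
#'   fitSteps(simulateBleachTrace(1 + i %% 2, 0.3, noiseSd = 15,
#'                                rngSeed = i)))
#' stepDistribution(fits)
#' @export
stepDistribution <- function(fits, assay = NULL, condition = "") {
  ns <- vapply(fits, nSteps, integer(1))
  classified <- ns > 0L
  if (!any(classified)) stop("no classifiable traces")

  pct <- function(v) 100 * vapply(1:4, function(k) mean(v == k),
                                  numeric(1))
  if (is.null(assay)) {
    tab <- data.frame(steps = 1:4, percent = pct(ns[classified]))
  } else {
    stopifnot(length(assay) == length(fits))
    byAssay <- split(ns[classified], assay[classified])
    mat <- vapply(byAssay, pct, numeric(4))
    tab <- data.frame(steps = 1:4, percent = rowMeans(mat),
                      sem = apply(mat, 1L, sd) / sqrt(ncol(mat)))
  }
  new("StepDistribution", table = tab,
      nClassified = sum(classified),
      nUnclassified = sum(!classified), condition = condition)
}
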