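## Per-spot intensity traces and their two-state (bound/unbound)
## segmentation.

#' Extract a per-spot intensity trace
#'
#' Per-frame intensity of one spot: the sum over a circular aperture minus
#' the median of a surrounding annulus scaled to the aperture area (local
#' background subtraction).
#'
#' @param stack a [MovieStack-class].
#' @param x,y spot position, pixels.
#' @param apertureRadius aperture radius, pixels (default 3).
#' @param annulus inner and outer radius of the background annulus,
#'   pixels (default `c(5, 7)`).
#' @param spotId identifier carried on the trace.
#' @return A [Trace-class].
#' @export
extractTrace <- function(stack, x, y, apertureRadius = 3,
                         annulus = c(5, 7), spotId = "spot") {
  stopifnot(is(stack, "MovieStack"))
  arr <- frames(stack)
  H <- dim(arr)[1]; W <- dim(arr)[2]; T <- dim(arr)[3]
  cx <- round(x); cy <- round(y)
  m <- annulus[2]
  if (cx - m < 1 || cx + m > W || cy - m < 1 || cy + m > H)
    stop("spot too close to the field edge for the requested aperture")

  off <- expand.grid(dy = -m:m, dx = -m:m)
  d <- sqrt(off$dx^2 + off$dy^2)
  apIdx <- off[d <= apertureRadius, ]
  anIdx <- off[d >= annulus[1] & d <= annulus[2], ]
  nAp <- nrow(apIdx)

  lin <- function(idx) (cy + idx$dy) + (cx + idx$dx - 1) * H
  frameOff <- (seq_len(T) - 1L) * (H * W)
  apMat <- matrix(arr[outer(lin(apIdx), frameOff, "+")], nrow = nAp)
  anMat <- matrix(arr[outer(lin(anIdx), frameOff, "+")],
                  nrow = nrow(anIdx))
  bg <- apply(anMat, 2L, median)
  trace(colSums(apMat) - nAp * bg, frameInterval(stack), spotId = spotId)
}

## Deterministic 1-D two-means (Lloyd iterations from the data range);
## returns the two cluster centres, lower first.
twoMeans <- function(y, maxIter = 100L) {
  c1 <- min(y); c2 <- max(y)
  if (c1 == c2) return(c(c1, c2))
  for (i in seq_len(maxIter)) {
    thr <- (c1 + c2) / 2
    lo <- y <= thr
    n1 <- mean(y[lo]); n2 <- mean(y[!lo])
    if (!any(!lo)) break
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) { c1 <- n1; c2 <- n2; break }
    c1 <- n1; c2 <- n2
  }
  c(c1, c2)
}

#' Binarize a trace into bound/unbound intervals
#'
#' Two-level segmentation: the intensities are clustered by deterministic
#' 1-D two-means and thresholded at the midpoint of the two centres. Each
#' run of frames on one side of the threshold becomes an interval; the
#' first and last interval are flagged censored (their true duration
#' extends beyond the movie). A trace whose two centres are separated by
#' less than `minSeparation` robust noise SDs is treated as single-level
#' and classified by comparison to `onLevelPrior` (below `onLevelPrior/2`
#' means unbound; with no prior a single-level trace is unbound). The
#' segmentation is invariant to affine rescaling of the intensities. No
#' gap closing is applied: a single dark frame counts as an
#' unbinding/rebinding cycle, which is the operational definition of
#' "blinking" used throughout.
#'
#' @param trc a [Trace-class] (length >= 2).
#' @param onLevelPrior expected on-level (counts) used only for
#'   single-level traces.
#' @param minSeparation minimum centre separation in units of the robust
#'   per-frame noise SD (default 3).
#' @param experiment experiment label carried on the result.
#' @return An [IntervalSet-class].
#' @examples
#' tr <- trace(rep(c(0, 100, 0), times = c(10, 5, 10)), 0.1)
#' intervals(binarizeTrace(tr))
#' @export
binarizeTrace <- function(trc, onLevelPrior = NULL, minSeparation = 3,
                          experiment = "exp1") {
  stopifnot(is(trc, "Trace"))
  y <- intensity(trc)
  if (length(y) < 2L) stop("trace must have at least 2 frames")
  dt <- frameInterval(trc)

  sigma <- mad(diff(y)) / sqrt(2)
  ctr <- twoMeans(y)
  if (ctr[2] - ctr[1] <= minSeparation * max(sigma, .Machine$double.eps)) {
    on <- if (!is.null(onLevelPrior)) mean(y) > onLevelPrior / 2 else FALSE
    state <- rep(on, length(y))
  } else {
    state <- y > mean(ctr)
  }

  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- c(0L, head(ends, -1L))
  iv <- data.frame(state = ifelse(r$values, "on", "off"),
                   start = starts * dt, end = ends * dt,
                   censored = FALSE)
  iv$censored[1L] <- TRUE
  iv$censored[nrow(iv)] <- TRUE
  new("IntervalSet", intervals = iv, frameInterval = dt,
      spotId = trc@spotId, experiment = experiment)
}

#' Export traces or interval sets as tidy CSV
#'
#' @param x a list of [Trace-class] or [IntervalSet-class] objects.
#' @param file output path.
#' @return Invisibly, the written data.frame.
#' @export
writeTidy <- function(x, file) {
  if (!length(x)) stop("nothing to write")
  if (is(x[[1]], "Trace")) {
    d <- do.call(rbind, lapply(x, function(t)
      data.frame(spot = t@spotId, frame = seq_along(t@intensity),
                 intensity = t@intensity)))
  } else if (is(x[[1]], "IntervalSet")) {
    d <- do.call(rbind, lapply(x, function(s) {
      iv <- s@intervals
      iv$spot <- s@spotId
      iv$experiment <- s@experiment
      iv
    }))
  } else stop("unsupported object type")
  write.csv(d, file, row.names = FALSE)
  invisible(d)
}
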