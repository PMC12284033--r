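## PSF-based spot detection and per-field counting.
##
## Detection is the standard matched-filter approach for diffraction-limited
## emitters: correlate the (time-averaged) image with the pixel-integrated
## Gaussian PSF, take local maxima above an SNR threshold on the filtered
## amplitude, refine each to subpixel precision by a local Gaussian
## (parabolic) fit, merge duplicates closer than 2 sigma and drop spots in
## the edge-exclusion band.

#' Detect diffraction-limited spots
#'
#' @param stack a [MovieStack-class].
#' @param psfSigma expected PSF width, pixels.
#' @param snrMin amplitude threshold in units of the robust noise (MAD) of
#'   the matched-filtered image.
#' @param frame `"mean"` to detect on the time-averaged image (default;
#'   used for counting acquisitions), or a single frame index.
#' @param edgeExclusion spots closer than this to the border are dropped
#'   (default `3 * psfSigma`).
#' @return A [SpotSet-class]. `amplitude` is the least-squares integrated
#'   intensity of the fitted PSF (counts); `sigma` is the filter width
#'   used.
#' @examples
#' cfg <- simConfig(imaging = imagingModel(fieldEdge = 64),
#'                  discDensity = 15, discFrames = 10, rngSeed = 7)
#' f <- simulateField(cfg, channels = "disc")
#' detectSpots(f$disc)
#' @export
detectSpots <- function(stack, psfSigma = 1.0, snrMin = 5,
                        frame = "mean", edgeExclusion = 3 * psfSigma) {
  stopifnot(is(stack, "MovieStack"))
  if (psfSigma <= 0) stop("psfSigma must be positive")
  arr <- frames(stack)
  img <- if (identical(frame, "mean")) rowMeans(arr, dims = 2L)
         else arr[, , as.integer(frame)]
  H <- nrow(img); W <- ncol(img)

  imgc <- img - median(img)
  hw <- max(3L, ceiling(3 * psfSigma))
  kernel <- psfPatch(0, 0, psfSigma, -hw:hw, -hw:hw)
  A <- convolve2d(imgc, kernel) / sum(kernel^2)

  noise <- mad(A)
  if (noise == 0) noise <- .Machine$double.eps
  thr <- snrMin * noise

  ## local maxima in the 8-neighbourhood (>= so plateaus survive until the
  ## merge step)
  isMax <- A > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0L && dj == 0L) next
    nb <- matrix(-Inf, H, W)
    rs <- max(1L, 1L + di):min(H, H + di)
    rd <- max(1L, 1L - di):min(H, H - di)
    cs <- max(1L, 1L + dj):min(W, W + dj)
    cd <- max(1L, 1L - dj):min(W, W - dj)
    nb[rd, cd] <- A[rs, cs]
    isMax <- isMax & (A >= nb)
  }
  idx <- which(isMax, arr.ind = TRUE)
  out <- data.frame(x = numeric(), y = numeric(), amplitude = numeric(),
                    sigma = numeric())
  if (nrow(idx)) {
    ## subpixel refinement: parabolic (local Gaussian) fit along each axis
    r <- idx[, 1L]; c <- idx[, 2L]
    interior <- r > 1L & r < H & c > 1L & c < W
    r <- r[interior]; c <- c[interior]
    if (length(r)) {
      ctr <- A[cbind(r, c)]
      up <- A[cbind(r - 1L, c)]; dn <- A[cbind(r + 1L, c)]
      lf <- A[cbind(r, c - 1L)]; rt <- A[cbind(r, c + 1L)]
      ## vertex of the parabola through the three samples along each axis;
      ## the curvature is negative at a maximum
      cy <- up - 2 * ctr + dn
      cxx <- lf - 2 * ctr + rt
      dy <- ifelse(cy < 0, 0.5 * (up - dn) / cy, 0)
      dx <- ifelse(cxx < 0, 0.5 * (lf - rt) / cxx, 0)
      dy <- pmin(pmax(dy, -0.5), 0.5)
      dx <- pmin(pmax(dx, -0.5), 0.5)
      out <- data.frame(x = c + dx, y = r + dy, amplitude = ctr,
                        sigma = psfSigma)
      ## merge duplicate maxima within 2 sigma, keeping the brighter
      out <- out[order(-out$amplitude), , drop = FALSE]
      keep <- rep(TRUE, nrow(out))
      for (i in seq_len(nrow(out))) {
        if (!keep[i]) next
        later <- which(keep & seq_len(nrow(out)) > i)
        if (length(later)) {
          d2 <- (out$x[later] - out$x[i])^2 + (out$y[later] - out$y[i])^2
          keep[later[d2 < (2 * psfSigma)^2]] <- FALSE
        }
      }
      out <- out[keep, , drop = FALSE]
      ## edge exclusion
      m <- edgeExclusion
      out <- out[out$x > 0.5 + m & out$x < W + 0.5 - m &
                 out$y > 0.5 + m & out$y < H + 0.5 - m, , drop = FALSE]
      rownames(out) <- NULL
    }
  }
  spotSet(out, channelLabel(stack), c(H, W), pixelSize(stack))
}

#' Background-adjusted spot count for one field
#'
#' The adjusted count is the number of spots after lysate addition minus
#' the number before (pre-lysate background), preserved even when
#' negative.
#'
#' @param before [SpotSet-class] detected before lysate addition.
#' @param after [SpotSet-class] detected after lysate addition.
#' @return A [FieldCount-class].
#' @export
countField <- function(before, after) {
  stopifnot(is(before, "SpotSet"), is(after, "SpotSet"))
  if (!isTRUE(all.equal(fieldArea(before), fieldArea(after))))
    stop("before/after fields have different areas")
  new("FieldCount", rawCount = as.numeric(nSpots(after)),
      backgroundCount = as.numeric(nSpots(before)),
      adjustedCount = as.numeric(nSpots(after) - nSpots(before)),
      area = fieldArea(after))
}

#' Summarize adjusted counts over fields
#'
#' Mean, sample SD and SEM of the adjusted counts over the imaged fields
#' of one assay. At least `minFields` fields are expected; fewer is an
#' error unless explicitly overridden, in which case a warning is raised.
#'
#' @param counts list of [FieldCount-class] objects, or a numeric vector
#'   of adjusted counts.
#' @param minFields minimum number of fields (default 10).
#' @param allowFewer proceed (with a warning) below `minFields`?
#' @return List with `mean`, `sd`, `sem`, `n`.
#' @examples
#' summarizeFields(c(70, 80, 90), minFields = 3)
#' @export
summarizeFields <- function(counts, minFields = 10, allowFewer = FALSE) {
  x <- if (is.numeric(counts)) counts
       else vapply(counts, adjustedCount, numeric(1))
  if (length(x) < minFields) {
    msg <- sprintf("only %d fields (expected >= %d)", length(x), minFields)
    if (!allowFewer) stop(msg, "; set allowFewer = TRUE to override")
    warning(msg)
  }
  mss(x)
}

#' Colocalize two spot sets
#'
#' Greedy nearest-neighbour matching of disc-channel and protein-channel
#' spots under a matching radius; each spot is used at most once.
#'
#' @param discs,proteins [SpotSet-class] objects from the same field.
#' @param radius matching radius, pixels (default 2).
#' @return List with `pairs` (data.frame `disc`, `protein`, `dist`),
#'   `orphanDiscs` and `orphanProteins` (row indices into the respective
#'   spot tables).
#' @export
colocalize <- function(discs, proteins, radius = 2) {
  stopifnot(is(discs, "SpotSet"), is(proteins, "SpotSet"))
  if (!identical(discs@fieldDim, proteins@fieldDim))
    stop("spot sets come from different field geometries")
  a <- spots(discs); b <- spots(proteins)
  m <- greedyMatch(a$x, a$y, b$x, b$y, radius)
  list(pairs = data.frame(disc = m$a, protein = m$b, dist = m$dist),
       orphanDiscs = setdiff(seq_len(nrow(a)), m$a),
       orphanProteins = setdiff(seq_len(nrow(b)), m$b))
}

#' Score detections against known positions
#'
#' Matches detected spots to ground-truth positions (greedy nearest
#' neighbour within `radius`) and reports recall, precision and the RMS
#' localization error of the matched pairs.
#'
#' @param spotset a [SpotSet-class].
#' @param positions data.frame with columns `x`, `y` (true positions,
#'   pixels).
#' @param radius matching radius, pixels.
#' @param exclude optional margin (pixels): true positions within this
#'   distance of the field border are not counted against recall,
#'   mirroring the detector's edge exclusion.
#' @return List with `recall`, `precision`, `nTrue`, `nDetected`,
#'   `nMatched`, `rmse` (pixels).
#' @export
detectionScore <- function(spotset, positions, radius = 2, exclude = 0) {
  stopifnot(is(spotset, "SpotSet"))
  H <- spotset@fieldDim[1]; W <- spotset@fieldDim[2]
  if (exclude > 0)
    positions <- positions[positions$x > 0.5 + exclude &
                           positions$x < W + 0.5 - exclude &
                           positions$y > 0.5 + exclude &
                           positions$y < H + 0.5 - exclude, , drop = FALSE]
  s <- spots(spotset)
  m <- greedyMatch(positions$x, positions$y, s$x, s$y, radius)
  list(recall = if (nrow(positions)) nrow(m) / nrow(positions) else NA_real_,
       precision = if (nrow(s)) nrow(m) / nrow(s) else NA_real_,
       nTrue = nrow(positions), nDetected = nrow(s), nMatched = nrow(m),
       rmse = if (nrow(m)) sqrt(mean(m$dist^2)) else NA_real_)
}

#' Export a spot set as CSV
#'
#' @param spotset a [SpotSet-class].
#' @param file output path.
#' @param field optional field identifier column.
#' @return Invisibly, the written data.frame.
#' @export
writeSpots <- function(spotset, file, field = NA) {
  d <- spots(spotset)
  d$channel <- channelLabel(spotset)
  d$field <- field
  write.csv(d, file, row.names = FALSE)
  invisible(d)
}
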