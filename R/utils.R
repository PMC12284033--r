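## Internal helpers shared across modules.

## Evaluate `code` under a given seed without disturbing the caller's RNG
## stream. seed = NA/NULL leaves the RNG alone.
withSeed <- function(seed, code) {
  if (!is.null(seed) && !is.na(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Counts round half away from zero (R's round() rounds half to even).
roundCount <- function(x) trunc(x + sign(x) * 0.5)

## Greedy nearest-neighbour matching of two point sets under a radius.
## Pairs are accepted in order of increasing distance; each point is used
## at most once. Returns indices into a and b plus the matched distance.
greedyMatch <- function(ax, ay, bx, by, radius) {
  na <- length(ax); nb <- length(bx)
  empty <- data.frame(a = integer(), b = integer(), dist = numeric())
  if (na == 0L || nb == 0L) return(empty)
  d2 <- outer(ax, bx, "-")^2 + outer(ay, by, "-")^2
  cand <- which(d2 <= radius^2, arr.ind = TRUE)
  if (!nrow(cand)) return(empty)
  ord <- order(d2[cand])
  cand <- cand[ord, , drop = FALSE]
  usedA <- logical(na); usedB <- logical(nb)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1L]; c <- cand[i, 2L]
    if (!usedA[r] && !usedB[c]) {
      usedA[r] <- TRUE; usedB[c] <- TRUE; keep[i] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]
  data.frame(a = cand[, 1L], b = cand[, 2L],
             dist = sqrt(d2[cand]))
}

## Pixel-integrated Gaussian PSF patch: the fraction of a unit-intensity
## emitter at (x, y) (pixel-centre coordinates, pixel 1 spans [0.5, 1.5])
## landing in each pixel of the window rows x cols.
psfPatch <- function(x, y, sigma, rows, cols) {
  fx <- pnorm(cols + 0.5, mean = x, sd = sigma) -
        pnorm(cols - 0.5, mean = x, sd = sigma)
  fy <- pnorm(rows + 0.5, mean = y, sd = sigma) -
        pnorm(rows - 0.5, mean = y, sd = sigma)
  outer(fy, fx)
}

## 2-D convolution of a matrix with a small centred kernel by shift-and-add;
## edges are handled by renormalising with the convolved all-ones image so
## border pixels are unbiased.
convolve2d <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  wgt <- matrix(0, H, W)
  for (i in -kr:kr) {
    rs <- max(1L, 1L + i):min(H, H + i)
    rd <- max(1L, 1L - i):min(H, H - i)
    for (j in -kc:kc) {
      cs <- max(1L, 1L + j):min(W, W + j)
      cd <- max(1L, 1L - j):min(W, W - j)
      k <- kernel[kr + 1L + i, kc + 1L + j]
      out[rd, cd] <- out[rd, cd] + k * img[rs, cs]
      wgt[rd, cd] <- wgt[rd, cd] + k
    }
  }
  ks <- sum(kernel)
  out * (ks / wgt)
}

## Sample mean / sd / sem in one place.
mss <- function(x) {
  n <- length(x)
  s <- if (n > 1L) sd(x) else NA_real_
  list(mean = mean(x), sd = s, sem = if (n > 1L) s / sqrt(n) else NA_real_,
       n = n)
}
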