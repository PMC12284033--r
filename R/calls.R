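## Binding-threshold derivation and binary binding calls.
##
## The assay is read out as a binary outcome. The detection threshold is
## the mean + 2 x sample SD of pooled adjusted counts from assays of
## protein-lipid pairs known not to interact (the nonbinder panel); a
## pair is called "bound" only when its per-assay mean adjusted counts
## both exceed the threshold and are significantly above it by a
## one-sample, one-tailed t-test at p < 0.05.

#' Derive the binding threshold from a nonbinder panel
#'
#' @param nonbinderCounts numeric vector of adjusted nonbinder counts
#'   (one value per assay; n >= 2).
#' @return A [BindingThreshold-class] with value
#'   `mean + 2 * sd(nonbinderCounts)`.
#' @examples
#' set.seed(1)
#' deriveThreshold(simulateNonbinderPanel(175, rngSeed = 1))
#' @export
deriveThreshold <- function(nonbinderCounts) {
  if (length(nonbinderCounts) < 2L)
    stop("at least 2 nonbinder assays are required")
  m <- mean(nonbinderCounts)
  s <- sd(nonbinderCounts)
  new("BindingThreshold", value = m + 2 * s, meanCount = m, sdCount = s,
      n = length(nonbinderCounts))
}

#' Binary binding call for one protein-lipid pair
#'
#' One-sample, one-tailed (upper) t-test of the per-assay mean adjusted
#' counts against the threshold. The pair is called bound only when the
#' mean exceeds the threshold AND p < 0.05.
#'
#' @param assayMeans numeric vector of per-assay mean adjusted counts
#'   (>= 3 independent assays).
#' @param threshold a [BindingThreshold-class], or a single numeric
#'   threshold value.
#' @param label pair label carried on the call.
#' @return A [BindingCall-class].
#' @examples
#' thr <- deriveThreshold(c(40, 20, 60, 40))
#' callBinding(c(100, 110, 120), thr, label = "example pair")
#' @export
callBinding <- function(assayMeans, threshold, label = "") {
  if (length(assayMeans) < 3L)
    stop("at least 3 independent assays are required")
  thr <- if (is(threshold, "BindingThreshold")) thresholdValue(threshold)
         else as.numeric(threshold)
  n <- length(assayMeans)
  if (sd(assayMeans) == 0) {
    ## degenerate zero-variance case t.test() refuses: the t statistic is
    ## +/- infinity (or 0 exactly at the threshold)
    d <- mean(assayMeans) - thr
    tStat <- if (d > 0) Inf else if (d < 0) -Inf else 0
    pValue <- if (d > 0) 0 else 1
    dfree <- n - 1
  } else {
    tt <- t.test(assayMeans, mu = thr, alternative = "greater")
    tStat <- unname(tt$statistic)
    pValue <- tt$p.value
    dfree <- unname(tt$parameter)
  }
  bound <- mean(assayMeans) > thr && pValue < 0.05
  new("BindingCall", label = label, assayMeans = assayMeans,
      threshold = thr, tStat = tStat, df = dfree, pValue = pValue,
      bound = bound)
}

#' Tabulate binding calls
#'
#' @param calls list of [BindingCall-class] objects.
#' @param file optional path; when given the table is written as JSON.
#' @return data.frame, one row per call.
#' @export
callTable <- function(calls, file = NULL) {
  if (is(calls, "BindingCall")) calls <- list(calls)
  out <- do.call(rbind, lapply(calls, function(cl)
    data.frame(label = cl@label, meanCount = mean(cl@assayMeans),
               nAssays = length(cl@assayMeans), threshold = cl@threshold,
               tStat = cl@tStat, df = cl@df, pValue = cl@pValue,
               bound = cl@bound)))
  if (!is.null(file))
    jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA)
  out
}
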