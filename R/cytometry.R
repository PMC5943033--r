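#' Split threshold between GFP-low and GFP-high FACS populations
#'
#' A deterministic surrogate for the hand-drawn division point on a
#' bimodal intensity histogram: a Gaussian kernel-density estimate of the
#' log-intensities (Silverman bandwidth) is searched for local maxima;
#' the threshold is the density minimum between the two largest modes,
#' mapped back to the intensity scale. If the density is unimodal the
#' data give no natural division point and an error suggests
#' `method = "fixed"`.
#'
#' @param events data.frame with a positive `intensity` column (see
#'   [simulateFacsEvents()]).
#' @param method `"valley"` (default) or `"fixed"`.
#' @param value fixed threshold on the intensity scale (required for
#'   `method = "fixed"`).
#' @param minEvents minimum event count required for valley estimation.
#' @return single numeric threshold on the intensity scale.
#' @export
splitThreshold <- function(events, method = c("valley", "fixed"),
                           value = NULL, minEvents = 100L) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value)) stop("method = 'fixed' requires a threshold value")
    return(value)
  }
  if (nrow(events) < minEvents)
    stop("valley estimation needs at least ", minEvents, " events (got ",
         nrow(events), ")")
  if (any(events$intensity <= 0)) stop("intensities must be positive")
  d <- density(log(events$intensity), bw = "nrd0")
  y <- d$y
  isMax <- which(diff(sign(diff(y))) == -2) + 1L
  # ignore spurious tail bumps of the KDE: a mode must carry at least 2% of
  # the peak density
  isMax <- isMax[y[isMax] >= 0.02 * max(y)]
  unimodal <- function()
    stop("intensity distribution looks unimodal: no valley found; ",
         "use method = 'fixed' with an explicit threshold")
  if (length(isMax) < 2L) unimodal()
  top2 <- sort(isMax[order(y[isMax], decreasing = TRUE)][1:2])
  between <- seq(top2[1L], top2[2L])
  valley <- between[which.min(y[between])]
  # a genuine division point must dip below both modes
  if (y[valley] > 0.95 * min(y[top2])) unimodal()
  exp(d$x[valley])
}

#' Low/high population proportions at a threshold
#'
#' Events with intensity strictly above the threshold are GFP-high;
#' events at or below it are GFP-low (the same tie rule as the imaging
#' classifier). The two percentages always sum to exactly 100.
#'
#' @param events data.frame with an `intensity` column.
#' @param threshold numeric gate on the intensity scale.
#' @return list with `pct_low`, `pct_high`, `n_low`, `n_high`.
#' @examples
#' ev <- data.frame(intensity = c(1, 2, 3, 4))
#' populationProportions(ev, 2.5)
#' @export
populationProportions <- function(events, threshold) {
  n <- nrow(events)
  if (!n) stop("no events: proportions are undefined")
  nHigh <- sum(events$intensity > threshold)
  pctHigh <- 100 * nHigh / n
  list(pct_low = 100 - pctHigh, pct_high = pctHigh,
       n_low = n - nHigh, n_high = nHigh)
}
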