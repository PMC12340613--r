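#' Otsu threshold for photon-count traces and image intensities
#'
#' Finds the threshold that maximizes between-class variance (equivalently,
#' minimizes intra-class variance) of a sample split into a low and a high
#' class. For integer photon counts the histogram uses unit-width bins so the
#' candidate thresholds are the observed count values themselves; for
#' continuous data (e.g. angiogram voxel intensities) the range is divided
#' into `nbins` equal bins and the threshold is a bin edge.
#'
#' Values `<= threshold` belong to the low class. Ties in between-class
#' variance are broken toward the lower threshold.
#'
#' @param x numeric vector of counts or intensities.
#' @param nbins number of histogram bins for continuous data. Ignored when
#'   `x` is integer-valued (unit bins are used).
#' @return the threshold (numeric scalar), with attribute `"separation"`, the
#'   ratio of between-class variance to total variance at the chosen
#'   threshold (0 for a constant input).
#' @examples
#' otsu_threshold(c(rpois(100, 20), rpois(10, 3)))
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) abort("no finite values to threshold")
  if (length(unique(x)) == 1L) {
    thr <- x[1]
    attr(thr, "separation") <- 0
    return(thr)
  }
  integerish <- all(x == round(x))
  if (integerish) {
    lo <- min(x)
    counts <- tabulate(x - lo + 1L, nbins = max(x) - lo + 1L)
    centers <- seq(lo, max(x))
  } else {
    edges <- seq(min(x), max(x), length.out = nbins + 1L)
    idx <- pmin(findInterval(x, edges, rightmost.closed = TRUE), nbins)
    counts <- tabulate(idx, nbins = nbins)
    centers <- (edges[-1L] + edges[-length(edges)]) / 2
  }
  n <- sum(counts)
  w0 <- cumsum(counts)
  m0 <- cumsum(counts * centers)
  mu <- m0[length(m0)] / n
  # between-class variance for every split "low = bins 1..k"
  k <- seq_len(length(counts) - 1L)
  p0 <- w0[k] / n
  valid <- p0 > 0 & p0 < 1
  mu0 <- m0[k] / w0[k]
  mu1 <- (m0[length(m0)] - m0[k]) / (n - w0[k])
  sb2 <- p0 * (1 - p0) * (mu0 - mu1)^2
  sb2[!valid] <- -Inf
  best <- which.max(sb2) # which.max takes the first maximum: lower threshold
  thr <- if (integerish) centers[best] else edges[best + 1L]
  tot <- sum((x - mu)^2) / n
  attr(thr, "separation") <- if (tot > 0) sb2[best] / tot else 0
  thr
}
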