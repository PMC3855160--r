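#' @include search.R
NULL

#' Robust-average pooling of channel disparity maps
#'
#' Combines the per-channel maps into the final disparity map. At each pixel
#' independently, the multiset of channel values is reduced by repeatedly
#' removing the value farthest from the current mean until ceiling(n/2)
#' survive; the output is the survivors' mean. Ties in "farthest from the
#' mean" remove the value from the lowest-indexed channel, making the
#' procedure deterministic and order-labelled (permuting identically-valued
#' maps does not change the result).
#'
#' @param maps list of \linkS4class{ChannelDisparityMap} (or plain matrices)
#'   of identical dimensions, length >= 2.
#' @param median use a plain per-pixel median instead (baseline, off by
#'   default).
#' @return a \linkS4class{DisparityMap} with an all-TRUE validity mask
#'   (border exclusion belongs to evaluation).
#' @export
robustAverage <- function(maps, median = FALSE) {
  if (length(maps) < 2) stop("need at least 2 maps to pool")
  mats <- lapply(maps, function(m)
    if (is(m, "ChannelDisparityMap")) m@disparity else m)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("all maps must have identical dimensions")
  vals <- do.call(cbind, lapply(mats, as.vector))
  pooled <- if (median) {
    apply(vals, 1, stats::median)
  } else {
    keep <- ceiling(ncol(vals) / 2)
    cpp_robust_pool(vals, as.integer(keep))
  }
  new("DisparityMap", disparity = matrix(pooled, d[1], d[2]),
      validMask = matrix(TRUE, d[1], d[2]))
}
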