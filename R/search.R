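#' @include energy.R
NULL

#' Interior local extrema of an energy-vs-disparity profile
#'
#' Strict interior local maxima and minima of the profile, with plateau
#' handling: a maximal run of equal values flanked on both sides by strictly
#' lower (maximum) or strictly higher (minimum) values counts as a single
#' extremum at the run's centre; for even-length runs the centre candidate
#' with the smaller |disparity| is used. Profile endpoints are never extrema
#' (an edge-maximal profile is treated as having none).
#'
#' @param profile numeric vector of energies, one per hypothesis (length >= 3).
#' @param hypotheses disparity values matching the profile, or a
#'   \linkS4class{DisparityHypothesisSet}.
#' @return data.frame with columns \code{index}, \code{disparity},
#'   \code{value}, \code{kind} ("max"/"min"); zero rows if none.
#' @export
findLocalExtrema <- function(profile, hypotheses) {
  if (is(hypotheses, "DisparityHypothesisSet")) hypotheses <- hypotheses@values
  n <- length(profile)
  if (n < 3) stop("profile must have at least 3 points")
  if (length(hypotheses) != n) stop("profile/hypotheses length mismatch")
  idx <- integer(); val <- numeric(); kind <- character()
  t <- 1L
  while (t <= n) {
    u <- t
    while (u < n && profile[u + 1L] == profile[t]) u <- u + 1L
    if (t > 1L && u < n) {
      isMax <- profile[t - 1L] < profile[t] && profile[u + 1L] < profile[t]
      isMin <- profile[t - 1L] > profile[t] && profile[u + 1L] > profile[t]
      if (isMax || isMin) {
        len <- u - t + 1L
        centre <- if (len %% 2L == 1L) t + len %/% 2L else {
          m1 <- t + len %/% 2L - 1L; m2 <- m1 + 1L
          if (abs(hypotheses[m2]) < abs(hypotheses[m1])) m2 else m1
        }
        idx <- c(idx, centre); val <- c(val, profile[t])
        kind <- c(kind, if (isMax) "max" else "min")
      }
    }
    t <- u + 1L
  }
  data.frame(index = idx, disparity = hypotheses[idx], value = val,
             kind = kind, stringsAsFactors = FALSE)
}

#' First-scale disparity selection
#'
#' At the coarsest spatial frequency no prior map exists: per pixel, among
#' the interior local extrema of the energy profile over hypotheses, the one
#' with the biggest |response| is selected. Ties resolve to the smaller
#' |disparity|, then the lower hypothesis index. Pixels with no interior
#' extremum fall back to the profile's global maximum.
#'
#' @param stack an \linkS4class{EnergyStack} from the coarsest channel.
#' @return a \linkS4class{ChannelDisparityMap}.
#' @export
selectFirstScale <- function(stack) {
  res <- cpp_select_first(stack@energies, stack@hypotheses@values)
  new("ChannelDisparityMap", disparity = res$disparity,
      response = res$response, spec = stack@spec)
}

#' Coarse-to-fine disparity refinement
#'
#' At every scale after the first, the extremum whose disparity is closest
#' to the previous (coarser) map's value is selected per pixel; equidistant
#' candidates resolve to the smaller |disparity|, then the lower index.
#' Pixels with no interior extremum keep the previous value.
#'
#' @param stack an \linkS4class{EnergyStack} from the finer channel.
#' @param previous the \linkS4class{ChannelDisparityMap} of the adjacent
#'   coarser scale (same orientation).
#' @return a \linkS4class{ChannelDisparityMap}.
#' @export
selectRefine <- function(stack, previous) {
  prev <- if (is(previous, "ChannelDisparityMap")) previous@disparity
          else previous
  if (!identical(dim(prev), dim(stack@energies)[1:2]))
    stop("previous map dimensions do not match the stack")
  res <- cpp_select_refine(stack@energies, stack@hypotheses@values, prev)
  new("ChannelDisparityMap", disparity = res$disparity,
      response = res$response, spec = stack@spec)
}

#' Run the coarse-to-fine search over a whole filter bank
#'
#' For each orientation independently, the hypothesis set is scanned at the
#' coarsest spatial frequency and selected with \code{\link{selectFirstScale}};
#' each finer scale is then selected with \code{\link{selectRefine}} against
#' the previous scale's map. The output is one map per (orientation,
#' frequency) combination, in bank order.
#'
#' Channels whose stripe orientations differ by exactly 180 degrees are
#' frequency-domain conjugates with identical energies; each such pair is
#' computed once and the map duplicated.
#'
#' @param pair a \linkS4class{StereoPair}.
#' @param bank a \linkS4class{FilterBank}, coarsest scale first.
#' @param hypotheses a \linkS4class{DisparityHypothesisSet}.
#' @param smooth energy smoothing option, see \code{\link{scanDisparities}}.
#' @return list of \linkS4class{ChannelDisparityMap}, one per channel.
#' @export
runCoarseToFine <- function(pair, bank, hypotheses, smooth = TRUE) {
  if (length(hypotheses@values) < 3)
    stop("need at least 3 hypotheses for extremum selection")
  sl <- fft(preprocessImage(pair@left))
  sr <- fft(preprocessImage(pair@right))
  grid <- buildFrequencyGrid(ncol(sl), nrow(sl))
  oris <- unique(vapply(bank@channels, function(ch) ch@orientationDeg,
                        numeric(1)))
  lams <- sort(unique(vapply(bank@channels, function(ch) ch@wavelengthPx,
                             numeric(1))), decreasing = TRUE)
  w <- ncol(sl)
  fx <- fftFrequencies(w)
  a <- hypotheses@values / 2
  m <- floor(a)
  fr <- round(a - m, 9)
  classes <- unique(fr)
  ramps <- exp(-2i * pi * outer(fx, classes))
  fracIdx <- match(fr, classes)
  chainFor <- function(ori) {
    prev <- NULL
    maps <- vector("list", length(lams))
    for (s in seq_along(lams)) {
      spec <- channelSpec(ori, lams[s], bank@params$sigmaRatio,
                          bank@params$angularSigmaRad, bank@family)
      filt <- composeFilter(grid, spec)
      res <- cpp_channel_map(halfTransform(sl, filt@transfer),
                             halfTransform(sr, filt@transfer),
                             ramps, fracIdx, as.integer(m),
                             smoothWindowFor(spec, smooth),
                             hypotheses@values,
                             if (is.null(prev)) matrix(0, 0, 0)
                             else prev@disparity)
      prev <- new("ChannelDisparityMap", disparity = res$disparity,
                  response = res$response, spec = spec)
      maps[[s]] <- prev
    }
    maps
  }
  chains <- list()
  for (ori in oris) {
    conj <- as.character((ori + 180) %% 360)
    if (!is.null(chains[[conj]])) {
      ## conjugate orientation: identical energies, duplicate the chain
      chains[[as.character(ori)]] <- lapply(chains[[conj]], function(m) {
        sp <- m@spec
        new("ChannelDisparityMap", disparity = m@disparity,
            response = m@response,
            spec = channelSpec(ori, sp@wavelengthPx, sp@sigmaRatio,
                               sp@angularSigmaRad, sp@family))
      })
    } else {
      chains[[as.character(ori)]] <- chainFor(ori)
    }
  }
  ## return in bank order: scale-major (coarse first), orientation-minor
  out <- list()
  for (s in seq_along(lams))
    for (ori in oris)
      out[[length(out) + 1L]] <- chains[[as.character(ori)]][[s]]
  out
}
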