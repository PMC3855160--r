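#' @include evaluation.R
NULL

#' Pipeline configuration
#'
#' Validated list of every tunable of the disparity pipeline, with the
#' defaults used for the synthetic-stereogram experiments.
#'
#' @param family filter family, "log_gabor" or "gabor".
#' @param orientationsDeg stripe orientations; NULL for the family default.
#' @param nScales,lambdaMinPx,scaleFactor log-Gabor scale ladder (4 scales,
#'   3 px, 1.6).
#' @param sigmaRatio radial bandwidth parameter (0.65, ~1.5 octaves).
#' @param angularSigmaRad angular Gaussian sigma (0.6545 rad).
#' @param pixelsPerDegree conversion for degree-based frequencies (12).
#' @param gaborFreqsCpd Gabor frequencies, cycles/degree.
#' @param hypMin,hypMax,hypStep disparity hypothesis range and step, pixels;
#'   \code{hypStep = NULL} lets callers pick the family convention.
#' @param smooth energy-map RF integration: TRUE (one-wavelength box),
#'   FALSE, or a window width in pixels.
#' @param poolMedian use median pooling instead of robust averaging.
#' @param threshold,border evaluation defaults (0.25 px, 13 px).
#' @return named list of class "stereoConfig".
#' @export
stereoConfig <- function(family = "log_gabor", orientationsDeg = NULL,
                         nScales = 4, lambdaMinPx = 3, scaleFactor = 1.6,
                         sigmaRatio = 0.65, angularSigmaRad = 0.6545,
                         pixelsPerDegree = 12,
                         gaborFreqsCpd = c(0.5, 1, 2, 4),
                         hypMin = -10, hypMax = 10, hypStep = NULL,
                         smooth = TRUE, poolMedian = FALSE,
                         threshold = 0.25, border = 13) {
  if (!family %in% c("log_gabor", "gabor"))
    stop("unknown filter family: ", family)
  if (hypMin >= hypMax) stop("hypMin must be below hypMax")
  if (!is.null(hypStep) && hypStep <= 0) stop("hypStep must be positive")
  if (threshold <= 0) stop("threshold must be positive")
  if (border < 0) stop("border must be nonnegative")
  structure(list(family = family, orientationsDeg = orientationsDeg,
                 nScales = nScales, lambdaMinPx = lambdaMinPx,
                 scaleFactor = scaleFactor, sigmaRatio = sigmaRatio,
                 angularSigmaRad = angularSigmaRad,
                 pixelsPerDegree = pixelsPerDegree,
                 gaborFreqsCpd = gaborFreqsCpd, hypMin = hypMin,
                 hypMax = hypMax, hypStep = hypStep, smooth = smooth,
                 poolMedian = poolMedian, threshold = threshold,
                 border = border),
            class = "stereoConfig")
}

## Coerce a plain list (e.g. from YAML) into a validated config.
asStereoConfig <- function(x) {
  if (inherits(x, "stereoConfig")) return(x)
  do.call(stereoConfig, x[names(x) %in% names(formals(stereoConfig))])
}

#' Estimate the disparity map of a stereo pair
#'
#' The full pipeline: mean-luminance subtraction, quadrature filter bank,
#' complex-cell energy over the disparity hypothesis set, per-orientation
#' coarse-to-fine extremum selection, and robust-average pooling of the
#' channel maps.
#'
#' @param pair a \linkS4class{StereoPair} (or
#'   \linkS4class{GroundTruthStereogram}).
#' @param config a \code{\link{stereoConfig}}; its \code{hypStep} defaults
#'   to 1 px here when unset.
#' @param returnChannels also return the per-channel maps.
#' @return a \linkS4class{DisparityMap}; if \code{returnChannels}, a list
#'   with elements \code{map} and \code{channels}.
#' @export
estimateDisparity <- function(pair, config = stereoConfig(),
                              returnChannels = FALSE) {
  config <- asStereoConfig(unclass(config))
  if (is.null(config$hypStep)) config$hypStep <- 1
  bank <- makeFilterBank(config$family, config$orientationsDeg,
                         config$nScales, config$lambdaMinPx,
                         config$scaleFactor, config$sigmaRatio,
                         config$angularSigmaRad, config$pixelsPerDegree,
                         config$gaborFreqsCpd)
  hyp <- disparityHypotheses(config$hypMin, config$hypMax, config$hypStep)
  maps <- runCoarseToFine(pair, bank, hyp, smooth = config$smooth)
  out <- robustAverage(maps, median = config$poolMedian)
  if (returnChannels) list(map = out, channels = maps) else out
}
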