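#' @import methods
NULL

#' Polar coordinates of a discrete 2D Fourier domain
#'
#' Per-bin normalized radial frequency (cycles/pixel) and anticlockwise
#' angular coordinate (radians) of an unshifted DFT layout: the DC bin sits
#' at matrix position (1,1), positive x-frequencies run along the first
#' columns, positive y-frequencies along the first rows.
#'
#' @slot width,height grid dimensions in pixels.
#' @slot radius height x width matrix of radial frequencies, 0 only at DC.
#' @slot angle height x width matrix of angles in (-pi, pi].
#' @export
setClass("FrequencyGrid",
  representation(width = "integer", height = "integer",
                 radius = "matrix", angle = "matrix"))

setValidity("FrequencyGrid", function(object) {
  msg <- character()
  if (!identical(dim(object@radius), c(object@height, object@width)))
    msg <- c(msg, "radius dimensions do not match width/height")
  if (!identical(dim(object@angle), dim(object@radius)))
    msg <- c(msg, "angle dimensions do not match radius")
  if (sum(object@radius == 0) != 1L)
    msg <- c(msg, "radius must be zero at exactly one (DC) bin")
  if (length(msg)) msg else TRUE
})

#' One (orientation, wavelength) channel of a filter bank
#'
#' Orientation is the receptive-field stripe orientation in degrees; the
#' channel's wave vector points at orientation - 90 degrees. The centre
#' frequency is 1/wavelengthPx cycles/pixel.
#'
#' @slot orientationDeg stripe orientation, degrees.
#' @slot wavelengthPx centre wavelength, pixels (>= 2, Nyquist).
#' @slot sigmaRatio radial bandwidth parameter sigma_r/f0, in (0, 1).
#' @slot angularSigmaRad angular Gaussian standard deviation, radians.
#' @slot family "log_gabor" or "gabor".
#' @export
setClass("ChannelSpec",
  representation(orientationDeg = "numeric", wavelengthPx = "numeric",
                 sigmaRatio = "numeric", angularSigmaRad = "numeric",
                 family = "character"))

setValidity("ChannelSpec", function(object) {
  msg <- character()
  if (object@wavelengthPx < 2)
    msg <- c(msg, "wavelengthPx must be >= 2 (Nyquist)")
  if (object@sigmaRatio <= 0 || object@sigmaRatio >= 1)
    msg <- c(msg, "sigmaRatio must be in (0, 1)")
  if (object@angularSigmaRad <= 0)
    msg <- c(msg, "angularSigmaRad must be positive")
  if (!object@family %in% c("log_gabor", "gabor"))
    msg <- c(msg, "family must be 'log_gabor' or 'gabor'")
  if (length(msg)) msg else TRUE
})

#' @describeIn ChannelSpec constructor.
#' @param orientationDeg,wavelengthPx,sigmaRatio,angularSigmaRad,family see slots.
#' @export
channelSpec <- function(orientationDeg, wavelengthPx, sigmaRatio = 0.65,
                        angularSigmaRad = 0.6545, family = "log_gabor") {
  new("ChannelSpec", orientationDeg = as.numeric(orientationDeg),
      wavelengthPx = as.numeric(wavelengthPx),
      sigmaRatio = as.numeric(sigmaRatio),
      angularSigmaRad = as.numeric(angularSigmaRad), family = family)
}

#' Quadrature (even/odd) filter pair in the frequency domain
#'
#' Stored as the one-sided complex transfer function T: the real response of
#' applying T to an image spectrum and inverse-transforming gives the even
#' (in-phase) simple-cell drive, the imaginary part the odd (Hilbert)
#' counterpart. \code{\link{evenWeights}} and \code{\link{oddWeights}}
#' recover the Hermitian-decomposed even and odd transfer weights.
#'
#' @slot transfer height x width complex matrix (unshifted DFT layout).
#' @slot spec the generating \linkS4class{ChannelSpec}.
#' @export
setClass("QuadratureFilter",
  representation(transfer = "matrix", spec = "ChannelSpec"))

setValidity("QuadratureFilter", function(object) {
  if (!is.complex(object@transfer)) "transfer must be a complex matrix" else TRUE
})

#' An ordered bank of disparity channels
#'
#' Channels are ordered coarsest spatial frequency first (largest
#' wavelength), the order the coarse-to-fine search consumes them in.
#'
#' @slot channels list of \linkS4class{ChannelSpec}.
#' @slot family filter family shared by all channels.
#' @slot params construction parameters (orientations, scales, ...).
#' @export
setClass("FilterBank",
  representation(channels = "list", family = "character", params = "list"))

setValidity("FilterBank", function(object) {
  lams <- vapply(object@channels, function(ch) ch@wavelengthPx, numeric(1))
  scales <- sort(unique(lams), decreasing = TRUE)
  if (any(diff(match(lams, scales)) < 0))
    "channels must be ordered coarsest (largest wavelength) first"
  else TRUE
})

#' A rectified stereo image pair
#' @slot left,right height x width luminance matrices of equal size.
#' @export
setClass("StereoPair", representation(left = "matrix", right = "matrix"))

setValidity("StereoPair", function(object) {
  if (!identical(dim(object@left), dim(object@right)))
    return("left and right images must have identical dimensions")
  if (!all(is.finite(object@left)) || !all(is.finite(object@right)))
    return("images must be finite")
  TRUE
})

#' @describeIn StereoPair constructor.
#' @param left,right luminance matrices.
#' @export
stereoPair <- function(left, right) new("StereoPair", left = left, right = right)

#' A stereogram with known per-pixel disparity
#' @slot truth height x width true disparity map (pixels).
#' @slot kind one of "square", "ramp", "gabor_surface", "uniform".
#' @slot seed integer seed that generated the dot pattern.
#' @export
setClass("GroundTruthStereogram", contains = "StereoPair",
  representation(truth = "matrix", kind = "character", seed = "integer"))

setValidity("GroundTruthStereogram", function(object) {
  msg <- character()
  if (!identical(dim(object@truth), dim(object@left)))
    msg <- c(msg, "truth dimensions must match the images")
  if (!all(is.finite(object@truth))) msg <- c(msg, "truth must be finite")
  if (!object@kind %in% c("square", "ramp", "gabor_surface", "uniform"))
    msg <- c(msg, "unknown stereogram kind")
  if (length(msg)) msg else TRUE
})

#' Monocular even/odd filter responses
#' @slot evenPart,oddPart real response images.
#' @slot spec generating channel.
#' @slot eye "left" or "right".
#' @slot shiftPx positional shift applied to the filter centre (pixels).
#' @export
setClass("MonocularResponse",
  representation(evenPart = "matrix", oddPart = "matrix", spec = "ChannelSpec",
                 eye = "character", shiftPx = "numeric"))

#' Complex-cell energy for one disparity hypothesis
#' @slot energy nonnegative height x width response map.
#' @slot spec generating channel.
#' @slot disparityPx the positional-disparity hypothesis (pixels).
#' @export
setClass("EnergyMap",
  representation(energy = "matrix", spec = "ChannelSpec",
                 disparityPx = "numeric"))

setValidity("EnergyMap", function(object) {
  if (any(object@energy < -1e-12)) "energy must be nonnegative" else TRUE
})

#' An ordered, uniformly spaced set of disparity hypotheses
#' @slot values strictly increasing disparities (pixels).
#' @slot step common spacing (pixels).
#' @export
setClass("DisparityHypothesisSet",
  representation(values = "numeric", step = "numeric"))

setValidity("DisparityHypothesisSet", function(object) {
  v <- object@values
  if (length(v) < 1) return("empty hypothesis set")
  if (length(v) > 1) {
    d <- diff(v)
    if (any(d <= 0)) return("hypotheses must be strictly increasing")
    if (max(abs(d - object@step)) > 1e-9) return("spacing must be uniform")
  }
  TRUE
})

#' @describeIn DisparityHypothesisSet constructor from a range and step.
#' @param from,to,step range endpoints and spacing in pixels.
#' @export
disparityHypotheses <- function(from = -10, to = 10, step = 1) {
  new("DisparityHypothesisSet",
      values = seq(from, to, by = step), step = step)
}

#' Per-channel complex-cell energies over all hypotheses
#' @slot energies height x width x n array, slice k for hypothesis k.
#' @slot hypotheses the scanned \linkS4class{DisparityHypothesisSet}.
#' @slot spec generating channel.
#' @export
setClass("EnergyStack",
  representation(energies = "array", hypotheses = "DisparityHypothesisSet",
                 spec = "ChannelSpec"))

setValidity("EnergyStack", function(object) {
  if (length(dim(object@energies)) != 3)
    return("energies must be a 3D array")
  if (dim(object@energies)[3] != length(object@hypotheses@values))
    return("third dimension must match the number of hypotheses")
  TRUE
})

#' Disparity selected per pixel for one channel
#' @slot disparity height x width map of selected hypotheses (pixels).
#' @slot response magnitude of the selected extremum.
#' @slot spec generating channel.
#' @export
setClass("ChannelDisparityMap",
  representation(disparity = "matrix", response = "matrix",
                 spec = "ChannelSpec"))

#' Final pooled disparity map
#' @slot disparity height x width disparity estimate (pixels).
#' @slot validMask logical matrix, FALSE in excluded border pixels.
#' @export
setClass("DisparityMap",
  representation(disparity = "matrix", validMask = "matrix"))

setValidity("DisparityMap", function(object) {
  if (!identical(dim(object@disparity), dim(object@validMask)))
    return("mask dimensions must match the map")
  if (!all(is.finite(object@disparity[object@validMask])))
    return("disparity must be finite where valid")
  TRUE
})

#' Evaluation result (bad-pixel percentage and RMSE)
#' @slot badPercent percent of valid pixels with |error| > threshold.
#' @slot rmse root-mean-squared disparity error over valid pixels.
#' @slot threshold error threshold (pixels).
#' @slot border pixels excluded on each side.
#' @slot nValid number of pixels evaluated.
#' @export
setClass("EvalResult",
  representation(badPercent = "numeric", rmse = "numeric",
                 threshold = "numeric", border = "numeric",
                 nValid = "integer"))

## ---- show methods --------------------------------------------------------

setMethod("show", "ChannelSpec", function(object) {
  cat(sprintf("ChannelSpec [%s]: orientation %g deg, wavelength %.3f px (f0 = %.4f c/px)\n",
              object@family, object@orientationDeg, object@wavelengthPx,
              1 / object@wavelengthPx))
})

setMethod("show", "FilterBank", function(object) {
  lams <- vapply(object@channels, function(ch) ch@wavelengthPx, numeric(1))
  oris <- vapply(object@channels, function(ch) ch@orientationDeg, numeric(1))
  cat(sprintf("FilterBank [%s]: %d channels\n", object@family,
              length(object@channels)))
  cat("  wavelengths (px, coarse->fine):",
      paste(signif(sort(unique(lams), decreasing = TRUE), 5), collapse = ", "), "\n")
  cat("  orientations (deg):",
      paste(sort(unique(oris)), collapse = ", "), "\n")
})

setMethod("show", "StereoPair", function(object) {
  cat(sprintf("%s: %d x %d px\n", class(object), nrow(object@left),
              ncol(object@left)))
  if (is(object, "GroundTruthStereogram"))
    cat(sprintf("  kind '%s', seed %d, disparity range [%.3g, %.3g] px\n",
                object@kind, object@seed, min(object@truth), max(object@truth)))
})

setMethod("show", "DisparityMap", function(object) {
  v <- object@disparity[object@validMask]
  cat(sprintf("DisparityMap: %d x %d px, %d valid (%.1f%%)\n",
              nrow(object@disparity), ncol(object@disparity), sum(object@validMask),
              100 * mean(object@validMask)))
  if (length(v))
    cat(sprintf("  disparity range [%.3g, %.3g] px\n", min(v), max(v)))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf(
    "EvalResult: B = %.2f%% (|err| > %g px), RMSE = %.3f px, border %g px, n = %d\n",
    object@badPercent, object@threshold, object@rmse, object@border,
    object@nValid))
})
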