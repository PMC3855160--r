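#' @include AllGenerics.R
NULL

## DFT bin frequencies in cycles/pixel, unshifted layout (DC first).
fftFrequencies <- function(n) {
  c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)] / n
}

## M(-k) on the unshifted layout: index reversal modulo n in both dimensions.
flipSpectrum <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c(1, if (h > 1) h:2), c(1, if (w > 1) w:2), drop = FALSE]
}

#' Polar frequency grid of an image-sized DFT
#'
#' Converts the Cartesian frequency coordinates of a width x height discrete
#' Fourier domain to polar form: radius rho = sqrt(fx^2 + fy^2) in
#' cycles/pixel (Nyquist 0.5) and anticlockwise angle phi = atan2(fy, fx).
#' The layout is unshifted: DC at bin (1,1), so filters built on the grid
#' multiply image spectra directly.
#'
#' @param width,height grid dimensions in pixels (>= 8).
#' @return a \linkS4class{FrequencyGrid}.
#' @examples
#' g <- buildFrequencyGrid(16, 16)
#' g@radius[1, 1]              # DC
#' max(g@radius)               # sqrt(2)/2 at the corner bin
#' @export
buildFrequencyGrid <- function(width, height) {
  if (width < 8 || height < 8)
    stop("grid dimensions must be at least 8 x 8")
  fx <- matrix(fftFrequencies(width), height, width, byrow = TRUE)
  fy <- matrix(fftFrequencies(height), height, width)
  new("FrequencyGrid", width = as.integer(width), height = as.integer(height),
      radius = sqrt(fx^2 + fy^2), angle = atan2(fy, fx))
}

## Cartesian frequency components of a grid (recomputed, cheap).
gridFx <- function(grid) {
  matrix(fftFrequencies(grid@width), grid@height, grid@width, byrow = TRUE)
}
gridFy <- function(grid) {
  matrix(fftFrequencies(grid@height), grid@height, grid@width)
}

## Wave-vector direction of a channel: stripe orientation minus 90 degrees.
waveAngleRad <- function(orientationDeg) (orientationDeg - 90) * pi / 180

#' Angular Gaussian envelope
#'
#' Gaussian weighting of the angular distance between each frequency bin and
#' the channel's wave-vector direction (stripe orientation - 90 degrees).
#' The distance is computed through the sine/cosine difference construction,
#' which wraps correctly at +/- pi.
#'
#' @param grid a \linkS4class{FrequencyGrid}.
#' @param orientationDeg stripe orientation in degrees.
#' @param angularSigmaRad Gaussian standard deviation sigma_theta, radians.
#' @return height x width matrix of weights in [0, 1], 1 on the filter axis.
#' @export
angularGaussian <- function(grid, orientationDeg, angularSigmaRad) {
  if (angularSigmaRad <= 0) stop("angularSigmaRad must be positive")
  th <- waveAngleRad(orientationDeg)
  dth <- abs(atan2(sin(grid@angle - th), cos(grid@angle - th)))
  exp(-dth^2 / (2 * angularSigmaRad^2))
}

#' Log-Gabor radial transfer function
#'
#' A Gaussian on the logarithmic frequency axis,
#' exp(-(ln(rho/f0))^2 / (2 ln(sigmaRatio)^2)), with the DC weight defined
#' as exactly zero. Symmetric on a log axis and zero-DC at any bandwidth,
#' unlike a linear-frequency Gaussian. sigmaRatio 0.65 gives a half-amplitude
#' bandwidth of about 1.5 octaves.
#'
#' @param grid a \linkS4class{FrequencyGrid}.
#' @param f0 centre frequency, cycles/pixel, in (0, 0.5).
#' @param sigmaRatio bandwidth parameter sigma_r/f0 in (0, 1).
#' @return height x width matrix of weights, peak 1 at rho = f0.
#' @export
radialLogGabor <- function(grid, f0, sigmaRatio) {
  if (f0 <= 0 || f0 >= 0.5) stop("f0 must be in (0, 0.5) cycles/pixel")
  if (sigmaRatio <= 0 || sigmaRatio >= 1) stop("sigmaRatio must be in (0, 1)")
  r <- grid@radius
  dc <- r == 0
  r[dc] <- f0   # placeholder, overwritten below
  w <- exp(-(log(r / f0))^2 / (2 * log(sigmaRatio)^2))
  w[dc] <- 0
  w
}

#' Compose a quadrature log-Gabor filter
#'
#' Multiplies the radial log-Gabor by the angular Gaussian and restricts the
#' product to the forward frequency half-plane (angular distance < pi/2 from
#' the wave-vector direction). The one-sided transfer is the analytic-signal
#' form of the quadrature pair: its Hermitian-even part is the even (cosine
#' phase) filter and its anti-Hermitian part the odd filter, the exact
#' Hilbert transform of the even one along the filter direction. The
#' half-plane restriction is what makes the pair an exact Hilbert pair on
#' the discrete grid (bins perpendicular to the wave vector would otherwise
#' carry even but no odd weight).
#'
#' @param grid a \linkS4class{FrequencyGrid}.
#' @param spec a \linkS4class{ChannelSpec} with family "log_gabor".
#' @return a \linkS4class{QuadratureFilter}.
#' @export
composeLogGabor <- function(grid, spec) {
  stopifnot(is(spec, "ChannelSpec"))
  f0 <- 1 / spec@wavelengthPx
  rad <- radialLogGabor(grid, f0, spec@sigmaRatio)
  th <- waveAngleRad(spec@orientationDeg)
  dth <- abs(atan2(sin(grid@angle - th), cos(grid@angle - th)))
  ang <- exp(-dth^2 / (2 * spec@angularSigmaRad^2))
  ang[dth >= pi / 2] <- 0
  tr <- rad * ang
  ## Nyquist rows/columns alias +0.5 and -0.5 cycles/pixel in one bin, so a
  ## one-sided (analytic) filter cannot assign them a consistent quadrature
  ## phase; they are excluded from the passband like the DC bin
  fxNyq <- fftFrequencies(grid@width) == 0.5
  fyNyq <- fftFrequencies(grid@height) == 0.5
  tr[fyNyq, ] <- 0
  tr[, fxNyq] <- 0
  new("QuadratureFilter", transfer = tr * (1 + 0i), spec = spec)
}

## Radial Gaussian sigma (fraction of f0) whose half-amplitude octave
## bandwidth matches the log-Gabor's at the given sigmaRatio.
gaborRadialSigma <- function(sigmaRatio) {
  boct <- 2 * sqrt(2 * log(2)) * abs(log(sigmaRatio)) / log(2)
  (2^boct - 1) / (2^boct + 1) / sqrt(2 * log(2))
}

#' Compose a quadrature Gabor filter
#'
#' Classical cosine/sine Gabor pair, represented by its one-sided complex
#' transfer: a single anisotropic Gaussian bump centred on the channel's
#' wave vector. The Hermitian-even part is the cosine Gabor transfer
#' (G(k - k0) + G(k + k0))/2 -- which is nonzero at DC for bandwidths over
#' one octave -- and the anti-Hermitian part the sine Gabor. No DC
#' correction is applied inside the filter; mean-luminance subtraction
#' happens on the images (\code{\link{preprocessImage}}).
#'
#' The radial Gaussian width is set so the half-amplitude octave bandwidth
#' matches a log-Gabor of the same \code{sigmaRatio}; the cross width is
#' f0 * angularSigmaRad (small-angle equivalent of the angular Gaussian).
#'
#' @inheritParams composeLogGabor
#' @param spec a \linkS4class{ChannelSpec} with family "gabor"; its
#'   \code{wavelengthPx} must already be in pixels (degree-based frequencies
#'   are converted by \code{\link{makeFilterBank}} via pixelsPerDegree).
#' @return a \linkS4class{QuadratureFilter}.
#' @export
composeGabor <- function(grid, spec) {
  stopifnot(is(spec, "ChannelSpec"))
  f0 <- 1 / spec@wavelengthPx
  if (f0 >= 0.5) stop("wavelengthPx below the Nyquist limit")
  sp <- gaborRadialSigma(spec@sigmaRatio) * f0
  sq <- f0 * spec@angularSigmaRad
  th <- waveAngleRad(spec@orientationDeg)
  fx <- gridFx(grid); fy <- gridFy(grid)
  p <- fx * cos(th) + fy * sin(th)
  q <- -fx * sin(th) + fy * cos(th)
  tr <- exp(-((p - f0)^2 / (2 * sp^2) + q^2 / (2 * sq^2)))
  new("QuadratureFilter", transfer = tr * (1 + 0i), spec = spec)
}

#' @rdname accessors
setMethod("evenWeights", "QuadratureFilter", function(x) {
  Re(x@transfer + flipSpectrum(x@transfer)) / 2
})

#' @rdname accessors
setMethod("oddWeights", "QuadratureFilter", function(x) {
  ## i * sign(projection) * even: purely imaginary at every bin
  1i * (x@transfer - flipSpectrum(x@transfer)) / 2
})

#' Build a filter bank
#'
#' For the log-Gabor family, wavelengths are lambdaMin * scaleFactor^k for
#' k = 0..nScales-1 (defaults 3 px, 1.6, 4 scales: 3, 4.8, 7.68, 12.288 px)
#' at stripe orientations 30, 60, 90, 210, 240, 270 degrees. For the Gabor
#' family, frequencies are given in cycles/degree (default 0.5, 1, 2, 4)
#' and converted through \code{pixelsPerDegree}, at orientations 30..180.
#' Channels are ordered coarsest frequency first.
#'
#' @param family "log_gabor" or "gabor".
#' @param orientationsDeg stripe orientations; NULL for the family default.
#' @param nScales number of spatial frequencies (log-Gabor).
#' @param lambdaMinPx smallest wavelength in pixels (log-Gabor).
#' @param scaleFactor wavelength ratio between successive scales (log-Gabor).
#' @param sigmaRatio radial bandwidth parameter (~1.5 octaves at 0.65).
#' @param angularSigmaRad angular Gaussian sigma, radians.
#' @param pixelsPerDegree conversion for degree-based Gabor frequencies.
#' @param gaborFreqsCpd Gabor centre frequencies, cycles/degree.
#' @return a \linkS4class{FilterBank}.
#' @export
makeFilterBank <- function(family = c("log_gabor", "gabor"),
                           orientationsDeg = NULL, nScales = 4,
                           lambdaMinPx = 3, scaleFactor = 1.6,
                           sigmaRatio = 0.65, angularSigmaRad = 0.6545,
                           pixelsPerDegree = 12,
                           gaborFreqsCpd = c(0.5, 1, 2, 4)) {
  family <- match.arg(family)
  if (is.null(orientationsDeg))
    orientationsDeg <- if (family == "log_gabor") c(30, 60, 90, 210, 240, 270)
                       else c(30, 60, 90, 120, 150, 180)
  lams <- if (family == "log_gabor") {
    lambdaMinPx * scaleFactor^(seq_len(nScales) - 1)
  } else {
    if (is.null(pixelsPerDegree))
      stop("pixelsPerDegree is required for the gabor family")
    pixelsPerDegree / gaborFreqsCpd
  }
  if (any(lams < 2))
    stop("all wavelengths must be >= 2 px (Nyquist); got ",
         paste(signif(lams, 4), collapse = ", "))
  lams <- sort(lams, decreasing = TRUE)  # coarse to fine
  chans <- list()
  for (lam in lams)
    for (o in orientationsDeg)
      chans[[length(chans) + 1L]] <-
        channelSpec(o, lam, sigmaRatio, angularSigmaRad, family)
  new("FilterBank", channels = chans, family = family,
      params = list(orientationsDeg = orientationsDeg, nScales = nScales,
                    lambdaMinPx = lambdaMinPx, scaleFactor = scaleFactor,
                    sigmaRatio = sigmaRatio, angularSigmaRad = angularSigmaRad,
                    pixelsPerDegree = pixelsPerDegree,
                    gaborFreqsCpd = gaborFreqsCpd))
}

#' Build the quadrature filter for one channel
#' @param grid a \linkS4class{FrequencyGrid}.
#' @param spec a \linkS4class{ChannelSpec}.
#' @return a \linkS4class{QuadratureFilter} of the spec's family.
#' @export
composeFilter <- function(grid, spec) {
  if (spec@family == "log_gabor") composeLogGabor(grid, spec)
  else composeGabor(grid, spec)
}

#' Spatial-domain kernels of a quadrature filter
#'
#' Inverse transform of the even and odd transfer weights, centred with
#' \code{fftshift}-style reordering. The even kernel is even-symmetric about
#' the filter centre, the odd kernel odd-symmetric.
#'
#' @param filter a \linkS4class{QuadratureFilter}.
#' @return list with matrices \code{even} and \code{odd}.
#' @export
spatialKernels <- function(filter) {
  tr <- filter@transfer
  h <- nrow(tr); w <- ncol(tr)
  even <- (tr + flipSpectrum(tr)) / 2
  odd <- (tr - flipSpectrum(tr)) / 2
  kE <- Re(fft(even, inverse = TRUE)) / (h * w)
  kO <- Re(fft(odd / 1i, inverse = TRUE)) / (h * w)
  shift <- function(m) {
    m[c((floor(h / 2) + 1):h, 1:floor(h / 2)),
      c((floor(w / 2) + 1):w, 1:floor(w / 2))]
  }
  list(even = shift(kE), odd = shift(kO))
}
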