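#' @include filterbank.R
NULL

#' Subtract the mean luminance from an image
#'
#' DC attenuation applied to both eyes' images before filtering, for both
#' filter families. Idempotent.
#'
#' @param image finite 2D luminance matrix.
#' @return zero-mean matrix of the same size.
#' @export
preprocessImage <- function(image) {
  if (!is.matrix(image) || length(image) == 0)
    stop("image must be a non-empty matrix")
  if (!all(is.finite(image))) stop("image must be finite")
  image - mean(image)
}

#' Shift a filter's centre by a (possibly fractional) pixel offset
#'
#' Multiplies the transfer function by the horizontal phase ramp
#' exp(-2*pi*i*fx*deltaPx), displacing the spatial kernel by +deltaPx along
#' x. Fractional shifts are exact in the frequency domain; successive shifts
#' compose additively.
#'
#' @param filter a \linkS4class{QuadratureFilter}.
#' @param deltaPx shift in pixels (positive rightward).
#' @return the shifted \linkS4class{QuadratureFilter}.
#' @export
applyPositionalShift <- function(filter, deltaPx) {
  if (deltaPx == 0) return(filter)
  w <- ncol(filter@transfer); h <- nrow(filter@transfer)
  fx <- matrix(fftFrequencies(w), h, w, byrow = TRUE)
  new("QuadratureFilter", transfer = filter@transfer * exp(-2i * pi * fx * deltaPx),
      spec = filter@spec)
}

#' Monocular even/odd responses of one eye's image
#'
#' Multiplies the (preprocessed) image spectrum by the one-sided transfer and
#' inverse-transforms: the real part is the even simple-cell drive, the
#' imaginary part the odd (quadrature) drive. \code{shiftPx} displaces the
#' filter centre before application.
#'
#' @param image zero-mean luminance matrix.
#' @param filter a \linkS4class{QuadratureFilter} built on a grid of the
#'   image's dimensions.
#' @param eye "left" or "right" (bookkeeping only).
#' @param shiftPx positional offset of the RF centre in pixels.
#' @return a \linkS4class{MonocularResponse}.
#' @export
filterImage <- function(image, filter, eye = "left", shiftPx = 0) {
  if (!identical(dim(image), dim(filter@transfer)))
    stop("image and filter dimensions differ")
  f <- applyPositionalShift(filter, shiftPx)
  resp <- fft(fft(image) * f@transfer, inverse = TRUE) / length(image)
  new("MonocularResponse", evenPart = Re(resp), oddPart = Im(resp),
      spec = filter@spec, eye = eye, shiftPx = shiftPx)
}

#' Push-pull simple-cell pair response
#'
#' Binocular sum s = left + right, half-wave rectified into an ON cell
#' max(s, 0) and an OFF cell max(-s, 0), each squared and summed:
#' ON^2 + OFF^2 = s^2 exactly. Pairing cells of opposite RF polarity is what
#' removes the rectification and preserves the bipolar signal.
#'
#' @param left,right \linkS4class{MonocularResponse}s of matching channel.
#' @param phase "even" or "odd": which quadrature component to combine.
#' @return nonnegative response matrix.
#' @export
simpleCellPair <- function(left, right, phase = c("even", "odd")) {
  phase <- match.arg(phase)
  if (!identical(left@spec@orientationDeg, right@spec@orientationDeg) ||
      !identical(left@spec@wavelengthPx, right@spec@wavelengthPx))
    stop("left and right responses come from different channels")
  l <- slot(left, paste0(phase, "Part"))
  r <- slot(right, paste0(phase, "Part"))
  if (!identical(dim(l), dim(r))) stop("response dimensions differ")
  s <- l + r
  on <- pmax(s, 0); off <- pmax(-s, 0)
  on^2 + off^2
}

#' Complex-cell energy for one disparity hypothesis
#'
#' The binocular energy at positional disparity Delta x: the left filter is
#' displaced by +Delta x / 2 and the right by -Delta x / 2, and the energy is
#' the sum of the squared even and odd push-pull pair responses
#' (the quadrature sum), a phase-invariant, disparity-tuned quantity.
#' Disparity convention: right-image content displaced by +Delta x relative
#' to left peaks the energy at hypothesis Delta x; crossed (near)
#' disparities are negative.
#'
#' @param pair a \linkS4class{StereoPair} (images are mean-subtracted here).
#' @param filter a \linkS4class{QuadratureFilter} matching the image size.
#' @param disparityPx hypothesis Delta x in pixels, |Delta x| < width/4.
#' @return an \linkS4class{EnergyMap}.
#' @export
complexCellEnergy <- function(pair, filter, disparityPx) {
  if (abs(disparityPx) >= ncol(pair@left) / 4)
    stop("|disparityPx| must be below width/4")
  l <- filterImage(preprocessImage(pair@left), filter, "left", +disparityPx / 2)
  r <- filterImage(preprocessImage(pair@right), filter, "right", -disparityPx / 2)
  e <- simpleCellPair(l, r, "even") + simpleCellPair(l, r, "odd")
  new("EnergyMap", energy = e, spec = filter@spec, disparityPx = disparityPx)
}

## Default smoothing window (px) for a channel: one wavelength, odd-rounded.
## The kernel applies three iterated box passes of this width, a close
## approximation to Gaussian integration with sigma = wavelength/2 -- the
## scale of the channel's receptive-field envelope. See the vignette.
smoothWindowFor <- function(spec, smooth = TRUE) {
  if (isFALSE(smooth)) return(1L)
  if (isTRUE(smooth)) {
    k <- as.integer(round(spec@wavelengthPx))
  } else {
    k <- as.integer(round(smooth))
  }
  if (k %% 2L == 0L) k <- k + 1L
  max(k, 1L)
}

## Half-transformed filtered spectrum for the fast per-hypothesis path:
## y inverse-transformed, x still in the frequency domain, transposed to
## width x height so x-frequency runs along rows.
halfTransform <- function(spectrum, transfer) {
  q <- spectrum * transfer
  t(mvfft(q, inverse = TRUE) / nrow(q))
}

#' Scan all disparity hypotheses for one channel
#'
#' Computes the complex-cell energy map for every hypothesis. Both eyes'
#' filtered responses are computed once; each hypothesis then costs a single
#' phase-ramp multiplication and a one-dimensional inverse transform along
#' x (the energy equals |shifted left response + shifted right response|^2).
#' Optionally each map is integrated over the RF extent by a separable box
#' average (default window: one channel wavelength).
#'
#' @param pair a \linkS4class{StereoPair}.
#' @param filter a \linkS4class{QuadratureFilter}.
#' @param hypotheses a \linkS4class{DisparityHypothesisSet}.
#' @param smooth TRUE for the default RF-sized box window, FALSE for none,
#'   or a numeric window width in pixels.
#' @return an \linkS4class{EnergyStack}.
#' @export
scanDisparities <- function(pair, filter, hypotheses, smooth = TRUE) {
  if (length(hypotheses@values) == 0) stop("empty hypothesis set")
  sl <- fft(preprocessImage(pair@left))
  sr <- fft(preprocessImage(pair@right))
  scanDisparitiesSpectra(sl, sr, filter, hypotheses, smooth)
}

## Internal: scan with precomputed image spectra (shared across channels).
## Each eye's shift a = +/- hyp/2 splits into integer + fractional parts:
## only the distinct fractional shifts need a frequency-domain phase ramp
## (and inverse FFT); integer parts are circular index shifts in the kernel.
scanDisparitiesSpectra <- function(sl, sr, filter, hypotheses, smooth = TRUE) {
  zl <- halfTransform(sl, filter@transfer)
  zr <- halfTransform(sr, filter@transfer)
  w <- ncol(sl)
  fx <- fftFrequencies(w)
  a <- hypotheses@values / 2
  m <- floor(a)
  fr <- round(a - m, 9)
  classes <- unique(fr)
  ramps <- exp(-2i * pi * outer(fx, classes))
  box <- smoothWindowFor(filter@spec, smooth)
  e <- cpp_energy_stack(zl, zr, ramps, match(fr, classes), as.integer(m), box)
  new("EnergyStack", energies = e, hypotheses = hypotheses, spec = filter@spec)
}
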