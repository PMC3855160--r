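#' @include pooling.R
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Seeded binary random-dot field
#'
#' @param width,height image size in pixels.
#' @param density probability of an "on" (value 1) pixel, in (0, 1).
#' @param seed integer seed; the same seed reproduces the same field.
#' @return height x width matrix of 0/1 values.
#' @export
randomDotField <- function(width = 200, height = 200, density = 0.5,
                           seed = 1) {
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)")
  withSeed(seed,
           matrix(as.numeric(rbinom(width * height, 1, density)),
                  height, width))
}

#' Square depth-profile disparity map
#'
#' 200 x 200 map with the centred 100 x 100 region at +5 px disparity and
#' -1 px in the surround.
#'
#' @param width,height,size map and central-square size in pixels.
#' @param centreDisparity,surroundDisparity disparities in pixels.
#' @return height x width disparity matrix.
#' @export
disparityProfileSquare <- function(width = 200, height = 200,
                                   size = round(min(width, height) / 2),
                                   centreDisparity = 5,
                                   surroundDisparity = -1) {
  m <- matrix(surroundDisparity, height, width)
  r0 <- (height - size) %/% 2; c0 <- (width - size) %/% 2
  m[r0 + seq_len(size), c0 + seq_len(size)] <- centreDisparity
  m
}

#' Ramp depth-profile disparity map
#'
#' Central 160 x 160 region with disparity varying linearly along x from
#' -5 px at its leftmost column to +5 px at its rightmost; zero surround.
#'
#' @param width,height,size map and central-region size in pixels.
#' @param fromDisparity,toDisparity ramp endpoints in pixels.
#' @return height x width disparity matrix.
#' @export
disparityProfileRamp <- function(width = 200, height = 200,
                                 size = round(0.8 * min(width, height)),
                                 fromDisparity = -5, toDisparity = 5) {
  m <- matrix(0, height, width)
  r0 <- (height - size) %/% 2; c0 <- (width - size) %/% 2
  ramp <- fromDisparity +
    (toDisparity - fromDisparity) * (seq_len(size) - 1) / (size - 1)
  m[r0 + seq_len(size), c0 + seq_len(size)] <-
    matrix(ramp, size, size, byrow = TRUE)
  m
}

#' Gabor-surface depth-profile disparity map
#'
#' A two-dimensional Gabor surface (Gaussian envelope times a cosine
#' carrier) scaled to a peak disparity of \code{maxDisparity} pixels. The
#' carrier frequency is given in cycles/degree and converted through
#' \code{pixelsPerDegree}; the carrier runs perpendicular to
#' \code{orientationDeg} stripes and the surface is centred on the image.
#'
#' Defaults: a 0.25 cycles/degree corrugation on a 40 pixels/degree display
#' (carrier wavelength 160 px, within the spatial-frequency range where
#' human sensitivity to disparity corrugations peaks), envelope sigma 40 px.
#'
#' @param width,height map size in pixels.
#' @param maxDisparity peak |disparity| in pixels.
#' @param freqCpd carrier frequency, cycles/degree.
#' @param pixelsPerDegree display scale (pixels per degree of visual angle);
#'   a stimulus property, distinct from the filter bank's conversion.
#' @param sigmaPx Gaussian envelope standard deviation, pixels.
#' @param orientationDeg stripe orientation of the corrugation, degrees.
#' @param phaseRad carrier phase at the centre, radians.
#' @return height x width disparity matrix.
#' @export
disparityProfileGabor <- function(width = 200, height = 200, maxDisparity = 5,
                                  freqCpd = 0.25, pixelsPerDegree = 40,
                                  sigmaPx = 40, orientationDeg = 90,
                                  phaseRad = 0) {
  f <- freqCpd / pixelsPerDegree
  th <- waveAngleRad(orientationDeg)
  ## centre on a pixel so the stated peak disparity is attained exactly
  x <- matrix(rep(seq_len(width) - (floor(width / 2) + 1), each = height),
              height, width)
  y <- matrix(rep(seq_len(height) - (floor(height / 2) + 1), width),
              height, width)
  p <- x * cos(th) + y * sin(th)
  maxDisparity * exp(-(x^2 + y^2) / (2 * sigmaPx^2)) *
    cos(2 * pi * f * p + phaseRad)
}

#' Warp a dot field into a stereo pair with a given disparity map
#'
#' The left image is the dot field; the right image samples the field at
#' x - truth(x, y) with linear interpolation for fractional disparities.
#' Source coordinates falling outside the image (uncovered regions) are
#' refilled with fresh seeded dots; wraparound never occurs.
#'
#' @param dots height x width dot field (the left image).
#' @param truth height x width disparity map, |truth| < width/4.
#' @param seed seed for the refill dots.
#' @param density refill dot density.
#' @return a \linkS4class{StereoPair}.
#' @export
warpStereogram <- function(dots, truth, seed = 1, density = 0.5) {
  if (!identical(dim(dots), dim(truth)))
    stop("dots and truth dimensions differ")
  w <- ncol(dots); h <- nrow(dots)
  if (max(abs(truth)) >= w / 4)
    stop("|disparity| must stay below width/4")
  xs <- matrix(rep(seq_len(w), each = h), h, w) - truth
  x0 <- floor(xs)
  fr <- xs - x0
  inside <- x0 >= 1 & (x0 + 1 <= w | (x0 <= w & fr < 1e-12))
  x0c <- pmin(pmax(x0, 1), w)
  x1c <- pmin(x0c + 1, w)
  rows <- matrix(rep(seq_len(h), w), h, w)
  right <- (1 - fr) * dots[cbind(as.vector(rows), as.vector(x0c))] +
    fr * dots[cbind(as.vector(rows), as.vector(x1c))]
  right <- matrix(right, h, w)
  nref <- sum(!inside)
  if (nref > 0)
    right[!inside] <- withSeed(seed + 10000L, rbinom(nref, 1, density))
  stereoPair(dots, right)
}

#' Generate a ground-truth random-dot stereogram
#'
#' Seeded generator for the stereogram families: "square" (+5 px centre,
#' -1 px surround), "ramp" (-5..+5 px central ramp, zero surround),
#' "gabor_surface" (Gabor corrugation, peak 5 px) and "uniform" (constant
#' disparity \code{uniformDisparity}).
#'
#' @param kind stereogram family.
#' @param seed integer seed for the dot pattern (and refill).
#' @param width,height image size in pixels.
#' @param density dot density.
#' @param uniformDisparity disparity for kind "uniform", pixels.
#' @param ... further arguments to the kind's disparity profile.
#' @return a \linkS4class{GroundTruthStereogram}.
#' @examples
#' rds <- makeStereogram("square", seed = 1)
#' range(truthMap(rds))
#' @export
makeStereogram <- function(kind = c("square", "ramp", "gabor_surface",
                                    "uniform"),
                           seed = 1, width = 200, height = 200,
                           density = 0.5, uniformDisparity = 0, ...) {
  kind <- match.arg(kind)
  truth <- switch(kind,
    square = disparityProfileSquare(width, height, ...),
    ramp = disparityProfileRamp(width, height, ...),
    gabor_surface = disparityProfileGabor(width, height, ...),
    uniform = matrix(uniformDisparity, height, width))
  dots <- randomDotField(width, height, density, seed)
  pair <- warpStereogram(dots, truth, seed, density)
  new("GroundTruthStereogram", left = pair@left, right = pair@right,
      truth = truth, kind = kind, seed = as.integer(seed))
}
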