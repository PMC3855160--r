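#' @include pipeline.R
NULL

#' Read a grayscale image
#'
#' PNG, TIFF, PGM (P2 text / P5 binary, 8- or 16-bit) or PFM. Colour images
#' are converted to luminance by averaging the colour channels. Values keep
#' the file's natural scale ([0, 1] for PNG/TIFF, integer for PGM, float
#' for PFM).
#'
#' @param path file path; the extension selects the reader.
#' @return numeric height x width matrix.
#' @export
readImageGray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    pgm = readPGM(path),
    pfm = readPFM(path),
    stop("unsupported image format '", ext, "' for ", path))
  if (length(dim(img)) == 3) {
    nc <- min(dim(img)[3], 3)  # average colour channels, ignore alpha
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  img
}

## ---- PGM ----------------------------------------------------------------

## Minimal netpbm grayscale reader (P2 ASCII and P5 raw, maxval <= 65535).
readPGM <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file: ", path)
  header <- integer(0)
  buf <- character(0)
  readToken <- function() {
    repeat {
      ch <- readChar(con, 1)
      if (length(ch) == 0 || ch == "") stop("truncated PGM header: ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1)
          if (ch %in% c("\n", "")) break
        }
      } else if (!grepl("[[:space:]]", ch)) {
        tok <- ch
        repeat {
          ch <- readChar(con, 1)
          if (ch == "" || grepl("[[:space:]]", ch)) break
          tok <- paste0(tok, ch)
        }
        return(tok)
      }
    }
  }
  w <- as.integer(readToken()); h <- as.integer(readToken())
  maxval <- as.integer(readToken())
  n <- w * h
  vals <- if (magic == "P2") {
    as.numeric(scan(con, what = numeric(), n = n, quiet = TRUE))
  } else {
    if (maxval < 256) as.numeric(readBin(con, "integer", n, size = 1,
                                         signed = FALSE))
    else as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE,
                            endian = "big"))
  }
  if (length(vals) != n) stop("truncated PGM data: ", path)
  matrix(vals, h, w, byrow = TRUE)
}

## ASCII (P2) PGM writer; values written as rounded integers in [0, maxval].
writePGM <- function(image, path, maxval = 255) {
  m <- round(image)
  if (any(m < 0) || any(m > maxval)) stop("values outside [0, maxval]")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(maxval)), con)
  apply(m, 1, function(r) writeLines(paste(r, collapse = " "), con))
  invisible(path)
}

## ---- PFM ----------------------------------------------------------------

#' Read a PFM (portable float map) file
#'
#' Grayscale ("Pf") single-precision maps; the sign of the scale line gives
#' the byte order, rows are stored bottom-up per the PFM convention.
#'
#' @param path file path.
#' @return numeric matrix (top-down row order).
#' @export
readPFM <- function(path) {
  if (!file.exists(path)) stop("cannot read PFM: file not found: ", path)
  con <- file(path, "rb"); on.exit(close(con))
  readLineRaw <- function() {
    out <- character(0)
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || ch == "\n") break
      out <- c(out, ch)
    }
    paste(out, collapse = "")
  }
  magic <- readLineRaw()
  if (magic != "Pf") stop("only grayscale 'Pf' PFM is supported: ", path)
  dims <- as.integer(strsplit(trimws(readLineRaw()), "[[:space:]]+")[[1]])
  scale <- as.numeric(readLineRaw())
  endian <- if (scale < 0) "little" else "big"
  w <- dims[1]; h <- dims[2]
  vals <- readBin(con, "numeric", w * h, size = 4, endian = endian)
  m <- matrix(vals, h, w, byrow = TRUE)
  m[h:1, , drop = FALSE]   # bottom-up storage -> top-down matrix
}

#' Write a matrix as a PFM file
#'
#' Little-endian grayscale PFM (scale -1), rows bottom-up. NaN encodes
#' invalid pixels.
#'
#' @param image numeric matrix.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writePFM <- function(image, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeChar(paste0("Pf\n", ncol(image), " ", nrow(image), "\n-1.0\n"), con,
            eos = NULL)
  writeBin(as.numeric(t(image[nrow(image):1, , drop = FALSE])), con,
           size = 4, endian = "little")
  invisible(path)
}

#' Write a disparity map to disk
#'
#' The map is stored as 32-bit float PFM with invalid pixels as NaN.
#' Optionally a scaled preview is written next to it: 16-bit PGM (min..max
#' of the valid disparities mapped to 0..65535, invalid pixels 0) and/or
#' 8-bit PNG.
#'
#' @param map a \linkS4class{DisparityMap} (or matrix).
#' @param path output PFM path.
#' @param previewPath optional preview path (.pgm for 16-bit, .png for
#'   8-bit).
#' @return \code{path}, invisibly.
#' @export
writeDisparity <- function(map, path, previewPath = NULL) {
  d <- if (is(map, "DisparityMap")) map@disparity else map
  mask <- if (is(map, "DisparityMap")) map@validMask else
    matrix(TRUE, nrow(d), ncol(d))
  out <- d
  out[!mask] <- NaN
  writePFM(out, path)
  if (!is.null(previewPath)) {
    v <- d[mask]
    rng <- range(v)
    scl <- if (diff(rng) > 0) (d - rng[1]) / diff(rng) else d * 0
    scl[!mask] <- 0
    if (tolower(tools::file_ext(previewPath)) == "png")
      png::writePNG(pmin(pmax(scl, 0), 1), previewPath)
    else
      writePGM(round(scl * 65535), previewPath, maxval = 65535)
  }
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys are the arguments of \code{\link{stereoConfig}}; unknown
#' keys are rejected.
#'
#' @param path YAML file path.
#' @return a validated \code{\link{stereoConfig}}.
#' @export
readStereoConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(stereoConfig)))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(stereoConfig, vals)
}
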