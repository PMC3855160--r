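#' @include stereogram.R
NULL

## Extract matrices and the valid interior region shared by both metrics.
evalErrors <- function(est, truth, border) {
  e <- if (is(est, "DisparityMap")) est@disparity else est
  tr <- if (is(truth, "GroundTruthStereogram")) truth@truth else truth
  if (!identical(dim(e), dim(tr))) stop("estimate/truth dimensions differ")
  h <- nrow(e); w <- ncol(e)
  if (2 * border >= min(h, w)) stop("border leaves no valid pixels")
  rows <- (border + 1):(h - border); cols <- (border + 1):(w - border)
  mask <- matrix(FALSE, h, w); mask[rows, cols] <- TRUE
  if (is(est, "DisparityMap")) mask <- mask & est@validMask
  abs(e[mask] - tr[mask])
}

#' Percentage of wrongly matched pixels
#'
#' Percent of valid (interior) pixels whose absolute disparity error
#' strictly exceeds the threshold. Borders of \code{border} pixels on all
#' four sides are excluded; errors exactly equal to the threshold are not
#' counted.
#'
#' @param est \linkS4class{DisparityMap} or matrix of estimates.
#' @param truth \linkS4class{GroundTruthStereogram} or matrix of true
#'   disparities.
#' @param threshold error threshold in pixels (> 0); 0.25 px for synthetic
#'   stereograms, 1 px for real-world pairs.
#' @param border excluded frame width in pixels (13 synthetic default,
#'   18 for real-world pairs).
#' @return bad-pixel percentage in [0, 100].
#' @export
badPixelRate <- function(est, truth, threshold = 0.25, border = 13) {
  if (threshold <= 0) stop("threshold must be positive")
  err <- evalErrors(est, truth, border)
  100 * mean(err > threshold)
}

#' Root-mean-squared disparity error
#'
#' @inheritParams badPixelRate
#' @return RMSE in pixels over the valid interior.
#' @export
disparityRMSE <- function(est, truth, border = 13) {
  err <- evalErrors(est, truth, border)
  sqrt(mean(err^2))
}

#' Evaluate a disparity map against ground truth
#'
#' @inheritParams badPixelRate
#' @return an \linkS4class{EvalResult}.
#' @export
evaluateDisparity <- function(est, truth, threshold = 0.25, border = 13) {
  err <- evalErrors(est, truth, border)
  new("EvalResult", badPercent = 100 * mean(err > threshold),
      rmse = sqrt(mean(err^2)), threshold = threshold, border = border,
      nValid = length(err))
}

#' Monte-Carlo evaluation over seeded stereograms
#'
#' Generates \code{nReps} stereograms of one family with seeds
#' \code{seed .. seed + nReps - 1}, runs the full disparity pipeline on
#' each, and evaluates against ground truth. Returns the per-replicate
#' table and the mean bad-pixel percentage and RMSE.
#'
#' @param kind stereogram family passed to \code{\link{makeStereogram}}.
#' @param nReps number of replicates (>= 1).
#' @param seed first seed.
#' @param config pipeline configuration from \code{\link{stereoConfig}};
#'   hypothesis step defaults to the family's convention (1 px for
#'   "square", 0.25 px otherwise) unless the config sets one.
#' @param ... arguments forwarded to \code{\link{makeStereogram}}.
#' @return list with elements \code{summary} (named vector: meanB, meanR,
#'   nReps) and \code{replicates} (data.frame: kind, seed, family, B, R).
#' @export
batchEvaluate <- function(kind, nReps = 10, seed = 1,
                          config = stereoConfig(), ...) {
  if (nReps < 1) stop("nReps must be at least 1")
  if (is.null(config$hypStep))
    config$hypStep <- if (kind == "square") 1 else 0.25
  config <- do.call(stereoConfig, config)
  rows <- vector("list", nReps)
  for (i in seq_len(nReps)) {
    s <- seed + i - 1
    rds <- makeStereogram(kind, seed = s, ...)
    est <- estimateDisparity(rds, config = config)
    ev <- evaluateDisparity(est, rds, threshold = config$threshold,
                            border = config$border)
    rows[[i]] <- data.frame(kind = kind, seed = s, family = config$family,
                            B = ev@badPercent, R = ev@rmse)
  }
  reps <- do.call(rbind, rows)
  list(summary = c(meanB = mean(reps$B), meanR = mean(reps$R),
                   nReps = nReps),
       replicates = reps)
}
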