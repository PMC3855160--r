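test_that("frequency grid follows the unshifted polar layout", {
  g <- buildFrequencyGrid(8, 8)
  expect_identical(g@radius[1, 1], 0)                  # DC at (1,1)
  expect_equal(sum(g@radius == 0), 1)                  # only one DC bin
  expect_equal(g@angle[1, 2], 0)                       # one step along +x
  expect_equal(g@angle[2, 1], pi / 2)                  # one step along +y
  g16 <- buildFrequencyGrid(16, 16)
  expect_equal(max(g16@radius), sqrt(2) * 0.5)         # corner bin
  expect_error(buildFrequencyGrid(4, 8), "at least")
})

test_that("angular Gaussian has unit mode, correct falloff and mirror symmetry", {
  g <- buildFrequencyGrid(16, 16)
  st <- 0.6545
  w <- angularGaussian(g, 90, st)          # wave vector along +x
  expect_equal(w[1, 2], 1)                 # on-axis bin
  expect_true(all(w >= 0 & w <= 1))
  # bin (2,2) sits at exactly pi/4 off axis: with sigma = pi/4 that is one
  # angular sigma -> exp(-1/2)
  w45 <- angularGaussian(g, 90, pi / 4)
  expect_equal(w45[2, 2], exp(-1 / 2), tolerance = 1e-12)
  expect_equal(w[2, 2], exp(-(pi / 4)^2 / (2 * st^2)), tolerance = 1e-12)
  # mirror symmetry about the filter axis: (fx, fy) vs (fx, -fy)
  flipY <- w[c(1, 16:2), ]
  expect_equal(w, flipY, tolerance = 1e-12)
  expect_error(angularGaussian(g, 90, 0), "positive")
})

test_that("radial log-Gabor matches its closed form and is log-axis symmetric", {
  g <- buildFrequencyGrid(16, 16)
  w <- radialLogGabor(g, f0 = 0.25, sigmaRatio = 0.65)
  expect_equal(w[1, 5], 1)                 # bin at exactly f0 = 4/16
  expect_identical(w[1, 1], 0)             # DC defined as zero
  w2 <- radialLogGabor(g, f0 = 0.125, sigmaRatio = 0.65)
  # hand evaluation at rho = 2 f0
  expect_equal(w2[1, 5], exp(-log(2)^2 / (2 * log(0.65)^2)), tolerance = 1e-12)
  expect_equal(w2[1, 5], 0.2742, tolerance = 1e-3)
  # symmetric on a log axis: f0*k and f0/k carry equal weight (k = 2)
  expect_equal(w[1, 9], w[1, 3])           # 0.5 and 0.125 around f0 = 0.25
  # monotone decay with |ln(rho/f0)|
  fx <- c(0:8, 7:1) / 16
  row <- w[1, ]
  dists <- abs(log(fx[2:9] / 0.25))
  ord <- order(dists)
  expect_true(all(diff(row[2:9][ord]) <= 0))
  expect_error(radialLogGabor(g, 0.6, 0.65), "cycles/pixel")
  expect_error(radialLogGabor(g, 0.25, 1.2), "sigmaRatio")
})

test_that("log-Gabor quadrature pair is zero-DC and an exact Hilbert pair", {
  g <- buildFrequencyGrid(32, 32)
  for (ori in c(30, 60, 90, 210)) {
    f <- composeLogGabor(g, channelSpec(ori, 6))
    ev <- evenWeights(f); od <- oddWeights(f)
    expect_identical(ev[1, 1], 0)
    expect_identical(od[1, 1], 0 + 0i)
    nonDC <- matrix(TRUE, 32, 32); nonDC[1, 1] <- FALSE
    expect_lt(max(abs(abs(ev[nonDC]) - abs(od[nonDC]))), 1e-12)
  }
})

test_that("log-Gabor half-amplitude bandwidth is about 1.5 octaves at sigma ratio 0.65", {
  g <- buildFrequencyGrid(512, 8)
  w <- radialLogGabor(g, f0 = 0.1, sigmaRatio = 0.65)
  fx <- (0:255) / 512
  row <- w[1, 1:256]
  above <- which(row >= 0.5)
  octaves <- log2(fx[max(above)] / fx[min(above)])
  expect_equal(octaves, 1.5, tolerance = 0.1)
})

test_that("spatial kernels are even/odd symmetric about the filter centre", {
  g <- buildFrequencyGrid(64, 64)
  for (spec in list(channelSpec(90, 8), channelSpec(30, 6),
                    channelSpec(60, 8, family = "gabor"))) {
    f <- composeFilter(g, spec)
    k <- spatialKernels(f)
    flip <- function(m) m[c(nrow(m):1), c(ncol(m):1)]
    # centre of the shifted layout sits at (n/2+1, n/2+1); reflecting the
    # full grid about it maps index i -> n+2-i, so drop row/col 1 first
    e <- k$even[-1, -1]; o <- k$odd[-1, -1]
    peak <- max(abs(k$even))
    expect_lt(max(abs(e - flip(e))) / peak, 1e-9)
    expect_lt(max(abs(o + flip(o))) / peak, 1e-9)
  }
})

test_that("Gabor pair keeps DC in the even filter but not the odd one", {
  g <- buildFrequencyGrid(64, 64)
  f <- composeGabor(g, channelSpec(90, 8, family = "gabor"))
  ev <- evenWeights(f); od <- oddWeights(f)
  expect_gt(ev[1, 1], 0)                   # DC leak above one octave
  expect_identical(od[1, 1], 0 + 0i)
  # even transfer peaks at f0 along the wave-vector axis
  expect_equal(which.max(ev[1, 1:32]), 9)  # f0 = 1/8 -> bin 8/64 + 1
})

test_that("filter banks use the documented wavelengths, orientations and ordering", {
  b <- makeFilterBank("log_gabor")
  lams <- vapply(channels(b), function(ch) ch@wavelengthPx, numeric(1))
  oris <- vapply(channels(b), function(ch) ch@orientationDeg, numeric(1))
  expect_equal(length(channels(b)), 24)
  expect_equal(sort(unique(lams)), c(3, 4.8, 7.68, 12.288))
  expect_equal(sort(unique(oris)), c(30, 60, 90, 210, 240, 270))
  # coarsest first
  expect_equal(lams[1], 12.288)
  expect_true(all(diff(match(lams, sort(unique(lams), TRUE))) >= 0))

  bg <- makeFilterBank("gabor", pixelsPerDegree = 12)
  lamsG <- vapply(channels(bg), function(ch) ch@wavelengthPx, numeric(1))
  expect_equal(sort(unique(lamsG)), c(3, 6, 12, 24))   # 4,2,1,0.5 c/deg
  expect_equal(sort(unique(vapply(channels(bg),
                                  function(ch) ch@orientationDeg,
                                  numeric(1)))),
               c(30, 60, 90, 120, 150, 180))
  expect_error(makeFilterBank("log_gabor", lambdaMinPx = 1.5), ">= 2 px")
})
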