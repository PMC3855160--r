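grating <- function(n, f0, oriDeg, phase = 0) {
  th <- (oriDeg - 90) * pi / 180
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  y <- matrix(rep(0:(n - 1), n), n, n)
  cos(2 * pi * f0 * (x * cos(th) + y * sin(th)) + phase)
}

test_that("mean-luminance subtraction is exact and idempotent", {
  img <- matrix(runif(64), 8, 8)
  p <- preprocessImage(img)
  expect_lt(abs(mean(p)), 1e-10)
  expect_equal(preprocessImage(p), p)
  expect_equal(preprocessImage(matrix(7, 5, 5)), matrix(0, 5, 5))
  expect_error(preprocessImage(matrix(numeric(0), 0, 0)), "non-empty")
  expect_error(preprocessImage(matrix(c(1, NA, 3, 4), 2, 2)), "finite")
})

test_that("filtering is linear and maps zero to zero", {
  g <- buildFrequencyGrid(32, 32)
  f <- composeLogGabor(g, channelSpec(90, 6))
  set.seed(1)
  i1 <- preprocessImage(matrix(runif(1024), 32, 32))
  i2 <- preprocessImage(matrix(runif(1024), 32, 32))
  r1 <- filterImage(i1, f); r2 <- filterImage(i2, f)
  r12 <- filterImage(2 * i1 - 3 * i2, f)
  expect_equal(r12@evenPart, 2 * r1@evenPart - 3 * r2@evenPart,
               tolerance = 1e-10)
  expect_equal(r12@oddPart, 2 * r1@oddPart - 3 * r2@oddPart,
               tolerance = 1e-10)
  r0 <- filterImage(matrix(0, 32, 32), f)
  expect_equal(max(abs(r0@evenPart)), 0)
  expect_error(filterImage(matrix(0, 16, 16), f), "dimensions")
})

test_that("a preferred grating drives a uniform-energy quadrature response", {
  n <- 64; f0 <- 1 / 8
  img <- grating(n, f0, 90)
  pair <- stereoPair(img, img)
  g <- buildFrequencyGrid(n, n)
  f <- composeLogGabor(g, channelSpec(90, 8))
  em <- complexCellEnergy(pair, f, 0)
  e <- em@energy
  expect_gt(min(e), 0)
  expect_lt(diff(range(e)) / mean(e), 1e-6)
})

test_that("positional shifts compose additively and integer shifts are circular", {
  g <- buildFrequencyGrid(32, 32)
  f <- composeLogGabor(g, channelSpec(60, 6))
  expect_identical(applyPositionalShift(f, 0)@transfer, f@transfer)
  ab <- applyPositionalShift(applyPositionalShift(f, 1.3), -0.55)
  once <- applyPositionalShift(f, 0.75)
  expect_equal(ab@transfer, once@transfer, tolerance = 1e-12)
  # integer shift on a periodic pattern equals a circular column roll
  set.seed(2)
  img <- preprocessImage(matrix(runif(1024), 32, 32))
  r0 <- filterImage(img, f)
  r3 <- filterImage(img, f, shiftPx = 3)
  expect_equal(r3@evenPart, r0@evenPart[, c(30:32, 1:29)], tolerance = 1e-9)
})

test_that("push-pull pairs square the binocular sum exactly", {
  sp <- channelSpec(90, 6)
  mk <- function(e, o, eye) new("MonocularResponse", evenPart = e,
                                oddPart = o, spec = sp, eye = eye,
                                shiftPx = 0)
  l <- mk(matrix(-3, 2, 2), matrix(1, 2, 2), "left")
  r <- mk(matrix(0, 2, 2), matrix(2, 2, 2), "right")
  expect_equal(simpleCellPair(l, r, "even"), matrix(9, 2, 2))   # (-3)^2
  expect_equal(simpleCellPair(l, r, "odd"), matrix(9, 2, 2))    # 3^2
  set.seed(3)
  a <- mk(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8), "left")
  b <- mk(matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8), "right")
  expect_equal(simpleCellPair(a, b, "even"), (a@evenPart + b@evenPart)^2)
  bad <- mk(matrix(0, 8, 8), matrix(0, 8, 8), "right")
  bad@spec <- channelSpec(30, 6)
  expect_error(simpleCellPair(a, bad), "different channels")
})

test_that("identical images at zero disparity quadruple the monocular energy", {
  set.seed(4)
  img <- matrix(runif(1024), 32, 32)
  g <- buildFrequencyGrid(32, 32)
  f <- composeLogGabor(g, channelSpec(90, 6))
  mono <- filterImage(preprocessImage(img), f)
  em <- complexCellEnergy(stereoPair(img, img), f, 0)
  expect_equal(em@energy, 4 * (mono@evenPart^2 + mono@oddPart^2),
               tolerance = 1e-10)
  expect_true(all(em@energy >= 0))
})

test_that("complex-cell energy is invariant to absolute stimulus phase", {
  n <- 64; f0 <- 1 / 8
  g <- buildFrequencyGrid(n, n)
  f <- composeLogGabor(g, channelSpec(90, 8))
  base <- NULL
  for (ph in seq(0, 2 * pi, length.out = 9)[-9]) {
    img <- grating(n, f0, 90, ph)
    e <- complexCellEnergy(stereoPair(img, img), f, 2)@energy
    m <- mean(e)
    if (is.null(base)) base <- m
    expect_lt(abs(m - base) / base, 1e-6)
  }
})

test_that("energy tuning is even in disparity for identical eyes", {
  set.seed(5)
  img <- matrix(runif(4096), 64, 64)
  pair <- stereoPair(img, img)
  g <- buildFrequencyGrid(64, 64)
  for (spec in list(channelSpec(90, 8), channelSpec(30, 12.288))) {
    f <- composeLogGabor(g, spec)
    for (d in c(1, 2.5, 4)) {
      ep <- complexCellEnergy(pair, f, d)@energy
      en <- complexCellEnergy(pair, f, -d)@energy
      expect_lt(max(abs(ep - en)) / max(ep), 1e-8)
    }
  }
})

test_that("spatially averaged energy peaks at the true uniform disparity", {
  hyp <- disparityHypotheses(-4, 4, 1)
  for (seed in 1:3) {
    for (d in c(-3, 0, 2)) {
      rds <- smallPair(seed, 64, d)
      g <- buildFrequencyGrid(64, 64)
      for (lam in c(12.288, 7.68)) {       # wavelength > 2|d|
        f <- composeLogGabor(g, channelSpec(90, lam))
        stk <- scanDisparities(rds, f, hyp, smooth = FALSE)
        prof <- apply(energies(stk)[15:50, 15:50, ], 3, mean)
        expect_equal(hypotheses(hyp)[which.max(prof)], d)
      }
    }
  }
})

test_that("the hypothesis scan matches per-hypothesis energy calls", {
  rds <- smallPair(7, 48, 1.5)
  g <- buildFrequencyGrid(48, 48)
  f <- composeLogGabor(g, channelSpec(60, 7.68))
  hyp <- disparityHypotheses(-3, 3, 0.25)
  stk <- scanDisparities(rds, f, hyp, smooth = FALSE)
  for (k in c(1, 7, 13, 25)) {
    em <- complexCellEnergy(rds, f, hypotheses(hyp)[k])
    expect_equal(energies(stk)[, , k], em@energy, tolerance = 1e-12)
  }
  # quadratic in contrast
  rds2 <- stereoPair(2 * leftImage(rds), 2 * rightImage(rds))
  stk2 <- scanDisparities(rds2, f, hyp, smooth = FALSE)
  expect_equal(energies(stk2), 4 * energies(stk), tolerance = 1e-10)
  expect_error(scanDisparities(rds, f,
                               new("DisparityHypothesisSet",
                                   values = numeric(0), step = 1)))
})
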