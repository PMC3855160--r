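test_that("local extrema detection handles peaks, plateaus and endpoints", {
  ex <- findLocalExtrema(c(1, 5, 1), c(-1, 0, 1))
  expect_equal(nrow(ex), 1)
  expect_equal(ex$disparity, 0)
  expect_equal(ex$value, 5)
  expect_equal(ex$kind, "max")

  expect_equal(nrow(findLocalExtrema(1:6, seq(-2.5, 2.5, 1))), 0)

  ex <- findLocalExtrema(c(3, 1, 4, 1, 5), -2:2)
  expect_equal(ex$disparity, c(-1, 0, 1))
  expect_equal(ex$value, c(1, 4, 1))
  expect_equal(ex$kind, c("min", "max", "min"))

  # odd plateau -> centre; even plateau -> centre candidate nearer zero
  ex <- findLocalExtrema(c(0, 2, 2, 2, 0), -2:2)
  expect_equal(ex$disparity, 0)
  ex <- findLocalExtrema(c(0, 2, 2, 0), c(-2, -1, 0, 1))
  expect_equal(ex$disparity, 0)
  # plateau touching an endpoint is not an extremum
  expect_equal(nrow(findLocalExtrema(c(2, 2, 0, 1), -2:1)), 1)
  expect_error(findLocalExtrema(c(1, 2), c(0, 1)), "at least 3")
})

test_that("extrema detection agrees with a brute-force oracle on random profiles", {
  set.seed(42)
  for (i in 1:500) {
    n <- sample(5:12, 1)
    p <- randomProfile(n, tied = i %% 2 == 0)
    hyp <- seq(-2, length.out = n, by = 0.5)
    got <- findLocalExtrema(p, hyp)
    want <- oracleExtrema(p, hyp)
    expect_equal(got$index, want$index)
    expect_equal(got$value, want$value)
    expect_equal(got$kind, want$kind)
  }
})

test_that("first-scale selection takes the biggest extremum, with stated ties and fallback", {
  # a lone minimum is selected even when endpoints dwarf it
  p <- c(20, 12, 13, 14, 15, 16)
  hyp <- -2:3
  stk <- stackFromProfiles(matrix(p, 1), hyp)
  sel <- selectFirstScale(stk)
  expect_equal(disparity(sel)[1, 1], -1)
  expect_equal(responseMap(sel)[1, 1], 12)
  # ... and the biggest |value| wins when maxima and minima coexist
  p2 <- c(20, 12, 30, 5, 10, 8)
  sel2 <- selectFirstScale(stackFromProfiles(matrix(p2, 1), hyp))
  expect_equal(disparity(sel2)[1, 1], 0)       # the 30-valued maximum
  expect_equal(responseMap(sel2)[1, 1], 30)
  # single peak
  sel <- selectFirstScale(stackFromProfiles(matrix(c(1, 5, 1), 1), -1:1))
  expect_equal(disparity(sel)[1, 1], 0)
  # no interior extremum -> global maximum
  sel <- selectFirstScale(stackFromProfiles(matrix(1:5, 1), -2:2))
  expect_equal(disparity(sel)[1, 1], 2)
  # magnitude tie -> smaller |disparity|
  sel <- selectFirstScale(stackFromProfiles(matrix(c(0, 7, 0, 7, 0, 0), 1),
                                            -3:2))
  expect_equal(disparity(sel)[1, 1], 0)
})

test_that("refinement picks the extremum nearest the previous map", {
  # extrema at -4, 1 and 2.75
  hyp <- seq(-5, 3, 0.25)
  p <- rep(1, length(hyp))
  p[hyp == -4] <- 9; p[hyp == 1] <- 5; p[hyp == 2.75] <- 7
  stk <- stackFromProfiles(matrix(p, 1), hyp)
  sel <- selectRefine(stk, matrix(3, 1, 1))
  expect_equal(disparity(sel)[1, 1], 2.75)
  # previous value already an extremum stays put
  sel <- selectRefine(stk, matrix(1, 1, 1))
  expect_equal(disparity(sel)[1, 1], 1)
  # no extrema -> carry previous
  flat <- stackFromProfiles(matrix(seq(1, 2, length.out = length(hyp)), 1),
                            hyp)
  sel <- selectRefine(flat, matrix(-1.5, 1, 1))
  expect_equal(disparity(sel)[1, 1], -1.5)
  expect_error(selectRefine(stk, matrix(0, 2, 2)), "dimensions")
})

test_that("selection agrees with exhaustive oracles on random profiles", {
  set.seed(7)
  nprof <- 1000
  n <- 9
  hyp <- seq(-2, 2, 0.5)
  profiles <- t(replicate(nprof, randomProfile(n, tied = runif(1) < 0.5)))
  stk <- stackFromProfiles(profiles, hyp)
  first <- selectFirstScale(stk)
  prev <- matrix(runif(nprof, -2.2, 2.2), 1, nprof)
  refined <- selectRefine(stk, prev)
  for (i in seq_len(nprof)) {
    expect_identical(disparity(first)[1, i],
                     oracleSelectFirst(profiles[i, ], hyp))
    expect_identical(disparity(refined)[1, i],
                     oracleSelectRefine(profiles[i, ], hyp, prev[1, i]))
  }
  # refinement locality: no other extremum lies closer to the previous value
  for (i in seq_len(nprof)) {
    ex <- oracleExtrema(profiles[i, ], hyp)
    if (nrow(ex) > 0)
      expect_true(all(abs(disparity(refined)[1, i] - prev[1, i]) <=
                        abs(ex$disparity - prev[1, i]) + 1e-12))
  }
})

test_that("coarse-to-fine yields one in-set map per orientation and scale", {
  rds <- smallPair(11, 64, 2)
  bank <- makeFilterBank("log_gabor")
  hyp <- disparityHypotheses(-4, 4, 1)
  maps <- runCoarseToFine(rds, bank, hyp)
  expect_length(maps, 24)
  for (m in maps)
    expect_true(all(disparity(m) %in% hypotheses(hyp)))   # closure
  # determinism
  maps2 <- runCoarseToFine(rds, bank, hyp)
  expect_identical(lapply(maps, disparity), lapply(maps2, disparity))
})

test_that("conjugate orientations produce identical energies and maps", {
  rds <- smallPair(13, 64, 1)
  g <- buildFrequencyGrid(64, 64)
  hyp <- disparityHypotheses(-3, 3, 1)
  s30 <- scanDisparities(rds, composeLogGabor(g, channelSpec(30, 7.68)), hyp,
                         smooth = FALSE)
  s210 <- scanDisparities(rds, composeLogGabor(g, channelSpec(210, 7.68)),
                          hyp, smooth = FALSE)
  expect_equal(energies(s30), energies(s210), tolerance = 1e-10)
  bank <- makeFilterBank("log_gabor")
  maps <- runCoarseToFine(rds, bank, hyp)
  oris <- vapply(maps, function(m) m@spec@orientationDeg, numeric(1))
  lams <- vapply(maps, function(m) m@spec@wavelengthPx, numeric(1))
  i30 <- which(oris == 30 & lams == 3)
  i210 <- which(oris == 210 & lams == 3)
  expect_identical(disparity(maps[[i30]]), disparity(maps[[i210]]))
})

test_that("refinement does not degrade the coarse ramp solution", {
  rmse_of <- function(m, truth, b = 13)
    sqrt(mean((disparity(m)[(b + 1):(128 - b), (b + 1):(128 - b)] -
                 truth[(b + 1):(128 - b), (b + 1):(128 - b)])^2))
  deltas <- c()
  for (seed in 1:3) {
    truth <- disparityProfileRamp(128, 128, size = 100)
    dots <- randomDotField(128, 128, seed = seed)
    pr <- warpStereogram(dots, truth, seed = seed)
    bank <- makeFilterBank("log_gabor", orientationsDeg = c(30, 60, 90))
    # raw responses: the property concerns the selection chain itself
    maps <- runCoarseToFine(pr, bank, disparityHypotheses(-6, 6, 0.25),
                            smooth = FALSE)
    lams <- vapply(maps, function(m) m@spec@wavelengthPx, numeric(1))
    oris <- vapply(maps, function(m) m@spec@orientationDeg, numeric(1))
    coarse <- rmse_of(maps[[which(oris == 90 & abs(lams - 12.288) < 1e-9)]],
                      truth)
    fine <- rmse_of(maps[[which(oris == 90 & abs(lams - 3) < 1e-9)]], truth)
    deltas <- c(deltas, fine - coarse)
  }
  expect_lte(median(deltas), 0)
})
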