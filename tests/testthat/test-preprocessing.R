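test_that("ROI cropping uses 0-based pixel-center index arithmetic", {
  spec <- cleanSpec()
  sim <- simulateSeries(spec, fairProtocol("FAIR-PI2_D"))
  # mark source pixel (43, 43) 0-based = [44, 44] 1-based
  marked <- sim$series
  px <- pixels(m0Frame(marked))
  px[44, 44] <- 12345
  marked@m0@pixels <- px
  crop <- cropROI(marked, sizePx = 64)
  expect_equal(dim(pixels(m0Frame(crop))), c(64, 64))
  expect_equal(pixels(m0Frame(crop))[1, 1], 12345)
  # full-grid window is the identity
  full <- cropROI(sim$series, centerPx = c(75, 75), sizePx = 150)
  expect_identical(pixels(m0Frame(full)), pixels(m0Frame(sim$series)))
  # window partially outside the grid is rejected
  expect_error(cropROI(sim$series, centerPx = c(10, 10), sizePx = 64),
               "exceeds")
})

test_that("inversion-time correction matches the signal model", {
  m0 <- ImageFrame(matrix(1000, 2, 2), "m0")
  frame <- ImageFrame(matrix(400, 2, 2), "control", index = 1,
                      actualTiMs = 1100)
  # dTI = +100 ms, T1 = 1700 ms: 1000 - 600 exp(100/1700) = 363.65
  out <- correctInversionTime(frame, m0, 1000, 1700)
  expect_equal(pixels(out)[1, 1], 1000 - 600 * exp(100 / 1700),
               tolerance = 1e-12)
  expect_equal(round(pixels(out)[1, 1], 2), 363.65)
  expect_equal(actualTI(out), 1000)
  # dTI = 0 is the identity
  same <- correctInversionTime(
    ImageFrame(matrix(400, 2, 2), "control", 1, 1000), m0, 1000, 1700)
  expect_identical(pixels(same), matrix(400, 2, 2))
  # I = M0 stays M0 for any dTI
  atM0 <- correctInversionTime(
    ImageFrame(matrix(1000, 2, 2), "control", 1, 1234), m0, 1000, 1700)
  expect_equal(pixels(atM0), matrix(1000, 2, 2))
  expect_error(correctInversionTime(frame, m0, 1000, -1), "positive")
})

test_that("inversion-time correction is invertible", {
  set.seed(7)
  m0 <- ImageFrame(matrix(1000, 8, 8), "m0")
  for (dTi in c(-80, 15, 120)) {
    px <- matrix(rnorm(64, 300, 150), 8, 8)
    f <- ImageFrame(px, "tagged", 2, 1000 + dTi)
    fwd <- correctInversionTime(f, m0, 1000, 1700)
    fwd@actualTiMs <- 1000
    back <- correctInversionTime(fwd, m0, 1000 + dTi, 1700)
    expect_equal(pixels(back), px, tolerance = 1e-12)
  }
})

test_that("series averaging is the pixelwise mean with mean TI", {
  frames <- lapply(1:6, function(i)
    ImageFrame(matrix(i, 3, 3), "control", i, 990 + i * 4))
  avg <- averageSeries(frames)
  expect_equal(pixels(avg$frame), matrix(3.5, 3, 3))
  expect_equal(avg$tiMs, mean(990 + (1:6) * 4))
  same <- averageSeries(frames[c(2, 2, 2)])
  expect_identical(pixels(same$frame), matrix(2, 3, 3))
  two <- averageSeries(list(
    ImageFrame(matrix(0, 2, 2), "tagged", 1, 990),
    ImageFrame(matrix(0, 2, 2), "tagged", 2, 1010)))
  expect_equal(two$tiMs, 1000)
  expect_error(averageSeries(list()), "empty")
})

test_that("registration recovers injected transforms", {
  img <- asymmetricImage()
  cases <- list(c(3, -2, 0), c(-2.2, 1.4, 0), c(0, 0, 5), c(1.5, -1, 2.5))
  for (par in cases) {
    tf <- RigidTransform(par[1], par[2], par[3])
    moving <- applyTransform(img, tf, fill = 50)
    attr(moving, "inBounds") <- NULL
    reg <- registerRigid(moving, img, "mean_squares")
    inv <- invertTransform(tf)
    expect_lt(abs(reg$transform@txPx - inv@txPx), 0.5)
    expect_lt(abs(reg$transform@tyPx - inv@tyPx), 0.5)
    expect_lt(abs(reg$transform@thetaDeg - inv@thetaDeg), 0.5)
  }
})

test_that("registration of identical frames returns the exact identity", {
  img <- asymmetricImage()
  for (metric in c("mean_squares", "mutual_information")) {
    reg <- registerRigid(img, img, metric)
    expect_identical(reg$transform@txPx, 0)
    expect_identical(reg$transform@tyPx, 0)
    expect_identical(reg$transform@thetaDeg, 0)
    expect_identical(reg$aligned, img)
  }
})

test_that("cross-contrast registration to M0 recovers translation", {
  fw <- forwardSignals(cleanSpec(), fairProtocol("FAIR-PI2_D"))
  img <- FAIRmbf:::cropMatrix(fw$control, sizePx = 64)
  m0c <- FAIRmbf:::cropMatrix(fw$m0, sizePx = 64)
  tf <- RigidTransform(2.5, -1.5, 0)
  moving <- applyTransform(img, tf, fill = 50)
  attr(moving, "inBounds") <- NULL
  reg <- registerRigid(moving, m0c, "mutual_information")
  expect_lt(abs(reg$transform@txPx + 2.5), 0.5)
  expect_lt(abs(reg$transform@tyPx - 1.5), 0.5)
})

test_that("transform composition and inversion are consistent", {
  set.seed(11)
  pts <- cbind(runif(20, -20, 20), runif(20, -20, 20))
  applyPts <- function(tf, p) {
    th <- tf@thetaDeg * pi / 180
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    t(R %*% t(p)) + rep(c(tf@txPx, tf@tyPx), each = nrow(p))
  }
  for (i in 1:5) {
    t1 <- RigidTransform(runif(1, -3, 3), runif(1, -3, 3), runif(1, -10, 10))
    t2 <- RigidTransform(runif(1, -3, 3), runif(1, -3, 3), runif(1, -10, 10))
    expect_equal(applyPts(composeTransforms(t2, t1), pts),
                 applyPts(t2, applyPts(t1, pts)), tolerance = 1e-12)
    expect_equal(applyPts(invertTransform(t1), applyPts(t1, pts)), pts,
                 tolerance = 1e-12)
  }
})

test_that("the full pipeline is exact on uncorrupted series", {
  spec <- cleanSpec(seed = 5)
  prot <- fairProtocol("FAIR-PI2_D")
  sim <- simulateSeries(spec, prot)
  prep <- preprocessSeries(sim$series)
  for (tf in prep@transformLog$withinControl)
    expect_true(FAIRmbf:::isIdentityTransform(tf))
  expect_true(FAIRmbf:::isIdentityTransform(prep@transformLog$controlToM0))
  fw <- forwardSignals(spec, prot)
  expect_equal(pixels(prep@controlAvg),
               FAIRmbf:::cropMatrix(fw$control, sizePx = 64),
               tolerance = 1e-12)
  map <- quantifyPrepared(prep, cropMask(sim$truth))
  expect_lt(max(abs(myoValues(map) - 1.5)) / 1.5, 1e-9)
})

test_that("inversion-time correction makes the jittered pipeline exact", {
  spec <- cleanSpec(seed = 5, tiJitterFrac = 0.05)
  sim <- simulateSeries(spec, fairProtocol("FAIR-PI2_D"))
  tis <- vapply(controls(sim$series), actualTI, numeric(1))
  expect_gt(diff(range(tis)), 1)  # jitter actually present
  prep <- preprocessSeries(sim$series)
  map <- quantifyPrepared(prep, cropMask(sim$truth))
  expect_lt(max(abs(myoValues(map) - 1.5)) / 1.5, 1e-6)
})

test_that("correcting after averaging is not equivalent (stage order guard)", {
  spec <- cleanSpec(seed = 8, tiJitterFrac = 0.05)
  sim <- simulateSeries(spec, fairProtocol("FAIR-PI2_D"))
  cropped <- cropROI(sim$series)
  # pipeline order: correct each frame, then average
  nomC <- mean(vapply(controls(cropped), actualTI, numeric(1)))
  corrected <- lapply(controls(cropped), correctInversionTime,
                      m0 = m0Frame(cropped), nominalTiMs = nomC, t1Ms = 1700)
  good <- averageSeries(corrected)$frame
  # swapped order: average raw frames, then correct once at the mean TI
  rawAvg <- averageSeries(controls(cropped))$frame
  swapped <- correctInversionTime(rawAvg, m0Frame(cropped), nomC, 1700)
  expect_gt(max(abs(pixels(good) - pixels(swapped))), 0.01)
})

test_that("stage failures carry the stage identity", {
  spec <- cleanSpec()
  sim <- simulateSeries(spec, fairProtocol("FAIR-PI2_D"))
  expect_error(preprocessSeries(sim$series, centerPx = c(5, 5)),
               "stage 'crop'")
})
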