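test_that("quantification matches a hand-evaluated scalar case", {
  # M0 = 1000, C = 600, T = 550, TI_C = TI_T = 1200 ms, T1 = 1700 ms:
  # 60000 * (50/1200) * exp(-1200/1700) / 2000 = 0.61709...
  m <- mbfMap(matrix(600), matrix(550), matrix(1000), 1200, 1200, 1700)
  expect_equal(as.numeric(mbfValues(m)),
               60000 / 2000 * (600 / 1200 - 550 / 1200) * exp(-1200 / 1700))
  expect_equal(as.numeric(mbfValues(m)), 0.617, tolerance = 1e-3)
})

test_that("quantification vanishes when the two terms balance", {
  # choose C so that (C/TI_C) e^(-TI_C/T1) = (T/TI_T) e^(-TI_T/T1)
  tiC <- 980; tiT <- 1040; t1 <- 1700; Tv <- 520
  Cv <- tiC * (Tv / tiT) * exp((tiC - tiT) / t1)
  m <- mbfMap(matrix(Cv), matrix(Tv), matrix(1000), tiC, tiT, t1)
  expect_equal(as.numeric(mbfValues(m)), 0, tolerance = 1e-12)
})

test_that("quantification is scale invariant and antisymmetric", {
  set.seed(3)
  C <- matrix(runif(64, 400, 700), 8, 8)
  T <- matrix(runif(64, 350, 650), 8, 8)
  M0 <- matrix(runif(64, 800, 1200), 8, 8)
  base <- mbfValues(mbfMap(C, T, M0, 1100, 1050, 1700))
  for (k in c(0.5, 3, 17)) {
    scaled <- mbfValues(mbfMap(k * C, k * T, k * M0, 1100, 1050, 1700))
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  swapped <- mbfValues(mbfMap(T, C, M0, 1100, 1100, 1700))
  direct <- mbfValues(mbfMap(C, T, M0, 1100, 1100, 1700))
  expect_equal(swapped, -direct, tolerance = 1e-12)
})

test_that("low-M0 pixels are invalidated, not zeroed", {
  M0 <- matrix(1000, 4, 4); M0[1, 1] <- 10  # below 5 % of max
  m <- mbfMap(matrix(600, 4, 4), matrix(550, 4, 4), M0, 1000, 1000, 1700)
  expect_false(validMask(m)[1, 1])
  expect_true(is.na(mbfValues(m)[1, 1]))
  expect_true(all(validMask(m)[-1]))
  # an all-invalid map is flagged, not an error
  allBad <- mbfMap(matrix(1, 2, 2), matrix(1, 2, 2),
                   matrix(0, 2, 2), 1000, 1000, 1700)
  expect_true(attr(allBad, "allInvalid"))
})

test_that("per-pair maps average to the averaged-pair map when TIs agree", {
  # with equal TIs the quantification is linear in C and T, so the mean
  # of the six per-pair maps equals the map of the averaged pair
  spec <- cleanSpec(seed = 6, thermalSigma = 0.01)
  prot <- fairProtocol("FAIR-PI2_D")
  sim <- simulateSeries(spec, prot)  # zero jitter: all TIs = 1000
  maps <- perPairMaps(sim$series, registration = FALSE)
  myo <- cropMask(sim$truth)
  meanOfMaps <- Reduce(`+`, lapply(maps, mbfValues)) / 6
  cropped <- cropROI(sim$series)
  avgC <- averageSeries(controls(cropped))
  avgT <- averageSeries(taggeds(cropped))
  ofAvg <- mbfMap(avgC$frame, avgT$frame, m0Frame(cropped),
                  avgC$tiMs, avgT$tiMs, 1700)
  expect_equal(meanOfMaps[myo], mbfValues(ofAvg)[myo], tolerance = 1e-9)
})

test_that("per-pair maps are unbiased under physiological noise", {
  # zero-mean signal noise: the pixelwise mean over seeds and pairs
  # converges to the truth (CS3 window: per-pair ROI-mean SD ~0.06)
  spec0 <- cleanSpec(physioK = 0.004)
  prot <- fairProtocol("FAIR-CS3_S")
  nSeeds <- 50
  acc <- NULL; myo <- NULL
  for (s in seq_len(nSeeds)) {
    spec0@seed <- 1000 + s
    sim <- simulateSeries(spec0, prot)
    if (is.null(myo)) myo <- cropMask(sim$truth)
    maps <- perPairMaps(sim$series, registration = FALSE)
    m <- Reduce(`+`, lapply(maps, mbfValues)) / 6
    acc <- if (is.null(acc)) m else acc + m
  }
  pixelMean <- acc[myo] / nSeeds
  expect_lt(mean(abs(pixelMean - 1.5)), 0.15)
  expect_lt(abs(mean(pixelMean) - 1.5), 0.05)
})

test_that("per-pair maps reproduce the truth on uncorrupted series", {
  spec <- cleanSpec(seed = 2)
  sim <- simulateSeries(spec, fairProtocol("FAIR-PI2_S"))
  myo <- cropMask(sim$truth)
  maps <- perPairMaps(sim$series, myo = myo)
  for (m in maps)
    expect_lt(max(abs(myoValues(m) - 1.5)) / 1.5, 1e-9)
})

test_that("regional sectors partition the annulus into balanced quadrants", {
  g <- makeGeometry(PhantomSpec(), "diastole")
  myo <- g$myocardium
  lab <- regionalSectors(myo, rvDirectionDeg = 180)
  expect_true(all(!is.na(lab[myo])))
  expect_true(all(is.na(lab[!myo])))
  counts <- table(lab[myo])
  expect_setequal(names(counts), c("septal", "anterior", "lateral", "inferior"))
  expect_equal(sum(counts), sum(myo))
  expect_true(all(abs(counts / sum(myo) - 0.25) <= 0.02))
  # septal quadrant faces image left; anterior faces the image top
  idx <- which(myo, arr.ind = TRUE)
  cx <- mean(idx[, "col"]); cy <- mean(idx[, "row"])
  septal <- which(lab == "septal", arr.ind = TRUE)
  expect_true(all(septal[, "col"] < cx))
  anterior <- which(lab == "anterior", arr.ind = TRUE)
  expect_true(all(anterior[, "row"] < cy))
  expect_error(regionalSectors(matrix(FALSE, 4, 4)), "empty")
})

test_that("map summaries report count, moments and histogram", {
  vals <- matrix(1.5, 30, 30)
  mask <- matrix(FALSE, 30, 30); mask[5:25, 5:25] <- TRUE
  m <- new("MBFMap", values = vals, validMask = matrix(TRUE, 30, 30),
           myoMask = mask)
  s <- summarizeMap(m)
  expect_equal(s$nPixels, sum(mask))
  expect_equal(s$meanMbf, 1.5)
  expect_equal(s$sdMbf, 0)
  expect_equal(sum(s$histogram$counts), sum(mask))
  # half at 1, half at 2
  vals2 <- vals; vals2[, 1:15] <- 1; vals2[, 16:30] <- 2
  m2 <- new("MBFMap", values = vals2, validMask = matrix(TRUE, 30, 30),
            myoMask = mask)
  s2 <- summarizeMap(m2)
  expect_equal(s2$meanMbf, 1.5, tolerance = 0.03)
  expect_length(s2$histogram$counts, 50)
  # regional means follow an imposed septal-lateral gradient
  lab <- regionalSectors(mask)
  s3 <- summarizeMap(m2, regions = lab)
  expect_setequal(s3$regional$region,
                  c("septal", "anterior", "lateral", "inferior"))
  sept <- s3$regional$mean_mbf[s3$regional$region == "septal"]
  lat <- s3$regional$mean_mbf[s3$regional$region == "lateral"]
  expect_lt(sept, lat)
})
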