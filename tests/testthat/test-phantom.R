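test_that("rasterized annulus areas match the analytic geometry", {
  spec <- PhantomSpec()
  dia <- makeGeometry(spec, "diastole")
  sys <- makeGeometry(spec, "systole")
  # pi (34^2 - 25^2) = 1668 mm^2 over 4 mm^2 pixels, +-5 % rasterization
  expect_gte(sum(dia$myocardium), 396)
  expect_lte(sum(dia$myocardium), 438)
  # pi (31^2 - 16^2) = 2215 mm^2 over 4 mm^2
  expect_gte(sum(sys$myocardium), 526)
  expect_lte(sum(sys$myocardium), 582)
  ratio <- sum(sys$myocardium) / sum(dia$myocardium)
  expect_gte(ratio, 1.2)
  expect_lte(ratio, 1.45)
  # compartments partition the grid
  total <- dia$myocardium + dia$lv_cavity + dia$background
  expect_true(all(total == 1))
})

test_that("degenerate and out-of-bounds geometries are handled", {
  spec <- PhantomSpec(diastoleRadiiMm = c(25, 25))
  expect_equal(sum(makeGeometry(spec, "diastole")$myocardium), 0)
  big <- PhantomSpec(diastoleRadiiMm = c(100, 160))
  expect_error(makeGeometry(big, "diastole"), "field of view")
})

test_that("forward control equals tagged when perfusion is zero", {
  spec <- cleanSpec(trueMbf = 0)
  spec@trueMbf <- 0
  fw <- forwardSignals(spec, fairProtocol("FAIR-PI2_D"))
  expect_equal(fw$control, fw$tagged)
})

test_that("forward model inverts the quantification formula exactly", {
  # scalar oracle: solve the quantification formula for C by root
  # finding, independently of the closed-form inversion
  M0 <- 1000; f <- 1.5; ti <- 1000; t1 <- 1700; Tstar <- -100
  quantifier <- function(C) {
    60000 / (2 * M0) * ((C / ti) * exp(-ti / t1) -
                          (Tstar / ti) * exp(-ti / t1)) - f
  }
  Cstar <- uniroot(quantifier, c(-1e5, 1e5), tol = 1e-12)$root
  closedForm <- ti * exp(ti / t1) * (2 * M0 * (f / 60000) +
                                       (Tstar / ti) * exp(-ti / t1))
  expect_equal(closedForm, Cstar, tolerance = 1e-9)

  # full-grid round trip at several perfusion levels and inversion times
  for (mbf in c(0.5, 1.5, 3)) {
    spec <- cleanSpec(trueMbf = mbf)
    prot <- fairProtocol("FAIR-PI2_S")
    prot@nominalTiMs <- 860
    fw <- forwardSignals(spec, prot)
    m <- mbfMap(fw$control, fw$tagged, fw$m0, 860, 860, 1700,
                myo = fw$masks$myocardium)
    expect_lt(max(abs(myoValues(m) - mbf)) / mbf, 1e-9)
  }
})

test_that("simulation is deterministic and exact at zero corruption", {
  spec <- cleanSpec(seed = 42)
  prot <- fairProtocol("FAIR-PI2_D")
  sim1 <- simulateSeries(spec, prot)
  sim2 <- simulateSeries(spec, prot)
  expect_identical(lapply(controls(sim1$series), pixels),
                   lapply(controls(sim2$series), pixels))
  expect_identical(sim1$truth@actualTis, sim2$truth@actualTis)
  fw <- forwardSignals(spec, prot)
  for (i in 1:6) {
    expect_identical(pixels(controls(sim1$series)[[i]]), fw$control)
    expect_identical(pixels(taggeds(sim1$series)[[i]]), fw$tagged)
  }
  expect_identical(pixels(m0Frame(sim1$series)), fw$m0)
})

test_that("physiological noise scales with the excess acquisition window", {
  # PI2 systole: 165 - 90 = 75 ms excess; CS3 systole: 110 - 90 = 20 ms;
  # expected per-frame SD ratio 75 / 20 = 3.75
  empSD <- function(prot) {
    spec <- cleanSpec(seed = 9, physioK = 0.004)
    sim <- simulateSeries(spec, prot)
    fw <- forwardSignals(spec, prot)
    myo <- fw$masks$myocardium
    devs <- unlist(lapply(1:6, function(i) c(
      (pixels(controls(sim$series)[[i]]) - fw$control)[myo],
      (pixels(taggeds(sim$series)[[i]]) - fw$tagged)[myo])))
    sd(devs)
  }
  ratio <- empSD(fairProtocol("FAIR-PI2_S")) / empSD(fairProtocol("FAIR-CS3_S"))
  expect_equal(ratio, 3.75, tolerance = 0.05)
})

test_that("physiological noise vanishes when the window fits the rest period", {
  # diastole: 165 ms window vs 180 ms rest period -> no excess
  spec <- cleanSpec(seed = 10, physioK = 0.004)
  prot <- fairProtocol("FAIR-PI2_D")
  sim <- simulateSeries(spec, prot)
  fw <- forwardSignals(spec, prot)
  for (i in 1:6)
    expect_identical(pixels(controls(sim$series)[[i]]), fw$control)
})

test_that("injected motion is recorded and applied per breath-hold pair", {
  spec <- cleanSpec(seed = 3, motionTransPx = 3, motionRotDeg = 3)
  sim <- simulateSeries(spec, fairProtocol("FAIR-PI2_D"))
  tfs <- sim$truth@transforms
  expect_length(tfs, 6)
  for (tf in tfs) {
    expect_lte(abs(tf@txPx), 3)
    expect_lte(abs(tf@tyPx), 3)
    expect_lte(abs(tf@thetaDeg), 3)
  }
  # both frames of a pair share the transform: undoing it recovers the
  # noiseless frame up to interpolation error
  fw <- forwardSignals(spec, fairProtocol("FAIR-PI2_D"))
  inv <- invertTransform(tfs[[2]])
  back <- applyTransform(pixels(controls(sim$series)[[2]]), inv, fill = 50)
  inb <- attr(back, "inBounds")
  expect_lt(mean(abs((back - fw$control)[inb])), 5)
})

test_that("a focal perfusion defect propagates into the ground truth", {
  spec <- cleanSpec()
  g <- makeGeometry(spec, "diastole")
  override <- matrix(1.5, 150, 150)
  override[, 1:75] <- 0.6
  spec@mbfOverride <- override
  fw <- forwardSignals(spec, fairProtocol("FAIR-PI2_D"))
  m <- mbfMap(fw$control, fw$tagged, fw$m0, 1000, 1000, 1700,
              myo = g$myocardium)
  vals <- mbfValues(m)
  expect_equal(sort(unique(round(vals[g$myocardium], 6))), c(0.6, 1.5))
  expect_true(all(fw$mbf[!g$myocardium] == 0))
})
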