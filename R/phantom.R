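#' Construct a phantom specification
#'
#' Builds the parameter set of the synthetic short-axis left-ventricular
#' phantom. The myocardium is an annulus whose wall thickens from
#' diastole (inner/outer radii 25/34 mm) to systole (16/31 mm), mimicking
#' systolic wall thickening on a 150 x 150 grid of 2 x 2 mm pixels.
#' Corruption defaults: 5 % uniform inversion-time jitter, +-3 px / +-3
#' deg rigid motion per breath-hold pair, thermal noise at 2 % of the
#' myocardial M0, and physiological noise growing at 0.004 per ms of
#' acquisition window in excess of the cardiac rest period.
#'
#' @param matrixSize grid size in pixels (nx, ny).
#' @param pixelMm pixel size in mm.
#' @param diastoleRadiiMm inner/outer myocardial radii in diastole, mm.
#' @param systoleRadiiMm inner/outer myocardial radii in systole, mm.
#' @param centerMm annulus center (x, y) in mm; default grid center.
#' @param rvDirectionDeg septum direction in degrees (180 = image left).
#' @param trueMbf true MBF, ml/g/min (uniform over the myocardium).
#' @param mbfOverride optional full-grid matrix of true MBF values.
#' @param m0Values named baseline signals for `myo`, `blood`, `background`.
#' @param t1BloodMs blood T1, ms.
#' @param t1MyoMs myocardial T1, ms.
#' @param tiJitterFrac relative half-width of the uniform TI jitter.
#' @param motionTransPx rigid translation range per breath-hold, +- px.
#' @param motionRotDeg rigid rotation range per breath-hold, +- degrees.
#' @param thermalSigma thermal noise SD as a fraction of myocardial M0.
#' @param physioK physiological-noise coefficient per ms of excess window.
#' @param seed integer seed for [simulateSeries()].
#' @return a [PhantomSpec-class] object.
#' @export
PhantomSpec <- function(matrixSize = c(150, 150),
                        pixelMm = c(2, 2),
                        diastoleRadiiMm = c(25, 34),
                        systoleRadiiMm = c(16, 31),
                        centerMm = matrixSize * pixelMm / 2,
                        rvDirectionDeg = 180,
                        trueMbf = 1.5,
                        mbfOverride = NULL,
                        m0Values = c(myo = 1000, blood = 1400, background = 50),
                        t1BloodMs = 1700,
                        t1MyoMs = 1500,
                        tiJitterFrac = 0.05,
                        motionTransPx = 3,
                        motionRotDeg = 3,
                        thermalSigma = 0.02,
                        physioK = 0.004,
                        seed = 1L) {
  new("PhantomSpec",
      matrixSize = as.numeric(matrixSize), pixelMm = as.numeric(pixelMm),
      diastoleRadiiMm = as.numeric(diastoleRadiiMm),
      systoleRadiiMm = as.numeric(systoleRadiiMm),
      centerMm = as.numeric(centerMm), rvDirectionDeg = rvDirectionDeg,
      trueMbf = trueMbf, mbfOverride = mbfOverride, m0Values = m0Values,
      t1BloodMs = t1BloodMs, t1MyoMs = t1MyoMs, tiJitterFrac = tiJitterFrac,
      motionTransPx = motionTransPx, motionRotDeg = motionRotDeg,
      thermalSigma = thermalSigma, physioK = physioK, seed = as.numeric(seed))
}

#' Rasterize the phantom geometry
#'
#' Builds the compartment masks of the phantom for one cardiac phase.
#' A pixel belongs to the myocardial annulus iff its center (pixel-center
#' convention: pixel `(ix, iy)` 0-based has center `((ix + 0.5) dx,
#' (iy + 0.5) dy)` mm, x rightward, y downward) lies at a radius
#' `inner <= r < outer` from the annulus center.
#'
#' @param spec a [PhantomSpec-class].
#' @param phase `"diastole"` or `"systole"`.
#' @return list of logical matrices `myocardium`, `lv_cavity`,
#'   `background`.
#' @examples
#' g <- makeGeometry(PhantomSpec(), "diastole")
#' sum(g$myocardium)  # about 417 pixels (1668 mm^2 / 4 mm^2)
#' @export
makeGeometry <- function(spec, phase = c("diastole", "systole")) {
  phase <- match.arg(phase)
  radii <- if (phase == "diastole") spec@diastoleRadiiMm else spec@systoleRadiiMm
  nx <- spec@matrixSize[1]; ny <- spec@matrixSize[2]
  fov <- spec@matrixSize * spec@pixelMm
  if (spec@centerMm[1] - radii[2] < 0 || spec@centerMm[1] + radii[2] > fov[1] ||
      spec@centerMm[2] - radii[2] < 0 || spec@centerMm[2] + radii[2] > fov[2])
    stop("annulus exceeds the field of view")
  x <- (seq_len(nx) - 0.5) * spec@pixelMm[1]
  y <- (seq_len(ny) - 0.5) * spec@pixelMm[2]
  r <- sqrt(outer((y - spec@centerMm[2])^2, (x - spec@centerMm[1])^2, "+"))
  myo <- r >= radii[1] & r < radii[2]
  cavity <- r < radii[1]
  list(myocardium = myo, lv_cavity = cavity,
       background = !(myo | cavity))
}

# Per-ms perfusion map (matrix over the full grid, 0 outside myocardium).
trueMbfMatrix <- function(spec, myo) {
  if (is.null(spec@mbfOverride)) {
    m <- matrix(0, nrow(myo), ncol(myo))
    m[myo] <- spec@trueMbf
  } else {
    stopifnot(all(dim(spec@mbfOverride) == dim(myo)))
    m <- spec@mbfOverride
    m[!myo] <- 0
  }
  m
}

# Noiseless compartment signals at separate control/tagged inversion
# times. The tagged (nonselective) myocardial signal is signed inversion
# recovery at the myocardial T1; the control signal is solved from the
# double-gated quantification model so that mbfMap() on these images
# returns the true MBF exactly at (tiC, tiT). The LV cavity follows blood
# inversion recovery at its own inversion time; background pixels carry
# the constant background baseline.
forwardSignalsAt <- function(spec, masks, tiC, tiT) {
  myo <- masks$myocardium
  if (spec@m0Values[["myo"]] <= 0)
    stop("myocardial M0 must be positive")
  m0 <- matrix(spec@m0Values[["background"]], nrow(myo), ncol(myo))
  m0[masks$lv_cavity] <- spec@m0Values[["blood"]]
  m0[myo] <- spec@m0Values[["myo"]]

  irBlood <- function(ti) spec@m0Values[["blood"]] *
    (1 - 2 * exp(-ti / spec@t1BloodMs))
  tagged <- m0
  tagged[masks$lv_cavity] <- irBlood(tiT)
  tagged[myo] <- spec@m0Values[["myo"]] * (1 - 2 * exp(-tiT / spec@t1MyoMs))

  mbf <- trueMbfMatrix(spec, myo)
  f <- mbf / 60000  # ml/g/min -> 1/ms at unit density
  control <- m0
  control[masks$lv_cavity] <- irBlood(tiC)
  control[myo] <- tiC * exp(tiC / spec@t1BloodMs) *
    (2 * m0[myo] * f[myo] + (tagged[myo] / tiT) * exp(-tiT / spec@t1BloodMs))
  list(control = control, tagged = tagged, m0 = m0, mbf = mbf, masks = masks)
}

#' Noiseless forward signals of the phantom
#'
#' Generates the noiseless control, tagged and M0 images of the phantom
#' at the protocol's nominal inversion time. The M0 image takes the
#' compartment baseline values. The tagged (nonselective inversion)
#' myocardial signal follows signed inversion recovery at the myocardial
#' T1, `T = M0 (1 - 2 exp(-TI / T1myo))`. The control signal is then
#' solved from the double-gated quantification model so that [mbfMap()]
#' applied to the noiseless frames returns the configured true MBF
#' exactly:
#' `C = TI exp(+TI / T1b) (2 M0 f + (T / TI) exp(-TI / T1b))`,
#' with `f` the true MBF converted from ml/g/min to 1/ms (divide by
#' 60000, unit tissue density). The LV cavity carries blood inversion
#' recovery with zero perfusion contrast (control = tagged); background
#' pixels carry the constant background baseline in all frames.
#'
#' @param spec a [PhantomSpec-class].
#' @param protocol an [AcquisitionProtocol-class]; its `cardiacPhase`
#'   selects the geometry and its `nominalTiMs` the inversion time.
#' @return list with matrices `control`, `tagged`, `m0`, `mbf` (true MBF
#'   map) and the geometry `masks`.
#' @export
forwardSignals <- function(spec, protocol) {
  stopifnot(is(spec, "PhantomSpec"), is(protocol, "AcquisitionProtocol"))
  ti <- protocol@nominalTiMs
  stopifnot(ti > 0)
  masks <- makeGeometry(spec, protocol@cardiacPhase)
  forwardSignalsAt(spec, masks, ti, ti)
}

#' Simulate a complete FAIR series with ground truth
#'
#' Builds six control and six tagged frames from the noiseless forward
#' model and corrupts them in this order: (1) each breath-hold pair's
#' actual inversion time is drawn uniformly from
#' `nominal * (1 +- tiJitterFrac)` — the two frames of one breath-hold
#' share the prevailing RR deviation, like they share its body position —
#' and the frame signal is evaluated with the inversion-recovery model
#' `S(TI) = M0 + (S_anchor - M0) exp((TI_anchor - TI) / T1blood)`,
#' anchored at the per-type mean of the drawn inversion times (the
#' "nominal" inversion time the pipeline corrects to), where `S_anchor`
#' is the exact forward signal at that mean; the pipeline's
#' inversion-time correction is therefore exact on noiseless data and
#' the corrected, averaged pair quantifies to the true MBF exactly;
#' (2) one rigid transform per breath-hold pair (translation and
#' rotation uniform in the configured ranges) is applied to both frames
#' of the pair; (3) physiological noise is added to the (moved)
#' myocardial pixels of every frame as independent zero-mean Gaussians
#' with SD `physioK x max(0, acquisitionWindow - restPeriod) x local M0`;
#' (4) thermal Gaussian noise with SD `thermalSigma x myocardial M0` is
#' added to every pixel of every frame, including the M0 frame. All
#' randomness derives from `spec@seed`; frames are drawn in the
#' alternating acquisition order (tagged/control for odd breath-holds,
#' control/tagged for even ones). The M0 frame is acquired separately and
#' carries no motion or inversion preparation.
#'
#' @param spec a [PhantomSpec-class].
#' @param protocol an [AcquisitionProtocol-class].
#' @param heartRateBpm subject heart rate stored on the series (bpm).
#' @return list with elements `series` (a [FairSeries-class]) and
#'   `truth` (a [GroundTruth-class]).
#' @examples
#' sim <- simulateSeries(PhantomSpec(seed = 7), fairProtocol("FAIR-PI2_D"))
#' sim$series
#' @export
simulateSeries <- function(spec, protocol, heartRateBpm = 60) {
  stopifnot(is(spec, "PhantomSpec"), is(protocol, "AcquisitionProtocol"))
  nomTi <- protocol@nominalTiMs
  stopifnot(nomTi > 0)
  masks <- makeGeometry(spec, protocol@cardiacPhase)
  window <- as.numeric(acquisitionWindow(protocol))
  sigmaPhys <- spec@physioK * max(0, window - protocol@restPeriodMs)
  sigmaTherm <- spec@thermalSigma * spec@m0Values[["myo"]]
  jit <- spec@tiJitterFrac

  set.seed(as.integer(spec@seed))
  controls <- vector("list", 6); taggeds <- vector("list", 6)
  transforms <- vector("list", 6)
  tiControl <- numeric(6); tiTagged <- numeric(6)

  # actual inversion times: one RR-interval deviation per breath-hold,
  # shared by the tagged and control image of that pair (heart rhythm
  # drifts between breath-holds, not within one)
  pairOrder <- lapply(1:6, function(p)
    if (p %% 2 == 1) c("tagged", "control") else c("control", "tagged"))
  tiDraws <- vector("list", 6)
  for (p in 1:6) {
    tiPair <- stats::runif(1, nomTi * (1 - jit), nomTi * (1 + jit))
    tiDraws[[p]] <- c(tiPair, tiPair)
    tiControl[p] <- tiPair
    tiTagged[p] <- tiPair
  }
  # anchor the inversion-recovery signal model at the per-type mean TI,
  # i.e. the nominal TI the pipeline will correct to and quantify at
  fw <- forwardSignalsAt(spec, masks, mean(tiControl), mean(tiTagged))
  anchorTi <- c(control = mean(tiControl), tagged = mean(tiTagged))

  makeRaw <- function(type, ti) {
    s0 <- if (type == "control") fw$control else fw$tagged
    if (ti == anchorTi[[type]]) return(s0)  # bit-exact at zero jitter
    fw$m0 + (s0 - fw$m0) * exp((anchorTi[[type]] - ti) / spec@t1BloodMs)
  }

  for (p in 1:6) {
    order <- pairOrder[[p]]
    tis <- tiDraws[[p]]
    frames <- lapply(1:2, function(k) makeRaw(order[k], tis[k]))
    tf <- RigidTransform(
      stats::runif(1, -spec@motionTransPx, spec@motionTransPx),
      stats::runif(1, -spec@motionTransPx, spec@motionTransPx),
      stats::runif(1, -spec@motionRotDeg, spec@motionRotDeg))
    transforms[[p]] <- tf
    if (!isIdentityTransform(tf)) {
      bg <- spec@m0Values[["background"]]
      frames <- lapply(frames, function(fr) {
        out <- applyTransform(fr, tf, fill = bg)
        attr(out, "inBounds") <- NULL
        out
      })
      myoMoved <- transformMask(fw$masks$myocardium, tf)
      m0Moved <- applyTransform(fw$m0, tf, fill = spec@m0Values[["background"]])
    } else {
      myoMoved <- fw$masks$myocardium
      m0Moved <- fw$m0
    }
    if (sigmaPhys > 0) {
      nMyo <- sum(myoMoved)
      for (k in 1:2)
        frames[[k]][myoMoved] <- frames[[k]][myoMoved] +
          stats::rnorm(nMyo) * sigmaPhys * m0Moved[myoMoved]
    }
    if (sigmaTherm > 0) {
      for (k in 1:2)
        frames[[k]] <- frames[[k]] +
          matrix(stats::rnorm(length(frames[[k]])) * sigmaTherm,
                 nrow(frames[[k]]), ncol(frames[[k]]))
    }
    for (k in 1:2) {
      fr <- new("ImageFrame", pixels = frames[[k]], frameType = order[k],
                index = p, actualTiMs = tis[k])
      if (order[k] == "control") { controls[[p]] <- fr; tiControl[p] <- tis[k] }
      else { taggeds[[p]] <- fr; tiTagged[p] <- tis[k] }
    }
  }
  m0px <- fw$m0
  if (sigmaTherm > 0)
    m0px <- m0px + matrix(stats::rnorm(length(m0px)) * sigmaTherm,
                          nrow(m0px), ncol(m0px))
  m0Frame <- new("ImageFrame", pixels = m0px, frameType = "m0",
                 index = NA_real_, actualTiMs = NA_real_)
  series <- new("FairSeries", protocol = protocol, controls = controls,
                taggeds = taggeds, m0 = m0Frame,
                heartRateBpm = heartRateBpm, bloodT1Ms = spec@t1BloodMs)
  truth <- new("GroundTruth", mbfMap = fw$mbf,
               myoMask = fw$masks$myocardium, transforms = transforms,
               actualTis = list(control = tiControl, tagged = tiTagged))
  list(series = series, truth = truth)
}
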