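#' @import methods
NULL

#' Acquisition protocol for a FAIR imaging strategy
#'
#' Holds the imaging parameters of one FAIR acquisition strategy: cardiac
#' phase, acceleration method and factor, geometry (field of view, matrix,
#' pixel and slice size), sequence timings (TR, TE, flip angle, nominal
#' inversion time), the slab thickness of the slice-selective control
#' inversion, and the rest-period duration used by the simulator.
#'
#' @slot name protocol label, e.g. `"FAIR-PI2_S"`.
#' @slot cardiacPhase `"diastole"` or `"systole"`.
#' @slot accelMethod `"parallel_imaging"`, `"compressed_sensing"` or `"none"`.
#' @slot accelFactor acceleration factor (>= 1).
#' @slot fovMm field of view in mm, length-2 numeric.
#' @slot matrixSize acquisition matrix, length-2 integer-valued numeric.
#' @slot pixelMm pixel size in mm, length-2 numeric; must equal
#'   `fovMm / matrixSize`.
#' @slot sliceMm slice thickness in mm.
#' @slot trMs repetition time in ms.
#' @slot teMs echo time in ms.
#' @slot flipDeg excitation flip angle in degrees.
#' @slot nominalTiMs nominal inversion time in ms (about one cardiac cycle).
#' @slot controlSlabMm slab thickness of the slice-selective inversion in mm.
#' @slot restPeriodMs duration of the quiescent cardiac rest period in ms
#'   (simulation parameter; phase dependent).
#' @seealso [AcquisitionProtocol()], [fairProtocol()], [acquisitionWindow()]
#' @exportClass AcquisitionProtocol
setClass("AcquisitionProtocol",
  slots = c(
    name          = "character",
    cardiacPhase  = "character",
    accelMethod   = "character",
    accelFactor   = "numeric",
    fovMm         = "numeric",
    matrixSize    = "numeric",
    pixelMm       = "numeric",
    sliceMm       = "numeric",
    trMs          = "numeric",
    teMs          = "numeric",
    flipDeg       = "numeric",
    nominalTiMs   = "numeric",
    controlSlabMm = "numeric",
    restPeriodMs  = "numeric"
  )
)

setValidity("AcquisitionProtocol", function(object) {
  msg <- character()
  if (!object@cardiacPhase %in% c("diastole", "systole"))
    msg <- c(msg, "cardiacPhase must be 'diastole' or 'systole'")
  if (!object@accelMethod %in% c("parallel_imaging", "compressed_sensing", "none"))
    msg <- c(msg, "accelMethod must be 'parallel_imaging', 'compressed_sensing' or 'none'")
  if (length(object@accelFactor) != 1 || object@accelFactor < 1)
    msg <- c(msg, "accelFactor must be a single value >= 1")
  if (length(object@fovMm) != 2 || length(object@matrixSize) != 2 ||
      length(object@pixelMm) != 2)
    msg <- c(msg, "fovMm, matrixSize and pixelMm must have length 2")
  else {
    if (any(abs(object@pixelMm - object@fovMm / object@matrixSize) > 1e-9))
      msg <- c(msg, "pixelMm must equal fovMm / matrixSize elementwise")
    if (any(object@matrixSize < 1 | object@matrixSize != round(object@matrixSize)))
      msg <- c(msg, "matrixSize must be positive integers")
  }
  times <- c(object@sliceMm, object@trMs, object@teMs, object@nominalTiMs,
             object@controlSlabMm, object@restPeriodMs)
  if (any(!is.finite(times)) || any(times <= 0))
    msg <- c(msg, "all geometry and timing parameters must be positive")
  if (length(msg)) msg else TRUE
})

#' Single 2-D image frame of a FAIR series
#'
#' A signed real-valued short-axis image with its role in the series
#' (control, tagged or M0), its position in the six-frame series and, for
#' control/tagged frames, the actual inversion time at which it was
#' acquired.
#'
#' @slot pixels numeric matrix of signal intensities (signed, arbitrary
#'   units); rows index y (downward), columns index x (rightward).
#' @slot frameType `"control"`, `"tagged"` or `"m0"`.
#' @slot index position 1-6 within its series (`NA` for the M0 frame).
#' @slot actualTiMs actual inversion time in ms (`NA` for the M0 frame).
#' @seealso [ImageFrame()], [pixels()], [actualTI()]
#' @exportClass ImageFrame
setClass("ImageFrame",
  slots = c(
    pixels     = "matrix",
    frameType  = "character",
    index      = "numeric",
    actualTiMs = "numeric"
  )
)

setValidity("ImageFrame", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels))
    msg <- c(msg, "pixels must be a numeric matrix")
  if (!object@frameType %in% c("control", "tagged", "m0"))
    msg <- c(msg, "frameType must be 'control', 'tagged' or 'm0'")
  if (object@frameType == "m0") {
    if (!is.na(object@actualTiMs))
      msg <- c(msg, "the M0 frame carries no inversion time")
  } else {
    if (!is.finite(object@actualTiMs) || object@actualTiMs <= 0)
      msg <- c(msg, "actualTiMs must be > 0 for control/tagged frames")
    if (!is.na(object@index) && !(object@index %in% 1:6))
      msg <- c(msg, "index must be in 1..6")
  }
  if (length(msg)) msg else TRUE
})

#' A complete FAIR perfusion series
#'
#' Six control frames (slice-selective inversion), six tagged frames
#' (nonselective inversion) and one unprepared M0 frame, each with its
#' actual inversion time, plus the acquisition protocol, the subject heart
#' rate and the blood longitudinal relaxation time used in quantification.
#'
#' @slot protocol an [AcquisitionProtocol-class] object.
#' @slot controls list of exactly six control [ImageFrame-class]s.
#' @slot taggeds list of exactly six tagged [ImageFrame-class]s.
#' @slot m0 the M0 [ImageFrame-class].
#' @slot heartRateBpm heart rate in beats per minute.
#' @slot bloodT1Ms longitudinal relaxation time of arterial blood in ms
#'   (default 1700 at 3 T).
#' @seealso [FairSeries()], [simulateSeries()], [preprocessSeries()]
#' @exportClass FairSeries
setClass("FairSeries",
  slots = c(
    protocol     = "AcquisitionProtocol",
    controls     = "list",
    taggeds      = "list",
    m0           = "ImageFrame",
    heartRateBpm = "numeric",
    bloodT1Ms    = "numeric"
  )
)

setValidity("FairSeries", function(object) {
  msg <- character()
  if (length(object@controls) != 6) msg <- c(msg, "exactly six control frames required")
  if (length(object@taggeds) != 6) msg <- c(msg, "exactly six tagged frames required")
  allFrames <- c(object@controls, object@taggeds, list(object@m0))
  if (!all(vapply(allFrames, is, logical(1), "ImageFrame")))
    msg <- c(msg, "all frames must be ImageFrame objects")
  else {
    dims <- vapply(allFrames, function(f) dim(f@pixels), numeric(2))
    if (any(dims != dims[, 1]))
      msg <- c(msg, "all frames must share one grid geometry")
    types <- vapply(object@controls, function(f) f@frameType, character(1))
    if (!all(types == "control")) msg <- c(msg, "controls must have frameType 'control'")
    types <- vapply(object@taggeds, function(f) f@frameType, character(1))
    if (!all(types == "tagged")) msg <- c(msg, "taggeds must have frameType 'tagged'")
    if (object@m0@frameType != "m0") msg <- c(msg, "m0 must have frameType 'm0'")
  }
  if (!is.finite(object@heartRateBpm) || object@heartRateBpm <= 0)
    msg <- c(msg, "heartRateBpm must be positive")
  if (!is.finite(object@bloodT1Ms) || object@bloodT1Ms <= 0)
    msg <- c(msg, "bloodT1Ms must be positive")
  if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic short-axis phantom
#'
#' Describes the annular left-ventricular phantom and its corruption
#' model: grid geometry, inner/outer myocardial radii per cardiac phase,
#' true perfusion, compartment baseline (M0) signals, relaxation times,
#' inversion-time jitter, per-breath-hold rigid motion ranges, thermal
#' noise and the physiological-noise coefficient.
#'
#' @slot matrixSize grid size in pixels, length-2 (nx, ny).
#' @slot pixelMm pixel size in mm, length-2.
#' @slot diastoleRadiiMm inner/outer myocardial radii in diastole, mm.
#' @slot systoleRadiiMm inner/outer myocardial radii in systole, mm.
#' @slot centerMm annulus center in mm (x, y), measured from the image
#'   corner with the pixel-center convention.
#' @slot rvDirectionDeg direction of the septum-facing side in degrees
#'   (180 = image left).
#' @slot trueMbf true myocardial blood flow in ml/g/min (uniform scalar).
#' @slot mbfOverride optional full-grid matrix of true MBF values
#'   (e.g. a focal defect); `NULL` for uniform `trueMbf`.
#' @slot m0Values named numeric: baseline signals for `myo`, `blood`,
#'   `background`.
#' @slot t1BloodMs blood T1 in ms.
#' @slot t1MyoMs myocardial T1 in ms.
#' @slot tiJitterFrac relative half-width of the uniform inversion-time
#'   jitter.
#' @slot motionTransPx per-breath-hold rigid translation range, +- pixels.
#' @slot motionRotDeg per-breath-hold rigid rotation range, +- degrees.
#' @slot thermalSigma additive Gaussian noise SD as a fraction of the
#'   myocardial M0.
#' @slot physioK physiological-noise coefficient per ms of acquisition
#'   window exceeding the rest period.
#' @slot seed integer seed driving all randomness of [simulateSeries()].
#' @seealso [PhantomSpec()], [makeGeometry()], [simulateSeries()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  slots = c(
    matrixSize      = "numeric",
    pixelMm         = "numeric",
    diastoleRadiiMm = "numeric",
    systoleRadiiMm  = "numeric",
    centerMm        = "numeric",
    rvDirectionDeg  = "numeric",
    trueMbf         = "numeric",
    mbfOverride     = "ANY",
    m0Values        = "numeric",
    t1BloodMs       = "numeric",
    t1MyoMs         = "numeric",
    tiJitterFrac    = "numeric",
    motionTransPx   = "numeric",
    motionRotDeg    = "numeric",
    thermalSigma    = "numeric",
    physioK         = "numeric",
    seed            = "numeric"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character()
  if (object@diastoleRadiiMm[1] > object@diastoleRadiiMm[2])
    msg <- c(msg, "diastolic inner radius must not exceed outer radius")
  if (object@systoleRadiiMm[1] > object@systoleRadiiMm[2])
    msg <- c(msg, "systolic inner radius must not exceed outer radius")
  nn <- c(object@tiJitterFrac, object@motionTransPx, object@motionRotDeg,
          object@thermalSigma, object@physioK)
  if (any(nn < 0)) msg <- c(msg, "noise, jitter and motion parameters must be >= 0")
  if (!all(c("myo", "blood", "background") %in% names(object@m0Values)))
    msg <- c(msg, "m0Values must name 'myo', 'blood' and 'background'")
  if (!is.null(object@mbfOverride) && !is.matrix(object@mbfOverride))
    msg <- c(msg, "mbfOverride must be NULL or a matrix")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated FAIR series
#'
#' @slot mbfMap true per-pixel MBF in ml/g/min; zero outside the
#'   myocardial mask.
#' @slot myoMask logical matrix marking the myocardium.
#' @slot transforms list of the six injected per-breath-hold
#'   [RigidTransform-class]s.
#' @slot actualTis list with numeric vectors `control` and `tagged` of
#'   the six drawn actual inversion times (ms).
#' @seealso [simulateSeries()]
#' @exportClass GroundTruth
setClass("GroundTruth",
  slots = c(
    mbfMap     = "matrix",
    myoMask    = "matrix",
    transforms = "list",
    actualTis  = "list"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (any(dim(object@mbfMap) != dim(object@myoMask)))
    msg <- c(msg, "mbfMap and myoMask must share dimensions")
  else if (any(object@mbfMap[!object@myoMask] != 0))
    msg <- c(msg, "mbfMap must be zero outside myoMask")
  if (length(msg)) msg else TRUE
})

#' Rigid in-plane transform
#'
#' Translation in pixels and rotation (degrees) about the image center.
#' Applied to an image, the content is rotated by `thetaDeg` about the
#' center and then shifted by (`txPx`, `tyPx`).
#'
#' @slot txPx translation along x (columns, rightward), pixels.
#' @slot tyPx translation along y (rows, downward), pixels.
#' @slot thetaDeg rotation about the image center, degrees.
#' @slot converged whether the registration optimizer reported
#'   convergence (`TRUE` for constructed transforms).
#' @slot metricValue final similarity-metric value (`NA` for constructed
#'   transforms).
#' @seealso [RigidTransform()], [registerRigid()], [applyTransform()]
#' @exportClass RigidTransform
setClass("RigidTransform",
  slots = c(
    txPx        = "numeric",
    tyPx        = "numeric",
    thetaDeg    = "numeric",
    converged   = "logical",
    metricValue = "numeric"
  )
)

setValidity("RigidTransform", function(object) {
  if (!all(is.finite(c(object@txPx, object@tyPx, object@thetaDeg))))
    "transform parameters must be finite" else TRUE
})

#' Averaged, aligned control/tagged pair ready for quantification
#'
#' The output of [preprocessSeries()]: one averaged control and one
#' averaged tagged frame, registered to the cropped M0 frame, with the
#' mean actual inversion times of each type and the log of all applied
#' rigid transforms.
#'
#' @slot controlAvg averaged control [ImageFrame-class].
#' @slot taggedAvg averaged tagged [ImageFrame-class].
#' @slot m0 cropped M0 [ImageFrame-class].
#' @slot tiControlMs mean actual inversion time of the controls, ms.
#' @slot tiTaggedMs mean actual inversion time of the taggeds, ms.
#' @slot transformLog named list of applied [RigidTransform-class]s.
#' @seealso [preprocessSeries()], [mbfMap()]
#' @exportClass PreparedPair
setClass("PreparedPair",
  slots = c(
    controlAvg   = "ImageFrame",
    taggedAvg    = "ImageFrame",
    m0           = "ImageFrame",
    tiControlMs  = "numeric",
    tiTaggedMs   = "numeric",
    transformLog = "list"
  )
)

setValidity("PreparedPair", function(object) {
  d1 <- dim(object@controlAvg@pixels); d2 <- dim(object@taggedAvg@pixels)
  d3 <- dim(object@m0@pixels)
  if (any(d1 != d3) || any(d2 != d3))
    "control/tagged averages must be on the M0 grid" else TRUE
})

#' Per-pixel myocardial blood flow map
#'
#' @slot values numeric matrix of MBF in ml/g/min; `NA` where invalid.
#' @slot validMask logical matrix: pixels whose M0 exceeds the noise
#'   floor (5 % of the M0 maximum).
#' @slot myoMask logical matrix: the analysis region (myocardium).
#' @seealso [mbfMap()], [summarizeMap()]
#' @exportClass MBFMap
setClass("MBFMap",
  slots = c(
    values    = "matrix",
    validMask = "matrix",
    myoMask   = "matrix"
  )
)

setValidity("MBFMap", function(object) {
  msg <- character()
  if (any(dim(object@values) != dim(object@validMask)) ||
      any(dim(object@values) != dim(object@myoMask)))
    msg <- c(msg, "values and masks must share dimensions")
  else if (any(!is.finite(object@values[object@validMask])))
    msg <- c(msg, "values must be finite wherever validMask is TRUE")
  if (length(msg)) msg else TRUE
})

#' Statistical comparison of acquisition protocols
#'
#' One-way ANOVA of a metric across protocols, with paired post-hoc
#' t-tests run only when the ANOVA rejects at `alpha`.
#'
#' @slot metric name of the compared metric.
#' @slot anovaF ANOVA F statistic.
#' @slot anovaP ANOVA p-value.
#' @slot anovaDf numeric length-2: between/within degrees of freedom.
#' @slot groupStats data.frame with per-protocol n, mean and SD.
#' @slot posthoc data.frame of pairwise paired t-tests (or `NULL` when
#'   the ANOVA is not significant).
#' @slot alpha significance threshold (default 0.05).
#' @seealso [compareMethods()]
#' @exportClass ComparisonReport
setClass("ComparisonReport",
  slots = c(
    metric     = "character",
    anovaF     = "numeric",
    anovaP     = "numeric",
    anovaDf    = "numeric",
    groupStats = "data.frame",
    posthoc    = "ANY",
    alpha      = "numeric"
  )
)

setValidity("ComparisonReport", function(object) {
  if (!is.null(object@posthoc) && !is.na(object@anovaP) &&
      object@anovaP >= object@alpha)
    "posthoc tests must only be present when the ANOVA rejects" else TRUE
})
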