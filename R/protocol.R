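#' Construct an acquisition protocol
#'
#' Builds an [AcquisitionProtocol-class] object. Defaults follow the
#' short-axis FAIR setup used throughout the package: 300 x 300 mm field
#' of view, 150 x 150 matrix (2 x 2 mm pixels), 10 mm slice, bSSFP-type
#' timings TR 2.2 ms / TE 1.1 ms, flip 50 degrees, a 30 mm slab for the
#' slice-selective control inversion, and a nominal inversion time of one
#' cardiac cycle at 60 bpm (1000 ms).
#'
#' @param name protocol label.
#' @param cardiacPhase `"diastole"` or `"systole"`.
#' @param accelMethod `"parallel_imaging"`, `"compressed_sensing"` or
#'   `"none"`.
#' @param accelFactor acceleration factor (>= 1).
#' @param fovMm field of view, mm (length 2).
#' @param matrixSize acquisition matrix (length 2).
#' @param pixelMm pixel size, mm (length 2); defaults to
#'   `fovMm / matrixSize`.
#' @param sliceMm slice thickness, mm.
#' @param trMs repetition time, ms.
#' @param teMs echo time, ms.
#' @param flipDeg flip angle, degrees.
#' @param nominalTiMs nominal inversion time, ms.
#' @param controlSlabMm slab thickness of the control inversion, mm.
#' @param restPeriodMs cardiac rest period, ms (simulation parameter;
#'   180 ms is a typical resting mid-diastolic window, 90 ms a systolic
#'   one).
#' @return an [AcquisitionProtocol-class] object.
#' @examples
#' p <- AcquisitionProtocol("demo", cardiacPhase = "systole",
#'                          accelMethod = "compressed_sensing",
#'                          accelFactor = 3, restPeriodMs = 90)
#' acquisitionWindow(p)
#' @export
AcquisitionProtocol <- function(name,
                                cardiacPhase = c("diastole", "systole"),
                                accelMethod = c("parallel_imaging",
                                                "compressed_sensing", "none"),
                                accelFactor = 2,
                                fovMm = c(300, 300),
                                matrixSize = c(150, 150),
                                pixelMm = fovMm / matrixSize,
                                sliceMm = 10,
                                trMs = 2.2,
                                teMs = 1.1,
                                flipDeg = 50,
                                nominalTiMs = 1000,
                                controlSlabMm = 30,
                                restPeriodMs = 180) {
  cardiacPhase <- match.arg(cardiacPhase)
  accelMethod <- match.arg(accelMethod)
  new("AcquisitionProtocol",
      name = name, cardiacPhase = cardiacPhase, accelMethod = accelMethod,
      accelFactor = accelFactor, fovMm = as.numeric(fovMm),
      matrixSize = as.numeric(matrixSize), pixelMm = as.numeric(pixelMm),
      sliceMm = sliceMm, trMs = trMs, teMs = teMs, flipDeg = flipDeg,
      nominalTiMs = nominalTiMs, controlSlabMm = controlSlabMm,
      restPeriodMs = restPeriodMs)
}

#' Shipped FAIR protocol presets
#'
#' Loads one of the three protocol presets shipped with the package:
#' `"FAIR-PI2_D"` (diastole, parallel imaging factor 2), `"FAIR-PI2_S"`
#' (systole, parallel imaging factor 2) and `"FAIR-CS3_S"` (systole,
#' compressed sensing factor 3). Presets are stored as JSON under
#' `inst/extdata/protocols` and read with [readProtocol()].
#'
#' @param name preset name.
#' @return an [AcquisitionProtocol-class] object.
#' @examples
#' acquisitionWindow(fairProtocol("FAIR-CS3_S"))
#' @export
fairProtocol <- function(name = c("FAIR-PI2_D", "FAIR-PI2_S", "FAIR-CS3_S")) {
  name <- match.arg(name)
  path <- system.file("extdata", "protocols", paste0(name, ".json"),
                      package = "FAIRmbf", mustWork = TRUE)
  readProtocol(path)
}

#' Acquisition window duration
#'
#' Duration of the single-shot image acquisition window:
#' `TR x (phase-encode lines / acceleration factor)`, with the
#' phase-encode direction along the second matrix dimension. No rounding
#' is applied; if the accelerated line count is not an integer the
#' fractional value is returned with a warning and the attribute
#' `fractionalLines = TRUE`.
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @return acquisition window in ms.
#' @examples
#' acquisitionWindow(fairProtocol("FAIR-PI2_S"))  # 165 ms
#' acquisitionWindow(fairProtocol("FAIR-CS3_S"))  # 110 ms
#' @export
acquisitionWindow <- function(protocol) {
  stopifnot(is(protocol, "AcquisitionProtocol"))
  lines <- protocol@matrixSize[2] / protocol@accelFactor
  out <- protocol@trMs * lines
  if (abs(lines - round(lines)) > 1e-9) {
    warning(sprintf("accelerated phase-encode line count is fractional (%.6g)",
                    lines))
    attr(out, "fractionalLines") <- TRUE
  }
  out
}

#' Duration of one double-gated control/tagged pair
#'
#' Each double-gated image spans two cardiac cycles: the inversion pulse
#' plays in one cycle and the readout in the next, both at the same
#' trigger delay. A breath-hold pair (one tagged plus one control image)
#' therefore takes `2 x 2 x (60 / heart rate)` seconds plus the rest gap
#' left between the two images for longitudinal magnetization recovery.
#'
#' @param protocol an [AcquisitionProtocol-class] (carried for context;
#'   the duration depends only on heart rate and rest gap).
#' @param heartRateBpm heart rate in beats per minute.
#' @param restGapS rest gap between the two images, seconds (default 8).
#' @return pair duration in seconds.
#' @examples
#' pairDuration(fairProtocol("FAIR-PI2_D"), 60, 8)  # 12 s
#' @export
pairDuration <- function(protocol, heartRateBpm, restGapS = 8) {
  stopifnot(is(protocol, "AcquisitionProtocol"), heartRateBpm > 0)
  2 * 2 * (60 / heartRateBpm) + restGapS
}

protocolToList <- function(protocol) {
  list(
    name = protocol@name,
    cardiac_phase = protocol@cardiacPhase,
    accel_method = protocol@accelMethod,
    accel_factor = protocol@accelFactor,
    fov_mm = protocol@fovMm,
    matrix = protocol@matrixSize,
    pixel_mm = protocol@pixelMm,
    slice_mm = protocol@sliceMm,
    tr_ms = protocol@trMs,
    te_ms = protocol@teMs,
    flip_deg = protocol@flipDeg,
    nominal_ti_ms = protocol@nominalTiMs,
    control_slab_mm = protocol@controlSlabMm,
    rest_period_ms = protocol@restPeriodMs
  )
}

protocolFromList <- function(x) {
  need <- c("name", "cardiac_phase", "accel_method", "accel_factor", "fov_mm",
            "matrix", "pixel_mm", "slice_mm", "tr_ms", "te_ms", "flip_deg",
            "nominal_ti_ms", "control_slab_mm", "rest_period_ms")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("protocol document is missing field(s): ",
         paste(missing, collapse = ", "))
  AcquisitionProtocol(
    name = x$name, cardiacPhase = x$cardiac_phase, accelMethod = x$accel_method,
    accelFactor = x$accel_factor, fovMm = unlist(x$fov_mm),
    matrixSize = unlist(x$matrix), pixelMm = unlist(x$pixel_mm),
    sliceMm = x$slice_mm, trMs = x$tr_ms, teMs = x$te_ms,
    flipDeg = x$flip_deg, nominalTiMs = x$nominal_ti_ms,
    controlSlabMm = x$control_slab_mm, restPeriodMs = x$rest_period_ms)
}

#' Read and write protocols as JSON
#'
#' Protocols are serialized as flat JSON documents mirroring the
#' imaging-parameter table field names (`cardiac_phase`, `accel_factor`,
#' `tr_ms`, ...).
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @param path file path.
#' @return `readProtocol()` returns an [AcquisitionProtocol-class];
#'   `writeProtocol()` returns `path` invisibly.
#' @export
writeProtocol <- function(protocol, path) {
  jsonlite::write_json(protocolToList(protocol), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeProtocol
#' @export
readProtocol <- function(path) {
  protocolFromList(jsonlite::read_json(path, simplifyVector = TRUE))
}
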