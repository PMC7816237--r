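#' Write and read a FAIR series as NIfTI plus JSON sidecar
#'
#' A series is exchanged as one NIfTI volume holding the thirteen frames
#' (stacked along the third dimension, 64-bit float so round trips are
#' bit-exact) plus a JSON sidecar listing, for each volume slot, the
#' frame type, series index and actual inversion time, together with the
#' full protocol document, heart rate and blood T1. The sidecar is the
#' authority on frame order; `readSeries()` validates frame counts,
#' types and inversion times and reports every missing field.
#'
#' @param series a [FairSeries-class].
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @param sidecarPath JSON sidecar path; default `path` with a `.json`
#'   extension appended.
#' @return `writeSeries()` returns `path` invisibly; `readSeries()`
#'   returns a [FairSeries-class].
#' @export
writeSeries <- function(series, path, sidecarPath = paste0(path, ".json")) {
  stopifnot(is(series, "FairSeries"))
  frames <- c(series@controls, series@taggeds, list(series@m0))
  d <- dim(series@m0@pixels)
  vol <- array(0, c(d[1], d[2], length(frames)))
  for (i in seq_along(frames)) vol[, , i] <- frames[[i]]@pixels
  img <- RNifti::asNifti(vol, datatype = "double")
  RNifti::writeNifti(img, path)
  sidecar <- list(
    format = "fair-series",
    protocol = protocolToList(series@protocol),
    heart_rate_bpm = series@heartRateBpm,
    blood_t1_ms = series@bloodT1Ms,
    frames = lapply(seq_along(frames), function(i) {
      f <- frames[[i]]
      x <- list(volume = i, frame_type = f@frameType)
      if (f@frameType != "m0") {
        x$index <- f@index
        x$actual_ti_ms <- f@actualTiMs
      }
      x
    }))
  jsonlite::write_json(sidecar, sidecarPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeSeries
#' @export
readSeries <- function(path, sidecarPath = paste0(path, ".json")) {
  if (!file.exists(sidecarPath)) stop("missing sidecar: ", sidecarPath)
  sc <- jsonlite::read_json(sidecarPath)
  need <- c("protocol", "heart_rate_bpm", "blood_t1_ms", "frames")
  missing <- setdiff(need, names(sc))
  if (length(missing))
    stop("sidecar is missing field(s): ", paste(missing, collapse = ", "))
  vol <- RNifti::readNifti(path)
  vol <- unclass(vol)[, , , drop = FALSE]
  if (dim(vol)[3] != length(sc$frames))
    stop(sprintf("volume has %d frames but sidecar lists %d",
                 dim(vol)[3], length(sc$frames)))
  prot <- protocolFromList(sc$protocol)
  controls <- list(); taggeds <- list(); m0 <- NULL
  for (i in seq_along(sc$frames)) {
    fr <- sc$frames[[i]]
    if (is.null(fr$frame_type))
      stop(sprintf("sidecar frame %d is missing 'frame_type'", i))
    px <- matrix(vol[, , fr$volume %||% i], dim(vol)[1], dim(vol)[2])
    if (fr$frame_type == "m0") {
      m0 <- new("ImageFrame", pixels = px, frameType = "m0",
                index = NA_real_, actualTiMs = NA_real_)
    } else {
      if (is.null(fr$actual_ti_ms))
        stop(sprintf("sidecar frame %d (%s) is missing 'actual_ti_ms'",
                     i, fr$frame_type))
      if (is.null(fr$index))
        stop(sprintf("sidecar frame %d (%s) is missing 'index'",
                     i, fr$frame_type))
      f <- new("ImageFrame", pixels = px, frameType = fr$frame_type,
               index = as.numeric(fr$index),
               actualTiMs = as.numeric(fr$actual_ti_ms))
      if (fr$frame_type == "control") controls[[length(controls) + 1]] <- f
      else taggeds[[length(taggeds) + 1]] <- f
    }
  }
  if (length(controls) != 6)
    stop(sprintf("expected 6 control frames, sidecar lists %d",
                 length(controls)))
  if (length(taggeds) != 6)
    stop(sprintf("expected 6 tagged frames, sidecar lists %d",
                 length(taggeds)))
  if (is.null(m0)) stop("sidecar lists no m0 frame")
  ordIdx <- function(fs) order(vapply(fs, function(f) f@index, numeric(1)))
  new("FairSeries", protocol = prot, controls = controls[ordIdx(controls)],
      taggeds = taggeds[ordIdx(taggeds)], m0 = m0,
      heartRateBpm = as.numeric(sc$heart_rate_bpm),
      bloodT1Ms = as.numeric(sc$blood_t1_ms))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write ground truth and MBF maps
#'
#' `writeGroundTruth()` stores the true MBF map and myocardial mask as
#' NIfTI files plus a JSON log of the injected transforms and actual
#' inversion times. `writeMbfMap()` stores an [MBFMap-class] as NIfTI
#' (map with `NA` at invalid pixels, plus the two masks).
#'
#' @param truth a [GroundTruth-class].
#' @param map an [MBFMap-class].
#' @param prefix output path prefix.
#' @return the written file paths, invisibly.
#' @export
writeGroundTruth <- function(truth, prefix) {
  stopifnot(is(truth, "GroundTruth"))
  pMap <- paste0(prefix, "_mbf.nii.gz")
  pMask <- paste0(prefix, "_myo_mask.nii.gz")
  pLog <- paste0(prefix, "_log.json")
  RNifti::writeNifti(RNifti::asNifti(truth@mbfMap, datatype = "double"), pMap)
  RNifti::writeNifti(RNifti::asNifti(truth@myoMask * 1L), pMask)
  jsonlite::write_json(list(
    transforms = lapply(truth@transforms, function(tf)
      list(tx_px = tf@txPx, ty_px = tf@tyPx, theta_deg = tf@thetaDeg)),
    actual_tis = truth@actualTis
  ), pLog, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(pMap, pMask, pLog))
}

#' @rdname writeGroundTruth
#' @export
writeMbfMap <- function(map, prefix) {
  stopifnot(is(map, "MBFMap"))
  pMap <- paste0(prefix, "_mbf.nii.gz")
  pValid <- paste0(prefix, "_valid_mask.nii.gz")
  pMyo <- paste0(prefix, "_myo_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(map@values, datatype = "double"), pMap)
  RNifti::writeNifti(RNifti::asNifti(map@validMask * 1L), pValid)
  RNifti::writeNifti(RNifti::asNifti(map@myoMask * 1L), pMyo)
  invisible(c(pMap, pValid, pMyo))
}

#' Write experiment results as CSV and JSON
#'
#' The per-subject results table is written as CSV with numbers rendered
#' at fixed precision (so repeated runs with one seed are byte
#' identical); the comparison reports are written as one JSON document.
#'
#' @param experiment the list returned by [runExperiment()].
#' @param dir output directory (created if needed).
#' @return the written file paths, invisibly.
#' @export
writeExperiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  resPath <- file.path(dir, "results.csv")
  res <- experiment$results
  num <- vapply(res, is.numeric, logical(1))
  res[num] <- lapply(res[num], function(x) sprintf("%.8g", x))
  utils::write.csv(res, resPath, row.names = FALSE, quote = FALSE)
  repPath <- file.path(dir, "comparison.json")
  reportList <- lapply(experiment$reports, function(r) list(
    metric = r@metric, anova_f = r@anovaF, anova_p = r@anovaP,
    df = r@anovaDf, group_stats = r@groupStats,
    posthoc = r@posthoc, alpha = r@alpha))
  jsonlite::write_json(list(config = experiment$config,
                            subjects = experiment$subjects,
                            reports = reportList),
                       repPath, auto_unbox = TRUE, digits = 8, pretty = TRUE,
                       dataframe = "rows")
  invisible(c(resPath, repPath))
}
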