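#' Crop a region of interest around the left ventricle
#'
#' Applies one square crop window identically to all thirteen frames of a
#' series. The window is specified by its center (0-based pixel
#' coordinates `(x, y)`; default the grid center) and its side length
#' (default 64 px), and must lie fully inside the grid. For a 150 px
#' grid and the default 64 px window, output pixel (0, 0) maps from
#' source pixel (43, 43).
#'
#' @param series a [FairSeries-class].
#' @param centerPx window center, 0-based `(x, y)`; default grid center.
#' @param sizePx window side length in pixels.
#' @return the cropped [FairSeries-class].
#' @export
cropROI <- function(series, centerPx = NULL, sizePx = 64) {
  stopifnot(is(series, "FairSeries"))
  d <- dim(series@m0@pixels)  # rows = y, cols = x
  if (is.null(centerPx)) centerPx <- c(d[2], d[1]) / 2
  x0 <- round(centerPx[1] - sizePx / 2)  # 0-based start column
  y0 <- round(centerPx[2] - sizePx / 2)
  if (x0 < 0 || y0 < 0 || x0 + sizePx > d[2] || y0 + sizePx > d[1])
    stop(sprintf("crop window [%d, %d] + %d px exceeds the %d x %d grid",
                 x0, y0, sizePx, d[2], d[1]))
  rows <- (y0 + 1):(y0 + sizePx); cols <- (x0 + 1):(x0 + sizePx)
  cropFrame <- function(f) { f@pixels <- f@pixels[rows, cols, drop = FALSE]; f }
  series@controls <- lapply(series@controls, cropFrame)
  series@taggeds <- lapply(series@taggeds, cropFrame)
  series@m0 <- cropFrame(series@m0)
  series
}

# Same window arithmetic for a bare matrix (used on truth masks/maps).
cropMatrix <- function(m, centerPx = NULL, sizePx = 64) {
  d <- dim(m)
  if (is.null(centerPx)) centerPx <- c(d[2], d[1]) / 2
  x0 <- round(centerPx[1] - sizePx / 2); y0 <- round(centerPx[2] - sizePx / 2)
  stopifnot(x0 >= 0, y0 >= 0, x0 + sizePx <= d[2], y0 + sizePx <= d[1])
  m[(y0 + 1):(y0 + sizePx), (x0 + 1):(x0 + sizePx), drop = FALSE]
}

#' Inversion-time correction of one frame
#'
#' Shifts a control or tagged frame from its actual inversion time to the
#' nominal one with the inversion-recovery signal model, pixelwise:
#' `I_corr = M0 + (I - M0) exp(dTI / T1)` with
#' `dTI = actual - nominal`. The corrected frame's inversion time is set
#' to the nominal value. The blood T1 (~1700 ms) is used for all pixels,
#' as in the reference pipeline.
#'
#' @param frame a control or tagged [ImageFrame-class].
#' @param m0 the M0 [ImageFrame-class] on the same grid.
#' @param nominalTiMs nominal inversion time, ms.
#' @param t1Ms longitudinal relaxation time, ms (> 0).
#' @return the corrected [ImageFrame-class].
#' @examples
#' # M0 = 1000, I = 400, dTI = +100 ms, T1 = 1700 ms -> 363.65
#' f <- new("ImageFrame", pixels = matrix(400), frameType = "control",
#'          index = 1, actualTiMs = 1100)
#' m <- new("ImageFrame", pixels = matrix(1000), frameType = "m0",
#'          index = NA_real_, actualTiMs = NA_real_)
#' pixels(correctInversionTime(f, m, 1000, 1700))
#' @export
correctInversionTime <- function(frame, m0, nominalTiMs, t1Ms) {
  stopifnot(is(frame, "ImageFrame"), is(m0, "ImageFrame"),
            all(dim(frame@pixels) == dim(m0@pixels)))
  if (!is.finite(t1Ms) || t1Ms <= 0) stop("t1Ms must be positive")
  if (is.na(frame@actualTiMs)) stop("frame carries no actual inversion time")
  dTi <- frame@actualTiMs - nominalTiMs
  if (dTi != 0)
    frame@pixels <- m0@pixels + (frame@pixels - m0@pixels) * exp(dTi / t1Ms)
  frame@actualTiMs <- nominalTiMs
  frame
}

#' Average a corrected frame series
#'
#' Pixelwise arithmetic mean of the (inversion-time corrected) frames of
#' one type, with the mean of their inversion times.
#'
#' @param frames non-empty list of [ImageFrame-class]s of one type.
#' @return list with `frame` (the averaged [ImageFrame-class], index
#'   `NA`) and `tiMs` (mean inversion time).
#' @export
averageSeries <- function(frames) {
  if (length(frames) == 0) stop("cannot average an empty series")
  types <- vapply(frames, function(f) f@frameType, character(1))
  stopifnot(length(unique(types)) == 1)
  px <- Reduce(`+`, lapply(frames, function(f) f@pixels)) / length(frames)
  ti <- mean(vapply(frames, function(f) f@actualTiMs, numeric(1)))
  out <- frames[[1]]
  out@pixels <- px; out@actualTiMs <- ti; out@index <- NA_real_
  list(frame = out, tiMs = ti)
}

#' Full preprocessing of a FAIR series
#'
#' Executes the postprocessing stages upstream of quantification, in
#' order: (1) crop the ROI around the left ventricle in the M0 frame and
#' propagate the window to all frames; (2) register controls 2-6 to
#' control 1 and taggeds 2-6 to tagged 1 (mean-squares metric); (3)
#' correct all twelve frames to the per-type mean actual inversion time
#' against the cropped M0; (4) average each type; (5) register both
#' averages to the cropped M0 (mutual information). Stage errors are
#' re-thrown with the stage name.
#'
#' @param series a [FairSeries-class].
#' @param centerPx crop window center, 0-based `(x, y)`; default grid
#'   center.
#' @param sizePx crop window side, pixels.
#' @param registration set `FALSE` to skip both registration stages (the
#'   motion-correction ablation); cropping, correction and averaging are
#'   unchanged.
#' @return a [PreparedPair-class].
#' @export
preprocessSeries <- function(series, centerPx = NULL, sizePx = 64,
                             registration = TRUE) {
  stopifnot(is(series, "FairSeries"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
  }
  cropped <- stage("crop", cropROI(series, centerPx, sizePx))
  log <- list(withinControl = vector("list", 5),
              withinTagged = vector("list", 5),
              controlToM0 = NULL, taggedToM0 = NULL)
  registerWithin <- function(frames, which) {
    stage("register_within", {
      for (i in 2:6) {
        reg <- registerRigid(frames[[i]], frames[[1]], "mean_squares")
        frames[[i]] <- reg$aligned
        log[[which]][[i - 1]] <<- reg$transform
      }
      frames
    })
  }
  if (registration) {
    cropped@controls <- registerWithin(cropped@controls, "withinControl")
    cropped@taggeds <- registerWithin(cropped@taggeds, "withinTagged")
  } else {
    log$withinControl <- log$withinTagged <-
      replicate(5, RigidTransform(), simplify = FALSE)
  }
  nomC <- mean(vapply(cropped@controls, actualTI, numeric(1)))
  nomT <- mean(vapply(cropped@taggeds, actualTI, numeric(1)))
  t1 <- series@bloodT1Ms
  corrected <- stage("ti_correction", list(
    controls = lapply(cropped@controls, correctInversionTime,
                      m0 = cropped@m0, nominalTiMs = nomC, t1Ms = t1),
    taggeds = lapply(cropped@taggeds, correctInversionTime,
                     m0 = cropped@m0, nominalTiMs = nomT, t1Ms = t1)))
  avgC <- stage("average", averageSeries(corrected$controls))
  avgT <- stage("average", averageSeries(corrected$taggeds))
  cFrame <- avgC$frame; tFrame <- avgT$frame
  if (registration) {
    regC <- stage("register_m0", registerRigid(cFrame, cropped@m0,
                                               "mutual_information"))
    regT <- stage("register_m0", registerRigid(tFrame, cropped@m0,
                                               "mutual_information"))
    cFrame <- regC$aligned; tFrame <- regT$aligned
    log$controlToM0 <- regC$transform; log$taggedToM0 <- regT$transform
  } else {
    log$controlToM0 <- log$taggedToM0 <- RigidTransform()
  }
  new("PreparedPair", controlAvg = cFrame, taggedAvg = tFrame,
      m0 = cropped@m0, tiControlMs = avgC$tiMs, tiTaggedMs = avgT$tiMs,
      transformLog = log)
}
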