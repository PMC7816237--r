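#' Construct an image frame
#'
#' @param pixels numeric matrix of signal intensities.
#' @param frameType `"control"`, `"tagged"` or `"m0"`.
#' @param index position 1-6 in the series (`NA` for M0).
#' @param actualTiMs actual inversion time in ms (`NA` for M0).
#' @return an [ImageFrame-class].
#' @export
ImageFrame <- function(pixels, frameType = c("control", "tagged", "m0"),
                       index = NA_real_, actualTiMs = NA_real_) {
  frameType <- match.arg(frameType)
  new("ImageFrame", pixels = pixels, frameType = frameType,
      index = as.numeric(index), actualTiMs = as.numeric(actualTiMs))
}

#' Construct a FAIR series
#'
#' @param protocol an [AcquisitionProtocol-class].
#' @param controls list of six control [ImageFrame-class]s.
#' @param taggeds list of six tagged [ImageFrame-class]s.
#' @param m0 the M0 [ImageFrame-class].
#' @param heartRateBpm heart rate, bpm.
#' @param bloodT1Ms blood T1, ms (default 1700).
#' @return a [FairSeries-class].
#' @export
FairSeries <- function(protocol, controls, taggeds, m0,
                       heartRateBpm = 60, bloodT1Ms = 1700) {
  new("FairSeries", protocol = protocol, controls = controls,
      taggeds = taggeds, m0 = m0, heartRateBpm = heartRateBpm,
      bloodT1Ms = bloodT1Ms)
}
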