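# Shared fixtures: phantom specs with selected corruption sources, all
# other sources switched off.

cleanSpec <- function(seed = 1, ...) {
  args <- list(tiJitterFrac = 0, motionTransPx = 0, motionRotDeg = 0,
               thermalSigma = 0, physioK = 0, seed = seed)
  do.call(PhantomSpec, utils::modifyList(args, list(...)))
}

# myocardial truth mask cropped to the default ROI window
cropMask <- function(truth, sizePx = 64) {
  FAIRmbf:::cropMatrix(truth@myoMask, sizePx = sizePx)
}

myoValues <- function(map) mbfValues(map)[myoMask(map)]

quantifyPrepared <- function(prep, myo, t1 = 1700) {
  mbfMap(prep@controlAvg, prep@taggedAvg, prep@m0,
         prep@tiControlMs, prep@tiTaggedMs, t1Ms = t1, myo = myo)
}

# an asymmetric test image (annulus plus off-axis structure at a large
# lever arm) on the cropped grid, so rotation is identifiable
asymmetricImage <- function() {
  fw <- forwardSignals(cleanSpec(), fairProtocol("FAIR-PI2_D"))
  img <- FAIRmbf:::cropMatrix(fw$control, sizePx = 64)
  img[8:14, 42:52] <- img[8:14, 42:52] + 400
  img[46:54, 10:16] <- img[46:54, 10:16] + 300
  img[31:33, 8:24] <- img[31:33, 8:24] + 350
  img
}
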