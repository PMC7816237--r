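#' Accessors for FAIRmbf objects
#'
#' Small accessor generics used across the package: `pixels()` returns the
#' raw signal matrix of a frame, `frameType()` its role in the series,
#' `actualTI()` its actual inversion time; `protocol()`, `controls()`,
#' `taggeds()` and `m0Frame()` extract the components of a
#' [FairSeries-class]; `mbfValues()`, `validMask()` and `myoMask()` the
#' components of an [MBFMap-class].
#'
#' @param object the object to access.
#' @return the corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("frameType", function(object) standardGeneric("frameType"))
#' @rdname accessors
#' @export
setGeneric("actualTI", function(object) standardGeneric("actualTI"))
#' @rdname accessors
#' @export
setGeneric("protocol", function(object) standardGeneric("protocol"))
#' @rdname accessors
#' @export
setGeneric("controls", function(object) standardGeneric("controls"))
#' @rdname accessors
#' @export
setGeneric("taggeds", function(object) standardGeneric("taggeds"))
#' @rdname accessors
#' @export
setGeneric("m0Frame", function(object) standardGeneric("m0Frame"))
#' @rdname accessors
#' @export
setGeneric("mbfValues", function(object) standardGeneric("mbfValues"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("myoMask", function(object) standardGeneric("myoMask"))

#' @rdname accessors
setMethod("pixels", "ImageFrame", function(object) object@pixels)
#' @rdname accessors
setMethod("frameType", "ImageFrame", function(object) object@frameType)
#' @rdname accessors
setMethod("actualTI", "ImageFrame", function(object) object@actualTiMs)
#' @rdname accessors
setMethod("protocol", "FairSeries", function(object) object@protocol)
#' @rdname accessors
setMethod("controls", "FairSeries", function(object) object@controls)
#' @rdname accessors
setMethod("taggeds", "FairSeries", function(object) object@taggeds)
#' @rdname accessors
setMethod("m0Frame", "FairSeries", function(object) object@m0)
#' @rdname accessors
setMethod("mbfValues", "MBFMap", function(object) object@values)
#' @rdname accessors
setMethod("validMask", "MBFMap", function(object) object@validMask)
#' @rdname accessors
setMethod("myoMask", "MBFMap", function(object) object@myoMask)

setMethod("show", "AcquisitionProtocol", function(object) {
  cat("AcquisitionProtocol '", object@name, "'\n", sep = "")
  cat("  phase: ", object@cardiacPhase,
      " | accel: ", object@accelMethod, " x", object@accelFactor, "\n", sep = "")
  cat("  matrix ", paste(object@matrixSize, collapse = "x"),
      " @ ", paste(object@pixelMm, collapse = "x"), " mm, slice ",
      object@sliceMm, " mm\n", sep = "")
  cat("  TR ", object@trMs, " ms, TE ", object@teMs, " ms, flip ",
      object@flipDeg, " deg, nominal TI ", object@nominalTiMs, " ms\n", sep = "")
  cat("  acquisition window ", format(acquisitionWindow(object), digits = 6),
      " ms, rest period ", object@restPeriodMs, " ms\n", sep = "")
})

setMethod("show", "ImageFrame", function(object) {
  d <- dim(object@pixels)
  cat("ImageFrame <", object@frameType, ">", sep = "")
  if (!is.na(object@index)) cat(" #", object@index, sep = "")
  cat(": ", d[1], "x", d[2], sep = "")
  if (!is.na(object@actualTiMs))
    cat(", TI ", format(object@actualTiMs, digits = 6), " ms", sep = "")
  cat("\n")
})

setMethod("show", "FairSeries", function(object) {
  d <- dim(object@m0@pixels)
  cat("FairSeries (", object@protocol@name, "): 6 control + 6 tagged + M0, ",
      d[1], "x", d[2], " px\n", sep = "")
  tiC <- vapply(object@controls, function(f) f@actualTiMs, numeric(1))
  tiT <- vapply(object@taggeds, function(f) f@actualTiMs, numeric(1))
  cat("  control TI ", format(mean(tiC), digits = 6), " ms (mean), tagged TI ",
      format(mean(tiT), digits = 6), " ms (mean)\n", sep = "")
  cat("  heart rate ", object@heartRateBpm, " bpm, blood T1 ",
      object@bloodT1Ms, " ms\n", sep = "")
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: t = (%.3f, %.3f) px, theta = %.3f deg%s\n",
              object@txPx, object@tyPx, object@thetaDeg,
              if (isTRUE(object@converged)) "" else " [not converged]"))
})

setMethod("show", "MBFMap", function(object) {
  d <- dim(object@values)
  v <- object@values[object@myoMask & object@validMask]
  cat("MBFMap: ", d[1], "x", d[2], " px, ", sum(object@myoMask),
      " myocardial px (", sum(object@myoMask & object@validMask),
      " valid)\n", sep = "")
  if (length(v))
    cat(sprintf("  myocardial MBF %.3f +- %.3f ml/g/min\n", mean(v), stats::sd(v)))
})

setMethod("show", "PreparedPair", function(object) {
  cat("PreparedPair: averaged control (TI ",
      format(object@tiControlMs, digits = 6), " ms) and tagged (TI ",
      format(object@tiTaggedMs, digits = 6), " ms) aligned to M0\n", sep = "")
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport for '", object@metric, "'\n", sep = "")
  cat(sprintf("  one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              object@anovaDf[1], object@anovaDf[2], object@anovaF, object@anovaP))
  print(object@groupStats, row.names = FALSE)
  if (is.null(object@posthoc)) {
    cat("  no post-hoc tests (ANOVA not significant at alpha = ",
        object@alpha, ")\n", sep = "")
  } else {
    cat("  paired post-hoc t-tests:\n")
    print(object@posthoc, row.names = FALSE)
  }
})
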