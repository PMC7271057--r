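#' @include AllClasses.R
NULL

#' @rdname ScintiImage-class
#' @param object,x a renoscint object.
#' @export
setGeneric("imgValues", function(x) standardGeneric("imgValues"))

#' @rdname ScintiImage-class
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @rdname ScintiVolume-class
#' @export
setGeneric("slices", function(x) standardGeneric("slices"))

#' @rdname ScintiVolume-class
#' @export
setGeneric("sliceSpacing", function(x) standardGeneric("sliceSpacing"))

#' @rdname DomainPartition-class
#' @export
setGeneric("phiS", function(x) standardGeneric("phiS"))

#' @rdname DomainPartition-class
#' @export
setGeneric("phiSbar", function(x) standardGeneric("phiSbar"))

#' @rdname IntensityDistribution-class
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname IntensityDistribution-class
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("kidneyMask", function(x) standardGeneric("kidneyMask"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("energyTrace", function(x) standardGeneric("energyTrace"))

#' @rdname SegmentationResult-class
#' @export
setGeneric("segLabels", function(x) standardGeneric("segLabels"))

#' @rdname QuantReport-class
#' @export
setGeneric("relFunction", function(x) standardGeneric("relFunction"))

setMethod("imgValues", "ScintiImage", function(x) x@values)
setMethod("pixelSpacing", "ScintiImage", function(x) x@pixelSpacing)
setMethod("slices", "ScintiVolume", function(x) x@slices)
setMethod("sliceSpacing", "ScintiVolume", function(x) x@sliceSpacing)
setMethod("phiS", "DomainPartition", function(x) x@phiS)
setMethod("phiSbar", "DomainPartition", function(x) x@phiSbar)
setMethod("binCenters", "IntensityDistribution", function(x) x@binCenters)
setMethod("probabilities", "IntensityDistribution", function(x) x@probabilities)
setMethod("kidneyMask", "SegmentationResult", function(x) x@kidneyMask)
setMethod("energyTrace", "SegmentationResult", function(x) x@energyTrace)
setMethod("segLabels", "SegmentationResult", function(x) x@labels)

#' @rdname QuantReport-class
#' @export
setMethod("relFunction", "QuantReport",
          function(x) c(right = x@rfRight, left = x@rfLeft))

#' @describeIn ScintiImage-class image dimensions (rows, columns).
#' @export
setMethod("dim", "ScintiImage", function(x) dim(x@values))

setMethod("show", "ScintiImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("ScintiImage %dx%d px (%.3g mm/px), counts in [%.4g, %.4g]\n",
              d[1], d[2], object@pixelSpacing,
              min(object@values), max(object@values)))
})

setMethod("show", "ScintiVolume", function(object) {
  d <- dim(object@slices[[1]]@values)
  cat(sprintf("ScintiVolume: %d slice(s) of %dx%d px, slice spacing %.3g mm\n",
              length(object@slices), d[1], d[2], object@sliceSpacing))
})

setMethod("show", "DomainPartition", function(object) {
  cat(sprintf(
    "DomainPartition (%s, %s split at %d): |phi_s| = %d, |phi_s_bar| = %d\n",
    object@sideChoice, object@splitKind, object@splitIndex,
    sum(object@phiS), sum(object@phiSbar)))
})

setMethod("show", "IntensityDistribution", function(object) {
  cat(sprintf("IntensityDistribution: %d bins on [%.4g, %.4g]\n",
              length(object@binCenters), min(object@binCenters),
              max(object@binCenters)))
})

setMethod("show", "SegmentationResult", function(object) {
  cat(sprintf(paste0(
    "SegmentationResult: %d kidney pixels, %d iteration(s), ",
    "C = %.6f (matching %.6f, smoothness %.6f)%s\n"),
    sum(object@kidneyMask), object@iterations,
    object@energyTrace[length(object@energyTrace)],
    object@matchingTerm, object@smoothnessTerm,
    if (length(object@flags)) paste0(" [", paste(object@flags, collapse = ","), "]")
    else ""))
})

setMethod("show", "QuantReport", function(object) {
  cat(sprintf("QuantReport (%s): RF right %.2f%% / left %.2f%%%s\n",
              object@method, object@rfRight, object@rfLeft,
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]") else ""))
})

setMethod("show", "AgreementResult", function(object) {
  cat(sprintf(paste0(
    "AgreementResult: bias %.4g, LoA [%.4g, %.4g], ICC single %.4f ",
    "(95%% CI %.4f-%.4f), average %.4f, r = %.4f\n"),
    object@bias, object@loaLow, object@loaHigh, object@iccSingle,
    object@ciSingle[1], object@ciSingle[2], object@iccAverage,
    object@pearsonR))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(paste0(
    "PhantomSpec '%s': %dx%d px, seed %d, rates bg %.3g + kidney ",
    "R %.3g / L %.3g, true split %.1f/%.1f\n"),
    object@preset, object@size, object@size, object@seed,
    object@backgroundRate, object@kidneyRateRight, object@kidneyRateLeft,
    object@trueSplit["right"], object@trueSplit["left"]))
})
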