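#' @name accessors
#' @title Accessors for EyeSphere classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object an EyeSphere S4 object.
NULL

#' @rdname accessors
#' @export
setGeneric("semiAxes", function(object) standardGeneric("semiAxes"))
#' @rdname accessors
#' @export
setGeneric("rimOpening", function(object) standardGeneric("rimOpening"))
#' @rdname accessors
#' @export
setGeneric("rimColatitude", function(object) standardGeneric("rimColatitude"))
#' @rdname accessors
#' @export
setGeneric("eyeHandedness", function(object) standardGeneric("eyeHandedness"))
#' @rdname accessors
#' @export
setGeneric("rMax", function(object) standardGeneric("rMax"))
#' @rdname accessors
#' @export
setGeneric("rotationAngles", function(object) standardGeneric("rotationAngles"))
#' @rdname accessors
#' @export
setGeneric("translationVec", function(object) standardGeneric("translationVec"))
#' @rdname accessors
#' @export
setGeneric("viewLabel", function(object) standardGeneric("viewLabel"))
#' @rdname accessors
#' @export
setGeneric("markPixel", function(object) standardGeneric("markPixel"))
#' @rdname accessors
#' @export
setGeneric("ntFraction", function(object) standardGeneric("ntFraction"))
#' @rdname accessors
#' @export
setGeneric("dvFraction", function(object) standardGeneric("dvFraction"))
#' @rdname accessors
#' @export
setGeneric("polarCoords", function(object) standardGeneric("polarCoords"))
#' @rdname accessors
#' @export
setGeneric("rayGap", function(object) standardGeneric("rayGap"))
#' @rdname accessors
#' @export
setGeneric("areaFraction", function(object) standardGeneric("areaFraction"))
#' @rdname accessors
#' @export
setGeneric("sceneTruth", function(object) standardGeneric("sceneTruth"))
#' @rdname accessors
#' @export
setGeneric("sceneImages", function(object) standardGeneric("sceneImages"))
#' @rdname accessors
#' @export
setGeneric("sessionEye", function(object) standardGeneric("sessionEye"))
#' @rdname accessors
#' @export
setGeneric("sessionViews", function(object) standardGeneric("sessionViews"))
#' @rdname accessors
#' @export
setGeneric("sessionMarks", function(object) standardGeneric("sessionMarks"))

#' @rdname accessors
#' @export
setMethod("semiAxes", "EyeModel", function(object) object@semiAxes)
#' @rdname accessors
#' @export
setMethod("rimOpening", "EyeModel", function(object) object@rimOpeningDeg)
#' @rdname accessors
#' @export
setMethod("rimColatitude", "EyeModel", function(object) 180 - object@rimOpeningDeg)
#' @rdname accessors
#' @export
setMethod("eyeHandedness", "EyeModel", function(object) object@handedness)
#' @rdname accessors
#' @export
setMethod("rMax", "EyeModel", function(object) max(object@semiAxes))

#' @rdname accessors
#' @export
setMethod("rotationAngles", "ViewTransform", function(object) object@rotationDeg)
#' @rdname accessors
#' @export
setMethod("translationVec", "ViewTransform", function(object) object@translation)
#' @rdname accessors
#' @export
setMethod("viewLabel", "ViewTransform", function(object) object@label)
#' @rdname accessors
#' @export
setMethod("markPixel", "ViewMark", function(object) object@pixel)
#' @rdname accessors
#' @export
setMethod("viewLabel", "ViewMark", function(object) object@label)

#' @rdname accessors
#' @export
setMethod("ntFraction", "LocalizationResult", function(object) object@ntFraction)
#' @rdname accessors
#' @export
setMethod("dvFraction", "LocalizationResult", function(object) object@dvFraction)
#' @rdname accessors
#' @export
setMethod("polarCoords", "LocalizationResult", function(object) object@polar)
#' @rdname accessors
#' @export
setMethod("rayGap", "LocalizationResult", function(object) object@rayGap)
#' @rdname accessors
#' @export
setMethod("areaFraction", "LocalizationResult", function(object) object@areaFraction)
#' @rdname accessors
#' @export
setMethod("areaFraction", "AreaEstimate", function(object) object@fraction)

#' @rdname accessors
#' @export
setMethod("sceneTruth", "SyntheticScene", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("sceneImages", "SyntheticScene", function(object)
  list(top = object@imageTop, side = object@imageSide))

#' @rdname accessors
#' @export
setMethod("sessionEye", "EyeSession", function(object) object@eye)
#' @rdname accessors
#' @export
setMethod("sessionViews", "EyeSession", function(object) object@views)
#' @rdname accessors
#' @export
setMethod("sessionMarks", "EyeSession", function(object) object@marks)

setMethod("show", "EyeModel", function(object) {
  cat(sprintf("EyeModel: semi-axes (%.4g, %.4g, %.4g), rim opening %.3g deg (rim colatitude %.3g deg), %s eye\n",
              object@semiAxes[1], object@semiAxes[2], object@semiAxes[3],
              object@rimOpeningDeg, 180 - object@rimOpeningDeg,
              object@handedness))
})

setMethod("show", "ViewTransform", function(object) {
  cat(sprintf("ViewTransform \"%s\": rotation (%.3g, %.3g, %.3g) deg, translation (%.4g, %.4g, %.4g)\n",
              object@label, object@rotationDeg[1], object@rotationDeg[2],
              object@rotationDeg[3], object@translation[1],
              object@translation[2], object@translation[3]))
})

setMethod("show", "WedgeCoordinate", function(object) {
  cat(sprintf("WedgeCoordinate [%s]: psi = %.4g deg, f = %.6g%s\n",
              object@axis, object@psiDeg, object@f,
              if (object@degenerate) " (degenerate tilt)" else ""))
})

setMethod("show", "LocalizationResult", function(object) {
  cat("LocalizationResult\n")
  cat(sprintf("  NT fraction: %.4f   DV fraction: %.4f\n",
              object@ntFraction, object@dvFraction))
  cat(sprintf("  polar: colatitude %.2f deg, azimuth %.2f deg\n",
              object@polar[1], object@polar[2]))
  cat(sprintf("  ray gap: %.4g eye units%s\n", object@rayGap,
              if (object@aboveRim) "  [point above rim]" else ""))
  if (!is.na(object@areaFraction))
    cat(sprintf("  area fraction: %.4g\n", object@areaFraction))
})

setMethod("show", "AreaEstimate", function(object) {
  cat(sprintf("AreaEstimate: fraction %.4g of the retina (%.4g sq units, %d pixels, threshold %.3g, %d rays dropped)\n",
              object@fraction, object@absoluteArea, object@nPixels,
              object@thresholdUsed, object@droppedRays))
})

setMethod("show", "SyntheticScene", function(object) {
  tr <- object@truth
  cat(sprintf("SyntheticScene (seed %d): injection centre at theta %.1f, phi %.1f deg; NT %.3f, DV %.3f; %d points%s\n",
              object@seed, tr@thetaInjDeg, tr@phiInjDeg, tr@ntTrue, tr@dvTrue,
              nrow(tr@points),
              if (length(object@imageTop)) "; rendered" else ""))
})

setMethod("show", "EyeSession", function(object) {
  cat(sprintf("EyeSession (schema %s): %s eye, %d marks, %d results\n",
              object@schemaVersion, object@eye@handedness,
              length(object@marks), length(object@results)))
})
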