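#' Ellipsoidal eye model
#'
#' The eye is modelled as an ellipsoid with semi-axes `r_x`, `r_y`, `r_z`
#' (any consistent length unit: micrometres for real eyes, pixels for
#' uncalibrated images) whose retinal cup opens towards +z. The opening is
#' described by the rim-opening angle, measured in degrees from the optical
#' (+z) axis; the retina occupies everything from the deepest point of the
#' cup up to the rim, which for typical rodent eyes is more than a
#' hemisphere. Internally the rim is also expressed as a colatitude from the
#' deepest point, `180 - rimOpeningDeg` (53 degrees opening = rim colatitude
#' 127 degrees). Handedness ("left" or "right") controls the orientation of
#' the dorsoventral axis.
#'
#' @slot semiAxes numeric(3), positive semi-axis lengths (r_x, r_y, r_z).
#' @slot rimOpeningDeg numeric(1), rim-opening angle from the optical axis,
#'   strictly between 0 and 90 degrees.
#' @slot handedness character(1), `"left"` or `"right"`.
#' @export
setClass("EyeModel", representation(
  semiAxes = "numeric",
  rimOpeningDeg = "numeric",
  handedness = "character"
))

setValidity("EyeModel", function(object) {
  msg <- character()
  if (length(object@semiAxes) != 3 || any(!is.finite(object@semiAxes)) ||
      any(object@semiAxes <= 0))
    msg <- c(msg, "semiAxes must be three positive finite lengths")
  if (length(object@rimOpeningDeg) != 1 || !is.finite(object@rimOpeningDeg) ||
      object@rimOpeningDeg <= 0 || object@rimOpeningDeg >= 90)
    msg <- c(msg, "rimOpeningDeg must lie strictly between 0 and 90 degrees")
  if (length(object@handedness) != 1 ||
      !object@handedness %in% c("left", "right"))
    msg <- c(msg, "handedness must be \"left\" or \"right\"")
  if (length(msg)) msg else TRUE
})

#' Construct an eye model
#'
#' @param semiAxes numeric(3) positive semi-axis lengths; a single number is
#'   recycled to a sphere.
#' @param rimOpeningDeg rim-opening angle in degrees from the optical axis
#'   (default 53, typical for an early-postnatal mouse eye).
#' @param handedness `"left"` (default) or `"right"`.
#' @return An [EyeModel-class] object.
#' @examples
#' eye <- eyeModel(c(1400, 1400, 1400), rimOpeningDeg = 53)
#' rimColatitude(eye)  # 127
#' @export
eyeModel <- function(semiAxes, rimOpeningDeg = 53, handedness = c("left", "right")) {
  if (length(semiAxes) == 1) semiAxes <- rep(semiAxes, 3)
  handedness <- match.arg(handedness)
  new("EyeModel", semiAxes = as.numeric(semiAxes),
      rimOpeningDeg = as.numeric(rimOpeningDeg), handedness = handedness)
}

#' Rigid view transform between the eye frame and a camera frame
#'
#' Maps eye-frame coordinates `a` to camera/image-frame coordinates
#' `T(a) = R a + t`, where `R = Rx(thx) Ry(thy) Rz(thz)` (applied in that
#' order, angles in degrees) and `t` is a translation in image units. The
#' camera looks along -z, so camera x/y are the image axes (y up) and larger
#' camera z is nearer the viewer.
#'
#' @slot rotationDeg numeric(3), rotation angles about x, y, z in degrees.
#' @slot translation numeric(3), translation in camera/image units.
#' @slot label character(1), free-text label such as "top" or "side".
#' @export
setClass("ViewTransform", representation(
  rotationDeg = "numeric",
  translation = "numeric",
  label = "character"
))

setValidity("ViewTransform", function(object) {
  msg <- character()
  if (length(object@rotationDeg) != 3 || any(!is.finite(object@rotationDeg)))
    msg <- c(msg, "rotationDeg must be three finite angles")
  if (length(object@translation) != 3 || any(!is.finite(object@translation)))
    msg <- c(msg, "translation must be a finite 3-vector")
  R <- rotationMatrix(object@rotationDeg)
  if (max(abs(crossprod(R) - diag(3))) > 1e-9 || abs(det(R) - 1) > 1e-9)
    msg <- c(msg, "rotation matrix is not a proper rotation")
  if (length(msg)) msg else TRUE
})

#' Construct a view transform
#'
#' @param rotationDeg numeric(3) rotation angles (degrees) about x, y, z;
#'   the rotation matrix is `Rx %*% Ry %*% Rz`.
#' @param translation numeric(3) translation in image units.
#' @param label free-text view label.
#' @return A [ViewTransform-class] object.
#' @export
viewTransform <- function(rotationDeg = c(0, 0, 0), translation = c(0, 0, 0),
                          label = "view") {
  new("ViewTransform", rotationDeg = as.numeric(rotationDeg),
      translation = as.numeric(translation), label = as.character(label))
}

#' A pixel mark of the injection in one view
#'
#' Pixel coordinates use the image convention: origin at the top-left,
#' x to the right, y downwards, 1-based pixel centres. Marks may be
#' fractional (e.g. a projected centroid).
#'
#' @slot label character(1) view label.
#' @slot pixel numeric(2) (x, y) pixel position.
#' @export
setClass("ViewMark", representation(label = "character", pixel = "numeric"))

setValidity("ViewMark", function(object) {
  if (length(object@pixel) != 2 || any(!is.finite(object@pixel)))
    "pixel must be a finite 2-vector" else TRUE
})

#' Construct a view mark
#' @param pixel numeric(2) (x, y) pixel coordinates (origin top-left, y down).
#' @param label view label.
#' @export
viewMark <- function(pixel, label = "view") {
  new("ViewMark", pixel = as.numeric(pixel), label = as.character(label))
}

#' Wedge coordinate on a named retinal axis
#'
#' A position on the retina expressed in the wedge coordinate system: `psi`
#' is the tilt (degrees, in \[-90, 90\]) of the plane through the two poles of
#' the axis, and `f` in \[0, 1\] the fractional distance along the circular
#' arc cut by that plane, from the first pole (nasal, or dorsal) to the
#' second. At the two poles and at the deepest point the tilt is degenerate;
#' such coordinates carry `degenerate = TRUE` and report `psi = 0`.
#'
#' @slot psiDeg numeric(1) plane tilt in degrees.
#' @slot f numeric(1) fractional arc distance in \[0, 1\].
#' @slot axis character(1) `"NT"` or `"DV"`.
#' @slot degenerate logical(1) tilt undefined at this point.
#' @export
setClass("WedgeCoordinate", representation(
  psiDeg = "numeric", f = "numeric", axis = "character", degenerate = "logical"
))

setValidity("WedgeCoordinate", function(object) {
  msg <- character()
  if (!is.finite(object@psiDeg) || abs(object@psiDeg) > 90 + 1e-9)
    msg <- c(msg, "psiDeg must lie in [-90, 90]")
  if (!is.finite(object@f) || object@f < -1e-9 || object@f > 1 + 1e-9)
    msg <- c(msg, "f must lie in [0, 1]")
  if (!object@axis %in% c("NT", "DV"))
    msg <- c(msg, "axis must be \"NT\" or \"DV\"")
  if (length(msg)) msg else TRUE
})

wedgeCoordinate <- function(psiDeg, f, axis = "NT", degenerate = FALSE) {
  new("WedgeCoordinate", psiDeg = as.numeric(psiDeg), f = as.numeric(f),
      axis = as.character(axis), degenerate = isTRUE(degenerate))
}

#' Result of localizing an injection from two views
#'
#' @slot pointEye numeric(3) recovered point in eye-frame coordinates (on the
#'   ellipsoid surface).
#' @slot pointUnit numeric(3) the same point mapped to the unit sphere.
#' @slot ntFraction,dvFraction numeric(1) fractional coordinates along the
#'   nasotemporal and dorsoventral axes.
#' @slot polar numeric(2) (colatitude, azimuth) in degrees; colatitude is
#'   measured from the deepest point of the cup, as in the flat polar export.
#' @slot rayGap numeric(1) distance between the two back-projection lines at
#'   their closest approach (triangulation residual, eye units).
#' @slot aboveRim logical(1) the recovered point lies above the rim.
#' @slot areaFraction numeric(1) optional injection area as a fraction of the
#'   retinal surface (NA when not estimated).
#' @export
setClass("LocalizationResult", representation(
  pointEye = "numeric", pointUnit = "numeric",
  ntFraction = "numeric", dvFraction = "numeric",
  polar = "numeric", rayGap = "numeric",
  aboveRim = "logical", areaFraction = "numeric"
))

setValidity("LocalizationResult", function(object) {
  msg <- character()
  if (object@ntFraction < -1e-9 || object@ntFraction > 1 + 1e-9 ||
      object@dvFraction < -1e-9 || object@dvFraction > 1 + 1e-9)
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (object@rayGap < 0) msg <- c(msg, "rayGap must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Injection area estimate
#'
#' @slot fraction numeric(1) injection area as a fraction of the reference
#'   surface (retina by default) in \[0, 1\].
#' @slot absoluteArea numeric(1) area in squared eye units.
#' @slot nPixels integer(1) number of mask pixels that contributed.
#' @slot droppedRays integer(1) mask pixels whose ray missed the ellipsoid.
#' @slot thresholdUsed numeric(1) chroma-distance threshold applied.
#' @export
setClass("AreaEstimate", representation(
  fraction = "numeric", absoluteArea = "numeric", nPixels = "integer",
  droppedRays = "integer", thresholdUsed = "numeric"
))

setValidity("AreaEstimate", function(object) {
  if (object@fraction < -1e-12 || object@fraction > 1 + 1e-9)
    "fraction must lie in [0, 1]" else TRUE
})

#' Ground truth of a synthetic scene
#'
#' @slot centreUnit numeric(3) unit-sphere position of the injection centre.
#' @slot thetaInjDeg,phiInjDeg numeric(1) spherical coordinates of the centre
#'   (azimuth in \[0, 360), colatitude from +z in \[0, 180\]).
#' @slot points matrix, one unit vector per row: the surviving injection
#'   points (at most 100; points above the rim are discarded).
#' @slot ntTrue,dvTrue numeric(1) wedge fractions of the centre.
#' @slot eye the sampled [EyeModel-class].
#' @slot views list of two [ViewTransform-class] ("top", "side").
#' @export
setClass("GroundTruth", representation(
  centreUnit = "numeric", thetaInjDeg = "numeric", phiInjDeg = "numeric",
  points = "matrix", ntTrue = "numeric", dvTrue = "numeric",
  eye = "EyeModel", views = "list"
))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (ncol(object@points) != 3) msg <- c(msg, "points must be an n x 3 matrix")
  zrim <- -cos(deg2rad(rimColatitude(object@eye)))
  if (nrow(object@points) && any(object@points[, 3] > zrim + 1e-9))
    msg <- c(msg, "injection points above the rim must be discarded")
  if (length(object@views) != 2)
    msg <- c(msg, "views must contain exactly two ViewTransform objects")
  if (length(msg)) msg else TRUE
})

#' A synthetic scene: ground truth plus (optionally) rendered views
#'
#' @slot truth a [GroundTruth-class].
#' @slot imageTop,imageSide rendered RGB rasters (H x W x 3 arrays in
#'   \[0, 1\]), or empty arrays when the scene has not been rendered.
#' @slot pixelScale numeric(1) eye units per pixel.
#' @slot imageSize integer(2) (width, height) of each rendered view.
#' @slot seed integer(1) RNG seed the scene was generated from.
#' @export
setClass("SyntheticScene", representation(
  truth = "GroundTruth", imageTop = "array", imageSide = "array",
  pixelScale = "numeric", imageSize = "integer", seed = "integer"
))

#' Analysis session
#'
#' Bundles everything needed to reproduce a localization: image references
#' (by path and checksum, never embedded), pixel scale, the eye model, the
#' two view transforms, optional marks and results, and provenance. Persisted
#' as versioned JSON by [saveSession()].
#'
#' @slot schemaVersion character(1).
#' @slot images list with `top` and `side` entries (path, checksum, width,
#'   height), possibly empty.
#' @slot pixelScale numeric(1) eye units per pixel (1 when unknown; all
#'   fractional outputs are scale-free).
#' @slot eye an [EyeModel-class].
#' @slot views list of two [ViewTransform-class].
#' @slot marks list of two [ViewMark-class] or empty list.
#' @slot results list (possibly empty) of serialized results.
#' @slot provenance list: seed, created, toolVersion.
#' @export
setClass("EyeSession", representation(
  schemaVersion = "character", images = "list", pixelScale = "numeric",
  eye = "EyeModel", views = "list", marks = "list", results = "list",
  provenance = "list"
))

setValidity("EyeSession", function(object) {
  msg <- character()
  if (length(object@views) != 2 ||
      !all(vapply(object@views, is, logical(1), "ViewTransform")))
    msg <- c(msg, "views must be a list of two ViewTransform objects")
  if (length(object@marks) &&
      !all(vapply(object@marks, is, logical(1), "ViewMark")))
    msg <- c(msg, "marks must be ViewMark objects")
  if (length(msg)) msg else TRUE
})

#' Construct a session
#' @param eye an [EyeModel-class].
#' @param views list of two [ViewTransform-class] (top, side).
#' @param pixelScale eye units per pixel.
#' @param images image reference list (see [EyeSession-class]).
#' @param marks optional list of two [ViewMark-class].
#' @param results optional list of results.
#' @param provenance optional provenance list.
#' @export
eyeSession <- function(eye, views, pixelScale = 1, images = list(),
                       marks = list(), results = list(), provenance = list()) {
  prov <- utils::modifyList(
    list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         toolVersion = as.character(utils::packageVersion("EyeSphere"))),
    provenance)
  new("EyeSession", schemaVersion = "1.0", images = images,
      pixelScale = as.numeric(pixelScale), eye = eye, views = views,
      marks = marks, results = results, provenance = prov)
}
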