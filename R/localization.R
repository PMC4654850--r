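#' Convert an image-pixel mark to camera coordinates
#'
#' Pixel coordinates have the origin at the top-left with y running down;
#' the camera frame is right-handed with y up. With an image of height `H`
#' (pixels) and a pixel scale `s` (eye units per pixel), a pixel (px, py)
#' maps to camera (px * s, (H + 1 - py) * s). When `imageHeight` is NULL the
#' mark is taken to be in camera coordinates already (y up), which is
#' convenient for purely geometric work.
#'
#' @param mark a [ViewMark-class] or numeric(2).
#' @param pixelScale eye units per pixel.
#' @param imageHeight image height in pixels, or NULL.
#' @return numeric(2) camera-frame (x, y).
#' @export
markToCamera <- function(mark, pixelScale = 1, imageHeight = NULL) {
  px <- if (is(mark, "ViewMark")) mark@pixel else as.numeric(mark)
  if (is.null(imageHeight)) return(px)
  c(px[1] * pixelScale, (imageHeight + 1 - px[2]) * pixelScale)
}

# inverse of markToCamera, used by the renderer / auto-marker
cameraToPixel <- function(xy, pixelScale = 1, imageHeight = NULL) {
  if (is.null(imageHeight)) return(xy)
  c(xy[1] / pixelScale, imageHeight + 1 - xy[2] / pixelScale)
}

#' Back-project a mark to a line segment in the eye frame
#'
#' Under orthographic projection a mark (x, y) in a view constrains the
#' injection to the segment between camera-frame points (x, y, +r_max) and
#' (x, y, -r_max), perpendicular to the image plane, where r_max is the
#' largest semi-axis. The segment is returned in eye-frame coordinates via
#' the inverse view transform; `q1` is the viewer-side endpoint.
#'
#' @param mark a [ViewMark-class] or numeric(2) mark.
#' @param view the [ViewTransform-class] of the marked view.
#' @param eye an [EyeModel-class].
#' @param pixelScale,imageHeight see [markToCamera()].
#' @return list with eye-frame endpoints `q1`, `q2` (class
#'   `"BackProjectionLine"`).
#' @export
backProject <- function(mark, view, eye, pixelScale = 1, imageHeight = NULL) {
  xy <- markToCamera(mark, pixelScale, imageHeight)
  rmax <- rMax(eye)
  q1 <- invertView(c(xy[1], xy[2], +rmax), view)
  q2 <- invertView(c(xy[1], xy[2], -rmax), view)
  structure(list(q1 = q1, q2 = q2,
                 label = if (is(mark, "ViewMark")) mark@label else view@label),
            class = "BackProjectionLine")
}

#' Triangulate two back-projection lines
#'
#' Returns the midpoint of the mutual-perpendicular segment between the two
#' (infinite) lines, and the length of that segment as the triangulation
#' residual. Equivalent to choosing the side-view point on the displayed
#' line: when the second mark lies exactly on the line projected from the
#' first view the gap is zero and the midpoint is the intersection.
#'
#' @param lineA,lineB back-projection lines from [backProject()].
#' @param minAngleDeg reject near-parallel lines whose directions are within
#'   this angle (default 5 degrees): a second view along (almost) the same
#'   axis adds no depth information.
#' @return list with `point` (3-vector) and `gap` (>= 0).
#' @export
triangulateLines <- function(lineA, lineB, minAngleDeg = 5) {
  p1 <- lineA$q1; d1 <- lineA$q2 - lineA$q1
  p2 <- lineB$q1; d2 <- lineB$q2 - lineB$q1
  u1 <- unitize(d1); u2 <- unitize(d2)
  ang <- rad2deg(acos(pmin(1, abs(sum(u1 * u2)))))
  if (ang < minAngleDeg)
    stop(sprintf("viewing rays are near-parallel (%.2f deg apart, minimum %g)",
                 ang, minAngleDeg))
  # closest points: p1 + s*u1, p2 + t*u2
  w <- p1 - p2
  b <- sum(u1 * u2)
  dd <- 1 - b^2
  s <- (b * sum(u2 * w) - sum(u1 * w)) / dd
  t <- (sum(u2 * w) - b * sum(u1 * w)) / dd
  a1 <- p1 + s * u1
  a2 <- p2 + t * u2
  list(point = (a1 + a2) / 2, gap = vnorm(a1 - a2))
}

#' Localize an injection from marks in two views
#'
#' Back-projects each mark, triangulates the two lines, snaps the result to
#' the eye surface by radial rescaling in semi-axis-normalized coordinates
#' (injections live on the retina), and reports the wedge fractions on the
#' nasotemporal and dorsoventral axes, the flat-export polar coordinates,
#' and the triangulation residual.
#'
#' @param markTop,markSide [ViewMark-class] objects or numeric(2) marks.
#' @param viewTop,viewSide the corresponding [ViewTransform-class] objects.
#' @param eye an [EyeModel-class]; its handedness sets the DV orientation.
#' @param pixelScale eye units per pixel (used when marks are pixels).
#' @param imageHeightTop,imageHeightSide image heights in pixels, or NULL
#'   when the marks are already camera coordinates.
#' @param minAngleDeg near-parallel rejection threshold for triangulation.
#' @return A [LocalizationResult-class]. If the snapped point lies above the
#'   rim a warning is raised and coordinates are still reported (fractions
#'   from the nearest rim point along the arc).
#' @export
localize <- function(markTop, markSide, viewTop, viewSide, eye,
                     pixelScale = 1, imageHeightTop = NULL,
                     imageHeightSide = NULL, minAngleDeg = 5) {
  la <- backProject(markTop, viewTop, eye, pixelScale, imageHeightTop)
  lb <- backProject(markSide, viewSide, eye, pixelScale, imageHeightSide)
  tri <- triangulateLines(la, lb, minAngleDeg)
  unit <- normalizeToSphere(tri$point, eye)
  pointEye <- unit * eye@semiAxes
  phi0 <- rimColatitude(eye)
  zrim <- -cos(deg2rad(phi0))
  aboveRim <- unit[3] > zrim + 1e-9
  wunit <- unit
  if (aboveRim) {
    warning("localized point lies above the rim; reporting nearest rim coordinates")
    # pull down to the rim along the meridian
    th <- atan2(unit[2], unit[1])
    srim <- sqrt(1 - zrim^2)
    wunit <- c(srim * cos(th), srim * sin(th), zrim)
  }
  w <- wedgeBothAxes(wunit, phi0, eye@handedness)
  pol <- sphericalPolar(wunit)
  new("LocalizationResult", pointEye = pointEye, pointUnit = unit,
      ntFraction = w$NT@f, dvFraction = w$DV@f,
      polar = c(pol$colatitudeDeg, pol$azimuthDeg),
      rayGap = tri$gap, aboveRim = aboveRim, areaFraction = NA_real_)
}

#' Legacy flat-retina projection method
#'
#' The classical estimate from a flattened-retina image: the nasal pole N is
#' the midpoint of the two nasal cut endpoints (N1, N2), the temporal pole T
#' the midpoint of (T1, T2), and the injection A is projected orthogonally
#' onto the NT line; the reported position is |NA'| / |NT| where A' is the
#' projection. Values outside \[0, 1\] (injections beyond a pole) are clamped
#' and flagged.
#'
#' @param N1,N2,T1,T2,A numeric(2) pixel positions on the flattened image.
#' @return list with `fraction` (clamped to \[0,1\]), `raw` (unclamped), and
#'   `outOfRange`.
#' @export
projectionMethod <- function(N1, N2, T1, T2, A) {
  N <- (as.numeric(N1) + as.numeric(N2)) / 2
  T <- (as.numeric(T1) + as.numeric(T2)) / 2
  nt <- T - N
  len2 <- sum(nt^2)
  if (len2 < 1e-18) stop("nasal and temporal poles coincide")
  raw <- sum((as.numeric(A) - N) * nt) / len2
  list(fraction = min(1, max(0, raw)), raw = raw,
       outOfRange = raw < 0 || raw > 1)
}
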