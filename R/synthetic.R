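#' Sample a synthetic eye
#'
#' Semi-axes are drawn independently from Normal(1400, 70) micrometres (a
#' P12 mouse eye), truncated to positive values, and the rim-opening angle
#' from Normal(53, 3) degrees, clamped to (10, 85). Uses the current RNG
#' stream; seed with [set.seed()] for reproducibility.
#'
#' @param handedness eye handedness for the sampled model.
#' @return An [EyeModel-class].
#' @export
sampleEye <- function(handedness = "left") {
  ax <- stats::rnorm(3, 1400, 70)
  while (any(ax <= 0)) ax[ax <= 0] <- stats::rnorm(sum(ax <= 0), 1400, 70)
  rim <- min(85, max(10, stats::rnorm(1, 53, 3)))
  eyeModel(ax, rim, handedness)
}

# one random view rotation: x/y tilts ~ Normal(0, 9) truncated at +-20 deg
# (resampled), free z-rotation
sampleTiltAngles <- function() {
  tilt <- stats::rnorm(2, 0, 9)
  while (any(abs(tilt) > 20)) {
    bad <- abs(tilt) > 20
    tilt[bad] <- stats::rnorm(sum(bad), 0, 9)
  }
  c(tilt, stats::runif(1, 0, 360))
}

#' Sample the two camera poses
#'
#' The top view is a random small tilt (Normal(0, 9) degrees about x and y,
#' truncated at +-20) with a free rotation about z. The side view is the top
#' view composed with a 90-degree rotation about the x axis, with its own
#' independent tilts and z-rotation applied on top, so the two optical axes
#' stay orthogonal up to one view's tilt budget (90 +- 28 degrees).
#' Translations place the eye centre near the image centre with a small
#' random offset.
#'
#' @param eye the [EyeModel-class] being imaged (sets the default scale).
#' @param imageSize integer(2) (width, height) in pixels.
#' @param pixelScale eye units per pixel; default scales the eye diameter to
#'   ~70 percent of the image width.
#' @param jitterPx SD of the random translation, in pixels.
#' @return list: `views` (two [ViewTransform-class]), `pixelScale`.
#' @export
sampleViews <- function(eye, imageSize = c(400L, 400L), pixelScale = NULL,
                        jitterPx = 8) {
  if (is.null(pixelScale))
    pixelScale <- 2 * rMax(eye) / (0.7 * imageSize[1])
  centre <- c(imageSize[1] / 2, imageSize[2] / 2) * pixelScale
  mk <- function(R, label) {
    t <- c(centre + stats::rnorm(2, 0, jitterPx * pixelScale), 0)
    viewTransform(eulerFromMatrix(R), t, label)
  }
  aTop <- sampleTiltAngles()
  Rtop <- rotationMatrix(aTop)
  aSide <- sampleTiltAngles()
  Rside <- rotationMatrix(aSide) %*% rotationMatrix(c(90, 0, 0)) %*% Rtop
  list(views = list(top = mk(Rtop, "top"), side = mk(Rside, "side")),
       pixelScale = pixelScale)
}

#' Sample an injection with ground truth
#'
#' The injection centre is drawn uniformly by area over the sub-rim portion
#' of the unit sphere (the retina). With `legacyAngles = TRUE` the centre's
#' spherical coordinates are instead drawn uniformly in angle (azimuth in
#' \[0, 360), colatitude in \[0, 180\] from +z), rejecting above-rim centres;
#' angle-uniform sampling concentrates mass at the poles and is kept only
#' for compatibility. The site is represented by `nPoints` (default 100)
#' points scattered around the centre with a 6-degree angular SD (isotropic
#' normal in the tangent plane, mapped by the exponential map); points above
#' the rim are discarded.
#'
#' @param eye an [EyeModel-class].
#' @param views list of two [ViewTransform-class] (stored in the truth).
#' @param nPoints number of scatter points (default 100).
#' @param scatterSdDeg angular scatter SD in degrees (default 6).
#' @param legacyAngles use angle-uniform centre sampling.
#' @return A [GroundTruth-class].
#' @export
sampleInjection <- function(eye, views, nPoints = 100, scatterSdDeg = 6,
                            legacyAngles = FALSE) {
  phi0 <- deg2rad(rimColatitude(eye))
  zrim <- -cos(phi0)
  if (legacyAngles) {
    repeat {
      th <- stats::runif(1, 0, 2 * pi)
      ph <- deg2rad(stats::runif(1, 0, 180))  # colatitude from +z
      centre <- c(sin(ph) * cos(th), sin(ph) * sin(th), cos(ph))
      if (centre[3] <= zrim) break
    }
  } else {
    z <- stats::runif(1, -1, zrim)
    th <- stats::runif(1, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    centre <- c(s * cos(th), s * sin(th), z)
  }
  pts <- scatterOnSphere(centre, nPoints, scatterSdDeg)
  pts <- pts[pts[, 3] <= zrim + 1e-12, , drop = FALSE]
  w <- wedgeBothAxes(centre, rimColatitude(eye), eye@handedness)
  pol <- sphericalPolar(centre)
  new("GroundTruth", centreUnit = centre,
      thetaInjDeg = (pol$azimuthDeg + 360) %% 360,
      phiInjDeg = rad2deg(acos(pmax(-1, pmin(1, centre[3])))),
      points = pts, ntTrue = w$NT@f, dvTrue = w$DV@f,
      eye = eye, views = views)
}

# isotropic normal scatter (sd in degrees) around a unit centre direction,
# via the exponential map in the tangent plane
scatterOnSphere <- function(centre, n, sdDeg) {
  c0 <- unitize(centre)
  a <- if (abs(c0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3(a, c0))
  e2 <- cross3(c0, e1)
  u <- stats::rnorm(n, 0, deg2rad(sdDeg))
  v <- stats::rnorm(n, 0, deg2rad(sdDeg))
  r <- sqrt(u^2 + v^2)
  dir <- outer(u / pmax(r, 1e-15), e1) + outer(v / pmax(r, 1e-15), e2)
  cos(r) %o% c0 + sin(r) * dir
}

#' Which points are visible in a view
#'
#' The eye is opaque: a surface point renders in a view iff its camera-frame
#' depth is at least the front-surface depth of the eye along its own ray
#' (minus a small tolerance).
#'
#' @param unitPts n x 3 unit-sphere points.
#' @param view a [ViewTransform-class].
#' @param eye an [EyeModel-class].
#' @param tol relative depth tolerance.
#' @return logical(n).
#' @export
visibleInView <- function(unitPts, view, eye, tol = 1e-6) {
  pts <- as_points(unitPts)
  pe <- sweep(pts, 2, eye@semiAxes, "*")
  pc <- applyView(pe, view)
  rmax <- rMax(eye)
  n <- nrow(pc)
  q1 <- invertView(cbind(pc[, 1], pc[, 2], rep(+rmax, n)), view)
  d <- invertView(cbind(pc[, 1], pc[, 2], rep(-rmax, n)), view) - q1
  qq <- ellipsoidQuadratic(q1, d, eye)
  disc <- qq$B^2 - 4 * qq$A * qq$C
  tfront <- (-qq$B - sqrt(pmax(0, disc))) / (2 * qq$A)
  zfront <- rmax - tfront * 2 * rmax  # camera z of the front intersection
  disc >= 0 & pc[, 3] >= zfront - tol * rmax
}

#' Generate a complete synthetic scene
#'
#' Samples an eye, two views and an injection, optionally requiring the
#' injection centre to be visible in both views (resampling the centre, as
#' real use requires the injection to appear in both images), and optionally
#' renders the two views.
#'
#' @param seed integer seed; the scene is a deterministic function of it.
#' @param imageSize integer(2) (width, height).
#' @param nPoints,scatterSdDeg,legacyAngles see [sampleInjection()].
#' @param requireVisible resample until the centre and at least 10 scatter
#'   points are visible in both views (default TRUE).
#' @param render render the two RGB views (default FALSE; rendering is only
#'   needed for image-based work).
#' @param handedness eye handedness.
#' @return A [SyntheticScene-class].
#' @export
simulateScene <- function(seed, imageSize = c(400L, 400L), nPoints = 100,
                          scatterSdDeg = 6, legacyAngles = FALSE,
                          requireVisible = TRUE, render = FALSE,
                          handedness = "left") {
  set.seed(as.integer(seed))
  for (attempt in 1:100) {
    eye <- sampleEye(handedness)
    sv <- sampleViews(eye, imageSize)
    ok <- FALSE
    for (try in 1:200) {
      truth <- sampleInjection(eye, sv$views, nPoints, scatterSdDeg,
                               legacyAngles)
      if (!requireVisible) { ok <- TRUE; break }
      visTop <- visibleInView(truth@points, sv$views$top, eye)
      visSide <- visibleInView(truth@points, sv$views$side, eye)
      cvis <- visibleInView(matrix(truth@centreUnit, 1), sv$views$top, eye) &&
        visibleInView(matrix(truth@centreUnit, 1), sv$views$side, eye)
      if (cvis && sum(visTop) >= 10 && sum(visSide) >= 10) { ok <- TRUE; break }
    }
    if (ok) break
  }
  if (!ok) stop("failed to generate a scene with a visible injection")
  scene <- new("SyntheticScene", truth = truth,
               imageTop = array(numeric(0), c(0, 0, 0)),
               imageSide = array(numeric(0), c(0, 0, 0)),
               pixelScale = sv$pixelScale,
               imageSize = as.integer(imageSize), seed = as.integer(seed))
  if (render) scene <- renderViews(scene)
  scene
}

# scene colour palette
.sceneCols <- list(
  background = c(1, 1, 1),
  disc = c(0.93, 0.89, 0.80),
  wire = c(0.62, 0.62, 0.62),
  rim = c(0.88, 0.78, 0.15),
  injection = c(0.55, 0.08, 0.18),
  glyph = c(0.10, 0.10, 0.10)
)

# paint square dots at camera xy positions into img (H x W x 3)
paintDots <- function(img, xy, pixelScale, h, col, radius = 1L) {
  if (!nrow(xy)) return(img)
  cols <- round(xy[, 1] / pixelScale)
  rows <- round(h + 1 - xy[, 2] / pixelScale)
  w <- dim(img)[2]
  for (dr in -radius:radius) for (dc in -radius:radius) {
    r <- rows + dr; c <- cols + dc
    okp <- r >= 1 & r <= h & c >= 1 & c <= w
    if (any(okp)) for (ch in 1:3) img[cbind(r[okp], c[okp], ch)] <- col[ch]
  }
  img
}

# strokes (list of 2x2 matrices, unit square coords) for the letter M
.glyphM <- list(rbind(c(0, 0), c(0, 1)), rbind(c(0, 1), c(0.5, 0.4)),
                rbind(c(0.5, 0.4), c(1, 1)), rbind(c(1, 1), c(1, 0)))

#' Render the two views of a synthetic scene
#'
#' Orthographic rendering: the eye silhouette as a filled disc, wire-frame
#' meridians and the rim circle (hidden parts removed), the injection points
#' as claret dots, and an "M" glyph beside the nasal rim pole where visible.
#' Only geometric fidelity is contractual; styling is fixed by the palette.
#'
#' @param scene a [SyntheticScene-class].
#' @param capHalfAngleDeg if non-NULL, additionally paint the geodesic cap
#'   of this angular radius around the injection centre (used for area
#'   validation against the closed-form cap area).
#' @return The scene with `imageTop` and `imageSide` filled.
#' @export
renderViews <- function(scene, capHalfAngleDeg = NULL) {
  truth <- scene@truth
  eye <- truth@eye
  w <- scene@imageSize[1]; h <- scene@imageSize[2]
  ps <- scene@pixelScale
  rmax <- rMax(eye)
  phi0 <- deg2rad(rimColatitude(eye))
  zrim <- -cos(phi0)

  renderOne <- function(view) {
    img <- array(rep(.sceneCols$background, each = h * w), c(h, w, 3))
    # per-pixel front-surface depth
    cols <- matrix(rep(1:w, each = h), h, w)
    rows <- matrix(rep(1:h, w), h, w)
    x <- as.vector(cols) * ps
    y <- (h + 1 - as.vector(rows)) * ps
    n <- length(x)
    q1 <- invertView(cbind(x, y, rep(+rmax, n)), view)
    d <- invertView(cbind(x, y, rep(-rmax, n)), view) - q1
    qq <- ellipsoidQuadratic(q1, d, eye)
    disc <- qq$B^2 - 4 * qq$A * qq$C
    inside <- disc >= 0
    for (ch in 1:3)
      img[, , ch][matrix(inside, h, w)] <- .sceneCols$disc[ch]
    if (!is.null(capHalfAngleDeg)) {
      tfront <- ifelse(inside, (-qq$B - sqrt(pmax(0, disc))) / (2 * qq$A), NA)
      fp <- q1 + tfront * d
      fu <- sweep(fp, 2, eye@semiAxes, "/")
      fu <- fu / pmax(sqrt(rowSums(fu^2)), 1e-12)
      cosang <- fu %*% truth@centreUnit
      incap <- inside & !is.na(cosang) &
        cosang >= cos(deg2rad(capHalfAngleDeg))
      for (ch in 1:3)
        img[, , ch][matrix(incap, h, w)] <- .sceneCols$injection[ch]
    }
    # wire-frame meridians (8) and the rim circle
    mu <- seq(0, rad2deg(phi0), length.out = 200)
    for (thDeg in seq(0, 315, by = 45)) {
      m <- deg2rad(mu)
      arc <- cbind(sin(m) * cos(deg2rad(thDeg)), sin(m) * sin(deg2rad(thDeg)),
                   -cos(m))
      vis <- visibleInView(arc, view, eye, tol = 1e-3)
      pc <- applyView(sweep(arc, 2, eye@semiAxes, "*"), view)
      img <- paintDots(img, pc[vis, 1:2, drop = FALSE], ps, h,
                       .sceneCols$wire, 0L)
    }
    tt <- seq(0, 2 * pi, length.out = 400)
    rimc <- cbind(sin(phi0) * cos(tt), sin(phi0) * sin(tt),
                  rep(zrim, length(tt)))
    vis <- visibleInView(rimc, view, eye, tol = 1e-3)
    pc <- applyView(sweep(rimc, 2, eye@semiAxes, "*"), view)
    img <- paintDots(img, pc[vis, 1:2, drop = FALSE], ps, h, .sceneCols$rim, 0L)
    # injection points
    vis <- visibleInView(truth@points, view, eye)
    pc <- applyView(sweep(truth@points, 2, eye@semiAxes, "*"), view)
    img <- paintDots(img, pc[vis, 1:2, drop = FALSE], ps, h,
                     .sceneCols$injection, 1L)
    # nasal marker "M" at the nasal rim pole, if visible
    nasal <- c(sin(phi0), 0, zrim)
    if (visibleInView(matrix(nasal, 1), view, eye, tol = 1e-3)) {
      npix <- applyView(nasal * eye@semiAxes, view)[1:2]
      gs <- 14 * ps  # glyph size in eye units
      for (seg in .glyphM) {
        t <- seq(0, 1, length.out = 40)
        pxy <- cbind(npix[1] + gs * (0.6 + seg[1, 1] + t * (seg[2, 1] - seg[1, 1])),
                     npix[2] + gs * (seg[1, 2] + t * (seg[2, 2] - seg[1, 2])))
        img <- paintDots(img, pxy, ps, h, .sceneCols$glyph, 0L)
      }
    }
    img
  }

  scene@imageTop <- renderOne(truth@views$top)
  scene@imageSide <- renderOne(truth@views$side)
  scene
}

#' Automatically mark the injection in both views
#'
#' Places each mark at the projected centroid of the injection points
#' visible in that view (replacing a human observer for automated
#' validation). Errors, naming the view, when the injection is not visible.
#'
#' @param scene a [SyntheticScene-class].
#' @param quantize round marks to whole pixels (default FALSE).
#' @return list of two [ViewMark-class] (`top`, `side`), in pixel
#'   coordinates of the scene's images.
#' @export
autoMark <- function(scene, quantize = FALSE) {
  truth <- scene@truth
  eye <- truth@eye
  h <- scene@imageSize[2]
  mk <- function(view, label) {
    vis <- visibleInView(truth@points, view, eye)
    if (!any(vis))
      stop(sprintf("injection not visible in the %s view", label))
    pc <- applyView(sweep(truth@points[vis, , drop = FALSE], 2,
                          eye@semiAxes, "*"), view)
    xy <- colMeans(pc[, 1:2, drop = FALSE])
    px <- cameraToPixel(xy, scene@pixelScale, h)
    if (quantize) px <- round(px)
    viewMark(px, label)
  }
  list(top = mk(truth@views$top, "top"), side = mk(truth@views$side, "side"))
}

#' Localize a scene's injection from its auto-marks
#'
#' Convenience wrapper: [autoMark()] then [localize()] with the true view
#' transforms (wire-frame alignment from ground truth).
#'
#' @param scene a [SyntheticScene-class].
#' @param quantize round marks to whole pixels.
#' @return A [LocalizationResult-class].
#' @export
localizeScene <- function(scene, quantize = FALSE) {
  marks <- autoMark(scene, quantize)
  truth <- scene@truth
  h <- scene@imageSize[2]
  localize(marks$top, marks$side, truth@views$top, truth@views$side,
           truth@eye, pixelScale = scene@pixelScale,
           imageHeightTop = h, imageHeightSide = h)
}
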