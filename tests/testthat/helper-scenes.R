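# Shared fixture builders. Everything is generated in code at test time.

sphereEye <- function(r = 1400, rim = 53, handedness = "left")
  eyeModel(c(r, r, r), rim, handedness)

# a view looking face-on at the deepest point of the cup (from -z),
# eye centred in a W x W image
bottomView <- function(W = 400L, pixelScale = 10) {
  viewTransform(c(180, 0, 0), c(W / 2 * pixelScale, W / 2 * pixelScale, 0),
                "bottom")
}

# scene with a single known injection point and fixed (non-random) geometry
pointScene <- function(centreUnit, eye = sphereEye(), W = 400L,
                       views = NULL, pixelScale = NULL) {
  if (is.null(pixelScale)) pixelScale <- 2 * rMax(eye) / (0.7 * W)
  if (is.null(views)) {
    centreImg <- c(W / 2 * pixelScale, W / 2 * pixelScale, 0)
    views <- list(top = viewTransform(c(0, 0, 0), centreImg, "top"),
                  side = viewTransform(c(90, 0, 0), centreImg, "side"))
  }
  w <- wedgeBothAxes(centreUnit, rimColatitude(eye), eyeHandedness(eye))
  pol <- sphericalPolar(centreUnit)
  truth <- new("GroundTruth", centreUnit = centreUnit,
               thetaInjDeg = (pol$azimuthDeg + 360) %% 360,
               phiInjDeg = acos(max(-1, min(1, centreUnit[3]))) * 180 / pi,
               points = matrix(centreUnit, 1), ntTrue = w$NT@f,
               dvTrue = w$DV@f, eye = eye, views = views)
  new("SyntheticScene", truth = truth,
      imageTop = array(numeric(0), c(0, 0, 0)),
      imageSide = array(numeric(0), c(0, 0, 0)),
      pixelScale = pixelScale, imageSize = c(W, W), seed = 0L)
}

# random unit vectors strictly below the rim (area-uniform)
randomSubRimPoints <- function(n, phi0Deg = 127) {
  zrim <- -cos(phi0Deg * pi / 180)
  z <- runif(n, -1, zrim)
  th <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  cbind(s * cos(th), s * sin(th), z)
}

# camera-frame projection (x, y) of a unit point under a view
projectPoint <- function(unitPt, view, eye)
  applyView(unitPt * semiAxes(eye), view)[1:2]

scatterOnSphereForTest <- EyeSphere:::scatterOnSphere
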