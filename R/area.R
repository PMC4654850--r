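#' Chroma-distance map of an image relative to a seed pixel
#'
#' Converts the RGB image to CIELAB (sRGB, D65 white point), discards the
#' lightness channel, and computes for every pixel the Euclidean distance in
#' the (a*, b*) chroma plane to the seed pixel:
#' `d = sqrt((a - a_seed)^2 + (b - b_seed)^2)`. Dye injections differ from
#' the surrounding tissue chiefly in hue, so this distance isolates the
#' injection irrespective of shading.
#'
#' @param image H x W x 3 numeric array with values in \[0, 1\] (as returned
#'   by [loadImages()]).
#' @param seed numeric(2) seed pixel (x, y) in image coordinates (origin
#'   top-left, x = column, y = row).
#' @return list of class `"ColorDistanceMap"` with `values` (H x W matrix of
#'   distances, 0 at the seed) and `seed`.
#' @export
colorDistanceMap <- function(image, seed) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3)
    stop("image must be an RGB raster (H x W x 3); grayscale images carry no chroma")
  h <- dim(image)[1]; w <- dim(image)[2]
  col <- round(seed[1]); row <- round(seed[2])
  if (col < 1 || col > w || row < 1 || row > h)
    stop("seed pixel lies outside the image")
  rgb <- cbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3])) * 255
  lab <- farver::convert_colour(rgb, from = "rgb", to = "lab")
  a <- matrix(lab[, 2], h, w)
  b <- matrix(lab[, 3], h, w)
  d <- sqrt((a - a[row, col])^2 + (b - b[row, col])^2)
  structure(list(values = d, seed = c(col, row)), class = "ColorDistanceMap")
}

# connected component of `mask` containing (row, col), 4-connectivity;
# vectorized flood fill by repeated masked dilation
connectedComponent <- function(mask, row, col) {
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[row, col]) {
    comp[row, col] <- TRUE  # the seed itself is always included
    return(comp)
  }
  comp[row, col] <- TRUE
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nrow(comp), ]
    grown[-nrow(comp), ] <- grown[-nrow(comp), ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -ncol(comp)]
    grown[, -ncol(comp)] <- grown[, -ncol(comp)] | comp[, -1]
    grown <- grown & mask
    grown[row, col] <- TRUE
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}

#' Threshold a chroma-distance map
#'
#' Pixels whose chroma distance to the seed is at most `threshold` (default
#' 5) are selected, and the mask is restricted to the connected component
#' containing the seed so that disjoint debris of similar colour elsewhere
#' in the image cannot inflate the injection.
#'
#' @param dmap a `"ColorDistanceMap"` from [colorDistanceMap()].
#' @param threshold non-negative chroma distance threshold (default 5).
#' @param connected restrict to the seed's connected component (default TRUE).
#' @return logical H x W matrix; the seed pixel is always TRUE.
#' @export
thresholdMask <- function(dmap, threshold = 5, connected = TRUE) {
  stopifnot(inherits(dmap, "ColorDistanceMap"), threshold >= 0)
  mask <- dmap$values <= threshold
  col <- dmap$seed[1]; row <- dmap$seed[2]
  mask[row, col] <- TRUE
  if (connected) mask <- connectedComponent(mask, row, col)
  mask
}

#' Project mask pixels onto the eye surface
#'
#' For every selected pixel a line perpendicular to the image plane is
#' back-projected into the eye frame and its nearest point on the ellipsoid
#' found by sampling the residual `v = |x^2/rx^2 + y^2/ry^2 + z^2/rz^2 - 1|`
#' at `nSamples` points (default 2000) and keeping the viewer-side minimum;
#' `mode = "exact"` solves the quadratic instead. Pixels whose best residual
#' exceeds `missTolerance` lie off the eye and are dropped.
#'
#' @param mask logical H x W matrix from [thresholdMask()].
#' @param view the [ViewTransform-class] of the imaged view.
#' @param eye an [EyeModel-class].
#' @param pixelScale eye units per pixel.
#' @param nSamples line samples per pixel in sampled mode.
#' @param mode `"sampled"` (default, as in the original) or `"exact"`.
#' @param missTolerance maximum accepted residual v (default 0.05).
#' @return list: `points` (n x 3 eye-frame surface points), `dropped`
#'   (number of pixels whose ray missed), `v` (residuals of kept points).
#' @export
maskToSphere <- function(mask, view, eye, pixelScale = 1, nSamples = 2000,
                         mode = c("sampled", "exact"), missTolerance = 0.05) {
  mode <- match.arg(mode)
  if (!any(mask)) stop("empty mask")
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  # pixel -> camera coordinates (y up)
  x <- idx[, 2] * pixelScale
  y <- (h + 1 - idx[, 1]) * pixelScale
  rmax <- rMax(eye)
  n <- nrow(idx)
  p1 <- cbind(x, y, rep(+rmax, n))
  p2 <- cbind(x, y, rep(-rmax, n))
  q1 <- invertView(p1, view)
  d <- invertView(p2, view) - q1
  qq <- ellipsoidQuadratic(q1, d, eye)
  if (mode == "exact") {
    s <- solveSegmentQuadratic(qq$A, qq$B, qq$C)
    t <- s$t; v <- s$v
  } else {
    ts <- seq(0, 1, length.out = nSamples)
    t <- v <- numeric(n)
    chunk <- max(1, floor(4e6 / nSamples))
    for (s in seq(1, n, by = chunk)) {
      i <- s:min(n, s + chunk - 1)
      vv <- abs(outer(qq$A[i], ts^2) + outer(qq$B[i], ts) + qq$C[i])
      # first local minimum per row = viewer-side crossing
      m <- ncol(vv)
      lm <- vv[, 2:(m - 1), drop = FALSE] <= vv[, 1:(m - 2), drop = FALSE] &
        vv[, 2:(m - 1), drop = FALSE] <= vv[, 3:m, drop = FALSE]
      has <- rowSums(lm) > 0
      j <- integer(nrow(vv))
      j[has] <- max.col(lm[has, , drop = FALSE], ties.method = "first") + 1
      if (any(!has))
        j[!has] <- max.col(-vv[!has, , drop = FALSE], ties.method = "first")
      t[i] <- ts[j]
      v[i] <- vv[cbind(seq_len(nrow(vv)), j)]
    }
  }
  keep <- v <= missTolerance
  if (!any(keep)) stop("all pixel rays miss the eye ellipsoid")
  pts <- q1[keep, , drop = FALSE] + t[keep] * d[keep, , drop = FALSE]
  list(points = pts, dropped = sum(!keep), v = v[keep])
}

# Gauss-ready surface area of the ellipsoid cap below a given colatitude
# (measured from the deepest point), by 2D quadrature: Simpson in the
# colatitude, trapezoid in the (periodic) azimuth.
#' Retinal surface area of the eye
#'
#' Area of the ellipsoid surface from the deepest point of the cup up to
#' `colatDeg` (default the rim colatitude, i.e. the retina), by numerical
#' quadrature; exact to ~1e-10 relative on spheres.
#'
#' @param eye an [EyeModel-class].
#' @param colatDeg upper colatitude bound in degrees (default the rim).
#' @param nMu,nTheta quadrature resolution.
#' @return area in squared eye units.
#' @export
retinalSurfaceArea <- function(eye, colatDeg = rimColatitude(eye),
                               nMu = 2049, nTheta = 512) {
  r <- eye@semiAxes
  mu <- seq(0, deg2rad(colatDeg), length.out = nMu)
  th <- seq(0, 2 * pi, length.out = nTheta + 1)[-(nTheta + 1)]
  smu <- sin(mu); cmu <- cos(mu)
  c2 <- cos(th)^2; s2 <- sin(th)^2
  # |J| = sin(mu) * sqrt(sin^2(mu) (ry^2 rz^2 cos^2 th + rx^2 rz^2 sin^2 th)
  #                      + rx^2 ry^2 cos^2(mu))
  inner <- outer(smu^2, r[2]^2 * r[3]^2 * c2 + r[1]^2 * r[3]^2 * s2) +
    outer(cmu^2, rep(r[1]^2 * r[2]^2, nTheta))
  g <- smu * rowSums(sqrt(inner)) * (2 * pi / nTheta)  # theta: exact-order trapezoid
  # Simpson in mu (nMu odd)
  hmu <- mu[2] - mu[1]
  wts <- rep(c(2, 4), length.out = nMu); wts[1] <- 1; wts[nMu] <- 1
  sum(wts * g) * hmu / 3
}

# Lambert azimuthal equal-area projection of unit points about a centre
# direction; scaled by `radius` so planar areas match areas on a sphere of
# that radius.
lambertProject <- function(unitPts, centre, radius = 1) {
  cz <- unitize(centre)
  # orthonormal basis with e3 = centre
  a <- if (abs(cz[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- unitize(cross3(a, cz))
  e2 <- cross3(cz, e1)
  x <- unitPts %*% e1
  y <- unitPts %*% e2
  z <- pmin(1, pmax(-1, unitPts %*% cz))
  k <- sqrt(2 / pmax(1e-12, 1 + z))
  cbind(radius * k * x, radius * k * y)
}

# area of the alpha complex of planar points: Delaunay triangles with
# circumradius <= alpha. Falls back to the convex hull when degenerate.
alphaShapeArea <- function(xy, alpha = NULL) {
  xy <- unique(round(xy, 12))
  if (nrow(xy) < 3) return(0)
  tri <- tryCatch({
    dd <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
    deldir::triang.list(dd)
  }, error = function(e) NULL)
  hullArea <- function() {
    h <- grDevices::chull(xy)
    hx <- xy[h, 1]; hy <- xy[h, 2]
    abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  }
  if (is.null(tri) || !length(tri)) return(hullArea())
  if (is.null(alpha)) {
    # 10x the median nearest-neighbour distance; NN graph is a subgraph of
    # the Delaunay triangulation, so per-point minimum incident edge length
    # is the exact NN distance
    dd2 <- deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE)
    sg <- dd2$delsgs
    len <- sqrt((sg$x1 - sg$x2)^2 + (sg$y1 - sg$y2)^2)
    nn <- tapply(c(len, len), c(sg$ind1, sg$ind2), min)
    alpha <- 10 * stats::median(nn)
  }
  areas <- vapply(tri, function(tt) {
    ax <- tt$x; ay <- tt$y
    ab <- c(ax[2] - ax[1], ay[2] - ay[1])
    ac <- c(ax[3] - ax[1], ay[3] - ay[1])
    bc <- c(ax[3] - ax[2], ay[3] - ay[2])
    area <- abs(ab[1] * ac[2] - ab[2] * ac[1]) / 2
    if (area < 1e-14) return(0)
    circ <- vnorm(ab) * vnorm(ac) * vnorm(bc) / (4 * area)
    if (circ <= alpha) area else 0
  }, numeric(1))
  tot <- sum(areas)
  if (tot <= 0) hullArea() else tot
}

#' Injection area as a fraction of the retina
#'
#' The surface points are mapped to the unit sphere, projected by a Lambert
#' azimuthal equal-area projection centred on their spherical centroid and
#' scaled by the geometric-mean radius, and the area of their alpha shape
#' (concave hull) in that plane is divided by the retinal surface area (the
#' ellipsoid below the rim; set `total = "ellipsoid"` to reference the whole
#' ellipsoid instead).
#'
#' @param points n x 3 eye-frame surface points (n >= 3, non-collinear),
#'   e.g. from [maskToSphere()].
#' @param eye an [EyeModel-class].
#' @param alpha alpha-shape scale in eye units; default 10x the median
#'   nearest-neighbour distance of the projected points.
#' @param total reference surface: `"retina"` (default) or `"ellipsoid"`.
#' @param threshold the chroma threshold used upstream (recorded only).
#' @param dropped dropped-ray count from [maskToSphere()] (recorded only).
#' @return An [AreaEstimate-class].
#' @export
injectionAreaFraction <- function(points, eye, alpha = NULL,
                                  total = c("retina", "ellipsoid"),
                                  threshold = NA_real_, dropped = 0L) {
  total <- match.arg(total)
  pts <- as_points(points)
  if (nrow(pts) < 3) stop("need at least 3 surface points")
  unit <- normalizeToSphere(pts, eye)
  centre <- colMeans(unit)
  if (vnorm(centre) < 1e-9)
    stop("surface points have no well-defined centroid direction")
  rgeo <- prod(eye@semiAxes)^(1 / 3)
  xy <- lambertProject(unit, centre, rgeo)
  # exactly collinear projections span no area
  ctr <- sweep(xy, 2, colMeans(xy))
  sv <- svd(ctr)$d
  if (sv[2] <= 1e-12 * max(sv[1], 1e-300))
    stop("points are collinear: no area is defined")
  area <- alphaShapeArea(xy, alpha)
  totalArea <- if (total == "retina") retinalSurfaceArea(eye)
               else retinalSurfaceArea(eye, 180)
  new("AreaEstimate", fraction = min(1, area / totalArea),
      absoluteArea = area, nPixels = as.integer(nrow(pts)),
      droppedRays = as.integer(dropped), thresholdUsed = as.numeric(threshold))
}

#' Full area-estimation pipeline from an image
#'
#' Runs [colorDistanceMap()], [thresholdMask()], [maskToSphere()] and
#' [injectionAreaFraction()] in sequence.
#'
#' @param image RGB raster (H x W x 3 in \[0, 1\]).
#' @param seed numeric(2) seed pixel (x, y).
#' @param view,eye scene geometry for the imaged view.
#' @param pixelScale eye units per pixel.
#' @param threshold chroma threshold (default 5).
#' @param nSamples line samples per pixel.
#' @param total reference surface, see [injectionAreaFraction()].
#' @return An [AreaEstimate-class].
#' @export
estimateInjectionArea <- function(image, seed, view, eye, pixelScale = 1,
                                  threshold = 5, nSamples = 2000,
                                  total = c("retina", "ellipsoid")) {
  dmap <- colorDistanceMap(image, seed)
  mask <- thresholdMask(dmap, threshold)
  proj <- maskToSphere(mask, view, eye, pixelScale, nSamples)
  injectionAreaFraction(proj$points, eye, total = match.arg(total),
                        threshold = threshold, dropped = proj$dropped)
}
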