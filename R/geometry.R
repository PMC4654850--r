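#' Rotation matrix from angles about x, y, z
#'
#' Builds the proper rotation `Rx(thx) %*% Ry(thy) %*% Rz(thz)` used by the
#' view transform, with angles in degrees.
#'
#' @param anglesDeg numeric(3), angles about x, y and z in degrees.
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
rotationMatrix <- function(anglesDeg) {
  stopifnot(length(anglesDeg) == 3, all(is.finite(anglesDeg)))
  a <- deg2rad(anglesDeg)
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# recover (thx, thy, thz) in degrees from M = Rx Ry Rz
eulerFromMatrix <- function(M) {
  sy <- max(-1, min(1, M[1, 3]))
  b <- asin(sy)
  if (abs(cos(b)) > 1e-10) {
    a <- atan2(-M[2, 3], M[3, 3])
    c <- atan2(-M[1, 2], M[1, 1])
  } else {
    # gimbal lock: fold everything into thx
    a <- atan2(M[3, 2], M[2, 2])
    c <- 0
  }
  rad2deg(c(a, b, c))
}

#' Apply / invert a view transform
#'
#' `applyView` maps eye-frame points to the camera frame, `T(a) = R a + t`;
#' `invertView` maps back, `T^{-1}(b) = R^T (b - t)`.
#'
#' @param points a 3-vector or an n x 3 matrix of points.
#' @param view a [ViewTransform-class].
#' @return Points in the other frame, same shape as the input.
#' @export
applyView <- function(points, view) {
  stopifnot(is(view, "ViewTransform"))
  p <- as_points(points)
  R <- rotationMatrix(view@rotationDeg)
  out <- p %*% t(R) + rep(view@translation, each = nrow(p))
  if (is.matrix(points)) out else drop(out)
}

#' @rdname applyView
#' @export
invertView <- function(points, view) {
  stopifnot(is(view, "ViewTransform"))
  p <- as_points(points)
  R <- rotationMatrix(view@rotationDeg)
  out <- (p - rep(view@translation, each = nrow(p))) %*% R
  if (is.matrix(points)) out else drop(out)
}

#' Wedge coordinates to unit-sphere Cartesian coordinates
#'
#' The wedge system for one retinal axis places the two poles on the rim at
#' `(+-sin(phi0), 0, -cos(phi0))` (phi0 = rim colatitude from the deepest
#' point). A plane through both poles, tilted `psi` from the vertical, cuts
#' the unit sphere in a circle of radius `rho` centred at `(0, y0, z0)`; the
#' retinal position is the point a fraction `f` of the way along the sub-rim
#' arc from the first pole, through the depths of the cup, to the second.
#'
#' @param psiDeg plane tilt(s) in degrees, in \[-90, 90\].
#' @param f fractional arc distance(s) in \[0, 1\].
#' @param phi0Deg rim colatitude in degrees, in (90, 180).
#' @return An n x 3 matrix of unit vectors (a plain 3-vector when both
#'   `psiDeg` and `f` have length 1).
#' @examples
#' wedgeForward(0, 0.5, 127)   # deepest point (0, 0, -1)
#' wedgeForward(30, 0.25, 127) # (0.8386, 0.4876, -0.2428)
#' @export
wedgeForward <- function(psiDeg, f, phi0Deg) {
  if (any(phi0Deg <= 90) || any(phi0Deg >= 180))
    stop("phi0Deg must lie strictly between 90 and 180 degrees")
  n <- max(length(psiDeg), length(f))
  psi <- deg2rad(rep_len(psiDeg, n))
  f <- rep_len(f, n)
  phi0 <- deg2rad(rep_len(phi0Deg, n))
  rho <- sqrt(sin(phi0)^2 + cos(phi0)^2 * cos(psi)^2)
  y0 <- -sin(psi) * cos(psi) * cos(phi0)
  z0 <- -sin(psi)^2 * cos(phi0)
  a0 <- asin(pmin(1, sin(phi0) / rho))
  a <- a0 + f * (2 * pi - 2 * a0)
  out <- cbind(x = rho * sin(a),
               y = y0 - rho * sin(psi) * cos(a),
               z = z0 + rho * cos(psi) * cos(a))
  if (n == 1) drop(out) else out
}

#' Unit-sphere point to wedge coordinates
#'
#' Inverse of [wedgeForward()]. The plane tilt is recovered as
#' `psi = atan2(y, -cos(phi0) - z)`, the angular parameter along the arc as
#' `alpha = atan2(x, v)` (wrapped by +2*pi when below the rim start), and
#' `f = (alpha - alpha0) / (2*pi - 2*alpha0)`. On the pole axis (both poles
#' and any point with y = 0, z = -cos(phi0)) the tilt is undefined: psi is
#' reported as 0 with `degenerate = TRUE`, and f is 0 or 1 by the sign of x.
#'
#' @param points unit 3-vector or n x 3 matrix, at or below the rim
#'   (`z <= -cos(phi0) + 1e-9`).
#' @param phi0Deg rim colatitude in degrees, in (90, 180).
#' @return A data.frame with columns `psiDeg`, `f`, `degenerate`.
#' @export
wedgeInverse <- function(points, phi0Deg) {
  if (phi0Deg <= 90 || phi0Deg >= 180)
    stop("phi0Deg must lie strictly between 90 and 180 degrees")
  p <- as_points(points)
  phi0 <- deg2rad(phi0Deg)
  zrim <- -cos(phi0)
  if (any(p[, 3] > zrim + 1e-9))
    stop("point(s) above the rim are outside the wedge coordinate domain")
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  degtol <- 1e-9
  deg <- sqrt(y^2 + (zrim - z)^2) < degtol  # on the pole axis
  bottom <- sqrt(x^2 + y^2) < degtol & z < 0 # at the deepest point
  psi <- ifelse(deg | bottom, 0, atan2(y, zrim - z))
  # fold psi into [-pi/2, pi/2]: psi and psi +- pi describe the same plane
  flip <- !deg & abs(psi) > pi / 2
  psi[flip] <- psi[flip] - sign(psi[flip]) * pi
  rho <- sqrt(sin(phi0)^2 + cos(phi0)^2 * cos(psi)^2)
  y0 <- -sin(psi) * cos(psi) * cos(phi0)
  z0 <- -sin(psi)^2 * cos(phi0)
  a0 <- asin(pmin(1, sin(phi0) / rho))
  v <- -(y - y0) * sin(psi) + (z - z0) * cos(psi)
  a <- atan2(x, v)
  a <- ifelse(a < a0 - 1e-12, a + 2 * pi, a)
  f <- (a - a0) / (2 * pi - 2 * a0)
  f[deg] <- ifelse(x[deg] > 0, 0, 1)
  f[bottom] <- 0.5
  f <- pmin(1, pmax(0, f))
  data.frame(psiDeg = rad2deg(psi), f = f, degenerate = deg | bottom)
}

#' Wedge fractions on both retinal axes
#'
#' The nasotemporal fraction comes from [wedgeInverse()] directly (nasal pole
#' at +x). The dorsoventral axis is the same construction rotated a quarter
#' turn about the optical axis: the point is rotated by -90 degrees about z
#' and inverted on the same wedge grid. For a right eye the DV fraction is
#' mirrored (`f -> 1 - f`), switching the dorsoventral axis between left and
#' right eyes.
#'
#' @param point unit 3-vector at or below the rim.
#' @param phi0Deg rim colatitude in degrees.
#' @param handedness `"left"` or `"right"`.
#' @return list with [WedgeCoordinate-class] elements `NT` and `DV`.
#' @export
wedgeBothAxes <- function(point, phi0Deg, handedness = c("left", "right")) {
  handedness <- match.arg(handedness)
  nt <- wedgeInverse(point, phi0Deg)
  # rotate -90 deg about z: (x, y, z) -> (y, -x, z)
  pd <- c(point[2], -point[1], point[3])
  dv <- wedgeInverse(pd, phi0Deg)
  fdv <- if (handedness == "right") 1 - dv$f else dv$f
  list(NT = wedgeCoordinate(nt$psiDeg, nt$f, "NT", nt$degenerate),
       DV = wedgeCoordinate(dv$psiDeg, fdv, "DV", dv$degenerate))
}

#' Map an eye-frame point onto the unit sphere
#'
#' Divides componentwise by the semi-axes and renormalizes, so ellipsoid
#' surface points land exactly on the unit sphere. All wedge and polar
#' coordinates are computed in this normalized frame.
#'
#' @param points 3-vector or n x 3 matrix in eye-frame coordinates.
#' @param eye an [EyeModel-class].
#' @return Unit vector(s), same shape as input.
#' @export
normalizeToSphere <- function(points, eye) {
  p <- as_points(points)
  s <- sweep(p, 2, eye@semiAxes, "/")
  n <- sqrt(rowSums(s^2))
  if (any(n < 1e-12)) stop("cannot normalize the origin onto the sphere")
  out <- s / n
  if (is.matrix(points)) out else drop(out)
}

#' Spherical polar coordinates for the flat export
#'
#' Colatitude is measured from the deepest point of the cup (0, 0, -1), so
#' the centre of the polar plot is the deepest point and the rim sits at the
#' rim colatitude (127 degrees for a 53-degree rim opening). Azimuth is
#' `atan2(y, x)` in (-180, 180\].
#'
#' @param points unit 3-vector or n x 3 matrix.
#' @return data.frame with `colatitudeDeg` and `azimuthDeg`.
#' @export
sphericalPolar <- function(points) {
  p <- as_points(points)
  data.frame(colatitudeDeg = rad2deg(acos(pmax(-1, pmin(1, -p[, 3])))),
             azimuthDeg = rad2deg(atan2(p[, 2], p[, 1])))
}

# index of the first local minimum of a sampled residual curve; for the
# |quadratic| residual along a ray this is the viewer-side surface crossing
# (the global sampled minimum can land on either root by rounding luck)
firstLocalMin <- function(v) {
  n <- length(v)
  if (n < 3) return(which.min(v))
  i <- which(v[2:(n - 1)] <= v[1:(n - 2)] & v[2:(n - 1)] <= v[3:n])
  if (length(i)) i[1] + 1 else which.min(v)
}

# quadratic coefficients for the ellipsoid value of q1 + t*(q2-q1):
# value(t) = x^2/rx^2 + y^2/ry^2 + z^2/rz^2 - 1 = A t^2 + B t + C
ellipsoidQuadratic <- function(q1, d, eye) {
  r2 <- eye@semiAxes^2
  A <- rowSums(sweep(d^2, 2, r2, "/"))
  B <- 2 * rowSums(sweep(q1 * d, 2, r2, "/"))
  C <- rowSums(sweep(q1^2, 2, r2, "/")) - 1
  list(A = A, B = B, C = C)
}

# closed-form minimizer of |A t^2 + B t + C| over the segment t in [0, 1],
# preferring the viewer-side (smaller-t) surface crossing. Vectorized.
solveSegmentQuadratic <- function(A, B, C, tol = 1e-9) {
  disc <- B^2 - 4 * A * C
  sq <- sqrt(pmax(0, disc))
  t1 <- (-B - sq) / (2 * A)
  t2 <- (-B + sq) / (2 * A)
  hit <- disc >= 0 & ((t1 >= -tol & t1 <= 1 + tol) |
                      (t2 >= -tol & t2 <= 1 + tol))
  t <- pmin(1, pmax(0, -B / (2 * A)))  # no crossing inside: clamped vertex
  useT1 <- disc >= 0 & t1 >= -tol & t1 <= 1 + tol
  useT2 <- disc >= 0 & !useT1 & t2 >= -tol & t2 <= 1 + tol
  t[useT2] <- pmin(1, pmax(0, t2[useT2]))
  t[useT1] <- pmin(1, pmax(0, t1[useT1]))
  # segment fully inside (t1 < 0 < 1 < t2): best endpoint, not the vertex
  insides <- disc >= 0 & t1 < -tol & t2 > 1 + tol
  if (any(insides)) t[insides] <- ifelse(abs(C[insides]) <=
                                           abs(A + B + C)[insides], 0, 1)
  v <- abs(A * t^2 + B * t + C)
  list(t = t, v = v, hit = hit)
}

#' Nearest point of a line on the eye ellipsoid
#'
#' Finds where the back-projection segment meets the eye surface. In
#' `"sampled"` mode the ellipsoid residual
#' `v = |x^2/rx^2 + y^2/ry^2 + z^2/rz^2 - 1|` is evaluated at `nSamples`
#' equally spaced points on the segment and the first minimizer is returned
#' (matching the original sampling scheme with its default of 2000 points).
#' In `"exact"` mode the quadratic is solved in closed form and the root
#' nearest the viewer (nearest `q1`) is returned, falling back to the
#' minimum-residual point of the continuous line when the ray misses.
#'
#' @param q1,q2 segment endpoints in eye-frame coordinates; `q1` is the
#'   viewer side.
#' @param eye an [EyeModel-class].
#' @param nSamples number of samples in sampled mode (default 2000).
#' @param mode `"sampled"` or `"exact"`.
#' @return list with `point` (3-vector), `v` (residual at the point), `t`
#'   (line parameter in \[0,1\] from q1), and `hit` (TRUE when the line truly
#'   intersects the ellipsoid).
#' @export
lineEllipsoidNearest <- function(q1, q2, eye, nSamples = 2000,
                                 mode = c("sampled", "exact")) {
  mode <- match.arg(mode)
  q1 <- as.numeric(q1); q2 <- as.numeric(q2)
  d <- q2 - q1
  if (vnorm(d) < 1e-12) stop("degenerate line: endpoints coincide")
  qq <- ellipsoidQuadratic(matrix(q1, 1), matrix(d, 1), eye)
  A <- qq$A; B <- qq$B; C <- qq$C
  if (mode == "sampled") {
    t <- seq(0, 1, length.out = nSamples)
    v <- abs(A * t^2 + B * t + C)
    i <- firstLocalMin(v)  # viewer-side crossing; ties -> smaller parameter
    list(point = q1 + t[i] * d, v = v[i], t = t[i], hit = any(v < 1e-6))
  } else {
    s <- solveSegmentQuadratic(A, B, C)
    list(point = q1 + s$t * d, v = s$v, t = s$t, hit = s$hit)
  }
}
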