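test_that("rotation matrices match the explicit factor product and are proper", {
  expect_equal(rotationMatrix(c(0, 0, 0)), diag(3))
  expect_equal(rotationMatrix(c(0, 0, 90)) %*% c(1, 0, 0), cbind(c(0, 1, 0)),
               tolerance = 1e-12)
  # independent oracle: explicit multiplication of the three factor matrices
  a <- c(30, 40, 50) * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])), c(0, sin(a[1]), cos(a[1])))
  Ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0), c(-sin(a[2]), 0, cos(a[2])))
  Rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0), c(0, 0, 1))
  expect_equal(rotationMatrix(c(30, 40, 50)), Rx %*% Ry %*% Rz,
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:1000) {
    R <- rotationMatrix(runif(3, -360, 360))
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-9)
    expect_lt(abs(det(R) - 1), 1e-9)
  }
})

test_that("view transforms apply and invert consistently", {
  v <- viewTransform(c(0, 0, 0), c(5, 0, 0))
  expect_equal(applyView(c(1, 2, 3), v), c(6, 2, 3))
  set.seed(12)
  for (i in 1:100) {
    v <- viewTransform(runif(3, -180, 180), rnorm(3, 0, 100))
    p <- rnorm(3, 0, 10)
    expect_equal(invertView(applyView(p, v), v), p, tolerance = 1e-9)
  }
  # matrix input round-trips too
  v <- viewTransform(c(10, -20, 30), c(1, 2, 3))
  P <- matrix(rnorm(30), ncol = 3)
  expect_equal(invertView(applyView(P, v), v), P, tolerance = 1e-9)
})

test_that("wedge forward maps poles, deepest point, and the worked example", {
  phi0 <- 127
  pole0 <- c(sin(phi0 * pi / 180), 0, -cos(phi0 * pi / 180))
  for (psi in c(-80, -30, 0, 45, 88)) {
    expect_equal(unname(wedgeForward(psi, 0, phi0)), pole0, tolerance = 1e-9)
    expect_equal(unname(wedgeForward(psi, 1, phi0)), pole0 * c(-1, 1, 1),
                 tolerance = 1e-9)
  }
  expect_equal(unname(wedgeForward(0, 0.5, phi0)), c(0, 0, -1),
               tolerance = 1e-12)
  # frozen from the independent circle-through-poles oracle (plane through
  # both rim poles tilted 30 deg, intersected with the unit sphere, walked
  # 25% of the arc from the nasal pole through the deepest point)
  expect_equal(unname(wedgeForward(30, 0.25, phi0)),
               c(0.838596, 0.487646, -0.242813), tolerance = 1e-6)
  expect_error(wedgeForward(0, 0.5, 80), "phi0")
})

test_that("wedge forward results always lie on the unit sphere", {
  set.seed(13)
  psi <- runif(500, -90, 90)
  f <- runif(500)
  for (phi0 in c(95, 110, 127, 150, 175)) {
    p <- wedgeForward(psi, f, phi0)
    expect_lt(max(abs(sqrt(rowSums(p^2)) - 1)), 1e-12)
  }
})

test_that("wedge inverse recovers coordinates and flags degeneracies", {
  phi0 <- 127
  w <- wedgeInverse(c(0.838596, 0.487646, -0.242813), phi0)
  expect_equal(w$psiDeg, 30, tolerance = 1e-3)
  expect_equal(w$f, 0.25, tolerance = 1e-4)
  expect_false(w$degenerate)
  # deepest point: f = 1/2, tilt degenerate
  w <- wedgeInverse(c(0, 0, -1), phi0)
  expect_equal(w$f, 0.5)
  expect_equal(w$psiDeg, 0)
  expect_true(w$degenerate)
  # poles: f = 0 / 1
  s <- sin(phi0 * pi / 180); cz <- -cos(phi0 * pi / 180)
  expect_equal(wedgeInverse(c(s, 0, cz), phi0)$f, 0)
  expect_equal(wedgeInverse(c(-s, 0, cz), phi0)$f, 1)
  expect_true(wedgeInverse(c(s, 0, cz), phi0)$degenerate)
  expect_error(wedgeInverse(c(0, 0, 1), phi0), "above the rim")
})

test_that("wedge transforms round-trip in both directions", {
  set.seed(14)
  n <- 2000
  psi <- runif(n, -89.9, 89.9)
  f <- runif(n, 1e-4, 1 - 1e-4)
  for (phi0 in c(110, 127, 160)) {
    w <- wedgeInverse(wedgeForward(psi, f, phi0), phi0)
    expect_lt(max(abs(w$f - f)), 1e-10)
    expect_lt(max(abs(w$psiDeg - psi)), 1e-8)
    p <- randomSubRimPoints(n, phi0)
    w <- wedgeInverse(p, phi0)
    p2 <- wedgeForward(w$psiDeg, w$f, phi0)
    expect_lt(max(abs(p2 - p)), 1e-8)
  }
})

test_that("the f = 0 pole is independent of the plane tilt", {
  psi <- seq(-90, 90, by = 5)
  p <- wedgeForward(psi, 0, 127)
  d <- as.matrix(dist(p))
  expect_lt(max(d), 1e-9)
})

test_that("the wedge arc never wraps a full circle", {
  for (phi0 in seq(90.5, 179.5, by = 1)) for (psi in c(0, 30, 60, 89)) {
    rho <- sqrt(sin(phi0 * pi / 180)^2 +
                cos(phi0 * pi / 180)^2 * cos(psi * pi / 180)^2)
    a0 <- asin(min(1, sin(phi0 * pi / 180) / rho))
    expect_gt(a0, 0)
    expect_lt(2 * pi - 2 * a0, 2 * pi)
  }
})

test_that("both-axes fractions obey the symmetry and handedness laws", {
  # deepest point: centre of both axes, either handedness
  for (h in c("left", "right")) {
    w <- wedgeBothAxes(c(0, 0, -1), 127, h)
    expect_equal(w$NT@f, 0.5)
    expect_equal(w$DV@f, 0.5)
  }
  # the NT pole lies on the DV mid-arc
  s <- sin(127 * pi / 180); cz <- -cos(127 * pi / 180)
  w <- wedgeBothAxes(c(s, 0, cz), 127, "left")
  expect_equal(w$NT@f, 0)
  expect_equal(w$DV@f, 0.5, tolerance = 1e-9)
  # left/right flip: f_DV mirrors, f_NT unchanged
  set.seed(15)
  for (i in 1:50) {
    p <- drop(randomSubRimPoints(1))
    wl <- wedgeBothAxes(p, 127, "left")
    wr <- wedgeBothAxes(p, 127, "right")
    expect_equal(wl$NT@f, wr$NT@f)
    expect_equal(wl$DV@f + wr$DV@f, 1, tolerance = 1e-12)
  }
})

test_that("normalizeToSphere divides by the semi-axes and renormalizes", {
  eye <- eyeModel(c(1000, 1500, 2000))
  expect_equal(normalizeToSphere(c(1000, 0, 0), eye), c(1, 0, 0))
  expect_equal(normalizeToSphere(c(1000 / sqrt(2), 1500 / sqrt(2), 0), eye),
               c(1 / sqrt(2), 1 / sqrt(2), 0), tolerance = 1e-12)
  # isotropic eye preserves direction
  s <- sphereEye(1200)
  v <- c(3, -4, 12)
  expect_equal(normalizeToSphere(v, s), v / sqrt(sum(v^2)), tolerance = 1e-12)
  expect_error(normalizeToSphere(c(0, 0, 0), eye), "origin|normalize")
})

test_that("spherical polar export measures colatitude from the deepest point", {
  expect_equal(sphericalPolar(c(0, 0, -1))$colatitudeDeg, 0)
  p <- sphericalPolar(c(1, 0, 0))
  expect_equal(p$colatitudeDeg, 90)
  expect_equal(p$azimuthDeg, 0)
  # every rim point of a 53-degree opening sits at exactly 127 degrees
  th <- seq(0, 2 * pi, length.out = 73)
  phi0 <- 127 * pi / 180
  rim <- cbind(sin(phi0) * cos(th), sin(phi0) * sin(th), -cos(phi0))
  expect_equal(sphericalPolar(rim)$colatitudeDeg, rep(127, 73),
               tolerance = 1e-9)
})

test_that("line/ellipsoid search picks the viewer-side surface point", {
  eye <- sphereEye(1)
  # axis line: viewer-side root is the one nearest q1
  hit <- lineEllipsoidNearest(c(2, 0, 0), c(-2, 0, 0), eye, mode = "exact")
  expect_equal(hit$point, c(1, 0, 0), tolerance = 1e-12)
  expect_true(hit$hit)
  hit <- lineEllipsoidNearest(c(2, 0, 0), c(-2, 0, 0), eye, mode = "sampled")
  expect_equal(hit$point, c(1, 0, 0), tolerance = 2 * 4 / 2000)
  # tangent line at (0, 1, 0)
  hit <- lineEllipsoidNearest(c(-1, 1, 0), c(1, 1, 0), eye, mode = "exact")
  expect_equal(hit$point, c(0, 1, 0), tolerance = 1e-6)
  expect_error(lineEllipsoidNearest(c(1, 1, 1), c(1, 1, 1), eye), "degenerate")
})

test_that("sampled line search converges to the closed form", {
  eye <- eyeModel(c(1.2, 1.0, 0.8))
  errAt <- function(n) {
    set.seed(16)  # same rays for every sampling density
    errs <- numeric(200)
    for (i in 1:200) {
      # random ray guaranteed to pass near the ellipsoid
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      off <- rnorm(3, 0, 0.3)
      q1 <- off + 2 * dir; q2 <- off - 2 * dir
      ex <- lineEllipsoidNearest(q1, q2, eye, mode = "exact")
      sa <- lineEllipsoidNearest(q1, q2, eye, nSamples = n, mode = "sampled")
      errs[i] <- sqrt(sum((ex$point - sa$point)^2))
    }
    errs
  }
  e500 <- errAt(500); e1000 <- errAt(1000); e2000 <- errAt(2000)
  len <- 4
  expect_lt(max(e2000), 2 * len / 2000)
  # error halves as the sampling doubles
  expect_lt(mean(e1000), 0.75 * mean(e500))
  expect_lt(mean(e2000), 0.75 * mean(e1000))
})
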