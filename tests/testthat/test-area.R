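solidImage <- function(h, w, col) {
  array(rep(col, each = h * w), c(h, w, 3))
}

test_that("chroma distances match an independent Lab conversion", {
  # uniform image: all distances zero
  img <- solidImage(8, 8, c(0.8, 0.5, 0.3))
  dm <- colorDistanceMap(img, c(4, 4))
  expect_true(all(dm$values == 0))
  # 2x2 card with two colours: hand computation through grDevices::convertColor
  c1 <- c(0.9, 0.85, 0.7); c2 <- c(0.55, 0.08, 0.18)
  img <- solidImage(2, 2, c1)
  img[1, 2, ] <- c2; img[2, 2, ] <- c2
  dm <- colorDistanceMap(img, c(1, 1))
  lab <- grDevices::convertColor(rbind(c1, c2), from = "sRGB", to = "Lab")
  dref <- sqrt(sum((lab[1, 2:3] - lab[2, 2:3])^2))
  expect_equal(dm$values[1, 1], 0)
  expect_equal(dm$values[1, 2], dref, tolerance = 0.02)
  expect_equal(dm$values[2, 2], dref, tolerance = 0.02)
  expect_error(colorDistanceMap(matrix(0.5, 8, 8), c(2, 2)), "chroma|RGB")
  expect_error(colorDistanceMap(img, c(50, 1)), "outside")
})

test_that("thresholding keeps the seed's connected component only", {
  bg <- c(0.93, 0.89, 0.80); spot <- c(0.55, 0.08, 0.18)
  img <- solidImage(30, 30, bg)
  spotPix <- as.matrix(expand.grid(r = 10:14, c = 8:12))
  for (k in seq_len(nrow(spotPix))) img[spotPix[k, 1], spotPix[k, 2], ] <- spot
  # disjoint debris of identical colour
  img[25, 25, ] <- spot
  dm <- colorDistanceMap(img, c(10, 12))  # seed (x=col, y=row) inside spot
  mask <- thresholdMask(dm, 5)
  expect_equal(sum(mask), nrow(spotPix))
  expect_true(all(mask[spotPix]))
  expect_false(mask[25, 25])
  # without the component restriction the debris is included
  expect_equal(sum(thresholdMask(dm, 5, connected = FALSE)),
               nrow(spotPix) + 1)
  # threshold 0 on a noisy image keeps only exact-chroma pixels
  set.seed(31)
  noisy <- img + array(runif(30 * 30 * 3, 0, 0.02), c(30, 30, 3))
  noisy[10:14, 8:12, ] <- rep(spot, each = 25)
  dmn <- colorDistanceMap(noisy, c(10, 12))
  m0 <- thresholdMask(dmn, 0)
  expect_equal(sum(m0), 25)
  # saturating threshold floods the seed's whole component
  mAll <- thresholdMask(dm, max(dm$values) + 1)
  expect_equal(sum(mAll), 900)
})

test_that("mask pixels project to the viewer-side surface", {
  eye <- sphereEye(1)
  v <- viewTransform(c(0, 0, 0), c(0, 0, 0))
  # single pixel at the eye's image centre: H=21, pixel (11,11) -> camera (11, 11)
  # use a view translating the centre there
  v <- viewTransform(c(0, 0, 0), c(11, 11, 0))
  mask <- matrix(FALSE, 21, 21); mask[11, 11] <- TRUE
  pr <- maskToSphere(mask, v, eye, pixelScale = 1)
  expect_equal(drop(pr$points), c(0, 0, 1), tolerance = 2 * 2 / 2000)
  expect_equal(pr$dropped, 0)
  # a far-corner pixel misses the unit sphere and is dropped
  mask[1, 1] <- TRUE
  expect_warning(pr <- maskToSphere(mask, v, eye, pixelScale = 1), NA)
  expect_equal(pr$dropped, 1)
  expect_equal(nrow(pr$points), 1)
  # all rays miss
  mask <- matrix(FALSE, 21, 21); mask[1, 1] <- TRUE
  expect_error(maskToSphere(mask, v, eye, pixelScale = 1), "miss")
})

test_that("a disc mask maps onto the matching spherical cap", {
  r <- 100
  eye <- sphereEye(r)
  H <- 121L
  v <- viewTransform(c(0, 0, 0), c(61, 61, 0))
  mask <- matrix(FALSE, H, H)
  discR <- 30
  for (i in 1:H) for (j in 1:H)
    if ((i - 61)^2 + (j - 61)^2 <= discR^2) mask[i, j] <- TRUE
  pr <- maskToSphere(mask, v, eye, pixelScale = 1)
  colat <- acos(pmin(1, pr$points[, 3] / r)) * 180 / pi  # from the +z apex
  capMax <- asin(discR / r) * 180 / pi
  expect_lt(max(colat), capMax + 1.5)  # pixel quantization slack
  expect_gt(max(colat), capMax - 1.5)
})

test_that("sampled projection agrees with the exact quadratic per pixel", {
  eye <- eyeModel(c(110, 95, 100))
  v <- viewTransform(c(20, -10, 35), c(61, 61, 0))
  mask <- matrix(FALSE, 121, 121)
  set.seed(32)
  mask[sample(121 * 121, 400)] <- TRUE
  ps <- maskToSphere(mask, v, eye, pixelScale = 1, mode = "sampled")
  pe <- maskToSphere(mask, v, eye, pixelScale = 1, mode = "exact")
  expect_equal(ps$dropped, pe$dropped)
  err <- sqrt(rowSums((ps$points - pe$points)^2))
  expect_lt(max(err), 2 * (2 * rMax(eye) / 2000))
})

test_that("retinal surface area matches the sphere closed form", {
  r <- 1400
  eye <- sphereEye(r, 53)
  phi0 <- 127 * pi / 180
  expect_equal(retinalSurfaceArea(eye), 2 * pi * r^2 * (1 - cos(phi0)),
               tolerance = 1e-6)
  expect_equal(retinalSurfaceArea(eye, 180), 4 * pi * r^2, tolerance = 1e-6)
  # ellipsoid area is bounded by the spheres of the extreme semi-axes
  e <- eyeModel(c(1300, 1400, 1500), 53)
  a <- retinalSurfaceArea(e, 180)
  expect_gt(a, 4 * pi * 1300^2)
  expect_lt(a, 4 * pi * 1500^2)
})

test_that("cap area fractions match the closed form", {
  r <- 1400
  eye <- sphereEye(r, 53)
  # dense samples of a polar cap of half-angle 10 degrees at the deepest point
  set.seed(33)
  n <- 3000
  z <- runif(n, cos(10 * pi / 180), 1)
  th <- runif(n, 0, 2 * pi)
  pts <- cbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), -z) * r
  est <- injectionAreaFraction(pts, eye)
  analytic <- (1 - cos(10 * pi / 180)) / (1 - cos(127 * pi / 180))
  expect_lt(abs(est@fraction / analytic - 1), 0.05)
  # a cap covering the whole retina saturates near 1
  zrim <- -cos(127 * pi / 180)
  full <- randomSubRimPoints(6000) * r
  estF <- injectionAreaFraction(full, eye)
  expect_gt(estF@fraction, 0.93)
  expect_lte(estF@fraction, 1)
  # degenerate patch
  tiny <- matrix(rep(c(0, 0, -r), 3), ncol = 3, byrow = TRUE) +
    matrix(rnorm(9, 0, 1e-4), 3)
  estT <- injectionAreaFraction(tiny, eye)
  expect_lt(estT@fraction, 1e-4)
  expect_error(injectionAreaFraction(pts[1:2, ], eye), "3")
})

test_that("equal-area projection preserves geodesic patch areas", {
  # geodesic polygon: densely sampled cap boundary plus an interior grid.
  # Planar alpha-shape area must match the spherical area within 1% for
  # patches of angular radius up to 30 degrees
  eye <- sphereEye(1, 53)
  for (ang in c(10, 30)) {
    a <- ang * pi / 180
    th <- seq(0, 2 * pi, length.out = 721)[-721]
    boundary <- cbind(sin(a) * cos(th), sin(a) * sin(th), rep(-cos(a), 720))
    rr <- seq(0.15, 0.95, by = 0.1) * a
    interior <- do.call(rbind, lapply(rr, function(ri)
      cbind(sin(ri) * cos(th[seq(1, 720, by = 12)]),
            sin(ri) * sin(th[seq(1, 720, by = 12)]),
            rep(-cos(ri), 60))))
    pts <- rbind(boundary, interior, c(0, 0, -1))
    est <- injectionAreaFraction(pts, eye)
    sph <- 2 * pi * (1 - cos(a)) / (2 * pi * (1 - cos(127 * pi / 180)))
    expect_lt(abs(est@fraction / sph - 1), 0.01)
  }
})

test_that("area fraction is stable under camera rotation", {
  # the same cap, viewed from rotated cameras, yields the same fraction
  eye <- sphereEye(100, 53)
  centre <- c(0, 0, -1)
  fr <- sapply(c(170, 180, 190), function(rx) {
    W <- 241L
    v <- viewTransform(c(rx, 5, 0), c(121, 121, 0), "v")
    sc <- pointScene(centre, eye, W = W,
                     views = list(top = v, side = v), pixelScale = 1)
    sc <- renderViews(sc, capHalfAngleDeg = 12)
    pc <- projectPoint(centre, v, eye)
    px <- c(pc[1], W + 1 - pc[2])
    est <- estimateInjectionArea(sc@imageTop, round(px), v, eye, pixelScale = 1)
    est@fraction
  })
  expect_lt(max(abs(fr / mean(fr) - 1)), 0.05)
})

test_that("fraction is monotone in the threshold for nested masks", {
  # radial colour gradient from claret to beige: thresholds yield nested
  # discs of pixels, so the area fraction must be non-decreasing
  H <- 41L
  claret <- c(0.55, 0.08, 0.18); beige <- c(0.93, 0.89, 0.80)
  img <- array(0, c(H, H, 3))
  for (i in 1:H) for (j in 1:H) {
    w <- min(1, sqrt((i - 21)^2 + (j - 21)^2) / 20)
    img[i, j, ] <- (1 - w) * claret + w * beige
  }
  eye <- sphereEye(100, 53)
  v <- viewTransform(c(180, 0, 0), c(21, 21, 0), "v")  # whole image on-eye
  dm <- colorDistanceMap(img, c(21, 21))
  fr <- sapply(c(3, 10, 25, 50), function(th) {
    mask <- thresholdMask(dm, th)
    pr <- maskToSphere(mask, v, eye, pixelScale = 1, mode = "exact")
    injectionAreaFraction(pr$points, eye)@fraction
  })
  expect_true(all(diff(fr) >= -1e-12))
  expect_gt(fr[4], fr[1])
})
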