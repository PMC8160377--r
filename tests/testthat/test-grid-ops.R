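test_that("resampling onto the identity geometry is exact", {
  set.seed(11)
  dg <- doseGrid(array(runif(4 * 5 * 6, 0, 70), c(4, 5, 6)),
                 spacing = c(1.5, 1.5, 3), origin = c(-2, 0, 1))
  out <- resampleTo(dg, gridOrigin(dg), gridSpacing(dg), gridDims(dg))
  expect_identical(out@values, dg@values)
})

test_that("resampling a constant field inside support stays constant", {
  dg <- doseGrid(array(60, c(6, 6, 6)), spacing = 3, origin = c(0, 0, 0))
  out <- resampleTo(dg, origin = c(1, 1, 1), spacing = 1, dims = c(10, 10, 10))
  expect_true(all(abs(out@values - 60) < 1e-12))
})

test_that("trilinear resampling reproduces an affine dose field exactly", {
  dims <- c(8, 6, 5)
  g <- expand.grid(x = 0:(dims[1] - 1) * 2, y = 0:(dims[2] - 1) * 2,
                   z = 0:(dims[3] - 1) * 2)
  vals <- array(10 + 0.5 * g$x + 0.25 * g$y + 1.5 * g$z, dims)
  dg <- doseGrid(vals, spacing = 2, origin = c(0, 0, 0))
  out <- resampleTo(dg, origin = c(0.7, 1.1, 0.5), spacing = c(1.1, 0.9, 1.3),
                    dims = c(5, 5, 5))
  gt <- expand.grid(x = 0.7 + 0:4 * 1.1, y = 1.1 + 0:4 * 0.9,
                    z = 0.5 + 0:4 * 1.3)
  expect_equal(as.vector(out@values), 10 + 0.5 * gt$x + 0.25 * gt$y + 1.5 * gt$z,
               tolerance = 1e-12)
})

test_that("resampling rejects bad spacing and zeroes outside support", {
  dg <- uniformDose(60, c(3, 3, 3))
  expect_error(resampleTo(dg, c(0, 0, 0), c(0, 1, 1), c(2, 2, 2)), "spacing")
  expect_warning(out <- resampleTo(dg, c(-5, 0, 0), 1, c(4, 3, 3)),
                 "outside")
  expect_equal(out@values[1, 1, 1], 0)
})

test_that("margin expansion matches the Euclidean-ball enumeration", {
  occ <- array(FALSE, c(9, 9, 9)); occ[5, 5, 5] <- TRUE
  m <- structureMask(occ, spacing = 1)
  expect_identical(expandMask(m, 0)@occupancy, occ)   # identity at margin 0
  e <- expandMask(m, 2)
  expect_equal(sum(e@occupancy), 33)   # offsets with squared distance <= 4
  # anisotropic spacing: ball radius measured in mm, not voxels
  m2 <- structureMask(occ, spacing = c(1, 2, 2))
  e2 <- expandMask(m2, 2)
  offs <- expand.grid(dx = -2:2, dy = -1:1, dz = -1:1)
  inBall <- (offs$dx * 1)^2 + (offs$dy * 2)^2 + (offs$dz * 2)^2 <= 4
  expect_equal(sum(e2@occupancy), sum(inBall))
})

test_that("margin expansion is monotone and contains its input", {
  set.seed(21)
  for (rep in 1:5) {
    occ <- array(runif(10^3) < 0.05, c(10, 10, 10))
    if (!any(occ)) next
    m <- structureMask(occ, spacing = c(1, 1.5, 2))
    e1 <- expandMask(m, 1.5); e2 <- expandMask(m, 3)
    expect_true(all(occ <= e1@occupancy))
    expect_true(all(e1@occupancy <= e2@occupancy))
  }
})

test_that("a tube expanded by 2 mm becomes the wider tube", {
  dims <- c(21, 21, 9)
  g <- expand.grid(x = -10:10, y = -10:10, z = 1:9)
  tube <- array(g$x^2 + g$y^2 <= 3^2, dims)
  m <- structureMask(tube, spacing = 1, role = "URETHRA")
  prv <- expandMask(m, 2, role = "PRV_URETHRA")
  # interior slices: every centre within 2 mm of a tube voxel centre
  mid <- prv@occupancy[, , 5]
  wide <- matrix(FALSE, 21, 21)
  for (i in 1:21) for (j in 1:21) {
    d2 <- outer(((i - 11) - (-10:10))^2, rep(1, 21)) +
      outer(rep(1, 21), ((j - 11) - (-10:10))^2)
    wide[i, j] <- any(d2[tube[, , 5]] <= 4)
  }
  expect_identical(mid, wide)
})

test_that("boolean mask algebra behaves like set operations", {
  occA <- array(FALSE, c(5, 5, 5)); occA[1:3, , ] <- TRUE
  occB <- array(FALSE, c(5, 5, 5)); occB[3:5, , ] <- TRUE
  a <- structureMask(occA, spacing = 1); b <- structureMask(occB, spacing = 1)
  expect_equal(sum(combineMasks(a, a, "difference")@occupancy), 0)
  expect_equal(sum(combineMasks(a, b, "intersection")@occupancy), 25)
  expect_equal(sum(combineMasks(a, b, "union")@occupancy), 125)
  disjoint <- structureMask(array(FALSE, c(5, 5, 5)), spacing = 1)
  expect_equal(sum(combineMasks(a, disjoint, "intersection")@occupancy), 0)
  off <- structureMask(occB, spacing = 1, origin = c(1, 0, 0))
  expect_error(combineMasks(a, off, "union"), "geometry")
})

test_that("contour rasterization agrees with a winding-number oracle", {
  ref <- doseGrid(array(0, c(14, 14, 3)), spacing = 1, origin = c(0, 0, 0))
  sq <- cbind(c(0.25, 10.25, 10.25, 0.25), c(0.25, 0.25, 10.25, 10.25), 1)
  m <- rasterizeContours(list(sq), ref)
  expect_equal(sum(m@occupancy), 100)
  expect_equal(sum(m@occupancy[, , 2]), 100)  # nearest slice z = 1
  # half-voxel shift: same count under the centre rule
  sqShift <- sq; sqShift[, 1] <- sqShift[, 1] + 0.5; sqShift[, 2] <- sqShift[, 2] + 0.5
  m2 <- rasterizeContours(list(sqShift), ref)
  expect_equal(sum(m2@occupancy), 100)
  # irregular polygon vs the independent winding-number test
  set.seed(5)
  ang <- sort(runif(7, 0, 2 * pi))
  rad <- runif(7, 2, 6)
  poly <- cbind(6.5 + rad * cos(ang), 6.5 + rad * sin(ang), 0)
  mp <- rasterizeContours(list(poly), ref)
  centres <- expand.grid(x = 0:13, y = 0:13)
  expected <- mapply(function(px, py)
    oracleInPolygon(px, py, poly[, 1], poly[, 2]), centres$x, centres$y)
  expect_equal(as.vector(mp@occupancy[, , 1]), expected)
})

test_that("rasterized volume converges to area x thickness with resolution", {
  sq <- cbind(c(0.2, 8.2, 8.2, 0.2), c(0.2, 0.2, 8.2, 8.2), 0)  # 64 mm^2
  ref1 <- doseGrid(array(0, c(12, 12, 1)), spacing = c(1, 1, 1),
                   origin = c(-1, -1, 0))
  ref2 <- doseGrid(array(0, c(48, 48, 1)), spacing = c(0.25, 0.25, 1),
                   origin = c(-1, -1, 0))
  v1 <- maskVolume(rasterizeContours(list(sq), ref1)) * 1000  # mm^3
  v2 <- maskVolume(rasterizeContours(list(sq), ref2)) * 1000
  expect_lt(abs(v2 - 64), abs(v1 - 64) + 1e-9)
  expect_lt(abs(v2 - 64) / 64, 0.07)
})

test_that("degenerate and out-of-grid contours are handled explicitly", {
  ref <- doseGrid(array(0, c(6, 6, 2)), spacing = 1, origin = c(0, 0, 0))
  expect_warning(m <- rasterizeContours(list(cbind(c(1, 2), c(1, 2), 0)), ref),
                 "degenerate")
  expect_equal(sum(m@occupancy), 0)
  far <- cbind(c(20, 25, 25), c(20, 20, 25), 0)
  expect_error(rasterizeContours(list(far), ref, name = "lesion"), "lesion")
  expect_warning(m0 <- rasterizeContours(list(), ref), "no contours")
  expect_equal(sum(m0@occupancy), 0)
})
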