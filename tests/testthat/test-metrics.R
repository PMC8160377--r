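test_that("DX% follows the exact order-statistic rule", {
  dims <- c(10, 10, 1)
  m <- fullMask(dims, spacing = 1)
  u <- uniformDose(70, dims, 1)
  for (pc in c(98, 50, 2)) expect_equal(doseAtVolume(u, m, pc), 70)
  dg <- doseGrid(array(1:100, dims), spacing = 1)
  expect_equal(doseAtVolume(dg, m, 50), 51)
  expect_equal(doseAtVolume(dg, m, 100), 1)   # minimum
  expect_equal(doseAtVolume(dg, m, 0), 100)   # maximum by convention
  expect_error(doseAtVolume(dg, m, 101), "percent")
})

test_that("DX% agrees with a counting oracle on random grids", {
  set.seed(61)
  for (rep in 1:6) {
    dims <- c(6, 5, 4)
    vals <- array(sample(seq(10, 80, by = 0.5), prod(dims), replace = TRUE),
                  dims)
    occ <- array(runif(prod(dims)) < 0.6, dims)
    if (!any(occ)) next
    dg <- doseGrid(vals, spacing = 1.5)
    m <- structureMask(occ, spacing = 1.5)
    for (pc in c(98, 90, 50, 10, 2)) {
      expect_equal(doseAtVolume(dg, m, pc),
                   oracleDoseAtVolume(vals[occ], pc))
    }
    d98 <- doseAtVolume(dg, m, 98)
    d50 <- doseAtVolume(dg, m, 50)
    d2 <- doseAtVolume(dg, m, 2)
    expect_true(d98 <= d50 && d50 <= d2)
  }
})

test_that("the cumulative DVH is a consistent non-increasing curve", {
  dims <- c(10, 10, 1)
  m <- fullMask(dims, spacing = 1)
  u <- uniformDose(65, dims, 1)
  cu <- cumulativeDVH(u, m, binWidth = 1)
  expect_true(all(diff(cu$volume) <= 0))
  expect_equal(cu$volume[cu$dose <= 65], rep(100, sum(cu$dose <= 65)))
  expect_equal(cu$volume[cu$dose > 65], rep(0, sum(cu$dose > 65)))
  two <- doseGrid(array(rep(c(60, 70), each = 50), dims), spacing = 1)
  ct <- cumulativeDVH(two, m, binWidth = 1)
  expect_equal(ct$volume[ct$dose <= 60], rep(100, sum(ct$dose <= 60)))
  expect_equal(ct$volume[ct$dose > 60 & ct$dose <= 70],
               rep(50, sum(ct$dose > 60 & ct$dose <= 70)))
  expect_equal(ct$volume[ct$dose > 70], rep(0, sum(ct$dose > 70)))
  # curve value at level DX% is at least X%
  set.seed(62)
  vals <- array(runif(100, 40, 80), dims)
  dg <- doseGrid(vals, spacing = 1)
  cv <- cumulativeDVH(dg, m, binWidth = 0.5)
  for (pc in c(98, 50, 2)) {
    dx <- doseAtVolume(dg, m, pc)
    lev <- max(cv$dose[cv$dose <= dx])
    expect_gte(cv$volume[cv$dose == lev], pc)
  }
  expect_error(cumulativeDVH(dg, m, binWidth = 0), "binWidth")
})

test_that("constraint verdicts report measured values, pass/fail and
           non-evaluable structures", {
  case60 <- tinyCase(doseLevel = 60)
  v <- checkConstraints(case60)
  u60 <- v[v$structure == "URETHRA", ]
  expect_true(u60$evaluable)
  expect_equal(u60$measured, 60)
  expect_true(u60$pass)                        # 60 <= 62.4
  case65 <- tinyCase(doseLevel = 65)
  v65 <- checkConstraints(case65)
  expect_false(v65$pass[v65$structure == "URETHRA"])
  # boost coverage: uniform 70 Gy passes D98% >= 68.6
  case70 <- tinyCase(doseLevel = 70)
  v70 <- checkConstraints(case70)
  b <- v70[v70$structure == "PTV3" & v70$metric == "D98%", ]
  expect_true(b$pass)
  # PTV2 is absent from the case: not evaluable, never a silent pass
  p2 <- v[v$structure == "PTV2", ]
  expect_false(any(p2$evaluable))
  expect_true(all(is.na(p2$pass)))
})

test_that("overlap metrics reduce to voxel counting", {
  dims <- c(10, 10, 2)
  mk <- function(n0, n1) {
    occ <- array(FALSE, dims); occ[seq(n0, n1)] <- TRUE
    structureMask(occ, spacing = 1)
  }
  a <- mk(1, 100); b <- mk(51, 110)   # |A|=100, |B|=60, |A^B|=50, 1 mm^3
  om <- overlapMetrics(a, b)
  expect_equal(om$dice, 2 * 50 / 160)
  expect_equal(om$intersectionCm3, 0.05)
  expect_equal(om$coverageOfAPct, 50)
  expect_equal(om$intersectionPctOfB, 100 * 50 / 60)
  same <- overlapMetrics(a, a)
  expect_equal(same$dice, 1); expect_equal(same$coverageOfAPct, 100)
  dj <- overlapMetrics(mk(1, 10), mk(11, 20))
  expect_equal(dj$dice, 0); expect_equal(dj$intersectionCm3, 0)
  # symmetry of Dice; coverage identity
  expect_equal(overlapMetrics(b, a)$dice, om$dice)
  empty <- structureMask(array(FALSE, dims), spacing = 1)
  expect_warning(oe <- overlapMetrics(empty, empty), "empty")
  expect_equal(oe$dice, 0)
})

test_that("minimum distances respect anisotropic spacing and match brute
           force", {
  dims <- c(8, 8, 8)
  one <- function(i, j, k) {
    occ <- array(FALSE, dims); occ[i, j, k] <- TRUE
    structureMask(occ, spacing = c(1, 1, 1.5))
  }
  # two voxels three slices apart along the 1.5 mm axis
  expect_equal(minDistance(one(4, 4, 2), one(4, 4, 5)), 4.5)
  # overlap gives zero
  big <- structureMask(array(TRUE, dims), spacing = c(1, 1, 1.5))
  expect_equal(minDistance(big, one(1, 1, 1)), 0)
  set.seed(63)
  for (rep in 1:5) {
    occA <- array(runif(prod(dims)) < 0.05, dims)
    occB <- array(runif(prod(dims)) < 0.05, dims)
    if (!any(occA) || !any(occB)) next
    a <- structureMask(occA, spacing = c(1, 2, 1.5))
    b <- structureMask(occB, spacing = c(1, 2, 1.5))
    expect_equal(minDistance(a, b), oracleMinDistance(a, b), tolerance = 1e-12)
    expect_equal(minDistance(a, b), minDistance(b, a))   # symmetry
    # expanding either mask shrinks the distance by at most the margin
    d0 <- minDistance(a, b)
    d1 <- minDistance(expandMask(a, 2), b)
    expect_lte(d1, d0 + 1e-12)
    expect_gte(d1, d0 - 2 - 1e-12)
  }
})

test_that("per-axial-slice distances are in-plane and bound the 3D minimum", {
  dims <- c(10, 10, 6)
  occA <- array(FALSE, dims); occA[2, 2, 2:4] <- TRUE
  occB <- array(FALSE, dims); occB[6, 2, 3:5] <- TRUE
  a <- structureMask(occA, spacing = c(1.5, 1.5, 3))
  b <- structureMask(occB, spacing = c(1.5, 1.5, 3))
  ps <- minDistance(a, b, mode = "per_axial_slice")
  expect_equal(ps$perSlice$slice, 3:4)
  expect_equal(ps$perSlice$distance, rep(6, 2))   # 4 voxels x 1.5 mm in-plane
  expect_gte(ps$minimum, minDistance(a, b))
  empty <- structureMask(array(FALSE, dims), spacing = c(1.5, 1.5, 3))
  expect_error(minDistance(a, empty), "non-empty")
})
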