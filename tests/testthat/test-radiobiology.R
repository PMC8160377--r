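test_that("isoeffect conversion reproduces hand-computed schedules", {
  expect_equal(eqd(60, 3, 1.6), 172.5)
  expect_equal(eqd(70, 3.5, 1.6, 2), 70 * (1 + 3.5 / 1.6) / (1 + 2 / 1.6))
  expect_equal(eqd(70, 3.5, 1.6, 2), 99.2, tolerance = 1e-3)
  # x = d is the identity for any alpha/beta
  for (ab in c(1.2, 3, 10)) expect_equal(eqd(55, 2, ab, 2), 55)
  expect_error(eqd(60, 3, -1), "abRatio")
  expect_error(eqd(-1, 3, 1.6), "non-negative")
})

test_that("voxelwise EQD equals the scalar conversion per voxel", {
  set.seed(31)
  for (rep in 1:5) {
    dims <- c(4, 3, 5)
    dg <- doseGrid(array(runif(prod(dims), 0, 80), dims), spacing = 1.5,
                   nFractions = 20)
    out <- voxelEQD(dg, 3, 2)
    ref <- eqd(dg@values, dg@values / 20, 3, 2)
    expect_equal(out@values, ref, tolerance = 1e-14)
    expect_equal(gridSpacing(out), gridSpacing(dg))
  }
  z <- voxelEQD(uniformDose(0), 1.6)
  expect_true(all(z@values == 0))
})

test_that("voxelized TCP equals the closed form under uniform dose", {
  # 4500 voxels of 1 mm^3 = the 4.5 cm^3 median ground-truth tumour volume
  dims <- c(30, 30, 5)
  eq <- doseGrid(array(172.5, dims), spacing = 1)
  target <- fullMask(dims, spacing = 1, role = "GTV_HISTO")
  p <- lqParams(rho = 2.8e8, alpha = 0.12050, abRatio = 1.6)
  got <- tcpPoisson(eq, target, p)
  expect_equal(got, oracleTcpUniform(2.8e8, 4.5, 0.12050, 172.5),
               tolerance = 1e-10)
  expect_equal(got, 0.306, tolerance = 2e-3)
  # random uniform cases
  set.seed(32)
  for (rep in 1:5) {
    lev <- runif(1, 100, 250)
    vox <- sample(50:500, 1)
    occ <- array(FALSE, c(10, 10, 10)); occ[seq_len(vox)] <- TRUE
    m <- structureMask(occ, spacing = 1.2, role = "GTV_HISTO")
    dgv <- doseGrid(array(lev, c(10, 10, 10)), spacing = 1.2)
    expect_equal(tcpPoisson(dgv, m, p),
                 oracleTcpUniform(2.8e8, vox * 1.2^3 / 1000, 0.12050, lev),
                 tolerance = 1e-10)
  }
})

test_that("TCP limits: zero dose kills control, huge dose secures it", {
  dims <- c(10, 10, 10)
  target <- fullMask(dims, spacing = 1, role = "GTV_HISTO")
  expect_lt(tcpPoisson(uniformDose(0, dims, 1), target, lqParams()), 1e-300)
  expect_gt(tcpPoisson(uniformDose(500, dims, 1), target, lqParams()),
            1 - 1e-6)
  empty <- structureMask(array(FALSE, dims), spacing = 1, role = "GTV_HISTO")
  expect_error(tcpPoisson(uniformDose(60, dims, 1), empty, lqParams()),
               "empty")
})

test_that("gEUD is the 1/n power mean with its classic special cases", {
  set.seed(33)
  d <- runif(40, 20, 90)
  expect_equal(gEUD(d, 1), mean(d))                 # n = 1: mean dose
  expect_equal(gEUD(rep(64, 9), 0.3), 64)           # uniform: the dose
  expect_equal(gEUD(c(100, 120), 0.3), 111.0, tolerance = 1e-3)
  for (n in c(0.1, 0.3, 1)) {
    g <- gEUD(d, n)
    expect_equal(g, oracleGeud(d, n), tolerance = 1e-12)
    expect_gte(g, min(d)); expect_lte(g, max(d))
  }
  expect_equal(gEUD(c(0, 0, 10), 0.5), oracleGeud(c(0, 0, 10), 0.5))
  expect_error(gEUD(numeric(0), 0.3), "empty")
  expect_error(gEUD(d, 0.3, volumes = rep(1, 40)), "sum to 1")
})

test_that("LKB NTCP hits its probit anchors", {
  dims <- c(5, 5, 4)
  organ <- fullMask(dims, spacing = 1, role = "URETHRA")
  pars <- lkbParams()   # D50 116.7, m 0.23, n 0.3, a/b 5
  # uniform EQD2 at D50: gEUD = D50, Phi(0) = 1/2 exactly
  expect_equal(ntcpLKB(doseGrid(array(116.7, dims), spacing = 1), organ,
                       pars, convert = FALSE), 0.5)
  # half/half 100/120 EQD2: Phi checked against numeric integration
  v <- array(rep(c(100, 120), each = 50), dims)
  got <- ntcpLKB(doseGrid(v, spacing = 1), organ, pars, convert = FALSE)
  t0 <- (oracleGeud(c(100, 120), 0.3) - 116.7) / (0.23 * 116.7)
  phi <- integrate(dnorm, -Inf, t0, rel.tol = 1e-12)$value
  expect_equal(got, phi, tolerance = 1e-9)
  expect_equal(got, 0.417, tolerance = 1e-3)
  # zero dose: Phi(-1/m), vanishingly small
  z <- ntcpLKB(uniformDose(0, dims, 1), organ, pars)
  expect_equal(z, pnorm(-1 / 0.23), tolerance = 1e-12)
  expect_lt(z, 1e-5)
})

test_that("relative seriality matches the brute-force product formula", {
  pars_b <- serialityParams()                      # bladder: s 1.3, g 2.59
  pars_r <- serialityParams(gamma = 1.79, s = 0.75)
  # uniform D50, s = 1: exactly P(D50) = 1/2
  dims <- c(5, 5, 4)
  organ <- fullMask(dims, spacing = 1, role = "BLADDER")
  s1 <- serialityParams(s = 1)
  expect_equal(ntcpRelativeSeriality(doseGrid(array(80, dims), spacing = 1),
                                     organ, s1, convert = FALSE),
               0.5, tolerance = 1e-12)
  # s = 1 uniform at any dose reduces to the single-voxel response
  for (d0 in c(40, 60, 75)) {
    pd <- 2^(-exp(exp(1) * s1@gamma * (1 - d0 / 80)))
    expect_equal(ntcpRelativeSeriality(doseGrid(array(d0, dims), spacing = 1),
                                       organ, s1, convert = FALSE),
                 pd, tolerance = 1e-12)
  }
  # half at D50, half at zero, s = 1.3
  expect_equal(ntcpSerialityCompartments(c(80, 0), c(0.5, 0.5), pars_b),
               0.322, tolerance = 1e-3)
  # zero dose: essentially zero
  expect_lt(ntcpRelativeSeriality(uniformDose(0, dims, 1), organ, pars_b),
            1e-300)
  # random compartment sets against the independent product oracle
  set.seed(34)
  for (rep in 1:8) {
    k <- sample(2:10, 1)
    doses <- runif(k, 30, 110)
    vols <- runif(k); vols <- vols / sum(vols)
    for (pars in list(pars_b, pars_r)) {
      expect_equal(ntcpSerialityCompartments(doses, vols, pars),
                   oracleSeriality(doses, vols, pars@d50, pars@gamma, pars@s),
                   tolerance = 1e-12)
    }
  }
})

test_that("alpha calibration recovers planted and closed-form values", {
  # single volume: closed form alpha = ln(rho V / (-ln T)) / EQD0
  a1 <- calibrateAlpha(1, 60, 3, 1.6, rho = 2.8e8, targetTcp = 0.7)
  closed <- log(2.8e8 * 1 / (-log(0.7))) / 172.5
  expect_equal(a1, closed, tolerance = 1e-6)
  expect_equal(a1, 0.11873, tolerance = 1e-4)
  # round trip: the fitted alpha reproduces the target TCP
  a2 <- calibrateAlpha(2.5, 60, 3, 1.6, targetTcp = 0.5)
  expect_equal(oracleTcpUniform(2.8e8, 2.5, a2, 172.5), 0.5, tolerance = 1e-7)
  # cohort recovery of a planted alpha under mean aggregation
  set.seed(35)
  vols <- runif(10, 1.5, 7)
  aTrue <- 0.13
  target <- mean(oracleTcpUniform(2.8e8, vols, aTrue, 172.5))
  aHat <- calibrateAlpha(vols, 60, 3, 1.6, targetTcp = target)
  expect_lt(abs(aHat - aTrue), 1e-6)
  # per-volume aggregation returns one exact alpha per volume
  pv <- calibrateAlpha(vols, 60, 3, 1.6, targetTcp = 0.7,
                       aggregation = "per_volume")
  expect_equal(oracleTcpUniform(2.8e8, vols, pv, 172.5), rep(0.7, 10),
               tolerance = 1e-10)
  expect_error(calibrateAlpha(1, 60, 3, 1.6, targetTcp = 1.2), "targetTcp")
})

test_that("dose-response models are monotone and produce probabilities", {
  set.seed(36)
  dims <- c(6, 6, 6)
  organ <- fullMask(dims, spacing = 1.5, role = "RECTUM")
  for (rep in 1:6) {
    v <- array(runif(prod(dims), 0, 90), dims)
    bump <- array(runif(prod(dims), 0, 10), dims)
    lo <- doseGrid(v, spacing = 1.5); hi <- doseGrid(v + bump, spacing = 1.5)
    tLo <- tcpPoisson(voxelEQD(lo, 1.6), organ, lqParams())
    tHi <- tcpPoisson(voxelEQD(hi, 1.6), organ, lqParams())
    expect_gte(tHi, tLo)
    for (fn in list(
      function(d) ntcpLKB(d, organ, lkbParams()),
      function(d) ntcpRelativeSeriality(d, organ, serialityParams()))) {
      pLo <- fn(lo); pHi <- fn(hi)
      expect_gte(pHi, pLo)
      expect_gte(pLo, 0); expect_lte(pHi, 1)
    }
  }
})
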