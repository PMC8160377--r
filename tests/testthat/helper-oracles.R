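# Independent brute-force oracles and small fixture builders. Each oracle
# deliberately uses a different algorithm than the implementation it checks.

uniformDose <- function(level, dims = c(4, 4, 4), spacing = 1,
                        nFractions = 20L) {
  doseGrid(array(level, dims), spacing = spacing, nFractions = nFractions)
}

fullMask <- function(dims = c(4, 4, 4), spacing = 1, role = "OTHER") {
  structureMask(array(TRUE, dims), role = role, spacing = spacing)
}

# tiny case with every role the pipeline needs, on an 8^3 grid
tinyCase <- function(doseLevel = 60, plan = "plan1", nFractions = 20L) {
  dims <- c(8, 8, 8)
  mk <- function(sel, role) {
    occ <- array(FALSE, dims)
    occ[sel[[1]], sel[[2]], sel[[3]]] <- TRUE
    structureMask(occ, name = tolower(role), role = role, spacing = 2)
  }
  st <- structureSet(list(
    gtv_histo = mk(list(3:5, 3:5, 3:5), "GTV_HISTO"),
    gtv_union = mk(list(3:6, 3:5, 3:5), "GTV_UNION"),
    prostate = mk(list(2:7, 2:7, 2:7), "PROSTATE"),
    urethra = mk(list(4:5, 4:5, 2:7), "URETHRA"),
    prv = mk(list(3:6, 3:6, 2:7), "PRV_URETHRA"),
    bladder = mk(list(2:7, 2:7, 8), "BLADDER"),
    rectum = mk(list(2:7, 8, 2:7), "RECTUM"),
    ptv3_1 = mk(list(2:6, 2:6, 2:6), "PTV3_1"),
    ptv3_2 = mk(list(2:6, 2:6, 2:6), "PTV3_2"),
    ptv3_3 = mk(list(2:6, 2:6, 2:6), "PTV3_3")))
  dose <- doseGrid(array(doseLevel, dims), spacing = 2,
                   nFractions = nFractions)
  planCase("tiny", plan, dose, st)
}

# closed-form uniform-dose LQ-Poisson TCP
oracleTcpUniform <- function(rho, volumeCm3, alpha, eqd0)
  exp(-rho * volumeCm3 * exp(-alpha * eqd0))

# power-mean gEUD by direct evaluation
oracleGeud <- function(doses, n, volumes = rep(1 / length(doses),
                                               length(doses)))
  sum(volumes * doses^(1 / n))^n

# relative-seriality product formula, plain arithmetic
oracleSeriality <- function(doses, volumes, d50, gamma, s) {
  p <- 2^(-exp(exp(1) * gamma * (1 - doses / d50)))
  (1 - prod((1 - p^s)^volumes))^(1 / s)
}

# dense (non-separable) truncated-Gaussian convolution, replicate padding
oracleBlur <- function(values, spacing, sigma, truncation = 4) {
  d <- dim(values)
  sv <- sigma / spacing
  r <- pmax(1L, as.integer(ceiling(truncation * sv)))
  r[sv == 0] <- 0L
  k1 <- function(ax) {
    if (sv[ax] == 0) return(1)
    w <- dnorm(-r[ax]:r[ax], sd = sv[ax])
    w / sum(w)
  }
  wx <- k1(1); wy <- k1(2); wz <- k1(3)
  out <- array(0, d)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    acc <- 0
    for (a in seq_along(wx)) for (b in seq_along(wy)) for (cc in seq_along(wz)) {
      acc <- acc + wx[a] * wy[b] * wz[cc] *
        values[cl(i + a - r[1] - 1L, d[1]), cl(j + b - r[2] - 1L, d[2]),
               cl(k + cc - r[3] - 1L, d[3])]
    }
    out[i, j, k] <- acc
  }
  out
}

# winding-number point-in-polygon (different algorithm from the even-odd
# crossing rule used by the implementation; equal for simple polygons)
oracleInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    a1 <- atan2(vy[i] - py, vx[i] - px)
    a2 <- atan2(vy[j] - py, vx[j] - px)
    da <- a2 - a1
    if (da > pi) da <- da - 2 * pi
    if (da < -pi) da <- da + 2 * pi
    total <- total + da
  }
  abs(total) > pi
}

# exact Wilcoxon signed-rank p by full enumeration of sign assignments
oracleWilcoxon <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(ws <= w + 1e-9), mean(ws >= w - 1e-9)))
}

# minimum distance by all-pairs double loop over voxel centres
oracleMinDistance <- function(a, b) {
  A <- which(occupancy(a), arr.ind = TRUE)
  B <- which(occupancy(b), arr.ind = TRUE)
  sp <- gridSpacing(a)
  best <- Inf
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    dd <- sum(((A[i, ] - B[j, ]) * sp)^2)
    if (dd < best) best <- dd
  }
  sqrt(best)
}

# DX% by linear search over observed dose levels
oracleDoseAtVolume <- function(doses, percent) {
  lv <- sort(unique(doses), decreasing = TRUE)
  for (x in lv) {
    if (100 * mean(doses >= x) >= percent) return(x)
  }
  min(doses)
}
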