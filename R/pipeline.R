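## Cohort-level evaluation: outcome records, summaries and exact paired
## Wilcoxon plan comparisons.

.dMetrics <- function(dose, mask, prefix) {
  out <- c(doseAtVolume(dose, mask, 98), doseAtVolume(dose, mask, 50),
           doseAtVolume(dose, mask, 2))
  names(out) <- paste0(prefix, c("D98", "D50", "D2"))
  out
}

#' Evaluate one plan case
#'
#' Computes the full radiobiological outcome record for a plan case: TCP on
#' GTV-Histo (LQ-Poisson on EQD0), NTCP of the urethra (LKB on EQD2),
#' NTCPs of bladder and rectum (relative seriality on EQD2), the total
#' probability of injury P_I with the parameter bundle's organ weights, the
#' complication-free tumour control P+ = TCP (1 - P_I), D98/D50/D2 metrics
#' for the active boost volume, GTV-Histo, urethra and PRV-urethra, and the
#' urethral sparing-constraint verdicts. With a motion kernel the record is
#' computed twice — on the planned and on the motion-blurred dose — against
#' the same masks.
#'
#' @param case A [PlanCase-class] providing roles GTV_HISTO, URETHRA,
#'   PRV_URETHRA, BLADDER and RECTUM (missing roles raise an error naming
#'   the role).
#' @param params A [RadiobioParams-class].
#' @param kernel Optional [MotionKernel-class].
#' @param constraints Constraint table (see [defaultConstraints()]).
#' @return `data.frame` with one row per motion state.
#' @export
evaluateCase <- function(case, params = defaultRadiobioParams(),
                         kernel = NULL, constraints = defaultConstraints()) {
  target <- getStructure(case, "GTV_HISTO")
  urethra <- getStructure(case, "URETHRA")
  prv <- getStructure(case, "PRV_URETHRA")
  bladder <- getStructure(case, "BLADDER")
  rectum <- getStructure(case, "RECTUM")
  boost <- getStructure(case, .boostRoleForPlan[[planLabel(case)]])
  w <- params@weights[c("urethra", "bladder", "rectum")]
  if (any(is.na(w))) w <- rep(1, 3)

  recordFor <- function(dose, motion) {
    tcp <- tcpPoisson(voxelEQD(dose, params@tumour@abRatio, 0),
                      target, params@tumour)
    ntcps <- c(urethra = ntcpLKB(dose, urethra, params@urethra),
               bladder = ntcpRelativeSeriality(dose, bladder, params@bladder),
               rectum = ntcpRelativeSeriality(dose, rectum, params@rectum))
    pI <- probabilityOfInjury(ntcps, w)
    cv <- checkConstraints(case, constraints, dose = dose)
    uPass <- cv$pass[cv$structure == "URETHRA" & cv$metric == "D2%"]
    pPass <- cv$pass[cv$structure == "PRV_URETHRA" & cv$metric == "D2%"]
    data.frame(caseId = caseId(case), plan = planLabel(case), motion = motion,
               tcp = tcp, ntcpUrethra = ntcps[["urethra"]],
               ntcpBladder = ntcps[["bladder"]],
               ntcpRectum = ntcps[["rectum"]],
               pInjury = pI, pPlus = pPlus(tcp, pI),
               t(.dMetrics(dose, boost, "boost")),
               t(.dMetrics(dose, target, "gtvHisto")),
               t(.dMetrics(dose, urethra, "urethra")),
               t(.dMetrics(dose, prv, "prv")),
               urethraD2Pass = if (length(uPass)) uPass[1] else NA,
               prvD2Pass = if (length(pPass)) pPass[1] else NA,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  rec <- recordFor(case@dose, FALSE)
  if (!is.null(kernel))
    rec <- rbind(rec, recordFor(blurDose(case@dose, kernel), TRUE))
  rec
}

#' Evaluate every case of a cohort
#'
#' @param cohort A [Cohort-class].
#' @param params A [RadiobioParams-class].
#' @param kernel Optional [MotionKernel-class] (adds motion records).
#' @param constraints Constraint table.
#' @return `data.frame` of outcome records, one row per (plan-case, motion
#'   state).
#' @export
evaluateCohort <- function(cohort, params = defaultRadiobioParams(),
                           kernel = NULL, constraints = defaultConstraints()) {
  do.call(rbind, lapply(cohort@cases, evaluateCase, params = params,
                        kernel = kernel, constraints = constraints))
}

#' Summarise outcome records per plan and motion state
#'
#' Median and interquartile range of every numeric endpoint, grouped by
#' (plan, motion). The median uses the midpoint convention for even counts.
#'
#' @param records Outcome records from [evaluateCohort()].
#' @param endpoints Columns to summarise (default: all numeric).
#' @return Long `data.frame`: `plan`, `motion`, `endpoint`, `median`, `q25`,
#'   `q75`, `n`.
#' @export
summarizeCohort <- function(records, endpoints = NULL) {
  if (!nrow(records)) stop("no records to summarise", call. = FALSE)
  if (is.null(endpoints))
    endpoints <- names(records)[vapply(records, is.numeric, logical(1))]
  groups <- unique(records[, c("plan", "motion")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    sel <- records$plan == groups$plan[i] & records$motion == groups$motion[i]
    do.call(rbind, lapply(endpoints, function(ep) {
      x <- records[[ep]][sel]
      data.frame(plan = groups$plan[i], motion = groups$motion[i],
                 endpoint = ep, median = stats::median(x),
                 q25 = unname(stats::quantile(x, 0.25)),
                 q75 = unname(stats::quantile(x, 0.75)), n = sum(sel),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact test on paired differences. Zero differences are dropped
#' (classic Wilcoxon; `zeroMethod = "pratt"` instead ranks them with the
#' rest and then discards their contribution). Tied absolute differences
#' receive midranks. The null distribution of the positive-rank sum is
#' computed exactly over all 2^m equally likely sign assignments (by
#' generating-function convolution, identical to full enumeration), and
#' p = min(1, 2 min(P(W <= w), P(W >= w))).
#'
#' @param x,y Equal-length paired samples.
#' @param zeroMethod `"wilcoxon"` (drop zeros, default) or `"pratt"`.
#' @return An object of class `"htest"` with the positive-rank sum `V`, the
#'   exact two-sided `p.value`, and `m`, the number of informative pairs.
#' @examples
#' wilcoxonSignedRankExact(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))$p.value # 1/16
#' @export
wilcoxonSignedRankExact <- function(x, y, zeroMethod = c("wilcoxon", "pratt")) {
  zeroMethod <- match.arg(zeroMethod)
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  d <- x - y
  if (all(d == 0)) {
    warning("all paired differences are zero; p = 1")
    return(structure(list(statistic = c(V = 0), p.value = 1,
                          m = 0L, method = "Exact Wilcoxon signed-rank test",
                          data.name = "x vs y"), class = "htest"))
  }
  if (zeroMethod == "wilcoxon") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r <- rank(abs(d))
    r <- r[d != 0]
    d <- d[d != 0]
  }
  m <- length(d)
  r2 <- round(2 * r)            # midranks live on a half-integer lattice
  w2 <- sum(r2[d > 0])
  total <- sum(r2)
  ## exact distribution of the (doubled) positive-rank sum
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (ri in r2) {
    g <- f / 2
    g[(ri + 1L):(total + 1L)] <- g[(ri + 1L):(total + 1L)] +
      f[1L:(total + 1L - ri)] / 2
    f <- g
  }
  pLe <- sum(f[seq_len(w2 + 1L)])
  pGe <- sum(f[(w2 + 1L):(total + 1L)])
  p <- min(1, 2 * min(pLe, pGe))
  structure(list(statistic = c(V = w2 / 2), p.value = p, m = m,
                 method = sprintf("Exact Wilcoxon signed-rank test (%s zeros)",
                                  zeroMethod),
                 data.name = "x vs y"), class = "htest")
}

#' Pairwise plan comparison on cohort records
#'
#' For each endpoint, motion state and plan pair, matches the records by
#' case id and reports the exact two-sided Wilcoxon signed-rank p-value and
#' the direction of the median paired difference (second plan minus first).
#'
#' @param records Outcome records from [evaluateCohort()].
#' @param endpoints Endpoint columns (default: the probability endpoints
#'   P+, TCP and the three NTCPs).
#' @param pairs List of length-2 plan-label vectors; default all three
#'   pairs.
#' @return `data.frame`: `motion`, `endpoint`, `planA`, `planB`, `p`,
#'   `medianDiff` (B - A), `direction`.
#' @export
comparePlans <- function(records,
                         endpoints = c("pPlus", "tcp", "ntcpUrethra",
                                       "ntcpBladder", "ntcpRectum"),
                         pairs = list(c("plan1", "plan2"),
                                      c("plan1", "plan3"),
                                      c("plan2", "plan3"))) {
  rows <- list()
  for (mo in unique(records$motion)) {
    recs <- records[records$motion == mo, ]
    for (pr in pairs) {
      a <- recs[recs$plan == pr[1], ]
      b <- recs[recs$plan == pr[2], ]
      a <- a[order(a$caseId), ]; b <- b[order(b$caseId), ]
      if (!nrow(a) || !identical(a$caseId, b$caseId))
        stop(sprintf("unmatched cases for %s vs %s", pr[1], pr[2]),
             call. = FALSE)
      for (ep in endpoints) {
        dm <- stats::median(b[[ep]] - a[[ep]])
        test <- suppressWarnings(wilcoxonSignedRankExact(a[[ep]], b[[ep]]))
        rows[[length(rows) + 1L]] <- data.frame(
          motion = mo, endpoint = ep, planA = pr[1], planB = pr[2],
          p = test$p.value, medianDiff = dm,
          direction = if (dm < 0) "lower" else if (dm > 0) "higher" else "equal",
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}
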