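test_that("phantom generation is deterministic given the seed", {
  a <- makePhantom(phantomSpec(), seed = 4)
  b <- makePhantom(phantomSpec(), seed = 4)
  for (nm in structureNames(a))
    expect_identical(occupancy(a[[nm]]), occupancy(b[[nm]]))
  c2 <- makePhantom(phantomSpec(), seed = 5)
  expect_false(identical(occupancy(getStructure(a, "GTV_UNION")),
                         occupancy(getStructure(c2, "GTV_UNION"))))
})

test_that("the default phantom carries every role the pipeline needs,
           with consistent derived volumes", {
  st <- makePhantom(phantomSpec(), seed = 1)
  roles <- vapply(st@masks, maskRole, character(1))
  for (r in c("PROSTATE", "URETHRA", "PRV_URETHRA", "GTV_UNION", "GTV_HISTO",
              "PTV3_1", "PTV3_2", "PTV3_3", "BLADDER", "RECTUM"))
    expect_true(r %in% roles, label = paste("role", r, "present"))
  # PRV contains the urethra; PTV3_2/3 are carved out of PTV3_1
  u <- getStructure(st, "URETHRA"); prv <- getStructure(st, "PRV_URETHRA")
  expect_true(all(occupancy(u) <= occupancy(prv)))
  p1 <- getStructure(st, "PTV3_1"); p2 <- getStructure(st, "PTV3_2")
  p3 <- getStructure(st, "PTV3_3")
  expect_true(all(occupancy(p2) <= occupancy(p1)))
  expect_true(all(occupancy(p3) <= occupancy(p2)))
  expect_equal(sum(occupancy(p2) & occupancy(u)), 0)
  expect_equal(sum(occupancy(p3) & occupancy(prv)), 0)
  # ground-truth volume inside the published interquartile range
  expect_gt(maskVolume(getStructure(st, "GTV_HISTO")), 1.8)
  expect_lt(maskVolume(getStructure(st, "GTV_HISTO")), 6.9)
  # coverage of GTV-Histo by GTV-Union near the 0.79 target
  cov <- overlapMetrics(getStructure(st, "GTV_HISTO"),
                        getStructure(st, "GTV_UNION"))$coverageOfAPct
  expect_gt(cov, 74); expect_lt(cov, 84)
})

test_that("full histology coverage nests GTV-Histo inside GTV-Union", {
  st <- makePhantom(phantomSpec(histoCoverage = 1), seed = 2)
  gh <- occupancy(getStructure(st, "GTV_HISTO"))
  gu <- occupancy(getStructure(st, "GTV_UNION"))
  expect_true(all(gh <= gu))
})

test_that("median ground-truth tumour volume over many seeds stays in the
           published interquartile range", {
  vols <- vapply(1:50, function(s)
    maskVolume(getStructure(makePhantom(phantomSpec(), seed = s),
                            "GTV_HISTO")), numeric(1))
  expect_gt(median(vols), 1.8)
  expect_lt(median(vols), 6.9)
})

test_that("dose painting hits the prescription levels and the sparing
           target", {
  st <- makePhantom(phantomSpec(), seed = 3)
  spec0 <- phantomSpec(noiseSd = 0)
  d1 <- paintDose(st, "plan1", spec0)
  boost <- getStructure(st, "PTV3_1")
  expect_equal(doseAtVolume(d1, boost, 50), 70, tolerance = 0.02)
  expect_true(all(d1@values >= 0))
  expect_equal(nFractions(d1), 20L)
  # plan 3 respects the PRV sparing constraint by construction
  d3 <- paintDose(st, "plan3", phantomSpec(), seed = 30)
  prv <- getStructure(st, "PRV_URETHRA")
  expect_lte(doseAtVolume(d3, prv, 2), 62.4)
  # suppression is a dose decrease: plan ordering on the urethra
  u <- getStructure(st, "URETHRA")
  d2 <- paintDose(st, "plan2", phantomSpec(), seed = 20)
  d1n <- paintDose(st, "plan1", phantomSpec(), seed = 10)
  expect_gt(doseAtVolume(d1n, u, 2), doseAtVolume(d2, u, 2))
  expect_gte(doseAtVolume(d2, u, 2), doseAtVolume(d3, u, 2))
  expect_error(paintDose(st, "planX"), "plan")
})

test_that("cohort generation is reproducible and sized n cases x 3 plans", {
  sp <- phantomSpec(dims = c(48, 48, 64))
  co <- makeCohort(2, sp, seed = 11)
  expect_equal(length(co), 6)
  expect_equal(sort(unique(vapply(co@cases, planLabel, character(1)))),
               c("plan1", "plan2", "plan3"))
  expect_equal(length(unique(vapply(co@cases, caseId, character(1)))), 2)
  co2 <- makeCohort(2, sp, seed = 11)
  expect_identical(doseValues(co[[1]]), doseValues(co2[[1]]))
  expect_identical(doseValues(co[[6]]), doseValues(co2[[6]]))
  co3 <- makeCohort(2, sp, seed = 12)
  expect_false(identical(doseValues(co[[1]]), doseValues(co3[[1]])))
})
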