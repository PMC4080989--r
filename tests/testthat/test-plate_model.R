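test_that("inhibition formula reproduces its control anchors", {
  # no-drug control, maximum-inhibitor control, and forced arithmetic
  expect_equal(computeInhibition(1000, 1000, 0), 0)
  expect_equal(computeInhibition(0, 1000, 0), 100)
  expect_equal(computeInhibition(250, 1000, 0), 75)
  # vectorized over test counts; affine and strictly decreasing in Test
  tests <- seq(1000, 0, by = -100)
  inh <- computeInhibition(tests, 1000, 0)
  expect_true(all(diff(inh) > 0))
  expect_equal(diff(inh), rep(10, 10))
  # clipped companion stays in [0, 100]
  expect_equal(computeInhibition(1200, 1000, 0, clip = TRUE), 0)
  expect_equal(computeInhibition(-0, 1000, 100, clip = TRUE), 100)
})

test_that("invalid controls and negative counts are rejected", {
  expect_error(computeInhibition(500, 100, 100), "control failure")
  expect_error(computeInhibition(500, 50, 100), "control failure")
  expect_error(computeInhibition(-5, 1000, 0), "non-negative")
})

test_that("dose series enforce the doubling-dilution design", {
  ds <- DoseSeries("gefitinib", tdc = 1)
  expect_equal(concentrations(ds), c(2, 1, 0.5, 0.25, 0.125, 0.0625))
  expect_equal(tdc(ds), 1)
  expect_equal(concentrations(ds)[1] / concentrations(ds)[6], 32)
  expect_error(DoseSeries("bad", concentrations = c(2, 1, 0.5, 0.25, 0.125)),
               "6 concentrations")
  expect_error(DoseSeries("bad", concentrations = c(2, 1, 0.5, 0.3, 0.15,
                                                    0.075)),
               "doubling")
})

test_that("ATP calibration inverts the standard line and flags range", {
  sc <- standardCurve(atp = c(0, 10), counts = c(0, 1000))
  expect_equal(calibrateAtp(sc, 500)$atp, 5)
  expect_equal(calibrateAtp(sc, 0)$atp, 0)
  expect_false(calibrateAtp(sc, 500)$outOfRange)
  expect_warning(out <- calibrateAtp(sc, 2000), "outside the calibrated")
  expect_equal(out$atp, 20)
  expect_true(out$outOfRange)
  # OLS with free intercept through noisy points, cross-checked with lm
  set.seed(7)
  atp <- 0:10
  counts <- 50 + 100 * atp + rnorm(11, sd = 5)
  sc2 <- standardCurve(atp, counts)
  ref <- lm(counts ~ atp)
  expect_equal(sc2@slope, unname(coef(ref)[2]))
  expect_equal(sc2@intercept, unname(coef(ref)[1]))
  expect_error(standardCurve(c(1, 1), c(5, 6)), "distinct")
})

test_that("condition summaries compute inhibition and replicate CV", {
  # identical replicates -> zero CV at every step
  wells <- manualPlate(rep(list(c(500, 500, 500)), 6),
                       moCounts = rep(1000, 3), miCounts = rep(0, 3))
  prof <- summarizeCondition(wells, DoseSeries("drugX", 1),
                             condition = "drugX")
  expect_s4_class(prof, "InhibitionProfile")
  expect_equal(replicateCV(prof), rep(0, 6))
  expect_equal(inhibition(prof), rep(50, 6))

  # direct sd/mean oracle: (900, 1000, 1100) -> 10.0%
  wells <- manualPlate(rep(list(c(900, 1000, 1100)), 6),
                       rep(1000, 3), rep(0, 3))
  prof <- summarizeCondition(wells, DoseSeries("drugX", 1),
                             condition = "drugX")
  expect_equal(replicateCV(prof),
               rep(100 * sd(c(900, 1000, 1100)) / 1000, 6))
  expect_equal(replicateCV(prof)[1], 10, tolerance = 1e-9)

  # midpoint of controls: MO 1000, MI 10, step mean 505 -> 50%
  wells <- manualPlate(rep(list(c(505, 505, 505)), 6),
                       rep(1000, 3), rep(10, 3))
  prof <- summarizeCondition(wells, DoseSeries("drugX", 1),
                             condition = "drugX")
  expect_equal(inhibition(prof), rep(50, 6))
})

test_that("summaries are idempotent under duplication of identical wells", {
  counts <- list(c(800, 820, 810), c(600, 610, 590), c(400, 420, 410),
                 c(300, 310, 290), c(250, 260, 240), c(220, 230, 210))
  wells1 <- manualPlate(counts, rep(1000, 3), rep(5, 3))
  p1 <- summarizeCondition(wells1, DoseSeries("drugX", 1), "drugX")
  dup <- manualPlate(lapply(counts, function(x) c(x, x)),
                     rep(1000, 3), rep(5, 3))
  p2 <- summarizeCondition(dup, DoseSeries("drugX", 1), "drugX")
  expect_equal(inhibition(p2), inhibition(p1))
  # sample sd shrinks slightly when identical values are duplicated
  expect_equal(replicateCV(p2), replicateCV(p1), tolerance = 0.2)
})

test_that("plate analysis is invariant to rescaling all counts", {
  counts <- list(c(800, 820, 810), c(600, 610, 590), c(400, 420, 410),
                 c(300, 310, 290), c(250, 260, 240), c(220, 230, 210))
  wells <- manualPlate(counts, c(990, 1000, 1010), c(5, 6, 7))
  p1 <- summarizeCondition(wells, DoseSeries("drugX", 1), "drugX")
  for (k in c(0.001, 7, 1e4)) {
    sc <- wells
    sc$counts <- sc$counts * k
    pk <- summarizeCondition(sc, DoseSeries("drugX", 1), "drugX")
    expect_equal(inhibition(pk), inhibition(p1), tolerance = 1e-12)
    expect_equal(replicateCV(pk), replicateCV(p1), tolerance = 1e-12)
  }
})

test_that("control handling: missing, inverted and outlier controls", {
  counts <- rep(list(c(500, 500, 500)), 6)
  noMI <- manualPlate(counts, rep(1000, 3), numeric(0))
  expect_error(summarizeCondition(noMI, DoseSeries("drugX", 1), "drugX"),
               "missing MI")
  inverted <- manualPlate(counts, rep(10, 3), rep(1000, 3))
  expect_error(summarizeCondition(inverted, DoseSeries("drugX", 1),
                                  "drugX"),
               "MO mean must exceed MI")
  # an extreme MO well is dropped with a warning, recovering the clean mean
  wells <- manualPlate(counts, c(1000, 1010, 990, 1005, 995, 20000),
                       rep(0, 3))
  expect_warning(
    prof <- summarizeCondition(wells, DoseSeries("drugX", 1), "drugX"),
    "outlier MO")
  expect_equal(inhibition(prof), rep(50, 6), tolerance = 1e-2)
})

test_that("QC flags steps above the CV limit", {
  prof <- makeProfile(rep(60, 6), cv = c(2, 4, 15, 3, 1, 0))
  qc <- qcProfile(prof, cvLimit = 10)
  expect_equal(qc$flagged, c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_false(qc$pass)
  # limit monotonicity: a looser limit passes the same data
  expect_true(qcProfile(prof, cvLimit = 20)$pass)
  clean <- makeProfile(rep(60, 6), cv = rep(0, 6))
  expect_true(qcProfile(clean)$pass)
  # a step with fewer than 2 replicates is flagged, not fatal
  lowN <- makeProfile(rep(60, 6), cv = c(NA, rep(1, 5)),
                      n = c(1L, rep(3L, 5)))
  qc2 <- qcProfile(lowN)
  expect_true(qc2$flagged[1])
  expect_false(qc2$pass)
})

test_that("well tables are validated structurally", {
  wells <- manualPlate(rep(list(c(1, 2, 3)), 6), rep(10, 3), rep(0, 3))
  expect_silent(validateWellTable(wells))
  bad <- wells; bad$well[1] <- "Z99"
  expect_error(validateWellTable(bad), "malformed well")
  bad <- wells; bad$counts[1] <- -1
  expect_error(validateWellTable(bad), "non-negative")
  bad <- wells; bad$dilution_step[bad$condition == "MO"][1] <- 2L
  expect_error(validateWellTable(bad), "control wells")
})
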