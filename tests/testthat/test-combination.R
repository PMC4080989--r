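test_that("combination index arithmetic matches its definition", {
  # sham self-combination at half doses is exactly additive
  expect_equal(combinationIndex(0.5, 0.5, 1, 1, alpha = 0), 1)
  # quarter doses
  expect_equal(combinationIndex(0.25, 0.25, 1, 1, alpha = 0), 0.5)
  expect_equal(combinationIndex(0.25, 0.25, 1, 1, alpha = 1), 0.5625)
  # censored / non-positive single-agent doses are not estimable
  expect_true(is.na(combinationIndex(0.5, 0.5, NA, 1)))
  expect_true(is.na(combinationIndex(0.5, 0.5, 0, 1)))
})

test_that("CI is symmetric in drug labels and monotone in alpha", {
  set.seed(3)
  for (i in 1:50) {
    d <- runif(4, 0.01, 10)
    a <- sample(c(0, 1), 1)
    expect_equal(combinationIndex(d[1], d[2], d[3], d[4], a),
                 combinationIndex(d[2], d[1], d[4], d[3], a))
    expect_gte(combinationIndex(d[1], d[2], d[3], d[4], 1),
               combinationIndex(d[1], d[2], d[3], d[4], 0))
  }
})

test_that("CI classification uses the 0.8 / 1.2 cutoffs", {
  expect_equal(classifyCI(0.23), "synergy")
  expect_equal(classifyCI(1.0), "additive")
  expect_equal(classifyCI(1.33), "antagonism")
  # boundary values fall in the additive band
  expect_equal(classifyCI(c(0.8, 1.2)), c("additive", "additive"))
  expect_equal(classifyCI(c(0.79999, 1.20001)),
               c("synergy", "antagonism"))
  expect_equal(classifyCI(NA_real_), "not estimable")
})

test_that("fixed-ratio designs split mixture crossings into components", {
  # equal-ratio design: crossing at A-component 0.25 -> (0.25, 0.25)
  dA <- DoseSeries("A", tdc = 1)
  dB <- DoseSeries("B", tdc = 1)
  design <- CombinationDesign(dA, dB)
  expect_equal(comboRatio(design), 1)
  prof <- makeProfile(c(95, 85, 70, 50, 30, 10),
                      conc = concentrations(dA), series = design)
  cmp <- comboComponentsAtEffect(prof, design, 0.5)
  expect_true(cmp$estimable)
  expect_equal(cmp$doseA, 0.25)
  expect_equal(cmp$doseB, 0.25)

  # 2:1 ratio: A-component 1.0 -> (1.0, 0.5)
  design2 <- CombinationDesign(DoseSeries("A", tdc = 2),
                               DoseSeries("B", tdc = 1))
  prof2 <- makeProfile(c(90, 50, 30, 20, 10, 5),
                       conc = c(4, 2, 1, 0.5, 0.25, 0.125),
                       series = design2)
  # crossing of 70% halfway (log2) between steps 1 and 2: A = 2 * 2^0.5;
  # crossing of 50% exactly at step 2: A = 2
  cmp2 <- comboComponentsAtEffect(prof2, design2, 0.5)
  expect_equal(cmp2$doseA, 2)
  expect_equal(cmp2$doseB, 1)

  # censored mixture crossing -> no component doses
  flat <- makeProfile(rep(20, 6), conc = concentrations(dA),
                      series = design)
  expect_false(comboComponentsAtEffect(flat, design, 0.5)$estimable)
})

test_that("components of a Loewe-additive mixture match the isobole oracle", {
  set.seed(41)
  for (i in 1:20) {
    imax <- runif(1, 60, 100)
    h <- runif(1, 0.5, 3)
    ec50A <- 10^runif(1, -0.5, 0.5)
    ec50B <- ec50A * 10^runif(1, -0.5, 0.5)
    mA <- DrugResponseModel("L", "A", imax, ec50A, h)
    mB <- DrugResponseModel("L", "B", imax, ec50B, h)
    icA <- hillInverse(50, imax, ec50A, h)
    icB <- hillInverse(50, imax, ec50B, h)
    design <- CombinationDesign(DoseSeries("A", tdc = icA),
                                DoseSeries("B", tdc = icB))
    prof <- loeweComboProfile(mA, mB, design)
    cmp <- comboComponentsAtEffect(prof, design, 0.5)
    orc <- oracleLoeweRayCrossing(mA, mB, comboRatio(design), 0.5)
    expect_true(cmp$estimable)
    expect_equal(cmp$doseA, orc$doseA, tolerance = 0.01)
    expect_equal(cmp$doseB, orc$doseB, tolerance = 0.01)
  }
})

test_that("sham self-combinations yield CI 1 and Loewe pairs stay additive", {
  # noiseless Hill drug combined with itself at half doses
  series <- DoseSeries("A", tdc = 1)
  single <- drugSensitivity(hillProfile(100, 0.15, 1, series))
  half <- DoseSeries("A", tdc = 0.5)
  design <- CombinationDesign(half, half)
  comboProf <- makeProfile(inhibition(hillProfile(100, 0.15, 1, series)),
                           conc = concentrations(half),
                           condition = "A+A", series = design)
  rep2 <- ciReport(single, single, comboProf |> drugSensitivity(),
                   design, alpha = 0)
  expect_true(isEstimable(rep2$ci50))
  expect_true(isEstimable(rep2$ci90))
  expect_equal(ciValue(rep2$ci50), 1, tolerance = 1e-6)
  expect_equal(ciValue(rep2$ci90), 1, tolerance = 1e-6)
  expect_equal(classification(rep2$ci50), "additive")

  # equal-shape Loewe-additive pairs: CI50 = 1 up to interpolation noise
  set.seed(13)
  for (i in 1:20) {
    imax <- runif(1, 60, 100)
    h <- runif(1, 0.5, 3)
    ec50A <- 10^runif(1, -0.5, 0.5)
    ec50B <- ec50A * 10^runif(1, -0.5, 0.5)
    mA <- DrugResponseModel("L", "A", imax, ec50A, h)
    mB <- DrugResponseModel("L", "B", imax, ec50B, h)
    design <- CombinationDesign(
      DoseSeries("A", tdc = hillInverse(50, imax, ec50A, h)),
      DoseSeries("B", tdc = hillInverse(50, imax, ec50B, h)))
    sA <- drugSensitivity(hillProfile(imax, ec50A, h, design@drugA))
    sB <- drugSensitivity(hillProfile(imax, ec50B, h, design@drugB))
    sC <- drugSensitivity(loeweComboProfile(mA, mB, design))
    ci <- ciValue(ciReport(sA, sB, sC, design, alpha = 0)$ci50)
    expect_gte(ci, 0.95); expect_lte(ci, 1.05)
  }
})

test_that("a ground-truth potency shift is recovered as the CI", {
  # rho = 0.25 synergy construction -> CI50 = 0.25 for equal-shape pairs
  set.seed(17)
  for (i in 1:10) {
    imax <- runif(1, 60, 100)
    h <- runif(1, 0.5, 3)
    ec50A <- 10^runif(1, -0.5, 0.5)
    ec50B <- ec50A * 10^runif(1, -0.5, 0.5)
    mA <- DrugResponseModel("L", "A", imax, ec50A, h)
    mB <- DrugResponseModel("L", "B", imax, ec50B, h)
    design <- CombinationDesign(
      DoseSeries("A", tdc = hillInverse(50, imax, ec50A, h)),
      DoseSeries("B", tdc = hillInverse(50, imax, ec50B, h)))
    sA <- drugSensitivity(hillProfile(imax, ec50A, h, design@drugA))
    sB <- drugSensitivity(hillProfile(imax, ec50B, h, design@drugB))
    sC <- drugSensitivity(loeweComboProfile(mA, mB, design, rho = 0.25))
    expect_equal(ciValue(ciReport(sA, sB, sC, design)$ci50), 0.25,
                 tolerance = 0.03 / 0.25)
  }

  # unequal Hill slopes (1 vs 3) under exact additivity: CI within 0.15
  mA <- DrugResponseModel("L", "A", 100, 0.4, 1)
  mB <- DrugResponseModel("L", "B", 100, 0.6, 3)
  design <- CombinationDesign(DoseSeries("A", tdc = 0.4),
                              DoseSeries("B", tdc = 0.6))
  sA <- drugSensitivity(hillProfile(100, 0.4, 1, design@drugA))
  sB <- drugSensitivity(hillProfile(100, 0.6, 3, design@drugB))
  sC <- drugSensitivity(loeweComboProfile(mA, mB, design))
  expect_equal(ciValue(ciReport(sA, sB, sC, design)$ci50), 1,
               tolerance = 0.15)
})

test_that("censoring propagates per effect level, never substituted", {
  series <- DoseSeries("A", tdc = 1)
  # single agent B flat at 30%: neither level estimable
  sA <- drugSensitivity(hillProfile(100, 0.15, 1, series))
  sB <- drugSensitivity(makeProfile(rep(30, 6),
                                    conc = concentrations(series)))
  design <- CombinationDesign(series, DoseSeries("B", tdc = 1))
  sC <- drugSensitivity(hillProfile(100, 0.1, 1, design@drugA))
  rep2 <- ciReport(sA, sB, sC, design)
  expect_false(isEstimable(rep2$ci50))
  expect_false(isEstimable(rep2$ci90))
  expect_equal(classification(rep2$ci50), "not estimable")
  expect_true(is.na(ciValue(rep2$ci50)))

  # CI50 estimable while CI90 is not (single A's IC90 beyond the range)
  sA2 <- drugSensitivity(hillProfile(100, 0.5, 1, series))
  sB2 <- drugSensitivity(hillProfile(100, 0.5, 1, DoseSeries("B", 1)))
  mA <- DrugResponseModel("L", "A", 100, 0.5, 1)
  mB <- DrugResponseModel("L", "B", 100, 0.5, 1)
  sC2 <- drugSensitivity(loeweComboProfile(mA, mB, design))
  mixed <- ciReport(sA2, sB2, sC2, design)
  expect_true(isEstimable(mixed$ci50))
  expect_false(isEstimable(mixed$ci90))
})
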