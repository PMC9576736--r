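test_that("peak positions follow the saturation spacing", {
  # frozen from the independent closed form: Kd = 6/0.88 - 1 = 5.81818,
  # mu2 = 6*2/(Kd + 2) = 1.5348837
  expect_equal(peakPositions(2, 0.88, 6), c(0, 0.88, 1.5348837),
               tolerance = 1e-6)
  expect_equal(peakPositions(2, 0.88, 6), oracleSaturation(0:2, 0.88, 6))
  # saturation makes the spacing sub-linear
  mu <- peakPositions(2, 0.88, 6)
  expect_lt(mu[3], 2 * mu[2])
  # linear spacing in the bMax -> Inf limit
  mu4 <- peakPositions(5, 0.9, 1e4)
  expect_lt(max(abs(mu4[-1] - (1:5) * 0.9) / ((1:5) * 0.9)), 1e-3)
  expect_error(peakPositions(3, 6.5, 6), "invalid saturation")
  # SaturationCurve input uses its Kd in vesicles directly
  expect_equal(peakPositions(2, NA, saturationCurve(5.9, 6.5)),
               5.9 * (0:2) / (6.5 + 0:2))
})

test_that("peak widths broaden with fluorescence in quadrature", {
  expect_equal(peakWidths(0.1, 0), 0.1)            # baseline width
  expect_equal(peakWidths(0.1, 3), 0.2)            # sqrt(1 + 3) = 2
  mu <- peakPositions(8, 0.84, 6)
  expect_true(all(diff(peakWidths(0.1, mu)) >= 0)) # non-decreasing
  expect_error(peakWidths(0, 1), "sigma0")
})

test_that("the mixture density is normalized with binomial weights", {
  mm <- predictAmplitudeDensity(5, 0.42, 0.88, noise = 0.1, bMax = 6)
  expect_equal(sum(mm$weights), 1)
  expect_equal(mm$weights[1], 0.58^5)
  # CDF reaches 0 and 1 (normalization before count scaling)
  expect_lt(abs(quantalglu:::.mixtureCdf(mm, 1e3) - 1), 1e-9)
  expect_lt(abs(quantalglu:::.mixtureCdf(mm, -1e3)), 1e-9)
  # p -> 0 collapses onto the failure component
  mm0 <- predictAmplitudeDensity(5, 1e-9, 0.88, noise = 0.1, bMax = 6,
                                 axis = seq(-0.5, 0.5, 0.01))
  expect_equal(mm0$weights[1], 1, tolerance = 1e-6)
})

test_that("sampled amplitudes match the predicted distribution", {
  # brute-force sampling oracle at a few random grid points
  set.seed(20)
  for (i in 1:3) {
    N <- sample(1:6, 1); p <- runif(1, 0.1, 0.9); q <- runif(1, 0.6, 1.4)
    truth <- gluGroundTruth(N, c(x = p), q = q, bMax = 6)
    a <- sampleAmplitudes(truth, "x", 2e4, 0.1)
    mm <- predictAmplitudeDensity(N, p, q, 0.1, bMax = 6)
    xs <- sort(a)
    ks <- max(abs(ecdf(a)(xs) - quantalglu:::.mixtureCdf(mm, xs)))
    expect_lt(ks, 0.02)
  }
})

test_that("the RMS score behaves like a per-bin count error", {
  mm <- predictAmplitudeDensity(3, 0.5, 0.84, noise = 0.08, bMax = 6)
  h <- amplitudeHistogram(sampleAmplitudes(gluGroundTruth(3, c(x = 0.5)),
                                           "x", 500, 0.08, seed = 21),
                          0.08)
  # histogram equal to the expected counts scores zero
  expCounts <- diff(quantalglu:::.mixtureCdf(mm, h$edges)) * 500
  expect_equal(scoreFit(mm, expCounts, h$edges), 0, tolerance = 1e-6)
  # one extra count in a far-tail bin scores ~ 1/sqrt(nbins); the
  # count rescaling adds a small O(sum of squared bin masses) term
  plus <- expCounts
  plus[1] <- plus[1] + 1
  expect_equal(scoreFit(mm, plus, h$edges), 1 / sqrt(length(plus)),
               tolerance = 0.05)
  expect_error(scoreFit(mm, plus, h$edges[-1]), "binning")
})

test_that("joint grid search recovers the generating parameters", {
  truth <- gluGroundTruth()      # N = 3, q = 0.84, p 0.08 / 0.79
  for (r in 1:3) {
    b <- sampleBouton(truth, n = 300, sigma0 = 0.08, seed = 30 + r)
    fit <- fitQuantalModel(b$amps, b$noise)
    expect_identical(nDocked(fit), 3L)
    expect_lt(abs(quantalSize(fit) - 0.84), 0.1)
    expect_lt(abs(pVes(fit, "4mM") - 0.79), 0.1)
    expect_lt(abs(pVes(fit, "1mM") - 0.08), 0.05)
    expect_lte(fit@parsimonyMargin, 0.02)
  }
})

test_that("a single-vesicle synapse is not inflated by the fitter", {
  truth <- gluGroundTruth(nDocked = 1, q = 0.9,
                          pVes = c("1mM" = 0.1, "4mM" = 0.8))
  hits <- 0
  for (r in 1:5) {
    b <- sampleBouton(truth, n = 300, sigma0 = 0.08, seed = 40 + r)
    if (nDocked(fitQuantalModel(b$amps, b$noise)) == 1L) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("the parsimony rule resolves the saturated identifiability limit", {
  # pVes = 1, noise off: a single spike at A(N); any (N', q') with
  # A'(N') = A(N) fits equally, the rule returns the smallest N' --
  # here N' = 1 with q' = A(3) = 1.68 on the grid
  aN <- amplitudeFromVesicles(3, 0.84, 6)
  amps <- list(hi = rep(aN, 200), lo = rep(aN, 200))
  nm <- list(hi = 0.05, lo = 0.05)
  fit <- fitQuantalModel(amps, nm)
  expect_identical(nDocked(fit), 1L)
  expect_equal(quantalSize(fit), aN, tolerance = 0.011)
  # determinism: identical inputs give the identical fit
  fit2 <- fitQuantalModel(amps, nm)
  expect_identical(nDocked(fit), nDocked(fit2))
  expect_identical(quantalSize(fit), quantalSize(fit2))
  expect_identical(pVes(fit), pVes(fit2))
})

test_that("grid search agrees with a brute-force likelihood oracle", {
  # tiny samples, small grid shared by both routes
  grid <- quantalGrid(nRange = c(1, 5), pStep = 0.02,
                      qRange = c(0.6, 1.2), qStep = 0.05)
  truth <- gluGroundTruth(nDocked = 3, q = 0.9,
                          pVes = c("1mM" = 0.15, "4mM" = 0.75))
  agree <- 0
  for (r in 1:8) {
    b <- sampleBouton(truth, n = 30, sigma0 = 0.04, seed = 50 + r)
    fit <- fitQuantalModel(b$amps, b$noise, grid = grid, binWidth = 0.1)
    ml <- quantalglu:::.gridSearchLikelihood(b$amps, b$noise,
                                            names(b$amps), grid, 6)
    if (fit@nDocked == ml$n) agree <- agree + 1
  }
  expect_gte(agree, 7)
})

test_that("fits are robust to the histogram bin width", {
  truth <- gluGroundTruth()
  b <- sampleBouton(truth, n = 300, sigma0 = 0.08, seed = 60)
  f1 <- fitQuantalModel(b$amps, b$noise, binWidth = 0.1)
  f2 <- fitQuantalModel(b$amps, b$noise, binWidth = 0.05)
  expect_lte(abs(nDocked(f1) - nDocked(f2)), 1)
  expect_lte(abs(quantalSize(f1) - quantalSize(f2)), 0.03)
  expect_lte(max(abs(pVes(f1) - pVes(f2))), 0.03)
})

test_that("fits are robust to the exact saturation asymptote", {
  truth <- gluGroundTruth()
  qerr <- matrix(NA, 3, 2)
  for (r in 1:3) {
    b <- sampleBouton(truth, n = 300, sigma0 = 0.08, seed = 70 + r)
    fTrue <- fitQuantalModel(b$amps, b$noise, bMax = 6)
    fLow <- fitQuantalModel(b$amps, b$noise, bMax = 4.4)
    fAlt <- fitQuantalModel(b$amps, b$noise, bMax = 7)
    qerr[r, ] <- c(abs(quantalSize(fTrue) - 0.84),
                   abs(quantalSize(fLow) - 0.84))
    # between bMax 6 and 7 the recovered parameters barely move
    expect_lte(abs(nDocked(fTrue) - nDocked(fAlt)), 1)
    expect_lte(abs(quantalSize(fTrue) - quantalSize(fAlt)), 0.05)
    expect_lte(max(abs(pVes(fTrue) - pVes(fAlt))), 0.05)
  }
  # the generating asymptote recovers q better than the sensor-intrinsic
  # value (RMSE over replicates)
  expect_lt(sqrt(mean(qerr[, 1]^2)), sqrt(mean(qerr[, 2]^2)))
})

test_that("quantal size estimators from independent datasets agree", {
  # low-p route: successes are mostly univesicular
  lows <- lapply(1:5, function(b) {
    tr <- gluGroundTruth(pVes = c("1mM" = 0.08, "4mM" = 0.79))
    set.seed(80 + b)
    a <- sampleAmplitudes(tr, "1mM", 300, 0.08)
    lab <- ifelse(a > 2 * 0.08, "success", "failure")
    new("AmplitudeSet",
        table = data.frame(condition = "1mM", trial = seq_along(a),
                           amplitude = a, label = lab),
        noise = list("1mM" = new("NoiseModel", sigma0 = 0.08,
                                 fwhm = 0.19, n = 300L)),
        templateTau = 40, bleachTau = c("1mM" = Inf), roi = 1L,
        psyn = c("1mM" = mean(lab == "success")),
        ppr = c("1mM" = NA_real_))
  })
  qLow <- estimateQLowP(lows)
  expect_lt(abs(qLow - 0.84) / 0.84, 0.1)
  # single bouton whose successes all equal q gives exactly q
  one <- lows[[1]]
  one@table$amplitude[one@table$label == "success"] <- 0.77
  expect_equal(as.numeric(estimateQLowP(one)), 0.77)
  # multivesicular contamination biases the estimate upward at high p
  hi <- lows[[1]]
  set.seed(86)
  aHi <- sampleAmplitudes(gluGroundTruth(pVes = c("1mM" = 0.6)),
                          "1mM", 300, 0.08)
  hi@table$amplitude <- aHi
  hi@table$label <- ifelse(aHi > 0.16, "success", "failure")
  hi@psyn <- c("1mM" = 0.45)   # nominally qualifying
  expect_gt(as.numeric(estimateQLowP(hi)), qLow)
  expect_error(estimateQLowP(lows[[2]], maxPsyn = 0), "not applicable")
})

test_that("synaptic strength accessors reproduce the defining product", {
  b <- sampleBouton(gluGroundTruth(), n = 300, sigma0 = 0.08, seed = 90)
  fit <- fitQuantalModel(b$amps, b$noise)
  for (cc in c("1mM", "4mM"))
    expect_equal(unname(synapticStrength(fit, cc)),
                 nDocked(fit) * unname(pVes(fit, cc)) * quantalSize(fit))
})
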