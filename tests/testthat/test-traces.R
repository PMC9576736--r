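tplDefault <- function(nLines = 44) defaultTemplate(40, nLines, 30, 500)

test_that("dynamic ROI recovers the release site and carries over", {
  acq <- quietAcq(sigma0 = 0)
  m <- synthesizeTrial(1.5, acq, 1)
  sel <- selectDynamicRoi(m, 30)
  expect_identical(sel$positions, defaultSite)
  expect_identical(sel$provenance, "current-trial")
  # pure-noise trial reuses the last success ROI
  set.seed(1)
  mn <- synthesizeTrial(0, quietAcq(sigma0 = 0.1), 1)
  sel2 <- selectDynamicRoi(mn, 30, lastSuccessRoi = defaultSite)
  expect_identical(sel2$positions, defaultSite)
  expect_identical(sel2$provenance, "carried-from-last-success")
  # without any prior success, all columns
  sel3 <- selectDynamicRoi(mn, 30)
  expect_identical(sel3$positions, 1:64)
  expect_error(selectDynamicRoi(matrix(1, 1, 1), 1), "malformed|post")
})

test_that("ROI-based amplitudes beat whole-matrix averages in SNR", {
  acq <- quietAcq(sigma0 = 0.1, nTrials = 200)
  truth <- gluGroundTruth(pVes = c(hi = 0.95))
  ses <- synthesizeSession(truth, acq, seed = 2)
  tpl <- tplDefault()
  mats <- lapply(trialMatrices(ses, "hi"),
                 function(m) m / mean(m[1:29, ]))
  aRoi <- vapply(mats, function(m) fitAmplitude(m, defaultSite, tpl), 1)
  aAll <- vapply(mats, function(m) fitAmplitude(m, 1:64, tpl), 1)
  snr <- function(a) mean(a) / sd(a)
  expect_gt(snr(aRoi), snr(aAll))
})

test_that("baseline noise estimation recovers the generator sigma0", {
  acq <- quietAcq(sigma0 = 0.1, nTrials = 200)
  ses <- synthesizeSession(gluGroundTruth(), acq, conditions = "1mM",
                           seed = 3)
  nm <- estimateBaselineNoise(trialMatrices(ses, "1mM"), defaultSite,
                              tplDefault())
  expect_lt(abs(sigma0(nm) - 0.1) / 0.1, 0.15)
  # FWHM/sigma identity for Gaussian noise (larger sample: the width
  # estimator's own sampling error must sit well inside the 5% band)
  acqBig <- quietAcq(sigma0 = 0.1, nTrials = 1000)
  sesBig <- synthesizeSession(gluGroundTruth(), acqBig,
                              conditions = "1mM", seed = 31)
  nmBig <- estimateBaselineNoise(trialMatrices(sesBig, "1mM"),
                                 defaultSite, tplDefault())
  expect_lt(abs(baselineFwhm(nmBig) / sigma0(nmBig) - 2.3548),
            0.05 * 2.3548)
  # noise-free trials give sigma0 ~ 0
  acq0 <- quietAcq(sigma0 = 0, nTrials = 25)
  ses0 <- synthesizeSession(gluGroundTruth(), acq0, conditions = "1mM",
                            seed = 4)
  nm0 <- estimateBaselineNoise(trialMatrices(ses0, "1mM"), defaultSite,
                               tplDefault())
  expect_lt(sigma0(nm0), 1e-6)
  expect_error(estimateBaselineNoise(trialMatrices(ses0, "1mM")[1:5],
                                     defaultSite, tplDefault()),
               "insufficient")
})

test_that("bouton QC applies the 0.4 FWHM rule with strict inequality", {
  mk <- function(f) new("NoiseModel", sigma0 = f / 2.3548, fwhm = f,
                        n = 100L)
  expect_true(qcBouton(mk(0.39)))
  expect_true(qcBouton(mk(0.40)))   # boundary passes: only > 0.4 rejected
  expect_false(qcBouton(mk(0.41)))
})

test_that("noisy boutons are rejected by the FWHM rule", {
  # sigma0 = 0.2 puts the baseline FWHM around 0.47
  acq <- quietAcq(sigma0 = 0.2, nTrials = 100)
  nFail <- 0
  for (b in 1:12) {
    ses <- synthesizeSession(gluGroundTruth(), acq, conditions = "1mM",
                             seed = 100 + b)
    nm <- estimateBaselineNoise(trialMatrices(ses, "1mM"), defaultSite,
                                tplDefault())
    if (!qcBouton(nm)) nFail <- nFail + 1
  }
  expect_gte(nFail, 11)
})

test_that("bleach correction flattens failure baselines and fixes bias", {
  truth <- gluGroundTruth(pVes = c(mid = 0.45))
  acq <- acquisitionParams(nTrials = 300, sigma0 = 0.06, bleachTau = 150,
                           artifactRate = 0)
  ses <- synthesizeSession(truth, acq, seed = 5)
  mats <- trialMatrices(ses, "mid")
  labels <- ifelse(trueCounts(ses, "mid") > 0, "success", "failure")
  bc <- correctBleach(mats, labels, 30)
  # recovered bleach constant within 20%
  expect_lt(abs(bc$bleachTau - 150) / 150, 0.2)
  # corrected failure-F0 slope reduced at least 10-fold
  f0raw <- vapply(mats, function(m) mean(m[1:29, ]), 1)
  f0cor <- vapply(bc$mats, function(m) mean(m[1:29, ]), 1)
  fails <- labels == "failure"
  slope <- function(y) abs(coef(lm(y ~ seq_along(y)))[2])
  expect_lt(slope(f0cor[fails]), slope(f0raw[fails]) / 10)
  # infinite bleach tau: correction factor ~ 1 everywhere
  acq2 <- quietAcq(nTrials = 60, sigma0 = 0.05)
  ses2 <- synthesizeSession(truth, acq2, seed = 6)
  lab2 <- ifelse(trueCounts(ses2, "mid") > 0, "success", "failure")
  bc2 <- correctBleach(trialMatrices(ses2, "mid"), lab2, 30)
  expect_true(all(abs(bc2$factors - 1) < 0.01))
  expect_error(correctBleach(mats[1:4], rep("failure", 4), 30),
               "5 failure")
})

test_that("late success amplitudes are unbiased only after correction", {
  truth <- gluGroundTruth(pVes = c(mid = 0.5))
  acq <- acquisitionParams(nTrials = 300, sigma0 = 0.06, bleachTau = 150,
                           artifactRate = 0)
  ses <- synthesizeSession(truth, acq, seed = 7)
  fitSlope <- function(bleachCorrect) {
    amps <- processSession(ses, bleachCorrect = bleachCorrect)
    tab <- amplitudes(amps)
    ok <- tab$label == "success"
    coef(summary(lm(amplitude ~ trial, tab[ok, ])))["trial", ]
  }
  on <- fitSlope(TRUE)
  off <- fitSlope(FALSE)
  # corrected: slope CI contains 0; uncorrected: significantly negative
  expect_gt(on["Pr(>|t|)"], 0.01)
  expect_lt(off["Estimate"] + 2 * off["Std. Error"], 0)
})

test_that("template construction recovers the decay constant", {
  # 64-line acquisition so the fit window spans enough of the decay
  acq <- quietAcq(sigma0 = 0.05, kernelTau = 50, nLines = 64)
  set.seed(8)
  traces <- lapply(1:20, function(i)
    rowMeans(synthesizeTrial(1.0, acq, 1)[, defaultSite]))
  tpl <- buildTemplate(traces, 30, 500, kLargest = 20)
  expect_lt(abs(tpl$tau - 50) / 50, 0.1)
  # noiseless single success: residual-free fit at the exact amplitude
  acq0 <- quietAcq(sigma0 = 0)
  m <- synthesizeTrial(1.3, acq0, 1)
  tr <- rowMeans(m[, defaultSite])
  tpl0 <- buildTemplate(list(tr), 30, 500)
  expect_lt(abs(tpl0$tau - 40) / 40, 1e-3)
  expect_equal(fitAmplitude(m, defaultSite, tpl0), 1.3, tolerance = 1e-6)
  # kLargest larger than available successes: uses all
  expect_silent(buildTemplate(traces[1:3], 30, 500, kLargest = 10))
  expect_error(buildTemplate(list(), 30, 500), "no-template")
})

test_that("the amplitude estimator is exact, linear and calibrated", {
  acq0 <- quietAcq(sigma0 = 0)
  tpl <- tplDefault()
  m1 <- synthesizeTrial(0.84, acq0, 1)
  expect_equal(fitAmplitude(m1, defaultSite, tpl), 0.84)
  m2 <- synthesizeTrial(1.68, acq0, 1)
  expect_equal(fitAmplitude(m2, defaultSite, tpl),
               2 * fitAmplitude(m1, defaultSite, tpl))
  # null calibration: mean 0, SD = sigma0
  acq <- quietAcq(sigma0 = 0.1)
  set.seed(9)
  a0 <- vapply(1:800, function(i)
    fitAmplitude(synthesizeTrial(0, acq, 1), defaultSite, tpl), 1.0)
  expect_lt(abs(mean(a0)), 3 * 0.1 / sqrt(800))
  expect_lt(abs(sd(a0) - 0.1) / 0.1, 0.1)
})

test_that("the 2-sigma classifier separates successes from failures", {
  nm <- new("NoiseModel", sigma0 = 0.1, fwhm = 0.2355, n = 100L)
  expect_identical(classifyTrial(0.201, nm), "success")
  expect_identical(classifyTrial(0.199, nm), "failure")
  # end-to-end agreement with the ledger at q/sigma0 > 5
  acq <- acquisitionParams(nTrials = 200, sigma0 = 0.08)
  ses <- synthesizeSession(gluGroundTruth(), acq, seed = 10)
  amps <- processSession(ses)
  tab <- amplitudes(amps)
  ok <- tab$label != "rejected"
  agree <- mean((tab$label[ok] == "success") == (tab$trueK[ok] > 0))
  expect_gte(agree, 0.95)
})

test_that("p_syn is monotone in pVes and in N", {
  psynAt <- function(N, p, seed) {
    truth <- gluGroundTruth(nDocked = N, pVes = c(x = p))
    ses <- synthesizeSession(truth, quietAcq(nTrials = 150, sigma0 = 0.08),
                             seed = seed)
    pSyn(processSession(ses))[["x"]]
  }
  sweepP <- vapply(c(0.1, 0.4, 0.8), function(p) psynAt(3, p, 11), 1.0)
  expect_true(all(diff(sweepP) > 0))
  sweepN <- vapply(c(1, 3, 6), function(N) psynAt(N, 0.3, 12), 1.0)
  expect_true(all(diff(sweepN) > 0))
})

test_that("amplitude estimates are unbiased per vesicle count", {
  acq <- acquisitionParams(nTrials = 400, sigma0 = 0.08)
  ses <- synthesizeSession(gluGroundTruth(), acq, seed = 13)
  tab <- amplitudes(processSession(ses))
  ok <- tab$label != "rejected" & !is.na(tab$trueK)
  for (k in sort(unique(tab$trueK[ok]))) {
    a <- tab$amplitude[ok & tab$trueK == k]
    if (length(a) < 20) next
    expect_lt(abs(mean(a) - amplitudeFromVesicles(k, 0.84, 6)),
              3 * sd(a) / sqrt(length(a)))
  }
})

test_that("trial-F0 QC removes elevated-F0 artifacts", {
  acq <- acquisitionParams(nTrials = 400, artifactRate = 0.05,
                           artifactFactor = 2, bleachTau = Inf,
                           sigma0 = 0.1)
  ses <- synthesizeSession(gluGroundTruth(), acq, conditions = "1mM",
                           seed = 14)
  keep <- qcF0(trialMatrices(ses, "1mM"), 30)
  art <- ses@ledger$artifact
  expect_gte(mean(!keep[art]), 0.95)           # sensitivity
  frac <- mean(!keep)
  expect_lt(abs(frac - 0.05), 0.03)            # overall rejected fraction
  # homogeneous noiseless session: everything kept
  ses0 <- synthesizeSession(gluGroundTruth(),
                            quietAcq(nTrials = 25, sigma0 = 0),
                            conditions = "1mM", seed = 15)
  expect_true(all(qcF0(trialMatrices(ses0, "1mM"), 30)))
})

test_that("p_syn arithmetic and the paired-pulse ratio", {
  tab <- data.frame(condition = "c", trial = 1:100,
                    amplitude = c(rep(1, 26), rep(0, 74)),
                    label = c(rep("success", 26), rep("failure", 74)))
  expect_equal(unname(computePsynPpr(tab)$psyn), 0.26)
  # identical pulse amplitudes give PPR = 100%
  tab$amplitude2 <- tab$amplitude
  expect_equal(unname(computePsynPpr(tab, paired = TRUE)$ppr), 100)
  expect_error(computePsynPpr(tab[tab$label == "rejected", ]), "usable")
  # generator draws pulses independently: no depression, PPR ~ 100%
  acq <- acquisitionParams(nTrials = 150, nLines = 64, sigma0 = 0.08,
                           pairedPulse = TRUE, artifactRate = 0,
                           bleachTau = Inf)
  ses <- synthesizeSession(gluGroundTruth(pVes = c(hi = 0.79)), acq,
                           seed = 16)
  amps <- processSession(ses)
  expect_lt(abs(amps@ppr[["hi"]] - 100), 12)
})
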