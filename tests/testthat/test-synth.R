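test_that("release outcomes follow binomial statistics", {
  truth <- gluGroundTruth(nDocked = 5, pVes = c(lo = 0.42))
  k <- drawReleaseOutcomes(truth, "lo", 2e4, seed = 1)
  expect_true(all(k >= 0 & k <= 5))
  # failure fraction at N = 5, p = 0.42 is (1 - 0.42)^5
  p0 <- 0.58^5
  se <- sqrt(p0 * (1 - p0) / 2e4)
  expect_lt(abs(mean(k == 0) - p0), 3 * se)
  # single-vesicle mean at p = 0.5
  t1 <- gluGroundTruth(nDocked = 1, pVes = c(lo = 0.5))
  k1 <- drawReleaseOutcomes(t1, "lo", 1e5, seed = 2)
  expect_lt(abs(mean(k1) - 0.5), 3 * 0.5 / sqrt(1e5))
  # degenerate always-release case
  t2 <- gluGroundTruth(nDocked = 3, pVes = c(lo = 1))
  expect_true(all(drawReleaseOutcomes(t2, "lo", 50, seed = 3) == 3L))
  expect_error(drawReleaseOutcomes(truth, "nope", 10), "unknown condition")
})

test_that("saturated amplitude mapping matches the hyperbolic model", {
  expect_equal(amplitudeFromVesicles(0, 0.88, 6), 0)
  expect_equal(amplitudeFromVesicles(1, 0.88, 6), 0.88)  # A(1) = q
  # half-saturation at the continuous extension k = Kd
  kd <- 6 / 0.88 - 1
  expect_equal(amplitudeFromVesicles(kd, 0.88, 6), 3)
  # strictly increasing and concave
  a <- amplitudeFromVesicles(0:10, 0.88, 6)
  expect_true(all(diff(a) > 0))
  expect_true(all(diff(diff(a)) < 0))
  expect_equal(a, oracleSaturation(0:10, 0.88, 6))
  expect_error(amplitudeFromVesicles(1, 6, 6), "invalid saturation")
  expect_error(amplitudeFromVesicles(-1, 0.88, 6), ">= 0")
})

test_that("noiseless trials realize the forward model exactly", {
  acq <- quietAcq(sigma0 = 0)
  m <- synthesizeTrial(2 * 0.84, acq, trialIndex = 1)
  tr <- rowMeans(m[, defaultSite]) - 1
  expect_equal(max(tr), 2 * 0.84)            # peak = amplitude * max kernel
  expect_equal(which.max(tr), 30L)           # at the onset line
  expect_true(all(abs(tr[1:29]) < 1e-12))    # zero expected pre-stimulus
  # signal confined to the release-site block
  outside <- m[, setdiff(1:64, defaultSite)]
  expect_true(all(abs(outside - 1) < 1e-12))
})

test_that("failure trials carry no stimulus-locked change", {
  acq <- quietAcq(sigma0 = 0.1)
  set.seed(4)
  nRej <- 0
  for (i in 1:200) {
    m <- synthesizeTrial(0, acq, 1)
    z <- t.test(colMeans(m[1:29, ]), colMeans(m[30:44, ]))$p.value
    if (z < 0.01) nRej <- nRej + 1
  }
  # two-sample test at alpha = 0.01 should pass for ~99% of trials
  expect_lte(nRej, 8)
})

test_that("bleaching follows the configured monoexponential", {
  acq <- quietAcq(sigma0 = 0.05, bleachTau = 300, nTrials = 150)
  set.seed(5)
  f0 <- vapply(1:150, function(i)
    mean(synthesizeTrial(0, acq, trialIndex = i)[1:29, ]), 1.0)
  fit <- coef(lm(log(f0) ~ seq_along(f0)))
  expect_lt(abs(-1 / fit[2] - 300) / 300, 0.2)
})

test_that("pixel variance scales linearly with expected photon count", {
  acq <- quietAcq(sigma0 = 0.08)
  set.seed(6)
  reps <- lapply(1:200, function(i) synthesizeTrial(3, acq, 1))
  arr <- simplify2array(reps)
  mu <- apply(arr, c(1, 2), mean)
  vv <- apply(arr, c(1, 2), var)
  sl <- coef(lm(log(as.vector(vv)) ~ log(as.vector(mu))))[2]
  expect_lt(abs(sl - 1), 0.05)
})

test_that("sessions are reproducible bit-exactly under a fixed seed", {
  truth <- gluGroundTruth()
  acq <- acquisitionParams(nTrials = 10)
  s1 <- synthesizeSession(truth, acq, seed = 11)
  s2 <- synthesizeSession(truth, acq, seed = 11)
  expect_identical(trialMatrices(s1), trialMatrices(s2))
  expect_identical(s1@ledger, s2@ledger)
})

test_that("session composition respects the ledger and edge cases", {
  truth <- gluGroundTruth()
  # empty session is a valid container
  s0 <- synthesizeSession(truth, quietAcq(nTrials = 0), seed = 1)
  expect_s4_class(s0, "GluSession")
  expect_equal(nrow(s0@ledger), 0)
  # pVes = 1, noise off: every amplitude equals A(N)
  t1 <- gluGroundTruth(pVes = c(hi = 1))
  s1 <- synthesizeSession(t1, quietAcq(nTrials = 5, sigma0 = 0), seed = 2)
  expect_true(all(s1@ledger$amplitude ==
                    amplitudeFromVesicles(3, 0.84, 6)))
  # success rates match 1 - (1 - p)^N within binomial SE
  acq <- quietAcq(nTrials = 4000)
  ses <- synthesizeSession(truth, acq, seed = 3)
  for (cc in c("1mM", "4mM")) {
    ps <- 1 - (1 - pVes(truth, cc))^3
    emp <- mean(trueCounts(ses, cc) > 0)
    expect_lt(abs(emp - ps), 3 * sqrt(ps * (1 - ps) / 4000))
  }
})

test_that("artifact trials are injected at the configured rate", {
  acq <- acquisitionParams(nTrials = 2000, artifactRate = 0.05,
                           bleachTau = Inf)
  ses <- synthesizeSession(gluGroundTruth(), acq, conditions = "1mM",
                           seed = 7)
  r <- mean(ses@ledger$artifact)
  expect_lt(abs(r - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  # artifact trials have elevated F0
  f0 <- vapply(trialMatrices(ses, "1mM"), function(m) mean(m[1:29, ]), 1)
  expect_gt(min(f0[ses@ledger$artifact]), max(f0[!ses@ledger$artifact]))
})

test_that("frame-scan stacks realize the imaging model", {
  # amplitude 0: difference image has zero mean
  st0 <- synthesizeFrameScanStack(c(1.6, 1.6), 0, sigmaPx = 0.1, seed = 8)
  expect_lt(abs(mean(differenceMap(st0))), 5e-3)
  # noise off: argmax of the difference image at the center pixel
  st <- synthesizeFrameScanStack(c(1.55, 1.75), 1, sigmaPx = 0)
  ij <- arrayInd(which.max(differenceMap(st)), c(32, 32))
  expect_equal(as.vector(ij), c(16, 18))   # pixel containing (1.55, 1.75)
  expect_error(synthesizeFrameScanStack(c(-1, 1), 1), "outside")
})
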