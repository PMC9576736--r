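# Reduced Brownian-dynamics simulation of cleft glutamate and the
# sensor-saturation analysis built on it. Small run counts here; the
# published-scale saturation experiment lives in the acceptance suite.

fastConfig <- function(...) cleftConfig(maxSteps = 2500L, ...)

test_that("geometry discretization and receptor counts are consistent", {
  cfg <- cleftConfig()
  geo <- buildCleftGeometry(cfg)
  # 1200 um^-2 on a 300 nm disc gives ~85 receptors
  expect_equal(geo$nAmpar, 85)
  # sensor count tracks density * membrane area within discretization
  on <- geo$cells$region != "off"
  areaMembrane <- sum(on) * geo$cellSize^2
  areaExpected <- 2 * pi * (cfg$boutonRadius * cfg$boutonLength +
                            cfg$axonRadius * (cfg$axonLength -
                                              cfg$boutonLength))
  expect_lt(abs(areaMembrane - areaExpected) / areaExpected, 0.05)
  # PSF weights are in (0, 1], maximal near the cleft center
  expect_true(all(geo$cells$w[on] > 0 & geo$cells$w[on] <= 1))
  expect_identical(geo$cells$region[which.max(geo$cells$w)], "cleft")
  expect_error(buildCleftGeometry(cfg, tiltSpine = 75), "invalid tilt")
})

test_that("free Brownian displacement obeys the diffusion law", {
  set.seed(1)
  pos <- quantalglu:::.freeDiffusionC(10000L, 50L, 200, 2e-7)
  msd <- mean(rowSums(pos^2))
  expect_lt(abs(msd - 6 * 200 * 50 * 2e-7) / (6 * 200 * 50 * 2e-7), 0.02)
})

test_that("the stepper refuses an unstable time step", {
  expect_error(cleftConfig(dt = 1e-5), "stability")
})

test_that("degenerate inputs give identically zero signals", {
  cfg <- fastConfig()
  s0 <- runCleftSim(cfg, 0, seed = 2)
  expect_equal(s0$peak, 0)
  expect_true(all(s0$dff$dff == 0))
  sD <- runCleftSim(cleftConfig(sensorDensity = 0, maxSteps = 500L), 1,
                    seed = 3)
  expect_equal(sD$peak, 0)
  # injection bookkeeping: 1 vesicle = 3000 molecules, 15 = 45000
  expect_equal(nrow(injectVesicles(1, cfg)), 3000)
  expect_equal(nrow(injectVesicles(15, cfg)), 45000)
  expect_equal(nrow(injectVesicles(0, cfg)), 0)
})

test_that("glutamate is conserved and leaves the cleft within 100 us", {
  cfg <- fastConfig()
  sim <- runCleftSim(cfg, 1, seed = 4)
  expect_true(sim$conserved)
  cnt <- sim$counts
  expect_true(all(abs(cnt$free + cnt$dim + cnt$bright + cnt$removed -
                        sim$nInjected) <= sim$nBound))
  expect_equal(sim$nBound + sim$nCaptured + sim$nEscaped, sim$nInjected)
  # >90% of the released glutamate has left the cleft cylinder at
  # least once within 100 us (first passage; the flattened slab lets
  # molecules re-enter more often than the open 3D geometry would)
  at100 <- max(which(sim$counts$t <= 1e-4))
  expect_gt(sim$counts$everLeftCleft[at100], 0.9 * sim$nInjected)
})

test_that("runs are bit-reproducible under a fixed seed", {
  cfg <- fastConfig()
  s1 <- runCleftSim(cfg, 2, seed = 5)
  s2 <- runCleftSim(cfg, 2, seed = 5)
  expect_identical(s1$peak, s2$peak)
  expect_identical(s1$bindings, s2$bindings)
})

test_that("with immobile glutamate no binding occurs after injection", {
  cfg <- cleftConfig(D = 0, maxSteps = 200L)
  sim <- runCleftSim(cfg, 1, seed = 6)
  expect_equal(sim$nBound, 0)
  expect_equal(sim$counts$free[nrow(sim$counts)], 3000)
})

test_that("peak response saturates with vesicle count", {
  cfg <- fastConfig()
  df <- runSaturationExperiment(cfg, nVesList = c(1, 3, 6, 10), runs = 4,
                                seed = 7)
  mp <- tapply(df$peak, df$nVes, mean)
  expect_true(all(diff(mp) > 0))                  # increasing
  # concave: quantal spacing compresses at high counts
  expect_gt((mp[2] - mp[1]) / 2, (mp[4] - mp[3]) / 4)
  # peaks stay below the sensor-intrinsic ceiling
  expect_true(all(df$peak < 4.4))
  # run-to-run variability shrinks with vesicle count
  cv <- tapply(df$peak, df$nVes, sd) / mp
  expect_gt(cv[1], cv[4])
})

test_that("the fluorescence readout respects the sensor ceiling", {
  cfg <- cleftConfig()
  geo <- buildCleftGeometry(cfg)
  on <- geo$cells$region != "off"
  w <- geo$cells$w[on]
  # all sensors bright: dF/F0 equals the contrast everywhere in time
  rd <- readoutDff(rep(0, length(w)), rep(Inf, length(w)), w,
                   geo$wTotal, contrast = 4.4, tGrid = c(0, 1e-3, 5e-3))
  expect_equal(rd$dff, rep(4.4, 3))
  # no bright sensors: zero
  rd0 <- readoutDff(numeric(0), numeric(0), numeric(0), geo$wTotal,
                    tGrid = c(0, 1e-3))
  expect_equal(rd0$dff, c(0, 0))
})

test_that("restricting the PSF to the cleft increases the relative signal", {
  cfg <- fastConfig()
  geoWide <- buildCleftGeometry(cfg)
  geoTight <- buildCleftGeometry(cleftConfig(psfFwhmLateral = 0.15,
                                             psfFwhmAxial = 0.4))
  sim <- runCleftSim(cfg, 3, seed = 8, geometry = geoWide)
  peakFor <- function(geo) {
    w <- geo$cells$w[match(sim$bindings$cell, geo$cells$id)]
    set.seed(9)
    tOn <- sim$bindings$time + rexp(nrow(sim$bindings), cfg$kIso)
    tOff <- tOn + rexp(nrow(sim$bindings), cfg$kRev)
    ev <- order(c(tOn, tOff))
    cfg$contrast * max(cumsum(c(w, -w)[ev])) / geo$wTotal
  }
  expect_gt(peakFor(geoTight), peakFor(geoWide))
})

test_that("hyperbolic saturation fits are exact on hyperbolic input", {
  n <- 1:15
  sc <- fitSaturation(n, 5.9 * n / (6.5 + n))
  expect_equal(bMax(sc), 5.9, tolerance = 1e-6)
  expect_equal(kD(sc), 6.5, tolerance = 1e-6)
  expect_error(fitSaturation(1:3, c(1, 2, 3)), "4 distinct")
})

test_that("apparent affinity falls as extrasynaptic sensors enter the PSF", {
  # 3-point PSF ladder sharing one set of binding realizations
  cfg <- fastConfig()
  geos <- lapply(c(0.8, 1.6, 2.4), function(fa)
    buildCleftGeometry(cleftConfig(psfFwhmAxial = fa)))
  counts <- c(1, 2, 4, 7, 11, 15)
  peaks <- array(0, c(length(geos), length(counts), 3))
  set.seed(10)
  for (j in seq_along(counts)) for (r in 1:3) {
    sim <- runCleftSim(cfg, counts[j], geometry = buildCleftGeometry(cfg))
    nb <- nrow(sim$bindings)
    tOn <- sim$bindings$time + rexp(nb, cfg$kIso)
    tOff <- tOn + rexp(nb, cfg$kRev)
    ev <- order(c(tOn, tOff))
    for (g in seq_along(geos)) {
      w <- geos[[g]]$cells$w[match(sim$bindings$cell,
                                   geos[[g]]$cells$id)]
      peaks[g, j, r] <- cfg$contrast * max(cumsum(c(w, -w)[ev])) /
        geos[[g]]$wTotal
    }
  }
  kds <- vapply(seq_along(geos), function(g)
    kD(fitSaturation(counts, rowMeans(peaks[g, , , drop = FALSE][1, , ]))),
    1.0)
  # wider axial PSF = larger extrasynaptic fraction = larger apparent Kd
  expect_true(all(diff(kds) > 0))
})

test_that("the optional receptor channel responds to cleft glutamate", {
  cfg <- fastConfig()
  sim <- runCleftSim(cfg, 5, seed = 11)
  occ <- amparOccupancy(sim, cfg)
  expect_true(all(occ$occupancy >= 0 & occ$occupancy <= 1))
  expect_gt(max(occ$occupancy), 0)
  # occupancy rises then falls as glutamate clears
  expect_lt(occ$occupancy[nrow(occ)], max(occ$occupancy))
})
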