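## MODULE cleft -- reduced Monte Carlo simulation of vesicular glutamate
## release, diffusion in the cleft, transporter capture and linearized
## sensor response with PSF-weighted dF/F0 readout.

AVOGADRO_UM3 <- 6.02214076e8   # molecules per µM^-1... (1 M in µm^-3)

#' Configuration of the cleft simulation
#'
#' Geometry (axis-aligned reduced model): an axon cylinder (diameter
#' 0.2 um, length 3 um) with a bouton varicosity (diameter 0.5 um,
#' length 0.5 um); the synaptic cleft is a 20 nm gap between the bouton
#' membrane and the spine contact (active zone and PSD as congruent
#' 300 nm discs); the extracellular space around the remaining membrane
#' is bounded at 20 nm by the astrocytic sheath carrying glutamate
#' transporters. Boundary conditions are reflective except for
#' transporter capture and the open axon ends.
#'
#' Kinetics: the two-step sensor scheme is linearized (glutamate
#' binding, then a slower bright-state isomerization at
#' \code{kIso} = 2481 s\eqn{^{-1}} with reversion at \code{kRev} = 111
#' s\eqn{^{-1}}, the cell-based values); the fluorescence change occurs
#' in the isomerization step and full bright occupancy corresponds to
#' the sensor-intrinsic ceiling \code{contrast} = 4.4 \eqn{\Delta
#' F/F_0}. The association rate of the first, rapid binding step is not
#' a published quantity; together with the sensor surface density and
#' the PSF dimensions it is a free parameter, with defaults calibrated
#' once so that the simulated bouton-level saturation curve matches the
#' published hyperbolic fit constants at optimal orientation.
#'
#' @param D glutamate diffusion coefficient, um^2/s.
#' @param moleculesPerVesicle glutamate content of one vesicle
#'   (2000--3000; default 3000).
#' @param gap cleft width, um.
#' @param cleftRadius active-zone/PSD disc radius, um (300 nm
#'   diameter).
#' @param spineRadius radius of the reflective spine contact, um.
#' @param boutonRadius,boutonLength,axonRadius,axonLength cylinder
#'   dimensions, um.
#' @param sensorDensity sensor molecules per um^2 of axonal membrane.
#' @param kOnSensor association rate of the rapid binding step,
#'   M^-1 s^-1.
#' @param kIso,kRev isomerization (dim to bright) and reversion rates,
#'   s^-1.
#' @param contrast \eqn{\Delta F/F_0} at full bright occupancy.
#' @param glutDensity transporter density on the astrocytic sheath,
#'   um^-2.
#' @param kOnGlut transporter association rate, M^-1 s^-1.
#' @param amparDensity AMPA-receptor density on the PSD, um^-2 (the
#'   optional receptor channel; only the receptor count and the
#'   occupancy proxy use it).
#' @param psfFwhmLateral,psfFwhmAxial two-photon PSF dimensions, um.
#' @param tiltSpine,tiltAxon orientation of the synapse relative to the
#'   optical axis, degrees (0--60).
#' @param dt time step, s; must satisfy
#'   \eqn{\sqrt{2 D \, dt} \le gap/2}.
#' @param tEnd readout horizon, s.
#' @param bulkClearTau first-order clearance time constant (s) of
#'   glutamate outside the cleft: beyond the 20 nm astrocytic sheath
#'   the extracellular space opens into three-dimensional tissue where
#'   the transmitter dilutes and is taken up, a pathway the flattened
#'   slab cannot represent geometrically.
#' @param maxSteps diffusion-phase step cap.
#' @return A validated list of class \code{"CleftConfig"}.
#' @export
cleftConfig <- function(D = 200, moleculesPerVesicle = 3000,
                        gap = 0.02, cleftRadius = 0.15,
                        spineRadius = 0.2, boutonRadius = 0.25,
                        boutonLength = 0.5, axonRadius = 0.1,
                        axonLength = 3, sensorDensity = 600,
                        kOnSensor = 1.45e6, kIso = 2481, kRev = 111,
                        contrast = 4.4, glutDensity = 1e4,
                        kOnGlut = 2e7, amparDensity = 1200,
                        psfFwhmLateral = 0.35, psfFwhmAxial = 1.6,
                        tiltSpine = 0, tiltAxon = 0, dt = 2.5e-7,
                        tEnd = 5e-3, bulkClearTau = 6e-4,
                        maxSteps = 3500L) {
  cfg <- list(D = D, moleculesPerVesicle = moleculesPerVesicle, gap = gap,
              cleftRadius = cleftRadius, spineRadius = spineRadius,
              boutonRadius = boutonRadius, boutonLength = boutonLength,
              axonRadius = axonRadius, axonLength = axonLength,
              sensorDensity = sensorDensity, kOnSensor = kOnSensor,
              kIso = kIso, kRev = kRev, contrast = contrast,
              glutDensity = glutDensity, kOnGlut = kOnGlut,
              amparDensity = amparDensity,
              psfFwhmLateral = psfFwhmLateral,
              psfFwhmAxial = psfFwhmAxial, tiltSpine = tiltSpine,
              tiltAxon = tiltAxon, dt = dt, tEnd = tEnd,
              bulkClearTau = bulkClearTau,
              maxSteps = as.integer(maxSteps))
  with(cfg, {
    stopifnot(D >= 0, moleculesPerVesicle >= 0, gap > 0,
              cleftRadius > 0, spineRadius >= cleftRadius,
              sensorDensity >= 0, glutDensity >= 0, dt > 0, tEnd > 0)
    if (sqrt(2 * D * dt) > gap / 2)
      stop("dt violates the stability rule sqrt(2 D dt) <= gap/2",
           call. = FALSE)
  })
  class(cfg) <- "CleftConfig"
  cfg
}

# per-contact reaction probability of a partially absorbing surface
# (Erban-Chapman): P = kappa * sqrt(pi * dt / D), kappa = kOn * rho / N_A
.contactProb <- function(kOn, density, D, dt) {
  if (D <= 0 || density <= 0 || kOn <= 0) return(0)
  kappa <- kOn / AVOGADRO_UM3 * density    # um/s
  min(kappa * sqrt(pi * dt / D), 1)
}

#' Build the discretized cleft geometry and PSF weights
#'
#' Places one sensor per density cell on the flattened axon/bouton
#' membrane, maps every cell back to its 3D position on the cylinder
#' surface (the cleft disc is the contact facet), applies the requested
#' spine/axon tilt, and computes the 3D-Gaussian PSF weight of every
#' sensor. Also reports the AMPA-receptor count implied by the PSD
#' density and disc size.
#'
#' @param config a \code{\link{cleftConfig}}.
#' @param tiltSpine,tiltAxon tilt angles in degrees (default from the
#'   config); allowed range 0--60.
#' @return List: \code{cells} (data.frame with grid indices, flattened
#'   and 3D coordinates, region and PSF weight), \code{nu}, \code{nv},
#'   \code{cellSize}, \code{wTotal}, \code{nAmpar}.
#' @examples
#' geo <- buildCleftGeometry(cleftConfig())
#' geo$nAmpar   # about 85 receptors on the 300 nm PSD disc
#' @export
buildCleftGeometry <- function(config, tiltSpine = config$tiltSpine,
                               tiltAxon = config$tiltAxon) {
  if (tiltSpine < 0 || tiltSpine > 60 || tiltAxon < 0 || tiltAxon > 60)
    stop("invalid tilt: angles must lie in [0, 60] degrees",
         call. = FALSE)
  cs <- 1 / sqrt(config$sensorDensity)
  uMax <- config$axonLength / 2
  vGlobal <- pi * config$boutonRadius
  nu <- ceiling(2 * uMax / cs)
  nv <- ceiling(2 * vGlobal / cs)
  iu <- rep(seq_len(nu) - 1L, times = nv)
  iv <- rep(seq_len(nv) - 1L, each = nu)
  u <- (iu + 0.5) * cs - uMax
  v <- (iv + 0.5) * cs - vGlobal
  R <- ifelse(abs(u) <= config$boutonLength / 2, config$boutonRadius,
              config$axonRadius)
  onMembrane <- abs(v) <= pi * R
  # wrap map to 3D: contact line at v = 0, circle center (u, -R, 0)
  phi <- v / R
  x <- u
  y <- -R + R * cos(phi)
  z <- R * sin(phi)
  # cleft disc is the flat contact facet
  inCleft <- u^2 + v^2 < config$cleftRadius^2
  y[inCleft] <- 0
  z[inCleft] <- v[inCleft]
  # orientation. Axon tilt takes the assembly out of the focal plane
  # (rotation about the in-plane y axis); spine tilt rotates the cleft
  # normal toward the optical axis (rotation about the axon axis), so
  # extrasynaptic tube membrane swings into the PSF while the contact
  # facet rotates partly out of the lateral focus.
  aA <- tiltAxon * pi / 180
  xr <- x * cos(aA) + z * sin(aA)
  zr <- -x * sin(aA) + z * cos(aA)
  x <- xr; z <- zr
  aS <- tiltSpine * pi / 180
  yr <- y * cos(aS) - z * sin(aS)
  zr2 <- y * sin(aS) + z * cos(aS)
  y <- yr; z <- zr2
  sl <- config$psfFwhmLateral / GAUSS_FWHM
  sa <- config$psfFwhmAxial / GAUSS_FWHM
  w <- exp(-(x^2 + y^2) / (2 * sl^2) - z^2 / (2 * sa^2))
  w[!onMembrane] <- 0
  cells <- data.frame(id = iu + nu * iv, iu = iu, iv = iv, u = u, v = v,
                      x = x, y = y, z = z, w = w,
                      region = ifelse(!onMembrane, "off",
                               ifelse(inCleft, "cleft",
                               ifelse(abs(u) <= config$boutonLength / 2,
                                      "bouton", "axon"))))
  list(cells = cells, nu = nu, nv = nv, cellSize = cs,
       uMax = uMax, wTotal = sum(w),
       nAmpar = round(config$amparDensity * pi * config$cleftRadius^2))
}

#' Inject vesicular glutamate
#'
#' Vesicle fusion is modelled as an instantaneous injection of
#' \code{nVesicles * moleculesPerVesicle} point molecules at the center
#' of the active zone (cleft side), all at t = 0 (simultaneous
#' release).
#'
#' @param nVesicles number of simultaneously fusing vesicles.
#' @param config a \code{\link{cleftConfig}}.
#' @return Matrix of initial positions (molecules x 3, flattened
#'   coordinates u, v, z).
#' @export
injectVesicles <- function(nVesicles, config) {
  if (nVesicles < 0) stop("nVesicles must be >= 0", call. = FALSE)
  n <- nVesicles * config$moleculesPerVesicle
  matrix(rep(c(0, 0, config$gap / 2), each = n), ncol = 3,
         dimnames = list(NULL, c("u", "v", "z")))
}

#' Run one cleft release simulation
#'
#' Simulates Brownian diffusion of the injected glutamate in the
#' extracellular slab with reflective walls, per-contact sensor binding
#' (Smoluchowski-consistent probability derived from the association
#' rate and sensor density), transporter capture on the astrocytic
#' sheath, and the dim-to-bright isomerization of bound sensors; then
#' reads out the PSF-weighted \eqn{\Delta F/F_0} time course.
#'
#' @param config a \code{\link{cleftConfig}}.
#' @param nVesicles vesicles released at t = 0.
#' @param seed optional RNG seed.
#' @param geometry optional prebuilt geometry (defaults to
#'   \code{buildCleftGeometry(config)}).
#' @param tGrid time grid (s) for the returned time courses.
#' @return List: \code{peak} (peak \eqn{\Delta F/F_0}), \code{dff}
#'   (data.frame t, dff), \code{counts} (free/cleft/dim/bright/removed
#'   molecule bookkeeping over time), \code{conserved} (exact integer
#'   mass conservation), \code{bindings} (bind time, cell, PSF weight),
#'   \code{amparOccupancy} (optional receptor-channel proxy, see
#'   details in the vignette).
#' @export
runCleftSim <- function(config, nVesicles, seed = NULL, geometry = NULL,
                        tGrid = seq(0, config$tEnd, by = 2e-5)) {
  stopifnot(inherits(config, "CleftConfig"))
  if (is.null(geometry)) geometry <- buildCleftGeometry(config)
  .setSeed(seed)
  n <- nVesicles * config$moleculesPerVesicle
  wTot <- geometry$wTotal
  if (n == 0 || config$sensorDensity == 0) {
    z <- data.frame(t = tGrid, dff = 0)
    return(list(peak = 0, dff = z,
                counts = data.frame(t = tGrid, free = 0, cleft = 0,
                                    dim = 0, bright = 0, removed = 0),
                conserved = TRUE,
                bindings = data.frame(time = numeric(), cell = integer(),
                                      w = numeric()),
                nInjected = n))
  }
  pBind <- .contactProb(config$kOnSensor, config$sensorDensity,
                        config$D, config$dt)
  pCap <- .contactProb(config$kOnGlut, config$glutDensity,
                       config$D, config$dt)
  occ <- integer(geometry$nu * geometry$nv)
  occ[geometry$cells$id[geometry$cells$region == "off"] + 1L] <- -1L
  # transporter capacity per astrocyte-facing cell (finite: GluT do not
  # recycle on the sub-millisecond timescale of the simulation)
  transCap <- rep.int(as.integer(round(config$glutDensity *
                                         geometry$cellSize^2)),
                      geometry$nu * geometry$nv)
  sim <- .cleftSimC(as.integer(n), config$gap, geometry$uMax,
                    config$boutonLength / 2, config$boutonRadius,
                    config$axonRadius, config$spineRadius,
                    geometry$cellSize, config$D, config$dt, pBind, pCap,
                    config$dt / config$bulkClearTau,
                    config$cleftRadius, config$maxSteps, 100L, occ,
                    transCap, geometry$nu, geometry$nv)
  w <- geometry$cells$w[match(sim$bindCell, geometry$cells$id)]
  nb <- length(sim$bindTime)
  tOn <- sim$bindTime + rexp(nb, rate = config$kIso)
  tOff <- tOn + rexp(nb, rate = config$kRev)
  # PSF-weighted bright occupancy over the time grid
  brightW <- vapply(tGrid, function(tt)
    sum(w[tOn <= tt & tOff > tt]), 1.0)
  dff <- config$contrast * brightW / wTot
  # exact peak from the on/off event sweep
  ev <- order(c(tOn, tOff))
  dw <- c(w, -w)[ev]
  peak <- if (nb) config$contrast * max(cumsum(dw)) / wTot else 0
  dimC <- vapply(tGrid, function(tt)
    sum(sim$bindTime <= tt & tOn > tt), 1.0)
  brightC <- vapply(tGrid, function(tt) sum(tOn <= tt & tOff > tt), 1.0)
  freeC <- stats::approx(c(0, sim$sampleTime), c(n, sim$freeCount),
                         xout = tGrid, method = "constant",
                         rule = 2)$y
  cleftC <- stats::approx(c(0, sim$sampleTime), c(n, sim$cleftCount),
                          xout = tGrid, method = "constant", rule = 2)$y
  everOut <- stats::approx(c(0, sim$sampleTime), c(0, sim$everLeftCleft),
                           xout = tGrid, method = "constant", rule = 2)$y
  counts <- data.frame(t = tGrid, free = freeC, cleft = cleftC,
                       everLeftCleft = everOut,
                       dim = dimC, bright = brightC,
                       removed = n - freeC - nb)
  list(peak = peak, dff = data.frame(t = tGrid, dff = dff),
       counts = counts, conserved = isTRUE(sim$conserved),
       bindings = data.frame(time = sim$bindTime, cell = sim$bindCell,
                             w = w),
       nInjected = n, nBound = nb, nCaptured = sim$nCaptured,
       nEscaped = sim$nEscaped)
}

#' PSF-weighted fluorescence readout from sensor states
#'
#' Given binding events (with PSF weights) and bright-state intervals,
#' computes \eqn{F(t) = \sum_i w_i (1 + contrast \cdot bright_i(t))}
#' and returns \eqn{\Delta F/F_0(t) = F(t)/F(0) - 1}, optionally
#' smoothed with a boxcar matched to the line rate.
#'
#' @param brightOn,brightOff bright-interval boundaries (s).
#' @param w PSF weight per event.
#' @param wTotal total PSF weight of all sensors.
#' @param contrast bright-state contrast.
#' @param tGrid evaluation times (s).
#' @param smoothMs optional boxcar width (ms).
#' @return data.frame(t, dff).
#' @export
readoutDff <- function(brightOn, brightOff, w, wTotal, contrast = 4.4,
                       tGrid, smoothMs = 0) {
  dff <- vapply(tGrid, function(tt)
    contrast * sum(w[brightOn <= tt & brightOff > tt]) / wTotal, 1.0)
  if (smoothMs > 0 && length(tGrid) > 3) {
    k <- max(1L, round(smoothMs / 1000 / diff(tGrid[1:2])))
    if (k > 1) dff <- stats::filter(dff, rep(1 / k, k), sides = 2) |>
        as.numeric()
  }
  data.frame(t = tGrid, dff = dff)
}

#' Saturation experiment: peak response vs vesicle count
#'
#' Runs the cleft simulation \code{runs} times for each vesicle count
#' and reads out the peak \eqn{\Delta F/F_0} under one or several
#' orientations. The diffusion/binding realization is shared between
#' orientations (tilt only changes which sensors fall into the PSF), so
#' orientation comparisons are paired.
#'
#' @param config a \code{\link{cleftConfig}}.
#' @param nVesList vesicle counts (default 1--15).
#' @param runs Monte Carlo runs per count.
#' @param tilts spine-tilt angles (degrees) to read out.
#' @param seed RNG seed.
#' @return data.frame(tilt, nVes, run, peak, nBound).
#' @export
runSaturationExperiment <- function(config, nVesList = 1:15, runs = 20,
                                    tilts = 0, seed = NULL) {
  stopifnot(inherits(config, "CleftConfig"))
  .setSeed(seed)
  geos <- lapply(tilts, function(tt)
    buildCleftGeometry(config, tiltSpine = tt))
  base <- geos[[1]]
  out <- list()
  for (nv in nVesList) {
    for (r in seq_len(runs)) {
      sim <- runCleftSim(config, nv, geometry = base,
                         tGrid = c(0, config$tEnd))
      nb <- nrow(sim$bindings)
      tOn <- sim$bindings$time + rexp(max(nb, 0), rate = config$kIso)
      tOff <- tOn + rexp(max(nb, 0), rate = config$kRev)
      for (g in seq_along(tilts)) {
        wg <- geos[[g]]$cells$w[match(sim$bindings$cell,
                                      geos[[g]]$cells$id)]
        pk <- if (nb) {
          ev <- order(c(tOn, tOff))
          dw <- c(wg, -wg)[ev]
          config$contrast * max(cumsum(dw)) / geos[[g]]$wTotal
        } else 0
        out[[length(out) + 1L]] <-
          data.frame(tilt = tilts[g], nVes = nv, run = r, peak = pk,
                     nBound = nb)
      }
    }
  }
  do.call(rbind, out)
}

#' Fit the hyperbolic saturation curve
#'
#' Least-squares fit of \eqn{r(n) = B_{max} n / (K_d + n)} to mean peak
#' responses versus vesicle count, treating the released vesicle count
#' as the glutamate dose. \eqn{K_d} is returned in vesicles: the number
#' of simultaneously released vesicles producing half-saturation, the
#' apparent affinity of the sensor-expressing bouton.
#'
#' @param nVes vesicle counts (\eqn{\ge 4} distinct values).
#' @param meanPeak mean peak \eqn{\Delta F/F_0} per count.
#' @return A \linkS4class{SaturationCurve}.
#' @examples
#' n <- 1:15
#' fitSaturation(n, 5.9 * n / (6.5 + n))  # recovers Bmax 5.9, Kd 6.5
#' @export
fitSaturation <- function(nVes, meanPeak) {
  if (length(unique(nVes)) < 4)
    stop("need at least 4 distinct vesicle counts", call. = FALSE)
  df <- data.frame(n = nVes, y = meanPeak)
  fit <- try(minpack.lm::nlsLM(y ~ b * n / (k + n), data = df,
                               start = list(b = max(meanPeak) * 1.5,
                                            k = median(nVes)),
                               lower = c(b = 1e-6, k = 1e-6),
                               control = minpack.lm::nls.lm.control(
                                 maxiter = 500)),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    stop("saturation fit failed: ", attr(fit, "condition")$message,
         call. = FALSE)
  cf <- coef(fit)
  saturationCurve(cf[["b"]], cf[["k"]])
}

#' Optional AMPA-receptor channel (occupancy proxy)
#'
#' The receptor channel is deliberately parametrized and reduced: given
#' the simulated free-glutamate count in the cleft, receptor activation
#' is integrated as a two-state scheme
#' \eqn{dO/dt = k_{on} c(t) (1 - O) - k_{off} O} with the cleft
#' concentration \eqn{c(t)} from molecule counts over the cleft volume.
#' Rates must be supplied by the user; the full published multi-state
#' receptor scheme is not reproduced here.
#'
#' @param sim result of \code{\link{runCleftSim}}.
#' @param config the \code{\link{cleftConfig}} used.
#' @param kOn,kOff receptor rates (M^-1 s^-1, s^-1).
#' @return data.frame(t, occupancy).
#' @export
amparOccupancy <- function(sim, config, kOn = 1e7, kOff = 8000) {
  cleftVol <- pi * config$cleftRadius^2 * config$gap   # um^3
  conc <- sim$counts$cleft / cleftVol / AVOGADRO_UM3   # molar
  tt <- sim$counts$t
  occ <- numeric(length(tt))
  # exact update for piecewise-constant concentration (unconditionally
  # stable, unlike a forward-Euler step at these rates)
  for (i in seq_along(tt)[-1]) {
    dtI <- tt[i] - tt[i - 1]
    rate <- kOn * conc[i - 1] + kOff
    occInf <- if (rate > 0) kOn * conc[i - 1] / rate else 0
    occ[i] <- occInf + (occ[i - 1] - occInf) * exp(-rate * dtI)
  }
  data.frame(t = tt, occupancy = occ)
}
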