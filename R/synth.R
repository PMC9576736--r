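## MODULE synth -- synthetic single-bouton sessions with known ground truth.
##
## The generator reproduces the statistical structure the downstream
## analysis assumes: binomially distributed vesicle counts per trial,
## amplitude compression by a hyperbolic saturation curve, Gaussian
## photon noise whose variance scales with total fluorescence,
## monoexponential bleaching across trials, exponential-decay response
## kernels, and occasional elevated-F0 artifact trials.

#' Draw per-trial vesicle release outcomes
#'
#' Vesicle counts per trial are independent draws from
#' \eqn{Binomial(N, p_{ves})} for the requested condition: each of the
#' \eqn{N} release-ready vesicles fuses independently with probability
#' \eqn{p_{ves}}.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param condition condition label, must exist in \code{pVes(truth)}.
#' @param nTrials number of trials to draw.
#' @param seed optional RNG seed (draws are reproducible under a fixed
#'   seed).
#' @return Integer vector of vesicle counts in \code{[0, nDocked]}.
#' @examples
#' k <- drawReleaseOutcomes(gluGroundTruth(), "4mM", 100, seed = 1)
#' mean(k > 0)   # empirical p_syn, approx 1 - (1 - 0.79)^3
#' @export
drawReleaseOutcomes <- function(truth, condition, nTrials, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  p <- .pickCondition(truth@pVes, condition)
  .setSeed(seed)
  rbinom(nTrials, size = truth@nDocked, prob = unname(p))
}

#' Map a vesicle count to a saturated response amplitude
#'
#' The bouton's peak response to \eqn{k} simultaneously released vesicles
#' follows the hyperbolic saturation curve
#' \deqn{A(k) = B_{max} \, k / (K_d + k), \qquad K_d = B_{max}/q - 1,}
#' so that \eqn{A(0) = 0}, \eqn{A(1) = q} and \eqn{A(k) \to B_{max}}.
#' This single implementation is shared by the generator and the quantal
#' fitter (\code{\link{peakPositions}} calls it), so the two cannot drift
#' apart.
#'
#' With \code{cvQ > 0} each vesicle's glutamate content is scaled by an
#' independent positive factor with the given coefficient of variation
#' before the counts are summed (sensitivity studies only; the default
#' analysis assumes uniform quanta).
#'
#' @param k vesicle count(s), \eqn{\ge 0} (non-integer values are allowed
#'   and interpreted as vesicle-equivalents of glutamate).
#' @param q quantal amplitude (\eqn{\Delta F/F_0}).
#' @param bMax saturation asymptote; must exceed \code{q}.
#' @param cvQ coefficient of variation of per-vesicle content (default 0).
#' @return Amplitude(s) in \eqn{\Delta F/F_0}.
#' @examples
#' amplitudeFromVesicles(0:5, q = 0.88, bMax = 6)
#' @export
amplitudeFromVesicles <- function(k, q, bMax, cvQ = 0) {
  if (any(k < 0)) stop("vesicle count must be >= 0", call. = FALSE)
  if (q <= 0 || q >= bMax)
    stop("invalid saturation model: need 0 < q < bMax", call. = FALSE)
  kd <- bMax / q - 1
  keff <- k
  if (cvQ > 0) {
    keff <- vapply(k, function(ki) {
      if (ki <= 0) return(0)
      sum(pmax(rnorm(ki, 1, cvQ), 0))
    }, 1.0)
  }
  bMax * keff / (kd + keff)
}

# signal field of one trial (no noise, no F0): lines x positions dF/F0
.trialSignal <- function(amplitude, acq, amplitude2 = NA,
                         delayedEvents = NULL) {
  k1 <- .kernelVec(acq@nLines, acq@stimLine, acq@kernelTau, acq@lineRate)
  sig <- amplitude * k1
  if (acq@pairedPulse && !is.na(amplitude2)) {
    k2 <- .kernelVec(acq@nLines, acq@stimLine + acq@interPulseLines,
                     acq@kernelTau, acq@lineRate)
    sig <- sig + amplitude2 * k2
  }
  if (!is.null(delayedEvents) && nrow(delayedEvents)) {
    for (i in seq_len(nrow(delayedEvents))) {
      ke <- .kernelVec(acq@nLines, delayedEvents$line[i], acq@kernelTau,
                       acq@lineRate)
      sig <- sig + delayedEvents$amplitude[i] * ke
    }
  }
  half <- ceiling(acq@siteWidth / 2)
  lo <- acq@siteCenter - half + 1L
  cols <- lo:(lo + acq@siteWidth - 1L)
  prof <- numeric(acq@nPositions)
  prof[cols] <- 1
  outer(sig, prof)
}

#' Synthesize one spiral-scan trial matrix
#'
#' Builds a lines-by-positions fluorescence matrix
#' \deqn{F = F_0\, b(t_i) \,[1 + A\, k(t - t_{stim})\, s(x)] + \epsilon,}
#' where \eqn{b} is the monoexponential bleach factor of trial
#' \eqn{t_i}, \eqn{k} a step-onset exponential-decay kernel, \eqn{s(x)} a
#' contiguous release-site column block, and \eqn{\epsilon} Gaussian
#' photon noise with per-pixel SD proportional to the square root of the
#' local expected photon count. The resting fluorescence unit is 1, so
#' matrices are directly on the \eqn{1 + \Delta F/F_0} scale before
#' bleaching.
#'
#' @param amplitude peak response amplitude (\eqn{\Delta F/F_0},
#'   \eqn{\ge 0}).
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param trialIndex 1-based global trial index (drives bleaching).
#' @param seed optional RNG seed.
#' @param artifact logical; multiply \eqn{F_0} by
#'   \code{acq@artifactFactor} (a fluorescent particle passing through
#'   the axon).
#' @param amplitude2 second-pulse amplitude (paired-pulse mode).
#' @param delayedEvents optional data.frame(line, amplitude) of
#'   additional desynchronized release events.
#' @return Numeric matrix, \code{nLines x nPositions}.
#' @examples
#' acq <- acquisitionParams(sigma0 = 0)
#' m <- synthesizeTrial(1.68, acq, trialIndex = 1)
#' max(rowMeans(m)) # peak of the column-averaged trace
#' @export
synthesizeTrial <- function(amplitude, acq, trialIndex = 1, seed = NULL,
                            artifact = FALSE, amplitude2 = NA,
                            delayedEvents = NULL) {
  stopifnot(is(acq, "AcquisitionParams"))
  if (amplitude < 0) stop("amplitude must be >= 0", call. = FALSE)
  .setSeed(seed)
  s <- .trialSignal(amplitude, acq, amplitude2, delayedEvents)
  bleach <- if (is.finite(acq@bleachTau))
    exp(-(trialIndex - 1) / acq@bleachTau) else 1
  f0 <- bleach * if (artifact) acq@artifactFactor else 1
  mu <- f0 * (1 + s)
  sigPx <- .pixelSigma(acq)
  if (sigPx > 0)
    mu <- mu + sigPx * sqrt(pmax(mu, 0)) *
      matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
  mu
}

#' Synthesize a full session across conditions
#'
#' Composes \code{\link{drawReleaseOutcomes}},
#' \code{\link{amplitudeFromVesicles}} and \code{\link{synthesizeTrial}}:
#' for each condition, vesicle counts are drawn binomially, compressed by
#' the saturation curve, and rendered as noisy trial matrices. Artifact
#' trials (elevated \eqn{F_0}) are injected at \code{acq@artifactRate};
#' the hidden ledger records true counts and artifact flags. Trial
#' indices (and hence bleaching) run continuously across conditions, as
#' in a real sequential recording.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param conditions condition labels to simulate (default: all in
#'   \code{truth}).
#' @param seed optional RNG seed; a fixed seed reproduces the session
#'   bit-exactly.
#' @return A \linkS4class{GluSession}.
#' @examples
#' ses <- synthesizeSession(gluGroundTruth(),
#'                          acquisitionParams(nTrials = 20), seed = 1)
#' ses
#' @export
synthesizeSession <- function(truth, acq, conditions = NULL, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"), is(acq, "AcquisitionParams"))
  if (is.null(conditions)) conditions <- names(truth@pVes)
  if (!all(conditions %in% names(truth@pVes)))
    stop("unknown condition label: ",
         paste(setdiff(conditions, names(truth@pVes)), collapse = ", "),
         call. = FALSE)
  .setSeed(seed)
  trials <- setNames(vector("list", length(conditions)), conditions)
  led <- list()
  idx <- 0L
  for (cc in conditions) {
    k1 <- drawReleaseOutcomes(truth, cc, acq@nTrials)
    k2 <- if (acq@pairedPulse)
      drawReleaseOutcomes(truth, cc, acq@nTrials) else
      rep(NA_integer_, acq@nTrials)
    a1 <- amplitudeFromVesicles(k1, truth@q, truth@bMax, truth@cvQ)
    a2 <- if (acq@pairedPulse)
      amplitudeFromVesicles(k2, truth@q, truth@bMax, truth@cvQ) else
      rep(NA_real_, acq@nTrials)
    art <- runif(acq@nTrials) < acq@artifactRate
    mats <- vector("list", acq@nTrials)
    for (i in seq_len(acq@nTrials)) {
      idx <- idx + 1L
      mats[[i]] <- synthesizeTrial(a1[i], acq, trialIndex = idx,
                                   artifact = art[i], amplitude2 = a2[i])
    }
    trials[[cc]] <- mats
    if (acq@nTrials > 0)
      led[[cc]] <- data.frame(condition = cc,
                              trial = idx - acq@nTrials +
                                seq_len(acq@nTrials),
                              k = k1, k2 = k2, amplitude = a1,
                              artifact = art)
  }
  ledger <- if (length(led))
    do.call(rbind, c(led, list(make.row.names = FALSE))) else NULL
  new("GluSession", conditions = conditions, trials = trials,
      ledger = if (is.null(ledger))
        data.frame(condition = character(), trial = integer(),
                   k = integer(), k2 = integer(), amplitude = numeric(),
                   artifact = logical()) else ledger,
      acq = acq, truth = truth)
}

#' Synthesize a strontium-wash-in (desynchronized release) session
#'
#' Emulates the calcium-to-strontium substitution experiment used to read
#' the quantal amplitude directly. Three phases: (i) evoked multivesicular
#' responses at the condition's full \eqn{p_{ves}}; (ii) wash-in, with the
#' evoked release probability shrinking trial-by-trial to zero while
#' desynchronized single-vesicle fusion events (amplitude \eqn{A(1) = q}
#' each) appear at Poisson times in the post-stimulus window; (iii) no
#' evoked release, delayed events only.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param acq an \linkS4class{AcquisitionParams}.
#' @param condition which condition's \eqn{p_{ves}} drives the evoked
#'   phase (default: the largest, the high-calcium condition).
#' @param delayedRate rate of delayed single-vesicle events during the
#'   post-stimulus window, events/s.
#' @param window length of the post-stimulus window carrying delayed
#'   events, ms.
#' @param nPhase trials per phase, length-3 integer vector.
#' @param seed optional RNG seed.
#' @return A \linkS4class{GluSession} with conditions
#'   \code{"evoked"}, \code{"washin"}, \code{"post"}; the delayed-event
#'   ledger (trial, line, amplitude) is in \code{meta$delayedEvents} and
#'   phase labels in the main ledger.
#' @export
synthesizeDesyncSession <- function(truth, acq, condition = NULL,
                                    delayedRate = 20, window = 40,
                                    nPhase = c(30L, 60L, 30L),
                                    seed = NULL) {
  stopifnot(is(truth, "GroundTruth"), is(acq, "AcquisitionParams"))
  if (delayedRate < 0) stop("delayedRate must be >= 0", call. = FALSE)
  if (is.null(condition))
    condition <- names(truth@pVes)[which.max(truth@pVes)]
  pFull <- unname(.pickCondition(truth@pVes, condition))
  .setSeed(seed)
  dtMs <- .lineDtMs(acq)
  winLines <- min(floor(window / dtMs),
                  acq@nLines - acq@stimLine - 1L)
  phases <- c("evoked", "washin", "post")
  nPhase <- as.integer(nPhase)
  trials <- setNames(vector("list", 3L), phases)
  led <- list(); evts <- list()
  idx <- 0L
  for (ph in seq_along(phases)) {
    mats <- vector("list", nPhase[ph])
    kk <- integer(nPhase[ph]); aa <- numeric(nPhase[ph])
    nDel <- integer(nPhase[ph])
    for (i in seq_len(nPhase[ph])) {
      idx <- idx + 1L
      pEff <- switch(ph, pFull, pFull * (1 - i / (nPhase[ph] + 1L)), 0)
      k <- if (pEff > 0) rbinom(1L, truth@nDocked, pEff) else 0L
      a <- amplitudeFromVesicles(k, truth@q, truth@bMax, truth@cvQ)
      del <- NULL
      if (ph >= 2L && delayedRate > 0) {
        nEv <- rpois(1L, delayedRate * winLines * dtMs / 1000)
        if (nEv > 0) {
          lines <- acq@stimLine + 1L +
            sort(sample.int(winLines, nEv, replace = TRUE))
          del <- data.frame(line = lines,
                            amplitude = amplitudeFromVesicles(
                              rep(1, nEv), truth@q, truth@bMax, truth@cvQ))
          evts[[length(evts) + 1L]] <-
            cbind(trial = idx, phase = phases[ph], del)
        }
      }
      nDel[i] <- if (is.null(del)) 0L else nrow(del)
      mats[[i]] <- synthesizeTrial(a, acq, trialIndex = idx,
                                   delayedEvents = del)
      kk[i] <- k; aa[i] <- a
    }
    trials[[phases[ph]]] <- mats
    led[[ph]] <- data.frame(condition = phases[ph],
                            trial = idx - nPhase[ph] + seq_len(nPhase[ph]),
                            k = kk, k2 = NA_integer_, amplitude = aa,
                            artifact = FALSE, nDelayed = nDel)
  }
  new("GluSession", conditions = phases, trials = trials,
      ledger = do.call(rbind, led), acq = acq, truth = truth,
      meta = list(delayedEvents = if (length(evts))
        do.call(rbind, evts) else
        data.frame(trial = integer(), phase = character(),
                   line = integer(), amplitude = numeric()),
        windowLines = winLines))
}

#' Sample response amplitudes from the generative amplitude model
#'
#' Draws amplitudes directly at the amplitude level (bypassing trial
#' rendering): a binomial vesicle count \eqn{k}, the saturated mean
#' \eqn{A(k)}, plus Gaussian measurement noise with SD
#' \eqn{\sigma_0 \sqrt{1 + A(k)}} (photon shot noise in quadrature).
#' This is the brute-force sampling counterpart of the mixture density
#' returned by \code{\link{predictAmplitudeDensity}} and is used as its
#' Monte Carlo oracle.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param condition condition label.
#' @param n number of amplitudes.
#' @param sigma0 baseline noise SD (\eqn{\Delta F/F_0}).
#' @param seed optional RNG seed.
#' @return Numeric vector of amplitudes.
#' @export
sampleAmplitudes <- function(truth, condition, n, sigma0, seed = NULL) {
  stopifnot(is(truth, "GroundTruth"))
  .setSeed(seed)
  k <- drawReleaseOutcomes(truth, condition, n)
  a <- amplitudeFromVesicles(k, truth@q, truth@bMax, truth@cvQ)
  a + .sigmaAtAmplitude(sigma0, a) * rnorm(n)
}

#' Synthesize a frame-scan image stack around a release site
#'
#' Emulates rapid frame scans of a bouton: frames before the stimulation
#' frame contain baseline plus photon noise; frames from the stimulation
#' frame on add a 2D Gaussian (given FWHM) at the release-site center,
#' decaying with the sensor kernel time constant.
#'
#' @param center release-site center \code{c(x, y)} in micrometers
#'   (origin at the field corner).
#' @param amplitude peak \eqn{\Delta F/F_0} of the event.
#' @param psfFwhm FWHM of the imaged spot, micrometers.
#' @param nFrames,stimFrame stack length and stimulation frame index.
#' @param pixelSize micrometers per pixel.
#' @param fieldPx field size in pixels (square field).
#' @param frameRate frames per second.
#' @param kernelTau sensor decay constant, ms.
#' @param sigmaPx per-pixel baseline noise SD in \eqn{\Delta F/F_0}
#'   units (0 for noise-free stacks).
#' @param seed optional RNG seed.
#' @return List with \code{stack} (array \code{fieldPx x fieldPx x
#'   nFrames}, resting level 1), \code{center}, \code{pixelSize},
#'   \code{stimFrame}.
#' @export
synthesizeFrameScanStack <- function(center, amplitude, psfFwhm = 0.35,
                                     nFrames = 16, stimFrame = 5,
                                     pixelSize = 0.1, fieldPx = 32,
                                     frameRate = 62.5, kernelTau = 40,
                                     sigmaPx = 0.15, seed = NULL) {
  fieldUm <- fieldPx * pixelSize
  if (any(center < 0) || any(center > fieldUm))
    stop("release-site center lies outside the imaged field",
         call. = FALSE)
  if (stimFrame <= 1 || stimFrame > nFrames)
    stop("need 1 < stimFrame <= nFrames", call. = FALSE)
  .setSeed(seed)
  sdUm <- psfFwhm / GAUSS_FWHM
  xc <- (seq_len(fieldPx) - 0.5) * pixelSize
  g <- outer(exp(-(xc - center[1])^2 / (2 * sdUm^2)),
             exp(-(xc - center[2])^2 / (2 * sdUm^2)))
  dtMs <- 1000 / frameRate
  stack <- array(0, c(fieldPx, fieldPx, nFrames))
  for (f in seq_len(nFrames)) {
    decay <- if (f < stimFrame) 0 else
      exp(-(f - stimFrame) * dtMs / kernelTau)
    mu <- 1 + amplitude * decay * g
    if (sigmaPx > 0)
      mu <- mu + sigmaPx * sqrt(pmax(mu, 0)) *
        matrix(rnorm(fieldPx * fieldPx), fieldPx, fieldPx)
    stack[, , f] <- mu
  }
  list(stack = stack, center = center, pixelSize = pixelSize,
       stimFrame = stimFrame, frameRate = frameRate)
}
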