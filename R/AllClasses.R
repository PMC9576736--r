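#' @import methods
#' @importFrom stats coef dbinom density lm median nls optim pnorm quantile
#'   rbinom rexp rnorm rpois runif sd var setNames mahalanobis cov qnorm
#'   predict resid
#' @importFrom utils head tail read.csv write.csv
#' @useDynLib quantalglu, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

GAUSS_FWHM <- 2 * sqrt(2 * log(2))  # FWHM / SD for a Gaussian

#' GroundTruth: quantal parameters of a simulated bouton
#'
#' Holds the quantal parameter triplet used both as input to the synthetic
#' session generator and as the reference when scoring fits: the number of
#' release-ready (docked) vesicles \eqn{N}, the per-vesicle fusion
#' probability \eqn{p_{ves}} for each extracellular calcium condition, the
#' quantal amplitude \eqn{q} (response to one vesicle, in \eqn{\Delta
#' F/F_0}) and the saturation asymptote \eqn{B_{max}} of the
#' sensor-expressing bouton.
#'
#' @slot nDocked integer, number of release-ready vesicles (\eqn{N \ge 1}).
#' @slot pVes named numeric, per-vesicle fusion probability per condition,
#'   each in (0, 1] (1 is the degenerate always-release case used in
#'   identifiability checks; 0 is rejected).
#' @slot q numeric, quantal amplitude in \eqn{\Delta F/F_0} units.
#' @slot bMax numeric, saturation asymptote in \eqn{\Delta F/F_0} units;
#'   must exceed \code{q}.
#' @slot cvQ numeric, coefficient of variation of vesicle glutamate
#'   content. Default 0: quantal variability is off, the only stochastic
#'   broadening of amplitude peaks is photon shot noise. Non-zero values
#'   are for sensitivity studies only.
#' @export
setClass("GroundTruth",
  representation(nDocked = "integer", pVes = "numeric", q = "numeric",
                 bMax = "numeric", cvQ = "numeric"),
  prototype(nDocked = 3L, pVes = c("1mM" = 0.08, "4mM" = 0.79),
            q = 0.84, bMax = 6, cvQ = 0))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (length(object@nDocked) != 1L || is.na(object@nDocked) ||
      object@nDocked < 1L)
    msg <- c(msg, "nDocked must be a single integer >= 1")
  if (length(object@pVes) < 1L || is.null(names(object@pVes)) ||
      any(!nzchar(names(object@pVes))))
    msg <- c(msg, "pVes must be a named numeric vector")
  if (any(object@pVes <= 0 | object@pVes > 1))
    msg <- c(msg, "each pVes must lie in (0, 1]")
  if (object@q <= 0 || object@q >= object@bMax)
    msg <- c(msg, "q must satisfy 0 < q < bMax")
  if (object@cvQ < 0) msg <- c(msg, "cvQ must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a GroundTruth object
#'
#' Defaults are the population medians reported for Schaffer collateral
#' boutons: \eqn{N = 3} docked vesicles, \eqn{q = 0.84\ \Delta F/F_0},
#' \eqn{p_{ves} = 0.08} in 1 mM and \eqn{0.79} in 4 mM extracellular
#' calcium, with a bouton saturation asymptote \eqn{B_{max} = 6\ \Delta
#' F/F_0}.
#'
#' @param nDocked number of release-ready vesicles.
#' @param pVes named vector of per-vesicle fusion probabilities, one entry
#'   per condition label.
#' @param q quantal amplitude (\eqn{\Delta F/F_0}).
#' @param bMax saturation asymptote (\eqn{\Delta F/F_0}).
#' @param cvQ coefficient of variation of vesicular glutamate content
#'   (default 0, i.e. uniform quanta).
#' @return A \linkS4class{GroundTruth} object.
#' @examples
#' truth <- gluGroundTruth()
#' nDocked(truth)
#' pVes(truth, "4mM")
#' @export
gluGroundTruth <- function(nDocked = 3, pVes = c("1mM" = 0.08, "4mM" = 0.79),
                           q = 0.84, bMax = 6, cvQ = 0) {
  new("GroundTruth", nDocked = as.integer(nDocked), pVes = pVes,
      q = as.numeric(q), bMax = as.numeric(bMax), cvQ = as.numeric(cvQ))
}

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: N =", object@nDocked,
      "| q =", format(object@q), "dF/F0",
      "| Bmax =", format(object@bMax), "dF/F0\n")
  cat("  pVes:", paste(sprintf("%s = %.3g", names(object@pVes),
                               object@pVes), collapse = ", "), "\n")
  if (object@cvQ > 0) cat("  quantal content CV:", object@cvQ, "\n")
})

#' AcquisitionParams: emulated spiral-scan acquisition settings
#'
#' Describes one emulated acquisition: trial count, the lines-by-positions
#' layout of each spiral-scan trial matrix, stimulation timing, the sensor
#' decay kernel, photobleaching, baseline noise and the rate of artifact
#' trials (fluorescent particles passing through the axon, emulated as an
#' elevated-\eqn{F_0} multiplier).
#'
#' Noise convention: \code{sigma0} is the standard deviation, in
#' \eqn{\Delta F/F_0} units, of the null template-fit amplitude (the
#' statistic the trace analysis measures on non-stimulated baseline
#' windows). The per-pixel photon-noise scale is derived from it so that
#' pixel variance is proportional to the expected photon count.
#' Alternatively \code{baselinePhotonRate} (expected photons per pixel at
#' rest) may be given; \code{sigma0 = NA} then derives the amplitude-level
#' noise from the photon rate.
#'
#' @slot nTrials trials per condition.
#' @slot nLines spiral lines per trial (time samples).
#' @slot lineRate line rate in Hz.
#' @slot nPositions spatial positions per line.
#' @slot stimLine line index of stimulation onset.
#' @slot siteCenter,siteWidth location and width (in positions) of the
#'   contiguous release-site column block.
#' @slot sigma0 baseline noise SD in \eqn{\Delta F/F_0} (amplitude scale).
#' @slot baselinePhotonRate expected photons per pixel at rest
#'   (alternative noise parameterization; NA when \code{sigma0} is used).
#' @slot kernelTau sensor decay time constant (ms).
#' @slot bleachTau monoexponential bleach time constant (trials; Inf for
#'   no bleaching).
#' @slot artifactRate probability that a trial is an artifact trial.
#' @slot artifactFactor \eqn{F_0} multiplier of artifact trials
#'   (\eqn{\ge 1.5}).
#' @slot pairedPulse logical; when TRUE each trial contains two stimuli.
#' @slot interPulseLines line offset of the second pulse.
#' @export
setClass("AcquisitionParams",
  representation(nTrials = "integer", nLines = "integer",
                 lineRate = "numeric", nPositions = "integer",
                 stimLine = "integer", siteCenter = "integer",
                 siteWidth = "integer", sigma0 = "numeric",
                 baselinePhotonRate = "numeric", kernelTau = "numeric",
                 bleachTau = "numeric", artifactRate = "numeric",
                 artifactFactor = "numeric", pairedPulse = "logical",
                 interPulseLines = "integer"),
  prototype(nTrials = 300L, nLines = 44L, lineRate = 500, nPositions = 64L,
            stimLine = 30L, siteCenter = 32L, siteWidth = 12L,
            sigma0 = 0.08, baselinePhotonRate = NA_real_, kernelTau = 40,
            bleachTau = 1500, artifactRate = 0.03, artifactFactor = 2,
            pairedPulse = FALSE, interPulseLines = 24L))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (object@stimLine < 1L || object@stimLine >= object@nLines)
    msg <- c(msg, "need nLines > stimLine >= 1")
  if (object@lineRate <= 0 || object@kernelTau <= 0 ||
      object@bleachTau <= 0)
    msg <- c(msg, "rates and time constants must be > 0")
  if (object@artifactRate < 0 || object@artifactRate >= 1)
    msg <- c(msg, "artifactRate must be in [0, 1)")
  if (!is.na(object@sigma0) && object@sigma0 < 0)
    msg <- c(msg, "sigma0 must be >= 0")
  if (is.na(object@sigma0) && is.na(object@baselinePhotonRate))
    msg <- c(msg, "one of sigma0 or baselinePhotonRate must be given")
  w <- object@siteCenter + c(-1, 1) * ceiling(object@siteWidth / 2)
  if (w[1] < 0L || w[2] > object@nPositions + 1L)
    msg <- c(msg, "release-site block must fit inside the positions range")
  if (object@pairedPulse &&
      object@stimLine + object@interPulseLines >= object@nLines)
    msg <- c(msg, "second pulse must fall inside the trial")
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters for the session generator
#'
#' Defaults emulate the published acquisition: 44 spiral lines per trial
#' at 500 Hz, 300 trials per condition, a 2--5\% artifact-trial rate and a
#' sensor decay time constant of 40 ms. The spiral scan is emulated as a
#' lines-by-positions matrix with a contiguous release-site column block;
#' the downstream analysis consumes only this time-space matrix, so the
#' exact spiral geometry is not reproduced.
#'
#' @param nTrials,nLines,lineRate,nPositions,stimLine,siteCenter,siteWidth
#'   see \linkS4class{AcquisitionParams}.
#' @param sigma0 baseline noise SD in \eqn{\Delta F/F_0} (null
#'   template-fit amplitude scale); set to 0 for noise-free trials.
#' @param baselinePhotonRate optional photons-per-pixel parameterization
#'   used when \code{sigma0} is NA.
#' @param kernelTau,bleachTau decay constants (ms; trials).
#' @param artifactRate,artifactFactor artifact-trial plumbing.
#' @param pairedPulse,interPulseLines two-pulse mode (independent
#'   binomial outcomes per pulse; no short-term plasticity is modelled).
#' @return An \linkS4class{AcquisitionParams} object.
#' @export
acquisitionParams <- function(nTrials = 300, nLines = 44, lineRate = 500,
                              nPositions = 64, stimLine = 30,
                              siteCenter = 32, siteWidth = 12,
                              sigma0 = 0.08, baselinePhotonRate = NA,
                              kernelTau = 40, bleachTau = 1500,
                              artifactRate = 0.03, artifactFactor = 2,
                              pairedPulse = FALSE, interPulseLines = 24) {
  new("AcquisitionParams", nTrials = as.integer(nTrials),
      nLines = as.integer(nLines), lineRate = as.numeric(lineRate),
      nPositions = as.integer(nPositions), stimLine = as.integer(stimLine),
      siteCenter = as.integer(siteCenter), siteWidth = as.integer(siteWidth),
      sigma0 = as.numeric(sigma0),
      baselinePhotonRate = as.numeric(baselinePhotonRate),
      kernelTau = as.numeric(kernelTau), bleachTau = as.numeric(bleachTau),
      artifactRate = as.numeric(artifactRate),
      artifactFactor = as.numeric(artifactFactor),
      pairedPulse = isTRUE(pairedPulse),
      interPulseLines = as.integer(interPulseLines))
}

setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams:", object@nTrials, "trials of", object@nLines,
      "lines x", object@nPositions, "positions @", object@lineRate, "Hz\n")
  cat("  stim line", object@stimLine, "| site",
      object@siteCenter, "+/-", ceiling(object@siteWidth / 2),
      "| sigma0", object@sigma0, "| kernel tau", object@kernelTau, "ms\n")
  cat("  bleach tau", object@bleachTau, "trials | artifact rate",
      object@artifactRate, "\n")
})

#' GluSession: a synthetic single-bouton imaging session
#'
#' Container for one bouton's trial matrices across conditions, together
#' with the hidden ground-truth ledger (true vesicle counts and artifact
#' flags per trial) and the acquisition metadata.
#'
#' @slot conditions character vector of condition labels.
#' @slot trials named list (one entry per condition) of lists of
#'   lines-by-positions trial matrices.
#' @slot ledger data.frame with columns condition, trial (global index),
#'   k (true vesicle count; for paired-pulse sessions k of pulse 1), k2
#'   (pulse 2 or NA), amplitude (true noise-free \eqn{\Delta F/F_0}),
#'   artifact (logical).
#' @slot acq the \linkS4class{AcquisitionParams} used.
#' @slot truth the \linkS4class{GroundTruth} used.
#' @slot meta list of generator extras (e.g. phase boundaries and the
#'   delayed-event ledger of desynchronized sessions).
#' @export
setClass("GluSession",
  representation(conditions = "character", trials = "list",
                 ledger = "data.frame", acq = "AcquisitionParams",
                 truth = "GroundTruth", meta = "list"),
  prototype(meta = list()))

setValidity("GluSession", function(object) {
  msg <- character()
  if (!identical(sort(object@conditions), sort(names(object@trials))))
    msg <- c(msg, "trials must be a list named by condition")
  ntr <- sum(vapply(object@trials, length, 1L))
  if (nrow(object@ledger) != ntr)
    msg <- c(msg, "ledger must have one row per trial")
  if (ntr > 0 && any(object@ledger$k < 0 |
                     object@ledger$k > object@truth@nDocked))
    msg <- c(msg, "ledger vesicle counts must lie in [0, nDocked]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GluSession", function(object) {
  cat("GluSession:", sum(vapply(object@trials, length, 1L)),
      "trials in", length(object@conditions), "condition(s)\n")
  for (cc in object@conditions) {
    led <- object@ledger[object@ledger$condition == cc, ]
    cat(sprintf("  %s: %d trials, true success fraction %.3f\n", cc,
                nrow(led), mean(led$k > 0)))
  }
})

#' NoiseModel: baseline amplitude noise of one bouton/condition
#'
#' @slot sigma0 SD of null (baseline) template-fit amplitudes, in
#'   \eqn{\Delta F/F_0}.
#' @slot fwhm full width at half maximum of the baseline amplitude
#'   distribution (\eqn{= 2\sqrt{2\ln 2}\,\sigma_0} under Gaussianity;
#'   estimated empirically from the null amplitudes).
#' @slot n number of trials entering the estimate.
#' @slot scalingExponent exponent of the fluorescence-dependent noise
#'   scaling law (fixed at 0.5: photon shot noise).
#' @export
setClass("NoiseModel",
  representation(sigma0 = "numeric", fwhm = "numeric", n = "integer",
                 scalingExponent = "numeric"),
  prototype(sigma0 = NA_real_, fwhm = NA_real_, n = 0L,
            scalingExponent = 0.5))

setValidity("NoiseModel", function(object) {
  if (!is.na(object@sigma0) && object@sigma0 < 0)
    "sigma0 must be >= 0" else TRUE
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf("NoiseModel: sigma0 = %.4g dF/F0, baseline FWHM = %.4g (n = %d)\n",
              object@sigma0, object@fwhm, object@n))
})

#' AmplitudeSet: per-trial amplitudes with labels and QC metadata
#'
#' The product of the trace-analysis pipeline and the input to the quantal
#' fitter: one row per trial with the fitted amplitude, its
#' success/failure/rejected label and rejection reason, plus per-bouton
#' metadata (noise model per condition, template decay constant, bleach
#' time constants, release probability per condition and, in paired-pulse
#' mode, the paired-pulse ratio).
#'
#' @slot table data.frame: condition, trial, amplitude, label
#'   ("success", "failure" or "rejected"), reason, and optionally trueK
#'   (ground-truth vesicle count when analysing synthetic sessions).
#' @slot noise named list of \linkS4class{NoiseModel}, one per condition.
#' @slot templateTau fitted template decay constant (ms).
#' @slot bleachTau named numeric, fitted bleach constant per condition
#'   (trials).
#' @slot roi integer vector, release-site column indices used.
#' @slot psyn named numeric, successes / (successes + failures) per
#'   condition (rejected trials excluded).
#' @slot ppr named numeric, paired-pulse ratio (percent) per condition,
#'   NA when not paired.
#' @export
setClass("AmplitudeSet",
  representation(table = "data.frame", noise = "list",
                 templateTau = "numeric", bleachTau = "numeric",
                 roi = "integer", psyn = "numeric", ppr = "numeric"))

setValidity("AmplitudeSet", function(object) {
  msg <- character()
  need <- c("condition", "trial", "amplitude", "label")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, paste("table must have columns",
                        paste(need, collapse = ", ")))
  if (nrow(object@table) &&
      !all(object@table$label %in% c("success", "failure", "rejected")))
    msg <- c(msg, "labels must be success/failure/rejected")
  if (length(object@psyn) && any(object@psyn < 0 | object@psyn > 1,
                                 na.rm = TRUE))
    msg <- c(msg, "psyn must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AmplitudeSet", function(object) {
  cat("AmplitudeSet:", nrow(object@table), "trials\n")
  for (cc in names(object@psyn)) {
    nm <- object@noise[[cc]]
    cat(sprintf("  %s: p_syn = %.3f, sigma0 = %.4g (%d rejected)\n", cc,
                object@psyn[[cc]], if (!is.null(nm)) nm@sigma0 else NA,
                sum(object@table$condition == cc &
                    object@table$label == "rejected")))
  }
  if (!all(is.na(object@ppr)))
    cat("  PPR (%):", paste(sprintf("%s = %.1f", names(object@ppr),
                                    object@ppr), collapse = ", "), "\n")
  cat(sprintf("  template tau = %.3g ms\n", object@templateTau))
})

#' SaturationCurve: hyperbolic sensor saturation model
#'
#' The mapping from simultaneously released vesicle count to peak sensor
#' response, \eqn{r(n) = B_{max} n / (K_d + n)}, where \eqn{K_d} is the
#' apparent affinity of the sensor-expressing bouton expressed in
#' vesicle-equivalents of glutamate.
#'
#' @slot bMax asymptote in \eqn{\Delta F/F_0}.
#' @slot kD half-saturation point in vesicles.
#' @export
setClass("SaturationCurve",
  representation(bMax = "numeric", kD = "numeric"))

setValidity("SaturationCurve", function(object) {
  if (object@bMax <= 0 || object@kD <= 0)
    "bMax and kD must be > 0" else TRUE
})

#' @rdname SaturationCurve-class
#' @param bMax asymptote (\eqn{\Delta F/F_0}).
#' @param kD half-saturation (vesicles).
#' @return A \linkS4class{SaturationCurve}.
#' @export
saturationCurve <- function(bMax, kD) {
  new("SaturationCurve", bMax = as.numeric(bMax), kD = as.numeric(kD))
}

setMethod("show", "SaturationCurve", function(object) {
  cat(sprintf("SaturationCurve: Bmax = %.3g dF/F0, Kd = %.3g vesicles\n",
              object@bMax, object@kD))
})

#' QuantalFit: result of the joint binomial-model grid search
#'
#' @slot nDocked selected number of release-ready vesicles.
#' @slot pVes named numeric, fitted per-vesicle release probability per
#'   condition.
#' @slot q fitted quantal amplitude (\eqn{\Delta F/F_0}).
#' @slot bMax saturation asymptote used for peak spacing.
#' @slot rmsError named numeric, per-condition RMS error of the selected
#'   fit.
#' @slot combinedError sum of per-condition RMS errors.
#' @slot globalMin smallest combined error over the whole grid.
#' @slot parsimonyMargin combinedError / globalMin - 1 (\eqn{\le} the 2\%
#'   parsimony window by construction).
#' @slot errorSurface data.frame: best combined error (and its q) for
#'   every candidate N, the diagnostic slice of the error surface.
#' @slot strength named numeric, synaptic strength
#'   \eqn{p_{ves} N q} per condition.
#' @export
setClass("QuantalFit",
  representation(nDocked = "integer", pVes = "numeric", q = "numeric",
                 bMax = "numeric", rmsError = "numeric",
                 combinedError = "numeric", globalMin = "numeric",
                 parsimonyMargin = "numeric", errorSurface = "data.frame",
                 strength = "numeric"))

setValidity("QuantalFit", function(object) {
  msg <- character()
  if (object@nDocked < 1L) msg <- c(msg, "nDocked must be >= 1")
  if (length(object@strength) && any(object@strength < 0))
    msg <- c(msg, "strength must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "QuantalFit", function(object) {
  cat(sprintf("QuantalFit: N = %d, q = %.3g dF/F0 (Bmax = %.3g)\n",
              object@nDocked, object@q, object@bMax))
  for (cc in names(object@pVes))
    cat(sprintf("  %s: pVes = %.3g, RMS = %.4g, strength = %.3g\n", cc,
                object@pVes[[cc]], object@rmsError[[cc]],
                object@strength[[cc]]))
  cat(sprintf("  combined RMS = %.4g (parsimony margin %.2f%%)\n",
              object@combinedError, 100 * object@parsimonyMargin))
})
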