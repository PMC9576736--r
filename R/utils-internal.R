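# Internal helpers shared by the session generator and the trace analysis.
# Both sides must use the same kernel discretization and the same
# fit-window rule, otherwise the generator's sigma0 calibration and the
# analysis' noise estimate drift apart.

.lineDtMs <- function(acq) 1000 / acq@lineRate

# step-onset monoexponential decay sampled at the line times, unit
# amplitude at the onset line
.kernelVec <- function(nLines, stimLine, tauMs, lineRate) {
  dt <- 1000 / lineRate
  tt <- (seq_len(nLines) - stimLine) * dt
  k <- ifelse(tt < 0, 0, exp(-tt / tauMs))
  k
}

# Template-fit window layout. The fit window is at most 6 decay
# constants, clipped to the post-stimulus length and to half the
# pre-stimulus segment, so that the null (baseline) fit -- used for the
# noise model -- can be laid out inside the pre-stimulus segment with an
# identically sized baseline and window. With identical layouts the null
# amplitude is distributed exactly like a failure-trial amplitude, which
# is what calibrates the 2-sigma classifier.
.fitWindowLen <- function(nLines, stimLine, tauMs, lineRate) {
  dt <- 1000 / lineRate
  L <- min(ceiling(6 * tauMs / dt), nLines - stimLine + 1L,
           floor((stimLine - 1L) / 2))
  max(L, 2L)
}

# lines used by the signal fit and the null fit (1-based indices)
.fitLayout <- function(nLines, stimLine, tauMs, lineRate) {
  L <- .fitWindowLen(nLines, stimLine, tauMs, lineRate)
  nb <- stimLine - 1L - L                       # baseline lines per fit
  list(L = L, nb = nb,
       sigBase = (stimLine - nb):(stimLine - 1L),
       sigWin = stimLine:(stimLine + L - 1L),
       nullBase = 1:nb,
       nullWin = (nb + 1L):(nb + L))
}

# SD of the template-fit amplitude per unit of per-line noise SD:
# a_hat = sum(k (y - mean(y_base))) / sum(k^2)
.ampSdFactor <- function(tauMs, lineRate, L, nb) {
  dt <- 1000 / lineRate
  k <- exp(-(seq_len(L) - 1) * dt / tauMs)
  sqrt(1 / sum(k^2) + (sum(k) / sum(k^2))^2 / nb)
}

# per-pixel noise SD (dF/F0 units at rest) that makes the SD of the
# template-fit amplitude equal sigma0 for a release-site block of
# `width` columns
.pixelSigma <- function(acq) {
  if (!is.na(acq@sigma0)) {
    if (acq@sigma0 == 0) return(0)
    lay <- .fitLayout(acq@nLines, acq@stimLine, acq@kernelTau, acq@lineRate)
    fac <- .ampSdFactor(acq@kernelTau, acq@lineRate, lay$L, lay$nb)
    acq@sigma0 * sqrt(acq@siteWidth) / fac
  } else {
    1 / sqrt(acq@baselinePhotonRate)
  }
}

# shot-noise broadening of an amplitude-level Gaussian: baseline variance
# scaled by total fluorescence (1 + dF/F0) in quadrature
.sigmaAtAmplitude <- function(sig0, amplitude, exponent = 0.5) {
  sig0 * (1 + pmax(amplitude, 0))^exponent
}

.setSeed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

# empirical FWHM of a sample: robust width from the interquartile
# range, converted to full width at half maximum under the Gaussian
# shape of baseline noise (FWHM = 2.3548 * IQR / 1.349). The robust
# route is stable at session-sized samples, where a kernel-density
# half-maximum span is both biased by the bandwidth and noisy.
.empiricalFwhm <- function(x) {
  if (length(x) < 10 || sd(x) == 0) return(GAUSS_FWHM * sd(x))
  GAUSS_FWHM * stats::IQR(x) / (2 * qnorm(0.75))
}
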