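## MODULE traces -- from raw trial matrices to a quality-controlled
## amplitude table: F0 QC, bleach correction, dynamic ROI, template
## fitting, noise model, 2-sigma classification.

# pre-stimulus F0 of each trial (mean over all pre-stimulus pixels)
.trialF0 <- function(mats, stimLine) {
  vapply(mats, function(m) mean(m[seq_len(stimLine - 1L), ]), 1.0)
}

# robust monoexponential fit of a trial-F0 sequence; returns fitted
# values, tau and the flags of >2 SD outliers (used by qcF0 and by the
# bleach correction)
.fitF0Trend <- function(f0, idx = seq_along(f0)) {
  stopifnot(length(f0) >= 3)
  fitOnce <- function(keep) {
    fit <- try(minpack.lm::nlsLM(
      y ~ A * exp(-x / tau),
      data = data.frame(x = idx[keep], y = f0[keep]),
      start = list(A = max(mean(f0[keep]), 1e-12),
                   tau = max(idx) * 4),
      lower = c(A = 1e-12, tau = 1),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    fit
  }
  keep <- rep(TRUE, length(f0))
  fit <- fitOnce(keep)
  if (is.null(fit)) {   # linear detrend fallback
    warning("monoexponential F0 fit did not converge; using linear detrend")
    lf <- lm(f0 ~ idx)
    fitted <- as.numeric(predict(lf, data.frame(idx = idx)))
    res <- f0 - fitted
    s <- sd(res)
    return(list(fitted = fitted, tau = Inf,
                flag = if (s > 0) abs(res) > 2 * s else rep(FALSE, length(f0))))
  }
  pred <- function(f) as.numeric(predict(f, data.frame(x = idx)))
  res <- f0 - pred(fit)
  s <- sd(res)
  flag <- if (s > 0) abs(res) > 2 * s else rep(FALSE, length(f0))
  if (any(flag) && sum(!flag) >= 3) {
    fit2 <- fitOnce(!flag)
    if (!is.null(fit2)) {
      fit <- fit2
      res <- f0 - pred(fit)
      s <- sd(res[!flag])
      flag <- if (s > 0) abs(res) > 2 * s else rep(FALSE, length(f0))
    }
  }
  list(fitted = pred(fit), tau = unname(coef(fit)["tau"]), flag = flag,
       flagHigh = if (s > 0) res > 2 * s else rep(FALSE, length(f0)))
}

#' Trial-F0 quality control
#'
#' Rejects trials whose pre-stimulus baseline fluorescence \eqn{F_0}
#' exceeds the session trend by more than 2 standard deviations of
#' the trial-\eqn{F_0} values (one-sided: the targeted artifacts are
#' bright particles that elevate \eqn{F_0}). The session trend is a robust
#' monoexponential (bleaching) fit, so an elevated-\eqn{F_0} artifact
#' trial late in a bleaching session is still caught. This removes
#' trials contaminated by fluorescent particles moving through the axon.
#'
#' @param mats list of raw trial matrices (one condition).
#' @param stimLine stimulation onset line.
#' @return Logical keep mask (TRUE = keep), with the per-trial
#'   \eqn{F_0} values and fitted trend attached as attributes
#'   \code{"f0"} and \code{"trend"}.
#' @export
qcF0 <- function(mats, stimLine) {
  if (length(mats) < 20)
    stop("qcF0 needs at least 20 trials", call. = FALSE)
  f0 <- .trialF0(mats, stimLine)
  tr <- .fitF0Trend(f0)
  # one-sided: the artifacts this rule targets elevate F0
  keep <- !tr$flagHigh
  attr(keep, "f0") <- f0
  attr(keep, "trend") <- tr$fitted
  keep
}

#' Bleach correction from failure-trial baselines
#'
#' Fits the \eqn{F_0} time course of failure trials with a
#' monoexponential across the session and divides every trial's matrix by
#' the fitted trial-specific bleach factor, normalizing resting
#' fluorescence to 1. Fitting only failures avoids contaminating the
#' bleach estimate with release events. Falls back to a linear detrend
#' with a warning when the exponential fit does not converge.
#'
#' @param mats list of raw trial matrices.
#' @param labels preliminary labels; trials with \code{"failure"} enter
#'   the fit (needs \eqn{\ge 5}).
#' @param stimLine stimulation onset line.
#' @param trialIndex global trial indices (default along the list).
#' @return List: \code{mats} (corrected, resting level 1),
#'   \code{bleachTau} (fitted trials constant), \code{factors} (fitted
#'   per-trial \eqn{F_0}).
#' @export
correctBleach <- function(mats, labels, stimLine,
                          trialIndex = seq_along(mats)) {
  fail <- labels == "failure"
  if (sum(fail) < 5)
    stop("correctBleach needs at least 5 failure trials", call. = FALSE)
  f0 <- .trialF0(mats, stimLine)
  tr <- .fitF0Trend(f0[fail], idx = trialIndex[fail])
  # evaluate the fitted trend at every trial
  if (is.finite(tr$tau)) {
    A <- tr$fitted[1] * exp(trialIndex[fail][1] / tr$tau)
    fac <- A * exp(-trialIndex / tr$tau)
  } else {
    lf <- lm(y ~ x, data = data.frame(x = trialIndex[fail], y = f0[fail]))
    fac <- as.numeric(predict(lf, data.frame(x = trialIndex)))
    fac[fac <= 0] <- min(f0)
  }
  list(mats = mapply(function(m, f) m / f, mats, fac, SIMPLIFY = FALSE),
       bleachTau = tr$tau, factors = fac)
}

#' Select the dynamic region of interest of one trial
#'
#' Spatial positions (matrix columns) are sorted by their change in
#' fluorescence. In trials with a clear stimulus-evoked change
#' (post-stimulus mean \eqn{\Delta F} above 2 baseline SE), only columns
#' with \eqn{\Delta F > \tfrac12 \max(\Delta F)} are selected
#' (provenance \code{"current-trial"}). Otherwise the columns selected in
#' the last success trial are reused (provenance
#' \code{"carried-from-last-success"}); with no prior success all columns
#' are used (provenance \code{"all-columns"}).
#'
#' @param mat one normalized trial matrix (resting level 1).
#' @param stimLine stimulation onset line.
#' @param lastSuccessRoi integer vector or NULL.
#' @param kernelTau,lineRate template decay constant (ms) and line rate
#'   (Hz), used only to size the evaluation window.
#' @param failureRule \code{"2sigma"} (default: two-sided z-test of the
#'   whole-matrix post-stimulus change against baseline fluctuations) or
#'   \code{"5pct"} (route to the carried ROI when no column exceeds its
#'   baseline by more than 5\% of the trial's maximum \eqn{\Delta F}).
#' @return List: \code{positions} (integer column indices),
#'   \code{provenance}, \code{colDf} (per-column \eqn{\Delta F}).
#' @export
selectDynamicRoi <- function(mat, stimLine, lastSuccessRoi = NULL,
                             kernelTau = 40, lineRate = 500,
                             failureRule = c("2sigma", "5pct")) {
  if (is.null(dim(mat)) || nrow(mat) < 2 || ncol(mat) < 1)
    stop("malformed trial matrix", call. = FALSE)
  failureRule <- match.arg(failureRule)
  if (nrow(mat) - stimLine + 1L < 4)
    stop("need at least 4 post-stimulus lines", call. = FALSE)
  lay <- .fitLayout(nrow(mat), stimLine, kernelTau, lineRate)
  pre <- seq_len(stimLine - 1L)
  post <- lay$sigWin
  colDf <- colMeans(mat[post, , drop = FALSE]) -
    colMeans(mat[pre, , drop = FALSE])
  tr <- rowMeans(mat)
  dbar <- mean(tr[post]) - mean(tr[pre])
  se <- sd(tr[pre]) * sqrt(1 / length(post) + 1 / length(pre))
  evoked <- if (failureRule == "2sigma") {
    if (se == 0) dbar > 0 else dbar > 2 * se
  } else {
    baseSpread <- max(abs(colDf[colDf <= 0]), 0)
    any(colDf > baseSpread + 0.05 * max(colDf))
  }
  if (evoked) {
    roi <- which(colDf > max(colDf) / 2)
    prov <- "current-trial"
  } else if (!is.null(lastSuccessRoi) && length(lastSuccessRoi)) {
    roi <- as.integer(lastSuccessRoi)
    prov <- "carried-from-last-success"
  } else {
    roi <- seq_len(ncol(mat))
    prov <- "all-columns"
  }
  list(positions = roi, provenance = prov, colDf = colDf)
}

# template object shared by the fitting routines
.makeTemplate <- function(tau, nLines, stimLine, lineRate) {
  lay <- .fitLayout(nLines, stimLine, tau, lineRate)
  dt <- 1000 / lineRate
  k <- exp(-(seq_len(lay$L) - 1) * dt / tau)
  c(list(tau = tau, lineRate = lineRate, nLines = nLines,
         stimLine = stimLine, k = k), lay)
}

# core least-squares scale of the kernel against a trace;
# null = TRUE lays the identical fit inside the pre-stimulus segment
.fitAmplitudeTrace <- function(trace, tpl, null = FALSE) {
  base <- if (null) tpl$nullBase else tpl$sigBase
  win <- if (null) tpl$nullWin else tpl$sigWin
  y <- trace[win] - mean(trace[base])
  sum(tpl$k * y) / sum(tpl$k^2)
}

#' Build the synapse-specific response template
#'
#' Averages the \code{kLargest} largest preliminary success traces
#' (ROI-averaged, baseline-subtracted), fits a step-onset
#' monoexponential decay, and returns the unit-amplitude kernel used for
#' single-parameter amplitude fitting. When fewer successes are
#' available than \code{kLargest}, all are used.
#'
#' @param successTraces list of ROI-averaged normalized traces (length
#'   \code{nLines}) of preliminary success trials.
#' @param stimLine,lineRate acquisition layout.
#' @param kLargest number of largest responses entering the average
#'   (default 5; automates the manual selection of large responses).
#' @param postEnd last line entering the decay fit (defaults to the
#'   trial end; paired-pulse sessions stop before the second pulse).
#' @return Template list: \code{tau} (ms), kernel samples \code{k}, and
#'   the fit-window layout.
#' @export
buildTemplate <- function(successTraces, stimLine, lineRate = 500,
                          kLargest = 5, postEnd = NULL) {
  if (length(successTraces) < 1)
    stop("no-template: no success trials available", call. = FALSE)
  nLines <- length(successTraces[[1]])
  if (is.null(postEnd)) postEnd <- nLines
  pre <- seq_len(stimLine - 1L)
  # rank candidates by their window-mean response, not the single-line
  # peak: selecting on the peak picks trials with upward noise at the
  # first post-stimulus lines and biases the fitted decay fast
  peaks <- vapply(successTraces, function(y)
    mean(y[stimLine:postEnd]) - mean(y[pre]), 1.0)
  sel <- order(peaks, decreasing = TRUE)[seq_len(min(kLargest,
                                                     length(peaks)))]
  avg <- Reduce(`+`, successTraces[sel]) / length(sel)
  avg <- avg - mean(avg[pre])
  post <- stimLine:postEnd
  tt <- (post - stimLine) * 1000 / lineRate
  df <- data.frame(t = tt, y = avg[post])
  fit <- try(minpack.lm::nlsLM(y ~ a * exp(-t / tau), data = df,
                               start = list(a = max(df$y), tau = 40),
                               lower = c(a = 1e-9, tau = 1e-3)),
             silent = TRUE)
  tau <- if (inherits(fit, "try-error")) {
    warning("template decay fit failed; using crude log-linear estimate")
    yy <- pmax(df$y, max(df$y) * 1e-3)
    -1 / coef(lm(log(yy) ~ df$t))[2]
  } else unname(coef(fit)["tau"])
  .makeTemplate(tau, nLines, stimLine, lineRate)
}

#' Fit the response amplitude of one trial
#'
#' Least-squares scale of the template kernel against the ROI-averaged,
#' baseline-subtracted \eqn{\Delta F/F_0} trace over the post-stimulus
#' window; the amplitude is the single free parameter and may be
#' negative for noise.
#'
#' @param mat normalized trial matrix (resting level 1).
#' @param roi integer vector of ROI column indices.
#' @param template template from \code{\link{buildTemplate}} (or
#'   \code{\link{defaultTemplate}}).
#' @return Amplitude in \eqn{\Delta F/F_0}.
#' @export
fitAmplitude <- function(mat, roi, template) {
  tr <- rowMeans(mat[, roi, drop = FALSE])
  .fitAmplitudeTrace(tr - 1, template)
}

#' Template from a configured decay constant
#'
#' Used when a session contains no successes to build a template from
#' (the no-template condition): amplitude fitting then uses this
#' configured decay constant.
#'
#' @param tau decay constant (ms).
#' @param nLines,stimLine,lineRate acquisition layout.
#' @return Template list as from \code{\link{buildTemplate}}.
#' @export
defaultTemplate <- function(tau, nLines, stimLine, lineRate = 500)
  .makeTemplate(tau, nLines, stimLine, lineRate)

#' Estimate the baseline noise model
#'
#' Applies the single-parameter template fit to non-stimulated
#' (pre-stimulus) windows, yielding null amplitudes whose SD is
#' \eqn{\sigma_0} and whose distribution FWHM (estimated from a kernel
#' density) characterizes baseline fluctuations. The null fit window has
#' the same layout as the post-stimulus fit, so null amplitudes are
#' distributed exactly like failure amplitudes.
#'
#' @param mats list of normalized trial matrices.
#' @param roi ROI column indices.
#' @param template template list.
#' @return A \linkS4class{NoiseModel}.
#' @export
estimateBaselineNoise <- function(mats, roi, template) {
  if (length(mats) < 20)
    stop("insufficient data: need >= 20 trials for the noise model",
         call. = FALSE)
  null <- vapply(mats, function(m)
    .fitAmplitudeTrace(rowMeans(m[, roi, drop = FALSE]) - 1, template,
                       null = TRUE), 1.0)
  s <- sd(null)
  new("NoiseModel", sigma0 = s, fwhm = .empiricalFwhm(null),
      n = length(null), scalingExponent = 0.5)
}

#' Bouton-level quality control
#'
#' A bouton fails QC when the FWHM of its baseline (non-stimulated)
#' amplitude distribution exceeds 0.4 \eqn{\Delta F/F_0}: imaging
#' conditions are then considered non-optimal and the bouton is excluded
#' from quantal analysis. The inequality is strict, FWHM = 0.4 passes.
#'
#' @param noise a \linkS4class{NoiseModel}.
#' @param maxFwhm rejection threshold (default 0.4 \eqn{\Delta F/F_0}).
#' @return TRUE (pass) or FALSE (reject).
#' @export
qcBouton <- function(noise, maxFwhm = 0.4) {
  stopifnot(is(noise, "NoiseModel"))
  !(noise@fwhm > maxFwhm)
}

#' Classify trials as successes or failures
#'
#' A trial is a success when its fitted amplitude exceeds twice the
#' baseline noise SD.
#'
#' @param amplitude fitted amplitude(s).
#' @param noise a \linkS4class{NoiseModel}.
#' @param threshold multiplier of \eqn{\sigma_0} (default 2).
#' @return Character vector, \code{"success"}/\code{"failure"}.
#' @export
classifyTrial <- function(amplitude, noise, threshold = 2) {
  stopifnot(is(noise, "NoiseModel"))
  ifelse(amplitude > threshold * noise@sigma0, "success", "failure")
}

#' Release probability and paired-pulse ratio of an amplitude set
#'
#' \eqn{p_{syn}} is the number of successes divided by the number of
#' non-rejected trials. In paired mode the paired-pulse ratio is the mean
#' second-pulse amplitude over the mean first-pulse amplitude, in
#' percent, over non-rejected trials.
#'
#' @param ampSet an \linkS4class{AmplitudeSet} (or its table).
#' @param paired logical, also compute PPR (needs an
#'   \code{amplitude2} column).
#' @return Named list: \code{psyn} per condition (+ \code{ppr} when
#'   paired).
#' @export
computePsynPpr <- function(ampSet, paired = FALSE) {
  tab <- if (is(ampSet, "AmplitudeSet")) ampSet@table else ampSet
  ok <- tab$label != "rejected"
  if (!any(ok)) stop("no usable trials", call. = FALSE)
  psyn <- vapply(split(tab$label[ok], tab$condition[ok]),
                 function(l) mean(l == "success"), 1.0)
  out <- list(psyn = psyn)
  if (paired) {
    if (is.null(tab$amplitude2))
      stop("paired = TRUE needs an amplitude2 column", call. = FALSE)
    out$ppr <- vapply(split(tab[ok, ], tab$condition[ok]), function(d)
      100 * mean(d$amplitude2) / mean(d$amplitude), 1.0)
  }
  out
}

#' Detect desynchronized release events in the post-stimulus window
#'
#' Greedy matched-filter search: the template is fit at every candidate
#' onset line; the largest amplitude above the detection threshold is
#' accepted, its fitted transient subtracted, and the search repeated.
#' Used to extract delayed single-vesicle fusion events from
#' strontium-wash-in trials.
#'
#' @param mat normalized trial matrix.
#' @param roi ROI column indices.
#' @param template template list.
#' @param noise \linkS4class{NoiseModel} for the detection threshold.
#' @param searchLines candidate onset lines (default: the stimulation
#'   line and every later line; the stimulation onset is always
#'   searched so that a decaying evoked response is fitted and
#'   subtracted before delayed events are scored, but detections at the
#'   stimulation line are not reported as delayed events).
#' @param threshold detection threshold in units of \eqn{\sigma_0}
#'   (default 3; conservative because many onsets are tested).
#' @param maxEvents safety cap.
#' @return data.frame(line, amplitude) of post-stimulus events,
#'   possibly empty; the fitted evoked amplitude (0 when none was
#'   detected) is attached as attribute \code{"evoked"}.
#' @export
detectDelayedEvents <- function(mat, roi, template, noise,
                                searchLines = NULL, threshold = 3,
                                maxEvents = 10) {
  tr <- rowMeans(mat[, roi, drop = FALSE]) - 1
  nL <- length(tr)
  if (is.null(searchLines))
    searchLines <- template$stimLine:(nL - 5L)
  dt <- 1000 / template$lineRate
  base <- mean(tr[template$nullBase])
  y <- tr - base
  kfull <- function(o) {          # kernel from onset o to the last line
    k <- numeric(nL)
    k[o:nL] <- exp(-((o:nL) - o) * dt / template$tau)
    k
  }
  fitAt <- function(yy, o) {      # LS amplitude and its relative SD
    L <- min(length(template$k), nL - o + 1L)
    k <- template$k[seq_len(L)]
    c(sum(k * yy[o:(o + L - 1L)]) / sum(k^2), 1 / sqrt(sum(k^2)))
  }
  onsets <- integer()
  res <- y
  for (it in seq_len(maxEvents)) {
    # onset selection on the noise-normalized score, so truncated late
    # windows are not preferred for their larger amplitude noise
    za <- vapply(searchLines, function(o) {
      f <- fitAt(res, o)
      c(f[1], f[1] / f[2])
    }, numeric(2))
    j <- which.max(za[2, ])
    sigRel <- za[1, j] / za[2, j]
    if (za[1, j] <= threshold * noise@sigma0 * sigRel /
        (1 / sqrt(sum(template$k^2)))) break
    onsets <- c(onsets, searchLines[j])
    res <- res - za[1, j] * kfull(searchLines[j])
  }
  if (!length(onsets)) {
    out <- data.frame(line = integer(), amplitude = numeric())
    attr(out, "evoked") <- 0
    return(out)
  }
  # joint least-squares refit of all amplitudes at the fixed onsets
  X <- vapply(onsets, kfull, numeric(nL))
  use <- template$stimLine:nL
  a <- tryCatch(as.numeric(solve(crossprod(X[use, , drop = FALSE]),
                                 crossprod(X[use, , drop = FALSE],
                                           y[use]))),
                error = function(e) za <- NULL)
  if (is.null(a)) a <- rep(NA_real_, length(onsets))
  out <- data.frame(line = onsets, amplitude = a)
  evoked <- sum(out$amplitude[out$line == template$stimLine])
  out <- out[out$line > template$stimLine, , drop = FALSE]
  out <- out[order(out$line), , drop = FALSE]
  attr(out, "evoked") <- evoked
  out
}

## ---- full pipeline -------------------------------------------------------

# preliminary z-statistic labels on whole-matrix averages
.prelimLabels <- function(mats, stimLine, kernelTau, lineRate) {
  lay <- .fitLayout(nrow(mats[[1]]), stimLine, kernelTau, lineRate)
  pre <- seq_len(stimLine - 1L)
  vapply(mats, function(m) {
    tr <- rowMeans(m)
    dbar <- mean(tr[lay$sigWin]) - mean(tr[pre])
    se <- sd(tr[pre]) * sqrt(1 / length(lay$sigWin) + 1 / length(pre))
    if (se > 0 && dbar > 2 * se) "success" else "failure"
  }, "x")
}

# two-kernel joint least squares for paired-pulse trials
.fitPairedTrace <- function(trace, tpl, ipi) {
  nL <- tpl$nLines
  dt <- 1000 / tpl$lineRate
  mkk <- function(onset) {
    k <- numeric(nL)
    k[onset:nL] <- exp(-((onset:nL) - onset) * dt / tpl$tau)
    k
  }
  k1 <- mkk(tpl$stimLine)
  k2 <- mkk(tpl$stimLine + ipi)
  use <- tpl$stimLine:nL
  y <- trace[use] - mean(trace[tpl$sigBase])
  X <- cbind(k1[use], k2[use])
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

#' Run the full trace-analysis pipeline on a session
#'
#' Orchestrates the complete analysis for every condition of a session:
#' trial-\eqn{F_0} QC (artifact removal), preliminary 2-sigma
#' classification on whole-matrix averages, bleach correction from
#' failure-trial baselines, dynamic ROI selection with carry-over from
#' the last success, template construction from the largest preliminary
#' successes (pooled across conditions), single-parameter amplitude
#' fitting, baseline noise estimation and final 2-sigma classification.
#' Final fits use the session-consensus ROI (columns selected in at
#' least half of the success-trial ROIs): choosing the ROI per trial on
#' the same noise the fit sees would bias small amplitudes upward,
#' while the bouton's release site -- and hence the informative column
#' block -- is stable across trials.
#'
#' @param session a \linkS4class{GluSession} (or a named list of lists
#'   of raw trial matrices).
#' @param kLargest number of large successes entering the template.
#' @param defaultTau decay constant (ms) used when no successes exist.
#' @param bleachCorrect logical; when FALSE, trials are normalized by
#'   the session-mean \eqn{F_0} instead of the fitted bleach trend
#'   (ablation switch; late-trial amplitudes then inherit the bleach
#'   bias).
#' @param failureRule ROI routing rule, see
#'   \code{\link{selectDynamicRoi}}.
#' @return An \linkS4class{AmplitudeSet}; when the input is a
#'   \linkS4class{GluSession} with a ledger, the table carries a
#'   \code{trueK} column.
#' @examples
#' ses <- synthesizeSession(gluGroundTruth(),
#'   acquisitionParams(nTrials = 60, artifactRate = 0), seed = 2)
#' amps <- processSession(ses)
#' pSyn(amps)
#' @export
processSession <- function(session, kLargest = 5, defaultTau = 40,
                           bleachCorrect = TRUE,
                           failureRule = c("2sigma", "5pct")) {
  failureRule <- match.arg(failureRule)
  if (is(session, "GluSession")) {
    allMats <- session@trials
    acq <- session@acq
    ledger <- session@ledger
  } else {
    allMats <- session
    acq <- NULL
    ledger <- NULL
  }
  conditions <- names(allMats)
  nLines <- nrow(allMats[[1]][[1]])
  stimLine <- if (!is.null(acq)) acq@stimLine else as.integer(0.68 * nLines)
  lineRate <- if (!is.null(acq)) acq@lineRate else 500
  ipi <- if (!is.null(acq) && acq@pairedPulse) acq@interPulseLines else NA

  perCond <- list()
  offset <- 0L
  for (cc in conditions) {
    mats <- allMats[[cc]]
    n <- length(mats)
    gidx <- offset + seq_len(n)
    offset <- offset + n
    if (n == 0) {
      perCond[[cc]] <- list(empty = TRUE)
      next
    }
    keep <- qcF0(mats, stimLine)
    prelim <- rep("rejected", n)
    prelim[keep] <- .prelimLabels(mats[keep], stimLine, defaultTau,
                                  lineRate)
    if (bleachCorrect && sum(prelim == "failure") >= 5) {
      bc <- correctBleach(mats[keep], prelim[keep],
                          stimLine, trialIndex = gidx[keep])
      norm <- bc$mats
      bleachTau <- bc$bleachTau
    } else {
      f0 <- .trialF0(mats[keep], stimLine)
      norm <- lapply(mats[keep], function(m) m / mean(f0))
      bleachTau <- NA_real_
    }
    perCond[[cc]] <- list(empty = FALSE, keep = keep, prelim = prelim,
                          norm = norm, bleachTau = bleachTau, gidx = gidx)
  }

  # ROI per kept trial (carried across trials within a condition)
  roiCommon <- NULL
  for (cc in conditions) {
    pc <- perCond[[cc]]
    if (isTRUE(pc$empty)) next
    lastRoi <- NULL
    rois <- vector("list", length(pc$norm))
    for (i in seq_along(pc$norm)) {
      sel <- selectDynamicRoi(pc$norm[[i]], stimLine, lastRoi,
                              kernelTau = defaultTau, lineRate = lineRate,
                              failureRule = failureRule)
      rois[[i]] <- sel$positions
      if (sel$provenance == "current-trial") lastRoi <- sel$positions
    }
    perCond[[cc]]$rois <- rois
    perCond[[cc]]$lastRoi <- lastRoi
  }
  # session-consensus ROI: columns selected in at least half of the
  # current-trial (success) ROIs. Per-trial ROIs are kept for routing
  # and QC, but the final single-parameter fits use the consensus: a
  # per-trial ROI is chosen on the same noise realization the fit
  # sees, which would bias small response amplitudes upward.
  votes <- integer(ncol(allMats[[1]][[1]]))
  nVoters <- 0L
  for (cc in conditions) {
    pc <- perCond[[cc]]
    if (isTRUE(pc$empty) || is.null(pc$lastRoi)) next
    for (i in seq_along(pc$rois)) {
      if (pc$prelim[pc$keep][i] == "success") {
        votes[pc$rois[[i]]] <- votes[pc$rois[[i]]] + 1L
        nVoters <- nVoters + 1L
      }
    }
  }
  roiCommon <- if (nVoters > 0) which(votes >= nVoters / 2) else NULL
  if (!length(roiCommon))
    roiCommon <- seq_len(ncol(allMats[[1]][[1]])) # no success anywhere

  # template from the largest preliminary successes, pooled
  candTraces <- list()
  for (cc in conditions) {
    pc <- perCond[[cc]]
    if (isTRUE(pc$empty)) next
    isSucc <- pc$prelim[pc$keep] == "success"
    for (i in which(isSucc))
      candTraces[[length(candTraces) + 1L]] <-
        rowMeans(pc$norm[[i]][, pc$rois[[i]], drop = FALSE])
  }
  template <- if (length(candTraces) >= 1) {
    buildTemplate(candTraces, stimLine, lineRate, kLargest,
                  postEnd = if (!is.na(ipi)) stimLine + ipi - 1L else NULL)
  } else {
    warning("no-template: session has no successes; using defaultTau")
    defaultTemplate(defaultTau, nLines, stimLine, lineRate)
  }

  fitPass <- function(template) {
    rows <- list(); noiseL <- list()
    psyn <- c(); pprv <- c(); btau <- c()
    succTraces <- list()
    for (cc in conditions) {
      pc <- perCond[[cc]]
      if (isTRUE(pc$empty)) {
        psyn[cc] <- NA_real_
        next
      }
      nKept <- length(pc$norm)
      amp <- numeric(nKept); amp2 <- rep(NA_real_, nKept)
      traces <- vector("list", nKept)
      for (i in seq_len(nKept)) {
        tr <- rowMeans(pc$norm[[i]][, roiCommon, drop = FALSE]) - 1
        traces[[i]] <- tr + 1
        if (!is.na(ipi)) {
          ab <- .fitPairedTrace(tr, template, ipi)
          amp[i] <- ab[1]; amp2[i] <- ab[2]
        } else {
          amp[i] <- .fitAmplitudeTrace(tr, template)
        }
      }
      nm <- if (nKept >= 20)
        estimateBaselineNoise(pc$norm, roiCommon, template)
      else new("NoiseModel", sigma0 = NA_real_, fwhm = NA_real_,
               n = as.integer(nKept))
      lab <- rep("rejected", length(pc$keep))
      if (!is.na(nm@sigma0))
        lab[pc$keep] <- classifyTrial(amp, nm)
      else
        lab[pc$keep] <- ifelse(amp > 0, "success", "failure")
      succTraces <- c(succTraces, traces[lab[pc$keep] == "success"])
      ampFull <- rep(NA_real_, length(pc$keep))
      ampFull[pc$keep] <- amp
      amp2Full <- rep(NA_real_, length(pc$keep))
      amp2Full[pc$keep] <- amp2
      rows[[cc]] <- data.frame(condition = cc,
                               trial = pc$gidx,
                               amplitude = ampFull,
                               amplitude2 = amp2Full,
                               label = lab,
                               reason = ifelse(lab == "rejected",
                                               "elevated F0", ""))
      noiseL[[cc]] <- nm
      psyn[cc] <- mean(lab[pc$keep] == "success")
      btau[cc] <- pc$bleachTau
      if (!is.na(ipi))
        pprv[cc] <- 100 * mean(amp2, na.rm = TRUE) /
          mean(amp, na.rm = TRUE)
      else pprv[cc] <- NA_real_
    }
    list(rows = rows, noiseL = noiseL, psyn = psyn, pprv = pprv,
         btau = btau, succTraces = succTraces)
  }

  pass1 <- fitPass(template)
  # refinement: re-fit the decay constant on all successes (the
  # few-trial template is the dominant noise source of the amplitude
  # scale) and re-extract the amplitudes with the refined kernel
  if (length(pass1$succTraces) >= 3) {
    template <- buildTemplate(pass1$succTraces, stimLine, lineRate,
                              kLargest = length(pass1$succTraces),
                              postEnd = if (!is.na(ipi))
                                stimLine + ipi - 1L else NULL)
    pass1 <- fitPass(template)
  }
  rows <- pass1$rows; noiseL <- pass1$noiseL
  psyn <- pass1$psyn; pprv <- pass1$pprv; btau <- pass1$btau
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (!is.null(ledger) && nrow(tab)) {
    m <- match(paste(tab$condition, tab$trial),
               paste(ledger$condition, ledger$trial))
    tab$trueK <- ledger$k[m]
  }
  new("AmplitudeSet", table = tab, noise = noiseL,
      templateTau = template$tau, bleachTau = btau,
      roi = as.integer(roiCommon), psyn = psyn, ppr = pprv)
}
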