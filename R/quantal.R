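## MODULE quantal -- binomial release-model fitting on amplitude
## histograms: saturation-spaced, shot-noise-broadened Gaussian mixtures,
## exhaustive grid search jointly over two calcium conditions, the
## parsimony rule, and the three independent quantal-size estimators.

#' Parameter grid for the exhaustive quantal search
#'
#' The default grid explores \eqn{N} from 1 to 15, \eqn{p_{ves}} from
#' 0.01 to 0.99 in 0.01 steps and \eqn{q} from 0.5 to 2.0
#' \eqn{\Delta F/F_0} in 0.01 steps. The \code{"paper"} preset uses the
#' literal published grid whose \eqn{p_{ves}} floor is 0.1; the default
#' floor is relaxed to 0.01 because fitted release probabilities below
#' 0.1 are routinely reported for the low-calcium condition.
#'
#' @param nRange integer range of vesicle numbers.
#' @param pRange,pStep release-probability range and step.
#' @param qRange,qStep quantal-amplitude range and step
#'   (\eqn{\Delta F/F_0}).
#' @param preset \code{"default"} or \code{"paper"}.
#' @return List with vectors \code{n}, \code{p}, \code{q}.
#' @export
quantalGrid <- function(nRange = c(1, 15), pRange = c(0.01, 0.99),
                        pStep = 0.01, qRange = c(0.5, 2.0), qStep = 0.01,
                        preset = c("default", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") pRange <- c(0.1, 0.99)
  stopifnot(pStep > 0, qStep > 0, nRange[1] >= 1,
            nRange[2] >= nRange[1], qRange[2] >= qRange[1],
            pRange[2] >= pRange[1])
  list(n = seq.int(nRange[1], nRange[2]),
       p = seq(pRange[1], pRange[2], by = pStep),
       q = seq(qRange[1], qRange[2], by = qStep))
}

#' Quantal peak positions under sensor saturation
#'
#' Expected quantal peaks are not integer multiples of \eqn{q} but
#' compressed by the hyperbolic saturation curve:
#' \eqn{\mu_k = B_{max} k / (K_d + k)} with \eqn{K_d = B_{max}/q - 1},
#' so \eqn{\mu_0 = 0} and \eqn{\mu_1 = q}. In the limit
#' \eqn{B_{max} \to \infty} the spacing becomes linear
#' (\eqn{\mu_k \to k q}).
#'
#' @param N number of vesicles (peaks for \eqn{k = 0..N}).
#' @param q quantal amplitude.
#' @param bMax saturation asymptote (scalar or
#'   \linkS4class{SaturationCurve}, in which case its \code{kD} --
#'   expressed in vesicles -- is used directly and \code{q} is the
#'   resulting \eqn{\mu_1}).
#' @return Numeric vector of \eqn{N + 1} strictly increasing means.
#' @examples
#' peakPositions(2, q = 0.88, bMax = 6)  # 0, 0.88, 1.648
#' @export
peakPositions <- function(N, q, bMax) {
  if (is(bMax, "SaturationCurve")) {
    sc <- bMax
    return(sc@bMax * (0:N) / (sc@kD + (0:N)))
  }
  amplitudeFromVesicles(0:N, q, bMax)
}

#' Shot-noise-broadened peak widths
#'
#' Photon shot noise grows with the square root of the detected photon
#' count, i.e. with total fluorescence \eqn{1 + \Delta F/F_0}.
#' Propagated in quadrature onto the baseline width this gives
#' \deqn{\sigma_k = \sigma_0 \sqrt{1 + \mu_k},}
#' so the failure peak keeps the baseline width and higher quantal peaks
#' broaden monotonically.
#'
#' @param noise a \linkS4class{NoiseModel} (or a bare \eqn{\sigma_0}).
#' @param means peak positions from \code{\link{peakPositions}}.
#' @param exponent scaling-law exponent (0.5 = shot noise).
#' @return Vector of component SDs, \eqn{\sigma_0} first.
#' @export
peakWidths <- function(noise, means, exponent = 0.5) {
  s0 <- if (is(noise, "NoiseModel")) noise@sigma0 else as.numeric(noise)
  if (is.na(s0) || s0 <= 0) stop("sigma0 must be > 0", call. = FALSE)
  .sigmaAtAmplitude(s0, means, exponent)
}

#' Predicted amplitude density of a binomial release model
#'
#' The mixture has one Gaussian component per outcome \eqn{k = 0..N}
#' with binomial weight \eqn{\binom{N}{k} p^k (1-p)^{N-k}}, mean
#' \eqn{\mu_k} from the saturation curve and SD \eqn{\sigma_k} from the
#' shot-noise law. The density integrates to 1 before count scaling.
#'
#' @param N,pVes,q model parameters.
#' @param noise \linkS4class{NoiseModel} or \eqn{\sigma_0}.
#' @param bMax saturation asymptote.
#' @param axis optional amplitude axis on which to evaluate the density.
#' @return List: \code{weights}, \code{means}, \code{sds}, and
#'   (when \code{axis} is given) \code{axis}, \code{density}.
#' @examples
#' mm <- predictAmplitudeDensity(5, 0.42, 0.88, noise = 0.1, bMax = 6)
#' mm$weights[1]    # 0.58^5
#' @export
predictAmplitudeDensity <- function(N, pVes, q, noise, bMax = 6,
                                    axis = NULL) {
  w <- dbinom(0:N, N, pVes)
  mu <- peakPositions(N, q, bMax)
  sdk <- peakWidths(noise, mu)
  out <- list(weights = w, means = mu, sds = sdk)
  if (!is.null(axis)) {
    dens <- numeric(length(axis))
    for (k in 0:N)
      dens <- dens + w[k + 1] * stats::dnorm(axis, mu[k + 1], sdk[k + 1])
    out$axis <- axis
    out$density <- dens
  }
  out
}

# cumulative distribution of a mixture at x
.mixtureCdf <- function(mm, x) {
  out <- numeric(length(x))
  for (k in seq_along(mm$weights))
    out <- out + mm$weights[k] * pnorm(x, mm$means[k], mm$sds[k])
  out
}

#' Histogram of amplitudes for quantal fitting
#'
#' Default bin width 0.1 \eqn{\Delta F/F_0}, spanning
#' \eqn{[\min a - 3\sigma_0, \max a + 3\sigma_0]}.
#'
#' @param amplitudes numeric vector.
#' @param sigma0 baseline noise SD (pads the range).
#' @param binWidth bin width (\eqn{\Delta F/F_0}).
#' @return List: \code{counts}, \code{edges}, \code{mids}, \code{n}.
#' @export
amplitudeHistogram <- function(amplitudes, sigma0, binWidth = 0.1) {
  lo <- min(amplitudes) - 3 * sigma0
  hi <- max(amplitudes) + 3 * sigma0
  edges <- seq(floor(lo / binWidth) * binWidth,
               ceiling(hi / binWidth) * binWidth + binWidth, by = binWidth)
  counts <- as.numeric(table(cut(amplitudes, edges,
                                 include.lowest = TRUE)))
  list(counts = counts, edges = edges,
       mids = (head(edges, -1) + tail(edges, -1)) / 2,
       n = length(amplitudes))
}

#' Root-mean-square error of a predicted density against a histogram
#'
#' The mixture density is integrated over the histogram bins, scaled to
#' the total observation count, and compared bin-wise:
#' \eqn{RMS = \sqrt{\mathrm{mean}((pred - obs)^2)}}.
#'
#' @param mm mixture from \code{\link{predictAmplitudeDensity}}.
#' @param counts observed bin counts.
#' @param edges bin edges (length \code{length(counts) + 1}).
#' @return RMS error (in counts).
#' @export
scoreFit <- function(mm, counts, edges) {
  if (length(edges) != length(counts) + 1L)
    stop("binning error: edges must bracket the counts", call. = FALSE)
  cdf <- .mixtureCdf(mm, edges)
  pred <- diff(cdf) * sum(counts)
  sqrt(mean((pred - counts)^2))
}

# all component bin masses for one (N, q): matrix bins x (N+1)
.binMassMatrix <- function(N, q, bMax, sigma0, edges) {
  mu <- peakPositions(N, q, bMax)
  sdk <- .sigmaAtAmplitude(sigma0, mu)
  nb <- length(edges) - 1L
  G <- matrix(0, nb, N + 1L)
  for (k in 0:N)
    G[, k + 1L] <- diff(pnorm(edges, mu[k + 1L], sdk[k + 1L]))
  G
}

#' Joint exhaustive grid search for the quantal parameters
#'
#' Evaluates every (\eqn{N}, \eqn{q}) cell of the grid; for each cell
#' the best \eqn{p_{ves}} is found independently for each condition
#' (only \eqn{p_{ves}} may differ between conditions; \eqn{N} and
#' \eqn{q} are shared), and the combined error is the sum of the
#' per-condition RMS errors. Because increasing \eqn{N} carries no cost
#' in the model, near-identical fits arise for different \eqn{N}; the
#' returned fit is the most parsimonious one: the smallest \eqn{N}
#' whose best combined error is within the parsimony window (2\%) of
#' the global minimum. Ties at equal \eqn{N} are broken by smaller
#' combined error, then smaller \eqn{q}.
#'
#' @param ampSet an \linkS4class{AmplitudeSet} covering two (or more)
#'   conditions, or a named list of numeric amplitude vectors.
#' @param noise named list of \linkS4class{NoiseModel} (required when
#'   \code{ampSet} is a plain list; otherwise taken from the set).
#'   Baseline noise is estimated per condition.
#' @param conditions conditions to fit (default: all).
#' @param grid a \code{\link{quantalGrid}}.
#' @param bMax saturation asymptote used for peak spacing (default 6
#'   \eqn{\Delta F/F_0}; 4.4 and 7.0 are the documented alternatives).
#' @param binWidth histogram bin width.
#' @param parsimony parsimony window (default 0.02 on the RMS scale).
#' @return A \linkS4class{QuantalFit}.
#' @export
fitQuantalModel <- function(ampSet, noise = NULL, conditions = NULL,
                            grid = quantalGrid(), bMax = 6,
                            binWidth = 0.1, parsimony = 0.02) {
  if (is(ampSet, "AmplitudeSet")) {
    tab <- ampSet@table
    ok <- tab$label != "rejected"
    amps <- split(tab$amplitude[ok], tab$condition[ok])
    if (is.null(noise)) noise <- ampSet@noise
  } else amps <- ampSet
  if (is.null(conditions)) conditions <- names(amps)
  amps <- amps[conditions]
  if (any(!vapply(amps, length, 1L)))
    stop("insufficient data: empty amplitude set", call. = FALSE)
  s0 <- vapply(conditions, function(cc) {
    nm <- noise[[cc]]
    if (is(nm, "NoiseModel")) nm@sigma0 else as.numeric(nm)
  }, 1.0)
  if (any(is.na(s0) | s0 <= 0))
    stop("need a positive sigma0 per condition", call. = FALSE)

  hists <- lapply(conditions, function(cc)
    amplitudeHistogram(amps[[cc]], s0[[cc]], binWidth))
  names(hists) <- conditions

  nN <- length(grid$n); nQ <- length(grid$q); nP <- length(grid$p)
  bestErr <- matrix(Inf, nN, nQ)       # combined error per (N, q)
  bestP <- array(NA_real_, c(nN, nQ, length(conditions)))
  condErr <- array(NA_real_, c(nN, nQ, length(conditions)))
  for (iN in seq_len(nN)) {
    N <- grid$n[iN]
    W <- vapply(grid$p, function(p) dbinom(0:N, N, p),
                numeric(N + 1L))      # (N+1) x nP
    for (iQ in seq_len(nQ)) {
      q <- grid$q[iQ]
      if (q >= bMax) next
      tot <- 0
      for (ic in seq_along(conditions)) {
        h <- hists[[ic]]
        G <- .binMassMatrix(N, q, bMax, s0[[ic]], h$edges)
        pred <- (G %*% W) * h$n       # bins x nP
        errs <- sqrt(colMeans((pred - h$counts)^2))
        j <- which.min(errs)
        bestP[iN, iQ, ic] <- grid$p[j]
        condErr[iN, iQ, ic] <- errs[j]
        tot <- tot + errs[j]
      }
      bestErr[iN, iQ] <- tot
    }
  }
  globalMin <- min(bestErr)
  # per-N best (q) with tie-break on smaller q (which.min takes first)
  perN <- apply(bestErr, 1, min)
  selN <- which(perN <= (1 + parsimony) * globalMin)[1]
  iQ <- which.min(bestErr[selN, ])
  pv <- setNames(bestP[selN, iQ, ], conditions)
  ce <- setNames(condErr[selN, iQ, ], conditions)
  N <- grid$n[selN]; q <- grid$q[iQ]
  new("QuantalFit", nDocked = as.integer(N), pVes = pv, q = q,
      bMax = as.numeric(bMax), rmsError = ce,
      combinedError = bestErr[selN, iQ], globalMin = globalMin,
      parsimonyMargin = bestErr[selN, iQ] / globalMin - 1,
      errorSurface = data.frame(n = grid$n, bestCombined = perN,
                                bestQ = grid$q[apply(bestErr, 1,
                                                     which.min)]),
      strength = pv * N * q)
}

#' Quantal size from successes under low release probability
#'
#' At boutons with \eqn{p_{syn} < 0.5} most successes are
#' single-vesicle events, so the median success amplitude estimates
#' \eqn{q} directly (per-bouton medians first, then the median across
#' qualifying boutons). The estimate is biased upward as
#' \eqn{p_{ves} \to 1} by multivesicular contamination.
#'
#' @param ampSets list of \linkS4class{AmplitudeSet} (or a single one).
#' @param maxPsyn qualification threshold (default 0.5).
#' @return Estimate of \eqn{q} with per-bouton values as an attribute.
#' @export
estimateQLowP <- function(ampSets, maxPsyn = 0.5) {
  if (is(ampSets, "AmplitudeSet")) ampSets <- list(ampSets)
  per <- c()
  for (as1 in ampSets) {
    for (cc in names(as1@psyn)) {
      if (!is.na(as1@psyn[[cc]]) && as1@psyn[[cc]] < maxPsyn) {
        tab <- as1@table
        a <- tab$amplitude[tab$condition == cc & tab$label == "success"]
        if (length(a)) per <- c(per, median(a))
      }
    }
  }
  if (!length(per))
    stop("not applicable: no boutons with p_syn < ", maxPsyn,
         call. = FALSE)
  out <- median(per)
  attr(out, "perBouton") <- per
  out
}

#' Quantal size from desynchronized release events
#'
#' Median (and mean) amplitude of delayed single-vesicle fusion events
#' detected during strontium wash-in; requires at least 10 events. The
#' median is the primary estimate because occasional coincident fusion
#' events within one line period are detected as a single event of
#' summed amplitude and would inflate the mean.
#'
#' @param delayedAmplitudes numeric vector of fitted delayed-event
#'   amplitudes (e.g. from \code{\link{detectDelayedEvents}} over the
#'   wash-in phase of a desynchronized session).
#' @return Median amplitude, with the mean and event count attached as
#'   attributes.
#' @export
estimateQDesync <- function(delayedAmplitudes) {
  delayedAmplitudes <- delayedAmplitudes[!is.na(delayedAmplitudes)]
  if (length(delayedAmplitudes) < 10)
    stop("insufficient data: need >= 10 delayed events", call. = FALSE)
  out <- median(delayedAmplitudes)
  attr(out, "mean") <- mean(delayedAmplitudes)
  attr(out, "n") <- length(delayedAmplitudes)
  out
}

# Independent likelihood route over the same grid: exact per-trial
# mixture log-likelihood, used as a brute-force cross-check of the
# histogram-RMS grid search on small samples.
.gridSearchLikelihood <- function(amps, s0, conditions, grid, bMax) {
  nN <- length(grid$n); nQ <- length(grid$q)
  best <- matrix(-Inf, nN, nQ)
  for (iN in seq_len(nN)) {
    N <- grid$n[iN]
    for (iQ in seq_len(nQ)) {
      q <- grid$q[iQ]
      if (q >= bMax) next
      tot <- 0
      for (ic in seq_along(conditions)) {
        mu <- peakPositions(N, q, bMax)
        sdk <- .sigmaAtAmplitude(s0[[ic]], mu)
        a <- amps[[ic]]
        ll <- vapply(grid$p, function(p) {
          w <- dbinom(0:N, N, p)
          dens <- rep(0, length(a))
          for (k in 0:N)
            dens <- dens + w[k + 1] * stats::dnorm(a, mu[k + 1],
                                                   sdk[k + 1])
          sum(log(pmax(dens, 1e-300)))
        }, 1.0)
        tot <- tot + max(ll)
      }
      best[iN, iQ] <- tot
    }
  }
  ij <- arrayInd(which.max(best), dim(best))
  list(n = grid$n[ij[1]], q = grid$q[ij[2]], logLik = max(best))
}

#' Parameter-recovery report over the full pipeline
#'
#' Runs the complete loop -- session synthesis, trace analysis, joint
#' quantal fit -- for a number of replicates and reports the recovery
#' rate of \eqn{N} and bias/RMSE of \eqn{p_{ves}} and \eqn{q}.
#'
#' @param truth \linkS4class{GroundTruth} generating the sessions.
#' @param acq \linkS4class{AcquisitionParams}.
#' @param nReplicates number of replicate boutons.
#' @param seed RNG seed (replicate r uses \code{seed + r}).
#' @param grid,bMax,binWidth fitting configuration (bMax defaults to
#'   the generating truth's asymptote).
#' @param bleachCorrect passed to \code{\link{processSession}}
#'   (ablation switch).
#' @return List: \code{fits} (data.frame of per-replicate estimates)
#'   and \code{summary} (recovery rate of \eqn{N}, bias and RMSE per
#'   parameter).
#' @export
recoveryReport <- function(truth, acq, nReplicates = 20, seed = 1,
                           grid = quantalGrid(), bMax = NULL,
                           binWidth = 0.1, bleachCorrect = TRUE) {
  if (is.null(bMax)) bMax <- truth@bMax
  conds <- names(truth@pVes)
  res <- vector("list", nReplicates)
  for (r in seq_len(nReplicates)) {
    ses <- synthesizeSession(truth, acq, seed = seed + r)
    amps <- processSession(ses, bleachCorrect = bleachCorrect)
    fit <- fitQuantalModel(amps, grid = grid, bMax = bMax,
                           binWidth = binWidth)
    row <- data.frame(replicate = r, n = fit@nDocked, q = fit@q)
    for (cc in conds) row[[paste0("p_", cc)]] <- fit@pVes[[cc]]
    res[[r]] <- row
  }
  fits <- do.call(rbind, res)
  summ <- data.frame(parameter = "N", truth = truth@nDocked,
                     recoveryRate = mean(fits$n == truth@nDocked),
                     bias = mean(fits$n) - truth@nDocked,
                     rmse = sqrt(mean((fits$n - truth@nDocked)^2)))
  summ <- rbind(summ, data.frame(parameter = "q", truth = truth@q,
                                 recoveryRate = NA,
                                 bias = mean(fits$q) - truth@q,
                                 rmse = sqrt(mean((fits$q - truth@q)^2))))
  for (cc in conds) {
    est <- fits[[paste0("p_", cc)]]
    tv <- truth@pVes[[cc]]
    summ <- rbind(summ, data.frame(parameter = paste0("p_", cc),
                                   truth = tv, recoveryRate = NA,
                                   bias = mean(est) - tv,
                                   rmse = sqrt(mean((est - tv)^2))))
  }
  list(fits = fits, summary = summ)
}
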